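category	description
head and packaging	capsid head assembly and DNA packaging proteins
tail	tail structural proteins
connector	head-tail connector proteins
lysis	host cell lysis proteins
nucleotide metabolism	DNA, RNA and nucleotide metabolism proteins
lysogeny	integration and excision proteins
gene expression	transcription regulation proteins
host takeover	host replication inhibition, superinfection exclusion, anti-defense
lysogenic conversion	toxins, antitoxins and resistance proteins
metabolic gene	proteins catalysing specific metabolic transformations
other	generic or unclassifiable annotated proteins
unknown	proteins of unknown function
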