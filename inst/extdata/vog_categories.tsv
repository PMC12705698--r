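category	description
structural	virion structural proteins
packaging	terminases, portal and head packaging proteins
exit	lysis, virion export and budding proteins
integration	integrases, excisionases and transposases
gene expression	transcription and translation regulation proteins
anti-host defense	counter-defense proteins
replication	nucleotide metabolism and genome replication proteins
other	annotated proteins outside the named categories
unknown	proteins of unknown function
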