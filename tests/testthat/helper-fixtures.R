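# Shared fixtures: tiny datasets and models built in code.

tiny_pset <- function(n_genomes = 3L, proteins = c(4L, 6L, 5L), d_in = 8L,
                      seed = 1L, n_scaffolds = 1L) {
  set.seed(seed)
  meta <- list(); emb <- list()
  for (g in seq_len(n_genomes)) {
    n <- proteins[(g - 1L) %% length(proteins) + 1L]
    scaf <- sort(rep(seq_len(n_scaffolds), length.out = n))
    meta[[g]] <- data.frame(
      protein_id = sprintf("g%d_p%d", g, seq_len(n)),
      genome_id = sprintf("g%d", g),
      scaffold_id = sprintf("g%d_s%d", g, scaf),
      position = positional_index(scaf),
      strand = sample(c(1L, -1L), n, replace = TRUE),
      stringsAsFactors = FALSE)
    emb[[g]] <- matrix(rnorm(n * d_in), n, d_in)
  }
  protein_set(do.call(rbind, meta), do.call(rbind, emb))
}

tiny_model <- function(d_in = 8L, seed = 1L, ...) {
  pst_model(model_config(d_in = d_in, pos_dim = 4L, strand_dim = 4L,
                         n_heads = 2L, n_layers = 2L, chunk_size = 5L,
                         seed = seed, ...))
}

# Dense oracle for the genome-scoped graph softmax: explicit matrices.
dense_graph_softmax <- function(scores, edge_list, genome_of_row, scope) {
  q <- edge_list[, 1L]
  out <- numeric(length(scores))
  groups <- if (scope == "genome") genome_of_row[q] else q
  for (g in unique(groups)) {
    sel <- groups == g
    e <- exp(scores[sel])
    out[sel] <- e / sum(e)
  }
  out
}
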