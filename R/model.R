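# Set-transformer genome model: a graph-attention encoder with
# genome-scoped softmax and pre-normalization residual blocks, and an
# attention-pooling decoder with a learnable seed vector.

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize a set-transformer genome model
#'
#' Creates the learnable weights for the configured architecture: positional
#' and strand lookup tables, `n_layers` encoder blocks (query/key/value
#' projections, two per-genome normalizations, a 2-layer GELU feed-forward),
#' a final per-genome normalization, and the decoder (input linear map, seed
#' vector, pooling attention projections, feed-forward blocks and output
#' projection).
#'
#' @param config A [model_config()].
#' @return Object of class `pst_model` with elements `config` and `params`
#'   (a named list of numeric matrices).
#' @export
pst_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  d <- config$d_model
  p <- list()
  p$pos_table <- matrix(stats::rnorm((config$max_pos + 1L) * config$pos_dim,
                                     sd = 0.02),
                        config$max_pos + 1L, config$pos_dim)
  p$strand_table <- matrix(stats::rnorm(2L * config$strand_dim, sd = 0.02),
                           2L, config$strand_dim)
  norm_params <- function(prefix) {
    out <- list(matrix(1, 1L, d), matrix(0, 1L, d), matrix(1, 1L, d))
    names(out) <- paste0(prefix, c("_gamma", "_beta", "_alpha"))
    out
  }
  ff_params <- function(prefix, d_in, d_hidden, d_out) {
    out <- list(glorot(d_in, d_hidden), matrix(0, 1L, d_hidden),
                glorot(d_hidden, d_out), matrix(0, 1L, d_out))
    names(out) <- paste0(prefix, c("_W1", "_b1", "_W2", "_b2"))
    out
  }
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("enc%d", l)
    p[[paste0(pre, "_Wq")]] <- glorot(d, d)
    p[[paste0(pre, "_Wk")]] <- glorot(d, d)
    p[[paste0(pre, "_Wv")]] <- glorot(d, d)
    p <- c(p, norm_params(paste0(pre, "_n1")))
    p <- c(p, norm_params(paste0(pre, "_n2")))
    p <- c(p, ff_params(paste0(pre, "_ff"), d, config$d_ff, d))
  }
  p <- c(p, norm_params("fin_n"))
  p$dec_W <- glorot(d, d)
  p$dec_b <- matrix(0, 1L, d)
  p <- c(p, norm_params("dec_n1"))
  p$dec_Wq <- glorot(d, d)
  p$dec_Wk <- glorot(d, d)
  p$dec_Wv <- glorot(d, d)
  p$dec_S <- matrix(stats::rnorm(d, sd = 1 / sqrt(d)), 1L, d)
  p <- c(p, norm_params("dec_n2"))
  p <- c(p, ff_params("dec_ff", d, config$d_ff, d))
  p <- c(p, ff_params("out_ff", d, config$d_ff, config$d_out))
  structure(list(config = config, params = p), class = "pst_model")
}

#' @export
print.pst_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("pst_model: %d layers, %d heads, d_model = %d, %d parameters\n",
              x$config$n_layers, x$config$n_heads, x$config$d_model, np))
  invisible(x)
}

# ---- numeric graph softmax (module surface; the tape op mirrors it) --------

#' Graph-scoped softmax over attention edges
#'
#' Exponentiates per-edge scores and normalizes them either over each query
#' protein's subgraph neighborhood (`scope = "query_node"`) or over all edges
#' whose query protein belongs to the same genome (`scope = "genome"`).
#' Edges only ever connect proteins of the same subgraph, so exponentials
#' are taken within subgraphs by construction.
#'
#' @param scores Numeric vector of raw attention scores, one per edge.
#' @param edge_list Two-column matrix of (query, key) row indices.
#' @param genome_of_row Integer genome id per protein row.
#' @param scope `"genome"` or `"query_node"`.
#' @return Numeric vector of attention weights; weights sum to one within
#'   each normalization group.
#' @export
graph_softmax <- function(scores, edge_list, genome_of_row,
                          scope = c("genome", "query_node")) {
  scope <- match.arg(scope)
  q <- edge_list[, 1L]
  groups <- if (scope == "genome") genome_of_row[q] else q
  mx <- tapply(scores, groups, max)
  e <- exp(scores - mx[as.character(groups)])
  tot <- tapply(e, groups, sum)
  as.vector(e / tot[as.character(groups)])
}

# ---- tape building blocks ---------------------------------------------------

# Per-genome feature standardization with learnable mean-scale (alpha),
# scale (gamma) and shift (beta); epsilon 1e-5.
tape_graphnorm <- function(X, groups, ngroups, gamma, beta, alpha,
                           eps = 1e-5) {
  mu <- ad_group_mean(X, groups, ngroups)
  xc <- ad_sub(X, ad_mul(ad_gather(mu, groups), alpha))
  v <- ad_group_mean(ad_square(xc), groups, ngroups)
  sd_ <- ad_sqrt(ad_add_scalar(v, eps))
  xn <- ad_div(xc, ad_gather(sd_, groups))
  ad_add_rowvec(ad_mul(xn, gamma), beta)
}

tape_dropout <- function(X, rate, training) {
  if (!training || rate <= 0) return(X)
  v <- ad_value(X)
  mask <- matrix(stats::rbinom(length(v), 1L, 1 - rate) / (1 - rate),
                 nrow(v), ncol(v))
  ad_mul(X, ad_const(X$tp, mask))
}

tape_ff <- function(X, W1, b1, W2, b2, rate, training) {
  h <- tape_dropout(ad_gelu(ad_add_rowvec(ad_matmul(X, W1), b1)),
                    rate, training)
  tape_dropout(ad_add_rowvec(ad_matmul(h, W2), b2), rate, training)
}

head_cols <- function(d, n_heads) {
  dh <- d %/% n_heads
  lapply(seq_len(n_heads), function(h) ((h - 1L) * dh + 1L):(h * dh))
}

# Multi-head graph self-attention (encoder): x_i <- W^Q x_i + sum over the
# subgraph neighborhood (self included) of alpha_ij W^V x_j, with the
# softmax normalized at the configured scope.
tape_encoder_attention <- function(X, batch, Wq, Wk, Wv, config) {
  tp <- X$tp
  n <- nrow(ad_value(X))
  qi <- batch$edge_list[, 1L]
  kj <- batch$edge_list[, 2L]
  groups <- if (config$softmax_scope == "genome") {
    batch$genome_of_row[qi]
  } else {
    qi
  }
  Q <- ad_matmul(X, Wq)
  K <- ad_matmul(X, Wk)
  V <- ad_matmul(X, Wv)
  outs <- vector("list", config$n_heads)
  for (h in seq_along(outs)) {
    cols <- head_cols(config$d_model, config$n_heads)[[h]]
    Qh <- ad_slice_cols(Q, cols)
    Kh <- ad_slice_cols(K, cols)
    Vh <- ad_slice_cols(V, cols)
    scores <- ad_scale(ad_rowsum(ad_mul(ad_gather(Qh, qi),
                                        ad_gather(Kh, kj))),
                       1 / sqrt(config$d_model))
    alpha <- ad_segment_softmax(scores, groups)
    msg <- ad_group_sum(ad_mul(ad_gather(Vh, kj), alpha), qi, n)
    outs[[h]] <- ad_add(Qh, msg)
  }
  ad_cbind(outs)
}

# One pre-normalization encoder block:
# X1 = GraphNorm(X0); X2 = MultiHeadAttn(X1); X3 = X0 + X2;
# X4 = GraphNorm(X3); X5 = FF(X4); X6 = X3 + X5.
tape_encoder_layer <- function(X0, batch, ps, l, config, training) {
  pre <- sprintf("enc%d", l)
  g <- batch$genome_of_row
  ng <- batch$n_genomes
  X1 <- tape_graphnorm(X0, g, ng, ps[[paste0(pre, "_n1_gamma")]],
                       ps[[paste0(pre, "_n1_beta")]],
                       ps[[paste0(pre, "_n1_alpha")]])
  X2 <- tape_dropout(
    tape_encoder_attention(X1, batch, ps[[paste0(pre, "_Wq")]],
                           ps[[paste0(pre, "_Wk")]],
                           ps[[paste0(pre, "_Wv")]], config),
    config$dropout, training)
  X3 <- ad_add(X0, X2)
  X4 <- tape_graphnorm(X3, g, ng, ps[[paste0(pre, "_n2_gamma")]],
                       ps[[paste0(pre, "_n2_beta")]],
                       ps[[paste0(pre, "_n2_alpha")]])
  X5 <- tape_ff(X4, ps[[paste0(pre, "_ff_W1")]], ps[[paste0(pre, "_ff_b1")]],
                ps[[paste0(pre, "_ff_W2")]], ps[[paste0(pre, "_ff_b2")]],
                config$dropout, training)
  ad_add(X3, X5)
}

# Build the stacked input X0 = [embedding | position feature | strand
# feature] on the tape, with an optional override of the raw embedding block
# (used for masking and augmentation).
tape_input <- function(tp, batch, ps, embeddings = NULL) {
  emb <- if (is.null(embeddings)) batch$embeddings else embeddings
  ad_cbind(list(ad_const(tp, emb),
                ad_gather(ps$pos_table, batch$pos_index),
                ad_gather(ps$strand_table, batch$strand_index)))
}

tape_encoder_forward <- function(tp, batch, ps, config, training,
                                 embeddings = NULL) {
  X <- tape_input(tp, batch, ps, embeddings)
  for (l in seq_len(config$n_layers)) {
    X <- tape_encoder_layer(X, batch, ps, l, config, training)
  }
  tape_graphnorm(X, batch$genome_of_row, batch$n_genomes,
                 ps$fin_n_gamma, ps$fin_n_beta, ps$fin_n_alpha)
}

# Decoder: seed-query multi-head attention pooling.
# X0 = GELU(W X^C); X1 = GraphNorm(X0); X2 = Attn(X1, S); X3 = X0 + X2;
# X4 = GraphNorm(X3); X5 = FF(X4); X6 = X3 + X5; X7 = per-genome mean;
# X^G = FF(X7).  Returns the genome embeddings plus per-head and head-mean
# pooling attention (each genome's attention sums to one).
tape_decoder_forward <- function(XC, batch, ps, config, training) {
  g <- batch$genome_of_row
  ng <- batch$n_genomes
  X0 <- ad_gelu(ad_add_rowvec(ad_matmul(XC, ps$dec_W), ps$dec_b))
  X1 <- tape_graphnorm(X0, g, ng, ps$dec_n1_gamma, ps$dec_n1_beta,
                       ps$dec_n1_alpha)
  q <- ad_matmul(ps$dec_S, ps$dec_Wq)    # 1 x d
  K <- ad_matmul(X1, ps$dec_Wk)
  V <- ad_matmul(X1, ps$dec_Wv)
  cols <- head_cols(config$d_model, config$n_heads)
  outs <- vector("list", config$n_heads)
  A_heads <- matrix(0, nrow(ad_value(XC)), config$n_heads)
  for (h in seq_len(config$n_heads)) {
    qh <- ad_slice_cols(q, cols[[h]])
    Kh <- ad_slice_cols(K, cols[[h]])
    Vh <- ad_slice_cols(V, cols[[h]])
    scores <- ad_scale(ad_rowsum(ad_mul(Kh, qh)), 1 / sqrt(config$d_model))
    alpha <- ad_segment_softmax(scores, g)
    A_heads[, h] <- as.vector(ad_value(alpha))
    outs[[h]] <- ad_mul(Vh, alpha)
  }
  X2 <- tape_dropout(ad_cbind(outs), config$dropout, training)
  X3 <- ad_add(X0, X2)
  X4 <- tape_graphnorm(X3, g, ng, ps$dec_n2_gamma, ps$dec_n2_beta,
                       ps$dec_n2_alpha)
  X5 <- tape_ff(X4, ps$dec_ff_W1, ps$dec_ff_b1, ps$dec_ff_W2, ps$dec_ff_b2,
                config$dropout, training)
  X6 <- ad_add(X3, X5)
  X7 <- ad_group_mean(X6, g, ng)
  XG <- tape_ff(X7, ps$out_ff_W1, ps$out_ff_b1, ps$out_ff_W2, ps$out_ff_b2,
                config$dropout, training)
  list(XG = XG, A_heads = A_heads, A = rowMeans(A_heads), X6 = X6, X7 = X7)
}

# Full forward on a fresh tape.  Returns tape refs (for training) plus
# numeric views.  With training = FALSE the pass is deterministic.
pst_tape_forward <- function(model, batch, training = FALSE,
                             embeddings = NULL, tp = NULL, ps = NULL) {
  if (is.null(tp)) {
    tp <- ad_tape()
    ps <- ad_params(tp, model$params)
  }
  XC <- tape_encoder_forward(tp, batch, ps, model$config, training,
                             embeddings)
  dec <- tape_decoder_forward(XC, batch, ps, model$config, training)
  list(tape = tp, params = ps, XC = XC, XG = dec$XG, A = dec$A,
       A_heads = dec$A_heads, X6 = dec$X6, X7 = dec$X7)
}

# ---- user-facing forward wrappers ------------------------------------------

#' Contextualize protein embeddings with the encoder
#'
#' @param model A [pst_model()].
#' @param batch A [build_genome_batch()] result.
#' @return Numeric matrix of contextualized protein embeddings
#'   (rows match the batch).
#' @export
encoder_forward <- function(model, batch) {
  tp <- ad_tape()
  ps <- ad_params(tp, model$params)
  ad_value(tape_encoder_forward(tp, batch, ps, model$config, FALSE))
}

#' One encoder layer applied to an explicit protein matrix
#'
#' Exposes a single pre-normalization attention block for inspection and
#' oracle testing; `X` replaces the assembled input features.
#'
#' @param model A [pst_model()].
#' @param batch A [build_genome_batch()] result.
#' @param X Numeric matrix (`nrow` equal to the batch rows, `ncol` equal to
#'   `d_model`).
#' @param layer Which layer's weights to use.
#' @return Numeric matrix of the same shape as `X`.
#' @export
encoder_layer <- function(model, batch, X, layer = 1L) {
  if (nrow(X) != nrow(batch$embeddings)) stop("X rows must match the batch")
  if (ncol(X) != model$config$d_model) stop("X must have d_model columns")
  tp <- ad_tape()
  ps <- ad_params(tp, model$params)
  ad_value(tape_encoder_layer(ad_const(tp, X), batch, ps, layer,
                              model$config, FALSE))
}

#' Pool contextualized proteins into genome embeddings
#'
#' Runs the attention-pooling decoder.  The per-protein pooling attention of
#' each genome sums to one (per head and for the head mean).
#'
#' @param model A [pst_model()].
#' @param batch A [build_genome_batch()] result.
#' @param XC Optional pre-computed encoder output; defaults to running the
#'   encoder.
#' @param debug Return decoder intermediates (`X6`, `X7`) as well.
#' @return List with `XG` (genome embedding matrix, rows named by genome
#'   id), `A` (head-mean per-protein pooling attention), `A_heads`
#'   (per-head attention matrix) and `genome_of_row`.
#' @export
decoder_forward <- function(model, batch, XC = NULL, debug = FALSE) {
  tp <- ad_tape()
  ps <- ad_params(tp, model$params)
  XCref <- if (is.null(XC)) {
    tape_encoder_forward(tp, batch, ps, model$config, FALSE)
  } else {
    ad_const(tp, XC)
  }
  dec <- tape_decoder_forward(XCref, batch, ps, model$config, FALSE)
  XG <- ad_value(dec$XG)
  rownames(XG) <- batch$genome_ids
  out <- list(XG = XG, A = dec$A, A_heads = dec$A_heads,
              genome_of_row = batch$genome_of_row)
  if (debug) {
    out$X6 <- ad_value(dec$X6)
    out$X7 <- ad_value(dec$X7)
  }
  out
}

#' Mean-pool scaffold embeddings into genome embeddings
#'
#' For fragmented genomes processed scaffold-by-scaffold, the genome
#' embedding is the arithmetic mean of its scaffold embeddings.
#'
#' @param scaffold_embeddings Numeric matrix, one row per scaffold.
#' @param genome Vector assigning each scaffold to a genome.
#' @return Matrix with one row per genome (first-appearance order).
#' @export
pool_scaffolds <- function(scaffold_embeddings, genome) {
  scaffold_embeddings <- as.matrix(scaffold_embeddings)
  if (length(genome) != nrow(scaffold_embeddings)) {
    stop("each scaffold needs exactly one genome assignment")
  }
  if (length(genome) == 0L) stop("no scaffolds given")
  lev <- unique(genome)
  idx <- match(genome, lev)
  out <- group_sum_mat(scaffold_embeddings, idx, length(lev)) /
    tabulate(idx, length(lev))
  rownames(out) <- as.character(lev)
  out
}

#' Unweighted per-genome mean of protein embeddings
#'
#' The context-average genome representation: the plain average of (input or
#' contextualized) protein embeddings over each genome.  Used for the
#' encoder-only and input-embedding baselines.
#'
#' @param protein_embeddings Numeric matrix of per-protein embeddings.
#' @param genome_ptr Monotone offsets delimiting each genome's rows
#'   (`c(0, ...)`, ending at `nrow(protein_embeddings)`), or an integer
#'   genome index per row.
#' @return Matrix with one row per genome.
#' @export
mean_protein_pool <- function(protein_embeddings, genome_ptr) {
  protein_embeddings <- as.matrix(protein_embeddings)
  n <- nrow(protein_embeddings)
  if (length(genome_ptr) > 1L && genome_ptr[1L] == 0L &&
      genome_ptr[length(genome_ptr)] == n && !is.unsorted(genome_ptr)) {
    sizes <- diff(genome_ptr)
    if (any(sizes == 0L)) stop("empty genome in genome_ptr")
    idx <- rep(seq_along(sizes), sizes)
  } else {
    idx <- as.integer(genome_ptr)
    if (length(idx) != n) stop("genome_ptr must be offsets or a per-row index")
  }
  ng <- max(idx)
  group_sum_mat(protein_embeddings, idx, ng) / tabulate(idx, ng)
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the configuration and the
#' named weight matrices; reloading restores the model bit-exactly.
#'
#' @param model A [pst_model()].
#' @param path File path.
#' @return `pst_load()` returns the restored model.
#' @export
pst_save <- function(model, path) {
  saveRDS(list(format = "genomeset-checkpoint-1", config = model$config,
               params = model$params), path)
  invisible(path)
}

#' @rdname pst_save
#' @export
pst_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "genomeset-checkpoint-1")) {
    stop("not a genomeset checkpoint")
  }
  structure(list(config = obj$config, params = obj$params),
            class = "pst_model")
}
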