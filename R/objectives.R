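# Self-supervised training objectives: triplet loss with Chamfer positive
# mining, semi-hard negative mining with exponential reweighting, PointSwap
# augmentation, and the masked-protein mean-squared-error variant.

#' Chamfer distance between two protein sets
#'
#' Symmetric average of nearest-neighbour squared Euclidean distances:
#' `mean_x min_y ||x - y||^2 + mean_y min_x ||y - x||^2`.  The flow records,
#' for every row of `X`, the row of `Y` it is closest to (ties to the lowest
#' index); it drives PointSwap augmentation.
#'
#' @param X,Y Numeric matrices (rows are proteins) with equal column counts.
#' @param flow Return the X -> Y nearest-neighbour map as well?
#' @return The distance, or (with `flow = TRUE`) a list with `distance` and
#'   integer vector `flow`.
#' @export
chamfer_distance <- function(X, Y, flow = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("Chamfer distance needs nonempty sets")
  D <- sq_dists(X, Y)
  d <- mean(apply(D, 1L, min)) + mean(apply(D, 2L, min))
  if (!flow) return(d)
  list(distance = d, flow = apply(D, 1L, which.min))
}

# Squared Euclidean cross-distance matrix, clipped at zero.
sq_dists <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

# All pairwise Chamfer distances between the genomes of one minibatch,
# computed in the input embedding space (no position/strand features).
chamfer_matrix <- function(embeddings, genome_of_row, n_genomes) {
  D2 <- sq_dists(embeddings, embeddings)
  rows <- split(seq_len(nrow(embeddings)), genome_of_row)
  CD <- matrix(0, n_genomes, n_genomes)
  for (i in seq_len(n_genomes - 1L)) {
    for (j in (i + 1L):n_genomes) {
      blk <- D2[rows[[i]], rows[[j]], drop = FALSE]
      d <- mean(apply(blk, 1L, min)) + mean(apply(blk, 2L, min))
      CD[i, j] <- CD[j, i] <- d
    }
  }
  CD
}

#' Mine positive genomes by Chamfer distance
#'
#' For every genome in the minibatch the positive example is the non-self
#' genome with the smallest Chamfer distance in the input embedding space
#' (ties broken by lowest index), computed before positional and strand
#' features are concatenated.
#'
#' @param embeddings Input protein embedding matrix for the whole minibatch.
#' @param genome_of_row Integer genome index per protein row.
#' @param n_genomes Number of genomes in the minibatch (>= 2).
#' @return List with `positive_idx` (per-genome positive index), `flow`
#'   (per-genome integer vector mapping each anchor protein to its nearest
#'   protein of the positive genome, by local row), and `cd` (the full
#'   Chamfer distance matrix).
#' @export
mine_positive <- function(embeddings, genome_of_row, n_genomes) {
  if (n_genomes < 2L) stop("positive mining needs at least 2 genomes")
  CD <- chamfer_matrix(embeddings, genome_of_row, n_genomes)
  rows <- split(seq_len(nrow(embeddings)), genome_of_row)
  positive_idx <- integer(n_genomes)
  flow <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    d <- CD[i, ]
    d[i] <- Inf
    positive_idx[i] <- which.min(d)   # lowest index on ties
    blk <- sq_dists(embeddings[rows[[i]], , drop = FALSE],
                    embeddings[rows[[positive_idx[i]]], , drop = FALSE])
    flow[[i]] <- apply(blk, 1L, which.min)
  }
  list(positive_idx = positive_idx, flow = flow, cd = CD)
}

#' Mine a semi-hard negative genome
#'
#' Distances are Euclidean in the current genome-embedding space.  Among
#' candidates farther from the anchor than the positive, the closest one is
#' the semi-hard negative; if none is farther, the candidate whose distance
#' is nearest to the anchor-positive distance is chosen.  The anchor and
#' positive are never candidates; ties break to the lowest index.
#'
#' @param genome_embeddings Current genome embedding matrix (one row per
#'   minibatch genome).
#' @param anchor_idx,positive_idx Row indices of the anchor and its positive.
#' @return Integer index of the negative genome.
#' @export
mine_negative <- function(genome_embeddings, anchor_idx, positive_idx) {
  n <- nrow(genome_embeddings)
  cand <- setdiff(seq_len(n), c(anchor_idx, positive_idx))
  if (length(cand) == 0L) stop("no negative candidates in a batch of 2")
  d <- sqrt(rowSums((genome_embeddings[cand, , drop = FALSE] -
                     matrix(genome_embeddings[anchor_idx, ], length(cand),
                            ncol(genome_embeddings), byrow = TRUE))^2))
  dp <- sqrt(sum((genome_embeddings[anchor_idx, ] -
                  genome_embeddings[positive_idx, ])^2))
  farther <- which(d > dp)
  if (length(farther) > 0L) {
    cand[farther[which.min(d[farther])]]
  } else {
    cand[which.min(abs(d - dp))]
  }
}

#' Exponential-decay weight for a mined negative
#'
#' `omega = exp(-cd / (2 (c sigma)^2))`, where `cd` is the anchor-negative
#' Chamfer distance in the input embedding space, `c` a scale factor and
#' `sigma` the standard deviation of the minibatch Chamfer distances.  A
#' degenerate batch (`sigma = 0`) yields `omega = 1`.
#'
#' @param cd Nonnegative Chamfer distance.
#' @param c Positive scale factor.
#' @param sigma Standard deviation of the minibatch Chamfer distances.
#' @return Weight in (0, 1].
#' @export
negative_weight <- function(cd, c, sigma) {
  if (c <= 0) stop("scale factor c must be > 0")
  if (sigma == 0) return(rep(1, length(cd)))
  exp(-cd / (2 * (c * sigma)^2))
}

#' Inverse-abundance class weights
#'
#' `C_i = N / n_k` for a genome of class `k` (`n_k` members out of `N`
#' genomes).  With `labels = NULL` weighting is disabled and all weights are
#' one.
#'
#' @param labels Per-genome class labels, or NULL.
#' @param n Number of genomes (only needed when `labels` is NULL).
#' @return Numeric vector of per-genome weights.
#' @export
class_weights <- function(labels, n = length(labels)) {
  if (is.null(labels)) return(rep(1, n))
  tab <- table(labels)
  as.numeric(length(labels) / tab[as.character(labels)])
}

#' PointSwap augmentation
#'
#' Creates a hybrid genome by swapping each anchor protein for its matched
#' protein in the positive genome with probability `rate`, using the flow
#' from [mine_positive()].  Mimics homologous recombination between closely
#' related genomes.
#'
#' @param X_anchor,X_positive Protein embedding matrices of the two genomes.
#' @param flow Integer vector: nearest positive-genome row per anchor row.
#' @param rate Swap probability in \[0, 1\].
#' @param u Optional uniform draws (length `nrow(X_anchor)`); defaults to
#'   fresh `runif` draws.
#' @return Matrix of the same shape as `X_anchor`.
#' @export
pointswap <- function(X_anchor, X_positive, flow, rate, u = NULL) {
  if (rate < 0 || rate > 1) stop("swap rate must lie in [0, 1]")
  n <- nrow(X_anchor)
  if (is.null(u)) u <- stats::runif(n)
  swap <- u < rate
  out <- X_anchor
  out[swap, ] <- X_positive[flow[swap], , drop = FALSE]
  out
}

#' Single triplet hinge term
#'
#' `max(0, ||f_a - f_p||^2 - omega ||f_a - f_n||^2 + alpha)`.
#'
#' @param f_a,f_p,f_n Genome embedding vectors.
#' @param omega Negative weight from [negative_weight()].
#' @param alpha Nonnegative margin.
#' @return Nonnegative scalar.
#' @export
triplet_term <- function(f_a, f_p, f_n, omega = 1, alpha = 0) {
  max(0, sum((f_a - f_p)^2) - omega * sum((f_a - f_n)^2) + alpha)
}

#' Class-weighted triplet loss over a minibatch
#'
#' `1/(2N) * sum_i C_i [D(a_i, p_i, n_i) + D(a_i, p'_i, n'_i)]`, the mean of
#' the real and PointSwap-augmented hinge terms, class weighted.
#'
#' @param XG Genome embedding matrix holding both real and augmented
#'   genomes.
#' @param triplets Data frame (or list) with columns `anchor`, `positive`,
#'   `negative`, `omega` for the real triplets.
#' @param triplets_aug Same structure for the augmented triplets (anchor is
#'   the real genome, positive its hybrid, negative mined among hybrids).
#' @param class_weight Per-anchor weights (default 1).
#' @param alpha Margin.
#' @return Scalar loss.
#' @export
triplet_loss <- function(XG, triplets, triplets_aug,
                         class_weight = rep(1, length(triplets$anchor)),
                         alpha = 0) {
  n <- length(triplets$anchor)
  term <- function(tr) {
    dp <- rowSums((XG[tr$anchor, , drop = FALSE] -
                   XG[tr$positive, , drop = FALSE])^2)
    dn <- rowSums((XG[tr$anchor, , drop = FALSE] -
                   XG[tr$negative, , drop = FALSE])^2)
    pmax(0, dp - tr$omega * dn + alpha)
  }
  sum(class_weight * (term(triplets) + term(triplets_aug))) / (2 * n)
}

# Tape version of the same quantity (gradients flow through XG).
tape_triplet_loss <- function(XGref, triplets, triplets_aug, class_weight,
                              alpha) {
  tp <- XGref$tp
  n <- length(triplets$anchor)
  term <- function(tr) {
    dp <- ad_rowsum(ad_square(ad_sub(ad_gather(XGref, tr$anchor),
                                     ad_gather(XGref, tr$positive))))
    dn <- ad_rowsum(ad_square(ad_sub(ad_gather(XGref, tr$anchor),
                                     ad_gather(XGref, tr$negative))))
    ad_relu(ad_add_scalar(ad_sub(dp, ad_mul(dn, ad_const(tp, matrix(tr$omega,
                                                                    ncol = 1L)))),
                          alpha))
  }
  hinge <- ad_add(term(triplets), term(triplets_aug))
  ad_scale(ad_sum(ad_mul(hinge, ad_const(tp, matrix(class_weight, ncol = 1L)))),
           1 / (2 * n))
}

# ---- masked-protein objective ----------------------------------------------

#' Mask proteins for the masked-language-model variant
#'
#' Each protein row is masked independently with probability `p_mask`; at
#' least one protein is always masked so the loss stays defined.  Masking
#' zeroes the raw embedding slice only -- positional and strand features are
#' kept, since position and strand are not unknown.
#'
#' @param batch A [build_genome_batch()] result.
#' @param p_mask Masking rate in (0, 1).
#' @return List with `mask_index` (masked rows), `masked_embeddings` (the
#'   input embedding matrix with masked rows zeroed), and `p_mask`.
#' @export
mask_proteins <- function(batch, p_mask) {
  if (p_mask <= 0 || p_mask >= 1) stop("p_mask must lie in (0, 1)")
  n <- nrow(batch$embeddings)
  mask <- which(stats::runif(n) < p_mask)
  if (length(mask) == 0L) mask <- sample.int(n, 1L)
  masked <- batch$embeddings
  masked[mask, ] <- 0
  list(mask_index = mask, masked_embeddings = masked, p_mask = p_mask)
}

#' Nearest-neighbour positive substitution
#'
#' Replaces every protein by its non-self Euclidean nearest neighbour in the
#' input embedding space, modeling that different proteins can occupy the
#' same genomic context.
#'
#' @param embeddings Input protein embedding matrix (>= 2 rows).
#' @return List with `neighbor` (integer map, no self-assignments) and
#'   `embeddings` (the substituted matrix).
#' @export
positive_substitute <- function(embeddings) {
  n <- nrow(embeddings)
  if (n < 2L) stop("positive substitution needs at least 2 proteins")
  D <- sq_dists(embeddings, embeddings)
  diag(D) <- Inf
  nb <- apply(D, 1L, which.min)
  list(neighbor = nb, embeddings = embeddings[nb, , drop = FALSE])
}

#' Masked-protein mean-squared-error loss
#'
#' `1/(2 n_m) * sum over masked rows of (||Y_pred - Y_target||^2 +
#' ||Y_pos - Y_target||^2)`: the average of the prediction error and the
#' positive-substitution error.
#'
#' @param Y_pred,Y_pos,Y_target Matrices aligned on the masked rows.
#' @return Scalar loss.
#' @export
mlm_loss <- function(Y_pred, Y_pos, Y_target) {
  Y_pred <- as.matrix(Y_pred); Y_pos <- as.matrix(Y_pos)
  Y_target <- as.matrix(Y_target)
  n_m <- nrow(Y_target)
  if (n_m == 0L) stop("no masked proteins")
  (sum((Y_pred - Y_target)^2) + sum((Y_pos - Y_target)^2)) / (2 * n_m)
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param objective `"triplet"` (encoder-decoder) or `"mlm"` (encoder only).
#' @param epochs Number of passes over the data.
#' @param batch_size Genomes per minibatch (positives and negatives are
#'   mined within a minibatch); `Inf` trains full-batch.
#' @param lr Adam learning rate; decays linearly to `lr / epochs` when
#'   `lr_decay` is TRUE.
#' @param margin Triplet margin `alpha`.
#' @param scale_c Scale factor `c` of the negative reweighting.
#' @param swap_rate PointSwap rate.
#' @param mask_rate Masking rate for the MLM objective.
#' @param class_labels Optional per-genome class labels for inverse-abundance
#'   loss weights (e.g. taxonomic realms); NULL disables weighting.
#' @param grad_clip Elementwise gradient clamp.
#' @param lr_decay Linearly decay the learning rate each epoch?
#' @param seed RNG seed for minibatch order, PointSwap and masking draws.
#' @return Object of class `train_config`.
#' @export
train_config <- function(objective = c("triplet", "mlm"), epochs = 50L,
                         batch_size = 16L, lr = 0.01, margin = 20,
                         scale_c = 1, swap_rate = 0.5,
                         mask_rate = 0.15, class_labels = NULL,
                         grad_clip = 1.0, lr_decay = TRUE, seed = 1L) {
  objective <- match.arg(objective)
  structure(list(objective = objective, epochs = as.integer(epochs),
                 batch_size = batch_size, lr = lr,
                 margin = margin, scale_c = scale_c, swap_rate = swap_rate,
                 mask_rate = mask_rate, class_labels = class_labels,
                 grad_clip = grad_clip, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Duplicate a batch structure so that N real genomes are followed by their N
# augmented copies (identical topology, embeddings substituted per epoch).
double_batch <- function(batch) {
  n <- nrow(batch$embeddings)
  b <- batch
  b$embeddings <- rbind(batch$embeddings, batch$embeddings)
  b$genome_of_row <- c(batch$genome_of_row,
                       batch$genome_of_row + batch$n_genomes)
  b$scaffold_of_row <- c(batch$scaffold_of_row,
                         batch$scaffold_of_row + max(batch$scaffold_of_row))
  b$subgraph_id <- c(batch$subgraph_id,
                     batch$subgraph_id + max(batch$subgraph_id))
  b$edge_list <- rbind(batch$edge_list, batch$edge_list + n)
  b$pos_index <- c(batch$pos_index, batch$pos_index)
  b$strand_index <- c(batch$strand_index, batch$strand_index)
  b$genome_ptr <- c(batch$genome_ptr, batch$genome_ptr[-1L] + n)
  b$scaffold_ptr <- c(batch$scaffold_ptr, batch$scaffold_ptr[-1L] + n)
  b$genome_ids <- c(batch$genome_ids, paste0(batch$genome_ids, "_aug"))
  b$n_genomes <- 2L * batch$n_genomes
  b
}

#' Train a set-transformer genome model
#'
#' Full-batch self-supervised training.  With the triplet objective each
#' epoch mines easy positives (Chamfer distance on input embeddings) and
#' semi-hard negatives (Euclidean distance on the current genome
#' embeddings), builds PointSwap hybrids, and minimizes the class-weighted
#' two-term hinge loss.  With the MLM objective each epoch masks proteins
#' and minimizes the masked mean-squared error of the contextualized outputs
#' against the original features for both the masked and the
#' positively-substituted inputs.
#'
#' @param pset A [protein_set()].
#' @param config A [model_config()] (its `d_in` must match the data).
#' @param tc A [train_config()].
#' @param verbose Print per-epoch losses?
#' @return List with `model` (trained), `log` (data frame of per-epoch
#'   losses) and `config`/`train_config` echoes.
#' @export
pst_train <- function(pset, config, tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(pset, "protein_set"))
  if (ncol(pset$embeddings) != config$d_in) {
    stop("embedding dimension does not match config d_in")
  }
  model <- pst_model(config)
  set.seed(tc$seed)
  if (tc$objective == "triplet") {
    fit <- train_triplet(model, pset, config, tc, verbose)
  } else {
    fit <- train_mlm(model, build_genome_batch(pset, config), tc, verbose)
  }
  list(model = fit$model, log = fit$log, config = config, train_config = tc)
}

# One triplet step on a minibatch: mine positives in input space, build
# PointSwap hybrids, forward real + augmented genomes, mine semi-hard
# negatives in the current embedding space, and return the tape loss.
triplet_minibatch_loss <- function(model, batch, tc, cw) {
  ng <- batch$n_genomes
  mined <- mine_positive(batch$embeddings, batch$genome_of_row, ng)
  sigma <- stats::sd(mined$cd[upper.tri(mined$cd)])
  if (is.na(sigma)) sigma <- 0
  rows <- split(seq_len(nrow(batch$embeddings)), batch$genome_of_row)
  aug <- batch$embeddings
  for (i in seq_len(ng)) {
    ri <- rows[[i]]
    aug[ri, ] <- pointswap(batch$embeddings[ri, , drop = FALSE],
                           batch$embeddings[rows[[mined$positive_idx[i]]], ,
                                            drop = FALSE],
                           mined$flow[[i]], tc$swap_rate)
  }
  big <- double_batch(batch)
  fw <- pst_tape_forward(model, big, training = model$config$dropout > 0,
                         embeddings = rbind(batch$embeddings, aug))
  XG <- ad_value(fw$XG)
  real <- XG[seq_len(ng), , drop = FALSE]
  hyb <- XG[ng + seq_len(ng), , drop = FALSE]

  neg <- vapply(seq_len(ng), function(i) {
    mine_negative(real, i, mined$positive_idx[i])
  }, integer(1))
  omega <- negative_weight(mined$cd[cbind(seq_len(ng), neg)], tc$scale_c,
                           sigma)
  # Augmented triplet: anchor = real genome, positive = its hybrid,
  # negative mined among the hybrids by the same semi-hard rule; omega
  # recomputed from the anchor vs augmented-negative Chamfer distance.
  neg_aug <- vapply(seq_len(ng), function(i) {
    d <- sqrt(rowSums((hyb - matrix(real[i, ], ng, ncol(real),
                                    byrow = TRUE))^2))
    dp <- sqrt(sum((real[i, ] - hyb[i, ])^2))
    cand <- setdiff(seq_len(ng), i)
    farther <- cand[d[cand] > dp]
    if (length(farther) > 0L) farther[which.min(d[farther])]
    else cand[which.min(abs(d[cand] - dp))]
  }, integer(1))
  cd_aug <- vapply(seq_len(ng), function(i) {
    chamfer_distance(batch$embeddings[rows[[i]], , drop = FALSE],
                     aug[rows[[neg_aug[i]]], , drop = FALSE])
  }, numeric(1))
  omega_aug <- negative_weight(cd_aug, tc$scale_c, sigma)

  triplets <- list(anchor = seq_len(ng), positive = mined$positive_idx,
                   negative = neg, omega = omega)
  triplets_aug <- list(anchor = seq_len(ng), positive = ng + seq_len(ng),
                       negative = ng + neg_aug, omega = omega_aug)
  tape_triplet_loss(fw$XG, triplets, triplets_aug, cw, tc$margin)
}

train_triplet <- function(model, pset, config, tc, verbose) {
  g_lev <- unique(pset$meta$genome_id)
  ng_all <- length(g_lev)
  if (ng_all < 3L) stop("triplet training needs at least 3 genomes")
  cw_all <- class_weights(tc$class_labels, ng_all)
  bs <- if (is.finite(tc$batch_size)) as.integer(tc$batch_size) else ng_all
  bs <- max(3L, min(bs, ng_all))
  st <- adam_state(model$params)
  log <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(ng_all)
    starts <- seq(1L, ng_all, by = bs)
    # a trailing minibatch of fewer than 3 genomes joins the previous one
    if (length(starts) > 1L && ng_all - starts[length(starts)] + 1L < 3L) {
      starts <- starts[-length(starts)]
    }
    ep_loss <- 0
    for (s in seq_along(starts)) {
      take <- ord[starts[s]:(if (s < length(starts)) starts[s + 1L] - 1L
                             else ng_all)]
      sel <- pset$meta$genome_id %in% g_lev[take]
      sub <- protein_set(pset$meta[sel, , drop = FALSE],
                         pset$embeddings[sel, , drop = FALSE])
      batch <- build_genome_batch(sub, config)
      cw <- cw_all[match(batch$genome_ids, g_lev)]
      loss <- triplet_minibatch_loss(model, batch, tc, cw)
      grads <- ad_backward(loss)
      lr <- if (tc$lr_decay) tc$lr * (1 - (ep - 1) / tc$epochs) else tc$lr
      upd <- adam_step(model$params, grads, st, lr = lr, clip = tc$grad_clip)
      model$params <- upd$params
      st <- upd$state
      ep_loss <- ep_loss + as.vector(ad_value(loss))
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss /
                                   length(starts)))
    if (verbose) message(sprintf("epoch %d  triplet loss %.5f", ep,
                                 log$loss[ep]))
  }
  list(model = model, log = log)
}

train_mlm <- function(model, batch, tc, verbose) {
  st <- adam_state(model$params)
  sub <- positive_substitute(batch$embeddings)
  log <- data.frame(epoch = integer(), loss = numeric())
  n_m_col <- integer()
  for (ep in seq_len(tc$epochs)) {
    mk <- mask_proteins(batch, tc$mask_rate)
    sub_masked <- sub$embeddings
    sub_masked[mk$mask_index, ] <- 0
    tp <- ad_tape()
    ps <- ad_params(tp, model$params)
    Yp <- tape_encoder_forward(tp, batch, ps, model$config,
                               model$config$dropout > 0, mk$masked_embeddings)
    Ys <- tape_encoder_forward(tp, batch, ps, model$config,
                               model$config$dropout > 0, sub_masked)
    target <- cbind(batch$embeddings,
                    model$params$pos_table[batch$pos_index, , drop = FALSE],
                    model$params$strand_table[batch$strand_index, ,
                                              drop = FALSE])
    Tm <- ad_const(tp, target[mk$mask_index, , drop = FALSE])
    n_m <- length(mk$mask_index)
    loss <- ad_scale(
      ad_add(ad_sum(ad_square(ad_sub(ad_gather(Yp, mk$mask_index), Tm))),
             ad_sum(ad_square(ad_sub(ad_gather(Ys, mk$mask_index), Tm)))),
      1 / (2 * n_m))
    grads <- ad_backward(loss)
    lr <- if (tc$lr_decay) tc$lr * (1 - (ep - 1) / tc$epochs) else tc$lr
    upd <- adam_step(model$params, grads, st, lr = lr, clip = tc$grad_clip)
    model$params <- upd$params
    st <- upd$state
    log <- rbind(log, data.frame(epoch = ep, loss = as.vector(ad_value(loss))))
    n_m_col <- c(n_m_col, n_m)
    if (verbose) message(sprintf("epoch %d  mlm loss %.5f", ep, log$loss[ep]))
  }
  log$n_masked <- n_m_col
  list(model = model, log = log)
}

#' Embed a dataset with a trained model
#'
#' @param model A [pst_model()].
#' @param pset A [protein_set()].
#' @return List with `protein` (contextualized protein embeddings, rows
#'   named by protein id), `genome` (genome embedding matrix, rows named by
#'   genome id), `genome_mean` (the unweighted context-average genome
#'   embeddings), and `attention` (data frame of per-protein head-mean
#'   pooling attention).
#' @export
pst_embed <- function(model, pset) {
  batch <- build_genome_batch(pset, model$config)
  fw <- pst_tape_forward(model, batch, training = FALSE)
  XC <- ad_value(fw$XC)
  rownames(XC) <- batch$meta$protein_id
  XG <- ad_value(fw$XG)
  rownames(XG) <- batch$genome_ids
  XGm <- mean_protein_pool(XC, batch$genome_of_row)
  rownames(XGm) <- batch$genome_ids
  list(protein = XC, genome = XG, genome_mean = XGm,
       attention = data.frame(protein_id = batch$meta$protein_id,
                              genome_id = batch$meta$genome_id,
                              attention = fw$A))
}
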