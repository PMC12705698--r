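# Heterogeneous graph neural network for virus-host link prediction:
# interaction-graph construction, edge-type-specific graph convolutions, a
# difference decoder, disjoint training splits, negative sampling and ranked
# prediction.

#' Virus-virus similarity edges
#'
#' Embedding mode: connect viruses whose genome embeddings reach at least
#' `min_similarity` angular similarity, then prune each virus's neighbour
#' list to the `max_neighbors` most similar.  Gene-sharing mode: drop
#' singleton protein clusters, build the dice-similarity graph over presence
#' profiles (edges where S > 0), cluster it with Leiden at resolution 0.1
#' and fully connect viruses within each community.
#'
#' @param x Virus genome embedding matrix (embedding mode) or binary
#'   virus x protein-cluster presence matrix (gene-sharing mode).
#' @param method `"embedding"` or `"gene_sharing"`.
#' @param min_similarity Angular-similarity threshold (embedding mode).
#' @param max_neighbors Neighbour cap per virus (embedding mode).
#' @param resolution Leiden resolution (gene-sharing mode).
#' @param seed RNG seed for the Leiden step.
#' @return Two-column integer matrix of undirected virus pairs (i < j).
#' @export
virus_virus_edges <- function(x, method = c("embedding", "gene_sharing"),
                              min_similarity = 0.75, max_neighbors = 15L,
                              resolution = 0.1, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 viruses")
  if (method == "embedding") {
    S <- angular_similarity_matrix(x)
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
      s <- S[i, ]
      s[i] <- -Inf
      nb <- which(s >= min_similarity)
      if (length(nb) > max_neighbors) {
        nb <- nb[order(-s[nb], nb)][seq_len(max_neighbors)]
      }
      ii <- c(ii, rep(i, length(nb)))
      jj <- c(jj, nb)
    }
    if (length(ii) == 0L) return(matrix(integer(), 0L, 2L))
    pairs <- unique(cbind(pmin(ii, jj), pmax(ii, jj)))
  } else {
    P <- (x > 0) * 1
    P <- P[, colSums(P) > 1L, drop = FALSE]  # drop singleton clusters
    S <- dice_matrix(P)
    diag(S) <- 0
    idx <- which(S > 0 & upper.tri(S), arr.ind = TRUE)
    if (nrow(idx) == 0L) return(matrix(integer(), 0L, 2L))
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(idx), weight = S[idx])
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(g)$weight)
    memb <- igraph::membership(cl)
    pairs <- do.call(rbind, lapply(split(seq_len(n), memb), function(v) {
      if (length(v) < 2L) return(NULL)
      t(utils::combn(v, 2L))
    }))
    if (is.null(pairs)) return(matrix(integer(), 0L, 2L))
  }
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Assemble a virus-host interaction graph
#'
#' Bipartite on the infects relation: virus and host nodes carry genome
#' embedding features; virus-host edges are the known pairs and virus-virus
#' edges link similar viruses.  Self-loops are added implicitly by the
#' convolution.
#'
#' @param virus_emb,host_emb Feature matrices (rows named by genome id).
#' @param vh_edges Data frame / matrix with virus and host indices (or ids)
#'   of known infection pairs.
#' @param vv_edges Optional precomputed virus pair matrix; default built
#'   from `virus_emb` in embedding mode.
#' @param test_viruses Integer indices (or ids) of held-out test viruses
#'   whose supervision edges must be masked during training.
#' @return Object of class `interaction_graph`.
#' @export
interaction_graph <- function(virus_emb, host_emb, vh_edges,
                              vv_edges = NULL, test_viruses = integer()) {
  virus_emb <- as.matrix(virus_emb)
  host_emb <- as.matrix(host_emb)
  stopifnot(ncol(virus_emb) == ncol(host_emb))
  vh <- as.matrix(vh_edges)[, 1:2, drop = FALSE]
  if (is.character(vh)) {
    vh <- cbind(match(vh[, 1L], rownames(virus_emb)),
                match(vh[, 2L], rownames(host_emb)))
  }
  storage.mode(vh) <- "integer"
  if (anyNA(vh)) stop("unknown virus or host id in the pair table")
  if (is.null(vv_edges)) vv_edges <- virus_virus_edges(virus_emb)
  if (is.character(test_viruses)) {
    test_viruses <- match(test_viruses, rownames(virus_emb))
  }
  structure(list(virus_emb = virus_emb, host_emb = host_emb,
                 vh = vh, vv = vv_edges,
                 n_virus = nrow(virus_emb), n_host = nrow(host_emb),
                 test_viruses = as.integer(test_viruses)),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "interaction_graph: %d viruses, %d hosts, %d infection edges, %d virus-virus edges\n",
    x$n_virus, x$n_host, nrow(x$vh), nrow(x$vv)))
  invisible(x)
}

#' Initialize a link-prediction model
#'
#' `n_layers` graph-convolution layers with separate weights per edge type
#' (virus-virus, virus-to-host, host-to-virus) followed by a 2-layer
#' feed-forward decoder over encoder-embedding differences ending in a
#' logistic unit.
#'
#' @param d_in Node feature dimension.
#' @param hidden Encoder layer width.
#' @param n_layers Number of convolution layers.
#' @param decoder_hidden Width of the decoder hidden layer.
#' @param dropout Dropout rate after the encoder and each decoder layer.
#' @param seed RNG seed for weight initialization.
#' @return Object of class `link_model`.
#' @export
link_model <- function(d_in, hidden = 64L, n_layers = 2L,
                       decoder_hidden = 64L, dropout = 0.25, seed = 1L) {
  set.seed(seed)
  p <- list()
  din <- d_in
  for (l in seq_len(n_layers)) {
    for (ty in c("vv", "vh", "hv")) {
      p[[sprintf("conv%d_W%s", l, ty)]] <- glorot(din, hidden)
    }
    din <- hidden
  }
  p$dec_W1 <- glorot(hidden, decoder_hidden)
  p$dec_b1 <- matrix(0, 1L, decoder_hidden)
  p$dec_W2 <- glorot(decoder_hidden, 1L)
  p$dec_b2 <- matrix(0, 1L, 1L)
  structure(list(params = p, n_layers = as.integer(n_layers),
                 hidden = as.integer(hidden), d_in = as.integer(d_in),
                 decoder_hidden = as.integer(decoder_hidden),
                 dropout = dropout),
            class = "link_model")
}

# Symmetrically normalized adjacency coefficients 1/sqrt(deg_i deg_j) where
# degrees count all message edges plus the self-loop.
conv_norm <- function(edges_src, edges_dst, n_nodes) {
  deg <- tabulate(edges_dst, n_nodes) + 1L  # +1 for self-loop
  list(deg = deg,
       coef = 1 / sqrt(deg[edges_src] * deg[edges_dst]),
       self = 1 / deg)
}

# One heterogeneous convolution layer on the tape.  Node order: viruses
# first, then hosts.  Message edges per type carry that type's weight
# matrix; virus self-loops use the virus-virus weights and host self-loops
# the host-to-virus (host feature) weights; contributions are summed and
# passed through ReLU unless `linear`.
tape_hetero_conv <- function(feats, graph, Wvv, Wvh, Whv, msg_vh,
                             linear = FALSE) {
  nv <- graph$n_virus; nh <- graph$n_host
  n <- nv + nh
  vv <- graph$vv
  src <- c(vv[, 1L], vv[, 2L], msg_vh[, 1L], nv + msg_vh[, 2L])
  dst <- c(vv[, 2L], vv[, 1L], nv + msg_vh[, 2L], msg_vh[, 1L])
  type <- c(rep(1L, 2L * nrow(vv)), rep(2L, nrow(msg_vh)),
            rep(3L, nrow(msg_vh)))
  nrm <- conv_norm(src, dst, n)
  tp <- feats$tp
  out <- NULL
  for (ty in 1:3) {
    W <- list(Wvv, Wvh, Whv)[[ty]]
    sel <- type == ty
    XW <- ad_matmul(feats, W)
    if (any(sel)) {
      msg <- ad_mul(ad_gather(XW, src[sel]),
                    ad_const(tp, matrix(nrm$coef[sel], ncol = 1L)))
      agg <- ad_group_sum(msg, dst[sel], n)
      out <- if (is.null(out)) agg else ad_add(out, agg)
    }
    # self-loops: viruses through the vv weights, hosts through the hv ones
    self_rows <- if (ty == 1L) seq_len(nv) else if (ty == 3L) nv + seq_len(nh)
      else integer()
    if (length(self_rows) > 0L) {
      mask <- matrix(0, n, 1L)
      mask[self_rows, 1L] <- nrm$self[self_rows]
      sl <- ad_mul(XW, ad_const(tp, mask))
      out <- if (is.null(out)) sl else ad_add(out, sl)
    }
  }
  if (linear) out else ad_relu(out)
}

#' One heterogeneous graph-convolution layer (numeric)
#'
#' Symmetrically normalized aggregation `D^{-1/2} (A + I) D^{-1/2}` applied
#' per edge type with that type's weight matrix, contributions summed, ReLU
#' applied.  Virus self-loops route through the virus-virus weights and host
#' self-loops through the host-to-virus weights.
#'
#' @param graph An [interaction_graph()].
#' @param features Node feature matrix (viruses then hosts).
#' @param Wvv,Wvh,Whv Weight matrices for virus-virus, virus-to-host and
#'   host-to-virus messages.
#' @param activation Apply the ReLU activation?
#' @return Updated node feature matrix.
#' @export
hetero_conv_layer <- function(graph, features, Wvv, Wvh, Whv,
                              activation = TRUE) {
  if (nrow(features) != graph$n_virus + graph$n_host) {
    stop("features must have one row per node")
  }
  if (!all(vapply(list(Wvv, Wvh, Whv), nrow, integer(1)) == ncol(features))) {
    stop("weight matrices do not match the feature dimension")
  }
  tp <- ad_tape()
  f <- ad_const(tp, features)
  out <- tape_hetero_conv(f, graph, ad_const(tp, Wvv), ad_const(tp, Wvh),
                          ad_const(tp, Whv), graph$vh, linear = !activation)
  ad_value(out)
}

tape_link_encoder <- function(tp, model, graph, ps, msg_vh, training) {
  feats <- ad_const(tp, rbind(graph$virus_emb, graph$host_emb))
  for (l in seq_len(model$n_layers)) {
    feats <- tape_hetero_conv(feats, graph,
                              ps[[sprintf("conv%d_Wvv", l)]],
                              ps[[sprintf("conv%d_Wvh", l)]],
                              ps[[sprintf("conv%d_Whv", l)]], msg_vh)
  }
  tape_dropout(feats, model$dropout, training)
}

tape_link_decoder_logits <- function(model, z, pairs, ps, training) {
  # q = z_virus - z_host, through two feed-forward layers (logits returned)
  nv_off <- attr(pairs, "nv_off")
  q <- ad_sub(ad_gather(z, pairs[, 1L]),
              ad_gather(z, nv_off + pairs[, 2L]))
  h <- tape_dropout(ad_relu(ad_add_rowvec(ad_matmul(q, ps$dec_W1),
                                          ps$dec_b1)),
                    model$dropout, training)
  ad_add_rowvec(ad_matmul(h, ps$dec_W2), ps$dec_b2)
}

#' Decode a virus-host pair into a link probability
#'
#' The pair is represented by the difference of the encoder embeddings,
#' passed through the 2-layer feed-forward decoder and squashed by the
#' logistic function, so the output lies strictly in (0, 1).
#'
#' @param z_v,z_h Encoder embeddings (vectors or matrices of aligned rows).
#' @param params Named list with `dec_W1`, `dec_b1`, `dec_W2`, `dec_b2`.
#' @return Probability vector.
#' @export
link_decode <- function(z_v, z_h, params) {
  q <- as_mat(z_v) - as_mat(z_h)
  h <- pmax(q %*% params$dec_W1 +
              matrix(params$dec_b1, nrow(q), ncol(params$dec_W1),
                     byrow = TRUE), 0)
  logit <- h %*% params$dec_W2 + as.vector(params$dec_b2)
  as.vector(1 / (1 + exp(-logit)))
}

#' Split infection edges and sample negatives
#'
#' Edges are split 80:20 (floor convention) into train and validation sets;
#' an equal number of negative virus-host pairs absent from the graph is
#' sampled uniformly, split disjointly to match.  With `disjoint` set (e.g.
#' 0.3), the training edges are further divided into message-passing and
#' supervision subsets (`|E_D| = floor(disjoint * |E_T|)`).
#'
#' @param graph An [interaction_graph()].
#' @param val_frac Validation fraction of the real edges.
#' @param disjoint Optional supervision fraction of the training edges.
#' @return Object of class `edge_split` with matrices `train`, `val`,
#'   `neg_train`, `neg_val` and optionally `mp` / `sup`.
#' @export
split_and_sample <- function(graph, val_frac = 0.2, disjoint = NULL) {
  E <- graph$vh
  m <- nrow(E)
  if (m < 5L) stop("need at least 5 infection edges")
  n_possible <- graph$n_virus * graph$n_host - m
  if (n_possible < m) stop("graph too dense to sample matching negatives")
  ord <- sample.int(m)
  n_val <- floor(m * val_frac)
  val <- E[ord[seq_len(n_val)], , drop = FALSE]
  train <- E[ord[-seq_len(n_val)], , drop = FALSE]
  neg <- sample_negative_edges(graph, m)
  neg_val <- neg[seq_len(n_val), , drop = FALSE]
  neg_train <- neg[-seq_len(n_val), , drop = FALSE]
  out <- list(train = train, val = val, neg_train = neg_train,
              neg_val = neg_val)
  if (!is.null(disjoint)) {
    nt <- nrow(train)
    n_sup <- floor(disjoint * nt)
    ord2 <- sample.int(nt)
    out$sup <- train[ord2[seq_len(n_sup)], , drop = FALSE]
    out$mp <- train[ord2[-seq_len(n_sup)], , drop = FALSE]
  }
  structure(out, class = "edge_split")
}

sample_negative_edges <- function(graph, m) {
  key <- graph$vh[, 1L] + (graph$vh[, 2L] - 1L) * graph$n_virus
  out <- integer(0)
  while (length(out) < m) {
    cand <- sample.int(graph$n_virus * graph$n_host, 2L * m, replace = TRUE)
    cand <- setdiff(unique(cand), key)
    out <- unique(c(out, cand))
  }
  out <- out[seq_len(m)]
  cbind(((out - 1L) %% graph$n_virus) + 1L,
        ((out - 1L) %/% graph$n_virus) + 1L)
}

#' Binary cross-entropy link loss
#'
#' Mean over the unmasked edges of `-(y log p + (1 - y) log(1 - p))`;
#' probabilities are clipped at 1e-7.  The mask removes test-virus edges
#' from the loss to prevent leakage.
#'
#' @param probabilities Predicted probabilities.
#' @param labels 0/1 labels.
#' @param mask Logical vector; TRUE keeps an edge in the loss.
#' @return Scalar loss.
#' @export
bce_link_loss <- function(probabilities, labels,
                          mask = rep(TRUE, length(labels))) {
  stopifnot(all(labels %in% c(0, 1)))
  p <- pmin(pmax(probabilities[mask], 1e-7), 1 - 1e-7)
  y <- labels[mask]
  if (length(y) == 0L) stop("no unmasked edges")
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the link-prediction model
#'
#' Each epoch resamples negatives, runs the heterogeneous encoder over the
#' real (message-passing) edges, decodes the supervision pairs, and
#' minimizes binary cross-entropy with test-virus edges masked out of the
#' loss.  Validation AUROC is tracked on the held-out edges.
#'
#' @param graph An [interaction_graph()].
#' @param model A [link_model()]; default built from the data.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled L2 shrinkage per update (regularizes the
#'   small planted graphs this model is typically fit to).
#' @param lr_decay Linearly decay the learning rate to zero over the run.
#' @param keep_best Return the parameters from the epoch with the lowest
#'   training loss (an early-stopping-style checkpoint rule) instead of the
#'   final epoch's.
#' @param val_frac,disjoint Passed to [split_and_sample()].
#' @param seed RNG seed (splits, negatives, dropout).
#' @param verbose Print progress?
#' @return List with `model`, `split`, `log` (per-epoch loss) and
#'   `val_auroc`.
#' @export
host_train <- function(graph, model = NULL, epochs = 200L, lr = 0.01,
                       weight_decay = 0.02, lr_decay = TRUE,
                       keep_best = TRUE, val_frac = 0.2,
                       disjoint = NULL, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  if (is.null(model)) model <- link_model(ncol(graph$virus_emb), seed = seed)
  split <- split_and_sample(graph, val_frac, disjoint)
  msg_vh <- if (is.null(split$mp)) split$train else split$mp
  sup <- if (is.null(split$sup)) split$train else split$sup
  st <- adam_state(model$params)
  log <- data.frame(epoch = integer(), loss = numeric())
  best <- list(loss = Inf, params = model$params)
  for (ep in seq_len(epochs)) {
    neg <- sample_negative_edges(graph, nrow(sup))
    pairs <- rbind(sup, neg)
    attr(pairs, "nv_off") <- graph$n_virus
    y <- c(rep(1, nrow(sup)), rep(0, nrow(neg)))
    mask <- !(pairs[, 1L] %in% graph$test_viruses)
    tp <- ad_tape()
    ps <- ad_params(tp, model$params)
    z <- tape_link_encoder(tp, model, graph, ps, msg_vh, training = TRUE)
    kept <- structure(pairs[mask, , drop = FALSE], nv_off = graph$n_virus)
    logits <- tape_link_decoder_logits(model, z, kept, ps, training = TRUE)
    ym <- ad_const(tp, matrix(y[mask], ncol = 1L))
    # mean(softplus(z) - y z): stable binary cross-entropy from logits
    loss <- ad_scale(ad_sum(ad_sub(ad_softplus(logits),
                                   ad_mul(logits, ym))),
                     1 / sum(mask))
    grads <- ad_backward(loss)
    lr_ep <- if (lr_decay) lr * (1 - (ep - 1) / epochs) else lr
    upd <- adam_step(model$params, grads, st, lr = lr_ep, clip = 1.0,
                     weight_decay = weight_decay)
    model$params <- upd$params
    st <- upd$state
    log <- rbind(log, data.frame(epoch = ep,
                                 loss = as.vector(ad_value(loss))))
    if (ep >= 5L) {
      recent <- mean(tail(log$loss, 5L))  # smoothed: negatives resample
      if (recent < best$loss) best <- list(loss = recent,
                                           params = model$params)
    }
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("epoch %d  bce %.4f", ep, log$loss[ep]))
    }
  }
  if (keep_best && is.finite(best$loss)) model$params <- best$params
  val_auroc <- link_val_auroc(model, graph, split)
  list(model = model, split = split, log = log, val_auroc = val_auroc)
}

link_probabilities <- function(model, graph, pairs,
                               msg_vh = graph$vh) {
  tp <- ad_tape()
  ps <- ad_params(tp, model$params)
  z <- tape_link_encoder(tp, model, graph, ps, msg_vh, training = FALSE)
  zv <- ad_value(z)
  link_decode(zv[pairs[, 1L], , drop = FALSE],
              zv[graph$n_virus + pairs[, 2L], , drop = FALSE], model$params)
}

#' Validation AUROC of a link model
#' @param model A [link_model()].
#' @param graph An [interaction_graph()].
#' @param split An [split_and_sample()] result.
#' @return AUROC on the validation positives vs sampled negatives.
#' @export
link_val_auroc <- function(model, graph, split) {
  pairs <- rbind(split$val, split$neg_val)
  y <- c(rep(1, nrow(split$val)), rep(0, nrow(split$neg_val)))
  p <- link_probabilities(model, graph, pairs,
                          msg_vh = if (is.null(split$mp)) split$train
                          else split$mp)
  auroc_score(p, y)
}

# Mann-Whitney formulation of the area under the ROC curve.
auroc_score <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank candidate hosts for every virus
#'
#' Decodes all virus x host pairs, keeps those at or above the confidence
#' threshold and orders them per virus by decreasing probability.  When true
#' hosts are supplied, the hit fraction (viruses whose true host appears
#' above the threshold) is reported.
#'
#' @param model A trained [link_model()].
#' @param graph An [interaction_graph()].
#' @param threshold Confidence cutoff (the operating points of interest are
#'   0.75 and 0.90).
#' @param viruses Subset of virus indices to score (default all).
#' @param true_hosts Optional named/indexed vector of each virus's true
#'   host.
#' @return List with `predictions` (data frame `virus`, `host`,
#'   `probability`) and, when truth is given, `hit_fraction`.
#' @export
predict_hosts <- function(model, graph, threshold = 0.75,
                          viruses = seq_len(graph$n_virus),
                          true_hosts = NULL) {
  pairs <- cbind(rep(viruses, each = graph$n_host),
                 rep(seq_len(graph$n_host), length(viruses)))
  p <- link_probabilities(model, graph, pairs)
  keep <- p >= threshold
  preds <- data.frame(virus = pairs[keep, 1L], host = pairs[keep, 2L],
                      probability = p[keep])
  preds <- preds[order(preds$virus, -preds$probability), , drop = FALSE]
  rownames(preds) <- NULL
  out <- list(predictions = preds, probabilities = p, pairs = pairs)
  if (!is.null(true_hosts)) {
    hits <- vapply(viruses, function(v) {
      any(preds$virus == v & preds$host == true_hosts[v])
    }, logical(1))
    out$hit_fraction <- mean(hits)
  }
  out
}
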