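# Evaluation statistics over embeddings: angular similarity, kNN similarity
# graphs, Leiden clustering, information-gain-ratio purity, KL-rescaled
# pooling attention, annotation transfer, co-clustering enrichment,
# functional-module detection, identity-score aggregation, dice-based CV
# grouping and the tetranucleotide baseline.

#' Angular similarity of two vectors
#'
#' `1 - arccos(cos(u, v)) / pi`, a similarity on \[0, 1\]: identical
#' directions score 1, orthogonal vectors 0.5, opposite directions 0.
#'
#' @param u,v Nonzero numeric vectors.
#' @return Scalar in \[0, 1\].
#' @export
angular_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("angular similarity of a zero vector")
  1 - acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) / pi
}

# Pairwise angular similarity matrix of row vectors.
angular_similarity_matrix <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("angular similarity of a zero vector")
  C <- tcrossprod(X / nrm)
  1 - acos(pmin(pmax(C, -1), 1)) / pi
}

#' Similarity-weighted k-nearest-neighbour graph
#'
#' Connects each item to its `k` most angularly similar neighbours
#' (exact search), weights edges by the similarity, drops edges below
#' `min_similarity`, and symmetrizes by union.
#'
#' @param embeddings Numeric matrix, one row per item; row names become
#'   vertex names.
#' @param k Number of neighbours (must be < number of items).
#' @param min_similarity Edges below this angular similarity are dropped.
#' @return Weighted undirected [igraph::graph] on all items.
#' @export
knn_similarity_graph <- function(embeddings, k = 15L, min_similarity = 0.9) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (k >= n) stop("k must be smaller than the number of items")
  S <- angular_similarity_matrix(embeddings)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(k)]
    keep <- s[nb] >= min_similarity
    ii <- c(ii, rep(i, sum(keep)))
    jj <- c(jj, nb[keep])
    ww <- c(ww, s[nb[keep]])
  }
  ids <- rownames(embeddings)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(ii) > 0L) {
    key <- paste(pmin(ii, jj), pmax(ii, jj))
    first <- !duplicated(key)
    g <- igraph::add_edges(g, rbind(ii[first], jj[first]),
                           weight = ww[first])
  }
  g
}

#' Leiden clustering of a weighted graph
#'
#' Deterministic for a fixed seed: the random number generator is reset and
#' seeded before each run.  Cluster labels are contiguous from 0 in order of
#' first appearance; vertices in size-1 clusters are flagged as singletons
#' (and are excluded by the downstream purity/co-clustering statistics).
#'
#' @param graph Weighted [igraph::graph].
#' @param resolution Leiden resolution parameter (modularity objective).
#' @param seed Integer RNG seed.
#' @param n_iterations Leiden refinement iterations.
#' @return Object of class `cluster_assignment`: data frame with columns
#'   `item`, `cluster`, `is_singleton`.
#' @export
leiden_clusters <- function(graph, resolution = 0.9, seed = 1L,
                            n_iterations = 3L) {
  n <- igraph::vcount(graph)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0L) {
    return(structure(data.frame(item = character(), cluster = integer(),
                                is_singleton = logical()),
                     class = c("cluster_assignment", "data.frame")))
  }
  set.seed(seed)
  memb <- if (igraph::ecount(graph) > 0L) {
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(graph)$weight,
                                 n_iterations = n_iterations)
    igraph::membership(cl)
  } else {
    seq_len(n)
  }
  lab <- match(memb, unique(memb)) - 1L
  size <- table(lab)
  structure(data.frame(item = ids, cluster = as.integer(lab),
                       is_singleton = as.integer(size[as.character(lab)]) == 1L,
                       stringsAsFactors = FALSE),
            class = c("cluster_assignment", "data.frame"))
}

#' Information-gain-ratio purity of a clustering
#'
#' `I = (H_background - sum_i H_i w_i) / H_background` with base-2
#' entropies.  Cluster entropies `H_i` use labeled members only; the cluster
#' weights `w_i` use full cluster sizes including unlabeled members,
#' normalized over all clustered (non-singleton) items.  The background is
#' either the label distribution of a single cluster holding everything
#' (`"single_cluster"`, the taxonomy mode) or a supplied category profile
#' (`"profile"`, the function mode).
#'
#' @param assignment A [leiden_clusters()] result (singletons are dropped).
#' @param labels Per-item labels aligned with `assignment$item`; NA marks
#'   unlabeled items.
#' @param background `"single_cluster"` or `"profile"`.
#' @param profile Named nonnegative weights per category (profile mode).
#' @return Object of class `purity_result`: list with `I`, `H_background`,
#'   and per-cluster `H` and `w`.
#' @export
purity <- function(assignment, labels,
                   background = c("single_cluster", "profile"),
                   profile = NULL) {
  background <- match.arg(background)
  stopifnot(length(labels) == nrow(assignment))
  keep <- !assignment$is_singleton
  cl <- assignment$cluster[keep]
  lab <- labels[keep]
  if (length(cl) == 0L || !any(!is.na(lab))) {
    stop("purity needs at least one labeled item in a cluster")
  }
  entropy2 <- function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log2(p))
  }
  H_bg <- if (background == "single_cluster") {
    entropy2(table(lab[!is.na(lab)]))
  } else {
    if (is.null(profile)) stop("profile background requires a profile")
    entropy2(profile)
  }
  if (H_bg == 0) stop("background entropy is zero; purity is undefined")
  clusters <- sort(unique(cl))
  n_i <- as.numeric(table(factor(cl, levels = clusters)))
  H_i <- vapply(clusters, function(k) {
    lk <- lab[cl == k]
    lk <- lk[!is.na(lk)]
    if (length(lk) == 0L) 0 else entropy2(table(lk))
  }, numeric(1))
  w_i <- n_i / sum(n_i)
  structure(list(I = (H_bg - sum(H_i * w_i)) / H_bg, H_background = H_bg,
                 H = H_i, w = w_i, cluster = clusters),
            class = "purity_result")
}

#' @export
print.purity_result <- function(x, ...) {
  cat(sprintf("purity I = %.4f over %d clusters (H_background = %.4f)\n",
              x$I, length(x$cluster), x$H_background))
  invisible(x)
}

#' Rescale pooling attention by KL divergence from uniform
#'
#' Per-genome attention vectors sum to one regardless of genome size, so raw
#' values are not comparable across genomes.  Each genome's attention is
#' rescaled by `D = (H_uniform - H(A)) / H_uniform` (base-2 entropies,
#' `H_uniform = log2(n)`), the normalized KL divergence from the uniform
#' distribution, which down-weights misleadingly large attention values that
#' are in fact uniformly spread.  A one-protein genome gets `D = 0` by
#' convention.
#'
#' @param A Numeric attention vector of one genome (nonnegative, summing to
#'   one), or a list of such vectors.
#' @return For a single vector: list with `A`, `D` and `A_prime = A * D`.
#'   For a list input: list of such results.
#' @examples
#' attention_rescale(c(0.5, 0.3, 0.05, 0.15))$A_prime
#' @export
attention_rescale <- function(A) {
  if (is.list(A)) return(lapply(A, attention_rescale))
  if (any(A < 0)) stop("attention values must be nonnegative")
  if (abs(sum(A) - 1) > 1e-6) stop("attention of a genome must sum to 1")
  n <- length(A)
  if (n == 1L) {
    return(list(A = A, D = 0, A_prime = A * 0))
  }
  p <- A[A > 0]
  H <- -sum(p * log2(p))
  D <- (log2(n) - H) / log2(n)
  list(A = A, D = D, A_prime = A * D)
}

#' Top attended proteins per functional category
#'
#' Rescaled attention values are first normalized per model by the model's
#' maximum (so the maximum is exactly 1), then the `top_n` proteins of each
#' category are selected by the normalized value (full-sort selection).
#'
#' @param scores Data frame with columns `protein_id`, `model`, `category`,
#'   `value` (rescaled attention).
#' @param top_n Number of proteins kept per (model, category).
#' @return Data frame of the selected rows with an added `norm_value`
#'   column, ordered by model, category, decreasing value.
#' @export
top_attended <- function(scores, top_n = 1000L) {
  stopifnot(all(c("protein_id", "model", "category", "value") %in%
                  names(scores)))
  mx <- tapply(scores$value, scores$model, max)
  scores$norm_value <- scores$value / as.numeric(mx[scores$model])
  parts <- split(scores, list(scores$model, scores$category), drop = TRUE)
  out <- lapply(parts, function(df) {
    df[order(-df$norm_value, df$protein_id), , drop = FALSE][
      seq_len(min(top_n, nrow(df))), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotation-transfer improvement curve
#'
#' For each hypothetical (unannotated) protein, its `k` nearest neighbours
#' by angular similarity (self excluded) are examined.  In mode `"any"` the
#' protein counts as improved if any neighbour is annotated; in mode
#' `"same_category"` it counts if at least one neighbour is annotated and
#' all annotated neighbours share a single category (unannotated neighbours
#' never penalize the score).  `AP_k = T_k / N_H`.
#'
#' @param embeddings Protein embedding matrix.
#' @param categories Per-protein category labels; NA marks unannotated
#'   (hypothetical) proteins.
#' @param k_max Largest neighbourhood size evaluated.
#' @param mode `"any"` or `"same_category"`.
#' @return Data frame with columns `k`, `T_k`, `AP_k`.
#' @export
annotation_improvement <- function(embeddings, categories, k_max = 10L,
                                   mode = c("any", "same_category")) {
  mode <- match.arg(mode)
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  stopifnot(length(categories) == n)
  hyp <- which(is.na(categories))
  if (length(hyp) == 0L) stop("no hypothetical proteins to score")
  k_max <- min(k_max, n - 1L)
  S <- angular_similarity_matrix(embeddings)
  out <- data.frame(k = seq_len(k_max), T_k = 0L, AP_k = 0)
  nb_order <- lapply(hyp, function(i) {
    s <- S[i, ]
    s[i] <- -Inf
    order(s, decreasing = TRUE)[seq_len(k_max)]
  })
  for (k in seq_len(k_max)) {
    hits <- vapply(nb_order, function(nb) {
      cats <- categories[nb[seq_len(k)]]
      ann <- cats[!is.na(cats)]
      if (mode == "any") length(ann) > 0L
      else length(ann) > 0L && length(unique(ann)) == 1L
    }, logical(1))
    out$T_k[k] <- sum(hits)
  }
  out$AP_k <- out$T_k / length(hyp)
  out
}

#' Functional co-clustering enrichment network
#'
#' Within each protein cluster the co-occurrence of two categories is the
#' product of their member counts, `C_i^{uv} = n_i^u * n_i^v`, summed over
#' clusters to `C^{uv}`.  The enrichment `E^{uv}` compares the observed
#' pair distribution against the background pair distribution built the
#' same way from the relative abundances of the annotation profiles (both
#' sides normalized over the pair set, so a cluster composition that is an
#' exact scaled copy of the background yields `E = 1` everywhere).  The
#' enrichment graph is clustered with Leiden at resolution 1.25.
#'
#' @param assignment A [leiden_clusters()] result (singletons dropped).
#' @param categories Per-item category labels aligned with
#'   `assignment$item`; NA and `"unknown"` are excluded.
#' @param background_profile Named nonnegative weights per category (e.g.
#'   annotation-database profile counts).
#' @param resolution Leiden resolution for the enrichment communities.
#' @param seed RNG seed for the community step.
#' @return List with `edges` (data frame `u`, `v`, `C`, `E`, `infinite`)
#'   and `communities` (per-category community id).
#' @export
cooccurrence_enrichment <- function(assignment, categories,
                                    background_profile, resolution = 1.25,
                                    seed = 1L) {
  stopifnot(length(categories) == nrow(assignment))
  keep <- !assignment$is_singleton & !is.na(categories) &
    categories != "unknown"
  cl <- assignment$cluster[keep]
  cat_ <- as.character(categories[keep])
  cats <- sort(unique(c(cat_, names(background_profile))))
  cats <- setdiff(cats, "unknown")
  K <- length(cats)
  if (K < 2L) stop("need at least two annotated categories")
  C <- matrix(0, K, K, dimnames = list(cats, cats))
  for (k in unique(cl)) {
    counts <- table(factor(cat_[cl == k], levels = cats))
    C <- C + outer(as.numeric(counts), as.numeric(counts))
  }
  p <- rep(0, K); names(p) <- cats
  bp <- background_profile[names(background_profile) != "unknown"]
  p[names(bp)] <- as.numeric(bp) / sum(bp)
  B <- outer(p, p)
  ut <- upper.tri(C)
  Cn <- if (sum(C[ut]) > 0) C[ut] / sum(C[ut]) else C[ut]
  Bn <- if (sum(B[ut]) > 0) B[ut] / sum(B[ut]) else B[ut]
  E <- ifelse(Bn > 0, Cn / Bn, ifelse(Cn > 0, Inf, 0))
  idx <- which(ut, arr.ind = TRUE)
  edges <- data.frame(u = cats[idx[, 1L]], v = cats[idx[, 2L]],
                      C = C[ut], E = E, infinite = is.infinite(E),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE,
                                     vertices = data.frame(name = cats))
  wfin <- ifelse(is.finite(edges$E), edges$E, max(edges$E[is.finite(edges$E)],
                                                  1))
  g <- igraph::set_edge_attr(g, "weight", value = wfin)
  set.seed(seed)
  cl_out <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   weights = igraph::E(g)$weight)
  list(edges = edges,
       communities = stats::setNames(as.integer(igraph::membership(cl_out)),
                                     cats))
}

#' Detect functional modules among protein clusters
#'
#' A cluster represents a functional module when all of its annotated
#' members (proteins of unknown function are ignored) fall inside the
#' module's category set and at least two distinct module categories are
#' present.
#'
#' @param assignment A [leiden_clusters()] result (singletons dropped).
#' @param categories Per-item category labels aligned with
#'   `assignment$item`; NA / `"unknown"` are ignored.
#' @param module Character vector of category names defining the module
#'   (e.g. the late-gene or DNA-interacting sets).
#' @return List with `clusters` (data frame `cluster`, `flagged`) and
#'   `proportion` (fraction of clusters flagged).
#' @export
detect_modules <- function(assignment, categories, module) {
  stopifnot(length(categories) == nrow(assignment))
  keep <- !assignment$is_singleton
  cl <- assignment$cluster[keep]
  cat_ <- as.character(categories[keep])
  cat_[cat_ %in% "unknown"] <- NA
  clusters <- sort(unique(cl))
  flagged <- vapply(clusters, function(k) {
    ann <- cat_[cl == k]
    ann <- ann[!is.na(ann)]
    length(ann) > 0L && all(ann %in% module) &&
      length(unique(ann)) >= 2L
  }, logical(1))
  list(clusters = data.frame(cluster = clusters, flagged = flagged),
       proportion = if (length(clusters)) mean(flagged) else 0)
}

#' Curated functional-category vocabularies
#'
#' The curated PHROG (12-category) and VOG (9-category) schemes ship as
#' editable TSV resources under `inst/extdata/`; this loader returns them
#' as data frames (`category`, `description`).
#'
#' @param scheme `"phrog"` or `"vog"`.
#' @return Data frame of category names and descriptions.
#' @export
category_scheme <- function(scheme = c("phrog", "vog")) {
  scheme <- match.arg(scheme)
  path <- system.file("extdata", paste0(scheme, "_categories.tsv"),
                      package = "genomeset")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Preset functional-module category sets
#'
#' Late-gene and DNA-interacting module definitions for the curated PHROG
#' (13-category) and VOG (9-category) schemes.
#'
#' @param module `"late_gene"` or `"dna_interacting"`.
#' @param scheme `"phrog"` or `"vog"`.
#' @return Character vector of category names.
#' @export
module_categories <- function(module = c("late_gene", "dna_interacting"),
                              scheme = c("phrog", "vog")) {
  module <- match.arg(module)
  scheme <- match.arg(scheme)
  sets <- list(
    phrog = list(
      late_gene = c("tail", "head and packaging", "connector", "lysis"),
      dna_interacting = c("nucleotide metabolism", "lysogeny",
                          "gene expression")),
    vog = list(
      late_gene = c("structural", "exit", "packaging"),
      dna_interacting = c("replication", "integration", "packaging",
                          "gene expression")))
  sets[[scheme]][[module]]
}

#' Harmonic aggregate of identity and shared-gene fraction
#'
#' `2xy / (x + y)` with `x` the mean pairwise identity (amino-acid or
#' structural) and `y` the smaller of the two genomes' shared-gene
#' fractions; 0 when both terms are 0.
#'
#' @param mean_identity Identity in \[0, 1\].
#' @param shared_fraction_a,shared_fraction_b Shared-gene fractions of the
#'   two genomes.
#' @return Scalar in \[0, 1\].
#' @export
harmonic_pair_score <- function(mean_identity, shared_fraction_a,
                                shared_fraction_b) {
  y <- pmin(shared_fraction_a, shared_fraction_b)
  x <- mean_identity
  ifelse(x + y == 0, 0, 2 * x * y / (x + y))
}

#' Dice similarity of two presence profiles
#'
#' `2 |v_i . v_j| / (|v_i| + |v_j|)` over binary protein-cluster presence
#' vectors.
#'
#' @param v_i,v_j Logical or 0/1 vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
dice_similarity <- function(v_i, v_j) {
  v_i <- as.logical(v_i); v_j <- as.logical(v_j)
  a <- sum(v_i); b <- sum(v_j)
  if (a + b == 0) stop("dice similarity of two empty profiles")
  2 * sum(v_i & v_j) / (a + b)
}

dice_matrix <- function(presence) {
  P <- (as.matrix(presence) > 0) * 1
  shared <- tcrossprod(P)
  sizes <- rowSums(P)
  denom <- outer(sizes, sizes, "+")
  S <- ifelse(denom > 0, 2 * shared / denom, 0)
  diag(S) <- ifelse(sizes > 0, 1, 0)
  S
}

#' Greedy protein-diversity cross-validation groups
#'
#' Genomes are linked when their protein-cluster presence profiles have dice
#' similarity at or above `threshold`; the connected components of that
#' graph are the unit of grouping.  The `n_groups` largest components seed
#' the groups; the remaining components enter per-seed priority queues
#' ordered by their mean dice similarity to the seed and are popped in
#' round-robin fashion (skipping components already taken).  Genomes sharing
#' no protein cluster with any other genome are appended to the smallest
#' group.
#'
#' @param presence Binary genome x protein-cluster matrix (row names are
#'   genome ids).
#' @param n_groups Number of groups (default 4).
#' @param threshold Dice threshold for the component graph.
#' @return Integer group id per genome, named by genome id.
#' @export
protein_diversity_groups <- function(presence, n_groups = 4L,
                                     threshold = 0.5) {
  P <- (as.matrix(presence) > 0) * 1
  n <- nrow(P)
  ids <- rownames(P)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  S <- dice_matrix(P)
  isolated <- which(rowSums((P %*% t(P) > 0)) <= 1)  # share nothing non-self
  adj <- S >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  comp[isolated] <- NA
  comps <- sort(unique(comp[!is.na(comp)]))
  if (length(comps) < n_groups) {
    stop("fewer connected components than requested groups")
  }
  members <- lapply(comps, function(k) which(comp == k))
  sizes <- lengths(members)
  seeds <- order(-sizes, comps)[seq_len(n_groups)]
  mean_dice_to <- function(a, b) mean(S[a, b, drop = FALSE])
  group_of_comp <- rep(NA_integer_, length(comps))
  group_of_comp[seeds] <- seq_len(n_groups)
  queues <- lapply(seeds, function(s) {
    others <- setdiff(seq_along(comps), seeds)
    sim <- vapply(others, function(o) mean_dice_to(members[[s]],
                                                   members[[o]]), numeric(1))
    others[order(-sim, others)]
  })
  taken <- rep(FALSE, length(comps))
  taken[seeds] <- TRUE
  repeat {
    progressed <- FALSE
    for (gix in seq_len(n_groups)) {
      q <- queues[[gix]]
      while (length(q) > 0L && taken[q[1L]]) q <- q[-1L]
      if (length(q) > 0L) {
        pick <- q[1L]
        q <- q[-1L]
        taken[pick] <- TRUE
        group_of_comp[pick] <- gix
        progressed <- TRUE
      }
      queues[[gix]] <- q
    }
    if (!progressed) break
  }
  groups <- rep(NA_integer_, n)
  for (k in seq_along(comps)) groups[members[[k]]] <- group_of_comp[k]
  if (any(is.na(groups))) {
    gsizes <- tabulate(groups[!is.na(groups)], n_groups)
    groups[is.na(groups)] <- which.min(gsizes)
  }
  stats::setNames(groups, ids)
}

#' Tetranucleotide frequency vector of a genome
#'
#' Counts overlapping 4-mers over the canonical ACGT alphabet (U is read as
#' T; any other character is removed before counting, so counts span the
#' junctions of removed characters) and normalizes them to frequencies.
#' Multi-scaffold genomes average the per-scaffold vectors.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] with one
#'   entry per scaffold.
#' @return Named numeric vector of length 256 (AAAA ... TTTT) summing to 1.
#' @export
tetranucleotide_frequencies <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0L) stop("no scaffolds given")
  per <- lapply(sequences, function(s) {
    s <- toupper(s)
    s <- chartr("U", "T", s)
    s <- gsub("[^ACGT]", "", s)
    if (nchar(s) < 4L) stop("no valid 4-mer after filtering")
    counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                   width = 4L)
    counts / sum(counts)
  })
  Reduce(`+`, per) / length(per)
}
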