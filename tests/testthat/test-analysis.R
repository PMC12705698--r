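# Embedding evaluation statistics: similarity, clustering, purity,
# attention rescaling, annotation transfer, enrichment, modules, identity
# aggregation, dice grouping and the tetranucleotide baseline.

test_that("angular similarity hits its closed-form anchors", {
  u <- c(1, 2, 3)
  expect_equal(angular_similarity(u, u), 1)
  expect_equal(angular_similarity(u, 2 * u), 1)
  expect_equal(angular_similarity(c(1, 0), c(0, 1)), 0.5)
  expect_equal(angular_similarity(u, -u), 0)
  expect_error(angular_similarity(u, c(0, 0, 0)), "zero vector")
})

test_that("kNN similarity graphs match exhaustive search", {
  # three identical points, k = 2 -> complete graph with weight 1
  E <- rbind(c(1, 1), c(1, 1), c(1, 1))
  g <- knn_similarity_graph(E, k = 2, min_similarity = 0.9)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::E(g)$weight, rep(1, 3))
  expect_error(knn_similarity_graph(E, k = 3), "smaller")

  # two well-separated blobs leave no cross-blob edges at threshold 0.9
  set.seed(1)
  blob1 <- matrix(rnorm(40, mean = 5, sd = 0.05), 20, 2)
  blob2 <- cbind(rnorm(20, -5, 0.05), rnorm(20, 5, 0.05))
  g2 <- knn_similarity_graph(rbind(blob1, blob2), k = 5,
                             min_similarity = 0.9)
  el <- igraph::as_edgelist(g2, names = FALSE)
  expect_false(any((el[, 1] <= 20) != (el[, 2] <= 20)))

  # neighbour sets match brute force on 200 random points
  set.seed(2)
  X <- matrix(rnorm(200 * 4), 200, 4)
  k <- 6
  g3 <- knn_similarity_graph(X, k = k, min_similarity = 0)
  S <- 1 - acos(pmin(pmax(tcrossprod(X / sqrt(rowSums(X^2))), -1), 1)) / pi
  el3 <- igraph::as_edgelist(g3, names = FALSE)
  key <- paste(pmin(el3[, 1], el3[, 2]), pmax(el3[, 1], el3[, 2]))
  for (i in sample(200, 25)) {
    s <- S[i, ]; s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(k)]
    expect_true(all(paste(pmin(i, nb), pmax(i, nb)) %in% key))
  }
})

test_that("Leiden clustering is seeded, flags singletons and recovers plants", {
  g <- igraph::make_graph(c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6), directed = FALSE)
  igraph::E(g)$weight <- 1
  cl <- leiden_clusters(g, seed = 42)
  expect_identical(length(unique(cl$cluster)), 2L)
  expect_identical(min(cl$cluster), 0L)
  expect_false(any(cl$is_singleton))
  cl2 <- leiden_clusters(g, seed = 42)
  expect_identical(cl$cluster, cl2$cluster)

  skip_if_not_installed("mclust")
  set.seed(3)
  centers <- rbind(diag(8, 4), rep(4, 4))  # five well-separated directions
  X <- centers[rep(1:5, each = 12), ] + matrix(rnorm(60 * 4, sd = 0.3), 60, 4)
  gg <- knn_similarity_graph(X, k = 15, min_similarity = 0.9)
  cl3 <- leiden_clusters(gg, resolution = 0.9, seed = 7)
  ari <- mclust::adjustedRandIndex(cl3$cluster, rep(1:5, each = 12))
  expect_gte(ari, 0.95)
})

# Independent loop oracle for the information gain ratio.
purity_oracle <- function(cl, labels, bg_counts) {
  ent <- function(x) {
    p <- x[x > 0] / sum(x); -sum(p * log2(p))
  }
  H_bg <- ent(bg_counts)
  tot <- length(cl)
  val <- 0
  for (k in unique(cl)) {
    lab <- labels[cl == k]
    w <- length(lab) / tot
    lab <- lab[!is.na(lab)]
    H <- if (length(lab)) ent(table(lab)) else 0
    val <- val + w * H
  }
  (H_bg - val) / H_bg
}

test_that("clustering purity follows the entropy-ratio definition", {
  mk <- function(cl) {
    structure(data.frame(item = as.character(seq_along(cl)), cluster = cl,
                         is_singleton = FALSE),
              class = c("cluster_assignment", "data.frame"))
  }
  # every cluster single-label -> I = 1
  p1 <- purity(mk(c(0, 0, 1, 1)), c("A", "A", "B", "B"))
  expect_equal(p1$I, 1)
  # one cluster holding everything -> I = 0
  p0 <- purity(mk(rep(0, 4)), c("A", "A", "B", "B"))
  expect_equal(p0$I, 0)
  # hand-computed mixed case with a profile background
  cl <- c(0, 0, 0, 1, 1)
  lab <- c("A", "A", "B", "B", "B")
  pr <- purity(mk(cl), lab, background = "profile",
               profile = c(A = 2, B = 3))
  expect_equal(pr$I, purity_oracle(cl, lab, c(2, 3)), tolerance = 1e-12)
  expect_equal(sum(pr$w), 1)
  # unlabeled members weight clusters but stay out of the entropy
  lab2 <- c("A", "A", NA, "B", "B")
  pr2 <- purity(mk(cl), lab2)
  expect_equal(pr2$I, purity_oracle(cl, lab2, table(lab2[!is.na(lab2)])),
               tolerance = 1e-12)
  # pure background is undefined
  expect_error(purity(mk(c(0, 0, 1, 1)), rep("A", 4)), "undefined|zero")
  # singletons are excluded before anything else
  asn <- mk(c(0, 0, 1, 1, 2))
  asn$is_singleton[5] <- TRUE
  pr3 <- purity(asn, c("A", "A", "B", "B", "C"))
  expect_equal(pr3$I, 1)
})

test_that("attention rescaling reproduces the printed worked example", {
  r <- attention_rescale(c(0.5, 0.3, 0.05, 0.15))
  expect_equal(round(r$A_prime, 4), c(0.0881, 0.0528, 0.0088, 0.0264))
  r2 <- attention_rescale(c(0.5, 0.5))
  expect_equal(r2$A_prime, c(0, 0))
  # one-hot attention is maximally informative: D = 1
  r3 <- attention_rescale(c(0, 0, 1, 0))
  expect_equal(r3$D, 1)
  expect_equal(r3$A_prime, c(0, 0, 1, 0))
  # single-protein genomes get D = 0 by convention
  expect_equal(attention_rescale(1)$D, 0)
  expect_error(attention_rescale(c(-0.1, 1.1)), "nonnegative")
  expect_error(attention_rescale(c(0.2, 0.2)), "sum to 1")
})

test_that("top attended selection max-normalizes per model and sorts", {
  set.seed(4)
  df <- data.frame(protein_id = sprintf("p%02d", 1:40),
                   model = rep(c("m1", "m2"), each = 20),
                   category = rep(c("tail", "head"), 20),
                   value = runif(40))
  out <- top_attended(df, top_n = 5)
  expect_equal(max(out$norm_value), 1)
  for (m in c("m1", "m2")) {
    expect_equal(max(out$norm_value[out$model == m]),
                 max(df$value[df$model == m]) / max(df$value[df$model == m]))
    for (cc in c("tail", "head")) {
      sel <- df[df$model == m & df$category == cc, ]
      want <- sel$protein_id[order(-sel$value)][1:5]
      expect_setequal(out$protein_id[out$model == m & out$category == cc],
                      want)
    }
  }
  # fewer proteins than top_n -> all returned
  out2 <- top_attended(df[1:3, ], top_n = 1000)
  expect_identical(nrow(out2), 3L)
})

test_that("annotation transfer scoring honours both hit modes", {
  # geometry: each hypothetical protein's nearest neighbour is annotated
  E <- rbind(c(1, 0), c(1, 0.01), c(0, 1), c(0.01, 1))
  cats <- c("structural", NA, "replication", NA)
  any1 <- annotation_improvement(E, cats, k_max = 1, mode = "any")
  expect_equal(any1$AP_k, 1)
  # {unknown, structural, unknown, structural} counts as a same-category hit
  E2 <- rbind(c(1, 0), c(1, 0.01), c(1, 0.02), c(1, 0.03), c(1, 0.04))
  c2 <- c(NA, NA, "structural", NA, "structural")
  sc <- annotation_improvement(E2, c2, k_max = 4, mode = "same_category")
  expect_equal(sc$AP_k[4], 1)
  # {structural, replication} among the neighbours is not a hit
  E3 <- rbind(c(1, 0), c(1, 0.01), c(1, 0.02))
  sc3 <- annotation_improvement(E3, c(NA, "structural", "replication"),
                                k_max = 2, mode = "same_category")
  expect_equal(sc3$AP_k[2], 0)
  expect_error(annotation_improvement(E, rep("x", 4), 2), "hypothetical")
  # AP_k is monotone non-decreasing in k for mode = any
  set.seed(5)
  for (rep in 1:10) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    cc <- sample(c("a", "b", NA), 30, replace = TRUE)
    if (!any(is.na(cc)) || all(is.na(cc))) next
    ap <- annotation_improvement(X, cc, k_max = 8, mode = "any")$AP_k
    expect_true(all(diff(ap) >= -1e-12))
  }
})

test_that("co-clustering enrichment compares against the profile background", {
  mk <- function(cl) {
    structure(data.frame(item = as.character(seq_along(cl)), cluster = cl,
                         is_singleton = FALSE),
              class = c("cluster_assignment", "data.frame"))
  }
  # cluster with 2 tail + 3 head contributes 6 to C[tail, head]
  cl <- c(rep(0, 5), rep(1, 4))
  cats <- c(rep("tail", 2), rep("head", 3), rep("tail", 2), rep("head", 2))
  en <- cooccurrence_enrichment(mk(cl), cats, c(tail = 1, head = 1))
  e_th <- en$edges[en$edges$u == "head" & en$edges$v == "tail" |
                     en$edges$u == "tail" & en$edges$v == "head", ]
  expect_equal(e_th$C, 2 * 3 + 2 * 2)
  # composition proportional to the background -> E = 1 everywhere
  cl2 <- rep(0:2, each = 6)
  cats2 <- rep(c("tail", "tail", "head", "head", "lysis", "lysis"), 3)
  en2 <- cooccurrence_enrichment(mk(cl2), cats2,
                                 c(tail = 10, head = 10, lysis = 10))
  expect_equal(en2$edges$E, rep(1, 3), tolerance = 1e-12)
  # single-category clusters have no off-diagonal co-occurrence
  cl3 <- rep(0:1, each = 3)
  cats3 <- rep(c("tail", "head"), each = 3)
  en3 <- cooccurrence_enrichment(mk(cl3), cats3, c(tail = 1, head = 1))
  expect_equal(en3$edges$C, 0)
  # unknown-function proteins are excluded
  en4 <- cooccurrence_enrichment(mk(cl), c(cats[-9], "unknown"),
                                 c(tail = 1, head = 1, unknown = 99))
  expect_false("unknown" %in% c(en4$edges$u, en4$edges$v))
})

test_that("functional module detection requires purity and two categories", {
  mk <- function(cl) {
    structure(data.frame(item = as.character(seq_along(cl)), cluster = cl,
                         is_singleton = FALSE),
              class = c("cluster_assignment", "data.frame"))
  }
  late <- module_categories("late_gene", "phrog")
  # {tail, head and packaging, unknown} -> flagged (unknowns ignored)
  d1 <- detect_modules(mk(rep(0, 3)),
                       c("tail", "head and packaging", "unknown"), late)
  expect_true(d1$clusters$flagged)
  # a single category is not a module
  d2 <- detect_modules(mk(rep(0, 2)), c("tail", "tail"), late)
  expect_false(d2$clusters$flagged)
  # any annotated member outside the module disqualifies the cluster
  d3 <- detect_modules(mk(rep(0, 3)),
                       c("tail", "head and packaging",
                         "nucleotide metabolism"), late)
  expect_false(d3$clusters$flagged)
  d4 <- detect_modules(mk(c(0, 0, 1, 1)),
                       c("tail", "lysis", "tail", "other"), late)
  expect_equal(d4$proportion, 0.5)
})

test_that("harmonic pair scores and dice similarity evaluate exactly", {
  expect_equal(harmonic_pair_score(1, 1, 1), 1)
  expect_equal(harmonic_pair_score(0.8, 0.5, 0.9), 2 * 0.8 * 0.5 / 1.3)
  expect_equal(harmonic_pair_score(0.7, 0, 0.4), 0)
  expect_equal(harmonic_pair_score(0, 0, 0), 0)

  expect_equal(dice_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(dice_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(dice_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_error(dice_similarity(c(0, 0), c(0, 0)), "empty")
})

test_that("greedy diversity grouping follows the seed-and-pop rule", {
  # 4 components exactly -> each seeds its own group
  P <- matrix(0, 8, 4)
  P[1:2, 1] <- 1; P[3:4, 2] <- 1; P[5:6, 3] <- 1; P[7:8, 4] <- 1
  g <- protein_diversity_groups(P, n_groups = 4)
  expect_identical(length(unique(g)), 4L)
  expect_true(all(table(g) == 2))

  # 5 components with hand-set similarities: the largest component seeds
  # group 1 and pops first in the round-robin, so the probe genome E (mean
  # dice 0.4 to A, 0 elsewhere, below the 0.5 component threshold) must
  # join A's group.
  P2 <- matrix(0, 10, 9)
  P2[1:3, 1] <- 1; P2[1:3, 5] <- 1      # A: 3 genomes, clusters 1+5
  P2[4:5, 2] <- 1; P2[4:5, 6] <- 1      # B
  P2[6:7, 3] <- 1; P2[8:9, 4] <- 1      # C, D
  P2[10, c(5, 7, 9)] <- 1               # E: weakly tied to A only
  g2 <- protein_diversity_groups(P2, n_groups = 4, threshold = 0.5)
  expect_equal(unname(g2[10]), unname(g2[1]))
  expect_identical(sort(unique(as.integer(g2))), 1:4)
  expect_identical(length(g2), 10L)

  # isolated genomes land in the smallest group
  P3 <- rbind(P, 0)
  g3 <- protein_diversity_groups(P3, n_groups = 4)
  expect_identical(length(g3), 9L)
  expect_false(any(is.na(g3)))
  expect_error(protein_diversity_groups(P[1:4, ], n_groups = 4), "fewer")
})

test_that("tetranucleotide vectors count overlapping filtered 4-mers", {
  f <- tetranucleotide_frequencies("AAAA")
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f), 1)
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
             collapse = "")
  counts <- tetranucleotide_frequencies(s)
  expect_equal(sum(counts > 0 | counts == 0), 256)
  # a length-L clean sequence has L - 3 windows
  raw <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), 4)
  expect_equal(sum(raw), 97)
  # non-ACGT characters are removed before counting
  dirty <- "AANA CGTxU"
  clean <- "AAACGTT"   # U -> T, others dropped
  expect_equal(tetranucleotide_frequencies(dirty),
               tetranucleotide_frequencies(clean))
  # multi-scaffold genomes average per-scaffold vectors
  two <- tetranucleotide_frequencies(c("AAAA", "CCCC"))
  expect_equal(unname(two[c("AAAA", "CCCC")]), c(0.5, 0.5))
  expect_error(tetranucleotide_frequencies("AAN"), "4-mer")
})

test_that("shipped category vocabularies load and cover the module presets", {
  ph <- category_scheme("phrog")
  vo <- category_scheme("vog")
  expect_true(all(c("category", "description") %in% names(ph)))
  expect_true(all(module_categories("late_gene", "phrog") %in% ph$category))
  expect_true(all(module_categories("dna_interacting", "vog") %in%
                    vo$category))
  expect_true("unknown" %in% ph$category)
  expect_identical(nrow(vo), 9L)
})
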