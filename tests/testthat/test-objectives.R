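# Training objectives: Chamfer distance, mining, PointSwap, triplet and
# masked losses, verified against brute-force oracles.

brute_chamfer <- function(X, Y) {
  a <- mean(sapply(seq_len(nrow(X)), function(i) {
    min(sapply(seq_len(nrow(Y)), function(j) sum((X[i, ] - Y[j, ])^2)))
  }))
  b <- mean(sapply(seq_len(nrow(Y)), function(j) {
    min(sapply(seq_len(nrow(X)), function(i) sum((Y[j, ] - X[i, ])^2)))
  }))
  a + b
}

test_that("Chamfer distance matches closed forms and brute force", {
  X <- matrix(c(0, 0), 1)
  Y <- matrix(c(3, 4), 1)
  expect_equal(chamfer_distance(X, Y), 50)            # 25 + 25
  X2 <- rbind(c(0, 0), c(1, 0))
  expect_equal(chamfer_distance(X2, X), 0.5)          # 0.5 + 0
  expect_equal(chamfer_distance(X2, X2), 0)
  expect_error(chamfer_distance(X2[0, , drop = FALSE], X), "nonempty")
  set.seed(4)
  for (rep in 1:10) {
    A <- matrix(rnorm(sample(1:30, 1) * 3), ncol = 3)
    B <- matrix(rnorm(sample(1:30, 1) * 3), ncol = 3)
    expect_equal(chamfer_distance(A, B), brute_chamfer(A, B),
                 tolerance = 1e-10)
    expect_equal(chamfer_distance(A, B), chamfer_distance(B, A))
    expect_gte(chamfer_distance(A, B), 0)
  }
})

test_that("positive mining finds the Chamfer-nearest non-self genome", {
  set.seed(8)
  # 4-genome toy batch vs an exhaustive O(N^2) oracle
  sizes <- c(3, 5, 4, 6)
  emb <- matrix(rnorm(sum(sizes) * 4), ncol = 4)
  gor <- rep(seq_along(sizes), sizes)
  mined <- mine_positive(emb, gor, 4L)
  for (i in 1:4) {
    cds <- sapply(1:4, function(j) {
      if (j == i) Inf else brute_chamfer(emb[gor == i, , drop = FALSE],
                                         emb[gor == j, , drop = FALSE])
    })
    expect_identical(mined$positive_idx[i], which.min(cds))
    expect_false(mined$positive_idx[i] == i)
  }
  # an exact duplicate of the anchor is always chosen (CD = 0)
  emb2 <- rbind(emb[gor == 1, ], emb[gor == 1, ], emb[gor == 2, ])
  gor2 <- rep(1:3, c(3, 3, 5))
  mined2 <- mine_positive(emb2, gor2, 3L)
  expect_identical(mined2$positive_idx[1], 2L)
  expect_identical(mined2$positive_idx[2], 1L)
  expect_error(mine_positive(emb[gor == 1, ], rep(1L, 3), 1L), "2 genomes")
})

test_that("semi-hard negative mining follows the farther-than-positive rule", {
  # embeddings on a line: distances from anchor 1 are 1 (pos), 2, 5
  XG <- cbind(c(0, 1, 2, 5), 0)
  expect_identical(mine_negative(XG, 1L, 2L), 3L)
  # fallback: positive farthest -> candidate closest to the positive distance
  XG2 <- cbind(c(0, 5, 1, 2), 0)
  expect_identical(mine_negative(XG2, 1L, 2L), 4L)
  expect_error(mine_negative(XG[1:2, ], 1L, 2L), "batch of 2")
  set.seed(9)
  for (rep in 1:20) {
    Z <- matrix(rnorm(12), 6, 2)
    a <- sample(6, 1); p <- sample(setdiff(1:6, a), 1)
    n <- mine_negative(Z, a, p)
    expect_false(n %in% c(a, p))
    d <- sqrt(colSums((t(Z) - Z[a, ])^2))
    if (any(d[-c(a, p)] > d[p])) expect_gt(d[n], d[p])
  }
})

test_that("negative weights decay exponentially with Chamfer distance", {
  expect_equal(negative_weight(0, 1, 2), 1)
  expect_equal(negative_weight(2 * (1 * 2)^2, 1, 2), exp(-1))
  expect_equal(negative_weight(5, 1, 0), 1)  # degenerate batch
  expect_error(negative_weight(1, 0, 1), "c must be")
  w <- negative_weight(seq(0, 10, by = 0.5), 1.5, 1)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
})

test_that("class weights are inverse abundance", {
  expect_equal(class_weights(c("A", "A", "A", "B")), c(4/3, 4/3, 4/3, 4))
  expect_equal(class_weights(rep("x", 5)), rep(1, 5))
  expect_equal(class_weights(NULL, 7), rep(1, 7))
  set.seed(2)
  lab <- sample(letters[1:4], 30, replace = TRUE)
  expect_equal(sum(class_weights(lab)), 30 * length(unique(lab)))
})

test_that("PointSwap replaces flowed rows at the requested rate", {
  set.seed(3)
  Xa <- matrix(rnorm(20), 5, 4)
  Xp <- matrix(rnorm(24), 6, 4)
  fl <- c(2L, 2L, 6L, 1L, 3L)
  expect_identical(pointswap(Xa, Xp, fl, 0), Xa)
  allswap <- pointswap(Xa, Xp, fl, 1)
  expect_identical(allswap, Xp[fl, ])
  u <- runif(5)
  out <- pointswap(Xa, Xp, fl, 0.5, u = u)
  swapped <- which(u < 0.5)
  expect_identical(out[swapped, , drop = FALSE],
                   Xp[fl[swapped], , drop = FALSE])
  expect_identical(out[-swapped, , drop = FALSE],
                   Xa[-swapped, , drop = FALSE])
  expect_error(pointswap(Xa, Xp, fl, 1.2), "rate")
})

test_that("triplet hinge terms evaluate as written", {
  f0 <- c(0, 0); fp <- c(1, 0); fn <- c(5, 0)
  # d2(a,p) = 1, omega d2(a,n) = 5, alpha = 2 -> hinge inactive
  expect_equal(triplet_term(f0, fp, c(5, 0), omega = 1/5, alpha = 2), 0)
  # d2(a,p) = 4, omega d2(a,n) = 1, alpha = 2 -> 5
  expect_equal(triplet_term(f0, c(2, 0), c(1, 0), omega = 1, alpha = 2), 5)
  expect_equal(triplet_term(f0, fp, fp, omega = 1, alpha = 3), 3)
})

test_that("minibatch triplet loss matches an explicit loop oracle", {
  set.seed(10)
  XG <- matrix(rnorm(16), 8, 2)   # 4 real + 4 augmented genomes
  tri <- list(anchor = 1:4, positive = c(2, 1, 4, 3),
              negative = c(3, 4, 1, 2), omega = runif(4))
  tria <- list(anchor = 1:4, positive = 5:8, negative = c(6, 7, 8, 5),
               omega = runif(4))
  cw <- c(1, 2, 1, 0.5)
  alpha <- 1.3
  loop <- 0
  for (i in 1:4) {
    h1 <- max(0, sum((XG[tri$anchor[i], ] - XG[tri$positive[i], ])^2) -
                tri$omega[i] * sum((XG[tri$anchor[i], ] -
                                      XG[tri$negative[i], ])^2) + alpha)
    h2 <- max(0, sum((XG[tria$anchor[i], ] - XG[tria$positive[i], ])^2) -
                tria$omega[i] * sum((XG[tria$anchor[i], ] -
                                       XG[tria$negative[i], ])^2) + alpha)
    loop <- loop + cw[i] * (h1 + h2)
  }
  loop <- loop / (2 * 4)
  expect_equal(triplet_loss(XG, tri, tria, cw, alpha), loop,
               tolerance = 1e-12)
  # the tape evaluation agrees with the numeric surface
  tp <- ad_tape()
  ref <- ad_const(tp, XG)
  tl <- genomeset:::tape_triplet_loss(ref, tri, tria, cw, alpha)
  expect_equal(as.vector(ad_value(tl)), loop, tolerance = 1e-12)
  # all hinges inactive -> zero
  expect_equal(triplet_loss(XG * 0, tri, tria, cw, alpha = 0), 0)
})

test_that("protein masking zeroes embeddings but keeps position and strand", {
  pset <- tiny_pset(n_genomes = 2L, proteins = 6L)
  cfg <- model_config(d_in = 8)
  b <- build_genome_batch(pset, cfg)
  set.seed(1)
  mk <- mask_proteins(b, 0.3)
  expect_true(length(mk$mask_index) >= 1)
  expect_true(all(mk$masked_embeddings[mk$mask_index, ] == 0))
  expect_identical(mk$masked_embeddings[-mk$mask_index, ],
                   b$embeddings[-mk$mask_index, ])
  # position/strand indices are untouched by masking
  expect_identical(b$pos_index, build_genome_batch(pset, cfg)$pos_index)
  expect_error(mask_proteins(b, 0), "p_mask")
  expect_error(mask_proteins(b, 1), "p_mask")
  # a vanishing rate still masks exactly one protein
  set.seed(2)
  mk2 <- mask_proteins(b, 1e-9)
  expect_identical(length(mk2$mask_index), 1L)
  # masked fraction concentrates around p_mask
  set.seed(3)
  fr <- replicate(1000, length(mask_proteins(b, 0.3)$mask_index) / 12)
  se <- sqrt(0.3 * 0.7 / 12) / sqrt(1000)
  expect_lt(abs(mean(fr) - 0.3), 3 * se + 1e-3)
})

test_that("positive substitution maps every protein to its nearest non-self neighbour", {
  # duplicated pair maps to each other
  E <- rbind(c(0, 0), c(0, 0), c(9, 9))
  sub <- positive_substitute(E)
  expect_identical(sub$neighbor[1:2], c(2L, 1L))
  set.seed(5)
  E2 <- matrix(rnorm(100), 50, 2)
  sub2 <- positive_substitute(E2)
  for (i in seq_len(50)) {
    d <- colSums((t(E2) - E2[i, ])^2)
    d[i] <- Inf
    expect_identical(sub2$neighbor[i], which.min(d))
  }
  expect_false(any(sub2$neighbor == seq_len(50)))
  expect_error(positive_substitute(E[1, , drop = FALSE]), "at least 2")
})

test_that("masked mean-squared-error loss averages the two error terms", {
  Yt <- matrix(c(0, 0), 1)
  expect_equal(mlm_loss(Yt, Yt, Yt), 0)
  expect_equal(mlm_loss(matrix(1), matrix(0), matrix(0)), 0.5)
  set.seed(6)
  Yp <- matrix(rnorm(8), 2, 4); Ys <- matrix(rnorm(8), 2, 4)
  Yt2 <- matrix(rnorm(8), 2, 4)
  base <- mlm_loss(Yp, Ys, Yt2)
  expect_equal(mlm_loss(rbind(Yp, Yp), rbind(Ys, Ys), rbind(Yt2, Yt2)),
               base)
  expect_error(mlm_loss(Yp[0, ], Ys[0, ], Yt2[0, ]), "masked")
})

test_that("planted duplicate batches are mined correctly in 100 seeded trials", {
  ok <- 0L
  for (trial in 1:100) {
    set.seed(trial)
    d <- 4L
    base <- matrix(rnorm(5 * d), 5, d)
    near <- base + matrix(rnorm(5 * d, sd = 0.01), 5, d)
    far <- matrix(rnorm(5 * d, mean = 30), 5, d)
    far2 <- matrix(rnorm(5 * d, mean = -30), 5, d)
    emb <- rbind(base, base, near, far, far2)  # genome 2 duplicates genome 1
    gor <- rep(1:5, each = 5)
    mined <- mine_positive(emb, gor, 5L)
    XG <- mean_protein_pool(emb, gor)  # any embedding space works here
    neg <- mine_negative(XG, 1L, mined$positive_idx[1])
    d_all <- sqrt(colSums((t(XG) - XG[1, ])^2))
    semi_ok <- if (any(d_all[-c(1, mined$positive_idx[1])] >
                         d_all[mined$positive_idx[1]])) {
      d_all[neg] > d_all[mined$positive_idx[1]]
    } else {
      TRUE
    }
    if (mined$positive_idx[1] == 2L && !neg %in% c(1L, mined$positive_idx[1]) &&
        semi_ok) {
      ok <- ok + 1L
    }
  }
  expect_identical(ok, 100L)
})
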