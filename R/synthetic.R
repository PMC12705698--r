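# Synthetic data: protein-embedding datasets with planted genome families,
# functional-category labels, nucleotide scaffolds, and virus-host
# interaction graphs.  The generator emulates the statistical structure the
# training objectives assume -- genomes sharing similar proteins are mutual
# Chamfer nearest neighbours -- without any language-model inference.

#' Specification of a synthetic embedding dataset
#'
#' Families are placed at the vertices of a scaled simplex in embedding
#' space, `family_separation` noise standard deviations apart.  Each family
#' owns `n_protein_clusters` protein-cluster centroids (family centre plus
#' a 2-SD within-family spread); a genome samples an ordered list of its
#' family's centroids, substituting a random same-family centroid at a 10%
#' rate so that genomes of one family share at least ~80% of their
#' centroids, and adds isotropic Gaussian noise.  Functional categories are
#' attached per centroid, with a configurable fraction left `"unknown"` to
#' mirror the 70-90% unannotated regime of real viromes.
#'
#' @param n_families Number of planted genome families.
#' @param genomes_per_family Genomes per family.
#' @param proteins_per_genome Length-2 range of per-genome protein counts.
#' @param d_in Embedding dimension.
#' @param n_protein_clusters Protein-cluster centroids per family.
#' @param family_separation Distance between family centres in units of
#'   `noise_sd`.
#' @param noise_sd Isotropic per-protein noise standard deviation.
#' @param unknown_fraction Fraction of centroids labelled `"unknown"`.
#' @param strand_flip Probability of switching strand between adjacent
#'   proteins.
#' @param n_scaffolds Scaffolds per genome (proteins split evenly).
#' @param seed RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 5L, genomes_per_family = 10L,
                           proteins_per_genome = c(5L, 30L), d_in = 16L,
                           n_protein_clusters = 15L, family_separation = 8,
                           noise_sd = 0.25, unknown_fraction = 0.7,
                           strand_flip = 0.1, n_scaffolds = 1L, seed = 1L) {
  stopifnot(n_families >= 1L, genomes_per_family >= 1L,
            all(proteins_per_genome >= 1L), d_in >= 2L,
            n_protein_clusters >= 1L, noise_sd >= 0,
            unknown_fraction >= 0, unknown_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Family centres on a scaled simplex: n unit vectors with equal pairwise
# distances, scaled to the requested separation.
simplex_centers <- function(n, d, separation) {
  stopifnot(d >= n - 1L)
  V <- diag(1, n, d)          # orthonormal corners, pairwise distance sqrt(2)
  V <- V - matrix(colMeans(V), n, d, byrow = TRUE)
  V * separation / sqrt(2)
}

#' Generate a synthetic protein-embedding dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pset` (a [protein_set()]), `genomes` (data frame
#'   `genome_id`, `family`), and `categories` (per-protein functional
#'   category, `"unknown"` where unannotated) plus `centroid_id` per
#'   protein.
#' @export
generate_embedding_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  vocab <- c("head and packaging", "tail", "connector", "lysis",
             "nucleotide metabolism", "lysogeny", "gene expression", "other")
  # separation is measured in noise standard deviations; with zero noise a
  # unit scale keeps the planted families distinct
  unit <- if (spec$noise_sd > 0) spec$noise_sd else 1
  centers <- simplex_centers(spec$n_families, spec$d_in,
                             spec$family_separation * unit)
  centroids <- vector("list", spec$n_families)
  centroid_cat <- vector("list", spec$n_families)
  for (f in seq_len(spec$n_families)) {
    centroids[[f]] <- matrix(stats::rnorm(spec$n_protein_clusters * spec$d_in,
                                          sd = 2 * spec$noise_sd),
                             spec$n_protein_clusters, spec$d_in) +
      matrix(centers[f, ], spec$n_protein_clusters, spec$d_in, byrow = TRUE)
    known <- stats::runif(spec$n_protein_clusters) >= spec$unknown_fraction
    centroid_cat[[f]] <- ifelse(known,
                                sample(vocab, spec$n_protein_clusters,
                                       replace = TRUE),
                                "unknown")
  }
  meta <- list(); emb <- list(); fam <- integer(); cats <- list()
  cent_ids <- list()
  gi <- 0L
  for (f in seq_len(spec$n_families)) {
    for (g in seq_len(spec$genomes_per_family)) {
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      n <- sample(seq(spec$proteins_per_genome[1L],
                      spec$proteins_per_genome[2L]), 1L)
      # ordered centroid walk with a 10% random same-family substitution
      base <- rep(seq_len(spec$n_protein_clusters), length.out = n)
      subst <- stats::runif(n) < 0.1
      base[subst] <- sample.int(spec$n_protein_clusters, sum(subst),
                                replace = TRUE)
      E <- centroids[[f]][base, , drop = FALSE] +
        matrix(stats::rnorm(n * spec$d_in, sd = spec$noise_sd), n, spec$d_in)
      # strand runs
      strand <- integer(n)
      strand[1L] <- sample(c(1L, -1L), 1L)
      for (j in seq_len(n - 1L)) {
        strand[j + 1L] <- if (stats::runif(1) < spec$strand_flip) {
          -strand[j]
        } else {
          strand[j]
        }
      }
      scaf <- sort(rep(seq_len(spec$n_scaffolds), length.out = n))
      pos <- positional_index(scaf)
      meta[[gi]] <- data.frame(
        protein_id = sprintf("%s_P%03d", gid, seq_len(n)),
        genome_id = gid,
        scaffold_id = sprintf("%s_S%d", gid, scaf),
        position = pos, strand = strand, stringsAsFactors = FALSE)
      emb[[gi]] <- E
      fam[gi] <- f
      cats[[gi]] <- centroid_cat[[f]][base]
      cent_ids[[gi]] <- sprintf("F%d_C%02d", f, base)
    }
  }
  meta <- do.call(rbind, meta)
  pset <- protein_set(meta, do.call(rbind, emb))
  list(pset = pset,
       genomes = data.frame(genome_id = unique(meta$genome_id),
                            family = fam, stringsAsFactors = FALSE),
       categories = unlist(cats), centroid_id = unlist(cent_ids))
}

#' Generate random nucleotide scaffolds
#'
#' Uniform i.i.d. ACGT sequences with optional N contamination, for the
#' tetranucleotide baseline.
#'
#' @param n Number of scaffolds.
#' @param length_range Length-2 range of scaffold lengths (each >= 4).
#' @param contamination Per-base probability of an N.
#' @param seed RNG seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
generate_nucleotide_scaffolds <- function(n, length_range = c(500L, 2000L),
                                          contamination = 0, seed = 1L) {
  stopifnot(all(length_range >= 4L))
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(seq(length_range[1L], length_range[2L]), 1L)
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (contamination > 0) {
      s[stats::runif(L) < contamination] <- "N"
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("scaffold_%04d", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Generate a planted virus-host interaction problem
#'
#' Host genome embeddings are cluster centres (simplex-like Gaussian
#' placement); every virus is its host's centre plus isotropic noise, and
#' the true edges connect each virus to its assigned host.  A fraction of
#' viruses is held out as the test set (their labels are retained for
#' evaluation).
#'
#' @param n_hosts Number of hosts.
#' @param viruses_per_host Viruses per host.
#' @param d Embedding dimension.
#' @param separation Expected distance between host centres in units of
#'   `noise_sd` (the embedding overlap strength).
#' @param noise_sd Virus noise standard deviation.
#' @param test_frac Fraction of viruses held out.
#' @param seed RNG seed.
#' @return An [interaction_graph()] with extra elements `truth` (true host
#'   per virus) and `test_viruses`.
#' @export
generate_virus_host_graph <- function(n_hosts = 40L, viruses_per_host = 5L,
                                      d = 16L, separation = 12,
                                      noise_sd = 1, test_frac = 0.2,
                                      seed = 1L) {
  stopifnot(n_hosts >= 2L, viruses_per_host >= 1L)
  set.seed(seed)
  # centers at norm ~ separation * noise_sd in random directions, so that
  # viruses of one host are angularly similar (they must clear the 75%
  # virus-virus similarity threshold of the interaction network) while
  # viruses of different hosts are near-perpendicular
  unit <- if (noise_sd > 0) noise_sd else 1
  centers <- matrix(stats::rnorm(n_hosts * d, sd = separation * unit /
                                   sqrt(d)),
                    n_hosts, d)
  nv <- n_hosts * viruses_per_host
  truth <- rep(seq_len(n_hosts), each = viruses_per_host)
  virus_emb <- centers[truth, , drop = FALSE] +
    matrix(stats::rnorm(nv * d, sd = noise_sd), nv, d)
  rownames(virus_emb) <- sprintf("V%04d", seq_len(nv))
  host_emb <- centers
  rownames(host_emb) <- sprintf("H%03d", seq_len(n_hosts))
  test_viruses <- sort(sample.int(nv, floor(test_frac * nv)))
  g <- interaction_graph(virus_emb, host_emb,
                         cbind(seq_len(nv), truth),
                         test_viruses = test_viruses)
  g$truth <- truth
  g
}
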