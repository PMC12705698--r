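# Genomes as ordered sets of protein embedding vectors: chunking scaffolds
# into fully connected subgraphs, stacking genomes without padding, and
# concatenating positional/strand features.

#' Model configuration
#'
#' Collects the architectural hyperparameters of the set-transformer genome
#' model.  The model width is `d_model = d_in + pos_dim + strand_dim` and
#' must be divisible by `n_heads`.
#'
#' @param d_in Dimension of the input protein embeddings.
#' @param pos_dim,strand_dim Widths of the learnable positional and strand
#'   feature tables concatenated onto each protein embedding.
#' @param n_heads Number of attention heads.
#' @param n_layers Number of encoder layers.
#' @param chunk_size Maximum number of contiguous proteins per fully
#'   connected subgraph (the tuned value for full-scale genomes lies in
#'   15-50; smaller values are allowed for small experiments).  Must be >= 2.
#' @param dropout Dropout rate applied after attention and feed-forward
#'   layers during training.
#' @param softmax_scope Either `"genome"` (attention scores are normalized
#'   over all within-subgraph edges whose query protein lies in the same
#'   genome) or `"query_node"` (classical per-query normalization).
#' @param max_pos Largest within-scaffold protein rank with its own
#'   positional feature; larger ranks are clamped to this index.
#' @param d_ff Hidden width of the feed-forward blocks (default `2 * d_model`).
#' @param d_out Dimension of the genome embeddings (default `d_model`).
#' @param seed Integer seed used when initializing model weights.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_in, pos_dim = 4L, strand_dim = 4L, n_heads = 4L,
                         n_layers = 2L, chunk_size = 15L, dropout = 0.1,
                         softmax_scope = c("genome", "query_node"),
                         max_pos = 64L, d_ff = NULL, d_out = NULL, seed = 1L) {
  softmax_scope <- match.arg(softmax_scope)
  if (chunk_size < 2L) stop("chunk_size must be >= 2")
  d_model <- d_in + pos_dim + strand_dim
  if (d_model %% n_heads != 0L) {
    stop("d_model = d_in + pos_dim + strand_dim must be divisible by n_heads")
  }
  if (is.null(d_ff)) d_ff <- 2L * d_model
  if (is.null(d_out)) d_out <- d_model
  structure(list(d_in = as.integer(d_in), pos_dim = as.integer(pos_dim),
                 strand_dim = as.integer(strand_dim),
                 n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
                 chunk_size = as.integer(chunk_size), dropout = dropout,
                 softmax_scope = softmax_scope, max_pos = as.integer(max_pos),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 d_out = as.integer(d_out), seed = as.integer(seed)),
            class = "model_config")
}

#' Partition a scaffold into contiguous subgraph sizes
#'
#' Greedy runs of `chunk_size` proteins; a trailing run of a single protein
#' is merged into the previous run so that no subgraph of a multi-protein
#' scaffold has fewer than two nodes.  A one-protein scaffold yields a single
#' size-1 subgraph carrying the attribute `singleton = TRUE`.
#'
#' @param n_proteins Number of proteins on the scaffold (>= 1).
#' @param chunk_size Maximum subgraph size (>= 2).
#' @return Integer vector of subgraph sizes summing to `n_proteins`; no size
#'   exceeds `chunk_size + 1`.
#' @examples
#' chunk_scaffold(31, 15)  # 15, 16 - trailing singleton merged
#' chunk_scaffold(15, 15)  # 15
#' @export
chunk_scaffold <- function(n_proteins, chunk_size) {
  if (chunk_size < 2L) stop("chunk_size must be >= 2")
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  n_proteins <- as.integer(n_proteins)
  chunk_size <- as.integer(chunk_size)
  if (n_proteins == 1L) {
    return(structure(1L, singleton = TRUE))
  }
  k <- n_proteins %/% chunk_size
  r <- n_proteins %% chunk_size
  sizes <- rep(chunk_size, k)
  if (r == 1L) {
    sizes[k] <- sizes[k] + 1L
  } else if (r > 1L) {
    sizes <- c(sizes, r)
  }
  sizes
}

#' Restart positions at zero within each scaffold
#'
#' Protein ordering is defined only relative to each scaffold, so positions
#' are 0-based ranks within a scaffold in the order the rows appear.
#'
#' @param scaffold_id Character/factor vector, one entry per protein, in row
#'   order.
#' @return Integer vector of 0-based per-scaffold positions.
#' @export
positional_index <- function(scaffold_id) {
  if (length(scaffold_id) == 0L) return(integer())
  f <- factor(scaffold_id, levels = unique(scaffold_id))
  stats::ave(seq_along(f), f, FUN = seq_along) - 1L
}

#' Assemble a protein-set dataset
#'
#' @param meta Data frame with columns `protein_id`, `genome_id`,
#'   `scaffold_id`, `position` (0-based within scaffold), `strand` (+1/-1).
#' @param embeddings Numeric matrix, one row per protein in `meta` order.
#' @return Object of class `protein_set`.
#' @export
protein_set <- function(meta, embeddings) {
  required <- c("protein_id", "genome_id", "scaffold_id", "position", "strand")
  if (!all(required %in% names(meta))) {
    stop("meta must have columns ", paste(required, collapse = ", "))
  }
  embeddings <- as.matrix(embeddings)
  if (nrow(meta) != nrow(embeddings)) {
    stop("meta and embeddings disagree on the number of proteins")
  }
  if (!all(meta$strand %in% c(-1L, 1L))) stop("strand must be +1 or -1")
  structure(list(meta = meta, embeddings = embeddings), class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set: %d proteins, %d genomes, d_in = %d\n",
              nrow(x$meta), length(unique(x$meta$genome_id)),
              ncol(x$embeddings)))
  invisible(x)
}

#' Stack genomes into a single padded-free batch
#'
#' Rows are ordered by (genome, scaffold, position) using the order genomes
#' and scaffolds first appear.  Each scaffold is chunked into contiguous
#' fully connected subgraphs (self-loops included) and positional/strand
#' feature indices are attached for the learnable lookup tables.
#'
#' @param pset A [protein_set()].
#' @param config A [model_config()].
#' @param position_table,strand_table Optional numeric lookup tables (rows:
#'   `max_pos + 1` positions / 2 strands).  When supplied, the concatenated
#'   input matrix `X0` is materialized; model forward passes rebuild it on
#'   the autodiff tape from the stored indices.
#' @return An object of class `genome_batch` with elements `embeddings`,
#'   `genome_ptr`, `scaffold_ptr`, `subgraph_id`, `edge_list` (query/key row
#'   pairs), `genome_of_row`, `pos_index`, `strand_index`, `genome_ids`,
#'   `scaffold_ids`, and optionally `X0`.
#' @export
build_genome_batch <- function(pset, config, position_table = NULL,
                               strand_table = NULL) {
  meta <- pset$meta
  emb <- pset$embeddings
  if (anyNA(emb)) stop("embeddings contain NA")
  g_lev <- unique(meta$genome_id)
  s_key <- paste(meta$genome_id, meta$scaffold_id, sep = "\r")
  s_lev <- unique(s_key)
  ord <- order(match(meta$genome_id, g_lev), match(s_key, s_lev),
               meta$position)
  meta <- meta[ord, , drop = FALSE]
  emb <- emb[ord, , drop = FALSE]
  s_key <- s_key[ord]
  s_lev <- unique(s_key)  # scaffold order as it appears after sorting

  if (anyDuplicated(paste(s_key, meta$position))) {
    stop("duplicate (scaffold, position) pairs")
  }
  scaf_sizes <- as.integer(table(factor(s_key, levels = s_lev)))
  pos_check <- unlist(lapply(scaf_sizes, function(n) 0:(n - 1L)))
  if (!identical(as.integer(meta$position), pos_check)) {
    stop("positions within each scaffold must be 0..n-1 with no gaps")
  }

  n_total <- nrow(meta)
  genome_of_row <- match(meta$genome_id, g_lev)
  genome_ptr <- c(0L, cumsum(as.integer(table(factor(meta$genome_id,
                                                     levels = g_lev)))))
  scaffold_ptr <- c(0L, cumsum(scaf_sizes))

  subgraph_id <- integer(n_total)
  edge_i <- vector("list", length(scaf_sizes))
  sg <- 0L
  for (s in seq_along(scaf_sizes)) {
    sizes <- chunk_scaffold(scaf_sizes[s], config$chunk_size)
    off <- scaffold_ptr[s]
    for (sz in sizes) {
      sg <- sg + 1L
      rows <- off + seq_len(sz)
      subgraph_id[rows] <- sg
      edge_i[[s]] <- c(edge_i[[s]],
                       list(cbind(rep(rows, each = sz), rep(rows, sz))))
      off <- off + sz
    }
  }
  edge_list <- do.call(rbind, unlist(edge_i, recursive = FALSE))
  colnames(edge_list) <- c("query", "key")

  pos_index <- pmin(as.integer(meta$position), config$max_pos) + 1L
  strand_index <- ifelse(meta$strand == 1L, 1L, 2L)

  batch <- structure(list(
    embeddings = emb,
    meta = meta,
    genome_ids = g_lev,
    scaffold_ids = s_lev,
    genome_ptr = genome_ptr,
    scaffold_ptr = scaffold_ptr,
    genome_of_row = genome_of_row,
    scaffold_of_row = match(s_key, s_lev),
    subgraph_id = subgraph_id,
    edge_list = edge_list,
    pos_index = pos_index,
    strand_index = strand_index,
    n_genomes = length(g_lev)
  ), class = "genome_batch")

  if (!is.null(position_table) && !is.null(strand_table)) {
    if (ncol(emb) + ncol(position_table) + ncol(strand_table) !=
        config$d_model) {
      stop("embedding/table widths do not add up to d_model")
    }
    batch$X0 <- cbind(emb, position_table[pos_index, , drop = FALSE],
                      strand_table[strand_index, , drop = FALSE])
  }
  batch
}

#' @export
print.genome_batch <- function(x, ...) {
  cat(sprintf("genome_batch: %d proteins, %d genomes, %d subgraphs, %d edges\n",
              nrow(x$embeddings), x$n_genomes, max(x$subgraph_id),
              nrow(x$edge_list)))
  invisible(x)
}
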