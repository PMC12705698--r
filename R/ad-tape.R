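# Reverse-mode automatic differentiation on a tape of dense matrix nodes.
#
# The set-transformer forward pass, both training objectives and the
# link-prediction network are all expressed once through these primitives, so
# a single gradient engine backs every trainable component.  Nodes hold plain
# numeric matrices; each operation records the parent ids and a closure that
# maps the incoming gradient to parent gradients.

#' Create an empty autodiff tape
#'
#' A tape records every intermediate matrix of a forward computation together
#' with the local backward rules, so that [ad_backward()] can accumulate
#' gradients of a scalar loss with respect to any registered parameter.
#'
#' @return An object of class `ad_tape`.
#' @keywords internal
#' @export
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- integer()
  class(tp) <- "ad_tape"
  tp
}

.ad_push <- function(tp, value, parents = integer(), backward = NULL) {
  # Force the operands before claiming a node id: R's lazy evaluation would
  # otherwise let inline-constructed children push themselves after this
  # node's id has been computed.
  force(value); force(parents); force(backward)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) length(tp$nodes) <- 2L * n
  tp$nodes[[n]] <- list(value = value, parents = parents, backward = backward)
  tp$n <- n
  structure(list(tp = tp, id = n), class = "ad_ref")
}

#' @export
print.ad_ref <- function(x, ...) {
  v <- ad_value(x)
  cat(sprintf("<ad_ref #%d: %d x %d>\n", x$id, nrow(v), ncol(v)))
  invisible(x)
}

#' Value held by a tape node
#' @param x An `ad_ref` handle.
#' @return The numeric matrix stored at that node.
#' @keywords internal
#' @export
ad_value <- function(x) x$tp$nodes[[x$id]]$value

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Register a constant (no gradient) on the tape
#' @param tp Tape.
#' @param x Numeric matrix or vector (vectors become 1-row matrices).
#' @keywords internal
#' @export
ad_const <- function(tp, x) .ad_push(tp, as_mat(x))

#' Register a parameter (gradient tracked by name)
#' @param tp Tape.
#' @param x Numeric matrix holding the current parameter value.
#' @param name Unique parameter name used to retrieve its gradient.
#' @keywords internal
#' @export
ad_param <- function(tp, x, name) {
  ref <- .ad_push(tp, as_mat(x))
  tp$params <- c(tp$params, stats::setNames(ref$id, name))
  ref
}

#' Register all matrices of a named list as parameters
#' @keywords internal
#' @export
ad_params <- function(tp, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ad_param(tp, params[[nm]], nm)
  out
}

# ---- elementwise arithmetic -------------------------------------------------

#' @rdname ad_ops
#' @export
ad_add <- function(a, b) {
  .ad_push(a$tp, ad_value(a) + ad_value(b), c(a$id, b$id),
           function(g) list(g, g))
}

#' @rdname ad_ops
#' @export
ad_sub <- function(a, b) {
  .ad_push(a$tp, ad_value(a) - ad_value(b), c(a$id, b$id),
           function(g) list(g, -g))
}

# Elementwise product.  `b` may be the same shape as `a`, a single-column
# matrix broadcast across columns, or a single-row matrix broadcast across
# rows.
#' Tape operations
#'
#' Low-level differentiable matrix operations used to assemble model forward
#' passes.  All take and return `ad_ref` handles.
#'
#' @param a,b `ad_ref` operands.
#' @param g Not user-facing; gradients are handled by [ad_backward()].
#' @name ad_ops
#' @keywords internal
#' @export
ad_mul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  if (identical(dim(va), dim(vb))) {
    .ad_push(a$tp, va * vb, c(a$id, b$id),
             function(g) list(g * vb, g * va))
  } else if (ncol(vb) == 1L && nrow(vb) == nrow(va)) {
    bv <- as.vector(vb)
    .ad_push(a$tp, va * bv, c(a$id, b$id),
             function(g) list(g * bv, matrix(rowSums(g * va), ncol = 1L)))
  } else if (nrow(vb) == 1L && ncol(vb) == ncol(va)) {
    vbm <- matrix(vb, nrow(va), ncol(va), byrow = TRUE)
    .ad_push(a$tp, va * vbm, c(a$id, b$id),
             function(g) list(g * vbm, matrix(colSums(g * va), nrow = 1L)))
  } else if (ncol(va) == 1L || nrow(va) == 1L) {
    ad_mul(b, a)
  } else {
    stop("ad_mul: incompatible shapes")
  }
}

# Same-shape elementwise division only.
#' @rdname ad_ops
#' @export
ad_div <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  stopifnot(identical(dim(va), dim(vb)))
  .ad_push(a$tp, va / vb, c(a$id, b$id),
           function(g) list(g / vb, -g * va / (vb * vb)))
}

#' @rdname ad_ops
#' @param k Numeric scalar.
#' @export
ad_scale <- function(a, k) {
  .ad_push(a$tp, ad_value(a) * k, a$id, function(g) list(g * k))
}

#' @rdname ad_ops
#' @export
ad_add_scalar <- function(a, k) {
  .ad_push(a$tp, ad_value(a) + k, a$id, function(g) list(g))
}

# Add a 1-row bias to every row.
#' @rdname ad_ops
#' @export
ad_add_rowvec <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  stopifnot(nrow(vb) == 1L, ncol(vb) == ncol(va))
  .ad_push(a$tp, va + matrix(vb, nrow(va), ncol(va), byrow = TRUE),
           c(a$id, b$id),
           function(g) list(g, matrix(colSums(g), nrow = 1L)))
}

#' @rdname ad_ops
#' @export
ad_square <- function(a) {
  va <- ad_value(a)
  .ad_push(a$tp, va * va, a$id, function(g) list(2 * va * g))
}

#' @rdname ad_ops
#' @export
ad_sqrt <- function(a) {
  v <- sqrt(ad_value(a))
  .ad_push(a$tp, v, a$id, function(g) list(0.5 * g / v))
}

# ---- matrix product and activations ----------------------------------------

#' @rdname ad_ops
#' @export
ad_matmul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  .ad_push(a$tp, va %*% vb, c(a$id, b$id),
           function(g) list(g %*% t(vb), crossprod(va, g)))
}

#' @rdname ad_ops
#' @export
ad_gelu <- function(a) {
  va <- ad_value(a)
  ph <- stats::pnorm(va)
  .ad_push(a$tp, va * ph, a$id,
           function(g) list(g * (ph + va * stats::dnorm(va))))
}

#' @rdname ad_ops
#' @export
ad_relu <- function(a) {
  va <- ad_value(a)
  .ad_push(a$tp, pmax(va, 0), a$id, function(g) list(g * (va > 0)))
}

#' @rdname ad_ops
#' @export
ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ad_value(a)))
  .ad_push(a$tp, s, a$id, function(g) list(g * s * (1 - s)))
}

# Numerically stable log(1 + exp(x)); derivative is the logistic function.
#' @rdname ad_ops
#' @export
ad_softplus <- function(a) {
  va <- ad_value(a)
  v <- pmax(va, 0) + log1p(exp(-abs(va)))
  .ad_push(a$tp, v, a$id, function(g) list(g / (1 + exp(-va))))
}

# ---- indexing, grouping, reductions ----------------------------------------

#' @rdname ad_ops
#' @param idx Integer row indices (may repeat).
#' @export
ad_gather <- function(a, idx) {
  va <- ad_value(a)
  n <- nrow(va)
  .ad_push(a$tp, va[idx, , drop = FALSE], a$id,
           function(g) {
             out <- matrix(0, n, ncol(va))
             acc <- rowsum(g, idx)
             out[as.integer(rownames(acc)), ] <- acc
             list(out)
           })
}

#' @rdname ad_ops
#' @param cols Integer column indices (contiguous or not).
#' @export
ad_slice_cols <- function(a, cols) {
  va <- ad_value(a)
  d <- ncol(va)
  .ad_push(a$tp, va[, cols, drop = FALSE], a$id,
           function(g) {
             out <- matrix(0, nrow(va), d)
             out[, cols] <- g
             list(out)
           })
}

#' @rdname ad_ops
#' @param refs List of `ad_ref` with equal row counts, bound column-wise.
#' @export
ad_cbind <- function(refs) {
  vals <- lapply(refs, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .ad_push(refs[[1L]]$tp, do.call(cbind, vals),
           vapply(refs, function(r) r$id, integer(1)),
           function(g) {
             lapply(seq_along(widths), function(k) {
               g[, starts[k]:ends[k], drop = FALSE]
             })
           })
}

group_sum_mat <- function(x, groups, ngroups) {
  acc <- rowsum(x, groups)
  out <- matrix(0, ngroups, ncol(x))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' @rdname ad_ops
#' @param groups Integer group id (1..ngroups) per row.
#' @param ngroups Number of groups.
#' @export
ad_group_sum <- function(a, groups, ngroups) {
  va <- ad_value(a)
  .ad_push(a$tp, group_sum_mat(va, groups, ngroups), a$id,
           function(g) list(g[groups, , drop = FALSE]))
}

#' @rdname ad_ops
#' @export
ad_group_mean <- function(a, groups, ngroups) {
  va <- ad_value(a)
  cnt <- tabulate(groups, nbins = ngroups)
  stopifnot(all(cnt > 0))
  .ad_push(a$tp, group_sum_mat(va, groups, ngroups) / cnt, a$id,
           function(g) list((g / cnt)[groups, , drop = FALSE]))
}

# Softmax of a score column within integer segments: exp(s) normalized over
# each segment.  Scores are shifted by the per-segment maximum for stability.
#' @rdname ad_ops
#' @export
ad_segment_softmax <- function(a, groups) {
  s <- as.vector(ad_value(a))
  mx <- tapply(s, groups, max)
  e <- exp(s - mx[as.character(groups)])
  tot <- tapply(e, groups, sum)
  p <- e / tot[as.character(groups)]
  .ad_push(a$tp, matrix(p, ncol = 1L), a$id,
           function(g) {
             gv <- as.vector(g)
             dot <- tapply(gv * p, groups, sum)
             list(matrix(p * (gv - dot[as.character(groups)]), ncol = 1L))
           })
}

#' @rdname ad_ops
#' @export
ad_rowsum <- function(a) {
  va <- ad_value(a)
  .ad_push(a$tp, matrix(rowSums(va), ncol = 1L), a$id,
           function(g) list(matrix(as.vector(g), nrow(va), ncol(va))))
}

#' @rdname ad_ops
#' @export
ad_sum <- function(a) {
  va <- ad_value(a)
  .ad_push(a$tp, matrix(sum(va)), a$id,
           function(g) list(matrix(as.vector(g), nrow(va), ncol(va))))
}

# ---- backward pass ----------------------------------------------------------

#' Backpropagate a scalar loss through the tape
#'
#' @param loss `ad_ref` holding a 1 x 1 matrix.
#' @return Named list of gradients, one per parameter registered with
#'   [ad_param()]/[ad_params()], each the same shape as the parameter.
#'   Parameters the loss does not depend on get zero gradients.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  tp <- loss$tp
  stopifnot(length(ad_value(loss)) == 1L)
  grads <- vector("list", tp$n)
  grads[[loss$id]] <- matrix(1)
  for (i in seq(loss$id, 1L)) {
    nd <- tp$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      pk <- pg[[k]]
      if (is.null(pk)) next
      j <- nd$parents[k]
      grads[[j]] <- if (is.null(grads[[j]])) pk else grads[[j]] + pk
    }
    grads[i] <- list(NULL)  # free without shifting indices
  }
  out <- vector("list", length(tp$params))
  names(out) <- names(tp$params)
  for (nm in names(tp$params)) {
    id <- tp$params[[nm]]
    g <- grads[[id]]
    out[[nm]] <- if (is.null(g)) array(0, dim(tp$nodes[[id]]$value)) else g
  }
  out
}

# ---- optimizer --------------------------------------------------------------

#' Adam optimizer state
#' @param params Named list of parameter matrices.
#' @keywords internal
#' @export
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update
#'
#' Gradients are clamped elementwise to `clip` before the update, matching
#' magnitude-1 gradient clipping used during training.
#'
#' @param params Named list of parameter matrices.
#' @param grads Named list of gradients from [ad_backward()].
#' @param state State from [adam_state()].
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param clip Elementwise gradient magnitude clamp (NULL disables).
#' @param weight_decay Decoupled L2 shrinkage applied with the update.
#' @return List with updated `params` and `state`.
#' @keywords internal
#' @export
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 1.0,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (!is.null(clip)) g <- pmin(pmax(g, -clip), clip)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
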