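#' Reverse-mode automatic differentiation tape
#'
#' A small tape-based reverse-mode engine over numeric arrays: the structure
#' module and loss functions are written against the `ag_*` primitives below,
#' which behave as ordinary numeric operations when no tracked value is
#' involved (so inference and the oracle-tested loss code share one code
#' path) and record a computation graph when operating on parameters created
#' with [ag_param()] inside [ag_with_tape()]. Gradients are obtained with
#' [ag_backward()] and are verified against central finite differences in the
#' test suite.
#'
#' @name autodiff
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$nodes <- NULL
.ag$active <- FALSE

#' @rdname autodiff
#' @param expr expression evaluated with an active tape.
#' @export
ag_with_tape <- function(expr) {
  old_nodes <- .ag$nodes; old_active <- .ag$active
  .ag$nodes <- vector("list", 1024L)
  .ag$count <- 0L
  .ag$active <- TRUE
  on.exit({ .ag$nodes <- old_nodes; .ag$active <- old_active })
  force(expr)
}

is_ag <- function(x) inherits(x, "ag")

#' @rdname autodiff
#' @param x numeric value (scalar, vector, matrix or array).
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

new_node <- function(value, parents, backfn) {
  if (!.ag$active) stop("no active tape: wrap the computation in ag_with_tape()")
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backfn <- backfn
  node$grad <- NULL
  .ag$count <- .ag$count + 1L
  if (.ag$count > length(.ag$nodes)) {
    .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
  }
  node$id <- .ag$count
  .ag$nodes[[.ag$count]] <- node
  class(node) <- "ag"
  node
}

#' @rdname autodiff
#' @export
ag_param <- function(x) new_node(x, list(), NULL)

# build a node only when at least one input is tracked
mk <- function(value, inputs, backfn) {
  if (!any(vapply(inputs, is_ag, TRUE))) return(value)
  new_node(value, inputs, backfn)
}

# fold a gradient back to the shape of the (possibly scalar) input
unbr <- function(g, target) {
  if (length(target) == 1L) return(sum(g))
  if (is.null(dim(target)) && !is.null(dim(g))) {
    if (length(g) == length(target)) return(as.numeric(g))
    stop("gradient shape mismatch")
  }
  g
}

#' @rdname autodiff
#' @param loss a scalar `ag` node.
#' @param params list of `ag` parameter nodes.
#' @return list of gradients, one per element of `params`.
#' @export
ag_backward <- function(loss, params) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  n <- loss$id
  for (i in seq_len(n)) {
    nd <- .ag$nodes[[i]]
    if (!is.null(nd)) nd$grad <- NULL
  }
  loss$grad <- 1
  for (i in rev(seq_len(n))) {
    nd <- .ag$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    contribs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!is_ag(p) || is.null(contribs[[k]])) next
      p$grad <- if (is.null(p$grad)) contribs[[k]] else p$grad + contribs[[k]]
    }
  }
  lapply(params, function(p) {
    if (is.null(p$grad)) array(0, if (is.null(dim(p$value))) length(p$value) else dim(p$value))
    else p$grad
  })
}

# ---- arithmetic primitives ------------------------------------------------

#' @rdname autodiff
#' @param a,b inputs (numeric or `ag`).
#' @export
ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk(va + vb, list(a, b), function(g) list(unbr(g, va), unbr(g, vb)))
}

#' @rdname autodiff
#' @export
ag_sub <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk(va - vb, list(a, b), function(g) list(unbr(g, va), unbr(-g, vb)))
}

#' @rdname autodiff
#' @export
ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk(va * vb, list(a, b),
     function(g) list(unbr(g * vb, va), unbr(g * va, vb)))
}

#' @rdname autodiff
#' @export
ag_div <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk(va / vb, list(a, b),
     function(g) list(unbr(g / vb, va), unbr(-g * va / vb^2, vb)))
}

#' @rdname autodiff
#' @export
ag_neg <- function(a) {
  va <- ag_value(a)
  mk(-va, list(a), function(g) list(-g))
}

#' @rdname autodiff
#' @export
ag_matmul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk(va %*% vb, list(a, b),
     function(g) list(g %*% t(vb), t(va) %*% g))
}

#' @rdname autodiff
#' @export
ag_tcrossprod <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk(tcrossprod(va, vb), list(a, b),
     function(g) list(g %*% vb, t(g) %*% va))
}

# ---- reductions -----------------------------------------------------------

#' @rdname autodiff
#' @export
ag_sum <- function(a) {
  va <- ag_value(a)
  mk(sum(va), list(a), function(g) {
    out <- va; out[] <- g; list(out)
  })
}

#' @rdname autodiff
#' @export
ag_mean <- function(a) {
  va <- ag_value(a)
  mk(mean(va), list(a), function(g) {
    out <- va; out[] <- g / length(va); list(out)
  })
}

#' @rdname autodiff
#' @export
ag_rowsums <- function(a) {
  va <- ag_value(a)
  mk(rowSums(va), list(a),
     function(g) list(matrix(g, nrow(va), ncol(va))))
}

#' @rdname autodiff
#' @export
ag_rowmeans <- function(a) {
  va <- ag_value(a)
  mk(rowMeans(va), list(a),
     function(g) list(matrix(g / ncol(va), nrow(va), ncol(va))))
}

# ---- elementwise nonlinearities -------------------------------------------

#' @rdname autodiff
#' @export
ag_exp <- function(a) {
  v <- exp(ag_value(a))
  mk(v, list(a), function(g) list(g * v))
}

#' @rdname autodiff
#' @export
ag_log <- function(a) {
  va <- ag_value(a)
  mk(log(va), list(a), function(g) list(g / va))
}

#' @rdname autodiff
#' @export
ag_sqrt <- function(a) {
  v <- sqrt(ag_value(a))
  mk(v, list(a), function(g) list(g / (2 * v)))
}

#' @rdname autodiff
#' @export
ag_relu <- function(a) {
  va <- ag_value(a)
  mk(pmax(va, 0) * 1, list(a), function(g) list(g * (va > 0)))
}

#' @rdname autodiff
#' @export
ag_abs <- function(a) {
  va <- ag_value(a)
  mk(abs(va), list(a), function(g) list(g * sign(va)))
}

#' @rdname autodiff
#' @export
ag_softplus <- function(a) {
  va <- ag_value(a)
  v <- ifelse(va > 30, va, log1p(exp(pmin(va, 30))))
  mk(v, list(a), function(g) list(g / (1 + exp(-va))))
}

#' @rdname autodiff
#' @export
ag_softmax_rows <- function(a) {
  va <- ag_value(a)
  m <- va - apply(va, 1, max)
  e <- exp(m)
  v <- e / rowSums(e)
  mk(v, list(a), function(g) list(v * (g - rowSums(g * v))))
}

#' @rdname autodiff
#' @param cap numeric clamp (not differentiated).
#' @export
ag_clamp_max <- function(a, cap) {
  va <- ag_value(a)
  mk(pmin(va, cap), list(a), function(g) list(g * (va < cap)))
}

#' @rdname autodiff
#' @export
ag_min2 <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  sel <- va <= vb
  mk(pmin(va, vb), list(a, b),
     function(g) list(unbr(g * sel, va), unbr(g * !sel, vb)))
}

# ---- shape manipulation ---------------------------------------------------

#' @rdname autodiff
#' @param ... matrices (numeric or `ag`) with equal row counts.
#' @export
ag_cbind <- function(...) {
  inputs <- list(...)
  vals <- lapply(inputs, ag_value)
  vals <- lapply(vals, function(v) if (is.null(dim(v))) matrix(v, ncol = 1) else v)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  mk(do.call(cbind, vals), inputs, function(g) {
    lapply(seq_along(vals), function(k) {
      gk <- g[, starts[k]:ends[k], drop = FALSE]
      if (is.null(dim(ag_value(inputs[[k]])))) as.numeric(gk) else gk
    })
  })
}

#' @rdname autodiff
#' @param idx column (or row) indices.
#' @export
ag_cols <- function(a, idx) {
  va <- ag_value(a)
  mk(va[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    for (k in seq_along(idx)) out[, idx[k]] <- out[, idx[k]] + g[, k]
    list(out)
  })
}

#' @rdname autodiff
#' @export
ag_rows <- function(a, idx) {
  va <- ag_value(a)
  mk(va[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    list(out)
  })
}

#' @rdname autodiff
#' @param d target dimension vector.
#' @export
ag_reshape <- function(a, d) {
  va <- ag_value(a)
  v <- if (length(d) == 1L) as.numeric(va) else array(va, d)
  mk(v, list(a), function(g) {
    if (is.null(dim(va))) list(as.numeric(g)) else list(array(g, dim(va)))
  })
}

#' @rdname autodiff
#' @param v a length-n vector; `m` the number of replicated columns.
#' @param m,n replication counts.
#' @export
ag_colvec_mat <- function(v, m) {
  vv <- ag_value(v)
  mk(matrix(vv, length(vv), m), list(v), function(g) list(rowSums(g)))
}

#' @rdname autodiff
#' @export
ag_rowvec_mat <- function(v, n) {
  vv <- ag_value(v)
  mk(matrix(vv, n, length(vv), byrow = TRUE), list(v),
     function(g) list(colSums(g)))
}

#' Numeric gradient by central finite differences
#'
#' Reference oracle for the tape: perturbs every element of every parameter.
#' Only usable for small parameter sets.
#'
#' @param f function taking a list of numeric arrays, returning a scalar.
#' @param params list of numeric arrays.
#' @param eps step size.
#' @return list of numeric gradients matching `params`.
#' @export
numeric_gradient <- function(f, params, eps = 1e-6) {
  lapply(seq_along(params), function(k) {
    p <- params[[k]]
    g <- p
    for (i in seq_along(p)) {
      up <- params; up[[k]][i] <- p[i] + eps
      dn <- params; dn[[k]][i] <- p[i] - eps
      g[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    g
  })
}
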