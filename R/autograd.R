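# Minimal reverse-mode automatic differentiation tape.
#
# Feature maps are matrices with one row per voxel (batch samples stacked
# along the rows, x-fastest spatial order) and one column per channel.
# Every differentiable op accepts either a plain numeric value (evaluation
# path, nothing recorded) or an `ag_tensor` node (training path). Network
# forward code is therefore written once and reused for both.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  class(t) <- "ag_tape"
  t
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  class(nd) <- "ag_tensor"
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

#' @export
print.ag_tensor <- function(x, ...) {
  cat("<ag_tensor> length", length(x$value), "\n")
  invisible(x)
}

is_tensor <- function(x) inherits(x, "ag_tensor")

ag_value <- function(x) if (is_tensor(x)) x$value else x

tape_of <- function(...) {
  for (a in list(...)) if (is_tensor(a)) return(a$tape)
  NULL
}

ag_param <- function(tape, value) ag_node(tape, value)

accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Run the reverse sweep from a scalar loss node.
ag_backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$value) == 1L)
  tape <- loss$tape
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) accumulate(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# ---- arithmetic / math group generics ------------------------------------

#' @export
Ops.ag_tensor <- function(e1, e2) {
  if (nargs() == 1L) { # unary
    v1 <- ag_value(e1)
    if (.Generic == "-")
      return(ag_node(e1$tape, -v1, list(e1), function(g) list(-g)))
    if (.Generic == "+") return(e1)
    stop("unsupported unary op for ag_tensor: ", .Generic)
  }
  v1 <- ag_value(e1); v2 <- ag_value(e2)
  tape <- tape_of(e1, e2)
  t1 <- is_tensor(e1); t2 <- is_tensor(e2)
  parents <- c(if (t1) list(e1), if (t2) list(e2))
  pick <- function(g1, g2) {
    out <- list()
    if (t1) out <- c(out, list(g1))
    if (t2) out <- c(out, list(g2))
    out
  }
  # reduce a gradient to a scalar when the operand was scalar
  red <- function(g, v) if (length(v) == 1L && length(g) > 1L) sum(g) else g
  switch(.Generic,
    "+" = ag_node(tape, v1 + v2, parents,
                  function(g) pick(red(g, v1), red(g, v2))),
    "-" = ag_node(tape, v1 - v2, parents,
                  function(g) pick(red(g, v1), red(-g, v2))),
    "*" = ag_node(tape, v1 * v2, parents,
                  function(g) pick(red(g * v2, v1), red(g * v1, v2))),
    "/" = ag_node(tape, v1 / v2, parents,
                  function(g) pick(red(g / v2, v1), red(-g * v1 / v2^2, v2))),
    "^" = {
      if (t2) stop("tensor exponent not supported")
      ag_node(tape, v1^v2, parents,
              function(g) pick(red(g * v2 * v1^(v2 - 1), v1), NULL))
    },
    "==" = v1 == v2, "!=" = v1 != v2, "<" = v1 < v2, ">" = v1 > v2,
    "<=" = v1 <= v2, ">=" = v1 >= v2,
    stop("unsupported op for ag_tensor: ", .Generic)
  )
}

#' @export
Math.ag_tensor <- function(x, ...) {
  v <- x$value
  switch(.Generic,
    abs = ag_node(x$tape, abs(v), list(x), function(g) list(g * sign(v))),
    exp = { y <- exp(v); ag_node(x$tape, y, list(x), function(g) list(g * y)) },
    log = ag_node(x$tape, log(v), list(x), function(g) list(g / v)),
    sqrt = { y <- sqrt(v); ag_node(x$tape, y, list(x), function(g) list(g / (2 * y))) },
    stop("unsupported math fn for ag_tensor: ", .Generic)
  )
}

#' @export
Summary.ag_tensor <- function(..., na.rm = FALSE) {
  args <- list(...)
  if (length(args) != 1L) stop("ag_tensor reductions take a single argument")
  x <- args[[1]]
  if (.Generic != "sum") stop("unsupported reduction for ag_tensor: ", .Generic)
  v <- x$value
  ag_node(x$tape, sum(v), list(x), function(g) {
    gg <- array(g, dim = if (is.null(dim(v))) length(v) else dim(v))
    list(gg)
  })
}

#' @export
mean.ag_tensor <- function(x, ...) sum(x) / length(x$value)

#' @export
length.ag_tensor <- function(x) length(x$value)

# positive part max(x, 0); generic so losses run on arrays and tensors alike
hinge_pos <- function(x) UseMethod("hinge_pos")

#' @export
hinge_pos.default <- function(x) {
  if (is.matrix(x)) .relu_fw(x) else pmax(x, 0)
}

#' @export
hinge_pos.ag_tensor <- function(x) {
  v <- x$value
  y <- if (is.matrix(v)) .relu_fw(v) else pmax(v, 0)
  ag_node(x$tape, y, list(x), function(g) {
    if (is.matrix(g)) list(.mask_pos(g, v)) else list(g * (v > 0))
  })
}

ag_relu <- hinge_pos

ag_sigmoid <- function(x) {
  v <- ag_value(x)
  y <- if (is.matrix(v)) .sigmoid_fw(v) else 1 / (1 + exp(-v))
  if (!is_tensor(x)) return(y)
  ag_node(x$tape, y, list(x), function(g) {
    if (is.matrix(g)) list(.sigmoid_bw(g, y)) else list(g * y * (1 - y))
  })
}

# ---- structural ops -------------------------------------------------------

# channel concatenation
ag_concat <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  v <- cbind(va, vb)
  if (!is_tensor(a) && !is_tensor(b)) return(v)
  tape <- tape_of(a, b)
  ca <- ncol(va)
  parents <- list(); ga <- NULL
  ta <- is_tensor(a); tb <- is_tensor(b)
  parents <- c(if (ta) list(a), if (tb) list(b))
  ag_node(tape, v, parents, function(g) {
    out <- list()
    if (ta) out <- c(out, list(g[, seq_len(ca), drop = FALSE]))
    if (tb) out <- c(out, list(g[, -seq_len(ca), drop = FALSE]))
    out
  })
}

# channel (column) selection
ag_cols <- function(x, j) {
  v <- ag_value(x)
  y <- v[, j, drop = FALSE]
  if (!is_tensor(x)) return(y)
  nr <- nrow(v); nc <- ncol(v)
  ag_node(x$tape, y, list(x), function(g) {
    gx <- matrix(0, nr, nc)
    gx[, j] <- g
    list(gx)
  })
}

# row gather (e.g. cropping a padded patch back to its core region)
ag_rows <- function(x, idx) {
  v <- ag_value(x)
  y <- v[idx, , drop = FALSE]
  if (!is_tensor(x)) return(y)
  nr <- nrow(v); nc <- ncol(v)
  ag_node(x$tape, y, list(x), function(g) {
    gx <- matrix(0, nr, nc)
    gx[idx, ] <- g
    list(gx)
  })
}

# ---- neural network ops ---------------------------------------------------

# 3D convolution; W (K*Cin x Cout), b length Cout. Frozen layers simply pass
# plain matrices for W/b and no weight gradient is computed.
ag_conv3d <- function(x, W, b, ind, nbatch, k, s, p) {
  outd <- conv_out_dims(ind, k, s, p)
  vx <- ag_value(x); vW <- ag_value(W); vb <- ag_value(b)
  y <- .conv3d_fw(vx, as.integer(ind), as.integer(nbatch), vW, vb,
                  as.integer(k), as.integer(s), as.integer(p),
                  as.integer(outd))
  tape <- tape_of(x, W, b)
  if (is.null(tape)) return(structure(y, d = outd))
  tx <- is_tensor(x); tW <- is_tensor(W); tb <- is_tensor(b)
  parents <- c(if (tx) list(x), if (tW) list(W), if (tb) list(b))
  nd <- ag_node(tape, structure(y, d = outd), parents, function(g) {
    bw <- .conv3d_bw(vx, g, as.integer(ind), as.integer(nbatch), vW,
                     as.integer(k), as.integer(s), as.integer(p),
                     as.integer(outd), tx, tW)
    out <- list()
    if (tx) out <- c(out, list(bw$gx))
    if (tW) out <- c(out, list(bw$gW))
    if (tb) out <- c(out, list(as.numeric(bw$gb)))
    out
  })
  nd
}

# transposed 3D convolution to an explicit output extent; W (K*Cout x Cin)
ag_tconv3d <- function(x, W, b, ind, nbatch, k, s, p, outd) {
  vx <- ag_value(x); vW <- ag_value(W); vb <- ag_value(b)
  stopifnot(all(conv_out_dims(outd, k, s, p) == ind))
  y <- .tconv3d_fw(vx, as.integer(ind), as.integer(nbatch), vW, vb,
                   as.integer(k), as.integer(s), as.integer(p),
                   as.integer(outd))
  tape <- tape_of(x, W, b)
  if (is.null(tape)) return(structure(y, d = outd))
  tx <- is_tensor(x); tW <- is_tensor(W); tb <- is_tensor(b)
  parents <- c(if (tx) list(x), if (tW) list(W), if (tb) list(b))
  ag_node(tape, structure(y, d = outd), parents, function(g) {
    bw <- .tconv3d_bw(vx, g, as.integer(ind), as.integer(nbatch), vW,
                      as.integer(k), as.integer(s), as.integer(p),
                      as.integer(outd), tx, tW)
    out <- list()
    if (tx) out <- c(out, list(bw$gx))
    if (tW) out <- c(out, list(bw$gW))
    if (tb) out <- c(out, list(as.numeric(bw$gb)))
    out
  })
}

ag_maxpool <- function(x, ind, nbatch, w = c(2L, 2L, 2L)) {
  vx <- ag_value(x)
  r <- .maxpool_fw(vx, as.integer(ind), as.integer(nbatch), as.integer(w))
  y <- structure(r$y, d = r$outd)
  if (!is_tensor(x)) return(y)
  am <- r$argmax
  ag_node(x$tape, y, list(x), function(g) {
    list(.maxpool_bw(g, am, as.integer(ind), as.integer(nbatch)))
  })
}

ag_resize <- function(x, ind, nbatch, outd) {
  vx <- ag_value(x)
  y <- .resize3d(vx, as.integer(ind), as.integer(nbatch), as.integer(outd),
                 FALSE)
  y <- structure(y, d = outd)
  if (!is_tensor(x)) return(y)
  ag_node(x$tape, y, list(x), function(g) {
    list(.resize3d(g, as.integer(ind), as.integer(nbatch), as.integer(outd),
                   TRUE))
  })
}

# Batch normalization over all rows (batch x spatial) per channel.
# `state` is an environment holding running_mean / running_var, updated as a
# side effect in training mode.
ag_batchnorm <- function(x, gamma, beta, state, training,
                         eps = 1e-5, momentum = 0.1) {
  vx <- ag_value(x); vg <- ag_value(gamma); vb <- ag_value(beta)
  if (!training) {
    invsd <- 1 / sqrt(state$running_var + eps)
    y <- .col_affine(vx, vg * invsd, vb - state$running_mean * vg * invsd)
    attr(y, "d") <- attr(vx, "d")
    return(y)
  }
  n <- nrow(vx)
  st <- .col_meanvar(vx)
  mu <- st$mean; va <- st$var
  state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
  state$running_var <- (1 - momentum) * state$running_var + momentum * va
  invsd <- 1 / sqrt(va + eps)
  y <- .col_affine(vx, vg * invsd, vb - mu * vg * invsd)
  attr(y, "d") <- attr(vx, "d")
  tape <- tape_of(x, gamma, beta)
  if (is.null(tape)) return(y)
  tx <- is_tensor(x); tg <- is_tensor(gamma); tb <- is_tensor(beta)
  parents <- c(if (tx) list(x), if (tg) list(gamma), if (tb) list(beta))
  ag_node(tape, y, parents, function(g) {
    xhat <- .col_affine(vx, invsd, -mu * invsd)
    gs <- .col_gstats(g, xhat)
    out <- list()
    if (tx)
      out <- c(out, list(.bn_bwx(g, xhat, gs$gmean, gs$gxmean, vg * invsd)))
    if (tg) out <- c(out, list(gs$gxmean * n))
    if (tb) out <- c(out, list(gs$gmean * n))
    out
  })
}

conv_out_dims <- function(ind, k, s, p) {
  as.integer(floor((ind + 2 * p - k) / s) + 1)
}
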