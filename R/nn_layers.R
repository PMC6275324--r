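# Parameter containers, initialization and the Adam optimizer for the two
# networks. A model is a plain list: config, params (named numeric arrays),
# states (batch-norm running statistics, one environment per layer).

init_conv <- function(cin, cout, k = c(3L, 3L, 3L)) {
  fan_in <- cin * prod(k)
  list(W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout))
}

# transposed conv stores W as (K*Cout x Cin)
init_tconv <- function(cin, cout, k = c(3L, 3L, 3L)) {
  fan_in <- cin * prod(k)
  list(W = matrix(rnorm(prod(k) * cout * cin, sd = sqrt(2 / fan_in)),
                  prod(k) * cout, cin),
       b = numeric(cout))
}

init_bn <- function(ch) list(gamma = rep(1, ch), beta = numeric(ch))

new_bn_state <- function(ch) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(ch)
  st$running_var <- rep(1, ch)
  st
}

# register a BN(cin) -> conv -> ReLU -> BN(cout) -> conv -> ReLU block
add_block <- function(store, prefix, cin, cout) {
  store$params[[paste0(prefix, ".bn1")]] <- init_bn(cin)
  store$params[[paste0(prefix, ".conv1")]] <- init_conv(cin, cout)
  store$params[[paste0(prefix, ".bn2")]] <- init_bn(cout)
  store$params[[paste0(prefix, ".conv2")]] <- init_conv(cout, cout)
  store$states[[paste0(prefix, ".bn1")]] <- new_bn_state(cin)
  store$states[[paste0(prefix, ".bn2")]] <- new_bn_state(cout)
  invisible(store)
}

bn_fw <- function(pp, states, name, x, training) {
  p <- pp[[name]]
  ag_batchnorm(x, p$gamma, p$beta, states[[name]], training)
}

conv_fw <- function(pp, name, x, ind, nbatch, k = c(3L, 3L, 3L),
                    s = c(1L, 1L, 1L), p = c(1L, 1L, 1L)) {
  pr <- pp[[name]]
  ag_conv3d(x, pr$W, pr$b, ind, nbatch, k, s, p)
}

dims_of <- function(x) attr(ag_value(x), "d")

block_fw <- function(pp, states, prefix, x, ind, nbatch, training) {
  h <- bn_fw(pp, states, paste0(prefix, ".bn1"), x, training)
  h <- ag_relu(conv_fw(pp, paste0(prefix, ".conv1"), h, ind, nbatch))
  h <- bn_fw(pp, states, paste0(prefix, ".bn2"), h, training)
  ag_relu(conv_fw(pp, paste0(prefix, ".conv2"), h, ind, nbatch))
}

# Wrap all parameter arrays of a model as trainable tape leaves. Returns a
# structure parallel to `params`; leaves can be read back for their grads.
wrap_params <- function(tape, params) {
  lapply(params, function(layer) lapply(layer, function(a) ag_param(tape, a)))
}

collect_grads <- function(wrapped) {
  lapply(wrapped, function(layer) lapply(layer, function(nd) {
    g <- nd$grad
    if (is.null(g)) array(0, dim = dim(nd$value) %||% length(nd$value)) else g
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of trainable parameters in a model
#'
#' Counts every convolution weight/bias and batch-normalization scale/shift;
#' running statistics are not trainable and are excluded.
#'
#' @param model a model built by [build_unet()] or [build_cae()]
#' @return integer parameter count
#' @export
n_parameters <- function(model) {
  if (!is.null(model$encoder)) {
    return(n_parameters(list(params = model$encoder$params)) +
             n_parameters(list(params = model$decoder$params)))
  }
  sum(vapply(model$params, function(layer)
    sum(vapply(layer, length, 1L)), 1L))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(layer) lapply(layer, function(a) a * 0))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zeros, v = zeros)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      g <- grads[[ln]][[pn]]
      opt$m[[ln]][[pn]] <- opt$beta1 * opt$m[[ln]][[pn]] + (1 - opt$beta1) * g
      opt$v[[ln]][[pn]] <- opt$beta2 * opt$v[[ln]][[pn]] + (1 - opt$beta2) * g^2
      step <- opt$lr * (opt$m[[ln]][[pn]] / bc1) /
        (sqrt(opt$v[[ln]][[pn]] / bc2) + opt$eps)
      params[[ln]][[pn]] <- params[[ln]][[pn]] - step
    }
  }
  list(opt = opt, params = params)
}

# deep copy of parameter values (checkpointing)
copy_params <- function(params) rapply(params, identity, how = "replace")

copy_states <- function(states) {
  out <- list()
  for (nm in names(states)) {
    st <- new.env(parent = emptyenv())
    st$running_mean <- states[[nm]]$running_mean
    st$running_var <- states[[nm]]$running_var
    out[[nm]] <- st
  }
  out
}

# volumes <-> voxel-row matrices
vol_as_mat <- function(a) {
  d <- dim(a)
  structure(matrix(as.numeric(a), ncol = 1L), d = as.integer(d))
}

mat_as_vol <- function(m, dims) array(m, dim = dims)
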