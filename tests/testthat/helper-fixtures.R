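# Shared fixtures: tiny volumes, cases and configurations used across the
# suite. Everything is generated in code; nothing is read from disk.

tiny_grid <- c(16L, 16L, 8L)

# a small hand-made case with exactly nested masks
tiny_case <- function(grid = tiny_grid, t_on = 2, t_tr = 4) {
  core <- array(0, grid); core[6:9, 6:9, 3:5] <- 1
  cp <- array(0, grid); cp[4:11, 4:11, 2:6] <- 1
  les <- array(0, grid); les[5:10, 5:10, 3:6] <- 1
  les <- pmax(les, core) * pmin(les + cp, 1)
  les <- pmin(pmax(les, core), cp)
  cbv <- array(1, grid) - 0.5 * core
  ttd <- array(1, grid) + 0.5 * cp + 0.5 * core
  perfusion_case("tiny", cbv, ttd, core, cp, les, t_on, t_tr)
}

# numeric gradient of a scalar-valued function
num_grad <- function(f, x, h = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# independent closed-form parameter count for the U-Net architecture:
# double-conv blocks (BN before each conv) on three levels plus decoder
# blocks on the concatenated skips and a 1x1x1 output convolution
unet_param_oracle <- function(cin, cout, ch) {
  block <- function(ci, co) {
    2 * ci + (27 * ci * co + co) + 2 * co + (27 * co * co + co)
  }
  block(cin, ch[1]) + block(ch[1], ch[2]) + block(ch[2], ch[3]) +
    block(ch[2] + ch[3], ch[2]) + block(ch[1] + ch[2], ch[1]) +
    ch[1] * cout + cout
}

# closed-form count for the CAE (encoder + mirrored decoder)
cae_param_oracle <- function(w, bc, kb) {
  block <- function(ci, co) {
    2 * ci + (27 * ci * co + co) + 2 * co + (27 * co * co + co)
  }
  conv <- function(ci, co, k = 27) k * ci * co + co
  enc <- block(1, w[1]) + conv(w[1], w[2]) + block(w[2], w[2]) +
    conv(w[2], w[3]) + block(w[3], w[3]) + conv(w[3], w[4]) +
    block(w[4], w[4]) + conv(w[4], bc, prod(kb))
  dec <- conv(bc, w[4], prod(kb)) + block(w[4], w[4]) +
    conv(w[4], w[3]) + block(w[3], w[3]) + conv(w[3], w[2]) +
    block(w[2], w[2]) + conv(w[2], w[1]) +
    (2 * w[1] + conv(w[1], w[1]) + 2 * w[1] + conv(w[1], 1))
  enc + dec
}

smoke_synth_config <- function(n_cases = 6L, seed = 11L,
                               grid = c(32L, 32L, 8L)) {
  synth_config(grid = grid, n_cases = n_cases, seed = seed)
}
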