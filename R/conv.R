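# Minimal 2-D convolution kernels for the desk-scale encoders. Inputs are
# H x W x C arrays; weights are kh x kw x Cin x Cout. Everything is plain
# cross-correlation (deep-learning convention), vectorised over the spatial
# grid with the shift-and-accumulate trick.

conv2d <- function(x, w, stride = 1L, padding = c("valid", "same"), bias = NULL) {
  padding <- match.arg(padding)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  kh <- dim(w)[1]
  kw <- dim(w)[2]
  cin <- dim(w)[3]
  cout <- dim(w)[4]
  stopifnot(dim(x)[3] == cin)
  if (padding == "same") {
    ph <- (kh - 1L) %/% 2L
    pw <- (kw - 1L) %/% 2L
    xp <- array(0, dim = dim(x) + c(2L * ph, 2L * pw, 0L))
    xp[ph + seq_len(dim(x)[1]), pw + seq_len(dim(x)[2]), ] <- x
    x <- xp
  }
  H <- dim(x)[1]
  W <- dim(x)[2]
  oh <- H - kh + 1L
  ow <- W - kw + 1L
  if (oh < 1L || ow < 1L) {
    stop(sprintf(
      "kernel %dx%d does not fit input %dx%d (shape trace: out would be %dx%d)",
      kh, kw, H, W, oh, ow
    ), call. = FALSE)
  }
  out <- array(0, dim = c(oh, ow, cout))
  for (o in seq_len(cout)) {
    acc <- matrix(0, oh, ow)
    for (ci in seq_len(cin)) {
      xc <- x[, , ci]
      for (di in seq_len(kh)) {
        for (dj in seq_len(kw)) {
          wv <- w[di, dj, ci, o]
          if (wv != 0) {
            acc <- acc + wv * xc[di:(di + oh - 1L), dj:(dj + ow - 1L)]
          }
        }
      }
    }
    out[, , o] <- acc + if (is.null(bias)) 0 else bias[o]
  }
  if (stride > 1L) {
    out <- out[seq(1L, oh, by = stride), seq(1L, ow, by = stride), , drop = FALSE]
  }
  out
}

# Depthwise convolution: one kh x kw filter per channel (w: kh x kw x C).
depthwise_conv2d <- function(x, w, stride = 1L, padding = "same", bias = NULL) {
  C <- dim(x)[3]
  stopifnot(dim(w)[3] == C)
  out <- NULL
  for (ci in seq_len(C)) {
    wc <- array(w[, , ci], dim = c(dim(w)[1], dim(w)[2], 1L, 1L))
    oc <- conv2d(x[, , ci, drop = FALSE], wc, stride = stride, padding = padding,
                 bias = if (is.null(bias)) NULL else bias[ci])
    if (is.null(out)) out <- array(0, dim = c(dim(oc)[1:2], C))
    out[, , ci] <- oc[, , 1L]
  }
  out
}

# Pointwise (1x1) convolution as a matrix product: w is Cin x Cout.
pointwise_conv2d <- function(x, w, bias = NULL) {
  H <- dim(x)[1]
  W <- dim(x)[2]
  cin <- dim(x)[3]
  stopifnot(nrow(w) == cin)
  flat <- matrix(x, H * W, cin)
  out <- flat %*% w
  if (!is.null(bias)) out <- sweep(out, 2L, bias, `+`)
  array(out, dim = c(H, W, ncol(w)))
}

relu <- function(x) pmax(x, 0)
silu <- function(x) x / (1 + exp(-x))

conv_out_size <- function(size, kernel, stride, padding = "valid") {
  valid <- if (padding == "same") size else size - kernel + 1L
  if (valid < 1L) return(NA_integer_)
  as.integer(ceiling(valid / stride))
}

# Deterministic weight draws: He-style Gaussian scaled by fan-in.
draw_weights <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}
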