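#' Squash nonlinearity for capsule vectors
#'
#' `squash(v) = (||v||^2 / (1 + ||v||^2)) * v / ||v||`. The output keeps
#' the direction of `v`, its norm lies in `[0, 1)` and increases strictly
#' with `||v||`, so a capsule's norm can be read as an existence
#' probability. The zero vector maps to itself.
#'
#' @param v numeric vector, or a matrix whose rows are capsule vectors.
#' @return Object of the same shape.
#' @export
squash <- function(v) {
  if (is.matrix(v)) {
    n2 <- rowSums(v^2)
    scale <- ifelse(n2 > 0, n2 / (1 + n2) / sqrt(n2), 0)
    return(v * scale)
  }
  n2 <- sum(v^2)
  if (n2 == 0) return(v)
  (n2 / (1 + n2)) * v / sqrt(n2)
}

#' Dynamic routing between capsule layers
#'
#' Routing-by-agreement: logits start at zero; each iteration computes
#' coupling coefficients as a softmax of the logits over output capsules
#' (so they sum to one per input capsule), forms each output as the squash
#' of the coupling-weighted sum of predictions, then increments every logit
#' by the scalar product of the prediction with the output it voted for.
#'
#' @param predictions array `n_in x n_out x d` of prediction vectors
#'   `u_hat[i, j, ]` (input capsule `i`'s vote for output capsule `j`).
#' @param iterations routing iteration count (>= 1).
#' @return A list: `outputs` (matrix `n_out x d` of squashed capsule
#'   vectors), `couplings` (final `n_in x n_out` coefficients), and
#'   `coupling_trace` (one coupling matrix per iteration).
#' @export
dynamic_routing <- function(predictions, iterations = 3L) {
  stopifnot(length(dim(predictions)) == 3L, iterations >= 1L)
  n_in <- dim(predictions)[1]
  n_out <- dim(predictions)[2]
  d <- dim(predictions)[3]
  logits <- matrix(0, n_in, n_out)
  trace <- vector("list", iterations)
  outputs <- matrix(0, n_out, d)
  for (it in seq_len(iterations)) {
    ex <- exp(logits - apply(logits, 1L, max))
    cpl <- ex / rowSums(ex)
    trace[[it]] <- cpl
    for (j in seq_len(n_out)) {
      s <- colSums(cpl[, j] * matrix(predictions[, j, ], n_in, d))
      outputs[j, ] <- squash(s)
    }
    agree <- matrix(predictions, n_in * n_out, d) %*% t(outputs) # (i,j) x j'
    # pick the agreement of prediction (i, j) with output j
    idx <- cbind(seq_len(n_in * n_out), rep(seq_len(n_out), each = n_in))
    logits <- logits + matrix(agree[idx], n_in, n_out)
  }
  list(outputs = outputs, couplings = trace[[iterations]], coupling_trace = trace)
}

#' Capsule encoder configuration
#'
#' Desk-scale capsule network: one standard convolution (`Conv1`, ReLU), a
#' strided convolution reshaped into primary capsules (squashed), and a
#' fully connected capsule layer (`EntityCaps`) reached through dynamic
#' routing. The default entity layer has 6 capsules of dimension 31 — one
#' capsule per haemorrhage subtype plus one "no lesion" capsule — so the
#' flattened feature vector has length `6 * 31 = 186`, which together with
#' the 1000-unit bottleneck head gives the default fused length 1186.
#'
#' @param conv1_filters,conv1_kernel,conv1_stride Conv1 spec.
#' @param primary_kernel,primary_stride,primary_channels,primary_dim
#'   primary-capsule convolution spec: `primary_channels` capsule maps of
#'   dimension `primary_dim`.
#' @param entity_caps,entity_dim entity capsule count and dimension;
#'   `entity_caps` must be at least the number of classes.
#' @param routing_iterations dynamic-routing iterations (>= 1).
#' @param seed integer seed for the deterministic weight draw.
#' @return A config list for [capsnet_encode()].
#' @export
caps_config <- function(conv1_filters = 8L, conv1_kernel = 9L, conv1_stride = 2L,
                        primary_kernel = 9L, primary_stride = 2L,
                        primary_channels = 4L, primary_dim = 8L,
                        entity_caps = 6L, entity_dim = 31L,
                        routing_iterations = 3L, seed = 42L) {
  if (routing_iterations < 1L) stop("`routing_iterations` must be >= 1", call. = FALSE)
  if (entity_caps < 1L || entity_dim < 1L) stop("entity layer must be non-empty", call. = FALSE)
  list(
    conv1_filters = as.integer(conv1_filters), conv1_kernel = as.integer(conv1_kernel),
    conv1_stride = as.integer(conv1_stride),
    primary_kernel = as.integer(primary_kernel), primary_stride = as.integer(primary_stride),
    primary_channels = as.integer(primary_channels), primary_dim = as.integer(primary_dim),
    entity_caps = as.integer(entity_caps), entity_dim = as.integer(entity_dim),
    routing_iterations = as.integer(routing_iterations), seed = as.integer(seed)
  )
}

#' Shape arithmetic for the capsule encoder
#'
#' @param cfg a [caps_config()].
#' @param height,width input image size.
#' @return A list with the spatial sizes after each stage, the primary
#'   capsule count, and the output feature length `n`.
#' @export
caps_shape <- function(cfg, height, width) {
  h1 <- conv_out_size(height, cfg$conv1_kernel, cfg$conv1_stride)
  w1 <- conv_out_size(width, cfg$conv1_kernel, cfg$conv1_stride)
  if (is.na(h1) || is.na(w1)) {
    stop(sprintf("Conv1 kernel %d does not fit input %dx%d", cfg$conv1_kernel, height, width),
         call. = FALSE)
  }
  h2 <- conv_out_size(h1, cfg$primary_kernel, cfg$primary_stride)
  w2 <- conv_out_size(w1, cfg$primary_kernel, cfg$primary_stride)
  if (is.na(h2) || is.na(w2)) {
    stop(sprintf("PrimaryCaps kernel %d does not fit Conv1 output %dx%d (input %dx%d)",
                 cfg$primary_kernel, h1, w1, height, width), call. = FALSE)
  }
  n_primary <- h2 * w2 * cfg$primary_channels
  list(
    conv1 = c(h1, w1), primary = c(h2, w2), n_primary = n_primary,
    n = cfg$entity_caps * cfg$entity_dim
  )
}

caps_weights <- function(cfg, shape) {
  with_opt_seed(cfg$seed, {
    list(
      conv1 = draw_weights(
        c(cfg$conv1_kernel, cfg$conv1_kernel, 1L, cfg$conv1_filters),
        fan_in = cfg$conv1_kernel^2
      ),
      primary = draw_weights(
        c(cfg$primary_kernel, cfg$primary_kernel, cfg$conv1_filters,
          cfg$primary_channels * cfg$primary_dim),
        fan_in = cfg$primary_kernel^2 * cfg$conv1_filters
      ),
      # W maps each primary capsule (dim primary_dim) to a vote of dim
      # entity_dim for each entity capsule: (n_primary * entity_caps) blocks.
      route = draw_weights(
        c(shape$n_primary, cfg$entity_caps, cfg$entity_dim, cfg$primary_dim),
        fan_in = cfg$primary_dim
      )
    )
  })
}

#' Encode an image with the capsule network
#'
#' Conv1 (ReLU) -> primary capsules (strided convolution reshaped to
#' capsule vectors, squashed) -> dynamic routing -> entity capsules. The
#' output is the flattened entity-capsule matrix, length
#' `entity_caps * entity_dim` (186 by default). Weights are drawn from a
#' seeded initializer, so the encoding is deterministic given the config;
#' training is not required for the desk-scale feature extractor.
#'
#' @param image a [gray_image()] or numeric matrix; intensities are scaled
#'   to `[0, 1]` internally.
#' @param cfg a [caps_config()].
#' @return A numeric feature vector with attributes `source = "capsnet"`
#'   and `capsule_norms`.
#' @export
capsnet_encode <- function(image, cfg = caps_config()) {
  img <- as_gray_image(image)
  x <- unclass(img) / (gray_levels(img) - 1)
  shape <- caps_shape(cfg, nrow(x), ncol(x))
  w <- caps_weights(cfg, shape)
  a1 <- relu(conv2d(array(x, dim = c(dim(x), 1L)), w$conv1, stride = cfg$conv1_stride))
  a2 <- conv2d(a1, w$primary, stride = cfg$primary_stride)
  # reshape to capsules: each group of primary_dim channels is one capsule map
  n_spatial <- dim(a2)[1] * dim(a2)[2]
  caps <- matrix(0, shape$n_primary, cfg$primary_dim)
  for (ch in seq_len(cfg$primary_channels)) {
    cols <- (ch - 1L) * cfg$primary_dim + seq_len(cfg$primary_dim)
    caps[(ch - 1L) * n_spatial + seq_len(n_spatial), ] <-
      matrix(a2[, , cols], n_spatial, cfg$primary_dim)
  }
  caps <- squash(caps)
  # prediction votes u_hat[i, j, ] = W[i, j, , ] %*% u_i
  preds <- array(0, dim = c(shape$n_primary, cfg$entity_caps, cfg$entity_dim))
  for (j in seq_len(cfg$entity_caps)) {
    # stack the per-capsule matrices: votes_i = W_ij u_i, done blockwise
    Wj <- w$route[, j, , , drop = TRUE] # n_primary x entity_dim x primary_dim
    for (dd in seq_len(cfg$primary_dim)) {
      preds[, j, ] <- preds[, j, ] + Wj[, , dd] * caps[, dd]
    }
  }
  routed <- dynamic_routing(preds, cfg$routing_iterations)
  out <- as.numeric(t(routed$outputs))
  structure(out, source = "capsnet",
            capsule_norms = sqrt(rowSums(routed$outputs^2)))
}
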