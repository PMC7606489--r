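# Dilated-convolution 3D FCN: 10 blocks of ReLU(BN(conv)) with kernel 3^3
# and dilations 1,1,2,2,4,4,2,2,1,1, followed by a 1x1x1 convolution and a
# softmax over 4 tissue classes. Zero padding equal to the dilation keeps
# the spatial grid unchanged at every layer, so per-voxel representations
# can be compared across layers. Activations are handled internally as
# C x V matrices (V voxels, column-major).

#' FCN architecture specification
#'
#' Defaults reproduce the baseline 10-layer dilated FCN: channels
#' 16,16,32,32,64,64,32,32,16,16 over a 3-channel input, 3x3x3 kernels with
#' dilations 1,1,2,2,4,4,2,2,1,1, and a 1x1x1 output convolution to 4
#' classes (~320k trainable parameters).
#'
#' @param channels integer vector of hidden-layer channel counts.
#' @param in_channels input channels.
#' @param n_classes output classes.
#' @param dilations integer dilation per hidden layer (same length as
#'   `channels`).
#' @param use_dropout if `TRUE`, a 3D (channel-wise) dropout layer follows
#'   every ReLU(BN(conv)) block.
#' @param dropout_rate dropout probability (default 0.1).
#' @return An object of class `fcn_spec`.
#' @export
fcn_spec <- function(channels = c(16, 16, 32, 32, 64, 64, 32, 32, 16, 16),
                     in_channels = 3,
                     n_classes = 4,
                     dilations = c(1, 1, 2, 2, 4, 4, 2, 2, 1, 1),
                     use_dropout = FALSE,
                     dropout_rate = 0.1) {
  channels <- as.integer(channels); dilations <- as.integer(dilations)
  if (length(channels) != length(dilations))
    stopf("channels and dilations must have the same length")
  if (any(channels < 1) || any(dilations < 1)) stopf("channels and dilations must be positive")
  if (!is_count(in_channels) || !is_count(n_classes)) stopf("invalid channel counts")
  if (use_dropout && (dropout_rate < 0 || dropout_rate >= 1)) stopf("invalid dropout rate")
  structure(list(channels = channels, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), kernel = 3L,
                 dilations = dilations, use_dropout = isTRUE(use_dropout),
                 dropout_rate = dropout_rate),
            class = "fcn_spec")
}

#' Closed-form trainable parameter count
#'
#' Per hidden layer `C_in * C_out * 27 + C_out` (kernel + bias) plus
#' `2 * C_out` batch-norm scale/shift, and `C_in * C_out + C_out` for the
#' 1x1x1 output convolution.
#'
#' @param spec an [fcn_spec()].
#' @return Named list with `per_layer` counts and the `total`.
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "fcn_spec"))
  cin <- c(spec$in_channels, head(spec$channels, -1))
  per <- cin * spec$channels * spec$kernel^3 + spec$channels + 2L * spec$channels
  out <- spec$channels[length(spec$channels)] * spec$n_classes + spec$n_classes
  list(per_layer = per, output = out, total = sum(per) + out)
}

#' Build an FCN with seeded He-style initialization
#'
#' Convolution kernels are stored flattened as `C_out x (C_in * 27)`
#' matrices (tap-major, channel-fastest), initialized
#' `N(0, sqrt(2 / fan_in))`; biases and BN shifts start at zero, BN scales
#' at one, BN running statistics at (0, 1).
#'
#' @param spec an [fcn_spec()].
#' @param seed integer seed for the weight draw.
#' @return An object of class `fcn_network`.
#' @export
build_fcn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fcn_spec"))
  cin <- c(spec$in_channels, head(spec$channels, -1))
  with_seed(seed, {
    layers <- lapply(seq_along(spec$channels), function(l) {
      fan_in <- cin[l] * spec$kernel^3
      list(W = matrix(rnorm(spec$channels[l] * fan_in, 0, sqrt(2 / fan_in)),
                      nrow = spec$channels[l]),
           b = numeric(spec$channels[l]),
           gamma = rep(1, spec$channels[l]),
           beta = numeric(spec$channels[l]),
           running_mean = numeric(spec$channels[l]),
           running_var = rep(1, spec$channels[l]),
           dilation = spec$dilations[l])
    })
    c_last <- spec$channels[length(spec$channels)]
    out <- list(W = matrix(rnorm(spec$n_classes * c_last, 0, sqrt(2 / c_last)),
                           nrow = spec$n_classes),
                b = numeric(spec$n_classes))
    structure(list(spec = spec, layers = layers, out = out, seed = as.integer(seed)),
              class = "fcn_network")
  })
}

#' @export
print.fcn_network <- function(x, ...) {
  pc <- param_count(x$spec)
  cat(sprintf("<fcn_network> %d hidden layers, channels %s, dilations %s\n",
              length(x$spec$channels), paste(x$spec$channels, collapse = ","),
              paste(x$spec$dilations, collapse = ",")))
  cat(sprintf("  %d trainable parameters; dropout %s\n", pc$total,
              if (x$spec$use_dropout) sprintf("rate %.2f", x$spec$dropout_rate) else "off"))
  invisible(x)
}

bn_eps <- 1e-5

# Coerce a labeled_volume / 4-D array into (C x V matrix, dims).
as_input_matrix <- function(x, spec) {
  if (inherits(x, "labeled_volume")) x <- x$intensities
  if (length(dim(x)) != 4L) stopf("input must be a (channel, x, y, z) array or labeled_volume")
  if (dim(x)[1] != spec$in_channels)
    stopf("input has %d channels, network expects %d", dim(x)[1], spec$in_channels)
  dims <- dim(x)[-1]
  list(mat = matrix(x, nrow = dim(x)[1]), dims = dims)
}

# Single forward pass on a C x V matrix. Modes:
#   train = TRUE  -> batch-norm uses batch statistics (and a cache for
#                    backprop is kept when keep_cache);
#   dropout = TRUE -> channel-wise 3D dropout masks are drawn (inverted
#                    scaling); caller controls the RNG via with_seed().
# keep_reps stores pre/post representations of every layer (inference only).
fcn_pass <- function(net, x_mat, dims, train = FALSE, dropout = FALSE,
                     keep_reps = FALSE, keep_cache = FALSE) {
  spec <- net$spec
  V <- prod(dims)
  h <- x_mat
  reps <- if (keep_reps) vector("list", 2L * length(net$layers)) else NULL
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    cols <- cpp_im2col(h, dims[1], dims[2], dims[3], ly$dilation)
    z <- ly$W %*% cols + ly$b
    if (train) {
      mu <- rowMeans(z)
      zc <- z - mu
      va <- rowMeans(zc * zc)
      xhat <- zc / sqrt(va + bn_eps)
    } else {
      xhat <- (z - ly$running_mean) / sqrt(ly$running_var + bn_eps)
    }
    a <- ly$gamma * xhat + ly$beta
    post <- pmax(a, 0)
    mask <- NULL
    if (dropout && spec$use_dropout && spec$dropout_rate > 0) {
      keep <- (runif(nrow(post)) >= spec$dropout_rate) / (1 - spec$dropout_rate)
      mask <- keep
      post <- post * keep
    }
    if (keep_reps) {
      reps[[2L * l - 1L]] <- layer_representation(l, "pre", t(cols), dims)
      reps[[2L * l]] <- layer_representation(l, "post", t(post), dims)
    }
    if (keep_cache) {
      cache[[l]] <- list(cols = cols, xhat = xhat, mu = mu, va = va,
                         relu_mask = a > 0, mask = mask)
    }
    h <- post
  }
  logits <- net$out$W %*% h + net$out$b
  prob <- softmax_cols(logits)
  list(prob = prob, logits = logits, h_last = h, reps = reps, cache = cache, dims = dims)
}

softmax_cols <- function(z) {
  mx <- do.call(pmax, lapply(seq_len(nrow(z)), function(i) z[i, ]))
  e <- exp(sweep(z, 2, mx, "-"))
  sweep(e, 2, colSums(e), "/")
}

#' Per-voxel feature representation at one layer/stage
#'
#' `stage = "pre"` holds the spatially aggregated (neighborhood-concatenated)
#' vectors entering layer `layer` (width `27 * C_{layer-1}`); `stage =
#' "post"` holds the ReLU(BN(conv)) output of that layer (width `C_layer`).
#'
#' @param layer 1-based layer index.
#' @param stage `"pre"` or `"post"`.
#' @param values `voxels x features` matrix (voxels in column-major grid
#'   order).
#' @param grid integer length-3 spatial grid.
#' @export
layer_representation <- function(layer, stage, values, grid) {
  stage <- match.arg(stage, c("pre", "post"))
  structure(list(layer = as.integer(layer), stage = stage,
                 values = values, grid = as.integer(grid)),
            class = "layer_representation")
}

#' @export
print.layer_representation <- function(x, ...) {
  cat(sprintf("<layer_representation> layer %d (%s), %d voxels x %d features, grid %s\n",
              x$layer, x$stage, nrow(x$values), ncol(x$values),
              paste(x$grid, collapse = "x")))
  invisible(x)
}

#' Per-voxel probability map
#'
#' @param values 3-D numeric array of scores in `[0, 1]`.
#' @param semantics one of `"fcn_output"`, `"embedding_output"`,
#'   `"calibrated"`, `"baseline"`.
#' @param logits optional matching array of (binary) logits.
#' @param provenance list of provenance fields (layer, stage, calibration
#'   constants, method, ...).
#' @export
probability_map <- function(values, semantics = "fcn_output", logits = NULL,
                            provenance = list()) {
  if (length(dim(values)) != 3L) stopf("probability map values must be a 3-D array")
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9) stopf("scores must lie in [0, 1]")
  structure(list(values = clamp(values, 0, 1), semantics = semantics,
                 logits = logits, provenance = provenance),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s, grid %s, range [%.3f, %.3f]\n", x$semantics,
              paste(dim(x$values), collapse = "x"), min(x$values), max(x$values)))
  invisible(x)
}

# Binary anomaly score from a 4-class softmax matrix: viable + necrosis.
anomaly_score <- function(prob) prob[3, ] + prob[4, ]

#' Run the FCN on a volume
#'
#' Inference-mode forward pass (frozen batch-norm statistics, dropout off).
#' Accepts any spatial size.
#'
#' @param net an [fcn_network][build_fcn].
#' @param volume a [labeled_volume()] or `(channel, x, y, z)` array.
#' @return A [probability_map()] of the binary anomaly score
#'   (viable + necrosis softmax mass) with the full 4-class softmax attached
#'   as attribute `class_probs` (`n_classes x voxels`) and the binary anomaly
#'   logit in `$logits`.
#' @export
fcn_predict <- function(net, volume) {
  inp <- as_input_matrix(volume, net$spec)
  fw <- fcn_pass(net, inp$mat, inp$dims)
  make_fcn_map(fw, inp$dims)
}

make_fcn_map <- function(fw, dims, semantics = "fcn_output", provenance = list()) {
  s <- anomaly_score(fw$prob)
  z <- qlogis(clamp(s, 1e-7, 1 - 1e-7))
  m <- probability_map(array(s, dims), semantics = semantics,
                       logits = array(z, dims), provenance = provenance)
  attr(m, "class_probs") <- fw$prob
  m
}

#' Forward pass exposing every layer representation
#'
#' Returns the output probability map together with the pre- and
#' post-convolution representation of each hidden layer (20 representation
#' sets for the 10-layer baseline).
#'
#' @inheritParams fcn_predict
#' @return List with `map` (a [probability_map()]) and `reps` (list of
#'   [layer_representation()] named `l<k>_pre`, `l<k>_post`).
#' @export
forward_with_representations <- function(net, volume) {
  inp <- as_input_matrix(volume, net$spec)
  fw <- fcn_pass(net, inp$mat, inp$dims, keep_reps = TRUE)
  reps <- fw$reps
  names(reps) <- as.vector(t(outer(seq_along(net$layers),
                                   c("pre", "post"),
                                   function(l, s) paste0("l", l, "_", s))))
  list(map = make_fcn_map(fw, inp$dims), reps = reps)
}
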