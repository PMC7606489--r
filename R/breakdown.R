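# Two-step decomposition of one convolutional layer:
#   spatial aggregation  - concatenate the 27 dilated-neighborhood feature
#                          vectors of every voxel (what the next convolution
#                          COULD use), and
#   information synthesis - ReLU(BN(W %*% h_hat + b)) (what it actually
#                          keeps).
# These are deliberately implemented in plain R with array shifts, separate
# from the C++ gather used inside the network forward pass, so that the
# layer-by-layer equivalence of the two routes is a meaningful consistency
# check of both.

#' Spatial information aggregation
#'
#' Builds the pre-convolution representation entering layer `layer + 1`:
#' each voxel's vector becomes the concatenation of the 27 neighbor vectors
#' at offsets `{-d, 0, +d}^3` (d = dilation of the receiving layer),
#' zero-padded at volume boundaries. Offsets are enumerated in column-major
#' order over the (3,3,3) tap grid; within one tap, features keep their
#' channel order, so the output width is `27 * N`.
#'
#' @param rep a post-stage [layer_representation()] (or any voxels x N
#'   matrix wrapped in one).
#' @param dilation dilation of the receiving layer.
#' @return A pre-stage [layer_representation()] of width `27 * N` tagged
#'   with `layer + 1`.
#' @export
spatial_aggregate <- function(rep, dilation) {
  stopifnot(inherits(rep, "layer_representation"))
  if (rep$stage != "post") stopf("spatial_aggregate expects a post-stage representation")
  dims <- rep$grid
  V <- prod(dims)
  N <- ncol(rep$values)
  d <- as.integer(dilation)
  co <- expand_grid_coords(dims)
  out <- matrix(0, nrow = V, ncol = 27L * N)
  o <- 0L
  for (dz in c(-d, 0L, d)) for (dy in c(-d, 0L, d)) for (dx in c(-d, 0L, d)) {
    o <- o + 1L
    sx <- co[, 1] + dx; sy <- co[, 2] + dy; sz <- co[, 3] + dz
    ok <- sx >= 1 & sx <= dims[1] & sy >= 1 & sy <= dims[2] & sz >= 1 & sz <= dims[3]
    src <- (sz[ok] - 1L) * dims[1] * dims[2] + (sy[ok] - 1L) * dims[1] + sx[ok]
    out[ok, ((o - 1L) * N + 1L):(o * N)] <- rep$values[src, , drop = FALSE]
  }
  layer_representation(rep$layer + 1L, "pre", out, dims)
}

#' Information synthesis
#'
#' Applies convolution weights, inference-mode batch normalization, and the
#' ReLU activation to a pre-convolution representation, yielding the
#' post-convolution representation of the receiving layer:
#' `ReLU(gamma * (W h_hat + b - mean) / sqrt(var + eps) + beta)`.
#'
#' @param pre_rep a pre-stage [layer_representation()] of width
#'   `27 * C_in` (or `C_in` for a 1x1x1 kernel).
#' @param weights `C_out x width` flattened kernel matrix.
#' @param bias length-`C_out` bias.
#' @param bn optional list with `gamma`, `beta`, `mean`, `var` (frozen
#'   running statistics); `NULL` disables batch normalization.
#' @param eps batch-norm variance floor.
#' @return A post-stage [layer_representation()] of width `C_out`.
#' @export
information_synthesize <- function(pre_rep, weights, bias = numeric(nrow(weights)),
                                   bn = NULL, eps = bn_eps) {
  stopifnot(inherits(pre_rep, "layer_representation"))
  if (pre_rep$stage != "pre") stopf("information_synthesize expects a pre-stage representation")
  if (ncol(pre_rep$values) != ncol(weights))
    stopf("representation width %d does not match kernel width %d",
          ncol(pre_rep$values), ncol(weights))
  z <- pre_rep$values %*% t(weights)
  z <- sweep(z, 2, bias, "+")
  if (!is.null(bn)) {
    z <- sweep(sweep(z, 2, bn$mean, "-"), 2, sqrt(bn$var + eps), "/")
    z <- sweep(sweep(z, 2, bn$gamma, "*"), 2, bn$beta, "+")
  }
  layer_representation(pre_rep$layer, "post", pmax(z, 0), pre_rep$grid)
}

#' Reproduce one network layer through the aggregation/synthesis breakdown
#'
#' Convenience wrapper: takes the post-representation at layer `l` (layer 0
#' meaning the input volume) and computes the post-representation at layer
#' `l + 1` via [spatial_aggregate()] + [information_synthesize()] using the
#' network's own weights and frozen batch-norm statistics. Composing this
#' over all layers must match [forward_with_representations()].
#'
#' @param net an [fcn_network][build_fcn].
#' @param rep post-stage [layer_representation()] at layer `l` (use layer 0
#'   and the raw input channels for the first layer).
#' @return Post-stage [layer_representation()] at layer `l + 1`.
#' @export
breakdown_step <- function(net, rep) {
  l_next <- rep$layer + 1L
  if (l_next > length(net$layers)) stopf("no layer %d in this network", l_next)
  ly <- net$layers[[l_next]]
  pre <- spatial_aggregate(rep, ly$dilation)
  information_synthesize(pre, ly$W, ly$b,
                         bn = list(gamma = ly$gamma, beta = ly$beta,
                                   mean = ly$running_mean, var = ly$running_var))
}
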