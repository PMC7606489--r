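# Probability calibration of the FCN output: embedding-guided weighting
# (the package's core method) plus the three baselines — Platt scaling,
# Monte Carlo dropout averaging, and deep-ensemble averaging.

#' Embedding-guided calibration
#'
#' Voxel-wise `sigma' = a * sigma^(l) * sigma + b`, clipped to `[0, 1]`
#' (clipping only matters for non-default a, b). With the default a = 1,
#' b = 0 this is a pure down-weighting: the early-layer embedding output
#' acts as a per-voxel reliability weight, so overconfident voxels the
#' probed layer does not support are attenuated and a calibrated score can
#' never exceed the raw one.
#'
#' @param sigma raw FCN anomaly [probability_map()].
#' @param sigma_l embedding-output [probability_map()] on the same grid.
#' @param a,b affine constants (defaults 1 and 0).
#' @return A [probability_map()] with semantics `"calibrated"`; provenance
#'   records `a`, `b` and the slot of `sigma_l`.
#' @export
calibrate_with_embedding <- function(sigma, sigma_l, a = 1, b = 0) {
  stopifnot(inherits(sigma, "probability_map"), inherits(sigma_l, "probability_map"))
  if (!identical(dim(sigma$values), dim(sigma_l$values)))
    stopf("probability maps are on different grids")
  vals <- a * sigma_l$values * sigma$values + b
  clipped <- any(vals < 0 | vals > 1)
  probability_map(clamp(vals, 0, 1), semantics = "calibrated",
                  provenance = c(list(a = a, b = b, clipped = clipped,
                                      method = "embedding"),
                                 sigma_l$provenance[c("layer", "stage")]))
}

#' Select the calibration layer from a validation sweep
#'
#' Picks the (layer, stage) slot whose calibrated output optimizes the
#' criterion on validation data: minimum calibrated ACE by default, ties
#' broken by higher calibrated AUC, then earlier layer, then pre- before
#' post-stage. Only this one hyper-parameter is learned from the validation
#' set; the full ranking is attached for logging.
#'
#' @param sweep data frame from [sweep_layers()].
#' @param criterion column to minimize (default `"cal_ace"`).
#' @return List with `layer`, `stage`, `slot`; attribute `ranking` holds the
#'   ordered table.
#' @export
select_layer <- function(sweep, criterion = "cal_ace") {
  if (!nrow(sweep)) stopf("empty sweep table")
  if (!criterion %in% names(sweep)) stopf("no column '%s' in the sweep table", criterion)
  ord <- order(sweep[[criterion]], -sweep$cal_auc, sweep$layer,
               match(sweep$stage, c("pre", "post")))
  ranked <- sweep[ord, ]
  best <- ranked[1L, ]
  structure(list(layer = best$layer, stage = best$stage, slot = best$slot),
            ranking = ranked)
}

#' Fit Platt scaling on validation logits
#'
#' Finds scalars `(a, b)` minimizing the cross-entropy of
#' `sigmoid(a * z + b)` against the binary labels — logistic regression of
#' the label on the logit, solved by deterministic IRLS. Operating on the
#' binary anomaly logit keeps the fit consistent with the binary
#' evaluation; because the map `z -> a z + b` is strictly increasing for
#' `a > 0`, Platt scaling preserves the score ordering and hence AUC and
#' DSC rankings.
#'
#' @param logits numeric vector (or logit array of a [probability_map()])
#'   of binary anomaly logits.
#' @param labels binary 0/1 labels.
#' @return List with scalars `a` and `b`.
#' @export
platt_fit <- function(logits, labels) {
  z <- as.vector(if (inherits(logits, "probability_map")) logits$logits else logits)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stopf("Platt fit requires both classes")
  fit <- glm.fit(cbind(1, z), y, family = binomial())
  co <- fit$coefficients
  list(a = unname(co[2L]), b = unname(co[1L]))
}

#' Apply Platt scaling to a probability map
#'
#' @param map a [probability_map()] carrying binary logits.
#' @param scaling list with `a`, `b` from [platt_fit()].
#' @return A [probability_map()] with semantics `"baseline"` and method
#'   `"platt"`.
#' @export
platt_apply <- function(map, scaling) {
  stopifnot(inherits(map, "probability_map"))
  if (is.null(map$logits)) stopf("map carries no logits")
  z <- scaling$a * map$logits + scaling$b
  probability_map(array(plogis(z), dim(map$values)), semantics = "baseline",
                  logits = z,
                  provenance = list(method = "platt", a = scaling$a, b = scaling$b))
}

#' Monte Carlo dropout prediction
#'
#' Averages `T` stochastic forward passes with the network's 3D
#' (channel-wise) dropout active at inference time. Batch-norm stays in
#' inference mode; only the dropout masks differ between passes.
#'
#' @param net an [fcn_network][build_fcn] built with `use_dropout = TRUE`.
#' @param volume input volume or array.
#' @param n_samples number of stochastic passes `T` (>= 1, default 10).
#' @param seed integer seed for the mask draws.
#' @return A [probability_map()] of the mean anomaly score (semantics
#'   `"baseline"`, method `"mc_dropout"`), with the mean 4-class softmax as
#'   attribute `class_probs`.
#' @export
mc_dropout_predict <- function(net, volume, n_samples = 10, seed = 1L) {
  if (!net$spec$use_dropout) stopf("network has no dropout layers")
  if (n_samples < 1) stopf("need at least one sample")
  inp <- as_input_matrix(volume, net$spec)
  acc <- NULL
  with_seed(seed, {
    for (t in seq_len(n_samples)) {
      fw <- fcn_pass(net, inp$mat, inp$dims, dropout = TRUE)
      acc <- if (is.null(acc)) fw$prob else acc + fw$prob
    }
  })
  prob <- acc / n_samples
  s <- anomaly_score(prob)
  m <- probability_map(array(s, inp$dims), semantics = "baseline",
                       logits = array(qlogis(clamp(s, 1e-7, 1 - 1e-7)), inp$dims),
                       provenance = list(method = "mc_dropout", n_samples = n_samples,
                                         rate = net$spec$dropout_rate))
  attr(m, "class_probs") <- prob
  m
}

#' Deep-ensemble prediction
#'
#' Voxel-wise arithmetic mean of the member softmax outputs; members must
#' share the architecture.
#'
#' @param models list of >= 2 trained [fcn_network][build_fcn]s with
#'   identical specs.
#' @param volume input volume or array.
#' @return A [probability_map()] (semantics `"baseline"`, method
#'   `"ensemble"`) with the mean 4-class softmax attached.
#' @export
ensemble_predict <- function(models, volume) {
  if (length(models) < 2L) stopf("an ensemble needs at least 2 members")
  ref <- models[[1L]]$spec
  specs_equal <- vapply(models, function(m)
    identical(m$spec[c("channels", "in_channels", "n_classes", "dilations")],
              ref[c("channels", "in_channels", "n_classes", "dilations")]), TRUE)
  if (!all(specs_equal)) stopf("ensemble members disagree on the architecture")
  inp <- as_input_matrix(volume, ref)
  probs <- lapply(models, function(m) fcn_pass(m, inp$mat, inp$dims)$prob)
  prob <- Reduce(`+`, probs) / length(probs)
  s <- anomaly_score(prob)
  m <- probability_map(array(s, inp$dims), semantics = "baseline",
                       logits = array(qlogis(clamp(s, 1e-7, 1 - 1e-7)), inp$dims),
                       provenance = list(method = "ensemble", n_members = length(models)))
  attr(m, "class_probs") <- prob
  m
}
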