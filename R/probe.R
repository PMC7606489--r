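# Layer-embedding probing: fit one auxiliary classifier per (layer, stage)
# slot on training-set per-voxel representations and evaluate its
# "embedding output" sigma^(l) on unseen volumes. Random forests (20 trees)
# are the workhorse; an exact k-nearest-neighbor estimator is provided as
# the non-parametric alternative.

slot_name <- function(layer, stage) paste0("l", layer, "_", stage)

# Extract one slot's representation matrix from a forward_with_representations
# result.
get_slot <- function(reps, layer, stage) {
  r <- reps[[slot_name(layer, stage)]]
  if (is.null(r)) stopf("no representation for layer %d stage %s", layer, stage)
  r
}

#' Collect training representations for one layer/stage slot
#'
#' Runs the network over each training volume, extracts the per-voxel
#' representation at the requested slot, subsamples voxels (seeded, at the
#' natural class prevalence but guaranteeing a minimum per class where
#' available), and binarizes labels to anomaly (viable + necrosis) vs
#' non-anomaly.
#'
#' @param net trained [fcn_network][build_fcn].
#' @param volumes list of labeled training volumes.
#' @param layer layer index.
#' @param stage `"pre"` or `"post"`.
#' @param n_per_volume voxels sampled per volume (capped at the voxel
#'   count; default 2000).
#' @param seed integer seed.
#' @param min_per_class minimum voxels per class kept per volume when the
#'   volume contains that class (default 25).
#' @param mask_background drop background voxels before sampling (default
#'   `FALSE`: background counts as non-anomaly).
#' @return List with `features` (matrix) and `labels` (0/1 integer vector).
#'   A volume without anomaly voxels contributes only negatives (with a
#'   warning).
#' @export
collect_training_representations <- function(net, volumes, layer, stage,
                                             n_per_volume = 2000, seed = 1L,
                                             min_per_class = 25,
                                             mask_background = FALSE) {
  stage <- match.arg(stage, c("pre", "post"))
  feats <- list(); labs <- list()
  for (i in seq_along(volumes)) {
    fr <- forward_with_representations(net, volumes[[i]])
    rep <- get_slot(fr$reps, layer, stage)
    y <- as.vector(anomaly_mask(volumes[[i]]))
    keep <- if (mask_background) which(as.vector(volumes[[i]]$labels) != 0L) else
      seq_along(y)
    if (!any(y[keep] == 1L))
      warning(sprintf("volume %d contributes no anomaly voxels", i))
    idx <- subsample_stratified(y[keep], n_per_volume, child_seed(seed, i), min_per_class)
    sel <- keep[idx]
    feats[[i]] <- rep$values[sel, , drop = FALSE]
    labs[[i]] <- y[sel]
  }
  list(features = do.call(rbind, feats), labels = as.integer(unlist(labs)))
}

# Seeded subsample of indices preserving the class mix, with a floor of
# min_per_class per present class. Returns all indices if n >= length(y).
subsample_stratified <- function(y, n, seed, min_per_class = 25) {
  if (n >= length(y)) return(seq_along(y))
  with_seed(seed, {
    idx <- sample.int(length(y), n)
    for (cls in unique(y)) {
      have <- sum(y[idx] == cls)
      pool <- which(y == cls)
      want <- min(min_per_class, length(pool))
      if (have < want) {
        pick <- function(x, size) x[sample.int(length(x), size)]  # length-1 safe
        extra <- pick(setdiff(pool, idx), want - have)
        # replace random majority picks to keep the total at n
        drop <- pick(which(!(idx %in% pool)), length(extra))
        idx[drop] <- extra
      }
    }
    sort(idx)
  })
}

#' Fit an embedding model on representation features
#'
#' @param features numeric matrix (samples x features).
#' @param labels binary 0/1 labels; both classes must be present.
#' @param kind `"random_forest"` (default; `ranger` probability forest with
#'   `trees` trees, remaining hyper-parameters at ranger defaults) or
#'   `"knn"` (exact Euclidean k-nearest neighbors, ties broken by lower
#'   training index).
#' @param trees random-forest tree count (default 20).
#' @param k neighbor count for `kind = "knn"` (default 5).
#' @param seed integer seed (forests are deterministic given the seed;
#'   prediction is single-threaded).
#' @param layer,stage optional slot provenance recorded in the model.
#' @param manifest optional list (subject ids, subsample seed/size)
#'   recorded verbatim.
#' @return An object of class `embedding_model`.
#' @export
fit_embedding_model <- function(features, labels, kind = c("random_forest", "knn"),
                                trees = 20, k = 5, seed = 1L,
                                layer = NA_integer_, stage = NA_character_,
                                manifest = list()) {
  kind <- match.arg(kind)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present to fit an embedding model")
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- if (kind == "random_forest") {
    ranger::ranger(x = features, y = factor(labels, levels = c(0L, 1L)),
                   probability = TRUE, num.trees = trees,
                   seed = seed, num.threads = 1)
  } else {
    list(train = features, labels = labels, k = as.integer(k))
  }
  structure(list(kind = kind, fit = fit, layer = as.integer(layer), stage = stage,
                 trees = trees, k = as.integer(k), seed = as.integer(seed),
                 n_features = ncol(features),
                 manifest = manifest),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %s, slot %s, %d features\n", x$kind,
              if (is.na(x$layer)) "?" else slot_name(x$layer, x$stage), x$n_features))
  invisible(x)
}

# Anomaly-class probability for a feature matrix.
predict_embedding_probs <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stopf("feature width %d does not match the model's %d", ncol(features), model$n_features)
  if (model$kind == "random_forest") {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
    p <- predict(model$fit, data = features, num.threads = 1)$predictions
    as.vector(p[, "1"])
  } else {
    dknn_embedding_output(features, model$fit$train, model$fit$labels, model$fit$k)
  }
}

#' Per-voxel embedding output on a volume
#'
#' Runs the network, extracts the model's (layer, stage) representation at
#' every voxel, and returns the estimator's anomaly-class probability as a
#' probability map tagged with the slot.
#'
#' @param model an [embedding_model][fit_embedding_model] with slot
#'   provenance.
#' @param net the [fcn_network][build_fcn] the model was fitted against.
#' @param volume a [labeled_volume()] (labels unused) or intensity array.
#' @param reps optional precomputed representations from
#'   [forward_with_representations()] (avoids repeating the forward pass
#'   when scoring many slots on one volume).
#' @return A [probability_map()] with semantics `"embedding_output"`.
#' @export
predict_embedding_output <- function(model, net, volume, reps = NULL) {
  if (is.na(model$layer)) stopf("model carries no layer/stage provenance")
  if (is.null(reps)) reps <- forward_with_representations(net, volume)$reps
  r <- get_slot(reps, model$layer, model$stage)
  p <- predict_embedding_probs(model, r$values)
  probability_map(array(p, r$grid), semantics = "embedding_output",
                  provenance = list(layer = model$layer, stage = model$stage,
                                    kind = model$kind))
}

#' Deep k-nearest-neighbor embedding output
#'
#' For each query vector, the anomaly-class frequency among its `k` nearest
#' training vectors under Euclidean distance; distance ties are broken by
#' the lower training index.
#'
#' @param query matrix of query vectors (rows).
#' @param train matrix of training vectors (rows).
#' @param labels binary 0/1 labels of the training rows.
#' @param k neighbor count, `1 <= k <= nrow(train)`.
#' @return Numeric vector of anomaly probabilities.
#' @export
dknn_embedding_output <- function(query, train, labels, k) {
  if (k <= 0) stopf("k must be positive")
  cpp_knn_freq(as.matrix(query), as.matrix(train), as.integer(labels), as.integer(k))
}

#' Fit embedding models for every (layer, stage) slot
#'
#' @inheritParams collect_training_representations
#' @param kind estimator kind passed to [fit_embedding_model()].
#' @param trees,k estimator hyper-parameters.
#' @param subject_ids optional ids recorded in each model's manifest.
#' @return Named list of 20 [embedding_model][fit_embedding_model]s (for the
#'   10-layer baseline), names `l<k>_pre` / `l<k>_post`.
#' @export
fit_all_embedding_models <- function(net, volumes, kind = "random_forest",
                                     n_per_volume = 2000, seed = 1L,
                                     trees = 20, k = 5,
                                     mask_background = FALSE,
                                     subject_ids = NULL) {
  n_layers <- length(net$layers)
  # one forward pass per volume, reused across all slots
  fwd <- lapply(volumes, function(v) forward_with_representations(net, v)$reps)
  ys <- lapply(volumes, function(v) as.vector(anomaly_mask(v)))
  keeps <- lapply(volumes, function(v)
    if (mask_background) which(as.vector(v$labels) != 0L) else seq_along(v$labels))
  sel <- lapply(seq_along(volumes), function(i)
    keeps[[i]][subsample_stratified(ys[[i]][keeps[[i]]], n_per_volume,
                                    child_seed(seed, i))])
  labs <- as.integer(unlist(lapply(seq_along(volumes), function(i) ys[[i]][sel[[i]]])))
  models <- list()
  for (l in seq_len(n_layers)) for (st in c("pre", "post")) {
    feats <- do.call(rbind, lapply(seq_along(volumes), function(i)
      get_slot(fwd[[i]], l, st)$values[sel[[i]], , drop = FALSE]))
    models[[slot_name(l, st)]] <-
      fit_embedding_model(feats, labs, kind = kind, trees = trees, k = k,
                          seed = child_seed(seed, 100L * l + (st == "post")),
                          layer = l, stage = st,
                          manifest = list(subject_ids = subject_ids,
                                          n_per_volume = n_per_volume,
                                          subsample_seed = seed))
  }
  models
}

#' Sweep embedding-output performance over all layers and stages
#'
#' For every (layer, stage) slot, scores the slot's embedding output and the
#' embedding-calibrated FCN output (`sigma' = sigma^(l) * sigma`, a = 1,
#' b = 0) on the given volumes, pooling voxels across volumes, and reports
#' ACE, AUC and DSC for both.
#'
#' @param net trained [fcn_network][build_fcn].
#' @param models named slot list from [fit_all_embedding_models()].
#' @param volumes evaluation volumes (labels required).
#' @param n_bins,mode,threshold metric settings (see [reliability_bins()]).
#' @return Data frame with one row per slot: `layer`, `stage`, `slot`,
#'   `ace`, `auc`, `dsc` (embedding output) and `cal_ace`, `cal_auc`,
#'   `cal_dsc` (calibrated output using that slot).
#' @export
sweep_layers <- function(net, models, volumes, n_bins = 10,
                         mode = "positive_frequency", threshold = 0.5) {
  n_layers <- length(net$layers)
  need <- as.vector(sapply(seq_len(n_layers), function(l) slot_name(l, c("pre", "post"))))
  missing <- setdiff(need, names(models))
  if (length(missing)) stopf("missing embedding models for slot(s): %s",
                             paste(missing, collapse = ", "))
  y <- unlist(lapply(volumes, function(v) as.vector(anomaly_mask(v))))
  fwd <- lapply(volumes, function(v) forward_with_representations(net, v))
  sigma <- unlist(lapply(fwd, function(f) as.vector(f$map$values)))
  rows <- lapply(need, function(sl) {
    m <- models[[sl]]
    emb <- unlist(lapply(seq_along(volumes), function(i)
      predict_embedding_probs(m, get_slot(fwd[[i]]$reps, m$layer, m$stage)$values)))
    cal <- clamp(emb * sigma, 0, 1)
    er <- reliability_report(emb, y, n_bins = n_bins, mode = mode, threshold = threshold)
    cr <- reliability_report(cal, y, n_bins = n_bins, mode = mode, threshold = threshold)
    data.frame(layer = m$layer, stage = m$stage, slot = sl,
               ace = er$ace, auc = er$auc, dsc = er$dsc,
               cal_ace = cr$ace, cal_auc = cr$auc, cal_dsc = cr$dsc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
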