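# Patch-wise training of the FCN: class-weighted voxel cross-entropy,
# Adam, subject-level cross-validation folds, and seed-varied ensembles.
# Backpropagation runs per patch (batch statistics for BN are computed over
# the voxels of each patch; gradients are averaged over the mini-batch of
# patches before each Adam step).

#' Subject-level k-fold split
#'
#' Shuffles subjects once (seeded) and partitions them into `n_folds`
#' contiguous test blocks; for fold `i`, the following block is the
#' validation set and the remainder trains, giving the 60/20/20 ratio for
#' five folds. Every subject is in the test split of exactly one fold.
#'
#' @param subject_ids character or integer vector of subject identifiers.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return List of `fold_split` objects with fields `fold`, `train`,
#'   `validation`, `test`, `seed`.
#' @export
kfold_split <- function(subject_ids, n_folds = 5, seed = 1L) {
  n <- length(subject_ids)
  if (n < n_folds) stopf("need at least %d subjects for %d folds", n_folds, n_folds)
  if (anyDuplicated(subject_ids)) stopf("subject ids must be unique")
  perm <- with_seed(seed, sample(subject_ids))
  blocks <- split(perm, cut(seq_len(n), breaks = n_folds, labels = FALSE))
  lapply(seq_len(n_folds), function(i) {
    test <- blocks[[i]]
    val <- blocks[[if (i == n_folds) 1L else i + 1L]]
    train <- setdiff(perm, c(test, val))
    structure(list(fold = i, train = train, validation = val, test = test,
                   seed = as.integer(seed)),
              class = "fold_split")
  })
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size patches per Adam step.
#' @param lr Adam learning rate.
#' @param patch_edge cubic patch edge (default 44).
#' @param patches_per_epoch patches sampled per epoch.
#' @param class_weights length-4 loss weights, or `NULL` for inverse class
#'   frequency estimated from the training volumes (normalized to mean 1).
#' @param anomaly_fraction fraction of sampled patches forced to contain
#'   anomaly voxels.
#' @param augment_kinds subset of `c("contrast","deform","noise")` applied
#'   to each sampled patch (default none).
#' @param seed master seed for sampling, augmentation, and dropout.
#' @param ensemble_size default member count for [train_ensemble()].
#' @param mc_samples default Monte Carlo dropout sample count.
#' @export
train_config <- function(epochs = 10, batch_size = 2, lr = 1e-3,
                         patch_edge = 44, patches_per_epoch = 8,
                         class_weights = NULL, anomaly_fraction = 0.5,
                         augment_kinds = character(0),
                         seed = 1L, ensemble_size = 5, mc_samples = 10) {
  stopifnot(epochs >= 0, is_count(batch_size), lr > 0, is_count(patch_edge),
            is_count(patches_per_epoch), is_count(ensemble_size), is_count(mc_samples))
  if (!is.null(class_weights) && length(class_weights) != 4L)
    stopf("class_weights must have length 4")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, patch_edge = as.integer(patch_edge),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 class_weights = class_weights, anomaly_fraction = anomaly_fraction,
                 augment_kinds = augment_kinds, seed = as.integer(seed),
                 ensemble_size = as.integer(ensemble_size),
                 mc_samples = as.integer(mc_samples)),
            class = "train_config")
}

# Inverse-frequency class weights over a list of labeled volumes,
# normalized to mean 1; frequencies floored at 1e-4 to bound the weights.
inverse_frequency_weights <- function(volumes) {
  counts <- Reduce(`+`, lapply(volumes, function(v)
    tabulate(as.integer(v$labels) + 1L, nbins = 4L)))
  freq <- pmax(counts / sum(counts), 1e-4)
  w <- 1 / freq
  w / mean(w)
}

# ---- backprop ---------------------------------------------------------------

# Class-weighted softmax cross-entropy over voxels.
# labels: integer vector in 0..3; weights: length-4.
# Returns loss and the gradient at the logits (n_classes x V).
weighted_ce <- function(prob, labels, weights) {
  V <- length(labels)
  wi <- weights[labels + 1L]
  wtot <- sum(wi)
  idx <- cbind(labels + 1L, seq_len(V))
  p_true <- pmax(prob[idx], 1e-12)
  loss <- sum(wi * -log(p_true)) / wtot
  g <- sweep(prob, 2, wi, "*")
  g[idx] <- g[idx] - wi
  list(loss = loss, grad = g / wtot)
}

# Backward pass through the cached forward; returns gradient list mirroring
# the parameter structure.
fcn_backward <- function(net, fw, dlogits, dims) {
  grads <- list(out = list(W = tcrossprod(dlogits, fw$h_last), b = rowSums(dlogits)),
                layers = vector("list", length(net$layers)))
  dh <- crossprod(net$out$W, dlogits)
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]; ca <- fw$cache[[l]]
    if (!is.null(ca$mask)) dh <- dh * ca$mask
    dh <- dh * ca$relu_mask
    # batch-norm backward (batch statistics over the V voxels)
    dgamma <- rowSums(dh * ca$xhat)
    dbeta <- rowSums(dh)
    dxhat <- dh * ly$gamma
    Nv <- ncol(dh)
    invstd <- 1 / sqrt(ca$va + bn_eps)
    dz <- (invstd / Nv) * (Nv * dxhat - rowSums(dxhat) - ca$xhat * rowSums(dxhat * ca$xhat))
    grads$layers[[l]] <- list(W = tcrossprod(dz, ca$cols), b = rowSums(dz),
                              gamma = dgamma, beta = dbeta)
    if (l > 1L) {
      dcols <- crossprod(ly$W, dz)
      dh <- cpp_col2im(dcols, dims[1], dims[2], dims[3], ly$dilation)
    }
  }
  grads
}

adam_state_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(out = zero_like(net$out[c("W", "b")]),
                layers = lapply(net$layers, function(ly) zero_like(ly[c("W", "b", "gamma", "beta")]))),
       v = list(out = zero_like(net$out[c("W", "b")]),
                layers = lapply(net$layers, function(ly) zero_like(ly[c("W", "b", "gamma", "beta")]))),
       t = 0L)
}

adam_update <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t; corr2 <- 1 - beta2^st$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in c("W", "b")) {
    u <- upd(net$out[[nm]], grads$out[[nm]], st$m$out[[nm]], st$v$out[[nm]])
    net$out[[nm]] <- u$p; st$m$out[[nm]] <- u$m; st$v$out[[nm]] <- u$v
  }
  for (l in seq_along(net$layers)) for (nm in c("W", "b", "gamma", "beta")) {
    u <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
             st$m$layers[[l]][[nm]], st$v$layers[[l]][[nm]])
    net$layers[[l]][[nm]] <- u$p; st$m$layers[[l]][[nm]] <- u$m; st$v$layers[[l]][[nm]] <- u$v
  }
  list(net = net, state = st)
}

scale_grads <- function(g, f) rapply(g, function(x) x * f, how = "replace")
add_grads <- function(a, b) {
  if (is.list(a)) mapply(add_grads, a, b, SIMPLIFY = FALSE) else a + b
}

#' Train the FCN on labeled volumes
#'
#' Minimizes class-weighted voxel-wise cross-entropy over randomly sampled
#' cubic patches with Adam. Batch-norm running statistics are updated with
#' momentum 0.1 during training and frozen at inference. Fully seeded: two
#' runs with the same inputs and config produce identical weights.
#'
#' @param net an [fcn_network][build_fcn].
#' @param volumes list of training [labeled_volume()]s.
#' @param config a [train_config()].
#' @return List with the trained `net` and `loss` (per-epoch mean loss).
#' @export
train_fcn <- function(net, volumes, config) {
  stopifnot(inherits(net, "fcn_network"), inherits(config, "train_config"))
  if (!length(volumes)) stopf("empty training set")
  weights <- config$class_weights %||% inverse_frequency_weights(volumes)
  if (config$epochs == 0L) return(list(net = net, loss = numeric(0), class_weights = weights))
  st <- adam_state_init(net)
  trace <- numeric(config$epochs)
  momentum <- 0.1
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      # sample this epoch's patches across volumes
      vol_idx <- sample.int(length(volumes), config$patches_per_epoch, replace = TRUE)
      patches <- lapply(seq_len(config$patches_per_epoch), function(i) {
        p <- extract_patches(volumes[[vol_idx[i]]],
                             min(config$patch_edge, min(dim(volumes[[vol_idx[i]]]$labels))),
                             1L, seed = sample.int(.Machine$integer.max, 1L),
                             anomaly_fraction = config$anomaly_fraction)[[1L]]
        if (length(config$augment_kinds))
          p <- augment(p, config$augment_kinds, seed = sample.int(.Machine$integer.max, 1L))
        p
      })
      losses <- numeric(0)
      b0 <- 1L
      while (b0 <= length(patches)) {
        batch <- patches[b0:min(b0 + config$batch_size - 1L, length(patches))]
        b0 <- b0 + config$batch_size
        acc <- NULL
        for (p in batch) {
          inp <- as_input_matrix(p, net$spec)
          fw <- fcn_pass(net, inp$mat, inp$dims, train = TRUE,
                         dropout = net$spec$use_dropout, keep_cache = TRUE)
          ce <- weighted_ce(fw$prob, as.integer(p$labels), weights)
          if (!is.finite(ce$loss))
            stopf("non-finite loss at epoch %d; lower the learning rate", ep)
          losses <- c(losses, ce$loss)
          g <- fcn_backward(net, fw, ce$grad, inp$dims)
          acc <- if (is.null(acc)) g else add_grads(acc, g)
          # update BN running statistics from this patch's batch stats
          for (l in seq_along(net$layers)) {
            net$layers[[l]]$running_mean <-
              (1 - momentum) * net$layers[[l]]$running_mean + momentum * fw$cache[[l]]$mu
            net$layers[[l]]$running_var <-
              (1 - momentum) * net$layers[[l]]$running_var + momentum * fw$cache[[l]]$va
          }
        }
        acc <- scale_grads(acc, 1 / length(batch))
        u <- adam_update(net, acc, st, config$lr)
        net <- u$net; st <- u$state
      }
      trace[ep] <- mean(losses)
    }
  })
  list(net = net, loss = trace, class_weights = weights)
}

#' Train a seed-varied ensemble
#'
#' Members share the architecture, training data, and schedule; only the
#' weight-initialization and patch-sampling seeds differ.
#'
#' @param spec an [fcn_spec()].
#' @param volumes training volumes.
#' @param config a [train_config()]; member `i` uses seeds derived from
#'   `config$seed` and `i`.
#' @param n_models ensemble size (>= 2, default `config$ensemble_size`).
#' @return List of trained [fcn_network][build_fcn]s.
#' @export
train_ensemble <- function(spec, volumes, config, n_models = config$ensemble_size) {
  if (n_models < 2) stopf("an ensemble needs at least 2 members")
  lapply(seq_len(n_models), function(i) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, i)
    net <- build_fcn(spec, seed = child_seed(config$seed, 1000L + i))
    train_fcn(net, volumes, cfg)$net
  })
}
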