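# embedding_probe: representation collection, RF/DkNN estimators, layer sweep.

test_that("layer-1 pre-stage features have width 81 for a 3-channel input", {
  fx <- toy_training_fixture()
  col <- collect_training_representations(fx$net, fx$train_vols[1], layer = 1,
                                          stage = "pre", n_per_volume = 100, seed = 1)
  expect_equal(ncol(col$features), 81)   # 3 channels x 27 offsets
  expect_equal(nrow(col$features), 100)
  expect_true(all(col$labels %in% c(0L, 1L)))
})

test_that("n_per_volume above the voxel count takes every voxel once", {
  fx <- toy_training_fixture()
  v <- fx$train_vols[[1]]
  col <- collect_training_representations(fx$net, list(v), layer = 1, stage = "post",
                                          n_per_volume = 1e6, seed = 1)
  expect_equal(nrow(col$features), length(v$labels))
  expect_identical(col$labels, as.integer(as.vector(anomaly_mask(v))))
})

test_that("collected labels binarize anomaly vs non-anomaly", {
  fx <- toy_training_fixture()
  v <- fx$train_vols[[1]]
  col <- collect_training_representations(fx$net, list(v), layer = 2, stage = "post",
                                          n_per_volume = 1e6, seed = 1)
  expect_identical(col$labels, as.integer(as.vector(v$labels) >= 2L))
})

test_that("a lesion-free volume contributes only negatives with a warning", {
  fx <- toy_training_fixture()
  v <- generate_phantom(phantom_config(noise_sd = 2, n_tumors = c(0, 0), seed = 3))
  expect_warning(
    col <- collect_training_representations(fx$net, list(v), layer = 1, stage = "post",
                                            n_per_volume = 200, seed = 1),
    "no anomaly")
  expect_true(all(col$labels == 0L))
})

test_that("stratified subsampling keeps a minimum per class", {
  y <- c(rep(1L, 30), rep(0L, 9970))
  idx <- layercal:::subsample_stratified(y, 100, seed = 4, min_per_class = 25)
  expect_length(idx, 100)
  expect_gte(sum(y[idx] == 1L), 25)
  # determinism
  expect_identical(idx, layercal:::subsample_stratified(y, 100, seed = 4, min_per_class = 25))
})

test_that("random forest fits separable 2-D toy features", {
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  X <- with_seed(5, cbind(rnorm(n, 4 * y), rnorm(n, -4 * y)))
  m <- fit_embedding_model(X, y, kind = "random_forest", seed = 1)
  p <- layercal:::predict_embedding_probs(m, X)
  expect_gte(compute_auc(p, y), 0.99)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("RF refits and duplicate rows are deterministic", {
  y <- rep(c(0L, 1L), each = 50)
  X <- with_seed(2, cbind(rnorm(100, 2 * y), rnorm(100)))
  m1 <- fit_embedding_model(X, y, seed = 9)
  m2 <- fit_embedding_model(X, y, seed = 9)
  q <- with_seed(3, matrix(rnorm(40), ncol = 2))
  expect_identical(layercal:::predict_embedding_probs(m1, q),
                   layercal:::predict_embedding_probs(m2, q))
  # duplicated query rows get identical predictions
  qq <- rbind(q, q)
  pp <- layercal:::predict_embedding_probs(m1, qq)
  expect_identical(pp[1:20], pp[21:40])
})

test_that("single-class labels are rejected", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_embedding_model(X, rep(1L, 10)), "both classes")
})

test_that("embedding output maps the whole volume with slot provenance", {
  fx <- toy_training_fixture()
  v <- fx$train_vols[[1]]
  col <- collect_training_representations(fx$net, fx$train_vols, layer = 2,
                                          stage = "post", n_per_volume = 300, seed = 2)
  m <- fit_embedding_model(col$features, col$labels, seed = 3, layer = 2, stage = "post")
  map <- predict_embedding_output(m, fx$net, v)
  expect_s3_class(map, "probability_map")
  expect_equal(map$semantics, "embedding_output")
  expect_equal(dim(map$values), dim(v$labels))
  expect_equal(map$provenance$layer, 2L)
  expect_equal(map$provenance$stage, "post")
  expect_true(all(map$values >= 0 & map$values <= 1))
})

test_that("a constant estimator yields a uniform map", {
  fx <- toy_training_fixture()
  # two coincident training points with opposite labels force every k=2
  # neighborhood to a 50/50 histogram
  width <- length(fx$net$layers[[1]]$gamma)
  m <- fit_embedding_model(matrix(0, 2, width), c(0L, 1L), kind = "knn", k = 2,
                           layer = 1, stage = "post")
  map <- predict_embedding_output(m, fx$net, fx$train_vols[[1]])
  expect_true(all(map$values == 0.5))
})

test_that("DkNN histogram matches hand cases", {
  train <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  expect_equal(dknn_embedding_output(matrix(c(0, 0), 1), train, c(1L, 1L, 0L), k = 3),
               2 / 3)
  expect_equal(dknn_embedding_output(matrix(c(5, 5), 1), train, c(1L, 1L, 1L), k = 2), 1)
  expect_equal(dknn_embedding_output(matrix(c(5, 5), 1), train, c(0L, 0L, 0L), k = 2), 0)
  expect_error(dknn_embedding_output(matrix(0, 1, 2), train, c(1L, 0L, 1L), k = 0),
               "positive")
})

test_that("DkNN matches a brute-force distance-sort oracle on 200 points", {
  set.seed(42)
  train <- matrix(round(rnorm(100 * 5), 1), ncol = 5)  # rounding forces ties
  labels <- rbinom(100, 1, 0.5)
  query <- matrix(round(rnorm(200 * 5), 1), ncol = 5)
  for (k in c(1L, 5L)) {
    got <- dknn_embedding_output(query, train, labels, k)
    oracle <- apply(query, 1, function(q) {
      d <- colSums((t(train) - q)^2)
      # stable order: ties broken by lower training index
      nb <- order(d, seq_along(d))[1:k]
      mean(labels[nb])
    })
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("RF and DkNN agree on well-separated Gaussian blobs", {
  n <- 2000
  y <- rep(c(0L, 1L), each = n / 2)
  X <- with_seed(6, cbind(rnorm(n, 5 * y), rnorm(n, -5 * y)))
  q_y <- rep(c(0L, 1L), each = 250)
  Q <- with_seed(7, cbind(rnorm(500, 5 * q_y), rnorm(500, -5 * q_y)))
  rf <- fit_embedding_model(X, y, kind = "random_forest", seed = 1)
  kn <- fit_embedding_model(X, y, kind = "knn", k = 5)
  p_rf <- layercal:::predict_embedding_probs(rf, Q)
  p_kn <- layercal:::predict_embedding_probs(kn, Q)
  concord <- mean((p_rf >= 0.5) == (p_kn >= 0.5))
  expect_gte(concord, 0.95)
})

test_that("deep layers probe at least as well as layer 1 when context is required", {
  # high-noise phantoms are barely separable voxel-wise, so the added spatial
  # context of deep representations must show up as probe AUC
  fx <- probe_fixture()
  models <- lapply(c(1L, 10L), function(l) {
    col <- collect_training_representations(fx$net, fx$train_vols, layer = l,
                                            stage = "post", n_per_volume = 500,
                                            seed = 11)
    fit_embedding_model(col$features, col$labels, seed = 12, layer = l, stage = "post")
  })
  for (v in list(fx$train_vols[[1]], fx$test_vol)) {
    fr <- forward_with_representations(fx$net, v)
    y <- anomaly_mask(v)
    a <- vapply(models, function(m)
      compute_auc(predict_embedding_output(m, fx$net, v, reps = fr$reps), y), 0)
    expect_gte(a[2], a[1])  # layer 10 post >= layer 1 post
  }
})

test_that("sweep covers all 20 slots of a 10-layer net and is deterministic", {
  fx <- probe_fixture()
  models <- fit_all_embedding_models(fx$net, fx$train_vols[1], n_per_volume = 300,
                                     seed = 21)
  expect_length(models, 20)
  expect_setequal(names(models),
                  as.vector(outer(paste0("l", 1:10), c("_pre", "_post"), paste0)))
  eval_vol <- generate_phantom(phantom_config(shape = c(16, 16, 16), noise_sd = 40,
                                              seed = 30))
  sw1 <- sweep_layers(fx$net, models, list(eval_vol))
  expect_equal(nrow(sw1), 20)
  expect_setequal(sw1$slot, names(models))
  expect_true(all(c("ace", "auc", "dsc", "cal_ace", "cal_auc", "cal_dsc") %in% names(sw1)))
  expect_true(all(sw1$ace >= 0 & sw1$ace <= 1))
  sw2 <- sweep_layers(fx$net, models, list(eval_vol))
  expect_identical(sw1, sw2)
  # missing slot is a typed error
  expect_error(sweep_layers(fx$net, models[-1], list(eval_vol)), "missing embedding")
})

test_that("probe manifests record the training subjects (leakage bookkeeping)", {
  fx <- toy_training_fixture()
  models <- fit_all_embedding_models(fx$net, fx$train_vols[1], n_per_volume = 100,
                                     seed = 2, subject_ids = "S01")
  expect_equal(models$l1_pre$manifest$subject_ids, "S01")
  expect_equal(models$l1_pre$manifest$n_per_volume, 100)
})
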