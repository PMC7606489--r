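# End-to-end reproducible experiment: generate (or load) subjects, split
# into subject-level folds, train the FCN, probe all 20 layer/stage slots,
# sweep the validation set, select the calibration layer, calibrate, and
# evaluate every method on the held-out test subjects. Every artifact is
# reachable from a JSON manifest carrying content hashes, so a rerun with
# the same config reproduces the output tree byte-for-byte.

#' Experiment configuration
#'
#' Defaults define the package's canonical desk-scale phantom study: 10
#' synthetic subjects on a 24^3 grid, a narrow 10-layer FCN (channels
#' 8,8,12,12,16,16,12,12,8,8 with the standard dilation ladder and dropout
#' rate 0.1), 16^3 training patches, one evaluated fold of a 5-fold
#' subject-level split, random-forest probes with 20 trees, and
#' positive-frequency reliability metrics with 10 bins.
#'
#' @param n_subjects number of synthetic subjects.
#' @param phantom a [phantom_config()] (its seed is re-derived per subject).
#' @param arch an [fcn_spec()].
#' @param train a [train_config()].
#' @param probe list: `kind`, `n_per_volume`, `trees`, `k`,
#'   `mask_background`.
#' @param calibration list: `a`, `b` (embedding calibration constants) and
#'   `criterion` for [select_layer()].
#' @param metrics list: `n_bins`, `mode`, `threshold`.
#' @param methods character subset of
#'   `c("raw", "embedding", "platt", "mc_dropout", "ensemble")`.
#' @param n_folds folds in the subject split.
#' @param folds which fold indices to run (default 1).
#' @param ensemble_size members for the ensemble baseline.
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10,
                              phantom = phantom_config(),
                              arch = fcn_spec(channels = c(8, 8, 12, 12, 16, 16, 12, 12, 8, 8),
                                              use_dropout = TRUE, dropout_rate = 0.1),
                              train = train_config(epochs = 12, batch_size = 2,
                                                   patch_edge = 16, patches_per_epoch = 8),
                              probe = list(kind = "random_forest", n_per_volume = 400,
                                           trees = 20, k = 5, mask_background = FALSE),
                              calibration = list(a = 1, b = 0, criterion = "cal_ace"),
                              metrics = list(n_bins = 10, mode = "positive_frequency",
                                             threshold = 0.5),
                              methods = c("raw", "embedding", "platt", "mc_dropout", "ensemble"),
                              n_folds = 5, folds = 1,
                              ensemble_size = 2,
                              seed = 1L) {
  methods <- match.arg(methods, c("raw", "embedding", "platt", "mc_dropout", "ensemble"),
                       several.ok = TRUE)
  stopifnot(inherits(phantom, "phantom_config"), inherits(arch, "fcn_spec"),
            inherits(train, "train_config"), n_subjects >= n_folds)
  if ("mc_dropout" %in% methods && !arch$use_dropout)
    stopf("mc_dropout method requires an architecture with use_dropout = TRUE")
  structure(list(n_subjects = as.integer(n_subjects), phantom = phantom, arch = arch,
                 train = train, probe = probe, calibration = calibration,
                 metrics = metrics, methods = methods,
                 n_folds = as.integer(n_folds), folds = as.integer(folds),
                 ensemble_size = as.integer(ensemble_size), seed = as.integer(seed)),
            class = "experiment_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage %s] %s", name, conditionMessage(e)))
}

#' Run a full calibration experiment
#'
#' Executes the pipeline described in [experiment_config()] and, when
#' `out_dir` is given, writes subject volumes (NIfTI), per-fold sweep /
#' selection / report tables (CSV), loss traces, and a JSON manifest with
#' md5 content hashes of every artifact.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory, or `NULL` to keep results in memory
#'   only.
#' @param quiet suppress progress messages.
#' @return An object of class `experiment_result`: list with `config`,
#'   `splits`, `folds` (per-fold list: trained `net`, embedding `models`,
#'   `sweep` table, `selection`, `platt` scalars, `reports` of pooled test
#'   metrics per method, `loss`), and `manifest` (also written to
#'   `out_dir/manifest.json`).
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  ids <- sprintf("S%02d", seq_len(config$n_subjects))

  say("stage simulate: %d phantoms %s", config$n_subjects,
      paste(config$phantom$shape, collapse = "x"))
  volumes <- run_stage("simulate", {
    setNames(lapply(seq_along(ids), function(i) {
      cfg <- config$phantom
      cfg$seed <- child_seed(config$seed, 10L + i)
      generate_phantom(cfg)
    }), ids)
  })

  splits <- run_stage("split", kfold_split(ids, config$n_folds,
                                           seed = child_seed(config$seed, 1L)))
  fold_results <- list()
  for (f in config$folds) {
    sp <- splits[[f]]
    say("stage train: fold %d (%d/%d/%d subjects)", f,
        length(sp$train), length(sp$validation), length(sp$test))
    train_vols <- volumes[sp$train]
    val_vols <- volumes[sp$validation]
    test_vols <- volumes[sp$test]

    tr <- run_stage("train", {
      cfg <- config$train
      cfg$seed <- child_seed(config$seed, 100L + f)
      net0 <- build_fcn(config$arch, seed = child_seed(config$seed, 200L + f))
      train_fcn(net0, train_vols, cfg)
    })
    net <- tr$net

    say("stage probe: fitting %d embedding models", 2L * length(net$layers))
    models <- run_stage("probe", {
      fit_all_embedding_models(net, train_vols, kind = config$probe$kind,
                               n_per_volume = config$probe$n_per_volume,
                               seed = child_seed(config$seed, 300L + f),
                               trees = config$probe$trees, k = config$probe$k,
                               mask_background = isTRUE(config$probe$mask_background),
                               subject_ids = sp$train)
    })

    say("stage sweep: validation set")
    sweep <- run_stage("sweep", {
      sweep_layers(net, models, val_vols, n_bins = config$metrics$n_bins,
                   mode = config$metrics$mode, threshold = config$metrics$threshold)
    })
    selection <- run_stage("select", select_layer(sweep, config$calibration$criterion))

    platt <- NULL
    if ("platt" %in% config$methods) {
      platt <- run_stage("platt", {
        zs <- unlist(lapply(val_vols, function(v) as.vector(fcn_predict(net, v)$logits)))
        ys <- unlist(lapply(val_vols, function(v) as.vector(anomaly_mask(v))))
        platt_fit(zs, ys)
      })
    }
    ens <- NULL
    if ("ensemble" %in% config$methods) {
      say("stage ensemble: %d members", config$ensemble_size)
      ens <- run_stage("ensemble", {
        cfg <- config$train
        cfg$seed <- child_seed(config$seed, 400L + f)
        spec <- config$arch
        train_ensemble(spec, train_vols, cfg, n_models = config$ensemble_size)
      })
    }

    say("stage evaluate: test set")
    ev <- run_stage("evaluate", {
      evaluate_methods(net, models, test_vols, selection, platt, ens, config, fold = f)
    })

    fold_results[[as.character(f)]] <-
      list(fold = f, split = sp, net = net, loss = tr$loss,
           class_weights = tr$class_weights, models = models, sweep = sweep,
           selection = selection, platt = platt,
           reports = ev$reports, metrics = ev$table)
  }

  res <- structure(list(config = config, splits = splits, folds = fold_results,
                        volumes = volumes),
                   class = "experiment_result")
  res$manifest <- build_manifest(res, out_dir)
  if (!is.null(out_dir)) res$manifest <- write_artifacts(res, out_dir)
  res
}

# Pooled test-set evaluation of every configured method.
evaluate_methods <- function(net, models, test_vols, selection, platt, ens,
                             config, fold) {
  mcfg <- config$metrics
  y <- unlist(lapply(test_vols, function(v) as.vector(anomaly_mask(v))))
  fwd <- lapply(test_vols, function(v) forward_with_representations(net, v))
  raw_maps <- lapply(fwd, `[[`, "map")
  pool <- function(maps) unlist(lapply(maps, function(m) as.vector(m$values)))
  score_sets <- list()
  if ("raw" %in% config$methods) score_sets$raw <- pool(raw_maps)
  if ("embedding" %in% config$methods) {
    mdl <- models[[selection$slot]]
    cal_maps <- lapply(seq_along(test_vols), function(i) {
      sl <- predict_embedding_output(mdl, net, test_vols[[i]], reps = fwd[[i]]$reps)
      calibrate_with_embedding(raw_maps[[i]], sl,
                               a = config$calibration$a, b = config$calibration$b)
    })
    score_sets$embedding <- pool(cal_maps)
  }
  if ("platt" %in% config$methods)
    score_sets$platt <- pool(lapply(raw_maps, platt_apply, scaling = platt))
  if ("mc_dropout" %in% config$methods)
    score_sets$mc_dropout <- pool(lapply(seq_along(test_vols), function(i)
      mc_dropout_predict(net, test_vols[[i]], n_samples = config$train$mc_samples,
                         seed = child_seed(config$seed, 500L + fold * 10L + i))))
  if ("ensemble" %in% config$methods)
    score_sets$ensemble <- pool(lapply(test_vols, function(v) ensemble_predict(ens, v)))

  reports <- lapply(names(score_sets), function(m) {
    rep <- reliability_report(score_sets[[m]], y, n_bins = mcfg$n_bins,
                              mode = mcfg$mode, threshold = mcfg$threshold)
    rep$provenance <- c(list(method = m),
                        if (m == "embedding")
                          list(layer = selection$layer, stage = selection$stage))
    rep
  })
  names(reports) <- names(score_sets)
  table <- do.call(rbind, lapply(names(reports), function(m)
    report_row(reports[[m]], fold = fold, method = m)))
  list(reports = reports, table = table)
}

build_manifest <- function(res, out_dir) {
  cfg <- res$config
  list(package = "layercal",
       version = as.character(utils::packageVersion("layercal")),
       seed = cfg$seed,
       config = config_digestible(cfg),
       splits = lapply(res$splits, function(s) s[c("fold", "train", "validation", "test")]),
       folds = lapply(res$folds, function(fr) list(
         fold = fr$fold,
         loss = fr$loss,
         class_weights = fr$class_weights,
         selection = list(slot = fr$selection$slot, layer = fr$selection$layer,
                          stage = fr$selection$stage,
                          criterion = cfg$calibration$criterion,
                          selected_on = "validation"),
         platt = fr$platt,
         test_metrics = fr$metrics)),
       artifacts = list())
}

# Plain-list view of the config for JSON serialization / hashing.
config_digestible <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  voldir <- file.path(out_dir, "volumes")
  dir.create(voldir, showWarnings = FALSE)
  for (id in names(res$volumes))
    write_volume(res$volumes[[id]], file.path(voldir, paste0(id, "_img.nii")),
                 file.path(voldir, paste0(id, "_lab.nii")), config = res$config$phantom)
  for (fr in res$folds) {
    fdir <- file.path(out_dir, sprintf("fold%d", fr$fold))
    dir.create(fdir, showWarnings = FALSE)
    write.csv(fr$sweep, file.path(fdir, "sweep.csv"), row.names = FALSE)
    write.csv(attr(fr$selection, "ranking"), file.path(fdir, "selection_ranking.csv"),
              row.names = FALSE)
    write.csv(fr$metrics, file.path(fdir, "test_metrics.csv"), row.names = FALSE)
    write.csv(data.frame(epoch = seq_along(fr$loss), loss = fr$loss),
              file.path(fdir, "loss.csv"), row.names = FALSE)
  }
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  res$manifest$artifacts <- as.list(hashes)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res$manifest)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d subjects, fold(s) %s\n",
              x$config$n_subjects, paste(names(x$folds), collapse = ", ")))
  for (fr in x$folds) {
    cat(sprintf(" fold %d: selected slot %s\n", fr$fold, fr$selection$slot))
    print(fr$metrics, row.names = FALSE)
  }
  invisible(x)
}
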