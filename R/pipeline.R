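#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable the analysis
#' leaves open, suitable for editing or YAML serialization. A `seed` is
#' mandatory for any run.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = NULL,
    output_dir = "rsbagging_out",
    # feature source: either `simulate` (synthetic cohort) or `features_csv`
    # + `labels_csv`, or `recordings` (named EEG file paths) + `labels_csv`
    simulate = list(preset = "table1", n_features = 190L, separation = 2),
    features_csv = NULL,
    labels_csv = NULL,
    recordings = NULL,
    # EEG-domain settings
    preprocessing = list(hp_hz = 0.5, lp_hz = 45, artifact_uv = 150),
    epoch_s = 2, epoch_overlap = 0,
    measures = "PPC", band = c(1, 45), mvar_order = 5,
    microstate_k = NULL,                 # set to use microstate features
    # classification
    tasks = "doc",
    ensemble = list(N = 11L, alpha = 0.5, svm_C = 1, svm_gamma = "auto",
                    test_fraction = 0.3, repeats = 5L),
    alphas = NULL                        # set to emit an alpha-sweep CSV
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full pipeline
#'
#' Orchestrates feature acquisition (synthetic cohort, precomputed CSV, or
#' EEG recordings put through preprocessing and feature extraction),
#' classification with RSBagging for each requested task, and report
#' writing. Outputs under `output_dir`: `features.csv` (one row per
#' subject), `report_<task>.json`, optional `sweep_<task>.csv`,
#' `config_echo.yaml` and `run.log`. Deterministic for a fixed seed.
#'
#' @param config configuration list (see [pipeline_defaults()]) or path to
#'   a YAML file holding one.
#' @return Invisibly, a named list of [run_task()] reports.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$seed)) stop("config error: `seed` is mandatory")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  cat("", file = log_path)
  logf("pipeline start: seed=%d", cfg$seed)
  logf("settings: epoch=%gs overlap=%g band=[%g,%g]Hz mvar_order=%s N=%d alpha=%g test_fraction=%g repeats=%d",
       cfg$epoch_s, cfg$epoch_overlap, cfg$band[1], cfg$band[2],
       paste(cfg$mvar_order, collapse = ""), cfg$ensemble$N, cfg$ensemble$alpha,
       cfg$ensemble$test_fraction, cfg$ensemble$repeats)

  if (!is.null(cfg$recordings)) {
    logf("feature source: %d EEG recordings (measures: %s)",
         length(cfg$recordings), paste(cfg$measures, collapse = ","))
    if (is.null(cfg$labels_csv)) stop("data error: `labels_csv` required with recordings")
    labels <- read_clinical_labels(cfg$labels_csv)
    feats <- do.call(rbind, lapply(names(cfg$recordings), function(sid) {
      rec <- read_recording(cfg$recordings[[sid]], subject_id = sid,
                            fs = cfg$fs)
      subject_features(rec, cfg)
    }))
    rownames(feats) <- names(cfg$recordings)
    feats <- feats[match(labels$subject_id, rownames(feats)), , drop = FALSE]
    if (anyNA(feats)) stop("data error: recordings missing for some labelled subjects")
  } else if (!is.null(cfg$features_csv)) {
    logf("feature source: %s", cfg$features_csv)
    fdf <- utils::read.csv(cfg$features_csv, check.names = FALSE)
    labels <- read_clinical_labels(cfg$labels_csv)
    feats <- as.matrix(fdf[, setdiff(names(fdf), "subject_id"), drop = FALSE])
    rownames(feats) <- fdf$subject_id
    feats <- feats[match(labels$subject_id, rownames(feats)), , drop = FALSE]
  } else {
    sim <- cfg$simulate
    logf("feature source: synthetic cohort (preset=%s, %d features)",
         sim$preset, sim$n_features)
    coh <- gen_cohort(preset = sim$preset, n_features = sim$n_features,
                      separation = sim$separation, seed = cfg$seed)
    feats <- coh$features
    labels <- coh$labels
  }

  fpath <- file.path(cfg$output_dir, "features.csv")
  utils::write.csv(data.frame(subject_id = rownames(feats), feats,
                              check.names = FALSE),
                   fpath, row.names = FALSE)
  logf("wrote %s (%d subjects x %d features)", fpath, nrow(feats), ncol(feats))

  ens <- cfg$ensemble
  rcfg <- rsb_config(N = ens$N, alpha = ens$alpha, svm_C = ens$svm_C,
                     svm_gamma = ens$svm_gamma, seed = cfg$seed,
                     test_fraction = ens$test_fraction, repeats = ens$repeats)
  reports <- list()
  for (task in cfg$tasks) {
    logf("task %s: running %d repeats", task, rcfg$repeats)
    rep_ <- run_task(feats, labels, task, rcfg)
    reports[[task]] <- rep_
    out <- list(task = task, class_sizes = as.list(rep_$class_sizes),
                positive = rep_$positive,
                mean = as.list(rep_$mean), sd = as.list(rep_$sd),
                per_repeat = rep_$per_repeat,
                config = unclass(rcfg),
                package_version = as.character(utils::packageVersion("rsbagging")))
    jpath <- file.path(cfg$output_dir, paste0("report_", task, ".json"))
    jsonlite::write_json(out, jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("task %s: accuracy %.2f%%, sensitivity %.2f%%, predict rate %.2f%% -> %s",
         task, rep_$mean[["accuracy"]], rep_$mean[["sensitivity"]],
         rep_$mean[["predict_rate"]], jpath)
    if (!is.null(cfg$alphas)) {
      sw <- sweep_alpha(feats, labels, task, rcfg, alphas = cfg$alphas)
      spath <- file.path(cfg$output_dir, paste0("sweep_", task, ".csv"))
      utils::write.csv(sw, spath, row.names = FALSE)
      logf("task %s: alpha sweep -> %s", task, spath)
    }
  }
  yaml::write_yaml(cfg, file.path(cfg$output_dir, "config_echo.yaml"))
  logf("pipeline done")
  invisible(reports)
}

# preprocess one recording and extract the configured feature vector
subject_features <- function(rec, cfg) {
  pp <- cfg$preprocessing
  rec <- preprocess(rec, hp_hz = pp$hp_hz, lp_hz = pp$lp_hz)
  if (!is.null(cfg$microstate_k)) {
    return(microstate_features(rec, k = cfg$microstate_k, seed = cfg$seed))
  }
  ep <- epoch(rec, cfg$epoch_s, cfg$epoch_overlap)
  if (!is.null(pp$artifact_uv)) ep <- drop_artifacts(ep, pp$artifact_uv)
  connectivity_features(ep, measures = cfg$measures, band = cfg$band,
                        mvar_order = cfg$mvar_order)
}
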