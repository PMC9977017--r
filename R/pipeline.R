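#' End-to-end pipeline configuration
#'
#' Defaults are the analysis' printed operating points: SQI acceptance
#' threshold 0.75, 100 surrogate imputations per visit, coarse-graining
#' scales 1-10, nocturnal interval 22:00-10:00, 5 classification
#' repetitions with inner 3-fold tuning.
#'
#' @param input_dir directory of per-visit subdirectories (as written by
#'   [write_cohort()]); ignored when `cohort` is given
#' @param cohort an in-memory `pm_cohort`
#' @param out_dir optional output directory for CSV/JSON reports
#' @param sqi_threshold strict SQI acceptance threshold
#' @param ensemble_m surrogate ensemble size per visit
#' @param th_g_grid gap threshold for 30-s HR/DC/activity grids (s)
#' @param th_g_rr gap threshold for raw RR series (s)
#' @param scales coarse-graining scales
#' @param night nocturnal interval hours `c(start, end)`
#' @param n_reps,inner_folds classifier repetitions and inner CV folds
#' @param min_cell,alpha Darbellay-Vajda partitioning settings
#' @param hrv_metrics HRV metric subset (default all 24)
#' @param master_seed master seed; every stage stream derives from it
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(input_dir = NULL, cohort = NULL, out_dir = NULL,
                            sqi_threshold = 0.75, ensemble_m = 100L,
                            th_g_grid = 60, th_g_rr = 300, scales = 1:10,
                            night = c(22, 10), n_reps = 5L,
                            inner_folds = 3L, min_cell = 8L, alpha = 0.05,
                            hrv_metrics = hrv_metric_names(),
                            master_seed = 1L) {
  structure(list(input_dir = input_dir, cohort = cohort, out_dir = out_dir,
                 sqi_threshold = sqi_threshold,
                 ensemble_m = as.integer(ensemble_m),
                 th_g_grid = th_g_grid, th_g_rr = th_g_rr, scales = scales,
                 night = night, n_reps = as.integer(n_reps),
                 inner_folds = as.integer(inner_folds),
                 min_cell = as.integer(min_cell), alpha = alpha,
                 hrv_metrics = hrv_metrics,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Read a cohort from per-visit directories
#'
#' Expects the layout written by [write_cohort()]: `rr.csv`,
#' `counts_30s.csv` or `acc.csv`, `sqi.csv`, `meta.json` per visit
#' directory.
#'
#' @param dir cohort directory
#' @return a `pm_cohort`
#' @export
read_cohort_dir <- function(dir) {
  vds <- list.dirs(dir, recursive = FALSE)
  if (!length(vds)) stop(sprintf("no visit directories under '%s'", dir))
  visits <- lapply(vds, function(vd) {
    meta <- jsonlite::read_json(file.path(vd, "meta.json"))
    counts <- if (file.exists(file.path(vd, "counts_30s.csv"))) {
      read_signal_csv(file.path(vd, "counts_30s.csv"), "series", "counts")
    } else {
      oakley_counts(read_signal_csv(file.path(vd, "acc.csv"), "acc")$z)
    }
    list(patient_id = meta$patient_id, visit_id = meta$visit_id,
         cgis = as.integer(meta$cgis),
         rr = read_signal_csv(file.path(vd, "rr.csv"), "rr"),
         counts = counts,
         sqi = read.csv(file.path(vd, "sqi.csv")))
  })
  structure(list(visits = visits, config = NULL), class = "pm_cohort")
}

# Drop RR beats in 60-s windows whose best channel SQI fails the strict
# threshold: the per-window outcome of max-SQI channel fusion.
apply_sqi_mask <- function(rr, sqi, threshold = 0.75, win = 60) {
  if (is.null(sqi) || !nrow(sqi)) return(rr)
  best <- aggregate(sqi ~ t_start_sec, data = sqi, FUN = max)
  bad <- best$t_start_sec[best$sqi <= threshold]
  if (!length(bad)) return(rr)
  w <- floor(rr$beat_t / win) * win
  keep <- !(w %in% bad)
  rr_series(rr$beat_t[keep], rr$rr[keep])
}

# Resample an (irregular) imputed series onto the regular 30-s grid.
snap_to_grid <- function(s, duration_s, dt = 30) {
  grid <- seq(0, duration_s - dt, by = dt)
  ts_series(grid, approx(s$t, s$v, xout = grid, rule = 2)$y, s$unit)
}

#' Compute all four feature blocks for one visit
#'
#' Stage order per visit: SQI masking of the RR series, HRV windowing and
#' nocturnal aggregation, 30-s HR/DC grids, actigraphy best-two-day
#' selection and block, surrogate imputation ensembles of the HR/DC/
#' activity grids, and the MSTE and MSNR ensemble blocks.
#'
#' @param visit a visit entry of a `pm_cohort`
#' @param config a [pipeline_config]
#' @param visit_seed seed for this visit's imputation streams
#' @return named numeric feature vector with attribute `family`, or NULL
#'   (attribute `reason`) when a validity rule excludes the visit
#' @export
visit_features <- function(visit, config = pipeline_config(),
                           visit_seed = 1L) {
  rr <- apply_sqi_mask(visit$rr, visit$sqi, config$sqi_threshold)
  rr <- clean_rr(rr)
  duration_s <- floor(max(rr$beat_t, visit$counts$t) / 86400) * 86400
  if (duration_s < 2 * 86400) {
    return(pm_excluded("less than two days of data"))
  }

  hrvb <- hrv_block(rr, night = config$night, metrics = config$hrv_metrics,
                    clean = FALSE)
  if (is.null(hrvb)) {
    return(pm_excluded("too few valid nocturnal HRV windows"))
  }
  actb <- actigraphy_block(visit$counts)
  if (is_excluded(actb)) {
    return(actb)
  }

  grids <- hr_dc_grids(rr, duration_s = duration_s)
  ens <- lapply(seq_len(config$ensemble_m), function(i) {
    hr_i <- surrogate_impute(grids$hr_grid, config$th_g_grid,
                             seed = seed_stream(visit_seed, 1, i))
    dc_i <- surrogate_impute(grids$dc_grid, config$th_g_grid,
                             seed = seed_stream(visit_seed, 2, i))
    act_i <- surrogate_impute(visit$counts, config$th_g_grid,
                              seed = seed_stream(visit_seed, 3, i))
    trivariate_grid(snap_to_grid(hr_i, duration_s)$t,
                    snap_to_grid(hr_i, duration_s)$v,
                    snap_to_grid(dc_i, duration_s)$v,
                    snap_to_grid(act_i, duration_s)$v)
  })
  msteb <- mste_block(ens, config$scales, config$min_cell, config$alpha)
  msnrb <- msnr_block(ens, config$scales, config$min_cell, config$alpha)

  out <- c(hrvb, actb, msteb, msnrb)
  attr(out, "family") <- c(rep("HRV", length(hrvb)),
                           rep("ACT", length(actb)),
                           rep("MSTE", length(msteb)),
                           rep("MSNR", length(msnrb)))
  out
}

#' Run the full pipeline on a cohort
#'
#' Computes the per-visit feature blocks, assembles the labelled feature
#' table, runs the 15 feature-combination classification experiments, and
#' (optionally) writes `features.csv`, `auc_summary.csv` and
#' `popularity_<combo>.csv` to `out_dir`. Visits failing validity rules
#' are excluded with a logged reason; stage errors exclude the visit and
#' the pipeline continues.
#'
#' @param config a [pipeline_config] with `cohort` or `input_dir` set
#' @return list with `features` (the [feature_table]), `experiment`
#'   (a `full_experiment`) and `excluded` (data.frame visit/reason)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$cohort)) config$cohort
            else read_cohort_dir(config$input_dir)
  feats <- list()
  meta <- list()
  excl <- data.frame(visit = character(0), reason = character(0))
  for (i in seq_along(cohort$visits)) {
    v <- cohort$visits[[i]]
    vid <- paste0(v$patient_id, "_", v$visit_id)
    fv <- tryCatch(
      visit_features(v, config, seed_stream(config$master_seed, i)),
      error = function(e) pm_excluded(conditionMessage(e)))
    if (is_excluded(fv)) {
      excl <- rbind(excl, data.frame(visit = vid, reason = attr(fv, "reason")))
      next
    }
    feats[[vid]] <- fv
    meta[[vid]] <- v
  }
  if (length(feats) < 4) stop("too few visits survived the validity rules")
  X <- do.call(rbind, feats)
  tab <- feature_table(X,
                       patient_id = vapply(meta, function(v) v$patient_id, ""),
                       label = vapply(meta, function(v) v$cgis, 0L),
                       family = attr(feats[[1]], "family"))
  exp <- run_full_experiment(tab, config$n_reps,
                             seed_stream(config$master_seed, 999))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(visit = rownames(X), X, check.names = FALSE),
              file.path(config$out_dir, "features.csv"), row.names = FALSE)
    write.csv(exp$summary, file.path(config$out_dir, "auc_summary.csv"),
              row.names = FALSE)
    roc_df <- do.call(rbind, lapply(names(exp$roc), function(nm)
      cbind(combination = nm, exp$roc[[nm]])))
    write.csv(roc_df, file.path(config$out_dir, "roc_points.csv"),
              row.names = FALSE)
    # provenance: configuration fingerprint and seed for reproducibility
    cfg_plain <- config[setdiff(names(config), c("cohort", "out_dir",
                                                 "input_dir"))]
    jsonlite::write_json(
      list(master_seed = config$master_seed,
           config = cfg_plain,
           n_visits = nrow(X),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file.path(config$out_dir, "provenance.json"), auto_unbox = TRUE)
    for (nm in names(exp$top_popularity)) {
      write.csv(exp$top_popularity[[nm]],
                file.path(config$out_dir,
                          paste0("popularity_", gsub("\\+", "_", nm),
                                 ".csv")),
                row.names = FALSE)
    }
    if (nrow(excl)) {
      write.csv(excl, file.path(config$out_dir, "excluded.csv"),
                row.names = FALSE)
    }
  }
  list(features = tab, experiment = exp, excluded = excl)
}

# Sentinel carrying an exclusion reason for a visit that failed a
# validity rule; distinguishable from a real feature vector.
pm_excluded <- function(reason) {
  structure(NA, reason = reason, class = "pm_excluded")
}

#' Test whether a per-visit result is an exclusion sentinel
#' @param x object returned by [visit_features()] or [actigraphy_block()]
#' @return TRUE when the visit was excluded (reason in attribute `reason`)
#' @export
is_excluded <- function(x) inherits(x, "pm_excluded")
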