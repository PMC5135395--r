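#' Analysis configuration
#'
#' All tunables of the pipeline in one validated list, mirroring the
#' defaults used throughout the package: return-map lag 1.5 ms with
#' classification cutoff 0.7; spike excision +/- 6 ms; ISI inclusion
#' filters 6 / 20 / 300 ms and 1.7 ms (FV); interburst threshold 0.5 s
#' for cycle-restricted CV2 statistics and 0.3 s for Vm-linked exclusions;
#' pre-spike lag 1.7 ms; spike-triggered ("sigma") lag 18 ms; critical
#' irregularity 0.5; population bin 10 ms; FV bin 0.5 mV; smoothing 20 ms.
#'
#' @param ... overrides of the defaults listed above.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    rmr_lag_ms = 1.5, rmr_cutoff = 0.7,
    excise_ms = 6,
    isi_min_temporal_ms = 6, isi_min_triggered_ms = 20,
    isi_max_ms = 300, isi_min_fv_ms = 1.7,
    interburst_cv2_s = 0.5, interburst_vm_s = 0.3,
    fv_pre_lag_ms = 1.7, sigma_lag_ms = 18,
    icrit = 0.5, icrit_grid = c(0.4, 0.5, 0.6),
    population_bin_s = 0.01, fv_bin_mV = 0.5,
    smoothing_ms = 20, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  durs <- c("rmr_lag_ms", "excise_ms", "isi_min_temporal_ms",
            "isi_min_triggered_ms", "isi_max_ms", "isi_min_fv_ms",
            "interburst_cv2_s", "interburst_vm_s", "fv_pre_lag_ms",
            "sigma_lag_ms", "population_bin_s", "fv_bin_mV",
            "smoothing_ms")
  for (k in durs) if (!is.numeric(cfg[[k]]) || any(cfg[[k]] < 0))
    stop("config key ", k, " must be non-negative")
  if (any(cfg$icrit <= 0) || any(cfg$icrit >= 2))
    stop("icrit must lie in (0, 2)")
  invisible(cfg)
}

#' Write / read an analysis configuration
#'
#' JSON round-trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param cfg an [analysis_config()].
#' @param path file path.
#' @return `write_config` the path invisibly; `read_config` an
#'   `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON carries no integer/double distinction; everything numeric is a
  # double except the seed
  raw <- lapply(raw, function(x) if (is.integer(x)) as.numeric(x) else x)
  raw$seed <- as.integer(raw$seed)
  do.call(analysis_config, raw)
}

#' Pearson correlation with significance
#'
#' @param x,y paired numeric vectors.
#' @return list `r`, `p`, `n`; for fewer than 3 finite pairs or a constant
#'   column, `r` and `p` are `NA` with `undefined = TRUE`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
}

analyze_recording <- function(rec, cfg) {
  trace <- rec$trace
  peaks <- detect_spike_peaks(trace)
  out <- list(n_spikes = length(peaks))
  if (length(peaks) >= 3) {
    cs <- cv2_sequence(peaks, interburst_s = cfg$interburst_cv2_s)
    out$mean_cv2 <- cs$mean_cv2_within
    fr <- regime_fractions(cs, icrit = cfg$icrit)
    out$time_fraction <- fr$time_fraction
    out$spike_fraction <- fr$spike_fraction
  }
  rm <- tryCatch(
    return_map_ratio(trace, peaks, lag = cfg$rmr_lag_ms,
                     excise = cfg$excise_ms,
                     interburst_ms = cfg$isi_max_ms,
                     cutoff = cfg$rmr_cutoff),
    error = function(e) NULL)
  if (!is.null(rm)) {
    out$rmr <- rm$return_map_ratio
    out$fluctuation_driven <- rm$is_fluctuation_driven
  }
  if (length(peaks) >= 5) {
    se <- tryCatch(
      suppressWarnings(estimate_thresholds_phase_plane(trace, peaks)),
      error = function(e) NULL)
    if (!is.null(se) && length(se$threshold_mV)) {
      out$mean_threshold <- se$mean_threshold
      out$tbt <- time_below_threshold(
        trace, se$most_hyperpolarized_threshold,
        smoothing = cfg$smoothing_ms)
    }
    rd <- tryCatch(
      rate_distribution(peaks,
                        interburst_threshold = cfg$interburst_vm_s),
      error = function(e) NULL)
    if (!is.null(rd)) {
      out$skewness_linear <- rd$skewness_linear
      out$skewness_log <- rd$skewness_log
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the intracellular, spike-metric, population and localization
#' stages on whatever inputs are supplied, assembling a per-unit summary
#' table, population scalars (Gini, TIF50, SIF50, pooled skewness) and
#' cross-metric correlations. Any stage failure is recorded in the stage
#' status without aborting the others. Deterministic given the inputs.
#'
#' @param inputs list with any of: `recordings` (list of
#'   `simulated_recording`, or lists with `trace` ([vm_trace()])),
#'   `raster` (named list of spike-time vectors), `unit_meta` (data.frame
#'   `unit_id`, `shank`, `depth_um`), `amplitude_maps` (list of
#'   `amplitude_map`), `geometry` ([probe_geometry()]).
#' @param config an [analysis_config()].
#' @return object of class `run_report`: `intracellular` (per-neuron
#'   data.frame), `units` (per-unit raster metrics), `population` (list of
#'   scalars), `localization` (positions table), `correlations`,
#'   `stage_status`, `config`.
#' @export
run_pipeline <- function(inputs, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  status <- list()
  report <- list(config = unclass(config))

  if (!is.null(inputs$recordings)) {
    res <- lapply(seq_along(inputs$recordings), function(i) {
      r <- tryCatch(analyze_recording(inputs$recordings[[i]], config),
                    error = function(e) list(error = conditionMessage(e)))
      r$neuron <- i
      r
    })
    errs <- vapply(res, function(r) !is.null(r$error), logical(1))
    cols <- c("neuron", "n_spikes", "rmr", "fluctuation_driven",
              "mean_cv2", "time_fraction", "spike_fraction",
              "mean_threshold", "tbt", "skewness_linear", "skewness_log")
    tab <- do.call(rbind, lapply(res[!errs], function(r) {
      r <- r[cols[cols %in% names(r)]]
      miss <- setdiff(cols, names(r))
      r[miss] <- NA
      as.data.frame(r[cols])
    }))
    report$intracellular <- tab
    status$intracellular <- if (any(errs))
      sprintf("%d/%d recordings failed", sum(errs), length(errs)) else "ok"
  }

  if (!is.null(inputs$raster)) {
    stage <- tryCatch({
      raster <- inputs$raster
      per_unit <- lapply(raster, function(st) {
        if (length(st) < 3) return(NULL)
        cs <- cv2_sequence(st, interburst_s = config$interburst_cv2_s)
        fr <- regime_fractions(cs, icrit = config$icrit)
        data.frame(mean_cv2 = cs$mean_cv2_within,
                   time_fraction = fr$time_fraction,
                   spike_fraction = fr$spike_fraction,
                   n_spikes = length(st))
      })
      keep <- !vapply(per_unit, is.null, logical(1))
      units <- do.call(rbind, per_unit[keep])
      units$unit_id <- names(raster)[keep]
      if (!is.null(inputs$unit_meta))
        units <- merge(units, inputs$unit_meta, by = "unit_id",
                       all.x = TRUE, sort = FALSE)
      report$units <- units

      pooled <- pooled_rate_distribution(raster)
      occ <- tif50_sif50(units$time_fraction[is.finite(units$time_fraction)],
                         units$spike_fraction[is.finite(units$spike_fraction)])
      report$population <- list(
        gini = lorenz_gini(pooled$rates_hz)$gini,
        tif50 = occ$tif50, sif50 = occ$sif50,
        pooled_skewness_linear = pooled$skewness_linear,
        pooled_skewness_log = pooled$skewness_log,
        n_units = length(pooled$rates_hz), n_silent = pooled$n_silent)
      "ok"
    }, error = function(e) conditionMessage(e))
    status$population <- stage
  }

  if (!is.null(inputs$amplitude_maps)) {
    stage <- tryCatch({
      geom <- if (is.null(inputs$geometry)) probe_geometry()
              else inputs$geometry
      fits <- lapply(inputs$amplitude_maps, trilaterate, geometry = geom)
      report$localization <- data.frame(
        unit = seq_along(fits),
        x_um = vapply(fits, `[[`, numeric(1), "x_um"),
        y_um = vapply(fits, `[[`, numeric(1), "y_um"),
        depth_um = vapply(fits, function(f)
          absolute_depth(f, geom$insertion_depth[1]), numeric(1)),
        residual = vapply(fits, `[[`, numeric(1), "residual"))
      "ok"
    }, error = function(e) conditionMessage(e))
    status$localization <- stage
  }

  if (!is.null(report$intracellular) && nrow(report$intracellular) >= 3) {
    ic <- report$intracellular
    report$correlations <- list(
      cv2_vs_rmr = correlate(ic$mean_cv2, ic$rmr),
      logskew_vs_rate = if (all(c("skewness_log", "n_spikes") %in%
                                names(ic)))
        correlate(ic$skewness_log, ic$n_spikes) else NULL)
  }

  report$stage_status <- status
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stage_status))
    cat(sprintf("  stage %-14s %s\n", s, x$stage_status[[s]]))
  if (!is.null(x$population))
    cat(sprintf("  gini %.3f, TIF50 %.1f%%, SIF50 %.1f%%\n",
                x$population$gini, x$population$tif50, x$population$sif50))
  invisible(x)
}

#' Write a run report to disk
#'
#' Scalars and provenance go to `report.json`; the per-neuron, per-unit
#' and localization tables to tab-delimited text files alongside it.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list(population = report$population,
                  correlations = report$correlations,
                  stage_status = report$stage_status,
                  config = report$config)
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (tab in c("intracellular", "units", "localization"))
    if (!is.null(report[[tab]]))
      utils::write.table(report[[tab]],
                         file.path(dir, paste0(tab, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
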