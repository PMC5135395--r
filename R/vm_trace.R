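#' Membrane-potential trace container
#'
#' A uniformly sampled intracellular membrane-potential recording. This is
#' the substrate for all intracellular analytics (spike detection, threshold
#' estimation, return-map ratio, FV-curves).
#'
#' @param vm numeric vector of membrane potential samples (mV).
#' @param fs sampling rate (Hz), > 0.
#' @param t0 time of the first sample (s).
#' @return an object of class `vm_trace` with fields `vm`, `fs`, `t0`.
#' @examples
#' tr <- vm_trace(rnorm(1000, -60), fs = 20000)
#' range(trace_times(tr))
#' @export
vm_trace <- function(vm, fs, t0 = 0) {
  vm <- as.numeric(vm)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(vm) < 1L) stop("`vm` must contain at least one sample")
  if (any(!is.finite(vm))) stop("`vm` must be finite")
  structure(list(vm = vm, fs = fs, t0 = t0), class = "vm_trace")
}

#' Sample times of a trace
#' @param trace a [vm_trace()].
#' @return numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "vm_trace"))
  trace$t0 + (seq_along(trace$vm) - 1) / trace$fs
}

#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("<vm_trace> %d samples @ %g kHz (%.3f s), Vm in [%.1f, %.1f] mV\n",
              length(x$vm), x$fs / 1000, length(x$vm) / x$fs,
              min(x$vm), max(x$vm)))
  invisible(x)
}

# index of the sample nearest to time t (s); clamped to the trace
time_to_index <- function(trace, t) {
  i <- round((t - trace$t0) * trace$fs) + 1L
  pmin(pmax(i, 1L), length(trace$vm))
}

#' Read / write membrane-potential traces
#'
#' Traces are stored as two-column delimited text with a header
#' (`time_s`, `vm_mV`); the sampling rate is recovered from the median time
#' step.
#'
#' @param path file path.
#' @param trace a [vm_trace()].
#' @return `read_vm_trace` returns a [vm_trace()]; `write_vm_trace` its path,
#'   invisibly.
#' @export
read_vm_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "vm_mV") %in% names(d)))
    stop("trace file must have columns time_s, vm_mV")
  if (nrow(d) < 2L) stop("trace file must contain at least two samples")
  dt <- stats::median(diff(d$time_s))
  vm_trace(d$vm_mV, fs = 1 / dt, t0 = d$time_s[1])
}

#' @rdname read_vm_trace
#' @export
write_vm_trace <- function(trace, path) {
  stopifnot(inherits(trace, "vm_trace"))
  utils::write.table(
    data.frame(time_s = trace_times(trace), vm_mV = trace$vm),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write spike rasters
#'
#' Rasters are delimited text with a header (`unit_id`, `time_s`), one row
#' per spike.
#'
#' @param path file path.
#' @param raster named list of per-unit spike-time vectors (s).
#' @return `read_spike_times` returns a named list of sorted numeric
#'   vectors; `write_spike_times` its path, invisibly.
#' @export
read_spike_times <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("unit_id", "time_s") %in% names(d)))
    stop("raster file must have columns unit_id, time_s")
  lapply(split(d$time_s, d$unit_id), sort)
}

#' @rdname read_spike_times
#' @export
write_spike_times <- function(raster, path) {
  if (is.numeric(raster)) raster <- list(u1 = raster)
  ids <- names(raster)
  if (is.null(ids)) ids <- paste0("u", seq_along(raster))
  d <- data.frame(
    unit_id = rep(ids, lengths(raster)),
    time_s  = unlist(raster, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
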