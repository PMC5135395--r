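#' Trilateration of an extracellular source from electrode amplitudes
#'
#' Least-squares fit of the inverse-square decay model
#' `A_j = S / r_j(x, y)^2` to the per-electrode mean spike amplitudes of
#' one shank, over the source position `(x, y)` and strength `S`. `S` is
#' profiled out in closed form at each candidate position, and the
#' position is optimized by bounded quasi-Newton search started from the
#' three highest-amplitude electrodes; the best residual wins. Distances
#' are clamped at 1 um so a source on top of an electrode cannot diverge.
#'
#' @param map an `amplitude_map` (see [generate_amplitude_map()]) or a
#'   numeric amplitude vector, one value per electrode.
#' @param geometry a [probe_geometry()] supplying the single-shank
#'   electrode layout; ignored when `map` carries its own electrodes.
#' @param search_margin bound of the search region around the electrode
#'   bounding box (um).
#' @param min_electrodes minimal number of electrodes with amplitude above
#'   the noise floor.
#' @param noise_floor amplitudes at or below this (uV) do not count
#'   towards `min_electrodes`.
#' @return object of class `source_fit`: `x_um`, `y_um`, `S`,
#'   `residual` (root-SSE), `converged`.
#' @export
trilaterate <- function(map, geometry = probe_geometry(),
                        search_margin = 400, min_electrodes = 3,
                        noise_floor = 0) {
  if (inherits(map, "amplitude_map")) {
    amp <- map$amplitude_uV
    el <- map$electrodes
  } else {
    amp <- as.numeric(map)
    el <- geometry$electrodes
  }
  if (length(amp) != nrow(el))
    stop("one amplitude per electrode is required")
  if (sum(amp > noise_floor) < min_electrodes)
    stop(sprintf("need >= %d electrodes above the noise floor",
                 min_electrodes))

  ex <- el$x_um; ey <- el$y_um
  sse_at <- function(pos) {
    r2 <- pmax((ex - pos[1])^2 + (ey - pos[2])^2, 1)
    g <- 1 / r2
    S <- sum(amp * g) / sum(g * g)      # closed-form profile of S
    sum((amp - S * g)^2)
  }
  lower <- c(min(ex) - search_margin, min(ey) - search_margin)
  upper <- c(max(ex) + search_margin, max(ey) + search_margin)
  # multi-start: the amplitude-weighted centroid first, then the three
  # highest-amplitude electrodes (offset so the r >= 1 um clamp does not
  # flatten the gradient right at an electrode)
  tops <- order(amp, decreasing = TRUE)[1:3]
  starts <- c(list(c(sum(ex * amp) / sum(amp), sum(ey * amp) / sum(amp))),
              lapply(tops, function(s) c(ex[s] + 7, ey[s] + 5)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, sse_at, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # a later start must improve strictly; near-ties keep the earlier
    # (interior) solution, which matters for symmetric degenerate maps
    if (is.null(best) || fit$value < best$value * (1 - 1e-6) - 1e-12)
      best <- fit
  }
  if (is.null(best))
    return(structure(list(x_um = NA_real_, y_um = NA_real_, S = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "source_fit"))
  r2 <- pmax((ex - best$par[1])^2 + (ey - best$par[2])^2, 1)
  g <- 1 / r2
  S <- sum(amp * g) / sum(g * g)
  structure(list(x_um = best$par[1], y_um = best$par[2], S = S,
                 residual = sqrt(best$value),
                 converged = best$convergence == 0),
            class = "source_fit")
}

#' @export
print.source_fit <- function(x, ...) {
  cat(sprintf("<source_fit> (%.1f, %.1f) um, S = %.3g, residual %.3g%s\n",
              x$x_um, x$y_um, x$S, x$residual,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Absolute depth of a localized source
#'
#' Converts the shank-local dorsoventral coordinate of a fitted source
#' (y = 0 at the deepest electrode, increasing towards the surface) to
#' depth below the cord surface, corrected for the shank's insertion
#' depth.
#'
#' @param fit a `source_fit`, or a numeric y coordinate (um).
#' @param insertion_depth depth of the deepest electrode below the surface
#'   (um).
#' @return depth below the surface (um).
#' @examples
#' absolute_depth(210, insertion_depth = 800)  # 590
#' @export
absolute_depth <- function(fit, insertion_depth) {
  y <- if (inherits(fit, "source_fit")) fit$y_um else as.numeric(fit)
  insertion_depth - y
}
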