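#' Silicon-probe geometry
#'
#' Geometry of a multi-shank silicon probe: by default 8 shanks at 200 um
#' pitch, each carrying 8 recording sites in a staggered two-column
#' configuration with 30 um vertical spacing between adjacent sites.
#' Electrode coordinates are local to a shank: x along the shank row
#' (staggered column offset), y dorsoventral with y = 0 at the deepest
#' site.
#'
#' @param n_shanks number of shanks.
#' @param shank_pitch shank spacing (um).
#' @param n_electrodes recording sites per shank.
#' @param dy vertical distance between adjacent sites (um).
#' @param stagger horizontal offset of the alternating column (um).
#' @param insertion_depth per-shank insertion depth of the deepest site
#'   below the cord surface (um); scalar recycled.
#' @return object of class `probe_geometry` with `shank_x` (um),
#'   `electrodes` (data.frame `electrode_id`, `x_um`, `y_um`, local to one
#'   shank) and `insertion_depth` (um, per shank).
#' @export
probe_geometry <- function(n_shanks = 8, shank_pitch = 200,
                           n_electrodes = 8, dy = 30, stagger = 20,
                           insertion_depth = 800) {
  if (n_shanks < 1 || n_electrodes < 1) stop("need >= 1 shank and electrode")
  el <- data.frame(
    electrode_id = seq_len(n_electrodes),
    x_um = ifelse(seq_len(n_electrodes) %% 2 == 1, 0, stagger),
    y_um = (seq_len(n_electrodes) - 1) * dy)
  if (anyDuplicated(el[c("x_um", "y_um")]))
    stop("electrode positions must be unique within a shank")
  structure(list(shank_x = (seq_len(n_shanks) - 1) * shank_pitch,
                 electrodes = el,
                 insertion_depth = rep_len(insertion_depth, n_shanks)),
            class = "probe_geometry")
}

#' Simulate per-electrode spike amplitudes from a point source
#'
#' Mean extracellular spike amplitude on electrode j follows the
#' inverse-square decay `A_j = S / r_j^2`, where `r_j` is the distance from
#' the source to the electrode (clamped at 1 um), plus Gaussian noise
#' rectified at zero.
#'
#' @param source list or vector with `x`, `y` (um, shank-local coordinates)
#'   and `S` (source strength, uV * um^2).
#' @param geometry a [probe_geometry()]; the single-shank electrode layout
#'   is used.
#' @param noise_sd amplitude noise SD (uV).
#' @param seed RNG seed.
#' @return object of class `amplitude_map`: `amplitude_uV` (one value per
#'   electrode), `electrodes`, `noise_sd`, and the true `source`.
#' @export
generate_amplitude_map <- function(source, geometry = probe_geometry(),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(inherits(geometry, "probe_geometry"))
  src <- as.list(source)
  if (!all(c("x", "y", "S") %in% names(src)))
    stop("source must provide x, y and S")
  el <- geometry$electrodes
  r2 <- pmax((el$x_um - src$x)^2 + (el$y_um - src$y)^2, 1)
  amp <- src$S / r2
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    amp <- amp + rnorm(length(amp), sd = noise_sd)
  }
  structure(list(amplitude_uV = pmax(amp, 0), electrodes = el,
                 noise_sd = noise_sd, source = src),
            class = "amplitude_map")
}
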