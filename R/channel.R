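# Channel geometry specification for region tracking and the collective
# coordinate.

#' Define the channel region
#'
#' The channel is a z-aligned cylinder spanning `[z_lo, z_hi]` with radius
#' `radial_cutoff` around the channel axis.  The axis (x, y) anchor is
#' either a fixed point (`center`) or the per-frame centroid of
#' `center_selection` (e.g. the NPA-motif backbone), which tolerates
#' lateral protein drift.  A water is in bulk only beyond the buffer
#' `z < z_lo - buffer` / `z > z_hi + buffer`, so a counted transit must
#' reach true bulk and mouth recrossings are not double counted.
#'
#' @param z_lo,z_hi channel span along z (Angstrom), `z_hi > z_lo`.
#' @param buffer bulk buffer delta (Angstrom, default 2).
#' @param radial_cutoff cylinder radius (Angstrom, default 6).
#' @param center fixed axis anchor `c(x, y)` (default origin).
#' @param center_selection optional `atom_selection` whose per-frame (x, y)
#'   centroid anchors the axis (overrides `center`).
#' @param water_resnames residue names identifying water.
#' @return a `channel_spec`.
#' @export
channel_spec <- function(z_lo, z_hi, buffer = 2, radial_cutoff = 6,
                         center = c(0, 0), center_selection = NULL,
                         water_resnames = c("HOH", "TIP3", "WAT", "SOL")) {
  if (!is.numeric(z_lo) || !is.numeric(z_hi) || z_hi <= z_lo)
    stop("need z_hi > z_lo", call. = FALSE)
  if (buffer < 0) stop("buffer must be >= 0", call. = FALSE)
  if (radial_cutoff <= 0) stop("radial_cutoff must be > 0", call. = FALSE)
  structure(list(z_lo = z_lo, z_hi = z_hi, buffer = buffer,
                 radial_cutoff = radial_cutoff, center = center,
                 center_selection = center_selection,
                 water_resnames = toupper(water_resnames),
                 L = z_hi - z_lo),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec> z [", x$z_lo, ", ", x$z_hi, "] A (L = ", x$L,
      "), r <= ", x$radial_cutoff, ", buffer ", x$buffer, "\n", sep = "")
  invisible(x)
}

#' Indices of water oxygen atoms
#' @param top a `topology`.
#' @param channel a `channel_spec` (supplies the water residue names).
#' @export
water_oxygens <- function(top, channel) {
  w <- toupper(top$residue_name) %in% channel$water_resnames &
    toupper(top$element) == "O"
  idx <- which(w)
  if (length(idx) == 0L)
    stop("no water oxygens found (residue names ",
         paste(channel$water_resnames, collapse = "/"), ")", call. = FALSE)
  idx
}
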