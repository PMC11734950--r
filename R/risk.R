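#' Relative encounter-risk surfaces
#'
#' The relative risk of a whale and a vessel co-occurring in a grid cell is
#' the product of two normalized occupancy probabilities: `W`, the whale's
#' relative probability of occupying cell k (habitat suitability divided by
#' its total over the study cells, assuming suitability scales linearly with
#' occupancy), and `B`, the vessel analogue built from vessel hours. The
#' per-cell encounter risk is `E = W * B`, reported either min-max rescaled
#' to \[0, 1\] or renormalized to sum 1.
#'
#' @name risk
NULL

#' Normalized whale-occupancy surface W
#'
#' `W_k = HSV_k / sum(HSV)` over masked-in study cells.
#'
#' @param hsv a habitat-suitability [surface()] (typically 1-degree, from
#'   [regrid_mean()]).
#' @return a [surface()] summing to 1 over study cells.
#' @export
normalize_occupancy <- function(hsv) {
  stopifnot(inherits(hsv, "surface"))
  v <- hsv$values
  if (any(v < 0, na.rm = TRUE)) stop("HSV must be non-negative")
  tot <- sum(v, na.rm = TRUE)
  if (tot <= 0) stop("all-zero HSV surface cannot be normalized")
  out <- hsv
  out$values <- v / tot
  out$units <- "occupancy probability"
  out
}

#' Normalized vessel-occupancy surface B
#'
#' `B_k = V_k / sum(V)` over masked-in study cells. Future periods reuse the
#' present-day vessel surface (stable-vessel-activity assumption); pass the
#' `period` label to record this.
#'
#' @param vessel_hours a vessel-hours [surface()].
#' @param period optional period label for the output.
#' @return a [surface()] summing to 1 over study cells.
#' @export
normalize_vessels <- function(vessel_hours, period = vessel_hours$period) {
  stopifnot(inherits(vessel_hours, "surface"))
  v <- vessel_hours$values
  if (any(v < 0, na.rm = TRUE)) stop("vessel hours must be non-negative")
  tot <- sum(v, na.rm = TRUE)
  if (tot <= 0) stop("all-zero vessel surface cannot be normalized")
  out <- vessel_hours
  out$values <- v / tot
  out$period <- period
  out$units <- "occupancy probability"
  out
}

#' Relative encounter risk E = W * B
#'
#' @param W,B [surface()]s from [normalize_occupancy()] and
#'   [normalize_vessels()], on identical grids.
#' @return the elementwise-product [surface()] (unnormalized).
#' @export
encounter_risk <- function(W, B) {
  stopifnot(inherits(W, "surface"), inherits(B, "surface"))
  g1 <- W$grid; g2 <- B$grid
  if (g1$ncell != g2$ncell || g1$resolution != g2$resolution ||
      g1$lon_min != g2$lon_min || g1$lat_min != g2$lat_min ||
      !identical(g1$mask, g2$mask))
    stop("W and B must live on identical grids")
  out <- W
  out$values <- W$values * B$values
  out$units <- "relative risk"
  out
}

#' Rescale an encounter-risk surface
#'
#' `range01`: (E - min) / (max - min), mapping the study cells onto \[0, 1\]
#' (hotspot maps). `sum1`: E / sum(E), a discrete probability surface
#' (cross-surface comparisons, overlap statistics).
#'
#' @param E_raw an [encounter_risk()] surface.
#' @param mode `"range01"` or `"sum1"`.
#' @return the rescaled [surface()] with attribute `"mode"`.
#' @export
rescale_risk <- function(E_raw, mode = c("range01", "sum1")) {
  mode <- match.arg(mode)
  stopifnot(inherits(E_raw, "surface"))
  v <- E_raw$values
  ok <- !is.na(v)
  out <- E_raw
  if (mode == "range01") {
    rng <- range(v[ok])
    if (diff(rng) == 0)
      stop("constant risk surface cannot be range-rescaled; use mode = 'sum1'")
    out$values[ok] <- (v[ok] - rng[1]) / (rng[2] - rng[1])
  } else {
    tot <- sum(v[ok])
    if (tot <= 0) stop("all-zero risk surface cannot be sum-normalized")
    out$values[ok] <- v[ok] / tot
  }
  attr(out, "mode") <- mode
  out
}

#' All risk surfaces for one species and period
#'
#' Convenience wrapper producing W, B, raw E and normalized E in one call.
#'
#' @param hsv,vessel_hours aligned [surface()]s.
#' @param mode normalization mode for `E_norm` (see [rescale_risk()]).
#' @param species,period labels recorded on the outputs.
#' @return list of class `risk_surfaces`: `W`, `B`, `E_raw`, `E_norm`.
#' @export
risk_surfaces <- function(hsv, vessel_hours, mode = "range01",
                          species = hsv$species, period = hsv$period) {
  W <- normalize_occupancy(hsv)
  B <- normalize_vessels(vessel_hours, period = period)
  E <- encounter_risk(W, B)
  En <- rescale_risk(E, mode)
  W$species <- B$species <- E$species <- En$species <- species
  structure(list(W = W, B = B, E_raw = E, E_norm = En,
                 species = species, period = period, mode = mode),
            class = "risk_surfaces")
}
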