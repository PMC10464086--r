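#' Gas-space volume fraction of a sediment layer
#'
#' Estimates the volume fraction of free gas (in lake sediments,
#' predominantly methane bubbles) in a sediment layer from paired water
#' content measurements:
#' \deqn{VP_a = 1 - \frac{Moi_v \cdot \rho_w}{Moi_m \cdot \rho_{w\&s}}}
#' where the volumetric water content \eqn{Moi_v = V_w/V_T} is measured
#' in situ on the bulk (gas-inclusive) volume, the mass water content
#' \eqn{Moi_m = M_w/(M_w + M_s)} by oven drying, \eqn{\rho_w} is the
#' pore-water density and \eqn{\rho_{w\&s}} the density of the degassed
#' water-plus-solid mixture (submerged weighing, so its volume basis is
#' \eqn{V_w + V_s}).  Under these conventions the ratio equals
#' \eqn{(V_w + V_s)/V_T} and the expression recovers \eqn{V_a/V_T} exactly.
#'
#' Raw values slightly below zero arise from measurement noise in saturated
#' (gas-free) layers; they are clamped to 0 and flagged via a warning (and
#' in the `raw` attribute).
#'
#' @param moi_v volumetric water content, fraction of total volume in (0, 1).
#' @param moi_m mass water content, fraction of total mass in (0, 1).
#' @param rho_w pore-water density, g/cm^3.
#' @param rho_ws density of the degassed sediment-water mixture, g/cm^3.
#' @return numeric vector of gas volume fractions in \[0, 1\], with
#'   attribute `raw` holding the unclamped values.
#' @examples
#' gas_volume_percent(0.6, 0.5, 1.0, 1.5)  # 0.20
#' @seealso [total_interstitial_space()]
#' @export
gas_volume_percent <- function(moi_v, moi_m, rho_w, rho_ws) {
  n <- max(length(moi_v), length(moi_m), length(rho_w), length(rho_ws))
  ok <- vapply(list(moi_v, moi_m, rho_w, rho_ws),
               function(a) length(a) %in% c(1L, n), logical(1))
  if (!all(ok)) stopf("argument lengths must match (or be 1)")
  moi_v <- rep_len(moi_v, n); moi_m <- rep_len(moi_m, n)
  rho_w <- rep_len(rho_w, n); rho_ws <- rep_len(rho_ws, n)
  if (any(!is.finite(c(moi_v, moi_m, rho_w, rho_ws)))) stopf("non-finite inputs")
  if (any(moi_v <= 0 | moi_v >= 1)) stopf("moi_v must lie in (0, 1)")
  if (any(moi_m <= 0 | moi_m >= 1)) stopf("moi_m must lie in (0, 1)")
  if (any(rho_w <= 0) || any(rho_ws <= 0)) stopf("densities must be positive")
  if (any(moi_m * rho_ws == 0)) stopf("moi_m * rho_ws must be non-zero")
  raw <- 1 - (moi_v * rho_w) / (moi_m * rho_ws)
  if (any(raw > 1)) stopf("gas volume fraction > 1: inconsistent inputs")
  vp <- pmax(raw, 0)
  neg <- raw < -.Machine$double.eps^0.5
  if (any(neg)) {
    warnf("%d gas volume value(s) below 0 (min %.4f) clamped to 0", sum(neg), min(raw))
  }
  attr(vp, "raw") <- raw
  vp
}

#' Total interstitial space of a sediment layer
#'
#' Total interstitial space (TIS) is the volume fraction of a layer not
#' occupied by solids: the volumetric water content plus the gas-space
#' volume fraction, `TIS = moi_v + VP_a`.
#'
#' @inheritParams gas_volume_percent
#' @return numeric vector of TIS fractions in \[0, 1\].
#' @examples
#' total_interstitial_space(0.6, 0.5, 1.0, 1.5)  # 0.8
#' @export
total_interstitial_space <- function(moi_v, moi_m, rho_w, rho_ws) {
  tis <- moi_v + gas_volume_percent(moi_v, moi_m, rho_w, rho_ws)
  attr(tis, "raw") <- NULL
  tis
}

#' Interstitial-space profile of a physics table
#'
#' Applies [gas_volume_percent()] and [total_interstitial_space()] to every
#' row of a per-layer physics table, carrying warning flags per row instead
#' of raising them.
#'
#' @param physics data frame with columns `layer`, `season`, `moi_v`,
#'   `moi_m`, `rho_w`, `rho_ws` (extra columns are preserved).
#' @return the input with added columns `vp_raw`, `vp`, `tis` and logical
#'   `flag_clamped` marking rows whose raw gas fraction was negative.
#' @export
physics_profile <- function(physics) {
  need <- c("layer", "season", "moi_v", "moi_m", "rho_w", "rho_ws")
  if (!all(need %in% names(physics))) {
    stopf("physics table must have columns: %s", paste(need, collapse = ", "))
  }
  vp <- withCallingHandlers(
    gas_volume_percent(physics$moi_v, physics$moi_m, physics$rho_w, physics$rho_ws),
    warning = function(w) invokeRestart("muffleWarning")
  )
  physics$vp_raw <- attr(vp, "raw")
  physics$vp <- as.vector(vp)
  physics$tis <- physics$moi_v + physics$vp
  physics$flag_clamped <- physics$vp_raw < -.Machine$double.eps^0.5
  physics
}

#' Age-depth model from dated anchors
#'
#' Builds a piecewise-linear age-depth model from dated anchor points
#' (e.g. the core surface at the sampling year and the 137-Cs activity
#' peak marking 1963).  Depths beyond the deepest anchor are extrapolated
#' at the deepest segment's constant deposition rate.
#'
#' @param depth numeric vector of anchor depths in cm, strictly increasing,
#'   starting at the surface (0 cm).
#' @param year numeric vector of calendar years, strictly decreasing.
#' @return object of class `age_depth_model`.
#' @examples
#' adm <- age_depth_model(c(0, 21.4, 55), c(2015, 1963, 1709))
#' depth_to_year(adm, 10.7)
#' @export
age_depth_model <- function(depth, year) {
  if (length(depth) < 2L || length(depth) != length(year)) {
    stopf("need at least two (depth, year) anchors of equal length")
  }
  if (any(diff(depth) <= 0)) stopf("anchor depths must be strictly increasing")
  if (any(diff(year) >= 0)) stopf("anchor years must be strictly decreasing")
  if (depth[1] < 0) stopf("anchor depths must be non-negative")
  structure(list(depth = as.numeric(depth), year = as.numeric(year)),
            class = "age_depth_model")
}

#' @export
print.age_depth_model <- function(x, ...) {
  cat("age_depth_model with anchors:\n")
  print(data.frame(depth_cm = x$depth, year = x$year), row.names = FALSE)
  invisible(x)
}

#' Interpolate calendar year at a sediment depth
#'
#' Piecewise-linear interpolation between age-depth anchors; depths below
#' the deepest anchor are extended along the terminal segment's slope.
#'
#' @param model an [age_depth_model()].
#' @param depth numeric vector of depths in cm, each >= 0.
#' @return numeric vector of calendar years (monotone decreasing in depth).
#' @export
depth_to_year <- function(model, depth) {
  stopifnot(inherits(model, "age_depth_model"))
  if (any(depth < 0)) stopf("depth must be non-negative")
  d <- model$depth
  y <- model$year
  seg <- pmin(pmax(findInterval(depth, d), 1L), length(d) - 1L)
  slope <- (y[seg + 1L] - y[seg]) / (d[seg + 1L] - d[seg])
  out <- y[seg] + slope * (depth - d[seg])
  ## depths shallower than the first anchor extend the first segment
  out
}

#' Interpolate sediment depth at a calendar year
#'
#' Inverse of [depth_to_year()] on the same piecewise-linear model.
#'
#' @param model an [age_depth_model()].
#' @param year numeric vector of calendar years.
#' @return numeric vector of depths in cm.
#' @export
year_to_depth <- function(model, year) {
  stopifnot(inherits(model, "age_depth_model"))
  d <- model$depth
  y <- model$year
  ## years decrease with index; findInterval needs increasing input
  seg <- pmin(pmax(findInterval(-year, -y), 1L), length(y) - 1L)
  slope <- (d[seg + 1L] - d[seg]) / (y[seg + 1L] - y[seg])
  d[seg] + slope * (year - y[seg])
}

#' Mean deposition rate over a depth interval
#'
#' @param model an [age_depth_model()].
#' @param depth_top,depth_bottom interval bounds in cm, `depth_top <
#'   depth_bottom`.
#' @return deposition rate in cm/year.
#' @examples
#' adm <- age_depth_model(c(0, 21.4), c(2015, 1963))
#' deposition_rate(adm, 0, 21.4)  # ~0.41 cm/yr
#' @export
deposition_rate <- function(model, depth_top, depth_bottom) {
  if (!is_number(depth_top) || !is_number(depth_bottom) || depth_top >= depth_bottom) {
    stopf("need depth_top < depth_bottom")
  }
  dy <- depth_to_year(model, depth_top) - depth_to_year(model, depth_bottom)
  if (dy == 0) stopf("zero year difference across the interval")
  (depth_bottom - depth_top) / dy
}
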