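# Tow geometry. The sled position lags the vessel by the cable layback,
# approximated by treating the cable catenary as a straight line.

#' Cable layback
#'
#' Horizontal distance from vessel to sled, `L = sqrt(R^2 - D^2)` for
#' cable length `R` and depth `D`, assuming a straight-line catenary.
#'
#' @param R Tow cable length, metres (>= D).
#' @param D Depth, metres (>= 0).
#' @return Layback in metres.
#' @export
layback <- function(R, D) {
  if (any(D < 0)) stop("depth must be >= 0", call. = FALSE)
  if (any(R < D)) stop("cable shorter than depth: layback undefined",
                       call. = FALSE)
  sqrt(R^2 - D^2)
}

#' Correct a vessel fix for sled layback
#'
#' Tows run along a north-south axis, so the layback is subtracted from
#' (heading north) or added to (heading south) the vessel latitude;
#' longitude is unchanged.
#'
#' @param vessel_lat,vessel_lon Vessel position, decimal degrees.
#' @param cable_out_m Cable length R, metres.
#' @param depth_m Depth D, metres.
#' @param heading `"north"` or `"south"`.
#' @param m_per_deg Metres per degree of latitude; default 111120
#'   (1 nautical mile = 1852 m, 60 nmi per degree).
#' @return Named list with `lat`, `lon` of the sled.
#' @export
correct_position <- function(vessel_lat, vessel_lon, cable_out_m, depth_m,
                             heading = c("north", "south"),
                             m_per_deg = 111120) {
  heading <- match.arg(heading)
  L <- layback(cable_out_m, depth_m)
  dlat <- L / m_per_deg
  lat <- if (heading == "north") vessel_lat - dlat else vessel_lat + dlat
  list(lat = lat, lon = vessel_lon)
}

#' Swept area of a tow
#'
#' `area = width * speed * duration`, e.g. a 1.83 m beam towed at
#' 1 m s^-1 for 600 s sweeps 1098 m^2.
#'
#' @param width_m Gear width, metres (> 0).
#' @param speed_ms Tow speed, m s^-1 (> 0).
#' @param duration_s Tow duration, seconds (> 0).
#' @return Swept area in square metres.
#' @export
swept_area <- function(width_m, speed_ms, duration_s) {
  if (any(c(width_m, speed_ms, duration_s) <= 0)) {
    stop("width, speed and duration must all be > 0", call. = FALSE)
  }
  width_m * speed_ms * duration_s
}
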