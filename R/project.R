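#' Azimuthal equidistant projection
#'
#' Planar computations (speeds, tortuosity, CTCRW fitting, rasterization) run
#' in kilometres on an azimuthal equidistant projection centred on the study
#' area; longitude/latitude appear only at I/O boundaries. At the high
#' latitudes of an Arctic overwintering ground a local azimuthal projection
#' keeps distances in km essentially undistorted over study-area scales.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param center Numeric length-2, `c(lon0, lat0)` of the projection centre.
#' @return `projectAEQD`: data.frame with planar `x`, `y` in km;
#'   `unprojectAEQD`: data.frame with `lon`, `lat` in degrees.
#' @export
#' @examples
#' p <- projectAEQD(-60, 68, center = c(-60, 68))  # origin maps to (0, 0)
projectAEQD <- function(lon, lat, center) {
  stopifnot(length(center) == 2)
  R <- 6371.0088
  d2r <- pi / 180
  lam <- lon * d2r; phi <- lat * d2r
  lam0 <- center[1] * d2r; phi0 <- center[2] * d2r
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- R * k * cos(phi) * sin(lam - lam0)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}

#' @rdname projectAEQD
#' @param x,y Planar coordinates in km.
#' @export
unprojectAEQD <- function(x, y, center) {
  stopifnot(length(center) == 2)
  R <- 6371.0088
  d2r <- pi / 180
  lam0 <- center[1] * d2r; phi0 <- center[2] * d2r
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / R
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- lam0 + ifelse(rho < 1e-12, 0,
                       atan2(x * sin(c_ang),
                             rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang)))
  data.frame(lon = lam / d2r, lat = phi / d2r)
}
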