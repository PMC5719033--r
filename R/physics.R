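## Idealized reflectron flight physics shared by all modules.
##
## Model: a singly charged ion emitted at height dh above the substrate is
## accelerated over the remaining gap (h_ex - dh) by the uniform extraction
## field; the reflectron exactly compensates the exit-velocity deficit, so
## the drift time is height-independent and the only topographic effect is
## the shortened acceleration time. Times scale as sqrt(m), which is what
## makes a single per-pixel correction factor valid for every mass.

.checkMassDh <- function(mass, dh, geom) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("ion mass must be positive (u)")
  if (any(!is.finite(dh)) || any(dh < 0) || any(dh >= geom@h_ex))
    stop("emission height dh must satisfy 0 <= dh < h_ex")
}

#' Acceleration time in the extraction gap
#'
#' Time a singly charged ion of mass `mass` spends in the uniform
#' extraction field when emitted at height `dh` above the substrate:
#' \deqn{t_{ac}(dh) = \sqrt{2 h_{ex}^2 m / (U_{ex} e)} \,
#'       \sqrt{(h_{ex}-dh)/h_{ex}}.}
#' With the default 2 kV / 1.5 mm geometry and the atomic weight of
#' potassium this evaluates to about 30.2 ns at the substrate.
#'
#' @param mass ion mass, u (vectorized).
#' @param geom an [InstrumentGeometry-class].
#' @param dh emission height above the substrate, meters (vectorized).
#' @return Acceleration time in seconds.
#' @examples
#' accelerationTime(ionMasses[["K_atomic"]], instrumentGeometry()) * 1e9
#' @export
accelerationTime <- function(mass, geom = instrumentGeometry(), dh = 0) {
  .checkMassDh(mass, dh, geom)
  t0 <- sqrt(2 * geom@h_ex^2 * mass * .UAMU / (geom@U_ex * .ECHARGE))
  t0 * sqrt((geom@h_ex - dh) / geom@h_ex)
}

#' Total time of flight of an ion emitted at height dh
#'
#' Substrate-level flight time follows the calibration anchor via the
#' sqrt(m) law, `T(m, 0) = T_cal * sqrt(m / m_cal)`; emission at height
#' dh shortens it by the acceleration-time deficit:
#' \deqn{T(m, dh) = T(m, 0) - t_{ac}(m, 0)\,
#'       \bigl(1 - \sqrt{(h_{ex}-dh)/h_{ex}}\bigr).}
#'
#' @inheritParams accelerationTime
#' @param dh emission height, meters.
#' @return Total time of flight, seconds.
#' @export
totalTof <- function(mass, dh = 0, geom = instrumentGeometry()) {
  .checkMassDh(mass, dh, geom)
  geom@T_cal * sqrt(mass / geom@m_cal) - tofShift(mass, dh, geom)
}

#' Topography-induced time-of-flight shift
#'
#' The reduction in total flight time for emission at height dh:
#' \deqn{\Delta T(m, dh) = t_{ac}(m, 0)
#'       \bigl(1 - \sqrt{(h_{ex}-dh)/h_{ex}}\bigr) \ge 0,}
#' strictly increasing in dh and proportional to sqrt(m).
#'
#' @inheritParams totalTof
#' @return Shift in seconds (>= 0).
#' @export
tofShift <- function(mass, dh, geom = instrumentGeometry()) {
  .checkMassDh(mass, dh, geom)
  t0 <- sqrt(2 * geom@h_ex^2 * mass * .UAMU / (geom@U_ex * .ECHARGE))
  t0 * (1 - sqrt((geom@h_ex - dh) / geom@h_ex))
}

#' Quadratic TOF-to-mass calibration
#'
#' Standard single-point quadratic law anchored on the calibration ion:
#' `m = m_cal * ((t - t0) / (T_cal - t0))^2`. Exact inverse of
#' [tofFromMass()].
#'
#' @param t time of flight, seconds (vectorized).
#' @param geom an [InstrumentGeometry-class].
#' @param t0 calibration time offset, seconds (default 0).
#' @return Mass in u.
#' @export
massFromTof <- function(t, geom = instrumentGeometry(), t0 = 0) {
  if (any(t <= t0)) stop("time of flight must exceed the offset t0")
  geom@m_cal * ((t - t0) / (geom@T_cal - t0))^2
}

#' Mass-to-TOF calibration (inverse of massFromTof)
#'
#' @param mass mass in u (vectorized).
#' @inheritParams massFromTof
#' @return Substrate-level time of flight in seconds.
#' @export
tofFromMass <- function(mass, geom = instrumentGeometry(), t0 = 0) {
  if (any(mass <= 0)) stop("mass must be positive")
  t0 + (geom@T_cal - t0) * sqrt(mass / geom@m_cal)
}

#' Emission height from a reference-peak shift
#'
#' Closed-form inverse of the shift law: given the observed shift dt of a
#' reference ion, the emission height is
#' \deqn{\Delta h = h_{ex}\bigl(1 - ((t_{ac}(0) - \Delta t)/t_{ac}(0))^2\bigr),}
#' with `t_ac(0)` the substrate-level acceleration time of the reference
#' ion estimated from the instrument geometry.
#'
#' @param dt observed shift, seconds (vectorized); must be < t_ac(0).
#' @param mass reference ion mass, u.
#' @param geom an [InstrumentGeometry-class].
#' @return Height in meters.
#' @export
heightFromShift <- function(dt, mass, geom = instrumentGeometry()) {
  tac0 <- accelerationTime(mass, geom, 0)
  if (any(dt >= tac0)) stop("shift must be smaller than t_ac(0)")
  if (any(dt < 0)) stop("shift must be non-negative")
  geom@h_ex * (1 - ((tac0 - dt) / tac0)^2)
}

#' Smallest detectable feature height
#'
#' Height at which the topographic shift of the given ion equals the TDC
#' bin width (the timing accuracy); about 5 um for K+ at the default
#' geometry. Features below this height produce sub-bin shifts.
#'
#' @param mass ion mass, u (default: atomic weight of potassium).
#' @param geom an [InstrumentGeometry-class].
#' @param dt timing accuracy, seconds (default: one TDC bin).
#' @return Height in meters.
#' @export
detectableHeightFloor <- function(mass = ionMasses[["K_atomic"]],
                                  geom = instrumentGeometry(),
                                  dt = geom@tof_bin) {
  heightFromShift(dt, mass, geom)
}

## Geometry (de)serialization used by the container, scene descriptors and
## the pipeline config.
.geomToList <- function(geom) {
  list(U_ex = geom@U_ex, h_ex = geom@h_ex, T_cal = geom@T_cal,
       m_cal = geom@m_cal, tof_bin = geom@tof_bin,
       t_window = geom@t_window, H_ef = geom@H_ef)
}

.geomFromList <- function(x) {
  need <- c("U_ex", "h_ex", "T_cal", "m_cal", "tof_bin", "t_window", "H_ef")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("geometry metadata is missing field(s): ", paste(miss, collapse = ", "))
  instrumentGeometry(U_ex = x$U_ex, h_ex = x$h_ex, T_cal = x$T_cal,
                     m_cal = x$m_cal, tof_bin = x$tof_bin,
                     t_window = x$t_window, H_ef = x$H_ef)
}

#' Serialize an instrument geometry to JSON
#' @param geom an [InstrumentGeometry-class].
#' @return A JSON string.
#' @export
geometryToJSON <- function(geom) {
  jsonlite::toJSON(.geomToList(geom), auto_unbox = TRUE, digits = NA)
}

#' Restore an instrument geometry from JSON
#' @param json a JSON string produced by [geometryToJSON()].
#' @return An [InstrumentGeometry-class].
#' @export
geometryFromJSON <- function(json) {
  .geomFromList(jsonlite::fromJSON(json))
}
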