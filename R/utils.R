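# Angle helpers. All user-facing angles are degrees, counterclockwise
# positive, 0 = rightward. Analyses work on unwrapped angles relative to a
# reference direction: spreads are far below 180 deg, so linear statistics
# apply once each angle is mapped into (ref - 180, ref + 180].

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles mapped into the interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Unwrap angles around a reference direction
#'
#' Maps each angle into the 360-degree interval centred on `ref`, so that
#' linear statistics (mean, SD, regression) are valid for narrowly spread
#' directions.
#'
#' @param x Numeric vector of angles in degrees.
#' @param ref Reference direction in degrees.
#' @return Angles within `(ref - 180, ref + 180]`.
#' @export
unwrap_to <- function(x, ref) ref + wrap_angle(x - ref)

# direction of a velocity vector, degrees CCW from +x
atan2_deg <- function(v, h) rad2deg(atan2(v, h))

`%||%` <- function(a, b) if (is.null(a)) b else a
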