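# Internal helpers shared across modules.

POSITION_CHANNELS <- c("pos_sagittal", "pos_transversal", "pos_longitudinal")
ROTATION_CHANNELS <- c("rot_flexion", "rot_lateral_flexion", "rot_rotation")
ALL_CHANNELS <- c(POSITION_CHANNELS, ROTATION_CHANNELS)

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a child seed from a parent seed and a stream index, < 2^31
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Elementary rotation matrices, angles in degrees.  Axes follow the lab
# convention: x = sagittal (front-back), y = transversal (side-to-side),
# z = longitudinal (vertical), right-handed.
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Compose a rotation matrix from the package Euler convention
#'
#' Intrinsic sequence rotation (about longitudinal z) -> flexion (about
#' transversal y) -> lateral flexion (about sagittal x), i.e.
#' R = Rz(rotation) Ry(flexion) Rx(lateral_flexion).  Angles in degrees.
#' @noRd
euler_to_matrix <- function(flexion, lateral_flexion, rotation) {
  rot_z(rotation) %*% rot_y(flexion) %*% rot_x(lateral_flexion)
}

#' Decompose a rotation matrix into the package Euler convention (degrees)
#' @noRd
matrix_to_euler <- function(R) {
  # R = Rz(a) Ry(b) Rx(c): R[3,1] = -sin b
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  } else {
    # gimbal lock: fold rotation into lateral flexion
    a <- 0
    c <- atan2(-R[2, 3], R[2, 2])
  }
  c(
    flexion = b * 180 / pi,
    lateral_flexion = c * 180 / pi,
    rotation = a * 180 / pi
  )
}

#' Unwrap angle series (degrees) so linear interpolation is safe
#' @noRd
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jumps <- round(d / 360)
  x - c(0, cumsum(jumps) * 360)
}

#' Linear-interpolation quantile (type 7), shared percentile definition
#' @noRd
pctl <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
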