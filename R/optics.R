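#' Jones matrix of a linear retarder
#'
#' @param delta Retardance in radians (>= 0).
#' @param theta Slow-axis orientation in radians.
#' @return A 2x2 complex (unitary, unimodular) matrix.
#' @export
jones_retarder <- function(delta, theta) {
  stopifnot(length(delta) == 1, length(theta) == 1, is.finite(delta),
            is.finite(theta), delta >= 0)
  cs <- cos(theta)
  sn <- sin(theta)
  rot <- matrix(c(cs, sn, -sn, cs), 2, 2)
  diag_m <- diag(c(exp(-1i * delta / 2), exp(1i * delta / 2)))
  rot %*% diag_m %*% t(rot)
}

#' Equivalent retardance of two stacked linear retarders
#'
#' Composes two linear retarders as Jones matrices and extracts the
#' retardance of the equivalent elliptical retarder from the phase
#' difference of the eigenvalues of the product. This is the mechanism that
#' produces the macular cross: the radially oriented HFL retarder beats
#' against a residual corneal retarder of fixed axis, so the net retardance
#' is modulated at twice the azimuthal frequency.
#'
#' The result agrees with the closed form
#' \deqn{\cos(\delta/2) = |\cos(\delta_1/2)\cos(\delta_2/2) -
#'   \sin(\delta_1/2)\sin(\delta_2/2)\cos 2(\theta_1-\theta_2)|}
#' (see [closed_form_retardance()], used as the vectorized fast path by the
#' simulator and as the independent oracle in the test suite).
#'
#' @param delta1,delta2 Retardances in radians (>= 0). Vectors are recycled.
#' @param theta1,theta2 Slow-axis orientations in radians.
#' @return Net retardance in radians, in \[0, pi\].
#' @export
#' @examples
#' composite_retardance(pi / 2, 0, pi / 2, pi / 4) * 180 / pi # 120 degrees
composite_retardance <- function(delta1, theta1, delta2, theta2) {
  if (any(delta1 < 0) || any(delta2 < 0)) {
    stop("retardances must be non-negative")
  }
  n <- max(length(delta1), length(theta1), length(delta2), length(theta2))
  args <- list(rep_len(delta1, n), rep_len(theta1, n),
               rep_len(delta2, n), rep_len(theta2, n))
  vapply(seq_len(n), function(i) {
    m <- jones_retarder(args[[3]][i], args[[4]][i]) %*%
      jones_retarder(args[[1]][i], args[[2]][i])
    ev <- eigen(m, only.values = TRUE)$values
    abs(Arg(ev[1] / ev[2]))
  }, numeric(1))
}

#' Closed-form two-retarder composition
#'
#' Vectorized closed form for the equivalent retardance of two stacked
#' linear retarders; the Jones-matrix route ([composite_retardance()]) and
#' this expression must agree to 1e-9 (a property enforced by the tests).
#'
#' @inheritParams composite_retardance
#' @return Net retardance in radians, in \[0, pi\].
#' @export
closed_form_retardance <- function(delta1, theta1, delta2, theta2) {
  if (any(delta1 < 0) || any(delta2 < 0)) {
    stop("retardances must be non-negative")
  }
  c1 <- cos(delta1 / 2); s1 <- sin(delta1 / 2)
  c2 <- cos(delta2 / 2); s2 <- sin(delta2 / 2)
  ch <- c1 * c2 - s1 * s2 * cos(2 * (theta1 - theta2))
  ## sin(delta/2) from the rotation-vector part of the composition;
  ## atan2 avoids the acos precision loss where |cos(delta/2)| is near 1
  ax <- s1 * c2 * cos(2 * theta1) + c1 * s2 * cos(2 * theta2)
  ay <- s1 * c2 * sin(2 * theta1) + c1 * s2 * sin(2 * theta2)
  az <- s1 * s2 * sin(2 * (theta1 - theta2))
  2 * atan2(sqrt(ax^2 + ay^2 + az^2), abs(ch))
}
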