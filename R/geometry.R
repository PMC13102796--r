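# truncation polynomial 1 + L + L^2 - L^3; shared by cavity and wall volumes
trunc_poly <- function(L) 1 + L + L^2 - L^3

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_truncation <- function(L) {
  if (any(!is.finite(L)) || any(L < 0) || any(L > 1)) {
    stop("truncation ratio 'L' must lie in [0, 1]", call. = FALSE)
  }
  invisible(L)
}

#' Long-axis height of a truncated prolate ellipsoid
#'
#' The left ventricle is modelled as a prolate ellipsoid of revolution,
#' truncated above the equator. \code{L} is the ratio of the long-axis height
#' above the equator to the semi-axis below it, so the total height is
#' \eqn{T = A(1 + L)}: \code{L = 0} is a half shell (\eqn{T = A}) and
#' \code{L = 1} a complete ellipsoid (\eqn{T = 2A}).
#'
#' @param a major semi-axis of the cavity ellipse, cm.
#' @param L dimensionless truncation ratio in \[0, 1\].
#' @return Total long-axis height \eqn{T}, cm.
#' @export
#' @examples
#' truncated_height(2, 0.75)  # 3.5
truncated_height <- function(a, L) {
  check_positive(a, "a")
  check_truncation(L)
  a * (1 + L)
}

#' Cavity volume of a truncated prolate ellipsoid
#'
#' Volume enclosed by the inner wall,
#' \eqn{LVV = (2/3)\pi A B^2 (1 + L + L^2 - L^3)}. At \code{L = 0} this is
#' half the full ellipsoid volume; at \code{L = 1} it is the complete
#' ellipsoid \eqn{(4/3)\pi A B^2}.
#'
#' @param a major semi-axis, cm.
#' @param b minor semi-axis (half the internal diameter), cm.
#' @inheritParams truncated_height
#' @return Cavity volume, mL.
#' @export
cavity_volume <- function(a, b, L) {
  check_positive(a, "a")
  check_positive(b, "b")
  check_truncation(L)
  (2 / 3) * pi * a * b^2 * trunc_poly(L)
}

#' Myocardial wall volume of a truncated ellipsoid shell
#'
#' \eqn{V_M = (2/3)\pi A H (1 + L + L^2 - L^3)(H + 2B)}. Algebraically this
#' equals \code{cavity_volume(a, b + h, L) - cavity_volume(a, b, L)}: the
#' wall is an outer ellipsoid with semi-axes \eqn{(A, B + H)} minus the
#' cavity, i.e. thickness is added radially.
#'
#' @inheritParams cavity_volume
#' @param h wall thickness, cm.
#' @return Wall volume, mL.
#' @export
wall_volume <- function(a, b, h, L) {
  check_positive(a, "a")
  check_positive(b, "b")
  check_positive(h, "h")
  check_truncation(L)
  (2 / 3) * pi * a * h * trunc_poly(L) * (h + 2 * b)
}

#' Mid-wall perimeter
#'
#' Circumference of the equatorial mid-wall chord,
#' \eqn{PMW = \pi(2B + H) = \pi(LVID + H)}.
#'
#' @param b minor semi-axis, cm (\code{LVID / 2}).
#' @param h wall thickness, cm.
#' @return Perimeter, cm.
#' @export
midwall_perimeter <- function(b, h) {
  check_positive(b, "b")
  check_positive(h, "h")
  pi * (2 * b + h)
}

new_shell_state <- function(b, h, k, L, pmw_am) {
  pmw <- pi * (2 * b + h)
  structure(
    list(
      B = b, A = k * b, H = h,
      PMW = pmw,
      LVV = cavity_volume(k * b, b, L),
      lambda = pmw / pmw_am
    ),
    class = "shell_state"
  )
}

#' @export
print.shell_state <- function(x, ...) {
  cat("Truncated-ellipsoid shell state\n")
  cat(sprintf("  B = %.4f cm, A = %.4f cm, H = %.4f cm\n", x$B, x$A, x$H))
  cat(sprintf("  PMW = %.4f cm, LVV = %.4f mL, lambda = %.6f\n",
              x$PMW, x$LVV, x$lambda))
  invisible(x)
}

#' @export
print.shell_shape <- function(x, ...) {
  cat("Truncated-ellipsoid shell shape\n")
  cat(sprintf("  L = %.4f, k (A/B) = %.4f, V_M = %.4f mL\n", x$L, x$k, x$V_M))
  invisible(x)
}

#' Build a shell heart from its fully contracted (AM) state
#'
#' Constructs the fixed geometric shape (truncation \code{L}, height-to-width
#' ratio \code{k = A/B}, myocardial wall volume \code{V_M}) and the absolute
#' minimum (AM) state of a model heart from the internal diameter and wall
#' thickness of the fully contracted left ventricle. The AM cavity volume is
#' the true dead-space volume \eqn{V_W} of the model.
#'
#' @param lvid_am internal diameter at the AM state, cm.
#' @param h_am wall thickness at the AM state, cm.
#' @param k height-to-width ratio \eqn{A/B} (1 = spherical), held constant
#'   across the cardiac cycle.
#' @param L truncation ratio, held constant across the cardiac cycle.
#' @return A list with elements \code{shape} (class \code{shell_shape}:
#'   \code{L}, \code{k}, \code{V_M}), \code{am} (class \code{shell_state} with
#'   \code{lambda = 1}) and \code{v_w}, the dead-space volume in mL.
#' @export
#' @examples
#' heart <- shell_from_am(lvid_am = 2.6, h_am = 1.0, k = 1, L = 0)
#' heart$am$PMW   # pi * 3.6
shell_from_am <- function(lvid_am, h_am, k = 1, L = 0) {
  check_positive(lvid_am, "lvid_am")
  check_positive(h_am, "h_am")
  check_truncation(L)
  if (!is.finite(k) || k < 1) stop("'k' must be >= 1", call. = FALSE)
  b <- lvid_am / 2
  if (h_am >= 2 * b) {
    stop("unsupported geometry: wall thickness must be less than the internal diameter (H < 2B)",
         call. = FALSE)
  }
  shape <- structure(
    list(L = L, k = k, V_M = wall_volume(k * b, b, h_am, L)),
    class = "shell_shape"
  )
  pmw_am <- midwall_perimeter(b, h_am)
  am <- new_shell_state(b, h_am, k, L, pmw_am)
  list(shape = shape, am = am, v_w = am$LVV)
}

# vectorised inflation core: given AM perimeter, wall volume and shape,
# return B, H, PMW, LVV at mid-wall stretch `lambda`.
# With P = lambda * PMW_AM / pi and C = (2/3) pi k (1 + L + L^2 - L^3),
# conservation of V_M = C * B * (P - 2B) * P is quadratic in B with roots
# B and H/2; the larger root is the physical one (H < 2B).
inflate_core <- function(pmw_am, v_m, k, L, lambda) {
  P <- lambda * pmw_am / pi
  C <- (2 / 3) * pi * k * trunc_poly(L)
  disc <- P^2 - 8 * v_m / (C * P)
  if (any(disc < 0)) {
    stop("stretch unattainable: wall volume exceeds what the perimeter can enclose",
         call. = FALSE)
  }
  b <- (P + sqrt(disc)) / 4
  list(B = b, H = P - 2 * b, PMW = lambda * pmw_am, LVV = C * b^3)
}

#' Inflate a shell heart to a prescribed mid-wall stretch
#'
#' Closed-form inflation of the incompressible shell: the state at stretch
#' \eqn{\lambda} has \eqn{PMW = \lambda\, PMW_{AM}}, conserved wall volume
#' \eqn{V_M}, and constant shape (\code{k}, \code{L}). Writing
#' \eqn{P = PMW/\pi} and \eqn{C = (2/3)\pi k (1 + L + L^2 - L^3)}, volume
#' conservation \eqn{V_M = C B (P - 2B) P} is quadratic in \eqn{B}; the root
#' with \eqn{H < 2B} is taken. \code{lambda = 1} returns the AM state itself
#' (fixed point).
#'
#' @param shape a \code{shell_shape} from \code{\link{shell_from_am}}.
#' @param am_state the AM \code{shell_state} of the same heart.
#' @param lambda target mid-wall stretch, \eqn{\ge 1}.
#' @return A \code{shell_state} at the requested stretch.
#' @export
inflate_to_stretch <- function(shape, am_state, lambda) {
  if (!is.finite(lambda) || lambda < 1) {
    stop("'lambda' must be >= 1 (the AM state is the zero-stretch reference)",
         call. = FALSE)
  }
  if (lambda == 1) {
    return(am_state)
  }
  pmw_am <- am_state$PMW
  st <- inflate_core(pmw_am, shape$V_M, shape$k, shape$L, lambda)
  new_shell_state(st$B, st$H, shape$k, shape$L, pmw_am)
}

#' Inflation trajectory over a stretch grid
#'
#' Evaluates the shell at each stretch in \code{lambda_grid}, returning a
#' plot-ready table. Used for the linearity diagnostic: cavity volume is very
#' nearly linear in \eqn{PMW^3} along the trajectory.
#'
#' @inheritParams inflate_to_stretch
#' @param lambda_grid sorted vector of stretches, all \eqn{\ge 1}.
#' @param heart_id identifier written into the output table.
#' @return A data.frame with columns \code{heart_id}, \code{lambda},
#'   \code{B_cm}, \code{H_cm}, \code{PMW_cm}, \code{LVV_ml}.
#' @export
shell_trajectory <- function(shape, am_state, lambda_grid, heart_id = 1L) {
  if (length(lambda_grid) == 0) stop("empty stretch grid", call. = FALSE)
  if (any(!is.finite(lambda_grid)) || any(lambda_grid < 1)) {
    stop("all grid stretches must be finite and >= 1", call. = FALSE)
  }
  if (is.unsorted(lambda_grid)) stop("stretch grid must be sorted", call. = FALSE)
  st <- inflate_core(am_state$PMW, shape$V_M, shape$k, shape$L, lambda_grid)
  # fixed point: report the AM state exactly where lambda == 1
  at_am <- lambda_grid == 1
  if (any(at_am)) {
    st$B[at_am] <- am_state$B
    st$H[at_am] <- am_state$H
    st$PMW[at_am] <- am_state$PMW
    st$LVV[at_am] <- am_state$LVV
  }
  data.frame(
    heart_id = heart_id,
    lambda = lambda_grid,
    B_cm = st$B,
    H_cm = st$H,
    PMW_cm = st$PMW,
    LVV_ml = st$LVV
  )
}
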