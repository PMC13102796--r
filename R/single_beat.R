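#' Rate-corrected velocity of circumferential fiber shortening
#'
#' \eqn{V_{CFC} = (PMW_{ED} - PMW_{ES}) / PMW_{ED} / RR^{1/3}}: fractional
#' mid-wall shortening from end diastole to end systole, normalised for
#' initial fiber length and rate-corrected by the cube root of the RR
#' interval.
#'
#' @param pmw_ed mid-wall perimeter at end diastole, cm.
#' @param pmw_es mid-wall perimeter at end systole, cm.
#' @param rr RR interval, s.
#' @return \eqn{V_{CFC}} in 1/s.
#' @export
vcfc <- function(pmw_ed, pmw_es, rr) {
  check_positive(pmw_ed, "pmw_ed")
  check_positive(pmw_es, "pmw_es")
  check_positive(rr, "rr")
  if (any(pmw_es > pmw_ed)) {
    stop("'pmw_es' must not exceed 'pmw_ed' (the ventricle shortens into systole)",
         call. = FALSE)
  }
  (pmw_ed - pmw_es) / pmw_ed / rr^(1 / 3)
}

#' Contractility Z-score from the VCFC-ESS relation
#'
#' Number of (vertical) standard deviations that a beat's rate-corrected
#' shortening velocity lies above the mean-normal line
#' \eqn{V_{CFC} = 1.23 - 0.0044\, ESS} (slope in s^-1 cm^2/g, intercept in
#' s^-1, vertical SD 0.06 s^-1, from a normal reference population):
#' \eqn{Z_C = (V_{CFC} + 0.0044\, ESS - 1.23) / 0.06}.
#'
#' @param vcfc rate-corrected shortening velocity, 1/s.
#' @param ess end-systolic wall stress, g/cm^2.
#' @return Dimensionless Z-score; positive means supranormal contractility.
#' @export
contractility_z <- function(vcfc, ess) {
  if (any(!is.finite(ess)) || any(ess < 0)) {
    stop("'ess' must be finite and non-negative", call. = FALSE)
  }
  (vcfc + 0.0044 * ess - 1.23) / 0.06
}

#' Contractility gain from a Z-score
#'
#' \eqn{G_C = C_1 Z_C + \sqrt{(C_1 Z_C)^2 + 1}}: a smooth, strictly positive,
#' strictly increasing map from the contractility Z-score to a multiplicative
#' gain with \eqn{G_C = 1} at normal contractility and the reciprocal
#' symmetry \eqn{G_C(z)\,G_C(-z) = 1}.
#'
#' @param z_c contractility Z-score.
#' @param c_1 dimensionless shape constant; default 0.2 (a coarse literature
#'   estimate, deliberately user-adjustable).
#' @return Dimensionless gain, > 0.
#' @export
contractility_gain <- function(z_c, c_1 = 0.2) {
  check_positive(c_1, "c_1")
  x <- c_1 * z_c
  x + sqrt(x^2 + 1)
}

#' End-systolic mid-wall stretch from wall stress
#'
#' Linear end-systolic stress-stretch law with x-intercept at stretch 1:
#' \eqn{\lambda_{ES} = 1 + ESS / (G_C M_N)}, where \eqn{M_N} is the normal
#' contractility slope (about 500 g/cm^2, from \eqn{\lambda_{ES} \approx
#' 1.12} and \eqn{ESS \approx 60} g/cm^2 in normal hearts).
#'
#' @inheritParams contractility_z
#' @param g_c contractility gain, > 0.
#' @param m_n normal stress-stretch slope, g/cm^2.
#' @return Stretch \eqn{\lambda_{ES} \ge 1}.
#' @export
#' @examples
#' lambda_es(ess = 60, g_c = 1)  # 1.12
lambda_es <- function(ess, g_c, m_n = 500) {
  if (any(!is.finite(ess)) || any(ess < 0)) {
    stop("'ess' must be finite and non-negative", call. = FALSE)
  }
  check_positive(g_c, "g_c")
  check_positive(m_n, "m_n")
  1 + ess / (g_c * m_n)
}

#' Single-beat estimate of the fully contracted mid-wall perimeter
#'
#' Since \eqn{\lambda_{ES} = PMW_{ES} / PMW_{AM}}, the stress-stretch law
#' inverts to \eqn{PMW_{AM} = PMW_{ES} / (1 + ESS/(G_C M_N))}. Always
#' \eqn{\le PMW_{ES}}, with equality at zero stress.
#'
#' @inheritParams lambda_es
#' @param pmw_es end-systolic mid-wall perimeter, cm.
#' @return Estimated AM perimeter, cm.
#' @export
pmw_am <- function(pmw_es, ess, g_c, m_n = 500) {
  check_positive(pmw_es, "pmw_es")
  pmw_es / lambda_es(ess, g_c, m_n)
}

#' Two-point cubic fit of cavity volume to mid-wall perimeter
#'
#' Fits the first-order volume-perimeter law \eqn{LVV = a\,PMW^3 - b}
#' through the end-diastolic and end-systolic states exactly:
#' \deqn{a = (EDV - ESV) / (PMW_{ED}^3 - PMW_{ES}^3)}
#' with \eqn{b} chosen so both states are reproduced. \eqn{b} is the volume
#' of muscle inside the mid-wall shell (the cavity vanishes at a non-zero
#' perimeter).
#'
#' @param edv,esv end-diastolic and end-systolic cavity volumes, mL.
#' @param pmw_ed,pmw_es mid-wall perimeters at ED and ES, cm.
#' @return An object of class \code{pmw_cubic} with coefficients \code{a}
#'   (mL/cm^3) and \code{b} (mL); supports \code{coef} and \code{predict}.
#' @seealso \code{\link{amv}}, \code{\link{amv_single_beat}}
#' @export
#' @examples
#' fit <- fit_ab(edv = 120, esv = 50, pmw_ed = 12, pmw_es = 10)
#' coef(fit)
#' predict(fit, pmw = 10)  # 50, the ES pass-through point
fit_ab <- function(edv, esv, pmw_ed, pmw_es) {
  check_positive(edv, "edv")
  check_positive(esv, "esv")
  check_positive(pmw_ed, "pmw_ed")
  check_positive(pmw_es, "pmw_es")
  if (edv <= esv) stop("'edv' must exceed 'esv'", call. = FALSE)
  d3 <- pmw_ed^3 - pmw_es^3
  if (abs(d3) <= 1e-9 * pmw_ed^3) {
    stop("degenerate fit: end-diastolic and end-systolic perimeters are too close",
         call. = FALSE)
  }
  a <- (edv - esv) / d3
  b <- -(esv * pmw_ed^3 - edv * pmw_es^3) / d3
  structure(
    list(a = a, b = b, edv = edv, esv = esv, pmw_ed = pmw_ed, pmw_es = pmw_es),
    class = "pmw_cubic"
  )
}

#' @export
coef.pmw_cubic <- function(object, ...) c(a = object$a, b = object$b)

#' Predict cavity volume from mid-wall perimeter
#'
#' @param object a \code{pmw_cubic} fit.
#' @param pmw mid-wall perimeter(s), cm.
#' @param ... unused.
#' @return Cavity volume(s) \eqn{a\,PMW^3 - b}, mL.
#' @export
predict.pmw_cubic <- function(object, pmw, ...) {
  check_positive(pmw, "pmw")
  object$a * pmw^3 - object$b
}

#' @export
print.pmw_cubic <- function(x, ...) {
  cat("Cubic volume-perimeter law: LVV = a * PMW^3 - b\n")
  cat(sprintf("  a = %.6g mL/cm^3, b = %.6g mL\n", x$a, x$b))
  cat(sprintf("  fitted through ED (PMW %.4g cm, %.4g mL) and ES (PMW %.4g cm, %.4g mL)\n",
              x$pmw_ed, x$edv, x$pmw_es, x$esv))
  invisible(x)
}

#' Absolute minimum volume from a fitted cubic law
#'
#' Evaluates \eqn{AMV = a\,PMW_{AM}^3 - b}. A negative value (possible for
#' pathological inputs) is returned raw; flagging is the caller's concern
#' (see \code{\link{amv_single_beat}}).
#'
#' @param fit a \code{pmw_cubic} fit.
#' @param pmw_am estimated fully contracted mid-wall perimeter, cm.
#' @return Estimated dead-space volume, mL.
#' @export
amv <- function(fit, pmw_am) {
  stopifnot(inherits(fit, "pmw_cubic"))
  predict(fit, pmw_am)
}

#' Construct and validate a single echo beat
#'
#' Bundles one beat's echocardiography-derived measurements. Perimeters are
#' derived as \eqn{PMW = \pi(LVID + H)} (since \eqn{PMW = \pi(2B + H)} and
#' \eqn{LVID = 2B}).
#'
#' @param lvid_ed,h_ed internal diameter and wall thickness at ED, cm.
#' @param lvid_es,h_es internal diameter and wall thickness at ES, cm.
#' @param edv,esv cavity volumes at ED and ES, mL.
#' @param ess end-systolic wall stress, g/cm^2.
#' @param rr RR interval, s.
#' @param map mean arterial pressure, mmHg; optional (needed for contractility
#'   and stroke-work metrics, not for the volume estimate).
#' @param vcfc_override optional literature value of \eqn{V_{CFC}} (1/s) used
#'   in place of the perimeter-derived one.
#' @return An object of class \code{echo_beat}.
#' @export
echo_beat <- function(lvid_ed, h_ed, lvid_es, h_es, edv, esv, ess, rr,
                      map = NA_real_, vcfc_override = NA_real_) {
  for (nm in c("lvid_ed", "h_ed", "lvid_es", "h_es", "edv", "esv", "rr")) {
    check_positive(get(nm), nm)
  }
  if (!is.finite(ess) || ess < 0) stop("'ess' must be finite and non-negative", call. = FALSE)
  if (edv <= esv) stop("'edv' must exceed 'esv'", call. = FALSE)
  pmw_ed <- pi * (lvid_ed + h_ed)
  pmw_es <- pi * (lvid_es + h_es)
  if (pmw_ed <= pmw_es) {
    stop("derived PMW_ED must exceed PMW_ES (no mid-wall shortening in this beat)",
         call. = FALSE)
  }
  structure(
    list(lvid_ed = lvid_ed, h_ed = h_ed, lvid_es = lvid_es, h_es = h_es,
         edv = edv, esv = esv, ess = ess, rr = rr, map = map,
         vcfc_override = vcfc_override,
         pmw_ed = pmw_ed, pmw_es = pmw_es),
    class = "echo_beat"
  )
}

#' @export
print.echo_beat <- function(x, ...) {
  cat("Echo beat\n")
  cat(sprintf("  ED: LVID %.3g cm, H %.3g cm, V %.4g mL (PMW %.4g cm)\n",
              x$lvid_ed, x$h_ed, x$edv, x$pmw_ed))
  cat(sprintf("  ES: LVID %.3g cm, H %.3g cm, V %.4g mL (PMW %.4g cm)\n",
              x$lvid_es, x$h_es, x$esv, x$pmw_es))
  cat(sprintf("  ESS %.4g g/cm^2, RR %.3g s, MAP %s mmHg\n",
              x$ess, x$rr, ifelse(is.na(x$map), "-", format(x$map))))
  invisible(x)
}

#' Single-beat estimate of the left-ventricular dead-space volume
#'
#' The central estimator. From one beat's end-diastolic and end-systolic
#' measurements it runs the full chain: rate-corrected shortening velocity
#' \eqn{V_{CFC}}, contractility Z-score and gain, the linear stress-stretch
#' law giving \eqn{\lambda_{ES}} and hence \eqn{PMW_{AM} =
#' PMW_{ES}/\lambda_{ES}}, the two-point cubic volume-perimeter fit through
#' the ED and ES states, and finally \eqn{AMV = a\,PMW_{AM}^3 - b}, the
#' single-beat estimate of the dead-space (absolute minimum) volume.
#'
#' Pathological outcomes are flagged, never clamped: \code{"NEGATIVE_AMV"}
#' when the extrapolated volume is below zero, \code{"AMV_ABOVE_ESV"} when it
#' exceeds the end-systolic volume (impossible for \eqn{ESS \ge 0} with a
#' positive slope, so its presence indicates inconsistent inputs).
#'
#' @param beat an \code{\link{echo_beat}}, or a one-row data.frame / named
#'   list with the \code{echo_beat} fields.
#' @param c_1 gain shape constant (see \code{\link{contractility_gain}}).
#' @param m_n normal stress-stretch slope, g/cm^2.
#' @return An object of class \code{amv_fit} holding every intermediate:
#'   \code{vcfc}, \code{z_c}, \code{g_c}, \code{lambda_es}, \code{pmw_am},
#'   the \code{pmw_cubic} fit, \code{amv} (mL) and \code{flags}. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict} and
#'   \code{plot}.
#' @export
#' @examples
#' b <- echo_beat(lvid_ed = 4.8, h_ed = 0.9, lvid_es = 3.2, h_es = 1.4,
#'                edv = 120, esv = 50, ess = 60, rr = 0.8, map = 92)
#' fit <- amv_single_beat(b)
#' fit
#' coef(fit)
amv_single_beat <- function(beat, c_1 = 0.2, m_n = 500) {
  if (!inherits(beat, "echo_beat")) {
    beat <- do.call(echo_beat, as.list(beat)[intersect(
      names(as.list(beat)),
      c("lvid_ed", "h_ed", "lvid_es", "h_es", "edv", "esv", "ess", "rr",
        "map", "vcfc_override"))])
  }
  v <- if (is.finite(beat$vcfc_override)) {
    beat$vcfc_override
  } else {
    vcfc(beat$pmw_ed, beat$pmw_es, beat$rr)
  }
  z <- contractility_z(v, beat$ess)
  g <- contractility_gain(z, c_1)
  lam <- lambda_es(beat$ess, g, m_n)
  p_am <- beat$pmw_es / lam
  fit <- fit_ab(beat$edv, beat$esv, beat$pmw_ed, beat$pmw_es)
  amv_hat <- amv(fit, p_am)
  flags <- character(0)
  if (amv_hat < 0) flags <- c(flags, "NEGATIVE_AMV")
  if (amv_hat >= beat$esv) flags <- c(flags, "AMV_ABOVE_ESV")
  structure(
    list(beat = beat, vcfc = v, z_c = z, g_c = g, lambda_es = lam,
         pmw_am = p_am, fit = fit, amv = amv_hat, flags = flags,
         c_1 = c_1, m_n = m_n),
    class = "amv_fit"
  )
}

#' @export
print.amv_fit <- function(x, ...) {
  cat("Single-beat dead-space volume estimate\n")
  cat(sprintf("  AMV = %.4g mL  (ESV %.4g mL, EDV %.4g mL)\n",
              x$amv, x$beat$esv, x$beat$edv))
  cat(sprintf("  PMW_AM = %.4g cm (lambda_ES %.4f, G_C %.4f, Z_C %+.3f)\n",
              x$pmw_am, x$lambda_es, x$g_c, x$z_c))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.amv_fit <- function(object, ...) coef(object$fit)

#' Predict cavity volume along the fitted cubic law
#'
#' @param object an \code{amv_fit}.
#' @param pmw mid-wall perimeter(s), cm; defaults to the estimated AM
#'   perimeter (returning the AMV itself).
#' @param ... unused.
#' @export
predict.amv_fit <- function(object, pmw = object$pmw_am, ...) {
  predict(object$fit, pmw)
}

#' @export
summary.amv_fit <- function(object, ...) {
  b <- object$beat
  out <- list(
    estimate = object,
    ff = if (object$amv <= b$edv && object$amv >= 0)
      (b$edv - object$amv) / b$edv else NA_real_,
    sv = b$edv - b$esv,
    ef = (b$edv - b$esv) / b$edv
  )
  out$m_w_mmHg <- if (!is.na(b$map) && is.finite(out$ff) && out$ff > 0) {
    out$ef * b$map / out$ff
  } else NA_real_
  class(out) <- "summary.amv_fit"
  out
}

#' @export
print.summary.amv_fit <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  EF = %.3f, FF = %.3f (fill volume %.4g mL)\n",
              x$ef, x$ff, x$ff * x$estimate$beat$edv))
  if (!is.na(x$m_w_mmHg)) {
    cat(sprintf("  M_W = %.4g mmHg (%.4g g/cm^2) at MAP %.4g mmHg\n",
                x$m_w_mmHg, x$m_w_mmHg * 1.35951, x$estimate$beat$map))
  }
  invisible(x)
}

#' Plot the fitted volume-perimeter law for one beat
#'
#' Base-graphics rendering of the single-beat extrapolation: cavity volume
#' against the cube of the mid-wall perimeter, the fitted line through the
#' ES and ED states (solid) and its extrapolation to the estimated absolute
#' minimum state (dashed).
#'
#' @param x an \code{amv_fit}.
#' @param ... further arguments passed to \code{plot.default}.
#' @export
plot.amv_fit <- function(x, ...) {
  b <- x$beat
  px <- c(x$pmw_am, b$pmw_es, b$pmw_ed)^3
  py <- c(x$amv, b$esv, b$edv)
  plot(px, py, pch = c(1, 16, 16),
       xlab = expression(PMW^3 ~ (cm^3)), ylab = "LVV (mL)", ...)
  segments(px[2], py[2], px[3], py[3], lty = 1)
  segments(px[1], py[1], px[2], py[2], lty = 2)
  text(px, py, c("AM", "ES", "ED"), pos = 3, cex = 0.8)
  invisible(x)
}
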