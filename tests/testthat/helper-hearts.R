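# independent inflation oracle: solve for B by bisection on wall-volume
# conservation instead of the closed-form quadratic root
inflate_bisect <- function(shape, am_state, lambda, tol = 1e-13) {
  pmw <- lambda * am_state$PMW
  P <- pmw / pi
  f <- function(b) wall_volume(shape$k * b, b, P - 2 * b, shape$L) - shape$V_M
  # physical branch has H < 2B, i.e. B in (P/4, P/2)
  lo <- P / 4
  hi <- P / 2 * (1 - 1e-12)
  while (hi - lo > tol * P) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  b <- (lo + hi) / 2
  list(B = b, H = P - 2 * b, PMW = pmw,
       LVV = cavity_volume(shape$k * b, b, shape$L))
}

# random valid AM geometries from the default sampling ranges
random_am_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    lvid_am = runif(n, 2.6, 4.6),
    h_am = runif(n, 1.0, 2.0),
    k = runif(n, 1.0, 2.0),
    L = runif(n, 0.0, 0.375)
  )
}

# a mid-range heart used across tests
mid_heart <- function() shell_from_am(lvid_am = 3.6, h_am = 1.5, k = 1.5, L = 0.2)

# synthesise a consistent echo beat from a simulated heart: states from the
# geometry module, ESS from the linear stress-stretch law, and a
# shortening-velocity override chosen so the Z-score/gain chain reproduces
# g_c exactly (the geometric shortening fraction is not on the scale of the
# normal-population velocity relation, so a literature-style value is
# supplied, as the estimator's override field intends)
beat_from_heart <- function(heart, lam_es = 1.12, lam_ed = 1.30,
                            g_c = 1, m_n = 500, rr = 0.8, map = 92,
                            c_1 = 0.2) {
  es <- inflate_to_stretch(heart$shape, heart$am, lam_es)
  ed <- inflate_to_stretch(heart$shape, heart$am, lam_ed)
  ess <- g_c * m_n * (lam_es - 1)
  z <- (g_c - 1 / g_c) / (2 * c_1)  # inverse of g = x + sqrt(x^2 + 1), x = c_1 z
  v_override <- 0.06 * z + 1.23 - 0.0044 * ess
  list(
    beat = echo_beat(
      lvid_ed = 2 * ed$B, h_ed = ed$H, lvid_es = 2 * es$B, h_es = es$H,
      edv = ed$LVV, esv = es$LVV, ess = ess, rr = rr, map = map,
      vcfc_override = v_override),
    es = es, ed = ed, g_c = g_c
  )
}
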