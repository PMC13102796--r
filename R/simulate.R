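#' Sampling plan for the synthetic heart cohort
#'
#' Defines the uniform, independent sampling ranges for the in-silico
#' verification cohort. Defaults reproduce the reference experiment: 10,000
#' hearts with fully contracted internal diameter 2.6-4.6 cm, fully
#' contracted wall thickness 1.0-2.0 cm, height-to-width ratio 1-2
#' (1 = spherical), truncation 0-0.375, end-systolic stretch 1.06-1.18 and
#' end-diastolic stretch 1.24-1.36. Physiological correlations between
#' parameters are deliberately not enforced.
#'
#' @param n number of hearts.
#' @param seed RNG seed; every run is a pure function of plan + seed.
#' @param lvid_am,h_am,k,L,lambda_es,lambda_ed length-2 closed intervals for
#'   each sampled parameter (cm, cm, dimensionless, dimensionless, and the
#'   two stretches).
#' @return An object of class \code{sampling_plan}.
#' @export
sampling_plan <- function(n = 10000L, seed = 20260302L,
                          lvid_am = c(2.6, 4.6),
                          h_am = c(1.0, 2.0),
                          k = c(1.0, 2.0),
                          L = c(0.0, 0.375),
                          lambda_es = c(1.06, 1.18),
                          lambda_ed = c(1.24, 1.36)) {
  ranges <- list(lvid_am = lvid_am, h_am = h_am, k = k, L = L,
                 lambda_es = lambda_es, lambda_ed = lambda_ed)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("range '%s' must be a finite interval c(lo, hi)", nm),
           call. = FALSE)
    }
  }
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (h_am[2] >= lvid_am[1]) {
    stop("wall-thickness range must stay below the internal-diameter range (H < LVID at AM)",
         call. = FALSE)
  }
  if (lambda_es[2] >= lambda_ed[1]) {
    stop("end-systolic stretch range must lie entirely below the end-diastolic range",
         call. = FALSE)
  }
  if (L[1] < 0 || L[2] > 1) stop("truncation range must lie in [0, 1]", call. = FALSE)
  if (k[1] < 1) stop("height-to-width ratio must be >= 1", call. = FALSE)
  if (lambda_es[1] < 1) stop("stretches must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed), ranges = ranges),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("Sampling plan: %d hearts, seed %d\n", x$n, x$seed))
  for (nm in names(x$ranges)) {
    cat(sprintf("  %-10s [%g, %g]\n", nm, x$ranges[[nm]][1], x$ranges[[nm]][2]))
  }
  invisible(x)
}

runif_range <- function(n, r) {
  if (r[1] == r[2]) rep(r[1], n) else runif(n, r[1], r[2])
}

#' Sample a cohort of synthetic hearts
#'
#' Draws \code{n} truncated prolate-ellipsoid hearts from the plan's uniform
#' ranges, builds each from its fully contracted (AM) state, and inflates it
#' (conserving wall volume, at constant shape) to its end-systolic and
#' end-diastolic stretches. The AM cavity volume is the true dead-space
#' volume \code{v_w} of each heart.
#'
#' @param plan a \code{\link{sampling_plan}}.
#' @return A data.frame with one row per heart: sampled parameters
#'   (\code{lvid_am}, \code{h_am}, \code{k}, \code{L}, \code{lambda_es},
#'   \code{lambda_ed}), the AM quantities (\code{pmw_am}, \code{v_m},
#'   \code{v_w}), and the ES/ED states (\code{b_es}, \code{h_es},
#'   \code{pmw_es}, \code{esv}, \code{b_ed}, \code{h_ed}, \code{pmw_ed},
#'   \code{edv}). The plan is attached as attribute \code{"plan"}.
#' @export
sample_hearts <- function(plan = sampling_plan()) {
  stopifnot(inherits(plan, "sampling_plan"))
  set.seed(plan$seed)
  n <- plan$n
  r <- plan$ranges
  d <- data.frame(
    id = seq_len(n),
    lvid_am = runif_range(n, r$lvid_am),
    h_am = runif_range(n, r$h_am),
    k = runif_range(n, r$k),
    L = runif_range(n, r$L),
    lambda_es = runif_range(n, r$lambda_es),
    lambda_ed = runif_range(n, r$lambda_ed)
  )
  b_am <- d$lvid_am / 2
  d$pmw_am <- pi * (2 * b_am + d$h_am)
  d$v_m <- wall_volume(d$k * b_am, b_am, d$h_am, d$L)
  d$v_w <- cavity_volume(d$k * b_am, b_am, d$L)
  es <- inflate_core(d$pmw_am, d$v_m, d$k, d$L, d$lambda_es)
  ed <- inflate_core(d$pmw_am, d$v_m, d$k, d$L, d$lambda_ed)
  d$b_es <- es$B; d$h_es <- es$H; d$pmw_es <- es$PMW; d$esv <- es$LVV
  d$b_ed <- ed$B; d$h_ed <- ed$H; d$pmw_ed <- ed$PMW; d$edv <- ed$LVV
  attr(d, "plan") <- plan
  d
}

# per-row R^2 of LVV on PMW^3 along a stretch grid, fully vectorised:
# hearts x grid matrices, closed-form correlation.
cohort_linearity_r2 <- function(hearts, n_grid = 50, lambda_max = 1.36) {
  lam <- seq(1, lambda_max, length.out = n_grid)
  n <- nrow(hearts)
  P <- outer(hearts$pmw_am / pi, lam)          # n x grid, perimeter / pi
  C <- (2 / 3) * pi * hearts$k * trunc_poly(hearts$L)
  disc <- P^2 - 8 * hearts$v_m / (C * P)
  B <- (P + sqrt(disc)) / 4
  lvv <- C * B^3
  x <- (pi * P)^3
  xc <- x - rowMeans(x)
  yc <- lvv - rowMeans(lvv)
  (rowSums(xc * yc))^2 / (rowSums(xc^2) * rowSums(yc^2))
}

#' Run the in-silico verification experiment
#'
#' For each sampled heart, fits the cubic volume-perimeter law through its ES
#' and ED states and extrapolates to the absolute minimum perimeter, then
#' compares the estimated dead-space volume \code{amv_hat} with the true
#' \code{v_w}.
#'
#' Two modes select where the AM perimeter comes from:
#' \describe{
#'   \item{\code{"true_pmw_am"}}{(default) the heart's known AM perimeter is
#'     used directly, isolating the cubic-law extrapolation (this mirrors the
#'     construction of the reference verification).}
#'   \item{\code{"ess_pathway"}}{an end-systolic wall stress is synthesised
#'     from the linear stress-stretch law,
#'     \eqn{ESS = G_C M_N (\lambda_{ES} - 1)}, and the estimator inverts it
#'     back to the AM perimeter, exercising the stress pathway end to end.
#'     With the same \code{g_c} on both sides the inversion is exact.}
#' }
#'
#' @param plan a \code{\link{sampling_plan}}.
#' @param mode \code{"true_pmw_am"} or \code{"ess_pathway"}.
#' @param g_c contractility gain used to synthesise and invert the stress in
#'   \code{"ess_pathway"} mode.
#' @param m_n normal stress-stretch slope, g/cm^2.
#' @param linearity logical; also compute each heart's R^2 of cavity volume
#'   on perimeter cubed over a 50-point inflation trajectory.
#' @return The \code{\link{sample_hearts}} data.frame with added columns
#'   \code{a}, \code{b_coef}, \code{pmw_am_used}, \code{amv_hat},
#'   \code{rel_err} (= (amv_hat - v_w)/v_w) and (optionally)
#'   \code{linearity_r2}; classed \code{amv_cohort}.
#' @export
run_experiment <- function(plan = sampling_plan(),
                           mode = c("true_pmw_am", "ess_pathway"),
                           g_c = 1, m_n = 500, linearity = TRUE) {
  mode <- match.arg(mode)
  d <- sample_hearts(plan)
  d3 <- d$pmw_ed^3 - d$pmw_es^3
  d$a <- (d$edv - d$esv) / d3
  d$b_coef <- -(d$esv * d$pmw_ed^3 - d$edv * d$pmw_es^3) / d3
  d$pmw_am_used <- if (mode == "true_pmw_am") {
    d$pmw_am
  } else {
    ess <- g_c * m_n * (d$lambda_es - 1)
    d$pmw_es / lambda_es(ess, g_c, m_n)
  }
  d$amv_hat <- d$a * d$pmw_am_used^3 - d$b_coef
  d$rel_err <- (d$amv_hat - d$v_w) / d$v_w
  if (linearity) {
    d$linearity_r2 <- cohort_linearity_r2(d, lambda_max = max(1.36, plan$ranges$lambda_ed[2]))
  }
  attr(d, "mode") <- mode
  class(d) <- c("amv_cohort", "data.frame")
  d
}

#' Agreement between estimated and true dead-space volumes
#'
#' Summarises a cohort: mean bias and RMSE of \code{amv_hat} against
#' \code{v_w}, the largest relative error, and the ordinary least-squares
#' regression of true on estimated volume (slope 1, intercept 0, R^2 1 under
#' perfect agreement). With a single heart the regression is degenerate and
#' returned as \code{NA} with a flag.
#'
#' @param results an \code{amv_cohort} from \code{\link{run_experiment}} (or
#'   any data.frame with \code{v_w} and \code{amv_hat}).
#' @return An object of class \code{agreement_stats}: \code{n}, \code{bias},
#'   \code{rmse}, \code{max_abs_rel_err}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{degenerate}.
#' @export
agreement_stats <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("empty results: nothing to summarise", call. = FALSE)
  }
  err <- results$amv_hat - results$v_w
  out <- list(
    n = nrow(results),
    bias = mean(err),
    rmse = sqrt(mean(err^2)),
    max_abs_rel_err = max(abs(err / results$v_w)),
    slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
    degenerate = nrow(results) < 2
  )
  if (!out$degenerate) {
    x <- results$amv_hat
    y <- results$v_w
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    out$slope <- sxy / sxx
    out$intercept <- mean(y) - out$slope * mean(x)
    r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
    out$r_squared <- r^2
  }
  structure(out, class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Dead-space volume agreement over %d hearts\n", x$n))
  cat(sprintf("  bias %+.4f mL, RMSE %.4f mL, max |rel err| %.4f\n",
              x$bias, x$rmse, x$max_abs_rel_err))
  if (x$degenerate) {
    cat("  regression degenerate (single heart)\n")
  } else {
    cat(sprintf("  v_w ~ amv_hat: slope %.5f, intercept %+.4f mL, R^2 %.6f\n",
                x$slope, x$intercept, x$r_squared))
  }
  invisible(x)
}

#' Export plot-ready tables from a cohort run
#'
#' Writes two CSV files to \code{out_dir}: \code{fig_trajectories.csv},
#' 50-point inflation trajectories (perimeter cubed vs cavity volume, with
#' AM/ES/ED state labels at their stretches) for a deterministic,
#' seed-selected subset of hearts; and \code{fig_scatter.csv}, the true vs
#' estimated dead-space volume for every heart.
#'
#' @param results an \code{amv_cohort}.
#' @param out_dir output directory (created if needed).
#' @param n_trajectories number of representative hearts to trace.
#' @return Invisibly, the paths of the written files.
#' @export
export_figures_data <- function(results, out_dir, n_trajectories = 10) {
  stopifnot(inherits(results, "amv_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  plan <- attr(results, "plan")
  set.seed(plan$seed + 1L)
  ids <- sort(sample(results$id, min(n_trajectories, nrow(results))))
  traj <- do.call(rbind, lapply(ids, function(i) {
    h <- results[results$id == i, ]
    grid <- sort(unique(c(seq(1, h$lambda_ed, length.out = 50),
                          h$lambda_es, h$lambda_ed)))
    heart <- shell_from_am(h$lvid_am, h$h_am, h$k, h$L)
    tr <- shell_trajectory(heart$shape, heart$am, grid, heart_id = i)
    tr$pmw3_cm3 <- tr$PMW_cm^3
    tr$state <- ""
    tr$state[tr$lambda == 1] <- "AM"
    tr$state[abs(tr$lambda - h$lambda_es) < 1e-12] <- "ES"
    tr$state[abs(tr$lambda - h$lambda_ed) < 1e-12] <- "ED"
    tr
  }))
  f_traj <- file.path(out_dir, "fig_trajectories.csv")
  f_scat <- file.path(out_dir, "fig_scatter.csv")
  write.csv(traj, f_traj, row.names = FALSE)
  write.csv(results[, c("id", "v_w", "amv_hat")], f_scat, row.names = FALSE)
  invisible(c(trajectories = f_traj, scatter = f_scat))
}
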