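beat_columns <- c("id", "lvid_ed_cm", "h_ed_cm", "lvid_es_cm", "h_es_cm",
                  "edv_ml", "esv_ml", "ess_g_cm2", "rr_s")

#' Read per-beat echocardiography measurements from CSV
#'
#' Expects one row per beat with columns \code{id, lvid_ed_cm, h_ed_cm,
#' lvid_es_cm, h_es_cm, edv_ml, esv_ml, ess_g_cm2, rr_s} and optionally
#' \code{map_mmhg} and \code{vcfc_s1}. Rows violating the beat invariants
#' (non-positive measurements, EDV below ESV, reversed perimeters) are
#' collected with their row number and reason; valid rows are kept.
#'
#' @param path CSV file path.
#' @return A list with \code{beats} (a list of \code{\link{echo_beat}}
#'   objects named by id), \code{table} (the valid rows as a data.frame) and
#'   \code{rejected} (data.frame of \code{row}, \code{id}, \code{reason}).
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(beat_columns, names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"map_mmhg" %in% names(d)) d$map_mmhg <- NA_real_
  if (!"vcfc_s1" %in% names(d)) d$vcfc_s1 <- NA_real_
  beats <- list()
  rejected <- data.frame(row = integer(0), id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    b <- tryCatch(
      echo_beat(
        lvid_ed = as.numeric(d$lvid_ed_cm[i]), h_ed = as.numeric(d$h_ed_cm[i]),
        lvid_es = as.numeric(d$lvid_es_cm[i]), h_es = as.numeric(d$h_es_cm[i]),
        edv = as.numeric(d$edv_ml[i]), esv = as.numeric(d$esv_ml[i]),
        ess = as.numeric(d$ess_g_cm2[i]), rr = as.numeric(d$rr_s[i]),
        map = as.numeric(d$map_mmhg[i]),
        vcfc_override = as.numeric(d$vcfc_s1[i])
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(b)) {
      rejected <- rbind(rejected, data.frame(
        row = i, id = as.character(d$id[i]), reason = b,
        stringsAsFactors = FALSE))
    } else {
      keep[i] <- TRUE
      beats[[as.character(d$id[i])]] <- b
    }
  }
  list(beats = beats, table = d[keep, , drop = FALSE], rejected = rejected)
}

#' Estimate dead-space volume and preload metrics for a table of beats
#'
#' Runs \code{\link{amv_single_beat}} and \code{\link{preload_report}} over a
#' set of beats, returning one tidy row per beat.
#'
#' @param beats a list of \code{\link{echo_beat}} objects (as produced by
#'   \code{\link{read_beats}}), or a data.frame in the beat CSV schema.
#' @param c_1,m_n estimator constants, see \code{\link{amv_single_beat}}.
#' @return A data.frame with columns \code{id}, \code{z_c}, \code{g_c},
#'   \code{lambda_es}, \code{pmw_am_cm}, \code{a}, \code{b}, \code{amv_ml},
#'   \code{ff}, \code{fv_ml}, \code{m_w_mmhg}, \code{m_w_g_cm2},
#'   \code{flags} (semicolon-separated).
#' @export
estimate_beats <- function(beats, c_1 = 0.2, m_n = 500) {
  if (is.data.frame(beats)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    utils::write.csv(beats, tmp, row.names = FALSE)
    beats <- read_beats(tmp)$beats
  }
  if (length(beats) == 0) {
    return(data.frame(
      id = character(0), z_c = numeric(0), g_c = numeric(0),
      lambda_es = numeric(0), pmw_am_cm = numeric(0), a = numeric(0),
      b = numeric(0), amv_ml = numeric(0), ff = numeric(0), fv_ml = numeric(0),
      m_w_mmhg = numeric(0), m_w_g_cm2 = numeric(0), flags = character(0),
      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(beats), function(id) {
    fit <- amv_single_beat(beats[[id]], c_1 = c_1, m_n = m_n)
    rep_ <- preload_report(fit)
    data.frame(
      id = id, z_c = fit$z_c, g_c = fit$g_c, lambda_es = fit$lambda_es,
      pmw_am_cm = fit$pmw_am, a = fit$fit$a, b = fit$fit$b,
      amv_ml = fit$amv, ff = rep_$ff, fv_ml = rep_$fv,
      m_w_mmhg = rep_$m_w_mmHg, m_w_g_cm2 = rep_$m_w_gcm2,
      flags = paste(fit$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

format_sig <- function(x, digits = 6) {
  if (is.numeric(x)) signif(x, digits) else x
}

#' Write a per-beat estimate table or cohort to CSV
#'
#' Numeric columns are rounded to 6 significant digits for stable,
#' human-readable files; use \code{digits = NA} for full precision.
#'
#' @param x a data.frame (estimates or cohort).
#' @param path output CSV path.
#' @param digits significant digits, or \code{NA} for full precision.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(x, path, digits = 6) {
  stopifnot(is.data.frame(x))
  if (!is.na(digits)) {
    x[] <- lapply(x, format_sig, digits = digits)
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write an agreement summary as JSON
#'
#' Full-precision JSON record of an \code{\link{agreement_stats}} summary,
#' including the plan (n, seed, ranges and mode) so runs are self-describing.
#'
#' @param stats an \code{agreement_stats} object.
#' @param results the cohort the stats came from (for plan metadata);
#'   optional.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_summary <- function(stats, path, results = NULL) {
  stopifnot(inherits(stats, "agreement_stats"))
  out <- unclass(stats)
  if (!is.null(results)) {
    plan <- attr(results, "plan")
    out$plan <- list(n = plan$n, seed = plan$seed, ranges = plan$ranges)
    out$mode <- attr(results, "mode")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
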