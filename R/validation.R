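# Model-qualification statistics: per-point fold error (FE = predicted
# over observed), average fold error (AFE, geometric mean of FE) and
# absolute average fold error (AAFE, geometric mean of |log FE|), with
# the 3-fold / AFE < 2 / AAFE < 2 acceptance rule.

#' Observed concentration-time profiles
#'
#' @param times_h Sampling times, hours, strictly increasing.
#' @param conc_ug_ml Observed concentrations, ug/mL.  Non-positive
#'   observations (below-quantification points) are dropped with a
#'   warning, because their fold error is undefined.
#' @param label Free-text label (species/dose/route).
#' @return An object of class `observed_profile`.
#' @export
observed_profile <- function(times_h, conc_ug_ml, label = "") {
  if (length(times_h) != length(conc_ug_ml)) {
    stop("times and concentrations differ in length", call. = FALSE)
  }
  if (length(times_h) == 0L) stop("empty profile", call. = FALSE)
  if (is.unsorted(times_h, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  drop <- conc_ug_ml <= 0 | !is.finite(conc_ug_ml)
  if (any(drop)) {
    warning(sum(drop), " non-positive observation(s) excluded (fold error ",
            "undefined)", call. = FALSE)
    times_h <- times_h[!drop]
    conc_ug_ml <- conc_ug_ml[!drop]
    if (length(times_h) == 0L) stop("no positive observations", call. = FALSE)
  }
  structure(list(times_h = times_h, conc_ug_ml = conc_ug_ml,
                 n = length(times_h), label = label),
            class = "observed_profile")
}

#' @export
print.observed_profile <- function(x, ...) {
  cat(sprintf("<observed_profile> %s: %d points over %g-%g h\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$n, min(x$times_h), max(x$times_h)))
  invisible(x)
}

#' Read/write observed profiles as CSV
#'
#' The CSV dialect has a header and columns `time_h, conc_ug_per_ml`
#' (dot decimal separator, UTF-8).
#'
#' @param path CSV path.
#' @param label Label for the loaded profile.
#' @return `read_observed_csv()`: an `observed_profile`.
#' @export
read_observed_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  need <- c("time_h", "conc_ug_per_ml")
  if (!all(need %in% names(d))) {
    stop("observed CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  observed_profile(d$time_h, d$conc_ug_per_ml, label = label)
}

#' @rdname read_observed_csv
#' @param obs An `observed_profile`.
#' @export
write_observed_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observed_profile"))
  utils::write.csv(data.frame(time_h = obs$times_h,
                              conc_ug_per_ml = obs$conc_ug_ml),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# log-linear interpolation of a predicted curve onto observed times
interp_predicted <- function(predicted, times_h) {
  if (inherits(predicted, "pbpk_sim")) {
    pt <- predicted$time
    pc <- predicted$plasma
  } else {
    pt <- predicted$time
    pc <- predicted$conc
  }
  if (any(times_h < min(pt)) || any(times_h > max(pt))) {
    stop("observed times fall outside the predicted grid", call. = FALSE)
  }
  pos <- pc > 0
  if (sum(pos) < 2L) stop("predicted curve has < 2 positive points",
                          call. = FALSE)
  exp(stats::approx(pt[pos], log(pc[pos]), xout = times_h, rule = 1)$y)
}

#' Per-point fold errors
#'
#' `FE_i = Predicted_i / Observed_i`.  Predicted input may be a
#' `pbpk_sim` (or `data.frame(time, conc)`), which is interpolated
#' log-linearly onto the observed times, or a numeric vector already
#' matched to the observations.
#'
#' @param predicted Predicted concentrations (see Details).
#' @param observed An `observed_profile`.
#' @return Numeric vector of fold errors.
#' @export
fold_errors <- function(predicted, observed) {
  stopifnot(inherits(observed, "observed_profile"))
  if (is.numeric(predicted)) {
    if (length(predicted) != observed$n) {
      stop("predicted and observed lengths differ", call. = FALSE)
    }
    pred <- predicted
  } else {
    pred <- interp_predicted(predicted, observed$times_h)
  }
  pred / observed$conc_ug_ml
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10 |FE|))`: the geometric mean fold error, below
#' 1 for net underprediction and above 1 for net overprediction.
#'
#' @param fe Fold-error vector.
#' @return AFE (dimensionless).
#' @export
afe <- function(fe) {
  if (length(fe) == 0L) stop("empty fold-error list", call. = FALSE)
  10^mean(log10(abs(fe)))
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10 FE|))`: the geometric mean absolute
#' deviation from the observations; always >= 1.
#'
#' @inheritParams afe
#' @return AAFE (dimensionless).
#' @export
aafe <- function(fe) {
  if (length(fe) == 0L) stop("empty fold-error list", call. = FALSE)
  10^mean(abs(log10(fe)))
}

#' Fold-error acceptance check
#'
#' A simulation qualifies when every fold error lies within 3-fold
#' (0.3 to 3) and both AFE and AAFE are below 2.  The fraction of
#' points within 2-fold is reported alongside.
#'
#' @param predicted Predicted curve or matched numeric vector (see
#'   [fold_errors()]); ignored when `fe` is given.
#' @param observed An `observed_profile`; ignored when `fe` is given.
#' @param fe Optionally, a precomputed fold-error vector.
#' @return An object of class `validation_report`: `fe`, `afe`,
#'   `aafe`, `within_3fold`, `within_2fold_fraction`, `outliers`
#'   (indices outside 3-fold), `pass`.
#' @examples
#' acceptance_check(fe = c(0.5, 1, 2))$pass
#' @export
acceptance_check <- function(predicted = NULL, observed = NULL, fe = NULL) {
  if (is.null(fe)) fe <- fold_errors(predicted, observed)
  if (length(fe) == 0L) stop("empty fold-error list", call. = FALSE)
  in3 <- fe >= 0.3 & fe <= 3
  rep <- structure(list(
    fe = fe,
    afe = afe(fe),
    aafe = aafe(fe),
    within_3fold = all(in3),
    within_2fold_fraction = mean(fe >= 0.5 & fe <= 2),
    outliers = which(!in3)
  ), class = "validation_report")
  rep$pass <- rep$within_3fold && rep$afe < 2 && rep$aafe < 2
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d, AFE %.3f, AAFE %.3f -> %s\n",
              length(x$fe), x$afe, x$aafe,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  %.0f%% of points within 2-fold", 100 * x$within_2fold_fraction))
  if (length(x$outliers)) {
    cat(sprintf("; 3-fold outliers at index %s (FE %s)",
                paste(x$outliers, collapse = ", "),
                paste(signif(x$fe[x$outliers], 3), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Export a fold-error table
#'
#' @param report A `validation_report`.
#' @param observed The `observed_profile` the report was computed from.
#' @param path Output CSV path.
#' @return Invisibly, the exported data frame.
#' @export
write_validation_csv <- function(report, observed, path) {
  stopifnot(inherits(report, "validation_report"),
            inherits(observed, "observed_profile"))
  out <- data.frame(time_h = observed$times_h,
                    observed = observed$conc_ug_ml,
                    fe = report$fe,
                    outlier = seq_along(report$fe) %in% report$outliers)
  summary_line <- sprintf("# afe=%.6g aafe=%.6g pass=%s",
                          report$afe, report$aafe, report$pass)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(summary_line, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(out)
}
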