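# Calibration, parameter sensitivity analysis, allometric scaling and
# the dissolution-rate comparison experiment.

#' Fit the renal clearance to an observed profile
#'
#' One-dimensional bounded least-squares fit of the renal clearance,
#' minimising the sum of squared log-concentration residuals between
#' the simulated and observed plasma profiles (concentrations span
#' orders of magnitude, so the objective is taken on the log scale).
#'
#' @param observed An `observed_profile` with at least 4 points
#'   spanning the elimination phase.
#' @param model A `disposition_model`; its clearance is replaced during
#'   the search.
#' @param dose A `dose_event` matching the observed study.
#' @param gut A `gut_model` for oral dosing.
#' @param bounds Clearance search interval, L/h.  The upper bound is
#'   additionally capped just below the kidney perfusion (renal
#'   extraction cannot exceed 1 in this elimination wiring).
#' @return A list of class `clearance_fit`: `cl_l_h`, `objective`,
#'   `boundary_flag` (optimum within 0.1% of a bound), `bounds`.
#' @export
fit_clearance <- function(observed, model, dose, gut = NULL,
                          bounds = c(1e-4, 100)) {
  stopifnot(inherits(observed, "observed_profile"),
            inherits(model, "disposition_model"))
  if (observed$n < 4L) {
    stop("at least 4 observed points are required", call. = FALSE)
  }
  if (bounds[1] <= 0 || diff(bounds) <= 0) {
    stop("bounds must be positive and increasing", call. = FALSE)
  }
  # the kidney cannot extract more than its perfusion delivers, so the
  # search space is capped just below the kidney blood flow
  bounds[2] <- min(bounds[2], 0.99 * model$q_tissue[["kidney"]])
  if (bounds[2] <= bounds[1]) {
    stop("clearance bounds collapse after capping at the kidney perfusion",
         call. = FALSE)
  }
  times <- sort(unique(c(0, observed$times_h)))
  obj <- function(cl) {
    m <- model
    m$cl_renal <- cl
    sim <- simulate_pk(m, dose, gut = gut, times = times)
    pred <- interp_predicted(sim, observed$times_h)
    sum((log(pred) - log(observed$conc_ug_ml))^2)
  }
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-7)
  cl <- opt$minimum
  flag <- (cl - bounds[1]) < 1e-3 * bounds[1] ||
    (bounds[2] - cl) < 1e-3 * bounds[2]
  if (flag) {
    warning("fitted clearance sits at a search bound; widen `bounds`",
            call. = FALSE)
  }
  structure(list(cl_l_h = cl, objective = opt$objective,
                 boundary_flag = flag, bounds = bounds),
            class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("<clearance_fit> CL = %.5g L/h (SSE(log) %.4g)%s\n",
              x$cl_l_h, x$objective,
              if (x$boundary_flag) " [AT BOUND]" else ""))
  invisible(x)
}

psa_parameters <- function() {
  c(paste0("kp_", PBPK_TISSUES), "cl_renal", "vmax_scale", "peff",
    "solubility")
}

apply_psa_factor <- function(model, gut, parameter, factor) {
  if (startsWith(parameter, "kp_")) {
    tissue <- sub("^kp_", "", parameter)
    model$kp[[tissue]] <- model$kp[[tissue]] * factor
    model$phys$tissues$kp[model$phys$tissues$name == tissue] <-
      model$kp[[tissue]]
  } else if (parameter == "cl_renal") {
    model$cl_renal <- model$cl_renal * factor
  } else if (parameter == "vmax_scale") {
    if (!is.null(gut)) gut$kinetics$scale <- gut$kinetics$scale * factor
  } else if (parameter == "peff") {
    model$drug$passive_peff_cm_s <- model$drug$passive_peff_cm_s * factor
  } else if (parameter == "solubility") {
    model$drug$solubility_mg_ml <- model$drug$solubility_mg_ml * factor
  } else {
    stop("unknown PSA parameter: ", parameter, " (supported: ",
         paste(psa_parameters(), collapse = ", "), ")", call. = FALSE)
  }
  list(model = model, gut = gut)
}

#' Parameter sensitivity sweep
#'
#' Re-simulates the model with one parameter multiplied by each factor
#' and records the plasma Cmax and AUC0-inf.
#'
#' @param model A `disposition_model`.
#' @param dose A `dose_event`.
#' @param parameter One of `kp_<tissue>`, `cl_renal`, `vmax_scale`,
#'   `peff`, `solubility`.
#' @param gut A `gut_model` for oral dosing.
#' @param factors Multiplicative factors; default 9 log-spaced values
#'   spanning 0.1 to 10.
#' @param t_end_h Simulation horizon.
#' @return A data frame of class `psa_result` with columns
#'   `parameter`, `factor`, `cmax`, `auc_0_inf`.
#' @export
psa_sweep <- function(model, dose, parameter, gut = NULL,
                      factors = 10^seq(-1, 1, length.out = 9),
                      t_end_h = NULL) {
  stopifnot(inherits(model, "disposition_model"))
  if (!parameter %in% psa_parameters()) {
    stop("unknown PSA parameter: ", parameter, call. = FALSE)
  }
  rows <- lapply(factors, function(f) {
    mg <- apply_psa_factor(model, gut, parameter, f)
    sim <- simulate_pk(mg$model, dose, gut = mg$gut, t_end_h = t_end_h)
    m <- pk_metrics(sim)
    data.frame(parameter = parameter, factor = f, cmax = m$cmax,
               auc_0_inf = m$auc_0_inf)
  })
  structure(do.call(rbind, rows), class = c("psa_result", "data.frame"))
}

#' Allometric power-law fit
#'
#' Ordinary least squares of `log(y)` on `log(BW)` for the power law
#' `Y = a * BW^b`; `a` is the back-transformed intercept (the value of
#' Y at 1 kg), `b` the exponent.
#'
#' @param y_values Per-species parameter values (e.g. Vss in L or CL in
#'   L/h), all positive.
#' @param body_weights_kg Matching body weights, kg; at least 3 species.
#' @return An object of class `allometric_fit`: `a`, `b`, `r_squared`,
#'   `fitted`.
#' @examples
#' allometric_fit(c(0.012, 0.159, 24.747), c(0.025, 0.31, 75.1))
#' @export
allometric_fit <- function(y_values, body_weights_kg) {
  if (length(y_values) < 3L || length(y_values) != length(body_weights_kg)) {
    stop("need matching values for at least 3 species", call. = FALSE)
  }
  if (any(y_values <= 0) || any(body_weights_kg <= 0)) {
    stop("allometric fits require positive values", call. = FALSE)
  }
  fit <- stats::lm(log(y_values) ~ log(body_weights_kg))
  # R^2 computed directly: summary.lm warns on exact power laws
  resid_ss <- sum(stats::residuals(fit)^2)
  total_ss <- sum((log(y_values) - mean(log(y_values)))^2)
  structure(list(
    a = unname(exp(stats::coef(fit)[1])),
    b = unname(stats::coef(fit)[2]),
    r_squared = if (total_ss == 0) 1 else 1 - resid_ss / total_ss,
    fitted = unname(exp(stats::fitted(fit))),
    body_weights_kg = body_weights_kg,
    y_values = y_values
  ), class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> Y = %.4f * BW^%.4f (R^2 = %.4f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Dissolution-rate comparison experiment
#'
#' Simulates the oral dose under first-order dissolution for each T85%
#' in the grid and reports the relative deviation (%) of Cmax and
#' AUC0-inf from the fastest-release reference.
#'
#' @param model A human `disposition_model`.
#' @param gut A `gut_model`; its dissolution spec is replaced per run.
#' @param dose_mg Oral dose, mg.
#' @param t85_grid_h T85% grid in hours; must contain `reference_h`.
#' @param reference_h The reference release rate (default 0.5 h,
#'   "very rapid dissolution").
#' @param t_end_h Simulation horizon.
#' @return A data frame of class `release_rate_comparison` with columns
#'   `t85_h`, `cmax`, `auc_0_inf`, `cmax_err_pct`, `auc_err_pct`.
#' @export
compare_release_rates <- function(model, gut = gut_model(),
                                  dose_mg = 1126.5,
                                  t85_grid_h = c(0.5, 1, 1.5, 2, 4, 6),
                                  reference_h = 0.5, t_end_h = 48) {
  stopifnot(inherits(model, "disposition_model"))
  if (!any(abs(t85_grid_h - reference_h) < 1e-12)) {
    stop("the T85% grid must contain the reference ", reference_h, " h",
         call. = FALSE)
  }
  run <- function(t85) {
    g <- gut
    g$dissolution <- dissolution_spec("first_order", t85_h = t85)
    m <- pk_metrics(simulate_pk(model, dose_event("oral", dose_mg),
                                gut = g, t_end_h = t_end_h))
    c(cmax = m$cmax, auc = m$auc_0_inf)
  }
  res <- t(vapply(t85_grid_h, run, numeric(2)))
  ref <- res[which.min(abs(t85_grid_h - reference_h)), ]
  out <- data.frame(
    t85_h = t85_grid_h,
    cmax = res[, "cmax"],
    auc_0_inf = res[, "auc"],
    cmax_err_pct = 100 * abs(res[, "cmax"] - ref[["cmax"]]) / ref[["cmax"]],
    auc_err_pct = 100 * abs(res[, "auc"] - ref[["auc"]]) / ref[["auc"]]
  )
  structure(out, class = c("release_rate_comparison", "data.frame"))
}
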