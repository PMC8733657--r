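# Noncompartmental analysis of simulated (or observed) profiles:
# Cmax/Tmax from the grid maximum, trapezoidal AUC/AUMC, terminal
# log-linear slope for extrapolation to infinity, and the
# dose-normalised clearance and steady-state volume for IV dosing.

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Noncompartmental PK metrics
#'
#' @param result A `pbpk_sim`, or a data frame with columns `time` and
#'   `conc` (in that case `dose_mg` and `route` must be supplied).
#' @param compartment Compartment to analyse: `"plasma"` (venous) or a
#'   tissue name.
#' @param dose_mg,route Dose information for plain data-frame input.
#' @param terminal_n Number of terminal points for the log-linear
#'   regression of the elimination slope (default 4).
#' @return An object of class `pk_metrics`: `cmax` (ug/mL), `tmax`
#'   (h), `auc_0_t`, `auc_0_inf` (ug*h/mL), `lambda_z` (1/h),
#'   `extrap_frac`, `aumc_0_inf`, `mrt_h`, and (IV only) `cl_l_h` and
#'   `vss_l`.  If the terminal slope is non-positive, extrapolated
#'   quantities are `NA` and `lambda_z_flag` is set.
#' @examples
#' prof <- data.frame(time = seq(0, 24, 0.01),
#'                    conc = 10 * exp(-0.5 * seq(0, 24, 0.01)))
#' m <- pk_metrics(prof, dose_mg = 100, route = "iv_bolus")
#' c(m$auc_0_inf, m$cl_l_h, m$vss_l)  # 20, 5, 10
#' @export
pk_metrics <- function(result, compartment = "plasma", dose_mg = NULL,
                       route = NULL, terminal_n = 4) {
  if (inherits(result, "pbpk_sim")) {
    time <- result$time
    conc <- if (compartment == "plasma") result$plasma
            else result$conc[[compartment]]
    if (is.null(conc)) {
      stop("unknown compartment: ", compartment, call. = FALSE)
    }
    dose_mg <- result$dose$amount_mg
    route <- result$dose$route
  } else {
    time <- result$time
    conc <- result$conc
    if (is.null(dose_mg) || is.null(route)) {
      stop("dose_mg and route are required for data-frame input",
           call. = FALSE)
    }
  }
  if (length(time) < 2L) stop("non-empty trajectory required", call. = FALSE)

  i_max <- which.max(conc)
  cmax <- conc[i_max]
  tmax <- time[i_max]
  auc_t <- trapz(time, conc)
  aumc_t <- trapz(time, time * conc)

  # terminal slope from the last `terminal_n` concentrations above a
  # dynamic-range floor (points within solver/assay noise of zero
  # carry no slope information)
  pos <- which(conc > max(conc) * 1e-6)
  lam <- NA_real_
  flag <- FALSE
  if (length(pos) >= terminal_n) {
    idx <- utils::tail(pos, terminal_n)
    fit <- stats::lm(log(conc[idx]) ~ time[idx])
    lam <- -unname(stats::coef(fit)[2])
  }
  if (!is.finite(lam) || lam <= 0) {
    flag <- TRUE
    auc_inf <- NA_real_
    aumc_inf <- NA_real_
  } else {
    c_last <- conc[utils::tail(pos, 1)]
    t_last <- time[utils::tail(pos, 1)]
    auc_inf <- auc_t + c_last / lam
    aumc_inf <- aumc_t + c_last * t_last / lam + c_last / lam^2
  }
  mrt <- if (flag) NA_real_ else aumc_inf / auc_inf
  iv <- identical(route, "iv_bolus")
  cl <- if (iv && !flag) dose_mg / auc_inf else NA_real_
  vss <- if (iv && !flag) cl * mrt else NA_real_
  structure(list(
    compartment = compartment, dose_mg = dose_mg, route = route,
    cmax = cmax, tmax = tmax,
    auc_0_t = auc_t, auc_0_inf = auc_inf,
    lambda_z = lam, lambda_z_flag = flag,
    extrap_frac = if (flag) NA_real_ else 1 - auc_t / auc_inf,
    aumc_0_inf = aumc_inf, mrt_h = mrt,
    cl_l_h = cl, vss_l = vss
  ), class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> %s (%s, %.4g mg)\n", x$compartment, x$route,
              x$dose_mg))
  cat(sprintf("  Cmax %.4g ug/mL at %.3g h; AUC0-t %.4g, AUC0-inf %.4g ug*h/mL\n",
              x$cmax, x$tmax, x$auc_0_t, x$auc_0_inf))
  if (x$lambda_z_flag) {
    cat("  terminal slope not identifiable; extrapolation refused\n")
  } else if (!is.na(x$cl_l_h)) {
    cat(sprintf("  lambda_z %.4g 1/h, MRT %.3g h, CL %.4g L/h, Vss %.4g L\n",
                x$lambda_z, x$mrt_h, x$cl_l_h, x$vss_l))
  }
  invisible(x)
}

#' @rdname pk_metrics
#' @param ... `pk_metrics` objects.
#' @return `pk_metrics_table()`: a data frame with one row per object.
#' @export
pk_metrics_table <- function(...) {
  ms <- list(...)
  do.call(rbind, lapply(ms, function(m)
    data.frame(compartment = m$compartment, route = m$route,
               dose_mg = m$dose_mg, cmax = m$cmax, tmax = m$tmax,
               auc_0_t = m$auc_0_t, auc_0_inf = m$auc_0_inf,
               cl_l_h = m$cl_l_h, vss_l = m$vss_l, mrt_h = m$mrt_h)))
}
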