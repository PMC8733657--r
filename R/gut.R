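# Compartmental absorption-transit gut model: stomach, duodenum,
# jejunum 1-2, ileum 1-3, caecum, ascending colon.  Serial first-order
# transit; first-order (or instant) dissolution with a solubility gate;
# passive permeation scaled by 2*Peff/r; saturable PEPT1 uptake
# distributed by segmental transporter expression.

GUT_SEGMENTS <- c("stomach", "duodenum", "jejunum1", "jejunum2",
                  "ileum1", "ileum2", "ileum3", "caecum", "colon")

#' Load the human gut segments
#'
#' Reads the bundled fasted-state segment geometry, transit times,
#' segmental PEPT1 expression and passive-permeation scale factors.
#' Luminal fluid volumes are `fluid_fraction * pi * r^2 * L`.
#'
#' @param path Optional path to a gut configuration file; defaults to
#'   the bundled human file.
#' @param overrides Optional named list of configuration keys to replace.
#' @return An object of class `gut_segments`: a data frame with columns
#'   `name`, `transit_h`, `radius_cm`, `length_cm`, `fluid_ml`,
#'   `pept1_mg`, `passive_scale`, carrying the transporter constants
#'   `km_mg_l`, `vmax_ug_s_mg` and calibrated `pept1_scale` as
#'   attributes.
#' @export
load_gut_segments <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) path <- cefapbpk_extdata("gut_human.conf")
  config <- read_config(path)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(config))
    if (length(unknown)) {
      stop("override names no configuration key: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    config[names(overrides)] <- vapply(overrides, format_value, character(1))
  }
  frac <- config_num(config, "fluid_fraction", positive = TRUE)
  seg <- do.call(rbind, lapply(GUT_SEGMENTS, function(s) {
    key <- function(f) paste0("segment.", s, ".", f)
    r <- config_num(config, key("radius_cm"), positive = TRUE)
    len <- config_num(config, key("length_cm"), positive = TRUE)
    data.frame(
      name = s,
      transit_h = config_num(config, key("transit_h"), positive = TRUE),
      radius_cm = r,
      length_cm = len,
      fluid_ml = frac * pi * r^2 * len,
      pept1_mg = config_num(config, key("pept1_mg")),
      passive_scale = config_num(config, key("passive_scale"))
    )
  }))
  if (any(seg$pept1_mg < 0) || any(seg$passive_scale < 0)) {
    stop("PEPT1 expression and passive scales must be >= 0", call. = FALSE)
  }
  structure(seg,
            km_mg_l = config_num(config, "km_mg_l", positive = TRUE),
            vmax_ug_s_mg = config_num(config, "vmax_ug_s_mg"),
            pept1_scale = config_num(config, "pept1_scale"),
            class = c("gut_segments", "data.frame"))
}

#' Transporter kinetics
#'
#' Michaelis-Menten constants of the intestinal PEPT1 carrier and the
#' global capacity multiplier calibrated against the fraction absorbed.
#'
#' @param km_mg_l Half-saturation luminal concentration, mg/L.
#' @param vmax_ug_s_mg Maximal transport rate per mg of segmental
#'   PEPT1 protein, ug/s/mg.
#' @param scale Dimensionless global capacity multiplier.
#' @return An object of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(km_mg_l = 860.31, vmax_ug_s_mg = 0.0025,
                                 scale = 1) {
  if (km_mg_l <= 0) stop("Km must be > 0", call. = FALSE)
  if (vmax_ug_s_mg < 0 || scale < 0) {
    stop("Vmax and scale must be >= 0", call. = FALSE)
  }
  structure(list(km_mg_l = km_mg_l, vmax_ug_s_mg = vmax_ug_s_mg,
                 scale = scale), class = "transporter_kinetics")
}

default_transporter_kinetics <- function(segments) {
  transporter_kinetics(km_mg_l = attr(segments, "km_mg_l"),
                       vmax_ug_s_mg = attr(segments, "vmax_ug_s_mg"),
                       scale = attr(segments, "pept1_scale"))
}

#' Saturable carrier-mediated absorption flux in one segment
#'
#' `flux = scale * Vmax * expression * C / (Km + C)`, converted from
#' ug/s to mg/h.  At `C = Km` the flux is exactly half the segmental
#' maximum.
#'
#' @param c_lumen Luminal concentration, mg/L.
#' @param segment One row of a `gut_segments` data frame (or any list
#'   with a `pept1_mg` field).
#' @param kin A `transporter_kinetics`.
#' @return Absorption flux in mg/h.
#' @export
transporter_flux <- function(c_lumen, segment, kin) {
  if (any(c_lumen < 0)) stop("negative luminal concentration", call. = FALSE)
  vmax_mg_h <- kin$scale * kin$vmax_ug_s_mg * segment$pept1_mg * 3.6
  vmax_mg_h * c_lumen / (kin$km_mg_l + c_lumen)
}

#' Passive first-order absorption rate in one segment
#'
#' The absorption rate constant is `ka = (2 * Peff / r) * passive_scale`
#' (surface-to-volume ratio of a cylindrical lumen), converted to 1/h;
#' the rate is `ka * dissolved`.
#'
#' @param dissolved_mg Dissolved luminal mass, mg.
#' @param segment One row of a `gut_segments` data frame.
#' @param peff_cm_s Passive effective permeability, cm/s.
#' @return Absorption rate in mg/h.
#' @export
passive_absorption_rate <- function(dissolved_mg, segment, peff_cm_s) {
  if (any(segment$radius_cm <= 0)) stop("non-positive radius", call. = FALSE)
  if (any(dissolved_mg < 0)) stop("negative dissolved mass", call. = FALSE)
  ka_h <- (2 * peff_cm_s / segment$radius_cm) * segment$passive_scale * 3600
  ka_h * dissolved_mg
}

#' Dissolution specification
#'
#' @param mode `"instant"` (the whole dose enters solution at dose
#'   time) or `"first_order"` (release parameterised by the time to 85%
#'   dissolution).
#' @param t85_h Time for 85% of the dose to dissolve, hours
#'   (`first_order` only).
#' @return An object of class `dissolution_spec`.
#' @export
dissolution_spec <- function(mode = c("instant", "first_order"),
                             t85_h = NULL) {
  mode <- match.arg(mode)
  if (mode == "first_order") {
    if (is.null(t85_h) || !is.numeric(t85_h) || t85_h <= 0) {
      stop("first_order dissolution requires t85_h > 0", call. = FALSE)
    }
  } else {
    t85_h <- NA_real_
  }
  structure(list(mode = mode, t85_h = t85_h), class = "dissolution_spec")
}

#' First-order dissolution transfer rate
#'
#' `rate = k_d * undissolved * max(0, 1 - C/Csat)` with
#' `k_d = ln(1/0.15) / t85`, so 85% of an unsaturated dose dissolves by
#' `t85`; the linear factor shuts dissolution off as the lumen
#' saturates.  In instant mode the dose is moved at dose time and the
#' continuous rate is zero.
#'
#' @param undissolved_mg Solid mass, mg.
#' @param c_lumen Dissolved luminal concentration, mg/L.
#' @param spec A `dissolution_spec`.
#' @param solubility_mg_ml Solubility, mg/mL.
#' @return Dissolution rate in mg/h.
#' @export
dissolution_transfer <- function(undissolved_mg, c_lumen, spec,
                                 solubility_mg_ml) {
  if (any(undissolved_mg < 0) || any(c_lumen < 0)) {
    stop("masses and concentrations must be >= 0", call. = FALSE)
  }
  if (spec$mode == "instant") return(0 * undissolved_mg)
  kd <- log(1 / 0.15) / spec$t85_h
  csat <- solubility_mg_ml * 1000  # mg/L
  kd * undissolved_mg * pmax(0, 1 - c_lumen / csat)
}

#' Assemble a gut absorption model
#'
#' @param segments A `gut_segments` data frame
#'   ([load_gut_segments()]).
#' @param kinetics A `transporter_kinetics`; defaults to the constants
#'   and calibrated scale carried by `segments`.
#' @param dissolution A `dissolution_spec`; default instant.
#' @param pept1_enabled Logical; set `FALSE` for the
#'   transporter-knockout experiment.
#' @param precipitation Logical; re-transfer of supersaturated
#'   dissolved drug to solid with the mean precipitation time (inert
#'   for cefadroxil, whose dissolution is already solubility-gated).
#'   Only active under first-order dissolution, where solid can
#'   redissolve.
#' @return An object of class `gut_model`.
#' @export
gut_model <- function(segments = load_gut_segments(),
                      kinetics = default_transporter_kinetics(segments),
                      dissolution = dissolution_spec("instant"),
                      pept1_enabled = TRUE,
                      precipitation = TRUE) {
  stopifnot(inherits(segments, "gut_segments"),
            inherits(kinetics, "transporter_kinetics"),
            inherits(dissolution, "dissolution_spec"))
  if (nrow(segments) == 0L) stop("empty segment list", call. = FALSE)
  structure(list(segments = segments, kinetics = kinetics,
                 dissolution = dissolution,
                 pept1_enabled = isTRUE(pept1_enabled),
                 precipitation = isTRUE(precipitation)),
            class = "gut_model")
}

#' @export
print.gut_model <- function(x, ...) {
  cat(sprintf(paste0("<gut_model> %d segments, PEPT1 %s (scale %.4g), ",
                     "dissolution %s\n"),
              nrow(x$segments), if (x$pept1_enabled) "on" else "off",
              x$kinetics$scale,
              if (x$dissolution$mode == "instant") "instant"
              else sprintf("first-order (T85 = %g h)", x$dissolution$t85_h)))
  invisible(x)
}

gut_state_names <- function(segments) {
  c(paste0("solid.", segments$name), paste0("dissolved.", segments$name),
    "absorbed", "faeces")
}

#' Build the gut ODE right-hand side
#'
#' Per segment: `d(dissolved)/dt = dissolution + transit inflow -
#' transit outflow - passive uptake - carrier uptake`; solids follow the
#' same serial transit chain.  The stomach has no absorption; outflow
#' from the last segment is counted as faecal loss; all absorbed drug
#' is routed to the liver through the portal inflow port of the
#' systemic model.
#'
#' @param gut A `gut_model`.
#' @param drug A `drug_properties` (supplies Peff, solubility and the
#'   precipitation time).
#' @return `function(state, t)` returning
#'   `list(deriv = d(state)/dt, absorbed_flux = mg/h)` for the state
#'   vector named `c(solid.<segment>, dissolved.<segment>, "absorbed",
#'   "faeces")`, all masses in mg.
#' @export
build_gut_rhs <- function(gut, drug) {
  stopifnot(inherits(gut, "gut_model"), inherits(drug, "drug_properties"))
  seg <- gut$segments
  n <- nrow(seg)
  k_tr <- 1 / seg$transit_h
  ka_h <- (2 * drug$passive_peff_cm_s / seg$radius_cm) *
    seg$passive_scale * 3600
  ka_h[seg$name == "stomach"] <- 0
  vmax_mg_h <- gut$kinetics$scale * gut$kinetics$vmax_ug_s_mg *
    seg$pept1_mg * 3.6
  if (!gut$pept1_enabled) vmax_mg_h[] <- 0
  km <- gut$kinetics$km_mg_l
  csat <- drug$solubility_mg_ml * 1000  # mg/L
  fluid_l <- seg$fluid_ml / 1000
  first_order <- gut$dissolution$mode == "first_order"
  kd <- if (first_order) log(1 / 0.15) / gut$dissolution$t85_h else 0
  k_prec <- if (gut$precipitation && first_order) {
    3600 / drug$mean_precipitation_time_s
  } else 0
  function(state, t) {
    s <- state[seq_len(n)]
    m <- state[n + seq_len(n)]
    c_lum <- m / fluid_l
    diss <- kd * s * pmax(0, 1 - c_lum / csat)
    prec <- k_prec * pmax(0, m - csat * fluid_l)
    passive <- ka_h * m
    carrier <- vmax_mg_h * c_lum / (km + c_lum)
    s_in <- c(0, (k_tr * s)[-n])
    m_in <- c(0, (k_tr * m)[-n])
    ds <- diss * (-1) + prec + s_in - k_tr * s
    dm <- diss - prec + m_in - k_tr * m - passive - carrier
    absorbed_flux <- sum(passive + carrier)
    deriv <- c(ds, dm, absorbed_flux, k_tr[n] * (s[n] + m[n]))
    list(deriv = deriv, absorbed_flux = absorbed_flux)
  }
}

#' Fraction of an oral dose absorbed
#'
#' @param result A `pbpk_sim` from an oral simulation.
#' @return Cumulative absorbed mass at the end of the simulation
#'   divided by the dose (fraction).
#' @export
compute_fa <- function(result) {
  stopifnot(inherits(result, "pbpk_sim"))
  if (result$dose$route != "oral" || is.null(result$gut)) {
    stop("fraction absorbed is defined for oral simulations only",
         call. = FALSE)
  }
  utils::tail(result$gut$absorbed, 1) / result$dose$amount_mg
}

#' Calibrate the global transporter capacity
#'
#' Finds the multiplier on PEPT1 capacity such that the simulated
#' fraction absorbed matches a target, by monotone bisection (the
#' fraction absorbed is non-decreasing in capacity).  This mirrors the
#' way the carrier Vmax is treated as a fitted model parameter.
#'
#' @param target_fa Target fraction absorbed, in (0, 1).
#' @param model A human `disposition_model`.
#' @param gut A `gut_model`; its kinetics scale is overridden during the
#'   search.
#' @param dose_mg Oral dose used for calibration (mg).
#' @param t_end_h Simulation horizon, hours.
#' @param bracket Initial scale bracket; the upper bound is doubled (up
#'   to `max_expand` times) until it over-absorbs the target.
#' @param tol Absolute tolerance on the achieved fraction absorbed.
#' @param max_expand Maximum number of bracket doublings.
#' @return The calibrated scale (numeric), with the achieved fraction
#'   absorbed as attribute `fa`.
#' @export
calibrate_transporter_scale <- function(target_fa, model,
                                        gut = gut_model(),
                                        dose_mg = 1126.5, t_end_h = 48,
                                        bracket = c(0, 256), tol = 5e-4,
                                        max_expand = 12) {
  stopifnot(inherits(model, "disposition_model"))
  if (target_fa < 0 || target_fa >= 1) {
    stop("target_fa must lie in [0, 1)", call. = FALSE)
  }
  fa_at <- function(scale) {
    g <- gut
    g$kinetics$scale <- scale
    compute_fa(simulate_pk(model, dose_event("oral", dose_mg), gut = g,
                           t_end_h = t_end_h, n_points = 201))
  }
  lo <- bracket[1]; hi <- bracket[2]
  fa_lo <- fa_at(lo)
  if (fa_lo > target_fa + tol) {
    stop(sprintf("passive absorption alone (Fa = %.4f) exceeds the target %.4f",
                 fa_lo, target_fa), call. = FALSE)
  }
  if (abs(fa_lo - target_fa) <= tol) {
    return(structure(lo, fa = fa_lo))
  }
  fa_hi <- fa_at(hi)
  expand <- 0
  while (fa_hi < target_fa && expand < max_expand) {
    lo <- hi; fa_lo <- fa_hi
    hi <- hi * 2
    fa_hi <- fa_at(hi)
    expand <- expand + 1
  }
  if (fa_hi < target_fa - tol) {
    stop(sprintf("target Fa %.4f unreachable within bracket (max Fa %.4f)",
                 target_fa, fa_hi), call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fa_mid <- fa_at(mid)
    if (abs(fa_mid - target_fa) <= tol) {
      return(structure(mid, fa = fa_mid))
    }
    if (fa_mid < target_fa) lo <- mid else hi <- mid
    if ((hi - lo) / max(hi, 1) < 1e-6) break
  }
  mid <- (lo + hi) / 2
  structure(mid, fa = fa_at(mid))
}
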