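# Systemic disposition: perfusion-limited well-stirred whole-body ODE
# system over 13 tissues plus lung is one of them, arterial and venous
# blood pools, renal elimination, and a portal inflow port for oral
# absorption.
#
# Working units throughout the dynamic code: mg, L, h (so mg/L = ug/mL).

#' Assemble a whole-body disposition model
#'
#' Combines a species physiology and drug properties into the
#' perfusion-limited systemic model.  Flows are converted to L/h and
#' volumes to L; the hepatic-artery flow is derived as total liver
#' outflow minus the splenic and gut flows.
#'
#' @param phys A `species_physiology`.
#' @param drug A `drug_properties` for the same species.
#' @return An object of class `disposition_model`.
#' @examples
#' mod <- disposition_model(load_species_physiology("rat"),
#'                          load_drug_properties("rat"))
#' @export
disposition_model <- function(phys, drug) {
  stopifnot(inherits(phys, "species_physiology"),
            inherits(drug, "drug_properties"))
  t <- phys$tissues
  q_l_h <- stats::setNames(t$flow_ml_s * 3.6, t$name)   # mL/s -> L/h
  v_l <- stats::setNames(t$volume_ml / 1000, t$name)
  kp <- stats::setNames(t$kp, t$name)
  q_gut <- phys$gut_flow_ml_s * 3.6
  q_ha <- q_l_h[["liver"]] - q_l_h[["spleen"]] - q_gut
  if (q_ha < 0) {
    stop("hepatic artery flow is negative: liver outflow must exceed ",
         "spleen + gut flows", call. = FALSE)
  }
  # circulating flow taken as the sum of venous-draining tissue flows
  # (equals the tabulated cardiac output up to table rounding); using
  # the consistent sum makes the circulation mass-conserving exactly
  q_co <- sum(q_l_h[setdiff(PBPK_TISSUES, c("lung", "spleen"))])
  if (drug$renal_clearance_l_h >= q_l_h[["kidney"]]) {
    stop(sprintf(paste0("renal clearance (%.3g L/h) must stay below the ",
                        "kidney perfusion (%.3g L/h): the kidney cannot ",
                        "extract more drug than its blood flow delivers"),
                 drug$renal_clearance_l_h, q_l_h[["kidney"]]), call. = FALSE)
  }
  structure(list(
    species = phys$species,
    phys = phys,
    drug = drug,
    v_tissue = v_l,
    q_tissue = q_l_h,
    kp = kp,
    v_art = phys$arterial_volume_ml / 1000,
    v_ven = phys$venous_volume_ml / 1000,
    q_co = q_co,
    q_gut = q_gut,
    q_ha = q_ha,
    cl_renal = drug$renal_clearance_l_h
  ), class = "disposition_model")
}

#' @export
print.disposition_model <- function(x, ...) {
  cat(sprintf(paste0("<disposition_model> %s: CO %.4g L/h, hepatic artery ",
                     "%.4g L/h, renal CL %.4g L/h\n"),
              x$species, x$q_co, x$q_ha, x$cl_renal))
  invisible(x)
}

# Tissues whose venous outflow drains directly to the venous pool
# (spleen drains through the liver; lung sits between the pools).
venous_draining_tissues <- function() {
  setdiff(PBPK_TISSUES, c("lung", "spleen"))
}

systemic_state_names <- function() {
  c("venous", "arterial", PBPK_TISSUES, "eliminated")
}

#' Build the systemic ODE right-hand side
#'
#' Returns the derivative function of the perfusion-limited model.  All
#' tissues are well stirred, with venous outflow at `C_t / Kp_t`
#' (partition coefficients act on total tissue and plasma
#' concentrations; with a blood:plasma ratio of 1, blood and plasma
#' concentrations coincide).  The kidney additionally clears drug at
#' `CL_renal * C_art`; the liver receives the hepatic artery, the
#' splenic outflow, the portal (gut) stream, and any oral absorption
#' flux through `gut_inflow`.
#'
#' @param model A `disposition_model`.
#' @return `function(state, t, gut_inflow = 0)` returning `d(state)/dt`
#'   for the state vector named as `c("venous", "arterial", tissues,
#'   "eliminated")`, concentrations in mg/L and the eliminated amount
#'   in mg.  `gut_inflow` is an absorption mass flux in mg/h delivered
#'   to the liver.
#' @export
build_systemic_rhs <- function(model) {
  stopifnot(inherits(model, "disposition_model"))
  v <- model$v_tissue; q <- model$q_tissue; kp <- model$kp
  direct <- venous_draining_tissues()
  q_liver_out <- q[["liver"]]  # total hepatic outflow (Table row)
  function(state, t, gut_inflow = 0) {
    c_ven <- state[["venous"]]
    c_art <- state[["arterial"]]
    c_t <- state[PBPK_TISSUES]
    c_out <- c_t / kp                       # venous-side concentrations
    d <- numeric(length(state))
    names(d) <- names(state)
    # lung: receives the whole cardiac output from the venous pool
    d[["lung"]] <- model$q_co * (c_ven - c_out[["lung"]]) / v[["lung"]]
    # ordinary perfused tissues (arterial supply, venous return)
    for (tn in setdiff(PBPK_TISSUES, c("lung", "liver"))) {
      d[[tn]] <- q[[tn]] * (c_art - c_out[[tn]]) / v[[tn]]
    }
    # kidney: perfusion plus clearance of arterial plasma
    elim_rate <- model$cl_renal * c_art
    d[["kidney"]] <- d[["kidney"]] - elim_rate / v[["kidney"]]
    # liver: hepatic artery + spleen + portal stream + absorbed drug
    liver_in <- model$q_ha * c_art +
      q[["spleen"]] * c_out[["spleen"]] +
      model$q_gut * c_art +
      gut_inflow
    d[["liver"]] <- (liver_in - q_liver_out * c_out[["liver"]]) / v[["liver"]]
    # blood pools
    d[["arterial"]] <- model$q_co * (c_out[["lung"]] - c_art) / model$v_art
    ven_in <- sum(q[direct] * c_out[direct])
    d[["venous"]] <- (ven_in - model$q_co * c_ven) / model$v_ven
    d[["eliminated"]] <- elim_rate
    d
  }
}

#' Check mass conservation of a simulation
#'
#' Computes the largest relative departure, over the stored trajectory,
#' of (body burden + eliminated + residual gut content + faecal loss)
#' from the administered dose.
#'
#' @param result A `pbpk_sim` from [simulate_pk()].
#' @param dose_mg Dose to balance against; defaults to the simulated dose.
#' @return Maximum relative error (fraction of dose); 0 for a zero dose.
#' @export
mass_balance_check <- function(result, dose_mg = NULL) {
  stopifnot(inherits(result, "pbpk_sim"))
  if (is.null(dose_mg)) dose_mg <- result$dose$amount_mg
  if (dose_mg == 0) return(0)
  if (nrow(result$conc) == 0L) stop("empty trajectory", call. = FALSE)
  model <- result$model
  burden <- as.matrix(result$conc[PBPK_TISSUES]) %*% model$v_tissue[PBPK_TISSUES] +
    result$conc$venous * model$v_ven +
    result$conc$arterial * model$v_art +
    result$conc$eliminated
  if (!is.null(result$gut)) {
    # luminal drug and faecal loss; absorbed drug is already part of
    # the systemic burden
    g <- result$gut
    mass_cols <- grep("^(solid|dissolved)\\.", names(g), value = TRUE)
    burden <- burden + rowSums(g[mass_cols]) + g$faeces
  }
  # before the dose time nothing is in the system
  dosed <- ifelse(result$conc$time >= result$dose$time_h, dose_mg, 0)
  max(abs(burden - dosed)) / dose_mg
}
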