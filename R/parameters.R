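# Parameter registry: species physiology (compartment volumes, blood
# flows), drug properties, partition coefficients, and the closed-form
# steady-state volume of distribution.

# The 13 perfused non-blood tissues of the systemic model, lung included.
PBPK_TISSUES <- c("lung", "adipose", "muscle", "liver", "spleen", "heart",
                  "brain", "kidney", "skin", "repro_organ", "red_marrow",
                  "yellow_marrow", "rest_of_body")

PBPK_SPECIES <- c("mouse", "rat", "human")

#' Load the physiology of a modelled species
#'
#' Reads the bundled compartment volumes (mL), blood flows (mL/s),
#' tissue:plasma partition coefficients (Kp), haematocrit and body
#' weight for one of the three supported species, applies any
#' overrides, and validates the result.  The liver blood flow is the
#' total hepatic outflow; the hepatic-artery flow is derived downstream
#' by difference with the splenic and gut flows.
#'
#' @param species One of `"mouse"`, `"rat"`, `"human"`.
#' @param overrides Optional named list of configuration keys to
#'   replace, using the same keys as the bundled file (e.g.
#'   `list("tissue.kidney.kp" = 5)` or `list(haematocrit = 0.4)`).
#'   Unknown keys are an error.
#' @param path Optional path to a physiology file in the same dialect;
#'   defaults to the bundled file for `species`.
#' @return An object of class `species_physiology`: a list with
#'   elements `species`, `body_weight_kg`, `haematocrit`,
#'   `cardiac_output_ml_s`, `arterial_volume_ml`, `venous_volume_ml`,
#'   `gut_flow_ml_s`, and `tissues` (a data frame with columns `name`,
#'   `volume_ml`, `flow_ml_s`, `kp` over the 13 perfused tissues).
#' @examples
#' rat <- load_species_physiology("rat")
#' subset(rat$tissues, name == "kidney")
#' @export
load_species_physiology <- function(species, overrides = NULL, path = NULL) {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% PBPK_SPECIES) {
    stop("unknown species: ", paste(species, collapse = ", "),
         " (supported: ", paste(PBPK_SPECIES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(path)) {
    path <- cefapbpk_extdata(paste0("species_", species, ".conf"))
  }
  config <- read_config(path)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("overrides must be a named list", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(config))
    if (length(unknown)) {
      stop("override names no configuration key: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    config[names(overrides)] <- vapply(overrides, format_value, character(1))
  }
  tissues <- data.frame(
    name = PBPK_TISSUES,
    volume_ml = vapply(PBPK_TISSUES, function(t)
      config_num(config, paste0("tissue.", t, ".volume_ml"), positive = TRUE),
      numeric(1)),
    flow_ml_s = vapply(PBPK_TISSUES, function(t)
      config_num(config, paste0("tissue.", t, ".flow_ml_s")), numeric(1)),
    kp = vapply(PBPK_TISSUES, function(t)
      config_num(config, paste0("tissue.", t, ".kp"), positive = TRUE),
      numeric(1)),
    row.names = NULL
  )
  phys <- structure(list(
    species = config[["species"]],
    body_weight_kg = config_num(config, "body_weight_kg", positive = TRUE),
    haematocrit = config_num(config, "haematocrit", positive = TRUE),
    cardiac_output_ml_s = config_num(config, "cardiac_output_ml_s",
                                     positive = TRUE),
    arterial_volume_ml = config_num(config, "arterial_volume_ml",
                                    positive = TRUE),
    venous_volume_ml = config_num(config, "venous_volume_ml", positive = TRUE),
    gut_flow_ml_s = config_num(config, "gut_flow_ml_s"),
    tissues = tissues
  ), class = "species_physiology")
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  t <- phys$tissues
  if (any(t$flow_ml_s < 0) || phys$gut_flow_ml_s < 0) {
    stop("blood flows must be non-negative", call. = FALSE)
  }
  if (phys$haematocrit >= 1) {
    stop("haematocrit must lie in (0, 1)", call. = FALSE)
  }
  # Flow reconciliation: all flows draining to the venous pool (the
  # liver row already carries the splenic and gut streams) must equal
  # cardiac output.  The bundled tables close this balance exactly.
  venous_draining <- setdiff(PBPK_TISSUES, c("lung", "spleen"))
  qsum <- sum(t$flow_ml_s[t$name %in% venous_draining])
  rel <- abs(qsum - phys$cardiac_output_ml_s) / phys$cardiac_output_ml_s
  if (rel > 0.02) {
    stop(sprintf(paste0("tissue blood flows (%.5f mL/s) do not reconcile ",
                        "with cardiac output (%.5f mL/s): %.1f%% off"),
                 qsum, phys$cardiac_output_ml_s, 100 * rel), call. = FALSE)
  }
  invisible(phys)
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s: BW %.3g kg, CO %.4g mL/s, Hct %.2f\n",
              x$species, x$body_weight_kg, x$cardiac_output_ml_s,
              x$haematocrit))
  cat(sprintf("  blood: arterial %.4g mL, venous %.4g mL; gut flow %.4g mL/s\n",
              x$arterial_volume_ml, x$venous_volume_ml, x$gut_flow_ml_s))
  print(x$tissues, row.names = FALSE)
  invisible(x)
}

#' Serialize a species physiology back to the key=value dialect
#'
#' Round-trips bit-for-bit with [load_species_physiology()].
#'
#' @param phys A `species_physiology` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_species_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "species_physiology"))
  config <- c(
    species = phys$species,
    body_weight_kg = phys$body_weight_kg,
    haematocrit = phys$haematocrit,
    cardiac_output_ml_s = phys$cardiac_output_ml_s,
    arterial_volume_ml = phys$arterial_volume_ml,
    venous_volume_ml = phys$venous_volume_ml,
    gut_flow_ml_s = phys$gut_flow_ml_s
  )
  for (i in seq_len(nrow(phys$tissues))) {
    t <- phys$tissues[i, ]
    config[paste0("tissue.", t$name, ".volume_ml")] <- t$volume_ml
    config[paste0("tissue.", t$name, ".flow_ml_s")] <- t$flow_ml_s
    config[paste0("tissue.", t$name, ".kp")] <- t$kp
  }
  write_config(config, path,
               header = paste("species physiology:", phys$species))
}

#' Load drug properties
#'
#' Reads the bundled cefadroxil physicochemical and disposition
#' parameters and selects the per-species renal clearance.
#'
#' @inheritParams load_species_physiology
#' @param overrides Optional named list of configuration keys to replace.
#' @return An object of class `drug_properties` with fields
#'   `molecular_weight_g_mol`, `log_p`, `pka` (data frame value/type),
#'   `fup`, `blood_plasma_ratio`, `solubility_mg_ml`,
#'   `passive_peff_cm_s`, `mean_precipitation_time_s`,
#'   `diffusion_coefficient_cm2_s`, `particle_density_g_ml`, and
#'   `renal_clearance_l_h` (the value for `species`).
#' @examples
#' drug <- load_drug_properties("rat")
#' drug$renal_clearance_l_h
#' @export
load_drug_properties <- function(species, overrides = NULL, path = NULL) {
  if (!species %in% PBPK_SPECIES) {
    stop("unknown species: ", species, call. = FALSE)
  }
  if (is.null(path)) path <- cefapbpk_extdata("drug_cefadroxil.conf")
  config <- read_config(path)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(config))
    if (length(unknown)) {
      stop("override names no configuration key: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    config[names(overrides)] <- vapply(overrides, format_value, character(1))
  }
  pka_raw <- strsplit(config[["pka"]], ",", fixed = TRUE)[[1]]
  pka <- do.call(rbind, lapply(strsplit(pka_raw, ":", fixed = TRUE),
                               function(p) data.frame(value = as.numeric(p[1]),
                                                      type = p[2])))
  drug <- structure(list(
    name = config[["name"]],
    species = species,
    molecular_weight_g_mol = config_num(config, "molecular_weight_g_mol",
                                        positive = TRUE),
    log_p = config_num(config, "log_p"),
    pka = pka,
    fup = config_num(config, "fup", positive = TRUE),
    blood_plasma_ratio = config_num(config, "blood_plasma_ratio",
                                    positive = TRUE),
    solubility_mg_ml = config_num(config, "solubility_mg_ml", positive = TRUE),
    passive_peff_cm_s = config_num(config, "passive_peff_cm_s"),
    mean_precipitation_time_s = config_num(config, "mean_precipitation_time_s",
                                           positive = TRUE),
    diffusion_coefficient_cm2_s = config_num(config,
                                             "diffusion_coefficient_cm2_s",
                                             positive = TRUE),
    particle_density_g_ml = config_num(config, "particle_density_g_ml",
                                       positive = TRUE),
    renal_clearance_l_h = config_num(config,
                                     paste0("renal_clearance_l_h.", species),
                                     positive = TRUE)
  ), class = "drug_properties")
  if (drug$fup > 1) stop("fup must lie in (0, 1]", call. = FALSE)
  if (drug$passive_peff_cm_s < 0) stop("Peff must be >= 0", call. = FALSE)
  drug
}

#' @export
print.drug_properties <- function(x, ...) {
  cat(sprintf("<drug_properties> %s (%s): MW %.2f, logP %.2f, fup %.3f\n",
              x$name, x$species, x$molecular_weight_g_mol, x$log_p, x$fup))
  cat(sprintf("  solubility %.4g mg/mL, Peff %.3g cm/s, renal CL %.4g L/h\n",
              x$solubility_mg_ml, x$passive_peff_cm_s,
              x$renal_clearance_l_h))
  invisible(x)
}

#' Body weight implied by a total dose and a per-kg dose
#'
#' Dosing arithmetic used to recover the body weights behind the
#' per-species dose tables (e.g. a 375.5 mg total dose at 5 mg/kg
#' implies 75.1 kg).
#'
#' @param total_dose_mg Total administered dose, mg.
#' @param dose_per_kg Dose normalised to body weight, mg/kg.
#' @return Body weight in kg.
#' @examples
#' derive_body_weight(375.5, 5)   # 75.1 kg
#' derive_body_weight(0.62, 2)    # 0.31 kg
#' @export
derive_body_weight <- function(total_dose_mg, dose_per_kg) {
  if (!is.numeric(total_dose_mg) || !is.numeric(dose_per_kg) ||
      any(total_dose_mg <= 0) || any(dose_per_kg <= 0)) {
    stop("doses must be strictly positive", call. = FALSE)
  }
  total_dose_mg / dose_per_kg
}

#' Structural steady-state volume of distribution
#'
#' Closed-form Vss of the perfusion-limited model: the Kp-weighted sum
#' of the 13 tissue volumes (lung included) plus the plasma fraction
#' `(1 - haematocrit)` of the arterial and venous blood volumes.  With
#' a blood:plasma ratio of 1 this is the volume that relates the
#' administered amount to the steady-state plasma concentration.
#'
#' @param phys A `species_physiology` (its `tissues$kp` column supplies
#'   the partition coefficients).
#' @return Vss in litres.
#' @examples
#' compute_pbpk_vss(load_species_physiology("mouse"))  # ~0.012 L
#' @export
compute_pbpk_vss <- function(phys) {
  stopifnot(inherits(phys, "species_physiology"))
  if (any(is.na(phys$tissues$kp))) {
    stop("missing Kp for tissue: ",
         paste(phys$tissues$name[is.na(phys$tissues$kp)], collapse = ", "),
         call. = FALSE)
  }
  tissue_ml <- sum(phys$tissues$kp * phys$tissues$volume_ml)
  plasma_ml <- (1 - phys$haematocrit) *
    (phys$arterial_volume_ml + phys$venous_volume_ml)
  (tissue_ml + plasma_ml) / 1000
}

#' Dose events
#'
#' @param route `"iv_bolus"` (deposited in the venous pool) or
#'   `"oral"` (deposited in the stomach of the gut model).
#' @param amount_mg Dose amount in mg.
#' @param time_h Dosing time in hours (default 0).
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(route = c("iv_bolus", "oral"), amount_mg, time_h = 0) {
  route <- match.arg(route)
  if (!is.numeric(amount_mg) || length(amount_mg) != 1L || amount_mg < 0) {
    stop("dose amount must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(time_h) || length(time_h) != 1L || time_h < 0) {
    stop("dose time must be a single non-negative number", call. = FALSE)
  }
  structure(list(route = route, amount_mg = amount_mg, time_h = time_h),
            class = "dose_event")
}

#' @export
print.dose_event <- function(x, ...) {
  cat(sprintf("<dose_event> %s %.4g mg at t = %g h\n",
              x$route, x$amount_mg, x$time_h))
  invisible(x)
}
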