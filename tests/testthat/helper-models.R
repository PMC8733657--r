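# Shared model constructors, memoised so the configuration files are
# parsed once per test run.

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, make(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

mouse_model <- function() cached("mouse", function()
  disposition_model(load_species_physiology("mouse"),
                    load_drug_properties("mouse")))

rat_model <- function() cached("rat", function()
  disposition_model(load_species_physiology("rat"),
                    load_drug_properties("rat")))

human_model <- function() cached("human", function()
  disposition_model(load_species_physiology("human"),
                    load_drug_properties("human")))

# default human gut with the bundled calibrated transporter capacity
human_gut <- function() cached("gut", function() gut_model())

species_model <- function(sp) switch(sp, mouse = mouse_model(),
                                     rat = rat_model(),
                                     human = human_model())

body_burden_mg <- function(sim) {
  model <- sim$model
  as.vector(as.matrix(sim$conc[cefapbpk:::PBPK_TISSUES]) %*%
              model$v_tissue[cefapbpk:::PBPK_TISSUES]) +
    sim$conc$venous * model$v_ven + sim$conc$arterial * model$v_art
}
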