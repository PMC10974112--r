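# Shared fixtures: small designs keep each fit in the tens of milliseconds.

bbma_params <- function() reference_polymer_params("bBMA")
sol_params <- function() reference_polymer_params("SOL")

# a GRI/SOL-like two-phase scenario: plasticizing drug whose solubility in
# the polymer rises with temperature, loaded above the dissolved limit
two_phase_scenario <- function() {
  list(
    p = sol_params(),
    d = drug_shift_params(s_plast = -4.5, s_filler = 5.5),
    curve = solubility_curve(data.frame(
      temperature_C = c(120, 130, 160, 200, 210),
      ws_fraction  = c(0.03, 0.05, 0.15, 0.30, 0.33))),
    w_drug = 0.3
  )
}

quiet_fit <- function(...) suppressWarnings(fit_carreau_arrhenius(...))
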