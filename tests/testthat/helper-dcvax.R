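## Shared fixtures: everything is generated in code at test time.

ref_p <- reference_parameters()
ref_con <- design_constants()
ref_v <- param_values(ref_p)

noiseless_config <- generator_config(sigma_lognormal = 0, sd_additive = 0)

## a small but valid state vector at the resting point for RHS-level tests
rest_state_full <- function(params = ref_p, constants = ref_con) {
  c(dc_blood = constants$DC_in / param_values(params)[["Q_Blood"]],
    dc_lung = 0, dc_liver = 0, dc_spleen = 0,
    signaling_rest_state(params, constants),
    naive = constants$T_0, early_effector = 0,
    short_lived_effector = 0, memory = 0)
}
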