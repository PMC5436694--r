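# shared fixtures: cached default parameters and small helpers

table1 <- default_parameters()

default_settings <- function(policy = "PD_FIRST", ...)
  analysis_settings(policy = policy, ...)

# parameter set with all uncertainty removed (every se = 0)
fix_all <- function(params) {
  zero <- function(e) { e$se <- 0; e }
  params$survival <- lapply(params$survival, zero)
  params$estimates <- lapply(params$estimates, zero)
  params
}

# swap the PD and HD parameter blocks (probabilities, costs, utilities);
# running the opposite policy on the swapped set must mirror the original
swap_modalities <- function(params) {
  swap <- function(a, b) {
    tmp <- params$estimates[[a]]
    params$estimates[[a]] <<- params$estimates[[b]]
    params$estimates[[b]] <<- tmp
  }
  swap("p_peritonitis_pd", "p_vascular_complication_hd")
  swap("p_switch_pd_to_hd", "p_switch_hd_to_pd")
  swap("cost_initial_pd", "cost_initial_hd")
  swap("cost_maintenance_pd_annual", "cost_maintenance_hd_annual")
  swap("cost_complication_pd_annual", "cost_complication_hd_annual")
  swap("cost_nonmedical_pd_annual", "cost_nonmedical_hd_annual")
  swap("cost_indirect_pd_annual", "cost_indirect_hd_annual")
  swap("utility_pd", "utility_hd")
  swap("utility_pd_complication", "utility_hd_complication")
  params$estimates$utility_supportive <- params$estimates$utility_hd_complication
  params
}

# random valid parameter set drawn from the input distributions
random_params <- function(seed) {
  set.seed(seed)
  sample_parameter_set(table1)
}
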