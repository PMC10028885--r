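# Small networks and probe utilities shared across tests.

# one PN and one basket per layer: fast single-cell dynamics probes
tiny_column <- function(specs = default_cell_specs()) {
  build_column(seed = 0, scale = 1, n_pn = 1, n_basket = 1, specs = specs)
}

comp_id_of <- function(network, cls, name) {
  comp <- network$flat$comp
  comp$comp_id[comp$cell_class == cls & comp$name == name]
}

# short no-stimulus config for probes
probe_config <- function(duration = 250, n_trials = 1, ...) {
  simulation_config(duration = duration, burn_in = 0, n_trials = n_trials,
                    ...)
}

# spike times of one class after a conductance injection at a compartment
inject_and_spikes <- function(network, cls, comp_name, g, t0 = 50, t1 = 60,
                              duration = 250) {
  cid <- comp_id_of(network, cls, comp_name)
  tr <- integrate_trial(network, probe_config(duration), 1,
                        injections = list(conductance_injection(cid, g, 0, t0, t1)),
                        use_local = FALSE)
  tr$spikes$time[tr$spikes$cell_class == cls]
}

preferred_network <- function(condition, scale = 300) {
  variant_network(build_variant("preferred"), condition, scale = scale)
}
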