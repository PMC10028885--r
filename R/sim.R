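#' Simulation configuration
#'
#' @param dt Integration step, ms.
#' @param duration Post-stimulus epoch length, ms (epoch time runs from
#'   `-burn_in` to `duration`; drives and recordings use epoch time, with
#'   0 at stimulus onset).
#' @param burn_in Drive-free lead-in before stimulus onset, ms.
#' @param n_trials Trials per batch.
#' @param base_seed Seed; trial `k` uses `base_seed + k`.
#' @param record_dt Observable recording interval, ms.
#' @param record_v Record all compartment voltages.
#' @param record_state Record full per-step current bookkeeping (intended
#'   for very small networks).
#' @param threshold Somatic spike threshold, mV.
#' @param refract Spike-detection refractory lockout, ms.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(dt = 0.025, duration = 450, burn_in = 50,
                              n_trials = 10, base_seed = 42, record_dt = 1,
                              record_v = FALSE, record_state = FALSE,
                              threshold = 0, refract = 3) {
  stopifnot(dt > 0, duration >= 0, burn_in >= 0, n_trials >= 1)
  structure(list(dt = dt, duration = duration, burn_in = burn_in,
                 n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed), record_dt = record_dt,
                 record_v = record_v, record_state = record_state,
                 threshold = threshold, refract = refract),
            class = "simulation_config")
}

.receptor_code <- c(ampa = 0L, nmda = 1L, gabaa = 2L, gabab = 3L)

# expand the class-level connectivity table into per-cell-pair entries with
# Gaussian horizontal-distance weight falloff
.expand_local <- function(network, connectivity = network$connectivity) {
  cells <- network$cells
  comp <- network$flat$comp
  out <- vector("list", nrow(connectivity))
  for (r in seq_len(nrow(connectivity))) {
    e <- connectivity[r, ]
    if (e$weight <= 0) next
    src <- cells$cell_id[cells$cell_class == e$src_class]
    tgt_comp <- comp[comp$cell_class == e$tgt_class & comp$name == e$tgt_comp, ]
    if (length(src) == 0 || nrow(tgt_comp) == 0) next
    pair <- expand.grid(src = src, ti = seq_len(nrow(tgt_comp)))
    tgt_cell <- tgt_comp$cell_id[pair$ti]
    keep <- pair$src != tgt_cell
    pair <- pair[keep, ]; tgt_cell <- tgt_cell[keep]
    if (nrow(pair) == 0) next
    d2 <- (cells$x[pair$src] - cells$x[tgt_cell])^2 +
      (cells$y[pair$src] - cells$y[tgt_cell])^2
    out[[r]] <- data.frame(src_cell = pair$src,
                           comp_id = tgt_comp$comp_id[pair$ti],
                           receptor = e$receptor,
                           weight = e$weight * exp(-d2 / e$lamtha^2),
                           delay = e$delay)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# per-drive target synapses with per-receptor weights
.drive_synapses <- function(network, drive) {
  tg <- drive_targets(network, drive$kind)
  out <- list()
  for (w_name in names(drive$weights)) {
    rec <- sub(".*_(ampa|nmda|gabaa|gabab)$", "\\1", w_name)
    cls <- sub("_(ampa|nmda|gabaa|gabab)$", "", w_name)
    rows <- tg$cell_class == cls
    if (!any(rows)) next
    out[[w_name]] <- data.frame(target = which(rows),
                                comp_id = tg$comp_id[rows], receptor = rec,
                                weight = unname(drive$weights[[w_name]]))
  }
  list(targets = tg, syn = do.call(rbind, out))
}

# build the merged conductance-state table and index maps
.assemble_states <- function(local_exp, drive_syn) {
  key <- function(df) paste(df$comp_id, df$receptor)
  all_keys <- character(0)
  if (!is.null(local_exp)) all_keys <- key(local_exp)
  for (ds in drive_syn)
    if (!is.null(ds$syn)) all_keys <- c(all_keys, key(ds$syn))
  uk <- unique(all_keys)
  comp_id <- as.integer(sub(" .*", "", uk))
  receptor <- sub(".* ", "", uk)
  kin <- lapply(receptor, receptor_kinetics)
  states <- list(
    comp = comp_id - 1L,
    E = vapply(kin, `[[`, numeric(1), "e_rev"),
    tau_r = vapply(kin, `[[`, numeric(1), "tau_rise"),
    tau_d = vapply(kin, `[[`, numeric(1), "tau_decay"),
    nmda = vapply(kin, `[[`, logical(1), "voltage_dependent"))
  list(states = states, keys = uk)
}

#' Integrate one trial
#'
#' Advances the full network state with a fixed step: exponential-Euler
#' gating updates against tabulated rates, semi-implicit voltage updates,
#' event-driven synaptic conductances.  Drive event times are sampled here
#' (deterministically from the drive seeds and `trial_seed`) and rounded to
#' the integration grid by the engine.  Aborts with a diagnostic if any
#' voltage exceeds 200 mV in magnitude.
#'
#' @param network A `column_network` with drives attached.
#' @param config A [simulation_config()].
#' @param trial_seed Integer seed for this trial's drive sampling.
#' @param injections Optional list of [current_injection()] /
#'   [conductance_injection()] objects.
#' @param use_local Include local (within-column) connectivity.
#' @return A `trial_result` with recorded axial currents (pyramidal axial
#'   segments), per-compartment transmembrane currents, spikes, and
#'   layer-V calcium traces, all on the epoch time grid.
#' @export
integrate_trial <- function(network, config = simulation_config(),
                            trial_seed = config$base_seed, injections = NULL,
                            use_local = TRUE) {
  flat <- network$flat
  local_exp <- if (use_local) .expand_local(network) else NULL
  drive_syn <- lapply(network$drives, function(d) .drive_synapses(network, d))
  .integrate_prepared(network, config, trial_seed, local_exp, drive_syn,
                      injections)
}

.integrate_prepared <- function(network, config, trial_seed, local_exp,
                                drive_syn, injections = NULL) {
  flat <- network$flat
  st <- .assemble_states(local_exp, drive_syn)
  state_of <- function(df) match(paste(df$comp_id, df$receptor), st$keys)

  # local connections -> (src cell, state, weight, delay)
  if (!is.null(local_exp) && nrow(local_exp) > 0) {
    lcl <- list(src = as.integer(local_exp$src_cell) - 1L,
                state = as.integer(state_of(local_exp)) - 1L,
                w = local_exp$weight, delay = local_exp$delay)
  } else {
    lcl <- list(src = integer(0), state = integer(0), w = numeric(0),
                delay = numeric(0))
  }

  # drive events (epoch time -> engine time)
  ev_t <- numeric(0); ev_st <- integer(0); ev_w <- numeric(0)
  for (dn in names(network$drives)) {
    d <- network$drives[[dn]]
    ds <- drive_syn[[dn]]
    if (is.null(ds$syn)) next
    sp <- sample_drive_spikes(d, ds$targets, trial_seed)
    n_sp <- d$n_spikes
    for (r in seq_len(nrow(ds$syn))) {
      tt <- sp[[ds$syn$target[r]]] + config$burn_in
      ev_t <- c(ev_t, tt)
      ev_st <- c(ev_st, rep(state_of(ds$syn[r, ]) - 1L, length(tt)))
      ev_w <- c(ev_w, rep(ds$syn$weight[r], length(tt)))
    }
  }

  inj <- list(comp = integer(0), type = integer(0), amp = numeric(0),
              E = numeric(0), t0 = numeric(0), t1 = numeric(0))
  for (j in injections) {
    inj$comp <- c(inj$comp, as.integer(j$comp_id) - 1L)
    inj$type <- c(inj$type, if (j$type == "current") 0L else 1L)
    inj$amp <- c(inj$amp, j$amp)
    inj$E <- c(inj$E, j$e_rev %||% 0)
    inj$t0 <- c(inj$t0, j$t0 + config$burn_in)
    inj$t1 <- c(inj$t1, j$t1 + config$burn_in)
  }

  nstep <- round((config$burn_in + config$duration) / config$dt)
  rec_every <- max(1L, round(config$record_dt / config$dt))
  comp <- flat$comp
  net_in <- list(C = comp$C, gL = comp$gL, EL = comp$EL, gNa = comp$gNa,
                 gK = comp$gK, gCa = comp$gCa, gKCa = comp$gKCa,
                 ca_tau = flat$ca_tau, ca_f = flat$ca_f,
                 cell = as.integer(comp$cell_id) - 1L,
                 soma_comp = as.integer(flat$soma_comp) - 1L,
                 v0 = comp$v0,
                 conn_i = as.integer(flat$conn$i) - 1L,
                 conn_j = as.integer(flat$conn$j) - 1L,
                 conn_g = flat$conn$g, conn_rec = flat$conn$is_pn,
                 ca0 = network$kinetics$ca0, kca_kd = network$kinetics$kca_kd,
                 tables = flat$tables$tab, tab_vmin = flat$tables$vmin,
                 tab_dv = flat$tables$dv)
  ctrl <- list(dt = config$dt, nstep = as.integer(nstep),
               rec_every = as.integer(rec_every),
               thresh = config$threshold, refract = config$refract,
               record_v = config$record_v, record_state = config$record_state,
               ENa = network$kinetics$ena, EK = network$kinetics$ek,
               ECa = network$kinetics$eca)
  raw <- .engine_run(net_in,
                     lapply(st$states, identity),
                     list(t = ev_t, state = ev_st, w = ev_w),
                     lcl, inj, ctrl)

  cells <- network$cells
  spikes <- data.frame(cell_id = as.integer(raw$spike_cell),
                       time = raw$spike_time - config$burn_in)
  spikes$cell_class <- cells$cell_class[spikes$cell_id]
  res <- list(time = raw$rec_t - config$burn_in,
              i_axial = raw$i_axial,
              conn = flat$conn[raw$conn_recorded + 1L, , drop = FALSE],
              i_membrane = raw$i_membrane,
              spikes = spikes,
              ca = raw$ca, ca_comp = raw$ca_comp + 1L,
              trial_seed = trial_seed, config = config)
  if (config$record_v) res$v <- raw$v
  if (config$record_state) res$bookkeeping <- raw$bookkeeping
  structure(res, class = "trial_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a batch of trials
#'
#' Trial `k` (1-based) uses seed `base_seed + k`, making trials independent
#' and the whole batch reproducible.
#'
#' @inheritParams integrate_trial
#' @return List of `trial_result` objects.
#' @export
run_batch <- function(network, config = simulation_config(),
                      injections = NULL, use_local = TRUE) {
  local_exp <- if (use_local) .expand_local(network) else NULL
  drive_syn <- lapply(network$drives, function(d) .drive_synapses(network, d))
  lapply(seq_len(config$n_trials), function(k)
    .integrate_prepared(network, config, config$base_seed + k, local_exp,
                        drive_syn, injections))
}

#' Current / conductance injection
#'
#' @param comp_id Target compartment id.
#' @param amp Current amplitude (nA) or peak conductance (uS).
#' @param t0,t1 Onset and offset, epoch ms.
#' @param e_rev Reversal potential for conductance injections, mV.
#' @return An injection descriptor.
#' @export
current_injection <- function(comp_id, amp, t0, t1) {
  list(comp_id = comp_id, type = "current", amp = amp, t0 = t0, t1 = t1,
       e_rev = NULL)
}

#' @rdname current_injection
#' @export
conductance_injection <- function(comp_id, amp, e_rev, t0, t1) {
  list(comp_id = comp_id, type = "conductance", amp = amp, t0 = t0, t1 = t1,
       e_rev = e_rev)
}

#' Check the unstimulated network stays at rest
#'
#' Simulates the network with no drives for `duration` ms and returns the
#' maximum absolute voltage drift from the resting potential over all
#' compartments and recorded samples.
#'
#' @param network A `column_network` (drives, if any, are ignored).
#' @param duration Simulated time, ms.
#' @return Maximum drift, mV.
#' @export
steady_state_check <- function(network, duration = 100) {
  if (duration <= 0) return(0)
  network$drives <- list()
  cfg <- simulation_config(duration = duration, burn_in = 0, n_trials = 1,
                           record_v = TRUE)
  tr <- integrate_trial(network, cfg, trial_seed = 1)
  max(abs(sweep(tr$v, 1, network$flat$comp$v0)))
}
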