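#' Exogenous evoked drive
#'
#' One proximal (feedforward) or distal (feedback) input to the column.
#' Proximal drives contact the basal and oblique dendrites of pyramidal
#' cells in both layers and the somata of both basket classes; distal
#' drives contact the apical tufts of pyramidal cells in both layers and
#' the somata of layer-II/III baskets only.  Each contacted compartment is
#' one target synapse; on every trial each target synapse receives
#' `n_spikes` presynaptic event times drawn independently from
#' `Normal(mean_time, sd_time)` truncated at 0 ms (stimulus onset).
#'
#' @param name Drive label.
#' @param kind `"proximal"` or `"distal"`.
#' @param mean_time,sd_time Gaussian event-time parameters, ms post
#'   stimulus onset.
#' @param n_spikes Events per target synapse per trial.
#' @param weights Named numeric vector of synaptic weights (uS), names of
#'   the form `<class>_<receptor>`, e.g. `L23_PN_ampa`, `L5_PN_nmda`,
#'   `L23_basket_ampa`.  A weight of 0 means no synapse.
#' @param seed Integer folded into the per-trial sampling seed.
#' @return An `evoked_drive` object.
#' @export
evoked_drive <- function(name, kind = c("proximal", "distal"), mean_time,
                         sd_time = 0, n_spikes = 1, weights, seed = 0) {
  kind <- match.arg(kind)
  if (sd_time < 0) stop("sd_time must be >= 0")
  if (n_spikes < 1) stop("n_spikes must be >= 1")
  classes <- if (kind == "proximal")
    c("L23_PN", "L5_PN", "L23_basket", "L5_basket")
  else c("L23_PN", "L5_PN", "L23_basket")
  ok <- as.vector(outer(classes, c("ampa", "nmda"), paste, sep = "_"))
  bad <- setdiff(names(weights)[weights != 0], ok)
  if (length(bad) > 0)
    stop("invalid drive weight target(s) for a ", kind, " drive: ",
         paste(bad, collapse = ", "))
  structure(list(name = name, kind = kind, mean_time = mean_time,
                 sd_time = sd_time, n_spikes = as.integer(n_spikes),
                 weights = weights[weights != 0], seed = as.integer(seed)),
            class = "evoked_drive")
}

#' Target synapses of a drive
#'
#' Enumerates the compartments a drive of the given kind contacts.
#'
#' @param network A `column_network`.
#' @param kind `"proximal"` or `"distal"`.
#' @return Data frame with `comp_id` and `cell_class`.
#' @export
drive_targets <- function(network, kind = c("proximal", "distal")) {
  kind <- match.arg(kind)
  ids <- if (kind == "proximal")
    c(.comps_of(network, c("L23_PN", "L5_PN"), c("basal", "oblique")),
      .comps_of(network, c("L23_basket", "L5_basket"), "soma"))
  else
    c(.comps_of(network, c("L23_PN", "L5_PN"), "apical_tuft"),
      .comps_of(network, "L23_basket", "soma"))
  comp <- network$flat$comp
  data.frame(comp_id = ids, cell_class = comp$cell_class[ids],
             comp_name = comp$name[ids])
}

#' Sample drive event times for one trial
#'
#' Each target synapse independently receives `n_spikes` times drawn from
#' `Normal(mean_time, sd_time)`, truncated at 0 ms.  Deterministic given
#' the drive seed and `trial_seed`.
#'
#' @param drive An [evoked_drive()].
#' @param targets Data frame of target synapses ([drive_targets()]), or an
#'   integer count.
#' @param trial_seed Integer trial seed.
#' @return List of numeric vectors of event times (ms), one per target.
#' @export
sample_drive_spikes <- function(drive, targets, trial_seed) {
  n_tgt <- if (is.data.frame(targets)) nrow(targets) else as.integer(targets)
  mix <- (abs(drive$seed) * 100003L + abs(as.integer(trial_seed)) * 7919L +
            .drive_name_hash(drive$name)) %% 2147483647L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(mix)
  draws <- matrix(stats::rnorm(n_tgt * drive$n_spikes, drive$mean_time,
                               drive$sd_time),
                  nrow = n_tgt)
  draws[draws < 0] <- 0
  lapply(seq_len(n_tgt), function(i) sort(draws[i, ]))
}

.drive_name_hash <- function(name) {
  sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 10007L
}

#' Attach a drive to a network
#'
#' Validates the drive against the network and appends it; synapses are
#' instantiated (and event times sampled) per trial at simulation time.
#' Compartment targeting follows the drive kind exclusively, so a distal
#' drive never touches basal or oblique dendrites and never contacts
#' layer-V baskets.
#'
#' @param network A `column_network`.
#' @param drive An [evoked_drive()].
#' @return The updated network.
#' @export
attach_drive <- function(network, drive) {
  stopifnot(inherits(network, "column_network"), inherits(drive, "evoked_drive"))
  network$drives[[drive$name]] <- drive
  network
}
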