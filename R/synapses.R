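#' Receptor kinetics
#'
#' Double-exponential conductance kinetics for the four receptor types.
#' Defaults (rise/decay ms, reversal mV): AMPA 0.5/5 at 0, NMDA 1/20 at 0
#' (with magnesium-block voltage dependence), GABA-A 0.5/5 at -80, GABA-B
#' 1/50 at -95.  NMDA decays more slowly than AMPA and GABA-B more slowly
#' than GABA-A, so feedback excitation and perisomatic GABA-B inhibition
#' act on the prolonged timescales the circuit model relies on.
#'
#' @param receptor One of `"ampa"`, `"nmda"`, `"gabaa"`, `"gabab"`.
#' @return A `receptor_kinetics` object with fields `receptor`, `tau_rise`,
#'   `tau_decay` (ms), `e_rev` (mV) and `voltage_dependent`.
#' @export
receptor_kinetics <- function(receptor = c("ampa", "nmda", "gabaa", "gabab")) {
  receptor <- match.arg(receptor)
  p <- switch(receptor,
    ampa  = list(tau_rise = 0.5, tau_decay = 5,  e_rev = 0,   vdep = FALSE),
    nmda  = list(tau_rise = 1,   tau_decay = 20, e_rev = 0,   vdep = TRUE),
    gabaa = list(tau_rise = 0.5, tau_decay = 5,  e_rev = -80, vdep = FALSE),
    gabab = list(tau_rise = 1,   tau_decay = 50, e_rev = -95, vdep = FALSE))
  structure(list(receptor = receptor, tau_rise = p$tau_rise,
                 tau_decay = p$tau_decay, e_rev = p$e_rev,
                 voltage_dependent = p$vdep),
            class = "receptor_kinetics")
}

#' Normalized double-exponential conductance
#'
#' Summed conductance at time `t` from a train of presynaptic events, for a
#' unit synaptic weight: each event contributes
#' `(exp(-(t-t0)/tau_decay) - exp(-(t-t0)/tau_rise)) / peak`, normalized so
#' a single event peaks at exactly 1.
#'
#' @param receptor A [receptor_kinetics()] object.
#' @param spike_times Sorted event times, ms.
#' @param t Evaluation time(s), ms.
#' @return Conductance in units of the synaptic weight (uS per uS).
#' @export
receptor_conductance <- function(receptor, spike_times, t) {
  stopifnot(inherits(receptor, "receptor_kinetics"))
  tr <- receptor$tau_rise; td <- receptor$tau_decay
  tp <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-tp / td) - exp(-tp / tr)
  g <- numeric(length(t))
  for (t0 in spike_times) {
    dtv <- t - t0
    on <- dtv > 0
    g[on] <- g[on] + (exp(-dtv[on] / td) - exp(-dtv[on] / tr)) / peak
  }
  g
}

#' Default local connectivity
#'
#' Fixed within-column connections.  Every pyramidal class projects to every
#' pyramidal class (all-to-all, with a Gaussian horizontal-distance weight
#' falloff of space constant `lamtha`); basket cells inhibit pyramidal somata
#' in their own layer through both GABA-A and GABA-B receptors, and
#' layer-II/III baskets additionally contact the layer-V apical trunk.  The
#' layer-V perisomatic GABA-B weight defaults to 0.025 uS, the quantity
#' doubled by the perisomatic-inhibition circuit variant.  Weights are peak
#' conductances at zero horizontal distance; a weight of 0 means no
#' connection.
#'
#' @return Data frame with columns `src_class`, `tgt_class`, `tgt_comp`,
#'   `receptor`, `weight` (uS), `delay` (ms), `lamtha` (um).
#' @export
default_local_connectivity <- function() {
  e <- function(src, tgt, comp, rec, w, lam = 100)
    data.frame(src_class = src, tgt_class = tgt, tgt_comp = comp,
               receptor = rec, weight = w, delay = 1, lamtha = lam)
  rbind(
    # PN -> PN (all class pairs)
    e("L23_PN", "L23_PN", "basal", "ampa", 2e-4, 300),
    e("L23_PN", "L23_PN", "basal", "nmda", 5e-5, 300),
    e("L23_PN", "L5_PN", "apical_trunk", "ampa", 2.5e-4, 300),
    e("L23_PN", "L5_PN", "apical_trunk", "nmda", 1e-4, 300),
    e("L5_PN", "L5_PN", "basal", "ampa", 2e-4, 300),
    e("L5_PN", "L5_PN", "basal", "nmda", 5e-5, 300),
    e("L5_PN", "L23_PN", "basal", "ampa", 5e-5, 300),
    # PN -> basket
    e("L23_PN", "L23_basket", "soma", "ampa", 5e-4),
    e("L5_PN", "L5_basket", "soma", "ampa", 5e-4),
    e("L23_PN", "L5_basket", "soma", "ampa", 5e-5),
    # basket -> PN
    e("L23_basket", "L23_PN", "soma", "gabaa", 0.02),
    e("L23_basket", "L23_PN", "soma", "gabab", 5e-4),
    e("L5_basket", "L5_PN", "soma", "gabaa", 2.5e-3),
    e("L5_basket", "L5_PN", "soma", "gabab", 0.025),
    e("L23_basket", "L5_PN", "apical_trunk", "gabaa", 1e-3),
    # basket -> basket
    e("L23_basket", "L23_basket", "soma", "gabaa", 2e-3),
    e("L5_basket", "L5_basket", "soma", "gabaa", 2e-3)
  )
}

#' Modify perisomatic GABA-B inhibition of layer-V pyramidal cells
#'
#' Multiplies the weight of the layer-V basket to layer-V pyramidal somatic
#' GABA-B entry by `factor`, leaving every other entry untouched (factor 2
#' takes the default 0.025 uS to 0.05 uS, the perisomatic-inhibition
#' circuit variant).
#'
#' @param connectivity A connectivity table, see
#'   [default_local_connectivity()].
#' @param factor Multiplicative factor.
#' @return The modified connectivity table.
#' @export
apply_perisomatic_modification <- function(connectivity, factor) {
  hit <- connectivity$src_class == "L5_basket" &
    connectivity$tgt_class == "L5_PN" &
    connectivity$tgt_comp == "soma" &
    connectivity$receptor == "gabab"
  if (!any(hit))
    stop("connectivity has no L5_basket -> L5_PN somatic GABA-B entry")
  connectivity$weight[hit] <- connectivity$weight[hit] * factor
  connectivity
}
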