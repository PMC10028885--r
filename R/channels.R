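#' Voltage-gated channel kinetics
#'
#' Rate functions for the transient sodium, delayed-rectifier potassium and
#' high-voltage-activated calcium channels used by all cells, plus the NMDA
#' magnesium-block factor.  Sodium/potassium rates follow the Traub-Miles
#' formulation with an adjustable activation offset `vt`; the calcium channel
#' uses Reuveni-style rates with a fixed reversal.  Steady states and time
#' constants are tabulated on a voltage grid and linearly interpolated by the
#' integrator.
#'
#' @name channel-kinetics
NULL

# vectorized x/(1-exp(-x/s)) with the removable singularity at x = 0
.vtrap <- function(x, s) ifelse(abs(x / s) < 1e-6, s * (1 + x / (2 * s)), x / (1 - exp(-x / s)))

#' Default channel kinetics set
#'
#' @param vt Spike-activation offset for the Na/K rate functions (mV).
#' @return A list of rate-function closures, one per gating variable, each
#'   returning `list(inf =, tau =)` for a voltage vector, plus reversal
#'   potentials (`ena`, `ek`, `eca`, mV) and calcium-pool constants
#'   (`ca_tau` ms, `ca0` mM, `kca_kd` mM).
#' @export
default_channel_kinetics <- function(vt = -58) {
  rate <- function(f) function(v) {
    a <- f$alpha(v); b <- f$beta(v)
    list(inf = a / (a + b), tau = pmax(1 / (a + b), 0.02))
  }
  list(
    na_m = rate(list(
      alpha = function(v) 0.32 * .vtrap(v - vt - 13, 4),
      beta  = function(v) 0.28 * .vtrap(-(v - vt - 40), 5))),
    na_h = rate(list(
      alpha = function(v) 0.128 * exp(-(v - vt - 17) / 18),
      beta  = function(v) 4 / (1 + exp(-(v - vt - 40) / 5)))),
    k_n = rate(list(
      alpha = function(v) 0.032 * .vtrap(v - vt - 15, 5),
      beta  = function(v) 0.5 * exp(-(v - vt - 10) / 40))),
    ca_p = rate(list(
      alpha = function(v) 0.055 * .vtrap(v + 27, 3.8),
      beta  = function(v) 0.94 * exp((-75 - v) / 17))),
    # slow voltage-dependent inactivation terminates apical calcium spikes
    ca_q = function(v) list(inf = 1 / (1 + exp((v + 40) / 5)),
                            tau = rep(50, length(v))),
    nmda_block = function(v) 1 / (1 + 0.28 * exp(-0.062 * v)),
    ena = 50, ek = -90, eca = 120,
    ca_tau = 60, ca0 = 5e-5, kca_kd = 2e-3
  )
}

# Tabulate all gating steady states / time constants plus the NMDA block on
# a regular voltage grid for the compiled integrator.
.channel_tables <- function(kin = default_channel_kinetics(),
                            vmin = -120, vmax = 60, dv = 0.05) {
  v <- seq(vmin, vmax, by = dv)
  m <- kin$na_m(v); h <- kin$na_h(v); n <- kin$k_n(v); p <- kin$ca_p(v)
  q <- kin$ca_q(v)
  tab <- cbind(minf = m$inf, mtau = m$tau, hinf = h$inf, htau = h$tau,
               ninf = n$inf, ntau = n$tau, pinf = p$inf, ptau = p$tau,
               nmda = kin$nmda_block(v), qinf = q$inf, qtau = q$tau)
  list(tab = tab, vmin = vmin, dv = dv)
}

#' NMDA receptor magnesium-block factor
#'
#' Sigmoidal voltage dependence of the NMDA conductance (Jahr-Stevens form
#' at 1 mM extracellular magnesium): near zero at strongly hyperpolarized
#' potentials, approaching one with depolarization.
#'
#' @param v Membrane potential(s), mV.
#' @return Scaling factor(s) in `[0, 1]`, non-decreasing in `v`.
#' @export
nmda_block <- function(v) 1 / (1 + 0.28 * exp(-0.062 * v))
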