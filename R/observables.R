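#' Primary current dipole of one trial
#'
#' The net longitudinal intracellular current in pyramidal-cell dendrites:
#' the sum over pyramidal axial segments of the axial current times the
#' signed segment extent along the vertical axis.  Positive values mean
#' current flow up the dendrites toward the pia.  Basket cells contribute
#' nothing.  Per-trial and unscaled; see [average_scale_smooth()] for the
#' trial-averaged, scaled waveform in nAm.
#'
#' @param trial A `trial_result`.
#' @param network The `column_network` that produced it.
#' @return A `dipole_trace`: list with `time` (epoch ms), `total`, `L23`,
#'   `L5` (nAm, unscaled), `scale = 1`.
#' @export
compute_dipole <- function(trial, network) {
  if (is.null(trial$i_axial)) stop("trial has no recorded axial currents")
  conn <- trial$conn
  # nA * um = fAm; 1e-6 -> nAm
  w <- conn$dz * 1e-6
  l23 <- network$cells$cell_class[conn$cell_id] == "L23_PN"
  total <- as.numeric(crossprod(trial$i_axial, w))
  comp_l23 <- as.numeric(crossprod(trial$i_axial, w * l23))
  structure(list(time = trial$time, total = total, L23 = comp_l23,
                 L5 = total - comp_l23, scale = 1L, smoothing = NULL),
            class = "dipole_trace")
}

#' Laminar decomposition of the dipole
#'
#' @inheritParams compute_dipole
#' @return List with `L23` and `L5` components (nAm, unscaled); their sum
#'   equals the total dipole at every sample.
#' @export
decompose_by_layer <- function(trial, network) {
  d <- compute_dipole(trial, network)
  list(L23 = d$L23, L5 = d$L5)
}

#' Average, scale and smooth dipole traces
#'
#' Mean over trials, multiplied by the network scale factor, then convolved
#' with a normalized Hamming window (DC gain one, so constants pass
#' through).  Optionally subtracts the baseline mean over a time window.
#'
#' @param traces List of `dipole_trace` objects on a common time grid.
#' @param scale Integer scale factor (the network's dipole scaling).
#' @param smooth_window Hamming window width, ms (0 disables smoothing).
#' @param baseline Optional `c(t0, t1)` epoch window whose mean is
#'   subtracted from every component (e.g. `c(-50, 0)`), or `NULL`.
#' @return A `dipole_trace` in nAm with per-layer components.
#' @export
average_scale_smooth <- function(traces, scale = 300, smooth_window = 30,
                                 baseline = NULL) {
  if (length(traces) == 0) stop("no dipole traces supplied")
  time <- traces[[1]]$time
  for (tr in traces)
    if (length(tr$time) != length(time) || any(tr$time != time))
      stop("dipole traces must share a time grid")
  avg <- function(field) {
    m <- rowMeans(vapply(traces, `[[`, numeric(length(time)), field)) * scale
    if (smooth_window > 0) m <- .hamming_smooth(m, time, smooth_window)
    if (!is.null(baseline))
      m <- m - mean(m[time >= baseline[1] & time <= baseline[2]])
    m
  }
  structure(list(time = time, total = avg("total"), L23 = avg("L23"),
                 L5 = avg("L5"), scale = as.integer(scale),
                 smoothing = smooth_window),
            class = "dipole_trace")
}

# normalized Hamming-window convolution with edge renormalization
.hamming_smooth <- function(x, time, width_ms) {
  dt <- time[2] - time[1]
  n <- max(3L, 2L * floor(width_ms / dt / 2) + 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- w / sum(w)
  half <- (n - 1L) / 2L
  xp <- c(rep(NA_real_, half), x, rep(NA_real_, half))
  vapply(seq_along(x), function(i) {
    seg <- xp[i:(i + n - 1L)]
    ok <- !is.na(seg)
    sum(seg[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Simulate the trial-averaged dipole for a network
#'
#' Convenience pipeline: [run_batch()], [compute_dipole()] per trial,
#' then [average_scale_smooth()] with baseline subtraction over the
#' pre-stimulus window.
#'
#' @inheritParams run_batch
#' @param smooth_window Hamming window width, ms.
#' @param baseline Baseline window, epoch ms.
#' @return A `dipole_trace` (nAm) with the per-trial traces attached as
#'   attribute `"trials"`.
#' @export
simulate_dipole <- function(network, config = simulation_config(),
                            smooth_window = 30, baseline = c(-50, 0),
                            use_local = TRUE) {
  batch <- run_batch(network, config, use_local = use_local)
  traces <- lapply(batch, compute_dipole, network = network)
  out <- average_scale_smooth(traces, scale = network$scale,
                              smooth_window = smooth_window,
                              baseline = baseline)
  attr(out, "trials") <- traces
  attr(out, "batch") <- batch
  out
}

#' Default laminar electrode array
#'
#' A vertical line of 50 contacts at 100-um spacing through the horizontal
#' center of the grid, starting above the layer-II/III tufts.
#'
#' @param network A `column_network`.
#' @param n_contacts Number of contacts.
#' @param spacing Intercontact spacing, um.
#' @param z_top z of the first (most superficial) contact, um.
#' @return Data frame with `x`, `y`, `z` (um).
#' @export
default_electrode_array <- function(network, n_contacts = 50, spacing = 100,
                                    z_top = 0) {
  data.frame(x = mean(range(network$cells$x)),
             y = mean(range(network$cells$y)),
             z = z_top - spacing * (seq_len(n_contacts) - 1))
}

#' Laminar local field potentials
#'
#' Point-source forward model: each compartment's total transmembrane
#' current (axial in plus injected, i.e. all membrane currents including
#' the capacitive component) contributes `I / (4 * pi * sigma * r)` at each
#' contact.  Contacts closer to a source than `min_dist` use `min_dist`.
#'
#' @param trial A `trial_result`.
#' @param network The `column_network`.
#' @param electrodes Electrode table, see [default_electrode_array()].
#' @param sigma Extracellular conductivity, S/m.
#' @param min_dist Guard distance, um.
#' @return An `lfp_grid`: list with `time` (ms), `z` (contact depths, um),
#'   `potential` (mV, contacts x samples), `sigma`.
#' @export
compute_lfp <- function(trial, network,
                        electrodes = default_electrode_array(network),
                        sigma = 0.3, min_dist = 10) {
  if (is.null(trial$i_membrane)) stop("trial has no recorded membrane currents")
  comp <- network$flat$comp
  cells <- network$cells
  sx <- cells$x[comp$cell_id]; sy <- cells$y[comp$cell_id]; sz <- comp$z
  pot <- matrix(0, nrow(electrodes), length(trial$time))
  for (e in seq_len(nrow(electrodes))) {
    r <- sqrt((sx - electrodes$x[e])^2 + (sy - electrodes$y[e])^2 +
                (sz - electrodes$z[e])^2)
    r <- pmax(r, min_dist)
    # nA / (S/m * um) -> mV
    pot[e, ] <- as.numeric(crossprod(trial$i_membrane, 1 / r)) / (4 * pi * sigma)
  }
  structure(list(time = trial$time, z = electrodes$z, potential = pot,
                 sigma = sigma), class = "lfp_grid")
}

#' Spike raster of one or more trials
#'
#' @param trials A `trial_result` or list of them.
#' @return A `spike_raster`: data.frame with `cell_id`, `cell_class`,
#'   `time` (epoch ms) and `trial`.
#' @export
spike_raster <- function(trials) {
  if (inherits(trials, "trial_result")) trials <- list(trials)
  out <- do.call(rbind, lapply(seq_along(trials), function(k) {
    sp <- trials[[k]]$spikes
    if (nrow(sp) == 0) return(NULL)
    cbind(sp, trial = k)
  }))
  if (is.null(out))
    out <- data.frame(cell_id = integer(), time = numeric(),
                      cell_class = character(), trial = integer())
  class(out) <- c("spike_raster", "data.frame")
  out
}

#' Per-class spike counts and burst tallies
#'
#' A burst is a run of >= 2 spikes of one cell (within one trial) with
#' inter-spike intervals below `burst_isi`.
#'
#' @param raster A [spike_raster()].
#' @param window `c(t0, t1)` epoch window, ms.
#' @param burst_isi Maximum intra-burst inter-spike interval, ms.
#' @return Data frame per cell class: `n_spikes`, `n_cells_active`,
#'   `n_bursts`.
#' @export
spike_stats <- function(raster, window = c(100, 300), burst_isi = 30) {
  classes <- c("L23_PN", "L5_PN", "L23_basket", "L5_basket")
  sub <- raster[raster$time >= window[1] & raster$time <= window[2], ,
                drop = FALSE]
  stats <- lapply(classes, function(cl) {
    s <- sub[sub$cell_class == cl, , drop = FALSE]
    n_bursts <- 0L
    if (nrow(s) > 1) {
      for (grp in split(s$time, paste(s$trial, s$cell_id))) {
        grp <- sort(grp)
        in_burst <- FALSE
        for (i in seq_along(grp)[-1]) {
          if (grp[i] - grp[i - 1] <= burst_isi) {
            if (!in_burst) n_bursts <- n_bursts + 1L
            in_burst <- TRUE
          } else in_burst <- FALSE
        }
      }
    }
    data.frame(cell_class = cl, n_spikes = nrow(s),
               n_cells_active = length(unique(s$cell_id)),
               n_bursts = n_bursts)
  })
  do.call(rbind, stats)
}
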