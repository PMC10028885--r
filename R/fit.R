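.wave_time <- function(x) if (inherits(x, "dipole_trace")) x$time else x$time
.wave_amp <- function(x) if (inherits(x, "dipole_trace")) x$total else x$amplitude

#' Root mean-squared error between a simulated and a target waveform
#'
#' The simulated trace is resampled (linear interpolation) onto the target
#' grid restricted to `window`; the RMSE is taken over those samples, in
#' nAm.
#'
#' @param sim A `dipole_trace` (or `target_waveform`).
#' @param target A `target_waveform`.
#' @param window `c(t0, t1)` comparison window, epoch ms.
#' @return RMSE, nAm.
#' @export
rmse <- function(sim, target, window = c(0, 450)) {
  ts <- .wave_time(sim); as_ <- .wave_amp(sim)
  tt <- .wave_time(target); at <- .wave_amp(target)
  keep <- tt >= max(window[1], min(ts)) & tt <= min(window[2], max(ts))
  if (!any(keep)) stop("simulated and target waveforms have disjoint support")
  sim_on_t <- stats::approx(ts, as_, xout = tt[keep])$y
  sqrt(mean((sim_on_t - at[keep])^2))
}

#' Difference waveform (detected minus undetected)
#'
#' @param detected,undetected Waveforms on a common time grid
#'   (`dipole_trace` or `target_waveform`).
#' @return A [target_waveform()] with condition `"difference"`.
#' @export
difference_waveform <- function(detected, undetected) {
  td <- .wave_time(detected); tu <- .wave_time(undetected)
  if (length(td) != length(tu) || any(abs(td - tu) > 1e-9))
    stop("waveforms are not on a common time grid")
  target_waveform(td, .wave_amp(detected) - .wave_amp(undetected),
                  "difference")
}

# apply free parameters to a variant's drive list for one condition
.apply_params <- function(drives, params) {
  for (p in params) {
    d <- drives[[p$drive]]
    if (p$param == "mean_time") d$mean_time <- p$value
    else if (p$param == "sd_time") d$sd_time <- max(p$value, 0)
    else if (p$param == "wscale") d$weights <- d$weights * p$value
    else stop("unknown drive parameter: ", p$param)
    drives[[p$drive]] <- d
  }
  drives
}

.free_params <- function(bounds) {
  out <- list()
  for (dn in names(bounds))
    for (pn in names(bounds[[dn]])) {
      b <- bounds[[dn]][[pn]]
      out[[length(out) + 1]] <- list(drive = dn, param = pn,
                                     lo = b[1], hi = b[2],
                                     value = if (pn == "wscale") 1 else NA)
    }
  out
}

#' Fit drive parameters to a target waveform
#'
#' Derivative-free, seeded coordinate pattern search over the non-frozen
#' drive parameters (start-time mean, start-time sd, and a multiplicative
#' weight scale per drive).  Every objective evaluation simulates
#' `config$n_trials` trials with the same trial seeds (common random
#' numbers), averages the dipole and computes the RMSE against the target
#' over `window`, so the objective is deterministic given `seed`.  Frozen
#' drives are never touched.
#'
#' @param variant A [build_variant()] result.
#' @param condition `"detected"` or `"undetected"`.
#' @param target A `target_waveform`.
#' @param bounds Named list: `bounds[[drive]][[param]] = c(lo, hi)` with
#'   `param` one of `"mean_time"`, `"sd_time"`, `"wscale"`.  Start values
#'   are the variant's drive values (`wscale` starts at 1).  Drives listed
#'   here must not be frozen for this condition.
#' @param budget Maximum objective evaluations beyond the initial one.
#' @param seed Base seed for the trial batch of every evaluation.
#' @param config A [simulation_config()]; `n_trials` controls the per-
#'   evaluation trial count.
#' @param window RMSE window, epoch ms.
#' @param scale Dipole scale factor.
#' @return A `fit_result`: final `drives`, `params`, `rmse`, best-so-far
#'   `trace`, evaluation count, seed and window.
#' @export
optimize_drives <- function(variant, condition, target, bounds, budget = 40,
                            seed = 1, config = simulation_config(n_trials = 3),
                            window = c(0, 450), scale = 300) {
  if (budget < 1 && budget != 0) stop("budget must be >= 0")
  frozen <- variant$frozen[[condition]]
  if (any(names(bounds) %in% frozen))
    stop("bounds refer to frozen drive(s): ",
         paste(intersect(names(bounds), frozen), collapse = ", "))
  drives0 <- variant$drives[[condition]]
  names(drives0) <- vapply(drives0, `[[`, character(1), "name")
  if (!all(names(bounds) %in% names(drives0)))
    stop("bounds refer to unknown drive(s)")
  params <- .free_params(bounds)
  for (i in seq_along(params))
    if (is.na(params[[i]]$value))
      params[[i]]$value <- drives0[[params[[i]]$drive]][[params[[i]]$param]]

  conn <- default_local_connectivity()
  if (variant$connectivity_factor != 1)
    conn <- apply_perisomatic_modification(conn, variant$connectivity_factor)
  net0 <- build_column(seed = 0, scale = scale, connectivity = conn)
  cfg <- config
  cfg$base_seed <- as.integer(seed)

  evaluate <- function(params) {
    net <- net0
    for (d in .apply_params(drives0, params)) net <- attach_drive(net, d)
    dip <- simulate_dipole(net, cfg)
    rmse(dip, target, window)
  }

  n_eval <- 1L
  best <- evaluate(params)
  trace <- best
  best_params <- params
  step <- vapply(params, function(p) 0.25 * (p$hi - p$lo), numeric(1))
  pass <- 0L
  while (n_eval <= budget && length(params) > 0) {
    pass <- pass + 1L
    improved <- FALSE
    for (i in seq_along(best_params)) {
      for (dir in c(1, -1)) {
        if (n_eval > budget) break
        cand <- best_params
        v <- cand[[i]]$value + dir * step[i]
        v <- min(max(v, cand[[i]]$lo), cand[[i]]$hi)
        if (v == cand[[i]]$value) next
        cand[[i]]$value <- v
        r <- evaluate(cand)
        n_eval <- n_eval + 1L
        if (r < best) {
          best <- r
          best_params <- cand
          improved <- TRUE
        }
        trace <- c(trace, best)
      }
    }
    if (!improved) {
      step <- step / 2
      if (all(step < 1e-3)) break
    }
  }

  structure(list(variant = variant$name, condition = condition,
                 drives = .apply_params(drives0, best_params),
                 params = best_params, rmse = best, trace = trace,
                 n_eval = n_eval, seed = seed, window = window),
            class = "fit_result")
}

#' Compare model variants on target waveforms
#'
#' Fits each variant to the undetected target, then (with the variant's
#' frozen drives untouched) to the detected target, and tabulates
#' per-condition RMSE, layer-V pyramidal spiking in the 100-300 ms window
#' of the detected fit, and two qualitative flags: `early_n1` (the
#' undetected fit shows a negative deflection between 80 and 120 ms) and
#' `aan` (the fitted detected-minus-undetected difference is predominantly
#' negative over 100-300 ms).
#'
#' @param variants List of [build_variant()] results.
#' @param targets List with `undetected` and `detected` target waveforms.
#' @param config A [simulation_config()] used for the final evaluation
#'   batches.
#' @param bounds_fn Function `(variant, condition) -> bounds` for
#'   [optimize_drives()]; the default optimizes a weight scale for each
#'   non-frozen drive.
#' @param budget Optimization budget per variant and condition (0 uses the
#'   shipped calibrated parameters as-is).
#' @param seed Seed passed to every fit.
#' @param window RMSE window.
#' @param scale Dipole scale factor.
#' @return A `model_comparison` data frame, one row per variant.
#' @export
compare_models <- function(variants, targets,
                           config = simulation_config(n_trials = 3),
                           bounds_fn = default_bounds, budget = 0, seed = 1,
                           window = c(0, 450), scale = 300) {
  rows <- lapply(variants, function(v) {
    fits <- lapply(c(undetected = "undetected", detected = "detected"),
                   function(cond) {
                     b <- if (budget > 0) bounds_fn(v, cond) else list()
                     optimize_drives(v, cond, targets[[cond]], b,
                                     budget = budget, seed = seed,
                                     config = config, window = window,
                                     scale = scale)
                   })
    waves <- lapply(fits, function(f) {
      net <- .network_with_drives(v, f$drives, scale)
      simulate_dipole(net, within_seed_config(config, seed))
    })
    batch_det <- attr(waves$detected, "batch")
    stats <- spike_stats(spike_raster(batch_det), window = c(100, 300))
    l5 <- stats[stats$cell_class == "L5_PN", ]
    u <- waves$undetected
    early <- u$total[u$time >= 80 & u$time <= 120]
    p1 <- max(u$total[u$time >= 30 & u$time <= 70])
    diff_w <- difference_waveform(waves$detected, waves$undetected)
    dmask <- diff_w$time >= 100 & diff_w$time <= 300
    data.frame(variant = v$name,
               rmse_undetected = fits$undetected$rmse,
               rmse_detected = fits$detected$rmse,
               l5_spikes_100_300 = l5$n_spikes / config$n_trials,
               l5_bursts_100_300 = l5$n_bursts / config$n_trials,
               early_n1 = min(early) < -0.5 * p1,
               aan = mean(diff_w$amplitude[dmask]) < 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Default optimization bounds
#'
#' A weight-scale interval for every non-frozen drive of the variant.
#'
#' @param variant A [build_variant()] result.
#' @param condition Condition name.
#' @return Bounds list for [optimize_drives()].
#' @export
default_bounds <- function(variant, condition) {
  drives <- variant$drives[[condition]]
  nms <- setdiff(vapply(drives, `[[`, character(1), "name"),
                 variant$frozen[[condition]])
  stats::setNames(lapply(nms, function(n) list(wscale = c(0.25, 4))), nms)
}

.network_with_drives <- function(variant, drives, scale) {
  conn <- default_local_connectivity()
  if (variant$connectivity_factor != 1)
    conn <- apply_perisomatic_modification(conn, variant$connectivity_factor)
  net <- build_column(seed = 0, scale = scale, connectivity = conn)
  for (d in drives) net <- attach_drive(net, d)
  net
}

within_seed_config <- function(config, seed) {
  config$base_seed <- as.integer(seed)
  config
}
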