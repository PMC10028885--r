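test_that("RMSE matches hand-computed values", {
  t3 <- c(0, 1, 2)
  tw <- function(a) target_waveform(t3, a, "undetected")
  expect_equal(rmse(tw(c(1, 2, 3)), tw(c(1, 2, 3)), c(0, 2)), 0)
  expect_equal(rmse(tw(c(1, 2, 3) + 4), tw(c(1, 2, 3)), c(0, 2)), 4)
  expect_equal(rmse(tw(c(3, 4, 0)), tw(c(0, 0, 0)), c(0, 2)),
               sqrt(25 / 3), tolerance = 1e-12)
  expect_error(rmse(tw(c(1, 2, 3)),
                    target_waveform(c(900, 901, 902), c(0, 0, 0), "u"),
                    c(0, 2)), "disjoint")
})

test_that("difference waveforms subtract pointwise on a common grid", {
  tg <- generate_targets(erf_component_set(noise_amp = 0))
  d <- difference_waveform(tg$detected, tg$undetected)
  expect_identical(attr(d, "condition"), "difference")
  expect_equal(difference_waveform(tg$detected, tg$detected)$amplitude,
               rep(0, 250))
  shifted <- target_waveform(tg$detected$time + 1, tg$detected$amplitude, "d")
  expect_error(difference_waveform(shifted, tg$undetected), "common time grid")
})

test_that("variants carry the study's drive timings and circuit modifiers", {
  pref <- build_variant("preferred")
  u <- pref$drives$undetected
  expect_length(u, 2)
  expect_equal(vapply(u, `[[`, numeric(1), "mean_time"), c(47.8, 84.3))
  expect_equal(vapply(u, `[[`, numeric(1), "sd_time"), c(13.2, 15.1))
  d <- pref$drives$detected
  expect_length(d, 3)
  expect_equal(d[[3]]$mean_time, 169.3)
  expect_equal(d[[3]]$sd_time, 50.4)
  expect_equal(d[[3]]$kind, "distal")
  expect_identical(pref$frozen$detected, c("prox1", "dist1"))
  # the first two detected drives equal the undetected drives
  expect_identical(d[[1]], u[[1]])
  expect_identical(d[[2]], u[[2]])

  peri <- build_variant("perisomatic_inhibition")
  expect_equal(peri$connectivity_factor, 2)
  expect_equal(vapply(peri$drives$detected, `[[`, numeric(1), "mean_time"),
               c(36, 84.3, 169.3))
  expect_equal(peri$drives$undetected[[1]]$sd_time, 25)
  net <- variant_network(peri, "detected")
  hit <- net$connectivity$src_class == "L5_basket" &
    net$connectivity$tgt_class == "L5_PN" &
    net$connectivity$tgt_comp == "soma" & net$connectivity$receptor == "gabab"
  expect_equal(net$connectivity$weight[hit], 0.05)

  red <- build_variant("reduced")
  expect_length(red$drives$undetected, 1)
  expect_equal(red$drives$undetected[[1]]$kind, "proximal")
  expect_equal(red$drives$undetected[[1]]$sd_time, 13.3)
  expect_equal(red$drives$detected[[2]]$mean_time, 154)

  pdp <- build_variant("prox_dist_prox")
  expect_identical(red$drives$undetected, pdp$drives$undetected)
  expect_equal(pdp$drives$detected[[3]]$mean_time, 395.4)
  expect_equal(pdp$drives$detected[[3]]$kind, "proximal")
  expect_error(build_variant("no_such_model"))
})

test_that("optimization respects the budget, freezes and monotone record", {
  v <- build_variant("preferred")
  tg <- generate_targets(erf_component_set(noise_amp = 0))
  cfg <- simulation_config(n_trials = 1, base_seed = 1)
  # bounds on frozen drives are rejected
  expect_error(optimize_drives(v, "detected", tg$detected,
                               list(prox1 = list(mean_time = c(30, 60))),
                               budget = 1, config = cfg),
               "frozen")
  # budget 0: the fit equals the initial evaluation
  f0 <- optimize_drives(v, "detected", tg$detected,
                        list(dist2 = list(wscale = c(0.5, 2))),
                        budget = 0, seed = 1, config = cfg)
  expect_identical(f0$n_eval, 1L)
  expect_length(f0$trace, 1)
  # small real fit: best-so-far RMSE non-increasing, frozen drives bitwise
  f <- optimize_drives(v, "detected", tg$detected,
                       list(dist2 = list(wscale = c(0.5, 2))),
                       budget = 4, seed = 1, config = cfg)
  expect_true(all(diff(f$trace) <= 0))
  expect_lte(f$rmse, f0$rmse)
  expect_identical(f$drives$prox1, v$drives$detected[[1]])
  expect_identical(f$drives$dist1, v$drives$detected[[2]])
})

test_that("the shipped model configuration round-trips through YAML", {
  cfg <- default_model_config()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_model_config(cfg, path)
  expect_identical(read_model_config(path), cfg)
  expect_setequal(names(cfg$variants),
                  c("preferred", "perisomatic_inhibition", "reduced",
                    "prox_dist_prox"))
})

test_that("network specifications round-trip through the YAML config", {
  net <- build_default_column(seed = 2, scale = 300)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_network_config(net, path)
  back <- build_column_from_config(path)
  expect_identical(cell_counts(back), cell_counts(net))
  expect_identical(back$flat$comp, net$flat$comp)
  expect_identical(back$scale, net$scale)
})
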