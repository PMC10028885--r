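test_that("synthetic targets have the canonical evoked morphology", {
  spec <- erf_component_set(noise_amp = 0)
  tg <- generate_targets(spec)
  u <- tg$undetected; d <- tg$detected
  expect_equal(nrow(u), 250)                       # 500 ms at 500 Hz
  expect_equal(u$time[1], -50)
  expect_equal(diff(u$time)[1], 2)
  # positive extremum in 40-60 ms, negative in 90-110 ms
  w1 <- u$amplitude[u$time >= 40 & u$time <= 60]
  w2 <- u$amplitude[u$time >= 90 & u$time <= 110]
  expect_gt(w1[which.max(abs(w1))], 0)
  expect_lt(w2[which.max(abs(w2))], 0)
  # difference recovers the awareness component exactly (zero noise)
  diff_w <- difference_waveform(d, u)
  expect_lt(max(abs(diff_w$amplitude -
                      spec$aan$amp * exp(-(diff_w$time - spec$aan$lat)^2 /
                                           (2 * spec$aan$width^2)))), 1e-12)
  ext <- diff_w$time[which.max(abs(diff_w$amplitude))]
  expect_equal(ext, 180)
  expect_lt(min(diff_w$amplitude), 0)
  # null awareness component: conditions identical
  tg0 <- generate_targets(erf_component_set(noise_amp = 0,
                                            aan = list(amp = 0, lat = 180, width = 50)))
  expect_equal(tg0$detected$amplitude, tg0$undetected$amplitude)
})

test_that("target generation with noise is seed-reproducible", {
  a <- generate_targets(erf_component_set(noise_amp = 2, seed = 9))
  b <- generate_targets(erf_component_set(noise_amp = 2, seed = 9))
  c <- generate_targets(erf_component_set(noise_amp = 2, seed = 10))
  expect_identical(a$detected$amplitude, b$detected$amplitude)
  expect_false(identical(a$detected$amplitude, c$detected$amplitude))
})

test_that("oddball sequences have ten evenly spaced tones and one deviant", {
  tls <- generate_oddball(seed = 4, n_sequences = 40)
  expect_length(tls, 40)
  for (tl in tls[1:5]) {
    expect_length(tl$onsets, 10)
    expect_equal(unique(diff(tl$onsets)), 0.5)
    expect_equal(tl$tone_duration, 100)
    expect_true(tl$deviant_index %in% 1:10)
  }
  expect_identical(generate_oddball(seed = 4, n_sequences = 40), tls)
  # deviant positions roughly uniform (loose chi-square sanity)
  dev <- vapply(generate_oddball(2, 400), `[[`, numeric(1), "deviant_index")
  expect_gt(chisq.test(table(factor(dev, levels = 1:10)))$p.value, 1e-4)
})

test_that("press-relative binning matches the worked example and its limits", {
  tl <- structure(list(onsets = seq(0, 4.5, by = 0.5), tone_duration = 100,
                       soa = 500, deviant_index = 5, sequence_length = 5,
                       press_time = 2.7), class = "oddball_timeline")
  b <- bin_tones(tl)
  expect_equal(sort(b$detected), c(1.5, 2.5, 3.0, 3.5, 4.0, 4.5))
  expect_equal(sort(b$undetected), c(0, 0.5, 1.0))
  # no press: everything undetected
  tl$press_time <- NA_real_
  b0 <- bin_tones(tl)
  expect_length(b0$detected, 0)
  expect_length(b0$undetected, 9)
  # press before the tones: everything detected
  tl$press_time <- -0.1
  b1 <- bin_tones(tl)
  expect_length(b1$undetected, 0)
  expect_length(b1$detected, 9)
})

test_that("binning partitions the standards on 1000 random timelines", {
  tls <- generate_oddball(seed = 123, n_sequences = 1000, p_detect = 0.6)
  for (tl in tls) {
    b <- bin_tones(tl)
    std <- tl$onsets[-tl$deviant_index]
    expect_setequal(c(b$detected, b$undetected), std)
    expect_length(intersect(b$detected, b$undetected), 0)
    expect_false(tl$onsets[tl$deviant_index] %in% c(b$detected, b$undetected))
  }
})

test_that("epoching yields fixed 250-sample segments and drops edge onsets", {
  t_cont <- seq(0, 10000, by = 2)                   # 10 s at 500 Hz
  x <- sin(t_cont / 500)
  ep <- epoch_trace(t_cont, x, onsets = 1000)
  expect_length(ep, 1)
  expect_equal(nrow(ep[[1]]), 250)
  expect_equal(ep[[1]]$time[1], -50)
  expect_length(epoch_trace(t_cont, x, onsets = numeric(0)), 0)
  # two onsets one SOA apart: identical relative grids
  ep2 <- epoch_trace(t_cont, x, onsets = c(1000, 1500))
  expect_identical(ep2[[1]]$time, ep2[[2]]$time)
  expect_warning(epoch_trace(t_cont, x, onsets = 20), "dropped")
})

test_that("waveforms round-trip through the two-column text format", {
  tg <- generate_targets(erf_component_set(seed = 2))$detected
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_waveform(tg, path)
  back <- read_waveform(path, condition = "detected")
  expect_equal(back$time, tg$time)
  expect_equal(back$amplitude, tg$amplitude, tolerance = 1e-12)
})
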