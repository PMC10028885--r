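test_that("the dipole is the axial-current-weighted sum of vertical extents", {
  net <- tiny_column()
  conn <- net$flat$conn[net$flat$conn$is_pn, ]
  # fabricated trial: steady 1 nA flowing up one L5 trunk segment
  k <- which(net$cells$cell_class[conn$cell_id] == "L5_PN" &
               abs(conn$dz - 417.5) < 1)[1]
  i_ax <- matrix(0, nrow(conn), 3)
  i_ax[k, ] <- 1
  trial <- structure(list(time = c(0, 1, 2), i_axial = i_ax, conn = conn),
                     class = "trial_result")
  dip <- compute_dipole(trial, net)
  expect_equal(dip$total, rep(1 * 417.5 * 1e-6, 3))   # nA * um -> nAm
  expect_equal(dip$L23, rep(0, 3))
  expect_equal(dip$L5, dip$total)
})

test_that("laminar components sum to the total on real trials", {
  net <- preferred_network("detected", scale = 1)
  batch <- run_batch(net, simulation_config(n_trials = 2, base_seed = 1))
  for (tr in batch) {
    d <- compute_dipole(tr, net)
    expect_equal(d$L23 + d$L5, d$total, tolerance = 1e-9)
    parts <- decompose_by_layer(tr, net)
    expect_identical(parts$L23, d$L23)
  }
})

test_that("averaging, scaling and smoothing behave as documented", {
  tr <- list(time = 0:100, total = rep(2, 101), L23 = rep(1.5, 101),
             L5 = rep(0.5, 101))
  class(tr) <- "dipole_trace"
  # identical traces: average equals input, then scaled; DC passes the window
  avg <- average_scale_smooth(list(tr, tr), scale = 300, smooth_window = 30)
  expect_equal(avg$total, rep(600, 101))
  # identity settings: pure mean
  tr2 <- tr; tr2$total <- tr$total + 2
  avg2 <- average_scale_smooth(list(tr, tr2), scale = 1, smooth_window = 0)
  expect_equal(avg2$total, rep(3, 101))
  # baseline subtraction
  avg3 <- average_scale_smooth(list(tr), scale = 1, smooth_window = 0,
                               baseline = c(0, 100))
  expect_equal(avg3$total, rep(0, 101))
  expect_error(average_scale_smooth(list()), "no dipole traces")
})

test_that("sign conventions: proximal drives up, distal drives down", {
  net <- build_default_column()
  cfg <- simulation_config(n_trials = 1, base_seed = 2)
  deflect <- function(kind) {
    d <- evoked_drive("x", kind, 60, 5, n_spikes = 1,
                      weights = c(L23_PN_ampa = 0.005, L5_PN_ampa = 0.005))
    dip <- simulate_dipole(attach_drive(net, d), cfg, use_local = FALSE)
    dip$total[which.max(abs(dip$total))]
  }
  expect_gt(deflect("proximal"), 0)
  expect_lt(deflect("distal"), 0)
})

test_that("LFP follows the closed-form point-source potential", {
  net <- tiny_column()
  comp <- net$flat$comp
  i <- comp_id_of(net, "L5_PN", "soma")
  trial <- structure(list(time = 0:2,
                          i_membrane = matrix(0, nrow(comp), 3)),
                     class = "trial_result")
  trial$i_membrane[i, ] <- 2                       # 2 nA point source
  sx <- net$cells$x[comp$cell_id[i]]; sy <- net$cells$y[comp$cell_id[i]]
  el <- data.frame(x = sx, y = sy, z = comp$z[i] + 250)
  lfp <- compute_lfp(trial, net, electrodes = el, sigma = 0.3)
  expect_equal(lfp$potential[1, ], rep(2 / (4 * pi * 0.3 * 250), 3),
               tolerance = 1e-12)
  # conductivity scaling
  lfp2 <- compute_lfp(trial, net, electrodes = el, sigma = 0.6)
  expect_equal(lfp2$potential, lfp$potential / 2, tolerance = 1e-12)
  # linearity over sources
  trialA <- trial; trialA$i_membrane[,] <- 0; trialA$i_membrane[1, ] <- 1
  trialB <- trial; trialB$i_membrane[,] <- 0; trialB$i_membrane[4, ] <- 3
  trialAB <- trial; trialAB$i_membrane[,] <- 0
  trialAB$i_membrane[1, ] <- 1; trialAB$i_membrane[4, ] <- 3
  grid <- default_electrode_array(net)
  expect_equal(nrow(grid), 50)
  expect_equal(unique(round(diff(grid$z))), -100)
  pAB <- compute_lfp(trialAB, net, grid)$potential
  expect_equal(pAB, compute_lfp(trialA, net, grid)$potential +
                 compute_lfp(trialB, net, grid)$potential, tolerance = 1e-12)
  # resting trial: zero potentials everywhere
  tr0 <- integrate_trial(net, probe_config(duration = 50), 1)
  expect_lt(max(abs(compute_lfp(tr0, net, grid)$potential)), 1e-6)
})

test_that("spike statistics count spikes and bursts by the stated rule", {
  r <- data.frame(cell_id = c(7L, 7L, 7L, 9L), cell_class = "L5_PN",
                  time = c(180, 190, 200, 50), trial = 1L)
  class(r) <- c("spike_raster", "data.frame")
  st <- spike_stats(r, window = c(100, 300))
  l5 <- st[st$cell_class == "L5_PN", ]
  expect_identical(l5$n_spikes, 3L)
  expect_identical(l5$n_bursts, 1L)
  expect_identical(l5$n_cells_active, 1L)
  st0 <- spike_stats(r, window = c(0, 100))
  expect_identical(st0$n_spikes[st0$cell_class == "L5_PN"], 1L)
  expect_identical(st0$n_bursts[st0$cell_class == "L5_PN"], 0L)
  # spikes > 30 ms apart are not bursts
  r2 <- r; r2$time <- c(100, 140, 180, 50)
  expect_identical(spike_stats(r2, c(0, 300))$n_bursts, rep(0L, 4))
  empty <- spike_raster(list())
  expect_identical(sum(spike_stats(empty, c(0, 450))$n_spikes), 0L)
})
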