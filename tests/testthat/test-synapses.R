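test_that("receptor kinetics satisfy the slow/fast orderings", {
  ampa <- receptor_kinetics("ampa"); nmda <- receptor_kinetics("nmda")
  gabaa <- receptor_kinetics("gabaa"); gabab <- receptor_kinetics("gabab")
  for (k in list(ampa, nmda, gabaa, gabab))
    expect_gt(k$tau_decay, k$tau_rise)
  expect_gt(nmda$tau_decay, ampa$tau_decay)
  expect_gt(gabab$tau_decay, gabaa$tau_decay)
  expect_true(nmda$voltage_dependent)
  expect_false(ampa$voltage_dependent)
})

test_that("double-exponential conductance peaks at 1 and superposes linearly", {
  ampa <- receptor_kinetics("ampa")
  expect_identical(receptor_conductance(ampa, numeric(0), c(0, 10)), c(0, 0))
  expect_identical(receptor_conductance(ampa, 10, 10), 0)  # onset
  tp <- with(ampa, tau_rise * tau_decay / (tau_decay - tau_rise) *
               log(tau_decay / tau_rise))
  expect_equal(receptor_conductance(ampa, 10, 10 + tp), 1, tolerance = 1e-12)
  expect_lt(receptor_conductance(ampa, 10, 10 + 5 * tp), 1)
  # superposition: two events equal the sum of single events
  tt <- seq(0, 60, by = 0.1)
  g2 <- receptor_conductance(ampa, c(10, 18), tt)
  expect_equal(g2, receptor_conductance(ampa, 10, tt) +
                 receptor_conductance(ampa, 18, tt), tolerance = 1e-12)
  # slow GABA-B outlasts GABA-A
  gabaa <- receptor_kinetics("gabaa"); gabab <- receptor_kinetics("gabab")
  lag <- 10 + 5 * gabaa$tau_decay
  expect_gt(receptor_conductance(gabab, 10, lag),
            receptor_conductance(gabaa, 10, lag))
})

test_that("NMDA magnesium block has the documented limits and midrange value", {
  expect_equal(nmda_block(100), 1, tolerance = 2e-3)
  expect_lt(nmda_block(-100), 1e-2)
  expect_lt(nmda_block(-65), 0.5)
  # frozen from direct evaluation of 1 / (1 + 0.28 exp(-0.062 V)) at -65 mV
  expect_equal(nmda_block(-65), 0.0596906, tolerance = 1e-6)
  v <- seq(-100, 60, by = 1)
  expect_true(all(diff(nmda_block(v)) > 0))
})

test_that("perisomatic modification doubles only the L5 somatic GABA-B weight", {
  conn <- default_local_connectivity()
  hit <- conn$src_class == "L5_basket" & conn$tgt_class == "L5_PN" &
    conn$tgt_comp == "soma" & conn$receptor == "gabab"
  expect_equal(conn$weight[hit], 0.025)
  mod <- apply_perisomatic_modification(conn, 2)
  expect_equal(mod$weight[hit], 0.05)
  expect_identical(mod$weight[!hit], conn$weight[!hit])
  expect_identical(apply_perisomatic_modification(conn, 1), conn)
  expect_error(apply_perisomatic_modification(conn[!hit, ], 2), "GABA-B")
})

test_that("PN-to-PN connectivity entries exist for all class pairs", {
  conn <- default_local_connectivity()
  pn <- c("L23_PN", "L5_PN")
  for (src in pn) for (tgt in pn)
    expect_true(any(conn$src_class == src & conn$tgt_class == tgt &
                      conn$weight > 0))
  # basket -> PN somatic inhibition through both receptor types
  for (lay in c("L23", "L5"))
    for (rec in c("gabaa", "gabab"))
      expect_true(any(conn$src_class == paste0(lay, "_basket") &
                        conn$tgt_class == paste0(lay, "_PN") &
                        conn$tgt_comp == "soma" & conn$receptor == rec))
})

test_that("drive spike sampling is Gaussian, truncated and reproducible", {
  d <- evoked_drive("p", "proximal", 47.8, 13.2, n_spikes = 1,
                    weights = c(L23_PN_ampa = 0.01), seed = 3)
  sp <- sample_drive_spikes(d, 10000, trial_seed = 1)
  x <- unlist(sp)
  expect_length(x, 10000)
  se <- 13.2 / sqrt(10000)
  expect_lt(abs(mean(x) - 47.8), 3 * se)
  expect_lt(abs(sd(x) - 13.2) / 13.2, 0.05)
  expect_true(all(x >= 0))
  expect_identical(sp, sample_drive_spikes(d, 10000, trial_seed = 1))
  expect_false(identical(sp, sample_drive_spikes(d, 10000, trial_seed = 2)))
  # degenerate sd: all events at the mean
  d0 <- evoked_drive("p", "proximal", 30, 0, n_spikes = 3,
                     weights = c(L23_PN_ampa = 0.01))
  expect_true(all(unlist(sample_drive_spikes(d0, 5, 1)) == 30))
})

test_that("drive targeting is exclusive to the mandated compartments", {
  net <- build_default_column()
  prox <- drive_targets(net, "proximal")
  expect_setequal(unique(prox$comp_name[grepl("PN", prox$cell_class)]),
                  c("basal", "oblique"))
  expect_true(all(c("L23_basket", "L5_basket") %in% prox$cell_class))
  dist <- drive_targets(net, "distal")
  expect_setequal(unique(dist$comp_name[grepl("PN", dist$cell_class)]),
                  "apical_tuft")
  expect_true("L23_basket" %in% dist$cell_class)
  expect_false("L5_basket" %in% dist$cell_class)
  # a distal drive cannot weight L5 baskets
  expect_error(evoked_drive("d", "distal", 80, 10,
                            weights = c(L5_basket_ampa = 0.01)),
               "invalid drive weight")
  # zero weights create no synapses
  d0 <- evoked_drive("d", "distal", 80, 10,
                     weights = c(L23_PN_ampa = 0, L5_PN_ampa = 0))
  expect_null(aancolumn:::.drive_synapses(net, d0)$syn)
})

test_that("proximal input depolarizes basal dendrites first, distal the tufts", {
  net <- tiny_column()
  cfg <- probe_config(duration = 150, record_v = TRUE, record_dt = 0.25)
  first_comp <- function(kind) {
    # weights weak enough that no cell fires: deviations spread passively
    d <- evoked_drive("x", kind, 50, 0, n_spikes = 1,
                      weights = c(L23_PN_ampa = 0.002, L5_PN_ampa = 0.002))
    tr <- integrate_trial(attach_drive(net, d), cfg, 1, use_local = FALSE)
    dev <- abs(tr$v - net$flat$comp$v0) > 1
    hit <- which(rowSums(dev) > 0)
    first <- hit[which.min(apply(dev[hit, , drop = FALSE], 1,
                                 function(z) which(z)[1]))]
    net$flat$comp$name[first]
  }
  expect_true(first_comp("proximal") %in% c("basal", "oblique"))
  expect_identical(first_comp("distal"), "apical_tuft")
})
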