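test_that("bead topologies have the documented connectivity", {
  wt <- wt_spec()
  par <- energy_params()
  mono <- build_monomer_topology(wt, par)
  expect_equal(nrow(mono$beads), 140L)
  expect_equal(nrow(mono$bonds), 139L)
  expect_equal(sum(!mono$beads$flexible), 0L)
  expect_equal(nrow(mono$sites), nrow(enumerate_all_titratable(wt)))
  # bonds connect consecutive residues only
  expect_true(all(abs(mono$bonds[, 1] - mono$bonds[, 2]) == 1L))

  fib10 <- build_fibril_topology(wt, synthetic_fibril(wt, n_planes = 10),
                                 par, seed = 2)
  expect_equal(nrow(fib10$beads), 1400L)
  expect_equal(sum(!fib10$beads$flexible), 720L)
  # 28 N-tail bonds (incl. graft 28-29) + 40 C-tail bonds (incl. 100-101)
  expect_equal(nrow(fib10$bonds), 10L * (28L + 40L))
  # initial conformation is clash-free
  xyz <- as.matrix(fib10$beads[, c("x", "y", "z")])
  expect_gte(min(dist(xyz)), 3.0)
  # rigid beads are exactly the core residues
  expect_true(all(fib10$beads$position[!fib10$beads$flexible] %in% 29:100))
})

test_that("pair energies define the Bjerrum length and Debye screening", {
  p_unscreened <- energy_params(ionic_strength = 0, lj_epsilon = 0)
  expect_equal(pair_energy(1, 1, 7, p_unscreened), 1.0)
  expect_equal(debye_length(5e-4), 136, tolerance = 0.02)
  expect_equal(debye_length(0.015), 3.04 / sqrt(0.015), tolerance = 0.02)
  expect_equal(debye_length(0), Inf)
  # neutral bead: pure Lennard-Jones, zero at r = sigma, minimum at 2^(1/6) sigma
  p <- energy_params()
  expect_equal(pair_energy(0, 1, 7, p), 0)
  expect_equal(pair_energy(0, 0, 7 * 2^(1 / 6), p), -p$lj_epsilon)
  # screening reduces the interaction
  expect_lt(pair_energy(1, 1, 50, energy_params(ionic_strength = 0.015,
                                                lj_epsilon = 0)),
            pair_energy(1, 1, 50, p_unscreened))
  expect_error(pair_energy(1, 1, 0, p), "positive")
})

test_that("swap trial energies are antisymmetric around pKa0", {
  expect_equal(swap_move_energy("protonate", 5, 5), 0)
  expect_equal(swap_move_energy("deprotonate", 5.4, 4.4), -log(10),
               tolerance = 1e-12)
  # detailed balance: forward and reverse chemical terms cancel
  for (ph in c(3, 5.5, 8)) {
    expect_equal(swap_move_energy("protonate", ph, 4.4) +
                   swap_move_energy("deprotonate", ph, 4.4), 0)
  }
  expect_equal(swap_move_energy("protonate", 6, 4, du_elec = 1.5),
               log(10) * 2 + 1.5)
})

test_that("a single ideal site titrates to one half at its pKa", {
  topo <- fixed_bead_topology(matrix(0, 1, 3), "Glu", TRUE, 4.4)
  r <- run_mc(topo, energy_params(bjerrum_length = 0),
              mc_config(pH = 4.4, n_sweeps = 30000, seed = 3))
  expect_lt(abs(r$sites$mean_protonation - 0.5), 3 * r$sites$se)
  expect_lt(abs(r$sites$mean_protonation - 0.5), 0.02)
})

test_that("fixed-bead sampling matches the exact partition sum", {
  # two acids 7 A apart, unscreened, at pH = pKa0: weights {1,1,1,e^-1}
  xyz2 <- rbind(c(0, 0, 0), c(7, 0, 0))
  oracle2 <- enumeration_oracle(xyz2, c(TRUE, TRUE), c(4.4, 4.4),
                                pH = 4.4, lB = 7)
  expect_equal(sum(oracle2), 4 / (3 + exp(-1)), tolerance = 1e-12)
  topo2 <- fixed_bead_topology(xyz2, c("Glu", "Glu"), c(TRUE, TRUE),
                               c(4.4, 4.4))
  p0 <- energy_params(ionic_strength = 0, lj_epsilon = 0)
  r2 <- run_mc(topo2, p0, mc_config(pH = 4.4, n_sweeps = 60000, seed = 42))
  tot_se <- sqrt(sum(r2$sites$se^2))
  expect_lt(abs(sum(r2$sites$mean_protonation) - 1.1877), 3 * tot_se)

  # three mixed sites, screened (15 mM), off-center pH; site-wise check
  xyz3 <- rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5, 0))
  acid3 <- c(TRUE, TRUE, FALSE)
  pka3 <- c(4.0, 4.4, 6.3)
  p15 <- energy_params(ionic_strength = 0.015, lj_epsilon = 0)
  for (ph in c(4.2, 5.5)) {
    oracle3 <- enumeration_oracle(xyz3, acid3, pka3, pH = ph, lB = 7,
                                  debye = p15$debye_length)
    topo3 <- fixed_bead_topology(xyz3, c("Asp", "Glu", "His"), acid3, pka3)
    r3 <- run_mc(topo3, p15, mc_config(pH = ph, n_sweeps = 60000,
                                       seed = 11))
    dev <- abs(r3$sites$mean_protonation - oracle3)
    expect_true(all(dev < pmax(3 * r3$sites$se, 0.01)))
  }
})

test_that("runs are bit-reproducible given the seed", {
  wt <- wt_spec()
  par <- energy_params()
  topo <- build_monomer_topology(wt, par)
  cfg <- mc_config(pH = 6.5, n_sweeps = 500, seed = 99)
  r1 <- run_mc(topo, par, cfg)
  r2 <- run_mc(topo, par, cfg)
  expect_identical(r1$sites$mean_protonation, r2$sites$mean_protonation)
  expect_identical(r1$coords, r2$coords)
  expect_identical(r1$mean_energy, r2$mean_energy)
  r3 <- run_mc(topo, par, mc_config(pH = 6.5, n_sweeps = 500, seed = 100))
  expect_false(identical(r1$coords, r3$coords))
})

test_that("incremental energies agree with full recomputation", {
  wt <- wt_spec()
  par <- energy_params()
  topo <- build_monomer_topology(wt, par)
  # 100 sweeps x 140 beads = 1.4e4 move attempts
  r <- run_mc(topo, par, mc_config(pH = 6.5, n_sweeps = 100, seed = 17))
  expect_lt(abs(r$energy_running - r$energy_recomputed), 1e-8)
})

test_that("rigid core beads never move", {
  wt <- wt_spec()
  par <- energy_params()
  topo <- build_fibril_topology(wt, synthetic_fibril(wt, n_planes = 2),
                                par, seed = 4)
  r <- run_mc(topo, par, mc_config(pH = 6.5, n_sweeps = 300, seed = 5))
  rigid <- !topo$beads$flexible
  expect_identical(r$coords[rigid, ],
                   unname(as.matrix(topo$beads[rigid, c("x", "y", "z")])))
  # and at least some flexible beads did move
  expect_gt(max(abs(r$coords[!rigid, ] -
                      as.matrix(topo$beads[!rigid, c("x", "y", "z")]))), 0.1)
})

test_that("stoichiometric pKa interpolates the half-ionization point", {
  # pure interpolation case: (4.0, 0.6), (5.0, 0.4) ionization -> 4.5
  fake <- list(pH = c(4, 5), ionization = matrix(c(0.6, 0.4), nrow = 1),
               sites = NULL)
  expect_equal(stoichiometric_pka(fake)$pKa_stoich, 4.5)
  # no crossing -> NA sentinel
  flat <- list(pH = c(4, 5), ionization = matrix(c(0.8, 0.7), nrow = 1),
               sites = NULL)
  expect_true(is.na(stoichiometric_pka(flat)$pKa_stoich))
  # ideal site: MC titration scan crosses 0.5 at pKa0
  topo <- fixed_bead_topology(matrix(0, 1, 3), "Glu", TRUE, 4.4)
  scan <- titration_scan(topo, energy_params(bjerrum_length = 0),
                         seq(3.4, 5.4, 0.5),
                         mc_config(pH = 4, n_sweeps = 20000, seed = 8))
  pk <- stoichiometric_pka(scan)$pKa_stoich
  expect_lt(abs(pk - 4.4), 0.05)
})

test_that("charge-shift maps are zero for identical runs and check pH", {
  wt <- wt_spec()
  par <- energy_params()
  topo <- build_monomer_topology(wt, par)
  r1 <- run_mc(topo, par, mc_config(pH = 6.5, n_sweeps = 400, seed = 23))
  shift <- charge_shift_map(r1, r1)
  expect_true(all(shift$shift == 0))
  expect_equal(net_proton_uptake(r1, r1), 0)
  r2 <- run_mc(topo, par, mc_config(pH = 5.5, n_sweeps = 400, seed = 23))
  expect_error(charge_shift_map(r1, r2), "different pH")
})
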