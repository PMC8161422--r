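wt_experiment <- function(residual = 4e-6)
  ph_experiment(5.6, 6.5, 20e-6, residual, label = "wt")

test_that("monomer-state bookkeeping composes bound and free pools", {
  wt <- wt_spec()
  set <- assign_pkas(enumerate_acidic_sites(wt, "tail_only"))
  st <- monomer_state(set, 6.5, 20e-6)
  expect_equal(st$free, 10^(-6.5))
  expect_equal(st$bound, 15 * average_protonation(set, 6.5) * 20e-6)
  expect_equal(st$total, st$bound + st$free)
  st2 <- monomer_state(set, 5.6, 20e-6)
  expect_equal(st2$bound, 15 * 0.0715 * 2e-5, tolerance = 1e-3)
  # zero protonation collapses total onto the free pool
  hi <- monomer_state(set, 13.9, 20e-6)
  expect_equal(hi$total, hi$free, tolerance = 1e-9)
  # hydroxide term reduces the conserved free pool above neutrality
  stw <- monomer_state(set, 7.5, 20e-6, autoionization = TRUE)
  expect_equal(stw$free, 10^(-7.5) - 1e-14 / 10^(-7.5))
})

test_that("the wild-type and 5Q inferences land on the reported shifts", {
  wt <- wt_spec(); q5 <- q5_spec()
  r <- infer_fibril_pka(wt_experiment(), wt)
  expect_equal(r$n_sites, 15L)
  expect_lt(abs(r$pKa_fib - 5.4), 0.15)
  expect_lt(abs(r$delta_pKa - 1.1), 0.15)
  r5 <- infer_fibril_pka(ph_experiment(6.4, 6.6, 20e-6, label = "5Q"), q5)
  expect_equal(r5$n_sites, 10L)
  expect_lt(abs(r5$pKa_fib - 4.7), 0.15)
  expect_lt(abs(r5$delta_pKa - 0.5), 0.15)
  # headline comparison: the less acidic tail regulates less
  expect_lt(r5$delta_pKa, r$delta_pKa)
  # error contracts
  expect_error(infer_fibril_pka(ph_experiment(5.6, 6.5, 2e-5, 2e-5), wt),
               "no fibril")
  # a pH *drop* implies proton release, which the balance cannot attribute
  # to fibril uptake
  expect_error(infer_fibril_pka(ph_experiment(5.6, 4.0, 2e-5), wt),
               "infeasible")
})

test_that("proton conservation holds to machine precision", {
  wt <- wt_spec()
  for (autoion in c(FALSE, TRUE)) {
    r <- infer_fibril_pka(wt_experiment(), wt, autoionization = autoion)
    expect_equal(r$bound_fib_tot + r$free_fib, r$total_mono,
                 tolerance = 1e-15)
    expect_equal(r$total_mono, r$bound_mono + r$free_mono,
                 tolerance = 1e-15)
    expect_gt(r$bound_fib_fib, 0)
    expect_gt(r$freeP_fib_fib, 0)
    expect_gt(r$Ka_fib, 0)
  }
})

test_that("forward_ph and infer_fibril_pka are mutual inverses", {
  wt <- wt_spec()
  # uniform monomer pKa equal to the fibril pKa: chemically nothing changes
  expect_equal(forward_ph(4.5, set = assign_pkas(
    enumerate_acidic_sites(wt, "tail_only"), 4.5),
    C_total = 20e-6, C_residual_mono = 5e-6, pH_mono = 5.6), 5.6,
    tolerance = 1e-8)
  # proton uptake raises the pH whenever the fibril pKa is upshifted
  for (pk in c(4.8, 5.2, 5.8)) {
    ph <- forward_ph(pk, wt, C_total = 20e-6, C_residual_mono = 4e-6,
                     pH_mono = 5.6)
    expect_gt(ph, 5.6)
  }
  # inverse of the reported configuration
  expect_lt(abs(forward_ph(5.5264, wt, C_total = 20e-6,
                           C_residual_mono = 4e-6, pH_mono = 5.6) - 6.5),
            0.01)
  # round trips at several pKa values and conventions
  for (conv in c("at_pH_fib", "at_pH_mono")) {
    for (pk_true in c(4.8, 5.4, 6.0)) {
      ph_fib <- forward_ph(pk_true, wt, C_total = 20e-6,
                           C_residual_mono = 4e-6, pH_mono = 5.6,
                           qave_convention = conv)
      r <- infer_fibril_pka(ph_experiment(5.6, ph_fib, 20e-6, 4e-6), wt,
                            qave_convention = conv)
      expect_lt(abs(r$pKa_fib - pk_true), 1e-6)
    }
  }
})

test_that("the inference is robust to the residual-monomer assumption", {
  wt <- wt_spec()
  # frozen-Q convention: < 0.15 spread over residual 0 to 40%
  pks <- vapply(c(0, 0.1, 0.2, 0.3, 0.4), function(f)
    infer_fibril_pka(wt_experiment(f * 20e-6), wt,
                     qave_convention = "at_pH_mono")$pKa_fib, numeric(1))
  expect_lt(max(pks) - min(pks), 0.15)
  expect_true(all(abs(pks - 5.4) < 0.15))
})

test_that("protons per monomer track the closed-system bookkeeping", {
  wt <- wt_spec()
  r <- infer_fibril_pka(wt_experiment(), wt)
  expect_equal(protons_per_monomer(r),
               r$bound_fib_fib / (20e-6 - 4e-6) - 15 * r$Q_ave_conv)
  # zero-shift scenario gives zero uptake
  set45 <- assign_pkas(enumerate_acidic_sites(wt, "tail_only"), 4.5)
  ph0 <- forward_ph(4.5, set = set45, C_total = 20e-6,
                    C_residual_mono = 4e-6, pH_mono = 5.6)
  r0 <- infer_fibril_pka(ph_experiment(5.6, ph0, 20e-6, 4e-6), wt,
                         set = set45, monomer_pka_mean = 4.5)
  expect_equal(protons_per_monomer(r0), 0, tolerance = 1e-6)
  expect_equal(r0$delta_pKa, 0, tolerance = 1e-6)
  # algebraic identity at zero residual monomer (frozen-Q convention):
  # uptake = n (Q_fib(pH_fib; pKa_fib) - Q_mono(pH_mono))
  rz <- infer_fibril_pka(ph_experiment(5.6, 6.5, 20e-6, 0), wt,
                         qave_convention = "at_pH_mono")
  expect_equal(protons_per_monomer(rz),
               15 * (degree_of_protonation(6.5, rz$pKa_fib) - rz$Q_ave_mono),
               tolerance = 1e-10)
})

test_that("water autoionization is a sub-0.001 correction below pH 7", {
  wt <- wt_spec()
  eff <- autoionization_effect(wt_experiment(), wt)
  expect_gt(eff, 0)
  expect_lt(eff, 0.001)
  # the hydroxide term matters more as the final pH crosses neutrality
  effs <- vapply(c(6.5, 6.8, 7.1, 7.4), function(pf)
    autoionization_effect(ph_experiment(5.6, pf, 20e-6), wt), numeric(1))
  expect_true(all(diff(effs) > 0))
})

test_that("the shift is stable under uniform monomer-pKa offsets", {
  wt <- wt_spec()
  scan <- sensitivity_scan(wt_experiment(), wt, seq(0, 1.3, 0.1))
  expect_equal(scan$delta_pKa[1],
               infer_fibril_pka(wt_experiment(), wt)$delta_pKa)
  expect_true(all(scan$delta_pKa > 0))
  in01 <- scan$offset <= 1.0
  expect_lt(max(scan$delta_pKa[in01]) - min(scan$delta_pKa[in01]), 0.5)
  expect_error(sensitivity_scan(wt_experiment(), wt, 10), "outside")
})
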