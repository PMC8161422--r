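test_that("degree of protonation follows the Henderson-Hasselbalch form", {
  expect_equal(degree_of_protonation(4.3, 4.3), 0.5)
  expect_equal(degree_of_protonation(5.6, 4.3), 1 / (1 + 10^1.3),
               tolerance = 1e-12)
  expect_equal(round(degree_of_protonation(5.6, 4.3), 5), 0.04773)
  expect_equal(degree_of_protonation(-30, 4.3), 1.0)
  expect_equal(degree_of_protonation(30, 4.3), 0.0, tolerance = 1e-20)
  # strictly decreasing in pH, Q(pKa) = 0.5 exactly
  grid <- seq(0, 14, 0.25)
  q <- degree_of_protonation(grid, 7)
  expect_true(all(diff(q) < 0))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("average protonation over the regional scheme matches direct sums", {
  wt <- wt_spec()
  all_set <- assign_pkas(enumerate_acidic_sites(wt, "all_acidic"))
  tail_set <- assign_pkas(enumerate_acidic_sites(wt, "tail_only"))
  direct <- function(set, pH) mean(1 / (1 + 10^(pH - set$sites$pKa_assigned)))
  expect_equal(average_protonation(all_set, 5.6), direct(all_set, 5.6))
  expect_equal(round(average_protonation(all_set, 5.6), 4), 0.0559)
  expect_equal(round(average_protonation(tail_set, 5.6), 4), 0.0715)
  # equal-pKa set reduces to the single-site value
  unif <- assign_pkas(enumerate_acidic_sites(wt, "tail_only"), 4.5)
  expect_equal(average_protonation(unif, 5.0), degree_of_protonation(5.0, 4.5))
  expect_error(average_protonation(assign_pkas(
    enumerate_all_titratable(wt), "intrinsic"), 7), "acid sites only")
})

test_that("net charge respects the acid/base conventions", {
  wt <- wt_spec()
  full <- assign_pkas(enumerate_all_titratable(wt), "intrinsic")
  n_base <- sum(!full$sites$acid)
  # far below every pKa: acids neutral, bases fully charged
  expect_equal(net_charge(full, -10), n_base)
  # direct-summation oracle at pH 7
  s <- full$sites
  q <- 1 / (1 + 10^(7 - s$pKa_assigned))
  expect_equal(net_charge(full, 7), sum(ifelse(s$acid, -(1 - q), q)))
  expect_lt(abs(net_charge(full, 7) - (-9)), 0.5)
  # removing five tail glutamates makes the tail 5 units less negative
  tail_wt <- assign_pkas(enumerate_acidic_sites(wt_spec(), "tail_only"))
  tail_q5 <- assign_pkas(enumerate_acidic_sites(q5_spec(), "tail_only"))
  expect_lt(abs(net_charge(tail_q5, 7.4) - net_charge(tail_wt, 7.4) - 5),
            0.01)
})

test_that("capacitance has the closed form and matches a finite difference", {
  one <- assign_pkas(data.frame(
    position = 1L, kind = "Glu", acid = TRUE, region = "ctail",
    pKa0 = 4.4, pKa_assigned = NA_real_), 4.4)
  expect_equal(capacitance(one, 4.4), log(10) / 4)
  expect_lt(capacitance(one, 4.4 + 5), 1e-4)
  expect_lt(capacitance(one, 4.4 - 5), 1e-4)
  # capacitance is maximal at pH = pKa (scan)
  grid <- seq(2, 7, 0.01)
  caps <- vapply(grid, function(p) capacitance(one, p), numeric(1))
  expect_lt(abs(grid[which.max(caps)] - 4.4), 0.011)
  # |d(bound)/dpH| on a multi-site set equals the analytic capacitance
  set <- assign_pkas(enumerate_acidic_sites(wt_spec(), "all_acidic"))
  h <- 1e-6
  bound <- function(p) nrow(set$sites) * average_protonation(set, p)
  fd <- -(bound(5 + h) - bound(5 - h)) / (2 * h)
  expect_equal(fd, capacitance(set, 5), tolerance = 1e-6)
  # per-site option is the per-molecule value over n
  expect_equal(capacitance(set, 5, per_site = TRUE),
               capacitance(set, 5) / nrow(set$sites))
})

test_that("titration curves are monotone and cross 0.5 at the pKa", {
  wt <- wt_spec()
  set <- assign_pkas(enumerate_acidic_sites(wt, "tail_only"))
  grid <- seq(2, 9, 0.1)
  curve <- titration_curve(set, grid)
  expect_true(all(curve$per_site >= 0 & curve$per_site <= 1))
  expect_true(all(diff(curve$average) < 0))
  # ideal single-site curve crosses 0.5 exactly at its pKa
  his <- assign_pkas(data.frame(position = 50L, kind = "His", acid = FALSE,
                                region = "core", pKa0 = 6.3,
                                pKa_assigned = NA_real_), 6.78)
  hcurve <- titration_curve(his, c(6.77, 6.78, 6.79))
  expect_equal(unname(hcurve$per_site[1, 2]), 0.5)
  # the nonperturbed reference curve uses pKa0
  ref <- titration_curve(set, grid, reference = TRUE)
  i <- which.min(abs(grid - 4.4))
  glu_rows <- set$sites$kind == "Glu"
  expect_true(all(abs(ref$per_site[glu_rows, i] - 0.5) < 0.01))
  expect_error(titration_curve(set, c(5, 4)), "increasing")
  # CSV export round-trips the grid
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(curve, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$pH, grid)
  expect_equal(back$average_protonation, unname(curve$average))
})
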