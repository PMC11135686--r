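test_that("preset construction, overrides and half-life consistency", {
  p <- pathway_params("hacat_like")
  expect_true(all(unlist(p[setdiff(names(p), "preset")]) >= 0))
  expect_equal(pathway_params("r1_rich")$pR1, 10 * p$pR1)
  expect_equal(pathway_params("r2_rich")$pR2, 10 * p$pR2)
  expect_error(pathway_params("nope"), "arg")
  expect_error(pathway_params(ka = -1), ">= 0")
  expect_error(pathway_params(bogus = 1), "unknown field")
  ph <- pathway_params(half_life_R1 = 120)
  expect_equal(ph$kdeg_R1, log(2) / 120)
})

test_that("R and compiled right-hand sides agree on random states", {
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- pathway_state()
      s[] <- 10^runif(length(s), -2, 4)
      p <- pathway_params("hacat_like",
                          k_NFR = 10^runif(1, -3, 0),
                          ka = 10^runif(1, -5, -2))
      expect_equal(pathway_rhs(s, p), pathway_rhs(s, p, compiled = TRUE),
                   tolerance = 1e-12)
    }
  })
})

test_that("rhs respects trivially-zero fluxes and SMAD2 conservation", {
  p0 <- pathway_params("hacat_like", pR1 = 0, pR2 = 0)
  d0 <- pathway_rhs(pathway_state(), p0)
  expect_true(all(d0 == 0))
  # no ligand: no complex formation or phosphorylation flux anywhere
  s <- pathway_state(R1m = 100, R2m = 100, S2c = 1e3, S2n = 500)
  d <- pathway_rhs(s, pathway_params("hacat_like"))
  expect_identical(unname(d["LRCm"]), 0)
  expect_identical(unname(d["L"]), 0)
  # SMAD2 pools cancel term by term whenever pS2 = kdeg_S2 = 0
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- pathway_state()
      s[] <- 10^runif(length(s), 0, 4)
      d <- pathway_rhs(s, pathway_params("hacat_like"))
      expect_equal(unname(d["S2c"] + d["S2n"] + d["pS2c"] + d["pS2n"]), 0,
                   tolerance = 1e-9 * max(abs(d)))
    }
  })
})

test_that("ligand-free steady state matches the closed-form flux balance", {
  p <- pathway_params("hacat_like")
  ss <- presimulation_steady_state(p)
  # total receptor = production / degradation
  expect_equal(ss[["R1m"]] + ss[["R1e"]], p$pR1 / p$kdeg_R1,
               tolerance = 1e-12)
  expect_equal(ss[["R2m"]] + ss[["R2e"]], p$pR2 / p$kdeg_R2,
               tolerance = 1e-12)
  # linearity: doubling production doubles every receptor pool
  p2 <- pathway_params("hacat_like", pR1 = 2 * p$pR1)
  ss2 <- presimulation_steady_state(p2)
  expect_equal(ss2[["R1m"]], 2 * ss[["R1m"]], tolerance = 1e-12)
  expect_equal(ss2[["R1e"]], 2 * ss[["R1e"]], tolerance = 1e-12)
  # complexes and P-SMAD2 absent before stimulation
  expect_true(all(ss[c("LRCm", "LRCe", "pS2c", "pS2n")] == 0))
  # SMAD2 partition follows import/export balance
  expect_equal(ss[["S2n"]] / ss[["S2c"]], p$kin / p$kex)
  # it is a fixed point: a long unstimulated run does not move it
  tc <- simulate_pathway(p, dose_nM = 0, t_grid = c(0, 10000))
  drift <- abs(tc$states[2, ] - tc$states[1, ]) / max(tc$states[1, ])
  expect_lt(max(drift), 1e-6)
})

test_that("zero dose is flat; a bolus depletes ligand monotonically", {
  p <- pathway_params("hacat_like")
  tc0 <- simulate_pathway(p, dose_nM = 0, t_grid = seq(0, 240, by = 60))
  for (j in seq_len(ncol(tc0$states)))
    expect_equal(tc0$states[, j], rep(tc0$states[1, j], 5),
                 tolerance = 1e-7, ignore_attr = TRUE)
  expect_true(all(diff(tc_100pM$states[, "L"]) <= 0))
})

test_that("100 pM stimulation peaks at an interior maximum near 1 h", {
  ps <- total_psmad2(tc_100pM)
  i <- which.max(ps$value)
  expect_gt(i, 1)
  expect_lt(i, length(ps$value))
  expect_gte(ps$t[i], 30)
  expect_lte(ps$t[i], 120)
})

test_that("halving integrator tolerances leaves observables unchanged", {
  p <- pathway_params("hacat_like")
  tg <- seq(0, 480, by = 30)
  a <- simulate_pathway(p, 0.1, tg, rtol = 1e-8, atol = 1e-6)
  b <- simulate_pathway(p, 0.1, tg, rtol = 5e-9, atol = 5e-7)
  rel <- abs(total_psmad2(a)$value[-1] - total_psmad2(b)$value[-1]) /
    total_psmad2(b)$value[-1]
  expect_lt(max(rel), 1e-6)
})

test_that("without feedback, steady-state P-SMAD2 is monotone in dose", {
  p <- pathway_params("hacat_like", k_NFR = 0, med_scale = 0)
  lvl <- vapply(c(0.003, 0.01, 0.03, 0.1, 0.3), function(d) {
    tc <- simulate_pathway(p, d, c(0, 3000))
    total_psmad2(tc)$value[2]
  }, numeric(1))
  expect_true(all(diff(lvl) > 0))
})

test_that("scarce-receptor bottleneck is stronger at lower doses", {
  # constant-ligand mode isolates receptor limitation from depletion
  p <- pathway_params("hacat_like", med_scale = 0)
  elast <- function(dose) {
    h <- 0.05
    rel <- function(mult) {
      pi <- p
      pi$pR1 <- p$pR1 * mult          # R1 is the scarce receptor below
      pi$pR2 <- p$pR2 * 100
      tc <- simulate_pathway(pi, dose, c(0, 60))
      relative_psmad2(tc)$value[2]
    }
    (log(rel(1 + h)) - log(rel(1 / (1 + h)))) / (2 * log(1 + h))
  }
  expect_gte(elast(0.01), elast(1))
})

test_that("dose schedules apply stepwise ligand set-points", {
  p <- pathway_params("hacat_like")
  tc <- simulate_pathway(p, schedule = cbind(c(0, 60), c(0.1, 1)),
                         t_grid = c(0, 30, 60, 90))
  expect_equal(tc$states[3, "L"], 1, ignore_attr = TRUE)
  expect_lt(tc$states[2, "L"], 0.1)
  expect_error(simulate_pathway(p, t_grid = c(5, 10)), "start at 0")
  expect_error(simulate_pathway(p, t_grid = c(0, 0, 10)),
               "strictly increasing")
})

test_that("dose_convert round-trips and matches the 25 kDa anchor", {
  expect_equal(dose_convert(100, "pM_to_ng_per_mL", mw = 25), 2.5)
  expect_identical(dose_convert(0, "pM_to_ng_per_mL"), 0)
  x <- c(3, 47, 1000)
  back <- dose_convert(dose_convert(x, "pM_to_ng_per_mL", mw = 13),
                       "ng_per_mL_to_pM", mw = 13)
  expect_equal(back, x, tolerance = 1e-12)
  expect_error(dose_convert(1, mw = 0), "mw")
  expect_error(dose_convert(-1), ">= 0")
})
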