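test_that("constructor validates domains", {
  expect_error(minimal_params(L = -1), ">= 0")
  expect_error(minimal_params(K1 = 0), "strictly positive")
  expect_error(minimal_params(R1tot = NA), "finite")
  expect_s3_class(minimal_params(), "minimal_params")
})

test_that("lrc_equilibrium handles degenerate and limiting cases", {
  # no type I receptor -> no complex
  expect_identical(
    lrc_equilibrium(minimal_params(L = 0.1, K1 = 1000, R1tot = 0,
                                   R2tot = 1e4)), 0)
  # K1*L = 0 returns 0 without error
  expect_identical(
    lrc_equilibrium(minimal_params(L = 0, R1tot = 10, R2tot = 10)), 0)
  # high-affinity limit: LRC -> min(R1tot, R2tot)
  lrc <- lrc_equilibrium(minimal_params(L = 1e4, K1 = 1e4, R1tot = 100,
                                        R2tot = 1e4))
  expect_lt(abs(lrc - 100) / 100, 1e-6)
  # near-underflow regime short-circuits to the linearized solution
  p <- minimal_params(L = 1e-160, K1 = 1e-150, R1tot = 1, R2tot = 1)
  expect_equal(lrc_equilibrium(p), 1e-310, tolerance = 1e-12)
})

test_that("lrc_equilibrium is symmetric in the receptors and bounded", {
  withr::with_seed(42, {
    for (i in 1:50) {
      p <- rand_minimal()
      q <- p
      q$R1tot <- p$R2tot
      q$R2tot <- p$R1tot
      expect_equal(lrc_equilibrium(p), lrc_equilibrium(q))
      expect_lte(lrc_equilibrium(p), min(p$R1tot, p$R2tot))
    }
  })
})

test_that("quadratic root agrees with the bisection oracle on random sets", {
  withr::with_seed(1, {
    for (i in 1:1000) {
      p <- rand_minimal()
      a <- lrc_equilibrium(p)
      b <- lrc_bisect(p)
      expect_lt(abs(a - b) / max(b, 1e-300), 1e-10)
    }
  })
})

test_that("small-affinity limit is proportional to the receptor product", {
  withr::with_seed(7, {
    for (i in 1:50) {
      r1 <- 10^runif(1, 0, 3)
      r2 <- 10^runif(1, 0, 3)
      kl <- 1e-4 / max(r1, r2)       # K1*L*max(R) = 1e-4 < 1e-3
      p <- minimal_params(L = 1, K1 = kl, R1tot = r1, R2tot = r2)
      ratio <- lrc_equilibrium(p) / (kl * r1 * r2)
      expect_gte(ratio, 0.99)
      expect_lte(ratio, 1)
    }
  })
})

test_that("signaling activity saturates, vanishes and stays monotone", {
  expect_identical(signaling_activity(minimal_params(L = 0)), 0)
  # saturation: K1*L and K2*min(R) both large
  sa <- signaling_activity(minimal_params(L = 1e5, K1 = 1e4, K2 = 1e5,
                                          R1tot = 1e4, R2tot = 1e4,
                                          Stot = 3))
  expect_equal(sa, 3, tolerance = 1e-4)
  expect_lt(sa, 3)
  # monotone nondecreasing in each argument
  base <- list(L = 0.1, K1 = 10, K2 = 1, R1tot = 50, R2tot = 200, Stot = 1)
  sa0 <- signaling_activity(do.call(minimal_params, base))
  for (nm in c("L", "K1", "K2", "R1tot", "R2tot")) {
    up <- base
    up[[nm]] <- up[[nm]] * 2
    expect_gte(signaling_activity(do.call(minimal_params, up)), sa0)
  }
  # fraction option
  p <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 100,
                      R2tot = 100, Stot = 5)
  expect_equal(signaling_activity(p, fraction = TRUE) * 5,
               signaling_activity(p))
})

test_that("Fig-2-style setting shows the minimum principle asymmetry", {
  # reflection symmetry across the balanced diagonal
  p1 <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 10,
                       R2tot = 1e4)
  p2 <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 1e4,
                       R2tot = 10)
  expect_equal(signaling_activity(p1), signaling_activity(p2))
  # reducing the scarce receptor 10-fold hurts much more than the abundant
  base <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 100,
                         R2tot = 1e4)
  scarce_down <- abundant_down <- base
  scarce_down$R1tot <- base$R1tot / 10
  abundant_down$R2tot <- base$R2tot / 10
  expect_lt(signaling_activity(scarce_down),
            signaling_activity(abundant_down))
})

test_that("receptor_grid_scan has the contracted shape and symmetry", {
  p <- minimal_params(L = 0.1, K1 = 1000, K2 = 10)
  sc <- receptor_grid_scan(p, n_per_axis = 3, decades = 2, center = 100)
  expect_equal(dim(sc$sa_matrix), c(3, 3))
  expect_true(all(sc$sa_matrix >= 0 & sc$sa_matrix <= p$Stot))
  expect_equal(sc$sa_matrix, t(sc$sa_matrix))
  # balanced diagonal monotone increasing
  sc2 <- receptor_grid_scan(p, n_per_axis = 11, decades = 5,
                            center = 10^2.5)
  expect_true(all(diff(diag(sc2$sa_matrix)) > 0))
  expect_error(receptor_grid_scan(p, n_per_axis = 1), "n_per_axis")
  expect_error(receptor_grid_scan(p, center = -1), "center")
})

test_that("low-affinity landscape is product-proportional (slope 1)", {
  p <- minimal_params(L = 1e-6, K1 = 1e-3, K2 = 10)
  sc <- receptor_grid_scan(p, n_per_axis = 9, decades = 3, center = 10)
  # LRC proxy: invert Sa -> LRC through the saturation function
  lrc <- sc$sa_matrix / (p$K2 * (1 - sc$sa_matrix))
  fit_r1 <- stats::lm(log(lrc[, 5]) ~ log(sc$r1_axis))
  fit_r2 <- stats::lm(log(lrc[5, ]) ~ log(sc$r2_axis))
  expect_equal(unname(stats::coef(fit_r1)[2]), 1, tolerance = 0.01)
  expect_equal(unname(stats::coef(fit_r2)[2]), 1, tolerance = 0.01)
})

test_that("log elasticity is symmetric when balanced, scarce-dominated when not", {
  bal <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 316,
                        R2tot = 316)
  e1 <- log_elasticity(bal, "R1")
  e2 <- log_elasticity(bal, "R2")
  expect_lt(abs(e1 - e2), 1e-6)
  imb <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 1e2,
                        R2tot = 1e4)
  expect_gte(log_elasticity(imb, "R1") / log_elasticity(imb, "R2"), 10)
  expect_error(log_elasticity(minimal_params(L = 0)), "undefined")
  expect_error(log_elasticity(bal, "R1", rel_step = 0.7), "rel_step")
})

test_that("elasticity finite-difference error shrinks as O(rel_step^2)", {
  p <- minimal_params(L = 0.1, K1 = 10, K2 = 1, R1tot = 30, R2tot = 300)
  e <- vapply(c(0.2, 0.1, 0.05), function(h) log_elasticity(p, "R1", h),
              numeric(1))
  # successive Richardson differences shrink ~4x per halving
  ratio <- (e[1] - e[2]) / (e[2] - e[3])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})
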