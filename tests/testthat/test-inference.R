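# small noiseless dataset for fast fitting problems
small_dataset <- function(truth = hacat, doses = c(0.1, 1),
                          times = c(15, 60, 240)) {
  gen_timecourse_dataset(synthetic_spec(truth = truth, doses_nM = doses,
                                        times_min = times, noise_cv = 0))
}

test_that("objective is zero at truth, order-invariant and sd-scaled", {
  ds <- small_dataset()
  fp <- fit_problem(hacat, ds, free = c("ka", "k_NFR"))
  expect_lt(objective(fp), 1e-8)
  # row order does not matter
  ds_shuf <- ds[rev(seq_len(nrow(ds))), ]
  fp_shuf <- fit_problem(hacat, ds_shuf, free = c("ka", "k_NFR"))
  cand <- c(ka = hacat$ka * 2, k_NFR = hacat$k_NFR / 3)
  expect_equal(objective(fp, cand), objective(fp_shuf, cand))
  # doubling all sd divides the objective by 4
  ds2 <- ds
  ds2$sd <- fp$dataset$sd * 2
  fp2 <- fit_problem(hacat, ds2, free = c("ka", "k_NFR"))
  expect_equal(objective(fp2, cand), objective(fp, cand) / 4,
               tolerance = 1e-10)
  # validation
  expect_error(fit_problem(hacat, ds, free = "nosuch"), "unknown free")
  expect_error(fit_problem(hacat, ds[, 1:3]), "columns")
  bad <- ds; bad$observable[1] <- "mystery"
  expect_error(fit_problem(hacat, bad), "unknown observable")
})

test_that("simulation failure yields the documented finite penalty", {
  ds <- small_dataset()
  fp <- fit_problem(hacat, ds, free = c("kdeg_R1", "ka"),
                    bound_decades = 30)
  # kdeg_R1 = 0-like lower corner has no presimulation steady state
  val <- objective(fp, c(kdeg_R1 = 0, ka = hacat$ka))
  expect_equal(as.numeric(val), 1e12)
  expect_true(attr(val, "failed"))
})

test_that("single-parameter recovery hits the analytic optimum", {
  ds <- small_dataset()
  fp <- fit_problem(hacat, ds, free = "k_NFR", bound_decades = 1)
  # start away from the center to make the search real
  fit <- fit_multistart(fp, n_starts = 4, seed = 2)
  expect_lt(abs(fit$estimates[["k_NFR"]] / hacat$k_NFR - 1), 1e-4)
  expect_lt(fit$objective, 1e-6)
  # deterministic under the seed
  expect_identical(fit_multistart(fp, n_starts = 4, seed = 2)$estimates,
                   fit$estimates)
})

test_that("three-parameter noiseless recovery and identifiable profiles", {
  ds <- small_dataset()
  fp <- fit_problem(hacat, ds, free = c("ka", "k_NFR", "kphos"),
                    bound_decades = 1.5)
  fit <- fit_multistart(fp, n_starts = 6, seed = 5)
  truth <- c(hacat$ka, hacat$k_NFR, hacat$kphos)
  expect_true(all(abs(fit$estimates / truth - 1) < 0.02))
  pc <- profile_likelihood(fp, fit, "k_NFR", half_width_decades = 0.7,
                           n_points = 7)
  expect_equal(attr(pc, "classification"), "identifiable")
  # profile minimum matches the global fit at the estimate
  expect_lt(min(pc$objective) - fit$objective, 1e-6)
  expect_gte(min(pc$objective), fit$objective - 1e-6)
  # profiles rise monotonically away from the optimum here
  i0 <- which.min(pc$objective)
  expect_true(all(diff(pc$objective[i0:length(pc$objective)]) > -1e-9))
  expect_true(all(diff(rev(pc$objective[1:i0])) > -1e-9))
})

test_that("a parameter with no influence profiles structurally flat", {
  # ka = 0: no complex ever forms, so k_NFR cannot enter the observables;
  # restrict to the medium ligand, which is then exactly constant
  dead <- pathway_params("hacat_like", ka = 0)
  ds <- small_dataset(truth = dead)
  ds <- ds[ds$observable == "medium_tgfb", ]
  fp <- fit_problem(dead, ds, free = c("k_NFR", "kin"))
  fit <- fit_multistart(fp, n_starts = 2, seed = 1)
  pc <- profile_likelihood(fp, fit, "k_NFR", n_points = 5)
  expect_equal(attr(pc, "classification"), "structurally-flat")
})
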