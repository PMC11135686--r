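#' Draw a heterogeneous single-cell population
#'
#' Each cell gets its own receptor production rates (`pR1`, `pR2`), total
#' SMAD2 and negative-feedback strength (`k_NFR`), drawn from log-normal
#' distributions whose arithmetic mean equals the population value times an
#' optional mean multiplier and whose coefficient of variation is `cv`
#' (default 0.1).  `tie_receptors` forces `pR2 = pR1` per cell, emulating
#' stoichiometric co-expression of the two receptors.
#'
#' @param p population [pathway_params()].
#' @param cv coefficient of variation of every varied parameter (>= 0).
#' @param n_cells number of cells.
#' @param mean_multipliers named multipliers of the population means, e.g.
#'   `c(pR1 = 5)` for a 5-fold TGFBR1-rich population; unnamed parameters
#'   keep multiplier 1.  Recognized names: `pR1`, `pR2`, `S2tot`, `k_NFR`.
#' @param tie_receptors force identical receptor production per cell.
#' @param seed RNG seed.
#' @return A `cell_population`: data.frame (one row per cell) of `pR1`,
#'   `pR2`, `S2tot`, `k_NFR`, with the base params and settings as attributes.
#' @export
draw_population <- function(p, cv = 0.1, n_cells = 1000,
                            mean_multipliers = NULL, tie_receptors = FALSE,
                            seed = 1L) {
  stopifnot(inherits(p, "pathway_params"))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  mm <- c(pR1 = 1, pR2 = 1, S2tot = 1, k_NFR = 1)
  if (!is.null(mean_multipliers)) {
    bad <- setdiff(names(mean_multipliers), names(mm))
    if (length(bad))
      stop("unknown mean_multipliers: ", paste(bad, collapse = ", "),
           call. = FALSE)
    mm[names(mean_multipliers)] <- mean_multipliers
  }
  cells <- with_rng_seed(seed, {
    pR1 <- rlnorm_mean_cv(n_cells, p$pR1 * mm[["pR1"]], cv)
    pR2 <- if (tie_receptors) pR1 else
      rlnorm_mean_cv(n_cells, p$pR2 * mm[["pR2"]], cv)
    data.frame(
      cell_id = seq_len(n_cells),
      pR1 = pR1, pR2 = pR2,
      S2tot = rlnorm_mean_cv(n_cells, p$S2tot * mm[["S2tot"]], cv),
      k_NFR = rlnorm_mean_cv(n_cells, p$k_NFR * mm[["k_NFR"]], cv)
    )
  })
  structure(cells, params = p, cv = cv, seed = seed,
            mean_multipliers = mm, tie_receptors = tie_receptors,
            class = c("cell_population", "data.frame"))
}

#' Simulate every cell of a population
#'
#' Each cell is re-equilibrated to its own ligand-free steady state (cells
#' are simulated independently; the ligand is a constant boundary per cell,
#' `med_scale = 0`) and stimulated with a ligand bolus; the SMAD2 N2C fold
#' change is read out at the requested response times.  Per-cell covariates
#' are the initial total receptor and SMAD2 amounts and the cell's `k_NFR`.
#'
#' @param pop a [draw_population()] result.
#' @param dose_nM ligand bolus (nM); default 100 pM.
#' @param response_times readout times (min); default 1 h and 8 h.
#' @param rtol integrator relative tolerance.
#' @return A `cell_responses` data.frame: `cell_id`, `R1_0`, `R2_0`, `S2_0`,
#'   `k_NFR`, `ok`, and one `n2c_fc_<t>min` column per response time.  Cells
#'   whose simulation failed are flagged `ok = FALSE` (responses `NA`); the
#'   run continues.
#' @export
simulate_population <- function(pop, dose_nM = 0.1,
                                response_times = c(60, 480), rtol = 1e-8) {
  stopifnot(inherits(pop, "cell_population"))
  p0 <- attr(pop, "params")
  t_grid <- sort(unique(c(0, response_times)))
  idx <- match(response_times, t_grid)
  n <- nrow(pop)
  res <- matrix(NA_real_, n, length(response_times))
  cov <- matrix(NA_real_, n, 3)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    pi <- p0
    pi$pR1 <- pop$pR1[i]
    pi$pR2 <- pop$pR2[i]
    pi$S2tot <- pop$S2tot[i]
    pi$k_NFR <- pop$k_NFR[i]
    pi$med_scale <- 0           # constant ligand per cell
    out <- tryCatch({
      ss <- presimulation_steady_state(pi)
      tc <- simulate_pathway(pi, dose_nM = dose_nM, t_grid = t_grid,
                             init = ss, rtol = rtol)
      list(fc = n2c_fold_change(tc)$value[idx],
           cov = c(ss[["R1m"]] + ss[["R1e"]], ss[["R2m"]] + ss[["R2e"]],
                   pi$S2tot))
    }, error = function(e) NULL)
    if (is.null(out)) { ok[i] <- FALSE; next }
    res[i, ] <- out$fc
    cov[i, ] <- out$cov
  }
  if (!all(ok))
    warning(sum(!ok), " cell simulation(s) failed; flagged ok = FALSE")
  out <- data.frame(cell_id = pop$cell_id, R1_0 = cov[, 1], R2_0 = cov[, 2],
                    S2_0 = cov[, 3], k_NFR = pop$k_NFR, ok = ok)
  for (k in seq_along(response_times))
    out[[sprintf("n2c_fc_%gmin", response_times[k])]] <- res[, k]
  structure(out, dose_nM = dose_nM, response_times = response_times,
            population = pop,
            class = c("cell_responses", "data.frame"))
}

#' Pearson correlation of single-cell responses with expression covariates
#'
#' Correlates the N2C fold change at one response time with the raw
#' (untransformed) per-cell covariates — initial TGFBR1, TGFBR2 and SMAD2
#' amounts and negative-feedback strength — exactly as scatter plots of
#' response versus expression would be quantified.
#'
#' @param responses a [simulate_population()] result.
#' @param response_time which readout time (min) to correlate.
#' @return A `correlation_report` data.frame: `covariate`, `pearson_r`,
#'   `p_value`, `n_cells`; zero-variance covariates are reported with `NA`
#'   correlation.
#' @export
correlate <- function(responses, response_time = 60) {
  stopifnot(inherits(responses, "cell_responses"))
  col <- sprintf("n2c_fc_%gmin", response_time)
  if (!col %in% names(responses))
    stop("no responses at t = ", response_time, " min", call. = FALSE)
  keep <- responses$ok & is.finite(responses[[col]])
  if (sum(keep) < 3)
    stop("need >= 3 cells with finite responses", call. = FALSE)
  y <- responses[[col]][keep]
  covs <- c(R1 = "R1_0", R2 = "R2_0", SMAD2 = "S2_0", k_NFR = "k_NFR")
  rows <- lapply(names(covs), function(nm) {
    x <- responses[[covs[[nm]]]][keep]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(covariate = nm, pearson_r = NA_real_,
                        p_value = NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(covariate = nm, pearson_r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$n_cells <- sum(keep)
  structure(out, response_time = response_time,
            class = c("correlation_report", "data.frame"))
}
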