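#' Specification of a synthetic time-course dataset
#'
#' Bundles the ground-truth parameters, dose/time layout and noise model of
#' a generated dataset.  The default layout mirrors a multi-dose immunoblot
#' campaign: doses of 10, 100 and 1000 pM, six observables (medium TGF-beta,
#' total P-SMAD2, cytoplasmic/nuclear SMAD2 and P-SMAD2), seven sampling
#' times at the middle dose and five at the others — 6 * (5 + 7 + 5) = 102
#' data points in total.
#'
#' @param truth ground-truth [pathway_params()].
#' @param doses_nM ligand doses (nM).
#' @param times_min either a numeric vector shared by all doses or a list of
#'   per-dose time vectors (min, excluding 0).
#' @param noise_model `"multiplicative-lognormal"` (default) or
#'   `"additive-gaussian"`.
#' @param noise_cv noise coefficient of variation (sd/mean per measurement).
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(truth = pathway_params("hacat_like"),
                           doses_nM = c(0.01, 0.1, 1),
                           times_min = list(c(30, 60, 120, 240, 480),
                                            c(15, 30, 45, 60, 120, 240, 480),
                                            c(30, 60, 120, 240, 480)),
                           noise_model = c("multiplicative-lognormal",
                                           "additive-gaussian"),
                           noise_cv = 0.05, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(truth, "pathway_params"))
  if (!is.list(times_min)) times_min <- rep(list(times_min),
                                            length(doses_nM))
  if (length(times_min) != length(doses_nM))
    stop("times_min must match doses_nM", call. = FALSE)
  if (length(doses_nM) == 0 || any(lengths(times_min) == 0))
    stop("doses and times must be non-empty", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(truth = truth, doses_nM = doses_nM, times_min = times_min,
                 noise_model = noise_model, noise_cv = noise_cv,
                 seed = seed),
            class = "synthetic_spec")
}

apply_noise <- function(values, spec) {
  if (spec$noise_cv == 0) return(values)
  if (spec$noise_model == "multiplicative-lognormal") {
    values * rlnorm_mean_cv(length(values), 1, spec$noise_cv)
  } else {
    values + stats::rnorm(length(values), 0, spec$noise_cv * abs(values))
  }
}

#' Generate a fit-ready synthetic time-course dataset
#'
#' Simulates the ground truth per dose, samples the six observables at the
#' layout's times and applies measurement noise.  The reported `sd` column
#' is `noise_cv * `noiseless value (the generating model's own noise scale),
#' so recovery fits are correctly weighted.  The ground truth travels with
#' the table as attribute `truth` (sidecar metadata) — recovery tests never
#' re-derive it from the noisy values.
#'
#' @param spec a [synthetic_spec()].
#' @return Data.frame `dose_nM`, `time_min`, `observable`, `value`, `sd`
#'   with attributes `truth`, `spec`.
#' @examples
#' ds <- gen_timecourse_dataset(synthetic_spec(noise_cv = 0))
#' nrow(ds)  # 102
#' @export
gen_timecourse_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  for (i in seq_along(spec$doses_nM)) {
    dose <- spec$doses_nM[i]
    tt <- sort(spec$times_min[[i]])
    tg <- sort(unique(c(0, tt)))
    tc <- simulate_pathway(spec$truth, dose_nM = dose, t_grid = tg)
    obs <- timecourse_observables(tc)
    it <- match(tt, tg)
    for (ob in names(obs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        dose_nM = dose, time_min = tt, observable = ob,
        value = obs[[ob]][it],
        sd = if (spec$noise_cv > 0)
          pmax(spec$noise_cv * obs[[ob]][it], 1e-12)
        else NA_real_)  # noiseless: let the fit fall back to 5% of range
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$value <- with_rng_seed(spec$seed, apply_noise(out$value, spec))
  structure(out, truth = spec$truth, spec = spec)
}

#' siRNA concentration to receptor fold change
#'
#' Saturating Hill-type knockdown curve
#' `fc(c) = 1 - kd_max * c^n / (kd_ic50^n + c^n)`: fold change 1 without
#' siRNA, decreasing towards `1 - kd_max` at saturating concentration.
#'
#' @param concs_nM siRNA concentrations (nM, >= 0).
#' @param kd_max maximal knockdown fraction, in `[0, 1]`.
#' @param kd_ic50 half-maximal knockdown concentration (nM).
#' @param kd_n Hill coefficient of the knockdown curve.
#' @return Receptor fold changes in `[1 - kd_max, 1]`.
#' @export
sirna_knockdown_curve <- function(concs_nM, kd_max = 0.95, kd_ic50 = 1,
                                  kd_n = 1) {
  if (any(concs_nM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (kd_max < 0 || kd_max > 1)
    stop("kd_max must be in [0, 1]", call. = FALSE)
  1 - kd_max * concs_nM^kd_n / (kd_ic50^kd_n + concs_nM^kd_n)
}

#' Generate a synthetic siRNA knockdown dose-response dataset
#'
#' Composes [sirna_knockdown_curve()] (siRNA dose to receptor fold change)
#' with [predict_knockdown_response()] (receptor fold change to normalized
#' P-SMAD2 response) and adds per-replicate measurement noise.  The
#' noiseless truth EC50 — obtained by Hill-fitting the noiseless curve — is
#' stored as attribute `truth_ec50`.
#'
#' @param p ground-truth [pathway_params()].
#' @param receptor `"R1"` or `"R2"`.
#' @param concs_nM siRNA concentrations; default an 8-point series spanning
#'   0.08-100 nM.
#' @param kd_max,kd_ic50,kd_n knockdown-curve parameters.
#' @param n_replicates biological replicates (default 3).
#' @param noise_cv multiplicative noise CV on the response.
#' @param seed RNG seed.
#' @return A `dose_response_dataset` with a `replicate` column and
#'   attributes `truth_ec50`, `noiseless`.
#' @export
gen_knockdown_dataset <- function(p = pathway_params("hacat_like"),
                                  receptor = c("R2", "R1"),
                                  concs_nM = c(0, 0.08, 0.4, 2, 5, 10, 50,
                                               100),
                                  kd_max = 0.95, kd_ic50 = 1, kd_n = 1,
                                  n_replicates = 3, noise_cv = 0.05,
                                  seed = 1L) {
  receptor <- match.arg(receptor)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  fc <- sirna_knockdown_curve(concs_nM, kd_max, kd_ic50, kd_n)
  base <- predict_knockdown_response(p, receptor, fold_changes = fc)
  truth_ec50 <- fit_hill(base)$ec50
  reps <- with_rng_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      v <- base$response_fc *
        (if (noise_cv > 0) rlnorm_mean_cv(nrow(base), 1, noise_cv) else 1)
      data.frame(receptor_fc = base$receptor_fc, response_fc = v,
                 replicate = r)
    }))
  })
  out <- dose_response_dataset(reps$receptor_fc, reps$response_fc,
                               receptor = receptor,
                               replicate = reps$replicate)
  attr(out, "truth_ec50") <- truth_ec50
  attr(out, "noiseless") <- base
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic single-cell imaging-style table
#'
#' Simulates a heterogeneous cell cohort (default n = 102, the size of a
#' typical live-imaging experiment) and emits what image quantification
#' would produce: a receptor-reporter intensity per cell (proportional to
#' the cell's initial TGFBR2 amount, with measurement noise) and the SMAD2
#' N2C fold change at the requested times, also with multiplicative
#' measurement noise.  Ground truth (the population draw) is attached as
#' attribute `population`.
#'
#' @param p population [pathway_params()].
#' @param n_cells cohort size; default 102.
#' @param cv biological coefficient of variation of the varied parameters.
#' @param tie_receptors co-express both receptors at equal amounts per cell
#'   (default `TRUE`, the co-translational reporter design).
#' @param dose_nM ligand bolus (nM).
#' @param times_min readout times (min); 0 is allowed and reports the
#'   pre-stimulation frame (fold change exactly 1 before noise).
#' @param intensity_noise_cv measurement noise CV (reporter and N2C).
#' @param reporter_gain arbitrary intensity units per abundance-unit.
#' @param seed RNG seed.
#' @return Data.frame `cell_id`, `reporter_intensity`, one
#'   `n2c_fc_<t>min` column per time; attributes `population`, `responses`.
#' @export
gen_single_cell_dataset <- function(p = pathway_params("hacat_like"),
                                    n_cells = 102, cv = 0.5,
                                    tie_receptors = TRUE, dose_nM = 0.1,
                                    times_min = c(0, 20, 60),
                                    intensity_noise_cv = 0.05,
                                    reporter_gain = 1e-2, seed = 1L) {
  pop <- draw_population(p, cv = cv, n_cells = n_cells,
                         tie_receptors = tie_receptors, seed = seed)
  resp <- simulate_population(pop, dose_nM = dose_nM,
                              response_times = times_min)
  out <- with_rng_seed(seed + 1L, {
    rep_int <- reporter_gain * resp$R2_0 *
      (if (intensity_noise_cv > 0)
        rlnorm_mean_cv(n_cells, 1, intensity_noise_cv) else 1)
    d <- data.frame(cell_id = resp$cell_id,
                    reporter_intensity = rep_int)
    for (tm in times_min) {
      col <- sprintf("n2c_fc_%gmin", tm)
      v <- resp[[col]]
      if (intensity_noise_cv > 0)
        v <- v * rlnorm_mean_cv(n_cells, 1, intensity_noise_cv)
      d[[col]] <- v
    }
    d
  })
  structure(out, population = pop, responses = resp,
            dose_nM = dose_nM, seed = seed)
}
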