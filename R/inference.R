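#' Define a least-squares fitting problem for the pathway model
#'
#' Couples a fit-ready dataset of time-course observables (long format:
#' `dose_nM`, `time_min`, `observable`, `value`, `sd`) to the model: the
#' named `free` parameters are estimated inside log10 box bounds around
#' their values in `p` (default +/- 2 decades); everything else stays fixed.
#' Observable names must be among `medium_tgfb`, `total_psmad2`,
#' `cyt_smad2`, `cyt_psmad2`, `nuc_smad2`, `nuc_psmad2`.
#'
#' Rows with missing or non-positive `sd` fall back to 5% of that
#' observable's dynamic range in the dataset.
#'
#' @param p a [pathway_params()] object holding the fixed values and the
#'   centers of the free-parameter bounds.
#' @param dataset the observed table.
#' @param free names of the free parameters; defaults to the nine kinetic
#'   unknowns of the pathway.  Directly measured quantities (receptor
#'   internalization rate, abundances, half-lives) stay fixed; the default
#'   free set is the binding, feedback, (de)phosphorylation, shuttling,
#'   recycling and medium-depletion constants.
#' @param bound_decades half-width of the log10 box bounds.
#' @return A `fit_problem` object.
#' @export
fit_problem <- function(p, dataset,
                        free = c("ka", "k_NFR", "kphos", "kdephos", "kin",
                                 "kex", "kin_p", "kr", "med_scale"),
                        bound_decades = 2) {
  stopifnot(inherits(p, "pathway_params"))
  dataset <- as.data.frame(dataset)
  need <- c("dose_nM", "time_min", "observable", "value")
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  known_obs <- c("medium_tgfb", "total_psmad2", "cyt_smad2", "cyt_psmad2",
                 "nuc_smad2", "nuc_psmad2")
  bad <- setdiff(unique(dataset$observable), known_obs)
  if (length(bad))
    stop("unknown observable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad_par <- setdiff(free, names(.hacat_like_defaults()))
  if (length(bad_par))
    stop("unknown free parameter(s): ", paste(bad_par, collapse = ", "),
         call. = FALSE)
  center <- vapply(free, function(nm) p[[nm]], numeric(1))
  if (any(center <= 0))
    stop("free parameters must be > 0 to fit in log space", call. = FALSE)
  sd <- if ("sd" %in% names(dataset)) dataset$sd else rep(NA_real_,
                                                          nrow(dataset))
  for (ob in unique(dataset$observable)) {
    sel <- dataset$observable == ob & (!is.finite(sd) | sd <= 0)
    if (any(sel)) {
      rng <- diff(range(dataset$value[dataset$observable == ob]))
      sd[sel] <- max(0.05 * rng, 1e-12)
    }
  }
  dataset$sd <- sd
  structure(list(params = p, dataset = dataset, free = free,
                 lower = log10(center) - bound_decades,
                 upper = log10(center) + bound_decades,
                 center = center),
            class = "fit_problem")
}

# Simulate the candidate and return the model value for every dataset row.
# `candidate` is a full named vector over fp$free in natural units.
model_predictions <- function(fp, candidate) {
  p <- fp$params
  p[names(candidate)] <- as.list(unname(candidate))
  d <- fp$dataset
  pred <- rep(NA_real_, nrow(d))
  for (dose in unique(d$dose_nM)) {
    rows <- which(d$dose_nM == dose)
    tg <- sort(unique(c(0, d$time_min[rows])))
    tc <- simulate_pathway(p, dose_nM = dose, t_grid = tg, rtol = 1e-8)
    obs <- timecourse_observables(tc)
    it <- match(d$time_min[rows], tg)
    pred[rows] <- mapply(function(ob, k) obs[[ob]][k],
                         d$observable[rows], it)
  }
  pred
}

#' Weighted residual sum of squares of a candidate parameter set
#'
#' `sum(((model - value) / sd)^2)` over all dataset rows, with the model
#' simulated per dose from the candidate's own ligand-free pre-stimulation
#' steady state.  Simulation failure yields the documented finite penalty
#' `1e12` (attribute `failed = TRUE`) so optimizers can retreat.
#'
#' @param fp a [fit_problem()].
#' @param candidate named numeric vector of the free parameters (natural
#'   units); defaults to the problem's center values.
#' @return Weighted SSR (scalar).
#' @export
objective <- function(fp, candidate = NULL) {
  stopifnot(inherits(fp, "fit_problem"))
  if (is.null(candidate)) candidate <- fp$center
  candidate <- candidate[fp$free]
  if (anyNA(candidate))
    stop("candidate must name all free parameters", call. = FALSE)
  pred <- tryCatch(model_predictions(fp, candidate), error = function(e) NULL)
  if (is.null(pred) || !all(is.finite(pred)))
    return(structure(1e12, failed = TRUE))
  sum(((pred - fp$dataset$value) / fp$dataset$sd)^2)
}

# residual vector in log10 space for the LM optimizer
.fit_residuals <- function(fp) {
  function(theta) {
    cand <- stats::setNames(10^theta, fp$free)
    pred <- tryCatch(model_predictions(fp, cand), error = function(e) NULL)
    if (is.null(pred) || !all(is.finite(pred)))
      return(rep(1e6, nrow(fp$dataset)))
    (pred - fp$dataset$value) / fp$dataset$sd
  }
}

#' Multistart least-squares estimation
#'
#' Runs a damped Gauss-Newton (Levenberg-Marquardt) local search in log10
#' parameter space from `n_starts` starting points drawn log-uniformly
#' within the box bounds (the problem center is always included as one
#' start), and returns the best local optimum.  Deterministic given `seed`.
#'
#' @param fp a [fit_problem()].
#' @param n_starts number of starts (>= 1).
#' @param seed RNG seed for the start draws.
#' @param max_iter per-start iteration cap.
#' @return A `fit_result`: list with `estimates` (named, natural units),
#'   `objective`, `n_starts`, `converged_starts`, `best_start`.
#' @export
fit_multistart <- function(fp, n_starts = 20, seed = 1L, max_iter = 200) {
  stopifnot(inherits(fp, "fit_problem"))
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  k <- length(fp$free)
  starts <- with_rng_seed(seed, {
    m <- matrix(stats::runif(n_starts * k), n_starts, k)
    sweep(sweep(m, 2, fp$upper - fp$lower, "*"), 2, fp$lower, "+")
  })
  starts[1, ] <- log10(fp$center)      # center is always one of the starts
  resid <- .fit_residuals(fp)
  best <- NULL
  converged <- 0L
  best_start <- NA_integer_
  for (s in seq_len(n_starts)) {
    fit <- lm_least_squares(resid, starts[s, ], lower = fp$lower,
                            upper = fp$upper, max_iter = max_iter)
    if (fit$converged) converged <- converged + 1L
    if (is.finite(fit$rss) && (is.null(best) || fit$rss < best$rss)) {
      best <- fit
      best_start <- s
    }
  }
  if (is.null(best))
    stop("estimation failed: no start produced a finite objective",
         call. = FALSE)
  structure(list(
    estimates = stats::setNames(10^best$par, fp$free),
    objective = best$rss,
    n_starts = n_starts, converged_starts = converged,
    best_start = best_start, problem = fp),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Multistart fit: objective %.6g (%d/%d starts converged)\n",
              x$objective, x$converged_starts, x$n_starts))
  print(signif(x$estimates, 4))
  invisible(x)
}

#' Profile likelihood of one fitted parameter
#'
#' Scans the parameter over a log10 grid around its estimate; at each grid
#' value all other free parameters are re-optimized (warm-started from the
#' neighboring grid point).  A parameter is classified `identifiable` when
#' the profiled objective rises above `objective + threshold` on both sides
#' of the optimum, `practically-non-identifiable-left`/`-right` when only
#' one side crosses, and `structurally-flat` when the whole profile stays
#' within re-optimization noise of the optimum.
#'
#' @param fp a [fit_problem()].
#' @param fit a [fit_multistart()] result.
#' @param param name of the profiled free parameter.
#' @param half_width_decades half-width of the log10 profile grid.
#' @param n_points grid size (>= 5, odd recommended).
#' @param threshold objective increase defining the confidence bound;
#'   default 3.84, the 95% pointwise chi-square cutoff.
#' @return A `profile_curve`: data.frame `value`, `objective` with
#'   attributes `param`, `threshold`, `classification`.
#' @export
profile_likelihood <- function(fp, fit, param, half_width_decades = 1,
                               n_points = 11, threshold = 3.84) {
  stopifnot(inherits(fp, "fit_problem"), inherits(fit, "fit_result"))
  if (!param %in% fp$free)
    stop("`param` must be one of the free parameters", call. = FALSE)
  if (n_points < 5) stop("n_points must be >= 5", call. = FALSE)
  others <- setdiff(fp$free, param)
  i_par <- match(param, fp$free)
  i_oth <- match(others, fp$free)
  theta_hat <- log10(fit$estimates[fp$free])
  grid <- seq(theta_hat[i_par] - half_width_decades,
              theta_hat[i_par] + half_width_decades,
              length.out = n_points)
  # enforce the box
  grid <- pmin(pmax(grid, fp$lower[i_par]), fp$upper[i_par])
  grid <- sort(unique(grid))
  prof <- rep(NA_real_, length(grid))
  reopt_one <- function(fixed_val, warm) {
    resid_sub <- function(th_o) {
      th <- numeric(length(fp$free))
      th[i_oth] <- th_o
      th[i_par] <- fixed_val
      .fit_residuals(fp)(th)
    }
    lm_least_squares(resid_sub, warm, lower = fp$lower[i_oth],
                     upper = fp$upper[i_oth], max_iter = 80)
  }
  i_mid <- which.min(abs(grid - theta_hat[i_par]))
  # sweep outwards from the optimum, warm-starting from the neighbor
  for (side in list(seq(i_mid, length(grid)), seq(i_mid, 1))) {
    warm <- theta_hat[i_oth]
    for (g in side) {
      fitg <- reopt_one(grid[g], warm)
      prof[g] <- fitg$rss
      warm <- fitg$par
    }
  }
  base <- min(fit$objective, min(prof, na.rm = TRUE))
  crosses_right <- any(prof[grid > theta_hat[i_par]] > base + threshold,
                       na.rm = TRUE)
  crosses_left <- any(prof[grid < theta_hat[i_par]] > base + threshold,
                      na.rm = TRUE)
  flat <- max(prof, na.rm = TRUE) < base + 1e-6 * max(1, base)
  classification <- if (flat) "structurally-flat"
  else if (crosses_left && crosses_right) "identifiable"
  else if (crosses_left) "practically-non-identifiable-right"
  else if (crosses_right) "practically-non-identifiable-left"
  else "structurally-flat"
  structure(data.frame(value = 10^grid, objective = prof),
            param = param, threshold = threshold,
            classification = classification, optimum = fit$objective,
            class = c("profile_curve", "data.frame"))
}
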