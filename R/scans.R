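#' Sample protein-expression space
#'
#' Draws independent log-uniform multipliers for receptor and SMAD2
#' production relative to a preset, emulating the heterogeneous expression of
#' TGFBR1, TGFBR2 and SMAD2 across cell types.  Receptor spans default to 5
#' decades; the SMAD2 span to 2 decades; all spans are centered on 1
#' (the preset itself).
#'
#' @param n number of draws (>= 1).
#' @param decades_r,decades_s log10 span of the receptor / SMAD2 multipliers.
#' @param seed RNG seed for reproducible draws.
#' @return An `expression_draws` object: data.frame with columns `r1_mult`,
#'   `r2_mult`, `s2_mult` plus attributes `seed` and `spans`.
#' @export
sample_expression_space <- function(n, decades_r = 5, decades_s = 2,
                                    seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (decades_r < 0 || decades_s < 0)
    stop("spans must be >= 0", call. = FALSE)
  draws <- with_rng_seed(seed, {
    data.frame(
      r1_mult = 10^stats::runif(n, -decades_r / 2, decades_r / 2),
      r2_mult = 10^stats::runif(n, -decades_r / 2, decades_r / 2),
      s2_mult = 10^stats::runif(n, -decades_s / 2, decades_s / 2)
    )
  })
  structure(draws, seed = seed,
            spans = c(decades_r = decades_r, decades_s = decades_s),
            class = c("expression_draws", "data.frame"))
}

#' Signaling landscape over expression space
#'
#' Simulates the extended model once per expression draw — each draw scales
#' receptor production (`pR1`, `pR2`) and total SMAD2 relative to the preset
#' and is re-equilibrated to its own ligand-free steady state — and records
#' relative P-SMAD2 and SMAD2 N2C fold change at the evaluation time.
#'
#' @param draws an `expression_draws` object (or data.frame with the three
#'   multiplier columns).
#' @param p a [pathway_params()] object (the population preset).
#' @param dose_nM ligand bolus (nM); default 100 pM.
#' @param t_eval readout time (min); default 60.
#' @param rtol integrator relative tolerance (relaxed slightly for bulk
#'   scans).
#' @return A `landscape_result` data.frame: multipliers plus `rel_psmad2`
#'   and `n2c_fc` per draw; attributes `t_eval`, `dose_nM`.
#' @export
landscape <- function(draws, p, dose_nM = 0.1, t_eval = 60, rtol = 1e-8) {
  stopifnot(inherits(p, "pathway_params"))
  draws <- as.data.frame(draws)
  need <- c("r1_mult", "r2_mult", "s2_mult")
  if (!all(need %in% names(draws)))
    stop("draws must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  t_grid <- sort(unique(c(0, t_eval)))
  i_eval <- match(t_eval, t_grid)
  n <- nrow(draws)
  rel <- n2c <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pi <- p
    pi$pR1 <- p$pR1 * draws$r1_mult[i]
    pi$pR2 <- p$pR2 * draws$r2_mult[i]
    pi$S2tot <- p$S2tot * draws$s2_mult[i]
    tc <- tryCatch(
      simulate_pathway(pi, dose_nM = dose_nM, t_grid = t_grid, rtol = rtol),
      error = function(e)
        stop(sprintf("draw %d: %s", i, conditionMessage(e)), call. = FALSE))
    rel[i] <- relative_psmad2(tc)$value[i_eval]
    n2c[i] <- n2c_fold_change(tc)$value[i_eval]
  }
  out <- cbind(draws, rel_psmad2 = rel, n2c_fc = n2c)
  structure(out, t_eval = t_eval, dose_nM = dose_nM,
            class = c("landscape_result", "data.frame"))
}

#' Aggregate a scattered landscape onto a 2-D receptor grid
#'
#' Bins draws by `log10(r1_mult)` and `log10(r2_mult)` and aggregates the
#' response by the median per bin — the gridded form used for contour-style
#' export of the scattered landscape.
#'
#' @param ls a `landscape_result`.
#' @param n_bins bins per axis.
#' @param response which response column to aggregate.
#' @return List with `r1_centers`, `r2_centers` (multipliers) and matrix `z`.
#' @export
grid_landscape <- function(ls, n_bins = 25, response = "rel_psmad2") {
  stopifnot(inherits(ls, "landscape_result"))
  lx <- log10(ls$r1_mult); ly <- log10(ls$r2_mult)
  bx <- seq(min(lx), max(lx), length.out = n_bins + 1)
  by <- seq(min(ly), max(ly), length.out = n_bins + 1)
  ix <- pmin(findInterval(lx, bx, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(ly, by, rightmost.closed = TRUE), n_bins)
  z <- matrix(NA_real_, n_bins, n_bins)
  agg <- tapply(ls[[response]], list(ix, iy), stats::median)
  z[cbind(as.integer(rep(rownames(agg), ncol(agg))),
          as.integer(rep(colnames(agg), each = nrow(agg))))] <- as.numeric(agg)
  list(r1_centers = 10^((bx[-1] + bx[-length(bx)]) / 2),
       r2_centers = 10^((by[-1] + by[-length(by)]) / 2),
       z = z)
}
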