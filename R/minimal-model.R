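#' Parameters of the two-reaction minimal TGF-beta model
#'
#' The minimal model reduces the TGF-beta pathway to two reactions: the
#' ligand `L` binds the type I (`R1`) and type II (`R2`) receptors with
#' affinity `K1` to form the signaling ligand-receptor complex (LRC), and the
#' LRC drives SMAD phosphorylation with equilibrium coefficient `K2`.
#' Receptors and SMAD are in arbitrary abundance-units; `L` is in nM, so `K1`
#' carries units 1/(nM * abundance-unit) and `K1 * L * R1 * R2` is
#' dimensionally an abundance.  The ligand is a fixed boundary condition
#' (no depletion).
#'
#' @param L ligand concentration (nM), held constant.
#' @param K1 ligand-receptor binding affinity, 1/(nM * abundance-unit).
#' @param K2 phosphorylation equilibrium coefficient, 1/abundance-unit.
#' @param R1tot,R2tot total type I / type II receptor (abundance-units).
#' @param Stot total SMAD (abundance-units); defaults to 1 so that signaling
#'   activity is reported as a fraction of total SMAD.
#' @return An object of class `minimal_params` (a validated list).
#' @examples
#' p <- minimal_params(L = 0.1, K1 = 1000, K2 = 10, R1tot = 100, R2tot = 1e4)
#' signaling_activity(p)
#' @export
minimal_params <- function(L = 0.1, K1 = 1000, K2 = 10,
                           R1tot = 1, R2tot = 1, Stot = 1) {
  vals <- list(L = L, K1 = K1, K2 = K2, R1tot = R1tot, R2tot = R2tot,
               Stot = Stot)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("minimal_params: `", nm, "` must be a finite numeric scalar",
           call. = FALSE)
    if (v < 0)
      stop("minimal_params: `", nm, "` must be >= 0", call. = FALSE)
  }
  if (K1 <= 0 || K2 <= 0)
    stop("minimal_params: K1 and K2 must be strictly positive", call. = FALSE)
  structure(vals, class = "minimal_params")
}

#' @export
print.minimal_params <- function(x, ...) {
  cat("Minimal TGF-beta model parameters\n")
  cat(sprintf("  L = %g nM, K1 = %g, K2 = %g\n", x$L, x$K1, x$K2))
  cat(sprintf("  R1tot = %g, R2tot = %g, Stot = %g (abundance-units)\n",
              x$R1tot, x$R2tot, x$Stot))
  invisible(x)
}

#' Steady-state ligand-receptor complex of the minimal model
#'
#' Solves the equilibrium relation
#' `LRC = K1 * L * (R1tot - LRC) * (R2tot - LRC)` for its unique physically
#' admissible root, the smaller root of the quadratic, which satisfies
#' `0 <= LRC <= min(R1tot, R2tot)`.  The smaller root is evaluated with the
#' numerically stable formula `2c / (-b + sqrt(b^2 - 4ac))`; when
#' `K1 * L * R1tot * R2tot` underflows the linearized solution
#' `K1 * L * R1tot * R2tot` is returned to avoid catastrophic cancellation.
#'
#' @param p a [minimal_params()] object.
#' @return Equilibrium LRC (abundance-units).
#' @export
lrc_equilibrium <- function(p) {
  stopifnot(inherits(p, "minimal_params"))
  kl <- p$K1 * p$L
  r1 <- p$R1tot
  r2 <- p$R2tot
  if (kl == 0 || r1 == 0 || r2 == 0) return(0)
  c0 <- kl * r1 * r2
  if (c0 < 1e-300) return(c0)          # linearized limit, LRC << min(R1,R2)
  # kl*LRC^2 - (kl*(r1+r2) + 1)*LRC + kl*r1*r2 = 0; b < 0 always
  b <- -(kl * (r1 + r2) + 1)
  disc <- b * b - 4 * kl * c0
  disc <- max(disc, 0)                 # clamp roundoff at the double root
  lrc <- 2 * c0 / (-b + sqrt(disc))
  min(lrc, r1, r2)                     # guard roundoff above the bound
}

#' Steady-state TGF-beta signaling activity of the minimal model
#'
#' `Sa = Stot * K2 * LRC / (1 + K2 * LRC)` with LRC from
#' [lrc_equilibrium()]: the phosphorylated fraction of total SMAD scaled by
#' `Stot`.  Monotone nondecreasing in each of `L`, `K1`, `K2`, `R1tot`,
#' `R2tot`, and strictly below `Stot`.
#'
#' @param p a [minimal_params()] object.
#' @param fraction if `TRUE`, return the fraction `Sa / Stot` instead of
#'   abundance-units.
#' @return Signaling activity (abundance-units, or fraction of `Stot`).
#' @export
signaling_activity <- function(p, fraction = FALSE) {
  lrc <- lrc_equilibrium(p)
  frac <- p$K2 * lrc / (1 + p$K2 * lrc)
  if (fraction) frac else p$Stot * frac
}

#' Receptor-abundance landscape of minimal-model signaling activity
#'
#' Evaluates [signaling_activity()] on a log-spaced 2-D grid of total
#' receptor abundances, emulating a response landscape over receptor
#' expression numbers spanning several orders of magnitude.
#'
#' @param p a [minimal_params()] object (its `R1tot`/`R2tot` are ignored).
#' @param n_per_axis grid points per axis (>= 2).
#' @param decades total log10 span of each axis (>= 1).
#' @param center geometric center of both axes (abundance-units).
#' @return An object of class `minimal_scan`: list with `r1_axis`, `r2_axis`
#'   and the `n_per_axis` x `n_per_axis` matrix `sa_matrix` (rows index
#'   `r1_axis`).
#' @export
receptor_grid_scan <- function(p, n_per_axis = 41, decades = 5,
                               center = 10^2.5) {
  stopifnot(inherits(p, "minimal_params"))
  if (n_per_axis < 2) stop("n_per_axis must be >= 2", call. = FALSE)
  if (decades < 1) stop("decades must be >= 1", call. = FALSE)
  if (center <= 0) stop("center must be > 0", call. = FALSE)
  half <- decades / 2
  axis <- 10^seq(log10(center) - half, log10(center) + half,
                 length.out = n_per_axis)
  sa <- matrix(NA_real_, n_per_axis, n_per_axis)
  for (i in seq_len(n_per_axis)) {
    for (j in seq_len(n_per_axis)) {
      pij <- p
      pij$R1tot <- axis[i]
      pij$R2tot <- axis[j]
      sa[i, j] <- signaling_activity(pij)
    }
  }
  structure(list(r1_axis = axis, r2_axis = axis, sa_matrix = sa,
                 params = p),
            class = "minimal_scan")
}

#' Log-log sensitivity (elasticity) of signaling activity to a receptor
#'
#' Central finite-difference estimate of `d ln(Sa) / d ln(Rtot)`.  In the
#' strongly imbalanced high-affinity regime the elasticity with respect to
#' the scarce receptor is much larger than that with respect to the abundant
#' one — the minimum principle in differential form.
#'
#' @param p a [minimal_params()] object with `Sa > 0`.
#' @param receptor `"R1"` or `"R2"`.
#' @param rel_step relative step of the central difference, in (0, 0.5].
#' @return Dimensionless elasticity.
#' @export
log_elasticity <- function(p, receptor = c("R1", "R2"), rel_step = 1e-4) {
  receptor <- match.arg(receptor)
  if (rel_step <= 0 || rel_step > 0.5)
    stop("rel_step must be in (0, 0.5]", call. = FALSE)
  if (signaling_activity(p) <= 0)
    stop("elasticity undefined: Sa = 0 at the evaluation point",
         call. = FALSE)
  field <- if (receptor == "R1") "R1tot" else "R2tot"
  up <- p; up[[field]] <- p[[field]] * (1 + rel_step)
  dn <- p; dn[[field]] <- p[[field]] / (1 + rel_step)
  (log(signaling_activity(up)) - log(signaling_activity(dn))) /
    (2 * log(1 + rel_step))
}
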