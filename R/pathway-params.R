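#' @useDynLib liebigsmad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Order of the kinetic parameter vector handed to the C++ RHS/integrator.
# Must match src/pathway_ode.cpp.
.PARAM_ORDER <- c("pR1", "pR2", "pS2", "kdeg_R1", "kdeg_R2", "kdeg_S2",
                  "ki", "kr", "ka", "k_NFR", "kphos", "kdephos",
                  "kin", "kex", "kin_p", "vol_ratio_nc", "med_scale")

# State vector layout; must match src/pathway_ode.cpp.
.STATE_NAMES <- c("L", "R1m", "R2m", "R1e", "R2e", "LRCm", "LRCe",
                  "S2c", "S2n", "pS2c", "pS2n")

#' Kinetic parameters of the extended TGF-beta pathway model
#'
#' Constructs the full parameter set of the mass-action ODE model: receptor
#' synthesis and turnover, internalization/recycling, one-step ligand-receptor
#' complex formation with medium depletion, ligand-induced complex degradation
#' (the negative feedback, `k_NFR`), SMAD2 phosphorylation by the endosomal
#' complex, nucleocytoplasmic shuttling and nuclear dephosphorylation.
#'
#' All first-order constants are per minute; `ka` is per (nM * abundance-unit
#' * min); amounts are in arbitrary abundance-units and the medium ligand in
#' nM.  By default SMAD2 is conserved (`pS2 = kdeg_S2 = 0`) with total
#' abundance `S2tot`; supplying a measured half-life via `half_life_R1` etc.
#' sets the corresponding degradation constant to `log(2) / t_half`.
#'
#' @param preset preset name; `"hacat_like"` is a keratinocyte-like cell with
#'   balanced receptor expression, `"r1_rich"` / `"r2_rich"` raise one
#'   receptor's production 10-fold (imbalanced cancer-line analogues).
#' @param ... named overrides of individual fields.
#' @param half_life_R1,half_life_R2,half_life_S2 optional protein half-lives
#'   (min); each overrides the corresponding `kdeg_*` as `log(2) / t_half`.
#' @return An object of class `pathway_params` (validated named list).
#' @examples
#' p <- pathway_params("hacat_like")
#' tc <- simulate_pathway(p, dose_nM = 0.1, t_grid = seq(0, 480, by = 5))
#' @export
pathway_params <- function(preset = c("hacat_like", "r1_rich", "r2_rich"),
                           ..., half_life_R1 = NULL, half_life_R2 = NULL,
                           half_life_S2 = NULL) {
  preset <- match.arg(preset)
  p <- .hacat_like_defaults()
  if (preset == "r1_rich") p$pR1 <- 10 * p$pR1
  if (preset == "r2_rich") p$pR2 <- 10 * p$pR2
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("pathway_params: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  if (!is.null(half_life_R1)) p$kdeg_R1 <- log(2) / half_life_R1
  if (!is.null(half_life_R2)) p$kdeg_R2 <- log(2) / half_life_R2
  if (!is.null(half_life_S2)) p$kdeg_S2 <- log(2) / half_life_S2
  p$preset <- preset
  validate_pathway_params(p)
}

# Fallback HaCaT-like preset.  Trafficking and shuttling constants follow the
# ranges established for TGF-beta receptor endocytosis and SMAD shuttling
# (internalization ~0.33/min, recycling ~0.03/min, receptor half-life ~4 h);
# ka, kphos, k_NFR and med_scale are calibrated so that a sustained 100 pM
# stimulation from the ligand-free steady state peaks in total P-SMAD2 near
# 1 h with roughly half of SMAD2 phosphorylated at the peak.
.hacat_like_defaults <- function() {
  list(
    pR1 = 28.881,          # receptor production, abundance/min (total 1e4)
    pR2 = 28.881,
    pS2 = 0,               # SMAD2 conserved by default
    kdeg_R1 = log(2) / 240,  # receptor half-life 4 h
    kdeg_R2 = log(2) / 240,
    kdeg_S2 = 0,
    ki = 0.33,             # internalization, 1/min
    kr = 0.033,            # recycling, 1/min
    ka = 9e-4,             # complex formation, 1/(nM*abundance*min)
    k_NFR = 0.0375,        # ligand-induced complex degradation, 1/min
    kphos = 6e-5,          # phosphorylation, 1/(abundance*min)
    kdephos = 0.09,        # nuclear dephosphorylation, 1/min
    kin = 0.16,            # SMAD2 nuclear import, 1/min
    kex = 0.34,            # SMAD2 nuclear export, 1/min
    kin_p = 0.16,          # P-SMAD2 nuclear import, 1/min
    vol_ratio_nc = 1 / 3,  # nuclear:cytoplasmic volume ratio
    med_scale = 6e-6,      # nM ligand consumed per complex formed
    mw_ligand = 25,        # TGF-beta1 molar mass, kDa
    S2tot = 6e4            # total SMAD2 in conservation mode
  )
}

validate_pathway_params <- function(p) {
  num <- setdiff(names(.hacat_like_defaults()), character())
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("pathway_params: `", nm, "` must be a finite numeric scalar",
           call. = FALSE)
    if (v < 0)
      stop("pathway_params: `", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$vol_ratio_nc <= 0)
    stop("pathway_params: vol_ratio_nc must be > 0", call. = FALSE)
  if (p$mw_ligand <= 0)
    stop("pathway_params: mw_ligand must be > 0", call. = FALSE)
  class(p) <- "pathway_params"
  p
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("Extended TGF-beta pathway parameters (preset: ",
      x$preset %||% "custom", ")\n", sep = "")
  nm <- setdiff(names(x), "preset")
  for (n in nm) cat(sprintf("  %-12s %g\n", n, x[[n]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric vector in C++ order.
param_vector <- function(p) {
  vapply(.PARAM_ORDER, function(nm) p[[nm]], numeric(1))
}

#' Convert a ligand dose between molar and mass concentration
#'
#' `pM -> ng/mL`: mass = molar * molar-mass; e.g. 100 pM of a 25 kDa ligand
#' is 2.5 ng/mL.
#'
#' @param value dose value (>= 0).
#' @param direction `"pM_to_ng_per_mL"` or `"ng_per_mL_to_pM"`.
#' @param mw molar mass in kDa (> 0).
#' @return Converted dose.
#' @examples
#' dose_convert(100, "pM_to_ng_per_mL", mw = 25)  # 2.5
#' @export
dose_convert <- function(value, direction = c("pM_to_ng_per_mL",
                                              "ng_per_mL_to_pM"),
                         mw = 25) {
  direction <- match.arg(direction)
  if (any(value < 0)) stop("dose must be >= 0", call. = FALSE)
  if (mw <= 0) stop("mw must be > 0", call. = FALSE)
  # 1 pM = 1e-12 mol/L; mass/L = 1e-12 * mw * 1e6 g = mw * 1e-6 g/L
  # = mw * 1e-3 ng/mL per pM
  if (direction == "pM_to_ng_per_mL") value * mw * 1e-3
  else value / (mw * 1e-3)
}
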