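#' Relative P-SMAD2 time series
#'
#' The whole-cell phosphorylated fraction of SMAD2,
#' `(pS2c + pS2n) / (S2c + S2n + pS2c + pS2n)`, the immunoblot-style
#' normalization that makes responses comparable across cells with different
#' SMAD2 abundance.  Always in `[0, 1]` and invariant to rescaling all SMAD2
#' pools by a common factor.
#'
#' @param tc a `timecourse` from [simulate_pathway()].
#' @return An `observable_series`: data.frame with `t`, `value` and
#'   attribute `kind = "relative_psmad2"`.
#' @export
relative_psmad2 <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  s <- tc$states
  tot <- s[, "S2c"] + s[, "S2n"] + s[, "pS2c"] + s[, "pS2n"]
  if (any(tot <= 0))
    stop("relative P-SMAD2 undefined: zero total SMAD2", call. = FALSE)
  observable_series(tc$t, (s[, "pS2c"] + s[, "pS2n"]) / tot,
                    "relative_psmad2")
}

#' Nuclear-to-cytoplasmic SMAD2 ratio and fold change
#'
#' Imaging-style readout: total SMAD2 (phosphorylated or not, as reported by
#' a fluorescent SMAD2 fusion) per unit volume in the nucleus divided by the
#' same in the cytoplasm,
#' `N2C(t) = [(S2n + pS2n) / Vn] / [(S2c + pS2c) / Vc]`, computed via the
#' nuclear:cytoplasmic volume ratio.  The fold change divides by `N2C(0)`
#' (per-cell normalization to the pre-stimulation frame), so the volume
#' ratio cancels and the series starts at exactly 1.
#'
#' @param tc a `timecourse`; its grid must include `t = 0`.
#' @param vol_ratio_nc nuclear:cytoplasmic volume ratio; defaults to the
#'   simulation's parameter value.
#' @param fold_change if `FALSE`, return the absolute N2C ratio instead.
#' @return An `observable_series` of kind `"n2c_fold_change"` (or `"n2c"`).
#' @export
n2c_fold_change <- function(tc, vol_ratio_nc = NULL, fold_change = TRUE) {
  stopifnot(inherits(tc, "timecourse"))
  if (tc$t[1] != 0) stop("t = 0 must be on the grid", call. = FALSE)
  if (is.null(vol_ratio_nc)) vol_ratio_nc <- tc$params$vol_ratio_nc
  s <- tc$states
  cyt <- s[, "S2c"] + s[, "pS2c"]
  if (any(cyt <= 0))
    stop("N2C undefined: zero cytoplasmic SMAD2", call. = FALSE)
  n2c <- ((s[, "S2n"] + s[, "pS2n"]) / vol_ratio_nc) / cyt
  # vol_ratio_nc scales nuclear concentration: amounts / (Vn/Vc) over cyt
  if (!fold_change) return(observable_series(tc$t, n2c, "n2c"))
  observable_series(tc$t, n2c / n2c[1], "n2c_fold_change")
}

observable_series <- function(t, value, kind) {
  structure(data.frame(t = t, value = value),
            kind = kind, class = c("observable_series", "data.frame"))
}

#' Total (whole-lysate) P-SMAD2 time series
#'
#' `pS2c + pS2n`, the immunoblot analogue of overall SMAD2 phosphorylation.
#'
#' @param tc a `timecourse`.
#' @return An `observable_series` of kind `"total_psmad2"`.
#' @export
total_psmad2 <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  observable_series(tc$t, tc$states[, "pS2c"] + tc$states[, "pS2n"],
                    "total_psmad2")
}

# All fit-ready observables of a time course, as a named list of numeric
# vectors aligned with tc$t.  Names match the synthetic dataset's
# `observable` column.
timecourse_observables <- function(tc) {
  s <- tc$states
  list(
    medium_tgfb  = s[, "L"],
    total_psmad2 = s[, "pS2c"] + s[, "pS2n"],
    cyt_smad2    = s[, "S2c"],
    cyt_psmad2   = s[, "pS2c"],
    nuc_smad2    = s[, "S2n"],
    nuc_psmad2   = s[, "pS2n"]
  )
}
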