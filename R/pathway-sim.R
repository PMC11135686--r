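#' Right-hand side of the extended pathway ODE system
#'
#' Pure-R reference implementation of the mass-action derivative; the
#' integrator itself uses an equivalent compiled version.  Every bimolecular
#' or transport term appears with opposite signs in its source and sink pools;
#' only synthesis (`pR1`, `pR2`, `pS2`), degradation (`kdeg_*`, `k_NFR`) and
#' medium depletion (`med_scale`) break that antisymmetry, so total SMAD2 is
#' conserved whenever `pS2 = kdeg_S2 = 0`.
#'
#' @param state named numeric state vector (see [pathway_state()]).
#' @param p a [pathway_params()] object.
#' @param compiled use the compiled RHS instead of the R reference.
#' @return Named derivative vector (per minute).
#' @export
pathway_rhs <- function(state, p, compiled = FALSE) {
  stopifnot(inherits(p, "pathway_params"))
  state <- state[.STATE_NAMES]
  if (anyNA(state)) stop("state must contain ", paste(.STATE_NAMES,
    collapse = ", "), call. = FALSE)
  if (compiled) {
    d <- cpp_pathway_rhs(unname(as.numeric(state)), param_vector(p))
    names(d) <- .STATE_NAMES
    return(d)
  }
  s <- as.list(state)
  bind <- p$ka * s$L * s$R1m * s$R2m
  phos <- p$kphos * s$LRCe * s$S2c
  d <- c(
    L    = -p$med_scale * bind,
    R1m  = p$pR1 - (p$ki + p$kdeg_R1) * s$R1m + p$kr * s$R1e - bind,
    R2m  = p$pR2 - (p$ki + p$kdeg_R2) * s$R2m + p$kr * s$R2e - bind,
    R1e  = p$ki * s$R1m - (p$kr + p$kdeg_R1) * s$R1e,
    R2e  = p$ki * s$R2m - (p$kr + p$kdeg_R2) * s$R2e,
    LRCm = bind - p$ki * s$LRCm,
    LRCe = p$ki * s$LRCm - p$k_NFR * s$LRCe,
    S2c  = p$pS2 - p$kdeg_S2 * s$S2c - phos - p$kin * s$S2c + p$kex * s$S2n,
    S2n  = p$kin * s$S2c - p$kex * s$S2n + p$kdephos * s$pS2n,
    pS2c = phos - p$kin_p * s$pS2c,
    pS2n = p$kin_p * s$pS2c - p$kdephos * s$pS2n
  )
  d
}

#' Construct a pathway state vector
#'
#' @param ... named state components among `L, R1m, R2m, R1e, R2e, LRCm,
#'   LRCe, S2c, S2n, pS2c, pS2n`; unnamed components default to 0.
#' @return Named numeric vector of length 11.
#' @export
pathway_state <- function(...) {
  s <- stats::setNames(numeric(length(.STATE_NAMES)), .STATE_NAMES)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .STATE_NAMES)
    if (length(bad))
      stop("unknown state component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    s[names(dots)] <- dots
  }
  s
}

#' Ligand-free pre-stimulation steady state
#'
#' With `L = 0` the model decouples into a linear receptor-trafficking
#' subsystem and passive SMAD2 shuttling, so the steady state is available in
#' closed form: each receptor's total equals `production / degradation`
#' (flux balance), split between surface and endosome by the
#' internalization/recycling cycle; SMAD2 partitions as `kin/kex`; all
#' complexes and P-SMAD2 are zero.  This state is the `t = 0` initial
#' condition for every stimulation.
#'
#' @param p a [pathway_params()] object.
#' @return Named steady-state vector (class as [pathway_state()]).
#' @export
presimulation_steady_state <- function(p) {
  stopifnot(inherits(p, "pathway_params"))
  rec <- function(prod, kdeg) {
    if (prod == 0) return(c(m = 0, e = 0))
    if (kdeg == 0)
      stop("no steady state: production without degradation", call. = FALSE)
    # surface: prod - (ki+kdeg) m + kr e = 0 ; endosome: ki m = (kr+kdeg) e
    m <- prod * (p$kr + kdeg) / (kdeg * (p$ki + p$kr + kdeg))
    e <- p$ki * m / (p$kr + kdeg)
    c(m = m, e = e)
  }
  r1 <- rec(p$pR1, p$kdeg_R1)
  r2 <- rec(p$pR2, p$kdeg_R2)
  if (p$pS2 > 0 || p$kdeg_S2 > 0) {
    if (p$kdeg_S2 == 0)
      stop("no steady state: SMAD2 production without degradation",
           call. = FALSE)
    s2c <- p$pS2 / p$kdeg_S2
  } else {
    s2c <- p$S2tot / (1 + p$kin / p$kex)
  }
  s2n <- s2c * p$kin / p$kex
  pathway_state(R1m = r1[["m"]], R1e = r1[["e"]],
                R2m = r2[["m"]], R2e = r2[["e"]],
                S2c = s2c, S2n = s2n)
}

#' Simulate the extended pathway model
#'
#' Integrates the model from the ligand-free pre-stimulation steady state
#' under a ligand schedule.  The dose schedule is a set of step changes of
#' the medium ligand concentration; the default is a single bolus at `t = 0`.
#' Integration uses an adaptive embedded Runge-Kutta 5(4) method whose steps
#' land exactly on the requested output grid (no interpolation error at
#' reported times).
#'
#' @param p a [pathway_params()] object.
#' @param dose_nM ligand bolus at `t = 0` (nM); ignored if `schedule` given.
#' @param t_grid strictly increasing output times (min), starting at 0.
#' @param schedule optional two-column matrix/data.frame `(time_min,
#'   ligand_nM)` of step set-points of the medium ligand.
#' @param init optional initial state; defaults to
#'   [presimulation_steady_state()].
#' @param rtol,atol integrator tolerances; `atol` defaults to `1e-10 *` the
#'   largest pool of the initial state.
#' @return A `timecourse` object: list with `t`, the `length(t) x 11` state
#'   matrix `states` (columns named, clipped to 0 for reporting), `dose_schedule`
#'   and `params`.
#' @export
simulate_pathway <- function(p, dose_nM = 0.1,
                             t_grid = seq(0, 480, by = 1),
                             schedule = NULL, init = NULL,
                             rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(p, "pathway_params"))
  if (t_grid[1] != 0) stop("t_grid must start at 0", call. = FALSE)
  if (any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing", call. = FALSE)
  if (is.null(schedule)) {
    schedule <- cbind(time_min = 0, ligand_nM = dose_nM)
  } else {
    schedule <- as.matrix(schedule)
    if (ncol(schedule) != 2) stop("schedule needs 2 columns", call. = FALSE)
    if (any(schedule[, 2] < 0)) stop("ligand must be >= 0", call. = FALSE)
  }
  y0 <- if (is.null(init)) presimulation_steady_state(p) else
    init[.STATE_NAMES]
  if (is.null(atol)) atol <- 1e-10 * max(y0, 1)
  res <- cpp_simulate(param_vector(p), unname(as.numeric(y0)),
                      as.numeric(t_grid),
                      as.numeric(schedule[, 1]), as.numeric(schedule[, 2]),
                      rtol, atol, 5e7)
  if (!isTRUE(res$success))
    stop(sprintf("simulation failed near t = %.4g min", res$t_fail),
         call. = FALSE)
  states <- res$y
  states[states < 0] <- 0            # clip integrator-tolerance negatives
  colnames(states) <- .STATE_NAMES
  structure(list(t = as.numeric(t_grid), states = states,
                 dose_schedule = schedule, params = p),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Pathway time course: %d time points over [%g, %g] min\n",
              length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  initial ligand %g nM; species: %s\n",
              x$dose_schedule[1, 2],
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  data.frame(t = x$t, x$states, check.names = FALSE)
}
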