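#' Mixing protocol for a subunit-exchange experiment
#'
#' Describes the two lysates, whether each is pre-equilibrated before
#' mixing, and the dilution each undergoes at the mixing instant (1:1
#' volume mixing dilutes every species of each lysate two-fold).
#'
#' @param lysate_unlabeled A [lysate()] with label `"unlabeled_tagged"`.
#' @param lysate_labeled A [lysate()] with label `"labeled_untagged"`.
#' @param equilibrate If `TRUE` (default) each lysate starts at detailed
#'   balance, computed analytically by [equilibrium_split()]. If `FALSE`,
#'   each lysate starts fully bound (all protein in complex), which lets the
#'   effect of incomplete pre-mix equilibration be explored.
#' @param dilution_factor Factor (>= 1) by which each lysate's species are
#'   diluted at mixing; 2 for equal-volume mixing.
#' @return An object of class `"mixing_protocol"`.
#' @examples
#' equivalent_protocol()
#' @export
mixing_protocol <- function(lysate_unlabeled, lysate_labeled,
                            equilibrate = TRUE, dilution_factor = 2) {
  stopifnot(inherits(lysate_unlabeled, "lysate"),
            inherits(lysate_labeled, "lysate"),
            is.logical(equilibrate), length(equilibrate) == 1L,
            is.numeric(dilution_factor), length(dilution_factor) == 1L)
  if (lysate_unlabeled$label != "unlabeled_tagged" ||
      lysate_labeled$label != "labeled_untagged")
    stop("lysates must carry their matching labels", call. = FALSE)
  if (!is.finite(dilution_factor) || dilution_factor < 1)
    stop("dilution_factor must be >= 1", call. = FALSE)
  structure(list(lysate_unlabeled = lysate_unlabeled,
                 lysate_labeled = lysate_labeled,
                 equilibrate = equilibrate,
                 dilution_factor = dilution_factor),
            class = "mixing_protocol")
}

#' Equivalent-lysate protocol (the MASE design assumption)
#'
#' Convenience constructor for the canonical design: both cultures contain
#' the complex at identical total concentrations, so the propositions
#' underlying the closed-form progress curve hold.
#'
#' @param total_A,total_B Per-lysate subunit totals (arbitrary units).
#' @param ... Passed to [mixing_protocol()].
#' @return A `"mixing_protocol"`.
#' @export
equivalent_protocol <- function(total_A = 1, total_B = 1, ...) {
  mixing_protocol(lysate(total_A, total_B, "unlabeled_tagged"),
                  lysate(total_A, total_B, "labeled_untagged"), ...)
}

# merged, diluted state at the mixing instant t = 0
initial_state <- function(protocol, rates) {
  pre <- function(lys) {
    if (protocol$equilibrate) return(equilibrium_split(lys, rates)$conc)
    x <- min(lys$total_A, lys$total_B)      # fully bound start
    conc <- if (lys$label == "unlabeled_tagged")
      c(A_TU = lys$total_A - x, B_U = lys$total_B - x, A_TU_B_U = x)
    else
      c(A_L = lys$total_A - x, B_L = lys$total_B - x, A_L_B_L = x)
    system_state(0, conc)$conc
  }
  mixed <- (pre(protocol$lysate_unlabeled) + pre(protocol$lysate_labeled)) /
    protocol$dilution_factor
  system_state(0, mixed)
}

mass_totals <- function(conc_mat) {
  A <- conc_mat[, "A_TU"] + conc_mat[, "A_L"] +
    conc_mat[, "A_TU_B_U"] + conc_mat[, "A_TU_B_L"] +
    conc_mat[, "A_L_B_U"] + conc_mat[, "A_L_B_L"]
  B <- conc_mat[, "B_U"] + conc_mat[, "B_L"] +
    conc_mat[, "A_TU_B_U"] + conc_mat[, "A_TU_B_L"] +
    conc_mat[, "A_L_B_U"] + conc_mat[, "A_L_B_L"]
  list(A = A, B = B)
}

new_trajectory <- function(times, conc, meta) {
  structure(list(times = times, conc = conc, meta = meta),
            class = "mase_trajectory")
}

#' @export
print.mase_trajectory <- function(x, ...) {
  cat(sprintf("Subunit-exchange trajectory: %d samples, t in [%g, %g] s, %s\n",
              length(x$times), min(x$times), max(x$times), x$meta$method))
  invisible(x)
}

#' @export
as.data.frame.mase_trajectory <- function(x, ...) {
  data.frame(t_seconds = rep(x$times, times = ncol(x$conc)),
             species = rep(colnames(x$conc), each = length(x$times)),
             concentration = as.vector(x$conc))
}

#' Deterministic mass-action simulation of subunit exchange
#'
#' Integrates the full eight-species reaction network after mixing: each of
#' the four complexes forms at rate `k_on * [free A variant] * [free B
#' variant]` and dissociates at rate `k_off * [complex]`. The initial state
#' is the concentration-weighted merge of the two (optionally
#' pre-equilibrated) diluted lysates. This is the brute-force oracle against
#' which the closed-form curve [exchange_ratio()] is checked.
#'
#' @param protocol A [mixing_protocol()].
#' @param rates A [rate_constants()].
#' @param t_grid Increasing sample times (seconds) starting at 0.
#' @param rtol,atol Solver tolerances. Defaults are tight because
#'   `k_on * concentration` can exceed `k_off` by many orders of magnitude,
#'   making the system stiff; the default method (lsoda) switches to a
#'   stiff integrator automatically.
#' @param method deSolve integration method.
#' @return A `"mase_trajectory"`: list with `times`, a samples-by-species
#'   concentration matrix `conc`, and solver metadata `meta`.
#' @examples
#' traj <- simulate_exchange(equivalent_protocol(),
#'                           rate_constants(1e6, 1e-3),
#'                           t_grid = seq(0, 3600, by = 600))
#' extract_R(traj)
#' @export
simulate_exchange <- function(protocol, rates, t_grid,
                              rtol = 1e-9, atol = 1e-12, method = "lsoda") {
  stopifnot(inherits(protocol, "mixing_protocol"),
            inherits(rates, "rate_constants"), is.numeric(t_grid))
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must start at 0 (the mixing instant) and increase strictly",
         call. = FALSE)
  y0 <- initial_state(protocol, rates)$conc
  kon <- rates$k_on; koff <- rates$k_off
  deriv <- function(t, y, parms) {
    vUU <- kon * y[1] * y[2]; vUL <- kon * y[1] * y[4]
    vLU <- kon * y[3] * y[2]; vLL <- kon * y[3] * y[4]
    wUU <- koff * y[5]; wUL <- koff * y[6]
    wLU <- koff * y[7]; wLL <- koff * y[8]
    list(c(-vUU - vUL + wUU + wUL,          # A_TU
          -vUU - vLU + wUU + wLU,           # B_U
          -vLU - vLL + wLU + wLL,           # A_L
          -vUL - vLL + wUL + wLL,           # B_L
          vUU - wUU, vUL - wUL, vLU - wLU, vLL - wLL))
  }
  out <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 1e6)
  diag <- attributes(out)
  if (!is.null(diag$istate) && diag$istate[1] < 0)
    stop("ODE solver failed (istate = ", diag$istate[1], "): ",
         paste(deSolve::diagnostics(out), collapse = " "), call. = FALSE)
  conc <- unname(out[, -1, drop = FALSE])
  if (any(!is.finite(conc)))
    stop("ODE solver produced non-finite concentrations", call. = FALSE)
  colnames(conc) <- MASE_SPECIES
  conc[conc < 0 & conc > -atol * 10] <- 0      # clip solver-scale undershoot
  tot <- mass_totals(conc)
  rel_dev <- max(abs(tot$A - tot$A[1]) / tot$A[1],
                 abs(tot$B - tot$B[1]) / tot$B[1])
  if (rel_dev > 1e-8)
    stop(sprintf("mass conservation violated (max rel. dev. %.3g)", rel_dev),
         call. = FALSE)
  new_trajectory(t_grid, conc,
                 meta = list(method = method, rtol = rtol, atol = atol,
                             rates = rates, protocol = protocol))
}

#' Extract the exchange progress ratio from a trajectory
#'
#' Computes `R_t = [A_TU_B_L] / [A_TU_B_U]` — hybrid over original tagged
#' complex — at every sample of a simulated trajectory. This is the
#' quantity a quantitative-proteomics readout of the affinity-purified
#' complex reports.
#'
#' @param traj A `"mase_trajectory"`.
#' @return Data frame with columns `t` (seconds) and `R`.
#' @export
extract_R <- function(traj) {
  stopifnot(inherits(traj, "mase_trajectory"))
  den <- traj$conc[, "A_TU_B_U"]
  num <- traj$conc[, "A_TU_B_L"]
  if (any(den <= 0))
    stop("original tagged complex [A_TU_B_U] is not positive at every ",
         "sample; R is undefined", call. = FALSE)
  data.frame(t = traj$times, R = num / den)
}

#' Numerical verification of the exchange-model propositions
#'
#' Checks, on a simulated trajectory, the three structural properties that
#' make the progress curve depend on `k_off` alone under equivalent
#' lysates: (1) all four free-subunit concentrations are constant; (2) the
#' total tagged complex `[A_TU_B_U] + [A_TU_B_L]` is constant; (3) the
#' ratio R approaches 1 at equilibrium. Proposition 3 is only judged when
#' the trajectory is long enough to reach equilibrium (at least `5 / k_off`
#' seconds); a shorter run reports `"not_reached"` rather than a failure.
#'
#' @param traj A `"mase_trajectory"`.
#' @param tol Relative tolerance for each check.
#' @return Object of class `"proposition_report"`: per-proposition maximum
#'   relative deviation, pass flag, and for proposition 3 a status of
#'   `"checked"` or `"not_reached"`. Always returns; never raises on a
#'   failed check.
#' @export
verify_propositions <- function(traj, tol = 1e-5) {
  stopifnot(inherits(traj, "mase_trajectory"), is.numeric(tol), tol > 0)
  conc <- traj$conc
  rel_span <- function(x) {
    scale <- max(abs(x[1]), max(abs(x)) * .Machine$double.eps, 1e-300)
    max(abs(x - x[1])) / scale
  }
  dev1 <- max(vapply(c("A_TU", "B_U", "A_L", "B_L"),
                     function(s) rel_span(conc[, s]), numeric(1)))
  dev2 <- rel_span(conc[, "A_TU_B_U"] + conc[, "A_TU_B_L"])
  k_off <- traj$meta$rates$k_off
  horizon_ok <- max(traj$times) >= 5 / k_off
  if (horizon_ok) {
    Rfin <- conc[nrow(conc), "A_TU_B_L"] / conc[nrow(conc), "A_TU_B_U"]
    dev3 <- abs(Rfin - 1)
    status3 <- "checked"
  } else {
    dev3 <- NA_real_
    status3 <- "not_reached"
  }
  structure(list(
    tol = tol,
    free_subunits = list(max_rel_dev = dev1, pass = dev1 <= tol),
    tagged_complex_total = list(max_rel_dev = dev2, pass = dev2 <= tol),
    equilibrium_ratio = list(dev = dev3, status = status3,
                             pass = if (horizon_ok) dev3 <= tol else NA)
  ), class = "proposition_report")
}

#' @export
print.proposition_report <- function(x, ...) {
  fmt <- function(p) if (isTRUE(p)) "PASS" else if (isFALSE(p)) "FAIL" else "--"
  cat(sprintf("Proposition checks (tol %g):\n", x$tol))
  cat(sprintf("  (1) free subunits constant:     max rel dev %.3g  [%s]\n",
              x$free_subunits$max_rel_dev, fmt(x$free_subunits$pass)))
  cat(sprintf("  (2) tagged complex total const: max rel dev %.3g  [%s]\n",
              x$tagged_complex_total$max_rel_dev,
              fmt(x$tagged_complex_total$pass)))
  if (x$equilibrium_ratio$status == "checked")
    cat(sprintf("  (3) R -> 1 at equilibrium:      |R - 1| = %.3g  [%s]\n",
                x$equilibrium_ratio$dev, fmt(x$equilibrium_ratio$pass)))
  else
    cat("  (3) R -> 1 at equilibrium:      not reached (horizon < 5/k_off)\n")
  invisible(x)
}
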