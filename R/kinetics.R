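#' Association/dissociation rate constants
#'
#' Bundles the kinetic parameters of the reversible binding reaction
#' \eqn{A + B \rightleftharpoons AB}: the bimolecular association rate
#' constant `k_on` (concentration^-1 s^-1, arbitrary concentration units)
#' and the unimolecular dissociation rate constant `k_off` (s^-1).
#'
#' @param k_on Association rate constant, > 0 and finite.
#' @param k_off Dissociation rate constant (s^-1), > 0 and finite.
#' @return An object of class `"rate_constants"`.
#' @examples
#' rate_constants(k_on = 1e6, k_off = 1e-4)
#' @export
rate_constants <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L,
            is.numeric(k_off), length(k_off) == 1L)
  if (!is.finite(k_on) || k_on <= 0)
    stop("k_on must be finite and > 0", call. = FALSE)
  if (!is.finite(k_off) || k_off <= 0)
    stop("k_off must be finite and > 0", call. = FALSE)
  structure(list(k_on = as.numeric(k_on), k_off = as.numeric(k_off)),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("Rate constants: k_on = %g (conc^-1 s^-1), k_off = %g (s^-1); Kd = %g\n",
              x$k_on, x$k_off, x$k_off / x$k_on))
  invisible(x)
}

#' Composition of one cell lysate before mixing
#'
#' Total (free + bound) concentrations of the two subunits in a single
#' lysate, together with its isotope/tag identity. In the MASE design the
#' `"unlabeled_tagged"` lysate carries affinity-tagged unlabeled protein
#' (species `A_TU`, `B_U`, complex `A_TU_B_U`) and the `"labeled_untagged"`
#' lysate carries the metabolically labeled wild-type protein (`A_L`, `B_L`,
#' `A_L_B_L`).
#'
#' @param total_A,total_B Total subunit concentrations (arbitrary units,
#'   >= 0).
#' @param label One of `"unlabeled_tagged"` or `"labeled_untagged"`.
#' @return An object of class `"lysate"`.
#' @examples
#' lysate(1, 1, "unlabeled_tagged")
#' @export
lysate <- function(total_A, total_B,
                   label = c("unlabeled_tagged", "labeled_untagged")) {
  label <- match.arg(label)
  stopifnot(is.numeric(total_A), length(total_A) == 1L,
            is.numeric(total_B), length(total_B) == 1L)
  if (!is.finite(total_A) || total_A < 0 || !is.finite(total_B) || total_B < 0)
    stop("subunit totals must be finite and >= 0", call. = FALSE)
  structure(list(total_A = as.numeric(total_A),
                 total_B = as.numeric(total_B), label = label),
            class = "lysate")
}

#' System state: concentrations of all eight species at one instant
#'
#' @param t Time since mixing (seconds, >= 0).
#' @param conc Named numeric vector over [MASE_SPECIES] (non-negative);
#'   missing species default to 0.
#' @return An object of class `"system_state"`: list with `t` and the full
#'   named concentration vector `conc`.
#' @export
system_state <- function(t, conc) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t), t >= 0,
            is.numeric(conc), !is.null(names(conc)))
  unknown <- setdiff(names(conc), MASE_SPECIES)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  full <- setNames(numeric(length(MASE_SPECIES)), MASE_SPECIES)
  full[names(conc)] <- conc
  if (any(!is.finite(full)) || any(full < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  structure(list(t = as.numeric(t), conc = full), class = "system_state")
}

check_koff_t <- function(k_off, t) {
  if (!is.numeric(k_off) || !is.numeric(t))
    stop("k_off and t must be numeric", call. = FALSE)
  if (any(!is.finite(k_off)) || any(k_off <= 0))
    stop("k_off must be finite and > 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
}

#' Closed-form exchange progress curve
#'
#' The abundance ratio \eqn{R_t} of hybrid tagged complex to original tagged
#' complex, as a function of time since mixing and the dissociation rate
#' constant alone:
#' \deqn{R_t = \frac{1 - e^{-k_{off} t}}{1 + e^{-k_{off} t}}
#'           = \tanh(k_{off} t / 2).}
#' With equivalent lysates the free-subunit pool is constant, so the hybrid
#' complex relaxes exponentially toward parity with the original complex and
#' the progress ratio depends on `k_off` only — not on `k_on` or on any
#' concentration.
#'
#' @param k_off Dissociation rate constant (s^-1), > 0. Recycled against `t`.
#' @param t Time since mixing (seconds, >= 0).
#' @return Dimensionless ratio in \[0, 1): 0 at `t = 0`, strictly increasing
#'   in both arguments, approaching 1 at equilibrium.
#' @examples
#' exchange_ratio(1e-5, 8 * 3600)   # ~0.14: slow complex after 8 h
#' exchange_ratio(1e-3, 2 * 3600)   # ~1: fast complex equilibrated in 2 h
#' @seealso [invert_ratio()], [exchange_sensitivity()]
#' @export
exchange_ratio <- function(k_off, t) {
  check_koff_t(k_off, t)
  tanh(k_off * t / 2)
}

#' Single-point analytic inversion of the progress curve
#'
#' Recovers the unique `k_off` for which [exchange_ratio()] equals `R` at
#' time `t`: \eqn{k_{off} = \log((1+R)/(1-R)) / t}. A measured ratio at one
#' informative time point therefore carries a point estimate of the
#' dissociation rate.
#'
#' @param R Observed ratio, strictly inside (0, 1). `R = 0` (no exchange
#'   yet) and `R >= 1` (at or past equilibrium) carry no finite single-point
#'   estimate and raise an error.
#' @param t Time since mixing (seconds, > 0).
#' @return Dissociation rate constant (s^-1).
#' @examples
#' invert_ratio(0.14, 8 * 3600)     # ~1e-5 s^-1
#' @export
invert_ratio <- function(R, t) {
  if (!is.numeric(R) || !is.numeric(t))
    stop("R and t must be numeric", call. = FALSE)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0", call. = FALSE)
  if (any(!is.finite(R)) || any(R <= 0) || any(R >= 1))
    stop("R must lie strictly inside (0, 1): R = 0 carries no rate ",
         "information and R >= 1 is at/past equilibrium", call. = FALSE)
  log((1 + R) / (1 - R)) / t
}

#' Sensitivity of the progress ratio to the dissociation rate
#'
#' \eqn{\partial R_t / \partial k_{off} = (t/2)\,\mathrm{sech}^2(k_{off}t/2)},
#' the local information a ratio measurement at time `t` carries about
#' `k_off`. Zero at `t = 0`, peaks at `t` about `1.543 / k_off`, and decays
#' as the curve saturates.
#'
#' @inheritParams exchange_ratio
#' @return Sensitivity in units of seconds (dimensionless ratio per s^-1).
#' @seealso [peak_sensitivity_time()]
#' @export
exchange_sensitivity <- function(k_off, t) {
  check_koff_t(k_off, t)
  (t / 2) / cosh(k_off * t / 2)^2
}

#' Most informative sampling time for a given dissociation rate
#'
#' Numerically maximizes [exchange_sensitivity()] over `t`. The maximizer
#' scales as `1/k_off` (the product `k_off * t*` is a universal constant,
#' about 1.5434), so one informative time point per decade of candidate
#' rates covers a prior range.
#'
#' @param k_off Dissociation rate constant (s^-1), scalar > 0.
#' @return Time (seconds) of maximal sensitivity.
#' @export
peak_sensitivity_time <- function(k_off) {
  check_koff_t(k_off, 0)
  stopifnot(length(k_off) == 1L)
  optimize(function(t) exchange_sensitivity(k_off, t),
           interval = c(0, 20 / k_off), maximum = TRUE,
           tol = 1e-10 / k_off)$maximum
}

#' Equilibrium partition of a lysate into free and bound subunits
#'
#' Before mixing, each lysate is incubated until the binding reaction is at
#' detailed balance, \eqn{k_{on}[A][B] = k_{off}[AB]}. With totals
#' \eqn{A_0, B_0} and \eqn{K_d = k_{off}/k_{on}}, the bound concentration is
#' the smaller root of \eqn{x^2 - (A_0 + B_0 + K_d)x + A_0 B_0 = 0} (the
#' larger root exceeds \eqn{\min(A_0, B_0)} and would force a negative free
#' concentration).
#'
#' @param lys A [lysate()].
#' @param rates A [rate_constants()].
#' @return A [system_state()] at `t = 0` in which only the lysate's own
#'   species are populated.
#' @examples
#' eq <- equilibrium_split(lysate(1, 1), rate_constants(1, 1))
#' eq$conc[["A_TU_B_U"]]    # (3 - sqrt(5))/2
#' @export
equilibrium_split <- function(lys, rates) {
  stopifnot(inherits(lys, "lysate"), inherits(rates, "rate_constants"))
  A0 <- lys$total_A; B0 <- lys$total_B
  Kd <- rates$k_off / rates$k_on
  # Solve for the free concentration of the scarcer subunit: with
  # m = min(A0,B0), M = max(A0,B0), d = M - m, the free scarcer-subunit
  # concentration a solves a^2 + (d + Kd) a - Kd m = 0, whose positive root
  # in the cancellation-free form is
  #   a = 2 Kd m / (d + Kd + sqrt((d + Kd)^2 + 4 Kd m)).
  # All terms are non-negative, so no subtraction loses precision; the
  # bound complex then comes from detailed balance itself, x = a b / Kd.
  m <- min(A0, B0); M <- max(A0, B0); d <- M - m
  a <- 2 * Kd * m / (d + Kd + sqrt((d + Kd)^2 + 4 * Kd * m))
  b <- d + a
  x <- a * b / Kd
  free_A <- if (A0 <= B0) a else b
  free_B <- if (A0 <= B0) b else a
  conc <- if (lys$label == "unlabeled_tagged")
    c(A_TU = free_A, B_U = free_B, A_TU_B_U = x)
  else
    c(A_L = free_A, B_L = free_B, A_L_B_L = x)
  system_state(0, conc)
}
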