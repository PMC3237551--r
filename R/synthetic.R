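#' Measurement noise model for isotope-ratio quantification
#'
#' Emulates how a quantitative-proteomics pipeline reports the exchange
#' ratio: each protein's ratio is the median over the ratios of its
#' quantified peptides, each peptide-level ratio carrying multiplicative
#' (log-normal) error. The paper-level workflow specifies no error model,
#' so these parameters are the generator's own, chosen to match common
#' metabolic-labeling practice and fully user-settable.
#'
#' @param cv Coefficient of variation of a single peptide-level ratio
#'   (>= 0; default 0.15).
#' @param n_peptides Peptides quantified per protein (>= 1; default 5).
#' @param floor Optional lower detection limit on R (in `[0, 1)`); reported
#'   values below it are flagged as censored, never dropped.
#' @param seed Integer seed making a sampled series reproducible.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(cv = 0.15, n_peptides = 5, floor = NULL, seed = 1) {
  stopifnot(is.numeric(cv), length(cv) == 1L, is.finite(cv), cv >= 0,
            is.numeric(n_peptides), length(n_peptides) == 1L, n_peptides >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (!is.null(floor)) {
    stopifnot(is.numeric(floor), length(floor) == 1L)
    if (!is.finite(floor) || floor < 0 || floor >= 1)
      stop("floor must lie in [0, 1)", call. = FALSE)
  }
  structure(list(cv = cv, n_peptides = as.integer(n_peptides),
                 floor = floor, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a noisy synthetic exchange time series
#'
#' Draws, at each requested time point, `n_peptides` log-normal
#' multiplicative deviates around the true ratio [exchange_ratio()]
#' `(k_off, t)` with the model's peptide-level CV, and reports their median
#' as the measured `R` and their scaled median absolute deviation as
#' `sigma`. Points with a true ratio of exactly 0 (i.e. `t = 0`) pass
#' through as exactly 0 with `sigma = NA`. If the noise model carries a
#' detection `floor`, reported values below it are flagged `censored =
#' TRUE` but retained.
#'
#' @param k_off True dissociation rate constant (s^-1).
#' @param t_points Sampling times (seconds, >= 0), non-empty.
#' @param noise A [noise_model()].
#' @return Data frame (an exchange series) with columns `t`, `R`, `sigma`,
#'   `censored`, one row per element of `t_points`, in input order.
#' @examples
#' sample_series(1e-4, c(0, 1800, 3600, 14400), noise_model(seed = 7))
#' @export
sample_series <- function(k_off, t_points, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"), is.numeric(t_points),
            length(t_points) >= 1L)
  check_koff_t(k_off, t_points)
  mu <- exchange_ratio(k_off, t_points)
  sdlog <- sqrt(log(1 + noise$cv^2))   # log-normal sdlog giving CV = cv
  np <- noise$n_peptides
  res <- with_seed(noise$seed, {
    t(vapply(mu, function(m) {
      if (m == 0 || noise$cv == 0) return(c(R = m, sigma = NA_real_))
      x <- m * exp(rnorm(np, mean = 0, sd = sdlog))
      c(R = median(x), sigma = if (np >= 2) mad(x) else NA_real_)
    }, c(R = 0, sigma = 0)))
  })
  sigma <- res[, "sigma"]
  sigma[!is.na(sigma) & sigma == 0] <- NA_real_
  censored <- if (is.null(noise$floor)) rep(FALSE, length(mu))
              else res[, "R"] < noise$floor & t_points > 0
  data.frame(t = as.numeric(t_points), R = unname(res[, "R"]),
             sigma = unname(sigma), censored = censored)
}

#' Default sampling design over a prior range of dissociation rates
#'
#' Places `n_points` sampling times for an experiment whose complex has an
#' unknown `k_off` believed to lie in `[k_off_prior_low, k_off_prior_high]`:
#' always `t = 0` (anchoring R = 0), plus points log-spaced from
#' `0.1 / k_off_prior_high` (early exchange of the fastest candidate) to
#' `3 / k_off_prior_low` (near-equilibrium of the slowest), capped at
#' `horizon`. The candidate closest in log-time to the peak-sensitivity
#' time of the geometric-mean rate, `1.543 / sqrt(low * high)`, is replaced
#' by that time, so the most informative region is always sampled.
#'
#' @param k_off_prior_low,k_off_prior_high Prior bounds on the rate
#'   (s^-1), `0 < low <= high`.
#' @param n_points Total number of time points (>= 3), including `t = 0`.
#' @param horizon Maximum practical incubation time (seconds; default 8 h).
#' @return Increasing vector of `n_points` distinct times (seconds),
#'   starting at 0, all `<= horizon`.
#' @examples
#' default_design(1e-5, 1e-3, n_points = 9)
#' @export
default_design <- function(k_off_prior_low, k_off_prior_high, n_points,
                           horizon = 8 * 3600) {
  stopifnot(is.numeric(k_off_prior_low), is.numeric(k_off_prior_high),
            is.numeric(n_points), length(n_points) == 1L,
            is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (!(k_off_prior_low > 0 && k_off_prior_low <= k_off_prior_high))
    stop("need 0 < k_off_prior_low <= k_off_prior_high", call. = FALSE)
  if (n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  lo <- 0.1 / k_off_prior_high
  hi <- min(3 / k_off_prior_low, horizon)
  if (hi <= lo)
    stop("horizon is shorter than the earliest informative time point",
         call. = FALSE)
  cand <- exp(seq(log(lo), log(hi), length.out = n_points - 1))
  t_star <- min(1.5434 / sqrt(k_off_prior_low * k_off_prior_high), horizon)
  cand[which.min(abs(log(cand) - log(t_star)))] <- t_star
  pts <- sort(unique(c(0, cand)))
  if (length(pts) != n_points)
    stop("degenerate design: replacement collapsed two time points",
         call. = FALSE)
  pts
}
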