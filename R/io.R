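#' Read an exchange time series from delimited text
#'
#' Expects a header line `t_seconds,R[,sigma][,censored]`; the delimiter
#' (comma or tab) is auto-detected from the header. Rows are validated
#' individually and rejected with errors naming the offending line and
#' column. Duplicate times are allowed (replicate measurements).
#'
#' @param path Path to a CSV/TSV file.
#' @return Data frame ordered by `t` with columns `t`, `R`, `sigma`,
#'   `censored` (the package's exchange-series layout).
#' @seealso [write_series()]
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("parse error in ", path, ": need a header line and at least one ",
         "data row", call. = FALSE)
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(lines[1], delim, fixed = TRUE)[[1]])
  required <- c("t_seconds", "R")
  missing <- setdiff(required, header)
  if (length(missing))
    stop("parse error in ", path, " line 1: missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(c("t_seconds", "R", "sigma", "censored"), header)
  parse_num <- function(field, line_no, col) {
    if (is.na(field) || field %in% c("", "NA")) return(NA_real_)
    x <- suppressWarnings(as.numeric(field))
    if (is.na(x))
      stop(sprintf("parse error in %s line %d, column '%s': '%s' is not numeric",
                   path, line_no, col, field), call. = FALSE)
    x
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- trimws(strsplit(lines[i], delim, fixed = TRUE)[[1]])
    t <- parse_num(f[idx[1]], i, "t_seconds")
    R <- parse_num(f[idx[2]], i, "R")
    if (is.na(t) || is.na(R))
      stop(sprintf("parse error in %s line %d: t_seconds and R are required",
                   path, i), call. = FALSE)
    if (t < 0)
      stop(sprintf("parse error in %s line %d, column 't_seconds': negative time",
                   path, i), call. = FALSE)
    if (R < 0)
      stop(sprintf("parse error in %s line %d, column 'R': negative ratio",
                   path, i), call. = FALSE)
    sigma <- if (!is.na(idx[3])) parse_num(f[idx[3]], i, "sigma") else NA_real_
    if (is.finite(sigma) && sigma <= 0)
      stop(sprintf("parse error in %s line %d: sigma must be positive when present",
                   path, i), call. = FALSE)
    cens <- if (!is.na(idx[4]) && !is.na(f[idx[4]]) && f[idx[4]] != "")
      as.logical(f[idx[4]]) else FALSE
    if (is.na(cens))
      stop(sprintf("parse error in %s line %d, column 'censored': '%s' is not logical",
                   path, i, f[idx[4]]), call. = FALSE)
    data.frame(t = t, R = R, sigma = sigma, censored = cens)
  })
  out <- do.call(rbind, rows)
  out[order(out$t), , drop = FALSE]
}

#' Write an exchange time series as delimited text
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces them bit-identically.
#'
#' @param series Exchange-series data frame (columns `t` or `t_seconds`,
#'   `R`, optional `sigma`, `censored`).
#' @param path Output path.
#' @param delim Field delimiter: `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, delim = ",") {
  s <- as_series_df(series)
  fmt <- function(x) ifelse(is.na(x), "NA",
                            formatC(x, digits = 17, format = "g"))
  lines <- c(paste(c("t_seconds", "R", "sigma", "censored"), collapse = delim),
             paste(fmt(s$t), fmt(s$R), fmt(s$sigma),
                   ifelse(s$censored, "TRUE", "FALSE"), sep = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Theoretical exchange progress curves for a set of dissociation rates
#'
#' Tabulates (and optionally plots) the closed-form curve for each rate in
#' `k_off_list` on a common time grid — the standard multi-decade picture
#' of how strongly `k_off` separates exchange time courses over a working
#' day: a complex at 1e-3 s^-1 equilibrates within 2 h while one at
#' 1e-5 s^-1 only reaches R of about 0.14 after 8 h.
#'
#' @param k_off_list Dissociation rates (s^-1).
#' @param horizon Last time point (seconds; default 8 h).
#' @param step Grid spacing (seconds; default 60 s). If `step > horizon`
#'   the grid is just `c(0, horizon)`.
#' @param out_table Optional CSV path for the table.
#' @param out_plot Optional plot path (`.png` or `.svg`).
#' @return Data frame: `t_seconds` plus one column per rate (named
#'   `koff_<rate>`), invisibly when writing files.
#' @examples
#' head(exchange_curves(c(1e-3, 1e-4, 1e-5), step = 3600))
#' @export
exchange_curves <- function(k_off_list = c(1e-3, 1e-4, 1e-5),
                            horizon = 8 * 3600, step = 60,
                            out_table = NULL, out_plot = NULL) {
  check_koff_t(k_off_list, 0)
  stopifnot(is.numeric(horizon), horizon > 0, is.numeric(step), step > 0)
  t_grid <- if (step > horizon) c(0, horizon)
            else unique(c(seq(0, horizon, by = step), horizon))
  tab <- data.frame(t_seconds = t_grid)
  for (k in k_off_list)
    tab[[sprintf("koff_%g", k)]] <- exchange_ratio(k, t_grid)
  if (!is.null(out_table))
    utils::write.csv(format(tab, digits = 17, trim = TRUE), out_table,
                     row.names = FALSE, quote = FALSE)
  if (!is.null(out_plot)) {
    open_device(out_plot)
    on.exit(grDevices::dev.off())
    plot_curves(tab, k_off_list)
  }
  if (is.null(out_table) && is.null(out_plot)) tab else invisible(tab)
}

open_device <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = 1200, height = 900, res = 150),
         svg = grDevices::svg(path, width = 8, height = 6),
         stop("unsupported plot format: .", ext, call. = FALSE))
}

plot_curves <- function(tab, k_off_list) {
  cols <- grDevices::hcl.colors(max(3, length(k_off_list)), "Dark 3")
  plot(NA, xlim = range(tab$t_seconds) / 3600, ylim = c(0, 1),
       xlab = "time since mixing (h)", ylab = expression(R[t]))
  for (i in seq_along(k_off_list))
    graphics::lines(tab$t_seconds / 3600, tab[[i + 1]],
                    col = cols[i], lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("k_off = %g s^-1", k_off_list),
                   col = cols[seq_along(k_off_list)], lwd = 2, bty = "n")
}

#' Serialize a fit result to JSON
#'
#' Writes the scalar summary of a [fit_koff()] result (`k_off_hat`,
#' `ci_low`, `ci_high`, `rss`, `n_used`, `converged`) as a JSON object.
#'
#' @param fit A `"mase_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mase_fit"))
  jsonlite::write_json(
    list(k_off_hat = fit$k_off_hat, ci_low = fit$ci_low,
         ci_high = fit$ci_high, rss = fit$rss, n_used = fit$n_used,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read / write a run configuration
#'
#' Run configurations are plain named lists (command parameters, seed,
#' output paths, log level) serialized as YAML; reading back a written
#' configuration reproduces it exactly.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return `read_run_config` returns the named list; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
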