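#' Oscillatory rheology time sweep
#'
#' Storage and loss moduli recorded during cure at fixed frequency and
#' strain amplitude (protocol: 1 rad/s, 0.5 percent strain).
#'
#' @param time_s strictly increasing times, s.
#' @param G_prime_Pa storage modulus G', Pa, > 0.
#' @param G_double_prime_Pa loss modulus G'', Pa, > 0.
#' @param temperature_C cure temperature, metadata.
#' @param angular_frequency_rad_s metadata, default 1.
#' @param strain_pct metadata, default 0.5.
#' @param formulation sample label.
#' @param covariates optional named list (e.g. stoichiometric ratio,
#'   catalyst ppm) used by [tgel_trend()].
#' @return Object of class `bb_sweep`.
#' @export
rheology_sweep <- function(time_s, G_prime_Pa, G_double_prime_Pa,
                           temperature_C = 37, angular_frequency_rad_s = 1,
                           strain_pct = 0.5, formulation = "",
                           covariates = list()) {
  n <- length(time_s)
  bb_check(n >= 4L, "a sweep needs at least 4 samples")
  bb_check(length(G_prime_Pa) == n && length(G_double_prime_Pa) == n,
           "time and moduli columns must have equal length")
  bb_check(all(is.finite(time_s)) && all(diff(time_s) > 0),
           "time must be finite and strictly increasing")
  bb_check(all(is.finite(G_prime_Pa)) && all(G_prime_Pa > 0) &&
             all(is.finite(G_double_prime_Pa)) && all(G_double_prime_Pa > 0),
           "moduli must be finite and strictly positive")
  structure(data.frame(time_s = as.numeric(time_s),
                       G_prime_Pa = as.numeric(G_prime_Pa),
                       G_double_prime_Pa = as.numeric(G_double_prime_Pa)),
            temperature_C = temperature_C,
            angular_frequency_rad_s = angular_frequency_rad_s,
            strain_pct = strain_pct, formulation = formulation,
            covariates = covariates,
            class = c("bb_sweep", "data.frame"))
}

#' Locate the gel point in a curing time sweep
#'
#' The gel point is taken as the first sustained G'/G'' crossover: the
#' first sign change of d(t) = log G' - log G'' that stays positive for
#' min(3, remaining) consecutive samples. Single-sample flickers are
#' skipped (and counted). t_gel comes from linear interpolation of d
#' against time within the bracketing pair; moduli are interpolated in
#' log space, matching the decades G' and G'' traverse during cure.
#'
#' @param sweep a [rheology_sweep()].
#' @param median_filter apply a 3-point running median to both moduli
#'   before detection (off by default; for noisy sweeps).
#' @return Object of class `bb_gel`: `t_gel` (s), `G_cross` (Pa), the
#'   bracketing pair `bracket`, `n_crossings` (upward sign changes seen,
#'   including flickers), and `method`.
#' @section Errors: a sweep with no sign change raises a classed error
#'   distinguishing `brushmech_all_liquid` (G'' above G' throughout) from
#'   `brushmech_all_solid` (G' above G'' throughout).
#' @export
find_gel_point <- function(sweep, median_filter = FALSE) {
  stopifnot(inherits(sweep, "bb_sweep"))
  t <- sweep$time_s
  gp <- sweep$G_prime_Pa; gpp <- sweep$G_double_prime_Pa
  if (median_filter) {
    gp <- stats::runmed(gp, 3L, endrule = "keep")
    gpp <- stats::runmed(gpp, 3L, endrule = "keep")
  }
  d <- log(gp) - log(gpp)
  n <- length(d)
  if (all(d < 0)) {
    bb_error("no gel point in window: G'' exceeds G' throughout (still liquid)",
             "brushmech_all_liquid")
  }
  if (all(d > 0)) {
    bb_error("no gel point in window: G' exceeds G'' throughout (already solid)",
             "brushmech_all_solid")
  }
  ups <- which(d[-n] <= 0 & d[-1] > 0)
  n_crossings <- length(ups)
  chosen <- NA_integer_
  for (i in ups) {
    k <- min(3L, n - i)
    if (all(d[(i + 1):(i + k)] > 0)) { chosen <- i; break }
  }
  if (is.na(chosen)) {
    bb_error("no sustained gel point: only transient crossings detected",
             "brushmech_all_liquid")
  }
  i <- chosen
  if (d[i] == 0) {
    t_gel <- t[i]
    g_cross <- gp[i]
  } else {
    frac <- -d[i] / (d[i + 1] - d[i])
    t_gel <- t[i] + frac * (t[i + 1] - t[i])
    g_cross <- exp(log(gp[i]) + frac * (log(gp[i + 1]) - log(gp[i])))
  }
  structure(list(t_gel = t_gel, G_cross = g_cross,
                 bracket = c(t[i], t[i + 1]), n_crossings = n_crossings,
                 method = "first-sustained log-crossover",
                 formulation = attr(sweep, "formulation"),
                 covariates = attr(sweep, "covariates")),
            class = "bb_gel")
}

#' @export
print.bb_gel <- function(x, ...) {
  cat(sprintf("Gel point%s: t_gel = %.4g s, G_cross = %.4g Pa\n",
              if (nzchar(x$formulation)) paste0(" [", x$formulation, "]") else "",
              x$t_gel, x$G_cross))
  cat(sprintf("  bracket [%.4g, %.4g] s, %d crossing(s) examined\n",
              x$bracket[1], x$bracket[2], x$n_crossings))
  invisible(x)
}

#' Gelation-time trend across a formulation variable
#'
#' Summarizes how t_gel scales with a covariate: `"loglog"` fits
#' log(t_gel) against log(covariate) (power-law exponent = slope);
#' `"arrhenius"` fits log(t_gel) against 1/T with T in kelvin (covariate
#' given in Celsius).
#'
#' @param results data frame with a `t_gel` column and one covariate
#'   column, or a list of `bb_gel` objects whose covariates share an axis.
#' @param covariate name of the covariate column.
#' @param model `"loglog"` or `"arrhenius"`.
#' @return list with `slope`, `intercept`, `r_squared`, `model`,
#'   `covariate`.
#' @export
tgel_trend <- function(results, covariate, model = c("loglog", "arrhenius")) {
  model <- match.arg(model)
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "bb_gel"))) {
    vals <- vapply(results, function(r) {
      v <- r$covariates[[covariate]]
      bb_check(!is.null(v), sprintf(
        "result lacks covariate '%s': mixed or missing covariate axes", covariate))
      as.numeric(v)
    }, numeric(1))
    results <- data.frame(t_gel = vapply(results, `[[`, numeric(1), "t_gel"))
    results[[covariate]] <- vals
  }
  bb_check(is.data.frame(results) && all(c("t_gel", covariate) %in% names(results)),
           sprintf("results must contain columns t_gel and %s", covariate))
  bb_check(nrow(results) >= 3L, "trend fitting needs at least 3 results")
  x_raw <- results[[covariate]]
  bb_check(!anyDuplicated(x_raw),
           "duplicate covariate values: trend design is rank-deficient")
  y <- log(results$t_gel)
  x <- switch(model,
              loglog = { bb_check(all(x_raw > 0), "loglog covariate must be positive"); log(x_raw) },
              arrhenius = 1 / (x_raw + 273.15))
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       model = model, covariate = covariate, n = nrow(results))
}

#' Read a rheology time sweep from CSV
#'
#' Header `time_s,G_prime_Pa,G_double_prime_Pa`; optional comment lines
#' `# temperature_C:`, `# formulation:`.
#'
#' @param path file path.
#' @return a [rheology_sweep()].
#' @export
read_rheology_csv <- function(path) {
  parsed <- parse_numeric_csv(path, c("time_s", "G_prime_Pa", "G_double_prime_Pa"))
  tc <- parsed$meta[["temperature_C"]]
  fm <- parsed$meta[["formulation"]]
  rheology_sweep(parsed$data$time_s, parsed$data$G_prime_Pa,
                 parsed$data$G_double_prime_Pa,
                 temperature_C = if (is.null(tc)) 37 else as.numeric(tc),
                 formulation = if (is.null(fm)) "" else fm)
}

#' Write a rheology sweep to CSV
#' @param sweep a [rheology_sweep()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_rheology_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "bb_sweep"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# temperature_C: %s", attr(sweep, "temperature_C")),
               sprintf("# formulation: %s", attr(sweep, "formulation")),
               "time_s,G_prime_Pa,G_double_prime_Pa"), con)
  writeLines(sprintf("%.15g,%.15g,%.15g", sweep$time_s, sweep$G_prime_Pa,
                     sweep$G_double_prime_Pa), con)
  invisible(path)
}

#' Serialize a gelation result to JSON
#' @param gel a `bb_gel` object.
#' @param path optional path.
#' @return JSON string.
#' @export
gel_to_json <- function(gel, path = NULL) {
  stopifnot(inherits(gel, "bb_gel"))
  x <- list(t_gel_s = gel$t_gel, G_cross_Pa = gel$G_cross,
            bracket_s = gel$bracket, n_crossings = gel$n_crossings,
            method = gel$method, formulation = gel$formulation)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
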