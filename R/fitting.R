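#' Initial parameter guess for the constitutive fit
#'
#' Estimates the Young's modulus from the small-strain slope (ordinary
#' least squares over the smallest-strain 20 percent of points, at least
#' 3), takes beta_init = clamp(1/lambda_last^2, 0.01, 0.9) from the last
#' recorded elongation, and inverts the Young's-modulus relation to get
#' the structural-modulus guess. A degenerate (non-positive slope)
#' small-strain region falls back to the global secant.
#'
#' @param curve a [stress_strain_curve()] (converted to true stress).
#' @return named numeric vector `c(E = ..., beta = ...)`, always strictly
#'   inside the optimizer bounds.
#' @export
initial_guess <- function(curve) {
  stopifnot(inherits(curve, "bb_curve"))
  curve <- as_true_stress(curve)
  lam <- curve$lambda; sig <- curve$sigma
  n <- length(lam)
  k <- max(3L, ceiling(0.2 * n))
  k <- min(k, n)
  slope <- if (k >= 2L) {
    stats::coef(stats::lm(sig[1:k] ~ lam[1:k]))[[2]]
  } else NA_real_
  if (!is.finite(slope) || slope <= 0) {
    # degenerate leading region: global secant
    slope <- (sig[n] - sig[1]) / (lam[n] - lam[1])
  }
  if (!is.finite(slope) || slope <= 0) slope <- 1
  beta_init <- min(max(1 / lam[n]^2, 0.01), 0.9)
  E_init <- 3 * slope / (1 + 2 / (1 - beta_init)^2)
  E_init <- max(E_init, 1e-6)
  c(E = E_init, beta = beta_init)
}

# Model residuals with a smooth penalty replacing points within 1% of the
# current iterate's singular elongation, keeping the objective finite and
# differentiable for the optimizer.
constitutive_residuals <- function(p, lam, sig, w) {
  E <- p[["E"]]; beta <- p[["beta"]]
  g <- stiffening_arg(lam, beta)
  lam_s <- if (beta > 0) lambda_sing(beta, tol = 1e-8) else Inf
  near <- lam >= 0.99 * lam_s
  denom <- pmax(1 - g, 1e-8)
  model <- (E / 9) * (lam^2 - 1 / lam) * (1 + 2 / denom^2)
  r <- sqrt(w) * (model - sig)
  if (any(near)) {
    # quadratic ramp in the overshoot distance; large but smooth
    over <- (lam[near] / (0.99 * lam_s) - 1) + 1e-3
    r[near] <- sqrt(w[near]) * 1e6 * over^2
  }
  r
}

#' Fit the brush-network equation of state to a tensile curve
#'
#' Estimates (E, beta) by bounded nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nls.lm()]) on the true-stress
#' equation of state, with E > 0 and beta in (1e-6, 1-1e-6). Engineering-
#' stress input is converted first. Points that wander within 1 percent of
#' the current iterate's singular elongation contribute a large smooth
#' penalty rather than an infinite residual. Non-convergence is reported
#' through the `converged` flag, never an exception.
#'
#' @param curve a [stress_strain_curve()] with at least 5 samples.
#' @param weighting `"uniform"` (default) or `"relative"` (residuals
#'   scaled by 1/max(|sigma|, floor), for curves spanning decades).
#' @param start optional named start values `c(E=, beta=)`; default from
#'   [initial_guess()].
#' @param max_iter maximum optimizer iterations.
#' @return Object of class `bb_fit`: fitted [material_params()], derived
#'   `E0` and `lambda_max_theo`, the experimental break elongation
#'   `lambda_max_exp` (last recorded lambda, no extrapolation), `rmse` and
#'   `relative_rmse`, per-parameter standard errors, `converged`, and
#'   `n_iter`.
#' @examples
#' tg <- gen_tensile(E = 4.2, beta = 0.10, n_points = 60)
#' fit <- fit_constitutive(tg$curve)
#' fit$params$E_struct
#' @export
fit_constitutive <- function(curve, weighting = c("uniform", "relative"),
                             start = NULL, max_iter = 500L) {
  stopifnot(inherits(curve, "bb_curve"))
  weighting <- match.arg(weighting)
  curve <- as_true_stress(curve)
  bb_check(nrow(curve) >= 5L, "fitting requires at least 5 samples")
  lam <- curve$lambda; sig <- curve$sigma
  w <- if (weighting == "uniform") rep(1, length(sig))
       else 1 / pmax(abs(sig), 0.05 * max(abs(sig)))^2
  if (is.null(start)) start <- initial_guess(curve)
  fit <- minpack.lm::nls.lm(
    par = list(E = unname(start[["E"]]), beta = unname(start[["beta"]])),
    lower = c(1e-10, 1e-6), upper = c(Inf, 1 - 1e-6),
    fn = function(p) constitutive_residuals(p, lam, sig, w),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  p <- fit$par
  converged <- fit$info %in% 1:4
  params <- material_params(max(p$E, 1e-10), min(max(p$beta, 0), 1 - 1e-6))
  resid <- true_stress(pmin(lam, if (params$beta > 0)
    0.9999 * lambda_sing(params$beta) else Inf), params) - sig
  rmse <- sqrt(mean(resid^2))
  scale <- sqrt(mean(sig^2))
  se <- tryCatch({
    cv <- stats::vcov(fit)
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  names(se) <- c("E", "beta")
  structure(list(
    params = params, E0 = params$E0,
    lambda_max_theo = params$lambda_max,
    lambda_max_exp = lam[length(lam)],
    rmse = rmse,
    relative_rmse = if (scale > 0) rmse / scale else NA_real_,
    param_uncertainties = se,
    converged = converged, n_iter = fit$niter,
    weighting = weighting, sample_id = attr(curve, "sample_id")
  ), class = "bb_fit")
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("Constitutive fit%s:\n",
              if (nzchar(x$sample_id)) paste0(" [", x$sample_id, "]") else ""))
  cat(sprintf("  E = %.4g kPa, beta = %.4g  (%s)\n",
              x$params$E_struct, x$params$beta,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  E0 = %.4g kPa, lambda_max,theo = %.3g, lambda_max,exp = %.3g\n",
              x$E0, x$lambda_max_theo, x$lambda_max_exp))
  cat(sprintf("  rmse = %.3g kPa (relative %.3g), %d iterations\n",
              x$rmse, x$relative_rmse, x$n_iter))
  invisible(x)
}

#' Model stress-strain curve on an elongation grid
#'
#' Evaluates the equation of state at the requested elongations and
#' returns a true-stress curve. Grid points at or beyond the singular
#' elongation are a domain error listing the offending values.
#'
#' @param params a [material_params()] object.
#' @param lambdas elongation grid, strictly increasing, first >= 1.
#' @return a [stress_strain_curve()] with `stress_kind = "true"`.
#' @export
predict_curve <- function(params, lambdas) {
  stopifnot(inherits(params, "bb_material"))
  stress_strain_curve(lambdas, true_stress(lambdas, params),
                      stress_kind = "true", sample_id = "model")
}

#' Serialize a fit result to JSON
#'
#' Full precision; one-decimal presentation belongs to the report layer.
#'
#' @param fit a `bb_fit` object.
#' @param path optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "bb_fit"))
  x <- list(E_struct_kPa = fit$params$E_struct, beta = fit$params$beta,
            E0_kPa = fit$E0, lambda_max_theo = fit$lambda_max_theo,
            lambda_max_exp = fit$lambda_max_exp, rmse_kPa = fit$rmse,
            relative_rmse = fit$relative_rmse,
            se_E = fit$param_uncertainties[["E"]],
            se_beta = fit$param_uncertainties[["beta"]],
            converged = fit$converged, n_iter = fit$n_iter,
            weighting = fit$weighting, sample_id = fit$sample_id)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Monte-Carlo parameter-recovery study
#'
#' Generates `n_rep` noisy synthetic tensile curves from known (E, beta),
#' fits each, and summarizes the relative parameter errors. Used to gauge
#' how measurement noise propagates into the fitted mechanical
#' characteristics.
#'
#' @param E,beta ground-truth parameters.
#' @param n_rep number of replicate curves.
#' @param noise_rel relative (multiplicative Gaussian) noise sd.
#' @param n_points samples per curve.
#' @param seed RNG seed (required; the study is the only stochastic fit
#'   path).
#' @return list with per-replicate relative errors (`rel_err_E`,
#'   `rel_err_beta`) and their medians.
#' @export
recovery_study <- function(E, beta, n_rep = 200L, noise_rel = 0.02,
                           n_points = 60L, seed) {
  bb_check(!missing(seed), "seed is required for the recovery study")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_rep))
  err_E <- numeric(n_rep); err_b <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tg <- gen_tensile(E = E, beta = beta, n_points = n_points,
                      noise = "multiplicative", noise_sd = noise_rel,
                      seed = seeds[i])
    f <- fit_constitutive(tg$curve)
    err_E[i] <- abs(f$params$E_struct - E) / E
    err_b[i] <- abs(f$params$beta - beta) / beta
  }
  list(rel_err_E = err_E, rel_err_beta = err_b,
       median_rel_err_E = stats::median(err_E),
       median_rel_err_beta = stats::median(err_b))
}
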