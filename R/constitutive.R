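#' Material parameters of a brush elastomer network
#'
#' Bundles the two mechanical characteristics of a strain-stiffening brush
#' network: the structural modulus `E_struct` (kPa), set by crosslink
#' density, and the firmness parameter `beta` = <R_in^2>/R_max^2, the
#' squared ratio of a network strand's initial end-to-end distance to its
#' contour length. `beta` quantifies strain-stiffening intensity and must
#' lie in (0, 1); `beta = 0` is accepted as the explicit non-stiffening
#' (neo-Hookean-like) limit.
#'
#' @param E_struct structural modulus, kPa; > 0.
#' @param beta firmness parameter in [0, 1); 0 flags the limiting case.
#' @param temperature absolute temperature in kelvin (metadata only).
#' @return An object of class `bb_material`, a list with the fields above
#'   plus the derived Young's modulus `E0` (kPa) and theoretical
#'   elongation-at-break `lambda_max` (`NA` when `beta = 0`).
#' @examples
#' p <- material_params(15.3, 0.23)
#' p$E0          # initial slope of the true-stress curve
#' p$lambda_max  # beta^(-1/2)
#' @export
material_params <- function(E_struct, beta, temperature = 293.15) {
  bb_check(is.numeric(E_struct) && length(E_struct) == 1L && is.finite(E_struct) &&
             E_struct > 0, "E_struct must be a single positive number")
  bb_check(is.numeric(beta) && length(beta) == 1L && is.finite(beta) &&
             beta >= 0 && beta < 1, "beta must lie in [0, 1)")
  structure(list(
    E_struct = E_struct, beta = beta, temperature = temperature,
    E0 = young_modulus_eb(E_struct, beta),
    lambda_max = if (beta > 0) lambda_max_theo(beta) else NA_real_
  ), class = "bb_material")
}

#' @export
print.bb_material <- function(x, ...) {
  cat(sprintf("Brush network material: E = %.4g kPa, beta = %.4g\n",
              x$E_struct, x$beta))
  cat(sprintf("  Young's modulus E0 = %.4g kPa, lambda_max,theo = %s\n",
              x$E0, if (is.na(x$lambda_max)) "Inf (beta = 0)"
                    else sprintf("%.4g", x$lambda_max)))
  invisible(x)
}

#' Network architecture descriptor
#'
#' The architectural triple controlling brush-network mechanics: `n_x`,
#' backbone degree of polymerization (DP) between crosslinks; `n_sc`,
#' side-chain DP; `n_bb`, precursor backbone DP. The spacer DP `n_g` is
#' carried as metadata only (default 1, densely grafted).
#'
#' @param n_x backbone DP between crosslinks (positive integer, <= n_bb).
#' @param n_sc side-chain DP (positive integer).
#' @param n_bb precursor backbone DP (positive integer).
#' @param chemistry crosslinking chemistry label
#'   (`"NCO:OH"`, `"NCO:NH2"`, `"F:M"`, `"PCMA"`).
#' @param ratio stoichiometry label, e.g. `"1:4"`.
#' @param n_g spacer DP between grafts (metadata, default 1).
#' @return Object of class `bb_architecture`.
#' @export
architecture <- function(n_x, n_sc, n_bb, chemistry = "NCO:OH",
                         ratio = "", n_g = 1L) {
  is_pos_int <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v) &&
    v > 0 && v == round(v)
  bb_check(is_pos_int(n_x), "n_x must be a positive integer")
  bb_check(is_pos_int(n_sc), "n_sc must be a positive integer")
  bb_check(is_pos_int(n_bb), "n_bb must be a positive integer")
  bb_check(n_x <= n_bb, "n_x cannot exceed the precursor backbone DP n_bb")
  chemistry <- match.arg(chemistry, c("NCO:OH", "NCO:NH2", "F:M", "PCMA"))
  structure(list(n_x = as.integer(n_x), n_sc = as.integer(n_sc),
                 n_bb = as.integer(n_bb), chemistry = chemistry,
                 ratio = ratio, n_g = n_g),
            class = "bb_architecture")
}

#' Constants for the architectural scaling law
#'
#' The scaling law predicts the structural modulus as
#' E = 3 k_B T (l/v)^{3/2} l^{0} ... beta/(1+n_sc)^{3/2}; in analytic mode
#' the prefactor 3 k_B T l^{3/2}/v^{3/2} is evaluated from the backbone
#' monomer length `l` and monomer volume `v`, in calibrated mode the
#' prefactor `C` (kPa) is taken from a through-origin regression against
#' reference data (see [calibrate_scaling()]). Calibrated mode is the
#' default because no reference value of `v` exists.
#'
#' @param mode `"calibrated"` or `"analytic"`.
#' @param C calibrated slope, kPa (required in calibrated mode).
#' @param l backbone monomer length, nm (default 0.25).
#' @param v monomer volume, nm^3 (required in analytic mode).
#' @param temperature kelvin, used by analytic mode.
#' @return Object of class `bb_scaling`.
#' @export
scaling_constants <- function(mode = c("calibrated", "analytic"), C = NULL,
                              l = 0.25, v = NULL, temperature = 293.15) {
  mode <- match.arg(mode)
  bb_check(is.numeric(l) && l > 0, "monomer length l must be positive")
  if (mode == "calibrated") {
    bb_check(!is.null(C) && is.numeric(C) && C > 0,
             "calibrated mode requires a positive slope C (kPa)",
             "brushmech_missing_constant")
  } else {
    bb_check(!is.null(v) && is.numeric(v) && v > 0,
             "analytic mode requires a positive monomer volume v (nm^3)",
             "brushmech_missing_constant")
  }
  structure(list(mode = mode, C = C, l = l, v = v, temperature = temperature),
            class = "bb_scaling")
}

# Eq-of-state helpers operating on bare numbers (internal fast path).
stiffening_arg <- function(lam, beta) beta * (lam^2 + 2 / lam) / 3

young_modulus_eb <- function(E_struct, beta) {
  (E_struct / 3) * (1 + 2 / (1 - beta)^2)
}

#' True stress of a strain-stiffening brush network
#'
#' Equation of state for uniaxial deformation of a brush polymer network:
#' \deqn{\sigma_{true} = \frac{E}{9}(\lambda^2-\lambda^{-1})
#'   \left[1 + 2\left(1-\frac{\beta(\lambda^2+2\lambda^{-1})}{3}\right)^{-2}\right]}
#' where E is the structural modulus and beta the firmness parameter.
#' The bracketed denominator vanishes at the finite-extensibility
#' singularity; elongations at or beyond it are a domain error. Compression
#' (`lam < 1`) is admitted and returns negative stress.
#'
#' @param lam elongation ratio L/L0 (> 0), vectorized.
#' @param params a [material_params()] object.
#' @return true stress in kPa, same length as `lam`.
#' @examples
#' true_stress(2, material_params(9, 0))   # 10.5 kPa, neo-Hookean limit
#' @export
true_stress <- function(lam, params) {
  stopifnot(inherits(params, "bb_material"))
  bb_check(is.numeric(lam) && all(is.finite(lam)) && all(lam > 0),
           "lam must be positive and finite", "brushmech_domain_error")
  denom <- 1 - stiffening_arg(lam, params$beta)
  if (any(denom <= 0)) {
    bb_error(sprintf(
      "elongation at or beyond the finite-extensibility singularity (lambda = %s)",
      paste(format(lam[denom <= 0]), collapse = ", ")),
      "brushmech_domain_error")
  }
  (params$E_struct / 9) * (lam^2 - 1 / lam) * (1 + 2 / denom^2)
}

#' Young's modulus from structural modulus and firmness
#'
#' The initial (lambda -> 1) slope of the true stress-elongation curve:
#' E0 = (E/3) (1 + 2/(1-beta)^2). Softness reported for a formulation is
#' this E0, not the structural modulus E.
#'
#' @param params a [material_params()] object, or a structural modulus in
#'   kPa when `beta` is also given.
#' @param beta optional firmness when `params` is numeric.
#' @return E0 in kPa.
#' @examples
#' young_modulus(material_params(15.3, 0.23))  # 22.3 kPa at one decimal
#' @export
young_modulus <- function(params, beta = NULL) {
  if (inherits(params, "bb_material")) {
    E <- params$E_struct; b <- params$beta
  } else {
    E <- params; b <- beta
  }
  bb_check(is.numeric(b) && all(b >= 0) && all(b < 1),
           "beta must lie in [0, 1)", "brushmech_domain_error")
  young_modulus_eb(E, b)
}

#' Theoretical elongation at break
#'
#' Finite strand extensibility bounds elongation at
#' lambda_max,theo = R_max/R_in = beta^(-1/2).
#'
#' @param beta firmness parameter, strictly inside (0, 1); vectorized.
#' @return beta^(-1/2), always > 1.
#' @examples
#' lambda_max_theo(0.25)  # 2
#' @export
lambda_max_theo <- function(beta) {
  bb_check(is.numeric(beta) && all(is.finite(beta)) && all(beta > 0) &&
             all(beta < 1),
           "beta must lie strictly inside (0, 1)", "brushmech_domain_error")
  beta^(-0.5)
}

#' Singular elongation of the equation of state
#'
#' The elongation where the strain-stiffening denominator
#' 1 - beta(lambda^2 + 2/lambda)/3 vanishes and the model stress diverges.
#' Located by bisection of g(lambda) = beta(lambda^2+2/lambda)/3 - 1 on
#' [1, 10/sqrt(beta)] to an absolute tolerance of 1e-10. Always at or above
#' the strand-extensibility estimate beta^(-1/2).
#'
#' @param beta firmness in (0, 1).
#' @param tol bisection tolerance on lambda.
#' @return the singular elongation, a single number > 1.
#' @export
lambda_sing <- function(beta, tol = 1e-10) {
  bb_check(is.numeric(beta) && length(beta) == 1L && beta > 0 && beta < 1,
           "beta must lie strictly inside (0, 1)", "brushmech_domain_error")
  g <- function(lam) stiffening_arg(lam, beta) - 1
  lo <- 1; hi <- 10 / sqrt(beta)
  # g(1) = beta - 1 < 0; widen hi in the (unreachable in practice) event
  # the bracket does not straddle the root
  while (g(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Structural modulus predicted by the architectural scaling law
#'
#' E scales as beta/(1 + n_sc)^{3/2}: longer side chains dilute stress-
#' supporting strands while pre-extending them. In analytic mode the
#' prefactor is 3 k_B T l^{3/2}/v^{3/2} converted to kPa; in calibrated
#' mode it is the slope C fitted from reference formulations.
#'
#' @param beta firmness in (0, 1), or 0 for the trivial origin.
#' @param n_sc side-chain DP (>= 0).
#' @param k a [scaling_constants()] object.
#' @return predicted structural modulus, kPa.
#' @examples
#' k <- scaling_constants("calibrated", C = 4500)
#' structural_modulus_predicted(0.1, 14, k)
#' @export
structural_modulus_predicted <- function(beta, n_sc, k) {
  stopifnot(inherits(k, "bb_scaling"))
  bb_check(is.numeric(beta) && all(beta >= 0) && all(beta < 1),
           "beta must lie in [0, 1)", "brushmech_domain_error")
  bb_check(is.numeric(n_sc) && all(n_sc >= 0), "n_sc must be >= 0")
  pref <- if (k$mode == "calibrated") {
    k$C
  } else {
    kB <- 1.380649e-23                       # J/K
    # l in nm, v in nm^3: l^{3/2}/v^{3/2} has units nm^{-3} = 1e27 m^-3;
    # kB*T * m^-3 = Pa, /1000 -> kPa
    3 * kB * k$temperature * (k$l^1.5 / k$v^1.5) * 1e27 / 1000
  }
  pref * beta / (1 + n_sc)^1.5
}

#' Convert engineering stress to true stress
#'
#' Under the incompressibility convention for uniaxial tension,
#' sigma_true = lambda * sigma_eng. Instruments record force over initial
#' cross-section (engineering stress); the equation of state is written in
#' true stress.
#'
#' @param lam elongation ratio (> 0), vectorized.
#' @param sigma_eng engineering stress, same units returned.
#' @return true stress.
#' @export
engineering_to_true <- function(lam, sigma_eng) {
  bb_check(is.numeric(lam) && all(is.finite(lam)) && all(lam > 0),
           "lam must be positive and finite", "brushmech_domain_error")
  lam * sigma_eng
}
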