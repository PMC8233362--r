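#' Target mechanics for inverse design
#'
#' @param E0_target target Young's modulus, kPa (> 0).
#' @param beta_target target firmness in (0, 1).
#' @param tol_E0,tol_beta relative tolerance bands in (0, 1].
#' @return Object of class `bb_target`.
#' @export
design_target <- function(E0_target, beta_target, tol_E0 = 0.2,
                          tol_beta = 0.2) {
  bb_check(E0_target > 0, "E0_target must be positive")
  bb_check(beta_target > 0 && beta_target < 1, "beta_target must lie in (0, 1)")
  bb_check(tol_E0 > 0 && tol_E0 <= 1 && tol_beta > 0 && tol_beta <= 1,
           "tolerance bands must lie in (0, 1]")
  structure(list(E0_target = E0_target, beta_target = beta_target,
                 tol_E0 = tol_E0, tol_beta = tol_beta),
            class = "bb_target")
}

#' Calibrate the architectural scaling law from reference data
#'
#' Least-squares slope through the origin of the structural modulus E
#' against beta/(1 + n_sc)^{3/2}, the proportional form the theory
#' predicts. Returns calibrated [scaling_constants()] carrying the slope
#' C (kPa), the residuals, and the Pearson correlation between predictor
#' and response.
#'
#' @param table a [reference_table()]-like data frame with columns
#'   `E_kPa`, `beta`, `n_sc` (and `chemistry` if filtering).
#' @param chemistry optional chemistry filter, e.g. `"NCO:OH"`.
#' @return a `bb_scaling` object (calibrated mode) with extra fields
#'   `residuals_kPa`, `pearson_r`, `n`.
#' @examples
#' k <- calibrate_scaling(reference_table(), chemistry = "NCO:OH")
#' k$C
#' @export
calibrate_scaling <- function(table, chemistry = NULL) {
  bb_check(is.data.frame(table) &&
             all(c("E_kPa", "beta", "n_sc") %in% names(table)),
           "table must contain E_kPa, beta and n_sc columns")
  if (!is.null(chemistry)) table <- table[table$chemistry == chemistry, ]
  bb_check(nrow(table) >= 3L,
           "calibration needs at least 3 rows after filtering")
  x <- table$beta / (1 + table$n_sc)^1.5
  y <- table$E_kPa
  bb_check(stats::sd(x) > 0, "degenerate calibration: identical predictor values")
  C <- sum(x * y) / sum(x^2)
  k <- scaling_constants("calibrated", C = C)
  k$residuals_kPa <- y - C * x
  k$pearson_r <- stats::cor(x, y)
  k$n <- nrow(table)
  k
}

# Empirical beta(n_x) within one side-chain family: log-linear
# interpolation of the reference anchors; extrapolations are clamped to
# the anchor range and flagged by the caller.
interp_beta <- function(n_x, anchors) {
  a <- stats::aggregate(beta ~ n_x, data = anchors, FUN = function(b)
    exp(mean(log(b))))
  a <- a[order(a$n_x), ]
  if (nrow(a) == 1L) return(rep(a$beta, length(n_x)))
  out <- stats::approx(log(a$n_x), log(a$beta), xout = log(n_x),
                       rule = 2, ties = mean)$y
  exp(out)
}

#' Firmness required by the scaling law at a target Young's modulus
#'
#' Solves the coupling between the Young's-modulus relation
#' E0 = (E/3)(1 + 2/(1-beta)^2) and the calibrated scaling law
#' E = C beta/(1+n_sc)^{3/2} self-consistently for beta by damped
#' fixed-point iteration (step damping 0.5, tolerance 1e-10, at most 100
#' iterations).
#'
#' @param E0_target target Young's modulus, kPa.
#' @param n_sc side-chain DP.
#' @param k calibrated [scaling_constants()].
#' @return the self-consistent beta, or `NA` if the iteration does not
#'   converge inside (0, 1).
#' @export
beta_required <- function(E0_target, n_sc, k) {
  stopifnot(inherits(k, "bb_scaling"))
  bb_check(k$mode == "calibrated", "beta_required needs calibrated constants",
           "brushmech_missing_constant")
  h <- function(b) 3 * E0_target / (1 + 2 / (1 - b)^2) * (1 + n_sc)^1.5 / k$C
  b <- 0.1
  for (i in seq_len(100L)) {
    b_new <- 0.5 * b + 0.5 * min(max(h(b), 1e-6), 1 - 1e-3)
    if (abs(b_new - b) < 1e-10) return(b_new)
    b <- b_new
  }
  NA_real_
}

#' Propose network architectures for target mechanics
#'
#' Grid search over candidate [n_x, n_sc] pairs. For each candidate the
#' firmness is interpolated from the empirical beta(n_x) anchors of the
#' reference table (per side-chain family, log-linear in n_x;
#' out-of-range n_x is clamped and flagged `extrapolated`), the
#' structural modulus follows from the calibrated scaling law, and the
#' Young's modulus from the constitutive relation. Candidates whose
#' relative deviations from the target fall inside the tolerance bands
#' are returned ranked by the summed relative error; when none qualify
#' the result is an empty table whose `diagnostics` attribute holds every
#' grid point examined.
#'
#' @param target a [design_target()].
#' @param k calibrated [scaling_constants()] (see [calibrate_scaling()]).
#' @param n_sc_choices side-chain DPs to consider.
#' @param n_x_grid backbone-strand DPs to consider.
#' @param anchors reference data frame of empirical anchors; default the
#'   packaged [reference_table()].
#' @param chemistry optional chemistry filter applied to the anchors.
#' @return data frame of feasible candidates sorted by `combined_err`,
#'   with attribute `diagnostics` (all grid points) and a `beta_required`
#'   attribute giving the per-n_sc self-consistent firmness.
#' @export
propose_architectures <- function(target, k, n_sc_choices = c(14, 70),
                                  n_x_grid = c(50, 100, 200, 400),
                                  anchors = reference_table(),
                                  chemistry = NULL) {
  stopifnot(inherits(target, "bb_target"), inherits(k, "bb_scaling"))
  bb_check(k$mode == "calibrated",
           "propose_architectures needs calibrated constants",
           "brushmech_missing_constant")
  bb_check(length(n_sc_choices) >= 1L && length(n_x_grid) >= 1L,
           "grid must be nonempty")
  if (!is.null(chemistry)) anchors <- anchors[anchors$chemistry == chemistry, ]
  rows <- list()
  breq <- vapply(n_sc_choices, function(nsc)
    beta_required(target$E0_target, nsc, k), numeric(1))
  names(breq) <- as.character(n_sc_choices)
  for (nsc in n_sc_choices) {
    fam <- anchors[anchors$n_sc == nsc, ]
    if (nrow(fam) == 0L) next
    b_hat <- interp_beta(n_x_grid, fam)
    extrap <- n_x_grid < min(fam$n_x) | n_x_grid > max(fam$n_x)
    E_hat <- structural_modulus_predicted(b_hat, nsc, k)
    E0_hat <- young_modulus_eb(E_hat, b_hat)
    rows[[length(rows) + 1L]] <- data.frame(
      n_x = n_x_grid, n_sc = nsc, beta_pred = b_hat, E_pred_kPa = E_hat,
      E0_pred_kPa = E0_hat,
      rel_err_E0 = abs(E0_hat - target$E0_target) / target$E0_target,
      rel_err_beta = abs(b_hat - target$beta_target) / target$beta_target,
      extrapolated = extrap)
  }
  bb_check(length(rows) > 0L, "no anchors available for any requested n_sc")
  all_rows <- do.call(rbind, rows)
  all_rows$combined_err <- all_rows$rel_err_E0 + all_rows$rel_err_beta
  all_rows$feasible <- all_rows$rel_err_E0 <= target$tol_E0 &
    all_rows$rel_err_beta <= target$tol_beta
  out <- all_rows[all_rows$feasible, ]
  out <- out[order(out$combined_err), ]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- all_rows
  attr(out, "beta_required") <- breq
  out
}

#' Rank candidate materials against a target tissue curve
#'
#' Scores each candidate parameter set by the root-mean-square relative
#' deviation between its model true-stress curve and the tissue curve,
#' evaluated at the tissue's own elongations over the overlapping
#' admissible range (points below the candidate's singular elongation;
#' zero-stress points are skipped in the relative deviation).
#'
#' @param tissue a [stress_strain_curve()] of the target tissue (true
#'   stress).
#' @param candidates list of [material_params()] objects.
#' @return data frame ranked by `rmsd_rel` with columns `candidate`
#'   (input index), `E_struct_kPa`, `beta`, `rmsd_rel`, `n_overlap`.
#' @export
match_tissue <- function(tissue, candidates) {
  stopifnot(inherits(tissue, "bb_curve"))
  bb_check(length(candidates) >= 1L &&
             all(vapply(candidates, inherits, logical(1), "bb_material")),
           "candidates must be a list of material_params objects")
  tissue <- as_true_stress(tissue)
  scores <- lapply(seq_along(candidates), function(i) {
    p <- candidates[[i]]
    lam_hi <- if (p$beta > 0) 0.9999 * lambda_sing(p$beta) else Inf
    keep <- tissue$lambda <= lam_hi & tissue$sigma != 0
    if (!any(keep)) return(NULL)
    model <- true_stress(tissue$lambda[keep], p)
    rel <- (model - tissue$sigma[keep]) / tissue$sigma[keep]
    data.frame(candidate = i, E_struct_kPa = p$E_struct, beta = p$beta,
               rmsd_rel = sqrt(mean(rel^2)), n_overlap = sum(keep))
  })
  scores <- scores[!vapply(scores, is.null, logical(1))]
  bb_check(length(scores) > 0L,
           "no elongation overlap between tissue curve and any candidate",
           "brushmech_no_overlap")
  out <- do.call(rbind, scores)
  out <- out[order(out$rmsd_rel), ]
  rownames(out) <- NULL
  out
}
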