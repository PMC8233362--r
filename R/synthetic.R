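#' Synthetic uniaxial tensile curve with known ground truth
#'
#' Forward-evaluates the equation of state on a uniform elongation grid
#' and optionally corrupts it with seeded noise. The grid ends at the
#' theoretical break beta^(-1/2) by default -- where real specimens
#' rupture -- rather than at the (higher) model singularity; an explicit
#' cap at a fraction of the singular elongation is also available.
#' Multiplicative noise is the default model for tensile data because
#' load-cell error scales with load.
#'
#' @param E,beta ground-truth structural modulus (kPa) and firmness.
#' @param n_points grid size (>= 5).
#' @param lambda_end grid endpoint; default `beta^(-1/2)` (required
#'   explicitly when `beta = 0`).
#' @param f_sing optional cap: grid never exceeds `f_sing * lambda_sing`;
#'   must be < 1.
#' @param noise `"none"`, `"multiplicative"` (sigma * (1 + eps)) or
#'   `"additive"` (sigma + eps), eps ~ N(0, noise_sd).
#' @param noise_sd noise scale: relative for multiplicative, kPa for
#'   additive.
#' @param seed RNG seed; mandatory whenever noise is applied.
#' @param sample_id label for the emitted curve.
#' @return list with `curve` (a [stress_strain_curve()]) and `truth`
#'   (the generating parameters).
#' @examples
#' tg <- gen_tensile(E = 4.2, beta = 0.10, n_points = 60)
#' range(tg$curve$lambda)
#' @export
gen_tensile <- function(E, beta, n_points = 60L, lambda_end = NULL,
                        f_sing = NULL, noise = c("none", "multiplicative",
                                                 "additive"),
                        noise_sd = 0.02, seed = NULL,
                        sample_id = "synthetic-tensile") {
  noise <- match.arg(noise)
  bb_check(n_points >= 5L, "n_points must be at least 5", "brushmech_spec_error")
  bb_check(noise_sd >= 0, "noise_sd must be >= 0", "brushmech_spec_error")
  params <- material_params(E, beta)
  if (is.null(lambda_end)) {
    bb_check(beta > 0,
             "lambda_end must be given explicitly when beta = 0",
             "brushmech_spec_error")
    lambda_end <- beta^(-0.5)
  }
  if (!is.null(f_sing)) {
    bb_check(f_sing < 1, "f_sing must be < 1", "brushmech_spec_error")
    bb_check(beta > 0, "f_sing needs beta > 0", "brushmech_spec_error")
    lambda_end <- min(lambda_end, f_sing * lambda_sing(beta))
  }
  bb_check(lambda_end > 1, "grid endpoint must exceed 1", "brushmech_spec_error")
  lam <- seq(1, lambda_end, length.out = n_points)
  sig <- true_stress(lam, params)
  if (noise != "none" && noise_sd > 0) {
    bb_check(!is.null(seed), "seed is mandatory when noise is applied",
             "brushmech_spec_error")
    eps <- with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
    sig <- if (noise == "multiplicative") sig * (1 + eps) else sig + eps
  }
  list(curve = stress_strain_curve(lam, sig, "true", sample_id = sample_id),
       truth = list(E = E, beta = beta, lambda_end = lambda_end,
                    noise = noise, noise_sd = noise_sd, seed = seed))
}

#' Synthetic curing rheology sweep with an exactly placed crossover
#'
#' Builds sigmoidally growing moduli
#' G'(t) = G'_inf u(t) and G''(t) = G''_0 + (G''_inf - G''_0) u(t) with
#' u(t) = t^h / (t^h + t_c^h), choosing t_c in closed form so that the
#' two curves intersect exactly at the requested gel time. The
#' construction requires G'_inf > G''_inf (a solid forms) and a positive
#' initial loss modulus; the generator verifies the intersection
#' numerically before returning. Additive noise is the default model,
#' reflecting the instrument floor that dominates the early liquid phase.
#'
#' @param t_gel requested crossover time, s.
#' @param G_inf_prime plateau storage modulus, Pa.
#' @param G_inf_dblprime plateau loss modulus, Pa (< G_inf_prime).
#' @param G0_dblprime initial loss modulus, Pa (> 0).
#' @param h shape exponent of the cure sigmoid.
#' @param n_points samples (>= 4).
#' @param t_max sweep end, s; default 4 * t_gel.
#' @param noise `"none"`, `"additive"` or `"multiplicative"`.
#' @param noise_sd Pa for additive, relative for multiplicative.
#' @param seed RNG seed; mandatory with noise.
#' @param formulation label.
#' @return list with `sweep` (a [rheology_sweep()]) and `truth`
#'   (`t_gel`, `G_cross`, generator parameters).
#' @export
gen_rheology <- function(t_gel, G_inf_prime = 1e4, G_inf_dblprime = 1e3,
                         G0_dblprime = 10, h = 3, n_points = 200L,
                         t_max = NULL, noise = c("none", "additive",
                                                 "multiplicative"),
                         noise_sd = 0, seed = NULL, formulation = "synthetic") {
  noise <- match.arg(noise)
  bb_check(t_gel > 0, "t_gel must be positive", "brushmech_spec_error")
  bb_check(G0_dblprime > 0, "G0_dblprime must be positive", "brushmech_spec_error")
  bb_check(G_inf_prime > G_inf_dblprime,
           "no crossover exists: plateau G' must exceed plateau G''",
           "brushmech_spec_error")
  if (is.null(t_max)) t_max <- 4 * t_gel
  bb_check(t_max > t_gel, "t_max must exceed t_gel", "brushmech_spec_error")
  u_star <- G0_dblprime / (G_inf_prime - G_inf_dblprime + G0_dblprime)
  t_c <- t_gel * ((1 - u_star) / u_star)^(1 / h)
  u <- function(t) t^h / (t^h + t_c^h)
  gp_f <- function(t) G_inf_prime * u(t)
  gpp_f <- function(t) G0_dblprime + (G_inf_dblprime - G0_dblprime) * u(t)
  # generator's own check: the construction must cross exactly at t_gel
  stopifnot(abs(gp_f(t_gel) - gpp_f(t_gel)) <= 1e-9 * gp_f(t_gel))
  t <- seq(t_max / n_points, t_max, length.out = n_points)
  gp <- gp_f(t); gpp <- gpp_f(t)
  if (noise != "none" && noise_sd > 0) {
    bb_check(!is.null(seed), "seed is mandatory when noise is applied",
             "brushmech_spec_error")
    e <- with_seed(seed, matrix(stats::rnorm(2 * n_points, 0, noise_sd),
                                ncol = 2))
    if (noise == "additive") {
      gp <- pmax(gp + e[, 1], 1e-6); gpp <- pmax(gpp + e[, 2], 1e-6)
    } else {
      gp <- pmax(gp * (1 + e[, 1]), 1e-6); gpp <- pmax(gpp * (1 + e[, 2]), 1e-6)
    }
  }
  list(sweep = rheology_sweep(t, gp, gpp, formulation = formulation),
       truth = list(t_gel = t_gel, G_cross = gp_f(t_gel), t_c = t_c, h = h,
                    grid_spacing = t[2] - t[1], noise = noise,
                    noise_sd = noise_sd, seed = seed))
}

#' Synthetic two-cycle TPA force trace with exact areas
#'
#' Builds a piecewise-linear double-compression force-time trace whose
#' trapezoidal phase areas equal the requested values exactly: each cycle
#' is a triangle rising from zero to its peak over 2*A_down/P seconds and
#' returning over 2*A_up/P seconds, separated by a dwell at baseline.
#' Segment vertices are always sample nodes, so trapezoidal integration
#' of the emitted trace reproduces the requested areas to machine
#' precision. Ground-truth metrics follow in closed form from the
#' requested areas and timings.
#'
#' @param peaks peak forces of the two cycles, N (both > 0).
#' @param A_down compression-phase areas (N s), length 2, > 0.
#' @param A_up withdrawal-phase areas (N s), length 2, > 0.
#' @param t_pre pre-contact baseline duration, s.
#' @param dwell pause between the cycles, s.
#' @param points_per_segment samples per linear segment.
#' @param noise `"none"` or `"multiplicative"` on force.
#' @param noise_sd relative noise scale.
#' @param seed RNG seed; mandatory with noise.
#' @param strain_pct nominal strain metadata.
#' @return list with `trace` (a [tpa_trace()]) and `truth` (requested
#'   areas, peaks, and closed-form `springiness`, `resilience`,
#'   `cohesiveness`).
#' @export
gen_tpa <- function(peaks = c(1, 1), A_down = c(0.5, 0.5),
                    A_up = c(0.5, 0.5), t_pre = 1, dwell = 1,
                    points_per_segment = 25L,
                    noise = c("none", "multiplicative"), noise_sd = 0,
                    seed = NULL, strain_pct = 50) {
  noise <- match.arg(noise)
  bb_check(length(peaks) == 2L && all(peaks > 0),
           "two positive peak forces are required", "brushmech_spec_error")
  bb_check(length(A_down) == 2L && length(A_up) == 2L &&
             all(A_down > 0) && all(A_up > 0),
           "all four phase areas must be positive", "brushmech_spec_error")
  bb_check(t_pre > 0 && dwell > 0, "t_pre and dwell must be positive",
           "brushmech_spec_error")
  rise <- 2 * A_down / peaks
  fall <- 2 * A_up / peaks
  # segments: (duration, f_start, f_end)
  segs <- rbind(c(t_pre, 0, 0),
                c(rise[1], 0, peaks[1]), c(fall[1], peaks[1], 0),
                c(dwell, 0, 0),
                c(rise[2], 0, peaks[2]), c(fall[2], peaks[2], 0),
                c(t_pre, 0, 0))
  t <- 0; times <- 0; forces <- 0
  for (s in seq_len(nrow(segs))) {
    tt <- seq(0, segs[s, 1], length.out = points_per_segment)[-1]
    times <- c(times, t + tt)
    forces <- c(forces, segs[s, 2] + (segs[s, 3] - segs[s, 2]) * tt / segs[s, 1])
    t <- t + segs[s, 1]
  }
  if (noise != "none" && noise_sd > 0) {
    bb_check(!is.null(seed), "seed is mandatory when noise is applied",
             "brushmech_spec_error")
    eps <- with_seed(seed, stats::rnorm(length(forces), 0, noise_sd))
    forces <- pmax(forces * (1 + eps), 0)
  }
  disp <- strain_pct / 100 * 4 * forces / max(forces)  # nominal, metadata-grade
  list(trace = tpa_trace(times, disp, forces, strain_pct = strain_pct,
                         specimen = "synthetic-tpa"),
       truth = list(peaks = peaks, A_down = A_down, A_up = A_up,
                    springiness = rise[2] / rise[1],
                    resilience = A_up[1] / A_down[1],
                    cohesiveness = (A_down[2] + A_up[2]) / (A_down[1] + A_up[1]),
                    seed = seed))
}

#' The packaged reference formulation table
#'
#' Eleven injectable bottlebrush formulations spanning three crosslinking
#' chemistries (NCO:OH, F:M, PCMA), shipped verbatim with their printed
#' architectural parameters (n_sc, n_bb, n_x), structural modulus E
#' (kPa), firmness beta, Young's modulus E0 (kPa), and experimental and
#' theoretical elongations at break.
#'
#' @return Object of class `bb_reftable` (a data frame, 11 rows).
#' @examples
#' tab <- gen_table1_fixture()
#' subset(tab, chemistry == "F:M")
#' @export
gen_table1_fixture <- function() {
  path <- system.file("extdata", "table1_formulations.csv",
                      package = "brushmech", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chemistry = "character",
                                       ratio = "character"))
  bb_check(nrow(df) == 11L, "reference table must have 11 rows")
  num <- c("n_sc", "n_bb", "n_x", "E_kPa", "beta", "E0_kPa",
           "lambda_max_exp", "lambda_max_calc")
  bb_check(all(vapply(df[num], function(v) all(is.finite(v) & v > 0),
                      logical(1))),
           "reference table numeric cells must be positive")
  bb_check(all(df$beta < 1), "reference table beta values must be < 1")
  structure(df, class = c("bb_reftable", "data.frame"))
}

#' @rdname gen_table1_fixture
#' @export
reference_table <- gen_table1_fixture
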