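#' Uniaxial stress-strain curve container
#'
#' An ordered record of (elongation ratio, stress) samples from a tensile
#' test, with the stress convention declared explicitly so raw instrument
#' files state whether they carry true or engineering stress.
#'
#' @param lambda elongation ratios, strictly increasing, first value >= 1.
#' @param sigma stress in kPa, same length as `lambda`.
#' @param stress_kind `"true"` or `"engineering"`.
#' @param sample_id specimen label.
#' @param temperature_C test temperature, metadata (protocol 20).
#' @param strain_rate_per_s strain rate, metadata (protocol 0.005).
#' @return Object of class `bb_curve`: a data frame with columns `lambda`
#'   and `sigma` plus metadata attributes.
#' @export
stress_strain_curve <- function(lambda, sigma, stress_kind = c("true", "engineering"),
                                sample_id = "", temperature_C = 20,
                                strain_rate_per_s = 0.005) {
  stress_kind <- match.arg(stress_kind)
  bb_check(length(lambda) == length(sigma) && length(lambda) >= 1L,
           "lambda and sigma must be non-empty and of equal length")
  bb_check(all(is.finite(lambda)) && all(is.finite(sigma)),
           "curve contains non-finite values")
  bb_check(lambda[1] >= 1, "tension records must start at lambda >= 1")
  bb_check(length(lambda) < 2L || all(diff(lambda) > 0),
           "lambda must be strictly increasing")
  structure(data.frame(lambda = as.numeric(lambda), sigma = as.numeric(sigma)),
            stress_kind = stress_kind, sample_id = sample_id,
            temperature_C = temperature_C,
            strain_rate_per_s = strain_rate_per_s,
            class = c("bb_curve", "data.frame"))
}

#' Coerce a curve to true stress
#'
#' Applies sigma_true = lambda * sigma_eng when the curve carries
#' engineering stress; a no-op on true-stress curves.
#'
#' @param curve a [stress_strain_curve()].
#' @return the curve with `stress_kind = "true"`.
#' @export
as_true_stress <- function(curve) {
  stopifnot(inherits(curve, "bb_curve"))
  if (attr(curve, "stress_kind") == "true") return(curve)
  stress_strain_curve(curve$lambda,
                      engineering_to_true(curve$lambda, curve$sigma),
                      stress_kind = "true",
                      sample_id = attr(curve, "sample_id"),
                      temperature_C = attr(curve, "temperature_C"),
                      strain_rate_per_s = attr(curve, "strain_rate_per_s"))
}

#' Read a stress-strain curve from CSV
#'
#' Expects header `lambda,sigma_kPa` preceded by optional comment metadata
#' lines `# stress_kind: true|engineering`, `# sample_id: ...`. Parsing is
#' strict; malformed lines raise errors carrying the line number.
#'
#' @param path file path.
#' @return a [stress_strain_curve()].
#' @export
read_curve_csv <- function(path) {
  parsed <- parse_numeric_csv(path, c("lambda", "sigma_kPa"))
  kind <- parsed$meta[["stress_kind"]]
  if (is.null(kind)) kind <- "true"
  bb_check(kind %in% c("true", "engineering"),
           sprintf("%s: unknown stress_kind '%s'", path, kind),
           "brushmech_parse_error")
  id <- parsed$meta[["sample_id"]]
  stress_strain_curve(parsed$data$lambda, parsed$data$sigma_kPa,
                      stress_kind = kind,
                      sample_id = if (is.null(id)) "" else id)
}

#' Write a stress-strain curve to CSV
#'
#' @param curve a [stress_strain_curve()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "bb_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# stress_kind: %s", attr(curve, "stress_kind")),
               sprintf("# sample_id: %s", attr(curve, "sample_id")),
               "lambda,sigma_kPa"), con)
  writeLines(sprintf("%.15g,%.15g", curve$lambda, curve$sigma), con)
  invisible(path)
}
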