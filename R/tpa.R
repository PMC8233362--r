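#' Texture-profile-analysis compression trace
#'
#' Force-time-displacement record of a double-compression test on a
#' disk-shaped specimen (protocol: 8 mm diameter, two compressions at a
#' nominal strain of 20, 50 or 70 percent).
#'
#' @param time_s strictly increasing times, s.
#' @param displacement_mm crosshead displacement, mm.
#' @param force_N measured force, N.
#' @param strain_pct nominal compression level, metadata.
#' @param specimen label, metadata.
#' @param diameter_mm specimen diameter, metadata (protocol 8).
#' @return Object of class `bb_tpa_trace`.
#' @export
tpa_trace <- function(time_s, displacement_mm, force_N, strain_pct = 50,
                      specimen = "", diameter_mm = 8) {
  n <- length(time_s)
  bb_check(n >= 8L, "a TPA trace needs at least 8 samples")
  bb_check(length(displacement_mm) == n && length(force_N) == n,
           "time, displacement and force must have equal length")
  bb_check(all(is.finite(time_s)) && all(diff(time_s) > 0),
           "time must be finite and strictly increasing")
  bb_check(all(is.finite(force_N)), "force contains non-finite values")
  structure(data.frame(time_s = as.numeric(time_s),
                       displacement_mm = as.numeric(displacement_mm),
                       force_N = as.numeric(force_N)),
            strain_pct = strain_pct, specimen = specimen,
            diameter_mm = diameter_mm,
            class = c("bb_tpa_trace", "data.frame"))
}

#' Segment a TPA trace into its two compression cycles
#'
#' Baseline is the median of the low-level samples (pre-contact and
#' dwell readings within 1 percent of full range above the force floor),
#' which makes segmentation invariant to a constant offset. Lobes of
#' baseline-corrected force above the 1-percent contact threshold are
#' located,
#' then extended outward to where the force returns to baseline, so each
#' cycle carries its full loading (compression) and unloading
#' (withdrawal) area. Exactly two cycles must emerge; each is split at
#' its force peak into a compression and a withdrawal phase.
#'
#' @param trace a [tpa_trace()].
#' @return Object of class `bb_tpa_cycles`: a list of two cycles, each
#'   holding `time`, `force` (baseline-corrected), `peak_index`,
#'   `t_start`, `t_peak`, `t_end`, `peak_force`, and the trapezoidal
#'   phase areas `A_down`, `A_up` (N s); plus `baseline` as an attribute.
#' @section Errors: a trace yielding a cycle count other than two raises
#'   `brushmech_cycle_count` with the detected count in the message.
#' @export
segment_cycles <- function(trace) {
  stopifnot(inherits(trace, "bb_tpa_trace"))
  t <- trace$time_s; f_raw <- trace$force_N
  rng <- max(f_raw) - min(f_raw)
  bb_check(rng > 0, "trace has constant force", "brushmech_cycle_count")
  # baseline from the low-level (pre-contact / dwell) samples: everything
  # within 1% of full range above the floor; shift-invariant by construction
  low <- f_raw <= min(f_raw) + 0.01 * rng
  baseline <- stats::median(f_raw[low])
  f <- f_raw - baseline
  thr <- 0.01 * max(f)
  above <- f > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lobes <- which(r$values)
  if (length(lobes) != 2L) {
    bb_error(sprintf("expected 2 compression cycles, detected %d",
                     length(lobes)), "brushmech_cycle_count")
  }
  n <- length(f)
  cycles <- lapply(lobes, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    # extend to the baseline return on both sides (force <= 0 or trace edge)
    while (i0 > 1L && f[i0 - 1L] > 0) i0 <- i0 - 1L
    if (i0 > 1L) i0 <- i0 - 1L          # include the baseline-touch sample
    while (i1 < n && f[i1 + 1L] > 0) i1 <- i1 + 1L
    if (i1 < n) i1 <- i1 + 1L
    idx <- i0:i1
    fc <- pmax(f[idx], 0)
    tp <- which.max(fc)
    list(time = t[idx], force = fc, peak_index = tp,
         t_start = t[idx][1], t_peak = t[idx][tp],
         t_end = t[idx][length(idx)], peak_force = fc[tp],
         A_down = trapz(t[idx][1:tp], fc[1:tp]),
         A_up = trapz(t[idx][tp:length(idx)], fc[tp:length(idx)]))
  })
  # guard against the two lobes sharing their boundary sample ordering
  bb_check(cycles[[1]]$t_end <= cycles[[2]]$t_start + 1e-12,
           "detected cycles overlap; trace is not a two-cycle TPA record",
           "brushmech_cycle_count")
  structure(cycles, baseline = baseline, class = "bb_tpa_cycles")
}

#' Texture metrics from segmented compression cycles
#'
#' Computes the three texture-profile metrics on the force-time signal
#' (trapezoidal integration), using the common instrument-software
#' conventions:
#' \itemize{
#'   \item cohesiveness = (A2_down + A2_up) / (A1_down + A1_up) -- total
#'     second-cycle work over first-cycle work;
#'   \item resilience = A1_up / A1_down -- withdrawal over compression
#'     work within the first cycle;
#'   \item springiness = loading duration of cycle 2 over cycle 1
#'     (contact-to-peak times; time-based convention).
#' }
#' All three equal 1 for a perfectly elastic specimen.
#'
#' @param cycles a `bb_tpa_cycles` object from [segment_cycles()], or a
#'   [tpa_trace()] (segmented first).
#' @return Object of class `bb_tpa_result` with fields `springiness`,
#'   `resilience`, `cohesiveness`, `areas` (A1_down, A1_up, A2_down,
#'   A2_up; N s) and `peaks` (P1, P2; N).
#' @export
tpa_metrics <- function(cycles) {
  if (inherits(cycles, "bb_tpa_trace")) cycles <- segment_cycles(cycles)
  stopifnot(inherits(cycles, "bb_tpa_cycles"))
  c1 <- cycles[[1]]; c2 <- cycles[[2]]
  a1 <- c1$A_down + c1$A_up
  bb_check(a1 > 0, "first-cycle area is zero: metrics undefined",
           "brushmech_undefined_metric")
  bb_check(c1$A_down > 0, "first-cycle compression area is zero: metrics undefined",
           "brushmech_undefined_metric")
  load1 <- c1$t_peak - c1$t_start
  load2 <- c2$t_peak - c2$t_start
  bb_check(load1 > 0, "first-cycle loading time is zero: springiness undefined",
           "brushmech_undefined_metric")
  structure(list(
    springiness = load2 / load1,
    resilience = c1$A_up / c1$A_down,
    cohesiveness = (c2$A_down + c2$A_up) / a1,
    areas = c(A1_down = c1$A_down, A1_up = c1$A_up,
              A2_down = c2$A_down, A2_up = c2$A_up),
    peaks = c(P1 = c1$peak_force, P2 = c2$peak_force)
  ), class = "bb_tpa_result")
}

#' @export
print.bb_tpa_result <- function(x, ...) {
  cat(sprintf("TPA metrics: springiness %.4g, resilience %.4g, cohesiveness %.4g\n",
              x$springiness, x$resilience, x$cohesiveness))
  cat(sprintf("  peaks %.4g / %.4g N; areas (N s) down/up: %.4g/%.4g, %.4g/%.4g\n",
              x$peaks[1], x$peaks[2], x$areas[1], x$areas[2],
              x$areas[3], x$areas[4]))
  invisible(x)
}

#' Read a TPA trace from CSV
#'
#' Header `time_s,displacement_mm,force_N`; optional `# strain_pct:` and
#' `# specimen:` comment metadata.
#'
#' @param path file path.
#' @return a [tpa_trace()].
#' @export
read_tpa_csv <- function(path) {
  parsed <- parse_numeric_csv(path, c("time_s", "displacement_mm", "force_N"))
  sp <- parsed$meta[["strain_pct"]]
  id <- parsed$meta[["specimen"]]
  tpa_trace(parsed$data$time_s, parsed$data$displacement_mm,
            parsed$data$force_N,
            strain_pct = if (is.null(sp)) 50 else as.numeric(sp),
            specimen = if (is.null(id)) "" else id)
}

#' Write a TPA trace to CSV
#' @param trace a [tpa_trace()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tpa_csv <- function(trace, path) {
  stopifnot(inherits(trace, "bb_tpa_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# strain_pct: %s", attr(trace, "strain_pct")),
               sprintf("# specimen: %s", attr(trace, "specimen")),
               "time_s,displacement_mm,force_N"), con)
  writeLines(sprintf("%.15g,%.15g,%.15g", trace$time_s,
                     trace$displacement_mm, trace$force_N), con)
  invisible(path)
}

#' Serialize TPA metrics to JSON
#' @param res a `bb_tpa_result`.
#' @param path optional path.
#' @return JSON string.
#' @export
tpa_to_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "bb_tpa_result"))
  x <- list(springiness = res$springiness, resilience = res$resilience,
            cohesiveness = res$cohesiveness,
            areas_Ns = as.list(res$areas), peaks_N = as.list(res$peaks))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
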