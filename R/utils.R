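#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
bb_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "brushmech_error"), call = call))
}

bb_check <- function(ok, msg, class = "brushmech_input_error") {
  if (!isTRUE(ok)) bb_error(msg, class, call = sys.call(-1))
  invisible(TRUE)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.35 -> 2.4), matching how the
#' reference formulation table prints one-decimal values. Base R's
#' [round()] rounds half to even and cannot reproduce printed cells that
#' sit exactly on a half.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(c(2.25, 2.35), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Evaluate a function with a temporary RNG state seeded from `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Parse "# key: value" comment headers from an instrument CSV; returns
# list(meta = named character, data_start = first non-comment line index).
read_comment_meta <- function(lines) {
  meta <- character(0)
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*#", lines[i])) {
    m <- regmatches(lines[i], regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[trimws(m[2])] <- trimws(m[3])
    i <- i + 1L
  }
  list(meta = as.list(meta), data_start = i)
}

# Strict numeric CSV body parser with line-numbered errors.
# `expected_header` is a character vector of required column names.
parse_numeric_csv <- function(path, expected_header) {
  lines <- readLines(path, warn = FALSE)
  bb_check(length(lines) > 0, sprintf("%s: empty file", path))
  hdr <- read_comment_meta(lines)
  i0 <- hdr$data_start
  bb_check(i0 <= length(lines), sprintf("%s: no header line found", path))
  header <- trimws(strsplit(lines[i0], ",")[[1]])
  if (!identical(header, expected_header)) {
    bb_error(sprintf("%s:%d: expected header '%s', found '%s'",
                     path, i0, paste(expected_header, collapse = ","),
                     paste(header, collapse = ",")),
             "brushmech_parse_error")
  }
  body <- lines[-seq_len(i0)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(j) {
    cells <- trimws(strsplit(body[j], ",")[[1]])
    if (length(cells) != length(expected_header)) {
      bb_error(sprintf("%s:%d: expected %d fields, found %d",
                       path, i0 + j, length(expected_header), length(cells)),
               "brushmech_parse_error")
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      bb_error(sprintf("%s:%d: non-numeric value '%s'",
                       path, i0 + j, cells[which(is.na(vals))[1]]),
               "brushmech_parse_error")
    }
    vals
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- expected_header
  list(data = df, meta = hdr$meta)
}
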