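#' Parse MLT frame timestamps
#'
#' MLT recordings stamp frames with relative session time serialised as
#' `"HH:MM:SS.fffffff"` or, in some writers, the shorter `"MM:SS.fffffff"`
#' (no hour field). Both dialects are accepted; plain seconds (`"2.016"`)
#' are tolerated as a degenerate one-field form. Sub-microsecond (100 ns)
#' resolution survives the round trip.
#'
#' @param x character vector of timestamp strings.
#' @return numeric vector of seconds since session start (t0 = 0).
#' @seealso [format_mlt_timestamp()]
#' @examples
#' parse_mlt_timestamp(c("00:00:02.0160129", "00:02.0282288"))
#' @export
parse_mlt_timestamp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  parts <- strsplit(trimws(x), ":", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) < 1L || length(p) > 3L || anyNA(p)) {
      stop("unparseable timestamp: ", sQuote(x[i]), call. = FALSE)
    }
    # right-align fields: last is seconds, then minutes, then hours
    mult <- c(1, 60, 3600)[seq_along(p)]
    out[i] <- sum(rev(p) * mult)
  }
  if (any(out < 0)) stop("negative timestamp in input", call. = FALSE)
  out
}

#' Format seconds as an MLT timestamp string
#'
#' Always emits the full `"HH:MM:SS.fffffff"` dialect (7 fractional digits,
#' 100 ns), the lossless superset of the forms accepted by
#' [parse_mlt_timestamp()].
#'
#' @param t numeric vector of non-negative seconds.
#' @return character vector.
#' @export
format_mlt_timestamp <- function(t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("cannot format negative times", call. = FALSE)
  # round to 100 ns first so carry into the minute field is handled
  ticks <- round(t * 1e7)
  s <- ticks / 1e7
  h <- floor(s / 3600)
  m <- floor((s - h * 3600) / 60)
  sec <- s - h * 3600 - m * 60
  sprintf("%02d:%02d:%010.7f", as.integer(h), as.integer(m), sec)
}
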