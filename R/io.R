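#' Pearson correlation between two signals
#'
#' Product-moment correlation over the unmasked samples; the standard score
#' for comparing a recovered input against the known truth.
#'
#' @param a,b signals of equal length (\code{resp_ts} or numeric).
#' @param mask optional logical vector; \code{TRUE} samples are excluded
#'   (e.g. the low-confidence flagged tail of a sequential solve).
#' @return correlation in \code{[-1, 1]}.
#' @export
pearson_correlation <- function(a, b, mask = NULL) {
  av <- .ts_values(a); bv <- .ts_values(b)
  if (length(av) != length(bv))
    stop("length mismatch: ", length(av), " vs ", length(bv))
  if (!is.null(mask)) {
    if (length(mask) != length(av)) stop("'mask' length mismatch")
    av <- av[!mask]; bv <- bv[!mask]
  }
  if (length(av) < 2L) stop("need at least two unmasked samples")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("correlation undefined: a series is constant on the unmasked region")
  stats::cor(av, bv)
}

#' Read a two-column signal file
#'
#' Reads the plain-text signal format: two columns (time in seconds, signal
#' value), whitespace- or comma-delimited, no header. The sampling interval
#' is inferred as the median time step; time must be monotone and uniform to
#' within a relative tolerance of 1e-6.
#'
#' @param path file path.
#' @return A [resp_ts()] with \code{t0} set to the first time stamp.
#' @seealso [write_signal_file()], [write_recovered_file()]
#' @export
read_signal_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  dat <- tryCatch(utils::read.table(path, header = FALSE, sep = sep),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e)))
  if (ncol(dat) < 2L) stop("'", path, "' has fewer than 2 columns")
  tt <- suppressWarnings(as.numeric(dat[[1L]]))
  vv <- suppressWarnings(as.numeric(dat[[2L]]))
  bad <- which(!is.finite(tt) | !is.finite(vv))
  if (length(bad) > 0L)
    stop("malformed row(s) in '", path, "' at line ", bad[1L])
  steps <- diff(tt)
  if (any(steps <= 0))
    stop("non-monotone time column in '", path, "' at line ",
         which(steps <= 0)[1L] + 1L)
  dt <- stats::median(steps)
  off <- which(abs(steps - dt) > 1e-6 * dt)
  if (length(off) > 0L)
    stop("non-uniform sampling in '", path, "' near line ", off[1L] + 1L,
         ": step ", steps[off[1L]], " vs dt ", dt)
  resp_ts(vv, dt = dt, t0 = tt[1L])
}

#' Write a two-column signal file
#'
#' @param path destination path.
#' @param ts a [resp_ts()].
#' @param digits significant digits written (default 9).
#' @return \code{path}, invisibly.
#' @export
write_signal_file <- function(path, ts, digits = 9L) {
  stopifnot(inherits(ts, "resp_ts"))
  tt <- ts_time(ts)
  lines <- paste(formatC(tt, digits = digits, format = "g"),
                 formatC(ts$values, digits = digits, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a recovered-signal file
#'
#' Three whitespace-delimited columns — time, original (measured) signal,
#' corrected (recovered) signal — the convention of the released analysis
#' codes, so downstream tooling can consume the output unchanged.
#'
#' @param path destination path.
#' @param time,original,corrected equal-length numeric vectors.
#' @param digits significant digits written (default 9).
#' @return \code{path}, invisibly.
#' @export
write_recovered_file <- function(path, time, original, corrected, digits = 9L) {
  n <- length(time)
  if (length(original) != n || length(corrected) != n)
    stop("'time', 'original' and 'corrected' must have equal length")
  lines <- paste(formatC(time, digits = digits, format = "g"),
                 formatC(original, digits = digits, format = "g"),
                 formatC(corrected, digits = digits, format = "g"))
  writeLines(lines, path)
  invisible(path)
}
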