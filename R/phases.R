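#' Parcellated BOLD time series container
#'
#' @param values numeric N x T matrix, one row per parcel, one column per
#'   volume, in arbitrary BOLD units.
#' @param TR sampling interval in seconds.
#' @return object of class `bold_ts` with elements `values` and `TR`.
#' @export
bold_ts <- function(values, TR) {
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values))) {
    stop_invalid("BOLD values must be finite with no missing entries")
  }
  if (ncol(values) < 2) stop_invalid("need at least 2 volumes")
  if (!is.numeric(TR) || length(TR) != 1L || TR <= 0) stop_invalid("TR must be a positive scalar (seconds)")
  structure(list(values = values, TR = TR), class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("<bold_ts> ", nrow(x$values), " nodes x ", ncol(x$values),
      " volumes, TR = ", x$TR, " s",
      if (isTRUE(attr(x, "bandpassed"))) ", band-passed" else "", "\n", sep = "")
  invisible(x)
}

#' Zero-phase Butterworth band-pass of BOLD signals
#'
#' Each node is demeaned and filtered with a second-order Butterworth
#' band-pass (default 0.008-0.08 Hz, the resting-state band that removes
#' slow scanner drifts below and physiological noise above), applied
#' forward and backward so no phase distortion is introduced. The series
#' is padded by odd reflection at both ends before filtering to limit edge
#' transients at short scan lengths.
#'
#' @param ts a `bold_ts` (or plain matrix combined with `TR`).
#' @param low,high band edges in Hz; `high` must be below the Nyquist
#'   frequency 1/(2 TR).
#' @param order Butterworth order (default 2).
#' @param TR sampling interval in seconds, required when `ts` is a matrix.
#' @return a `bold_ts` with the same shape, flagged as band-passed.
#' @export
bandpass <- function(ts, low = 0.008, high = 0.08, order = 2, TR = NULL) {
  if (!inherits(ts, "bold_ts")) ts <- bold_ts(ts, TR)
  fs <- 1 / ts$TR
  nyq <- fs / 2
  if (!(low > 0 && low < high)) stop_invalid("need 0 < low < high")
  if (high >= nyq) {
    stop_invalid("high cutoff ", high, " Hz is at or above the Nyquist limit ",
                 signif(nyq, 4), " Hz for TR = ", ts$TR, " s")
  }
  filt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x <- ts$values - rowMeans(ts$values)
  out <- t(apply(x, 1L, filtfilt_reflect, b = filt$b, a = filt$a))
  res <- bold_ts(out, ts$TR)
  attr(res, "bandpassed") <- TRUE
  res
}

# forward-backward IIR filtering with odd-reflection padding at both ends
filtfilt_reflect <- function(x, b, a) {
  n <- length(x)
  p <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 12L))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(p + 1):(p + n)]
}

#' Instantaneous BOLD phases via the analytic signal
#'
#' Takes the Hilbert analytic signal of each (band-passed) node time course
#' and returns its complex argument: the instantaneous phase in (-pi, pi].
#' Nodes whose signal is identically zero have no defined phase and are
#' flagged as degenerate (their rows are NA) with a warning rather than
#' silently reported as zero phase.
#'
#' @param ts a `bold_ts`, normally the output of [bandpass()]. A warning is
#'   emitted if the series is not flagged as band-passed.
#' @param trim number of volumes to drop from each end of the series after
#'   the transform (default 0).
#' @return object of class `phase_field`: list with `phases` (N x T, rad),
#'   `amplitude` (analytic-signal modulus), `TR`, and `degenerate` (indices
#'   of flagged nodes).
#' @export
extract_phases <- function(ts, trim = 0L) {
  stopifnot(inherits(ts, "bold_ts"))
  if (!isTRUE(attr(ts, "bandpassed"))) {
    warning("input is not flagged as band-passed; phases assume band-limited signals", call. = FALSE)
  }
  x <- ts$values
  degenerate <- which(apply(x, 1L, function(r) all(abs(r) < .Machine$double.eps * 100)))
  z <- t(apply(x, 1L, analytic_signal))
  phases <- Arg(z)
  amplitude <- Mod(z)
  if (length(degenerate)) {
    warning(length(degenerate), " all-zero node(s) have undefined phase: ",
            paste(utils::head(degenerate, 5), collapse = ", "),
            if (length(degenerate) > 5) ", ..." else "", call. = FALSE)
    phases[degenerate, ] <- NA_real_
    amplitude[degenerate, ] <- NA_real_
  }
  if (trim > 0) {
    keep <- (trim + 1):(ncol(phases) - trim)
    phases <- phases[, keep, drop = FALSE]
    amplitude <- amplitude[, keep, drop = FALSE]
  }
  structure(
    list(phases = phases, amplitude = amplitude, TR = ts$TR, degenerate = degenerate),
    class = "phase_field"
  )
}

# analytic signal by the FFT construction: double positive frequencies,
# zero negative ones, keep DC (and Nyquist for even length) unchanged
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' @export
print.phase_field <- function(x, ...) {
  cat("<phase_field> ", nrow(x$phases), " nodes x ", ncol(x$phases),
      " volumes, TR = ", x$TR, " s\n", sep = "")
  invisible(x)
}

#' Read / write a BOLD matrix as delimited text
#'
#' Matrices are stored nodes-as-rows with tab separation; the TR travels in
#' a one-line `<path>.tr` sidecar so a directory of subjects stays
#' self-describing.
#'
#' @param ts a `bold_ts`.
#' @param path file path.
#' @param TR optional TR in seconds overriding the sidecar on read.
#' @export
write_bold <- function(ts, path) {
  stopifnot(inherits(ts, "bold_ts"))
  utils::write.table(ts$values, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(format(ts$TR), paste0(path, ".tr"))
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path, TR = NULL) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  if (is.null(TR)) {
    side <- paste0(path, ".tr")
    if (!file.exists(side)) stop_invalid("no TR given and no sidecar ", side)
    TR <- as.numeric(readLines(side, n = 1L))
  }
  bold_ts(values, TR)
}
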