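# Deterministic quantitative rules for the clinical myotonia instruments:
# needle-EMG discharge grading (Streib criteria), quantitative grip
# relaxation time (90% -> 5% of maximal force) and transient-paresis peak
# force decline within a fixed window.

#' Grade myotonic discharges from needle insertion counts
#'
#' Streib grading over 10 needle insertions: detection in 0-2 insertions is
#' grade "0", 3-5 is "1+", 6-9 is "2+" (more than half) and 10/10 is "3+"
#' (discharges with every needle movement).
#'
#' @param n_detections insertions (out of 10) eliciting myotonic discharges.
#' @return character grade in \code{c("0", "1+", "2+", "3+")}; vectorized.
#' @examples
#' grade_myotonic_discharges(c(2, 4, 7, 10))  # "0" "1+" "2+" "3+"
#' @export
grade_myotonic_discharges <- function(n_detections) {
  if (!is.numeric(n_detections) || any(is.na(n_detections)) ||
      any(n_detections != round(n_detections)) ||
      any(n_detections < 0) || any(n_detections > 10))
    stop("n_detections must be integer counts in [0, 10]", call. = FALSE)
  cut(n_detections, breaks = c(-1, 2, 5, 9, 10),
      labels = c("0", "1+", "2+", "3+")) |> as.character()
}

#' Force trace container
#'
#' @param force ordered force samples (arbitrary units, >= 2 samples).
#' @param rate sampling rate, Hz (> 0); ignored when \code{time} is given.
#' @param time optional explicit sample times, seconds.
#' @param mvic_onset optional event marker (seconds) for contraction onset;
#'   samples before it are ignored by the analyses.
#' @return an object of class \code{force_trace}.
#' @export
force_trace <- function(force, rate = NULL, time = NULL, mvic_onset = 0) {
  if (length(force) < 2L) stop("need >= 2 force samples", call. = FALSE)
  if (is.null(time)) {
    if (is.null(rate) || rate <= 0)
      stop("sampling rate must be > 0", call. = FALSE)
    time <- (seq_along(force) - 1) / rate
  }
  if (length(time) != length(force) || any(diff(time) <= 0))
    stop("time must be strictly increasing and match force", call. = FALSE)
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 mvic_onset = mvic_onset),
            class = "force_trace")
}

#' Read a force trace from CSV
#'
#' Accepts two-column (time, force) files, or single-column force files with
#' a \code{# rate: <Hz>} header line.
#'
#' @param path CSV file path.
#' @return a \code{\link{force_trace}}.
#' @export
read_force_trace <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*rate:", first)) {
    rate <- as.numeric(sub("^#\\s*rate:\\s*", "", first))
    df <- utils::read.csv(path, comment.char = "#", header = FALSE)
    force_trace(df[[1L]], rate = rate)
  } else {
    df <- utils::read.csv(path)
    if (ncol(df) < 2L) stop("expected (time, force) columns", call. = FALSE)
    force_trace(df[[2L]], time = df[[1L]])
  }
}

# Linearly interpolated time at which the segment (t1,f1)-(t2,f2) crosses
# level y.
cross_time <- function(t1, t2, f1, f2, y) t1 + (y - f1) / (f2 - f1) * (t2 - t1)

#' Grip relaxation time from 90% to 5% of maximal force
#'
#' The degree of myotonia is the relaxation time after a maximal voluntary
#' isometric contraction: the time from the force falling through 90\% of
#' peak to it first falling through 5\% of peak. Crossing times are linearly
#' interpolated between samples; when the decay is non-monotone the last
#' 90\% down-crossing before the 5\% crossing is used. The result is
#' invariant to rescaling of the force units.
#'
#' @param trace a \code{\link{force_trace}}.
#' @return relaxation time, seconds.
#' @export
relaxation_time <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  keep <- trace$time >= trace$mvic_onset
  tt <- trace$time[keep]; ff <- trace$force[keep]
  if (length(ff) < 2L || max(ff) <= 0 || stats::var(ff) == 0)
    stop("invalid trace: flat or empty force signal", call. = FALSE)
  peak <- max(ff)
  ipk <- which.max(ff)
  hi <- 0.90 * peak; lo <- 0.05 * peak
  # first 5%-of-peak down-crossing after the peak
  i05 <- NA_integer_
  for (j in seq(ipk + 1L, length.out = max(0L, length(ff) - ipk))) {
    if (ff[j] <= lo) { i05 <- j; break }
  }
  if (is.na(i05))
    stop("not relaxed: force never falls to 5% of peak", call. = FALSE)
  t05 <- if (ff[i05] == lo) tt[i05]
         else cross_time(tt[i05 - 1L], tt[i05], ff[i05 - 1L], ff[i05], lo)
  # last 90% down-crossing before the 5% crossing
  t90 <- NA_real_
  for (j in seq(ipk + 1L, i05)) {
    if (ff[j - 1L] > hi && ff[j] <= hi)
      t90 <- if (ff[j] == hi) tt[j]
             else cross_time(tt[j - 1L], tt[j], ff[j - 1L], ff[j], hi)
  }
  if (is.na(t90)) t90 <- tt[ipk]  # peak already at/below 90% band edge
  t05 - t90
}

#' Transient-paresis force decline within a window after the peak
#'
#' Percent decline of the peak force (PF) within a fixed window (3 seconds,
#' the MVIC duration) after the peak: 100 * (PF - min force) / PF. A peak at
#' the very end of the window leaves nothing to decline and returns 0 with a
#' warning.
#'
#' @param trace a \code{\link{force_trace}}.
#' @param window window length after the peak, seconds.
#' @return percent decline in [0, 100].
#' @export
transient_paresis_decline <- function(trace, window = 3) {
  stopifnot(inherits(trace, "force_trace"), window > 0)
  keep <- trace$time >= trace$mvic_onset
  tt <- trace$time[keep]; ff <- trace$force[keep]
  if (length(ff) < 2L || max(ff) <= 0)
    stop("invalid trace: flat or empty force signal", call. = FALSE)
  if (window > max(tt) - min(tt))
    window <- max(tt) - min(tt)
  ipk <- which.max(ff)
  peak <- ff[ipk]
  in_win <- which(tt > tt[ipk] & tt <= tt[ipk] + window)
  if (!length(in_win)) {
    warning("peak at window end: no samples after the peak", call. = FALSE)
    return(0)
  }
  100 * (peak - min(ff[in_win], peak)) / peak
}
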