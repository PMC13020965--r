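#' Local activation time of a trace
#'
#' The time of the minimum central-difference temporal derivative (steepest
#' downstroke), the clinical unipolar convention; ties break to the earliest
#' time.  The same rule is applied to simulated transmembrane histories and
#' to extracellular traces.
#'
#' @param phi numeric trace (mV) or a trace list from [egm_trace()].
#' @param time sample times, ms (ignored when `phi` is a trace list).
#' @return LAT, ms.
#' @export
detect_lat <- function(phi, time = NULL) {
  if (is.list(phi)) { time <- phi$time; phi <- phi$phi }
  .stop_if(length(phi) < 3, "need at least 3 samples")
  .stop_if(diff(range(phi)) == 0, "constant trace has no defined activation")
  d <- .central_diff(phi, time)
  time[which.min(d)]
}

# local extrema (maxima of x and of -x) with topographic prominence
.extrema_prominence <- function(x) {
  n <- length(x)
  out <- list(idx = integer(0), prom = numeric(0), kind = integer(0))
  for (sgn in c(1, -1)) {
    y <- sgn * x
    d <- diff(y)
    # strict local maxima (plateaus take their first sample)
    cand <- which(diff(sign(c(-1, d))) < 0)
    cand <- cand[cand > 1 & cand < n]
    for (i in cand) {
      # walk left/right to nearest strictly higher ground, track minima
      lmin <- y[i]; j <- i
      while (j > 1 && y[j] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
      lbase <- if (y[j] > y[i]) lmin else min(y[seq_len(i)])
      rmin <- y[i]; j <- i
      while (j < n && y[j] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
      rbase <- if (y[j] > y[i]) rmin else min(y[i:n])
      out$idx <- c(out$idx, i)
      out$prom <- c(out$prom, y[i] - max(lbase, rbase))
      out$kind <- c(out$kind, sgn)
    }
  }
  out
}

#' Count deflections in an electrogram
#'
#' A deflection is a local extremum (positive or negative) whose topographic
#' prominence reaches `prominence_frac` of the trace's peak-to-peak
#' amplitude, counted inside the active window; the count is invariant to
#' amplitude scaling and additive offset.
#'
#' @param phi numeric trace or [egm_trace()] list.
#' @param time sample times, ms.
#' @param prominence_frac prominence threshold as a fraction of peak-to-peak.
#' @param window optional `c(t0, t1)` restricting the count (defaults to the
#'   whole trace).
#' @return Integer deflection count (0 for a flat trace).
#' @export
count_deflections <- function(phi, time = NULL, prominence_frac = 0.10,
                              window = NULL) {
  if (is.list(phi)) { time <- phi$time; phi <- phi$phi }
  p2p <- diff(range(phi))
  if (p2p == 0) return(0L)
  ex <- .extrema_prominence(phi)
  keep <- ex$prom >= prominence_frac * p2p
  if (!is.null(window) && !is.null(time))
    keep <- keep & time[ex$idx] >= window[1] & time[ex$idx] <= window[2]
  sum(keep)
}

#' Characterize an electrogram
#'
#' Extracts the eight characteristic parameters plus the LAT:
#' downstroke (minimum derivative), rising upstroke (maximum derivative
#' before the steepest downstroke), recovery upstroke (maximum derivative
#' after it), signal width (time between the absolute maximum and minimum
#' peaks), EGM duration (span where the trace leaves the baseline band),
#' baseline, peak-to-peak amplitude and deflection count.  Derivatives are
#' central differences in mV/ms.  The baseline is the mean of the first and
#' last 10 ms unless activity overlaps those windows, in which case the
#' trace median is used; the activity threshold is
#' `max(5% of peak-to-peak, 3 x baseline-segment SD)`.
#'
#' @param phi numeric trace (mV) or [egm_trace()] list.
#' @param time sample times, ms.
#' @param prominence_frac deflection prominence threshold.
#' @return One-row `data.frame` with columns `downstroke`, `rising_upstroke`,
#'   `recovery_upstroke`, `signal_width`, `egm_duration`, `baseline`,
#'   `peak_to_peak`, `deflection_count`, `lat`.
#' @export
characterize <- function(phi, time = NULL, prominence_frac = 0.10) {
  if (is.list(phi)) { time <- phi$time; phi <- phi$phi }
  .stop_if(length(phi) < 5, "trace too short")
  .stop_if(diff(range(phi)) == 0, "constant trace cannot be characterized")
  n <- length(phi)
  dt <- time[2] - time[1]
  edge <- max(2L, min(round(10 / dt), floor(n / 4)))   # ~10 ms head/tail
  seg <- c(phi[seq_len(edge)], phi[(n - edge + 1):n])
  baseline <- mean(seg)
  p2p <- max(phi) - min(phi)
  thr <- max(0.05 * p2p, 3 * sd(seg))
  act <- abs(phi - baseline) > thr
  if (any(act[c(seq_len(edge), (n - edge + 1):n)])) {
    baseline <- median(phi)
    seg_sd <- sd(seg)
    thr <- max(0.05 * p2p, 3 * seg_sd)
    act <- abs(phi - baseline) > thr
  }
  d <- .central_diff(phi, time)
  i_dn <- which.min(d)
  downstroke <- d[i_dn]
  rising <- if (i_dn > 1) max(d[seq_len(i_dn - 1)]) else NA_real_
  recovery <- if (i_dn < n) max(d[(i_dn + 1):n]) else NA_real_
  signal_width <- abs(time[which.max(phi)] - time[which.min(phi)])
  egm_duration <- if (any(act)) diff(range(time[act])) else 0
  data.frame(downstroke = downstroke, rising_upstroke = rising,
             recovery_upstroke = recovery, signal_width = signal_width,
             egm_duration = egm_duration, baseline = baseline,
             peak_to_peak = p2p,
             deflection_count = count_deflections(phi, time, prominence_frac),
             lat = time[i_dn])
}

#' Characterize every trace of an EGM set
#'
#' @param set an [egm_set()].
#' @param prominence_frac deflection prominence threshold.
#' @return `data.frame` with one row per electrode (plus column `electrode`).
#' @export
characterize_set <- function(set, prominence_frac = 0.10) {
  stopifnot(inherits(set, "egm_set"))
  rows <- lapply(seq_len(ncol(set$phi)), function(i)
    characterize(set$phi[, i], set$time, prominence_frac))
  out <- do.call(rbind, rows)
  cbind(electrode = seq_len(ncol(set$phi)), out)
}
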