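# Feature extraction from displacement traces: pulse-peak detection,
# chest-to-wrist transit-time delay, pulse wave velocity, and the
# area-under-curve (AUC) sharpness of the systolic peak at half
# amplitude.

#' Detect systolic pulse peaks
#'
#' Finds local maxima separated by at least `min_separation_s`, ranks
#' them by topographic prominence (height above the higher of the two
#' flanking valleys, tolerant of baseline drift), and returns the `k`
#' most prominent in time order.
#'
#' @param trace A [displacement_trace()] of at least 2 s.
#' @param min_separation_s Minimum peak spacing (s); default 0.4 s,
#'   roughly the shortest plausible beat interval.
#' @param k_peaks Number of peaks to return (default 3: the feature is
#'   averaged over the three highest peaks of a record).
#' @return An object of class `peak_set`: `peak_indices` (1-based, time
#'   order), `peak_amplitudes` (mm), `prominences`, `n_candidates`, and
#'   `short` = TRUE if fewer than `k_peaks` were found (also warned).
#' @export
detect_pulse_peaks <- function(trace, min_separation_s = 0.4, k_peaks = 3L) {
  stopifnot(inherits(trace, "displacement_trace"), k_peaks >= 1)
  x <- trace$values
  n <- length(x)
  if (n * trace$sample_period_s < 2) {
    stop("trace must cover at least 2 s", call. = FALSE)
  }
  cand <- local_maxima(x)
  if (!length(cand)) {
    warning("no local maxima found", call. = FALSE)
    return(structure(list(peak_indices = integer(0),
                          peak_amplitudes = numeric(0),
                          prominences = numeric(0),
                          n_candidates = 0L, short = TRUE),
                     class = "peak_set"))
  }
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  # greedy min-separation enforcement, most prominent first
  min_sep <- max(1L, round(min_separation_s / trace$sample_period_s))
  ord <- order(prom, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(cand[keep] - cand[i]) >= min_sep)) {
      keep <- c(keep, i)
    }
  }
  keep <- keep[seq_len(min(k_peaks, length(keep)))]
  short <- length(keep) < k_peaks
  if (short) {
    warning(sprintf("only %d of %d requested peaks found",
                    length(keep), k_peaks), call. = FALSE)
  }
  o <- order(cand[keep])
  idx <- cand[keep][o]
  structure(list(peak_indices = idx, peak_amplitudes = x[idx],
                 prominences = prom[keep][o],
                 n_candidates = length(cand), short = short),
            class = "peak_set")
}

# Interior local maxima, plateau-tolerant: a rise followed (possibly
# after a flat stretch) by a fall marks one maximum at the plateau
# midpoint.
local_maxima <- function(x) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (!length(nz)) return(integer(0))
  # carry the preceding non-zero slope through plateaus
  idx <- findInterval(seq_along(s), nz)
  filled <- ifelse(idx == 0L, 0, s[nz][pmax(idx, 1L)])
  ends <- which(filled[-length(filled)] == 1 & s[-1] == -1) + 1L
  vapply(ends, function(e) {
    st <- e
    while (st > 1L && x[st - 1L] == x[st]) st <- st - 1L
    as.integer(round((st + e) / 2))
  }, integer(1))
}

# Topographic prominence of local maximum p: walk out on each side until
# a strictly higher sample or the edge; base on that side is the minimum
# encountered; prominence = height - max(left base, right base).
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- if (p > 1L) {
    seg <- x[seq_len(p - 1L)]
    higher <- which(seg > h)
    min(x[seq(if (length(higher)) max(higher) else 1L, p)])
  } else h
  right <- if (p < length(x)) {
    seg <- x[seq(p + 1L, length(x))]
    higher <- which(seg > h)
    hi <- if (length(higher)) p + min(higher) else length(x)
    min(x[seq(p, hi)])
  } else h
  h - max(left, right)
}

#' Estimate pulse transit time between chest and wrist traces
#'
#' The PTT is the lag maximizing the normalized cross-correlation of the
#' two synchronized displacement traces over a physiological search
#' window; resolution is one frame period. The correlation is computed on
#' the overlapping (mean-removed) segments at each candidate lag.
#'
#' @param chest,wrist [displacement_trace()]s with identical sample
#'   periods (the two radars share a time base).
#' @param search_window_s Lag window (s); default `c(0.05, 0.5)`.
#' @param min_correlation Reject estimates whose peak normalized
#'   correlation falls below this (default 0.3) with an error.
#' @return PTT in seconds (numeric scalar) with attributes
#'   `correlation` (peak normalized cross-correlation) and `at_boundary`
#'   (TRUE, with a warning, when the best lag sits on a window edge -
#'   e.g. a true delay below the window's lower bound).
#' @export
estimate_ptt <- function(chest, wrist, search_window_s = c(0.05, 0.5),
                         min_correlation = 0.3) {
  stopifnot(inherits(chest, "displacement_trace"),
            inherits(wrist, "displacement_trace"),
            isTRUE(all.equal(chest$sample_period_s, wrist$sample_period_s)),
            length(search_window_s) == 2L,
            search_window_s[1] < search_window_s[2])
  dt <- chest$sample_period_s
  n <- min(length(chest$values), length(wrist$values))
  x <- chest$values[seq_len(n)] - mean(chest$values[seq_len(n)])
  y <- wrist$values[seq_len(n)] - mean(wrist$values[seq_len(n)])
  lags <- seq(max(1L, round(search_window_s[1] / dt)),
              round(search_window_s[2] / dt))
  if (max(lags) >= n - 1L) stop("trace too short for search window",
                                call. = FALSE)
  r <- vapply(lags, function(L) {
    a <- x[seq_len(n - L)]
    b <- y[seq(L + 1L, n)]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(0)
    sum(a * b) / den
  }, numeric(1))
  best <- which.max(r)
  if (r[best] < min_correlation) {
    stop(sprintf(paste0("unreliable PTT estimate: peak correlation %.2f ",
                        "below %.2f"), r[best], min_correlation),
         call. = FALSE)
  }
  at_boundary <- best == 1L || best == length(lags)
  if (at_boundary) {
    warning(sprintf("PTT estimate %.3f s sits on the search-window edge",
                    lags[best] * dt), call. = FALSE)
  }
  structure(lags[best] * dt, correlation = r[best],
            at_boundary = at_boundary)
}

#' Pulse wave velocity from transit time
#'
#' `PWV = L / PTT`: arterial path length (heart to wrist) over transit
#' time.
#'
#' @param ptt Pulse transit time (s), strictly positive.
#' @param arm_length Heart-to-wrist path length L (m), strictly positive.
#' @return Pulse wave velocity (m/s).
#' @export
compute_pwv <- function(ptt, arm_length) {
  if (any(ptt <= 0)) stop("`ptt` must be strictly positive", call. = FALSE)
  if (any(arm_length <= 0)) stop("`arm_length` must be strictly positive",
                                 call. = FALSE)
  arm_length / ptt
}

#' Area-under-curve sharpness of the systolic peaks
#'
#' For each detected peak: take the segment bounded by the adjacent
#' valleys (monotone descent on each side), subtract the local baseline
#' (the lower valley), normalize the peak to unit amplitude, and
#' integrate `x(t) - 0.5` over the contiguous region around the peak
#' where `x(t) >= 0.5` (trapezoidal rule at the frame period, with the
#' half-amplitude crossings located by linear interpolation). The AUC of
#' a record is the mean over the peaks; units are seconds. Because of the
#' normalization the value is invariant to amplitude gain and offset;
#' sharper (narrower) peaks give smaller AUC.
#'
#' @param trace A [displacement_trace()].
#' @param peaks A [detect_pulse_peaks()] result with at least one peak.
#' @return Mean AUC (s) with attribute `per_peak`.
#' @export
#' @examples
#' # raised-cosine peak of width B has AUC exactly B / (2*pi)
#' dt <- 5e-4; B <- 0.2
#' t <- seq(0, 3, by = dt)
#' x <- ifelse(abs(t - 1.5) <= B / 2, 0.5 * (1 + cos(2 * pi * (t - 1.5) / B)), 0)
#' tr <- displacement_trace(x, dt)
#' compute_auc(tr, detect_pulse_peaks(tr, k_peaks = 1))  # ~0.03183
compute_auc <- function(trace, peaks) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(peaks, "peak_set"))
  if (!length(peaks$peak_indices)) stop("need at least one peak",
                                        call. = FALSE)
  x <- trace$values
  dt <- trace$sample_period_s
  per_peak <- vapply(peaks$peak_indices, function(p) {
    l <- walk_to_valley(x, p, -1L)
    r <- walk_to_valley(x, p, +1L)
    seg <- x[l:r]
    base <- min(seg)
    height <- x[p] - base
    if (height <= 0) return(NA_real_)
    z <- (seg - base) / height            # peak normalized to 1
    pk <- p - l + 1L
    auc_half_peak(z, pk, dt)
  }, numeric(1))
  structure(mean(per_peak, na.rm = TRUE), per_peak = per_peak)
}

# Walk from peak p towards the adjacent valley: follow the running
# minimum and stop once the trace has risen off the valley floor by
# tol_frac of the trace's peak-to-floor span (a fixed scale, so plateaus
# and sample-level noise on the flanks do not end the walk prematurely).
# Returns the valley index.
walk_to_valley <- function(x, p, dir, tol_frac = 0.1) {
  tol <- tol_frac * (x[p] - min(x))
  i <- p
  m <- x[p]; mi <- p
  n <- length(x)
  repeat {
    j <- i + dir
    if (j < 1L || j > n) break
    if (x[j] < m) {
      m <- x[j]; mi <- j
    } else if (x[j] > m + tol) {
      break
    }
    i <- j
  }
  mi
}

# Integrate (z - 0.5) over the contiguous region around index pk where
# z >= 0.5, interpolating the 0.5 crossings between samples.
auc_half_peak <- function(z, pk, dt) {
  n <- length(z)
  a <- pk; while (a > 1L && z[a - 1L] >= 0.5) a <- a - 1L
  b <- pk; while (b < n && z[b + 1L] >= 0.5) b <- b + 1L
  tt <- (seq(a, b) - pk) * dt
  yy <- z[a:b] - 0.5
  if (a > 1L) {                       # left crossing by interpolation
    frac <- (0.5 - z[a - 1L]) / (z[a] - z[a - 1L])
    tt <- c(tt[1] - (1 - frac) * dt, tt)
    yy <- c(0, yy)
  } else {
    warning("peak segment never crosses the half-amplitude line on the left; integrating to the segment edge",
            call. = FALSE)
  }
  if (b < n) {
    frac <- (0.5 - z[b + 1L]) / (z[b] - z[b + 1L])
    tt <- c(tt, tt[length(tt)] + (1 - frac) * dt)
    yy <- c(yy, 0)
  } else {
    warning("peak segment never crosses the half-amplitude line on the right; integrating to the segment edge",
            call. = FALSE)
  }
  trapz(tt, yy)
}

#' Extract a full feature record from a chest/wrist trace pair
#'
#' Runs [estimate_ptt()], [compute_pwv()] and (on the wrist trace, whose
#' waveform carries the pulse shape) [detect_pulse_peaks()] +
#' [compute_auc()].
#'
#' @param chest,wrist [displacement_trace()]s.
#' @param arm_length Heart-to-wrist path length (m).
#' @param subject_id Identifier copied into the record.
#' @param k_peaks,min_separation_s Passed to [detect_pulse_peaks()].
#' @param search_window_s Passed to [estimate_ptt()].
#' @return One-row data frame: `subject_id`, `ptt_s`, `pwv_mps`, `auc_s`.
#' @export
extract_features <- function(chest, wrist, arm_length,
                             subject_id = NA, k_peaks = 3L,
                             min_separation_s = 0.4,
                             search_window_s = c(0.05, 0.5)) {
  ptt <- estimate_ptt(chest, wrist, search_window_s = search_window_s)
  peaks <- detect_pulse_peaks(wrist, min_separation_s = min_separation_s,
                              k_peaks = k_peaks)
  auc <- compute_auc(wrist, peaks)
  data.frame(subject_id = subject_id, ptt_s = as.numeric(ptt),
             pwv_mps = compute_pwv(as.numeric(ptt), arm_length),
             auc_s = as.numeric(auc), stringsAsFactors = FALSE)
}
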