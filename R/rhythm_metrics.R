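# Spike, burst and rhythm metrics for two-cell circuit traces.

#' Detect spikes by upward threshold crossing
#'
#' A spike is counted whenever the voltage crosses the threshold (-30 mV)
#' from below; the event time is the first sample at or above threshold.
#'
#' @param V Voltage samples, mV.
#' @param times Sample times, ms (same length as `V`).
#' @param threshold Crossing threshold, mV.
#' @return Numeric vector of spike times (possibly empty).
#' @export
detect_spikes <- function(V, times, threshold = -30) {
  stopifnot(length(V) == length(times))
  if (length(V) < 2) return(numeric(0))
  idx <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1L
  times[idx]
}

#' Interspike-interval burst threshold
#'
#' The burst-segmentation threshold is one half of the sum of the 90th
#' percentile (nearest-rank) and the minimum of the interspike-interval
#' distribution.  When this threshold falls within 10 ms of the minimum or
#' maximum ISI the train has no separable burst structure and the cell is
#' considered tonically spiking.
#'
#' @param spike_times Sorted spike times, ms (at least two).
#' @param tonic_margin Distance (ms) to the ISI extremes below which the
#'   train is called tonic.
#' @return List with `threshold` (ms) and logical `tonic`.
#' @export
isi_burst_threshold <- function(spike_times, tonic_margin = 10) {
  if (length(spike_times) < 2)
    stop("at least two spikes are required to define an ISI threshold")
  isi <- diff(spike_times)
  p90 <- sort(isi)[ceiling(0.9 * length(isi))]  # nearest-rank percentile
  thr <- 0.5 * (p90 + min(isi))
  tonic <- (thr - min(isi)) < tonic_margin || (max(isi) - thr) < tonic_margin
  list(threshold = thr, tonic = tonic)
}

#' Group spikes into bursts by an ISI threshold
#'
#' Consecutive spikes separated by at most `threshold` share a burst; an
#' isolated spike forms a single-spike burst.
#'
#' @param spike_times Sorted spike times, ms.
#' @param threshold ISI threshold, ms.
#' @return Data frame with columns `onset`, `offset` (ms) and `n_spikes`.
#' @export
segment_bursts <- function(spike_times, threshold) {
  n <- length(spike_times)
  if (n == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0)))
  brk <- which(diff(spike_times) > threshold)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  data.frame(onset = spike_times[starts], offset = spike_times[ends],
             n_spikes = ends - starts + 1L)
}

#' Merge bursts with no opponent activity between them
#'
#' In a coupled circuit, consecutive bursts of one cell with no event (spike)
#' of the other cell strictly between them are considered one long burst.
#' Applied transitively along the burst sequence.
#'
#' @param bursts Burst data frame of the focal cell ([segment_bursts()]).
#' @param events_other Sorted event times (spikes) of the other cell, ms.
#' @return Merged burst data frame.
#' @export
merge_opponent_gaps <- function(bursts, events_other) {
  n <- nrow(bursts)
  if (n <= 1) return(bursts)
  grp <- integer(n)
  grp[1] <- 1L
  for (i in 2:n) {
    gap_has_event <- any(events_other > bursts$offset[i - 1] &
                           events_other < bursts$onset[i])
    grp[i] <- if (gap_has_event) grp[i - 1] + 1L else grp[i - 1]
  }
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(ix) {
    data.frame(onset = bursts$onset[ix[1]],
               offset = bursts$offset[ix[length(ix)]],
               n_spikes = sum(bursts$n_spikes[ix]))
  }))
  rownames(out) <- NULL
  out
}

#' Burst-train extraction for one cell of a circuit
#'
#' Full per-cell pipeline: spike detection, ISI threshold (tonic cells fall
#' back to single-spike bursts), burst segmentation, and the opponent-gap
#' merge using the other cell's spikes.
#'
#' @param spikes Spike times of the focal cell, ms.
#' @param spikes_other Spike times of the other cell, ms.
#' @return List of class `burst_train`: `spike_times`, `bursts` (data frame),
#'   `mode` (one of `"bursting"`, `"spiking"`, `"silent"`).
#' @export
burst_train <- function(spikes, spikes_other = numeric(0)) {
  if (length(spikes) == 0)
    return(structure(list(spike_times = spikes,
                          bursts = segment_bursts(numeric(0), 0),
                          mode = "silent"), class = "burst_train"))
  if (length(spikes) == 1) {
    bursts <- segment_bursts(spikes, Inf)
    mode <- "bursting"
  } else {
    thr <- isi_burst_threshold(spikes)
    if (thr$tonic) {
      bursts <- data.frame(onset = spikes, offset = spikes,
                           n_spikes = rep(1L, length(spikes)))
      mode <- "spiking"
    } else {
      bursts <- segment_bursts(spikes, thr$threshold)
      mode <- "bursting"
    }
  }
  merged <- merge_opponent_gaps(bursts, spikes_other)
  # a tonic cell whose spikes merge into multi-spike alternating groups is
  # rhythmic at the circuit level
  if (mode == "spiking" && nrow(merged) < nrow(bursts) && nrow(merged) >= 2)
    mode <- "bursting"
  structure(list(spike_times = spikes, bursts = merged, mode = mode),
            class = "burst_train")
}

#' Burst-exclusion metric
#'
#' Measures how exclusively two cells partition the trial: with total active
#' times `t1`, `t2`, measured co-active overlap `O_network`, chance overlap
#' `O_random = t1 t2 / T` and minimum possible overlap
#' `O_min = max(0, t1 + t2 - T)`, the metric is
#' `x = (O_random - O_network) / (O_random - O_min)`.
#' Perfect alternation gives 1, chance-level overlap gives 0.  Values outside
#' \[0, 1\] from degenerate interval sets are clamped with a warning.
#'
#' @param active1,active2 Two-column matrices (start, end) of active
#'   intervals, ms; intervals within a cell must be disjoint.
#' @param T_trial Total trial duration, ms.
#' @return List with `x_network`, `t_cell1`, `t_cell2`, `O_network`,
#'   `O_random`, `O_min`.
#' @export
burst_exclusion <- function(active1, active2, T_trial) {
  active1 <- matrix(as.numeric(active1), ncol = 2)
  active2 <- matrix(as.numeric(active2), ncol = 2)
  t1 <- sum(active1[, 2] - active1[, 1])
  t2 <- sum(active2[, 2] - active2[, 1])
  if (t1 <= 0 || t2 <= 0)
    return(list(x_network = NA_real_, t_cell1 = t1, t_cell2 = t2,
                O_network = NA_real_, O_random = NA_real_, O_min = NA_real_))
  # sweep-free exact overlap: sum of pairwise intersections (intervals within
  # a cell are disjoint, so no double counting)
  ov <- 0
  for (i in seq_len(nrow(active1))) {
    lo <- pmax(active1[i, 1], active2[, 1])
    hi <- pmin(active1[i, 2], active2[, 2])
    ov <- ov + sum(pmax(0, hi - lo))
  }
  O_random <- t1 * t2 / T_trial
  O_min <- max(0, t1 + t2 - T_trial)
  x <- (O_random - ov) / (O_random - O_min)
  if (is.finite(x) && (x < 0 || x > 1)) {
    warning("burst exclusion outside [0,1]; clamped")
    x <- min(1, max(0, x))
  }
  list(x_network = x, t_cell1 = t1, t_cell2 = t2,
       O_network = ov, O_random = O_random, O_min = O_min)
}

#' Phase difference and period from two burst trains
#'
#' The period is the mean inter-onset interval of the reference cell
#' (cell 1, the designated perturbed cell).  For each reference cycle the
#' per-cycle phase is the delay from the reference onset to the next onset of
#' the other cell, divided by the period; the phase difference is the mean
#' over cycles, wrapped to \[0, 1).
#'
#' @param bursts1,bursts2 Burst data frames (reference cell first).
#' @return List with `phi` and `period` (ms); both `NA` when either cell has
#'   fewer than two burst onsets.
#' @export
phase_and_period <- function(bursts1, bursts2) {
  on1 <- bursts1$onset
  on2 <- bursts2$onset
  if (length(on1) < 2 || length(on2) < 2)
    return(list(phi = NA_real_, period = NA_real_))
  period <- mean(diff(on1))
  phis <- vapply(on1[-length(on1)], function(t0) {
    nxt <- on2[on2 >= t0]
    if (length(nxt) == 0) return(NA_real_)
    ((nxt[1] - t0) / period) %% 1
  }, numeric(1))
  phis <- phis[!is.na(phis)]
  if (length(phis) == 0) return(list(phi = NA_real_, period = period))
  list(phi = mean(phis) %% 1, period = period)
}

#' Classify circuit output
#'
#' Applies the functionality criteria to a simulated trace: the circuit is
#' functional iff both cells burst regularly in alternation
#' (`x_network >= x_min`), the phase difference is 0.5 +/- `phi_tol` and the
#' period lies within `period_range`.  A cell with no spike after the
#' transient makes the circuit `one_silent`.
#'
#' @param trace A `simulation_trace`.
#' @param transient Initial time excluded from all metrics, ms.
#' @param x_min Burst-exclusion threshold for functionality.
#' @param phi_tol Allowed deviation of the phase difference from 0.5.
#' @param period_range Allowed period range, ms.
#' @param cv_max Maximum coefficient of variation of inter-onset intervals
#'   for "regular" firing.
#' @return List of class `circuit_output`: `classification` (one of
#'   `"functional"`, `"active_nonfunctional"`, `"one_silent"`),
#'   `silenced_cell` (`"none"`, `"cell1"`, `"cell2"`, `"both"`), `phi`,
#'   `period`, `x_network`, `t_cell1`, `t_cell2`, and the two `burst_train`s.
#' @export
classify_output <- function(trace, transient = 1000, x_min = 0.95,
                            phi_tol = 0.03, period_range = c(100, 800),
                            cv_max = 0.1) {
  keep <- trace$times >= transient
  tt <- trace$times[keep]
  T_trial <- if (length(tt)) max(tt) - transient else 0
  s1 <- detect_spikes(trace$V1[keep], tt)
  s2 <- detect_spikes(trace$V2[keep], tt)
  base <- list(phi = NA_real_, period = NA_real_, x_network = NA_real_,
               t_cell1 = 0, t_cell2 = 0, train1 = NULL, train2 = NULL)
  finish <- function(cls, silenced, extra = list()) {
    structure(utils::modifyList(c(list(classification = cls,
                                       silenced_cell = silenced), base),
                                extra),
              class = "circuit_output")
  }
  if (isTRUE(trace$blown)) {
    sil <- if (length(s1) == 0 && length(s2) == 0) "both"
           else if (length(s1) == 0) "cell1"
           else if (length(s2) == 0) "cell2" else "none"
    return(finish("one_silent", if (sil == "none") "both" else sil,
                  list(failure = "blow_up")))
  }
  if (length(s1) == 0 || length(s2) == 0) {
    sil <- if (length(s1) == 0 && length(s2) == 0) "both"
           else if (length(s1) == 0) "cell1" else "cell2"
    # keep the surviving cell's burst train for downstream spike statistics
    return(finish("one_silent", sil,
                  list(train1 = if (length(s1)) burst_train(s1, s2) else NULL,
                       train2 = if (length(s2)) burst_train(s2, s1) else NULL)))
  }
  tr1 <- burst_train(s1, s2)
  tr2 <- burst_train(s2, s1)
  pp <- phase_and_period(tr1$bursts, tr2$bursts)
  act1 <- as.matrix(tr1$bursts[, c("onset", "offset")])
  act2 <- as.matrix(tr2$bursts[, c("onset", "offset")])
  bx <- suppressWarnings(burst_exclusion(act1, act2, T_trial))
  regular <- function(tr) {
    on <- tr$bursts$onset
    if (length(on) < 3) return(FALSE)  # need >= 2 intervals for a CV
    stats::sd(diff(on)) / mean(diff(on)) < cv_max
  }
  ok <- !is.na(pp$phi) && !is.na(bx$x_network) &&
    bx$x_network >= x_min &&
    abs(pp$phi - 0.5) <= phi_tol &&
    pp$period >= period_range[1] && pp$period <= period_range[2] &&
    regular(tr1) && regular(tr2)
  finish(if (ok) "functional" else "active_nonfunctional", "none",
         list(phi = pp$phi, period = pp$period, x_network = bx$x_network,
              t_cell1 = bx$t_cell1, t_cell2 = bx$t_cell2,
              train1 = tr1, train2 = tr2))
}
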