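# Single- and double-conductance perturbations and the global stability
# value theta: the mean proximity of the perturbed phase difference to the
# unperturbed phase difference over a full ramp of conductance scalings.

#' Scale one maximal conductance of one cell
#'
#' Returns a copy of the circuit with `gbar[channel]` of the chosen cell
#' multiplied by `fraction`; everything else untouched.
#'
#' @param circuit A `circuit_parameters`.
#' @param cell `"cell1"` or `"cell2"`.
#' @param channel One of the seven gated channel names.
#' @param fraction Scale factor in \[0, 2\].
#' @return A new `circuit_parameters`.
#' @export
scale_conductance <- function(circuit, cell, channel, fraction) {
  cell <- match.arg(cell, c("cell1", "cell2"))
  channel <- match.arg(channel, GATED_CHANNELS)
  if (fraction < 0 || fraction > 2)
    stop("fraction must lie in [0, 2]")
  circuit[[cell]]$gbar[channel] <- circuit[[cell]]$gbar[channel] * fraction
  circuit
}

#' Proximity of a perturbed phase difference to the reference
#'
#' 1 when the phase difference is unchanged, 0 for a dysfunctional circuit,
#' and linearly decreasing in the circular phase distance otherwise:
#' `max(0, 1 - d(phi_i, phi_0) / phi_0)` with
#' `d` the wrapped distance on the unit circle.
#'
#' @param phi_i Perturbed phase difference in \[0, 1), or `NA`.
#' @param phi_0 Unperturbed phase difference in (0, 1).
#' @param functional Logical; `FALSE` scores 0 regardless of phase.
#' @return Proximity in \[0, 1\].
#' @export
proximity <- function(phi_i, phi_0, functional) {
  if (!isTRUE(functional) || is.na(phi_i)) return(0)
  d <- abs(phi_i - phi_0)
  d <- min(d, 1 - d)
  max(0, 1 - d / phi_0)
}

#' Stability value from per-step proximities
#'
#' @param proximities Numeric vector of per-step proximities in \[0, 1\].
#' @return Their arithmetic mean.
#' @export
stability_value <- function(proximities) {
  stopifnot(all(proximities >= 0 & proximities <= 1))
  mean(proximities)
}

# Evaluate one perturbed parameter point: returns phase, classification and
# the ingredients of the proximity score.  A step is "dysfunctional" (score
# 0) when a cell is silent or no alternating rhythm with a measurable phase
# remains; otherwise the step is scored by phase proximity alone.
eval_perturbed <- function(circuit, eval_duration, dt, transient,
                           record_every = 4L) {
  tr <- integrate_circuit(circuit, eval_duration, dt = dt,
                          record_every = record_every)
  cl <- classify_output(tr, transient = transient)
  step_ok <- cl$classification != "one_silent" && !is.na(cl$phi)
  sbp <- c(NA_real_, NA_real_); ibi <- c(NA_real_, NA_real_)
  for (k in 1:2) {
    trn <- cl[[paste0("train", k)]]
    if (!is.null(trn)) {
      sbp[k] <- mean(trn$bursts$n_spikes)
      ibi[k] <- within_burst_isi(trn)
    }
  }
  list(phi = cl$phi, period = cl$period, classification = cl$classification,
       silenced_cell = cl$silenced_cell, functional_step = step_ok,
       spikes_per_burst = sbp, within_isi = ibi,
       train1 = cl$train1, train2 = cl$train2)
}

# mean ISI between consecutive spikes inside the same burst
within_burst_isi <- function(train) {
  sp <- train$spike_times
  b <- train$bursts
  isis <- numeric(0)
  for (i in seq_len(nrow(b))) {
    s <- sp[sp >= b$onset[i] & sp <= b$offset[i]]
    if (length(s) >= 2) isis <- c(isis, diff(s))
  }
  if (length(isis)) mean(isis) else NA_real_
}

#' Stability of a circuit to one single-conductance perturbation
#'
#' Scales the chosen channel of the chosen cell in `n_steps` equally spaced
#' fractions along one half-axis (down: towards 0; up: towards 200%), and
#' simulates and scores each step.  The unperturbed point is not a step; no
#' early termination (every step is scored independently).
#'
#' @param circuit A functional `circuit_parameters`.
#' @param channel Perturbed channel.
#' @param direction `"down"` or `"up"`.
#' @param cell Perturbed cell (default `"cell1"`).
#' @param n_steps Steps per half-axis (default 15).
#' @param phi_0 Unperturbed phase difference; computed if `NULL`.
#' @param grid A `synaptic_grid_spec` supplying durations, dt, transient.
#' @return List of class `stability_record`: `theta`, `phi_0`, `steps`
#'   (data frame with `fraction`, `phi`, `period`, `classification`,
#'   `silenced_cell`, `proximity`), plus ids.
#' @export
single_perturbation_stability <- function(circuit, channel,
                                          direction = c("down", "up"),
                                          cell = "cell1", n_steps = 15,
                                          phi_0 = NULL,
                                          grid = synaptic_grid_spec()) {
  direction <- match.arg(direction)
  fractions <- if (direction == "down") 1 - seq_len(n_steps) / n_steps
               else 1 + seq_len(n_steps) / n_steps
  if (is.null(phi_0)) phi_0 <- unperturbed_phase(circuit, grid)
  steps <- lapply(fractions, function(f) {
    pert <- scale_conductance(circuit, cell, channel, f)
    ev <- eval_perturbed(pert, grid$eval_duration, grid$dt, grid$transient)
    data.frame(fraction = f, phi = ev$phi, period = ev$period,
               classification = ev$classification,
               silenced_cell = ev$silenced_cell,
               proximity = proximity(ev$phi, phi_0, ev$functional_step),
               spikes_per_burst_1 = ev$spikes_per_burst[1],
               spikes_per_burst_2 = ev$spikes_per_burst[2],
               within_isi_1 = ev$within_isi[1],
               within_isi_2 = ev$within_isi[2])
  })
  steps <- do.call(rbind, steps)
  structure(list(circuit_id = circuit$circuit_id,
                 perturbation = paste(channel, direction, sep = "_"),
                 channel = channel, direction = direction, cell = cell,
                 phi_0 = phi_0, steps = steps,
                 theta = stability_value(steps$proximity)),
            class = "stability_record")
}

#' Unperturbed phase difference of a circuit
#'
#' @param circuit A `circuit_parameters`.
#' @param grid A `synaptic_grid_spec`.
#' @return Phase difference in \[0, 1), or `NA`.
#' @export
unperturbed_phase <- function(circuit, grid = synaptic_grid_spec()) {
  ev <- eval_perturbed(circuit, grid$eval_duration, grid$dt, grid$transient)
  ev$phi
}

#' Crash category of a full single-channel scan
#'
#' Combines the down and up records of one channel into the four response
#' categories: `all_functional` (both cells active at every step),
#' `perturbed_silenced`, `unperturbed_silenced`, or `either_silenced` (both
#' kinds occurred at different steps).
#'
#' @param record_down,record_up `stability_record`s for the two directions.
#' @param perturbed_cell Which cell carried the perturbation.
#' @return Character scalar.
#' @export
crash_category <- function(record_down, record_up,
                           perturbed_cell = "cell1") {
  sil <- c(record_down$steps$silenced_cell, record_up$steps$silenced_cell)
  other <- setdiff(c("cell1", "cell2"), perturbed_cell)
  pert_sil <- any(sil %in% c(perturbed_cell, "both"))
  unpert_sil <- any(sil %in% c(other, "both"))
  if (!pert_sil && !unpert_sil) "all_functional"
  else if (pert_sil && unpert_sil) "either_silenced"
  else if (pert_sil) "perturbed_silenced"
  else "unperturbed_silenced"
}

#' Stability of a circuit to double-conductance perturbations
#'
#' Simultaneously perturbs two channels of the same cell.  The scan covers
#' `n_directions` radial half-lines (equally spaced in angle, including the
#' four cardinals) in the `(fraction_A, fraction_B)` plane centred at (1, 1),
#' with `n_steps` magnitude steps per half-line reaching the \[0, 2\] x
#' \[0, 2\] box boundary: 40 x 15 = 600 perturbed circuits by default.  The
#' four cardinal directions coincide exactly with the four single
#' perturbations of the two channels.
#'
#' @param circuit A functional `circuit_parameters`.
#' @param channel_a,channel_b The two perturbed channels (A varies along the
#'   horizontal axis, B along the vertical).
#' @param cell Perturbed cell.
#' @param n_directions Number of radial directions (default 40).
#' @param n_steps Steps per direction (default 15).
#' @param phi_0 Unperturbed phase difference; computed if `NULL`.
#' @param grid A `synaptic_grid_spec`.
#' @return List of class `double_stability_scan`: `records` (one
#'   `stability_record` per direction with the direction angle attached),
#'   `theta` (vector over directions), `map` (long data frame `frac_a`,
#'   `frac_b`, `proximity`, `angle`), `phi_0`.
#' @export
double_perturbation_scan <- function(circuit, channel_a, channel_b,
                                     cell = "cell1", n_directions = 40,
                                     n_steps = 15, phi_0 = NULL,
                                     grid = synaptic_grid_spec()) {
  stopifnot(channel_a != channel_b)
  if (is.null(phi_0)) phi_0 <- unperturbed_phase(circuit, grid)
  angles <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  records <- vector("list", n_directions)
  map <- list()
  for (d in seq_along(angles)) {
    a <- angles[d]
    ca <- cos(a); sb <- sin(a)
    # snap cardinals exactly so they coincide with the single perturbations
    if (abs(ca) < 1e-12) ca <- 0
    if (abs(sb) < 1e-12) sb <- 0
    reach <- min(if (ca != 0) 1 / abs(ca) else Inf,
                 if (sb != 0) 1 / abs(sb) else Inf)
    steps <- lapply(seq_len(n_steps), function(i) {
      r <- reach * i / n_steps
      fa <- min(2, max(0, 1 + r * ca))
      fb <- min(2, max(0, 1 + r * sb))
      pert <- scale_conductance(circuit, cell, channel_a, fa)
      pert <- scale_conductance(pert, cell, channel_b, fb)
      ev <- eval_perturbed(pert, grid$eval_duration, grid$dt, grid$transient)
      data.frame(fraction_a = fa, fraction_b = fb, phi = ev$phi,
                 period = ev$period, classification = ev$classification,
                 silenced_cell = ev$silenced_cell,
                 proximity = proximity(ev$phi, phi_0, ev$functional_step))
    })
    steps <- do.call(rbind, steps)
    records[[d]] <- structure(
      list(circuit_id = circuit$circuit_id,
           perturbation = sprintf("(%s,%s)@%.3f", channel_a, channel_b, a),
           channel_a = channel_a, channel_b = channel_b, angle = a,
           cell = cell, phi_0 = phi_0, steps = steps,
           theta = stability_value(steps$proximity)),
      class = "stability_record")
    map[[d]] <- data.frame(angle = a, frac_a = steps$fraction_a,
                           frac_b = steps$fraction_b,
                           proximity = steps$proximity)
  }
  structure(list(records = records,
                 theta = vapply(records, `[[`, numeric(1), "theta"),
                 angles = angles, map = do.call(rbind, map), phi_0 = phi_0,
                 channel_a = channel_a, channel_b = channel_b),
            class = "double_stability_scan")
}

#' Spiking statistics at silencing transitions
#'
#' Scans stability records for step transitions where the circuit goes from
#' both-cells-active to one cell silenced, and compares the surviving cell's
#' spikes per burst and mean within-burst ISI at the silencing step against
#' the unperturbed circuit.  Returns the fraction of transitions with more
#' spikes per burst and the fraction with a shorter within-burst ISI.
#'
#' @param records List of `stability_record`s (each must carry the per-step
#'   `spikes_per_burst_*` and `within_isi_*` columns).
#' @param baseline Named list per circuit id with elements
#'   `spikes_per_burst` (length 2) and `within_isi` (length 2) of the
#'   unperturbed circuit.
#' @return List with `n_transitions`, `frac_more_spikes`,
#'   `frac_shorter_isi`.
#' @export
transition_statistics <- function(records, baseline) {
  more <- integer(0); shorter <- integer(0)
  for (rec in records) {
    st <- rec$steps
    base <- baseline[[rec$circuit_id]]
    if (is.null(base)) next
    for (i in seq_len(nrow(st))) {
      prev_active <- if (i == 1) "none" else st$silenced_cell[i - 1]
      if (st$silenced_cell[i] %in% c("cell1", "cell2") &&
            prev_active == "none") {
        surv <- if (st$silenced_cell[i] == "cell1") 2L else 1L
        sbp <- st[[paste0("spikes_per_burst_", surv)]][i]
        isi <- st[[paste0("within_isi_", surv)]][i]
        if (!is.na(sbp) && !is.na(base$spikes_per_burst[surv]))
          more <- c(more, sbp > base$spikes_per_burst[surv])
        if (!is.na(isi) && !is.na(base$within_isi[surv]))
          shorter <- c(shorter, isi < base$within_isi[surv])
      }
    }
  }
  list(n_transitions = length(more),
       frac_more_spikes = if (length(more)) mean(more) else NA_real_,
       frac_shorter_isi = if (length(shorter)) mean(shorter) else NA_real_)
}
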