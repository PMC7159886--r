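# Synthetic ground-truth generators, scaled pipeline presets, and
# serialization of populations, stability tables and traces.

#' Square-wave burster specification
#'
#' Describes an idealized bursting "cell" whose voltage is a square wave
#' with spike excursions: bursts of `spikes_per_burst` spikes at
#' `intra_burst_isi` spacing recur with the given period and phase offset.
#' Used as an analytic ground truth for the rhythm metrics.
#'
#' @param period Burst period, ms.
#' @param phase_offset Burst onset as a fraction of the period.
#' @param duty Fraction of the period the cell is active.
#' @param spikes_per_burst Spikes per burst (>= 1).
#' @param intra_burst_isi Within-burst ISI, ms.
#' @param overlap Extra active time appended to each active window, ms
#'   (forces co-activity between the two cells).
#' @return List of class `burster_spec`.
#' @export
burster_spec <- function(period = 400, phase_offset = 0, duty = 0.4,
                         spikes_per_burst = 5, intra_burst_isi = 20,
                         overlap = 0) {
  stopifnot(period > 0, duty > 0, duty < 1, spikes_per_burst >= 1,
            intra_burst_isi > 0, overlap >= 0)
  structure(as.list(environment()), class = "burster_spec")
}

#' Generate synthetic two-cell burster traces with known ground truth
#'
#' Builds piecewise-constant voltage traces (baseline -65 mV, active plateau
#' -40 mV, spikes to +10 mV lasting 1 ms) for two square-wave bursters, and
#' returns the traces together with the analytic spike times, bursts, active
#' windows, phase difference and period.
#'
#' @param spec1,spec2 `burster_spec`s for the two cells.
#' @param duration Trace duration, ms.
#' @param dt Sample interval, ms.
#' @return List with `trace` (a `simulation_trace`), `truth1`, `truth2`
#'   (each: `spike_times`, `bursts`, `active`), `phi`, `period`.
#' @export
make_burster_traces <- function(spec1, spec2, duration = 4000, dt = 0.5) {
  times <- seq(0, duration, by = dt)
  cell <- function(spec) {
    onsets <- seq(spec$phase_offset * spec$period, duration,
                  by = spec$period)
    onsets <- onsets[onsets + 1 <= duration]
    spikes <- as.vector(vapply(onsets, function(o)
      o + (seq_len(spec$spikes_per_burst) - 1) * spec$intra_burst_isi,
      numeric(spec$spikes_per_burst)))
    spikes <- sort(spikes[spikes + 1 <= duration])
    act_end <- pmin(onsets + spec$duty * spec$period + spec$overlap,
                    duration)
    V <- rep(-65, length(times))
    for (i in seq_along(onsets))
      V[times >= onsets[i] & times < act_end[i]] <- -40
    for (s in spikes) V[times >= s & times < s + 1] <- 10
    bursts <- data.frame(
      onset = vapply(onsets, function(o) min(spikes[spikes >= o - 1e-9]),
                     numeric(1)),
      offset = vapply(seq_along(onsets), function(i) {
        inb <- spikes[spikes >= onsets[i] - 1e-9 &
                        spikes < onsets[i] + spec$period - 1e-9]
        max(inb)
      }, numeric(1)))
    bursts$n_spikes <- as.integer(rep(spec$spikes_per_burst,
                                      nrow(bursts)))
    list(V = V, spike_times = spikes, bursts = bursts,
         active = cbind(onsets, act_end))
  }
  c1 <- cell(spec1); c2 <- cell(spec2)
  phi <- ((spec2$phase_offset - spec1$phase_offset) %% 1)
  trace <- structure(list(times = times, V1 = c1$V, V2 = c2$V,
                          blown = FALSE, dt = dt, duration = duration),
                     class = "simulation_trace")
  list(trace = trace,
       truth1 = c1[c("spike_times", "bursts", "active")],
       truth2 = c2[c("spike_times", "bursts", "active")],
       phi = phi, period = spec1$period)
}

#' Pipeline configuration presets
#'
#' Bundles every tunable of the pipeline at three scales.  The `full` preset
#' carries the full-scale protocol constants (750 neurons, 7690 circuits,
#' 15 perturbation steps per direction, batches of 32, 4.5 s evaluation and
#' 120 s validation runs, 0.025 uS synaptic grid); `desk` and `ci` are
#' reduced-scale presets for workstation and test use.
#'
#' @param preset `"ci"`, `"desk"` or `"full"`.
#' @return List of class `pipeline_config` with `n_neurons`,
#'   `target_circuits`, `n_steps`, `grid` (a `synaptic_grid_spec`),
#'   `ranges`, `x_min`, `phi_tol`, `period_range`, `cv_max`.
#' @export
pipeline_config <- function(preset = c("ci", "desk", "full")) {
  preset <- match.arg(preset)
  base <- list(ranges = conductance_ranges(), n_steps = 15, x_min = 0.95,
               phi_tol = 0.03, period_range = c(100, 800), cv_max = 0.1,
               preset = preset)
  scale <- switch(preset,
    ci = list(n_neurons = 10, target_circuits = 20,
              grid = synaptic_grid_spec(eval_duration = 2000,
                                        validation_duration = 20000)),
    desk = list(n_neurons = 60, target_circuits = 200,
                grid = synaptic_grid_spec()),
    full = list(n_neurons = 750, target_circuits = 7690,
                grid = synaptic_grid_spec()))
  structure(c(base, scale), class = "pipeline_config")
}

#' Reduced-scale end-to-end population with stability table
#'
#' Runs the full pipeline (neuron sampling, self-refining scans, selection,
#' validation, single-perturbation stability) at a reduced scale;
#' deterministic for a fixed seed.
#'
#' @param preset `"ci"` or `"desk"`.
#' @param seed Master seed.
#' @param n_neurons,target_circuits,channels Optional overrides of the
#'   preset (smaller values keep test runtimes short).
#' @return List with `population`, `stability` (matrix), `config`.
#' @export
mini_population <- function(preset = c("ci", "desk"), seed = 1,
                            n_neurons = NULL, target_circuits = NULL,
                            channels = GATED_CHANNELS) {
  cfg <- pipeline_config(match.arg(preset))
  if (!is.null(n_neurons)) cfg$n_neurons <- n_neurons
  if (!is.null(target_circuits)) cfg$target_circuits <- target_circuits
  pop <- build_population(cfg$n_neurons, cfg$target_circuits,
                          grid = cfg$grid, ranges = cfg$ranges, seed = seed)
  tab <- compute_stability_table(pop, grid = cfg$grid, channels = channels)
  list(population = pop, stability = tab, config = cfg)
}

# serialization ---------------------------------------------------------------

circuit_to_record <- function(circ) {
  list(circuit_id = circ$circuit_id,
       gbar_cell1 = as.list(circ$cell1$gbar),
       gbar_cell2 = as.list(circ$cell2$gbar),
       g_leak = circ$cell1$g_leak,
       g12 = circ$synapse$g12, g21 = circ$synapse$g21,
       provenance = circ$provenance)
}

record_to_circuit <- function(rec) {
  circuit_parameters(
    neuron_parameters(unlist(rec$gbar_cell1), g_leak = rec$g_leak,
                      neuron_id = rec$provenance$neuron1 %||% NA_character_),
    neuron_parameters(unlist(rec$gbar_cell2), g_leak = rec$g_leak,
                      neuron_id = rec$provenance$neuron2 %||% NA_character_),
    synapse_parameters(rec$g12, rec$g21),
    circuit_id = rec$circuit_id,
    provenance = rec$provenance)
}

#' Write / read a circuit population (JSON)
#'
#' Lossless round-trip of every circuit parameter (full double precision).
#'
#' @param population An `hcc_population` or list of circuits.
#' @param path File path.
#' @return `read_population()` returns a list of `circuit_parameters`.
#' @export
write_population <- function(population, path) {
  circuits <- if (inherits(population, "hcc_population"))
    population$circuits else population
  jsonlite::write_json(lapply(circuits, circuit_to_record), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, record_to_circuit)
}

#' Write / read a stability table (CSV)
#'
#' @param table Stability matrix (rownames = circuit ids).
#' @param path File path.
#' @return `read_stability_table()` returns the matrix.
#' @export
write_stability_table <- function(table, path) {
  df <- data.frame(circuit_id = rownames(table),
                   format(as.data.frame(unclass(table)), digits = 17,
                          scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stability_table
#' @export
read_stability_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$circuit_id
  m
}

#' Export burst trains as CSV
#'
#' One row per burst, columns `cell`, `onset_ms`, `offset_ms`, `n_spikes`.
#'
#' @param train1,train2 `burst_train` objects (cell 1 and cell 2), either
#'   may be `NULL` (silent cell).
#' @param path File path.
#' @export
write_burst_trains <- function(train1, train2, path) {
  rows <- list()
  for (cell in 1:2) {
    trn <- if (cell == 1) train1 else train2
    if (is.null(trn) || nrow(trn$bursts) == 0) next
    rows[[cell]] <- data.frame(cell = paste0("cell", cell),
                               onset_ms = trn$bursts$onset,
                               offset_ms = trn$bursts$offset,
                               n_spikes = trn$bursts$n_spikes)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(cell = character(0), onset_ms = numeric(0),
                        offset_ms = numeric(0), n_spikes = integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation trace (CSV)
#'
#' Plain-text export with columns `time_ms`, `V1_mV`, `V2_mV`; metadata
#' (dt, duration, circuit id) stored in a JSON sidecar header line prefixed
#' with `#`.
#'
#' @param trace A `simulation_trace`.
#' @param path File path.
#' @return `read_trace()` returns a `simulation_trace`.
#' @export
write_trace <- function(trace, path) {
  meta <- jsonlite::toJSON(list(dt = trace$dt, duration = trace$duration,
                                circuit_id = trace$circuit_id %||% NA),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", meta), con)
  utils::write.csv(data.frame(time_ms = trace$times, V1_mV = trace$V1,
                              V2_mV = trace$V2), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) stop("malformed trace file: ", path)
  meta <- jsonlite::fromJSON(sub("^#", "", header))
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(times = df$time_ms, V1 = df$V1_mV, V2 = df$V2_mV,
                 blown = FALSE, dt = meta$dt, duration = meta$duration,
                 circuit_id = meta$circuit_id),
            class = "simulation_trace")
}
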