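#' Single-neuron parameter set
#'
#' Maximal conductances of the seven gated channels plus the fixed leak and
#' reversal/calcium constants of one model cell.
#'
#' @param gbar Named numeric vector of maximal conductances (uS) for
#'   `Na, CaT, CaS, A, KCa, Kd, H` (any order; all seven required).
#' @param g_leak Leak conductance, uS.
#' @param neuron_id Optional identifier.
#' @return Object of class `neuron_parameters`.
#' @export
neuron_parameters <- function(gbar, g_leak = 0.01, neuron_id = NA_character_) {
  stopifnot(is.numeric(gbar), all(GATED_CHANNELS %in% names(gbar)),
            all(gbar >= 0), g_leak >= 0)
  structure(list(gbar = gbar[GATED_CHANNELS], g_leak = g_leak,
                 neuron_id = neuron_id),
            class = "neuron_parameters")
}

#' Synapse parameter set
#'
#' Directed graded-synapse conductances; `g12` is the synapse onto cell 1
#' (driven by cell 2), `g21` the synapse onto cell 2 (driven by cell 1).
#' Shared synapse constants (midpoint, slope, time constant, reversal) live in
#' [model_constants()].
#'
#' @param g12,g21 Synaptic conductances, uS (non-negative).
#' @return Object of class `synapse_parameters`.
#' @export
synapse_parameters <- function(g12, g21) {
  stopifnot(g12 >= 0, g21 >= 0)
  structure(list(g12 = g12, g21 = g21), class = "synapse_parameters")
}

#' Two-cell circuit parameter set
#'
#' @param cell1,cell2 `neuron_parameters` objects.  Cell 1 is by convention
#'   the perturbed cell and the phase reference.
#' @param synapse A `synapse_parameters` object.
#' @param circuit_id Opaque identifier.
#' @param provenance Optional list (neuron ids, seeds) recording origin.
#' @return Object of class `circuit_parameters`.
#' @export
circuit_parameters <- function(cell1, cell2, synapse,
                               circuit_id = NA_character_,
                               provenance = list()) {
  stopifnot(inherits(cell1, "neuron_parameters"),
            inherits(cell2, "neuron_parameters"),
            inherits(synapse, "synapse_parameters"))
  structure(list(cell1 = cell1, cell2 = cell2, synapse = synapse,
                 circuit_id = circuit_id, provenance = provenance),
            class = "circuit_parameters")
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("Half-center circuit", if (!is.na(x$circuit_id)) x$circuit_id else "",
      "\n  gbar cell1:", paste(sprintf("%s=%.3g", names(x$cell1$gbar),
                                       x$cell1$gbar), collapse = " "),
      "\n  gbar cell2:", paste(sprintf("%s=%.3g", names(x$cell2$gbar),
                                       x$cell2$gbar), collapse = " "),
      sprintf("\n  synapse: g12=%.4g g21=%.4g\n",
              x$synapse$g12, x$synapse$g21))
  invisible(x)
}

# state vector layout helpers ------------------------------------------------
INACTIVATING <- c("Na", "CaT", "CaS", "A")

state_names <- function() {
  per_cell <- c("V", paste0("m_", GATED_CHANNELS), paste0("h_", INACTIVATING),
                "Ca")
  c(paste0(per_cell, "1"), paste0(per_cell, "2"), "s12", "s21")
}

#' Default initial state of a circuit
#'
#' Both cells start near rest with gating variables at their steady state for
#' the initial voltage, calcium at the buffer baseline and synapses off.  A
#' small voltage offset on cell 2 breaks the exchange symmetry so that
#' antiphase alternation emerges deterministically.
#'
#' @param circuit A `circuit_parameters` object (unused except for interface
#'   symmetry; the default state does not depend on conductances).
#' @param V1,V2 Initial membrane voltages, mV.
#' @param constants Model constants.
#' @return Named numeric state vector (length 28).
#' @export
initial_state <- function(circuit = NULL, V1 = -65, V2 = -64,
                          constants = model_constants()) {
  cell_state <- function(V) {
    m <- vapply(GATED_CHANNELS, function(ch) {
      k <- channel_kinetics(ch)
      if (ch == "KCa") k$m_inf(V, constants$Ca_base) else k$m_inf(V)
    }, numeric(1))
    h <- vapply(INACTIVATING, function(ch) channel_kinetics(ch)$h_inf(V),
                numeric(1))
    c(V, m, h, constants$Ca_base)
  }
  st <- c(cell_state(V1), cell_state(V2), 0, 0)
  names(st) <- state_names()
  st
}

#' Full state derivative of the two-cell circuit
#'
#' Reference (pure R) implementation of the right-hand side:
#' `c dV/dt = -sum(I_channel) - I_leak - I_syn` per cell, first-order
#' relaxation for every gating variable and synaptic activation, and the
#' linear calcium buffer.  The C++ integrator advances the same vector field;
#' this function exists for testing (finite-difference consistency, symmetry)
#' and documentation.
#'
#' @param circuit A `circuit_parameters` object.
#' @param state Named state vector as produced by [initial_state()].
#' @param constants Model constants.
#' @return Named vector `d(state)/dt`.
#' @export
circuit_derivatives <- function(circuit, state,
                                constants = model_constants()) {
  if (!all(is.finite(state))) stop("non-finite state")
  st <- state
  d <- numeric(length(st))
  names(d) <- names(st)
  n_cell <- 13
  for (cell in 1:2) {
    off <- (cell - 1) * n_cell
    V <- unname(st[off + 1])
    Ca <- unname(st[off + 13])
    E_Ca <- calcium_reversal(Ca, constants)
    E_rev <- c(Na = constants$E_Na, CaT = E_Ca, CaS = E_Ca,
               A = constants$E_K, KCa = constants$E_K, Kd = constants$E_K,
               H = constants$E_H)
    gbar <- if (cell == 1) circuit$cell1$gbar else circuit$cell2$gbar
    g_leak <- if (cell == 1) circuit$cell1$g_leak else circuit$cell2$g_leak
    g_syn <- if (cell == 1) circuit$synapse$g12 else circuit$synapse$g21
    s <- unname(if (cell == 1) st["s12"] else st["s21"])
    I_total <- g_leak * (V - constants$E_leak) +
      g_syn * s * (V - constants$E_syn)
    I_Ca <- 0
    for (i in seq_along(GATED_CHANNELS)) {
      ch <- GATED_CHANNELS[i]
      k <- channel_kinetics(ch)
      m <- st[off + 1 + i]
      h <- if (ch %in% INACTIVATING) st[off + 8 + match(ch, INACTIVATING)] else 1
      I <- channel_current(gbar[ch], m, h, k$p, k$q, V, E_rev[ch])
      I_total <- I_total + I
      if (ch %in% c("CaT", "CaS")) I_Ca <- I_Ca + I
      # gating dynamics
      mi <- if (ch == "KCa") k$m_inf(V, Ca) else k$m_inf(V)
      d[off + 1 + i] <- (mi - m) / k$tau_m(V)
      if (ch %in% INACTIVATING) {
        j <- off + 8 + match(ch, INACTIVATING)
        d[j] <- (k$h_inf(V) - st[j]) / k$tau_h(V)
      }
    }
    d[off + 1] <- -I_total / constants$c_m
    d[off + 13] <- (-constants$Ca_influx * I_Ca - Ca + constants$Ca_base) /
      constants$tau_Ca
  }
  d["s12"] <- (synaptic_activation_target(st["V2"], constants) - st["s12"]) /
    constants$tau_syn
  d["s21"] <- (synaptic_activation_target(st["V1"], constants) - st["s21"]) /
    constants$tau_syn
  d
}

#' Simulate a half-center circuit
#'
#' Deterministic fixed-step integration (exponential Euler on every state
#' variable) of the two-cell circuit.
#'
#' @param circuit A `circuit_parameters` object.
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms (default 0.025).
#' @param init Initial state vector; default [initial_state()].
#' @param record_every Store every k-th step (thinning of the output grid;
#'   integration always proceeds at `dt`).
#' @param use_tables Use voltage-indexed lookup tables (1/50 mV resolution,
#'   linear interpolation) for the gating functions; ~5-10x faster, accurate
#'   to ~1e-9 in the gating targets.  Set `FALSE` for the direct evaluation
#'   used by cross-check tests.
#' @param record_state Also store the full 28-dimensional state at recorded
#'   times (matrix `states`).
#' @param constants Model constants.
#' @return Object of class `simulation_trace`: list with `times`, `V1`, `V2`
#'   (mV), `dt` (the recording step), `duration`, `blown` (numerical failure
#'   flag), `final_state`, gating-range monitors `gate_min`/`gate_max`/
#'   `ca_min`, and optionally `states`.
#' @export
integrate_circuit <- function(circuit, duration, dt = 0.025, init = NULL,
                              record_every = 1L, use_tables = TRUE,
                              record_state = FALSE,
                              constants = model_constants()) {
  stopifnot(duration > 0, dt > 0)
  nsteps <- duration / dt
  if (abs(nsteps - round(nsteps)) > 1e-6)
    stop("duration must be an integer multiple of dt")
  if (is.null(init)) init <- initial_state(circuit, constants = constants)
  cv <- unlist(constants[c("E_leak", "E_Na", "E_K", "E_H", "E_syn", "V_half",
                           "V_slope", "tau_syn", "Ca_out", "tau_Ca",
                           "Ca_base", "Ca_influx", "KCa_halfsat",
                           "nernst_RT2F", "c_m")])
  res <- simulate_hcc_cpp(unname(circuit$cell1$gbar),
                          unname(circuit$cell2$gbar),
                          circuit$cell1$g_leak, circuit$cell2$g_leak,
                          circuit$synapse$g12, circuit$synapse$g21,
                          cv, duration, dt, unname(init),
                          as.integer(record_every), use_tables, record_state)
  names(res$final_state) <- state_names()
  structure(c(res, list(dt = dt * record_every, duration = duration,
                        circuit_id = circuit$circuit_id)),
            class = "simulation_trace")
}

#' Advance a circuit state by one integrator step
#'
#' Exposes the one-step map of the exponential-Euler scheme (used by
#' consistency tests against [circuit_derivatives()]).
#'
#' @param circuit A `circuit_parameters`.
#' @param dt Step size, ms.
#' @param state Named state vector.
#' @param constants Model constants.
#' @return The state after one step.
#' @export
hcc_step <- function(circuit, dt, state, constants = model_constants()) {
  cv <- unlist(constants[c("E_leak", "E_Na", "E_K", "E_H", "E_syn", "V_half",
                           "V_slope", "tau_syn", "Ca_out", "tau_Ca",
                           "Ca_base", "Ca_influx", "KCa_halfsat",
                           "nernst_RT2F", "c_m")])
  out <- hcc_step_cpp(unname(circuit$cell1$gbar), unname(circuit$cell2$gbar),
                      circuit$cell1$g_leak, circuit$cell2$g_leak,
                      circuit$synapse$g12, circuit$synapse$g21,
                      cv, dt, unname(state))
  names(out) <- state_names()
  out
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("simulation_trace: %d samples, dt=%g ms, duration=%g ms%s\n",
              length(x$times), x$dt, x$duration,
              if (isTRUE(x$blown)) " [numerical failure]" else ""))
  invisible(x)
}
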