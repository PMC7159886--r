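#' @useDynLib hccstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gated channel identifiers, in canonical order.  "leak" is handled separately
# (m = h = 1, no kinetics).
GATED_CHANNELS <- c("Na", "CaT", "CaS", "A", "KCa", "Kd", "H")

# Physical / model constants shared across the package.  Units are the model's
# nominal system: mV, ms, uS, nF (c = 1), nA, uM for intracellular Ca.
#' Fixed model constants
#'
#' Returns the constants of the two-cell model that are never sampled:
#' reversal potentials, capacitance, leak conductance, calcium buffer
#' constants and the Nernst thermal voltage.
#'
#' @param temperature_K Temperature used for the calcium Nernst potential, in
#'   Kelvin. Default 283 K (10 degrees C, a crustacean-relevant temperature).
#' @return Named list of constants.
#' @export
model_constants <- function(temperature_K = 283) {
  R_gas <- 8.31446
  Faraday <- 96485.33
  list(
    c_m = 1,              # capacitance (nF, nominal)
    g_leak = 0.01,        # uS
    E_leak = -50, E_Na = 50, E_K = -80, E_H = -20,   # mV
    E_syn = -78,          # mV
    V_half = 45, V_slope = -2, tau_syn = 100,        # graded synapse
    Ca_out = 3000,        # uM (3 mM extracellular)
    tau_Ca = 200,         # ms
    Ca_base = 0.05,       # uM, buffer baseline
    Ca_influx = 0.94,     # uM/nA, influx coefficient on -(I_CaT + I_CaS)
    KCa_halfsat = 3,      # uM, Ca half-saturation of the KCa activation
    temperature_K = temperature_K,
    nernst_RT2F = R_gas * temperature_K / (2 * Faraday) * 1000  # mV
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Functional forms of the voltage dependence, one entry per gated channel.
# x_inf are sigmoids 1/(1+exp((V - Vh)/k)); time constants are the
# depressed-sigmoid and double-exponential forms of the adopted LP-neuron
# model.  KCa activation carries an extra Ca/(Ca + 3 uM) factor.
.kinetics_table <- list(
  Na = list(
    p = 3L, q = 1L,
    m_inf = function(V) 1 / (1 + exp((V + 25.5) / -5.29)),
    tau_m = function(V) 1.32 - 1.26 / (1 + exp((V + 120) / -25)),
    h_inf = function(V) 1 / (1 + exp((V + 48.9) / 5.18)),
    tau_h = function(V) (0.67 / (1 + exp((V + 62.9) / -10))) *
      (1.5 + 1 / (1 + exp((V + 34.9) / 3.6)))
  ),
  CaT = list(
    p = 3L, q = 1L,
    m_inf = function(V) 1 / (1 + exp((V + 27.1) / -7.2)),
    tau_m = function(V) 21.7 - 21.3 / (1 + exp((V + 68.1) / -20.5)),
    h_inf = function(V) 1 / (1 + exp((V + 32.1) / 5.5)),
    tau_h = function(V) 105 - 89.8 / (1 + exp((V + 55) / -16.9))
  ),
  CaS = list(
    p = 3L, q = 1L,
    m_inf = function(V) 1 / (1 + exp((V + 33) / -8.1)),
    tau_m = function(V) 1.4 + 7 / (exp((V + 27) / 10) + exp((V + 70) / -13)),
    h_inf = function(V) 1 / (1 + exp((V + 60) / 6.2)),
    tau_h = function(V) 60 + 150 / (exp((V + 55) / 9) + exp((V + 65) / -16))
  ),
  A = list(
    p = 3L, q = 1L,
    m_inf = function(V) 1 / (1 + exp((V + 27.2) / -8.7)),
    tau_m = function(V) 11.6 - 10.4 / (1 + exp((V + 32.9) / -15.2)),
    h_inf = function(V) 1 / (1 + exp((V + 56.9) / 4.9)),
    tau_h = function(V) 38.6 - 29.2 / (1 + exp((V + 38.9) / -26.5))
  ),
  KCa = list(
    p = 4L, q = 0L,
    # Ca in uM; half-saturation 3 uM
    m_inf = function(V, Ca) (Ca / (Ca + 3)) / (1 + exp((V + 28.3) / -12.6)),
    tau_m = function(V) 90.3 - 75.1 / (1 + exp((V + 46) / -22.7))
  ),
  Kd = list(
    p = 4L, q = 0L,
    m_inf = function(V) 1 / (1 + exp((V + 12.3) / -11.8)),
    tau_m = function(V) 7.2 - 6.4 / (1 + exp((V + 28.3) / -19.2))
  ),
  H = list(
    p = 1L, q = 0L,
    m_inf = function(V) 1 / (1 + exp((V + 70) / 6)),
    tau_m = function(V) 272 + 1499 / (1 + exp((V + 42.2) / -8.73))
  )
)

#' Channel kinetics descriptor
#'
#' Builds the kinetics object for one gated channel (or the leak): activation
#' exponent `p`, inactivation exponent `q`, and the steady-state and
#' time-constant functions of voltage (and intracellular calcium for KCa).
#'
#' @param channel One of `"Na"`, `"CaT"`, `"CaS"`, `"A"`, `"KCa"`, `"Kd"`,
#'   `"H"`, `"leak"`.
#' @return An object of class `channel_kinetics` with fields `channel`, `p`,
#'   `q`, `m_inf`, `tau_m` and, for inactivating channels, `h_inf`, `tau_h`.
#' @examples
#' k <- channel_kinetics("Na")
#' evaluate_kinetics(k, V = -55)
#' @export
channel_kinetics <- function(channel) {
  channel <- match.arg(channel, c(GATED_CHANNELS, "leak"))
  if (channel == "leak") {
    out <- list(channel = "leak", p = 0L, q = 0L,
                m_inf = function(V) rep(1, length(V)),
                tau_m = NULL, h_inf = NULL, tau_h = NULL)
  } else {
    out <- c(list(channel = channel), .kinetics_table[[channel]])
    if (is.null(out$h_inf)) out[c("h_inf", "tau_h")] <- list(NULL, NULL)
  }
  structure(out, class = "channel_kinetics")
}

#' Evaluate channel kinetics at a voltage
#'
#' Evaluates steady-state activation/inactivation and their time constants at
#' membrane voltage `V`.  The calcium-dependent potassium channel (KCa)
#' additionally requires the intracellular calcium concentration.
#'
#' @param kinetics A `channel_kinetics` object (or a channel name).
#' @param V Membrane voltage, mV.
#' @param Ca Intracellular calcium, uM; required iff the channel is KCa.
#' @return List with `m_inf`, `tau_m` and (inactivating channels only)
#'   `h_inf`, `tau_h`.  Time constants are in ms.
#' @export
evaluate_kinetics <- function(kinetics, V, Ca = NULL) {
  if (is.character(kinetics)) kinetics <- channel_kinetics(kinetics)
  stopifnot(inherits(kinetics, "channel_kinetics"), all(is.finite(V)))
  if (kinetics$channel == "KCa") {
    if (is.null(Ca)) stop("KCa kinetics require the intracellular Ca concentration")
    m <- kinetics$m_inf(V, Ca)
  } else {
    if (!is.null(Ca) && kinetics$channel != "KCa")
      stop("Ca must only be supplied for the KCa channel")
    m <- kinetics$m_inf(V)
  }
  out <- list(m_inf = m,
              tau_m = if (!is.null(kinetics$tau_m)) kinetics$tau_m(V) else NULL)
  if (kinetics$q > 0L) {
    out$h_inf <- kinetics$h_inf(V)
    out$tau_h <- kinetics$tau_h(V)
  }
  out
}

#' Ionic current through one channel
#'
#' Ohmic current `gbar * m^p * h^q * (V - E)`; positive current is outward
#' (hyperpolarizing when `E < V`).
#'
#' @param gbar Maximal conductance, uS.
#' @param m,h Activation and inactivation gating variables in \[0, 1\].
#' @param p,q Integer gating exponents (`q = 0` for non-inactivating channels).
#' @param V Membrane voltage, mV.
#' @param E Reversal potential, mV.
#' @return Current in nA.
#' @export
channel_current <- function(gbar, m, h, p, q, V, E) {
  stopifnot(gbar >= 0)
  gbar * m^p * (if (q > 0) h^q else 1) * (V - E)
}

#' Calcium reversal potential (Nernst)
#'
#' `E_Ca = (RT/2F) * log(Ca_out / Ca_in)` for the divalent calcium ion.
#'
#' @param Ca_in Intracellular calcium, uM (> 0).
#' @param constants Model constants, see [model_constants()].
#' @return Reversal potential in mV.
#' @export
calcium_reversal <- function(Ca_in, constants = model_constants()) {
  if (any(Ca_in <= 0)) stop("Ca_in must be positive")
  constants$nernst_RT2F * log(constants$Ca_out / Ca_in)
}

#' Time derivative of intracellular calcium
#'
#' Linear buffer with time constant `tau_Ca` plus influx proportional to the
#' total calcium current:
#' `dCa/dt = (-f * (I_CaT + I_CaS) - Ca + Ca_base) / tau_Ca`.
#' Inward (negative) calcium current raises Ca.
#'
#' @param Ca Intracellular calcium, uM.
#' @param I_CaT,I_CaS Calcium currents, nA.
#' @param constants Model constants.
#' @return dCa/dt in uM/ms.
#' @export
calcium_derivative <- function(Ca, I_CaT, I_CaS, constants = model_constants()) {
  (-constants$Ca_influx * (I_CaT + I_CaS) - Ca + constants$Ca_base) /
    constants$tau_Ca
}

#' Steady-state graded synaptic activation
#'
#' Sigmoid of the presynaptic voltage,
#' `s_inf = 1 / (1 + exp((V_half + V_pre) / V_slope))` with `V_half = 45` mV
#' and `V_slope = -2` mV: midpoint at `V_pre = -45` mV, increasing with
#' presynaptic depolarization.  The activation `s` relaxes towards `s_inf`
#' with time constant `tau_syn = 100` ms.
#'
#' @param V_pre Presynaptic membrane voltage, mV.
#' @param constants Model constants.
#' @return `s_inf` in \[0, 1\].
#' @export
synaptic_activation_target <- function(V_pre, constants = model_constants()) {
  1 / (1 + exp((constants$V_half + V_pre) / constants$V_slope))
}
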