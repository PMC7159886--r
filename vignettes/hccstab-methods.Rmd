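---
title: "Quantifying half-center circuit stability to conductance perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying half-center circuit stability to conductance perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccstab)
```

## The scientific problem

Rhythmic circuits built from neurons with widely different ion-channel
expression can nonetheless produce nearly identical output — the hallmark of
*degeneracy*. `hccstab` studies the smallest such circuit, the half-center
circuit (HCC): two conductance-based neurons coupled by reciprocal graded
inhibition, producing antiphase bursting like the rhythm generators of the
leech heartbeat or the crustacean stomatogastric ganglion. The central
question the package addresses is: **how robust is a degenerate circuit's
rhythm when one (or two) of its intrinsic maximal conductances is scaled
away from its original value, and which conductance combinations predict
that robustness?**

## The neuron and circuit model

Each cell is a single-compartment Hodgkin–Huxley style model with seven
gated currents — fast sodium (Na), fast and slow calcium (CaT, CaS),
transient potassium (A), calcium-dependent potassium (KCa), delayed
rectifier (Kd) and a hyperpolarization-activated inward current (H) — plus
an ohmic leak:

$$c\,\frac{dV}{dt} \;=\; -\sum_i \bar g_i\, m_i^{p_i} h_i^{q_i} (V - E_i)
\;-\; g_\mathrm{leak}(V - E_\mathrm{leak}) \;-\; I_\mathrm{syn},$$

with first-order gating kinetics
$\dot x = (x_\infty(V) - x)/\tau_x(V)$. The gating functions are the
classic lateral-pyloric-neuron forms from the Liu/Marder model family; the
KCa activation additionally carries a calcium factor
$[\mathrm{Ca}]/([\mathrm{Ca}] + 3\,\mu M)$. At the spike-threshold voltage
of $-55$ mV the transcribed time constants are (ms):

```{r tau-table}
taus <- sapply(c("Na", "CaT", "CaS", "A", "KCa", "Kd", "H"), function(ch) {
  ev <- evaluate_kinetics(channel_kinetics(ch), -55,
                          Ca = if (ch == "KCa") 1 else NULL)
  c(tau_m = ev$tau_m, tau_h = if (!is.null(ev$tau_h)) ev$tau_h else NA)
})
round(taus, 2)
```

Calcium follows a linear buffer,
$\tau_{Ca}\,d[\mathrm{Ca}]/dt = -f\,(I_{CaT} + I_{CaS}) - [\mathrm{Ca}] +
[\mathrm{Ca}]_0$ with $\tau_{Ca} = 200$ ms, and the calcium reversal
potential is recomputed every step from the Nernst equation with 3 mM
extracellular calcium. The H-current kinetics use the original
single-exponential-sigmoid form whose activation time constant at $-55$ mV
is 553.09 ms; the faster variant used by some later model generations
(≈597 ms at the same voltage) is inconsistent with the tabulated constants
and was rejected.

The graded synapse drives each cell with
$I_\mathrm{syn} = \bar g_\mathrm{syn}\, s\,(V - E_\mathrm{syn})$,
$E_\mathrm{syn} = -78$ mV, where the activation relaxes with
$\tau_\mathrm{syn} = 100$ ms towards
$s_\infty(V_\mathrm{pre}) = 1/(1 + \exp((V_\mathrm{half} +
V_\mathrm{pre})/V_\mathrm{slope}))$, $V_\mathrm{half} = 45$ mV,
$V_\mathrm{slope} = -2$ mV. Note the placement of $V_\mathrm{half}$:
with these printed constants the sigmoid midpoint sits at
$V_\mathrm{pre} = -45$ mV and depolarization activates the synapse, which
is the convention of the graded-inhibition literature; a naive reading
with a midpoint at $+45$ mV would make the synapse permanently silent.

### Units, and constants the sources leave open

Conductances are quoted in µS with capacitance $c = 1$ and voltages in mV;
we treat this as a nominal, internally consistent unit system (µS · mV =
nA, nA/nF = mV/ms) without asserting absolute physical units. Three
calcium constants are not printed anywhere in the adopting sources; we fix
them once, from the original Liu-model formulation, as the package's
stated world: influx coefficient $f = 0.94\ \mu M/nA$, buffer baseline
$[\mathrm{Ca}]_0 = 0.05\ \mu M$, KCa half-saturation $3\ \mu M$
(intracellular calcium is handled in µM). The Nernst thermal voltage uses
$T = 283$ K (10 °C, a crustacean-relevant temperature), exposed as an
argument of `model_constants()`.

## Numerical integration

All state variables — voltage, gating, calcium, synaptic activation — are
advanced by **exponential Euler** with a fixed step of `dt = 0.025` ms.
Every membrane current is ohmic in $V$ at frozen gating, so the voltage
equation is linear within a step; exponential Euler is therefore
unconditionally stable, which matters because $g_\mathrm{tot}/c$
transiently reaches $\sim 10^3/\mathrm{ms}$ during the sodium upstroke,
far beyond the stability limit of forward Euler at this step size. We
deliberately use this scheme for $V$ as well as for the gating variables
(not a forward-Euler/RK4 hybrid): it is exact for the leak-only membrane,
first-order convergent on the full model (verified by a dt-refinement
test), and cannot blow up. The gating functions are optionally tabulated
on a 1/50 mV voltage grid with linear interpolation (≈5–10× faster,
differences below 0.05 mV over hundreds of ms; `use_tables = FALSE`
recovers direct evaluation and the test suite cross-checks the two paths).

Initial conditions: both cells at $-65$ mV with a $+1$ mV offset on cell 2
to break the exchange symmetry (the model is deterministic; perfectly
symmetric initial conditions of identical cells would never desynchronize),
gating at steady state for the initial voltage, calcium at the buffer
baseline, synapses off. The first 1000 ms of every run are excluded from
all metrics as a settling transient.

## Rhythm metrics and the functionality criteria

Spikes are upward crossings of $-30$ mV. Bursts are groups of spikes whose
interspike intervals (ISIs) fall below a data-derived threshold: one half
of the sum of the 90th ISI percentile (nearest-rank) and the minimum ISI.
If that threshold lands within 10 ms of the ISI extremes the train has no
burst structure and the cell is treated as tonically spiking
(single-spike bursts). In a coupled circuit, consecutive bursts of one
cell with no spike of the other cell between them are merged into one
burst.

A circuit is **functional** when

1. the two cells fire in alternation — burst-exclusion metric
   $x_\mathrm{network} \ge 0.95$, where
   $x = (O_\mathrm{random} - O_\mathrm{network}) / (O_\mathrm{random} -
   O_\mathrm{min})$ compares the measured co-active time against the
   chance overlap $t_1 t_2 / T$ and the minimum possible overlap
   $\max(0, t_1 + t_2 - T)$ (1 = perfect alternation, 0 = chance);
2. the phase difference $\varphi$ (burst-onset delay of cell 2 after
   cell 1, as a fraction of the period, averaged per cycle and wrapped to
   $[0,1)$) is $0.5 \pm 0.03$;
3. the period lies in $[100, 800]$ ms; and
4. both cells fire *regularly*, which we quantify — the sources leave it
   unquantified — as a coefficient of variation of inter-onset intervals
   below 0.1.

The thresholds $x_\mathrm{min} = 0.95$ and the CV bound are configurable;
the defaults are the package's documented reading of "close to 1" and
"fire regularly". A cell with no post-transient spike makes the circuit
`one_silent`.

## Population generation

Single neurons are drawn with uniformly random maximal conductances
(µS): Na [800, 1200], CaT [0, 6], CaS [0, 12], A [20, 130], KCa [20, 140],
Kd [90, 120], H [0, 2]. Pairs of neurons are coupled through synapse
candidates from a 40 × 40 grid over (0, 1] µS at 0.025 µS resolution
(1600 candidate connections; the zero point is excluded since a missing
synapse cannot support reciprocal inhibition), each candidate jittered by
a discrete offset in [−0.0125, 0.0125] µS (0.0025 µS resolution, redrawn
per candidate).

The scan is **self-refining Monte Carlo**: candidates are evaluated in a
random order in batches of 32 (4.5 s per evaluation at full scale);
whenever a candidate silences cell 2 at $(\bar g_{12}^*, \bar g_{21}^*)$,
all unevaluated candidates with $\bar g_{21} > \bar g_{21}^*$ *and*
$\bar g_{12} \le \bar g_{12}^*$ are pruned (stronger inhibition onto the
silenced cell with no stronger defence keeps it silent), with the mirror
rule for cell 1. The pruning is an empirical monotonicity heuristic, so
the suite checks it statistically: force-evaluated pruned points are
non-functional in ≥ 95% of sampled cases. The scan stops after a complete
batch once at least three functional circuits are found; one of them is
chosen uniformly at random and must stay functional over a 120 s
validation run. We keep the candidate order as one global random
permutation filtered to surviving candidates, which is distributionally
identical to re-permuting the un-pruned set each batch.

At full scale this protocol is cluster-sized (750 neurons, 281,625 pairs,
7690 circuits). The `ci` preset (10 neurons, 2 s evaluations, 20 s
validation) and `desk` preset (60 neurons, full durations) scale it to
test and workstation budgets. In our reduced-scale runs roughly a quarter
to a half of random pairs yield a functional circuit — consistent with the
full-scale anchor of ≈ 49% only within the wide binomial tolerance that a
few dozen pairs allow, and sensitive to the regularity criterion above,
which the sources do not pin down.

## The stability value θ

For a perturbation of channel $X$ in cell 1 we rescale $\bar g_X$ in 15
equally spaced steps per half-axis — down to 0%, or up to 200% — simulate
every step independently (no early termination: circuits may in principle
recover at larger perturbations), and compare each resulting phase
difference $\varphi_i$ with the unperturbed $\varphi_0$ through a
*proximity* score: 0 if a cell is silent or no measurable alternating
rhythm remains, otherwise $\max(0,\, 1 - d(\varphi_i, \varphi_0)/
\varphi_0)$ with $d$ the wrapped circular distance. The exact printed
functional form of the proximity is not recoverable from our sources; this
fallback satisfies the two printed endpoint conditions (1 when the phase
is unchanged, 0 for a dysfunctional circuit) and decreases linearly in
phase distance. The **stability value** $\theta$ is the mean proximity
over the 15 steps, one value per direction ($\theta_{X\downarrow}$,
$\theta_{X\uparrow}$), so $\theta \in [0,1]$ with 1 = unaffected and 0 =
dysfunctional at every step.

Double perturbations scale two channels of the same cell simultaneously
along 40 equally spaced radial directions in the
$(\mathrm{frac}_A, \mathrm{frac}_B)$ plane centred at $(1,1)$ and reaching
the $[0,2]^2$ box boundary, 15 magnitude steps per direction — 600
perturbed circuits per channel pair, an order of magnitude more than the
30 of a single-channel scan. The four cardinal directions re-simulate
exactly the single-perturbation parameter points, which the tests exploit
as a bit-level consistency check.

Crash categories summarize a full single-channel scan: whether the
perturbed cell, the unperturbed cell, either, or neither fell silent at
some step. At silencing transitions the package also records the surviving
cell's spikes per burst and within-burst ISI relative to the unperturbed
circuit (`transition_statistics()`); the full-scale fractions (77% more
spikes, 70% shorter ISI) are cluster-scale observables that we do not
assert at reduced scale.

## Population statistics

* `spearman_matrix()` — Spearman rank correlation (average ranks on ties)
  between all 14 stability values, with two-sided p-values.
* `cluster_reorder()` — agglomerative single-linkage clustering on
  Euclidean column distances of the correlation matrix,
  $d(u,v) = \min_{i \in u, j \in v} d(i,j)$, used only to reorder the
  matrix into contiguous blocks.
* `subset_attribute_correlations()` — within subsets of circuits sharing
  the identical perturbed cell, Spearman correlations between a stability
  value and circuit attributes: the synapse onto the perturbed cell
  ($\bar g_{12}$), onto the unperturbed cell ($\bar g_{21}$), and the
  period of the unperturbed cell simulated uncoupled. With 100 such tests
  at $p < 0.05$, ≈ 5 significant results are expected by chance; raw
  p-values are reported deliberately (no multiplicity correction), with
  `null_spearman_calibration()` quantifying that chance level.
* `train_stability_classifier()` — ridge (L2) logistic regression on the
  16 min–max-scaled features (7 + 7 intrinsic conductances and both
  synaptic conductances; a 15-feature variant with only the synapse onto
  the perturbed cell is available, resolving the sources' internal
  15-vs-16 ambiguity in favour of 16), labels = top/bottom 20% of
  circuits by the chosen θ (proportional split with a stable tie-break on
  circuit id), stratified 10-fold cross-validation. The penalty is matched
  to a unit-regularization objective: glmnet's $\lambda = 1/n$ is the
  objective-level equivalent of the scikit-learn convention with $C = 1$.
* `weight_geometry()` — pairwise angles between classifier weight vectors
  in the full feature space and their projection onto the first three
  principal components.
* `fit_double_from_single()` — nonlinear least squares for
  $\theta_{1,2} = (\alpha\theta_1 + \beta\theta_2)^\gamma$ with
  $\alpha, \beta \ge 0$, $\gamma > 0$, multi-started over a
  $\{0.25, 0.5, 1\} \times \{0.25, 0.5, 1\} \times \{0.5, 1, 2\}$ grid
  with a Nelder–Mead polish (power-law fits are initialization-sensitive;
  the best residual sum of squares wins). $\gamma > 1$ means the double
  perturbation is worse than the weighted single combination, $\gamma < 1$
  better; $R^2$ is computed on the fitted data (not cross-validated) and a
  constant response is flagged degenerate rather than fitted.

## What the synthetic data do and do not establish

Two generators make every stage testable without cluster-scale runs.
`make_burster_traces()` produces square-wave "cells" with analytically
known spikes, bursts, phase, period and overlap — ground truth for the
rhythm metrics, but with none of the waveform variability, spike-height
dynamics or period drift of the conductance-based model. `mini_population()`
runs the real pipeline at reduced scale; its green tests establish
protocol conformance (counts, determinism, bounds), *not* the paper-scale
population statistics, which are explicitly out of reach on one CPU. A
frozen reduced-scale population (25 circuits from 264 seeded scanned
pairs, shipped as JSON in `inst/extdata/`, generated by the package's own
scans at the `ci` preset with each record carrying its scan seed) supports
the classifier above-chance check with stability values recomputed at test
time. Notably, at this preset only ~10% of scanned pairs survive both the
short evaluation and the long validation: the 2 s evaluation estimates the
phase difference from ~3 cycles, and the longer run often reveals a phase
that has drifted outside $0.5 \pm 0.03$.

## Numerical and design choices worth knowing

* Calcium is clamped below at $10^{-6}\ \mu M$ so the Nernst potential
  stays defined; the clamp never engages outside pathological parameter
  sets.
* Burst-exclusion values outside $[0,1]$ (possible for degenerate interval
  sets) are clamped with a warning. A cell whose bursts are all single
  spikes has zero measurable active time, so `x_network` is undefined
  (`NA`) and such a circuit is never classified functional — single-spike
  bursts count for phase and period, but cannot demonstrate alternation.
* The phase reference is always cell 1 (the perturbed cell); swapping the
  cells maps $\varphi \to (1-\varphi) \bmod 1$.
* A simulation that leaves $|V| \le 500$ mV or goes non-finite is recorded
  as a flagged failure (`blown`), scored like a silent outcome, and never
  raises an error that would lose scan state. With exponential Euler the
  voltage is a convex combination of its previous value and a bounded
  drive, so this flag is a guard rather than an expected path.
* Jitter is redrawn per candidate evaluation, and the ≥3-functional stop
  is checked after complete batches; both readings of ambiguous protocol
  details are fixed and documented here.
* All stages derive their randomness from explicit integer seeds; repeated
  runs are byte-identical, which the suite asserts on serialized output.

## Known limitations

Single-compartment cells; no temperature dependence, channel noise or
spike-mediated transmission; perturbations only of intrinsic maximal
conductances of one cell (not synapses, not both cells); and all
population-level numbers quoted from the full-scale study (7690 circuits)
are anchors for scaled-down statistical checks, not quantities this
package reproduces on a desktop.
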