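# Population construction: random single neurons, the self-refining Monte
# Carlo scan over the synaptic grid, and assembly of functional circuits.

#' Default maximal-conductance sampling ranges
#'
#' Uniform per-channel ranges (uS) for single-neuron generation.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
conductance_ranges <- function() {
  list(Na = c(800, 1200), CaT = c(0, 6), CaS = c(0, 12), A = c(20, 130),
       KCa = c(20, 140), Kd = c(90, 120), H = c(0, 2))
}

#' Synaptic grid specification
#'
#' The Monte Carlo scan evaluates candidate synapse pairs on a square grid
#' with per-candidate jitter.  The grid spans (0, 1\] uS at 0.025 uS
#' resolution (40 values per axis, 1600 candidate connections per pair);
#' jitter is drawn from the discrete range \[-0.0125, 0.0125\] uS at 0.0025
#' uS resolution.
#'
#' @param resolution Grid resolution, uS.
#' @param jitter_range,jitter_resolution Jitter grid, uS.
#' @param batch_size Simulations per batch.
#' @param eval_duration Evaluation run length per candidate, ms.
#' @param validation_duration Long validation run length, ms.
#' @param stop_after_functional Stop once this many functional circuits found.
#' @param dt Integration step, ms.
#' @param transient Transient excluded from metrics, ms.
#' @return List of class `synaptic_grid_spec`.
#' @export
synaptic_grid_spec <- function(resolution = 0.025,
                               jitter_range = c(-0.0125, 0.0125),
                               jitter_resolution = 0.0025,
                               batch_size = 32,
                               eval_duration = 4500,
                               validation_duration = 120000,
                               stop_after_functional = 3,
                               dt = 0.025, transient = 1000) {
  structure(list(values = seq(resolution, 1, by = resolution),
                 resolution = resolution,
                 jitter = seq(jitter_range[1], jitter_range[2],
                              by = jitter_resolution),
                 batch_size = batch_size, eval_duration = eval_duration,
                 validation_duration = validation_duration,
                 stop_after_functional = stop_after_functional,
                 dt = dt, transient = transient),
            class = "synaptic_grid_spec")
}

#' Sample a population of single neurons
#'
#' Each maximal conductance is drawn independently and uniformly within its
#' range; deterministic for a fixed seed.
#'
#' @param n Number of neurons.
#' @param ranges Per-channel ranges, see [conductance_ranges()].
#' @param seed Integer RNG seed.
#' @return List of `neuron_parameters` with ids `"n<seed>_<i>"`.
#' @export
sample_neurons <- function(n, ranges = conductance_ranges(), seed = 1) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  rng <- local({ set.seed(seed); lapply(seq_len(n), function(i)
    vapply(ranges, function(r) stats::runif(1, r[1], r[2]), numeric(1))) })
  lapply(seq_len(n), function(i) {
    g <- rng[[i]]
    names(g) <- names(ranges)
    neuron_parameters(g, neuron_id = sprintf("n%d_%d", seed, i))
  })
}

#' Self-refining Monte Carlo scan over the synaptic grid
#'
#' Candidate synapse pairs `(g12, g21)` are evaluated in random order in
#' batches.  After each batch, candidates implied non-functional by observed
#' suppression are pruned: if cell 2 fell silent at `(g12*, g21*)`, every
#' unevaluated candidate with `g21 > g21*` and `g12 <= g12*` (stronger
#' inhibition onto the silenced cell, no stronger defence) is discarded;
#' mirror rule when cell 1 fell silent.  The scan stops early once at least
#' `stop_after_functional` functional circuits have been found (checked after
#' each complete batch) or the grid is exhausted.
#'
#' @param cell1,cell2 `neuron_parameters` of the pair.
#' @param grid A `synaptic_grid_spec`.
#' @param seed Integer seed controlling candidate order and jitter.
#' @return List with `outcomes` (data frame: `g12_grid`, `g21_grid`, `g12`,
#'   `g21` (jittered), `outcome`, `phi`, `period`, `x_network`) where pruned
#'   candidates carry outcome `"pruned_unevaluated"`, `functional` (list
#'   of `circuit_parameters` for the functional candidates, jittered
#'   values), and `eval_order` (row indices in evaluation sequence).
#' @export
self_refining_scan <- function(cell1, cell2, grid = synaptic_grid_spec(),
                               seed = 1) {
  gv <- grid$values
  cand <- expand.grid(g12 = gv, g21 = gv)
  n_cand <- nrow(cand)
  set.seed(seed)
  order_all <- sample.int(n_cand)
  alive <- rep(TRUE, n_cand)      # not yet evaluated, not pruned
  pruned <- rep(FALSE, n_cand)
  res <- data.frame(g12_grid = cand$g12, g21_grid = cand$g21,
                    g12 = NA_real_, g21 = NA_real_,
                    outcome = "pruned_unevaluated",
                    phi = NA_real_, period = NA_real_, x_network = NA_real_,
                    stringsAsFactors = FALSE)
  functional <- list()
  eval_order <- integer(0)
  ptr <- 1L
  while (any(alive) && length(functional) < grid$stop_after_functional) {
    batch <- integer(0)
    while (length(batch) < grid$batch_size && ptr <= n_cand) {
      i <- order_all[ptr]; ptr <- ptr + 1L
      if (alive[i]) batch <- c(batch, i)
    }
    if (length(batch) == 0) break
    suppressors <- list()
    for (i in batch) {
      alive[i] <- FALSE
      eval_order <- c(eval_order, i)
      j12 <- sample(grid$jitter, 1)
      j21 <- sample(grid$jitter, 1)
      g12 <- cand$g12[i] + j12
      g21 <- cand$g21[i] + j21
      circ <- circuit_parameters(cell1, cell2,
                                 synapse_parameters(g12, g21),
                                 circuit_id = sprintf("%s|%s|%g|%g",
                                                      cell1$neuron_id,
                                                      cell2$neuron_id,
                                                      g12, g21),
                                 provenance = list(seed = seed))
      tr <- integrate_circuit(circ, grid$eval_duration, dt = grid$dt,
                              record_every = 4L)
      cl <- classify_output(tr, transient = grid$transient)
      res$g12[i] <- g12; res$g21[i] <- g21
      res$outcome[i] <- if (cl$classification == "one_silent")
        paste0("one_silent_", cl$silenced_cell) else cl$classification
      res$phi[i] <- cl$phi; res$period[i] <- cl$period
      res$x_network[i] <- cl$x_network
      if (cl$classification == "functional")
        functional[[length(functional) + 1L]] <- circ
      if (cl$classification == "one_silent" &&
            cl$silenced_cell %in% c("cell1", "cell2"))
        suppressors[[length(suppressors) + 1L]] <-
          list(cell = cl$silenced_cell, i = i)
    }
    # pruning is applied after the complete batch: stronger inhibition onto
    # a silenced cell (with no stronger defence) keeps it silent
    for (sp in suppressors) {
      i <- sp$i
      kill <- if (sp$cell == "cell2")
        alive & cand$g21 > cand$g21[i] & cand$g12 <= cand$g12[i]
      else
        alive & cand$g12 > cand$g12[i] & cand$g21 <= cand$g21[i]
      alive[kill] <- FALSE
      pruned[kill] <- TRUE
    }
  }
  res$outcome[pruned] <- "pruned_unevaluated"
  list(outcomes = res, functional = functional, eval_order = eval_order,
       batch_size = grid$batch_size)
}

#' Select one functional circuit from a scan
#'
#' Uniform random choice among the functional candidates, deterministic for a
#' fixed seed.
#'
#' @param functional_list List of `circuit_parameters`.
#' @param seed Integer seed.
#' @return One `circuit_parameters`, or `NULL` for an empty list.
#' @export
select_functional_circuit <- function(functional_list, seed = 1) {
  if (length(functional_list) == 0) return(NULL)
  set.seed(seed)
  functional_list[[sample.int(length(functional_list), 1)]]
}

#' Long-run validation of a functional circuit
#'
#' Re-simulates the circuit for the validation duration (120 s at full scale)
#' and checks that the output is still classified functional; numerical
#' failure counts as invalid.
#'
#' @param circuit A `circuit_parameters`.
#' @param grid A `synaptic_grid_spec` (supplies duration, dt, transient).
#' @return Logical.
#' @export
validate_long <- function(circuit, grid = synaptic_grid_spec()) {
  tr <- integrate_circuit(circuit, grid$validation_duration, dt = grid$dt,
                          record_every = 8L)
  if (isTRUE(tr$blown)) return(FALSE)
  cl <- classify_output(tr, transient = grid$transient)
  cl$classification == "functional"
}

#' Build a population of functional half-center circuits
#'
#' Samples `n_neurons` single neurons, iterates over random unordered pairs
#' without replacement, runs the self-refining scan on each pair, picks one
#' functional circuit per successful pair, validates it on the long run, and
#' stops when `target_circuits` circuits are collected or the pairs are
#' exhausted.  Fully reproducible given `seed` (a master seed spawning
#' recorded per-stage child seeds).
#'
#' @param n_neurons Number of single neurons to sample (>= 2).
#' @param target_circuits Circuits to collect.
#' @param grid A `synaptic_grid_spec`.
#' @param ranges Conductance sampling ranges.
#' @param seed Master seed.
#' @param validate Run the long validation (default TRUE).
#' @param max_pairs Optional cap on the number of pairs scanned.
#' @return List of class `hcc_population`: `circuits` (list of
#'   `circuit_parameters`), `neurons`, `log` (one row per scanned pair:
#'   neuron indices, child seed, n functional, selected, validated).
#' @export
build_population <- function(n_neurons, target_circuits,
                             grid = synaptic_grid_spec(),
                             ranges = conductance_ranges(), seed = 1,
                             validate = TRUE, max_pairs = Inf) {
  stopifnot(n_neurons >= 2)
  neurons <- sample_neurons(n_neurons, ranges, seed = seed)
  pairs <- utils::combn(n_neurons, 2)
  set.seed(seed + 1L)
  pair_order <- sample.int(ncol(pairs))
  child_seeds <- sample.int(2^30, ncol(pairs))
  circuits <- list()
  log <- list()
  for (k in seq_along(pair_order)) {
    if (length(circuits) >= target_circuits || k > max_pairs) break
    pr <- pairs[, pair_order[k]]
    sd_k <- child_seeds[k]
    scan <- self_refining_scan(neurons[[pr[1]]], neurons[[pr[2]]],
                               grid = grid, seed = sd_k)
    sel <- select_functional_circuit(scan$functional, seed = sd_k + 1L)
    ok <- FALSE
    if (!is.null(sel)) {
      ok <- if (validate) validate_long(sel, grid) else TRUE
      if (ok) {
        sel$circuit_id <- sprintf("c%03d", length(circuits) + 1L)
        sel$provenance <- list(neuron1 = neurons[[pr[1]]]$neuron_id,
                               neuron2 = neurons[[pr[2]]]$neuron_id,
                               seed = sd_k)
        circuits[[length(circuits) + 1L]] <- sel
      }
    }
    log[[k]] <- data.frame(pair_i = pr[1], pair_j = pr[2], seed = sd_k,
                           n_functional = length(scan$functional),
                           selected = !is.null(sel), validated = ok)
  }
  if (length(circuits) < target_circuits)
    warning(sprintf("collected %d of %d target circuits",
                    length(circuits), target_circuits))
  structure(list(circuits = circuits, neurons = neurons,
                 log = do.call(rbind, log), seed = seed),
            class = "hcc_population")
}

#' @export
print.hcc_population <- function(x, ...) {
  cat(sprintf("hcc_population: %d circuits from %d neurons (%d pairs scanned)\n",
              length(x$circuits), length(x$neurons),
              if (is.null(x$log)) 0L else nrow(x$log)))
  invisible(x)
}
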