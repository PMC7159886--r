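# Population-level analyses of stability values: correlation structure,
# clustering, attribute correlations, classifiers, and the double-from-single
# nonlinear prediction.

#' Stability table of a population
#'
#' Computes the 14 single-perturbation stability values (`<channel>_down`,
#' `<channel>_up` for the seven gated channels, perturbed cell fixed) for
#' every circuit in a population.
#'
#' @param population An `hcc_population` (or plain list of circuits).
#' @param grid A `synaptic_grid_spec` (durations, dt, transient).
#' @param cell Perturbed cell.
#' @param channels Channels to perturb (default all seven).
#' @return Numeric matrix, rows = circuits (rownames = circuit ids), columns
#'   = perturbations; attribute `"records"` holds the full
#'   `stability_record` list, attribute `"phi0"` / `"baseline"` the
#'   unperturbed phase and spiking statistics.
#' @export
compute_stability_table <- function(population, grid = synaptic_grid_spec(),
                                    cell = "cell1",
                                    channels = GATED_CHANNELS) {
  circuits <- if (inherits(population, "hcc_population"))
    population$circuits else population
  cols <- as.vector(t(outer(channels, c("down", "up"), paste, sep = "_")))
  tab <- matrix(NA_real_, length(circuits), length(cols),
                dimnames = list(vapply(circuits, `[[`, character(1),
                                       "circuit_id"), cols))
  records <- list()
  baseline <- list()
  for (i in seq_along(circuits)) {
    circ <- circuits[[i]]
    ev0 <- eval_perturbed(circ, grid$eval_duration, grid$dt, grid$transient)
    baseline[[circ$circuit_id]] <- list(spikes_per_burst = ev0$spikes_per_burst,
                                        within_isi = ev0$within_isi)
    for (ch in channels) for (dir in c("down", "up")) {
      rec <- single_perturbation_stability(circ, ch, dir, cell = cell,
                                           phi_0 = ev0$phi, grid = grid)
      tab[i, paste(ch, dir, sep = "_")] <- rec$theta
      records[[length(records) + 1L]] <- rec
    }
  }
  attr(tab, "records") <- records
  attr(tab, "baseline") <- baseline
  tab
}

#' Spearman correlation matrix of stability values
#'
#' Pairwise Spearman rank correlation (average ranks for ties) between all
#' stability-value columns, with two-sided p-values.  Constant columns yield
#' `NA` correlations (flagged by the `constant` attribute).
#'
#' @param table Numeric matrix, rows = circuits, columns = stability values.
#' @return List with `rho` (symmetric, unit diagonal), `p`, and logical
#'   vector `constant`.
#' @export
spearman_matrix <- function(table) {
  stopifnot(nrow(table) >= 3)
  k <- ncol(table)
  rho <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(colnames(table), colnames(table))
  diag(p) <- 0
  const <- apply(table, 2, function(x) stats::sd(x) == 0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) { rho[i, j] <- rho[j, i] <- NA; next }
    ct <- suppressWarnings(stats::cor.test(table[, i], table[, j],
                                           method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p, constant = const)
}

#' Reorder a correlation matrix by single-linkage clustering
#'
#' Agglomerative clustering of the matrix columns with Euclidean column
#' distance and single linkage (`d(u, v)` = minimum distance over
#' cross-cluster column pairs); returns the leaf order used to reorder the
#' matrix and the dendrogram.
#'
#' @param corr Square symmetric matrix (e.g. `spearman_matrix()$rho`).
#' @return List with `order` (integer leaf order), `labels`, `hclust`.
#' @export
cluster_reorder <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  d <- stats::dist(t(corr), method = "euclidean")
  hc <- stats::hclust(d, method = "single")
  list(order = hc$order, labels = colnames(corr)[hc$order], hclust = hc)
}

#' Uncoupled firing period of a single neuron
#'
#' Simulates the neuron in isolation (no synapse) and returns the mean
#' inter-onset interval of its bursts (tonic cells: mean interspike
#' interval); `NA` for silent cells.
#'
#' @param neuron A `neuron_parameters`.
#' @param grid A `synaptic_grid_spec`.
#' @return Period in ms, or `NA`.
#' @export
uncoupled_period <- function(neuron, grid = synaptic_grid_spec()) {
  circ <- circuit_parameters(neuron, neuron, synapse_parameters(0, 0))
  tr <- integrate_circuit(circ, grid$eval_duration, dt = grid$dt,
                          record_every = 4L)
  keep <- tr$times >= grid$transient
  sp <- detect_spikes(tr$V1[keep], tr$times[keep])
  if (length(sp) < 2) return(NA_real_)
  thr <- isi_burst_threshold(sp)
  if (thr$tonic) return(mean(diff(sp)))
  b <- segment_bursts(sp, thr$threshold)
  if (nrow(b) < 2) return(NA_real_)
  mean(diff(b$onset))
}

#' Correlations between stability and circuit attributes within subsets
#'
#' For subsets of circuits sharing an identical perturbed cell, computes the
#' Spearman correlation (and p-value) between each chosen stability value
#' and each circuit attribute: the synaptic conductance onto the perturbed
#' cell (`g12`), onto the unperturbed cell (`g21`), and the uncoupled period
#' of the unperturbed cell.
#'
#' @param population An `hcc_population`.
#' @param table Stability table ([compute_stability_table()]).
#' @param perturbations Column names of `table` to correlate.
#' @param size_range Allowed subset sizes (inclusive); subsets are formed by
#'   grouping circuits on the perturbed-cell neuron id.
#' @param min_size Subsets smaller than this are skipped with a warning.
#' @param grid A `synaptic_grid_spec` (for the uncoupled-period simulations).
#' @return Data frame: `subset`, `n`, `perturbation`, `attribute`, `rho`,
#'   `p`.  Attributes constant within a subset yield `NA` (flagged).
#' @export
subset_attribute_correlations <- function(population, table,
                                          perturbations = colnames(table),
                                          size_range = c(18, 29),
                                          min_size = 3,
                                          grid = synaptic_grid_spec()) {
  circuits <- population$circuits
  ids <- vapply(circuits, `[[`, character(1), "circuit_id")
  pc <- vapply(circuits, function(c.) c.$provenance$neuron1 %||%
                 NA_character_, character(1))
  groups <- split(seq_along(circuits), pc)
  groups <- groups[vapply(groups, length, integer(1)) >= min_size]
  small <- vapply(groups, length, integer(1)) < size_range[1] |
    vapply(groups, length, integer(1)) > size_range[2]
  if (any(small))
    message(sprintf("%d subsets outside the full-scale size range %d-%d",
                    sum(small), size_range[1], size_range[2]))
  per_cache <- new.env()
  rows <- list()
  for (s in seq_along(groups)) {
    ix <- groups[[s]]
    if (length(ix) < min_size) { warning("subset too small; skipped"); next }
    g12 <- vapply(circuits[ix], function(c.) c.$synapse$g12, numeric(1))
    g21 <- vapply(circuits[ix], function(c.) c.$synapse$g21, numeric(1))
    up <- vapply(circuits[ix], function(c.) {
      key <- c.$provenance$neuron2 %||% c.$circuit_id
      if (is.null(per_cache[[key]]))
        per_cache[[key]] <- uncoupled_period(c.$cell2, grid)
      per_cache[[key]]
    }, numeric(1))
    attrs <- list(g12 = g12, g21 = g21, period_unperturbed = up)
    for (pert in perturbations) for (at in names(attrs)) {
      th <- table[match(ids[ix], rownames(table)), pert]
      x <- attrs[[at]]
      ok <- !is.na(th) & !is.na(x)
      if (sum(ok) < min_size || stats::sd(x[ok]) == 0 ||
            stats::sd(th[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          subset = s, n = length(ix), perturbation = pert, attribute = at,
          rho = NA_real_, p = NA_real_)
        next
      }
      ct <- suppressWarnings(stats::cor.test(th[ok], x[ok],
                                             method = "spearman",
                                             exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        subset = s, n = length(ix), perturbation = pert, attribute = at,
        rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chance-level calibration of repeated Spearman tests
#'
#' Draws independent null datasets (uncorrelated Gaussian pairs) of the
#' subset sizes used in the attribute analysis and counts how many of the
#' `n_subsets` Spearman tests are significant at `alpha`; with 100 tests at
#' alpha = 0.05 about 5 are expected by chance.
#'
#' @param n_subsets Tests per replicate (default 100).
#' @param size_range Subset sizes drawn uniformly from this range.
#' @param alpha Significance level.
#' @param replicates Number of replicates.
#' @param seed RNG seed.
#' @return List with `mean_significant` and the per-replicate `counts`.
#' @export
null_spearman_calibration <- function(n_subsets = 100,
                                      size_range = c(18, 29),
                                      alpha = 0.05, replicates = 200,
                                      seed = 1) {
  set.seed(seed)
  counts <- vapply(seq_len(replicates), function(r) {
    sum(vapply(seq_len(n_subsets), function(i) {
      n <- sample(size_range[1]:size_range[2], 1)
      ct <- suppressWarnings(stats::cor.test(stats::rnorm(n),
                                             stats::rnorm(n),
                                             method = "spearman",
                                             exact = FALSE))
      ct$p.value < alpha
    }, logical(1)))
  }, numeric(1))
  list(mean_significant = mean(counts), counts = counts)
}

#' Circuit feature matrix for the stability classifiers
#'
#' The 14 maximal conductances (7 per cell) plus the two directed synaptic
#' conductances, min-max scaled to \[0, 1\] column-wise.
#'
#' @param population An `hcc_population` or list of circuits.
#' @param include_both_synapses Use both `g12` and `g21` (16 features,
#'   default) or only the synapse onto the perturbed cell (15 features).
#' @return Numeric matrix with attribute `"scaling"` (per-column ranges).
#' @export
circuit_features <- function(population, include_both_synapses = TRUE) {
  circuits <- if (inherits(population, "hcc_population"))
    population$circuits else population
  f <- t(vapply(circuits, function(c.) {
    v <- c(c.$cell1$gbar, c.$cell2$gbar, c.$synapse$g12, c.$synapse$g21)
    names(v) <- c(paste0(GATED_CHANNELS, "_cell1"),
                  paste0(GATED_CHANNELS, "_cell2"), "g12", "g21")
    v
  }, numeric(16)))
  rownames(f) <- vapply(circuits, `[[`, character(1), "circuit_id")
  if (!include_both_synapses) f <- f[, colnames(f) != "g21"]
  lo <- apply(f, 2, min); hi <- apply(f, 2, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  scaled <- sweep(sweep(f, 2, lo), 2, span, "/")
  attr(scaled, "scaling") <- cbind(low = lo, high = hi)
  scaled
}

#' Logistic stability classifier for one perturbation
#'
#' Labels the top and bottom `split` fraction of circuits by the chosen
#' stability value as stable/unstable, and fits an L2-penalized (ridge)
#' logistic regression on the min-max-scaled circuit features, matching a
#' unit-regularization objective (penalty `1/(2n) * ||w||^2` relative to the
#' mean log-loss).  Reports stratified 10-fold cross-validated accuracy and
#' the full-data weight vector.
#'
#' @param features Scaled feature matrix ([circuit_features()]).
#' @param theta Stability values aligned with `features` rows.
#' @param split Fraction per class (default 0.2).
#' @param n_folds Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param perturbation Label carried through to the result.
#' @return List of class `classifier_result`: `weights` (named, no
#'   intercept), `intercept`, `cv_accuracy`, `n_per_class`, `perturbation`.
#' @export
train_stability_classifier <- function(features, theta, split = 0.2,
                                       n_folds = 10, seed = 1,
                                       perturbation = NA_character_) {
  stopifnot(nrow(features) == length(theta))
  n <- length(theta)
  k <- max(2L, floor(split * n))
  ord <- order(theta, rownames(features))  # stable tie-break on circuit id
  unstable <- ord[seq_len(k)]
  stable <- ord[seq(n - k + 1L, n)]
  x <- features[c(unstable, stable), , drop = FALSE]
  y <- c(rep(0L, k), rep(1L, k))
  fit_ridge <- function(x, y) {
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = 1 / length(y), standardize = FALSE,
                   thresh = 1e-10)
  }
  full <- fit_ridge(x, y)
  w <- as.numeric(full$beta)
  names(w) <- colnames(x)
  # stratified folds
  set.seed(seed)
  fold <- integer(2 * k)
  fold[y == 0] <- sample(rep_len(seq_len(n_folds), k))
  fold[y == 1] <- sample(rep_len(seq_len(n_folds), k))
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    m <- fit_ridge(x[tr, , drop = FALSE], y[tr])
    pr <- stats::predict(m, x[!tr, , drop = FALSE], type = "response")
    mean((pr > 0.5) == (y[!tr] == 1))
  }, numeric(1))
  structure(list(weights = w, intercept = as.numeric(full$a0),
                 cv_accuracy = mean(acc, na.rm = TRUE),
                 n_per_class = k, perturbation = perturbation),
            class = "classifier_result")
}

#' Geometry of classifier weight vectors
#'
#' Pairwise angles between weight vectors in the full feature space
#' (`arccos` of the normalized inner product) and the projection of the
#' weights onto the first three principal components of the stacked weight
#' matrix.
#'
#' @param classifiers List of `classifier_result`s (equal feature
#'   dimension).
#' @return List with `angles` (radians, `NA` for zero-norm vectors),
#'   `projection` (n x 3), `pca` (the `prcomp` object).
#' @export
weight_geometry <- function(classifiers) {
  stopifnot(length(classifiers) >= 2)
  W <- t(vapply(classifiers, `[[`,
                numeric(length(classifiers[[1]]$weights)), "weights"))
  rownames(W) <- vapply(classifiers, function(c.)
    as.character(c.$perturbation), character(1))
  nrm <- sqrt(rowSums(W^2))
  k <- nrow(W)
  ang <- matrix(NA_real_, k, k, dimnames = list(rownames(W), rownames(W)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (nrm[i] == 0 || nrm[j] == 0) next
    cosij <- sum(W[i, ] * W[j, ]) / (nrm[i] * nrm[j])
    ang[i, j] <- acos(pmin(1, pmax(-1, cosij)))
  }
  pca <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  ncomp <- min(3, ncol(pca$x))
  list(angles = ang, projection = pca$x[, seq_len(ncomp), drop = FALSE],
       pca = pca)
}

#' Predict double-perturbation stability from single stabilities
#'
#' Fits `theta12 = (alpha * theta1 + beta * theta2)^gamma` by nonlinear
#' least squares with constraints `alpha, beta >= 0`, `gamma > 0`,
#' multi-started from all combinations of `{0.5, 1}` for the three
#' parameters; the best residual sum of squares is kept.
#' `gamma > 1` means the double perturbation is worse than the weighted
#' combination of the single perturbations, `gamma < 1` better.
#'
#' @param theta1,theta2,theta12 Aligned stability vectors in \[0, 1\]
#'   (>= 10 circuits).
#' @return List of class `double_fit_result`: `alpha`, `beta`, `gamma`,
#'   `r_squared` (`NA` with `degenerate = TRUE` when `theta12` is constant),
#'   `converged`.
#' @export
fit_double_from_single <- function(theta1, theta2, theta12) {
  stopifnot(length(theta1) == length(theta2),
            length(theta1) == length(theta12), length(theta1) >= 10,
            all(theta1 >= 0 & theta1 <= 1), all(theta2 >= 0 & theta2 <= 1),
            all(theta12 >= 0 & theta12 <= 1))
  ss_tot <- sum((theta12 - mean(theta12))^2)
  obj <- function(par) {
    base <- par[1] * theta1 + par[2] * theta2
    sum((theta12 - base^par[3])^2)
  }
  best <- NULL
  for (a0 in c(0.25, 0.5, 1)) for (b0 in c(0.25, 0.5, 1))
    for (g0 in c(0.5, 1, 2)) {
      fit <- try(stats::optim(c(a0, b0, g0), obj, method = "L-BFGS-B",
                              lower = c(0, 0, 1e-3),
                              upper = c(10, 10, 10),
                              control = list(maxit = 500, factr = 1e5)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  if (!is.null(best)) {
    # derivative-free polish, then re-clamp to the constraint box
    nm <- stats::optim(best$par, function(p)
      if (any(p[1:2] < 0) || p[3] <= 0) Inf else obj(p),
      method = "Nelder-Mead", control = list(maxit = 2000,
                                             reltol = 1e-12))
    if (nm$value < best$value) best <- nm
  }
  if (is.null(best))
    return(structure(list(alpha = NA, beta = NA, gamma = NA,
                          r_squared = NA, converged = FALSE,
                          degenerate = FALSE),
                     class = "double_fit_result"))
  structure(list(alpha = best$par[1], beta = best$par[2],
                 gamma = best$par[3],
                 r_squared = if (ss_tot > 0) 1 - best$value / ss_tot
                             else NA_real_,
                 converged = best$convergence == 0,
                 degenerate = ss_tot == 0),
            class = "double_fit_result")
}
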