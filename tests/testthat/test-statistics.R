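# Correlation structure, clustering, classifiers and the double-from-single
# nonlinear fit.

test_that("Spearman matrix agrees with a rank-then-Pearson oracle and flags constants", {
  set.seed(10)
  tab <- matrix(stats::runif(50 * 14), 50, 14,
                dimnames = list(NULL, paste0("c", 1:14)))
  sm <- spearman_matrix(tab)
  expect_equal(diag(sm$rho), rep(1, 14), ignore_attr = TRUE)
  expect_equal(sm$rho, t(sm$rho))
  oracle <- stats::cor(apply(tab, 2, rank))
  expect_equal(unname(sm$rho), unname(oracle), tolerance = 1e-12)
  # self and negation
  two <- cbind(a = tab[, 1], b = -tab[, 1])
  sm2 <- spearman_matrix(two)
  expect_equal(sm2$rho["a", "b"], -1)
  # rank invariance under strictly monotone transforms
  tab2 <- tab; tab2[, 3] <- exp(5 * tab2[, 3]); tab2[, 7] <- tab2[, 7]^3
  expect_equal(spearman_matrix(tab2)$rho, sm$rho, tolerance = 1e-12)
  # constant column flagged
  tab3 <- tab; tab3[, 2] <- 0.5
  sm3 <- spearman_matrix(tab3)
  expect_true(sm3$constant[2])
  expect_true(all(is.na(sm3$rho[2, -2])))
})

test_that("single-linkage reordering matches a hand-computed agglomeration", {
  # four columns with known pairwise Euclidean distances
  M <- cbind(a = c(0, 0, 0, 0), b = c(0.1, 0, 0, 0),
             c = c(1, 0, 0, 0), d = c(1, 0.5, 0, 0))
  rownames(M) <- colnames(M)
  res <- cluster_reorder(M)
  hc <- res$hclust
  # manual single linkage: d(a,b)=0.1 merge first; d(c,d)=0.5 second;
  # d({a,b},{c,d}) = min over pairs = d(b,c)=0.9... compute explicitly
  D <- as.matrix(stats::dist(t(M)))
  expect_equal(hc$height[1], D["a", "b"])
  expect_equal(hc$height[2], D["c", "d"])
  expect_equal(hc$height[3],
               min(D[c("a", "b"), c("c", "d")]))
  # first merge joins a and b, second joins c and d
  expect_setequal(-hc$merge[1, ], c(1, 2))
  expect_setequal(-hc$merge[2, ], c(3, 4))
  # identical columns merge first at distance zero
  M2 <- cbind(x = c(1, 2, 0), y = c(5, 1, 2), z = c(1, 2, 0))
  hc2 <- cluster_reorder(M2)$hclust
  expect_equal(hc2$height[1], 0)
  expect_setequal(-hc2$merge[1, ], c(1, 3))
  # leaf order is a permutation
  expect_setequal(res$order, 1:4)
})

test_that("planted correlation blocks stay contiguous after reordering", {
  set.seed(22)
  n <- 60
  u <- stats::runif(n); v <- stats::runif(n)
  tab <- cbind(u + stats::rnorm(n, 0, 0.05), u + stats::rnorm(n, 0, 0.05),
               u + stats::rnorm(n, 0, 0.05), v + stats::rnorm(n, 0, 0.05),
               v + stats::rnorm(n, 0, 0.05), v + stats::rnorm(n, 0, 0.05))
  colnames(tab) <- c("u1", "u2", "u3", "v1", "v2", "v3")
  ord <- cluster_reorder(spearman_matrix(tab)$rho)$labels
  block <- substr(ord, 1, 1)
  expect_equal(length(rle(block)$lengths), 2)
})

test_that("repeated null Spearman tests are calibrated at the nominal level", {
  res <- null_spearman_calibration(n_subsets = 100, replicates = 40,
                                   seed = 4)
  expect_gt(res$mean_significant, 3)
  expect_lt(res$mean_significant, 7)
})

test_that("subset attribute correlations recover a planted monotone effect", {
  # synthetic population: one shared perturbed cell, varying partner and
  # synapses; stability planted as a monotone function of g12
  cellA <- fixture_circuit_a()$cell1
  cellB <- fixture_circuit_a()$cell2
  set.seed(14)
  circuits <- lapply(1:12, function(i) {
    g12 <- stats::runif(1, 0.05, 1)
    circuit_parameters(cellA, cellB,
                       synapse_parameters(g12, stats::runif(1, 0.05, 1)),
                       circuit_id = sprintf("s%02d", i),
                       provenance = list(neuron1 = "shared", neuron2 = "p"))
  })
  pop <- structure(list(circuits = circuits), class = "hcc_population")
  g12s <- vapply(circuits, function(c.) c.$synapse$g12, numeric(1))
  theta <- rank(g12s) / 12 + stats::rnorm(12, 0, 0.01)
  tab <- matrix(pmin(1, pmax(0, theta)), ncol = 1,
                dimnames = list(sprintf("s%02d", 1:12), "CaT_up"))
  suppressMessages(
    res <- subset_attribute_correlations(pop, tab, grid = fast_grid()))
  r <- res[res$attribute == "g12" & res$perturbation == "CaT_up", ]
  expect_equal(nrow(r), 1)
  expect_gt(r$rho, 0.9)
  expect_lt(r$p, 0.05)
  # a constant attribute is flagged as NA: all circuits share cell2, so
  # period_unperturbed is constant across the subset
  rp <- res[res$attribute == "period_unperturbed", ]
  expect_true(is.na(rp$rho))
})

test_that("the stability classifier separates planted structure and is at chance on shuffled labels", {
  set.seed(33)
  n <- 1000
  feats <- matrix(stats::runif(n * 16), n, 16,
                  dimnames = list(sprintf("c%04d", 1:n),
                                  c(paste0(rep(c("Na", "CaT", "CaS", "A",
                                                 "KCa", "Kd", "H"), 2),
                                           rep(c("_cell1", "_cell2"),
                                               each = 7)), "g12", "g21")))
  # perfectly separable: theta driven by one feature
  theta <- feats[, "CaT_cell1"]
  cl <- train_stability_classifier(feats, theta, perturbation = "planted")
  expect_gt(cl$cv_accuracy, 0.95)
  expect_gt(cl$weights[["CaT_cell1"]], max(abs(cl$weights[-2])))
  # chance level: labels carry no information about the features
  theta_rnd <- sample(theta)
  cl0 <- train_stability_classifier(feats, theta_rnd, seed = 2,
                                    perturbation = "shuffled")
  expect_gt(cl0$cv_accuracy, 0.4)
  expect_lt(cl0$cv_accuracy, 0.6)
})

test_that("weight geometry matches the arccos oracle and spans three components", {
  set.seed(44)
  mk <- function(w, id) structure(list(weights = w, perturbation = id),
                                  class = "classifier_result")
  w1 <- stats::rnorm(16); w2 <- stats::rnorm(16)
  cls <- list(mk(w1, "p1"), mk(-w1, "p2"), mk(w2, "p3"),
              mk(rep(0, 16), "p4"))
  geo <- weight_geometry(cls)
  expect_equal(geo$angles["p1", "p1"], 0)
  expect_equal(geo$angles["p1", "p2"], pi)
  oracle <- acos(sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2)))
  expect_equal(geo$angles["p1", "p3"], oracle, tolerance = 1e-12)
  expect_true(all(is.na(geo$angles["p4", ])))
  expect_equal(ncol(geo$projection), 3)
})

test_that("the double-from-single fit recovers its own model class", {
  set.seed(55)
  n <- 200
  th1 <- stats::runif(n); th2 <- stats::runif(n)
  # identity: theta12 = theta1
  fit_id <- fit_double_from_single(th1, th2, th1)
  expect_gt(fit_id$r_squared, 1 - 1e-6)
  expect_equal(fit_id$alpha, 1, tolerance = 0.05)
  expect_lt(fit_id$beta, 0.05)
  expect_equal(fit_id$gamma, 1, tolerance = 0.05)
  # noisy quadratic combination: gamma recovered within +/- 0.1
  th12 <- pmin(1, pmax(0, (0.5 * th1 + 0.5 * th2)^2 +
                         stats::rnorm(n, 0, 0.01)))
  fit_q <- fit_double_from_single(th1, th2, th12)
  expect_equal(fit_q$gamma, 2, tolerance = 0.1)
  # noise-free draws from the model class fit essentially perfectly
  # (a + b <= 1 keeps the response inside [0, 1], i.e. in the model class)
  for (k in 1:20) {
    a <- stats::runif(1, 0.2, 0.5); b <- stats::runif(1, 0.2, 0.5)
    g <- stats::runif(1, 0.5, 3)
    y <- (a * th1 + b * th2)^g
    fit <- fit_double_from_single(th1, th2, y)
    expect_gt(fit$r_squared, 0.99)
  }
  # constant response is degenerate
  fit_c <- fit_double_from_single(th1, th2, rep(0.5, n))
  expect_true(fit_c$degenerate)
  expect_true(is.na(fit_c$r_squared))
})

test_that("correlated single stabilities produce supralinear fits more often than uncorrelated ones", {
  # stylized generative story: when the two perturbations act alike
  # (rank-correlated thetas), their joint effect compounds
  # multiplicatively; when they are unrelated, the stronger mechanism
  # dominates.  The fitted exponent should detect the compounding case.
  set.seed(66)
  n <- 150
  gamma_gt1 <- function(correlated) {
    th1 <- stats::runif(n)
    th2 <- if (correlated) pmin(1, pmax(0, th1 + stats::rnorm(n, 0, 0.05)))
           else stats::runif(n)
    th12 <- if (correlated) th1 * th2 else pmax(th1, th2)
    fit_double_from_single(th1, th2, pmin(1, pmax(0, th12)))$gamma > 1
  }
  reps <- 20
  corr_hits <- mean(vapply(1:reps, function(i) gamma_gt1(TRUE), logical(1)))
  unc_hits <- mean(vapply(1:reps, function(i) gamma_gt1(FALSE), logical(1)))
  expect_gt(corr_hits, unc_hits)
})
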