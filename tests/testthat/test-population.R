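# Neuron sampling, the self-refining scan, selection and population assembly.

test_that("neuron sampling is uniform within the printed ranges and seeded", {
  expect_length(sample_neurons(0), 0)
  r <- conductance_ranges()
  expect_equal(r$Na, c(800, 1200))
  expect_equal(r$Kd, c(90, 120))
  n1 <- sample_neurons(50, seed = 5)
  n2 <- sample_neurons(50, seed = 5)
  expect_identical(n1, n2)
  for (nn in n1)
    for (ch in names(r))
      expect_true(nn$gbar[ch] >= r[[ch]][1] && nn$gbar[ch] <= r[[ch]][2])
  # Kolmogorov-Smirnov against the uniform CDF per channel
  big <- sample_neurons(10000, seed = 6)
  for (ch in names(r)) {
    x <- vapply(big, function(n) n$gbar[[ch]], numeric(1))
    ks <- stats::ks.test(x, "punif", r[[ch]][1], r[[ch]][2])
    expect_gt(ks$p.value, 0.01, label = ch)
  }
})

test_that("the frozen fixture circuits are functional at short and long durations", {
  for (circ in list(fixture_circuit_a(), fixture_circuit_b())) {
    tr <- integrate_circuit(circ, 4500, record_every = 4)
    cl <- classify_output(tr)
    expect_equal(cl$classification, "functional", label = circ$circuit_id)
    expect_lte(abs(cl$phi - 0.5), 0.03)
    expect_true(cl$period >= 100 && cl$period <= 800)
    expect_gte(cl$x_network, 0.95)
  }
  expect_true(validate_long(fixture_circuit_a()))
})

test_that("the self-refining scan stops early, respects the grid bounds and prunes soundly", {
  neurons <- sample_neurons(40, seed = 11)
  grid <- fast_grid()
  scan <- self_refining_scan(neurons[[32]], neurons[[7]], grid = grid,
                             seed = 77)
  o <- scan$outcomes
  evaluated <- o[!is.na(o$g12), ]
  # jittered conductances stay within [grid min - jitter, 1.0125]
  expect_true(all(evaluated$g12 > 0 & evaluated$g12 <= 1.0125))
  expect_true(all(evaluated$g21 > 0 & evaluated$g21 <= 1.0125))
  # early stop: evaluation ends with the batch containing the third
  # functional hit
  if (length(scan$functional) >= grid$stop_after_functional) {
    fun_pos <- which(o$outcome[scan$eval_order] == "functional")
    pos3 <- fun_pos[grid$stop_after_functional]
    expect_lte(length(scan$eval_order),
               ceiling(pos3 / grid$batch_size) * grid$batch_size)
  }
  expect_identical(sort(scan$eval_order), which(!is.na(o$g12)))
  # pruned entries lie strictly above an observed suppression point in the
  # corresponding direction
  pruned <- o[o$outcome == "pruned_unevaluated" & is.na(o$g12), ]
  sil2 <- evaluated[evaluated$outcome == "one_silent_cell2", ]
  sil1 <- evaluated[evaluated$outcome == "one_silent_cell1", ]
  if (nrow(pruned) > 0) {
    justified <- vapply(seq_len(nrow(pruned)), function(i) {
      any(pruned$g21_grid[i] > sil2$g21_grid &
            pruned$g12_grid[i] <= sil2$g12_grid) ||
        any(pruned$g12_grid[i] > sil1$g12_grid &
              pruned$g21_grid[i] <= sil1$g21_grid)
    }, logical(1))
    expect_true(all(justified))
  }
  # determinism: identical seed reproduces the identical outcome table
  scan2 <- self_refining_scan(neurons[[32]], neurons[[7]], grid = grid,
                              seed = 77)
  expect_identical(scan$outcomes, scan2$outcomes)
})

test_that("pruned candidates are almost always non-functional when force-evaluated", {
  neurons <- sample_neurons(40, seed = 11)
  grid <- fast_grid()
  set.seed(31)
  checked <- 0; nonfunctional <- 0
  for (pair in list(c(32, 7), c(8, 12))) {
    scan <- self_refining_scan(neurons[[pair[1]]], neurons[[pair[2]]],
                               grid = grid, seed = 900 + pair[1])
    o <- scan$outcomes
    pruned <- which(o$outcome == "pruned_unevaluated" & is.na(o$g12))
    if (length(pruned) == 0) next
    for (i in sample(pruned, min(20, length(pruned)))) {
      circ <- circuit_parameters(neurons[[pair[1]]], neurons[[pair[2]]],
                                 synapse_parameters(o$g12_grid[i],
                                                    o$g21_grid[i]))
      tr <- integrate_circuit(circ, grid$eval_duration, record_every = 4)
      cl <- classify_output(tr, transient = grid$transient)
      checked <- checked + 1
      nonfunctional <- nonfunctional + (cl$classification != "functional")
    }
  }
  expect_gt(checked, 10)
  expect_gte(nonfunctional / checked, 0.95)
})

test_that("selection among functional circuits is seeded, uniform and safe on empty input", {
  expect_null(select_functional_circuit(list(), seed = 1))
  lst <- list("a", "b", "c")
  expect_identical(select_functional_circuit(lst, seed = 9),
                   select_functional_circuit(lst, seed = 9))
  picks <- vapply(1:10000, function(s)
    select_functional_circuit(lst, seed = s)[[1]], character(1))
  counts <- table(picks)
  # binomial 3 sigma around 10000/3
  sigma <- sqrt(10000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 10000 / 3) < 3 * sigma))
})

test_that("population assembly is reproducible and emits only validated functional circuits", {
  grid <- fast_grid()
  pop1 <- suppressWarnings(build_population(8, target_circuits = 1,
                                            grid = grid, seed = 42,
                                            max_pairs = 2))
  pop2 <- suppressWarnings(build_population(8, target_circuits = 1,
                                            grid = grid, seed = 42,
                                            max_pairs = 2))
  expect_identical(pop1$log, pop2$log)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_population(pop1, f1); write_population(pop2, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (circ in pop1$circuits) {
    tr <- integrate_circuit(circ, grid$eval_duration, record_every = 4)
    expect_equal(classify_output(tr, transient = grid$transient)$classification,
                 "functional")
    expect_true(circ$synapse$g12 <= 1.0125 && circ$synapse$g21 <= 1.0125)
  }
  # an unproductive pair budget gives an empty population with a warning
  expect_warning(p0 <- build_population(4, target_circuits = 5,
                                        grid = grid, seed = 1,
                                        max_pairs = 1),
                 "collected")
  expect_lte(length(p0$circuits), 1)
})
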