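test_that("correlation and overlap kernels match their closed forms", {
  p <- energy_params()
  expect_equal(activity_correlation(5, 5, p), 1)
  expect_equal(activity_correlation(1, 12, p), exp(-1), tolerance = 1e-12)
  expect_equal(sc_overlap(10, 10, p), 1)
  expect_equal(sc_overlap(4, 7, p), exp(-0.5), tolerance = 1e-12)
  expect_lt(sc_overlap(1, 31, p), 1e-21)
  set.seed(1)
  a <- runif(20, 1, 100); b <- runif(20, 1, 100)
  expect_equal(activity_correlation(a, b, p), activity_correlation(b, a, p))
  expect_equal(sc_overlap(a, b, p), sc_overlap(b, a, p))
})

test_that("two-neuron toy energies evaluate by hand", {
  p <- energy_params(alpha = 200, gamma = 0, n_neurons = 2)
  st <- map_state(1:2, source_receptor = c(1, 2), target_ligand = c(1, 2))
  e <- total_energy(st, p)
  expect_equal(e$chem, 200 * (1 * 1 + 2 * 2))
  expect_equal(e$act, 0)
  expect_equal(e$total, e$chem + e$act)
  # swapping the two targets: chem changes by alpha (R1-R2) (L(t2)-L(t1))
  expect_equal(swap_delta(st, 1, 2, p), 200 * (1 - 2) * (2 - 1))
  st2 <- map_state(2:1, source_receptor = c(1, 2), target_ligand = c(1, 2))
  expect_equal(swap_delta(st, 1, 2, p),
               total_energy(st2, p)$total - total_energy(st, p)$total)
  expect_error(swap_delta(st, 1, 1, p), "differ")
})

test_that("incremental swap delta equals brute-force recomputation on random instances", {
  set.seed(99)
  worst <- 0
  for (rep in 1:1000) {
    n <- sample(5:30, 1)
    p <- energy_params(alpha = runif(1, 0, 300), gamma = runif(1, 0, 3),
                       d = runif(1, 1, 5), b = runif(1, 0.05, 0.3),
                       n_neurons = n)
    st <- map_state(sample.int(n),
                    source_positions = sort(runif(n, 1, n)),
                    source_receptor = runif(n, 0, 4),
                    target_ligand = runif(n, 0, 4))
    ij <- sample.int(n, 2)
    got <- swap_delta(st, ij[1], ij[2], p)
    st2 <- st
    st2$target_of_source[ij] <- st$target_of_source[rev(ij)]
    want <- total_energy(st2, p)$total - total_energy(st, p)$total
    worst <- max(worst, abs(got - want) / max(1, abs(want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("swap acceptance probability is logistic, stable and monotone", {
  expect_equal(swap_probability(0), 0.5)
  expect_equal(swap_probability(-1), 1 / (1 + exp(-4)), tolerance = 1e-12)
  expect_equal(swap_probability(1000), 0)         # saturates without overflow
  expect_equal(swap_probability(-1000), 1)
  d <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(swap_probability(d)) < 0))  # monotone decreasing
  set.seed(3)
  expect_equal(mean(accept_swap(rep(0, 20000))), 0.5, tolerance = 0.02)
})

test_that("the swap engine preserves the bijection, is seeded and descends in energy", {
  x <- 1:60
  p <- energy_params(n_neurons = 60, iterations = 2e5)
  R <- retinal_epha(x)
  L <- collicular_efna(seq(1, 100, length.out = 60))
  set.seed(5)
  st <- run_mapping(R, L, p, trace = 40)
  set.seed(5)
  st2 <- run_mapping(R, L, p, trace = 40)
  expect_identical(st$target_of_source, st2$target_of_source)
  expect_setequal(st$target_of_source, 1:60)
  tr <- attr(st, "energy_trace")
  n <- length(tr)
  expect_lte(median(tail(tr, ceiling(n / 10))),
             median(head(tr, ceiling(n / 10))))
  # the engine's incremental energy bookkeeping agrees with full recomputation
  expect_equal(tail(tr, 1), total_energy(st, p)$total,
               tolerance = 1e-8)
  expect_error(run_mapping(R, L[1:10], p), "same length")
})

test_that("with activity off, strictly monotone gradients anneal to the anti-rank pairing", {
  n <- 40
  p <- energy_params(gamma = 0, n_neurons = n, iterations = 2e5)
  set.seed(8)
  st <- run_mapping(1 + 0.2 * seq_len(n), 0.2 * seq_len(n), p)
  t <- st$target_of_source
  # high receptor with low ligand: targets decrease with source position
  frac_antiranked <- mean(diff(t) < 0)
  expect_gt(frac_antiranked, 0.9)
})

test_that("with both strengths off the dynamics is an unbiased shuffle", {
  n <- 40
  p <- energy_params(alpha = 0, gamma = 0, n_neurons = n, iterations = 1e4)
  set.seed(11)
  a <- run_mapping(rep(1, n), rep(1, n), p)$target_of_source
  b <- run_mapping(rep(1, n), rep(1, n), p)$target_of_source
  expect_setequal(a, seq_len(n))
  expect_false(identical(a, b))
  expect_lt(abs(cor(a, seq_len(n))), 0.6)  # no systematic ordering
})
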