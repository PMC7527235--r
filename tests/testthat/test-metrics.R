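test_that("intrinsic dispersion index behaves on degenerate and exact maps", {
  const <- map_state(rep(40, 50), source_positions = 1:50, simulated = FALSE)
  expect_equal(idi(const, "literal"), 0)
  expect_equal(idi(const, "detrended"), 0, tolerance = 1e-12)
  ident <- map_state(1:100)
  expect_equal(idi(ident, "literal"), (100^2 - 1) / 12)  # 833.25
  expect_lt(idi(ident, "detrended"), 1e-12)
  expect_error(idi(ident, "nonsense"))
})

test_that("detrended dispersion recovers the jitter variance and ignores smooth trends", {
  set.seed(12)
  v <- replicate(40, idi(make_fixture("single", jitter_sd = 2)))
  # LOESS absorbs ~span-dependent degrees of freedom; expectation is
  # sigma^2 (n - df)/n, a shade under 4
  expect_equal(mean(v), 4, tolerance = 0.15)
  # invariance under adding a common smooth trend
  set.seed(13)
  fx <- make_fixture("single", jitter_sd = 2)
  shifted <- fx
  shifted$target_of_source <- fx$target_of_source +
    8 * sin(fx$source_positions / 40)
  expect_equal(idi(shifted), idi(fx), tolerance = 0.25)
})

test_that("local IDV is zero for constant maps and window-1 for unit-slope maps", {
  const <- map_state(rep(10, 60), source_positions = 1:60, simulated = FALSE)
  expect_true(all(local_idv(const, window = 10)$idv == 0))
  for (w in c(5, 10, 20)) {
    cv <- local_idv(map_state(1:100), window = w)
    expect_true(all(cv$idv == w - 1))
    expect_equal(nrow(cv), 100 - w + 1)
  }
  expect_error(local_idv(map_state(1:100), window = 1), "window")
  expect_error(local_idv(map_state(1:10), window = 11), "larger")
})

test_that("duplicated maps dominate single maps in local IDV wherever branches coexist", {
  single <- make_fixture("single", seed = 21)
  dup <- make_fixture("duplicated", seed = 21)
  s <- local_idv(single)
  d <- local_idv(dup)
  expect_true(all(d$idv > s$idv))  # branches interleave over the whole axis
})

test_that("alignment index is exact on constructed pairs", {
  aligned <- make_fixture("misaligned_pair", shift = 0)
  expect_equal(alignment_index(aligned$rc, aligned$cc), 0)
  for (k in c(3, 7, 25)) {
    mp <- make_fixture("misaligned_pair", shift = k)
    expect_equal(alignment_index(mp$rc, mp$cc), k)
  }
  expect_gte(alignment_index(aligned$rc, make_fixture("single")), 0)
  expect_error(alignment_index(aligned$rc,
                               map_state(1:10, type = "CC")), "size")
})

test_that("Jaccard similarity of binarized IDV curves covers the boundary cases", {
  curve <- function(vals) {
    out <- data.frame(position = seq_along(vals), idv = vals)
    class(out) <- c("idv_curve", class(out))
    out
  }
  a <- curve(rep(c(1, 0), c(60, 40)))
  b <- curve(rep(c(0, 1), c(40, 60)))
  expect_equal(idv_jaccard(a, a, 0.5), 1)
  expect_equal(idv_jaccard(a, b, 0.5), 20 / 100)  # overlap 41..60
  expect_equal(idv_jaccard(curve(rep(0, 10)), curve(rep(0, 10)), 0.5), 1)
  expect_equal(idv_jaccard(curve(c(1, 0, 0)), curve(c(0, 0, 1)), 0.5), 0)
  # shrinking one above-threshold set never increases the index
  set.seed(31)
  v <- runif(50)
  a2 <- curve(v); b2 <- curve(runif(50))
  j1 <- idv_jaccard(a2, b2, 0.5)
  v[which(v > 0.5)[1:5]] <- 0
  expect_lte(idv_jaccard(curve(v), b2, 0.5), j1)
  expect_error(idv_jaccard(a, curve(rep(1, 3)), 0.5), "positions")
})

test_that("IDV covariance is the population covariance", {
  curve <- function(vals) data.frame(position = seq_along(vals), idv = vals)
  a <- curve(c(1, 2, 3)); b <- curve(c(2, 4, 6))
  expect_equal(idv_covariance(a, b), 4 / 3)
  set.seed(4)
  x <- curve(runif(30))
  expect_equal(idv_covariance(x, x), mean((x$idv - mean(x$idv))^2))
  neg <- curve(2 * mean(x$idv) - x$idv)
  expect_equal(idv_covariance(x, neg), -idv_covariance(x, x))
  expect_error(idv_covariance(a, curve(1:5)), "length")
})

test_that("the wild-type IDV threshold reduces to window-1 on exact ensembles", {
  mk <- function(rc, cc) list(rc = rc, cc = cc)
  fake <- structure(list(
    runs = replicate(3, mk(map_state(100:1), map_state(1:100, type = "CC")),
                     simplify = FALSE),
    n_runs = 3), class = "map_align")
  expect_equal(idv_threshold(fake, window = 10), 9)
  const <- map_state(rep(5, 100), simulated = FALSE)
  fake0 <- structure(list(runs = replicate(2, mk(const, const), simplify = FALSE),
                          n_runs = 2), class = "map_align")
  expect_equal(idv_threshold(fake0), 0)
})

test_that("LOESS profiling reproduces lines exactly and flags influential points", {
  x <- 1:30
  y <- 2 * x + 5
  pr <- loess_profile(x, y, leave_one_out = TRUE)
  expect_equal(pr$smooth, 2 * sort(x) + 5, tolerance = 1e-8)
  expect_lt(max(pr$loo_upper - pr$loo_lower), 1e-8)
  # a single outlier widens the leave-one-out envelope most near its position
  y2 <- y; y2[15] <- y2[15] + 30
  pr2 <- loess_profile(x, y2, leave_one_out = TRUE)
  width <- pr2$loo_upper - pr2$loo_lower
  expect_equal(pr2$grid[which.max(width)], 15, tolerance = 3)
  expect_error(loess_profile(rep(1, 10), 1:10), "degenerate")
  expect_error(loess_profile(1:3, 1:3), "4 points")
  expect_error(loess_profile(1:10, 1:10, span = 1.5), "span")
})

test_that("collapse-point estimation recovers programmed merge fractions", {
  for (f in c(0.5, 0.7)) {
    set.seed(round(100 * f))
    est <- replicate(6, {
      fx <- make_fixture("collapsing", collapse_fraction = f, jitter_sd = 1)
      collapse_point(fx, branches = fx$isl2)
    })
    expect_true(all(abs(est - f) <= 0.03 + 1e-9))
  }
  one <- make_fixture("single", seed = 2)
  expect_true(is.na(collapse_point(one)))
  dup <- make_fixture("duplicated", seed = 2)
  expect_true(is.na(collapse_point(dup, branches = dup$isl2)))
})

test_that("the KS statistic matches the empirical-CDF sweep oracle", {
  expect_equal(ks_compare(1:10, 1:10)$D, 0)
  expect_equal(ks_compare(c(1, 2, 3), c(4, 5, 6))$D, 1)
  set.seed(17)
  for (rep in 1:20) {
    a <- runif(sample(5:40, 1), 0, 100)
    b <- rnorm(sample(5:40, 1), 50, 30)
    got <- ks_compare(a, b)
    want <- suppressWarnings(stats::ks.test(a, b)$statistic)
    expect_equal(got$D, unname(want), tolerance = 1e-12)
    # rank statistic: invariant under a common monotone transform
    expect_equal(ks_compare(exp(a / 50), exp(b / 50))$D, got$D)
  }
  r <- ks_compare(runif(15), runif(100))
  expect_equal(r$critical, 1.358 * sqrt((15 + 100) / (15 * 100)),
               tolerance = 1e-12)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})
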