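test_that("tpm implements the count-per-million formula", {
  expect_equal(tpm(250, 1e6), 250)
  expect_equal(tpm(0, 123456), 0)
  expect_equal(tpm(5, 28557077), 5 / 28557077 * 1e6)
  expect_lt(abs(tpm(5, 28557077) - 0.17509), 5e-6)
  expect_error(tpm(1, 0), "positive")

  m <- matrix(c(10, 20, 30, 5, 5, 90), ncol = 2)
  tm <- tpm_matrix(m)
  expect_equal(unname(colSums(tm)), c(1e6, 1e6))
})

test_that("the exact count test matches its binomial limit and symmetries", {
  # perfectly balanced observation is the modal outcome
  expect_equal(exact_count_test(c(5, 5), c(5, 5), rep(1e4, 2), rep(1e4, 2)), 1)
  # all-zero rows return 1 by convention
  expect_equal(exact_count_test(c(0, 0), c(0, 0), rep(1e4, 2), rep(1e4, 2)), 1)
  # dispersion 0, pooled 12 vs 0 at equal depths: two-sided binomial tail
  p <- exact_count_test(12, 0, 1e4, 1e4, dispersion = 0)
  expect_equal(p, 2 * 0.5^12)
  # two-sidedness: swapping condition labels leaves p unchanged
  set.seed(61)
  for (i in 1:20) {
    a <- rpois(2, 40); b <- rpois(2, 60)
    t1 <- exact_count_test(a, b, c(1e5, 1.2e5), c(0.9e5, 1.1e5), 0.05)
    t2 <- exact_count_test(b, a, c(0.9e5, 1.1e5), c(1e5, 1.2e5), 0.05)
    expect_equal(t1, t2)
  }
  # invariance under uniform scaling of library sizes
  p1 <- exact_count_test(c(30, 35), c(20, 25), c(1e5, 1e5), c(1e5, 1e5), 0.02)
  p2 <- exact_count_test(c(30, 35), c(20, 25), c(5e5, 5e5), c(5e5, 5e5), 0.02)
  expect_equal(p1, p2)
})

test_that("p-values are monotone beyond the balanced point", {
  prev <- 1
  for (k in 10:40) {
    p <- exact_count_test(k, 10, 1e5, 1e5, dispersion = 0)
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
})

test_that("the exact test agrees with the reference implementation", {
  # independent cross-check against edgeR's exact test at a fixed common
  # dispersion and equal library sizes (where no pseudo-count adjustment
  # is needed and both reduce to the conditional NB double tail)
  library(edgeR)
  set.seed(62)
  counts <- matrix(rnbinom(400, mu = 80, size = 1 / 0.1), ncol = 4)
  rownames(counts) <- sprintf("g%03d", 1:100)
  group <- c("salt", "salt", "control", "control")
  d <- DGEList(counts = counts, group = factor(group, c("control", "salt")),
               lib.size = rep(1e5, 4))
  d$common.dispersion <- 0.1
  d$samples$norm.factors <- 1
  ref_p <- exactTest(d, dispersion = 0.1)$table$PValue
  our_p <- vapply(seq_len(nrow(counts)), function(i)
    exact_count_test(counts[i, 1:2], counts[i, 3:4],
                     rep(1e5, 2), rep(1e5, 2), dispersion = 0.1), 0)
  expect_lt(max(abs(our_p - ref_p)), 0.02)
  expect_gt(cor(our_p, ref_p), 0.999)
})

test_that("differential calls follow the ratio and threshold invariants", {
  counts <- rbind(up = c(800, 800, 100, 100),
                  flat = c(400, 410, 405, 395))
  cond <- c("salt", "salt", "control", "control")
  de <- call_differential(counts, cond, totals = rep(1e6, 4), dispersion = 0)
  expect_lt(abs(de$ratio[1] - 8), 0.05)
  expect_equal(de$mark[1], "UP")
  expect_equal(de$mark[2], "NS")
  # the mark invariant holds row by row
  expect_true(all(
    (de$mark == "UP") == (de$p_value <= 0.05 & de$ratio > 1) &
    (de$mark == "DOWN") == (de$p_value <= 0.05 & de$ratio < 1)))
  # pseudocount keeps ratios finite when a condition is all zero
  z <- rbind(only_salt = c(50, 60, 0, 0))
  dez <- call_differential(z, cond, totals = rep(1e6, 4), dispersion = 0)
  expect_true(is.finite(dez$ratio))
  expect_equal(dez$mark, "UP")
})

test_that("row scaling centers and normalizes, mapping constant rows to zero", {
  m <- rbind(a = c(1, 3), b = c(5, 5))
  s <- scaled_matrix(m)
  expect_equal(unname(s["a", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(s["b", ]), c(0, 0))
  set.seed(63)
  r <- matrix(rnorm(60), ncol = 6)
  sr <- scaled_matrix(r)
  expect_lt(max(abs(rowMeans(sr))), 1e-12)
  expect_equal(unname(apply(sr, 1, sd)), rep(1, 10), tolerance = 1e-12)
  expect_error(scaled_matrix(matrix(1, 2, 1)), "2 columns")
})

test_that("dispersion estimation recovers the simulation parameter", {
  truth <- count_truth(sprintf("m%04d", 1:1500))
  des <- sim_design(n_replicates = 2, library_depth = 500000,
                    nb_dispersion = 0.08, contaminant_fraction = 0, seed = 64)
  cnt <- simulate_counts(truth, des)
  est <- estimate_dispersion(cnt, attr(cnt, "condition"))
  expect_lt(abs(est - 0.08) / 0.08, 0.25)
  # Poisson data estimates near zero
  des0 <- sim_design(n_replicates = 2, library_depth = 500000,
                     nb_dispersion = 0, contaminant_fraction = 0, seed = 65)
  cnt0 <- simulate_counts(truth, des0)
  expect_lt(estimate_dispersion(cnt0, attr(cnt0, "condition")), 0.01)
})
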