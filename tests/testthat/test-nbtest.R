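test_that("identical groups give log2FC 0 and p 1", {
  res <- nbExactTest(c(5, 9, 3), c(5, 9, 3), dispersion = 0.1)
  expect_equal(res$log2FC, 0)
  expect_equal(res$p_value, 1)
  # both groups empty
  res0 <- nbExactTest(c(0, 0), c(0, 0), dispersion = 0.1)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$log2FC, 0)
})

test_that("the zero-dispersion limit is the conditional binomial exact test", {
  res <- nbExactTest(c(4, 6), c(40, 60), dispersion = 0)
  expect_equal(res$p_value, binom.test(10, 110, 0.5)$p.value,
               tolerance = 1e-9)
  set.seed(12)
  for (i in 1:10) {
    a <- rpois(2, 20); b <- rpois(2, 55)
    expect_equal(nbExactTest(a, b, dispersion = 0)$p_value,
                 binom.test(sum(a), sum(a) + sum(b), 0.5)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the test is symmetric under group exchange", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnbinom(4, mu = 20, size = 10)
    b <- rnbinom(4, mu = 35, size = 10)
    r1 <- nbExactTest(a, b, dispersion = 0.1)
    r2 <- nbExactTest(b, a, dispersion = 0.1)
    expect_equal(r1$log2FC, -r2$log2FC)
    expect_equal(r1$p_value, r2$p_value)
  }
})

test_that("p-values agree with the independent edgeR small-p exact test", {
  set.seed(14)
  A <- matrix(rnbinom(300 * 3, mu = 30, size = 1 / 0.15), 300)
  B <- matrix(rnbinom(300 * 3, mu = 30, size = 1 / 0.15), 300)
  p1 <- nbExactTest(A, B, dispersion = 0.15)$p_value
  p2 <- edgeR::exactTestBySmallP(B, A, dispersion = 0.15)
  expect_equal(p1, as.numeric(p2), tolerance = 1e-10)
})

test_that("moment dispersion estimators recover the simulated dispersion", {
  set.seed(15)
  phi <- 0.12
  m <- matrix(rnbinom(5000 * 12, mu = 40, size = 1 / phi), 5000)
  grp <- rep(c("A", "B"), each = 6)
  expect_equal(estimateCommonDispersion(m, grp), phi, tolerance = 0.1)
  trend <- estimateTrendedDispersion(m, grp)
  expect_equal(length(trend), 5000L)
  expect_equal(median(trend), phi, tolerance = 0.15)
})

test_that("trended dispersion tracks a mean-dependent variance", {
  set.seed(16)
  # low-abundance rows carry strong extra noise, high-abundance rows do not
  lowMu <- 10; hiMu <- 200
  low <- matrix(rnbinom(1000 * 8, mu = lowMu, size = 1 / 1.5), 1000)
  hi <- matrix(rnbinom(1000 * 8, mu = hiMu, size = 1 / 0.05), 1000)
  m <- rbind(low, hi)
  trend <- estimateTrendedDispersion(m, rep(c("A", "B"), each = 4))
  expect_gt(median(trend[1:1000]), 5 * median(trend[1001:2000]))
})

test_that("null p-values are calibrated at the thresholds used downstream", {
  set.seed(17)
  n <- 2000
  A <- matrix(rnbinom(n * 6, mu = 10, size = 10), n)
  B <- matrix(rnbinom(n * 6, mu = 10, size = 10), n)
  p <- nbExactTest(A, B)$p_value
  expect_gte(mean(p <= 0.05), 0.02)
  expect_lte(mean(p <= 0.05), 0.08)
})

test_that("low-read filtering keeps regions at the inclusive boundary", {
  m <- rbind(c(0, 0, 0), c(4, 3, 3), c(5, 4, 0))
  keep <- filterLowReads(m, minTotal = 10)
  expect_equal(keep, c(FALSE, TRUE, FALSE))
  expect_equal(filterLowReads(m, 0), rep(TRUE, 3))
})

test_that("DER calling applies inclusive p and strict fold-change bounds", {
  res <- data.frame(
    region = c("r1", "r2", "r3", "r4"),
    feature_class = "cpg_island",
    log2FC = c(0.6, 0.5, -0.8, 2),
    p_value = c(0.005, 0.005, 0.01, 0.2))
  out <- callDERs(res)
  expect_equal(out$table$passes, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$table$direction, c("gain", "gain", "loss", "gain"))
  expect_equal(out$summary$n_der, 2L)
  expect_equal(out$summary$gains + out$summary$losses, out$summary$n_der)
})
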