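# independent oracle: smallest k with CDF(k) >= target, by explicit scan of
# the binomial probability mass
scan_quantile <- function(target, n, p) {
  cdf <- cumsum(dbinom(0:n, n, p))
  (0:n)[which(cdf >= target - 1e-12)[1]]
}
scan_interval <- function(n, dosage, ploidy, conf = 0.95) {
  p <- dosage / ploidy
  a <- (1 - conf) / 2
  c(scan_quantile(a, n, p), scan_quantile(1 - a, n, p)) / n
}

test_that("exact interval matches the CDF-scan oracle over a grid", {
  grid <- expand.grid(depth = c(1:12, 20, 40, 59, 100, 137),
                      dp = I(list(c(1, 2), c(1, 4), c(2, 4), c(3, 4))),
                      conf = c(0.5, 0.9, 0.95, 0.99))
  for (i in seq_len(nrow(grid))) {
    d <- grid$depth[i]; dp <- grid$dp[[i]]; cf <- grid$conf[i]
    iv <- snp_index_interval(d, dp[1], dp[2], cf)
    expect_equal(c(iv$lo, iv$hi), scan_interval(d, dp[1], dp[2], cf),
                 info = sprintf("depth %d dosage %d/%d conf %.2f",
                                d, dp[1], dp[2], cf))
    # at conventional confidence the interval brackets the expected index
    # (a 50% central interval may legitimately exclude it at depth 1);
    # endpoints always sit on the 1/depth grid
    if (cf >= 0.9) {
      expect_lte(iv$lo, dp[1] / dp[2])
      expect_gte(iv$hi, dp[1] / dp[2])
    }
    expect_equal(iv$lo * d, round(iv$lo * d))
    expect_equal(iv$hi * d, round(iv$hi * d))
  }
})

test_that("diploid heterozygous intervals behave as reported at shallow depth", {
  iv6 <- snp_index_interval(6, 1, 2)
  expect_equal(iv6$lo, 1 / 6)
  expect_equal(iv6$hi, 5 / 6)
  expect_gt(iv6$lo, 0.16)
  expect_lt(iv6$hi, 0.84)
  iv5 <- snp_index_interval(5, 1, 2)
  expect_identical(c(iv5$lo, iv5$hi), c(0, 1))
  iv1 <- snp_index_interval(1, 1, 2)
  expect_identical(c(iv1$lo, iv1$hi), c(0, 1))
})

test_that("interval rejects invalid genotype parameters", {
  expect_error(snp_index_interval(10, 2, 2), "dosage")
  expect_error(snp_index_interval(10, 0, 2), "dosage")
  expect_error(snp_index_interval(10, 1, 2, confidence = 1), "confidence")
})

test_that("dosage symmetry: interval for d mirrors interval for ploidy-d", {
  for (d in c(5, 6, 20, 59, 100)) for (dos in 1:3) {
    a <- snp_index_interval(d, dos, 4)
    b <- snp_index_interval(d, 4 - dos, 4)
    expect_equal(a$lo, 1 - b$hi)
    expect_equal(a$hi, 1 - b$lo)
  }
})

test_that("interval width shrinks with depth along multiples", {
  for (dp in list(c(1, 2), c(1, 4))) {
    w <- vapply(c(10, 20, 40, 80, 160, 320), function(d) {
      iv <- snp_index_interval(d, dp[1], dp[2]); iv$hi - iv$lo
    }, numeric(1))
    expect_true(all(diff(w) <= 0))
    expect_lt(w[length(w)], 0.25)
  }
})

test_that("Monte-Carlo interval equals the exact interval on the quantile grid", {
  grid <- expand.grid(depth = c(5, 6, 20), dp = I(list(c(1, 2), c(1, 4),
                                                       c(2, 4), c(3, 4))))
  for (i in seq_len(nrow(grid))) {
    d <- grid$depth[i]; dp <- grid$dp[[i]]
    ex <- snp_index_interval(d, dp[1], dp[2])
    mc <- monte_carlo_interval(d, dp[1], dp[2],
                               replicates = mc_replicates(d), seed = 42L)
    expect_equal(c(mc$lo, mc$hi), c(ex$lo, ex$hi),
                 info = sprintf("depth %d dosage %d/%d", d, dp[1], dp[2]))
  }
})

test_that("tabulated empirical quantiles match the type-1 sample quantile", {
  mc <- monte_carlo_interval(20, 1, 4, replicates = 5e4, seed = 5L)
  draws <- armscaps:::with_seed(5L, rbinom(5e4, 20, 0.25)) / 20
  q <- unname(quantile(draws, c(0.025, 0.975), type = 1))
  expect_identical(c(mc$lo, mc$hi), q)
})

test_that("Monte-Carlo interval enforces its replicate floor and seed", {
  expect_error(monte_carlo_interval(6, 1, 2, replicates = 10), "replicates")
  a <- monte_carlo_interval(200, 1, 4, seed = 7L)
  b <- monte_carlo_interval(200, 1, 4, seed = 7L)
  expect_identical(a, b)
  expect_lte(a$lo, 0.25)
  expect_gte(a$hi, 0.25)
})

test_that("minimal depth separating heterozygous from homozygous is 6 (diploid)", {
  expect_identical(min_depth_excluding_homozygous(2, 1, 0.95), 6L)
  # brute-force oracle at lower confidence: scan depths directly
  brute <- function(conf) {
    for (d in 1:100) {
      iv <- scan_interval(d, 1, 2, conf)
      if (iv[1] > 0 && iv[2] < 1) return(d)
    }
  }
  expect_identical(min_depth_excluding_homozygous(2, 1, 0.5), brute(0.5))
  expect_lt(min_depth_excluding_homozygous(2, 1, 0.5), 6L)
  expect_error(min_depth_excluding_homozygous(2, 1, 1), "confidence")
})

test_that("autotetraploid dosage classes separate in the high-50s depth range", {
  d95 <- min_discernible_depth(4, 0.95)
  expect_gte(d95, 56L)
  expect_lte(d95, 62L)
  # all three dosage intervals pairwise disjoint at d95, not at d95 - 1
  disjoint <- function(d) {
    ivs <- lapply(1:3, function(k) snp_index_interval(d, k, 4))
    ivs[[1]]$hi < ivs[[2]]$lo && ivs[[2]]$hi < ivs[[3]]$lo
  }
  expect_true(disjoint(d95))
  expect_false(disjoint(d95 - 1L))
  expect_lt(min_discernible_depth(4, 0.5), d95)
  expect_error(min_discernible_depth(2), "ploidy")
})

test_that("interval table covers the requested grid", {
  tab <- snp_index_interval_table(c(6, 10), ploidy = 4)
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$lo <= tab$dosage / 4 & tab$hi >= tab$dosage / 4))
})
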