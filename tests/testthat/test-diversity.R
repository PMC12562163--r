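test_that("allele frequencies match a brute-force tally", {
  gt <- small_gt(list(c(150, 150), c(150, 154)))
  af <- allele_frequencies(gt)
  expect_equal(af$L1$freq, c(`150` = 0.75, `154` = 0.25))
  expect_equal(af$L1$n_typed, 2L)

  gt2 <- small_gt(list(c(0, 0), c(0, 0)))
  expect_true(allele_frequencies(gt2)$L1$excluded)

  cfg <- sim_config(seed = 13, n_pops = 3, n_per_pop = 20, n_loci = 4,
                    missing_rate = 0.1)
  g <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)
  af <- allele_frequencies(g, scope = "P02")
  rows <- which(g$pop == "P02")
  for (j in seq_along(g$loci)) {
    tally <- integer(0)
    for (i in rows) for (sl in 1:2) {
      a <- g$alleles[i, j, sl]
      if (a != 0L) tally <- c(tally, a)
    }
    expect_equal(af[[j]]$freq,
                 table(tally) / length(tally),
                 ignore_attr = TRUE)
    expect_equal(names(af[[j]]$freq), names(table(tally)))
  }
})

test_that("closed forms hold at equifrequency and paper-style inputs", {
  gt <- small_gt(list(c(150, 154), c(150, 154), c(150, 150), c(154, 154)))
  ls <- locus_stats(gt, hwe = "none")
  expect_equal(ls$Na, 2L)
  expect_equal(ls$Ne, 2)
  expect_equal(ls$He, 0.5)
  expect_equal(ls$I, log(2))
  expect_equal(ls$PIC, 0.375)
  expect_equal(ls$Ho, 0.5)
  expect_equal(ls$F, 0)
})

test_that("the F identity reproduces the published nine-locus rows", {
  ref <- snail_reference("locus_stats")
  expect_equal(inbreeding_coefficient(0.484, 0.74), 0.346, tolerance = 1e-3)
  expect_equal(inbreeding_coefficient(0.474, 0.727), 0.348, tolerance = 1e-3)
  f_all <- inbreeding_coefficient(ref$Ho, ref$He)
  expect_lt(max(abs(f_all - ref$F)), 2e-3)   # printed values are 3-decimal
})

test_that("He equals 1 - 1/Ne algebraically and on random frequency vectors", {
  set.seed(17)
  for (r in 1:200) {
    k <- sample(2:15, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    he <- 1 - sum(p^2)
    ne <- 1 / sum(p^2)
    expect_equal(he, 1 - 1 / ne, tolerance = 1e-12)
  }
})

test_that("PIC < He < 1 and I <= log(Na) with equality iff equifrequent", {
  set.seed(19)
  for (r in 1:500) {
    k <- sample(2:12, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    sp2 <- sum(p^2)
    he <- 1 - sp2
    pic <- 1 - sp2 - (sp2^2 - sum(p^4))
    I <- -sum(p * log(p))
    expect_lt(pic, he)
    expect_lt(he, 1)
    expect_lte(I, log(k) + 1e-12)
  }
  p <- rep(1 / 5, 5)
  expect_equal(-sum(p * log(p)), log(5))
})

test_that("monomorphic loci report He = 0 and missing F with a warning", {
  gt <- small_gt(list(c(150, 150), c(150, 150)))
  expect_warning(ls <- locus_stats(gt, hwe = "none"), "monomorphic")
  expect_equal(ls$He, 0)
  expect_true(is.na(ls$F))
})

test_that("HWE chi-square is zero at exact proportions and n at full deficit", {
  a1 <- c(rep(1, 25), rep(1, 50), rep(2, 25))
  a2 <- c(rep(1, 25), rep(2, 50), rep(2, 25))
  h <- hwe_test(a1, a2)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  expect_equal(h$df, 1)

  b1 <- c(rep(1, 50), rep(2, 50))
  b2 <- b1
  hb <- hwe_test(b1, b2)
  expect_equal(hb$chi2, 100)          # n for complete heterozygote deficit
  expect_lt(hb$p, 0.001)

  expect_error(hwe_test(rep(1, 5), rep(1, 5)), "monomorphic")
})

test_that("HWE chi-square type-I error is calibrated near 0.05", {
  set.seed(5)
  rej <- mean(replicate(1000, {
    p <- c(0.5, 0.3, 0.2)
    g <- replicate(200, sample(1:3, 2, replace = TRUE, prob = p))
    hwe_test(g[1, ], g[2, ])$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Monte-Carlo HWE p agrees with chi-square p on a clear deficit", {
  set.seed(8)
  g <- replicate(120, sample(1:2, 2, replace = TRUE, prob = c(0.6, 0.4)))
  h1 <- hwe_test(g[1, ], g[2, ], method = "chi2")
  h2 <- hwe_test(g[1, ], g[2, ], method = "mc", mc_reps = 2000, seed = 42)
  expect_equal(h1$chi2, h2$chi2)
  expect_lt(abs(h1$p - h2$p), 0.08)
  expect_error(hwe_test(g[1, ], g[2, ], method = "mc"), "seed")
})

test_that("population summary equals pooled stats for a single population", {
  cfg <- sim_config(seed = 29, n_pops = 1, n_per_pop = 40, n_loci = 5,
                    planted_f = 0.2)
  g <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)
  ps <- population_summary(g)
  ls <- suppressWarnings(locus_stats(g, hwe = "none"))
  expect_equal(ps$Na, mean(ls$Na))
  expect_equal(ps$He, mean(ls$He))
  expect_equal(ps$Ho, mean(ls$Ho))
  expect_equal(nrow(ps), 1L)
})

test_that("pooled summary uses unweighted across-locus means", {
  cfg <- sim_config(seed = 37, n_pops = 4, n_per_pop = 15, n_loci = 6)
  g <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)
  su <- pooled_summary(g, hwe = "none")
  m <- attr(su, "means")
  expect_equal(unname(m["Na"]), mean(su$Na))
  expect_equal(unname(m["F"]), mean(su$F, na.rm = TRUE))
  # within-population mean He never exceeds pooled He (Wahlund)
  expect_true(all(su$mean_He_within <= su$He + 1e-9))
})

test_that("planted inbreeding is recovered by 1 - Ho/He", {
  fh <- vapply(1:8, function(r) {
    cfg <- sim_config(seed = 4000 + r, n_pops = 1, n_per_pop = 360,
                      planted_f = 0.39)
    g <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)
    mean(suppressWarnings(locus_stats(g, hwe = "none"))$F, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fh) - 0.39), 0.05)
})
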