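test_that("gene flow follows the island-model identity and is decreasing", {
  expect_equal(round(nm_from_fst(0.017), 3), 14.456)
  expect_equal(round(nm_from_fst(0.409), 3), 0.361)
  expect_equal(nm_from_fst(0.2), 1)
  expect_equal(nm_from_fst(1), 0)
  expect_identical(nm_from_fst(0), Inf)
  expect_error(nm_from_fst(-0.1), "nonnegative")
  x <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(nm_from_fst(x)) < 0))
})

test_that("theta is near zero without differentiation and one at fixation", {
  set.seed(61)
  al <- array(0L, dim = c(400, 1, 2))
  al[, 1, 1] <- sample(c(100L, 104L), 400, replace = TRUE)
  al[, 1, 2] <- sample(c(100L, 104L), 400, replace = TRUE)
  gt <- genotype_table(rep(c("A", "B"), each = 200),
                       paste0("i", 1:400), al, "L1")
  expect_lt(abs(pairwise_fst(gt, "A", "B")), 0.02)

  al2 <- array(0L, dim = c(40, 1, 2))
  al2[1:20, 1, ] <- 100L
  al2[21:40, 1, ] <- 104L
  gt2 <- genotype_table(rep(c("A", "B"), each = 20),
                        paste0("i", 1:40), al2, "L1")
  expect_equal(pairwise_fst(gt2, "A", "B"), 1)
  expect_equal(pairwise_fst(gt2, "A", "B", estimator = "nei"), 1)
})

test_that("theta recovers planted Fst at study scale", {
  for (target in c(0.05, 0.409)) {
    th <- vapply(1:8, function(r) {
      cfg <- sim_config(seed = round(10000 * target) + r,
                        planted_fst = target, planted_f = 0)
      wc_theta(simulate_genotypes(simulate_allele_freqs(cfg), cfg))
    }, numeric(1))
    expect_lt(abs(mean(th) - target), 0.05)
  }
})

test_that("Nei 1972 distance matches the hand-computed example", {
  # one locus, p_a = (.5,.5), p_b = (.9,.1): D = -ln(.5/sqrt(.41))
  al <- array(0L, dim = c(20, 1, 2))
  al[1:10, 1, 1] <- rep(c(100L, 104L), 5)
  al[1:10, 1, 2] <- rep(c(100L, 104L), each = 5)
  # pop B: 18 copies of 100, 2 of 104
  al[11:20, 1, 1] <- 100L
  al[11:20, 1, 2] <- c(rep(100L, 8), 104L, 104L)
  gt <- genotype_table(rep(c("A", "B"), each = 10), paste0("i", 1:20),
                       al, "L1")
  expect_equal(nei_distance(gt, "A", "B"), -log(0.5 / sqrt(0.41)),
               tolerance = 1e-12)
  expect_equal(round(nei_distance(gt, "A", "B"), 4), 0.2473)
  expect_equal(nei_distance(gt, "A", "A"), 0)

  # disjoint support -> infinite sentinel
  al2 <- array(0L, dim = c(4, 1, 2))
  al2[1:2, 1, ] <- 100L
  al2[3:4, 1, ] <- 104L
  gt2 <- genotype_table(rep(c("A", "B"), each = 2), paste0("j", 1:4),
                        al2, "L1")
  expect_identical(nei_distance(gt2, "A", "B"), Inf)
  expect_error(upgma(suppressWarnings(nei_distance_matrix(gt2))),
               "non-finite")
})

test_that("UPGMA reproduces the hand example and ultrametric fixed point", {
  d <- dist_matrix(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3),
                   c("A", "B", "C"))
  tr <- upgma(d)
  expect_equal(sort(tr$heights), c(1, 3))
  expect_equal(unclass(cophenetic_upgma(tr)), unclass(d),
               ignore_attr = TRUE)
  txt <- write_newick(tr)
  phy <- ape::read.tree(text = txt)
  expect_true(ape::is.ultrametric(phy))

  set.seed(71)
  dm <- random_dist_matrix(8)
  tr1 <- upgma(dm)
  fix <- upgma(cophenetic_upgma(tr1))
  expect_equal(unclass(cophenetic_upgma(fix)),
               unclass(cophenetic_upgma(tr1)), tolerance = 1e-12)
})

test_that("UPGMA equals the naive reference and average-linkage hclust", {
  set.seed(83)
  for (r in 1:30) {
    n <- sample(4:15, 1)
    dm <- random_dist_matrix(n)
    tr <- upgma(dm)
    expect_equal(unclass(cophenetic_upgma(tr)),
                 naive_upgma_cophenetic(unclass(dm)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    hc <- stats::hclust(stats::as.dist(unclass(dm)), method = "average")
    expect_equal(unclass(cophenetic_upgma(tr))[dm |> rownames(), dm |> rownames()],
                 as.matrix(stats::cophenetic(hc))[rownames(dm), rownames(dm)],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("AMOVA df identity holds and clone populations give zero among", {
  cfg <- sim_config(seed = 101, n_pops = 5, n_per_pop = c(8))
  g <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)
  res <- amova(g)
  expect_equal(res$table$df[1] + res$table$df[2], res$table$df[3])
  expect_equal(res$pct_among + res$pct_within, 100)
  expect_gt(res$sigma2_w, 0)

  # identical clone populations: no among-population variance
  al <- array(rep(c(100L, 104L), each = 24), dim = c(24, 1, 2))
  gt <- genotype_table(rep(c("A", "B", "C"), each = 8), paste0("i", 1:24),
                       al, "L1")
  res0 <- amova(gt)
  expect_equal(res0$pct_among, 0)
  expect_equal(res0$phi_pt, 0)
})

test_that("AMOVA permutation p is high under exchangeability, low under structure", {
  cfg <- sim_config(seed = 107, n_pops = 4, n_per_pop = 12, n_loci = 4,
                    planted_fst = 0.3, planted_f = 0)
  g <- simulate_genotypes(simulate_allele_freqs(cfg), cfg)
  res <- amova(g, permutations = 199, seed = 1)
  expect_lt(res$p_value, 0.05)
  expect_error(amova(g, permutations = 10), "seed")
})

test_that("PCoA round-trips Euclidean configurations", {
  set.seed(113)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(stats::dist(X))
  dm <- dist_matrix(D, paste0("p", 1:10))
  pc <- pcoa(dm)
  expect_lte(length(pc$eigenvalues), 2L)
  Dhat <- as.matrix(stats::dist(pc$coordinates))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-9)
  # agrees with classical scaling in stats
  cs <- stats::cmdscale(D, k = 2)
  expect_equal(abs(unname(pc$coordinates[, 1:2])), abs(unname(cs)),
               tolerance = 1e-6)
  # duplicate points map to identical coordinates
  D2 <- as.matrix(stats::dist(X[c(1, 1, 2:10), ]))
  pc2 <- pcoa(dist_matrix(D2, paste0("q", 1:11)))
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ], tolerance = 1e-9)

  # collinear points give a single positive axis
  D3 <- as.matrix(stats::dist(c(0, 1, 3)))
  pc3 <- pcoa(dist_matrix(D3, c("a", "b", "c")))
  expect_equal(length(pc3$eigenvalues), 1L)
  expect_equal(as.numeric(stats::dist(pc3$coordinates)),
               as.numeric(stats::dist(c(0, 1, 3))), tolerance = 1e-9)
})

test_that("Evanno delta K follows the second-difference formula", {
  res <- evanno_delta_k(1:4, c(-100, -80, -75, -74), rep(1, 4))
  expect_equal(res$delta_k, c(NA, 15, 4, NA))
  expect_equal(attr(res, "best_k"), 2L)

  lin <- evanno_delta_k(1:5, seq(-100, -60, by = 10), rep(1, 5))
  expect_equal(lin$delta_k[2:4], c(0, 0, 0))

  expect_error(evanno_delta_k(1:4, c(-4, -3, -2, -1), c(1, 0, 1, 1)), "sd")
  expect_error(evanno_delta_k(c(1, 3, 4), c(-3, -2, -1), rep(1, 3)),
               "contiguous")
  expect_error(evanno_delta_k(1:2, c(-2, -1), c(1, 1)), "three")
})

test_that("published Fst/Nm matrix satisfies the island-model identity", {
  m <- snail_reference("fst_nm")
  parts <- split_fst_nm(m)
  fst <- parts$fst[lower.tri(parts$fst)]
  nm <- parts$nm[lower.tri(parts$nm)]
  expect_equal(length(fst), 66L)
  expect_lt(max(abs(nm_from_fst(fst) - nm)), 1e-3)
})
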