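test_that("motif canonicalization picks the smallest rotation/revcomp", {
  expect_equal(canonical_motif("GT"), "AC")
  expect_equal(canonical_motif("ATT"), "AAT")
  expect_equal(canonical_motif("TCTA"), "AGAT")
  expect_equal(canonical_motif("a"), "A")
  expect_error(canonical_motif("ACAC"), "degenerate")
  expect_error(canonical_motif("AAA"), "degenerate")
  expect_error(canonical_motif("ACX"), "A,C,G,T")
})

test_that("canonicalization is constant on the rotation/revcomp class", {
  rc <- function(m) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(m, "")[[1]]), collapse = ""))
  rot <- function(m, i) paste0(substring(m, i + 1, nchar(m)), substring(m, 1, i))
  set.seed(1)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    if (is_degenerate_motif(m)) next
    canon <- canonical_motif(m)
    for (i in seq_len(k) - 1L) {
      expect_equal(canonical_motif(rot(m, i)), canon)
      expect_equal(canonical_motif(rot(rc(m), i)), canon)
    }
  }
})

test_that("threshold boundaries match the per-size minimum repeat counts", {
  hit <- detect_ssrs("ACACACACACAC")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "AC")
  expect_equal(hit$repeats, 6L)
  expect_equal(c(hit$start, hit$end), c(0L, 12L))

  expect_equal(nrow(detect_ssrs("ACACACACAC")), 0L)     # 5 copies < 6

  mono <- detect_ssrs("AAAAAAAAAA")
  expect_equal(mono$motif, "A")
  expect_equal(mono$repeats, 10L)
  expect_equal(nrow(detect_ssrs("AAAAAAAAA")), 0L)      # 9 copies < 10

  for (k in 3:6) {
    motif <- substr("ACGTAG", 1, k)
    expect_equal(detect_ssrs(strrep(motif, 5))$repeats, 5L)
    expect_equal(nrow(detect_ssrs(strrep(motif, 4))), 0L)
  }
})

test_that("partial trailing copies are excluded and N breaks runs", {
  hit <- detect_ssrs(paste0(strrep("AGAT", 6), "AGA"))
  expect_equal(hit$end - hit$start, hit$repeats * 4L)
  expect_equal(hit$repeats, 6L)

  two <- detect_ssrs(paste0(strrep("AC", 7), "N", strrep("AC", 6)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$repeats, c(7L, 6L))

  expect_equal(nrow(detect_ssrs(strrep("N", 30))), 0L)
})

test_that("detected loci re-scan to themselves (idempotence)", {
  set.seed(7)
  for (r in 1:10) {
    s <- paste0(random_dna(300), strrep("AAT", 8), random_dna(300))
    loci <- detect_ssrs(s)
    for (i in seq_len(nrow(loci))) {
      sub <- substr(s, loci$start[i] + 1L, loci$end[i])
      again <- detect_ssrs(sub)
      expect_equal(nrow(again), 1L)
      expect_equal(again$start, 0L)
      expect_equal(again$end, nchar(sub))
      expect_equal(again$motif, loci$motif[i])
    }
  }
})

test_that("scanner equals the exhaustive brute-force oracle on random DNA", {
  set.seed(202)
  for (r in 1:40) {
    L <- sample(500:2000, 1)
    s <- random_dna(L, p_n = 0.03)
    salt <- paste0(strrep("AC", sample(6:9, 1)), random_dna(40),
                   strrep("AAAT", 5))
    pos <- sample(L - 100, 1)
    s <- paste0(substr(s, 1, pos), salt, substr(s, pos + 1, L))
    a <- detect_ssrs(s)
    b <- oracle_ssrs(s)
    expect_identical(a$start, b$start)
    expect_identical(a$end, b$end)
    expect_identical(a$motif, b$motif)
    expect_identical(a$repeats, b$repeats)
  }
})

test_that("compound grouping chains at the interval boundary", {
  gapfill <- function(n) substr(strrep("ACGGTCA", 20), 1, n)   # SSR-free
  mk <- function(gap) paste0(strrep("AAT", 6), gapfill(gap), strrep("AGAT", 6))
  loci100 <- group_compound(detect_ssrs(mk(100)), 100)
  expect_true(all(!is.na(loci100$compound_id)))
  expect_equal(length(unique(loci100$compound_id)), 1L)

  loci101 <- group_compound(detect_ssrs(mk(101)), 100)
  expect_true(all(is.na(loci101$compound_id)))

  chain <- paste0(strrep("AAT", 6), gapfill(10), strrep("AGAT", 6),
                  gapfill(10), strrep("AC", 7))
  loci3 <- group_compound(detect_ssrs(chain), 100)
  expect_equal(sum(!is.na(loci3$compound_id)), 3L)
  expect_equal(length(unique(stats::na.omit(loci3$compound_id))), 1L)
})

test_that("census computes both occurrence frequencies and consistent types", {
  seqs <- seq_set(c(paste0(strrep("ACGGTCA", 10), strrep("AAT", 6)),
                    strrep("ACGGTCA", 10),
                    paste0(strrep("AC", 8), strrep("ACGGTCA", 20),
                           strrep("AGAT", 5))),
                  c("s1", "s2", "s3"))
  loci <- group_compound(detect_ssrs_all(seqs), 100)
  cz <- ssr_census(seqs, loci)
  expect_equal(cz$n_sequences_examined, 3L)
  expect_equal(cz$n_ssr, 3L)
  expect_equal(cz$n_sequences_with_ssr, 2L)
  expect_equal(cz$n_sequences_with_multiple_ssr, 1L)
  expect_equal(cz$pct_sequences_with_ssr, 100 * 2 / 3)
  expect_equal(cz$ssr_per_100_sequences, 100)
  expect_equal(sum(cz$by_type$n), cz$n_ssr)
  expect_equal(sum(cz$by_type$pct), 100)
  expect_equal(sum(cz$repeat_bins), cz$n_ssr)

  one <- seq_set(strrep("AAT", 6), "only")
  cz1 <- ssr_census(one, group_compound(detect_ssrs_all(one), 100))
  expect_equal(cz1$pct_sequences_with_ssr, 100)
  expect_equal(cz1$ssr_per_100_sequences, 100)

  expect_error(ssr_census(character(0), loci), "no sequences")
})
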