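# Synthetic data with the statistical structure the analyses assume:
# Balding-Nichols allele frequencies at a planted Fst, an inbreeding mixture
# for genotypes, and FASTA sequences with planted SSR loci and flank-sharing
# allele families. All generators are pure functions of (config, seed).

#' Simulation configuration
#'
#' Defaults emulate the study design the analyses are built for: 12
#' populations x 30 diploids x 9 loci, a planted Fst of 0.175 and planted
#' inbreeding of 0.390. Sequence simulation defaults produce flank-sharing
#' allele families with 40 bp flanks (so a flank-SSR-flank amplicon clears
#' the 100 bp product minimum) against an SSR-free background.
#'
#' @param seed Integer seed (mandatory; every generator takes the config).
#' @param n_pops,n_per_pop,n_loci Genotype design.
#' @param n_alleles Ancestral allele count per locus.
#' @param planted_fst Balding-Nichols Fst in (0, 1).
#' @param planted_f Inbreeding coefficient in [0, 1).
#' @param missing_rate Fraction of calls erased to (0,0).
#' @param allele_step Spacing of allele fragment sizes in bp (3 or 4 matches
#'   tri-/tetranucleotide markers).
#' @param n_families,variants_per_family,flank_len Sequence-family design.
#' @param motifs Candidate motifs for planted SSRs (canonical, non-degenerate).
#' @param repeat_range Repeat-count range for planted SSRs.
#' @param n_background,background_len Background sequences without SSRs.
#' @param gc Background GC content.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(seed,
                       n_pops = 12L, n_per_pop = 30L, n_loci = 9L,
                       n_alleles = 10L,
                       planted_fst = 0.175, planted_f = 0.390,
                       missing_rate = 0,
                       allele_step = 4L,
                       n_families = 10L, variants_per_family = 5L,
                       flank_len = 40L,
                       motifs = c("AAT", "AGAT", "AC", "ATCC", "ACTA"),
                       repeat_range = c(8L, 14L),
                       n_background = 20L, background_len = 300L,
                       gc = 0.4) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(planted_fst > 0, planted_fst < 1,
            planted_f >= 0, planted_f < 1,
            missing_rate >= 0, missing_rate < 1,
            flank_len >= 20L, n_alleles >= 2L,
            repeat_range[1L] >= 5L, gc > 0, gc < 1)
  cfg <- list(seed = as.integer(seed), n_pops = n_pops, n_per_pop = n_per_pop,
              n_loci = n_loci, n_alleles = n_alleles,
              planted_fst = planted_fst, planted_f = planted_f,
              missing_rate = missing_rate, allele_step = allele_step,
              n_families = n_families,
              variants_per_family = variants_per_family,
              flank_len = flank_len, motifs = motifs,
              repeat_range = repeat_range, n_background = n_background,
              background_len = background_len, gc = gc)
  for (m in motifs) canonical_motif(m)   # rejects degenerate motifs
  structure(cfg, class = "sim_config")
}

# Dirichlet draw via rgamma
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Balding-Nichols population allele frequencies
#'
#' For each locus an ancestral frequency vector is drawn from a uniform
#' Dirichlet; each population's frequencies are then drawn from
#' \code{Dirichlet(p * (1 - Fst) / Fst)}. Draws with a numerically zero
#' component are resampled with a warning.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{ancestral} (matrix loci x alleles) and
#'   \code{freqs} (array pops x loci x alleles); allele fragment sizes in
#'   \code{allele_sizes} (loci x alleles).
#' @export
simulate_allele_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    K <- config$n_alleles
    anc <- matrix(0, config$n_loci, K)
    freqs <- array(0, dim = c(config$n_pops, config$n_loci, K))
    lambda <- (1 - config$planted_fst) / config$planted_fst
    for (j in seq_len(config$n_loci)) {
      repeat {
        p <- .rdirichlet(rep(1, K))
        if (all(p > 1e-6)) break
        warning("degenerate ancestral frequency resampled")
      }
      anc[j, ] <- p
      for (i in seq_len(config$n_pops)) {
        repeat {
          q <- .rdirichlet(p * lambda)
          if (all(is.finite(q)) && sum(q) > 0) break
        }
        freqs[i, j, ] <- q
      }
    }
    sizes <- matrix(0L, config$n_loci, K)
    for (j in seq_len(config$n_loci)) {
      base <- 100L + 20L * j
      sizes[j, ] <- base + config$allele_step * (seq_len(K) - 1L)
    }
    list(ancestral = anc, freqs = freqs, allele_sizes = sizes,
         pops = paste0("P", sprintf("%02d", seq_len(config$n_pops))),
         loci = paste0("L", sprintf("%02d", seq_len(config$n_loci))))
  })
}

#' Simulate diploid genotypes under an inbreeding mixture
#'
#' Per individual and locus: with probability \code{planted_f} a single allele
#' is drawn and duplicated (autozygous call), otherwise two alleles are drawn
#' independently from the population's frequencies. \code{missing_rate}
#' erases calls to (0,0). The RNG stream is a pure function of
#' \code{config$seed} (offset so frequency and genotype draws are
#' independent).
#'
#' @param freqs Result of \code{\link{simulate_allele_freqs}}.
#' @param config The same \code{\link{sim_config}}.
#' @return A \code{\link{genotype_table}} with allele codes equal to fragment
#'   sizes in bp.
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed + 1000003L, {
    np <- config$n_pops; ni <- config$n_per_pop; nl <- config$n_loci
    N <- np * ni
    pop <- rep(freqs$pops, each = ni)
    ind <- paste0(pop, "_", rep(sprintf("%03d", seq_len(ni)), times = np))
    alleles <- array(0L, dim = c(N, nl, 2L))
    for (i in seq_len(np)) {
      rows <- (i - 1L) * ni + seq_len(ni)
      for (j in seq_len(nl)) {
        q <- freqs$freqs[i, j, ]
        sizes <- freqs$allele_sizes[j, ]
        auto <- stats::runif(ni) < config$planted_f
        a1 <- sample(sizes, ni, replace = TRUE, prob = q)
        a2 <- sample(sizes, ni, replace = TRUE, prob = q)
        a2[auto] <- a1[auto]
        alleles[rows, j, 1L] <- a1
        alleles[rows, j, 2L] <- a2
      }
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(N * nl) < config$missing_rate, N, nl)
      for (j in seq_len(nl)) {
        alleles[drop[, j], j, ] <- 0L
      }
    }
    genotype_table(pop, ind, alleles, freqs$loci)
  })
}

# random background base sampler
.rand_seq <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# identity between two flank strings (ungapped, same length): fraction equal
.flank_identity <- function(a, b) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  mean(x == y)
}

#' Simulate FASTA sequences with planted SSR loci
#'
#' Emits \code{n_background} sequences carrying no SSR above the scanner
#' thresholds (rejection-sampled), plus \code{n_families} flank-sharing
#' families whose members differ only in SSR repeat count
#' (\code{variants_per_family} distinct lengths). Flanks of different
#' families are kept below 0.8 ungapped identity by rejection. The ground
#' truth lists every planted locus.
#'
#' @param config A \code{\link{sim_config}}.
#' @param min_repeats Scanner thresholds used for the SSR-free background
#'   check.
#' @return List with \code{seqs} (named character vector) and \code{truth}
#'   (data.frame: seq_id, family, start, end, motif, repeats).
#' @export
simulate_ssr_sequences <- function(config, min_repeats = default_min_repeats()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed + 2000003L, {
    seqs <- character(0); ids <- character(0)
    truth <- list()
    # background without SSRs
    if (config$n_background > 0L) {
      for (b in seq_len(config$n_background)) {
        repeat {
          s <- .rand_seq(config$background_len, config$gc)
          if (nrow(detect_ssrs(s, min_repeats = min_repeats)) == 0L) break
        }
        ids <- c(ids, sprintf("bg%03d", b))
        seqs <- c(seqs, s)
      }
    }
    # flank-sharing families
    fl <- config$flank_len
    flank_pairs <- list()
    for (fam in seq_len(config$n_families)) {
      motif <- sample(config$motifs, 1L)
      reps0 <- sample(seq(config$repeat_range[1L], config$repeat_range[2L]), 1L)
      repeat {
        left <- .rand_seq(fl, config$gc)
        right <- .rand_seq(fl, config$gc)
        ok <- nrow(detect_ssrs(paste0(left, right),
                               min_repeats = min_repeats)) == 0L
        if (ok && !is_degenerate_motif(motif)) {
          # no accidental motif copies adjoining the planted run
          probe <- paste0(left, strrep(motif, reps0), right)
          hits <- detect_ssrs(probe, min_repeats = default_min_repeats())
          ok <- nrow(hits) == 1L &&
            hits$start[1L] == fl && hits$end[1L] == fl + reps0 * nchar(motif)
        }
        if (ok) {
          sim <- vapply(flank_pairs, function(fp) {
            max(.flank_identity(left, fp[1L]), .flank_identity(right, fp[2L]))
          }, numeric(1L))
          if (all(sim < 0.8)) break
        }
      }
      flank_pairs[[fam]] <- c(left, right)
      reps_set <- reps0 + seq_len(config$variants_per_family) - 1L
      for (v in seq_along(reps_set)) {
        id <- sprintf("fam%02d_v%02d", fam, v)
        run <- strrep(motif, reps_set[v])
        s <- paste0(left, run, right)
        ids <- c(ids, id)
        seqs <- c(seqs, s)
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = id, family = fam, start = fl,
          end = fl + nchar(run), motif = motif, repeats = reps_set[v],
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_id = character(), family = integer(), start = integer(),
                 end = integer(), motif = character(), repeats = integer())
    list(seqs = seq_set(seqs, ids), truth = truth)
  })
}
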