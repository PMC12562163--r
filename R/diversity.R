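# Codominant diversity indices: allele frequencies, Na, Ne, Shannon I, Ho,
# He (Nei gene diversity, uncorrected), Botstein PIC, inbreeding F = 1-Ho/He,
# and the Hardy-Weinberg chi-square / Monte-Carlo test.

#' Allele frequencies at every locus
#'
#' Counts both alleles of every nonmissing call. \code{scope} restricts the
#' tally to one population or pools over all individuals.
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param scope \code{"pooled"} (default) or a population label.
#' @return Named list over loci; each element has \code{freq} (named numeric,
#'   names are allele codes), \code{n_typed} (diploid individuals with data)
#'   and \code{excluded} (TRUE when no individual is typed).
#' @export
allele_frequencies <- function(gt, scope = "pooled") {
  stopifnot(inherits(gt, "genotype_table"))
  if (identical(scope, "pooled")) {
    rows <- seq_along(gt$individual)
  } else {
    if (!scope %in% levels(gt$pop)) stop("unknown population '", scope, "'")
    rows <- which(gt$pop == scope)
  }
  out <- lapply(seq_along(gt$loci), function(j) {
    a <- c(gt$alleles[rows, j, 1L], gt$alleles[rows, j, 2L])
    typed <- gt$alleles[rows, j, 1L] != 0L
    a <- a[a != 0L]
    if (length(a) == 0L) {
      return(list(freq = numeric(0), n_typed = 0L, excluded = TRUE))
    }
    tab <- table(a)
    list(freq = stats::setNames(as.numeric(tab) / length(a), names(tab)),
         n_typed = sum(typed), excluded = FALSE)
  })
  names(out) <- gt$loci
  out
}

# internal: frequencies as named numeric for one locus/scope
.freq_vec <- function(af) af$freq

#' Per-locus diversity indices
#'
#' Computes, from allele frequencies \eqn{p_i} and the genotypes at the locus:
#' Na (observed alleles), Ne = 1/sum(p^2) (effective alleles), Shannon's
#' I = -sum(p log p), Ho (observed heterozygote fraction), He = 1 - sum(p^2)
#' (Nei gene diversity, no small-sample correction, so He = 1 - 1/Ne holds
#' exactly), Botstein's PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2, the
#' inbreeding coefficient F = 1 - Ho/He, and the Hardy-Weinberg test.
#' An unbiased He (2n/(2n-1) correction) is reported as \code{He_unbiased}.
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param scope \code{"pooled"} or a population label.
#' @param hwe \code{"chi2"} (default), \code{"mc"} for a Monte-Carlo test, or
#'   \code{"none"}.
#' @param mc_reps Permutation count for the Monte-Carlo test.
#' @param seed Seed for the Monte-Carlo test (required when \code{hwe="mc"}).
#' @return Data.frame of class \code{"locus_stats"}, one row per locus with
#'   data: \code{locus, n_typed, Na, Ne, I, Ho, He, He_unbiased, PIC, F,
#'   hwe_chi2, hwe_df, hwe_p}. Monomorphic loci get \code{He = 0} and
#'   \code{F = NA} with a warning.
#' @export
locus_stats <- function(gt, scope = "pooled", hwe = c("chi2", "mc", "none"),
                        mc_reps = 999L, seed = NULL) {
  hwe <- match.arg(hwe)
  af <- allele_frequencies(gt, scope)
  rows <- if (identical(scope, "pooled")) seq_along(gt$individual) else
    which(gt$pop == scope)
  res <- lapply(seq_along(gt$loci), function(j) {
    f <- af[[j]]
    if (f$excluded) return(NULL)
    p <- f$freq
    a1 <- gt$alleles[rows, j, 1L]; a2 <- gt$alleles[rows, j, 2L]
    typed <- a1 != 0L
    a1 <- a1[typed]; a2 <- a2[typed]
    n <- length(a1)
    Na <- length(p)
    sp2 <- sum(p^2)
    Ne <- 1 / sp2
    I <- -sum(p * log(p))
    Ho <- mean(a1 != a2)
    He <- 1 - sp2
    Heu <- if (n > 0L) (2 * n / (2 * n - 1)) * He else NA_real_
    PIC <- 1 - sp2 - (sp2^2 - sum(p^4))
    Fis <- inbreeding_coefficient(Ho, He)
    if (is.na(Fis))
      warning("monomorphic locus '", gt$loci[j], "': F undefined", call. = FALSE)
    h <- if (hwe == "none" || Na < 2L) {
      list(chi2 = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      hwe_test(a1, a2, method = hwe, mc_reps = mc_reps, seed = seed)
    }
    data.frame(locus = gt$loci[j], n_typed = n, Na = Na, Ne = Ne, I = I,
               Ho = Ho, He = He, He_unbiased = Heu, PIC = PIC, F = Fis,
               hwe_chi2 = h$chi2, hwe_df = h$df, hwe_p = h$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  class(res) <- c("locus_stats", "data.frame")
  res
}

#' @export
print.locus_stats <- function(x, digits = 3, ...) {
  cat("Per-locus diversity (", nrow(x), " loci)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  num <- c("Na", "Ne", "I", "Ho", "He", "PIC", "F")
  cat("Unweighted means:\n")
  print(round(colMeans(x[num], na.rm = TRUE), digits))
  invisible(x)
}

#' Inbreeding coefficient from observed and expected heterozygosity
#'
#' \code{F = 1 - Ho/He}; positive values indicate a heterozygote deficit.
#'
#' @param ho Observed heterozygosity.
#' @param he Expected heterozygosity (> 0).
#' @return F value(s); \code{NA} where \code{he} is zero.
#' @export
inbreeding_coefficient <- function(ho, he) {
  ifelse(he == 0, NA_real_, 1 - ho / he)
}

#' Hardy-Weinberg equilibrium test at one locus
#'
#' Chi-square goodness of fit of observed genotype counts against
#' Hardy-Weinberg expectations computed from the observed allele frequencies,
#' with \code{df = Na(Na-1)/2}. The Monte-Carlo variant permutes the allele
#' pool among individuals and reports the fraction of permutations whose
#' statistic is at least the observed one.
#'
#' @param a1,a2 Integer allele codes of the two allele columns (nonmissing).
#' @param method \code{"chi2"} or \code{"mc"}.
#' @param mc_reps Number of permutations for \code{"mc"}.
#' @param seed Seed for \code{"mc"} (required for reproducibility).
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
hwe_test <- function(a1, a2, method = c("chi2", "mc"), mc_reps = 999L,
                     seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(a1) == length(a2), all(a1 != 0L), all(a2 != 0L))
  n <- length(a1)
  if (n < 1L) stop("no typed individuals")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) stop("Hardy-Weinberg test undefined for a monomorphic locus")
  chi2_stat <- function(x1, x2) {
    p <- as.numeric(table(factor(c(x1, x2), levels = alleles))) / (2 * n)
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    obs <- table(factor(lo, levels = alleles), factor(hi, levels = alleles))
    exp <- outer(p, p) * n
    exp <- exp + t(exp) - diag(diag(exp))      # 2*p_i*p_j off-diagonal, p_i^2 diag
    ut <- upper.tri(exp, diag = TRUE)
    e <- exp[ut]; o <- as.numeric(obs[ut])
    ok <- e > 0
    sum((o[ok] - e[ok])^2 / e[ok])
  }
  chi2 <- chi2_stat(a1, a2)
  df <- k * (k - 1) / 2
  if (method == "chi2") {
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    if (is.null(seed)) stop("Monte-Carlo HWE test requires a seed")
    pool <- c(a1, a2)
    cnt <- withr_seed(seed, {
      hits <- 0L
      for (b in seq_len(mc_reps)) {
        perm <- sample(pool)
        s <- chi2_stat(perm[seq_len(n)], perm[n + seq_len(n)])
        if (s >= chi2 - 1e-12) hits <- hits + 1L
      }
      hits
    })
    p <- (cnt + 1) / (mc_reps + 1)
  }
  list(chi2 = chi2, df = df, p = p)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-population diversity summary
#'
#' For every population, per-locus indices are computed from within-population
#' allele frequencies and averaged (unweighted) across loci.
#'
#' @param gt A \code{\link{genotype_table}}.
#' @return Data.frame of class \code{"pop_stats"}: one row per population with
#'   mean \code{Na, Ne, I, Ho, He, F} across loci (F averaged over loci where
#'   defined).
#' @export
population_summary <- function(gt) {
  pops <- levels(gt$pop)
  res <- lapply(pops, function(p) {
    ls <- suppressWarnings(locus_stats(gt, scope = p, hwe = "none"))
    data.frame(population = p,
               n = sum(gt$pop == p),
               Na = mean(ls$Na), Ne = mean(ls$Ne), I = mean(ls$I),
               Ho = mean(ls$Ho), He = mean(ls$He),
               F = mean(ls$F, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  class(res) <- c("pop_stats", "data.frame")
  res
}

#' Pooled per-locus summary with within-population heterozygosity
#'
#' The pooled table uses allele frequencies over all individuals (one row per
#' locus across every population) and adds \code{mean_He_within}, the
#' unweighted mean of within-population He across populations. Across-locus
#' unweighted means are attached as \code{attr(, "means")}.
#'
#' @inheritParams locus_stats
#' @return A \code{"locus_stats"} data.frame with the extra column
#'   \code{mean_He_within} and a \code{"means"} attribute.
#' @export
pooled_summary <- function(gt, hwe = c("chi2", "mc", "none"), mc_reps = 999L,
                           seed = NULL) {
  hwe <- match.arg(hwe)
  ls <- locus_stats(gt, scope = "pooled", hwe = hwe, mc_reps = mc_reps,
                    seed = seed)
  pops <- levels(gt$pop)
  he_within <- sapply(pops, function(p) {
    w <- suppressWarnings(locus_stats(gt, scope = p, hwe = "none"))
    w$He[match(ls$locus, w$locus)]
  })
  ls$mean_He_within <- rowMeans(matrix(he_within, nrow = nrow(ls)), na.rm = TRUE)
  num <- c("Na", "Ne", "I", "Ho", "He", "PIC", "F", "mean_He_within")
  attr(ls, "means") <- colMeans(ls[num], na.rm = TRUE)
  ls
}
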