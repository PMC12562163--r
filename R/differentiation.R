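# Between-population analyses: Weir-Cockerham theta, island-model gene flow,
# Nei (1972) standard distance, UPGMA, allele-level AMOVA, PCoA, Evanno dK.

# Weir & Cockerham (1984) variance components a, b, c for one allele at one
# locus across r populations. n = diploid sample sizes, p = allele
# frequencies, h = observed frequency of heterozygotes carrying the allele.
.wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Multiallelic Weir-Cockerham theta across populations
#'
#' Fst estimated as Weir & Cockerham's theta, with variance components summed
#' over alleles and loci before the ratio. Populations and loci without typed
#' individuals are skipped; a negative estimate is clamped to 0 with a
#' warning.
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param pops Populations to include (default: all).
#' @param clamp Clamp negative estimates to zero (default TRUE).
#' @return Theta as a single number.
#' @export
wc_theta <- function(gt, pops = levels(gt$pop), clamp = TRUE) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(pops) < 2L) stop("need at least two populations")
  if (!all(pops %in% levels(gt$pop))) stop("unknown population label")
  A <- 0; BC <- 0
  any_locus <- FALSE
  for (j in seq_along(gt$loci)) {
    n <- integer(0); pmat <- NULL; hmat <- NULL
    alleles <- sort(unique(c(gt$alleles[gt$pop %in% pops, j, ])))
    alleles <- alleles[alleles != 0L]
    if (length(alleles) < 2L) next
    pl <- list(); hl <- list(); nn <- numeric(0)
    for (pp in pops) {
      rows <- which(gt$pop == pp)
      a1 <- gt$alleles[rows, j, 1L]; a2 <- gt$alleles[rows, j, 2L]
      typed <- a1 != 0L
      a1 <- a1[typed]; a2 <- a2[typed]
      if (length(a1) == 0L) next
      nn <- c(nn, length(a1))
      cnt <- table(factor(c(a1, a2), levels = alleles))
      pl[[length(pl) + 1L]] <- as.numeric(cnt) / (2 * length(a1))
      het <- a1 != a2
      hl[[length(hl) + 1L]] <- vapply(alleles, function(al) {
        mean(het & (a1 == al | a2 == al))
      }, numeric(1L))
    }
    if (length(nn) < 2L) next
    any_locus <- TRUE
    P <- do.call(rbind, pl); H <- do.call(rbind, hl)
    for (k in seq_along(alleles)) {
      comp <- .wc_components(nn, P[, k], H[, k])
      A <- A + comp["a"]
      BC <- BC + comp["a"] + comp["b"] + comp["c"]
    }
  }
  if (!any_locus) stop("no shared typed polymorphic locus among the populations")
  theta <- as.numeric(A / BC)
  if (clamp && theta < 0) {
    warning("negative theta clamped to 0")
    theta <- 0
  }
  theta
}

#' Pairwise Fst between two populations
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param pop_a,pop_b Population labels.
#' @param estimator \code{"wc"} (Weir-Cockerham theta, default) or
#'   \code{"nei"} ((Ht - Hs)/Ht with Ht from pooled pair frequencies and Hs
#'   the mean within-population He).
#' @return Fst estimate in [0, 1].
#' @export
pairwise_fst <- function(gt, pop_a, pop_b, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  if (estimator == "wc") return(wc_theta(gt, c(pop_a, pop_b)))
  ht <- 0; hs <- 0; nl <- 0L
  for (j in seq_along(gt$loci)) {
    pa <- .pop_locus_freq(gt, pop_a, j)
    pb <- .pop_locus_freq(gt, pop_b, j)
    if (is.null(pa) || is.null(pb)) next
    alleles <- sort(unique(c(names(pa), names(pb))))
    va <- stats::setNames(numeric(length(alleles)), alleles); va[names(pa)] <- pa
    vb <- stats::setNames(numeric(length(alleles)), alleles); vb[names(pb)] <- pb
    pm <- (va + vb) / 2
    ht <- ht + 1 - sum(pm^2)
    hs <- hs + ((1 - sum(va^2)) + (1 - sum(vb^2))) / 2
    nl <- nl + 1L
  }
  if (nl == 0L) stop("no shared typed locus between '", pop_a, "' and '", pop_b, "'")
  if (ht == 0) return(0)
  fst <- (ht - hs) / ht
  if (fst < 0) { warning("negative Fst clamped to 0"); fst <- 0 }
  fst
}

.pop_locus_freq <- function(gt, pop, j) {
  rows <- which(gt$pop == pop)
  a <- c(gt$alleles[rows, j, 1L], gt$alleles[rows, j, 2L])
  a <- a[a != 0L]
  if (length(a) == 0L) return(NULL)
  tab <- table(a)
  stats::setNames(as.numeric(tab) / length(a), names(tab))
}

#' Pairwise Fst and gene-flow matrices
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param estimator Passed to \code{\link{pairwise_fst}}.
#' @return List with symmetric matrices \code{fst} and \code{nm}.
#' @export
fst_matrix <- function(gt, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  pops <- levels(gt$pop)
  P <- length(pops)
  fst <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in seq((i + 1L), P)) {
    fst[i, j] <- fst[j, i] <- pairwise_fst(gt, pops[i], pops[j], estimator)
  }
  nm <- matrix(Inf, P, P, dimnames = list(pops, pops))
  pos <- fst > 0
  nm[pos] <- 0.25 * (1 - fst[pos]) / fst[pos]
  diag(nm) <- NA_real_
  list(fst = fst, nm = nm)
}

#' Gene flow from Fst (Wright's island model)
#'
#' \code{Nm = 0.25 (1 - Fst) / Fst}.
#'
#' @param fst Fst value(s) in (0, 1]. \code{fst = 0} returns \code{Inf}
#'   (unbounded gene flow); negative values are a domain error.
#' @return Nm value(s).
#' @export
nm_from_fst <- function(fst) {
  if (any(fst < 0)) stop("Fst must be nonnegative")
  if (any(fst > 1)) stop("Fst must be at most 1")
  ifelse(fst == 0, Inf, 0.25 * (1 - fst) / fst)
}

#' Nei's (1972) standard genetic distance between two populations
#'
#' \eqn{D = -\ln(J_{xy} / \sqrt{J_x J_y})} with the gene identities
#' \eqn{J_{xy} = \sum p_a p_b}, \eqn{J_x = \sum p_a^2}, \eqn{J_y = \sum p_b^2}
#' averaged across loci before the ratio. \code{per_locus = TRUE} instead
#' averages the per-locus distances.
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param pop_a,pop_b Population labels.
#' @param per_locus Average D per locus instead of averaging the J's.
#' @return Distance (\code{Inf} when the populations share no allele).
#' @export
nei_distance <- function(gt, pop_a, pop_b, per_locus = FALSE) {
  jxy <- numeric(0); jx <- numeric(0); jy <- numeric(0)
  for (j in seq_along(gt$loci)) {
    pa <- .pop_locus_freq(gt, pop_a, j)
    pb <- .pop_locus_freq(gt, pop_b, j)
    if (is.null(pa) || is.null(pb)) next
    alleles <- sort(unique(c(names(pa), names(pb))))
    va <- stats::setNames(numeric(length(alleles)), alleles); va[names(pa)] <- pa
    vb <- stats::setNames(numeric(length(alleles)), alleles); vb[names(pb)] <- pb
    jxy <- c(jxy, sum(va * vb)); jx <- c(jx, sum(va^2)); jy <- c(jy, sum(vb^2))
  }
  if (length(jxy) == 0L) stop("no shared typed locus")
  if (per_locus) {
    d <- -log(jxy / sqrt(jx * jy))
    return(mean(d))
  }
  I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (I == 0) return(Inf)
  -log(I)
}

#' Nei distance matrix over all populations
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param per_locus See \code{\link{nei_distance}}.
#' @return A \code{\link{dist_matrix}}.
#' @export
nei_distance_matrix <- function(gt, per_locus = FALSE) {
  pops <- levels(gt$pop)
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in seq((i + 1L), P)) {
    m[i, j] <- m[j, i] <- nei_distance(gt, pops[i], pops[j], per_locus)
  }
  dist_matrix(m, pops)
}

# ---- UPGMA ------------------------------------------------------------------

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from the
#' merged cluster to any other is the member-count-weighted arithmetic mean of
#' the two parts' distances (true UPGMA). Node height is half the merge
#' distance, so cophenetic distances on an ultrametric input reproduce it
#' exactly. Ties are broken by the smallest (row, column) index pair in the
#' current label order.
#'
#' @param dm A \code{\link{dist_matrix}} (finite entries required).
#' @return Object of class \code{"upgma_tree"}: a list with an
#'   \code{hclust} component (heights = merge distances), the leaf
#'   \code{labels}, and \code{heights} (ultrametric node heights, half the
#'   merge distance).
#' @export
upgma <- function(dm) {
  m <- unclass(dm)
  labs <- rownames(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least two labels")
  if (any(!is.finite(m)))
    stop("non-finite distances: resolve infinite/NaN entries before UPGMA")
  active <- seq_len(n)                 # current cluster ids (neg = leaf idx)
  id <- -seq_len(n)                    # hclust convention
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  d <- m
  for (s in seq_len(n - 1L)) {
    nn <- length(active)
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (i in seq_len(nn - 1L)) for (j in seq((i + 1L), nn)) {
      if (d[i, j] < bd - 1e-15) { bd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    merge[s, ] <- c(id[i], id[j])
    height[s] <- bd
    wi <- size[i]; wj <- size[j]
    newd <- (wi * d[i, ] + wj * d[j, ]) / (wi + wj)
    keep <- setdiff(seq_len(nn), c(i, j))
    nd <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    d <- nd
    id <- c(id[keep], s)
    size <- c(size[keep], wi + wj)
    active <- c(active[keep], 0L)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = .hclust_order(merge, n),
                       labels = labs, method = "upgma",
                       call = match.call(), dist.method = "user"),
                  class = "hclust")
  # hclust stores the merge distance; the ultrametric node height is half it
  structure(list(hclust = hc, labels = labs, heights = height / 2),
            class = "upgma_tree")
}

# leaf ordering for plotting: left-to-right traversal of the merge tree
.hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Cophenetic distances of a UPGMA tree
#'
#' @param tree A \code{"upgma_tree"}.
#' @return A \code{\link{dist_matrix}} of cophenetic distances
#'   (2 x node height of the lowest common ancestor).
#' @export
cophenetic_upgma <- function(tree) {
  cd <- as.matrix(stats::cophenetic(tree$hclust))
  dist_matrix(cd[tree$labels, tree$labels], tree$labels)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree with", length(x$labels), "leaves\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' @method plot upgma_tree
#' @export
plot.upgma_tree <- function(x, ...) {
  plot(x$hclust, hang = -1, ylab = "merge distance", ...)
  invisible(x)
}

# ---- AMOVA ------------------------------------------------------------------

#' Allele-level analysis of molecular variance
#'
#' One-level AMOVA on gene copies: every typed diploid call contributes two
#' units, distances between gene copies are 0/1 allele mismatches, and sums
#' of squares are accumulated over loci. Degrees of freedom follow the
#' gene-copy layout: \code{df_among = P - 1}, \code{df_within = 2N - P},
#' \code{df_total = 2N - 1} (N = diploid individuals). The variance
#' components are \code{sigma2_w = MS_within} and
#' \code{sigma2_a = (MS_among - MS_within) / n0} with
#' \code{n0 = (Nc - sum(c_p^2)/Nc) / (P - 1)} on gene copies \code{c_p}.
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param permutations Number of permutations for the Phi_PT test
#'   (0 disables it).
#' @param seed Seed for the permutation test (required when permuting).
#' @return Object of class \code{"amova_result"} with the AMOVA table,
#'   variance components, percentages, \code{phi_pt} and optional
#'   permutation p-value.
#' @export
amova <- function(gt, permutations = 0L, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  pops <- levels(gt$pop)
  P <- length(pops)
  if (P < 2L) stop("AMOVA needs at least two populations")
  for (p in pops) {
    rows <- which(gt$pop == p)
    if (all(gt$alleles[rows, , 1L] == 0L))
      stop("population '", p, "' has no typed individuals")
  }
  ss <- .amova_ss(gt$pop, gt$alleles)
  N <- length(gt$individual)
  df_among <- P - 1L
  df_within <- 2L * N - P
  df_total <- 2L * N - 1L
  ms_among <- ss$among / df_among
  ms_within <- ss$within / df_within
  copies <- 2 * as.numeric(table(gt$pop))
  Nc <- sum(copies)
  n0 <- (Nc - sum(copies^2) / Nc) / (P - 1)
  s2w <- ms_within
  s2a <- max(0, (ms_among - ms_within) / n0)
  tot <- s2a + s2w
  phi <- if (tot > 0) s2a / tot else 0
  res <- list(
    table = data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = c(df_among, df_within, df_total),
      SS = c(ss$among, ss$within, ss$among + ss$within),
      MS = c(ms_among, ms_within, NA_real_),
      stringsAsFactors = FALSE),
    sigma2_a = s2a, sigma2_w = s2w,
    pct_among = 100 * s2a / tot, pct_within = 100 * s2w / tot,
    phi_pt = phi, n0 = n0, p_value = NA_real_, permutations = permutations)
  if (permutations > 0L) {
    if (is.null(seed)) stop("permutation test requires a seed")
    obs <- phi
    hits <- withr_seed(seed, {
      h <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(gt$pop)
        sb <- .amova_ss(perm, gt$alleles)
        msa <- sb$among / df_among; msw <- sb$within / df_within
        sa <- max(0, (msa - msw) / n0)
        ph <- if (sa + msw > 0) sa / (sa + msw) else 0
        if (ph >= obs - 1e-12) h <- h + 1L
      }
      h
    })
    res$p_value <- (hits + 1) / (permutations + 1)
  }
  class(res) <- "amova_result"
  res
}

# among/within sums of squares over loci from 0/1 allele mismatch distances.
# For n gene copies with allele counts n_a: SS = (n - sum(n_a^2)/n) / 2.
.amova_ss <- function(pop, alleles) {
  n_loci <- dim(alleles)[2L]
  ss_total <- 0; ss_within <- 0
  for (j in seq_len(n_loci)) {
    a <- c(alleles[, j, 1L], alleles[, j, 2L])
    popg <- c(as.character(pop), as.character(pop))
    keep <- a != 0L
    a <- a[keep]; popg <- popg[keep]
    if (length(a) == 0L) next
    ssfun <- function(x) {
      n <- length(x)
      (n - sum(table(x)^2) / n) / 2
    }
    ss_total <- ss_total + ssfun(a)
    for (p in unique(popg)) ss_within <- ss_within + ssfun(a[popg == p])
  }
  list(among = ss_total - ss_within, within = ss_within)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (gene-copy level)\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat(sprintf("Variance components: among = %.4f (%.1f%%), within = %.4f (%.1f%%)\n",
              x$sigma2_a, x$pct_among, x$sigma2_w, x$pct_within))
  cat(sprintf("Phi_PT = %.4f", x$phi_pt))
  if (!is.na(x$p_value))
    cat(sprintf("  (p = %.4f, %d permutations)", x$p_value, x$permutations))
  cat("\n")
  invisible(x)
}

# ---- PCoA -------------------------------------------------------------------

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-D^2/2}, eigendecomposes, and returns coordinates for
#' the positive eigenvalues in descending order. Each axis's sign is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param dm A \code{\link{dist_matrix}}.
#' @param eps Eigenvalues below \code{eps} (relative to the largest) are
#'   treated as zero.
#' @return Object of class \code{"pcoa_result"}: list with \code{coordinates}
#'   (labelled matrix), \code{eigenvalues} (positive ones) and
#'   \code{pct_variation}.
#' @export
pcoa <- function(dm, eps = 1e-9) {
  m <- unclass(dm)
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(!is.finite(m))) stop("distance matrix must be finite")
  n <- nrow(m)
  B <- -0.5 * m^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  # symmetrize against rounding
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- eps * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(m), NULL))
    return(structure(list(coordinates = coords, eigenvalues = numeric(0),
                          pct_variation = numeric(0)), class = "pcoa_result"))
  }
  vals <- e$values[pos]
  vec <- e$vectors[, pos, drop = FALSE]
  coords <- vec %*% diag(sqrt(vals), nrow = length(vals))
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(m), paste0("Axis", seq_along(vals)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 pct_variation = 100 * vals / sum(e$values[e$values > 0])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "points,", length(x$eigenvalues),
      "positive axes\n")
  if (length(x$pct_variation)) {
    cat("Variation explained (%):",
        paste(sprintf("%.1f", utils::head(x$pct_variation, 5)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @method plot pcoa_result
#' @export
plot.pcoa_result <- function(x, axes = c(1, 2), ...) {
  co <- x$coordinates
  if (ncol(co) < max(axes)) stop("not enough axes")
  plot(co[, axes[1L]], co[, axes[2L]],
       xlab = sprintf("Axis %d (%.1f%%)", axes[1L], x$pct_variation[axes[1L]]),
       ylab = sprintf("Axis %d (%.1f%%)", axes[2L], x$pct_variation[axes[2L]]),
       ...)
  graphics::text(co[, axes[1L]], co[, axes[2L]], rownames(co), pos = 3, cex = 0.8)
  invisible(x)
}

# ---- Evanno delta K ---------------------------------------------------------

#' Evanno delta-K from replicate log-likelihood summaries
#'
#' \eqn{\Delta K = |L(K+1) - 2 L(K) + L(K-1)| / sd(K)} computed on the mean
#' log-likelihood of replicate runs per K; the endpoints are undefined.
#'
#' @param k Integer vector of contiguous K values (>= 3 points).
#' @param mean_l Mean log-likelihood per K.
#' @param sd_l Replicate standard deviation per K (must be > 0 at interior K).
#' @return Data.frame with \code{k} and \code{delta_k} (NA at the endpoints),
#'   with the optimal K in \code{attr(, "best_k")}.
#' @export
evanno_delta_k <- function(k, mean_l, sd_l) {
  stopifnot(length(k) == length(mean_l), length(k) == length(sd_l))
  if (length(k) < 3L) stop("need at least three K values")
  o <- order(k)
  k <- k[o]; mean_l <- mean_l[o]; sd_l <- sd_l[o]
  if (any(diff(k) != 1L)) stop("K values must be contiguous")
  n <- length(k)
  interior <- 2:(n - 1L)
  if (any(sd_l[interior] <= 0))
    stop("delta K undefined where the replicate sd is zero")
  dk <- rep(NA_real_, n)
  dk[interior] <- abs(mean_l[interior + 1L] - 2 * mean_l[interior] +
                        mean_l[interior - 1L]) / sd_l[interior]
  res <- data.frame(k = k, delta_k = dk)
  attr(res, "best_k") <- k[which.max(dk)]
  res
}
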