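# Independent reference implementations used only to check the package.

# Brute-force SSR scanner: per-start alignment extension, unit by unit.
# N positions are replaced by unique sentinels so nothing ever matches them.
oracle_ssrs <- function(s, min_repeats = default_min_repeats()) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  nidx <- which(ch == "N")
  if (length(nidx)) ch[nidx] <- paste0("n", seq_along(nidx))
  res <- list()
  for (k in 1:6) {
    thr <- min_repeats[[as.character(k)]]
    if (L < 2L * k) next
    for (i in seq_len(L - k)) {
      if (i > 1L && ch[i - 1L] == ch[i + k - 1L]) next   # not left-maximal
      unit <- ch[i:(i + k - 1L)]
      cc <- 1L
      while (i + (cc + 1L) * k - 1L <= L &&
             all(ch[(i + cc * k):(i + (cc + 1L) * k - 1L)] == unit)) cc <- cc + 1L
      if (cc < thr) next
      u <- paste(unit, collapse = "")
      if (grepl("n", u, fixed = TRUE)) next
      if (is_degenerate_motif(u)) next
      res[[length(res) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + cc * k, motif = u, repeats = cc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeats = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, p_n = 0, gc = 0.5) {
  probs <- c((1 - p_n) * (1 - gc) / 2, (1 - p_n) * gc / 2,
             (1 - p_n) * gc / 2, (1 - p_n) * (1 - gc) / 2, p_n)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Naive UPGMA cophenetic matrix: cluster distance recomputed at every step as
# the plain mean of the ORIGINAL pairwise distances between the two sets.
naive_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  sets <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(sets) > 1L) {
    best <- NULL; bd <- Inf
    for (i in seq_len(length(sets) - 1L)) for (j in (i + 1L):length(sets)) {
      dd <- mean(m[sets[[i]], sets[[j]]])
      if (dd < bd - 1e-15) { bd <- dd; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    coph[sets[[i]], sets[[j]]] <- bd
    coph[sets[[j]], sets[[i]]] <- bd
    sets[[i]] <- c(sets[[i]], sets[[j]])
    sets[[j]] <- NULL
  }
  dimnames(coph) <- dimnames(m)
  coph
}

random_dist_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 2)
  m <- m + t(m)
  dist_matrix(m, paste0("t", seq_len(n)))
}

# tiny genotype table builder: calls is a list of c(a1, a2) per individual
small_gt <- function(calls, pop = rep("P1", length(calls)), locus = "L1") {
  al <- array(0L, dim = c(length(calls), 1L, 2L))
  for (i in seq_along(calls)) al[i, 1L, ] <- as.integer(calls[[i]])
  genotype_table(pop, paste0("i", seq_along(calls)), al, locus)
}
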