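# In-silico polymorphism screen: mask the SSR run with a single "R", drop
# candidates with short flanks, cluster masked sequences greedily by
# identity/coverage, and score per-cluster allele-length polymorphism.

#' Mask SSR runs and filter short flanks
#'
#' One candidate is produced per (sequence, SSR locus) pair; a sequence with
#' several SSRs yields several candidates. The repeat run is replaced by a
#' single placeholder letter \code{"R"}, so candidates that are allelic length
#' variants of one locus share an identical masked sequence. Candidates whose
#' left or right flank is shorter than \code{min_flank} bp are dropped.
#'
#' @param seqs Named character vector of sequences.
#' @param loci \code{"ssr_loci"} data.frame from \code{\link{detect_ssrs_all}}.
#' @param min_flank Minimum flank length in bp (default 20).
#' @return A data.frame of class \code{"masked_candidates"} with columns
#'   \code{cand_id, seq_id, masked_seq, ssr_len, unmasked_len, left_flank_len,
#'   right_flank_len, motif, start, end}.
#' @export
mask_and_filter <- function(seqs, loci, min_flank = 20L) {
  if (nrow(loci) == 0L) {
    res <- data.frame(cand_id = character(), seq_id = character(),
                      masked_seq = character(), ssr_len = integer(),
                      unmasked_len = integer(), left_flank_len = integer(),
                      right_flank_len = integer(), motif = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    class(res) <- c("masked_candidates", "data.frame")
    return(res)
  }
  s <- seqs[loci$seq_id]
  slen <- nchar(s)
  left <- loci$start
  right <- slen - loci$end
  masked <- paste0(substring(s, 1L, loci$start),
                   "R",
                   substring(s, loci$end + 1L, slen))
  res <- data.frame(
    cand_id = paste0(loci$seq_id, ":", loci$start, "-", loci$end),
    seq_id = loci$seq_id,
    masked_seq = masked,
    ssr_len = loci$end - loci$start,
    unmasked_len = slen,
    left_flank_len = left,
    right_flank_len = right,
    motif = loci$motif_canonical,
    start = loci$start,
    end = loci$end,
    stringsAsFactors = FALSE)
  res <- res[res$left_flank_len >= min_flank & res$right_flank_len >= min_flank, ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("masked_candidates", "data.frame")
  res
}

# Substitution matrix over the masked alphabet: exact character matches score
# 1, base-vs-base mismatches 0, and the placeholder "R" is heavily penalized
# against anything but itself so repeat placeholders align to each other.
.screen_submat <- function() {
  a <- c("A", "C", "G", "T", "N", "R")
  m <- matrix(0, 6L, 6L, dimnames = list(a, a))
  diag(m) <- 1
  m["R", a != "R"] <- -2
  m[a != "R", "R"] <- -2
  m
}

#' Align two masked sequences (ends-free global)
#'
#' Ends-free (overlap) global alignment with the screen's gap penalties.
#' Identity is matched positions divided by the length of the shorter
#' sequence; coverage is the aligned span of the shorter sequence divided by
#' its length.
#'
#' @param a,b Masked sequences (strings over \code{A,C,G,T,N,R}).
#' @param gap_open,gap_ext Gap penalties (nonnegative).
#' @return List with \code{identity} and \code{coverage}.
#' @export
align_masked <- function(a, b, gap_open = 1, gap_ext = 0) {
  if (a == b) return(list(identity = 1, coverage = 1))
  if (nchar(a) <= nchar(b)) { shorter <- a; longer <- b } else { shorter <- b; longer <- a }
  aln <- Biostrings::pairwiseAlignment(
    pattern = shorter, subject = longer, type = "overlap",
    substitutionMatrix = .screen_submat(),
    gapOpening = gap_open, gapExtension = gap_ext)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  matches <- sum(pat == sub & pat != "-")
  span <- sum(pat != "-")
  list(identity = matches / nchar(shorter),
       coverage = span / nchar(shorter))
}

#' Greedy identity/coverage clustering of masked candidates
#'
#' cd-hit-style greedy incremental clustering: candidates are sorted by masked
#' length descending (ties by \code{cand_id}); each joins the first existing
#' cluster whose representative aligns at \code{identity} and
#' \code{coverage} or better, otherwise it founds a new cluster. The
#' representative is the founding (longest) member.
#'
#' @param candidates \code{"masked_candidates"} data.frame.
#' @param identity Minimum identity over the shorter sequence (default 0.90).
#' @param coverage Minimum aligned coverage of the shorter sequence (0.70).
#' @param gap_open,gap_ext Alignment gap penalties.
#' @return An object of class \code{"ssr_clusters"}: the candidate table with a
#'   \code{cluster} column, plus a per-cluster summary in
#'   \code{attr(, "clusters")} (columns \code{cluster, n, representative,
#'   polymorphism_value}).
#' @export
cluster_candidates <- function(candidates, identity = 0.90, coverage = 0.70,
                               gap_open = 1, gap_ext = 0) {
  if (nrow(candidates) == 0L) stop("no candidates to cluster")
  ord <- order(-nchar(candidates$masked_seq), candidates$cand_id)
  cand <- candidates[ord, , drop = FALSE]
  reps <- character(0)         # representative masked sequences
  rep_id <- character(0)
  assign <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$masked_seq[i]
    hit <- 0L
    for (j in seq_along(reps)) {
      al <- align_masked(s, reps[j], gap_open, gap_ext)
      if (al$identity >= identity && al$coverage >= coverage) { hit <- j; break }
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      rep_id <- c(rep_id, cand$cand_id[i])
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  cand$cluster <- assign
  cand <- cand[order(cand$cluster, cand$cand_id), , drop = FALSE]
  rownames(cand) <- NULL
  summ <- data.frame(
    cluster = seq_along(reps),
    n = as.integer(table(factor(assign, levels = seq_along(reps)))),
    representative = rep_id,
    stringsAsFactors = FALSE)
  summ$polymorphism_value <- vapply(summ$cluster, function(k) {
    length(unique(cand$ssr_len[cand$cluster == k]))
  }, integer(1L))
  attr(cand, "clusters") <- summ
  class(cand) <- c("ssr_clusters", "data.frame")
  cand
}

#' Per-cluster polymorphism value
#'
#' The number of distinct SSR run lengths among a cluster's members: 1 when
#' all members carry the same allele length, 2 for two distinct lengths, etc.
#'
#' @param ssr_lens Integer vector of SSR total lengths of the cluster members.
#' @return Integer polymorphism value (>= 1).
#' @export
polymorphism_value <- function(ssr_lens) {
  if (length(ssr_lens) == 0L) stop("empty cluster")
  length(unique(ssr_lens))
}

#' Cluster summary table
#'
#' @param clusters An \code{"ssr_clusters"} object.
#' @return The per-cluster summary data.frame.
#' @export
cluster_summary <- function(clusters) attr(clusters, "clusters")

#' Select candidate marker clusters
#'
#' Keeps clusters whose polymorphism value is strictly greater than
#' \code{min_poly - 1} (the default keeps values > 2) and whose representative
#' admits an amplicon inside \code{product_range}: the representative's
#' unmasked length must fall within the range, since primers sit on the two
#' flanks and the product spans flank-SSR-flank.
#'
#' @param clusters An \code{"ssr_clusters"} object.
#' @param min_poly Minimum polymorphism value to keep (default 3).
#' @param product_range Allowed amplicon length range in bp (default 100-400).
#' @return Data.frame of selected clusters with member counts, distinct
#'   lengths, and the representative candidate id.
#' @export
select_candidates <- function(clusters, min_poly = 3L,
                              product_range = c(100L, 400L)) {
  summ <- cluster_summary(clusters)
  rep_len <- clusters$unmasked_len[match(summ$representative, clusters$cand_id)]
  summ$representative_len <- rep_len
  keep <- summ$polymorphism_value >= min_poly &
    rep_len >= product_range[1L] & rep_len <= product_range[2L]
  out <- summ[keep, , drop = FALSE]
  out$member_ids <- vapply(out$cluster, function(k) {
    paste(clusters$cand_id[clusters$cluster == k], collapse = ";")
  }, character(1L))
  out$ssr_lengths <- vapply(out$cluster, function(k) {
    paste(sort(unique(clusters$ssr_len[clusters$cluster == k])), collapse = ";")
  }, character(1L))
  rownames(out) <- NULL
  out
}

#' @export
print.ssr_clusters <- function(x, ...) {
  summ <- cluster_summary(x)
  cat("SSR screen:", nrow(x), "candidates in", nrow(summ), "clusters\n")
  cat("Polymorphism values:\n")
  print(table(summ$polymorphism_value))
  invisible(x)
}
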