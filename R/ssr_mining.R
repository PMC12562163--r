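# Perfect-microsatellite detection with MISA-style per-motif-size thresholds.
# Coordinates are 0-based, half-open on the forward strand throughout.

.ssr_types <- c("mono", "di", "tri", "tetra", "penta", "hexa")

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

.rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k) - 1L, function(i) {
    paste0(substring(m, i + 1L, k), substring(m, 1L, i))
  }, character(1L))
}

#' Is a motif a tandem repetition of a shorter unit?
#'
#' @param motif Motif string over \code{A,C,G,T}.
#' @return \code{TRUE} for degenerate motifs such as \code{"ACAC"} or
#'   \code{"AAA"}.
#' @export
is_degenerate_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && motif == strrep(substring(motif, 1L, d), k %/% d))
      return(TRUE)
  }
  FALSE
}

#' Canonical representative of a motif class
#'
#' Microsatellite motifs are equivalent under cyclic rotation and reverse
#' complementation (\code{GT}, \code{TG}, \code{CA} and \code{AC} all name the
#' \code{(AC/GT)n} class). The canonical representative is the
#' lexicographically smallest string among all rotations of the motif and of
#' its reverse complement.
#'
#' @param motif Motif string of length 1--6 over \code{A,C,G,T}.
#' @return The canonical motif string.
#' @examples
#' canonical_motif("GT")    # "AC"
#' canonical_motif("TCTA")  # "AGAT"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over A,C,G,T")
  if (nchar(motif) < 1L || nchar(motif) > 6L) stop("motif length must be 1-6")
  if (is_degenerate_motif(motif))
    stop("degenerate motif '", motif, "': tandem of a shorter unit")
  min(c(.rotations(motif), .rotations(.revcomp(motif))))
}

#' Default minimum repeat counts per motif size
#'
#' At least 10 copies for mononucleotide motifs, 6 for dinucleotide, and 5 for
#' tri- through hexanucleotide motifs.
#'
#' @return Named integer vector indexed by motif size "1".."6".
#' @export
default_min_repeats <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

#' Detect perfect microsatellites in one sequence
#'
#' Finds every maximal perfect tandem run of a 1--6 bp motif meeting its
#' size-class minimum repeat count. Runs are maximal: partial trailing motif
#' copies are excluded so that the locus length is always an integer multiple
#' of the motif length. A run whose motif is itself a tandem of a shorter unit
#' is reported only under the shortest unit's class, and \code{N} breaks every
#' run.
#'
#' @param seq Nucleotide string over \code{A,C,G,T,N}.
#' @param seq_id Identifier carried into the output.
#' @param min_repeats Named integer vector of minimum full-motif copies per
#'   motif size, as from \code{\link{default_min_repeats}}.
#' @return A data.frame of class \code{"ssr_loci"} with columns
#'   \code{seq_id, start, end, motif, motif_canonical, repeats, type},
#'   0-based half-open coordinates, sorted by \code{start}.
#' @export
detect_ssrs <- function(seq, seq_id = "seq", min_repeats = default_min_repeats()) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- vector("list", 6L)
  for (k in 1:6) {
    if (L < 2L * k) next
    thr <- min_repeats[[as.character(k)]]
    i <- seq_len(L - k)
    # m[i] TRUE when position i matches position i+k; N never matches
    m <- ch[i] == ch[i + k] & ch[i] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths + k >= thr * k
    if (!any(keep)) next
    st <- starts[keep]
    reps <- (r$lengths[keep] + k) %/% k
    motif <- substring(seq, st, st + k - 1L)
    ok <- !vapply(motif, is_degenerate_motif, logical(1L), USE.NAMES = FALSE)
    if (!any(ok)) next
    out[[k]] <- data.frame(
      seq_id = seq_id,
      start = st[ok] - 1L,                 # to 0-based
      end = st[ok] - 1L + reps[ok] * k,
      motif = motif[ok],
      repeats = reps[ok],
      type = .ssr_types[k],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) {
    res <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      motif = character(), repeats = integer(),
                      type = character(), stringsAsFactors = FALSE)
  }
  res$motif_canonical <- vapply(res$motif, canonical_motif, character(1L),
                                USE.NAMES = FALSE)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ssr_loci", "data.frame")
  res
}

#' Detect microsatellites in a collection of sequences
#'
#' @param seqs Named character vector (e.g. from \code{\link{read_fasta}}).
#' @param min_repeats See \code{\link{detect_ssrs}}.
#' @return Combined \code{"ssr_loci"} data.frame.
#' @export
detect_ssrs_all <- function(seqs, min_repeats = default_min_repeats()) {
  parts <- lapply(seq_along(seqs), function(i) {
    detect_ssrs(seqs[[i]], names(seqs)[i], min_repeats)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  class(res) <- c("ssr_loci", "data.frame")
  res
}

#' Group compound microsatellites
#'
#' Consecutive loci on one sequence separated by at most \code{max_interval}
#' bp chain transitively into one compound SSR.
#'
#' @param loci An \code{"ssr_loci"} data.frame (one or many sequences).
#' @param max_interval Maximum gap in bp between members (inclusive).
#' @return \code{loci} with an added integer column \code{compound_id}
#'   (\code{NA} for solitary loci; ids are unique across sequences).
#' @export
group_compound <- function(loci, max_interval = 100L) {
  loci$compound_id <- NA_integer_
  next_id <- 1L
  for (sid in unique(loci$seq_id)) {
    idx <- which(loci$seq_id == sid)
    idx <- idx[order(loci$start[idx])]
    if (length(idx) > 1L) {
      st <- loci$start[idx]; en <- loci$end[idx]
      if (any(st[-1L] < en[-length(en)]))
        stop("overlapping loci on sequence '", sid, "'")
      gap <- st[-1L] - en[-length(en)]
      grp <- cumsum(c(0L, gap > max_interval))
      for (g in unique(grp)) {
        mem <- idx[grp == g]
        if (length(mem) >= 2L) {
          loci$compound_id[mem] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
  }
  loci
}

# ---- census -----------------------------------------------------------------

.repeat_bins <- c(as.character(5:20), ">20")

#' Census of detected microsatellites
#'
#' Aggregates an \code{"ssr_loci"} table (with compound grouping applied) into
#' the survey statistics customarily reported for transcriptome SSR screens:
#' totals, both occurrence frequencies, per-type counts/percentages/average
#' lengths, per-canonical-motif counts, and the repeat-number distribution
#' binned at 5..20 and ">20".
#'
#' Two occurrence frequencies are reported and labelled explicitly:
#' \code{pct_sequences_with_ssr} = sequences containing at least one SSR /
#' sequences examined, and \code{ssr_per_100_sequences} = SSR loci / sequences
#' examined, both times 100.
#'
#' @param seqs The scanned sequence set (named character vector).
#' @param loci \code{"ssr_loci"} with a \code{compound_id} column.
#' @return An object of class \code{"ssr_census"}.
#' @export
ssr_census <- function(seqs, loci) {
  n_seq <- length(seqs)
  if (n_seq == 0L) stop("no sequences examined")
  per_seq <- table(factor(loci$seq_id, levels = names(seqs)))
  counts <- list(
    n_sequences_examined = n_seq,
    total_bp = sum(nchar(seqs)),
    n_ssr = nrow(loci),
    n_compound_member_ssr = sum(!is.na(loci$compound_id)),
    n_sequences_with_ssr = sum(per_seq > 0L),
    n_sequences_with_multiple_ssr = sum(per_seq > 1L))
  census_from_counts(counts, loci)
}

#' Census statistics from raw counts
#'
#' Computes the derived census percentages from pre-tabulated counts; used
#' both by \code{\link{ssr_census}} and to check published count tables for
#' internal consistency.
#'
#' @param counts List with elements \code{n_sequences_examined},
#'   \code{total_bp}, \code{n_ssr}, \code{n_compound_member_ssr},
#'   \code{n_sequences_with_ssr}, \code{n_sequences_with_multiple_ssr}.
#' @param loci Optional \code{"ssr_loci"} table used for the per-type,
#'   per-motif and repeat-bin breakdowns.
#' @return An object of class \code{"ssr_census"}: the counts plus
#'   \code{pct_sequences_with_ssr}, \code{ssr_per_100_sequences},
#'   \code{pct_compound}, and (when \code{loci} is given) data.frames
#'   \code{by_type}, \code{by_motif} and \code{repeat_bins}.
#' @export
census_from_counts <- function(counts, loci = NULL) {
  need <- c("n_sequences_examined", "n_ssr", "n_compound_member_ssr",
            "n_sequences_with_ssr")
  if (!all(need %in% names(counts))) stop("missing count fields")
  if (counts$n_sequences_examined == 0L) stop("no sequences examined")
  cz <- counts
  cz$pct_sequences_with_ssr <-
    100 * counts$n_sequences_with_ssr / counts$n_sequences_examined
  cz$ssr_per_100_sequences <-
    100 * counts$n_ssr / counts$n_sequences_examined
  cz$pct_compound <-
    if (counts$n_ssr > 0L) 100 * counts$n_compound_member_ssr / counts$n_ssr else NA_real_
  if (!is.null(loci)) {
    type <- factor(loci$type, levels = .ssr_types)
    len <- loci$end - loci$start
    nt <- as.integer(table(type))
    cz$by_type <- data.frame(
      type = .ssr_types,
      n = nt,
      pct = if (nrow(loci) > 0L) 100 * nt / nrow(loci) else rep(NA_real_, 6L),
      avg_len = as.numeric(tapply(len, type, mean, default = NA_real_)),
      n_motifs = as.integer(tapply(loci$motif_canonical, type,
                                   function(x) length(unique(x)), default = 0L)),
      stringsAsFactors = FALSE)
    bm <- as.data.frame(table(motif = loci$motif_canonical),
                        stringsAsFactors = FALSE)
    if (nrow(bm)) {
      names(bm) <- c("motif", "n")
      bm$pct <- 100 * bm$n / nrow(loci)
      bm <- bm[order(-bm$n, bm$motif), , drop = FALSE]
      rownames(bm) <- NULL
    } else {
      bm <- data.frame(motif = character(), n = integer(), pct = numeric())
    }
    cz$by_motif <- bm
    bin <- ifelse(loci$repeats > 20L, ">20", as.character(loci$repeats))
    bin <- factor(bin, levels = .repeat_bins)
    tab <- table(bin, type)
    cz$repeat_bins <- as.data.frame.matrix(tab)
  }
  structure(cz, class = "ssr_census")
}

#' @export
print.ssr_census <- function(x, ...) {
  cat("SSR census\n")
  cat(sprintf("  sequences examined: %s\n",
              format(x$n_sequences_examined, big.mark = ",")))
  cat(sprintf("  SSR loci: %s (%s in compound formation, %.2f%%)\n",
              format(x$n_ssr, big.mark = ","),
              format(x$n_compound_member_ssr, big.mark = ","),
              x$pct_compound))
  cat(sprintf("  sequences with >=1 SSR: %s (%.2f%%)\n",
              format(x$n_sequences_with_ssr, big.mark = ","),
              x$pct_sequences_with_ssr))
  cat(sprintf("  SSR loci per 100 sequences: %.2f\n", x$ssr_per_100_sequences))
  if (!is.null(x$by_type)) {
    cat("  by type:\n")
    print(x$by_type, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
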