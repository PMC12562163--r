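#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are uppercased on input and validated against the alphabet
#' \code{A,C,G,T,N}. Record ids must be unique.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @return A named character vector of uppercase sequences; names are record
#'   ids. The result carries class \code{"seq_set"}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("not a readable FASTA file: ", path))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(ids == "")) stop("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in record '", ids[bad][1L], "'")
  }
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in FASTA")
  seq_set(seqs, ids)
}

#' Construct a sequence set
#'
#' @param seqs Character vector of sequences over \code{A,C,G,T,N}.
#' @param ids Record identifiers, unique and non-empty.
#' @return Named character vector of class \code{"seq_set"}.
#' @export
seq_set <- function(seqs, ids = names(seqs)) {
  if (is.null(ids)) stop("sequence ids are required")
  stopifnot(length(seqs) == length(ids))
  seqs <- toupper(as.character(seqs))
  if (any(!nzchar(ids))) stop("empty sequence id")
  if (anyDuplicated(ids)) stop("duplicate sequence id")
  if (any(grepl("[^ACGTN]", seqs))) stop("sequence contains non-ACGTN characters")
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence")
  structure(stats::setNames(seqs, ids), class = "seq_set")
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (e.g. a \code{seq_set}).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  ss <- Biostrings::BStringSet(as.character(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("Sequence set:", length(x), "records,",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

# ---- genotype tables --------------------------------------------------------

#' Construct a diploid codominant genotype table
#'
#' Alleles are positive integer codes (fragment sizes in bp); \code{0} marks a
#' missing allele and a call must be either fully missing \code{(0,0)} or fully
#' typed. Population labels keep their order of first appearance.
#'
#' @param pop Character vector of population labels, one per individual.
#' @param individual Character vector of individual ids, unique.
#' @param alleles Integer array of dimension \code{c(n_individuals, n_loci, 2)}.
#' @param loci Character vector of locus names.
#' @return An object of class \code{"genotype_table"}: a list with elements
#'   \code{pop} (factor), \code{individual}, \code{loci} and \code{alleles}.
#' @export
genotype_table <- function(pop, individual, alleles, loci) {
  pop <- as.character(pop)
  individual <- as.character(individual)
  loci <- as.character(loci)
  if (length(pop) != length(individual)) stop("pop/individual length mismatch")
  if (anyDuplicated(individual)) stop("duplicate individual id")
  if (length(loci) < 1L) stop("at least one locus required")
  if (length(pop) < 1L) stop("at least one individual required")
  alleles <- array(as.integer(alleles),
                   dim = c(length(individual), length(loci), 2L))
  if (anyNA(alleles) || any(alleles < 0L)) stop("alleles must be nonnegative integers")
  half <- xor(alleles[, , 1L, drop = FALSE] == 0L,
              alleles[, , 2L, drop = FALSE] == 0L)
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1L, ]
    stop("half-missing call for individual '", individual[idx[1L]],
         "' at locus '", loci[idx[2L]], "'")
  }
  structure(list(pop = factor(pop, levels = unique(pop)),
                 individual = individual,
                 loci = loci,
                 alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$individual), "individuals,",
      nlevels(x$pop), "populations,", length(x$loci), "loci\n")
  miss <- mean(x$alleles[, , 1L] == 0L)
  cat(sprintf("Missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @method summary genotype_table
#' @export
summary.genotype_table <- function(object, ...) {
  tab <- table(object$pop)
  cat("Individuals per population:\n")
  print(tab)
  invisible(object)
}

#' Read a genotype table from CSV
#'
#' Expected dialect: header \code{pop,individual,<locus>.1,<locus>.2,...}; one
#' row per individual; integer allele codes; \code{0,0} marks a missing call.
#'
#' @param path Path to the CSV file.
#' @return A \code{\link{genotype_table}}.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 4L) stop("genotype CSV needs pop, individual and at least one locus pair")
  if (!identical(colnames(df)[1:2], c("pop", "individual")))
    stop("genotype CSV must start with columns 'pop,individual'")
  lcols <- colnames(df)[-(1:2)]
  base <- sub("\\.[12]$", "", lcols)
  suff <- sub("^.*\\.", "", lcols)
  loci <- unique(base)
  expect <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!identical(lcols, expect))
    stop("locus columns must come in '<locus>.1','<locus>.2' pairs")
  n <- nrow(df)
  if (n < 1L) stop("genotype CSV has no rows")
  mat <- suppressWarnings(vapply(df[-(1:2)], as.integer, integer(n)))
  mat <- matrix(mat, nrow = n)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1L]
    stop("non-integer allele code at row ", bad + 1L)
  }
  alleles <- array(0L, dim = c(n, length(loci), 2L))
  alleles[, , 1L] <- mat[, seq(1L, ncol(mat), by = 2L), drop = FALSE]
  alleles[, , 2L] <- mat[, seq(2L, ncol(mat), by = 2L), drop = FALSE]
  half <- xor(alleles[, , 1L] == 0L, alleles[, , 2L] == 0L)
  if (any(half)) {
    bad <- which(apply(matrix(half, nrow = n), 1L, any))[1L]
    stop("half-missing call at row ", bad + 1L)
  }
  genotype_table(df$pop, df$individual, alleles, loci)
}

#' Write a genotype table to CSV
#'
#' @param gt A \code{\link{genotype_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- length(gt$individual)
  out <- data.frame(pop = as.character(gt$pop), individual = gt$individual,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(gt$loci)) {
    out[[paste0(gt$loci[j], ".1")]] <- gt$alleles[, j, 1L]
    out[[paste0(gt$loci[j], ".2")]] <- gt$alleles[, j, 2L]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- distance matrices and trees -------------------------------------------

#' Construct a labelled distance matrix
#'
#' @param m Square numeric matrix, symmetric with zero diagonal.
#' @param labels Row/column labels.
#' @return Matrix of class \code{"dist_matrix"}.
#' @export
dist_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(labels)) stop("distance matrix needs labels")
  fin <- is.finite(m)
  if (any(m[fin] < 0)) stop("negative distances")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9) stop("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop("nonzero diagonal")
  dimnames(m) <- list(labels, labels)
  class(m) <- c("dist_matrix", "matrix")
  m
}

#' Serialize an ultrametric tree to Newick text
#'
#' @param tree A \code{"upgma_tree"} (see \code{\link{upgma}}) or an
#'   \code{hclust} object with labels.
#' @param path Optional path; when given the text is also written to the file.
#' @return Newick string terminated by \code{";"}.
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "upgma_tree")) tree <- tree$hclust
  if (!inherits(tree, "hclust")) stop("tree must be an hclust or upgma_tree")
  labs <- tree$labels
  if (is.null(labs) || any(is.na(labs)) || any(!nzchar(labs)))
    stop("every leaf must be labelled")
  if (length(labs) == 1L) {
    txt <- paste0(labs, ";")
  } else {
    phy <- ape::as.phylo(tree)
    txt <- ape::write.tree(phy)
  }
  if (!is.null(path)) writeLines(txt, path)
  txt
}
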