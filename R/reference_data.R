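#' Published reference tables for the snail microsatellite study
#'
#' Plain-text copies of the published summary tables from the
#' \emph{Angulyagra polyzonata} (Guangxi freshwater snail) microsatellite
#' survey that this package's methods mirror: the transcriptome SSR census
#' counts, per-type and dominant-motif breakdowns, the nine-locus diversity
#' table, per-population diversity, the pairwise Fst/Nm matrix, the AMOVA
#' table and the Nei genetic-distance matrix. These are inputs for arithmetic
#' consistency checks (e.g. the census percentages, the F = 1 - Ho/He
#' identity, the island-model Nm identity) and for worked examples; the raw
#' reads and genotypes behind them are not public.
#'
#' @param name One of \code{"census_counts"}, \code{"type_counts"},
#'   \code{"motif_counts"}, \code{"locus_stats"}, \code{"pop_stats"},
#'   \code{"fst_nm"}, \code{"amova"}, \code{"distance"}.
#' @return A data.frame (\code{"fst_nm"} and \code{"distance"} return a
#'   matrix with population dimnames).
#' @export
snail_reference <- function(name = c("census_counts", "type_counts",
                                     "motif_counts", "locus_stats",
                                     "pop_stats", "fst_nm", "amova",
                                     "distance")) {
  name <- match.arg(name)
  file <- switch(name,
    census_counts = "snail_ssr_census_counts.csv",
    type_counts = "snail_ssr_type_counts.csv",
    motif_counts = "snail_ssr_motif_counts.csv",
    locus_stats = "snail_locus_stats.csv",
    pop_stats = "snail_pop_stats.csv",
    fst_nm = "snail_fst_nm.csv",
    amova = "snail_amova.csv",
    distance = "snail_genetic_distance.csv")
  path <- system.file("extdata", file, package = "ssrpopgen", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (name %in% c("fst_nm", "distance")) {
    m <- as.matrix(df[, -1L])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    return(m)
  }
  df
}

#' Split a combined Fst/Nm matrix into its two symmetric halves
#'
#' The combined layout carries gene flow Nm in the upper triangle and Fst in
#' the lower triangle.
#'
#' @param m Square matrix in the combined layout.
#' @return List with symmetric matrices \code{fst} and \code{nm}.
#' @export
split_fst_nm <- function(m) {
  stopifnot(nrow(m) == ncol(m))
  fst <- m; fst[upper.tri(fst)] <- t(m)[upper.tri(m)]
  diag(fst) <- 0
  nm <- m; nm[lower.tri(nm)] <- t(m)[lower.tri(m)]
  diag(nm) <- NA_real_
  list(fst = fst, nm = nm)
}
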