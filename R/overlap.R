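#' Donor inclusion for clonal-overlap analyses
#'
#' A donor enters the CD4 clonal-overlap analyses when it has repertoire
#' data in at least `min_subsets` CD4 subsets from *both* tissues and more
#' than `min_shared` clonotypes present in more than one of its CD4
#' samples. The shared-clone boundary is strict: a donor with exactly
#' `min_shared` shared clones is excluded.
#'
#' @param cohort a clone table.
#' @param lineage lineage the inclusion rule applies to (default CD4).
#' @param min_subsets minimum distinct subsets with data per tissue.
#' @param min_shared shared-clone threshold (strictly more required).
#' @return data.frame with one row per donor: subset counts per tissue,
#'   `n_shared_clones`, `included` and a semicolon-separated `reasons`
#'   column for exclusions.
#' @export
select_donors <- function(cohort, lineage = "CD4", min_subsets = 3L,
                          min_shared = 150L) {
  .check_clone_table(cohort, "select_donors() input")
  sub <- cohort[cohort$lineage == lineage, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("cohort has no %s samples", lineage), call. = FALSE)
  }
  tissues <- sort(unique(sub$tissue))
  donors <- sort(unique(cohort$donor_id))
  rows <- lapply(donors, function(d) {
    dsub <- sub[sub$donor_id == d, , drop = FALSE]
    n_per_tissue <- vapply(tissues, function(t) {
      length(unique(dsub$subset[dsub$tissue == t]))
    }, integer(1))
    per_sample <- unique(data.frame(sample = .sample_key(dsub),
                                    cdr3_nt = dsub$cdr3_nt,
                                    stringsAsFactors = FALSE))
    shared <- sum(table(per_sample$cdr3_nt) >= 2L)
    reasons <- character(0)
    for (t in tissues) {
      if (n_per_tissue[[t]] < min_subsets) {
        reasons <- c(reasons, sprintf("%s subsets < %d", t, min_subsets))
      }
    }
    if (shared <= min_shared) {
      reasons <- c(reasons, sprintf("shared clones <= %d", min_shared))
    }
    out <- data.frame(donor_id = d, stringsAsFactors = FALSE)
    for (t in tissues) out[[paste0("n_subsets_", t)]] <- n_per_tissue[[t]]
    out$n_shared_clones <- shared
    out$included <- length(reasons) == 0L
    out$reasons <- paste(reasons, collapse = "; ")
    out
  })
  do.call(rbind, rows)
}

#' Sample-by-clonotype frequency matrix under a sharing filter
#'
#' Builds the matrix behind the overlap heatmaps, clustering and MDS: rows
#' are samples, columns are clonotypes (CDR3 nucleotide keys, in
#' lexicographic order), values are within-sample clone frequencies
#' (computed on the full sample before any column is dropped, so row sums
#' never exceed 1). With the `"ge2"` filter only clonotypes present in
#' two or more of the matrix's samples are retained -- the cohort-scope
#' reading is "clones present in two or more samples", the donor-scope
#' reading (when the input is restricted to one donor's subsets) is
#' "clones present in more than one subset".
#'
#' @param cohort a clone table; restrict it to one donor's samples for
#'   donor-scope matrices.
#' @param filter `"ge2"` (default) or `"none"`.
#' @param lineage optional lineage restriction applied before building.
#' @return A numeric matrix of class `clone_matrix` with sample keys as
#'   row names, plus attributes `meta` (sample annotation data.frame) and
#'   `filter`.
#' @export
build_clone_matrix <- function(cohort, filter = c("ge2", "none"),
                               lineage = NULL) {
  filter <- match.arg(filter)
  .check_clone_table(cohort, "build_clone_matrix() input")
  if (!is.null(lineage)) {
    cohort <- cohort[cohort$lineage %in% lineage, , drop = FALSE]
  }
  collapsed <- collapse_cohort(cohort)
  keys <- .sample_key(collapsed)
  samples <- sort(unique(keys))
  if (length(samples) < 2L) {
    stop("a clone matrix needs at least 2 samples", call. = FALSE)
  }
  clones <- sort(unique(collapsed$cdr3_nt))
  mat <- matrix(0, nrow = length(samples), ncol = length(clones),
                dimnames = list(samples, clones))
  mat[cbind(match(keys, samples), match(collapsed$cdr3_nt, clones))] <-
    collapsed$frequency
  if (filter == "ge2") {
    mat <- mat[, colSums(mat > 0) >= 2L, drop = FALSE]
  }
  attr(mat, "meta") <- .split_key(samples)
  attr(mat, "filter") <- filter
  class(mat) <- c("clone_matrix", class(mat))
  mat
}

#' Top shared clonotypes of a donor matrix
#'
#' Orders the clonotypes of a (donor-scope, sharing-filtered) clone matrix
#' for overlap heatmaps: primarily by breadth (number of samples carrying
#' the clone, descending), then by summed frequency (descending), then by
#' lexicographic clone key; alternatively by summed frequency first.
#' Returns all clones when fewer than `n` exist.
#'
#' @param matrix a [build_clone_matrix()] result.
#' @param n number of clones to return (default 75).
#' @param rank_by `"breadth"` (default) or `"frequency"` for the primary
#'   sort key.
#' @return character vector of clonotype keys, best first.
#' @export
top_overlap_clones <- function(matrix, n = 75L,
                               rank_by = c("breadth", "frequency")) {
  rank_by <- match.arg(rank_by)
  breadth <- colSums(matrix > 0)
  total <- colSums(matrix)
  ord <- if (rank_by == "breadth") {
    order(-breadth, -total, colnames(matrix))
  } else {
    order(-total, -breadth, colnames(matrix))
  }
  head(colnames(matrix)[ord], n)
}
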