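#' Hierarchical clustering of one donor's subsets
#'
#' Agglomerative clustering of the subset frequency vectors of a
#' donor-scope clone matrix on pairwise Euclidean distances. Complete
#' linkage by default; single, average and Ward linkage are available.
#'
#' @param matrix a donor-scope [build_clone_matrix()] result (sharing
#'   filter applied).
#' @param linkage `"complete"` (default), `"single"`, `"average"` or
#'   `"ward.D2"`.
#' @return An [stats::hclust] tree whose labels are the sample keys, with
#'   the sample annotation attached as attribute `meta` and the linkage
#'   recorded in attribute `linkage`.
#' @export
donor_hclust <- function(matrix, linkage = c("complete", "single",
                                             "average", "ward.D2")) {
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2L) {
    stop("clustering needs at least 2 subsets", call. = FALSE)
  }
  hc <- hclust(dist(matrix, method = "euclidean"), method = linkage)
  attr(hc, "meta") <- attr(matrix, "meta")
  attr(hc, "linkage") <- linkage
  hc
}

#' Tissue concordance of a subset dendrogram
#'
#' Cuts the donor dendrogram into its two top-level clusters and asks, for
#' every *memory* subset, whether its tissue matches the majority tissue
#' of its cluster (majority over all leaves of the cluster; an exact tie
#' counts as non-concordant). Naive subsets take part in the clustering
#' but are not tallied. An alternative operationalization scores a memory
#' leaf by the majority tissue of the subtree it first merges with.
#'
#' @param tree a [donor_hclust()] result (or any hclust whose labels are
#'   sample keys, with a `meta` attribute or `meta` supplied).
#' @param meta sample annotation data.frame with `sample_id`, `tissue`,
#'   `subset` (taken from the tree attribute when missing).
#' @param rule `"top2_majority"` (default) or `"first_merge"`.
#' @return list with `concordant`, `total` and a per-leaf `detail`
#'   data.frame.
#' @export
tissue_concordance <- function(tree, meta = NULL,
                               rule = c("top2_majority", "first_merge")) {
  rule <- match.arg(rule)
  if (is.null(meta)) meta <- attr(tree, "meta")
  if (is.null(meta)) {
    stop("sample annotation (meta) is required", call. = FALSE)
  }
  meta <- meta[match(tree$labels, meta$sample_id), , drop = FALSE]
  if (length(tree$labels) < 2L) {
    stop("concordance needs at least 2 leaves", call. = FALSE)
  }
  if (length(unique(meta$tissue)) < 2L) {
    stop("concordance needs leaves from at least 2 tissues", call. = FALSE)
  }
  is_memory <- meta$subset != "naive"
  if (rule == "top2_majority") {
    cl <- cutree(tree, k = 2L)
    concordant <- vapply(seq_along(tree$labels), function(i) {
      members <- meta$tissue[cl == cl[i]]
      tt <- table(members)
      winners <- names(tt)[tt == max(tt)]
      length(winners) == 1L && winners == meta$tissue[i]
    }, logical(1))
  } else {
    concordant <- .first_merge_concordance(tree, meta)
  }
  detail <- data.frame(sample_id = tree$labels, tissue = meta$tissue,
                       subset = meta$subset, memory = is_memory,
                       concordant = concordant, stringsAsFactors = FALSE)
  list(concordant = sum(concordant[is_memory]), total = sum(is_memory),
       detail = detail)
}

# concordance by the majority tissue of the subtree each leaf first
# merges with
.first_merge_concordance <- function(tree, meta) {
  n <- length(tree$labels)
  # leaves under each internal node
  members <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    members[[k]] <- unlist(lapply(tree$merge[k, ], function(j) {
      if (j < 0) -j else members[[j]]
    }))
  }
  vapply(seq_len(n), function(i) {
    k <- which(apply(tree$merge, 1L, function(r) any(r == -i)))[1L]
    other <- tree$merge[k, tree$merge[k, ] != -i]
    partner <- if (other < 0) -other else members[[other]]
    tt <- table(meta$tissue[partner])
    winners <- names(tt)[tt == max(tt)]
    length(winners) == 1L && winners == meta$tissue[i]
  }, logical(1))
}

#' Exact binomial test of tissue concordance
#'
#' Pools the per-donor tallies and tests the total number of
#' tissue-concordant memory subsets against the null that each subset
#' lands on either side of its donor's top split with probability
#' `p0 = 0.5`. The two-sided P value is the exact binomial mass of all
#' outcomes no more probable than the observed one (for `p0 = 0.5` this
#' equals twice the smaller tail, capped at 1).
#'
#' @param concordant successes: summed concordant memory subsets, or a
#'   list of per-donor [tissue_concordance()] results to be summed.
#' @param total trials: summed memory subsets (ignored when `concordant`
#'   is a list).
#' @param p0 null concordance probability.
#' @return list with `k`, `n` and `p_value`.
#' @examples
#' binomial_concordance_test(32, 35)$p_value  # 4.18e-7
#' @export
binomial_concordance_test <- function(concordant, total = NULL, p0 = 0.5) {
  if (is.list(concordant)) {
    k <- sum(vapply(concordant, `[[`, numeric(1), "concordant"))
    n <- sum(vapply(concordant, `[[`, numeric(1), "total"))
  } else {
    k <- concordant
    n <- total
  }
  if (is.null(n) || n < 1L) stop("total must be >= 1", call. = FALSE)
  if (k > n || k < 0) stop("need 0 <= concordant <= total", call. = FALSE)
  list(k = as.integer(k), n = as.integer(n),
       p_value = binom.test(k, n, p = p0)$p.value)
}

#' Per-donor clustering and pooled concordance test for a cohort
#'
#' Runs the full tissue-concordance analysis: applies the donor inclusion
#' rule ([select_donors()]), builds each included donor's CD4 subset
#' matrix under the shared-clone filter, clusters it ([donor_hclust()]),
#' tallies tissue concordance of the memory subsets and pools the tallies
#' into the exact binomial test.
#'
#' @param cohort a clone table.
#' @param lineage lineage analysed (default CD4).
#' @param linkage linkage passed to [donor_hclust()].
#' @param rule concordance rule passed to [tissue_concordance()].
#' @param min_subsets,min_shared inclusion thresholds for
#'   [select_donors()].
#' @return An object of class `concordance_result`: list with `inclusion`
#'   (the [select_donors()] table), `donors` (per-donor list with the
#'   tree and tally), `k`, `n`, `p_value`, `linkage`, `rule`.
#' @export
cohort_concordance <- function(cohort, lineage = "CD4",
                               linkage = "complete",
                               rule = "top2_majority",
                               min_subsets = 3L, min_shared = 150L) {
  inclusion <- select_donors(cohort, lineage = lineage,
                             min_subsets = min_subsets,
                             min_shared = min_shared)
  included <- inclusion$donor_id[inclusion$included]
  donors <- lapply(included, function(d) {
    sub <- cohort[cohort$donor_id == d, , drop = FALSE]
    mat <- build_clone_matrix(sub, filter = "ge2", lineage = lineage)
    tree <- donor_hclust(mat, linkage = linkage)
    conc <- tissue_concordance(tree, rule = rule)
    list(donor_id = d, tree = tree, concordant = conc$concordant,
         total = conc$total, detail = conc$detail)
  })
  names(donors) <- included
  k <- sum(vapply(donors, `[[`, numeric(1), "concordant"))
  n <- sum(vapply(donors, `[[`, numeric(1), "total"))
  test <- if (n > 0) binomial_concordance_test(k, n) else
    list(k = 0L, n = 0L, p_value = NA_real_)
  structure(list(inclusion = inclusion, donors = donors, k = test$k,
                 n = test$n, p_value = test$p_value, linkage = linkage,
                 rule = rule),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Tissue concordance: %d of %d memory subsets (%d/%d donors included)\n",
              x$k, x$n, sum(x$inclusion$included), nrow(x$inclusion)))
  cat(sprintf("Exact binomial test (p0 = 0.5): P = %.3g\n", x$p_value))
  cat(sprintf("Linkage: %s; rule: %s\n", x$linkage, x$rule))
  invisible(x)
}

#' Newick export of a donor dendrogram
#'
#' @param tree an [donor_hclust()] result.
#' @param path optional file path; when `NULL` the newick string is
#'   returned.
#' @return newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
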