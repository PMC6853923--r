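#' Frequency-independent V-J usage table
#'
#' Tallies unique clonotypes into a V x J count matrix, counting each
#' clone exactly once regardless of its read count or frequency. When
#' pooling across donors, a clonotype is counted once per donor in which
#' it occurs: identical CDR3 sequences in different individuals arise
#' from independent rearrangement events. Within a donor and scope, a
#' clonotype present in several subsets contributes a single count. V or
#' J labels outside the catalog are tallied under `"unassigned"` with a
#' warning.
#'
#' @param samples a clone table.
#' @param subset,tissue,lineage optional scope restrictions (character
#'   vectors) applied before tallying.
#' @param pooled pool donors into one table (default); otherwise a list
#'   of per-donor tables is returned.
#' @param catalog a [segment_catalog()] anchoring the table's rows and
#'   columns.
#' @return An object of class `vj_usage`: list with `counts` (V x J
#'   integer matrix), `v_margin`, `j_margin`, `n_clones` and `scope`.
#'   With `pooled = FALSE`, a named list of such objects.
#' @export
usage_counts <- function(samples, subset = NULL, tissue = NULL,
                         lineage = NULL, pooled = TRUE,
                         catalog = segment_catalog()) {
  .check_clone_table(samples, "usage_counts() input")
  sel <- rep(TRUE, nrow(samples))
  if (!is.null(subset)) sel <- sel & samples$subset %in% subset
  if (!is.null(tissue)) sel <- sel & samples$tissue %in% tissue
  if (!is.null(lineage)) sel <- sel & samples$lineage %in% lineage
  scoped <- samples[sel, , drop = FALSE]
  scope <- list(subset = subset, tissue = tissue, lineage = lineage)
  if (!pooled) {
    donors <- sort(unique(scoped$donor_id))
    out <- lapply(donors, function(d) {
      .tally_usage(scoped[scoped$donor_id == d, , drop = FALSE],
                   catalog, c(scope, donor = d))
    })
    names(out) <- donors
    return(out)
  }
  .tally_usage(scoped, catalog, scope)
}

.tally_usage <- function(scoped, catalog, scope) {
  if (nrow(scoped) > 0L) {
    # one count per clonotype per donor, highest-count row carries V/J
    ord <- order(scoped$donor_id, scoped$cdr3_nt, -scoped$read_count,
                 scoped$v_gene, scoped$j_gene)
    scoped <- scoped[ord, , drop = FALSE]
    scoped <- scoped[!duplicated(scoped[c("donor_id", "cdr3_nt")]), ,
                     drop = FALSE]
  }
  v_levels <- catalog$v_names
  j_levels <- catalog$j_names
  unknown_v <- setdiff(unique(scoped$v_gene), v_levels)
  unknown_j <- setdiff(unique(scoped$j_gene), j_levels)
  if (length(unknown_v) + length(unknown_j) > 0L) {
    warning(sprintf("segment label(s) outside catalog counted as unassigned: %s",
                    paste(c(unknown_v, unknown_j), collapse = ", ")),
            call. = FALSE)
    if (length(unknown_v)) v_levels <- c(v_levels, "unassigned")
    if (length(unknown_j)) j_levels <- c(j_levels, "unassigned")
    scoped$v_gene[scoped$v_gene %in% unknown_v] <- "unassigned"
    scoped$j_gene[scoped$j_gene %in% unknown_j] <- "unassigned"
  }
  counts <- table(factor(scoped$v_gene, levels = v_levels),
                  factor(scoped$j_gene, levels = j_levels))
  counts <- matrix(as.integer(counts), nrow = length(v_levels),
                   dimnames = list(v_levels, j_levels))
  structure(list(counts = counts, v_margin = rowSums(counts),
                 j_margin = colSums(counts), n_clones = sum(counts),
                 scope = scope),
            class = "vj_usage")
}

#' Over/under-representation scores for segment usage
#'
#' Scores each V segment against a uniform null (expected count
#' `total / |V|`) and each V-J cell against the margin-product null
#' (expected `rowTotal * colTotal / total`). Both a Pearson residual
#' `(obs - exp) / sqrt(exp)` and, per V segment, an exact binomial P
#' value against the null proportion are reported. Segments with a
#' residual above `+threshold` are flagged over-represented, below
#' `-threshold` under-represented. Cells with zero expectation are
#' skipped with a warning.
#'
#' @param table a [usage_counts()] result.
#' @param threshold residual flag threshold (default 3).
#' @return list with `v_scores` (per-V data.frame: `count`, `expected`,
#'   `residual`, `p_value`, `flag`), `cell_scores` (long-format per-cell
#'   data.frame under the margin-product null), `flagged_over`,
#'   `flagged_under`, `threshold`.
#' @export
representation_scores <- function(table, threshold = 3) {
  if (!inherits(table, "vj_usage")) {
    stop("table must be a usage_counts() result", call. = FALSE)
  }
  total <- table$n_clones
  if (total == 0L) stop("usage table is empty", call. = FALSE)
  v <- table$v_margin
  nv <- length(v)
  exp_v <- rep(total / nv, nv)
  resid_v <- (v - exp_v) / sqrt(exp_v)
  p_v <- vapply(v, function(k) binom.test(k, total, p = 1 / nv)$p.value,
                numeric(1))
  flag <- ifelse(resid_v > threshold, "over",
                 ifelse(resid_v < -threshold, "under", "none"))
  v_scores <- data.frame(v_gene = names(v), count = as.integer(v),
                         expected = exp_v, residual = resid_v,
                         p_value = p_v, flag = flag,
                         stringsAsFactors = FALSE, row.names = NULL)

  cnt <- table$counts
  exp_cell <- outer(table$v_margin, table$j_margin) / total
  keep <- exp_cell > 0
  if (any(!keep)) {
    warning(sprintf("%d cell(s) with zero expectation skipped", sum(!keep)),
            call. = FALSE)
  }
  idx <- which(keep, arr.ind = TRUE)
  cell_scores <- data.frame(
    v_gene = rownames(cnt)[idx[, 1L]], j_gene = colnames(cnt)[idx[, 2L]],
    count = as.integer(cnt[keep]), expected = exp_cell[keep],
    residual = (cnt[keep] - exp_cell[keep]) / sqrt(exp_cell[keep]),
    stringsAsFactors = FALSE
  )
  cell_scores <- cell_scores[order(cell_scores$v_gene, cell_scores$j_gene), ,
                             drop = FALSE]
  rownames(cell_scores) <- NULL
  list(v_scores = v_scores, cell_scores = cell_scores,
       flagged_over = v_scores$v_gene[flag == "over"],
       flagged_under = v_scores$v_gene[flag == "under"],
       threshold = threshold)
}
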