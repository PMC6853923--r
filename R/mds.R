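#' Pooled classical multidimensional scaling of repertoire samples
#'
#' Classical (Torgerson) MDS of all samples of a cohort-scope clone
#' matrix on pairwise Euclidean distances between the clone frequency
#' vectors. Coordinates are deterministic up to reflection; the sign of
#' each axis is fixed so that its first nonzero coordinate is positive.
#' In full-rank mode every axis with a positive eigenvalue is kept, in
#' which case embedding distances reproduce the input distances exactly
#' (Euclidean input implies a positive semi-definite Gram matrix).
#'
#' @param matrix a [build_clone_matrix()] result (cohort scope,
#'   shared-clone filter).
#' @param n_dims number of embedding dimensions (default 2).
#' @param full_rank keep all positive-eigenvalue axes instead.
#' @return An object of class `repertoire_mds`: list with `points`
#'   (samples x dims), `eig` (all eigenvalues), `n_negative_eig`
#'   (number of negative eigenvalues truncated) and `meta`.
#' @export
pooled_mds <- function(matrix, n_dims = 2L, full_rank = FALSE) {
  if (nrow(matrix) < 2L) {
    stop("MDS needs at least 2 samples", call. = FALSE)
  }
  if (all(matrix == 0)) {
    stop("degenerate clone matrix: all frequencies are zero", call. = FALSE)
  }
  if (!full_rank && n_dims < 1L) stop("n_dims must be >= 1", call. = FALSE)
  d <- dist(unclass(matrix), method = "euclidean")
  k <- if (full_rank) nrow(matrix) - 1L else min(n_dims, nrow(matrix) - 1L)
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (full_rank && ncol(pts) > 0L) {
    keep <- fit$eig[seq_len(ncol(pts))] > max(fit$eig) * 1e-12
    pts <- pts[, keep, drop = FALSE]
  }
  # reflection convention: first nonzero loading of each axis positive
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 0)
    if (length(nz) > 0L && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  structure(list(points = pts, eig = fit$eig,
                 n_negative_eig = sum(fit$eig < 0),
                 meta = attr(matrix, "meta")),
            class = "repertoire_mds")
}

#' Per-donor MDS distance groups
#'
#' Summarizes each donor's embedding distances into the comparison groups
#' used for tissue-level boxplots, all as arithmetic means of pairwise
#' embedding distances among the donor's CD4 subsets:
#' * `d_naive_mem_<tissue>`: mean distance between the tissue's naive
#'   sample and each of its memory samples, per tissue;
#' * `d_within_<tissue>`: mean pairwise distance among the tissue's
#'   memory samples;
#' * `d_cross_identical`: mean distance between the two tissues'
#'   instances of the same memory subset.
#' Entries whose required samples are missing are `NA` (never imputed);
#' the reasons are recorded in the `missing` attribute.
#'
#' @param mds a [pooled_mds()] result.
#' @param lineage lineage summarized (default CD4).
#' @return data.frame with one row per donor and one column per distance
#'   group, plus attribute `missing` listing skipped entries.
#' @export
distance_groups <- function(mds, lineage = "CD4") {
  meta <- mds$meta
  pts <- mds$points
  sel <- meta$lineage == lineage
  meta <- meta[sel, , drop = FALSE]
  pts <- pts[sel, , drop = FALSE]
  tissues <- sort(unique(meta$tissue))
  donors <- sort(unique(meta$donor_id))
  pdist <- function(a, b) sqrt(sum((pts[a, ] - pts[b, ])^2))
  missing <- character(0)
  rows <- lapply(donors, function(d) {
    dm <- meta$donor_id == d
    out <- list(donor_id = d)
    for (t in tissues) {
      naive <- which(dm & meta$tissue == t & meta$subset == "naive")
      mem <- which(dm & meta$tissue == t & meta$subset != "naive")
      col_nm <- paste0("d_naive_mem_", t)
      col_wi <- paste0("d_within_", t)
      if (length(naive) == 1L && length(mem) >= 1L) {
        out[[col_nm]] <- mean(vapply(mem, function(m) pdist(naive, m),
                                     numeric(1)))
      } else {
        out[[col_nm]] <- NA_real_
        missing <<- c(missing, sprintf("%s/%s: naive or memory sample absent",
                                       d, col_nm))
      }
      if (length(mem) >= 2L) {
        prs <- utils::combn(mem, 2L)
        out[[col_wi]] <- mean(apply(prs, 2L, function(p) pdist(p[1], p[2])))
      } else {
        out[[col_wi]] <- NA_real_
        missing <<- c(missing, sprintf("%s/%s: fewer than 2 memory samples",
                                       d, col_wi))
      }
    }
    subsets <- setdiff(unique(meta$subset[dm]), "naive")
    cross <- vapply(subsets, function(s) {
      a <- which(dm & meta$tissue == tissues[1] & meta$subset == s)
      b <- which(dm & meta$tissue == tissues[2] & meta$subset == s)
      if (length(a) == 1L && length(b) == 1L) pdist(a, b) else NA_real_
    }, numeric(1))
    if (all(is.na(cross))) {
      out$d_cross_identical <- NA_real_
      missing <<- c(missing,
                    sprintf("%s/d_cross_identical: no subset present in both tissues", d))
    } else {
      out$d_cross_identical <- mean(cross, na.rm = TRUE)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "missing") <- missing
  out
}

#' Wilcoxon rank-sum comparison of two distance groups
#'
#' Exact two-sided Wilcoxon rank-sum test when the smaller group has at
#' most 8 values and there are no ties; normal approximation with tie
#' correction otherwise. Two groups with entirely identical values give
#' P = 1 with a warning.
#'
#' @param group_a,group_b numeric vectors (NAs dropped).
#' @return list with `U` (rank-sum statistic of `group_a`), `p_value` and
#'   `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both groups; P = 1", call. = FALSE)
    return(list(U = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                     correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Standard distance-group comparisons
#'
#' Applies [wilcoxon_rank_sum()] across donors to the canonical pairs of
#' distance groups: naive-vs-memory against within-tissue memory (per
#' tissue), and the cross-tissue identical-subset distances against
#' naive-vs-memory (pooled over tissues) and against each tissue's
#' within-tissue memory distances.
#'
#' @param groups a [distance_groups()] result.
#' @return data.frame with columns `comparison`, `U`, `p_value`, `n_a`,
#'   `n_b`.
#' @export
compare_distance_groups <- function(groups) {
  cols <- names(groups)
  within_cols <- grep("^d_within_", cols, value = TRUE)
  naive_cols <- grep("^d_naive_mem_", cols, value = TRUE)
  pairs <- list()
  for (w in within_cols) {
    t <- sub("^d_within_", "", w)
    nm <- paste0("d_naive_mem_", t)
    if (nm %in% naive_cols) {
      pairs[[sprintf("naive_mem_%s vs within_%s", t, t)]] <- list(
        a = groups[[nm]], b = groups[[w]])
    }
  }
  pooled_naive <- unlist(groups[naive_cols], use.names = FALSE)
  pairs[["naive_mem_pooled vs cross_identical"]] <-
    list(a = pooled_naive, b = groups$d_cross_identical)
  for (w in within_cols) {
    t <- sub("^d_within_", "", w)
    pairs[[sprintf("within_%s vs cross_identical", t)]] <-
      list(a = groups[[w]], b = groups$d_cross_identical)
  }
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]]$a
    b <- pairs[[nm]]$b
    res <- wilcoxon_rank_sum(a, b)
    data.frame(comparison = nm, U = res$U, p_value = res$p_value,
               n_a = sum(!is.na(a)), n_b = sum(!is.na(b)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
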