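#' Analytic rarefaction curve of a repertoire sample
#'
#' Expected number of unique clonotypes recovered when subsampling `m`
#' reads without replacement from a sample with clone counts n_i and
#' total N:
#' \deqn{E[S_m] = \sum_i \left(1 - \binom{N - n_i}{m} / \binom{N}{m}\right)}
#' evaluated through `lchoose()` so the binomial ratios stay stable at
#' sequencing-scale depths.
#'
#' @param x a `repertoire_sample` from [collapse_clones()], or a numeric
#'   vector of clone read counts.
#' @param depths increasing subsample sizes; defaults to 20 log-spaced
#'   depths from 1 to N.
#' @return A `rarefaction_curve` data.frame with columns `depth` and
#'   `expected_unique`, plus attributes `total_reads` and `total_unique`.
#' @examples
#' rarefy_sample(c(50, 30, 20), depths = c(1, 10, 100))
#' @export
rarefy_sample <- function(x, depths = NULL) {
  counts <- if (is.data.frame(x)) x$read_count else x
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("cannot rarefy an empty sample", call. = FALSE)
  }
  N <- sum(counts)
  S <- length(counts)
  if (is.null(depths)) {
    depths <- unique(round(exp(seq(0, log(N), length.out = 20L))))
  }
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1L) || any(depths > N)) {
    stop(sprintf("depths must lie in [1, %d]", N), call. = FALSE)
  }
  expected <- vapply(depths, function(m) {
    # log-space ratio C(N - n_i, m) / C(N, m); clones with n_i > N - m
    # cannot be missed
    lr <- lchoose(N - counts, m) - lchoose(N, m)
    sum(1 - exp(lr))
  }, numeric(1))
  out <- data.frame(depth = depths, expected_unique = expected)
  attr(out, "total_reads") <- N
  attr(out, "total_unique") <- S
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Clonality of a repertoire sample
#'
#' One minus the Pielou evenness of the clone frequency distribution:
#' `1 - H / log(S)` with `H` the Shannon entropy of the frequencies and
#' `S` the number of clonotypes. 0 means a perfectly even repertoire, 1 a
#' monoclonal one. A single-clone sample has clonality 1 by convention
#' (the normalization `log(S)` is degenerate there).
#'
#' @param x a `repertoire_sample`, or a numeric vector of clone
#'   frequencies or counts (normalized internally).
#' @return clonality score in \[0, 1\].
#' @examples
#' clonality(rep(1, 10))      # 0: maximal evenness
#' clonality(c(0.9, 0.1))     # ~0.531
#' @export
clonality <- function(x) {
  p <- if (is.data.frame(x)) x$frequency else x
  p <- p[p > 0]
  if (length(p) == 0L) {
    stop("clonality is undefined for an empty sample", call. = FALSE)
  }
  p <- p / sum(p)
  S <- length(p)
  if (S == 1L) return(1)
  H <- -sum(p * log(p))
  1 - H / log(S)
}

#' Cohort-wide unique clone census
#'
#' Counts unique clonotypes (keyed by CDR3 nucleotide sequence) across all
#' samples of a cohort and the fraction observed in two or more samples.
#'
#' @param cohort a clone table covering one or more samples.
#' @return list with `total_unique`, `n_multi_sample` and
#'   `fraction_multi_sample`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_donors = 2,
#'   lineages = "CD4", pool_size_per_tissue = 100, sample_depth = 200))
#' unique_clone_census(cohort)
#' @export
unique_clone_census <- function(cohort) {
  .check_clone_table(cohort, "unique_clone_census() input")
  if (nrow(cohort) == 0L) {
    stop("census needs at least one sample with clones", call. = FALSE)
  }
  per_sample <- unique(data.frame(sample = .sample_key(cohort),
                                  cdr3_nt = cohort$cdr3_nt,
                                  stringsAsFactors = FALSE))
  n_samples <- table(per_sample$cdr3_nt)
  total <- length(n_samples)
  multi <- sum(n_samples >= 2L)
  list(total_unique = total, n_multi_sample = multi,
       fraction_multi_sample = multi / total)
}
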