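#' TRBV/TRBJ segment catalog
#'
#' A catalog of human TRB V and J gene-segment labels used by the synthetic
#' generator and by [usage_counts()] to anchor usage tables. The default V
#' list covers commonly observed human TRBV segments, including the
#' segments most relevant to memory-repertoire usage-bias analyses
#' (V5-1, V7-2, V20-1 among frequently used; V5-2, V22-2, V26 among rarely
#' used segments); the default J list is the full TRBJ1/TRBJ2 set.
#'
#' @param v_names character vector of unique TRBV labels.
#' @param j_names character vector of unique TRBJ labels.
#' @return An object of class `segment_catalog`: a list with elements
#'   `v_names` and `j_names`.
#' @examples
#' cat <- segment_catalog()
#' length(cat$v_names)
#' @export
segment_catalog <- function(v_names = c(
                              "V2", "V3-1", "V4-1", "V5-1", "V5-2", "V6-1",
                              "V6-5", "V7-2", "V9", "V10-3", "V11-2",
                              "V12-3", "V14", "V15", "V18", "V19", "V20-1",
                              "V22-2", "V25-1", "V26", "V27", "V28",
                              "V29-1", "V30"),
                            j_names = c(
                              "J1-1", "J1-2", "J1-3", "J1-4", "J1-5",
                              "J1-6", "J2-1", "J2-2", "J2-3", "J2-4",
                              "J2-5", "J2-6", "J2-7")) {
  v_names <- as.character(v_names)
  j_names <- as.character(j_names)
  if (anyDuplicated(v_names) || anyDuplicated(j_names)) {
    stop("segment labels must be unique", call. = FALSE)
  }
  if (length(v_names) < 2L || length(j_names) < 1L) {
    stop("catalog needs at least two V and one J segment", call. = FALSE)
  }
  structure(list(v_names = v_names, j_names = j_names),
            class = "segment_catalog")
}

#' Configuration for the synthetic repertoire generator
#'
#' Defines a multi-donor, two-tissue cohort of T cell subset repertoires
#' with a controllable sharing structure. Each memory sample draws its
#' reads from a three-way mixture: the progenitor pool of its own tissue
#' (probability `share_within`), the progenitor pool of the donor's other
#' tissue (probability `share_cross`, modelling donor-level trafficking
#' between the tissues), and a sample-private pool (the remainder). Naive
#' samples are near-private: they draw from a much larger uniform private
#' space and touch the two tissue pools only at rate `share_cross` in
#' total. Pool clone frequencies follow a discrete power law with exponent
#' `clone_size_alpha`.
#'
#' Mixing `share_cross` as a draw from the *opposite-tissue* pool makes the
#' two tissues exchangeable when `share_within == share_cross`: the
#' expected clonal similarity of two memory samples then no longer depends
#' on whether they sit in the same tissue, so tissue-concordant clustering
#' degrades to chance. This gives the generator a well-defined null.
#'
#' @param n_donors number of donors.
#' @param lineages,subsets character vectors; their cross defines the
#'   phenotypes generated per (donor, tissue). `"naive"` is special-cased
#'   as the near-private subset.
#' @param tissues exactly two tissue labels.
#' @param pool_size_per_tissue distinct progenitor clonotypes per
#'   (donor, tissue) memory pool.
#' @param sample_depth reads drawn per sample.
#' @param share_within probability a memory read is drawn from its own
#'   tissue's shared pool.
#' @param share_cross probability a memory read is drawn from the donor's
#'   opposite-tissue pool.
#' @param clone_size_alpha power-law exponent of pool clone frequencies
#'   (rank r has weight proportional to r^-alpha).
#' @param vj_bias optional named numeric vector of sampling weights for V
#'   and/or J segment labels; unlisted segments have weight 1.
#' @param naive_diversity_factor multiplier on `pool_size_per_tissue`
#'   giving the size of the uniform private space of naive samples.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration including the seed.
#' @param catalog a [segment_catalog()].
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_donors = 11L,
                             lineages = c("CD4", "CD8"),
                             subsets = c("naive", "CM", "EM", "TRM"),
                             tissues = c("lung", "LDLN"),
                             pool_size_per_tissue = 2000L,
                             sample_depth = 5000L,
                             share_within = 0.3,
                             share_cross = 0.02,
                             clone_size_alpha = 1,
                             vj_bias = NULL,
                             naive_diversity_factor = 10,
                             seed = 1L,
                             catalog = segment_catalog()) {
  if (length(tissues) != 2L || anyDuplicated(tissues)) {
    stop("exactly two distinct tissues are required", call. = FALSE)
  }
  probs <- c(share_within = share_within, share_cross = share_cross)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("share_within and share_cross must lie in [0, 1]", call. = FALSE)
  }
  if (share_within + share_cross > 1) {
    stop("share_within + share_cross must not exceed 1", call. = FALSE)
  }
  counts <- c(n_donors = n_donors, pool_size_per_tissue = pool_size_per_tissue,
              sample_depth = sample_depth)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("n_donors, pool_size_per_tissue and sample_depth must be positive integers",
         call. = FALSE)
  }
  if (naive_diversity_factor < 1) {
    stop("naive_diversity_factor must be >= 1", call. = FALSE)
  }
  if (!is.null(vj_bias)) {
    if (is.null(names(vj_bias)) || any(vj_bias < 0)) {
      stop("vj_bias must be a named vector of non-negative weights",
           call. = FALSE)
    }
    known <- c(catalog$v_names, catalog$j_names)
    unknown <- setdiff(names(vj_bias), known)
    if (length(unknown) > 0L) {
      stop(sprintf("vj_bias names not in catalog: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(
    n_donors = as.integer(n_donors), lineages = lineages, subsets = subsets,
    tissues = tissues, pool_size_per_tissue = as.integer(pool_size_per_tissue),
    sample_depth = as.integer(sample_depth), share_within = share_within,
    share_cross = share_cross, clone_size_alpha = clone_size_alpha,
    vj_bias = vj_bias, naive_diversity_factor = naive_diversity_factor,
    seed = as.integer(seed), catalog = catalog
  ), class = "synthetic_config")
}

# the 61 sense codons; sampling from these keeps every sequence productive
.sense_codons <- local({
  nt <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# Random in-frame, stop-free CDR3 nucleotide sequences (9-18 codons).
.random_cdr3 <- function(n, min_codons = 9L, max_codons = 18L) {
  if (n == 0L) return(character(0))
  len <- sample(seq.int(min_codons, max_codons), n, replace = TRUE)
  out <- character(n)
  for (L in sort(unique(len))) {
    idx <- which(len == L)
    m <- matrix(sample(.sense_codons, length(idx) * L, replace = TRUE),
                nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out
}

.segment_weights <- function(labels, bias) {
  w <- rep(1, length(labels))
  if (!is.null(bias)) {
    hit <- match(names(bias), labels)
    w[hit[!is.na(hit)]] <- bias[!is.na(hit)]
  }
  w / sum(w)
}

#' Simulate a set of distinct clonotypes
#'
#' Draws `n` random in-frame, stop-free CDR3 nucleotide sequences (9-18
#' codons) and assigns each a V and J segment sampled independently with
#' the weights in `vj_bias` (unlisted segments weight 1). This is the
#' clonotype primitive used by [generate_cohort()]; it is exported so that
#' segment-usage analyses can be exercised on clone sets with a planted,
#' known bias.
#'
#' @param n number of clonotypes.
#' @param catalog a [segment_catalog()].
#' @param vj_bias optional named weight vector (see [synthetic_config()]).
#' @param seed optional integer; when given, draws use a private seeded
#'   stream and the caller's RNG state is untouched.
#' @return data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`.
#' @examples
#' head(simulate_clonotypes(5, seed = 1))
#' @export
simulate_clonotypes <- function(n, catalog = segment_catalog(),
                                vj_bias = NULL, seed = NULL) {
  draw <- function() {
    data.frame(
      cdr3_nt = .random_cdr3(n),
      v_gene = sample(catalog$v_names, n, replace = TRUE,
                      prob = .segment_weights(catalog$v_names, vj_bias)),
      j_gene = sample(catalog$j_names, n, replace = TRUE,
                      prob = .segment_weights(catalog$j_names, vj_bias)),
      stringsAsFactors = FALSE
    )
  }
  out <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  out$cdr3_aa <- translate_cdr3(out$cdr3_nt)
  out[, c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene")]
}

#' Generate a synthetic multi-donor two-tissue clone cohort
#'
#' Produces one clone table row per (sample, clonotype) for every
#' (donor, tissue, lineage, subset) combination in the configuration,
#' deterministic given the seed. See [synthetic_config()] for the sharing
#' model. All generated sequences are productive by construction;
#' non-productive rows can be planted afterwards with
#' [inject_nonproductive()].
#'
#' @param config a [synthetic_config()].
#' @return A `data.frame` (class `clone_cohort`) with the native clone
#'   table columns `donor_id`, `tissue`, `lineage`, `subset`, `cdr3_nt`,
#'   `cdr3_aa`, `v_gene`, `j_gene`, `read_count`, `productive`.
#' @examples
#' cfg <- synthetic_config(n_donors = 2, lineages = "CD4",
#'                         pool_size_per_tissue = 100, sample_depth = 300,
#'                         seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$tissue, cohort$subset)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be created by synthetic_config()", call. = FALSE)
  }
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  rows <- .with_seed(config$seed, {
    lapply(donors, function(d) .generate_donor(d, config))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$cdr3_aa <- translate_cdr3(out$cdr3_nt)
  out$productive <- TRUE
  out <- out[, c("donor_id", "tissue", "lineage", "subset", "cdr3_nt",
                 "cdr3_aa", "v_gene", "j_gene", "read_count", "productive")]
  class(out) <- c("clone_cohort", "data.frame")
  out
}

# One donor: two tissue pools with power-law weights plus per-sample
# private pools; memory mixes (own pool, other pool, private) with
# probabilities (share_within, share_cross, rest); naive mixes
# (share_cross/2, share_cross/2, rest) over a larger uniform private space.
.generate_donor <- function(donor, config) {
  P <- config$pool_size_per_tissue
  w <- seq_len(P)^(-config$clone_size_alpha)
  w <- w / sum(w)
  t1 <- config$tissues[1]
  t2 <- config$tissues[2]

  grid <- expand.grid(tissue = config$tissues, lineage = config$lineages,
                      subset = config$subsets, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  draws <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tissue <- grid$tissue[i]
    naive <- identical(grid$subset[i], "naive")
    if (naive) {
      M <- round(P * config$naive_diversity_factor)
      p <- c(w * config$share_cross / 2, w * config$share_cross / 2,
             rep((1 - config$share_cross) / M, M))
    } else {
      M <- P
      p_priv <- 1 - config$share_within - config$share_cross
      own <- w * config$share_within
      oth <- w * config$share_cross
      p <- if (tissue == t1) c(own, oth, rep(p_priv / M, M)) else
                             c(oth, own, rep(p_priv / M, M))
    }
    cnt <- rmultinom(1L, config$sample_depth, p)[, 1L]
    nz <- which(cnt > 0L)
    src <- ifelse(nz <= P, "pool1", ifelse(nz <= 2L * P, "pool2", "private"))
    idx <- ifelse(nz <= P, nz, ifelse(nz <= 2L * P, nz - P, nz - 2L * P))
    draws[[i]] <- data.frame(sample = i, source = src, index = idx,
                             read_count = cnt[nz], stringsAsFactors = FALSE)
  }
  all_draws <- do.call(rbind, draws)

  # materialize sequences + V/J only for observed pool members, in sorted
  # index order so the mapping is deterministic
  pool_clones <- lapply(c("pool1", "pool2"), function(src) {
    obs <- sort(unique(all_draws$index[all_draws$source == src]))
    cl <- .draw_clonotypes(length(obs), config)
    cl$index <- obs
    cl
  })
  names(pool_clones) <- c("pool1", "pool2")

  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dr <- draws[[i]]
    cl <- data.frame(cdr3_nt = character(nrow(dr)),
                     v_gene = character(nrow(dr)),
                     j_gene = character(nrow(dr)), stringsAsFactors = FALSE)
    for (src in c("pool1", "pool2")) {
      sel <- dr$source == src
      if (any(sel)) {
        m <- match(dr$index[sel], pool_clones[[src]]$index)
        cl[sel, ] <- pool_clones[[src]][m, c("cdr3_nt", "v_gene", "j_gene")]
      }
    }
    sel <- dr$source == "private"
    if (any(sel)) {
      cl[sel, ] <- .draw_clonotypes(sum(sel), config)
    }
    res[[i]] <- data.frame(
      donor_id = donor, tissue = grid$tissue[i], lineage = grid$lineage[i],
      subset = grid$subset[i], cdr3_nt = cl$cdr3_nt, v_gene = cl$v_gene,
      j_gene = cl$j_gene, read_count = dr$read_count,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

.draw_clonotypes <- function(n, config) {
  cat <- config$catalog
  data.frame(
    cdr3_nt = .random_cdr3(n),
    v_gene = if (n) sample(cat$v_names, n, replace = TRUE,
                           prob = .segment_weights(cat$v_names, config$vj_bias))
             else character(0),
    j_gene = if (n) sample(cat$j_names, n, replace = TRUE,
                           prob = .segment_weights(cat$j_names, config$vj_bias))
             else character(0),
    stringsAsFactors = FALSE
  )
}

#' Plant non-productive rearrangements in a clone table
#'
#' Marks `floor(fraction * nrow(table))` rows, chosen by a seeded shuffle,
#' as non-productive by mutating their CDR3 nucleotide sequence: alternate
#' rows get a frameshift (one appended nucleotide) or a stop codon
#' (second codon replaced by TAA). Used to build fixtures for the
#' productive-rearrangement filter.
#'
#' @param table a clone table.
#' @param fraction fraction of rows to alter, in \[0, 1\].
#' @param seed integer seed for the row shuffle.
#' @return The table with altered rows (columns `cdr3_nt`, `cdr3_aa` and
#'   `productive` updated); the number of altered rows is attached as
#'   attribute `n_altered`.
#' @export
inject_nonproductive <- function(table, fraction, seed = 1L) {
  .check_clone_table(table, "inject_nonproductive() input")
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  n_alter <- floor(fraction * nrow(table))
  if (n_alter > 0L) {
    rows <- .with_seed(seed, sample.int(nrow(table)))[seq_len(n_alter)]
    frameshift <- rep(c(TRUE, FALSE), length.out = n_alter)
    nt <- table$cdr3_nt[rows]
    nt[frameshift] <- paste0(nt[frameshift], "A")
    nt[!frameshift] <- paste0(substr(nt[!frameshift], 1L, 3L), "TAA",
                              substr(nt[!frameshift], 7L,
                                     nchar(nt[!frameshift])))
    table$cdr3_nt[rows] <- nt
    if ("cdr3_aa" %in% names(table)) {
      table$cdr3_aa[rows] <- translate_cdr3(nt)
    }
    if ("productive" %in% names(table)) {
      table$productive[rows] <- is_productive(nt)
    }
  }
  attr(table, "n_altered") <- n_alter
  table
}
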