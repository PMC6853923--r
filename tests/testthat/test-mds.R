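freq_matrix <- function(mat, meta) {
  rownames(mat) <- meta$sample_id
  attr(mat, "meta") <- meta
  attr(mat, "filter") <- "ge2"
  class(mat) <- c("clone_matrix", class(mat))
  mat
}

mds_meta <- function(tissue, subset, donor = "D01") {
  meta <- data.frame(donor_id = donor, tissue = tissue, subset = subset,
                     lineage = "CD4", stringsAsFactors = FALSE)
  meta$sample_id <- paste(donor, tissue, "CD4", subset, sep = "|")
  meta
}

test_that("full-rank classical MDS reproduces Euclidean input distances", {
  mat <- build_clone_matrix(generate_cohort(small_config(seed = 4L)),
                            filter = "ge2")
  mds <- pooled_mds(mat, full_rank = TRUE)
  orig <- dist(unclass(mat))
  emb <- dist(mds$points)
  expect_lt(max(abs(orig - emb)), 1e-8)
  expect_equal(rownames(mds$points), rownames(mat))
})

test_that("identical samples embed at identical coordinates", {
  meta <- mds_meta(c("lung", "lung", "LDLN"), c("CM", "EM", "CM"))
  mat <- freq_matrix(rbind(c(0.3, 0.2), c(0.3, 0.2), c(0.0, 0.6)), meta)
  mds <- pooled_mds(mat, n_dims = 2)
  expect_lt(max(abs(mds$points[1, ] - mds$points[2, ])), 1e-6)
})

test_that("a 3-4-5 triangle is reproduced up to rigid motion, signs fixed", {
  meta <- mds_meta(c("lung", "lung", "LDLN"), c("CM", "EM", "CM"))
  # frequency vectors whose pairwise distances are 3, 4, 5
  mat <- freq_matrix(rbind(c(0, 0), c(0, 3), c(4, 0)), meta)
  mds <- pooled_mds(mat, n_dims = 2)
  emb <- as.numeric(dist(mds$points))
  expect_equal(sort(emb), c(3, 4, 5), tolerance = 1e-8)
  # reflection convention: first nonzero loading of each axis is positive
  for (j in seq_len(ncol(mds$points))) {
    nz <- mds$points[abs(mds$points[, j]) > 1e-12, j]
    if (length(nz)) expect_gt(nz[1], 0)
  }
  # determinism under the convention
  expect_equal(mds$points, pooled_mds(mat, n_dims = 2)$points)
  expect_error(pooled_mds(freq_matrix(rbind(c(0, 0), c(0, 0)),
                                      meta[1:2, ])), "degenerate")
})

test_that("distance groups average pairwise embedding distances", {
  meta <- mds_meta(rep(c("lung", "LDLN"), each = 4),
                   rep(c("naive", "CM", "EM", "TRM"), 2))
  pts <- rbind(c(10, 10),              # lung naive
               c(0, 0), c(0, 3), c(4, 0),   # lung memory: 3-4-5 triangle
               c(20, 20),              # LDLN naive
               c(0, 0), c(0, 3), c(4, 0))   # LDLN memory at lung coords
  mds <- structure(list(points = pts, meta = meta), class = "repertoire_mds")
  rownames(mds$points) <- meta$sample_id
  g <- distance_groups(mds)
  expect_equal(g$d_within_lung, 4)          # (3 + 4 + 5) / 3
  expect_equal(g$d_within_LDLN, 4)
  expect_equal(g$d_cross_identical, 0)      # identical coordinates
  expect_equal(g$d_naive_mem_lung,
               mean(sqrt(c(200, 100 + 49, 36 + 100))))

  # missing naive sample: entry absent with a recorded reason
  drop <- meta$subset != "naive" | meta$tissue != "lung"
  mds2 <- structure(list(points = pts[drop, ], meta = meta[drop, ]),
                    class = "repertoire_mds")
  g2 <- distance_groups(mds2)
  expect_true(is.na(g2$d_naive_mem_lung))
  expect_match(paste(attr(g2, "missing"), collapse = "; "),
               "d_naive_mem_lung")
})

test_that("wilcoxon rank-sum matches exact enumeration and handles edge cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)           # 2 / C(6,3)
  expect_equal(res$method, "exact")
  expect_equal(wilcoxon_rank_sum(1, 2)$p_value, 1)
  expect_warning(res2 <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(res2$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("exact wilcoxon equals exhaustive permutation for all sizes up to 10", {
  perm_p <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    na <- length(a)
    obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
    combos <- utils::combn(n, na)
    stats <- apply(combos, 2, function(idx) {
      sum(rank(pooled)[idx]) - na * (na + 1) / 2
    })
    mu <- na * (n - na) / 2
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(17)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      vals <- sample(100, na + nb)   # distinct, no ties
      a <- vals[seq_len(na)]
      b <- vals[-seq_len(na)]
      expect_equal(wilcoxon_rank_sum(a, b)$p_value, perm_p(a, b),
                   tolerance = 1e-9,
                   label = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("distance-group comparisons run across donors", {
  cohort <- do.call(rbind, lapply(1:4, function(d) {
    co <- generate_cohort(small_config(seed = d))
    co$donor_id <- sprintf("D%02d", d)
    co
  }))
  mds <- pooled_mds(build_clone_matrix(cohort, filter = "ge2"))
  groups <- distance_groups(mds)
  expect_equal(nrow(groups), 4L)
  expect_true(all(groups$d_within_lung >= 0, na.rm = TRUE))
  tests <- compare_distance_groups(groups)
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  expect_gte(nrow(tests), 4L)
})
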