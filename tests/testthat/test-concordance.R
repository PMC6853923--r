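# build a clone_matrix-like object directly from coordinates
coord_matrix <- function(coords, meta) {
  rownames(coords) <- meta$sample_id
  attr(coords, "meta") <- meta
  attr(coords, "filter") <- "ge2"
  class(coords) <- c("clone_matrix", class(coords))
  coords
}

sample_meta <- function(tissue, subset, donor = "D01") {
  meta <- data.frame(donor_id = donor, tissue = tissue, subset = subset,
                     lineage = "CD4", stringsAsFactors = FALSE)
  meta$sample_id <- paste(donor, tissue, "CD4", subset, sep = "|")
  meta
}

test_that("donor clustering reproduces hand-computed geometry", {
  meta <- sample_meta(c("lung", "lung"), c("CM", "EM"))
  ident <- coord_matrix(rbind(c(1, 0), c(1, 0)), meta)
  hc <- donor_hclust(ident)
  expect_equal(hc$height, 0)

  apart <- coord_matrix(rbind(c(1, 0), c(0, 1)), meta)
  expect_equal(donor_hclust(apart)$height, sqrt(2))

  # two tight tissue pairs far apart merge within tissue first
  meta4 <- sample_meta(c("lung", "lung", "LDLN", "LDLN"),
                       c("CM", "EM", "CM", "EM"))
  mat4 <- coord_matrix(rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1)),
                       meta4)
  hc4 <- donor_hclust(mat4)
  first_two <- hc4$merge[1:2, ]
  expect_true(all(first_two < 0))          # leaf-leaf merges
  expect_setequal(-as.vector(first_two), 1:4)
  expect_error(donor_hclust(mat4[1, , drop = FALSE]), "at least 2")
})

test_that("tissue concordance tallies memory subsets by cluster majority", {
  # perfect separation: (6, 6)
  meta <- sample_meta(rep(c("lung", "LDLN"), each = 3),
                      rep(c("CM", "EM", "TRM"), 2))
  mat <- coord_matrix(rbind(c(0, 0), c(0, 1), c(1, 0),
                            c(50, 0), c(50, 1), c(51, 0)), meta)
  res <- tissue_concordance(donor_hclust(mat))
  expect_equal(c(res$concordant, res$total), c(6L, 6L))

  # one lung subset inside the LDLN-majority cluster: (5, 6)
  mat2 <- coord_matrix(rbind(c(0, 0), c(0, 1), c(50, 5),
                             c(50, 0), c(50, 1), c(51, 0)), meta)
  res2 <- tissue_concordance(donor_hclust(mat2))
  expect_equal(c(res2$concordant, res2$total), c(5L, 6L))
  stray <- res2$detail[res2$detail$tissue == "lung" &
                         !res2$detail$concordant, ]
  expect_equal(nrow(stray), 1L)

  # two leaves, one per tissue: singleton clusters are concordant
  meta2 <- sample_meta(c("lung", "LDLN"), c("CM", "CM"))
  two <- coord_matrix(rbind(c(0, 0), c(5, 0)), meta2)
  res3 <- tissue_concordance(donor_hclust(two))
  expect_equal(c(res3$concordant, res3$total), c(2L, 2L))

  # naive leaves cluster but are not tallied
  meta_n <- sample_meta(rep(c("lung", "LDLN"), each = 2),
                        rep(c("naive", "CM"), 2))
  mat_n <- coord_matrix(rbind(c(0, 0), c(0, 1), c(50, 0), c(50, 1)), meta_n)
  res4 <- tissue_concordance(donor_hclust(mat_n))
  expect_equal(res4$total, 2L)

  # single-tissue donors are rejected
  meta_s <- sample_meta(c("lung", "lung"), c("CM", "EM"))
  expect_error(tissue_concordance(donor_hclust(coord_matrix(
    rbind(c(0, 0), c(1, 0)), meta_s))), "2 tissues")
})

test_that("an exact cluster-majority tie counts as non-concordant", {
  meta <- sample_meta(c("lung", "LDLN", "lung", "LDLN"),
                      c("CM", "CM", "EM", "EM"))
  # clusters {1,2} and {3,4}, each a 1-1 tissue tie
  mat <- coord_matrix(rbind(c(0, 0), c(0, 1), c(50, 0), c(50, 1)), meta)
  res <- tissue_concordance(donor_hclust(mat))
  expect_equal(res$concordant, 0L)
})

test_that("exact binomial test matches its closed forms and the printed example", {
  res <- binomial_concordance_test(32, 35)
  expect_equal(res$p_value, 2 * 7176 / 2^35, tolerance = 1e-12)
  expect_equal(signif(res$p_value, 2), 4.2e-7)

  all_conc <- binomial_concordance_test(35, 35)
  expect_equal(all_conc$p_value, 2 / 2^35, tolerance = 1e-12)

  center <- binomial_concordance_test(18, 35)
  expect_equal(center$p_value, 1)

  expect_error(binomial_concordance_test(5, 4), "<=")
  expect_error(binomial_concordance_test(1, 0), ">= 1")
})

test_that("binomial test equals pmf enumeration and is symmetric", {
  enum_p <- function(k, n) {
    pmf <- dbinom(0:n, n, 0.5)
    sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  }
  for (n in c(3, 10, 17, 35)) {
    for (k in c(0, 1, floor(n / 2), n - 1, n)) {
      expect_equal(binomial_concordance_test(k, n)$p_value, enum_p(k, n),
                   tolerance = 1e-9, label = sprintf("k=%d n=%d", k, n))
      expect_equal(binomial_concordance_test(k, n)$p_value,
                   binomial_concordance_test(n - k, n)$p_value,
                   tolerance = 1e-12)
    }
  }
})

test_that("cohort concordance separates tissues under strong within-tissue sharing", {
  cfg <- synthetic_config(n_donors = 2L, lineages = "CD4",
                          pool_size_per_tissue = 600L, sample_depth = 2500L,
                          seed = 8L)
  res <- cohort_concordance(generate_cohort(cfg))
  expect_s3_class(res, "concordance_result")
  expect_equal(sum(res$inclusion$included), 2L)
  expect_equal(res$n, 12L)
  expect_gte(res$k, 11L)
  expect_lt(res$p_value, 1e-2)
  # newick export has one leaf per subset
  nwk <- dendrogram_newick(res$donors[[1]]$tree)
  expect_equal(lengths(regmatches(nwk, gregexpr("CD4", nwk))), 8L)
})
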