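test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(share_within = 0.8, share_cross = 0.3),
               "exceed 1")
  expect_error(synthetic_config(share_within = -0.1), "0, 1")
  expect_error(synthetic_config(n_donors = 0), "positive integers")
  expect_error(synthetic_config(tissues = c("lung", "lung")), "two distinct")
  expect_error(synthetic_config(vj_bias = c("V99-9" = 2)), "not in catalog")
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- small_config(seed = 42L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and a different seed gives a different cohort
  c <- generate_cohort(small_config(seed = 43L))
  expect_false(identical(a$cdr3_nt, c$cdr3_nt))
})

test_that("generated sequences are in-frame, stop-free and sample-complete", {
  cohort <- generate_cohort(small_config(seed = 7L))
  expect_true(all(nchar(cohort$cdr3_nt) %% 3 == 0))
  expect_true(all(is_productive(cohort$cdr3_nt)))
  expect_true(all(cohort$read_count >= 1L))
  # every configured sample present, per-sample reads sum to depth
  key <- paste(cohort$donor_id, cohort$tissue, cohort$subset)
  depths <- tapply(cohort$read_count, key, sum)
  expect_length(depths, 2 * 2 * 4)
  expect_true(all(depths == 400L))
})

test_that("share_cross = 0 gives no cross-tissue clone sharing", {
  cfg <- small_config(seed = 3L, share_cross = 0)
  cohort <- generate_cohort(cfg)
  lung <- unique(cohort$cdr3_nt[cohort$tissue == "lung"])
  ldln <- unique(cohort$cdr3_nt[cohort$tissue == "LDLN"])
  expect_length(intersect(lung, ldln), 0L)
})

test_that("vj_bias shifts unique-clone segment usage to its multinomial expectation", {
  cat <- segment_catalog()
  k <- length(cat$v_names)
  n <- 10000L
  cl <- simulate_clonotypes(n, catalog = cat, vj_bias = c("V5-1" = 5),
                            seed = 123L)
  p <- 5 / (5 + k - 1)
  se <- sqrt(p * (1 - p) / n)
  share <- mean(cl$v_gene == "V5-1")
  expect_lt(abs(share - p), 3 * se)
})

test_that("within-tissue shared-clone count increases with share_within", {
  shared_count <- function(sw, seed) {
    cohort <- generate_cohort(small_config(seed = seed, share_within = sw))
    mem <- cohort[cohort$subset != "naive" & cohort$donor_id == "D01" &
                    cohort$tissue == "lung", ]
    cm <- mem$cdr3_nt[mem$subset == "CM"]
    em <- mem$cdr3_nt[mem$subset == "EM"]
    length(intersect(cm, em))
  }
  grid <- c(0.05, 0.2, 0.45)
  means <- vapply(grid, function(sw) {
    mean(vapply(1:3, function(s) shared_count(sw, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("memory rank-frequency follows the configured power law", {
  # a memory sample dominated by a single pool isolates the clone-size
  # law; mixed samples interleave three power-law components and flatten
  # at mid-ranks
  for (seed in c(5L, 6L)) {
    cfg <- synthetic_config(n_donors = 1L, lineages = "CD4",
                            pool_size_per_tissue = 2000L,
                            sample_depth = 20000L, clone_size_alpha = 1,
                            share_within = 0.98, share_cross = 0.01,
                            seed = seed)
    cohort <- generate_cohort(cfg)
    mem <- cohort[cohort$subset == "CM" & cohort$tissue == "lung", ]
    f <- sort(mem$read_count / sum(mem$read_count), decreasing = TRUE)
    top <- seq_len(floor(length(f) / 10))
    fit <- stats::lm(log(f[top]) ~ log(top))
    slope <- unname(stats::coef(fit)[2])
    expect_lt(abs(slope + cfg$clone_size_alpha), 0.2)
  }
})

test_that("inject_nonproductive alters exactly floor(fraction * n) rows", {
  cohort <- generate_cohort(small_config(seed = 9L))
  tab <- cohort[seq_len(400), ]

  same <- inject_nonproductive(tab, 0)
  expect_equal(attr(same, "n_altered"), 0L)
  expect_identical(same$cdr3_nt, tab$cdr3_nt)

  quarter <- inject_nonproductive(tab, 0.25, seed = 2L)
  expect_equal(attr(quarter, "n_altered"), 100L)
  expect_equal(sum(!is_productive(quarter$cdr3_nt)), 100L)

  all_bad <- inject_nonproductive(tab, 1, seed = 2L)
  expect_equal(attr(all_bad, "n_altered"), 400L)
  expect_true(all(!is_productive(all_bad$cdr3_nt)))
  expect_error(inject_nonproductive(tab, 1.5), "0, 1")
})
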