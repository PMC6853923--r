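# In-code fixtures shared across the suite.

# a minimal clone table row set; cdr3 defaults are in-frame and stop-free
make_clones <- function(cdr3, donor = "D01", tissue = "lung",
                        lineage = "CD4", subset = "CM", count = 1L,
                        v = "V5-1", j = "J1-1") {
  out <- data.frame(donor_id = donor, tissue = tissue, lineage = lineage,
                    subset = subset, cdr3_nt = if (length(cdr3)) cdr3 else "",
                    v_gene = v, j_gene = j, read_count = as.integer(count),
                    stringsAsFactors = FALSE)
  if (length(cdr3) == 0L) out <- out[0L, , drop = FALSE]
  out
}

# distinct productive CDR3 sequences: codon blocks of AAA/CCC/GGG/TTT etc.
fixed_cdr3 <- function(n, codons = 9L) {
  base <- c("GCA", "GCC", "GCG", "GCT", "TGC", "GAC", "GAA", "TTC", "GGA")
  vapply(seq_len(n), function(i) {
    idx <- (((i - 1L) + seq_len(codons)) %% length(base)) + 1L
    # prefix one of 9^3 codon triplets so sequences are distinct
    a <- base[(i - 1L) %% 9L + 1L]
    b <- base[((i - 1L) %/% 9L) %% 9L + 1L]
    d <- base[((i - 1L) %/% 81L) %% 9L + 1L]
    paste0(a, b, d, paste(base[idx[seq_len(codons - 3L)]], collapse = ""))
  }, character(1))
}

# a small two-donor cohort with hand-built sharing used by matrix tests
toy_cohort <- function() {
  seqs <- fixed_cdr3(8)
  rbind(
    make_clones(seqs[1:3], subset = "CM", count = c(6L, 3L, 1L)),
    make_clones(seqs[c(2, 3, 4)], subset = "EM", count = c(2L, 2L, 6L)),
    make_clones(seqs[c(5, 6)], subset = "TRM", count = c(5L, 5L)),
    make_clones(seqs[7:8], tissue = "LDLN", subset = "CM", count = c(4L, 6L))
  )
}

# donor with an exact number of clones shared between >=2 CD4 subsets,
# >= min_subsets subsets per tissue, used for the inclusion boundary
boundary_donor <- function(n_shared, donor = "D01") {
  shared <- fixed_cdr3(n_shared)
  private <- fixed_cdr3(n_shared + 6L)[(n_shared + 1L):(n_shared + 6L)]
  rbind(
    make_clones(c(shared, private[1]), donor = donor, tissue = "lung",
                subset = "CM"),
    make_clones(c(shared, private[2]), donor = donor, tissue = "lung",
                subset = "EM"),
    make_clones(private[3], donor = donor, tissue = "lung", subset = "TRM"),
    make_clones(private[4], donor = donor, tissue = "LDLN", subset = "CM"),
    make_clones(private[5], donor = donor, tissue = "LDLN", subset = "EM"),
    make_clones(private[6], donor = donor, tissue = "LDLN", subset = "TRM")
  )
}

# small synthetic config for fast end-to-end tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(n_donors = 2L, lineages = "CD4",
                   pool_size_per_tissue = 150L, sample_depth = 400L,
                   naive_diversity_factor = 4, seed = seed, ...)
}
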