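#' @name clone_dialects
#' @title Clone table dialects
#' @description
#' Three tab-separated clone-table dialects are supported. All carry the
#' same eight mandatory fields under different headers:
#'
#' | field        | `native`     | `airr-like`       | `mixcr-like` |
#' |--------------|--------------|-------------------|--------------|
#' | donor_id     | `donor_id`   | `donor_id`        | `donor_id`   |
#' | tissue       | `tissue`     | `tissue`          | `tissue`     |
#' | lineage      | `lineage`    | `lineage`         | `lineage`    |
#' | subset       | `subset`     | `subset`          | `subset`     |
#' | cdr3_nt      | `cdr3_nt`    | `junction`        | `nSeqCDR3`   |
#' | v_gene       | `v_gene`     | `v_call`          | `bestVGene`  |
#' | j_gene       | `j_gene`     | `j_call`          | `bestJGene`  |
#' | read_count   | `read_count` | `duplicate_count` | `cloneCount` |
#'
#' The sample annotation columns (`donor_id`, `tissue`, `lineage`,
#' `subset`) are carried verbatim in every dialect, as extension columns
#' in the AIRR- and MiXCR-style files.
NULL

.dialect_maps <- list(
  "native" = c(donor_id = "donor_id", tissue = "tissue", lineage = "lineage",
               subset = "subset", cdr3_nt = "cdr3_nt", v_gene = "v_gene",
               j_gene = "j_gene", read_count = "read_count"),
  "airr-like" = c(donor_id = "donor_id", tissue = "tissue",
                  lineage = "lineage", subset = "subset",
                  cdr3_nt = "junction", v_gene = "v_call",
                  j_gene = "j_call", read_count = "duplicate_count"),
  "mixcr-like" = c(donor_id = "donor_id", tissue = "tissue",
                   lineage = "lineage", subset = "subset",
                   cdr3_nt = "nSeqCDR3", v_gene = "bestVGene",
                   j_gene = "bestJGene", read_count = "cloneCount")
)

#' Translate CDR3 nucleotide sequences
#'
#' Standard genetic code, frame 0. Out-of-frame sequences (length not a
#' multiple of 3) translate to `NA`; stop codons appear as `*`.
#'
#' @param nt character vector of nucleotide sequences over A/C/G/T.
#' @return character vector of amino-acid sequences.
#' @examples
#' translate_cdr3(c("TGTGCCAGC", "TGTTAGAGC", "TGTGCCAGCA"))
#' @export
translate_cdr3 <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) > 0L & nchar(nt) %% 3L == 0L
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[ok]),
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

#' Productive-rearrangement test
#'
#' A CDR3 nucleotide sequence is productive when it is in frame (length
#' divisible by 3) and its translation contains no stop codon.
#'
#' @param nt character vector of nucleotide sequences.
#' @return logical vector.
#' @examples
#' is_productive(c("TGTGCCAGC", "TGTTAGAGC", "TGTGCCAGCA"))
#' @export
is_productive <- function(nt) {
  aa <- translate_cdr3(nt)
  !is.na(aa) & !grepl("*", aa, fixed = TRUE)
}

#' Read a clone table
#'
#' Reads a tab-separated clone table in one of the supported dialects
#' (see [clone_dialects]), derives the `cdr3_aa` and `productive` columns,
#' and validates every row. Malformed rows (non-positive read counts,
#' CDR3 sequences with characters outside A/C/G/T, missing annotations)
#' are dropped with a warning; the full parse report, with file line
#' numbers, is attached as attribute `parse_report` and optionally written
#' to a JSON sidecar.
#'
#' @param path path to the TSV file.
#' @param dialect one of `"native"`, `"airr-like"`, `"mixcr-like"`.
#' @param report_path optional path for a JSON parse-report sidecar.
#' @return A clone table `data.frame` in native column order with derived
#'   `cdr3_aa` and `productive` columns.
#' @seealso [write_clone_table()]
#' @export
read_clone_table <- function(path, dialect = c("native", "airr-like",
                                               "mixcr-like"),
                             report_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("clone table not found: %s", path), call. = FALSE)
  }
  map <- .dialect_maps[[dialect]]
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(unname(map), names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("%s file %s lacks mandatory column(s): %s", dialect, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning(sprintf("empty clone table: %s", path), call. = FALSE)
    empty <- data.frame(matrix(character(0), nrow = 0,
                               ncol = length(.required_cols),
                               dimnames = list(NULL, .required_cols)),
                        stringsAsFactors = FALSE)
    empty$read_count <- integer(0)
    empty$cdr3_aa <- character(0)
    empty$productive <- logical(0)
    return(empty[, c(.required_cols[1:5], "cdr3_aa",
                     .required_cols[6:8], "productive")])
  }
  tab <- setNames(raw[, unname(map), drop = FALSE], names(map))
  count <- suppressWarnings(as.numeric(tab$read_count))
  bad_count <- is.na(count) | count < 1 | count != round(count)
  bad_seq <- !grepl("^[ACGT]+$", tab$cdr3_nt)
  bad_meta <- Reduce(`|`, lapply(tab[c("donor_id", "tissue", "lineage",
                                       "subset", "v_gene", "j_gene")],
                                 function(x) is.na(x) | x == ""))
  bad <- bad_count | bad_seq | bad_meta
  report <- list(
    path = path, dialect = dialect, n_rows = nrow(tab),
    n_parsed = sum(!bad), n_rejected = sum(bad),
    rejected = data.frame(
      line = which(bad) + 1L,  # +1 for the header line
      reason = ifelse(bad_count[bad], "invalid read_count",
                      ifelse(bad_seq[bad], "invalid cdr3_nt",
                             "missing annotation")),
      stringsAsFactors = FALSE
    )
  )
  if (any(bad)) {
    warning(sprintf("%d of %d row(s) in %s rejected (see parse report)",
                    sum(bad), nrow(tab), path), call. = FALSE)
  }
  tab <- tab[!bad, , drop = FALSE]
  tab$read_count <- as.integer(count[!bad])
  tab$cdr3_aa <- translate_cdr3(tab$cdr3_nt)
  tab$productive <- is_productive(tab$cdr3_nt)
  tab <- tab[, c("donor_id", "tissue", "lineage", "subset", "cdr3_nt",
                 "cdr3_aa", "v_gene", "j_gene", "read_count", "productive")]
  rownames(tab) <- NULL
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  attr(tab, "parse_report") <- report
  tab
}

#' Write a clone table
#'
#' @param table a clone table with the native columns.
#' @param path output TSV path.
#' @param dialect output dialect (see [clone_dialects]).
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(table, path,
                              dialect = c("native", "airr-like",
                                          "mixcr-like")) {
  dialect <- match.arg(dialect)
  .check_clone_table(table, "write_clone_table() input")
  map <- .dialect_maps[[dialect]]
  out <- setNames(as.data.frame(table)[, names(map), drop = FALSE],
                  unname(map))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the productive-rearrangement filter
#'
#' Keeps rows whose CDR3 nucleotide sequence is in frame and free of stop
#' codons; productivity is recomputed from the sequence, not taken from
#' any pre-existing column.
#'
#' @param records a clone table.
#' @return list with elements `kept` (clone table), `removed` (clone
#'   table) and `n_removed`.
#' @examples
#' tab <- data.frame(donor_id = "D1", tissue = "lung", lineage = "CD4",
#'                   subset = "CM",
#'                   cdr3_nt = c("TGTGCCAGC", "TGTTAGAGC", "TGTGCCAGCA"),
#'                   v_gene = "V5-1", j_gene = "J1-1", read_count = 1L)
#' filter_productive(tab)$n_removed
#' @export
filter_productive <- function(records) {
  .check_clone_table(records, "filter_productive() input")
  ok <- is_productive(records$cdr3_nt)
  kept <- records[ok, , drop = FALSE]
  removed <- records[!ok, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, n_removed = nrow(removed))
}

#' Collapse reads into clonotypes by CDR3 nucleotide identity
#'
#' Merges rows of one sample that share the same CDR3 nucleotide sequence,
#' summing read counts. The merged clone's V and J calls are those of the
#' constituent (V, J) pair with the highest summed count, ties broken by
#' lexicographically smallest pair. Frequencies are read counts normalized
#' by the sample total.
#'
#' @param records clone table rows, all from a single
#'   (donor, tissue, lineage, subset) sample.
#' @return A `repertoire_sample`: a data.frame of unique clonotypes with a
#'   `frequency` column, and attributes `sample_id` and `total_reads`.
#' @examples
#' tab <- data.frame(donor_id = "D1", tissue = "lung", lineage = "CD4",
#'                   subset = "CM", cdr3_nt = c("TGTGCC", "TGTGCC"),
#'                   v_gene = "V5-1", j_gene = "J1-1",
#'                   read_count = c(3L, 7L))
#' collapse_clones(tab)
#' @export
collapse_clones <- function(records) {
  .check_clone_table(records, "collapse_clones() input")
  keys <- unique(.sample_key(records))
  if (length(keys) > 1L) {
    stop(sprintf("collapse_clones() expects one sample, got %d: %s",
                 length(keys), paste(keys, collapse = ", ")), call. = FALSE)
  }
  if (nrow(records) == 0L) {
    out <- records
    out$frequency <- numeric(0)
    attr(out, "sample_id") <- NA_character_
    attr(out, "total_reads") <- 0L
    class(out) <- c("repertoire_sample", "data.frame")
    return(out)
  }
  # counts per (clone, V, J) to pick the plurality segment call
  per_vj <- aggregate(read_count ~ cdr3_nt + v_gene + j_gene,
                      data = records, FUN = sum)
  per_vj <- per_vj[order(per_vj$cdr3_nt, -per_vj$read_count,
                         per_vj$v_gene, per_vj$j_gene), , drop = FALSE]
  rep_vj <- per_vj[!duplicated(per_vj$cdr3_nt), , drop = FALSE]
  totals <- rowsum(records$read_count, records$cdr3_nt)
  m <- match(rep_vj$cdr3_nt, rownames(totals))
  out <- data.frame(
    donor_id = records$donor_id[1], tissue = records$tissue[1],
    lineage = records$lineage[1], subset = records$subset[1],
    cdr3_nt = rep_vj$cdr3_nt,
    cdr3_aa = translate_cdr3(rep_vj$cdr3_nt),
    v_gene = rep_vj$v_gene, j_gene = rep_vj$j_gene,
    read_count = as.integer(totals[m, 1L]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cdr3_nt), , drop = FALSE]
  total <- sum(out$read_count)
  out$frequency <- out$read_count / total
  out$productive <- is_productive(out$cdr3_nt)
  rownames(out) <- NULL
  attr(out, "sample_id") <- keys
  attr(out, "total_reads") <- total
  class(out) <- c("repertoire_sample", "data.frame")
  out
}

#' Collapse every sample of a cohort
#'
#' Applies [collapse_clones()] within each (donor, tissue, lineage,
#' subset) sample of a cohort table and recombines the results, adding a
#' per-sample `frequency` column.
#'
#' @param cohort a clone table covering one or more samples.
#' @return A `clone_cohort` data.frame of unique clonotypes per sample.
#' @export
collapse_cohort <- function(cohort) {
  .check_clone_table(cohort, "collapse_cohort() input")
  pieces <- split(seq_len(nrow(cohort)), .sample_key(cohort))
  out <- do.call(rbind, lapply(pieces, function(idx) {
    s <- collapse_clones(cohort[idx, , drop = FALSE])
    class(s) <- "data.frame"
    s
  }))
  rownames(out) <- NULL
  class(out) <- c("clone_cohort", "data.frame")
  out
}
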