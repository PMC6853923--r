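#' Run the full repertoire analysis pipeline
#'
#' Wires the stages together in a fixed order -- input (synthetic
#' generation or clone-table files), productive filter, clonotype
#' collapse, donor inclusion, then the requested analyses (diversity,
#' overlap, clustering, MDS, V-J usage) -- and writes every artifact to
#' `out_dir` together with a checksum manifest, the resolved
#' configuration and a per-stage log. Identical configuration and seed
#' reproduce the bundle byte for byte (the log file carries no
#' timestamps either; it is nevertheless excluded from the manifest).
#'
#' @param config a [synthetic_config()] (synthetic mode), or a character
#'   vector of clone-table paths read with `dialect`.
#' @param out_dir output directory (created if needed).
#' @param analyses subset of
#'   `c("diversity", "overlap", "clustering", "mds", "vj")`; an empty
#'   vector gives a validation-only run.
#' @param dialect input dialect for file mode.
#' @param lineage lineage for the donor-level analyses (default CD4).
#' @param linkage,rule clustering options, see [cohort_concordance()].
#' @param n_dims MDS dimensions, see [pooled_mds()].
#' @param threshold residual flag threshold, see
#'   [representation_scores()].
#' @param min_subsets,min_shared donor inclusion thresholds.
#' @return An object of class `repclone_run`: list with `out_dir`,
#'   `files` (manifest data.frame), `counts` (per-stage record counts)
#'   and the in-memory stage results.
#' @seealso [summarize_run()]
#' @export
run_pipeline <- function(config, out_dir,
                         analyses = c("diversity", "overlap", "clustering",
                                      "mds", "vj"),
                         dialect = "native", lineage = "CD4",
                         linkage = "complete", rule = "top2_majority",
                         n_dims = 2L, threshold = 3,
                         min_subsets = 3L, min_shared = 150L) {
  if (length(analyses) > 0L) {
    analyses <- match.arg(analyses, several.ok = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) writeLines(sprintf(fmt, ...), log_con)
  counts <- list()

  # --- stage: input -----------------------------------------------------
  if (inherits(config, "synthetic_config")) {
    cohort <- generate_cohort(config)
    resolved <- config[setdiff(names(config), "catalog")]
    resolved$catalog <- list(v_names = config$catalog$v_names,
                             j_names = config$catalog$j_names)
    say("input: synthetic cohort, %d rows", nrow(cohort))
  } else if (is.character(config)) {
    missing <- config[!file.exists(config)]
    if (length(missing) > 0L) {
      stop(sprintf("input file(s) missing: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    cohort <- do.call(rbind, lapply(config, read_clone_table,
                                    dialect = dialect))
    resolved <- list(inputs = config, dialect = dialect)
    say("input: %d file(s), %d rows", length(config), nrow(cohort))
  } else {
    stop("config must be a synthetic_config or a vector of file paths",
         call. = FALSE)
  }
  counts$parsed <- nrow(cohort)
  resolved <- c(resolved, list(analyses = analyses, lineage = lineage,
                               linkage = linkage, rule = rule,
                               n_dims = n_dims, threshold = threshold,
                               min_subsets = min_subsets,
                               min_shared = min_shared,
                               version = as.character(utils::packageVersion("repclone"))))

  # --- stage: productive filter + collapse ------------------------------
  filt <- filter_productive(cohort)
  say("productive filter: kept %d, removed %d", nrow(filt$kept),
      filt$n_removed)
  counts$productive <- nrow(filt$kept)
  counts$nonproductive_removed <- filt$n_removed
  collapsed <- collapse_cohort(filt$kept)
  say("collapse: %d clonotype rows across %d samples", nrow(collapsed),
      length(unique(.sample_key(collapsed))))
  counts$collapsed <- nrow(collapsed)
  write_clone_table(collapsed, file.path(out_dir, "cohort_collapsed.tsv"))

  # --- stage: donor inclusion -------------------------------------------
  inclusion <- select_donors(collapsed, lineage = lineage,
                             min_subsets = min_subsets,
                             min_shared = min_shared)
  counts$donors_included <- sum(inclusion$included)
  say("inclusion: %d of %d donors included", sum(inclusion$included),
      nrow(inclusion))
  write.table(inclusion, file.path(out_dir, "inclusion.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  results <- list(inclusion = inclusion)

  # --- stage: diversity --------------------------------------------------
  if ("diversity" %in% analyses) {
    keys <- unique(.sample_key(collapsed))
    clon <- vapply(keys, function(k) {
      clonality(collapsed[.sample_key(collapsed) == k, , drop = FALSE])
    }, numeric(1))
    clon_tab <- cbind(.split_key(keys), clonality = unname(clon))
    write.table(clon_tab, file.path(out_dir, "clonality.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rare <- do.call(rbind, lapply(keys, function(k) {
      rc <- rarefy_sample(collapsed[.sample_key(collapsed) == k, ,
                                    drop = FALSE])
      data.frame(sample_id = k, depth = rc$depth,
                 expected_unique = rc$expected_unique,
                 stringsAsFactors = FALSE)
    }))
    write.table(rare, file.path(out_dir, "rarefaction.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    census <- unique_clone_census(collapsed)
    jsonlite::write_json(census, file.path(out_dir, "census.json"),
                         auto_unbox = TRUE, digits = NA)
    say("diversity: %d unique clones, %.4f in >1 sample",
        census$total_unique, census$fraction_multi_sample)
    results$clonality <- clon_tab
    results$census <- census
  }

  # --- stage: overlap ----------------------------------------------------
  if ("overlap" %in% analyses) {
    included <- inclusion$donor_id[inclusion$included]
    overlap <- lapply(included, function(d) {
      mat <- build_clone_matrix(collapsed[collapsed$donor_id == d, ,
                                          drop = FALSE],
                                filter = "ge2", lineage = lineage)
      top <- top_overlap_clones(mat)
      sub <- mat[, top, drop = FALSE]
      long <- data.frame(
        donor_id = d,
        sample_id = rep(rownames(sub), times = ncol(sub)),
        cdr3_nt = rep(colnames(sub), each = nrow(sub)),
        frequency = as.vector(unclass(sub)), stringsAsFactors = FALSE)
      long[long$frequency > 0, , drop = FALSE]
    })
    overlap_tab <- do.call(rbind, overlap)
    write.table(overlap_tab, file.path(out_dir, "top_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("overlap: %d donor heatmap table(s)", length(included))
    results$top_overlap <- overlap_tab
  }

  # --- stage: clustering -------------------------------------------------
  if ("clustering" %in% analyses) {
    conc <- cohort_concordance(collapsed, lineage = lineage,
                               linkage = linkage, rule = rule,
                               min_subsets = min_subsets,
                               min_shared = min_shared)
    jsonlite::write_json(
      list(k = conc$k, n = conc$n, p_value = conc$p_value,
           linkage = linkage, rule = rule,
           donors = lapply(unname(conc$donors), function(x) {
             list(donor_id = x$donor_id, concordant = x$concordant,
                  total = x$total)
           })),
      file.path(out_dir, "concordance.json"), auto_unbox = TRUE,
      digits = NA)
    for (d in names(conc$donors)) {
      dendrogram_newick(conc$donors[[d]]$tree,
                        file.path(out_dir, sprintf("dendrogram_%s.nwk", d)))
    }
    say("clustering: %d of %d memory subsets tissue-concordant, P = %.3g",
        conc$k, conc$n, conc$p_value)
    results$concordance <- conc
  }

  # --- stage: mds --------------------------------------------------------
  if ("mds" %in% analyses) {
    mat <- build_clone_matrix(collapsed, filter = "ge2")
    mds <- pooled_mds(mat, n_dims = n_dims)
    coords <- cbind(mds$meta, as.data.frame(mds$points))
    write.table(coords, file.path(out_dir, "mds_coords.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    groups <- distance_groups(mds, lineage = lineage)
    write.table(groups, file.path(out_dir, "distance_groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- compare_distance_groups(groups)
    write.table(tests, file.path(out_dir, "group_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("mds: %d samples embedded in %d dim(s)", nrow(coords),
        ncol(mds$points))
    results$mds <- mds
    results$distance_groups <- groups
    results$group_tests <- tests
  }

  # --- stage: vj ---------------------------------------------------------
  if ("vj" %in% analyses) {
    usage <- usage_counts(collapsed)
    scores <- representation_scores(usage, threshold = threshold)
    write.table(scores$v_scores, file.path(out_dir, "vj_v_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scores$cell_scores, file.path(out_dir, "vj_cell_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("vj: %d clones tallied; over-represented: %s", usage$n_clones,
        paste(scores$flagged_over, collapse = ", "))
    results$vj <- scores
  }

  # --- manifest ----------------------------------------------------------
  jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(out_dir), c("run.log", "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(list(files = manifest, counts = counts),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %d artifact(s)", nrow(manifest))
  structure(c(list(out_dir = out_dir, files = manifest, counts = counts),
              results),
            class = "repclone_run")
}

#' One-page summary of a pipeline run
#'
#' @param run a [run_pipeline()] result or the path of its output
#'   directory.
#' @return character vector of summary lines (also printed).
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    dir <- run
    man_path <- file.path(dir, "manifest.json")
    if (!file.exists(man_path)) {
      stop(sprintf("not a run bundle (no manifest.json): %s", dir),
           call. = FALSE)
    }
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    for (f in man$files$file) {
      p <- file.path(dir, f)
      if (!file.exists(p) || unname(tools::md5sum(p)) != man$files$md5[man$files$file == f]) {
        stop(sprintf("corrupt bundle: artifact %s missing or modified", f),
             call. = FALSE)
      }
    }
    counts <- man$counts
    inclusion <- utils::read.delim(file.path(dir, "inclusion.tsv"))
    conc <- if (file.exists(file.path(dir, "concordance.json"))) {
      jsonlite::read_json(file.path(dir, "concordance.json"),
                          simplifyVector = TRUE)
    }
    groups <- if (file.exists(file.path(dir, "distance_groups.tsv"))) {
      utils::read.delim(file.path(dir, "distance_groups.tsv"))
    }
    vj <- if (file.exists(file.path(dir, "vj_v_scores.tsv"))) {
      utils::read.delim(file.path(dir, "vj_v_scores.tsv"))
    }
  } else {
    counts <- run$counts
    inclusion <- run$inclusion
    conc <- run$concordance
    groups <- run$distance_groups
    vj <- if (!is.null(run$vj)) run$vj$v_scores
  }
  lines <- c(
    sprintf("records parsed: %d; productive: %d (removed %d); clonotypes: %d",
            counts$parsed, counts$productive, counts$nonproductive_removed,
            counts$collapsed),
    sprintf("donors included: %d of %d", sum(inclusion$included),
            nrow(inclusion))
  )
  excl <- inclusion[!inclusion$included, , drop = FALSE]
  if (nrow(excl) > 0L) {
    lines <- c(lines, sprintf("  excluded %s: %s", excl$donor_id,
                              excl$reasons))
  }
  if (sum(inclusion$included) == 0L) {
    lines <- c(lines, "no donors passed filters; donor-level sections skipped")
  } else if (!is.null(conc)) {
    k <- if (is.list(conc) && !is.null(conc$k)) conc$k else NA
    n <- if (is.list(conc) && !is.null(conc$n)) conc$n else NA
    p <- if (is.list(conc) && !is.null(conc$p_value)) conc$p_value else NA
    lines <- c(lines, sprintf("tissue concordance: %d/%d memory subsets, binomial P = %.3g",
                              k, n, p))
  }
  if (!is.null(groups)) {
    med <- vapply(groups[setdiff(names(groups), "donor_id")],
                  function(x) stats::median(x, na.rm = TRUE), numeric(1))
    lines <- c(lines, paste0("median distances: ",
                             paste(sprintf("%s = %.3g", names(med), med),
                                   collapse = ", ")))
  }
  if (!is.null(vj)) {
    over <- vj$v_gene[vj$flag == "over"]
    under <- vj$v_gene[vj$flag == "under"]
    lines <- c(lines,
               sprintf("V segments over-represented: %s",
                       if (length(over)) paste(over, collapse = ", ") else "none"),
               sprintf("V segments under-represented: %s",
                       if (length(under)) paste(under, collapse = ", ") else "none"))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
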