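# Reporting: the consequence-category summary table, helpers for working
# with printed count tables, the run configuration, and the end-to-end
# pipeline orchestrator.

#' Consequence-category summary by carrier group
#'
#' Tallies countable events into the nine-category reporting table with a
#' totals row; totals equal the column sums and match the counts fed to the
#' pooled count test.
#'
#' @param events Event tibble from [detect_events()].
#' @return Tibble with columns `category`, `probands`, `parents`, ending in
#'   a `"Total"` row.
#' @export
annotation_summary <- function(events) {
  ev <- countable_distinct(events)
  cats <- c(consequence_categories(), "other")
  tab <- vapply(cats, function(ct) {
    c(probands = sum(ev$category == ct & ev$carrier == "proband"),
      parents = sum(ev$category == ct & ev$carrier == "parent"))
  }, numeric(2))
  present <- cats %in% consequence_categories() | tab["probands", ] + tab["parents", ] > 0
  out <- tibble(category = cats[present],
                probands = as.integer(tab["probands", present]),
                parents = as.integer(tab["parents", present]))
  rbind(out, tibble(category = "Total",
                    probands = sum(out$probands),
                    parents = sum(out$parents)))
}

#' Read a printed category-count table
#'
#' TSV with header columns `category`, `probands`, `parents` — the layout of
#' a published consequence-annotation summary.
#'
#' @param path Path to the TSV.
#' @return Tibble of per-category counts.
#' @export
read_annotation_count_table <- function(path) {
  if (!file.exists(path)) stop("annotation count table not found: ", path, call. = FALSE)
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE))
}

#' Expand a category-count table into pseudo-events
#'
#' Turns per-category, per-group counts into an event tibble (one countable
#' row per counted variant) so that summary and sensitivity operations can
#' be applied to published tallies exactly as to detected events. Pseudo
#' variant identities are synthesized; CADD scores and segmental-duplication
#' flags are absent unless supplied downstream.
#'
#' @param counts Tibble with columns `category`, `probands`, `parents`
#'   (no totals row required; a `"Total"` row is ignored).
#' @return Event tibble compatible with [annotation_summary()],
#'   [sensitivity_reanalysis()] and [carrier_summary()].
#' @export
expand_category_counts <- function(counts) {
  counts <- counts[counts$category != "Total", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (grp in c("proband", "parent")) {
      k <- if (grp == "proband") counts$probands[i] else counts$parents[i]
      if (!k) next
      idx <- seq_len(k)
      rows[[length(rows) + 1L]] <- tibble(
        family_id = sprintf("T%s_%s_%d", substr(grp, 1, 3), counts$category[i], idx),
        gene_id = "pooled",
        deletion_chrom = "chrU", deletion_start = 0L, deletion_end = 1L,
        sample_id = sprintf("%s_%s_%d", grp, counts$category[i], idx),
        carrier = grp, chrom = "chrU",
        pos = 0L, ref = "N", alt = "N", genotype = "hom_alt",
        category = counts$category[i], scaled_cadd = NA_real_,
        in_segdup = FALSE, scenario = 1L, countable = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_events())
  # give each pseudo-variant a unique site so deduplication keeps them all
  out$pos <- seq_len(nrow(out))
  out
}

# ---------------------------------------------------------------------------
# run configuration

#' Read a YAML run configuration
#'
#' Expected top-level keys: `inputs` (paths `ped`, `cnv`, `vcf`, `genes`,
#' `cadd`), optional `thresholds` (`qc` sub-list passed to
#' [qc_thresholds()], `cadd_threshold`, `fuzzy_border`, `alpha`, `n_tests`),
#' and `out_dir`.
#'
#' @param path Path to the YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Build a run configuration from components
#'
#' @param inputs Named list of input paths (`ped`, `cnv`, `vcf`, `genes`,
#'   `cadd`).
#' @param out_dir Output directory.
#' @param thresholds Optional threshold overrides (see [read_run_config()]).
#' @return Configuration list of class `run_config`.
#' @export
run_config <- function(inputs, out_dir, thresholds = list()) {
  as_run_config(list(inputs = inputs, out_dir = out_dir,
                     thresholds = thresholds))
}

as_run_config <- function(cfg) {
  needed <- c("ped", "cnv", "vcf", "genes", "cadd")
  missing_keys <- setdiff(needed, names(cfg$inputs))
  if (length(missing_keys)) {
    stop("run config lacks input path(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("run config lacks out_dir", call. = FALSE)
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    qc = do.call(qc_thresholds, th$qc %||% list()),
    cadd_threshold = th$cadd_threshold %||% 10,
    fuzzy_border = as.integer(th$fuzzy_border %||% 500000L),
    min_algorithms = th$min_algorithms %||% 2L,
    max_freq = th$max_freq %||% 0.10,
    min_length = th$min_length %||% 5000L,
    alpha = th$alpha %||% 0.05,
    n_tests = th$n_tests %||% 3L
  )
  structure(cfg, class = "run_config")
}

# ---------------------------------------------------------------------------
# pipeline

#' Run the full analysis pipeline
#'
#' Executes the stages in order: CNV filtering, family exclusion, variant
#' QC, event detection, pooled count test, CADD aggregation and burden
#' tests (carriers-only and full-sample), deleteriousness filters with the
#' filtered count test, and both sensitivity re-analyses. Writes six
#' outputs to `out_dir`: `events.tsv`, `carrier_summary.tsv`,
#' `annotation_summary.tsv`, `filter_matrix.tsv`, `statistics.tsv`, and
#' `run_log.yaml` (resolved thresholds plus stage-by-stage counts). A stage
#' failure aborts with a stage-named diagnostic and removes partial outputs.
#'
#' @param config A `run_config` from [read_run_config()] or [run_config()].
#' @return List of class `pipeline_result` with elements `events`,
#'   `carrier_summary`, `annotation`, `filter_matrix`, `statistics`,
#'   `aggregates`, `log`, and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (nm in names(config$inputs)) {
    if (!file.exists(config$inputs[[nm]])) {
      stop(sprintf("stage input: %s file missing: %s", nm, config$inputs[[nm]]),
           call. = FALSE)
    }
  }
  th <- config$thresholds
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(events = file.path(out_dir, "events.tsv"),
             carriers = file.path(out_dir, "carrier_summary.tsv"),
             annotation = file.path(out_dir, "annotation_summary.tsv"),
             filters = file.path(out_dir, "filter_matrix.tsv"),
             statistics = file.path(out_dir, "statistics.tsv"),
             log = file.path(out_dir, "run_log.yaml"))
  on_fail <- function(stage, e) {
    unlink(paths)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(name, e))
  }
  log <- list(thresholds = th)

  ped <- stage("read_pedigree", read_pedigree(config$inputs$ped))
  cnv <- stage("read_cnv", read_cnv_table(config$inputs$cnv))
  genes <- stage("read_genes", read_gene_bed(config$inputs$genes))
  cadd <- stage("read_cadd", read_cadd_table(config$inputs$cadd))
  variants <- stage("read_vcf", read_vcf(config$inputs$vcf, cadd = cadd))
  log$counts <- list(families_in = nrow(ped), cnv_calls_in = nrow(cnv),
                     variant_records_in = nrow(variants))

  cnv_f <- stage("filter_cnv", filter_cnv_calls(
    cnv, min_algorithms = th$min_algorithms, max_freq = th$max_freq,
    min_length = th$min_length))
  log$counts$cnv_calls_retained <- nrow(cnv_f)

  excl <- stage("exclude_families", exclude_families(ped, cnv_f))
  ped_kept <- excl$retained
  log$counts$families_excluded <- nrow(excl$excluded)
  log$counts$families_retained <- nrow(ped_kept)

  variants_qc <- stage("variant_qc", {
    v <- call_quality_filter(variants, thresholds = th$qc)
    v[v$qc_pass, , drop = FALSE]
  })
  log$counts$variant_records_qc_pass <- nrow(variants_qc)

  events <- stage("detect_events", detect_events(
    ped_kept, cnv_f, genes, variants_qc, fuzzy_border = th$fuzzy_border))
  log$counts$events <- nrow(events)
  log$counts$countable_events <- nrow(countable_distinct(events))

  n_probands <- nrow(ped_kept)
  n_parents <- sum(ped_kept$n_parents)
  carriers <- stage("carrier_summary",
                    carrier_summary(events, n_probands, n_parents))
  annotation <- stage("annotation_summary", annotation_summary(events))

  a <- carriers$n_variants[carriers$group == "proband"]
  b <- carriers$n_variants[carriers$group == "parent"]
  stats_rows <- list()
  add_stat <- function(analysis, res, n_pro, n_par) {
    stats_rows[[length(stats_rows) + 1L]] <<- tibble(
      analysis = analysis, n_proband = n_pro, n_parent = n_par,
      statistic = res$chi_square %||% res$beta %||% NA_real_,
      df_or_se = res$df %||% res$standard_error %||% NA_real_,
      p_value = res$p_value %||% NA_real_,
      significant = if (!is.null(res$p_value) && !is.na(res$p_value)) {
        is_significant(res$p_value, th$alpha, th$n_tests)
      } else NA)
  }

  if (a + b > 0) {
    add_stat("pooled_count", stage("pooled_count", pooled_count_test(a, b)), a, b)
  }

  ev_flagged <- stage("union_filter", {
    ev <- events
    if (nrow(ev)) suppressWarnings(union_filter(ev, cadd_threshold = th$cadd_threshold))
    else ev
  })
  fmatrix <- stage("union_tally", if (nrow(ev_flagged)) union_tally(ev_flagged)
                   else tibble(gene_id = "Total", cadd10_parents = 0L,
                               cadd10_probands = 0L, protein_parents = 0L,
                               protein_probands = 0L, union_parents = 0L,
                               union_probands = 0L))
  u_pro <- fmatrix$union_probands[fmatrix$gene_id == "Total"]
  u_par <- fmatrix$union_parents[fmatrix$gene_id == "Total"]
  if (u_pro + u_par > 0) {
    ev_union <- ev_flagged[ev_flagged$passes_union, , drop = FALSE]
    add_stat("union_filtered_count",
             stage("union_count_test", pooled_count_test(u_pro, u_par)),
             u_pro, u_par)
    seg <- stage("sensitivity_segdup",
                 sensitivity_reanalysis(ev_union, "exclude_segdup"))
    add_stat("union_minus_segdup", seg$test, seg$n_proband, seg$n_parent)
  }
  if (a + b > 0) {
    syn <- stage("sensitivity_synonymous",
                 sensitivity_reanalysis(events, "exclude_synonymous"))
    add_stat("minus_synonymous", syn$test, syn$n_proband, syn$n_parent)
  }

  agg_car <- stage("aggregate_cadd", {
    if (nrow(countable_distinct(events))) {
      aggregate_cadd(events, mode = "carriers", missing_score = "drop")
    } else NULL
  })
  roster <- tibble(
    sample_id = c(ped_kept$proband_id,
                  ped_kept$father_id[!is.na(ped_kept$father_id)],
                  ped_kept$mother_id[!is.na(ped_kept$mother_id)]),
    role = c(rep("proband", nrow(ped_kept)),
             rep("parent", sum(!is.na(ped_kept$father_id)) +
                   sum(!is.na(ped_kept$mother_id)))))
  agg_full <- stage("aggregate_cadd_full", {
    if (nrow(countable_distinct(events))) {
      aggregate_cadd(events, mode = "full", individuals = roster,
                     missing_score = "drop")
    } else NULL
  })
  if (!is.null(agg_car) && length(unique(agg_car$role)) == 2L) {
    bt <- stage("burden_carriers",
                logistic_burden_test(agg_car$cadd_sum, agg_car$role))
    add_stat("cadd_burden_carriers", bt, sum(agg_car$role == "proband"),
             sum(agg_car$role == "parent"))
  }
  if (!is.null(agg_full) && length(unique(agg_full$role)) == 2L) {
    bt <- stage("burden_full",
                logistic_burden_test(agg_full$cadd_sum, agg_full$role))
    add_stat("cadd_burden_full", bt, sum(agg_full$role == "proband"),
             sum(agg_full$role == "parent"))
  }
  statistics <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    tibble(analysis = character(), n_proband = numeric(),
           n_parent = numeric(), statistic = numeric(),
           df_or_se = numeric(), p_value = numeric(), significant = logical())

  wt <- function(x, p) write.table(as.data.frame(x), p, sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  stage("write_outputs", {
    wt(events, paths["events"])
    wt(carriers, paths["carriers"])
    wt(annotation, paths["annotation"])
    wt(fmatrix, paths["filters"])
    wt(statistics, paths["statistics"])
    yaml::write_yaml(log, paths["log"])
  })

  structure(list(events = events, carrier_summary = carriers,
                 annotation = annotation, filter_matrix = fmatrix,
                 statistics = statistics,
                 aggregates = list(carriers = agg_car, full = agg_full),
                 log = log, paths = paths),
            class = "pipeline_result")
}
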