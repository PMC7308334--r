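# Deleteriousness filtering: the CADD-10 filter, the protein-altering
# (missense / splice-site altering) filter, their union, and the two
# sensitivity re-analyses.

protein_altering_categories <- c("missense", "missense_splice_region",
                                 "splice_region_intron")

#' CADD-10 deleteriousness filter
#'
#' Flags variants whose scaled CADD score is at least `threshold` (default
#' 10, i.e. the top 10% of all possible genome variants under the scaled
#' PHRED construction; the boundary score 10.0 passes). A missing score
#' fails the filter with a warning, or raises an error in strict mode.
#'
#' @param variants Tibble with a `scaled_cadd` column.
#' @param threshold Scaled-score threshold, inclusive (default 10).
#' @param strict Error on missing scores instead of warning (default FALSE).
#' @return Logical vector `passes_cadd10`.
#' @export
cadd10_filter <- function(variants, threshold = 10, strict = FALSE) {
  s <- variants$scaled_cadd
  if (anyNA(s)) {
    if (strict) stop("variant(s) without CADD score under strict mode", call. = FALSE)
    warning(sprintf("%d variant(s) without CADD score fail the CADD-10 filter",
                    sum(is.na(s))), call. = FALSE)
  }
  !is.na(s) & s >= threshold
}

#' Protein-altering consequence filter
#'
#' Flags variants predicted to change the encoded protein: missense,
#' missense + splice-region, and splice-region + intron categories. All
#' other categories fail; category `"other"` fails with a warning.
#'
#' @param variants Tibble with a `category` column.
#' @return Logical vector `passes_protein_altering`.
#' @export
protein_altering_filter <- function(variants) {
  if (any(variants$category %in% "other")) {
    warning(sprintf("%d variant(s) with category 'other' fail the protein-altering filter",
                    sum(variants$category %in% "other")), call. = FALSE)
  }
  variants$category %in% protein_altering_categories
}

#' Union of the two deleteriousness filters
#'
#' A variant is retained when identified by either or both filters. Returns
#' the per-variant flags; see [union_tally()] for group and per-gene counts.
#'
#' @param variants Tibble with `scaled_cadd` and `category` columns.
#' @param cadd_threshold Passed to [cadd10_filter()].
#' @return The input with logical columns `passes_cadd10`,
#'   `passes_protein_altering`, `passes_union`.
#' @export
union_filter <- function(variants, cadd_threshold = 10) {
  variants$passes_cadd10 <- cadd10_filter(variants, threshold = cadd_threshold)
  variants$passes_protein_altering <- protein_altering_filter(variants)
  variants$passes_union <- variants$passes_cadd10 |
    variants$passes_protein_altering
  variants
}

#' Per-gene, per-group filter tallies
#'
#' Counts variants passing each filter and their union, split by carrier
#' group, per gene and in total — the layout of a per-gene filter matrix
#' with a totals row. Operates on countable events (deduplicated per
#' variant and carrier).
#'
#' @param events Event tibble from [detect_events()] with filter flags from
#'   [union_filter()].
#' @return Tibble with one row per gene plus a `"Total"` row: `gene_id`,
#'   `cadd10_parents`, `cadd10_probands`, `protein_parents`,
#'   `protein_probands`, `union_parents`, `union_probands`.
#' @export
union_tally <- function(events) {
  ev <- countable_distinct(events)
  count <- function(flag, grp, gene = NULL) {
    sel <- ev[[flag]] & ev$carrier == grp
    if (!is.null(gene)) sel <- sel & ev$gene_id == gene
    sum(sel)
  }
  gene_ids <- sort(unique(ev$gene_id))
  rows <- lapply(c(gene_ids, NA_character_), function(g) {
    gene <- if (is.na(g)) NULL else g
    tibble(gene_id = if (is.na(g)) "Total" else g,
           cadd10_parents = count("passes_cadd10", "parent", gene),
           cadd10_probands = count("passes_cadd10", "proband", gene),
           protein_parents = count("passes_protein_altering", "parent", gene),
           protein_probands = count("passes_protein_altering", "proband", gene),
           union_parents = count("passes_union", "parent", gene),
           union_probands = count("passes_union", "proband", gene))
  })
  do.call(rbind, rows)
}

#' Read a printed per-gene filter-count table
#'
#' Loads a TSV with columns `gene`, `cadd10_parents`, `cadd10_probands`,
#' `missense_splice_parents`, `missense_splice_probands`, `union_parents`,
#' `union_probands` — the layout in which per-gene deleteriousness-filter
#' counts are reported.
#'
#' @param path Path to the TSV.
#' @return Tibble of per-gene counts.
#' @export
read_filter_count_table <- function(path) {
  if (!file.exists(path)) stop("filter count table not found: ", path, call. = FALSE)
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE))
}

#' Column totals of a per-gene filter-count table
#'
#' @param counts Tibble from [read_filter_count_table()].
#' @return Named numeric vector of the six column totals plus
#'   `union_total`.
#' @export
filter_count_totals <- function(counts) {
  num <- counts[vapply(counts, is.numeric, logical(1))]
  tot <- colSums(num)
  c(tot, union_total = unname(tot["union_parents"] + tot["union_probands"]))
}

#' Sensitivity re-analysis of the pooled count test
#'
#' Removes a specified subset of countable variants from both groups and
#' re-runs the pooled count test: `"exclude_synonymous"` drops synonymous
#' variants; `"exclude_segdup"` drops variants flagged as lying in a
#' segmental duplication region.
#'
#' @param events Event tibble (countable events are used).
#' @param mode `"exclude_synonymous"` or `"exclude_segdup"`.
#' @return List with `n_proband`, `n_parent`, `n_removed` and `test`
#'   (a `pooled_burden` result).
#' @export
sensitivity_reanalysis <- function(events,
                                   mode = c("exclude_synonymous",
                                            "exclude_segdup")) {
  mode <- match.arg(mode)
  ev <- countable_distinct(events)
  drop <- switch(mode,
                 exclude_synonymous = ev$category %in% "synonymous",
                 exclude_segdup = ev$in_segdup %in% TRUE)
  kept <- ev[!drop, , drop = FALSE]
  a <- sum(kept$carrier == "proband")
  b <- sum(kept$carrier == "parent")
  list(n_proband = a, n_parent = b, n_removed = sum(drop),
       test = pooled_count_test(a, b))
}
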