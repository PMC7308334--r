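# Core detection logic: gene content of inherited deletions (with fuzzy
# border), variant-level quality control, the hemizygous genotype exclusion
# rule, per-family event detection with scenario classification, and the
# carrier summary.

#' Genes within a deletion's fuzzy-bordered footprint
#'
#' Returns the genes overlapping `[start - fuzzy_border, end + fuzzy_border)`
#' of the deletion (clipped at 0), on the same chromosome, ordered by start.
#' Intervals are half-open: a gene starting exactly at
#' `end + fuzzy_border` is excluded.
#'
#' @param deletion One CNV call (single-row tibble or list with `chrom`,
#'   `start`, `end`).
#' @param genes Gene tibble from [read_gene_bed()].
#' @param fuzzy_border Extension in bases applied at both ends
#'   (default 500000, i.e. 500 kb).
#' @return The overlapping genes, ordered by start.
#' @export
gene_content <- function(deletion, genes, fuzzy_border = 500000L) {
  lo <- max(0L, deletion$start[1] - fuzzy_border)
  hi <- deletion$end[1] + fuzzy_border
  same <- genes$chrom == deletion$chrom[1]
  cand <- genes[same, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  # half-open [a,b) maps to the closed integer range [a+1, b]
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(start = cand$start + 1L, end = cand$end),
    IRanges::IRanges(start = lo + 1L, end = hi))
  out <- cand[hits, , drop = FALSE]
  out[order(out$start, out$gene_id), , drop = FALSE]
}

#' Default variant quality-control thresholds
#'
#' Coverage at least 10 reads, sequencing quality above Q20, non-reference
#' allele fraction above 15%, more than 3 supporting reads on each strand,
#' and at most 5 identical supporting reads.
#'
#' @param min_depth Minimum read depth (inclusive).
#' @param min_quality Minimum Phred quality (exclusive).
#' @param min_allele_balance Minimum non-reference fraction (exclusive).
#' @param min_strand_reads Minimum supporting reads per strand (exclusive).
#' @param max_identical_reads Maximum identical supporting reads (inclusive).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(min_depth = 10L, min_quality = 20,
                          min_allele_balance = 0.15, min_strand_reads = 3L,
                          max_identical_reads = 5L) {
  list(min_depth = min_depth, min_quality = min_quality,
       min_allele_balance = min_allele_balance,
       min_strand_reads = min_strand_reads,
       max_identical_reads = max_identical_reads)
}

#' Variant call-quality filter
#'
#' A call passes when depth >= 10, quality > 20, allele balance > 0.15,
#' both strand read counts > 3, and identical read count <= 5 (defaults;
#' see [qc_thresholds()]). A metric recorded as absent (`NA`) fails its
#' criterion.
#'
#' @param variants Tibble of variant calls.
#' @param thresholds List from [qc_thresholds()].
#' @return The input with logical column `qc_pass` and character column
#'   `qc_failed` (comma-separated failed criteria, `""` when passing).
#' @export
call_quality_filter <- function(variants, thresholds = qc_thresholds()) {
  t <- thresholds
  crit <- cbind(
    coverage = !is.na(variants$depth) & variants$depth >= t$min_depth,
    quality = !is.na(variants$site_quality) &
      variants$site_quality > t$min_quality,
    allele_balance = !is.na(variants$allele_balance) &
      variants$allele_balance > t$min_allele_balance,
    strand_forward = !is.na(variants$strand_fwd) &
      variants$strand_fwd > t$min_strand_reads,
    strand_reverse = !is.na(variants$strand_rev) &
      variants$strand_rev > t$min_strand_reads,
    identical_reads = !is.na(variants$identical_read_count) &
      variants$identical_read_count <= t$max_identical_reads
  )
  variants$qc_pass <- rowSums(!crit) == 0L
  variants$qc_failed <- apply(!crit, 1L, function(f) {
    paste(colnames(crit)[f], collapse = ",")
  })
  variants
}

# Effective genotype under the missing-coding rule: homozygous reference and
# uncalled genotypes are both treated as missing, so they can never yield an
# event for that carrier.
effective_genotype <- function(genotype) {
  ifelse(genotype %in% c("hom_ref", "missing"), "missing", genotype)
}

#' Genotype exclusion rule at a shared site
#'
#' At a site observed in both the proband and the deletion-transmitting
#' parent, the pair of calls is excluded when both show the identical
#' hemizygous/homozygous-alt allele (an inherited, not compound, state).
#' Homozygous-reference and uncalled genotypes are coded missing; a site
#' missing in one carrier is retained for the other carrier only.
#'
#' @param proband,parent Single-row variant calls at the same site (same
#'   `chrom`, `pos`, `alt`).
#' @return List with logicals `keep_proband`, `keep_parent` and a `reason`
#'   string (`"identical_homozygous"`, `"missing"` or `""`).
#' @export
genotype_exclusion_filter <- function(proband, parent) {
  if (proband$chrom != parent$chrom || proband$pos != parent$pos ||
      proband$alt != parent$alt) {
    stop("genotype_exclusion_filter: calls refer to different sites", call. = FALSE)
  }
  g_pro <- effective_genotype(proband$genotype)
  g_par <- effective_genotype(parent$genotype)
  if (g_pro == "hom_alt" && g_par == "hom_alt") {
    return(list(keep_proband = FALSE, keep_parent = FALSE,
                reason = "identical_homozygous"))
  }
  list(keep_proband = g_pro != "missing", keep_parent = g_par != "missing",
       reason = if (g_pro == "missing" || g_par == "missing") "missing" else "")
}

empty_events <- function() {
  tibble(family_id = character(), gene_id = character(),
         deletion_chrom = character(), deletion_start = integer(),
         deletion_end = integer(), sample_id = character(),
         carrier = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), genotype = character(),
         category = character(), scaled_cadd = numeric(),
         in_segdup = logical(), scenario = integer(), countable = logical())
}

#' Detect compound heterozygous events across families
#'
#' For every family, for each of the proband's inherited deletions, the
#' deletion's gene content (500 kb fuzzy border by default) defines the
#' queried sequence — identical for proband and transmitting parent by
#' construction. Variants of both carriers inside those genes, after the
#' missing-coding and identical-homozygous exclusion rules, become events.
#' Each event is classified scenario 1 (variant inside the reported deletion
#' boundaries, no fuzzy border) or scenario 2 (inside the gene but outside
#' the deletion); only scenario-1 events are flagged `countable`. In trios
#' the non-transmitting parent is never a carrier source. Deletions whose
#' transmitting parent cannot be identified (inheritance `"unknown"`, or the
#' implicated parent not genotyped) are skipped with a warning.
#'
#' Inputs are expected to be quality-filtered already (see
#' [call_quality_filter()] and [filter_cnv_calls()]).
#'
#' @param pedigrees Tibble from [read_pedigree()].
#' @param cnv_calls Filtered CNV calls.
#' @param genes Gene tibble.
#' @param variants Variant calls (QC-passing).
#' @param fuzzy_border Gene-content border in bases (default 500000).
#' @return Event tibble; one row per (family, gene, variant, carrier). A
#'   variant lying in two overlapping genes appears once per gene; pooled
#'   counting downstream deduplicates by variant.
#' @export
detect_events <- function(pedigrees, cnv_calls, genes, variants,
                          fuzzy_border = 500000L) {
  res <- lapply(seq_len(nrow(pedigrees)), function(i) {
    detect_events_family(pedigrees[i, ], cnv_calls, genes, variants,
                         fuzzy_border)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(empty_events())
  out
}

detect_events_family <- function(fam, cnv_calls, genes, variants,
                                 fuzzy_border) {
  dels <- cnv_calls[cnv_calls$sample_id == fam$proband_id &
                      cnv_calls$cnv_type == "del", , drop = FALSE]
  if (!nrow(dels)) return(NULL)
  events <- list()
  for (d in seq_len(nrow(dels))) {
    del <- dels[d, ]
    if (!del$inheritance %in% c("maternal", "paternal")) {
      if (del$inheritance == "unknown") {
        warning(sprintf("family %s: deletion %s:%d-%d has unknown inheritance; skipped",
                        fam$family_id, del$chrom, del$start, del$end),
                call. = FALSE)
      }
      next
    }
    parent_id <- if (del$inheritance == "maternal") fam$mother_id else fam$father_id
    if (is.na(parent_id)) {
      warning(sprintf("family %s: transmitting (%s) parent not genotyped; deletion skipped",
                      fam$family_id, del$inheritance), call. = FALSE)
      next
    }
    content <- gene_content(del, genes, fuzzy_border = fuzzy_border)
    if (!nrow(content)) next
    for (g in seq_len(nrow(content))) {
      gene <- content[g, ]
      in_gene <- variants$chrom == gene$chrom &
        variants$pos >= gene$start & variants$pos < gene$end
      pro <- variants[in_gene & variants$sample_id == fam$proband_id, , drop = FALSE]
      par <- variants[in_gene & variants$sample_id == parent_id, , drop = FALSE]
      pro$genotype <- effective_genotype(pro$genotype)
      par$genotype <- effective_genotype(par$genotype)
      pro <- pro[pro$genotype != "missing", , drop = FALSE]
      par <- par[par$genotype != "missing", , drop = FALSE]
      # identical hemizygous/hom-alt allele in both carriers: inherited with
      # the deletion, excluded from both
      key_pro <- paste(pro$chrom, pro$pos, pro$alt)
      key_par <- paste(par$chrom, par$pos, par$alt)
      hom_pro <- key_pro[pro$genotype == "hom_alt"]
      hom_par <- key_par[par$genotype == "hom_alt"]
      shared <- intersect(hom_pro, hom_par)
      pro <- pro[!(key_pro %in% shared), , drop = FALSE]
      par <- par[!(key_par %in% shared), , drop = FALSE]
      emit <- function(v, carrier) {
        if (!nrow(v)) return(NULL)
        scen <- ifelse(v$pos >= del$start & v$pos < del$end, 1L, 2L)
        tibble(family_id = fam$family_id, gene_id = gene$gene_id,
               deletion_chrom = del$chrom, deletion_start = del$start,
               deletion_end = del$end, sample_id = v$sample_id,
               carrier = carrier, chrom = v$chrom, pos = v$pos, ref = v$ref,
               alt = v$alt, genotype = v$genotype, category = v$category,
               scaled_cadd = v$scaled_cadd, in_segdup = v$in_segdup,
               scenario = scen, countable = scen == 1L)
      }
      events[[length(events) + 1L]] <- emit(pro, "proband")
      events[[length(events) + 1L]] <- emit(par, "parent")
    }
  }
  if (!length(events)) return(NULL)
  do.call(rbind, events)
}

# Distinct countable variants per carrier group (a variant spanning two
# overlapping genes counts once).
countable_distinct <- function(events) {
  ev <- events[events$countable, , drop = FALSE]
  ev[!duplicated(paste(ev$sample_id, ev$chrom, ev$pos, ev$alt)), , drop = FALSE]
}

#' Summarize carriers and pooled variant counts per group
#'
#' Counts distinct individuals with at least one countable event and the
#' pooled number of countable variants, for probands and transmitting
#' parents. Percentages use the supplied group denominators, which the
#' caller controls (the parental denominator in particular depends on
#' whether all sequenced parents or only transmitting parents are counted).
#'
#' @param events Event tibble from [detect_events()].
#' @param n_probands Denominator for the proband percentage.
#' @param n_parents Denominator for the parent percentage.
#' @return Tibble with one row per group: `group`, `n_carriers`,
#'   `denominator`, `pct_carriers`, `n_variants`.
#' @export
carrier_summary <- function(events, n_probands, n_parents) {
  ev <- countable_distinct(events)
  one <- function(grp, denom) {
    sub <- ev[ev$carrier == grp, , drop = FALSE]
    n_car <- length(unique(sub$sample_id))
    tibble(group = grp, n_carriers = n_car, denominator = denom,
           pct_carriers = if (denom > 0) 100 * n_car / denom else NA_real_,
           n_variants = nrow(sub))
  }
  rbind(one("proband", n_probands), one("parent", n_parents))
}
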