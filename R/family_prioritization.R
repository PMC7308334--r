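# CNV call filtering, family exclusion rules, and the rank-based priority
# score used to select families enriched for potential compound heterozygous
# events.

#' Filter CNV calls on caller concordance, cohort frequency and length
#'
#' Retains calls concordant across at least `min_algorithms` callers, below
#' `max_freq` cohort frequency (strict `<`), and longer than `min_length`
#' bases (strict `>`). Row order is preserved and the filter is idempotent.
#'
#' @param calls Tibble of CNV calls from [read_cnv_table()].
#' @param min_algorithms Minimum concordant calling algorithms (default 2).
#' @param max_freq Maximum cohort frequency, exclusive (default 0.10).
#' @param min_length Minimum length in bases, exclusive (default 5000).
#' @return The retained calls.
#' @export
filter_cnv_calls <- function(calls, min_algorithms = 2L, max_freq = 0.10,
                             min_length = 5000L) {
  len <- calls$end - calls$start
  keep <- calls$n_algorithms >= min_algorithms &
    calls$cohort_freq < max_freq &
    len > min_length
  calls[keep, , drop = FALSE]
}

#' Exclude multiplex families and probands with homozygous deletions
#'
#' Removes families with more than one affected child (`multiplex`) and
#' families whose proband carries any homozygous deletion among the supplied
#' (already filtered) CNV calls.
#'
#' @param pedigrees Tibble from [read_pedigree()].
#' @param cnv_calls Filtered CNV calls.
#' @return List with `retained` (pedigree tibble) and `excluded` (tibble of
#'   `family_id`, `reason`; reasons `"multiplex"` or
#'   `"homozygous_deletion"`).
#' @export
exclude_families <- function(pedigrees, cnv_calls) {
  if (anyNA(pedigrees$proband_id)) {
    bad <- pedigrees$family_id[which(is.na(pedigrees$proband_id))[1]]
    stop("family ", bad, " has no identifiable proband", call. = FALSE)
  }
  hom_del_samples <- unique(cnv_calls$sample_id[cnv_calls$cnv_type == "del" &
                                                  cnv_calls$zygosity == "hom"])
  reason <- rep(NA_character_, nrow(pedigrees))
  reason[pedigrees$proband_id %in% hom_del_samples] <- "homozygous_deletion"
  reason[pedigrees$multiplex] <- "multiplex"
  list(
    retained = pedigrees[is.na(reason), , drop = FALSE],
    excluded = tibble(family_id = pedigrees$family_id[!is.na(reason)],
                      reason = reason[!is.na(reason)])
  )
}

#' Per-family CNV features feeding the priority score
#'
#' For each pedigree, counts the proband's filtered CNV calls by type
#' (deletions doubly weighted downstream), the subset overlapping at least
#' one brain-relevant gene (using the fuzzy-border gene content), the
#' inherited fraction per type, and the number of de novo CNVs. A ratio with
#' zero calls of that type is defined as 0.
#'
#' @param pedigrees Tibble from [read_pedigree()].
#' @param cnv_calls Filtered CNV calls.
#' @param genes Gene tibble from [read_gene_bed()].
#' @param fuzzy_border Border in bases for gene-content determination
#'   (default 500000).
#' @return Tibble with one row per family: the six features plus
#'   `n_denovo`.
#' @export
priority_features <- function(pedigrees, cnv_calls, genes,
                              fuzzy_border = 500000L) {
  brain <- genes[genes$brain_relevant, , drop = FALSE]
  inherited <- cnv_calls$inheritance %in% c("maternal", "paternal")
  touches_brain <- vapply(seq_len(nrow(cnv_calls)), function(i) {
    nrow(gene_content(cnv_calls[i, ], brain, fuzzy_border = fuzzy_border)) > 0L
  }, logical(1))
  one_family <- function(pb) {
    mine <- cnv_calls$sample_id == pb
    is_del <- mine & cnv_calls$cnv_type == "del"
    is_dup <- mine & cnv_calls$cnv_type == "dup"
    ratio <- function(sel) if (!any(sel)) 0 else sum(sel & inherited) / sum(sel)
    tibble(n_del = sum(is_del & inherited),
           n_brain_del = sum(is_del & inherited & touches_brain),
           inherit_ratio_del = ratio(is_del),
           n_dup = sum(is_dup & inherited),
           n_brain_dup = sum(is_dup & inherited & touches_brain),
           inherit_ratio_dup = ratio(is_dup),
           n_denovo = sum(mine & cnv_calls$inheritance == "denovo"))
  }
  feats <- do.call(rbind, lapply(pedigrees$proband_id, one_family))
  cbind(tibble(family_id = pedigrees$family_id), feats)
}

#' Weighted rank-sum priority score across families
#'
#' Each of the six features (inherited deletion count, brain-relevant
#' inherited deletion count, inherited deletion fraction, and the
#' duplication analogues) is converted to an ascending rank across families
#' (larger value, larger rank; ties receive the average rank). The score
#' doubles the deletion terms:
#' `R = 2*(rank_del + rank_brain_del + rank_inherit_del) +
#'     (rank_dup + rank_brain_dup + rank_inherit_dup)`.
#' Families are returned sorted by ascending de novo CNV count (fewest de
#' novo events preferred) and then by descending score.
#'
#' @param features Tibble from [priority_features()].
#' @return The features augmented with the six ranks and `R_i`, sorted.
#' @export
priority_score <- function(features) {
  if (!nrow(features)) stop("priority_score needs at least one family", call. = FALSE)
  feat_cols <- c("n_del", "n_brain_del", "inherit_ratio_del",
                 "n_dup", "n_brain_dup", "inherit_ratio_dup")
  if (anyNA(features[feat_cols])) {
    stop("priority features contain NA/NaN values", call. = FALSE)
  }
  ranks <- lapply(features[feat_cols], rank, ties.method = "average")
  names(ranks) <- paste0("rank_", feat_cols)
  out <- cbind(features, as_tibble(ranks))
  out$R_i <- 2 * (out$rank_n_del + out$rank_n_brain_del +
                    out$rank_inherit_ratio_del) +
    1 * (out$rank_n_dup + out$rank_n_brain_dup + out$rank_inherit_ratio_dup)
  ord <- order(out$n_denovo, -out$R_i, out$family_id)
  out[ord, , drop = FALSE]
}
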