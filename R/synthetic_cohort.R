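# Synthetic family-cohort generator. Emulates the structure the analysis
# assumes: proband-parent pairs and trios, one inherited heterozygous
# deletion per family covering ~3 brain-relevant genes, per-allele variant
# placement inside/outside deletion boundaries (hemizygous calls presenting
# as homozygous), consequence categories at the reporting distribution, and
# a plantable proband enrichment effect. A truth record of planted events
# allows exact scoring of detection downstream.

#' Default consequence-category weights of the generator
#'
#' Pooled relative frequencies of the nine reporting categories (3' UTR,
#' downstream, intron, missense, missense+splice-region, non-coding exon,
#' splice-region+intron, synonymous, upstream) over 109 observed variants.
#'
#' @return Named numeric vector over [consequence_categories()], summing to 1.
#' @export
default_category_weights <- function() {
  counts <- c(utr3 = 4, downstream_gene = 7, intron = 55, missense = 15,
              missense_splice_region = 1, noncoding_exon = 4,
              splice_region_intron = 2, synonymous = 14, upstream_gene = 7)
  counts / sum(counts)
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 149 families of which 47 are
#' complete trios, an average of 3.08 brain-relevant genes per inherited
#' deletion (shifted Poisson, minimum 1), a parental per-gene variant rate
#' sized to yield roughly 41 parental variants cohort-wide, a proband/parent
#' rate ratio of 68/41, category weights at the observed distribution, and
#' scaled CADD scores drawn Exponential(ln(10)/10) so that exactly 10% of
#' variants exceed the CADD-10 threshold in expectation.
#'
#' @param n_families Number of families (> 0).
#' @param trio_fraction Fraction of families that are complete trios.
#' @param mean_genes_per_deletion Mean brain-relevant genes per deletion
#'   (>= 1; generated as 1 + Poisson(mean - 1)).
#' @param per_gene_variant_rate_parent Poisson rate of variants per deleted
#'   gene on the transmitting parent's remaining allele.
#' @param proband_rate_ratio Multiplier (>= 0) on that rate for probands;
#'   1 is the null of no enrichment.
#' @param category_weights Distribution over the nine consequence categories.
#' @param cadd_rate Rate of the exponential scaled-CADD generator;
#'   the default ln(10)/10 gives P(score >= 10) = 0.10 exactly.
#' @param scenario2_fraction Fraction of genes that straddle a deletion
#'   boundary, so part of the gene body lies outside the deletion.
#' @param segdup_fraction Fraction of genes flagged as lying in a segmental
#'   duplication region.
#' @param seed Integer random seed; fixed seed gives byte-identical output.
#' @return A list of validated parameters, class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_families = 149,
                              trio_fraction = 47 / 149,
                              mean_genes_per_deletion = 3.08,
                              per_gene_variant_rate_parent = 0.09,
                              proband_rate_ratio = 68 / 41,
                              category_weights = default_category_weights(),
                              cadd_rate = log(10) / 10,
                              scenario2_fraction = 0.2,
                              segdup_fraction = 0.03,
                              seed = 1L) {
  if (n_families < 1) stop("n_families must be at least 1", call. = FALSE)
  if (trio_fraction < 0 || trio_fraction > 1) {
    stop("trio_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (mean_genes_per_deletion < 1) {
    stop("mean_genes_per_deletion must be >= 1", call. = FALSE)
  }
  if (per_gene_variant_rate_parent < 0 || proband_rate_ratio < 0) {
    stop("variant rates must be >= 0", call. = FALSE)
  }
  cats <- consequence_categories()
  if (length(category_weights) != length(cats)) {
    stop(sprintf("category_weights must have %d entries (one per category)",
                 length(cats)), call. = FALSE)
  }
  if (any(category_weights < 0) || abs(sum(category_weights) - 1) > 1e-8) {
    stop("category_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(names(category_weights))) names(category_weights) <- cats
  if (scenario2_fraction < 0 || scenario2_fraction > 1) {
    stop("scenario2_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_families = as.integer(n_families),
                 trio_fraction = trio_fraction,
                 mean_genes_per_deletion = mean_genes_per_deletion,
                 per_gene_variant_rate_parent = per_gene_variant_rate_parent,
                 proband_rate_ratio = proband_rate_ratio,
                 category_weights = category_weights,
                 cadd_rate = cadd_rate,
                 scenario2_fraction = scenario2_fraction,
                 segdup_fraction = segdup_fraction,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Generate a synthetic family cohort
#'
#' Lays each family's inherited deletion out in its own genomic block
#' (10 Mb apart, cycling chr1-chr22), places brain-relevant genes inside the
#' deletion — a configurable fraction straddling a boundary so variants can
#' fall outside it — and plants carrier-specific variants on the remaining
#' allele at Poisson rates, with the proband rate inflated by
#' `proband_rate_ratio`. Variants inside the deletion are emitted in the
#' hemizygous/homozygous-alt encoding; straddling-gene variants outside the
#' deletion are heterozygous. The non-carrier family members receive
#' homozygous-reference calls at every family site, and the transmitting
#' parent carries the same heterozygous deletion as the proband. QC metrics
#' are generated above all default quality thresholds.
#'
#' @param params A `cohort_sim_params` object.
#' @return A list of class `synthetic_cohort` with elements `params`,
#'   `pedigrees` (parsed form), `ped_rows` (PED file rows), `genes`,
#'   `cnv_calls`, `variants` (typed calls for family members at family
#'   sites), `cadd` (a `cadd_table`), and `truth` (planted events with
#'   scenario labels, one row per carrier variant).
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_families
  fam_id <- sprintf("FAM%04d", seq_len(n))
  n_trios <- as.integer(round(params$trio_fraction * n))
  is_trio <- seq_len(n) %in% sample.int(n, n_trios)
  transmit <- sample(c("maternal", "paternal"), n, replace = TRUE)

  proband <- paste0(fam_id, "_P")
  father <- paste0(fam_id, "_F")
  mother <- paste0(fam_id, "_M")
  trans_parent <- ifelse(transmit == "maternal", mother, father)
  other_parent <- ifelse(transmit == "maternal", father, mother)

  # genomic layout: one 10 Mb block per family, deletions well separated so
  # the 500 kb fuzzy border never crosses family blocks
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% 22L) + 1L)
  block <- (seq_len(n) - 1L) %/% 22L
  region_start <- 1000000L + block * 10000000L

  # genes per deletion: shifted Poisson, mean exactly mean_genes_per_deletion
  k_genes <- 1L + rpois(n, params$mean_genes_per_deletion - 1)
  gene_fam <- rep(seq_len(n), k_genes)
  fam_factor <- factor(gene_fam, levels = seq_len(n))
  n_gene <- length(gene_fam)
  gene_w <- as.integer(round(runif(n_gene, 5000, 20000)))
  # pack genes side by side with 2 kb gaps, starting 15 kb into the deletion
  # (the margin keeps relocated boundary-straddling genes from overlapping)
  off <- unlist(lapply(split(gene_w, fam_factor), function(w) {
    cumsum(c(0L, head(w, -1L) + 2000L))
  }), use.names = FALSE)
  gene_start <- region_start[gene_fam] + 2000000L + 15000L + off
  gene_end <- gene_start + gene_w

  # deletion spans all of its genes plus margins; minimum length 300 kb
  span_end <- vapply(split(gene_end, fam_factor), max, numeric(1))
  del_start <- region_start + 2000000L
  del_end <- as.integer(pmax(del_start + 300000L, span_end + 15000L))

  # straddling (scenario-2-capable) genes: relocate to overlap the 3' (or,
  # for a second straddler, the 5') deletion boundary by half their width
  straddle <- runif(n_gene) < params$scenario2_fraction
  idx_in_fam <- unlist(lapply(k_genes, seq_len), use.names = FALSE)
  str_rank <- stats::ave(as.integer(straddle), gene_fam, FUN = cumsum) * straddle
  at3 <- straddle & str_rank == 1L
  at5 <- straddle & str_rank == 2L
  straddle[straddle & str_rank > 2L] <- FALSE
  gene_start[at3] <- del_end[gene_fam[at3]] - gene_w[at3] %/% 2L
  gene_end[at3] <- gene_start[at3] + gene_w[at3]
  gene_end[at5] <- del_start[gene_fam[at5]] + gene_w[at5] %/% 2L
  gene_start[at5] <- gene_end[at5] - gene_w[at5]

  genes <- tibble(
    gene_id = sprintf("%s_G%d", fam_id[gene_fam], idx_in_fam),
    name = sprintf("SYNG%05d", seq_len(n_gene)),
    chrom = chrom[gene_fam],
    start = as.integer(gene_start),
    end = as.integer(gene_end),
    brain_relevant = TRUE,
    in_segdup = runif(n_gene) < params$segdup_fraction
  )

  # CNV calls: the proband's inherited deletion plus the transmitting
  # parent's own copy (origin unknown at the parent generation)
  cnv_calls <- tibble(
    sample_id = c(proband, trans_parent),
    chrom = c(chrom, chrom),
    start = rep(del_start, 2L),
    end = rep(del_end, 2L),
    cnv_type = "del",
    inheritance = c(transmit, rep("unknown", n)),
    n_algorithms = sample(2:3, 2L * n, replace = TRUE),
    cohort_freq = round(runif(2L * n, 0.005, 0.05), 4),
    zygosity = "het",
    length = rep(del_end - del_start, 2L)
  )

  # variants: per gene, carrier-specific counts on the remaining allele
  rate_parent <- params$per_gene_variant_rate_parent
  n_var_parent <- rpois(n_gene, rate_parent)
  n_var_proband <- rpois(n_gene, rate_parent * params$proband_rate_ratio)
  var_gene <- c(rep(seq_len(n_gene), n_var_parent),
                rep(seq_len(n_gene), n_var_proband))
  var_role <- rep(c("parent", "proband"),
                  c(sum(n_var_parent), sum(n_var_proband)))
  n_var <- length(var_gene)

  truth <- if (n_var) {
    vf <- gene_fam[var_gene]
    pos <- as.integer(floor(runif(n_var, genes$start[var_gene],
                                  genes$end[var_gene])))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_var, replace = TRUE)
    alt_shift <- sample.int(3L, n_var, replace = TRUE)
    alt <- bases[((match(ref, bases) - 1L + alt_shift) %% 4L) + 1L]
    scen <- ifelse(pos >= del_start[vf] & pos < del_end[vf], 1L, 2L)
    tr <- tibble(
      family_id = fam_id[vf],
      sample_id = ifelse(var_role == "proband", proband[vf], trans_parent[vf]),
      role = var_role,
      gene_id = genes$gene_id[var_gene],
      chrom = genes$chrom[var_gene],
      pos = pos,
      ref = ref,
      alt = alt,
      genotype = ifelse(scen == 1L, "hom_alt", "het"),
      scenario = scen,
      category = sample(names(params$category_weights), n_var, replace = TRUE,
                        prob = params$category_weights),
      scaled_cadd = round(rexp(n_var, params$cadd_rate), 3),
      in_segdup = genes$in_segdup[var_gene]
    )
    # one variant per genomic site: drop rare position collisions
    tr <- tr[!duplicated(paste(tr$chrom, tr$pos)), , drop = FALSE]
    tr[order(chrom_order(tr$chrom), tr$pos), , drop = FALSE]
  } else {
    tibble(family_id = character(), sample_id = character(), role = character(),
           gene_id = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), genotype = character(),
           scenario = integer(), category = character(),
           scaled_cadd = numeric(), in_segdup = logical())
  }

  # typed calls at family sites: the carrier's call plus homozygous-reference
  # calls for the other sequenced family members (hemizygous-reference inside
  # the deletion also presents as 0/0)
  qc_calls <- function(tr, sample_ids, genotype) {
    nn <- nrow(tr)
    ab <- ifelse(genotype == "hom_alt", round(runif(nn, 0.90, 1.00), 3),
          ifelse(genotype == "het", round(runif(nn, 0.35, 0.65), 3), 0))
    tibble(sample_id = sample_ids, chrom = tr$chrom, pos = tr$pos,
           ref = tr$ref, alt = tr$alt, genotype = genotype,
           depth = sample(20:60, nn, replace = TRUE),
           site_quality = sample(30:60, nn, replace = TRUE) + 0,
           allele_balance = ab,
           strand_fwd = sample(4:20, nn, replace = TRUE),
           strand_rev = sample(4:20, nn, replace = TRUE),
           identical_read_count = sample(1:5, nn, replace = TRUE),
           category = tr$category, scaled_cadd = tr$scaled_cadd,
           in_segdup = tr$in_segdup)
  }
  if (nrow(truth)) {
    tf <- match(truth$family_id, fam_id)
    carrier <- qc_calls(truth, truth$sample_id, truth$genotype)
    other_of_pair <- ifelse(truth$role == "proband", trans_parent[tf], proband[tf])
    homref1 <- qc_calls(truth, other_of_pair, rep("hom_ref", nrow(truth)))
    homref1$allele_balance <- round(runif(nrow(truth), 0, 0.05), 3)
    extra <- which(is_trio[tf])
    homref2 <- qc_calls(truth[extra, , drop = FALSE], other_parent[tf[extra]],
                        rep("hom_ref", length(extra)))
    homref2$allele_balance <- round(runif(length(extra), 0, 0.05), 3)
    variants <- rbind(carrier, homref1, homref2)
    variants <- variants[order(chrom_order(variants$chrom), variants$pos,
                               variants$sample_id), , drop = FALSE]
  } else {
    variants <- empty_variant_calls()
  }

  cadd <- structure(
    setNames(truth$scaled_cadd,
             paste(truth$chrom, truth$pos + 1L, truth$ref, truth$alt, sep = ":")),
    class = c("cadd_table", "numeric"))

  # PED rows: genotyped individuals only (pairs carry just the transmitting
  # parent); ungenotyped parents are referenced by id with the usual PED
  # conventions intact
  ped_rows_list <- list(
    tibble(family_id = fam_id, individual_id = proband, father_id = father,
           mother_id = mother, sex = sample(c("1", "2"), n, replace = TRUE),
           affected = "2"),
    tibble(family_id = fam_id[is_trio | transmit == "paternal"],
           individual_id = father[is_trio | transmit == "paternal"],
           father_id = "0", mother_id = "0", sex = "1", affected = "1"),
    tibble(family_id = fam_id[is_trio | transmit == "maternal"],
           individual_id = mother[is_trio | transmit == "maternal"],
           father_id = "0", mother_id = "0", sex = "2", affected = "1")
  )
  ped_rows <- do.call(rbind, ped_rows_list)
  ped_rows <- ped_rows[order(ped_rows$family_id, ped_rows$individual_id), ,
                       drop = FALSE]

  pedigrees <- tibble(
    family_id = fam_id,
    proband_id = proband,
    father_id = ifelse(is_trio | transmit == "paternal", father, NA_character_),
    mother_id = ifelse(is_trio | transmit == "maternal", mother, NA_character_),
    n_parents = ifelse(is_trio, 2L, 1L),
    type = ifelse(is_trio, "trio", "pair"),
    multiplex = FALSE,
    n_affected = 1L
  )
  pedigrees <- pedigrees[order(pedigrees$family_id), , drop = FALSE]

  structure(list(params = params, pedigrees = pedigrees, ped_rows = ped_rows,
                 genes = genes, cnv_calls = cnv_calls, variants = variants,
                 cadd = cadd, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits six files readable by the `io_formats` readers: `cohort.ped`,
#' `cnv_calls.tsv`, `variants.vcf`, `genes.bed`, `cadd_scores.tsv`, and the
#' truth record `truth_events.tsv` (scoring reference only — never consumed
#' by the analysis pipeline). Output is deterministic: the same cohort
#' writes byte-identical files.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the six file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- c(ped = file.path(dir, "cohort.ped"),
             cnv = file.path(dir, "cnv_calls.tsv"),
             vcf = file.path(dir, "variants.vcf"),
             genes = file.path(dir, "genes.bed"),
             cadd = file.path(dir, "cadd_scores.tsv"),
             truth = file.path(dir, "truth_events.tsv"))
  write_pedigree(cohort$ped_rows, paths["ped"])
  write_cnv_table(cohort$cnv_calls, paths["cnv"])
  write_vcf(cohort$variants, paths["vcf"],
            samples = sort(unique(cohort$ped_rows$individual_id)))
  write_gene_bed(cohort$genes, paths["genes"])
  write_cadd_table(cohort$cadd, paths["cadd"])
  write.table(as.data.frame(cohort$truth), paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
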