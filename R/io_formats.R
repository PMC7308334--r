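# Readers and writers for the formats the pipeline touches: 6-column PED,
# BED-like CNV and gene tables, VCF 4.x, and a 5-column CADD score table.
# Every reader normalizes coordinates into the internal 0-based half-open
# convention and field dialects into the closed consequence vocabulary.

# ---------------------------------------------------------------------------
# consequence vocabulary

#' The closed consequence-category vocabulary
#'
#' Nine reporting categories for SnpEff-style variant annotations, plus
#' `"other"` for tokens outside the vocabulary.
#'
#' @return Character vector of category names.
#' @export
consequence_categories <- function() {
  c("utr3", "downstream_gene", "intron", "missense",
    "missense_splice_region", "noncoding_exon", "splice_region_intron",
    "synonymous", "upstream_gene")
}

#' Default dialect table mapping SnpEff annotation tokens to categories
#'
#' Maps raw SnpEff 4.x `ANN` effect tokens (and the canonical category names
#' themselves) onto the closed vocabulary of [consequence_categories()].
#' Extend or replace it when consuming a VCF produced by a different
#' annotation pipeline.
#'
#' @return Named character vector: names are input tokens, values categories.
#' @export
consequence_dialect <- function() {
  canon <- consequence_categories()
  c(
    setNames(canon, canon),
    "3_prime_UTR_variant"                        = "utr3",
    "downstream_gene_variant"                    = "downstream_gene",
    "intron_variant"                             = "intron",
    "missense_variant"                           = "missense",
    "missense_variant&splice_region_variant"     = "missense_splice_region",
    "non_coding_exon_variant"                    = "noncoding_exon",
    "non_coding_transcript_exon_variant"         = "noncoding_exon",
    "splice_region_variant&intron_variant"       = "splice_region_intron",
    "splice_region_variant"                      = "splice_region_intron",
    "synonymous_variant"                         = "synonymous",
    "upstream_gene_variant"                      = "upstream_gene"
  )
}

#' Map annotation tokens onto the closed consequence vocabulary
#'
#' Tokens not present in the dialect are recorded as `"other"` with a warning.
#'
#' @param tokens Character vector of annotation tokens (`NA` allowed).
#' @param dialect Named character vector, as from [consequence_dialect()].
#' @return Character vector of categories.
#' @export
map_consequence <- function(tokens, dialect = consequence_dialect()) {
  out <- unname(dialect[tokens])
  unknown <- !is.na(tokens) & is.na(out)
  if (any(unknown)) {
    warning(sprintf("%d consequence token(s) outside the vocabulary recorded as 'other' (e.g. '%s')",
                    sum(unknown), tokens[which(unknown)[1]]), call. = FALSE)
  }
  out[is.na(out)] <- "other"
  out
}

# ---------------------------------------------------------------------------
# genotype encoding

# Normalize a VCF GT string with respect to alt allele index `k`.
# Haploid "1" and diploid "1/1" both normalize to hom_alt: inside a deletion
# the locus is hemizygous and callers report it as homozygous.
normalize_gt <- function(gt, k = 1L) {
  vapply(gt, function(g) {
    if (is.na(g) || g == "." ) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return("missing")
    hits <- sum(alleles == as.character(k))
    if (hits == length(alleles)) return("hom_alt")
    if (hits >= 1L) return("het")
    "hom_ref"
  }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# PED

#' Read a 6-column PED pedigree file
#'
#' Columns: family, individual, father, mother, sex, affected (2 = affected).
#' Each family yields one pedigree record; the proband is the (first)
#' affected individual, and the family is classified `"trio"` or `"pair"` by
#' how many of the proband's parents are themselves genotyped (present as
#' rows). Families with more than one affected child are flagged multiplex.
#'
#' @param path Path to the PED file (no header).
#' @return Tibble with columns `family_id`, `proband_id`, `father_id`,
#'   `mother_id` (`NA` when not genotyped), `n_parents`, `type`
#'   (`"trio"`/`"pair"`), `multiplex`, `n_affected`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(family_id = character(), proband_id = character(),
                  father_id = character(), mother_id = character(),
                  n_parents = integer(), type = character(),
                  multiplex = logical(), n_affected = integer()))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    stop(sprintf("malformed PED line %d: expected 6 columns, found %d", bad, nf[bad]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  ped <- tibble(family_id = m[, 1], individual_id = m[, 2],
                father_id = m[, 3], mother_id = m[, 4],
                sex = m[, 5], affected = m[, 6])
  selfref <- ped$individual_id == ped$father_id | ped$individual_id == ped$mother_id
  if (any(selfref)) {
    stop(sprintf("PED line %d: individual '%s' listed as their own parent",
                 which(selfref)[1], ped$individual_id[which(selfref)[1]]), call. = FALSE)
  }
  res <- lapply(split(seq_len(nrow(ped)), ped$family_id), function(idx) {
    fam <- ped[idx, ]
    aff <- fam$individual_id[fam$affected == "2"]
    if (!length(aff)) aff <- NA_character_
    proband <- aff[1]
    genotyped <- fam$individual_id
    father <- fam$father_id[fam$individual_id == proband]
    mother <- fam$mother_id[fam$individual_id == proband]
    father <- if (length(father) && father %in% genotyped) father else NA_character_
    mother <- if (length(mother) && mother %in% genotyped) mother else NA_character_
    n_par <- sum(!is.na(c(father, mother)))
    tibble(family_id = fam$family_id[1], proband_id = proband,
           father_id = father, mother_id = mother,
           n_parents = n_par, type = if (n_par == 2L) "trio" else "pair",
           multiplex = sum(fam$affected == "2", na.rm = TRUE) > 1L,
           n_affected = sum(fam$affected == "2", na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  out[order(out$family_id), , drop = FALSE]
}

#' Write a pedigree table as a 6-column PED file
#'
#' @param ped_rows Tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affected` (one row per individual;
#'   `"0"` marks unknown parents).
#' @param path Output path.
#' @export
write_pedigree <- function(ped_rows, path) {
  lines <- if (nrow(ped_rows)) {
    paste(ped_rows$family_id, ped_rows$individual_id, ped_rows$father_id,
          ped_rows$mother_id, ped_rows$sex, ped_rows$affected, sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CNV table

cnv_required_cols <- c("sample", "chrom", "start", "end", "type", "inheritance",
                       "n_algorithms", "cohort_freq", "zygosity")

#' Read a CNV call table (TSV, 1-based inclusive coordinates)
#'
#' Expected columns: `sample`, `chrom`, `start`, `end`, `type` (`del`/`dup`),
#' `inheritance` (`denovo`/`maternal`/`paternal`/`unknown`), `n_algorithms`,
#' `cohort_freq`, `zygosity` (`het`/`hom`). Coordinates are converted to the
#' internal 0-based half-open convention; row order is preserved.
#'
#' @param path Path to the TSV (header required).
#' @return Tibble of CNV calls with columns `sample_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `inheritance`, `n_algorithms`, `cohort_freq`,
#'   `zygosity`, `length`.
#' @export
read_cnv_table <- function(path) {
  if (!file.exists(path)) stop("CNV table not found: ", path, call. = FALSE)
  raw <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(cnv_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("CNV table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(raw)) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), cnv_type = character(),
                  inheritance = character(), n_algorithms = integer(),
                  cohort_freq = numeric(), zygosity = character(),
                  length = integer()))
  }
  bad_type <- !raw$type %in% c("del", "dup")
  if (any(bad_type)) {
    stop(sprintf("CNV table row %d: unknown type token '%s'",
                 which(bad_type)[1], raw$type[which(bad_type)[1]]), call. = FALSE)
  }
  bad_inh <- !raw$inheritance %in% c("denovo", "maternal", "paternal", "unknown")
  if (any(bad_inh)) {
    stop(sprintf("CNV table row %d: unknown inheritance token '%s'",
                 which(bad_inh)[1], raw$inheritance[which(bad_inh)[1]]), call. = FALSE)
  }
  ext_start <- as.integer(raw$start)
  ext_end <- as.integer(raw$end)
  if (any(ext_end <= ext_start)) {
    bad <- which(ext_end <= ext_start)[1]
    stop(sprintf("CNV table row %d: end must exceed start", bad), call. = FALSE)
  }
  int <- coords_to_internal(ext_start, ext_end)
  check_intervals(raw$chrom, int$start, int$end, what = "CNV call")
  tibble(sample_id = raw$sample, chrom = raw$chrom,
         start = int$start, end = int$end, cnv_type = raw$type,
         inheritance = raw$inheritance,
         n_algorithms = as.integer(raw$n_algorithms),
         cohort_freq = as.numeric(raw$cohort_freq),
         zygosity = raw$zygosity,
         length = int$end - int$start)
}

#' Write a CNV call table (TSV, 1-based inclusive coordinates)
#'
#' @param calls Tibble as returned by [read_cnv_table()].
#' @param path Output path.
#' @export
write_cnv_table <- function(calls, path) {
  ext <- coords_to_external(calls$start, calls$end)
  out <- data.frame(sample = calls$sample_id, chrom = calls$chrom,
                    start = ext$start, end = ext$end, type = calls$cnv_type,
                    inheritance = calls$inheritance,
                    n_algorithms = calls$n_algorithms,
                    cohort_freq = calls$cohort_freq, zygosity = calls$zygosity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# gene table (BED convention: already 0-based half-open)

#' Read a BED-like gene table
#'
#' Seven tab-separated columns without header: chrom, start, end (0-based
#' half-open, BED convention), gene_id, name, brain_relevant (0/1),
#' in_segdup (0/1). Lines starting with `#` are ignored.
#'
#' @param path Path to the gene BED file.
#' @return Tibble with columns `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `brain_relevant`, `in_segdup`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(gene_id = character(), name = character(), chrom = character(),
                  start = integer(), end = integer(), brain_relevant = logical(),
                  in_segdup = logical()))
  }
  m <- do.call(rbind, strsplit(lines, "\t"))
  if (ncol(m) != 7L) stop("gene BED must have 7 columns", call. = FALSE)
  out <- tibble(gene_id = m[, 4], name = m[, 5], chrom = m[, 1],
                start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                brain_relevant = m[, 6] == "1", in_segdup = m[, 7] == "1")
  if (anyDuplicated(out$gene_id)) {
    stop("gene_id values must be unique within a gene set", call. = FALSE)
  }
  check_intervals(out$chrom, out$start, out$end, what = "gene")
  out
}

#' Write a gene table in the 7-column BED-like layout
#'
#' @param genes Tibble as returned by [read_gene_bed()].
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  lines <- if (nrow(genes)) {
    paste(genes$chrom, genes$start, genes$end, genes$gene_id, genes$name,
          as.integer(genes$brain_relevant), as.integer(genes$in_segdup),
          sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CADD table

#' Read a CADD scaled-score table
#'
#' TSV with header columns `chrom`, `pos` (1-based), `ref`, `alt`, `scaled`.
#' Duplicate (chrom, pos, ref, alt) keys keep the last score, with a warning.
#'
#' @param path Path to the score table.
#' @return Named numeric vector keyed `"chrom:pos:ref:alt"` (1-based pos),
#'   of class `cadd_table`. Use [cadd_lookup()] for internal-coordinate
#'   queries; absent keys yield `NA`, never zero.
#' @export
read_cadd_table <- function(path) {
  if (!file.exists(path)) stop("CADD table not found: ", path, call. = FALSE)
  raw <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("chrom", "pos", "ref", "alt", "scaled")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("CADD table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scores <- suppressWarnings(as.numeric(raw$scaled))
  if (nrow(raw) && anyNA(scores)) {
    bad <- which(is.na(scores))[1]
    stop(sprintf("CADD table row %d: non-numeric score '%s'", bad, raw$scaled[bad]),
         call. = FALSE)
  }
  keys <- paste(raw$chrom, raw$pos, raw$ref, raw$alt, sep = ":")
  if (anyDuplicated(keys)) {
    warning(sprintf("%d duplicate CADD key(s); keeping the last score for each",
                    sum(duplicated(keys))), call. = FALSE)
    keep <- !duplicated(keys, fromLast = TRUE)
    keys <- keys[keep]
    scores <- scores[keep]
  }
  structure(setNames(scores, keys), class = c("cadd_table", "numeric"))
}

#' Look up scaled CADD scores for variants in internal coordinates
#'
#' @param cadd A `cadd_table` from [read_cadd_table()].
#' @param chrom,pos,ref,alt Vectors describing variants; `pos` is the
#'   internal 0-based position.
#' @return Numeric vector of scaled scores; `NA` marks a missing score
#'   (never silently zero).
#' @export
cadd_lookup <- function(cadd, chrom, pos, ref, alt) {
  keys <- paste(chrom, pos + 1L, ref, alt, sep = ":")
  unname(cadd[keys])
}

#' Write a CADD scaled-score table
#'
#' @param cadd A `cadd_table` (named numeric vector keyed
#'   `"chrom:pos:ref:alt"`, 1-based pos).
#' @param path Output path.
#' @export
write_cadd_table <- function(cadd, path) {
  if (length(cadd)) {
    parts <- do.call(rbind, strsplit(names(cadd), ":", fixed = TRUE))
    out <- data.frame(chrom = parts[, 1], pos = parts[, 2], ref = parts[, 3],
                      alt = parts[, 4], scaled = format(unname(cadd), trim = TRUE))
  } else {
    out <- data.frame(chrom = character(), pos = character(), ref = character(),
                      alt = character(), scaled = character())
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF

#' Default FORMAT/INFO field dialect for [read_vcf()]
#'
#' Names the per-sample FORMAT tags carrying each QC metric and the INFO keys
#' carrying the consequence annotation and the segmental-duplication flag.
#' Override entries to consume VCFs from other calling pipelines.
#'
#' @param genotype,depth,quality,allele_balance,strand_fwd,strand_rev,identical_reads
#'   FORMAT tag names.
#' @param consequence,segdup INFO keys (`segdup` is a flag).
#' @return Named list of field names.
#' @export
vcf_dialect <- function(genotype = "GT", depth = "DP", quality = "SQ",
                        allele_balance = "AB", strand_fwd = "ADF",
                        strand_rev = "ADR", identical_reads = "MIR",
                        consequence = "ANN", segdup = "SEGDUP") {
  list(genotype = genotype, depth = depth, quality = quality,
       allele_balance = allele_balance, strand_fwd = strand_fwd,
       strand_rev = strand_rev, identical_reads = identical_reads,
       consequence = consequence, segdup = segdup)
}

empty_variant_calls <- function() {
  tibble(sample_id = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), genotype = character(),
         depth = integer(), site_quality = numeric(),
         allele_balance = numeric(), strand_fwd = integer(),
         strand_rev = integer(), identical_read_count = integer(),
         category = character(), scaled_cadd = numeric(), in_segdup = logical())
}

#' Read variant calls from a VCF 4.x file
#'
#' Produces one record per sample x site (x alt allele for multi-allelic
#' sites, which are decomposed). Genotypes are normalized into four states:
#' `hom_alt` (covering haploid/hemizygous `"1"` and diploid `"1/1"`), `het`,
#' `hom_ref`, and `missing`. QC metrics absent from the file are recorded as
#' `NA`, never as zero.
#'
#' @param path Path to the VCF file.
#' @param cadd Optional `cadd_table` used to populate `scaled_cadd`.
#' @param dialect FORMAT/INFO field names, see [vcf_dialect()].
#' @param categories Consequence dialect table, see [consequence_dialect()].
#' @return Tibble of variant calls (see [empty_variant_calls()] columns);
#'   `pos` is internal 0-based.
#' @export
read_vcf <- function(path, cadd = NULL, dialect = vcf_dialect(),
                     categories = consequence_dialect()) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(vcf@fix) == 0L) return(empty_variant_calls())
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF carries no sample genotype columns", call. = FALSE)
  }
  fmt_keys <- strsplit(gt_raw[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt_keys, function(k) dialect$genotype %in% k, logical(1)))) {
    stop("VCF FORMAT lacks the genotype field '", dialect$genotype, "'",
         call. = FALSE)
  }
  samples <- colnames(gt_raw)[-1]
  n_site <- nrow(fix)

  grab <- function(tag, numeric = TRUE) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = tag, as.numeric = numeric),
                  error = function(e) NULL)
    if (is.null(m)) {
      m <- matrix(if (numeric) NA_real_ else NA_character_,
                  nrow = n_site, ncol = length(samples))
      colnames(m) <- samples
    }
    m
  }
  gt_m <- vcfR::extract.gt(vcf, element = dialect$genotype)
  dp_m <- grab(dialect$depth)
  sq_m <- grab(dialect$quality)
  ab_m <- grab(dialect$allele_balance)
  adf_m <- grab(dialect$strand_fwd)
  adr_m <- grab(dialect$strand_rev)
  mir_m <- grab(dialect$identical_reads)

  info <- fix$INFO
  ann_pat <- sprintf("(^|;)%s=([^;]*)", dialect$consequence)
  hit <- regexpr(ann_pat, info)
  ann_tok <- rep(NA_character_, length(info))
  got <- hit > 0L & !is.na(info)
  ann_tok[got] <- sub(ann_pat, "\\2", regmatches(info, hit))
  ann_tok[ann_tok %in% "."] <- NA_character_
  segdup <- !is.na(info) & grepl(sprintf("(^|;)%s(;|$)", dialect$segdup), info)

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)

  site_idx <- rep(seq_len(n_site), times = n_alt)
  alt_k <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  n_rec <- length(site_idx)

  rows <- vector("list", n_rec)
  cats <- map_consequence(ann_tok, categories)
  for (r in seq_len(n_rec)) {
    i <- site_idx[r]; k <- alt_k[r]
    pos0 <- as.integer(fix$POS[i]) - 1L
    rows[[r]] <- tibble(
      sample_id = samples,
      chrom = fix$CHROM[i],
      pos = pos0,
      ref = fix$REF[i],
      alt = alt_list[[i]][k],
      genotype = normalize_gt(unname(gt_m[i, ]), k = k),
      depth = as.integer(dp_m[i, ]),
      site_quality = as.numeric(sq_m[i, ]),
      allele_balance = as.numeric(ab_m[i, ]),
      strand_fwd = as.integer(adf_m[i, ]),
      strand_rev = as.integer(adr_m[i, ]),
      identical_read_count = as.integer(mir_m[i, ]),
      category = cats[i],
      scaled_cadd = NA_real_,
      in_segdup = segdup[i]
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(cadd)) {
    out$scaled_cadd <- cadd_lookup(cadd, out$chrom, out$pos, out$ref, out$alt)
  }
  out
}

#' Write variant calls to a VCF 4.2 file
#'
#' Inverse of [read_vcf()] for single-alt records: one VCF row per unique
#' (chrom, pos, ref, alt), with per-sample FORMAT fields for every sample in
#' `samples`; samples without a record at a site are emitted as missing
#' (`./.`). Genotype states map back as `hom_alt` -> `1/1`, `het` -> `0/1`,
#' `hom_ref` -> `0/0`.
#'
#' @param calls Tibble of variant calls (internal 0-based `pos`).
#' @param path Output path.
#' @param samples Character vector fixing the sample column order; defaults
#'   to the samples present in `calls`.
#' @param dialect Field names, see [vcf_dialect()].
#' @export
write_vcf <- function(calls, path, samples = NULL, dialect = vcf_dialect()) {
  if (is.null(samples)) samples <- unique(calls$sample_id)
  d <- dialect
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence annotation\">", d$consequence),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Site in a segmental duplication region\">", d$segdup),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=String,Description=\"Genotype\">", d$genotype),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Read depth\">", d$depth),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Sequencing quality (Phred)\">", d$quality),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Non-reference allele fraction\">", d$allele_balance),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Alt-supporting forward reads\">", d$strand_fwd),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Alt-supporting reverse reads\">", d$strand_rev),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Maximum identical supporting reads\">", d$identical_reads),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (!nrow(calls)) {
    writeLines(header, path)
    return(invisible(path))
  }
  fmt <- paste(d$genotype, d$depth, d$quality, d$allele_balance,
               d$strand_fwd, d$strand_rev, d$identical_reads, sep = ":")
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  ord <- order(chrom_order(calls$chrom), calls$pos, calls$alt)
  ukey <- unique(key[ord])
  site_of <- match(key, ukey)
  gt_code <- c(hom_alt = "1/1", het = "0/1", hom_ref = "0/0", missing = "./.")
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  body <- vapply(seq_along(ukey), function(s) {
    rows <- calls[site_of == s, , drop = FALSE]
    first <- rows[1, ]
    info <- sprintf("%s=%s", d$consequence,
                    if (is.na(first$category)) "." else first$category)
    if (isTRUE(first$in_segdup)) info <- paste0(info, ";", d$segdup)
    cells <- setNames(rep("./.", length(samples)), samples)
    filled <- rows$sample_id %in% samples
    cell_vals <- paste(gt_code[rows$genotype], fmt_num(rows$depth),
                       fmt_num(rows$site_quality), fmt_num(rows$allele_balance),
                       fmt_num(rows$strand_fwd), fmt_num(rows$strand_rev),
                       fmt_num(rows$identical_read_count), sep = ":")
    cells[rows$sample_id[filled]] <- cell_vals[filled]
    paste(c(first$chrom, first$pos + 1L, ".", first$ref, first$alt, ".",
            "PASS", info, fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# Sortable key for chromosome labels: chr1..chr22, chrX, chrY, then others.
chrom_order <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(stripped))
  num[stripped == "X"] <- 23L
  num[stripped == "Y"] <- 24L
  num[is.na(num)] <- 25L
  num
}
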