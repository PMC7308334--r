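# Shared helpers: small cohorts, on-the-fly fixture writers.

small_params <- function(n_families = 30, seed = 7, ...) {
  cohort_sim_params(n_families = n_families,
                    trio_fraction = 1 / 3,
                    per_gene_variant_rate_parent = 0.15,
                    seed = seed, ...)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal handcrafted VCF with the default dialect tags.
tiny_vcf <- function(body_lines, samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=SEGDUP,Number=0,Type=Flag,Description=\"Segdup\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=SQ,Number=1,Type=Float,Description=\"Quality\">",
    "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance\">",
    "##FORMAT=<ID=ADF,Number=1,Type=Integer,Description=\"Fwd reads\">",
    "##FORMAT=<ID=ADR,Number=1,Type=Integer,Description=\"Rev reads\">",
    "##FORMAT=<ID=MIR,Number=1,Type=Integer,Description=\"Identical reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  write_lines_tmp(c(header, body_lines), ext = ".vcf")
}

# One variant-call row with passing QC metrics; override any field.
make_variant <- function(...) {
  base <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
    genotype = "hom_alt", depth = 30L, site_quality = 50,
    allele_balance = 0.95, strand_fwd = 10L, strand_rev = 10L,
    identical_read_count = 2L, category = "missense", scaled_cadd = 15,
    in_segdup = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# Events tibble from compact arguments (defaults: countable scenario-1).
make_event <- function(...) {
  base <- tibble::tibble(
    family_id = "FAM1", gene_id = "G1", deletion_chrom = "chr1",
    deletion_start = 500L, deletion_end = 2000L, sample_id = "FAM1_P",
    carrier = "proband", chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
    genotype = "hom_alt", category = "missense", scaled_cadd = 15,
    in_segdup = FALSE, scenario = 1L, countable = TRUE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "comphet", mustWork = TRUE)
}
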