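# Gene content, variant QC, genotype exclusion, event detection, carriers.

del1 <- tibble::tibble(chrom = "chr1", start = 1000000L, end = 1100000L)

make_gene <- function(gene_id = "G1", chrom = "chr1", start = 1000L,
                      end = 2000L, brain = TRUE, segdup = FALSE) {
  tibble::tibble(gene_id = gene_id, name = gene_id, chrom = chrom,
                 start = start, end = end, brain_relevant = brain,
                 in_segdup = segdup)
}

test_that("gene content applies the 500 kb fuzzy border half-open", {
  genes <- rbind(
    make_gene("inside", start = 1010000L, end = 1020000L),
    make_gene("downstream_within", start = 1550000L, end = 1560000L),
    make_gene("at_border", start = 1600000L, end = 1610000L),   # == end+500kb
    make_gene("upstream_within", start = 510000L, end = 520000L),
    make_gene("too_far", start = 2000000L, end = 2010000L),
    make_gene("other_chrom", chrom = "chr2", start = 1010000L, end = 1020000L))
  got <- gene_content(del1, genes)
  expect_setequal(got$gene_id, c("inside", "downstream_within", "upstream_within"))
  expect_equal(got$gene_id, sort_by <- got$gene_id[order(got$start)])
})

test_that("gene content equals the brute-force all-pairs overlap oracle", {
  set.seed(51)
  for (rep in 1:20) {
    dstart <- sample.int(5e6, 1)
    dend <- dstart + sample.int(2e6, 1)
    del <- tibble::tibble(chrom = "chr1", start = dstart, end = dend)
    gs <- sample.int(8e6, 30)
    genes <- make_gene()[rep(1, 30), ]
    genes$gene_id <- sprintf("G%02d", 1:30)
    genes$start <- gs
    genes$end <- gs + sample.int(5e4, 30)
    got <- gene_content(del, genes)
    lo <- max(0, dstart - 500000); hi <- dend + 500000
    oracle <- genes[genes$start < hi & genes$end > lo, ]
    oracle <- oracle[order(oracle$start, oracle$gene_id), ]
    expect_equal(as.data.frame(got), as.data.frame(oracle))
  }
})

test_that("quality filter passes the boundary case and names failed criteria", {
  pass <- make_variant(depth = 10L, site_quality = 21, allele_balance = 0.16,
                       strand_fwd = 4L, strand_rev = 4L,
                       identical_read_count = 5L)
  got <- call_quality_filter(pass)
  expect_true(got$qc_pass)
  expect_equal(got$qc_failed, "")

  low_depth <- call_quality_filter(make_variant(depth = 9L, site_quality = 21,
                                                allele_balance = 0.16,
                                                strand_fwd = 4L, strand_rev = 4L,
                                                identical_read_count = 5L))
  expect_false(low_depth$qc_pass)
  expect_equal(low_depth$qc_failed, "coverage")

  # an absent metric fails its criterion
  no_ab <- call_quality_filter(make_variant(allele_balance = NA_real_))
  expect_false(no_ab$qc_pass)
  expect_match(no_ab$qc_failed, "allele_balance")
})

test_that("quality filter equals the brute-force conjunction on random variants", {
  set.seed(61)
  n <- 1000
  v <- make_variant()[rep(1, n), ]
  v$depth <- sample(5:15, n, replace = TRUE)
  v$site_quality <- sample(15:25, n, replace = TRUE)
  v$allele_balance <- round(runif(n, 0.05, 0.3), 3)
  v$strand_fwd <- sample(1:6, n, replace = TRUE)
  v$strand_rev <- sample(1:6, n, replace = TRUE)
  v$identical_read_count <- sample(3:7, n, replace = TRUE)
  got <- call_quality_filter(v)$qc_pass
  oracle <- v$depth >= 10 & v$site_quality > 20 & v$allele_balance > 0.15 &
    v$strand_fwd > 3 & v$strand_rev > 3 & v$identical_read_count <= 5
  expect_equal(got, oracle)
})

test_that("genotype exclusion drops identical hemizygous calls, keeps the rest", {
  pro <- make_variant(sample_id = "P", genotype = "hom_alt")
  par <- make_variant(sample_id = "D", genotype = "hom_alt")
  res <- genotype_exclusion_filter(pro, par)
  expect_false(res$keep_proband)
  expect_false(res$keep_parent)
  expect_equal(res$reason, "identical_homozygous")

  res2 <- genotype_exclusion_filter(pro, make_variant(genotype = "missing"))
  expect_true(res2$keep_proband)
  expect_false(res2$keep_parent)

  # homozygous reference is coded missing
  res3 <- genotype_exclusion_filter(make_variant(genotype = "hom_ref"), par)
  expect_false(res3$keep_proband)
  expect_true(res3$keep_parent)

  expect_error(genotype_exclusion_filter(pro, make_variant(pos = 999L)),
               "different sites")
})

# One handcrafted family: deletion chr1:[1,000,000-1,100,000), trio.
handcrafted <- function(variants) {
  ped <- tibble::tibble(family_id = "F1", proband_id = "P", father_id = "D",
                        mother_id = "M", n_parents = 2L, type = "trio",
                        multiplex = FALSE, n_affected = 1L)
  cnv <- tibble::tibble(sample_id = "P", chrom = "chr1", start = 1000000L,
                        end = 1100000L, cnv_type = "del",
                        inheritance = "paternal", n_algorithms = 3L,
                        cohort_freq = 0.01, zygosity = "het",
                        length = 100000L)
  genes <- make_gene("G1", start = 1050000L, end = 1150000L)  # straddles 3' end
  detect_events(ped, cnv, genes, variants)
}

test_that("scenario classification and carrier attribution follow the deletion boundary", {
  v_in <- make_variant(sample_id = "P", pos = 1060000L)
  v_out <- make_variant(sample_id = "P", pos = 1120000L, genotype = "het")
  v_par <- make_variant(sample_id = "D", pos = 1070000L)
  v_nontrans <- make_variant(sample_id = "M", pos = 1075000L)
  ev <- handcrafted(rbind(v_in, v_out, v_par, v_nontrans))
  expect_equal(nrow(ev), 3L)  # non-transmitting parent is never a source
  expect_equal(ev$scenario[ev$pos == 1060000L], 1L)
  expect_true(ev$countable[ev$pos == 1060000L])
  expect_equal(ev$scenario[ev$pos == 1120000L], 2L)
  expect_false(ev$countable[ev$pos == 1120000L])
  expect_equal(ev$carrier[ev$pos == 1070000L], "parent")
  # every countable event lies inside its deletion
  expect_true(all(ev$pos[ev$countable] >= ev$deletion_start[ev$countable] &
                    ev$pos[ev$countable] < ev$deletion_end[ev$countable]))
})

test_that("identical hemizygous calls in proband and parent yield no event", {
  v_pro <- make_variant(sample_id = "P", pos = 1060000L)
  v_par <- make_variant(sample_id = "D", pos = 1060000L)
  ev <- handcrafted(rbind(v_pro, v_par))
  expect_equal(nrow(ev), 0L)
  # but a hom_ref parent call means the proband variant stands alone
  v_par_ref <- make_variant(sample_id = "D", pos = 1060000L,
                            genotype = "hom_ref")
  ev2 <- handcrafted(rbind(v_pro, v_par_ref))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$carrier, "proband")
})

test_that("deletions without an identifiable transmitting parent are skipped with warning", {
  ped <- tibble::tibble(family_id = "F1", proband_id = "P",
                        father_id = NA_character_, mother_id = "M",
                        n_parents = 1L, type = "pair", multiplex = FALSE,
                        n_affected = 1L)
  cnv <- tibble::tibble(sample_id = "P", chrom = "chr1", start = 1000000L,
                        end = 1100000L, cnv_type = "del",
                        inheritance = "paternal", n_algorithms = 3L,
                        cohort_freq = 0.01, zygosity = "het", length = 100000L)
  genes <- make_gene("G1", start = 1010000L, end = 1020000L)
  v <- make_variant(sample_id = "P", pos = 1015000L)
  expect_warning(ev <- detect_events(ped, cnv, genes, v), "not genotyped")
  expect_equal(nrow(ev), 0L)
  cnv$inheritance <- "unknown"
  expect_warning(ev2 <- detect_events(ped, cnv, genes, v), "unknown inheritance")
  expect_equal(nrow(ev2), 0L)
})

test_that("full synthetic pipeline recovers exactly the planted scenario-1 events", {
  co <- generate_cohort(small_params(seed = 17))
  vq <- call_quality_filter(co$variants)
  ev <- detect_events(co$pedigrees, filter_cnv_calls(co$cnv_calls), co$genes,
                      vq[vq$qc_pass, ])
  got <- comphet:::countable_distinct(ev)
  truth1 <- co$truth[co$truth$scenario == 1L, ]
  expect_identical(sort(paste(got$sample_id, got$chrom, got$pos, got$alt)),
                   sort(paste(truth1$sample_id, truth1$chrom, truth1$pos,
                              truth1$alt)))
  # queried gene sets are identical for proband and transmitting parent by
  # construction: detection is a pure per-family computation
  one_fam <- co$pedigrees[3, ]
  ev_alone <- detect_events(one_fam, filter_cnv_calls(co$cnv_calls),
                            co$genes, vq[vq$qc_pass, ])
  expect_equal(as.data.frame(ev_alone),
               as.data.frame(ev[ev$family_id == one_fam$family_id, ]),
               ignore_attr = TRUE)
})

test_that("carrier summary counts distinct carriers with configurable denominators", {
  ev <- rbind(
    make_event(sample_id = "P1", pos = 1L),
    make_event(sample_id = "P1", pos = 2L),
    make_event(sample_id = "P2", pos = 3L),
    make_event(sample_id = "D1", pos = 4L, carrier = "parent"),
    make_event(sample_id = "P3", pos = 5L, scenario = 2L, countable = FALSE))
  cs <- carrier_summary(ev, n_probands = 10, n_parents = 12)
  expect_equal(cs$n_carriers[cs$group == "proband"], 2L)
  expect_equal(cs$n_variants[cs$group == "proband"], 3L)
  expect_equal(cs$pct_carriers[cs$group == "proband"], 20)
  expect_equal(cs$n_carriers[cs$group == "parent"], 1L)
  expect_equal(cs$denominator[cs$group == "parent"], 12)
  empty <- carrier_summary(ev[0, ], 10, 10)
  expect_equal(empty$n_carriers, c(0L, 0L))
  expect_equal(empty$pct_carriers, c(0, 0))
})
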