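# CNV filtering, family exclusion, and the weighted rank-sum priority score.

make_cnv <- function(n_algorithms = 2L, cohort_freq = 0.05, start = 0L,
                     end = 10000L, sample_id = "P1", cnv_type = "del",
                     inheritance = "paternal", zygosity = "het",
                     chrom = "chr1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, cnv_type = cnv_type, inheritance = inheritance,
                 n_algorithms = n_algorithms, cohort_freq = cohort_freq,
                 zygosity = zygosity, length = end - start)
}

test_that("CNV filter applies the three criteria at their exact boundaries", {
  boundary_pass <- make_cnv(n_algorithms = 2L, cohort_freq = 0.09,
                            end = 5001L)
  expect_equal(nrow(filter_cnv_calls(boundary_pass)), 1L)
  # length exactly 5000 is removed (strict >)
  expect_equal(nrow(filter_cnv_calls(make_cnv(end = 5000L))), 0L)
  # frequency exactly 0.10 is removed (strict <)
  expect_equal(nrow(filter_cnv_calls(make_cnv(cohort_freq = 0.10))), 0L)
  # single-algorithm call is removed (>= 2)
  expect_equal(nrow(filter_cnv_calls(make_cnv(n_algorithms = 1L))), 0L)
})

test_that("CNV filter equals the brute-force three-predicate filter and is idempotent", {
  set.seed(21)
  n <- 50
  calls <- make_cnv()[rep(1, n), ]
  calls$n_algorithms <- sample(1:4, n, replace = TRUE)
  calls$cohort_freq <- round(runif(n, 0, 0.2), 3)
  calls$end <- calls$start + sample(c(4000L, 5000L, 5001L, 80000L), n,
                                    replace = TRUE)
  calls$length <- calls$end - calls$start
  got <- filter_cnv_calls(calls)
  oracle <- calls[sapply(seq_len(n), function(i) {
    calls$n_algorithms[i] >= 2 && calls$cohort_freq[i] < 0.10 &&
      (calls$end[i] - calls$start[i]) > 5000
  }), ]
  expect_equal(as.data.frame(got), as.data.frame(oracle))
  expect_equal(filter_cnv_calls(got), got)
})

test_that("family exclusion removes multiplex families and homozygous deletions", {
  ped <- tibble::tibble(
    family_id = c("F1", "F2", "F3"), proband_id = c("P1", "P2", "P3"),
    father_id = c("D1", "D2", "D3"), mother_id = NA_character_,
    n_parents = 1L, type = "pair",
    multiplex = c(FALSE, TRUE, FALSE), n_affected = c(1L, 2L, 1L))
  calls <- rbind(make_cnv(sample_id = "P1", zygosity = "hom", end = 9000L),
                 make_cnv(sample_id = "P3", zygosity = "het", end = 9000L))
  res <- exclude_families(ped, calls)
  expect_equal(res$retained$family_id, "F3")
  expect_equal(res$excluded$reason[res$excluded$family_id == "F2"], "multiplex")
  expect_equal(res$excluded$reason[res$excluded$family_id == "F1"],
               "homozygous_deletion")
  # neither condition: everything is retained
  clean <- exclude_families(ped[3, ], calls[2, ])
  expect_equal(nrow(clean$retained), 1L)
  expect_equal(nrow(clean$excluded), 0L)
})

test_that("a single family gets the identity-rank score of 9", {
  feats <- tibble::tibble(family_id = "F1", n_del = 2L, n_brain_del = 1L,
                          inherit_ratio_del = 1, n_dup = 0L, n_brain_dup = 0L,
                          inherit_ratio_dup = 0, n_denovo = 0L)
  scored <- priority_score(feats)
  expect_equal(scored$R_i, 2 * 3 + 1 * 3)
})

test_that("deletion-feature dominance wins under equal duplication features", {
  feats <- tibble::tibble(
    family_id = c("A", "B"),
    n_del = c(3L, 1L), n_brain_del = c(2L, 0L), inherit_ratio_del = c(1, 0.5),
    n_dup = c(1L, 1L), n_brain_dup = c(1L, 1L), inherit_ratio_dup = c(1, 1),
    n_denovo = c(0L, 0L))
  scored <- priority_score(feats)
  expect_equal(scored$family_id[1], "A")
  expect_gt(scored$R_i[scored$family_id == "A"],
            scored$R_i[scored$family_id == "B"])
})

test_that("priority ordering equals brute-force weighted rank-sum recomputation", {
  set.seed(31)
  n <- 20
  feats <- tibble::tibble(
    family_id = sprintf("F%02d", 1:n),
    n_del = rpois(n, 2), n_brain_del = rpois(n, 1),
    inherit_ratio_del = round(runif(n), 2),
    n_dup = rpois(n, 2), n_brain_dup = rpois(n, 1),
    inherit_ratio_dup = round(runif(n), 2),
    n_denovo = rpois(n, 0.5))
  scored <- priority_score(feats)
  brute <- 2 * (rank(feats$n_del) + rank(feats$n_brain_del) +
                  rank(feats$inherit_ratio_del)) +
    (rank(feats$n_dup) + rank(feats$n_brain_dup) +
       rank(feats$inherit_ratio_dup))
  expect_equal(scored$R_i[match(feats$family_id, scored$family_id)], brute)
  ord <- order(feats$n_denovo, -brute, feats$family_id)
  expect_equal(scored$family_id, feats$family_id[ord])
})

test_that("deletion perturbations move the score twice as far as duplication ones", {
  set.seed(41)
  n <- 12
  n_cnv <- rpois(n, 3); n_brain <- rpois(n, 1); ratio <- round(runif(n), 2)
  # symmetric deletion and duplication features, so the same perturbation
  # displaces ranks identically in both blocks
  base <- tibble::tibble(
    family_id = sprintf("F%02d", 1:n),
    n_del = n_cnv, n_brain_del = n_brain, inherit_ratio_del = ratio,
    n_dup = n_cnv, n_brain_dup = n_brain, inherit_ratio_dup = ratio,
    n_denovo = 0L)
  r0 <- priority_score(base)
  r0 <- r0$R_i[match(base$family_id, r0$family_id)]
  # swapping ranks within the weight-1 (dup) block changes R_i by at most
  # half of what the same perturbation in the weight-2 (del) block does
  bump_dup <- base; bump_dup$n_dup[1] <- max(base$n_dup) + 10L
  bump_del <- base; bump_del$n_del[1] <- max(base$n_del) + 10L
  rd <- priority_score(bump_dup); rd <- rd$R_i[match(base$family_id, rd$family_id)]
  rl <- priority_score(bump_del); rl <- rl$R_i[match(base$family_id, rl$family_id)]
  delta_dup <- rd[1] - r0[1]
  delta_del <- rl[1] - r0[1]
  expect_equal(delta_del, 2 * delta_dup)
})

test_that("priority features are computed from CNV calls and gene content", {
  co <- generate_cohort(small_params(seed = 13))
  feats <- priority_features(co$pedigrees, co$cnv_calls, co$genes)
  expect_equal(nrow(feats), nrow(co$pedigrees))
  # every family has exactly one inherited brain-relevant deletion
  expect_true(all(feats$n_del == 1L))
  expect_true(all(feats$n_brain_del == 1L))
  expect_true(all(feats$inherit_ratio_del == 1))
  expect_true(all(feats$n_dup == 0L))
  scored <- priority_score(feats)
  expect_true(all(scored$R_i > 0))
  expect_error(priority_score(feats[0, ]), "at least one")
})
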