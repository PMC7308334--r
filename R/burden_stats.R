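# The three statistical procedures: the pooled equal-sequence count test,
# CADD score aggregation with a logistic burden test, and the Bonferroni
# multiple-testing rule.

#' Pooled-count test of equal variant rates
#'
#' By design the pooled proband sequence and the pooled transmitting-parent
#' sequence are identical in gene identity and length, so under the null the
#' observed variants split 50:50 between the two groups. The test is the
#' 1-degree-of-freedom chi-square goodness of fit against the equal split
#' `E = (a + b)/2`, without continuity correction:
#' `X^2 = (a - E)^2/E + (b - E)^2/E`.
#'
#' @param n_proband,n_parent Pooled variant counts in the two groups
#'   (total must be positive).
#' @return List of class `pooled_burden` with `n_proband`, `n_parent`,
#'   `chi_square`, `df` (= 1), `p_value`.
#' @examples
#' pooled_count_test(68, 41) # X^2 = 6.69, p = 0.0097
#' @export
pooled_count_test <- function(n_proband, n_parent) {
  if (length(n_proband) != 1L || length(n_parent) != 1L ||
      is.na(n_proband) || is.na(n_parent) || n_proband < 0 || n_parent < 0) {
    stop("counts must be single non-negative numbers", call. = FALSE)
  }
  if (n_proband + n_parent == 0) {
    stop("pooled count test undefined: both counts are zero", call. = FALSE)
  }
  ct <- suppressWarnings(
    chisq.test(c(n_proband, n_parent), p = c(0.5, 0.5), correct = FALSE))
  structure(list(n_proband = n_proband, n_parent = n_parent,
                 chi_square = unname(ct$statistic), df = 1L,
                 p_value = unname(ct$p.value)),
            class = "pooled_burden")
}

#' @method print pooled_burden
#' @export
print.pooled_burden <- function(x, ...) {
  cat(sprintf("Pooled count test: probands %d vs parents %d\n",
              x$n_proband, x$n_parent))
  cat(sprintf("  X^2 = %.2f (df = 1), p = %.4g\n", x$chi_square, x$p_value))
  invisible(x)
}

#' Aggregate scaled CADD scores per individual
#'
#' Sums the scaled CADD scores of each individual's countable (scenario-1)
#' variants. In `"carriers"` mode only individuals with at least one event
#' appear; in `"full"` mode every individual in `individuals` appears, with
#' an aggregated score of 0 when they carry no event.
#'
#' @param events Event tibble from [detect_events()].
#' @param mode `"carriers"` or `"full"`.
#' @param individuals For `"full"` mode: tibble with columns `sample_id` and
#'   `role` (`"proband"`/`"parent"`) listing the full analyzed sample.
#' @param missing_score Policy for a countable variant lacking a score:
#'   `"error"` (default) or `"drop"`.
#' @return Tibble with `sample_id`, `role`, `cadd_sum`, `n_variants`.
#' @export
aggregate_cadd <- function(events, mode = c("carriers", "full"),
                           individuals = NULL,
                           missing_score = c("error", "drop")) {
  mode <- match.arg(mode)
  missing_score <- match.arg(missing_score)
  ev <- countable_distinct(events)
  if (anyNA(ev$scaled_cadd)) {
    bad <- ev[which(is.na(ev$scaled_cadd))[1], ]
    if (missing_score == "error") {
      stop(sprintf("variant %s:%d %s>%s has no CADD score",
                   bad$chrom, bad$pos + 1L, bad$ref, bad$alt), call. = FALSE)
    }
    ev <- ev[!is.na(ev$scaled_cadd), , drop = FALSE]
  }
  if (nrow(ev)) {
    sums <- tapply(ev$scaled_cadd, ev$sample_id, sum)
    counts <- tapply(ev$scaled_cadd, ev$sample_id, length)
    roles <- ev$carrier[match(names(sums), ev$sample_id)]
    agg <- tibble(sample_id = names(sums), role = roles,
                  cadd_sum = as.numeric(sums),
                  n_variants = as.integer(counts))
  } else {
    agg <- tibble(sample_id = character(), role = character(),
                  cadd_sum = numeric(), n_variants = integer())
  }
  if (mode == "carriers") return(agg[order(agg$sample_id), , drop = FALSE])
  if (is.null(individuals)) {
    stop("full-sample aggregation needs the `individuals` roster", call. = FALSE)
  }
  idx <- match(individuals$sample_id, agg$sample_id)
  out <- tibble(sample_id = individuals$sample_id, role = individuals$role,
                cadd_sum = ifelse(is.na(idx), 0, agg$cadd_sum[idx]),
                n_variants = ifelse(is.na(idx), 0L, agg$n_variants[idx]))
  out[order(out$sample_id), , drop = FALSE]
}

#' Logistic burden test on aggregated CADD scores
#'
#' Fits `log-odds(proband) = intercept + beta * score` by maximum
#' likelihood (probands coded 1, parents 0) and reports the score
#' coefficient with its Wald standard error and p value. Under complete or
#' quasi-complete separation the fit is flagged `converged = FALSE` and no
#' estimate is reported, rather than returning unstable values.
#'
#' @param scores Numeric vector of per-individual aggregated scores.
#' @param labels Character vector, `"proband"` or `"parent"`, same length.
#' @return List of class `burden_test` with `beta`, `standard_error`,
#'   `p_value`, `n_individuals`, `converged`, `message`.
#' @export
logistic_burden_test <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!all(labels %in% c("proband", "parent"))) {
    stop("labels must be 'proband' or 'parent'", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both labels must be present", call. = FALSE)
  }
  if (length(scores) < 2L) stop("need at least 2 individuals", call. = FALSE)
  y <- as.integer(labels == "proband")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ scores, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  converged <- fit$converged && !sep_warn
  if (!converged) {
    return(structure(list(beta = NA_real_, standard_error = NA_real_,
                          p_value = NA_real_, n_individuals = length(scores),
                          converged = FALSE,
                          message = "separation or non-convergence; no stable estimate"),
                     class = "burden_test"))
  }
  sm <- summary(fit)$coefficients
  structure(list(beta = unname(sm["scores", "Estimate"]),
                 standard_error = unname(sm["scores", "Std. Error"]),
                 p_value = unname(sm["scores", "Pr(>|z|)"]),
                 n_individuals = length(scores), converged = TRUE,
                 message = ""),
            class = "burden_test")
}

#' @method print burden_test
#' @export
print.burden_test <- function(x, ...) {
  if (!x$converged) {
    cat("Logistic burden test: not converged (", x$message, ")\n", sep = "")
  } else {
    cat(sprintf("Logistic burden test (n = %d): beta = %.4g (SE %.4g), p = %.4g\n",
                x$n_individuals, x$beta, x$standard_error, x$p_value))
  }
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise level in (0, 1) (default 0.05).
#' @param m Number of tests, >= 1 (default 3: count test, burden test,
#'   filtered count test).
#' @return The per-test threshold `alpha / m`.
#' @examples
#' bonferroni_threshold() # 0.05/3
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Bonferroni significance decision
#'
#' @param p Vector of p values.
#' @inheritParams bonferroni_threshold
#' @return Logical vector: `p < alpha/m`.
#' @export
is_significant <- function(p, alpha = 0.05, m = 3L) {
  p < bonferroni_threshold(alpha, m)
}
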