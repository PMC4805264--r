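# Group-level statistics: between-group comparison of reliability scores
# with a Bonferroni-adjusted significance level, plus demographic-table
# utilities that work from printed summary statistics alone.

new_group_comparison <- function(label, statistic, df, p, m_tests) {
  alpha <- 0.05 / m_tests
  structure(list(network = label, statistic = statistic, df = df, p = p,
                 significant_bonferroni = is.finite(p) && p < alpha,
                 alpha = alpha, m_tests = m_tests),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %.4f%s (Bonferroni alpha = %.4f)\n",
              x$network %||% "comparison", x$df, x$statistic, x$p,
              if (x$significant_bonferroni) " *" else "", x$alpha))
  invisible(x)
}

#' Compare a reliability score between two groups
#'
#' Two-sided pooled-variance (Student) t-test on per-subject scores, with a
#' significance flag at the Bonferroni-adjusted level `0.05 / m_tests`
#' (0.0056 when nine networks are compared). Degenerate inputs with zero
#' pooled variance yield p = 1 when the means agree and an error otherwise.
#'
#' @param scores_a,scores_b per-subject scores of the two groups (NAs are
#'   dropped).
#' @param m_tests number of simultaneous comparisons the Bonferroni level
#'   divides by (default 9, one per network).
#' @param label label carried into the result (e.g. the network name).
#' @return a `group_comparison`: `network`, `statistic`, `df`, `p`,
#'   `significant_bonferroni`, `alpha`.
#' @export
compare_groups <- function(scores_a, scores_b, m_tests = 9L, label = NA) {
  a <- scores_a[!is.na(scores_a)]
  b <- scores_b[!is.na(scores_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 non-missing scores")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(new_group_comparison(label, 0, length(a) + length(b) - 2L, 1,
                                  m_tests))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  new_group_comparison(label, unname(tt$statistic), unname(tt$parameter),
                       tt$p.value, m_tests)
}

#' Summary statistics (mean, SD, n) of one group
#'
#' @param mean,sd,n group mean, standard deviation and size.
#' @return a `summary_stats` list.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0")
  if (n < 2) stop("n must be >= 2")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)), class = "summary_stats")
}

#' Unpaired t-test from printed summary statistics
#'
#' Pooled-variance two-sided t-test computed from means, SDs and group
#' sizes alone, `df = n_a + n_b - 2` — exactly what is needed to recompute
#' a demographics table's p-values from its printed cells. Pooling (rather
#' than Welch's correction) is the convention such tables follow.
#'
#' @param a,b `summary_stats` (or lists with `mean`, `sd`, `n`).
#' @param m_tests Bonferroni divisor for the significance flag (default 1:
#'   demographic comparisons are typically reported unadjusted).
#' @param label label carried into the result.
#' @return a `group_comparison`.
#' @export
#' @examples
#' # age: HC mean 29.1 (SD 10.3, n 14) vs MS 33.1 (9.3, n 20) -> p ~ 0.25
#' ttest_from_summary(summary_stats(29.1, 10.3, 14),
#'                    summary_stats(33.1, 9.3, 20))
ttest_from_summary <- function(a, b, m_tests = 1L, label = NA) {
  stopifnot(all(c("mean", "sd", "n") %in% names(a)),
            all(c("mean", "sd", "n") %in% names(b)))
  if (a$sd == 0 && b$sd == 0)
    stop("both SDs are zero: degenerate input, t is undefined")
  df <- a$n + b$n - 2
  pooled_var <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(pooled_var * (1 / a$n + 1 / b$n))
  t <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  new_group_comparison(label, t, df, p, m_tests)
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Chi-square without continuity correction, df = 1 — the form whose
#' statistic equals `n (ad - bc)^2` over the product of the margins, and
#' the one demographic sex-ratio comparisons are reported with.
#'
#' @param a_yes,a_no,b_yes,b_no nonnegative integer cell counts (group A /
#'   B by outcome yes / no).
#' @param m_tests Bonferroni divisor for the significance flag (default 1).
#' @param label label carried into the result.
#' @return a `group_comparison` (statistic is the chi-square).
#' @export
#' @examples
#' chisq_2x2(6, 8, 5, 15)  # 6/14 male HC vs 5/20 male MS -> p ~ 0.27
chisq_2x2 <- function(a_yes, a_no, b_yes, b_no, m_tests = 1L, label = NA) {
  cells <- c(a_yes, a_no, b_yes, b_no)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square is undefined when a row or column margin is zero")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_group_comparison(label, unname(res$statistic), unname(res$parameter),
                       res$p.value, m_tests)
}

#' Per-network between-group comparison of overlap ratios
#'
#' Runs [compare_groups()] on the per-subject R12 scores of every network,
#' Bonferroni-adjusting for the number of networks, and returns a tidy
#' table mirroring the "does reliability differ between groups?" question.
#'
#' @param subject_scores the `"subject_scores"` attribute of a
#'   [network_reproducibility()] table (columns `subject_id`, `group`,
#'   `network`, `r12`).
#' @param m_tests Bonferroni divisor; defaults to the number of networks.
#' @param value column of `subject_scores` to compare (default `"r12"`).
#' @return data frame: `network`, per-group mean (SD) columns, `t`, `df`,
#'   `p`, `significant_bonferroni`.
#' @export
group_score_comparison <- function(subject_scores, m_tests = NULL,
                                   value = "r12") {
  groups <- unique(subject_scores$group)
  if (length(groups) != 2L)
    stop(sprintf("need exactly 2 groups, found %d", length(groups)))
  networks <- unique(subject_scores$network)
  m_tests <- m_tests %||% length(networks)
  rows <- lapply(networks, function(nw) {
    sub <- subject_scores[subject_scores$network == nw, ]
    va <- sub[[value]][sub$group == groups[1]]
    vb <- sub[[value]][sub$group == groups[2]]
    cmp <- compare_groups(va, vb, m_tests = m_tests, label = nw)
    out <- data.frame(network = nw,
                      mean_a = mean(va, na.rm = TRUE),
                      sd_a = stats::sd(va, na.rm = TRUE),
                      mean_b = mean(vb, na.rm = TRUE),
                      sd_b = stats::sd(vb, na.rm = TRUE),
                      t = cmp$statistic, df = cmp$df, p = cmp$p,
                      significant_bonferroni = cmp$significant_bonferroni,
                      stringsAsFactors = FALSE)
    names(out)[2:5] <- c(paste0("mean_", groups[1]), paste0("sd_", groups[1]),
                         paste0("mean_", groups[2]), paste0("sd_", groups[2]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
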