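# Clinical association tests on dichotomized covariates.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value follows the probability-mass rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of every table whose point probability does not exceed that of the
#' observed table (up to a relative tolerance of 1e-7). Computation is
#' delegated to [stats::fisher.test()], which implements exactly this rule.
#'
#' @param tab 2x2 matrix (or 4 counts `a, b, c, d` filled by row) of
#'   non-negative integers; rows are exposure groups, columns outcome.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(1, 7, 7, 2), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (length(tab) == 4L && !all(dim(tab) == c(2L, 2L)))
    tab <- matrix(as.vector(tab), 2, 2, byrow = TRUE)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("entries must be non-negative integers")
  if (sum(tab) < 1) stop("empty table")
  stats::fisher.test(tab)$p.value
}

#' Dichotomized clinical association report
#'
#' Builds two 2x2 tables from the subject metadata — enrollment order
#' (rank <= `split_rank` vs later) against mucositis class, and BMI
#' (> `bmi_cut` vs <=, boundary values falling in the low group) against
#' mucositis class — and tests each with Fisher's exact test. Class 2
#' (GM grade >= 1) is the positive column.
#'
#' @param meta metadata data frame with `gm_grade` (or `class_label`),
#'   `enrollment_rank`, `bmi`.
#' @param split_rank enrollment-rank split point (default 8: first 8
#'   enrolled vs the rest).
#' @param bmi_cut BMI dichotomization cut (default 30).
#' @return list with `enrollment` and `bmi`, each holding `table` (2x2,
#'   rows = exposure groups, cols = GM+/GM-) and `p_value`.
#' @export
association_report <- function(meta, split_rank = 8L, bmi_cut = 30) {
  y <- if ("class_label" %in% names(meta)) meta$class_label else class_labels(meta)
  pos <- y == 2L
  early <- meta$enrollment_rank <= split_rank
  high_bmi <- meta$bmi > bmi_cut
  if (all(early) || !any(early)) stop("degenerate enrollment split")
  if (all(high_bmi) || !any(high_bmi)) stop("degenerate BMI split")
  mk <- function(grp, labels) {
    t <- rbind(c(sum(grp & pos), sum(grp & !pos)),
               c(sum(!grp & pos), sum(!grp & !pos)))
    dimnames(t) <- list(labels, c("GM+", "GM-"))
    t
  }
  enr <- mk(early, c(paste0("rank<=", split_rank), paste0("rank>", split_rank)))
  bmi <- mk(high_bmi, c(paste0("BMI>", bmi_cut), paste0("BMI<=", bmi_cut)))
  list(enrollment = list(table = enr, p_value = fisher_exact_2x2(enr)),
       bmi = list(table = bmi, p_value = fisher_exact_2x2(bmi)))
}

#' Clinical characteristics summary by mucositis subgroup
#'
#' Mirrors a standard cohort table: mean (range) for continuous covariates
#' and n (percent) for categorical flags, split by GM-positive (class 2)
#' vs GM-negative (class 1) subgroup.
#'
#' @param meta metadata data frame.
#' @return data frame with one row per characteristic.
#' @export
clinical_summary <- function(meta) {
  y <- if ("class_label" %in% names(meta)) meta$class_label else class_labels(meta)
  grp <- list(`GM positive` = meta[y == 2L, ], `GM negative` = meta[y == 1L, ])
  cont <- function(col) vapply(grp, function(g)
    sprintf("%.1f (%.1f - %.1f)", mean(g[[col]]), min(g[[col]]), max(g[[col]])),
    character(1))
  flag <- function(col, lev = TRUE) vapply(grp, function(g) {
    k <- sum(g[[col]] == lev); sprintf("%d (%.1f)", k, 100 * k / nrow(g))
  }, character(1))
  rows <- list(BMI = cont("bmi"), Age = cont("age"))
  for (col in intersect(c("smoker", "chemoradiation", "brachytherapy"),
                        names(meta)))
    rows[[col]] <- flag(col)
  if ("cancer_type" %in% names(meta))
    for (ct in unique(meta$cancer_type))
      rows[[paste("Cancer:", ct)]] <- flag("cancer_type", ct)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- sprintf("%s (n=%d)", names(grp),
                        vapply(grp, nrow, integer(1)))
  out
}
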