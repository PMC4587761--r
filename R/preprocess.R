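# Spectral-count preprocessing: replicate averaging, total-count
# normalization, sparsity filtering, covariate augmentation.
#
# The predictor matrix ("profile matrix") is a plain numeric matrix with
# subject IDs as rownames and predictor IDs as colnames, plus a
# "covariates" attribute naming the appended non-protein columns (these
# bypass normalization and filtering).

covariate_cols <- function(x) {
  cv <- attr(x, "covariates")
  if (is.null(cv)) character(0) else cv
}

protein_cols <- function(x) setdiff(colnames(x), covariate_cols(x))

set_covariates <- function(x, cv) { attr(x, "covariates") <- cv; x }

#' Average technical replicates into a subject-by-protein matrix
#'
#' Each subject's spectral counts are averaged over that subject's
#' technical replicates; a protein absent from a replicate contributes a
#' zero (absent-as-zero convention), so a protein seen in one of two
#' replicates with count 6 averages to 3. Subjects with a single replicate
#' are passed through unchanged (with a warning when replicate counts are
#' unbalanced).
#'
#' @param raw long-format data frame with columns `subject_id`,
#'   `replicate_id`, `protein_id` (or `gene_id`, used for column names when
#'   present), and `count` (non-negative spectral counts).
#' @return numeric matrix, one row per subject, one column per protein,
#'   cells the replicate-averaged counts.
#' @export
average_replicates <- function(raw) {
  if (!is.data.frame(raw) || nrow(raw) == 0L)
    stop("raw count table is empty")
  need <- c("subject_id", "replicate_id", "count")
  if (!all(need %in% names(raw)))
    stop("raw count table must have columns subject_id, replicate_id, count")
  key_col <- if ("gene_id" %in% names(raw)) "gene_id" else "protein_id"
  if (!key_col %in% names(raw))
    stop("raw count table must have a protein_id or gene_id column")
  if (any(raw$count < 0)) stop("negative spectral counts")
  key <- paste(raw$subject_id, raw$replicate_id, raw[[key_col]], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, replicate, protein) rows in raw count table")
  subjects <- unique(as.character(raw$subject_id))
  proteins <- unique(as.character(raw[[key_col]]))
  totals <- tapply(raw$count,
                   list(factor(raw$subject_id, levels = subjects),
                        factor(raw[[key_col]], levels = proteins)),
                   sum, default = 0)
  totals <- matrix(totals, length(subjects), length(proteins),
                   dimnames = list(subjects, proteins))
  nrep <- vapply(subjects, function(s)
    length(unique(raw$replicate_id[raw$subject_id == s])), integer(1))
  if (length(unique(nrep)) > 1L)
    warning("unbalanced replicate counts across subjects; ",
            "averaging over available replicates")
  out <- totals / nrep
  set_covariates(out, character(0))
}

#' Normalize profiles by total spectral count
#'
#' Scales each subject's protein row so that all row totals equal the grand
#' mean of the original row totals (total-count scaling to the mean library
#' size). Covariate columns are excluded from both the totals and the
#' scaling.
#'
#' @param x profile matrix from [average_replicates()].
#' @return profile matrix with equalized protein row totals.
#' @export
normalize_profiles <- function(x) {
  pc <- protein_cols(x)
  totals <- rowSums(x[, pc, drop = FALSE])
  if (any(totals <= 0))
    stop("subject(s) with all-zero protein profile: ",
         paste(rownames(x)[totals <= 0], collapse = ", "))
  x[, pc] <- x[, pc, drop = FALSE] * (mean(totals) / totals)
  x
}

#' Filter proteins by minimum non-zero prevalence
#'
#' Keeps only protein columns with a strictly positive value in at least
#' `min_nonzero` subjects (boundary inclusive: exactly `min_nonzero`
#' non-zero subjects is retained). Covariate columns always survive.
#' Column order of survivors is preserved.
#'
#' @param x profile matrix.
#' @param min_nonzero integer >= 1; default 12.
#' @return filtered profile matrix.
#' @export
filter_proteins <- function(x, min_nonzero = 12L) {
  stopifnot(min_nonzero >= 1L)
  pc <- protein_cols(x)
  nz <- colSums(x[, pc, drop = FALSE] > 0)
  keep_prot <- pc[nz >= min_nonzero]
  if (length(keep_prot) == 0L)
    stop("no proteins survive the min_nonzero = ", min_nonzero, " filter")
  keep <- colnames(x)[colnames(x) %in% c(keep_prot, covariate_cols(x))]
  out <- x[, keep, drop = FALSE]
  set_covariates(out, covariate_cols(x))
}

#' Append clinical covariates as extra predictor columns
#'
#' Covariates (e.g. age, BMI) are appended after the protein columns in
#' their native units; they are never normalized or filtered.
#'
#' @param x profile matrix.
#' @param meta subject metadata data frame with a `subject_id` column.
#' @param names character vector of metadata columns to append (may be
#'   empty, in which case `x` is returned unchanged).
#' @return augmented profile matrix.
#' @export
augment_covariates <- function(x, meta, names = character(0)) {
  if (length(names) == 0L) return(x)
  missing_cv <- setdiff(names, colnames(meta))
  if (length(missing_cv))
    stop("covariate(s) not in metadata: ", paste(missing_cv, collapse = ", "))
  idx <- match(rownames(x), meta$subject_id)
  if (anyNA(idx)) stop("metadata missing subjects: ",
                       paste(rownames(x)[is.na(idx)], collapse = ", "))
  add <- as.matrix(meta[idx, names, drop = FALSE])
  if (anyNA(add)) stop("missing covariate values")
  storage.mode(add) <- "double"
  colnames(add) <- names
  out <- cbind(x, add)
  set_covariates(out, union(covariate_cols(x), names))
}

#' Derive 1/2 class labels from GM grades
#'
#' Grade 0 maps to class 1 (negative, no mucositis); grades 1-2 map to
#' class 2 (positive).
#'
#' @param meta metadata data frame with `gm_grade`.
#' @return integer vector of 1/2 labels named by subject.
#' @export
class_labels <- function(meta) {
  stopifnot(all(meta$gm_grade %in% 0:4))
  y <- ifelse(meta$gm_grade == 0, 1L, 2L)
  names(y) <- meta$subject_id
  y
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper applying the fixed composition
#' average -> normalize -> filter -> augment.
#'
#' @inheritParams average_replicates
#' @inheritParams filter_proteins
#' @param meta subject metadata (needed only when `covariates` is
#'   non-empty).
#' @param covariates character vector of metadata columns to append.
#' @return profile matrix ready for [train_ensemble()].
#' @export
preprocess_cohort <- function(raw, meta = NULL, min_nonzero = 12L,
                              covariates = character(0)) {
  x <- filter_proteins(normalize_profiles(average_replicates(raw)),
                       min_nonzero = min_nonzero)
  if (length(covariates)) x <- augment_covariates(x, meta, covariates)
  x
}
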