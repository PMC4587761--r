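# Repeated k-fold cross-validation, performance indices with abstention
# handling, t-based summaries, and the label-permutation validity control.

#' Cross-validation configuration
#'
#' @param k_folds number of folds (default 10).
#' @param repetitions number of repeated CV runs (default 20).
#' @param base_seed integer; run r uses seed `base_seed + r`.
#' @param stratified logical; stratify fold assignment by class (default
#'   `FALSE`: plain random division).
#' @return list of class `cv_config`.
#' @export
cv_config <- function(k_folds = 10L, repetitions = 20L, base_seed = 1L,
                      stratified = FALSE) {
  stopifnot(k_folds >= 2L, repetitions >= 1L)
  structure(list(k_folds = as.integer(k_folds),
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Partition sample indices into folds
#'
#' Fold sizes are deterministic given `(n, k_folds)`: `n %% k_folds` folds
#' of size `floor(n/k_folds) + 1` and the rest of size `floor(n/k_folds)`,
#' so sizes differ by at most one (n = 17, k = 10 gives seven 2-subsets and
#' three 1-subsets). The assignment of subjects to folds is a uniform
#' random permutation.
#'
#' @param n number of samples.
#' @param k_folds number of folds (<= n).
#' @param seed optional integer; when given, the assignment is drawn from a
#'   local RNG stream without disturbing the global one.
#' @param y optional class labels; when given, assignment is stratified.
#' @return list of integer vectors partitioning `1:n`.
#' @export
make_folds <- function(n, k_folds, seed = NULL, y = NULL) {
  if (k_folds > n) stop("k_folds exceeds number of samples")
  sizes <- rep(floor(n / k_folds), k_folds)
  extra <- n %% k_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (!is.null(y)) {
    # stratified: shuffle within class, deal round-robin across folds
    perm <- with_local_seed(seed, unlist(lapply(split(seq_len(n), y),
                                                function(ix) ix[sample.int(length(ix))])))
    assign <- integer(n)
    assign[perm] <- rep_len(seq_len(k_folds), n)
    return(unname(split(seq_len(n), assign)))
  }
  perm <- with_local_seed(seed, sample.int(n))
  unname(split(perm, rep.int(seq_len(k_folds), sizes)))
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Performance indices from a confusion summary
#'
#' Class 2 is the positive class. Abstained (unclassified) subjects are
#' excluded from every denominator. A zero denominator leaves the index
#' undefined (`NA`), never 0.
#'
#' @param confusion list or named vector with `tp`, `fp`, `tn`, `fn` (and
#'   optionally `abstained`).
#' @return named numeric vector `acc`, `sen`, `spc`, `ppv`, `npv` (with
#'   `NA` for undefined indices).
#' @export
performance_indices <- function(confusion) {
  tp <- confusion[["tp"]]; fp <- confusion[["fp"]]
  tn <- confusion[["tn"]]; fn <- confusion[["fn"]]
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  c(acc = rat(tp + tn, tp + tn + fp + fn),
    sen = rat(tp, tp + fn),
    spc = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn))
}

#' Run repeated k-fold cross-validation of the hull ensemble
#'
#' Each repetition draws a fresh random fold assignment (seed
#' `base_seed + run`), trains a full ensemble on each training fold
#' (pair ranking and hull trimming see only the training subjects), and
#' classifies the held-out subjects. Abstentions are recorded, never
#' imputed. A fold assignment that leaves a training set single-class is
#' re-drawn (with a message).
#'
#' @param x predictor matrix (subjects in rows).
#' @param y class labels coded 1/2.
#' @param cv a [cv_config()].
#' @param config an [ensemble_config()].
#' @param keep_top number of top-ranked pairs per training fold to keep in
#'   the trace for prominence analysis (default 10).
#' @return object of class `repeated_cv`: list of per-run results, each
#'   with `predictions` (subject, truth, class, tallies), `confusion`,
#'   `indices`, `fold_pairs` (per-fold top-ranked pairs).
#' @export
run_repeated_cv <- function(x, y, cv = cv_config(), config = ensemble_config(),
                            keep_top = 10L) {
  x <- as.matrix(x)
  y <- normalize_labels(y)
  n <- nrow(x)
  runs <- vector("list", cv$repetitions)
  for (r in seq_len(cv$repetitions)) {
    seed <- cv$base_seed + r
    folds <- make_folds(n, cv$k_folds, seed = seed,
                        y = if (cv$stratified) y else NULL)
    tries <- 0L
    while (any(vapply(folds, function(f)
        length(unique(y[-f])) < 2L, logical(1)))) {
      tries <- tries + 1L
      message("run ", r, ": single-class training fold; re-drawing (", tries, ")")
      folds <- make_folds(n, cv$k_folds, seed = seed + 1000L * tries,
                          y = if (cv$stratified) y else NULL)
      if (tries > 50L) stop("could not draw folds with both classes in training")
    }
    preds <- data.frame(subject = rownames(x) %||% as.character(seq_len(n)),
                        truth = y, class = NA_integer_,
                        votes1 = NA_integer_, votes2 = NA_integer_,
                        fold = NA_integer_, row.names = NULL)
    fold_pairs <- vector("list", length(folds))
    for (fi in seq_along(folds)) {
      test <- folds[[fi]]
      ens <- train_ensemble(x[-test, , drop = FALSE], y[-test], config)
      fold_pairs[[fi]] <- utils::head(ens$ranked_pairs, keep_top)
      for (s in test) {
        cl <- ensemble_classify(ens, x[s, ])
        preds$class[s] <- cl$class
        preds$votes1[s] <- cl$votes1
        preds$votes2[s] <- cl$votes2
        preds$fold[s] <- fi
      }
    }
    conf <- c(tp = sum(preds$class == 2L & y == 2L, na.rm = TRUE),
              fp = sum(preds$class == 2L & y == 1L, na.rm = TRUE),
              tn = sum(preds$class == 1L & y == 1L, na.rm = TRUE),
              fn = sum(preds$class == 1L & y == 2L, na.rm = TRUE),
              abstained = sum(is.na(preds$class)))
    runs[[r]] <- list(run = r, seed = seed, predictions = preds,
                      confusion = conf,
                      indices = performance_indices(conf),
                      abstained_subjects = preds$subject[is.na(preds$class)],
                      fold_pairs = fold_pairs)
  }
  structure(list(runs = runs, cv = cv, config = config,
                 predictor_ids = colnames(x)),
            class = "repeated_cv")
}

#' Extract the per-run index table from a repeated CV result
#'
#' @param res a `repeated_cv` object.
#' @return data frame with one row per run and columns
#'   `acc`, `sen`, `spc`, `ppv`, `npv`.
#' @export
cv_index_table <- function(res) {
  as.data.frame(do.call(rbind, lapply(res$runs, `[[`, "indices")))
}

#' Summarize performance indices across repeated CV runs
#'
#' For each index, reports the average, sample standard deviation, 95%
#' margin of error `MOE = t(0.975, reps - 1) * SD / sqrt(reps)` and the
#' confidence interval `AVG +/- MOE`. Undefined (`NA`) run values are
#' dropped pairwise with a warning.
#'
#' @param x a `repeated_cv` object, or a data frame / matrix whose columns
#'   are per-run index values.
#' @param conf_level confidence level for the margin of error.
#' @param strict error when an index has fewer than 2 defined run values
#'   (default); `FALSE` drops such indices from the summary instead.
#' @return data frame with rows per index and columns
#'   `avg`, `sd`, `moe`, `ci_low`, `ci_high`, `n_runs`.
#' @export
summarize_runs <- function(x, conf_level = 0.95, strict = TRUE) {
  tab <- if (inherits(x, "repeated_cv")) cv_index_table(x) else as.data.frame(x)
  out <- lapply(names(tab), function(nm) {
    v <- tab[[nm]]
    if (anyNA(v)) {
      warning("dropping ", sum(is.na(v)), " undefined value(s) for ", nm)
      v <- v[!is.na(v)]
    }
    if (length(v) < 2L) {
      if (strict) stop("fewer than 2 defined values for ", nm)
      warning("omitting index ", nm, ": fewer than 2 defined values")
      return(NULL)
    }
    reps <- length(v)
    avg <- mean(v); sdev <- stats::sd(v)
    moe <- stats::qt(1 - (1 - conf_level) / 2, reps - 1) * sdev / sqrt(reps)
    data.frame(index = nm, avg = avg, sd = sdev, moe = moe,
               ci_low = avg - moe, ci_high = avg + moe, n_runs = reps)
  })
  do.call(rbind, out)
}

#' Label-permutation validity control
#'
#' Randomly re-assigns the class labels (a uniform permutation, preserving
#' class counts), reports how many permuted labels coincide with the truth,
#' and re-runs the full repeated cross-validation on the permuted labels.
#' Near-chance accuracy under permutation supports the validity of the
#' true-label result.
#'
#' @param x predictor matrix.
#' @param y true class labels.
#' @param cv a [cv_config()].
#' @param config an [ensemble_config()].
#' @param perm_seed seed for the label permutation (independent of the CV
#'   seeds).
#' @param ... passed to [run_repeated_cv()].
#' @return list with `permuted_labels`, `n_coincident`, `result`
#'   (a `repeated_cv`), `summary`.
#' @export
permutation_control <- function(x, y, cv = cv_config(),
                                config = ensemble_config(),
                                perm_seed = 1L, ...) {
  y <- normalize_labels(y)
  yperm <- with_local_seed(perm_seed, sample(y))
  names(yperm) <- names(y)
  res <- run_repeated_cv(x, yperm, cv = cv, config = config, ...)
  list(permuted_labels = yperm,
       n_coincident = sum(yperm == y),
       result = res,
       summary = summarize_runs(res, strict = FALSE))
}
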