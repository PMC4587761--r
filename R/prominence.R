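# Prominence tabulation: which proteins and protein pairs recur among the
# top R-squared-ranked pairs across all cross-validation training folds.

#' Collect the top-ranked pairs from every CV training fold
#'
#' Concatenates, with multiplicity, the `top_n` highest-R-squared predictor
#' pairs from each training fold of each run (20 runs x 10 folds x top 10
#' gives 2000 pairs). The ranking is the one already computed during
#' ensemble training, so prominence is consistent with classification.
#'
#' @param res a `repeated_cv` object from [run_repeated_cv()] (run with
#'   `keep_top >= top_n`).
#' @param top_n pairs to take per fold (default 10). Folds with fewer
#'   ranked pairs contribute all of them (with a message).
#' @return data frame with columns `run`, `fold`, `rank`, `i`, `j`, `r2`
#'   and predictor-name columns `id_i`, `id_j`; one row per collected pair.
#' @export
collect_top_pairs <- function(res, top_n = 10L) {
  stopifnot(inherits(res, "repeated_cv"))
  ids <- res$predictor_ids
  out <- list()
  for (run in res$runs) {
    for (fi in seq_along(run$fold_pairs)) {
      rp <- run$fold_pairs[[fi]]
      if (nrow(rp) < top_n)
        message("run ", run$run, " fold ", fi, ": only ", nrow(rp),
                " ranked pairs available")
      rp <- utils::head(rp, top_n)
      out[[length(out) + 1L]] <- data.frame(
        run = run$run, fold = fi, rank = seq_len(nrow(rp)),
        i = rp$i, j = rp$j, r2 = rp$r2,
        id_i = ids[rp$i], id_j = ids[rp$j])
    }
  }
  do.call(rbind, out)
}

#' Tabulate protein and pair frequencies among collected top pairs
#'
#' Counts how often each predictor and each predictor pair occurs in the
#' multiset from [collect_top_pairs()], and returns thresholded views
#' containing only entries whose frequency strictly exceeds `threshold`.
#' Each pair contributes one pair incidence and two protein incidences, so
#' the protein counts always sum to twice the pair counts.
#'
#' @param pairs data frame from [collect_top_pairs()].
#' @param threshold retain only entries with count > threshold (strict;
#'   default 50).
#' @return list of class `pair_frequency_table` with `protein_counts`,
#'   `pair_counts` (full tables, sorted descending), `retained_proteins`,
#'   `retained_pairs` (thresholded views), `total_pairs_collected`,
#'   `threshold`.
#' @export
tabulate_prominence <- function(pairs, threshold = 50L) {
  pair_key <- paste(pairs$id_i, pairs$id_j, sep = " : ")
  pc <- sort(table(pair_key), decreasing = TRUE)
  prot <- sort(table(c(pairs$id_i, pairs$id_j)), decreasing = TRUE)
  pair_counts <- data.frame(pair = names(pc), count = as.integer(pc),
                            row.names = NULL)
  protein_counts <- data.frame(protein = names(prot),
                               count = as.integer(prot), row.names = NULL)
  structure(list(
    protein_counts = protein_counts,
    pair_counts = pair_counts,
    retained_proteins = protein_counts[protein_counts$count > threshold, ,
                                       drop = FALSE],
    retained_pairs = pair_counts[pair_counts$count > threshold, ,
                                 drop = FALSE],
    total_pairs_collected = nrow(pairs),
    threshold = threshold), class = "pair_frequency_table")
}

#' @export
print.pair_frequency_table <- function(x, ...) {
  cat("Pair-frequency table:", x$total_pairs_collected, "pairs collected\n")
  cat("Retained (count >", x$threshold, "):",
      nrow(x$retained_proteins), "proteins,",
      nrow(x$retained_pairs), "pairs\n")
  if (nrow(x$retained_proteins))
    print(utils::head(x$retained_proteins, 12), row.names = FALSE)
  invisible(x)
}

#' Bar chart of prominent protein or pair frequencies
#'
#' @param x a `pair_frequency_table`.
#' @param what `"proteins"` or `"pairs"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_prominence <- function(x, what = c("proteins", "pairs"), ...) {
  what <- match.arg(what)
  tab <- if (what == "proteins") x$retained_proteins else x$retained_pairs
  if (nrow(tab) == 0L) stop("no entries above threshold ", x$threshold)
  nm <- tab[[1]]
  graphics::barplot(tab$count, names.arg = nm, las = 2,
                    ylab = "frequency among top pairs",
                    cex.names = 0.7, ...)
  invisible(tab)
}
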