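# The convex-hull selective-voting ensemble classifier.
#
# Each member is a pair of predictors; its model is the pair of trimmed,
# mutually disjoint class hulls in that 2-D predictor plane. Members vote
# for class 1 or class 2 when a sample falls inside their hull for that
# class, and abstain otherwise; a simple majority among voting members
# classifies the sample, with ties (and all-abstain) left unclassified.

#' Ensemble configuration
#'
#' @param m number of top predictor pairs (by regression R-squared) retained
#'   as ensemble members; default 100.
#' @param boundary_inclusive logical; a sample on a hull boundary counts as
#'   inside (default `TRUE`).
#' @param max_trim_iterations cap on hull-trimming iterations.
#' @param tol absolute geometric tolerance in predictor units.
#' @return a list of class `ensemble_config`.
#' @export
ensemble_config <- function(m = 100L, boundary_inclusive = TRUE,
                            max_trim_iterations = 100L, tol = 1e-9) {
  stopifnot(m >= 1L, max_trim_iterations >= 1L, tol > 0)
  structure(list(m = as.integer(m),
                 boundary_inclusive = isTRUE(boundary_inclusive),
                 max_trim_iterations = as.integer(max_trim_iterations),
                 tol = tol),
            class = "ensemble_config")
}

#' Rank predictor pairs by two-variable regression R-squared
#'
#' Scores every unordered pair of predictors by the coefficient of
#' determination of an ordinary least-squares fit of the numeric class
#' label on the two predictors plus an intercept (main effects only), and
#' returns the top `m` pairs in descending R-squared, ties broken
#' lexicographically on the pair index. R-squared is invariant to affine
#' recoding of the labels, so coding the classes 1/2 or 0/1 is equivalent.
#' Pairs whose normal-equation system is singular (constant or collinear
#' predictors) fall back to the better single-predictor fit, or 0 when both
#' are constant.
#'
#' @param x numeric predictor matrix (subjects in rows).
#' @param y class labels (two distinct values).
#' @param m number of pairs to return; capped at `choose(p, 2)`.
#' @return data frame with columns `i`, `j` (column indices, `i < j`) and
#'   `r2`, sorted by decreasing `r2`.
#' @export
rank_predictor_pairs <- function(x, y, m = 100L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2L) stop("need at least 2 predictors")
  if (n < 3L) stop("need at least 3 samples")
  yn <- as.numeric(y)
  if (length(unique(yn)) < 2L) stop("y must contain both classes")
  xc <- sweep(x, 2, colMeans(x))
  yc <- yn - mean(yn)
  syy <- sum(yc^2)
  S <- crossprod(xc)            # p x p centered cross-products
  cvec <- drop(crossprod(xc, yc))
  ij <- which(upper.tri(S), arr.ind = TRUE)   # all i < j pairs
  i <- ij[, 1]; j <- ij[, 2]
  sii <- diag(S)[i]; sjj <- diag(S)[j]; sij <- S[ij]
  ci <- cvec[i]; cj <- cvec[j]
  det <- sii * sjj - sij^2
  scale <- sii * sjj
  ok <- det > 1e-12 * pmax(scale, 1e-300)
  r2 <- numeric(length(i))
  r2[ok] <- (cj[ok]^2 * sii[ok] + ci[ok]^2 * sjj[ok] -
             2 * ci[ok] * cj[ok] * sij[ok]) / (det[ok] * syy)
  if (any(!ok)) {
    # singular 2x2 system: best single-predictor R2 (0 if constant)
    r1 <- ifelse(diag(S) > 0, cvec^2 / (diag(S) * syy), 0)
    r2[!ok] <- pmax(r1[i[!ok]], r1[j[!ok]])
  }
  r2 <- pmin(pmax(r2, 0), 1)    # clamp numerical noise
  ord <- order(-r2, i, j)
  m <- min(as.integer(m), length(ord))
  sel <- ord[seq_len(m)]
  data.frame(i = i[sel], j = j[sel], r2 = r2[sel])
}

#' Train a convex-hull selective-voting ensemble
#'
#' Ranks all predictor pairs by R-squared, keeps the top `m`, and for each
#' retained pair builds class-1 and class-2 convex hulls from the training
#' points in that pair's plane, trimmed to complete separation
#' ([fit_trimmed_hulls()]). Members whose trimming failed to converge or
#' whose hulls are both empty are dropped. Training is fully deterministic.
#'
#' @param x numeric predictor matrix (subjects in rows, named columns).
#' @param y class labels coded 1/2 (anything coercible to two distinct
#'   values; the smaller value is class 1).
#' @param config an [ensemble_config()].
#' @return object of class `hull_ensemble` with elements `members` (list of
#'   pair models with `i`, `j`, `r2`, `hull_1`, `hull_2`), `ranked_pairs`
#'   (the retained ranking), `predictor_ids`, `config`.
#' @export
train_ensemble <- function(x, y, config = ensemble_config()) {
  x <- as.matrix(x)
  yf <- normalize_labels(y)
  ranked <- rank_predictor_pairs(x, yf, m = config$m)
  members <- vector("list", nrow(ranked))
  usable <- logical(nrow(ranked))
  for (k in seq_len(nrow(ranked))) {
    i <- ranked$i[k]; j <- ranked$j[k]
    fit <- fit_trimmed_hulls(x[yf == 1L, c(i, j), drop = FALSE],
                             x[yf == 2L, c(i, j), drop = FALSE], config)
    ok <- fit$converged &&
      !(fit$hull_1$type == "empty" && fit$hull_2$type == "empty")
    usable[k] <- ok
    if (ok) members[[k]] <- list(i = i, j = j, r2 = ranked$r2[k],
                                 hull_1 = fit$hull_1, hull_2 = fit$hull_2)
  }
  members <- members[usable]
  if (length(members) == 0L) stop("no usable ensemble members")
  structure(list(members = members, ranked_pairs = ranked,
                 predictor_ids = colnames(x), config = config),
            class = "hull_ensemble")
}

normalize_labels <- function(y) {
  lv <- sort(unique(as.vector(y)))
  if (length(lv) != 2L) stop("y must contain exactly two classes")
  ifelse(y == lv[1], 1L, 2L)
}

#' Single-member vote on a 2-D point
#'
#' Returns `"class1"` if the point falls within the member's trimmed
#' class-1 hull, `"class2"` if within the class-2 hull, and `"abstain"`
#' otherwise. Disjointness of the trimmed hulls makes containment in both
#' impossible.
#'
#' @param model a pair model from a trained ensemble.
#' @param point numeric length-2 point in the member's predictor plane.
#' @param config an [ensemble_config()] (boundary convention, tolerance).
#' @return one of `"class1"`, `"class2"`, `"abstain"`.
#' @export
member_vote <- function(model, point, config = ensemble_config()) {
  inc <- config$boundary_inclusive
  if (hull_contains(model$hull_1, point, inc, config$tol)) return("class1")
  if (hull_contains(model$hull_2, point, inc, config$tol)) return("class2")
  "abstain"
}

#' Classify one sample by selective majority vote
#'
#' Each member votes or abstains via [member_vote()]; the majority among
#' voting members decides. Equal non-zero tallies, or universal abstention,
#' leave the sample unclassified (`NA`).
#'
#' @param ensemble a trained `hull_ensemble`.
#' @param sample_row named numeric vector (or single-row matrix) holding a
#'   value for every predictor the ensemble was trained on.
#' @return list with `class` (1, 2 or `NA`), `votes1`, `votes2`,
#'   `abstentions`.
#' @export
ensemble_classify <- function(ensemble, sample_row) {
  v <- as.numeric(sample_row)
  if (length(v) != length(ensemble$predictor_ids))
    stop("sample has ", length(v), " values; ensemble expects ",
         length(ensemble$predictor_ids))
  if (anyNA(v)) stop("missing predictor value in sample")
  votes <- vapply(ensemble$members, function(mb)
    member_vote(mb, v[c(mb$i, mb$j)], ensemble$config), character(1))
  n1 <- sum(votes == "class1"); n2 <- sum(votes == "class2")
  cls <- if (n1 > n2) 1L else if (n2 > n1) 2L else NA_integer_
  list(class = cls, votes1 = n1, votes2 = n2,
       abstentions = sum(votes == "abstain"))
}

#' @export
predict.hull_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$predictor_ids %in% colnames(newdata)))
    newdata <- newdata[, object$predictor_ids, drop = FALSE]
  res <- lapply(seq_len(nrow(newdata)),
                function(r) ensemble_classify(object, newdata[r, ]))
  data.frame(subject = rownames(newdata) %||% seq_len(nrow(newdata)),
             class = vapply(res, `[[`, integer(1), "class"),
             votes1 = vapply(res, `[[`, integer(1), "votes1"),
             votes2 = vapply(res, `[[`, integer(1), "votes2"),
             abstentions = vapply(res, `[[`, integer(1), "abstentions"),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hull_ensemble <- function(x, ...) {
  cat("Convex-hull selective-voting ensemble\n")
  cat("  members:", length(x$members), "of", x$config$m, "retained pairs\n")
  cat("  predictors:", length(x$predictor_ids), "\n")
  cat("  top pair: (", x$predictor_ids[x$members[[1]]$i], ", ",
      x$predictor_ids[x$members[[1]]$j], ")  R2 = ",
      signif(x$members[[1]]$r2, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize a trained ensemble to JSON
#'
#' Writes pairs, R-squared values, hull vertices and the configuration so a
#' trained ensemble can be inspected or reloaded exactly.
#'
#' @param ensemble a `hull_ensemble`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
ensemble_to_json <- function(ensemble, path = NULL) {
  obj <- list(
    predictor_ids = ensemble$predictor_ids,
    config = unclass(ensemble$config),
    members = lapply(ensemble$members, function(m) list(
      i = m$i, j = m$j, r2 = m$r2,
      hull_1 = list(type = m$hull_1$type, vertices = m$hull_1$vertices),
      hull_2 = list(type = m$hull_2$type, vertices = m$hull_2$vertices)))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Reload an ensemble serialized with [ensemble_to_json()]
#'
#' @param json JSON string or path to a JSON file.
#' @return a `hull_ensemble` equivalent to the serialized one.
#' @export
ensemble_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  cfg <- do.call(ensemble_config, obj$config)
  as_hull <- function(h) {
    v <- if (length(h$vertices))
      do.call(rbind, lapply(h$vertices, unlist)) else matrix(numeric(0), 0, 2)
    structure(list(type = h$type, vertices = v), class = "hull2d")
  }
  members <- lapply(obj$members, function(m)
    list(i = m$i, j = m$j, r2 = m$r2,
         hull_1 = as_hull(m$hull_1), hull_2 = as_hull(m$hull_2)))
  ranked <- data.frame(i = vapply(members, `[[`, numeric(1), "i"),
                       j = vapply(members, `[[`, numeric(1), "j"),
                       r2 = vapply(members, `[[`, numeric(1), "r2"))
  structure(list(members = members, ranked_pairs = ranked,
                 predictor_ids = unlist(obj$predictor_ids), config = cfg),
            class = "hull_ensemble")
}
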