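# Independent oracles, deliberately coded by different routes than the
# package implementation.

# -- geometry oracle: ray casting + pairwise segment intersection ---------

# point strictly/boundary inside polygon by ray casting; boundary detected
# by explicit per-edge point-on-segment checks
oracle_point_in_poly <- function(p, verts, eps = 1e-9) {
  n <- nrow(verts)
  if (n == 1L) return(sum((p - verts[1, ])^2) <= eps^2)
  on_edge <- function(a, b) {
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    len <- sqrt(sum((b - a)^2))
    if (len == 0) return(sum((p - a)^2) <= eps^2)
    if (abs(cr) / len > eps) return(FALSE)
    t <- ((p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])) / len^2
    t >= -eps && t <= 1 + eps
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (on_edge(verts[i, ], verts[j, ])) return(TRUE)
  }
  if (n < 3L) return(FALSE)
  inside <- FALSE
  for (i in seq_len(n)) {           # ray cast to +x
    j <- if (i == n) 1L else i + 1L
    yi <- verts[i, 2]; yj <- verts[j, 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- verts[i, 1] + (p[2] - yi) * (verts[j, 1] - verts[i, 1]) / (yj - yi)
      if (p[1] < xint) inside <- !inside
    }
  }
  inside
}

oracle_segs_cross <- function(a1, a2, b1, b2, eps = 1e-12) {
  den <- (a2[1] - a1[1]) * (b2[2] - b1[2]) - (a2[2] - a1[2]) * (b2[1] - b1[1])
  if (abs(den) < eps) return(FALSE)  # parallel/collinear: vertex tests cover
  t <- ((b1[1] - a1[1]) * (b2[2] - b1[2]) - (b1[2] - a1[2]) * (b2[1] - b1[1])) / den
  u <- ((b1[1] - a1[1]) * (a2[2] - a1[2]) - (b1[2] - a1[2]) * (a2[1] - a1[1])) / den
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

oracle_hulls_disjoint <- function(h1, h2) {
  v1 <- h1$vertices; v2 <- h2$vertices
  if (nrow(v1) == 0L || nrow(v2) == 0L) return(TRUE)
  for (i in seq_len(nrow(v1)))
    if (oracle_point_in_poly(v1[i, ], v2)) return(FALSE)
  for (i in seq_len(nrow(v2)))
    if (oracle_point_in_poly(v2[i, ], v1)) return(FALSE)
  edges <- function(v) {
    n <- nrow(v)
    if (n < 2L) return(NULL)
    m <- if (n == 2L) 1L else n
    lapply(seq_len(m), function(i) list(v[i, ], v[if (i == n) 1L else i + 1L, ]))
  }
  for (ea in edges(v1)) for (eb in edges(v2))
    if (oracle_segs_cross(ea[[1]], ea[[2]], eb[[1]], eb[[2]])) return(FALSE)
  TRUE
}

# -- Fisher oracle: full enumeration over fixed margins -------------------

oracle_fisher_2x2 <- function(tab) {
  tab <- matrix(as.vector(t(tab)), 2, 2, byrow = TRUE)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  logp <- function(a) {                 # P(table | margins), a = cell (1,1)
    lchoose(r1, a) + lchoose(N - r1, c1 - a) - lchoose(N, c1)
  }
  as <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- exp(vapply(as, logp, numeric(1)))
  pobs <- exp(logp(tab[1, 1]))
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# -- OLS R-squared oracle via lm() ----------------------------------------

oracle_pair_r2 <- function(x, y) {
  cb <- utils::combn(ncol(x), 2)
  data.frame(i = cb[1, ], j = cb[2, ],
             r2 = apply(cb, 2, function(p)
               summary(stats::lm(y ~ x[, p[1]] + x[, p[2]]))$r.squared))
}

# -- fixtures -------------------------------------------------------------

# minimal long-format raw count table
make_raw <- function(df) {
  data.frame(subject_id = df$s, replicate_id = df$r,
             protein_id = df$p, gene_id = df$p, count = df$n)
}

# mock repeated-CV trace carrying only the per-fold ranked-pair lists
make_mock_trace <- function(runs = 20L, folds = 10L, n_pairs = 15L,
                            p = 30L, seed = 1L) {
  set.seed(seed)
  runlist <- lapply(seq_len(runs), function(r) {
    fp <- lapply(seq_len(folds), function(f) {
      ij <- t(replicate(n_pairs, sort(sample.int(p, 2))))
      data.frame(i = ij[, 1], j = ij[, 2],
                 r2 = sort(runif(n_pairs), decreasing = TRUE))
    })
    list(run = r, fold_pairs = fp)
  })
  structure(list(runs = runlist,
                 cv = cv_config(k_folds = folds, repetitions = runs),
                 config = ensemble_config(),
                 predictor_ids = sprintf("P%03d", seq_len(p))),
            class = "repeated_cv")
}

# small fully separable two-class dataset in p dimensions
make_separable <- function(n1 = 8, n2 = 8, p = 6, gap = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1),
             matrix(rnorm(n2 * p, mean = gap), n2))
  colnames(x) <- sprintf("V%02d", seq_len(p))
  rownames(x) <- sprintf("S%02d", seq_len(n1 + n2))
  list(x = x, y = rep(c(1L, 2L), c(n1, n2)))
}
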