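# Convex-hull geometry for two-predictor ensemble members.
#
# Hulls are stored as a list with a `type` field:
#   "empty"   - no surviving points
#   "point"   - a single distinct point
#   "segment" - two distinct endpoints (collinear point sets collapse here)
#   "polygon" - >= 3 vertices in counter-clockwise order
# All vertices are original training points; nothing is interpolated.
# Containment and crossing tests are vectorized over points / edge pairs:
# trimming calls them inside an iteration over ~100 members per fold.

#' Build a convex hull from 2-D points
#'
#' Constructs the convex hull of a set of points in the plane, collapsing
#' degenerate configurations (single point, collinear points) to a point or
#' segment representation so that tiny training folds still yield usable
#' classifier members.
#'
#' @param pts numeric matrix with two columns (or NULL/zero rows for an
#'   empty hull).
#' @return an object of class `hull2d`: a list with `type` (one of
#'   `"empty"`, `"point"`, `"segment"`, `"polygon"`) and `vertices`, a
#'   matrix of hull vertices in counter-clockwise order.
#' @examples
#' build_hull(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
build_hull <- function(pts) {
  if (is.null(pts) || nrow(pts) == 0L) {
    return(structure(list(type = "empty",
                          vertices = matrix(numeric(0), 0, 2)),
                     class = "hull2d"))
  }
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  verts <- pts[idx, , drop = FALSE]
  # drop coordinate duplicates, preserving hull order
  dup <- duplicated(verts)
  verts <- verts[!dup, , drop = FALSE]
  m <- nrow(verts)
  if (m == 1L)
    return(structure(list(type = "point", vertices = verts), class = "hull2d"))
  if (m == 2L || hull_vertices_collinear(verts)) {
    # collapse to the extreme pair along the dominant direction
    d <- (verts[, 1] - verts[1, 1])^2 + (verts[, 2] - verts[1, 2])^2
    far <- verts[which.max(d), ]
    d2 <- (verts[, 1] - far[1])^2 + (verts[, 2] - far[2])^2
    other <- verts[which.max(d2), ]
    return(structure(list(type = "segment", vertices = rbind(far, other)),
                     class = "hull2d"))
  }
  # chull returns clockwise order; reverse for counter-clockwise
  verts <- verts[rev(seq_len(m)), , drop = FALSE]
  structure(list(type = "polygon", vertices = verts), class = "hull2d")
}

hull_vertices_collinear <- function(v, tol = 1e-12) {
  a <- v[1, ]; b <- v[2, ]
  cr <- (b[1] - a[1]) * (v[, 2] - a[2]) - (b[2] - a[2]) * (v[, 1] - a[1])
  scale <- max(abs(v)) + 1
  all(abs(cr) <= tol * scale^2)
}

#' Test whether points lie within a convex hull
#'
#' Containment includes the hull boundary when `inclusive = TRUE` (the
#' default voting convention: a sample "falls within" a hull if it is in
#' the hull or on its boundary). Degenerate hulls use exact point/segment
#' containment within `tol` in predictor units.
#'
#' @param hull a `hull2d` object from [build_hull()].
#' @param pts numeric length-2 point or a two-column matrix of points.
#' @param inclusive logical; count boundary points as contained.
#' @param tol absolute tolerance for boundary/degenerate comparisons.
#' @return logical vector, one entry per point.
#' @export
hull_contains <- function(hull, pts, inclusive = TRUE, tol = 1e-9) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  switch(hull$type,
    empty = rep(FALSE, length(px)),
    point = {
      v <- hull$vertices[1, ]
      (px - v[1])^2 + (py - v[2])^2 <= tol^2
    },
    segment = points_on_segment(px, py, hull$vertices[1, ],
                                hull$vertices[2, ], tol),
    polygon = {
      v <- hull$vertices
      m <- nrow(v)
      nxt <- c(2:m, 1)
      ex <- v[nxt, 1] - v[, 1]
      ey <- v[nxt, 2] - v[, 2]
      # cross_{edge,point} = ex*(py - vy) - ey*(px - vx); CCW => inside
      # has non-negative cross for every edge
      cr <- outer(ex, py) - outer(ey, px) + (ey * v[, 1] - ex * v[, 2])
      if (inclusive) colSums(cr >= -tol) == m else colSums(cr > tol) == m
    }
  )
}

points_on_segment <- function(px, py, a, b, tol = 1e-9) {
  seglen2 <- sum((b - a)^2)
  if (seglen2 == 0) return((px - a[1])^2 + (py - a[2])^2 <= tol^2)
  seglen <- sqrt(seglen2)
  cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  dot <- (px - a[1]) * (b[1] - a[1]) + (py - a[2]) * (b[2] - a[2])
  abs(cross) / seglen <= tol & dot >= -tol * seglen &
    dot <= seglen2 + tol * seglen
}

hull_edge_matrix <- function(hull) {
  v <- hull$vertices
  if (hull$type %in% c("empty", "point")) return(NULL)
  if (hull$type == "segment")
    return(cbind(v[1, 1], v[1, 2], v[2, 1], v[2, 2]))
  m <- nrow(v)
  nxt <- c(2:m, 1)
  cbind(v[, 1], v[, 2], v[nxt, 1], v[nxt, 2])
}

# proper crossings between every edge of e1 and every edge of e2
# (rows: x1, y1, x2, y2); touching/collinear contact is handled by the
# vertex-containment checks in hulls_disjoint
any_proper_crossing <- function(e1, e2, tol = 1e-12) {
  n1 <- nrow(e1); n2 <- nrow(e2)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  a1x <- e1[i, 1]; a1y <- e1[i, 2]; a2x <- e1[i, 3]; a2y <- e1[i, 4]
  b1x <- e2[j, 1]; b1y <- e2[j, 2]; b2x <- e2[j, 3]; b2y <- e2[j, 4]
  o <- function(px, py, qx, qy, rx, ry)
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- o(b1x, b1y, b2x, b2y, a1x, a1y)
  d2 <- o(b1x, b1y, b2x, b2y, a2x, a2y)
  d3 <- o(a1x, a1y, a2x, a2y, b1x, b1y)
  d4 <- o(a1x, a1y, a2x, a2y, b2x, b2y)
  any(((d1 > tol & d2 < -tol) | (d1 < -tol & d2 > tol)) &
      ((d3 > tol & d4 < -tol) | (d3 < -tol & d4 > tol)))
}

#' Test whether two hulls are disjoint
#'
#' Two hulls are disjoint when no vertex of either lies inside or on the
#' other and no pair of boundary edges crosses. (Collinear edge contact
#' always places a vertex of one hull on the other, so it is caught by the
#' vertex test.) Empty hulls are disjoint from everything.
#'
#' @param h1,h2 `hull2d` objects.
#' @param tol absolute tolerance.
#' @return logical scalar.
#' @export
hulls_disjoint <- function(h1, h2, tol = 1e-9) {
  if (h1$type == "empty" || h2$type == "empty") return(TRUE)
  if (any(hull_contains(h2, h1$vertices, inclusive = TRUE, tol = tol)))
    return(FALSE)
  if (any(hull_contains(h1, h2$vertices, inclusive = TRUE, tol = tol)))
    return(FALSE)
  e1 <- hull_edge_matrix(h1); e2 <- hull_edge_matrix(h2)
  if (!is.null(e1) && !is.null(e2) && any_proper_crossing(e1, e2))
    return(FALSE)
  TRUE
}

#' Trim class hulls to complete separation
#'
#' Deterministic peeling: repeatedly (1) build each class's hull from its
#' surviving points; (2) from each class, remove the single surviving
#' point lying deepest inside the opposite class's hull (ties broken by
#' lowest point index); (3) if no point of either class lies in the
#' opposite hull but the boundaries still cross, remove from each class
#' the hull vertex nearest (Euclidean) to the opposite class's vertex
#' centroid, ties broken by lowest point index. Stops when the hulls are
#' disjoint or one is empty. Every iteration removes at least one point,
#' so termination is guaranteed.
#'
#' Removing one point per class per sweep (rather than all overlapping
#' points at once) matters for nested distributions: when one class's
#' spread engulfs the other's support — common for overdispersed counts —
#' a mass removal empties the narrow class entirely and leaves the wide
#' class's hull covering the narrow class's territory, systematically
#' inverting votes. Gradual peeling lets both hulls recede from the
#' overlap and preserves each class's core.
#'
#' @param points_1,points_2 two-column matrices of class-1 / class-2
#'   training points (each with at least one row).
#' @param config an [ensemble_config()] list (uses `max_trim_iterations`
#'   and `tol`).
#' @return list with `hull_1`, `hull_2` (disjoint `hull2d` objects) and
#'   `converged` (logical; `FALSE` if the iteration cap was hit).
#' @export
fit_trimmed_hulls <- function(points_1, points_2, config = ensemble_config()) {
  p1 <- as.matrix(points_1); p2 <- as.matrix(points_2)
  stopifnot(nrow(p1) >= 1L, nrow(p2) >= 1L, ncol(p1) == 2L, ncol(p2) == 2L)
  tol <- config$tol
  for (iter in seq_len(config$max_trim_iterations)) {
    h1 <- build_hull(p1); h2 <- build_hull(p2)
    if (hulls_disjoint(h1, h2, tol = tol))
      return(list(hull_1 = h1, hull_2 = h2, converged = TRUE))
    d1 <- containment_depth(h2, p1, tol)
    d2 <- containment_depth(h1, p2, tol)
    if (any(d1 > -tol) || any(d2 > -tol)) {
      if (any(d1 > -tol)) p1 <- p1[-which.max(d1), , drop = FALSE]
      if (any(d2 > -tol)) p2 <- p2[-which.max(d2), , drop = FALSE]
    } else {
      # boundaries cross without containment: peel the vertex of each class
      # nearest the opposite class's vertex centroid
      p1 <- peel_nearest_vertex(p1, h1, colMeans(h2$vertices))
      p2 <- peel_nearest_vertex(p2, h2, colMeans(h1$vertices))
    }
    if (nrow(p1) == 0L || nrow(p2) == 0L) {
      return(list(hull_1 = build_hull(p1), hull_2 = build_hull(p2),
                  converged = TRUE))
    }
  }
  list(hull_1 = build_hull(matrix(numeric(0), 0, 2)),
       hull_2 = build_hull(matrix(numeric(0), 0, 2)), converged = FALSE)
}

# signed depth of each point inside a hull: positive depths are interior
# distances to the nearest boundary, ~0 on the boundary, negative outside.
# which.max() over the result picks the most deeply contained point,
# ties resolved at the lowest index.
containment_depth <- function(hull, pts, tol = 1e-9) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  switch(hull$type,
    empty = rep(-Inf, length(px)),
    point = {
      v <- hull$vertices[1, ]
      -sqrt((px - v[1])^2 + (py - v[2])^2)
    },
    segment = {
      a <- hull$vertices[1, ]; b <- hull$vertices[2, ]
      on <- points_on_segment(px, py, a, b, tol)
      ifelse(on, 0, -Inf)
    },
    polygon = {
      v <- hull$vertices
      m <- nrow(v)
      nxt <- c(2:m, 1)
      ex <- v[nxt, 1] - v[, 1]
      ey <- v[nxt, 2] - v[, 2]
      len <- sqrt(ex^2 + ey^2)
      cr <- outer(ex, py) - outer(ey, px) + (ey * v[, 1] - ex * v[, 2])
      apply(cr / len, 2, min)   # min signed distance over edges
    }
  )
}

peel_nearest_vertex <- function(pts, hull, centroid) {
  if (hull$type == "empty" || nrow(pts) == 0L) return(pts)
  v <- hull$vertices
  d <- sqrt((v[, 1] - centroid[1])^2 + (v[, 2] - centroid[2])^2)
  target <- v[which.min(d), ]
  # lowest-index surviving point equal to that vertex
  hit <- which(pts[, 1] == target[1] & pts[, 2] == target[2])[1]
  pts[-hit, , drop = FALSE]
}
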