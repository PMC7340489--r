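# Planar polygon utilities on open rings (n x 2 matrices, map metres).
# All operations assume a projected CRS; no geodesic arithmetic anywhere.

# Signed area (shoelace); positive for counter-clockwise rings.
polygon_area <- function(ring) {
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(ring[j, 1] * ring[, 2] - ring[, 1] * ring[j, 2]) / 2
}

# Force counter-clockwise orientation.
ccw_ring <- function(ring) {
  if (polygon_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  else ring
}

is_convex_ring <- function(ring) {
  r <- ccw_ring(ring)
  n <- nrow(r)
  nxt <- c(seq_len(n)[-1], 1L)
  nx2 <- nxt[nxt]
  e1 <- r[nxt, , drop = FALSE] - r
  e2 <- r[nx2, , drop = FALSE] - r[nxt, , drop = FALSE]
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  all(cross >= -1e-9 * max(abs(ring)))
}

# Even-odd (crossing number) point-in-polygon, vectorised over points.
# Half-open in the sense that points exactly on a horizontal edge follow the
# crossing rule deterministically; pixel centres in this package never sit on
# field borders by construction of the grid convention.
points_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Clip a polygon by the half-plane {p : dot(p, nrm) <= d} (Sutherland-Hodgman
# step). Returns possibly empty matrix.
clip_halfplane <- function(ring, nrm, d) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  out <- matrix(numeric(0), ncol = 2)
  val <- ring %*% nrm - d
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- val[i] <= 1e-12; cj <- val[j] <= 1e-12
    if (ci) out <- rbind(out, ring[i, ])
    if (ci != cj) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  if (nrow(out) >= 3) {
    keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-12)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) >= 2 &&
        sum(abs(out[1, ] - out[nrow(out), ])) < 1e-12)
      out <- out[-nrow(out), , drop = FALSE]
  }
  if (nrow(out) < 3 || abs(polygon_area(out)) < 1e-12) {
    return(matrix(numeric(0), ncol = 2))
  }
  out
}

# Inward Euclidean offset of a convex ring by `dist` metres: intersect the
# half-planes obtained by moving every edge inward along its normal. Exact
# for convex rings; returns an empty matrix when the polygon collapses.
inward_offset_convex <- function(ring, dist) {
  r <- ccw_ring(ring)
  if (!is_convex_ring(r))
    stop("negative buffering is supported for convex rings only")
  n <- nrow(r)
  out <- r
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- r[j, ] - r[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    # outward normal of a CCW edge is (ey, -ex)/len; keep points at
    # dot(p, nrm) <= dot(vertex, nrm) - dist
    nrm <- c(e[2], -e[1]) / len
    out <- clip_halfplane(out, nrm, sum(r[i, ] * nrm) - dist)
    if (nrow(out) == 0L) break
  }
  out
}
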