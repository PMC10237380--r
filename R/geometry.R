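# Planar geometry helpers (coordinates in metres).

# Distance from points (px, py) to segment (x1,y1)-(x2,y2); vectorised over
# points.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Min distance from each point to a polyline given as a 2-column vertex
# matrix.
dist_to_polyline <- function(px, py, vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 2L) return(sqrt((px - v[1, 1])^2 + (py - v[1, 2])^2))
  d <- NULL
  for (s in seq_len(nrow(v) - 1L)) {
    ds <- dist_point_segment(px, py, v[s, 1], v[s, 2], v[s + 1, 1], v[s + 1, 2])
    d <- if (is.null(d)) ds else pmin(d, ds)
  }
  d
}

# Segment-segment distance (0 if they intersect).
dist_segment_segment <- function(a1, a2, b1, b2) {
  d1 <- sign((a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1]))
  d2 <- sign((a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1]))
  d3 <- sign((b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1]))
  d4 <- sign((b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1]))
  if (d1 != d2 && d3 != d4 && d1 != 0 && d3 != 0) return(0)
  min(dist_point_segment(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
      dist_point_segment(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2]),
      dist_point_segment(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
      dist_point_segment(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]))
}

# Min distance between two polylines (vertex matrices).
dist_polyline_polyline <- function(va, vb) {
  va <- as.matrix(va); vb <- as.matrix(vb)
  if (nrow(va) == 1L) return(min(dist_to_polyline(va[1, 1], va[1, 2], vb)))
  if (nrow(vb) == 1L) return(min(dist_to_polyline(vb[1, 1], vb[1, 2], va)))
  best <- Inf
  for (i in seq_len(nrow(va) - 1L)) {
    for (j in seq_len(nrow(vb) - 1L)) {
      best <- min(best, dist_segment_segment(va[i, ], va[i + 1, ],
                                             vb[j, ], vb[j + 1, ]))
    }
  }
  best
}

polyline_length <- function(vertices) {
  v <- as.matrix(vertices)
  sum(sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}
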