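# Internal spherical / planar geometry helpers.
#
# All vector data live in lon/lat degrees. Lengths and distances use the
# same spherical model as cell_areas() (radius EARTH_RADIUS_KM) so road
# densities (km/km2) are unit-consistent with cell areas. Segments are
# treated as straight in lon/lat space (the generating model for all
# synthetic vectors); at the ~10 km cell scale the difference from great
# circles is negligible relative to the grid resolution.

deg2rad <- function(x) x * pi / 180

# great-circle distance, vectorized (haversine)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- p2 - p1; dl <- deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# distance (km) from points (plon, plat) to segment (a -> b); vectorized
# over points. Planar in a tangent plane anchored at the segment midpoint:
# accurate to well under 1% at the sub-degree spans used here.
point_segment_dist_km <- function(plon, plat, alon, alat, blon, blat) {
  lat0 <- (alat + blat) / 2                 # reference latitude for scale
  kx <- EARTH_RADIUS_KM * pi / 180 * cos(deg2rad(lat0))
  ky <- EARTH_RADIUS_KM * pi / 180
  px <- (plon - alon) * kx; py <- (plat - alat) * ky
  bx <- (blon - alon) * kx; by <- (blat - alat) * ky
  len2 <- bx^2 + by^2
  if (len2 == 0) return(sqrt(px^2 + py^2))
  t <- pmin(1, pmax(0, (px * bx + py * by) / len2))
  sqrt((px - t * bx)^2 + (py - t * by)^2)
}

# even-odd point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# do segments (p -> p2) and (q -> q2) properly or improperly intersect?
# vectorized over the first segment set
segments_cross <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- d(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- d(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- d(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- d(p1x, p1y, p2x, p2y, q2x, q2y)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# Does `poly` (matrix lon/lat) intersect each axis-aligned rectangle?
# Rectangles given by vectors x0 < x1, y0 < y1. Vectorized over rectangles.
# True iff a rect corner is inside the polygon, a polygon vertex is inside
# the rect, or any polygon edge crosses any rect edge.
rect_polygon_intersects <- function(x0, y0, x1, y1, poly) {
  m <- length(x0)
  hit <- logical(m)
  # quick bbox reject
  bb <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  cand <- !(x1 < bb[1] | x0 > bb[3] | y1 < bb[2] | y0 > bb[4])
  if (!any(cand)) return(hit)
  cx0 <- x0[cand]; cy0 <- y0[cand]; cx1 <- x1[cand]; cy1 <- y1[cand]
  h <- point_in_polygon(cx0, cy0, poly) |
    point_in_polygon(cx1, cy0, poly) |
    point_in_polygon(cx0, cy1, poly) |
    point_in_polygon(cx1, cy1, poly)
  # polygon vertex inside rect (any vertex, per rect)
  if (!all(h)) {
    for (k in seq_len(nrow(poly))) {
      h <- h | (poly[k, 1] >= cx0 & poly[k, 1] <= cx1 &
                  poly[k, 2] >= cy0 & poly[k, 2] <= cy1)
      if (all(h)) break
    }
  }
  # edge crossings
  if (!all(h)) {
    n <- nrow(poly)
    j <- n
    for (i in seq_len(n)) {
      ax <- poly[j, 1]; ay <- poly[j, 2]
      bx <- poly[i, 1]; by <- poly[i, 2]
      todo <- !h
      if (any(todo)) {
        tx0 <- cx0[todo]; ty0 <- cy0[todo]; tx1 <- cx1[todo]; ty1 <- cy1[todo]
        cr <- segments_cross(tx0, ty0, tx1, ty0, ax, ay, bx, by) |
          segments_cross(tx1, ty0, tx1, ty1, ax, ay, bx, by) |
          segments_cross(tx1, ty1, tx0, ty1, ax, ay, bx, by) |
          segments_cross(tx0, ty1, tx0, ty0, ax, ay, bx, by)
        h[todo] <- h[todo] | cr
      }
      j <- i
    }
  }
  hit[cand] <- h
  hit
}

# Split one lon/lat segment at every grid line it crosses and attribute
# each piece to the cell holding its midpoint. Returns a data.frame with
# one row per in-grid piece, in traversal order:
#   row, col, t0, t1 (segment parameters), len_km.
clip_segment_to_grid <- function(lon0, lat0, lon1, lat1, grid) {
  cs <- grid$cell_size
  gx0 <- grid$origin[1]
  gy_top <- grid$origin[2]
  ts <- c(0, 1)
  # crossings with vertical grid lines x = gx0 + k*cs
  if (lon1 != lon0) {
    kmin <- ceiling((min(lon0, lon1) - gx0) / cs)
    kmax <- floor((max(lon0, lon1) - gx0) / cs)
    if (kmax >= kmin) {
      xs <- gx0 + (kmin:kmax) * cs
      ts <- c(ts, (xs - lon0) / (lon1 - lon0))
    }
  }
  # crossings with horizontal grid lines y = gy_top - k*cs
  if (lat1 != lat0) {
    kmin <- ceiling((gy_top - max(lat0, lat1)) / cs)
    kmax <- floor((gy_top - min(lat0, lat1)) / cs)
    if (kmax >= kmin) {
      ys <- gy_top - (kmin:kmax) * cs
      ts <- c(ts, (ys - lat0) / (lat1 - lat0))
    }
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  if (length(ts) < 2) return(NULL)
  t0 <- ts[-length(ts)]; t1 <- ts[-1]
  keep <- (t1 - t0) > 1e-12
  t0 <- t0[keep]; t1 <- t1[keep]
  if (!length(t0)) return(NULL)
  tm <- (t0 + t1) / 2
  mlon <- lon0 + tm * (lon1 - lon0)
  mlat <- lat0 + tm * (lat1 - lat0)
  col <- floor((mlon - gx0) / cs) + 1
  row <- floor((gy_top - mlat) / cs) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  if (!any(ok)) return(NULL)
  t0 <- t0[ok]; t1 <- t1[ok]; row <- row[ok]; col <- col[ok]
  a_lon <- lon0 + t0 * (lon1 - lon0); a_lat <- lat0 + t0 * (lat1 - lat0)
  b_lon <- lon0 + t1 * (lon1 - lon0); b_lat <- lat0 + t1 * (lat1 - lat0)
  data.frame(row = as.integer(row), col = as.integer(col), t0 = t0, t1 = t1,
             len_km = haversine_km(a_lon, a_lat, b_lon, b_lat))
}

# polyline length in km under the spherical model
polyline_length_km <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  sum(haversine_km(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2]))
}
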