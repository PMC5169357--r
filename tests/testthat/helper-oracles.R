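# Independent brute-force oracles. Every function here recomputes a
# package quantity by the most direct scalar method available, sharing no
# code with the implementation it checks.

# midrank 0-1 rescaling by explicit pairwise counting
oracle_midrank_rescale <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(v < v[i])
    ties <- sum(v == v[i])
    r <- below + (1 + ties) / 2          # midrank
    out[i] <- (r - 0.5) / n
  }
  out
}

# production gap by scalar loops over cells and crops
oracle_production_gap <- function(crops, grid) {
  out <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    if (!grid$valid_mask[i, j]) { out[i, j] <- NA; next }
    acc <- 0
    for (cr in crops) {
      g <- cr$yield_gap$values[i, j]; a <- cr$harvested_area$values[i, j]
      if (!is.na(g) && !is.na(a)) acc <- acc + g * a * cr$energy_content
    }
    out[i, j] <- acc
  }
  out
}

# per-cell carbon loss (raw tonnes) by scalar loop
oracle_carbon_raw <- function(biomass, soil30, cover, areas) {
  nr <- nrow(biomass); nc <- ncol(biomass)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    b <- biomass[i, j]; s <- soil30[i, j]; cv <- cover[i, j]
    if (is.na(b) || is.na(s) || is.na(cv)) next
    net <- b - 0.10 * s
    if (net < 0) net <- 0
    out[i, j] <- net * cv * areas[i, j] * 100
  }
  out
}

# mean/max aggregation by scalar loop
oracle_aggregate <- function(mats, rule) {
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- vapply(mats, function(m) m[i, j], numeric(1))
    if (any(is.na(vals))) next
    out[i, j] <- if (rule == "mean") mean(vals) else max(vals)
  }
  out
}

# quadrant counts by scalar loop
oracle_quadrant_counts <- function(benefit, cost) {
  counts <- c("high-benefit/low-cost" = 0, "low-benefit/low-cost" = 0,
              "low-benefit/high-cost" = 0, "high-benefit/high-cost" = 0)
  for (i in seq_len(nrow(benefit))) for (j in seq_len(ncol(benefit))) {
    b <- benefit[i, j]; cst <- cost[i, j]
    if (is.na(b) || is.na(cst)) next
    key <- if (b >= 0.5 && cst < 0.5) "high-benefit/low-cost"
    else if (b < 0.5 && cst < 0.5) "low-benefit/low-cost"
    else if (b < 0.5) "low-benefit/high-cost"
    else "high-benefit/high-cost"
    counts[key] <- counts[key] + 1
  }
  counts
}

oracle_changed_fraction <- function(delta, threshold) {
  n <- 0; hit <- 0
  for (d in delta) {
    if (is.na(d)) next
    n <- n + 1
    if (abs(d) > threshold) hit <- hit + 1
  }
  hit / n
}

# Liang-Barsky parametric clip of one segment to one rectangle; returns
# c(t0, t1) or NULL
liang_barsky <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  dx <- x1 - x0; dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - xmin, xmax - x0, y0 - ymin, ymax - y0)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(NULL)
    } else {
      r <- q[k] / p[k]
      if (p[k] < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  c(t0, t1)
}

hav_km <- function(lon1, lat1, lon2, lat2) {
  R <- 6371.0088
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  a <- sin((p2 - p1) / 2)^2 +
    cos(p1) * cos(p2) * sin((lon2 - lon1) * pi / 360 * 2 / 2)^2
  2 * R * asin(min(1, sqrt(a)))
}

# road length per cell by per-cell Liang-Barsky clipping (independent of
# the grid-line-splitting implementation)
oracle_road_length_per_cell <- function(network, grid, levels) {
  cs <- grid$cell_size
  len <- matrix(0, grid$n_rows, grid$n_cols)
  for (rd in network) {
    if (identical(rd$level, "proposal") || !(rd$level %in% levels)) next
    cd <- rd$coords
    for (s in seq_len(nrow(cd) - 1)) {
      x0 <- cd[s, 1]; y0 <- cd[s, 2]; x1 <- cd[s + 1, 1]; y1 <- cd[s + 1, 2]
      for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
        xmin <- grid$origin[1] + (j - 1) * cs; xmax <- xmin + cs
        ymax <- grid$origin[2] - (i - 1) * cs; ymin <- ymax - cs
        tt <- liang_barsky(x0, y0, x1, y1, xmin, xmax, ymin, ymax)
        if (is.null(tt) || tt[2] <= tt[1]) next
        ax <- x0 + tt[1] * (x1 - x0); ay <- y0 + tt[1] * (y1 - y0)
        bx <- x0 + tt[2] * (x1 - x0); by <- y0 + tt[2] * (y1 - y0)
        len[i, j] <- len[i, j] + hav_km(ax, ay, bx, by)
      }
    }
  }
  len
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle
sutherland_hodgman <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    if (!nrow(pts)) return(pts)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(pts)
    for (k in seq_len(n)) {
      cur <- pts[k, ]; prev <- pts[if (k == 1) n else k - 1, ]
      ci <- inside(cur); pi_ <- inside(prev)
      if (ci) {
        if (!pi_) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi_) out <- rbind(out, intersect(prev, cur))
    }
    out
  }
  ix <- function(a, b, at, coord) {
    t <- (at - a[coord]) / (b[coord] - a[coord])
    a + t * (b - a)
  }
  p <- poly
  p <- clip_edge(p, function(q) q[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_edge(p, function(q) q[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_edge(p, function(q) q[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_edge(p, function(q) q[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}

shoelace_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  n <- nrow(p)
  s <- 0
  for (k in seq_len(n)) {
    a <- p[k, ]; b <- p[if (k == n) 1 else k + 1, ]
    s <- s + a[1] * b[2] - b[1] * a[2]
  }
  abs(s) / 2
}

# presence of a polygon in each cell via clipped-area > 0; cells whose
# rectangle lies entirely outside the polygon's bounding box cannot
# intersect it, so only bbox cells need clipping (exact, not approximate)
oracle_range_presence <- function(poly, grid) {
  cs <- grid$cell_size
  pres <- matrix(FALSE, grid$n_rows, grid$n_cols)
  j_lo <- max(1, floor((min(poly[, 1]) - grid$origin[1]) / cs) + 1)
  j_hi <- min(grid$n_cols, floor((max(poly[, 1]) - grid$origin[1]) / cs) + 1)
  i_lo <- max(1, floor((grid$origin[2] - max(poly[, 2])) / cs) + 1)
  i_hi <- min(grid$n_rows, floor((grid$origin[2] - min(poly[, 2])) / cs) + 1)
  if (j_lo > j_hi || i_lo > i_hi) return(pres)
  for (i in i_lo:i_hi) for (j in j_lo:j_hi) {
    xmin <- grid$origin[1] + (j - 1) * cs
    ymax <- grid$origin[2] - (i - 1) * cs
    cp <- sutherland_hodgman(poly, xmin, xmin + cs, ymax - cs, ymax)
    pres[i, j] <- shoelace_area(cp) > 1e-12
  }
  pres
}

# raw vertebrate class score by per-species scalar loop
oracle_vertebrate_raw <- function(ranges, cover, areas, grid) {
  raw <- matrix(0, grid$n_rows, grid$n_cols)
  for (sp in ranges) {
    pres <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (poly in sp$geometry)
      pres <- pres | oracle_range_presence(poly, grid)
    raw <- raw + pres * areas / sp$global_range_area
  }
  raw * cover
}

# ordered cell traversal of a polyline by dense sampling
oracle_profile_cells <- function(coords, grid, n_samples = 20000) {
  cs <- grid$cell_size
  seg_len <- sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)
  total <- sum(seg_len)
  ts <- seq(0, 1, length.out = n_samples)
  cum <- c(0, cumsum(seg_len)) / total
  lon <- approx(cum, coords[, 1], ts)$y
  lat <- approx(cum, coords[, 2], ts)$y
  col <- floor((lon - grid$origin[1]) / cs) + 1
  row <- floor((grid$origin[2] - lat) / cs) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  key <- paste(row[ok], col[ok])
  first <- !duplicated(key)
  data.frame(row = row[ok][first], col = col[ok][first])
}
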