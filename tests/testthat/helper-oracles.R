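# Independent brute-force oracles used to validate the pipeline on small
# fixtures. Deliberately naive implementations (queue-based flood fill,
# per-pixel loops, exhaustive enumeration): slow but transparently correct.

# 8-connected component labelling by breadth-first flood fill.
bfs_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# Canonical partition signature: multiset of sorted pixel-index groups, so
# two labelings can be compared independent of label numbering.
partition_signature <- function(lab) {
  grp <- split(which(lab > 0L), lab[lab > 0L])
  sig <- vapply(grp, function(g) paste(sort(g), collapse = ","), character(1))
  sort(unname(sig))
}

# The background-relative threshold rule, written out directly.
oracle_threshold_relative <- function(raster, region, k) {
  vals <- raster[region]
  q90 <- quantile(vals, 0.9, names = FALSE, type = 7)
  bg <- vals[vals <= q90]
  thr <- median(bg) + k * mad(bg)
  region & (raster > thr)
}

# Vessel detection oracle: threshold rule + BFS components + area filter.
# Returns the sorted areas (um^2) of surviving components.
oracle_vessel_areas <- function(lectin, region, crit, px) {
  m <- oracle_threshold_relative(lectin, region, crit$intensity_k)
  lab <- bfs_label(m)
  if (max(lab) == 0L) return(numeric(0))
  areas <- as.numeric(table(lab[lab > 0L])) * px^2
  sort(areas[areas >= crit$min_area_um2 & areas <= crit$max_area_um2])
}

# Hemoglobin score oracle: per-pixel loops, minimum distance to the vessel
# mask computed by exhaustive pairwise distances.
oracle_hb_score <- function(hb, region, crit, px, vessel_mask = NULL,
                            proximity_radius_um = NULL) {
  m <- oracle_threshold_relative(hb, region, crit$intensity_k)
  vals <- hb[region]
  q90 <- quantile(vals, 0.9, names = FALSE, type = 7)
  bg_med <- median(vals[vals <= q90])
  lab <- bfs_label(m)
  if (max(lab) == 0L) return(0)
  vx <- NULL
  if (!is.null(proximity_radius_um)) {
    idx <- which(vessel_mask)
    vx <- cbind((idx - 1L) %% nrow(vessel_mask) + 1L,
                (idx - 1L) %/% nrow(vessel_mask) + 1L)
  }
  total <- 0
  for (l in seq_len(max(lab))) {
    px_idx <- which(lab == l)
    area <- length(px_idx) * px^2
    if (area < crit$min_area_um2 || area > crit$max_area_um2) next
    if (!is.null(proximity_radius_um)) {
      pts <- cbind((px_idx - 1L) %% nrow(lab) + 1L,
                   (px_idx - 1L) %/% nrow(lab) + 1L)
      mind <- Inf
      for (r in seq_len(nrow(pts))) {
        d <- sqrt((vx[, 1] - pts[r, 1])^2 + (vx[, 2] - pts[r, 2])^2) * px
        mind <- min(mind, min(d))
      }
      if (mind > proximity_radius_um) next
    }
    total <- total + sum(hb[px_idx] - bg_med)
  }
  total / (sum(region) * px^2 / 1e6)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n1 + n2, n1) group assignments (no ties assumed).
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  mid <- n1 * n2 / 2
  p <- if (u_obs > mid) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# Grubbs critical value straight from the t-quantile formula.
oracle_grubbs_critical <- function(n, alpha) {
  tc <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
}

# Uniform region set covering the whole frame with a single class, handy for
# fixtures that do not need cord geometry.
flat_regions <- function(nr, nc, class = "gray") {
  code <- c(gray = 1L, white = 2L, anterior_horn_left = 3L)[[class]]
  region_set(matrix(code, nr, nc))
}

# Solid disk mask/raster helpers.
disk_mask <- function(nr, nc, cr, cc, radius_px) {
  (row(matrix(0, nr, nc)) - cr)^2 + (col(matrix(0, nr, nc)) - cc)^2 <=
    radius_px^2
}
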