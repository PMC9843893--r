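# Independent naive oracles used to cross-check the implementation.
# Everything here is deliberately written by direct enumeration, never by
# calling the package's own compiled paths.

# directions matching the package convention
oracle_directions <- function(threeD) {
  if (!threeD)
    return(list(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(-1, 1, 0)))
  d <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      d[[length(d) + 1]] <- c(dx, dy, dz)
  }
  d
}

oracle_neighbors <- function(threeD) {
  d <- list()
  zr <- if (threeD) 1 else 0
  for (dz in -zr:zr) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    d[[length(d) + 1]] <- c(dx, dy, dz)
  }
  d
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetrized pair-count GLCM per direction by exhaustive enumeration
oracle_glcm <- function(idx, nlev, threeD) {
  d <- dim(idx)
  lapply(oracle_directions(threeD), function(dir) {
    m <- matrix(0, nlev, nlev)
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- idx[x, y, z]
      if (i == 0) next
      q <- c(x, y, z) + dir
      if (!in_grid(q, d)) next
      j <- idx[q[1], q[2], q[3]]
      if (j == 0) next
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
    m
  })
}

# run-length matrix per direction by walking maximal runs
oracle_glrlm <- function(idx, nlev, threeD) {
  d <- dim(idx)
  maxrun <- max(d)
  lapply(oracle_directions(threeD), function(dir) {
    m <- matrix(0, nlev, maxrun)
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- idx[x, y, z]
      if (i == 0) next
      prev <- c(x, y, z) - dir
      if (in_grid(prev, d) && idx[prev[1], prev[2], prev[3]] == i) next
      len <- 1
      nxt <- c(x, y, z) + dir
      while (in_grid(nxt, d) && idx[nxt[1], nxt[2], nxt[3]] == i) {
        len <- len + 1
        nxt <- nxt + dir
      }
      m[i, len] <- m[i, len] + 1
    }
    m
  })
}

# size-zone matrix via recursive region growing over equal-level neighbors
oracle_glszm <- function(idx, nlev, threeD) {
  d <- dim(idx)
  nbs <- oracle_neighbors(threeD)
  seen <- array(FALSE, d)
  zones <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (seen[x, y, z] || idx[x, y, z] == 0) next
    lev <- idx[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (nb in nbs) {
        q <- p + nb
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] &&
            idx[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  maxsize <- max(1, vapply(zones, `[`, 0, 2))
  m <- matrix(0, nlev, maxsize)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1
  m
}

oracle_gldm <- function(idx, nlev, threeD, alpha = 0) {
  d <- dim(idx)
  nbs <- oracle_neighbors(threeD)
  m <- matrix(0, nlev, length(nbs) + 1)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- idx[x, y, z]
    if (i == 0) next
    dep <- 0
    for (nb in nbs) {
      q <- c(x, y, z) + nb
      if (!in_grid(q, d)) next
      j <- idx[q[1], q[2], q[3]]
      if (j != 0 && abs(i - j) <= alpha) dep <- dep + 1
    }
    m[i, dep + 1] <- m[i, dep + 1] + 1
  }
  m
}

oracle_ngtdm <- function(idx, nlev, threeD) {
  d <- dim(idx)
  nbs <- oracle_neighbors(threeD)
  m <- matrix(0, nlev, 2)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- idx[x, y, z]
    if (i == 0) next
    vals <- c()
    for (nb in nbs) {
      q <- c(x, y, z) + nb
      if (in_grid(q, d) && idx[q[1], q[2], q[3]] != 0)
        vals <- c(vals, idx[q[1], q[2], q[3]])
    }
    if (length(vals) == 0) next
    m[i, 1] <- m[i, 1] + 1
    m[i, 2] <- m[i, 2] + abs(i - mean(vals))
  }
  m
}

# feature formulas by direct summation over the oracle matrices
oracle_glcm_feats <- function(mats) {
  per <- list()
  for (m in mats) {
    tot <- sum(m)
    if (tot == 0) next
    p <- m / tot
    nl <- nrow(p)
    I <- row(p); J <- col(p)
    px <- rowSums(p); py <- colSums(p)
    mux <- sum((1:nl) * px); muy <- sum((1:nl) * py)
    sx <- sqrt(sum(((1:nl) - mux)^2 * px))
    sy <- sqrt(sum(((1:nl) - muy)^2 * py))
    hxy <- -sum(p[p > 0] * log2(p[p > 0]))
    pq <- outer(px, py)
    hxy2 <- -sum(pq[pq > 0] * log2(pq[pq > 0]))
    off <- I != J
    per[[length(per) + 1]] <- c(
      contrast = sum((I - J)^2 * p),
      correlation = if (sx * sy > 0)
        (sum(I * J * p) - mux * muy) / (sx * sy) else 1,
      imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
      inverse_variance = sum(p[off] / (I[off] - J[off])^2),
      inverse_difference_moment = sum(p / (1 + (I - J)^2)),
      joint_entropy = hxy)
  }
  Reduce(`+`, per) / length(per)
}

oracle_glrlm_feats <- function(mats, n_vox) {
  per <- list()
  for (m in mats) {
    nr <- sum(m)
    if (nr == 0) next
    r <- col(m)
    per[[length(per) + 1]] <- c(
      short_run_emphasis = sum(m / r^2) / nr,
      long_run_emphasis = sum(m * r^2) / nr,
      run_percentage = nr / n_vox,
      gray_level_nonuniformity = sum(rowSums(m)^2) / nr)
  }
  Reduce(`+`, per) / length(per)
}

oracle_glszm_feats <- function(m, n_vox) {
  nz <- sum(m)
  s <- col(m)
  c(small_area_emphasis = sum(m / s^2) / nz,
    large_area_emphasis = sum(m * s^2) / nz,
    zone_percentage = nz / n_vox,
    gray_level_nonuniformity = sum(rowSums(m)^2) / nz)
}

oracle_gldm_feats <- function(m) {
  nz <- sum(m)
  p <- m / nz
  jd <- col(m)
  pg <- rowSums(p)
  mu <- sum((1:nrow(m)) * pg)
  c(small_dependence_emphasis = sum(m / jd^2) / nz,
    large_dependence_emphasis = sum(m * jd^2) / nz,
    gray_level_variance = sum(pg * ((1:nrow(m)) - mu)^2),
    dependence_entropy = -sum(p[p > 0] * log2(p[p > 0])),
    dependence_nonuniformity = sum(colSums(m)^2) / nz)
}

oracle_ngtdm_feats <- function(m) {
  ni <- m[, 1]; si <- m[, 2]
  n <- sum(ni)
  p <- ni / n
  act <- which(ni > 0)
  ngp <- length(act)
  denom_c <- sum(p * si)
  ipi <- act * p[act]
  denom_b <- sum(abs(outer(ipi, ipi, `-`)))
  c(busyness = if (denom_b > 0) denom_c / denom_b else 0,
    coarseness = if (denom_c > 0) 1 / denom_c else 1e6,
    contrast = if (ngp > 1)
      sum(outer(p[act], p[act]) * outer(act, act, `-`)^2) /
        (ngp * (ngp - 1)) * sum(si) / n else 0)
}

oracle_firstorder <- function(v, bw = 16) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  lev <- floor((v - min(v)) / bw) + 1
  p <- as.numeric(table(lev)) / n
  c(mean = mu, median = median(v), minimum = min(v), maximum = max(v),
    range = max(v) - min(v), variance = m2,
    skewness = if (m2 > 0) (sum((v - mu)^3) / n) / m2^1.5 else 0,
    mean_absolute_deviation = sum(abs(v - mu)) / n,
    entropy = -sum(p * log2(p)),
    root_mean_squared = sqrt(sum(v^2) / n))
}

# random gray-level index array over a random ROI
random_index_array <- function(d, nlev, roi_frac = 0.8) {
  idx <- array(sample.int(nlev, prod(d), replace = TRUE), dim = d)
  idx[runif(prod(d)) > roi_frac] <- 0L
  storage.mode(idx) <- "integer"
  idx
}

# O(n^2) pairwise AUC with half credit for ties
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# largest per-slice 8-connected region by recursive flood fill
oracle_largest_region <- function(hot) {
  d <- dim(hot)
  best <- 0
  seen <- array(FALSE, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (!hot[x, y, z] || seen[x, y, z]) next
    stack <- list(c(x, y))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        q <- p + c(dx, dy)
        if (q[1] >= 1 && q[1] <= d[1] && q[2] >= 1 && q[2] <= d[2] &&
            hot[q[1], q[2], z] && !seen[q[1], q[2], z]) {
          seen[q[1], q[2], z] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    best <- max(best, size)
  }
  best
}

# all stride-lattice windows (including flush-edge) with ROI overlap > thr
oracle_valid_windows <- function(roi_slice, w = 20, stride = 5, frac = 0.05) {
  d <- dim(roi_slice)
  xs <- unique(c(seq(0, d[1] - w, by = stride), d[1] - w))
  ys <- unique(c(seq(0, d[2] - w, by = stride), d[2] - w))
  out <- NULL
  for (y0 in ys) for (x0 in xs) {
    ov <- sum(roi_slice[x0 + 1:w, y0 + 1:w])
    if (ov > frac * w * w)
      out <- rbind(out, c(x0 = x0, y0 = y0, ov = ov))
  }
  out
}
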