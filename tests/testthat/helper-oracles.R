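# Independent oracles used across the suite. These deliberately avoid
# the package's own search / filter code paths.

# Dijkstra cost oracle for the reconnection objective, via igraph:
# node-entry costs are folded into directed edge weights, and a
# super-source / super-sink absorbs the multi-source/multi-target
# boundary conditions.
dijkstra_cost_oracle <- function(den, source, target, forbidden, fs,
                                 spacing, connectivity = 26) {
  d <- dim(den)
  n <- prod(d)
  idx <- array(seq_len(n), dim = d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  ok <- !forbidden
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    xr <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- as.vector(idx[xr, yr, zr])
    b <- as.vector(idx[xr + o[1], yr + o[2], zr + o[3]])
    keep <- ok[a] & ok[b]
    a <- a[keep]; b <- b[keep]
    step <- sqrt(sum((o * spacing)^2))
    from <- c(from, a)
    to <- c(to, b)
    wt <- c(wt, step + (1 - den[b]) * fs)
  }
  ssrc <- n + 1L
  ssink <- n + 2L
  sv <- which(source & ok)
  tv <- which(target & ok)
  if (length(sv) == 0 || length(tv) == 0) return(Inf)
  from <- c(from, rep(ssrc, length(sv)), tv)
  to <- c(to, sv, rep(ssink, length(tv)))
  wt <- c(wt, (1 - den[sv]) * fs, rep(0, length(tv)))
  g <- igraph::make_graph(rbind(from, to), n = n + 2L, directed = TRUE)
  as.numeric(igraph::distances(g, v = ssrc, to = ssink, mode = "out",
                               weights = wt, algorithm = "dijkstra"))
}

# naive sliding-window median (even windows anchored toward +axis,
# reflective borders, lower-middle order statistic)
median_filter_oracle <- function(v, w) {
  d <- dim(v)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  off <- function(wk) (-((wk - 1) %/% 2)):(wk %/% 2)
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    vals <- numeric(0)
    for (dz in off(w[3])) for (dy in off(w[2])) for (dx in off(w[1]))
      vals <- c(vals, v[refl(x + dx, d[1]), refl(y + dy, d[2]),
                        refl(z + dz, d[3])])
    out[x, y, z] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

# brute-force connected-component partition by repeated BFS in plain R
components_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        p <- ijk + offs[r, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# scalar-loop weighted cross entropy (natural log, clamped like the
# implementation)
wcel_oracle <- function(pred, gt_labels, weight) {
  d <- dim(gt_labels)
  total <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    k <- gt_labels[x, y, z] + 1L
    p <- max(pred[x, y, z, k], 1e-12)
    w <- if (length(weight) == 1) weight else weight[x, y, z]
    total <- total - w * log(p)
  }
  total
}

# scalar-loop generalized Dice loss
gdl_oracle <- function(pred, gt_labels) {
  d <- dim(gt_labels)
  num <- 0; den <- 0
  for (k in 0:2) {
    nk <- sum(gt_labels == k)
    if (nk == 0) next
    wk <- 1 / nk^2
    inter <- 0; tot <- 0
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      r <- as.numeric(gt_labels[x, y, z] == k)
      p <- pred[x, y, z, k + 1]
      inter <- inter + r * p
      tot <- tot + r + p
    }
    num <- num + wk * inter
    den <- den + wk * tot
  }
  1 - 2 * num / den
}

# random probability 4-D array (per-voxel softmax-normalized)
random_probs <- function(d) {
  raw <- array(stats::runif(prod(c(d, 3)), 0.05, 1), dim = c(d, 3))
  s <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
  raw / as.vector(s)
}

# small phantom helper with overridable fields
phantom_cfg <- function(...) {
  cfg <- default_config()$phantom
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}
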