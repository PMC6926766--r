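# Independent brute-force oracles and small fixture builders. Everything
# here deliberately avoids the code paths it checks.

# Build a land_use_grid from a plain matrix (codes 1..8 or NA).
toy_grid <- function(m, cell = 100, year = 2000, xll = 0, yll = 0) {
  land_use_grid(matrix(as.integer(m), nrow(m)), cell, xll, yll, year = year)
}

# Assessment units where each raster cell is its own unit.
lattice_units <- function(nrow, ncol, unit_m = 1000) {
  g <- land_use_grid(matrix(1L, nrow, ncol), unit_m, year = 2000)
  tessellate(g, unit_m)
}

# Literal double-sum Moran's I from the printed formula.
brute_moran <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n)
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  s2 <- sum((x - xb)^2) / n
  num / (s2 * sum(W))
}

# Direct Gi* formula evaluation, one unit at a time.
brute_gistar <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  s <- sqrt(sum(x^2) / n - xb^2)
  vapply(1:n, function(i) {
    wi <- W[i, ]
    num <- sum(wi * x) - xb * sum(wi)
    den <- s * sqrt((n * sum(wi^2) - sum(wi)^2) / (n - 1))
    num / den
  }, numeric(1))
}

# Cost-distance oracle: Gauss-Seidel relaxation to the fixed point of the
# shortest-path Bellman equation (algorithmically unrelated to Dijkstra).
relax_cost <- function(resistance, sources, cell = 1, connectivity = 8) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  cost <- matrix(Inf, nr, nc)
  cost[sources] <- 0
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c2 in 1:nc) {
      if (is.na(resistance[r, c2])) next
      for (s in shifts) {
        r2 <- r + s[1]; c3 <- c2 + s[2]
        if (r2 < 1 || r2 > nr || c3 < 1 || c3 > nc) next
        if (is.na(resistance[r2, c3])) next
        step <- (resistance[r, c2] + resistance[r2, c3]) / 2 *
          cell * sqrt(sum(s^2))
        cand <- cost[r2, c3] + step
        if (cand < cost[r, c2] - 1e-12) { cost[r, c2] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  cost
}

# Exhaustive simple-path enumeration oracle (tiny grids only).
enum_cost <- function(resistance, source_idx, cell = 1, connectivity = 4) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  best <- matrix(Inf, nr, nc)
  visit <- function(r, c2, acc, seen) {
    if (acc < best[r, c2]) best[r, c2] <<- acc
    for (s in shifts) {
      r2 <- r + s[1]; c3 <- c2 + s[2]
      if (r2 < 1 || r2 > nr || c3 < 1 || c3 > nc) next
      key <- (c3 - 1) * nr + r2
      if (key %in% seen) next
      step <- (resistance[r, c2] + resistance[r2, c3]) / 2 * cell * sqrt(sum(s^2))
      if (acc + step >= best[r2, c3]) next  # prune dominated prefixes
      visit(r2, c3, acc + step, c(seen, key))
    }
  }
  for (src in source_idx) {
    rc <- arrayInd(src, c(nr, nc))
    visit(rc[1], rc[2], 0, (rc[2] - 1) * nr + rc[1])
  }
  best
}

# Optimal 1-D k-partition by exhaustive enumeration of cut positions.
brute_jenks <- function(x, k) {
  v <- sort(x)
  n <- length(v)
  best <- Inf; best_cuts <- NULL
  for (cuts in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cuts, n)
    sse <- 0
    for (b in 1:k) {
      seg <- v[(bounds[b] + 1):bounds[b + 1]]
      sse <- sse + sum((seg - mean(seg))^2)
    }
    if (sse < best - 1e-12) { best <- sse; best_cuts <- cuts }
  }
  list(sse = best, breaks = v[best_cuts])
}

# Dense weight matrix of a spatial_weights object.
dense_w <- function(w) as.matrix(w$W)

# All permutations of 1..n (tiny n only).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (i in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = i)
  out
}
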