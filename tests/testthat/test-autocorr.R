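test_that("contiguity weights have the expected neighbour counts", {
  u <- lattice_units(3, 3)
  rook <- build_weights(u, "rook")
  deg <- Matrix::rowSums(rook$W)
  m <- matrix(deg, 3, 3)
  expect_equal(m[1, 1], 2)  # corners
  expect_equal(m[3, 3], 2)
  expect_equal(m[2, 2], 4)  # centre
  queen <- build_weights(u, "queen")
  expect_equal(matrix(Matrix::rowSums(queen$W), 3, 3)[2, 2], 8)
  rw <- build_weights(u, "queen", "row")
  expect_equal(as.numeric(Matrix::rowSums(rw$W)), rep(1, 9))
  star <- build_weights(u, "queen", include_self = TRUE)
  expect_equal(as.numeric(Matrix::diag(star$W)), rep(1, 9))
})

test_that("distance-band weights respect the band and report islands", {
  u <- lattice_units(4, 4)
  w <- build_weights(u, "distance", band = 1000)
  expect_equal(matrix(Matrix::rowSums(w$W), 4, 4)[2, 2], 4)  # rook-like
  expect_error(build_weights(u, "distance", band = 10), "island")
})

test_that("the 2x2 checkerboard yields Moran's I of exactly -1", {
  u <- lattice_units(2, 2)
  w <- build_weights(u, "rook", "binary")
  r <- global_morans_i(c(1, 0, 0, 1), w, permutations = 0)
  expect_equal(r$i, -1)
  expect_equal(r$expected, -1 / 3)
})

test_that("Moran's I equals the literal double-sum on random fields", {
  u <- lattice_units(6, 6)
  for (scheme in c("rook", "queen")) {
    w <- build_weights(u, scheme, "binary")
    Wd <- dense_w(w)
    for (s in 1:20) {
      set.seed(s)
      x <- rnorm(36)
      r <- global_morans_i(x, w, permutations = 0)
      expect_equal(r$i, brute_moran(x, Wd), tolerance = 1e-12)
    }
  }
})

test_that("a constant field raises the undefined-statistic error", {
  u <- lattice_units(3, 3)
  w <- build_weights(u, "rook")
  expect_error(global_morans_i(rep(2, 9), w), "zero variance")
  ws <- build_weights(u, "queen", include_self = TRUE)
  expect_error(getis_ord_gistar(rep(2, 9), ws), "zero variance")
})

test_that("the exhaustive permutation mean of I equals -1/(n-1)", {
  u <- lattice_units(2, 2)
  w <- build_weights(u, "rook", "binary")
  Wd <- dense_w(w)
  x <- c(0.3, 1.1, 2.7, 5.0)
  perms <- do.call(rbind, lapply(combinat_perms(4), function(p) x[p]))
  is <- apply(perms, 1, brute_moran, W = Wd)
  expect_equal(mean(is), -1 / 3, tolerance = 1e-12)
  # the implementation agrees on every permutation
  impl <- apply(perms, 1, function(v) global_morans_i(v, w, permutations = 0)$i)
  expect_equal(impl, is, tolerance = 1e-12)
})

test_that("permutation inference is calibrated and seeded", {
  u <- lattice_units(10, 10)
  w <- build_weights(u, "queen")
  set.seed(77)
  x <- rnorm(100)
  r <- global_morans_i(x, w, permutations = 999, seed = 5)
  mc_se <- stats::sd(r$perm_values) / sqrt(999)
  expect_lt(abs(mean(r$perm_values) - (-1 / 99)), 3 * mc_se)
  expect_gt(r$p_perm, 0); expect_lte(r$p_perm, 1)
  r2 <- global_morans_i(x, w, permutations = 999, seed = 5)
  expect_identical(r$perm_values, r2$perm_values)
})

test_that("adding a constant changes neither I nor Gi* z", {
  u <- lattice_units(5, 5)
  w <- build_weights(u, "queen", "row")
  ws <- build_weights(u, "queen", include_self = TRUE)
  set.seed(4)
  x <- rnorm(25)
  expect_equal(global_morans_i(x, w, permutations = 0)$i,
               global_morans_i(x + 17, w, permutations = 0)$i)
  expect_equal(getis_ord_gistar(x, ws)$z, getis_ord_gistar(x + 17, ws)$z)
})

test_that("Gi* matches the direct formula and finds a planted block", {
  u <- lattice_units(8, 8)
  ws <- build_weights(u, "queen", include_self = TRUE)
  Wd <- dense_w(ws)
  set.seed(3)
  x <- rnorm(64, 0, 0.1)
  block <- as.vector(matrix(seq_len(64), 8, 8)[3:5, 3:5])
  x[block] <- x[block] + 3
  g <- getis_ord_gistar(x, ws)
  expect_equal(g$z, brute_gistar(x, Wd), tolerance = 1e-12)
  expect_true(all(abs(g$z[block]) >= 1.96))
  expect_equal(which.max(g$z) %in% block, TRUE)
  far <- setdiff(seq_len(64), as.vector(matrix(seq_len(64), 8, 8)[2:6, 2:6]))
  expect_gte(mean(abs(g$z[far]) < 1.65), 0.95)
})

test_that("a mirror-symmetric field yields a mirror-symmetric z map", {
  u <- lattice_units(4, 6)
  ws <- build_weights(u, "queen", include_self = TRUE)
  set.seed(10)
  half <- matrix(rnorm(12), 4, 3)
  x <- cbind(half, half[, 3:1])
  z <- matrix(getis_ord_gistar(as.vector(x), ws)$z, 4, 6)
  expect_equal(z, z[, 6:1], tolerance = 1e-12)
})

test_that("seven-grade classification follows the confidence thresholds", {
  g <- classify_seven_grades(c(-3, -0.1, 0, 3))
  expect_equal(as.character(g),
               c("cold-high", "not significant", "not significant", "hot-high"))
  expect_equal(as.character(classify_seven_grades(1.96)), "hot-middle")
  expect_equal(as.character(classify_seven_grades(2.58)), "hot-high")
  expect_equal(as.character(classify_seven_grades(-1.65)), "cold-low")
  expect_true(all(classify_seven_grades(c(0.3, -1.2, 1.5)) == "not significant"))
  expect_error(classify_seven_grades(1, method = "nope"))
})

test_that("an FDR gate forces non-significant units to 'not significant'", {
  z <- c(-4, -2, 2, 4)
  g <- classify_seven_grades(z, p_adj = c(0.001, 0.2, 0.2, 0.001),
                             sig_level = 0.05)
  expect_equal(as.character(g), c("cold-high", "not significant",
                                  "not significant", "hot-high"))
})

test_that("Jenks breaks minimise within-class SSE", {
  set.seed(6)
  for (rep in 1:5) {
    x <- rnorm(12)
    for (k in 2:4) {
      br <- jenks_breaks(x, k)
      cls <- findInterval(x, br, left.open = TRUE) + 1
      sse <- sum(tapply(x, cls, function(v) sum((v - mean(v))^2)))
      expect_equal(sse, brute_jenks(x, k)$sse, tolerance = 1e-10)
    }
  }
  expect_equal(jenks_breaks(c(1, 2, 10, 11), 2), 2)
})

test_that("breaks-based grading assigns all seven grades in z order", {
  set.seed(15)
  z <- sort(rnorm(70, sd = 2))
  g <- classify_seven_grades(z, method = "breaks")
  expect_equal(length(unique(g)), 7)
  expect_true(all(diff(as.integer(g)) >= 0))  # monotone in z
})

test_that("optimized hotspot selects a sensible scale and flags the cluster", {
  u <- lattice_units(10, 10)
  set.seed(12)
  x <- rnorm(100, 0, 0.15)
  # compact planted cluster of diameter ~3 units (3 km)
  cl <- as.vector(matrix(seq_len(100), 10, 10)[4:6, 4:6])
  x[cl] <- x[cl] + 2
  h <- optimized_hotspot(x, u, fdr_level = 0.05)
  scale <- attr(h, "scale")
  expect_gte(scale, 1500)            # within a factor of 2 of the diameter
  expect_lte(scale, 6000)
  expect_true(all(grepl("hot", h$grade[cl])))
  h2 <- optimized_hotspot(x, u, fdr_level = 0.05)
  expect_identical(h, h2)            # deterministic
})

test_that("relabelling units permutes the Gi* z map consistently", {
  u <- lattice_units(5, 5)
  ws <- build_weights(u, "queen", include_self = TRUE)
  set.seed(30)
  x <- rnorm(25)
  z <- getis_ord_gistar(x, ws)$z
  # transpose the lattice: unit (r, c) -> (c, r); same geometry by symmetry
  perm <- as.vector(t(matrix(seq_len(25), 5, 5)))
  z2 <- getis_ord_gistar(x[perm], ws)$z
  expect_equal(z2, z[perm], tolerance = 1e-12)
})
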