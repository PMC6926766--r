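# Helper: a zone_map with given cell codes on a simple geometry.
toy_zone_map <- function(codes, cell = 100) {
  structure(list(unit_zone = NULL, cell_codes = codes,
                 geometry = list(nrow = nrow(codes), ncol = ncol(codes),
                                 cell_size_m = cell, xll = 0, yll = 0),
                 cell_size_m = cell),
            class = "zone_map")
}

test_that("resistance combines the two ranked tables with 0.5 weights", {
  # water inside core protection -> 1; construction in core restoration -> 8;
  # farmland in 'other' -> 5
  grid <- toy_grid(matrix(c(5L, 7L, 6L), 1, 3))
  zones <- toy_zone_map(matrix(zone_code(c("core_protection", "core_restoration",
                                           "other")), 1, 3))
  r <- build_resistance(grid, zones)
  expect_equal(as.numeric(r), c(1, 8, 5))
  expect_true(all(r >= 1 & r <= 8))
})

test_that("cost distance is zero on sources and Manhattan on uniform ground", {
  res <- matrix(1, 5, 5)
  src <- matrix(FALSE, 5, 5); src[3, 3] <- TRUE
  cost <- mcr_cost_distance(res, src, cell_size_m = 1, connectivity = 4)
  man <- abs(row(res) - 3) + abs(col(res) - 3)
  expect_equal(cost, man * 1, ignore_attr = TRUE)
  expect_equal(cost[3, 3], 0)
})

test_that("cost distance equals exhaustive path enumeration on tiny grids", {
  set.seed(19)
  m <- matrix(runif(9, 1, 8), 3, 3)
  for (conn in c(4, 8)) {
    cost <- mcr_cost_distance(m, 1L, cell_size_m = 1, connectivity = conn)
    expect_equal(cost, enum_cost(m, 1L, 1, conn), tolerance = 1e-12)
  }
})

test_that("cost distance matches the relaxation oracle on random grids", {
  set.seed(23)
  for (rep in 1:50) {
    m <- matrix(runif(16, 0.5, 8), 4, 4)
    src <- sample(16, sample(1:3, 1))
    cost <- mcr_cost_distance(m, src, cell_size_m = 1, connectivity = 8)
    expect_equal(cost, relax_cost(m, src, 1, 8), tolerance = 1e-10)
  }
})

test_that("raising one cell's resistance never lowers any cost", {
  set.seed(29)
  m <- matrix(runif(36, 1, 5), 6, 6)
  src <- c(1L, 20L)
  base <- mcr_cost_distance(m, src, cell_size_m = 10)
  for (rep in 1:10) {
    m2 <- m
    i <- sample(36, 1)
    m2[i] <- m2[i] + runif(1, 0.5, 3)
    up <- mcr_cost_distance(m2, src, cell_size_m = 10)
    expect_true(all(up >= base - 1e-9))
  }
})

test_that("cost distance validates its inputs", {
  m <- matrix(1, 3, 3)
  expect_error(mcr_cost_distance(m, integer(0)), "empty source")
  expect_error(mcr_cost_distance(matrix(c(-1, rep(1, 8)), 3, 3), 1L), "positive")
  expect_true(is.infinite(
    mcr_cost_distance(matrix(c(1, NA, 1), 1, 3), 1L)[1, 3]))  # barrier
})

test_that("the default overlay rule table is complete and as documented", {
  rules <- default_overlay_rules()
  expect_equal(nrow(rules), 3 * 7 * 3)
  expect_false(any(duplicated(rules[c("y1_state", "y2_grade", "opt_state")])))
  look <- function(y1, y2, opt)
    rules$zone[rules$y1_state == y1 & rules$y2_grade == y2 & rules$opt_state == opt]
  expect_equal(look("hot", "hot-high", "ns"), "core_protection")
  expect_equal(look("ns", "hot-low", "ns"), "ideal_protection")
  expect_equal(look("ns", "not significant", "hot"), "ecological_potential")
  # cold in the final year only -> risk supervisory (documented table)
  expect_equal(look("ns", "cold-high", "cold"), "risk_supervisory")
  expect_equal(look("cold", "cold-low", "ns"), "risk_prevention")
  expect_equal(look("cold", "cold-middle", "ns"), "key_restoration")
  expect_equal(look("cold", "cold-high", "hot"), "core_restoration")
  expect_equal(look("ns", "not significant", "ns"), "other")
})

# Hotspot fields with prescribed grades for a set of units.
fake_field <- function(grades, n) {
  z <- rep(0, n)
  structure(data.frame(unit = seq_len(n), z = z, p = 1, p_adj = 1,
                       grade = factor(grades, levels = levels(classify_seven_grades(0)))),
            class = c("hotspot_field", "data.frame"))
}

test_that("overlay partition applies the rule table and water promotion", {
  g <- toy_grid(matrix(c(rep(5L, 4), rep(2L, 12)), 4, 4), cell = 500)  # col 1 water
  u <- tessellate(g, 500)   # 16 units of one cell each
  ns <- rep("not significant", 16)
  hot <- ns; hot[1:4] <- "hot-high"        # units 1-4 = water column
  hot[5] <- "hot-middle"
  cold <- ns; cold[9] <- "cold-high"; cold[10] <- "cold-middle"
  y1 <- fake_field(hot, 16)
  y2g <- hot; y2g[9:10] <- cold[9:10]
  y2 <- fake_field(y2g, 16)
  opt <- fake_field(ns, 16)
  zm <- overlay_partition(y1, y2, opt, u)
  zk <- zone_table()$key[zm$unit_zone]
  expect_equal(zk[1], "bottomline_protection")  # persistent hot + water
  expect_equal(zk[5], "core_protection")        # persistent hot, grass
  expect_equal(zk[9], "risk_supervisory")       # cold in final year only
  expect_equal(zk[16], "other")
  expect_true(all(!is.na(zm$cell_codes)))
})

test_that("all-not-significant fields map every unit to 'other'", {
  g <- toy_grid(matrix(2L, 4, 4), cell = 500)
  u <- tessellate(g, 500)
  f <- fake_field(rep("not significant", 16), 16)
  zm <- overlay_partition(f, f, f, u)
  expect_true(all(zm$unit_zone == zone_code("other")))
})

test_that("protection partition honours thresholds, sources and conflicts", {
  grid <- toy_grid(matrix(c(6L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L), 3, 3))
  zc <- matrix(zone_code("other"), 3, 3)
  zc[2, 2] <- zone_code("core_protection")
  zones <- toy_zone_map(zc)
  res <- build_resistance(grid, zones)
  src <- matrix(FALSE, 3, 3); src[2, 2] <- TRUE
  cost <- mcr_cost_distance(res, src, cell_size_m = 100)
  inf <- matrix(Inf, 3, 3)

  # generous threshold: everything reachable is protected; the farmland
  # cell (cost 10 * its step cost < 20-scale) becomes ecological conflict
  p <- protection_partition(cost, inf, grid, zones,
                            thresholds = c(core = 1e9, potential = 1e9))
  zk <- matrix(zone_table()$key[p$cell_codes], 3, 3)
  expect_equal(zk[2, 2], "core_protection")
  expect_equal(zk[1, 1], "ecological_conflict")   # farmland inside protection
  expect_true(all(zk[zk != "ecological_conflict" & zk != "core_protection"] ==
                    "ecological_buffer"))

  # epsilon threshold: only the source (cost 0 cells are not < 0 away, but
  # retained source labels stay protected)
  p0 <- protection_partition(cost, inf, grid, zones,
                             thresholds = c(core = 1e-9, potential = 1e-9))
  zk0 <- matrix(zone_table()$key[p0$cell_codes], 3, 3)
  expect_equal(zk0[2, 2], "core_protection")
  expect_equal(sum(zk0 != "other"), 1)
  expect_error(protection_partition(cost, inf, grid, zones,
                                    thresholds = c(core = 0, potential = 1)),
               "positive")
})

test_that("raising a threshold never shrinks the protection area", {
  set.seed(33)
  grid <- toy_grid(matrix(sample(1:8, 64, TRUE), 8, 8))
  zc <- matrix(zone_code("other"), 8, 8); zc[4, 4] <- zone_code("core_protection")
  zones <- toy_zone_map(zc)
  res <- build_resistance(grid, zones)
  cost <- mcr_cost_distance(res, which(zc == zone_code("core_protection")),
                            cell_size_m = 100)
  inf <- matrix(Inf, 8, 8)
  sizes <- vapply(c(200, 500, 1000, 5000, 1e9), function(th) {
    p <- protection_partition(cost, inf, grid, zones,
                              thresholds = c(core = th, potential = 1))
    sum(p$cell_codes != zone_code("other"))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("area reports reconcile exactly with cell tallies", {
  zc <- matrix(NA_integer_, 2, 5)
  zc[1, ] <- c(1L, 1L, 2L, 9L, 10L)
  zc[2, ] <- c(11L, 11L, 7L, 7L, 5L)
  zm <- toy_zone_map(zc, cell = 1000)
  rep <- area_report(zm)
  expect_equal(rep$areas$area_km2[rep$areas$zone == "core_restoration"], 2)
  expect_equal(rep$areas$area_km2[rep$areas$zone == "core_protection"], 2)
  expect_equal(rep$warning_km2, 2 + 1 + 1)        # core/key restoration + potential
  expect_equal(rep$protection_km2, 1 + 1 + 2)     # buffer + conflict + core
  expect_equal(rep$total_km2, 10)
  expect_equal(sum(rep$areas$area_km2), rep$total_km2)
  empty <- toy_zone_map(matrix(NA_integer_, 2, 2))
  expect_true(all(area_report(empty)$areas$area_km2 == 0))
})
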