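cfg <- indicator_config()

test_that("min-max normalization matches the linear formula and polarity", {
  expect_equal(minmax_normalize(c(0, 5, 10), "+"), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 5, 10), "-"), c(1, 0.5, 0))
  expect_equal(minmax_normalize(3, "+", range = c(3, 7)), 0)
  expect_equal(minmax_normalize(7, "-", range = c(3, 7)), 0)
  expect_warning(y <- minmax_normalize(c(2, 2, 2), "+"), "degenerate")
  expect_equal(y, c(0.5, 0.5, 0.5))
})

test_that("normalization is invariant to positive affine rescaling", {
  set.seed(2)
  for (rep in 1:10) {
    x <- rnorm(20)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(minmax_normalize(x, "+"), minmax_normalize(a * x + b, "+"))
    expect_equal(minmax_normalize(x, "-"), minmax_normalize(a * x + b, "-"))
  }
})

make_series <- function(...) {
  df <- data.frame(
    year = c(2000, 2010),
    city_gdp = c(100, 150), national_gdp = c(10000, 16000),
    city_population = c(50, 60),
    oil_production = c(400, 380), national_oil = c(2000, 2100),
    si_city = c(50, 70), si_national = c(4200, 6600),
    wastewater_city = c(1, 1.2), wastewater_national = c(100, 128),
    energy_city = c(4, 5), energy_national = c(400, 533.3333333),
    eco_investment = c(1, 2),
    urban_city = c(0.4, 0.5), urban_national = c(0.3, 0.4)
  )
  mod <- list(...)
  df[names(mod)] <- mod
  class(df) <- c("socioeconomic_series", "data.frame")
  df
}

test_that("city-level indicators follow the printed formulas", {
  # city urbanization tracks the nation -> UGI = 1
  s <- make_series()
  ind <- socio_indicators(s, 2000, 2010)
  expect_equal(ind[["D1"]], 1)
  expect_equal(ind[["D2"]], 150 / 60)
  # resource-curse coefficient: production share over industry share
  expect_equal(ind[["P1"]], (380 / 2100) / (70 / 6600))
  expect_equal(ind[["R1"]], 2 / 150)
  # EI_d = 2, g_d = 100 -> IEC = 0.02
  s2 <- make_series(eco_investment = c(2, 2), city_gdp = c(100, 100))
  expect_equal(socio_indicators(s2, 2000, 2010)[["R1"]], 0.02)
})

test_that("EPI equals 1 when city intensity matches the national intensity", {
  # x/g = X/G for both categories
  s <- make_series(wastewater_city = c(1, 1.5), wastewater_national = c(100, 160),
                   energy_city = c(2, 3), energy_national = c(200, 320),
                   city_gdp = c(100, 150), national_gdp = c(10000, 16000))
  expect_equal(socio_indicators(s, 2000, 2010)[["P2"]], 1)
})

test_that("degenerate socio-economic inputs are handled explicitly", {
  s <- make_series(urban_national = c(0.3, 0.3))
  expect_true(is.na(socio_indicators(s, 2000, 2010)[["D1"]]))
  s2 <- make_series(city_gdp = c(100, 0))
  expect_error(socio_indicators(s2, 2000, 2010), "GDP")
  expect_error(socio_indicators(make_series(), 2000, 2015), "missing")
})

test_that("ERI is the share-weighted mean of interference x vulnerability", {
  keys <- land_use_classes()$key
  cfg2 <- indicator_config(
    e_i = setNames(c(4, 8, rep(1, 6)), keys),
    f_i = setNames(c(0.5, 0.5, rep(0.5, 6)), keys))
  a <- setNames(rep(0, 8), keys)
  a["woodland"] <- 2
  expect_equal(eri(a, cfg2), 4 * 0.5)          # single-class unit
  a["grass_high"] <- 2
  expect_equal(eri(a, cfg2), (2 + 4) / 2)      # half E.F=2, half E.F=4
  expect_true(is.na(eri(setNames(rep(0, 8), keys), cfg2)))  # empty unit
})

test_that("ERI of a mixed unit lies between the extreme class products", {
  keys <- land_use_classes()$key
  ef <- cfg$e_i * cfg$f_i
  set.seed(8)
  for (rep in 1:20) {
    a <- setNames(runif(8), keys)
    v <- eri(a, cfg)
    expect_gte(v, min(ef) - 1e-12)
    expect_lte(v, max(ef) + 1e-12)
  }
})

test_that("ECO_res follows area x elasticity / fragmentation", {
  # one class, one patch, area 10 km^2, P = 2 -> C = 0.1, ECO_res = 200
  keys <- land_use_classes()$key
  cfg2 <- indicator_config(p_i = setNames(c(2, rep(1, 7)), keys))
  patches <- data.frame(class = keys, code = 1:8, n_patches = c(1, rep(0, 7)),
                        area_km2 = c(10, rep(0, 7)), c_i = c(0.1, rep(NA, 7)))
  expect_equal(eco_res(patches, cfg2), 200)
  # doubling every elasticity doubles the result
  cfg3 <- indicator_config(p_i = setNames(c(4, rep(2, 7)), keys))
  expect_equal(eco_res(patches, cfg3), 400)
  # splitting the patch into two doubles C and halves the contribution
  patches2 <- patches; patches2$n_patches[1] <- 2; patches2$c_i[1] <- 0.2
  expect_equal(eco_res(patches2, cfg2), 100)
})

test_that("ESV is the coefficient-weighted area sum", {
  keys <- land_use_classes()$key
  cfg2 <- indicator_config(vc_i = setNames(c(5, rep(0, 7)), keys))
  a <- setNames(rep(0, 8), keys)
  expect_equal(esv(a, cfg2), 0)
  a["woodland"] <- 2
  expect_equal(esv(a, cfg2), 10)
  a["construction"] <- 100  # zero-VC class leaves ESV unchanged
  expect_equal(esv(a, cfg2), 10)
  expect_error(indicator_config(vc_i = setNames(c(-1, rep(1, 7)), keys)),
               "negative")
})

test_that("non-ecological proportion follows the legend split", {
  keys <- land_use_classes()$key
  water <- setNames(c(rep(0, 4), 1, 0, 0, 0), keys)
  expect_equal(nonecological_proportion(water), 0)
  constr <- setNames(c(rep(0, 6), 1, 0), keys)
  expect_equal(nonecological_proportion(constr), 1)
  half <- setNames(c(1, rep(0, 4), 1, 0, 0), keys)
  expect_equal(nonecological_proportion(half), 0.5)
})

test_that("AHP recovers weights from consistent matrices", {
  r <- ahp_weights(matrix(1, 3, 3))
  expect_equal(r$weights, rep(1 / 3, 3))
  expect_equal(r$cr, 0)

  w <- c(0.5, 0.25, 0.25)
  m <- outer(w, w, "/")
  r <- ahp_weights(m)
  expect_lt(max(abs(r$weights - w)), 1e-10)
  expect_lt(abs(r$cr), 1e-10)

  expect_equal(ahp_weights(matrix(c(1, 2, 0.5, 1), 2, 2))$cr, 0)
  bad <- matrix(c(1, 2, 3, 1), 2, 2)
  expect_error(ahp_weights(bad), "reciprocal")
})

test_that("AHP recovery holds across random consistent matrices", {
  set.seed(13)
  for (n in c(3, 5, 8)) for (rep in 1:5) {
    w <- runif(n); w <- w / sum(w)
    r <- ahp_weights(outer(w, w, "/"))
    expect_lt(max(abs(r$weights - w)), 1e-10)
    expect_lte(r$cr, 1e-10)
    expect_true(r$consistent)
  }
})

test_that("inconsistent judgements are flagged by CR", {
  m <- matrix(c(1, 9, 1 / 9,
                1 / 9, 1, 9,
                9, 1 / 9, 1), 3, 3, byrow = TRUE)  # cyclic preferences
  r <- ahp_weights(m)
  expect_gt(r$cr, 0.1)
  expect_false(r$consistent)
})

test_that("the aggregated index honours the two-level weighted sum", {
  all1 <- setNames(rep(1, 11), c("D1", "D2", "P1", "P2", "S1", "S2", "S3",
                                 "I1", "I2", "I3", "R1"))
  expect_equal(aggregate_index(all1, cfg)$index, 1)
  expect_equal(aggregate_index(all1 * 0, cfg)$index, 0)
  # single live indicator: y(I1) = 1, rest 0 -> 0.5 x 0.5 = 0.25
  y <- all1 * 0; y["I1"] <- 1
  expect_equal(aggregate_index(y, cfg)$index, 0.25)
  bad <- cfg; bad$dimension_weights["D"] <- 0.5
  expect_error(aggregate_index(all1, bad), "sum to 1")
})

test_that("missing indicators renormalize weights instead of dragging to 0", {
  y <- setNames(rep(0.5, 11), c("D1", "D2", "P1", "P2", "S1", "S2", "S3",
                                "I1", "I2", "I3", "R1"))
  y[c("S1", "S2", "D1")] <- NA
  r <- aggregate_index(y, cfg)
  expect_equal(r$index, 0.5)   # every observed indicator is 0.5
  y2 <- y; y2[c("D1", "D2")] <- NA  # whole dimension missing
  expect_equal(aggregate_index(y2, cfg)$index, 0.5)
})

test_that("the index is bounded and monotone in positive indicators", {
  nm <- c("D1", "D2", "P1", "P2", "S1", "S2", "S3", "I1", "I2", "I3", "R1")
  set.seed(31)
  for (rep in 1:50) {
    y <- setNames(runif(11), nm)
    r <- aggregate_index(y, cfg)$index
    expect_gte(r, 0); expect_lte(r, 1)
    k <- sample(11, 1)
    y2 <- y; y2[k] <- min(1, y2[k] + runif(1, 0, 1 - y2[k]))
    expect_gte(aggregate_index(y2, cfg)$index, r - 1e-12)
  }
})
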