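# Driver: compute every DPSIR indicator per assessment unit and year, pool
# the normalization, and aggregate the eco-security index.
#
# Spatial resolution follows the assessment design: D, P and R indicators
# derive from citywide statistics and are constant across units within a
# year; S and I indicators are computed per unit from the land-use state and
# its change. Indicators are normalized over the pooled set of all units and
# all years jointly so indices are comparable across time.

UNIT_INDICATORS <- c("S1", "S2", "S3", "I1", "I2", "I3")
SCALAR_INDICATORS <- c("D1", "D2", "P1", "P2", "R1")

# Degradation / restoration transition lookup over (from, to) code pairs.
transition_kind <- function() {
  deg <- matrix(FALSE, 8, 8); res <- matrix(FALSE, 8, 8)
  for (g in grassland_codes()) {
    deg[g, degradation_targets(g)] <- TRUE
    res[g, restoration_targets(g)] <- TRUE
  }
  list(deg = deg, res = res)
}

# Per-unit pooled grassland intensities between two co-registered grids.
# Cell counts cancel in the ratio, so areas need no unit conversion here.
unit_grass_intensities <- function(prev, cur, uid, n_units, dt) {
  tk <- transition_kind()
  ok <- !is.na(prev) & !is.na(cur)
  grass <- ok & prev %in% grassland_codes()
  s_it <- tabulate(uid[grass], nbins = n_units)
  # index the transition lookup only on grassland cells
  gidx <- which(grass)
  is_deg <- tk$deg[cbind(prev[gidx], cur[gidx])]
  is_res <- tk$res[cbind(prev[gidx], cur[gidx])]
  deg <- tabulate(uid[gidx][is_deg], nbins = n_units)
  res <- tabulate(uid[gidx][is_res], nbins = n_units)
  k1 <- ifelse(s_it > 0, deg / s_it / dt, NA_real_)
  k2 <- ifelse(s_it > 0, res / s_it / dt, NA_real_)
  list(k1 = k1, k2 = k2)
}

# Per-unit ECO_res: patch statistics restricted to each unit's cell block.
unit_eco_res <- function(grid, units, config, connectivity = 8) {
  u <- units$units
  ca <- cell_area_km2(grid)
  vapply(seq_len(nrow(u)), function(i) {
    sub <- grid$codes[u$row0[i]:u$row1[i], u$col0[i]:u$col1[i], drop = FALSE]
    if (all(is.na(sub))) return(NA_real_)
    total <- 0
    for (code in 1:8) {
      mask <- !is.na(sub) & sub == code
      n_cells <- sum(mask)
      if (n_cells == 0) next
      np <- count_patches(mask, connectivity)
      a <- n_cells * ca
      total <- total + a * config$p_i[[code]] / (np / a)
    }
    total
  }, numeric(1))
}

#' Run the full DPSIR eco-security assessment
#'
#' Computes all eleven indicators for every assessment unit and year,
#' normalizes each indicator over the pooled set of all units and years
#' (scalar city-level indicators over all years), and aggregates the
#' two-level weighted index. Change indicators (D1, S1, S2) refer to the
#' step ending at each year and are missing for the first year; missing
#' indicators have their weights renormalized within their dimension.
#'
#' @param series Named list of `land_use_grid` (one per year, identical
#'   geometry, numeric year labels).
#' @param socio A `socioeconomic_series` covering all years.
#' @param unit_size_m Assessment unit edge (default 1000 m).
#' @param config An `indicator_config`.
#' @param connectivity Patch connectivity for ECO_res (4 or 8).
#' @return A `security_assessment` list: `$indicators` (long data.frame:
#'   unit, year, indicator, raw, normalized), `$index` (unit, year,
#'   dimension sub-indices, index), `$units` (the tessellation of the final
#'   year, with quadrants), `$years`, `$config`, `$ranges`.
#' @export
assess_security <- function(series, socio, unit_size_m = 1000,
                            config = indicator_config(), connectivity = 8) {
  years <- unname(vapply(series, function(g) as.numeric(g$year), numeric(1)))
  if (any(is.na(years)) || any(diff(years) <= 0))
    stop("grids must carry strictly increasing numeric year labels")
  for (k in seq_along(series)[-1]) stop_geometry(series[[1]], series[[k]])
  ny <- length(series)
  tess <- lapply(series, tessellate, unit_size_m = unit_size_m)
  n_units <- nrow(tess[[1]]$units)
  f <- tess[[1]]$cell_factor
  nr <- tess[[1]]$geometry$nrow; nc <- tess[[1]]$geometry$ncol
  uid <- matrix((seq_len(nr) - 1L) %/% f + 1L, nr, nc) +
    (matrix((seq_len(nc) - 1L) %/% f, nr, nc, byrow = TRUE)) * tess[[1]]$n_urow

  ef <- config$e_i * config$f_i
  noneco <- !land_use_classes()$ecological

  raw <- list()   # raw[[indicator]] = n_units x ny matrix
  for (ind in UNIT_INDICATORS) raw[[ind]] <- matrix(NA_real_, n_units, ny)
  scal <- matrix(NA_real_, length(SCALAR_INDICATORS), ny,
                 dimnames = list(SCALAR_INDICATORS, NULL))

  for (k in seq_len(ny)) {
    areas <- tess[[k]]$areas
    valid <- rowSums(areas)
    raw$I1[, k] <- ifelse(valid > 0, as.numeric(areas %*% ef) / valid, NA)
    raw$I3[, k] <- as.numeric(areas %*% config$vc_i)
    raw$S3[, k] <- ifelse(valid > 0, rowSums(areas[, noneco, drop = FALSE]) / valid, NA)
    raw$I2[, k] <- unit_eco_res(series[[k]], tess[[k]], config, connectivity)
    if (k > 1) {
      dt <- years[k] - years[k - 1]
      ks <- unit_grass_intensities(series[[k - 1]]$codes, series[[k]]$codes,
                                   uid, n_units, dt)
      raw$S1[, k] <- ks$k1
      raw$S2[, k] <- ks$k2
      scal[, k] <- socio_indicators(socio, years[k - 1], years[k],
                                    config$epi_categories)
    } else {
      scal[, k] <- socio_indicators(socio, years[k], years[k],
                                    config$epi_categories)
    }
  }

  # pooled normalization ranges
  ranges <- list()
  norm <- list()
  for (ind in UNIT_INDICATORS) {
    v <- raw[[ind]]
    rng <- suppressWarnings(range(v, na.rm = TRUE))
    ranges[[ind]] <- rng
    norm[[ind]] <- if (all(is.na(v))) v else {
      if (rng[2] > rng[1])
        matrix(minmax_normalize(as.vector(v), config$polarity[[ind]], rng),
               n_units, ny)
      else suppressWarnings(
        matrix(minmax_normalize(as.vector(v), config$polarity[[ind]], rng),
               n_units, ny))
    }
  }
  scal_norm <- scal
  for (ind in SCALAR_INDICATORS) {
    v <- scal[ind, ]
    rng <- suppressWarnings(range(v, na.rm = TRUE))
    ranges[[ind]] <- rng
    scal_norm[ind, ] <- if (all(is.na(v))) v else
      suppressWarnings(minmax_normalize(v, config$polarity[[ind]], rng))
  }

  # aggregate
  idx <- expand.grid(unit = seq_len(n_units), year = years)
  idx$index <- NA_real_
  dims <- names(config$dimension_weights)
  for (d in dims) idx[[d]] <- NA_real_
  for (k in seq_len(ny)) {
    for (u in seq_len(n_units)) {
      y <- c(stats::setNames(vapply(UNIT_INDICATORS, function(i) norm[[i]][u, k],
                                    numeric(1)), UNIT_INDICATORS),
             stats::setNames(scal_norm[, k], SCALAR_INDICATORS))
      agg <- aggregate_index(y, config)
      row <- (k - 1) * n_units + u
      idx$index[row] <- agg$index
      for (d in dims) idx[[d]][row] <- agg$dimensions[[d]]
    }
  }

  long <- do.call(rbind, lapply(seq_len(ny), function(k) {
    unit_part <- do.call(rbind, lapply(UNIT_INDICATORS, function(i)
      data.frame(unit = seq_len(n_units), year = years[k], indicator = i,
                 raw = raw[[i]][, k], normalized = norm[[i]][, k])))
    scal_part <- do.call(rbind, lapply(SCALAR_INDICATORS, function(i)
      data.frame(unit = NA_integer_, year = years[k], indicator = i,
                 raw = scal[i, k], normalized = scal_norm[i, k])))
    rbind(unit_part, scal_part)
  }))

  structure(list(indicators = long, index = idx,
                 units = assign_quadrants(tess[[ny]]),
                 years = years, config = config, ranges = ranges),
            class = "security_assessment")
}

#' @export
print.security_assessment <- function(x, ...) {
  cat(sprintf("<security_assessment> %d units x %d years\n",
              nrow(x$units$units), length(x$years)))
  print(index_trend(x))
  invisible(x)
}

#' Security-index values of one year as a unit-lattice matrix
#'
#' @param assessment A `security_assessment`.
#' @param year One of the assessed years.
#' @return Matrix (n_urow x n_ucol) of index values, NA for empty units.
#' @export
index_matrix <- function(assessment, year) {
  k <- match(year, assessment$years)
  if (is.na(k)) stop("year not assessed: ", year)
  v <- assessment$index$index[assessment$index$year == year]
  matrix(v, assessment$units$n_urow, assessment$units$n_ucol)
}

#' Area-weighted whole-area index per year
#' @param assessment A `security_assessment`.
#' @return data.frame(year, index).
#' @export
index_trend <- function(assessment) {
  a_k <- assessment$units$units$a_k
  out <- vapply(assessment$years, function(y) {
    v <- assessment$index$index[assessment$index$year == y]
    ok <- !is.na(v)
    sum(v[ok] * a_k[ok]) / sum(a_k[ok])
  }, numeric(1))
  data.frame(year = assessment$years, index = out)
}

#' Export the tidy indicator table as CSV
#' @param assessment A `security_assessment`.
#' @param path Output path.
#' @export
write_indicators_csv <- function(assessment, path) {
  utils::write.csv(assessment$indicators, path, row.names = FALSE)
  invisible(path)
}
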