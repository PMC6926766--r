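# Time-space overlay zoning and minimum-cumulative-resistance (MCR)
# delineation of protection areas.

#' Zone legend
#'
#' Integer codes for the risk/protection zones. The risk warning area is the
#' union of the five `warning` zones (derived from persistent cold-spot
#' patterns); the protection area unions the `protection` zones (ecological
#' sources, ideal protection, buffer and conflict).
#'
#' @return data.frame with columns `code`, `key`, `label`, `group`.
#' @export
zone_table <- function() {
  data.frame(
    code = 1:11,
    key = c("core_restoration", "key_restoration", "risk_prevention",
            "risk_supervisory", "ecological_potential", "ideal_protection",
            "core_protection", "bottomline_protection", "ecological_buffer",
            "ecological_conflict", "other"),
    label = c("Core restoration", "Key restoration", "Risk prevention",
              "Risk supervisory", "Ecological potential", "Ideal protection",
              "Core protection", "Bottom-line protection", "Ecological buffer",
              "Ecological conflict", "Other"),
    group = c(rep("warning", 5), rep("protection", 5), "other"),
    stringsAsFactors = FALSE
  )
}

zone_code <- function(key) {
  zt <- zone_table()
  stats::setNames(zt$code, zt$key)[key]
}

#' Resistance value tables
#'
#' The two ranked resistance maps combined into the resistance surface:
#' per land-use class (water 1 ... construction 8) and per overlay zone
#' (core/bottom-line protection 1 ... core restoration 8; buffer, conflict
#' and unzoned cells count as "other area", rank 4), each weighted 0.5.
#'
#' @return List with `land` (named by class key), `zone` (named by zone
#'   key), and `weights`.
#' @export
resistance_config <- function() {
  list(
    land = c(water = 1, woodland = 2, grass_high = 3, grass_medium = 4,
             grass_low = 5, farmland = 6, saline_alkali = 7, construction = 8),
    zone = c(core_protection = 1, bottomline_protection = 1,
             ecological_potential = 2, ideal_protection = 3, other = 4,
             ecological_buffer = 4, ecological_conflict = 4,
             risk_supervisory = 5, risk_prevention = 6,
             key_restoration = 7, core_restoration = 8),
    weights = c(land = 0.5, zone = 0.5)
  )
}

# ---- Overlay partition --------------------------------------------------

grade_state <- function(grade) {
  g <- as.character(grade)
  ifelse(startsWith(g, "hot"), "hot", ifelse(startsWith(g, "cold"), "cold", "ns"))
}

#' Default overlay rule table
#'
#' Explicit, overridable lookup covering every (earlier-year state, final-year
#' grade, optimized state) triple. Defaults: persistent hot -> core
#' protection (promoted to bottom-line protection for water-dominated units
#' at partition time); hot in the final year only -> ideal protection; not
#' significant both years but optimized-hot -> ecological potential; cold in
#' the final year only -> risk supervisory; persistent cold graded by the
#' final-year intensity -> risk prevention / key restoration / core
#' restoration; everything else -> other.
#'
#' @return data.frame with columns `y1_state`, `y2_grade`, `opt_state`,
#'   `zone` (zone key).
#' @export
default_overlay_rules <- function() {
  tri <- expand.grid(y1_state = c("hot", "cold", "ns"),
                     y2_grade = GRADE_LEVELS,
                     opt_state = c("hot", "cold", "ns"),
                     stringsAsFactors = FALSE)
  y2s <- grade_state(tri$y2_grade)
  zone <- rep("other", nrow(tri))
  zone[tri$y1_state == "hot" & y2s == "hot"] <- "core_protection"
  zone[tri$y1_state != "hot" & y2s == "hot"] <- "ideal_protection"
  zone[tri$y1_state == "ns" & y2s == "ns" & tri$opt_state == "hot"] <-
    "ecological_potential"
  zone[tri$y1_state != "cold" & y2s == "cold"] <- "risk_supervisory"
  pc <- tri$y1_state == "cold" & y2s == "cold"
  zone[pc & tri$y2_grade == "cold-low"] <- "risk_prevention"
  zone[pc & tri$y2_grade == "cold-middle"] <- "key_restoration"
  zone[pc & tri$y2_grade == "cold-high"] <- "core_restoration"
  tri$zone <- zone
  tri
}

#' Overlay two yearly hotspot fields and an optimized field into zones
#'
#' Applies the rule table to every unit's grade triple, then promotes
#' persistent-hot units whose dominant land-use class is water from core
#' protection to bottom-line protection. The unit-level result is
#' materialized at cell level by broadcasting each unit's zone over its cell
#' block, so later land-use-dependent rules act on cells.
#'
#' @param hotspots_y1,hotspots_y2 `hotspot_field`s of the two overlay years.
#' @param optimized_y2 Optimized `hotspot_field` of the final year.
#' @param units The `assessment_units` (with `$areas` of the final year).
#' @param rules Rule table as from [default_overlay_rules()].
#' @return A `zone_map`: `$unit_zone` (zone code per unit), `$cell_codes`
#'   (zone-code matrix), `$geometry`, `$cell_size_m`.
#' @export
overlay_partition <- function(hotspots_y1, hotspots_y2, optimized_y2, units,
                              rules = default_overlay_rules()) {
  n <- nrow(units$units)
  if (nrow(hotspots_y1) != n || nrow(hotspots_y2) != n || nrow(optimized_y2) != n)
    stop("hotspot fields and units disagree in length")
  need <- c("y1_state", "y2_grade", "opt_state", "zone")
  if (!all(need %in% names(rules))) stop("malformed rule table")
  key <- function(a, b, c) paste(a, b, c, sep = "|")
  lut <- stats::setNames(rules$zone, key(rules$y1_state, rules$y2_grade, rules$opt_state))
  triples <- key(grade_state(hotspots_y1$grade), as.character(hotspots_y2$grade),
                 grade_state(optimized_y2$grade))
  miss <- setdiff(unique(triples), names(lut))
  if (length(miss))
    stop("rule table does not cover: ", paste(miss, collapse = "; "))
  zkey <- lut[triples]
  # bottom-line promotion: persistent-hot units dominated by water
  dominant <- max.col(units$areas, ties.method = "first")
  water <- which(land_use_classes()$key == "water")
  promote <- zkey == "core_protection" & dominant == water &
    units$areas[cbind(seq_len(n), dominant)] > 0
  zkey[promote] <- "bottomline_protection"
  unit_zone <- as.integer(zone_code(zkey))
  cell_codes <- broadcast_units(unit_zone, units)
  structure(list(unit_zone = unit_zone, cell_codes = cell_codes,
                 geometry = units$geometry,
                 cell_size_m = units$geometry$cell_size_m),
            class = "zone_map")
}

# Broadcast a per-unit integer label onto the cell raster.
broadcast_units <- function(values, units) {
  g <- units$geometry
  f <- units$cell_factor
  uid <- matrix((seq_len(g$nrow) - 1L) %/% f + 1L, g$nrow, g$ncol) +
    (matrix((seq_len(g$ncol) - 1L) %/% f, g$nrow, g$ncol, byrow = TRUE)) * units$n_urow
  matrix(values[uid], g$nrow, g$ncol)
}

#' @export
print.zone_map <- function(x, ...) {
  cat("<zone_map>\n")
  print(area_report(x)$areas)
  invisible(x)
}

# ---- Resistance surface and cost distance -------------------------------

#' Build the resistance surface
#'
#' Per-cell weighted sum of the land-use resistance rank and the
#' overlay-zone resistance rank (weights 0.5/0.5 by default), giving values
#' in \[1, 8\]. NA wherever land use is nodata.
#'
#' @param grid A `land_use_grid`.
#' @param overlay_zones A `zone_map` co-registered with `grid`.
#' @param config A [resistance_config()] list.
#' @return Numeric matrix of resistances.
#' @export
build_resistance <- function(grid, overlay_zones, config = resistance_config()) {
  if (!identical(dim(grid$codes), dim(overlay_zones$cell_codes)))
    stop("grid and overlay zones are not co-registered")
  keys <- land_use_classes()$key
  if (!all(keys %in% names(config$land)))
    stop("land resistance table must cover all 8 classes")
  zt <- zone_table()
  if (!all(zt$key %in% names(config$zone)))
    stop("zone resistance table must cover all zones")
  land_r <- config$land[keys][grid$codes]
  zone_r <- config$zone[zt$key][overlay_zones$cell_codes]
  r <- config$weights[["land"]] * land_r + config$weights[["zone"]] * zone_r
  matrix(r, nrow(grid$codes))
}

#' Minimum-cumulative-resistance cost distance
#'
#' Exact Dijkstra shortest-path accumulation over the cell graph
#' (8-connected by default): the cost of a step between two cells is the
#' mean of their resistances times the step length (cell size, x sqrt(2)
#' diagonally), and the cost of a cell is the minimum accumulated cost over
#' paths from any source cell. Source cells cost 0; unreachable cells +Inf.
#'
#' @param resistance Numeric matrix of positive per-cell resistances (NA =
#'   impassable).
#' @param sources Logical matrix (same shape) or integer cell indices.
#' @param cell_size_m Step length scale.
#' @param connectivity 4 or 8.
#' @return Numeric matrix of accumulated costs.
#' @export
mcr_cost_distance <- function(resistance, sources, cell_size_m = 1,
                              connectivity = 8) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  if (is.logical(sources)) sources <- which(sources)
  sources <- as.integer(sources)
  if (!length(sources)) stop("empty source set")
  if (any(resistance[!is.na(resistance)] <= 0))
    stop("resistances must be positive")
  valid <- which(!is.na(resistance))
  if (!all(sources %in% valid)) stop("sources must lie on valid cells")
  vid <- rep(NA_integer_, nr * nc)
  vid[valid] <- seq_along(valid)
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  else if (connectivity != 4) stop("connectivity must be 4 or 8")
  rc <- arrayInd(valid, c(nr, nc))
  ii <- integer(0); jj <- integer(0); wt <- numeric(0)
  for (s in shifts) {
    r2 <- rc[, 1] + s[1]; c2 <- rc[, 2] + s[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    tgt <- ifelse(ok, (c2 - 1) * nr + r2, NA_integer_)
    ok[ok] <- !is.na(vid[tgt[ok]])
    if (!any(ok)) next
    len <- cell_size_m * sqrt(sum(s^2))
    ii <- c(ii, vid[valid[ok]])
    jj <- c(jj, vid[tgt[ok]])
    wt <- c(wt, (resistance[valid[ok]] + resistance[tgt[ok]]) / 2 * len)
  }
  nv <- length(valid)
  # virtual super-source (vertex nv + 1) with zero-cost links to all sources
  el <- rbind(cbind(ii, jj), cbind(rep(nv + 1L, length(sources)), vid[sources]))
  w <- c(wt, rep(0, length(sources)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < nv + 1)
    g <- igraph::add_vertices(g, nv + 1 - igraph::vcount(g))
  d <- as.numeric(igraph::distances(g, v = nv + 1, weights = w,
                                    algorithm = "dijkstra"))[seq_len(nv)]
  out <- matrix(NA_real_, nr, nc)
  out[valid] <- d
  out
}

# ---- Protection partition and area accounting ---------------------------

#' Delineate the protection area from cost fields
#'
#' The protection area is the union of cells whose accumulated cost from
#' the core sources (core + bottom-line protection) is below the core
#' threshold, cells below the potential-source threshold, the source cells
#' themselves and the ideal-protection zones. Within it, source and ideal
#' cells retain their zone labels; remaining farmland and construction
#' cells become ecological conflict; the rest becomes ecological buffer.
#' Cells outside the protection area are labelled "other".
#'
#' @param cost_core,cost_potential Cost matrices from [mcr_cost_distance()]
#'   for the core and potential source sets.
#' @param grid The `land_use_grid` (for the conflict classes).
#' @param overlay_zones The overlay `zone_map` (supplies source and ideal
#'   cells).
#' @param thresholds `c(core = 30000, potential = 14000)` in
#'   resistance x metres units.
#' @return A `zone_map` of the protection partition.
#' @export
protection_partition <- function(cost_core, cost_potential, grid, overlay_zones,
                                 thresholds = c(core = 30000, potential = 14000)) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  zc <- overlay_zones$cell_codes
  retained <- c("core_protection", "bottomline_protection",
                "ecological_potential", "ideal_protection")
  keep <- matrix(zc %in% zone_code(retained), nrow(zc))
  prot <- keep |
    (!is.na(cost_core) & cost_core < thresholds[["core"]]) |
    (!is.na(cost_potential) & cost_potential < thresholds[["potential"]])
  out <- matrix(zone_code("other"), nrow(zc), ncol(zc))
  conflict <- prot & !keep & !is.na(grid$codes) & grid$codes %in% c(6L, 7L)
  buffer <- prot & !keep & !conflict
  out[keep] <- zc[keep]
  out[conflict] <- zone_code("ecological_conflict")
  out[buffer] <- zone_code("ecological_buffer")
  out[is.na(grid$codes)] <- NA_integer_
  structure(list(unit_zone = NULL, cell_codes = out,
                 geometry = overlay_zones$geometry,
                 cell_size_m = overlay_zones$cell_size_m),
            class = "zone_map")
}

#' Zone area report
#'
#' km^2 per zone plus the two grouped totals: the risk warning total (core
#' and key restoration, risk prevention, risk supervisory, ecological
#' potential) and the protection total (ideal, core and bottom-line
#' protection, ecological buffer, ecological conflict). Totals are sums of
#' their member zones, so the report is internally consistent by
#' construction; the per-zone areas reconcile exactly with the classified
#' cell counts.
#'
#' @param zonemap A `zone_map`.
#' @return List with `areas` (data.frame zone/label/area_km2),
#'   `warning_km2`, `protection_km2`, `total_km2`.
#' @export
area_report <- function(zonemap) {
  zt <- zone_table()
  ca <- (zonemap$cell_size_m / 1000)^2
  counts <- tabulate(zonemap$cell_codes[!is.na(zonemap$cell_codes)],
                     nbins = nrow(zt))
  areas <- data.frame(zone = zt$key, label = zt$label, group = zt$group,
                      area_km2 = counts * ca, stringsAsFactors = FALSE)
  list(areas = areas,
       warning_km2 = sum(areas$area_km2[areas$group == "warning"]),
       protection_km2 = sum(areas$area_km2[areas$group == "protection"]),
       total_km2 = sum(areas$area_km2))
}

#' Write a zone map as an ESRI ASCII raster of zone codes
#' @param zonemap A `zone_map`.
#' @param path Output path.
#' @export
write_zone_asc <- function(zonemap, path) {
  g <- zonemap$geometry
  geom <- list(cell_size_m = g$cell_size_m, xll = g$xll, yll = g$yll)
  write_field_asc(zonemap$cell_codes, geom, path)
  invisible(path)
}
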