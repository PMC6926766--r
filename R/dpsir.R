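# DPSIR composite landscape eco-security index.
#
# Five weighted dimensions (Driving forces, Pressure, State, Impact,
# Response) holding eleven indicators; indicator values are min-max
# normalized with polarity over a pooled set and aggregated with a two-level
# weighted sum into an index in [0, 1] (higher = more secure).

#' Indicator configuration: weights, polarities and coefficient tables
#'
#' Dimension and indicator weights follow the published AHP-derived
#' assessment system (D 0.05, P 0.2, S 0.2, I 0.5, R 0.05; within-dimension
#' weights as printed, polarities as printed). The four per-class
#' coefficient tables (interference E_i, vulnerability F_i, elasticity P_i,
#' ecosystem-service value VC_i per km^2) are documented synthetic stand-ins
#' ordered by ecological intuition (construction and saline-alkali land:
#' high interference/vulnerability, low elasticity; water and woodland:
#' high service value); every value is overridable.
#'
#' @param dimension_weights Named weights over D, P, S, I, R (sum 1).
#' @param indicator_weights Named list: per dimension, named indicator
#'   weights summing to 1.
#' @param polarity Named "+"/"-" per indicator.
#' @param e_i,f_i,p_i,vc_i Named numeric vectors over the 8 class keys.
#' @param epi_categories Pollutant/consumption category names used by the
#'   environmental performance index; each needs `<cat>_city` and
#'   `<cat>_national` columns in the socio-economic series.
#' @return An `indicator_config` object.
#' @export
indicator_config <- function(
    dimension_weights = c(D = 0.05, P = 0.2, S = 0.2, I = 0.5, R = 0.05),
    indicator_weights = list(
      D = c(D1 = 0.5, D2 = 0.5),
      P = c(P1 = 0.5, P2 = 0.5),
      S = c(S1 = 0.25, S2 = 0.25, S3 = 0.5),
      I = c(I1 = 0.5, I2 = 0.25, I3 = 0.25),
      R = c(R1 = 1)),
    polarity = c(D1 = "+", D2 = "+", P1 = "+", P2 = "+",
                 S1 = "-", S2 = "+", S3 = "-",
                 I1 = "-", I2 = "+", I3 = "+", R1 = "+"),
    e_i = c(woodland = 2, grass_high = 2, grass_medium = 3, grass_low = 4,
            water = 1, farmland = 5, construction = 8, saline_alkali = 7),
    f_i = c(woodland = 0.3, grass_high = 0.4, grass_medium = 0.5, grass_low = 0.6,
            water = 0.2, farmland = 0.6, construction = 0.8, saline_alkali = 0.9),
    p_i = c(woodland = 0.9, grass_high = 0.8, grass_medium = 0.6, grass_low = 0.4,
            water = 0.7, farmland = 0.4, construction = 0.1, saline_alkali = 0.15),
    vc_i = c(woodland = 25, grass_high = 15, grass_medium = 10, grass_low = 5,
             water = 40, farmland = 6, construction = 0, saline_alkali = 1),
    epi_categories = c("wastewater", "energy")) {
  keys <- land_use_classes()$key
  if (abs(sum(dimension_weights) - 1) > 1e-8)
    stop("dimension weights must sum to 1")
  for (d in names(indicator_weights))
    if (abs(sum(indicator_weights[[d]]) - 1) > 1e-8)
      stop("indicator weights within dimension ", d, " must sum to 1")
  if (!all(polarity %in% c("+", "-"))) stop("polarities must be '+' or '-'")
  for (tab in list(e_i = e_i, f_i = f_i, p_i = p_i, vc_i = vc_i)) {
    if (!all(keys %in% names(tab)))
      stop("coefficient tables must cover all 8 classes")
  }
  if (any(vc_i < 0)) stop("negative ESV coefficient")
  structure(list(dimension_weights = dimension_weights,
                 indicator_weights = indicator_weights,
                 polarity = polarity,
                 e_i = e_i[keys], f_i = f_i[keys], p_i = p_i[keys],
                 vc_i = vc_i[keys], epi_categories = epi_categories),
            class = "indicator_config")
}

#' Min-max normalization with polarity
#'
#' Positive polarity: y = (x - min)/(max - min); negative polarity reverses
#' the scale: y = (max - x)/(max - min). The normalization range defaults to
#' the range of `values` but should be supplied when normalizing over a
#' pooled set (all units and years jointly). A degenerate range (max == min)
#' maps every value to 0.5 with a warning.
#'
#' @param values Numeric vector (NAs propagate).
#' @param polarity "+" or "-".
#' @param range Optional `c(min, max)` of the pooled normalization set.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(values, polarity = "+", range = NULL) {
  if (is.null(range)) range <- range(values, na.rm = TRUE)
  lo <- range[1]; hi <- range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    warning("degenerate normalization range; mapping all values to 0.5")
    return(ifelse(is.na(values), NA_real_, 0.5))
  }
  y <- (values - lo) / (hi - lo)
  if (polarity == "-") y <- 1 - y
  pmin(pmax(y, 0), 1)
}

#' City-level DPSIR indicators from the socio-economic series
#'
#' For a pair of years (a = earlier, b = later) computes the driving-force,
#' pressure and response indicators: urbanization growth intensity
#' UGI = (U_bd - U_ad)/(U_b - U_a); per-capita GDP; the resource-curse
#' coefficient ES = (city oil share of national production)/(city
#' secondary-industry share of national output); the environmental
#' performance index EPI = mean over categories of (x_i/g_d)/(X_i/G); and
#' the ecological-construction investment intensity IEC = EI_d/g_d.
#' UGI is undefined (NA) when the national urbanization index did not
#' change.
#'
#' @param series A `socioeconomic_series`.
#' @param year_a,year_b The two years (both must be rows of the series);
#'   D2/P1/P2/R1 are evaluated at `year_b`.
#' @param epi_categories Category names, see [indicator_config()].
#' @return Named numeric vector `c(D1, D2, P1, P2, R1)`.
#' @export
socio_indicators <- function(series, year_a, year_b,
                             epi_categories = c("wastewater", "energy")) {
  row_of <- function(y) {
    i <- match(y, series$year)
    if (is.na(i)) stop("year ", y, " missing from the socio-economic series")
    series[i, ]
  }
  a <- row_of(year_a); b <- row_of(year_b)
  d_nat <- b$urban_national - a$urban_national
  ugi <- if (abs(d_nat) < .Machine$double.eps) NA_real_
         else (b$urban_city - a$urban_city) / d_nat
  if (b$city_gdp <= 0 || b$national_gdp <= 0) stop("non-positive GDP")
  es <- (b$oil_production / b$national_oil) / (b$si_city / b$si_national)
  epi <- mean(vapply(epi_categories, function(cat) {
    x <- b[[paste0(cat, "_city")]]; X <- b[[paste0(cat, "_national")]]
    if (is.null(x) || is.null(X))
      stop("missing EPI category columns for '", cat, "'")
    (x / b$city_gdp) / (X / b$national_gdp)
  }, numeric(1)))
  c(D1 = ugi, D2 = b$city_gdp / b$city_population, P1 = es, P2 = epi,
    R1 = b$eco_investment / b$city_gdp)
}

#' Ecological risk index of one assessment unit
#'
#' ERI_k = sum_i (A_ki/A_k) (E_i x F_i): the area-share weighted mean of the
#' per-class interference-times-vulnerability products, so a mixed unit's
#' risk always lies between the extreme per-class products. Units with no
#' valid area return NA.
#'
#' @param areas_ki Named per-class areas of the unit (km^2).
#' @param config An `indicator_config`.
#' @return Scalar ERI (NA if the unit has no valid area).
#' @export
eri <- function(areas_ki, config) {
  keys <- land_use_classes()$key
  if (!all(keys %in% names(areas_ki))) stop("areas must cover all 8 classes")
  a <- as.numeric(areas_ki[keys])
  total <- sum(a)
  if (total <= 0) return(NA_real_)
  sum(a / total * (config$e_i * config$f_i))
}

#' Ecological resilience from patch statistics
#'
#' ECO_res = sum_i A_i x P_i / C_i over the classes present, with P_i the
#' elasticity score and C_i the fragmentation index: large, unfragmented
#' areas of elastic land contribute most.
#'
#' @param patches A [patch_stats()] data.frame.
#' @param config An `indicator_config`.
#' @return Scalar ECO_res.
#' @export
eco_res <- function(patches, config) {
  present <- patches$area_km2 > 0
  if (!any(present)) return(0)
  p <- config$p_i[patches$class[present]]
  c_i <- patches$c_i[present]
  if (any(!is.finite(c_i) | c_i <= 0))
    stop("fragmentation index must be positive for classes with area")
  sum(patches$area_km2[present] * p / c_i)
}

#' Ecosystem service value of a set of class areas
#'
#' ESV = sum_i A_i x VC_i with VC_i the per-km^2 service-value coefficient.
#'
#' @param areas Named per-class areas (km^2).
#' @param config An `indicator_config`.
#' @return Scalar ESV (same monetary units as VC_i).
#' @export
esv <- function(areas, config) {
  keys <- land_use_classes()$key
  if (!all(keys %in% names(areas))) stop("areas must cover all 8 classes")
  sum(as.numeric(areas[keys]) * config$vc_i)
}

#' Proportion of non-ecological land in a unit
#'
#' U_i = (farmland + construction + saline-alkali areas) / valid unit area,
#' following the ecological/non-ecological split of the land-use legend.
#'
#' @param areas_ki Named per-class areas of the unit (km^2).
#' @return Scalar in \[0, 1\] (NA for an empty unit).
#' @export
nonecological_proportion <- function(areas_ki) {
  keys <- land_use_classes()$key
  a <- as.numeric(areas_ki[keys])
  total <- sum(a)
  if (total <= 0) return(NA_real_)
  sum(a[!land_use_classes()$ecological]) / total
}

# Saaty random consistency indices for n = 1..10.
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP weights from a pairwise comparison matrix
#'
#' Weights are the normalized principal eigenvector of the positive
#' reciprocal comparison matrix; consistency is measured by
#' CR = ((lambda_max - n)/(n - 1)) / RI(n) with Saaty's random indices
#' (CR = 0 by convention for n = 2, where reciprocal matrices are always
#' consistent). CR > 0.1 is flagged.
#'
#' @param m Square positive reciprocal matrix, size 2-10.
#' @param tol Reciprocity tolerance.
#' @return List with `weights`, `lambda_max`, `cr`, `consistent`.
#' @export
ahp_weights <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || n < 2 || n > 10) stop("matrix must be square, size 2-10")
  if (any(m <= 0)) stop("comparison matrix must be positive")
  if (max(abs(m * t(m) - 1)) > tol)
    stop("matrix is not reciprocal (a_ji != 1/a_ij)")
  e <- eigen(m)
  k <- which.max(Re(e$values))
  lambda <- Re(e$values[k])
  w <- Re(e$vectors[, k])
  w <- w / sum(w)
  cr <- if (n == 2) 0 else ((lambda - n) / (n - 1)) / SAATY_RI[n]
  list(weights = w, lambda_max = lambda, cr = cr, consistent = cr <= 0.1)
}

#' Aggregate normalized indicators into the eco-security index
#'
#' Two-level weighted sum: index = sum_dim w_dim sum_ind w_ind y_ind. When
#' an indicator is missing (NA) its weight is renormalized over the
#' remaining indicators of its dimension; a dimension with no observed
#' indicator is dropped and the dimension weights renormalized, so missing
#' data never drags the index toward 0.
#'
#' @param y Named numeric vector of normalized indicator values in \[0, 1\]
#'   (names as in `indicator_weights`).
#' @param config An `indicator_config`.
#' @return List with `index` and `dimensions` (per-dimension sub-indices).
#' @export
aggregate_index <- function(y, config) {
  obs <- y[!is.na(y)]
  if (length(obs) && (min(obs) < -1e-9 || max(obs) > 1 + 1e-9))
    stop("normalized indicators must lie in [0, 1]")
  dw <- config$dimension_weights
  if (abs(sum(dw) - 1) > 1e-8) stop("dimension weights must sum to 1")
  sub <- stats::setNames(rep(NA_real_, length(dw)), names(dw))
  for (d in names(dw)) {
    iw <- config$indicator_weights[[d]]
    yv <- y[names(iw)]
    ok <- !is.na(yv)
    if (any(ok)) sub[d] <- sum(iw[ok] / sum(iw[ok]) * yv[ok])
  }
  ok <- !is.na(sub)
  if (!any(ok)) return(list(index = NA_real_, dimensions = sub))
  list(index = sum(dw[ok] / sum(dw[ok]) * sub[ok]), dimensions = sub)
}
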