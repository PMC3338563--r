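# Seeded generator of FAO-like economic panels, macro series and
# Monfreda-like crop rasters with construction-known ground truth.
# Component sub-seeds are fixed offsets from the base seed so that adding
# a component never shifts the draws of an earlier one.

.seed_offsets <- c(dependency = 1L, scales = 2L, production = 3L,
                   prices = 4L, inflation = 5L, ppp = 6L, macro = 7L,
                   beehives = 8L, rasters = 11L, climate = 12L,
                   cropland = 13L)

.sub_seed <- function(seed, component) {
  (as.integer(seed) + .seed_offsets[[component]]) %% .Machine$integer.max
}

#' Configuration of a synthetic world
#'
#' Defaults describe a deliberately modest world: a few dozen countries of
#' very unequal economic size (log-normal dispersion of one log-unit, as
#' national crop statistics are), 17 years of panel data, multiplicative
#' producer-price noise of ~15%, annual inflation between 1 and 6%, and
#' purchasing-power factors between 0.8 and 3 with one reference country
#' fixed at 1.
#'
#' @param n_countries,n_crops,n_staples World dimensions; staples are
#'   pollination-independent (all dependency ratios 0).
#' @param years Inclusive year range of the panels.
#' @param seed Base seed; all randomness derives from it.
#' @param price_volatility Std. dev. of multiplicative log price noise.
#' @param inflation_drift Range of per-country annual inflation rates.
#' @param ppp_range Range of purchasing-power factors.
#' @param size_dispersion Std. dev. of the log-normal country size scale.
#' @param target_ag_dependency Optional ratio: when set, GDP and
#'   agricultural shares are constructed so the true agricultural-GDP
#'   dependency on pollination equals it exactly in every country-year.
#' @param beehive_trend_correlation Optional rho in \[-1, 1\]: country
#'   beehive trend slopes are drawn correlated with benefit trend slopes
#'   at this level.
#' @param cells_per_country Raster cells per country block.
#' @param resolution Raster cell size in degrees (default 5 arc-minutes).
#' @param map_year Year whose national production the rasters allocate;
#'   defaults to 2000 when the window covers it, else the mid-window year.
#' @return A `world_config` list.
#' @export
world_config <- function(n_countries = 30, n_crops = 15, n_staples = 4,
                         years = 1993:2009, seed = 1L,
                         price_volatility = 0.15,
                         inflation_drift = c(0.01, 0.06),
                         ppp_range = c(0.8, 3.0),
                         size_dispersion = 1.0,
                         target_ag_dependency = NULL,
                         beehive_trend_correlation = NULL,
                         cells_per_country = 100,
                         resolution = 1 / 12,
                         map_year = NULL) {
  stopifnot(n_staples <= n_crops, n_countries >= 1,
            length(years) >= 2, price_volatility >= 0,
            inflation_drift[1] <= inflation_drift[2], inflation_drift[1] >= 0,
            ppp_range[1] > 0, ppp_range[1] <= ppp_range[2])
  if (!is.null(beehive_trend_correlation) &&
      abs(beehive_trend_correlation) > 1) {
    stop("beehive_trend_correlation must lie in [-1, 1]", call. = FALSE)
  }
  if (!is.null(target_ag_dependency) &&
      (target_ag_dependency <= 0 || target_ag_dependency > 1)) {
    stop("target_ag_dependency must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(map_year)) {
    # the spatial snapshot year: 2000 when covered, else the mid-window year
    map_year <- if (2000 %in% years) 2000L else years[ceiling(length(years) / 2)]
  }
  if (!map_year %in% years) stop("map_year must lie within years",
                                 call. = FALSE)
  structure(list(
    n_countries = n_countries, n_crops = n_crops, n_staples = n_staples,
    years = years, seed = as.integer(seed),
    price_volatility = price_volatility,
    inflation_drift = inflation_drift, ppp_range = ppp_range,
    size_dispersion = size_dispersion,
    target_ag_dependency = target_ag_dependency,
    beehive_trend_correlation = beehive_trend_correlation,
    cells_per_country = cells_per_country, resolution = resolution,
    map_year = map_year), class = "world_config")
}

#' Generate a synthetic world of panels with known ground truth
#'
#' Draws a dependency table (ordered lower/median/upper ratios, staples at
#' 0), a production panel (log-normal country scales, mild per-crop
#' trends, multiplicative noise), a price panel (AR(1)-like multiplicative
#' log noise around per-crop base prices), correction factors (inflation
#' compounding toward the final reference year; constant per-country
#' purchasing-power factors with the first country as reference), and the
#' macro panel. With `target_ag_dependency` set, GDP is constructed from
#' the realized benefit so the agricultural dependency indicator is exact
#' by construction; with `beehive_trend_correlation` set, beehive series
#' are exactly linear with slopes correlated to benefit trend slopes at
#' the requested level. Everything is reproducible from `config$seed`.
#'
#' @param config A [world_config()].
#' @return List: `dependency`, `production`, `prices`, `corrections`,
#'   `macro` (validated tibbles) and `truth` (construction-known values:
#'   country scales, per-country benefit series, target dependency,
#'   beehive slopes).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cc <- config
  countries <- sprintf("C%03d", seq_len(cc$n_countries))
  crops <- sprintf("crop_%02d", seq_len(cc$n_crops))
  staples <- crops[seq_len(cc$n_staples)]
  years <- cc$years
  ref_year <- max(years)

  # dependency ratios
  set.seed(.sub_seed(cc$seed, "dependency"))
  n_dep <- cc$n_crops - cc$n_staples
  dr_median <- c(rep(0, cc$n_staples), stats::runif(n_dep, 0.05, 0.95))
  dr_lower <- dr_median * c(rep(1, cc$n_staples), stats::runif(n_dep, 0.3, 0.9))
  dr_upper <- dr_median + (1 - dr_median) *
    c(rep(0, cc$n_staples), stats::runif(n_dep, 0.1, 0.7))
  dependency <- tibble::tibble(
    crop_id = crops, dr_lower = dr_lower, dr_median = dr_median,
    dr_upper = dr_upper, is_staple = crops %in% staples)

  # country size scales
  set.seed(.sub_seed(cc$seed, "scales"))
  scale_j <- stats::rlnorm(cc$n_countries, meanlog = 0,
                           sdlog = cc$size_dispersion)
  names(scale_j) <- countries

  grid <- tidyr::expand_grid(country_id = countries, crop_id = crops,
                             year = years)

  # production quantities: scale * crop base * growth^t * noise
  set.seed(.sub_seed(cc$seed, "production"))
  crop_base <- stats::rlnorm(cc$n_crops, meanlog = log(5e4), sdlog = 0.8)
  names(crop_base) <- crops
  growth <- matrix(stats::runif(cc$n_countries * cc$n_crops, -0.01, 0.04),
                   cc$n_countries, cc$n_crops,
                   dimnames = list(countries, crops))
  noise_q <- stats::rnorm(nrow(grid), 0, 0.05)
  t_rel <- grid$year - min(years)
  production <- tibble::tibble(
    country_id = grid$country_id, crop_id = grid$crop_id, year = grid$year,
    quantity = unname(scale_j[grid$country_id] * crop_base[grid$crop_id] *
      (1 + growth[cbind(grid$country_id, grid$crop_id)])^t_rel *
      exp(noise_q)))

  # producer prices: per-crop base, per-country level, AR(1) log noise
  set.seed(.sub_seed(cc$seed, "prices"))
  price_base <- stats::rlnorm(cc$n_crops, meanlog = log(400), sdlog = 0.6)
  names(price_base) <- crops
  level_cj <- matrix(stats::rlnorm(cc$n_countries * cc$n_crops, 0, 0.2),
                     cc$n_countries, cc$n_crops,
                     dimnames = list(countries, crops))
  ny <- length(years)
  ar_noise <- array(0, dim = c(cc$n_countries, cc$n_crops, ny))
  eps <- array(stats::rnorm(cc$n_countries * cc$n_crops * ny, 0,
                            cc$price_volatility),
               dim = dim(ar_noise))
  ar_noise[, , 1] <- eps[, , 1]
  if (ny > 1) {
    for (t in 2:ny) ar_noise[, , t] <- 0.6 * ar_noise[, , t - 1] + eps[, , t]
  }
  idx <- cbind(match(grid$country_id, countries),
               match(grid$crop_id, crops),
               match(grid$year, years))
  prices <- tibble::tibble(
    country_id = grid$country_id, crop_id = grid$crop_id, year = grid$year,
    price_nominal = unname(price_base[grid$crop_id] *
      level_cj[cbind(grid$country_id, grid$crop_id)] * exp(ar_noise[idx])))

  # inflation factors compounding toward the reference year
  set.seed(.sub_seed(cc$seed, "inflation"))
  infl_rate <- stats::runif(cc$n_countries, cc$inflation_drift[1],
                            cc$inflation_drift[2])
  names(infl_rate) <- countries
  cgrid <- tidyr::expand_grid(country_id = countries, year = years)
  inflation_factor <- (1 + infl_rate[cgrid$country_id])^(ref_year - cgrid$year)

  set.seed(.sub_seed(cc$seed, "ppp"))
  ppp_j <- stats::runif(cc$n_countries, cc$ppp_range[1], cc$ppp_range[2])
  ppp_j[1] <- 1 # reference country
  names(ppp_j) <- countries
  corrections <- tibble::tibble(
    country_id = cgrid$country_id, year = cgrid$year,
    inflation_factor = unname(inflation_factor),
    ppp_factor = unname(ppp_j[cgrid$country_id]))

  # realized per-country benefit (median scenario), reused for truths
  aligned <- align_panels(production, prices, corrections, dependency)
  benefit_country <- pollination_benefit(aligned, "median", "country")

  set.seed(.sub_seed(cc$seed, "macro"))
  ag_share_j <- stats::runif(cc$n_countries, 0.05, 0.5)
  names(ag_share_j) <- countries
  bmap <- stats::setNames(benefit_country$value,
                          paste(benefit_country$group, benefit_country$year))
  bvec <- bmap[paste(cgrid$country_id, cgrid$year)]
  if (is.null(cc$target_ag_dependency)) {
    gdp <- scale_j[cgrid$country_id] * 5e9 *
      stats::rlnorm(nrow(cgrid), 0, 0.1)
  } else {
    if (any(bvec <= 0)) {
      stop("target_ag_dependency infeasible: zero pollination benefit ",
           "(all-staple world?)", call. = FALSE)
    }
    gdp <- bvec / (cc$target_ag_dependency * ag_share_j[cgrid$country_id])
  }

  # beehives: exactly linear series with slopes correlated to benefit slopes
  set.seed(.sub_seed(cc$seed, "beehives"))
  slopes_b <- country_trends(benefit_country)
  z_b <- as.numeric(scale(slopes_b$slope[match(countries,
                                               slopes_b$country_id)]))
  if (is.null(cc$beehive_trend_correlation)) {
    h <- stats::rnorm(cc$n_countries)
  } else {
    rho <- cc$beehive_trend_correlation
    h <- rho * z_b + sqrt(1 - rho^2) * stats::rnorm(cc$n_countries)
  }
  hive_slope <- h * 1e3
  names(hive_slope) <- countries
  # base level large enough that the linear series never clips at zero
  hive_base <- 1e5 + 1e4 * scale_j
  beehives <- hive_base[cgrid$country_id] +
    hive_slope[cgrid$country_id] * (cgrid$year - min(years))
  beehives <- pmax(beehives, 0)

  macro <- tibble::tibble(
    country_id = cgrid$country_id, year = cgrid$year,
    gdp = unname(gdp), ag_share = unname(ag_share_j[cgrid$country_id]),
    beehives = unname(beehives))

  list(
    dependency = validate_panel(dependency, "dependency"),
    production = validate_panel(production, "production"),
    prices = validate_panel(prices, "price"),
    corrections = validate_panel(corrections, "corrections"),
    macro = validate_panel(macro, "macro"),
    truth = list(
      config = cc,
      country_scale = scale_j,
      ppp = ppp_j,
      inflation_rate = infl_rate,
      ag_share = ag_share_j,
      target_ag_dependency = cc$target_ag_dependency,
      benefit_country = benefit_country,
      beehive_slope = hive_slope,
      beehive_trend_correlation = cc$beehive_trend_correlation))
}

#' Generate crop, climate and cropland rasters consistent with a world
#'
#' Assigns each country a contiguous block of grid rows (blocks stacked
#' from north to south around the equator), then allocates the national
#' production of each crop in the map year across the country's cells:
#' random cultivated-area fractions whose per-cell sum over crops stays
#' below 1, and a uniform per-country yield chosen so the zonal sum
#' `yield x fraction x cell_area` reproduces the national tonnage
#' exactly. Temperature falls with absolute latitude, precipitation is a
#' smooth spatial field, and cropland fraction tracks the total cultivated
#' fraction with noise — all seeded from the world's base seed.
#'
#' @param world Output of [generate_world()].
#' @param config The same [world_config()] (defaults to the one stored in
#'   `world$truth`).
#' @return List: `stack` (a [crop_raster_stack()]), `temperature`,
#'   `precipitation`, `cropland` (`pv_raster`s), and `truth`
#'   (`national_quantity`: the allocated country-by-crop tonnages).
#' @export
generate_rasters <- function(world, config = world$truth$config) {
  cc <- config
  countries <- unique(world$production$country_id)
  crops <- unique(world$production$crop_id)

  w <- floor(sqrt(cc$cells_per_country))
  while (w > 1 && cc$cells_per_country %% w != 0) w <- w - 1
  rows_per_country <- cc$cells_per_country / w
  n_rows <- rows_per_country * length(countries)
  if (n_rows * cc$resolution > 170) {
    stop("cells insufficient to place all countries within the lattice ",
         "(grid would span more than 170 degrees of latitude)",
         call. = FALSE)
  }
  yll <- -n_rows * cc$resolution / 2
  xll <- 0
  lat <- yll + (seq(n_rows, 1) - 0.5) * cc$resolution # north to south

  zone <- matrix(rep(seq_along(countries), each = rows_per_country * w),
                 n_rows, w, byrow = TRUE)
  zones <- pv_raster(zone, xll, yll, cc$resolution)
  area_row <- cell_area(lat, cc$resolution)

  pq <- world$production[world$production$year == cc$map_year, ]
  pq_mat <- matrix(0, length(countries), length(crops),
                   dimnames = list(countries, crops))
  pq_mat[cbind(pq$country_id, pq$crop_id)] <- pq$quantity

  set.seed(.sub_seed(cc$seed, "rasters"))
  yield <- list(); frac <- list()
  for (crop in crops) {
    yield[[crop]] <- matrix(NA_real_, n_rows, w)
    frac[[crop]] <- matrix(NA_real_, n_rows, w)
  }
  for (k in seq_along(countries)) {
    rows_k <- which(zone[, 1] == k)
    ncell <- length(rows_k) * w
    raw <- matrix(stats::runif(ncell * length(crops), 0.2, 1),
                  ncell, length(crops))
    margin <- stats::runif(ncell, 0.4, 0.9)
    fr <- raw / rowSums(raw) * margin # per-cell sum over crops = margin < 1
    area_cell <- rep(area_row[rows_k], times = w)
    for (ci in seq_along(crops)) {
      crop <- crops[ci]
      q <- pq_mat[k, ci]
      if (q <= 0) next # crop absent: yield and fraction stay nodata
      f <- fr[, ci]
      y <- q / sum(f * area_cell) # uniform national yield, exact zonal sum
      fm <- matrix(f, length(rows_k), w)
      ym <- matrix(y, length(rows_k), w)
      frac[[crop]][rows_k, ] <- fm
      yield[[crop]][rows_k, ] <- ym
    }
  }
  yield_r <- lapply(yield, pv_raster, xll = xll, yll = yll,
                    res = cc$resolution)
  frac_r <- lapply(frac, pv_raster, xll = xll, yll = yll,
                   res = cc$resolution)
  stack <- crop_raster_stack(yield_r, frac_r, zones, countries)

  set.seed(.sub_seed(cc$seed, "climate"))
  lat_m <- matrix(lat, n_rows, w)
  lon_m <- matrix(xll + (seq_len(w) - 0.5) * cc$resolution, n_rows, w,
                  byrow = TRUE)
  temperature <- 28 - 0.45 * abs(lat_m) +
    matrix(stats::rnorm(n_rows * w, 0, 1.5), n_rows, w)
  precipitation <- matrix(pmax(0,
    900 + 500 * sin(lat_m * pi / 30) + 250 * cos(lon_m * pi / 20) +
      matrix(stats::rnorm(n_rows * w, 0, 80), n_rows, w)), n_rows, w)

  set.seed(.sub_seed(cc$seed, "cropland"))
  total_frac <- Reduce(`+`, lapply(frac, function(m) ifelse(is.na(m), 0, m)))
  cropland <- matrix(pmin(1, pmax(0, total_frac +
    matrix(stats::rnorm(n_rows * w, 0, 0.03), n_rows, w))), n_rows, w)

  list(
    stack = stack,
    temperature = pv_raster(temperature, xll, yll, cc$resolution),
    precipitation = pv_raster(precipitation, xll, yll, cc$resolution),
    cropland = pv_raster(cropland, xll, yll, cc$resolution),
    truth = list(national_quantity = pq_mat, map_year = cc$map_year))
}
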