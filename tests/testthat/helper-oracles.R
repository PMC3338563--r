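# Shared fixtures and independent oracles used across the test files.

# Naive triple-loop benefit sum: the independent oracle for the grouped
# vectorised sums. Loops over every (country, crop, year) row explicitly.
brute_force_benefit <- function(production, prices, corrections, dependency,
                                dr_col = "dr_median", ppp_enabled = TRUE,
                                weight_only = FALSE) {
  out <- list()
  for (i in seq_len(nrow(production))) {
    co <- production$country_id[i]
    cr <- production$crop_id[i]
    yr <- production$year[i]
    pr <- prices[prices$country_id == co & prices$crop_id == cr &
                   prices$year == yr, ]
    kr <- corrections[corrections$country_id == co & corrections$year == yr, ]
    dep <- dependency[dependency$crop_id == cr, ]
    if (nrow(pr) == 0 || nrow(kr) == 0 || nrow(dep) == 0) next
    dr <- dep[[dr_col]]
    term <- if (weight_only) {
      production$quantity[i] * dr
    } else {
      pr$price_nominal * production$quantity[i] * dr *
        kr$inflation_factor * (if (ppp_enabled) kr$ppp_factor else 1)
    }
    key <- as.character(yr)
    out[[key]] <- (out[[key]] %||% 0) + term
  }
  vals <- unlist(out)
  vals[order(as.integer(names(vals)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small random panel set with optional gaps, built row by row.
random_panels <- function(n_countries, n_crops, n_years, seed,
                          drop_price_frac = 0) {
  set.seed(seed)
  countries <- sprintf("C%02d", seq_len(n_countries))
  crops <- sprintf("crop%02d", seq_len(n_crops))
  years <- seq(2000, length.out = n_years)
  grid <- expand.grid(country_id = countries, crop_id = crops, year = years,
                      stringsAsFactors = FALSE)
  production <- tibble::tibble(grid,
                               quantity = stats::runif(nrow(grid), 0, 1e4))
  prices <- tibble::tibble(grid,
                           price_nominal = stats::runif(nrow(grid), 10, 2000))
  if (drop_price_frac > 0) {
    keep <- stats::runif(nrow(prices)) >= drop_price_frac
    prices <- prices[keep, ]
  }
  cgrid <- expand.grid(country_id = countries, year = years,
                       stringsAsFactors = FALSE)
  corrections <- tibble::tibble(
    cgrid,
    inflation_factor = stats::runif(nrow(cgrid), 1, 2),
    ppp_factor = ifelse(cgrid$country_id == countries[1], 1,
                        stats::runif(nrow(cgrid), 0.5, 3)))
  med <- stats::runif(n_crops, 0.05, 0.9)
  dependency <- tibble::tibble(
    crop_id = crops,
    dr_lower = med * stats::runif(n_crops, 0.3, 1),
    dr_median = med,
    dr_upper = med + (1 - med) * stats::runif(n_crops, 0, 0.8),
    is_staple = FALSE)
  list(production = production, prices = prices, corrections = corrections,
       dependency = dependency)
}

# One-country, two-crop, one-year panel behind the worked hand sums.
hand_panel <- function() {
  list(
    production = tibble::tibble(
      country_id = "AAA", crop_id = c("fruit", "seed"), year = 2000L,
      quantity = c(50, 10)),
    prices = tibble::tibble(
      country_id = "AAA", crop_id = c("fruit", "seed"), year = 2000L,
      price_nominal = c(200, 100)),
    corrections = tibble::tibble(
      country_id = "AAA", year = 2000L,
      inflation_factor = 1, ppp_factor = 1),
    dependency = tibble::tibble(
      crop_id = c("fruit", "seed"),
      dr_lower = c(0.65, 0.05), dr_median = c(0.65, 0.05),
      dr_upper = c(0.65, 0.05), is_staple = FALSE))
}

# Handcrafted 3x3 single-crop raster stack exercising all mask states.
tiny_stack <- function() {
  res <- 1 / 12
  yv <- matrix(c(2,  2,  NA,
                 2,  0,  2,
                 NA, 2,  2), 3, 3, byrow = TRUE)
  fv <- matrix(c(0.5, NA,  0.5,
                 0.5, 0.5, 0.5,
                 NA,  NA,  0.5), 3, 3, byrow = TRUE)
  zv <- matrix(1, 3, 3)
  mk <- function(m) pv_raster(m, 0, 0, res)
  crop_raster_stack(list(apple = mk(yv)), list(apple = mk(fv)),
                    mk(zv), "AAA")
}
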