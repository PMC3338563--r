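# Describing the spatial pattern of gridded benefits: raster correlations
# and trend-surface generalized additive regressions on climate & cropland.

#' Build the regression table from benefit, climate and cropland rasters
#'
#' Keeps cells where the benefit is strictly positive and every predictor
#' is defined, and natural-log-transforms the response (zero and nodata
#' cells cannot be log-valued and are excluded up front; the exclusion
#' counts are kept for reporting).
#'
#' @param benefit A `pv_benefit` or `pv_raster` of $/ha values.
#' @param temperature,precipitation `pv_raster`s of mean annual
#'   temperature (deg C) and yearly precipitation (mm/yr).
#' @param cropland `pv_raster` of cropland area fraction in \[0, 1\].
#' @return Tibble with columns `log_benefit, temperature, precipitation,
#'   cropland_fraction, lon, lat`, and attribute `exclusions`:
#'   `list(n_valid_benefit, n_zero, n_missing_predictor, n_rows)`.
#' @export
build_regression_table <- function(benefit, temperature, precipitation,
                                   cropland) {
  b <- if (inherits(benefit, "pv_benefit")) benefit$values else benefit
  .check_lattice(list(b, temperature, precipitation, cropland))
  v <- b$values
  lat <- matrix(raster_lats(b), nrow(v), ncol(v))
  lon <- matrix(raster_lons(b), nrow(v), ncol(v), byrow = TRUE)

  valid_b <- !is.na(v)
  positive <- valid_b & v > 0
  preds_ok <- !is.na(temperature$values) & !is.na(precipitation$values) &
    !is.na(cropland$values)
  keep <- positive & preds_ok

  out <- tibble::tibble(
    log_benefit = log(v[keep]),
    temperature = temperature$values[keep],
    precipitation = precipitation$values[keep],
    cropland_fraction = cropland$values[keep],
    lon = lon[keep], lat = lat[keep])
  if (nrow(out) == 0) stop("no usable cells for regression", call. = FALSE)
  attr(out, "exclusions") <- list(
    n_valid_benefit = sum(valid_b),
    n_zero = sum(valid_b & v == 0),
    n_missing_predictor = sum(positive & !preds_ok),
    n_rows = nrow(out))
  out
}

#' Trend-surface GAM of log benefit on climate and cropland
#'
#' Penalized additive regression of the log benefit: a bivariate tensor
#' smooth of temperature and precipitation (capturing their interaction),
#' a univariate smooth of cropland fraction, and optionally a
#' two-dimensional coordinate smooth absorbing spatial structure the
#' predictors miss. Smoothness is selected by generalized
#' cross-validation. Non-linear relationships are expected, hence smooths
#' rather than linear terms; the fit describes the spatial pattern and is
#' not a climate-projection model.
#'
#' @param table Output of [build_regression_table()].
#' @param formula One of `"climate"`, `"cropland"`,
#'   `"climate+cropland"`.
#' @param include_coordinate_smooth Add `s(lon, lat)` (default FALSE).
#' @param k_smooth Basis dimension per univariate/tensor smooth margin
#'   product (default 20: tensor margins of 4-5 each; cropland smooth
#'   k = 20).
#' @param k_coords Basis dimension of the coordinate smooth (default 50).
#' @param subsample Optional row count: fit on a seeded random subset for
#'   large rasters.
#' @param seed Seed used when `subsample` is given.
#' @return List: `n`, `formula` (character), `explained_variance`
#'   (proportion of deviance explained), `terms` (tibble of smooth terms
#'   with effective degrees of freedom and p-values), `fit` (the `gam`
#'   object).
#' @export
fit_trend_surface <- function(table,
                              formula = c("climate", "cropland",
                                          "climate+cropland"),
                              include_coordinate_smooth = FALSE,
                              k_smooth = 20, k_coords = 50,
                              subsample = NULL, seed = 1L) {
  formula <- match.arg(formula)
  table <- tibble::as_tibble(table)
  if (!is.null(subsample) && subsample < nrow(table)) {
    set.seed(seed)
    table <- table[sample.int(nrow(table), subsample), ]
  }

  k_margin <- max(3, floor(sqrt(k_smooth)))
  terms <- character()
  if (formula %in% c("climate", "climate+cropland")) {
    terms <- c(terms, sprintf("te(temperature, precipitation, k = %d)",
                              k_margin))
  }
  if (formula %in% c("cropland", "climate+cropland")) {
    terms <- c(terms, sprintf("s(cropland_fraction, k = %d)", k_smooth))
  }
  if (include_coordinate_smooth) {
    terms <- c(terms, sprintf("s(lon, lat, k = %d)", k_coords))
  }
  fml <- stats::as.formula(paste("log_benefit ~", paste(terms, collapse = " + ")))

  n_par <- if (include_coordinate_smooth) k_smooth * 2 + k_coords
           else k_smooth * 2
  if (nrow(table) < 10 * 3) {
    stop("too few rows for a stable smooth fit", call. = FALSE)
  }

  fit <- tryCatch(
    mgcv::gam(fml, data = table, method = "GCV.Cp"),
    error = function(e) stop("trend-surface fit failed (", conditionMessage(e),
                             ")", call. = FALSE))
  s <- summary(fit)
  term_tab <- tibble::tibble(
    term = rownames(s$s.table),
    edf = s$s.table[, "edf"],
    p_value = s$s.table[, "p-value"])
  list(n = nrow(table), formula = formula,
       explained_variance = unname(s$dev.expl),
       terms = term_tab, fit = fit)
}
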