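# Gridded pollination benefits: per-crop and total $/ha maps with
# country-zone price assignment, missing-data semantics and zonal totals.

#' Bundle per-crop yield and area-fraction rasters with a country-zone grid
#'
#' All layers must share the lattice. Yields are tons per harvested
#' hectare; area fractions are the share of each cell cultivated with the
#' crop, in \[0, 1\]. The zone raster carries integer indices into
#' `country_ids` (NA = no country). Cells whose area fractions sum to more
#' than 1 across crops (a known artefact of sub-national allocation) are
#' counted and reported, not renormalised.
#'
#' @param yield Named list of `pv_raster` (one per crop).
#' @param area_fraction Named list of `pv_raster`, same crop names.
#' @param zones `pv_raster` of integer country indices.
#' @param country_ids Character vector mapping zone index to country id.
#' @param overallocation_tol Tolerance on the per-cell fraction sum.
#' @return A `crop_raster_stack` with attribute `n_overallocated`.
#' @export
crop_raster_stack <- function(yield, area_fraction, zones, country_ids,
                              overallocation_tol = 1e-6) {
  if (!setequal(names(yield), names(area_fraction))) {
    stop("yield and area_fraction crop names differ", call. = FALSE)
  }
  area_fraction <- area_fraction[names(yield)]
  .check_lattice(c(yield, area_fraction, list(zones)))
  frac_sum <- 0
  for (crop in names(area_fraction)) {
    f <- area_fraction[[crop]]$values
    if (any(f < 0 | f > 1, na.rm = TRUE)) {
      stop("area_fraction for '", crop, "' outside [0, 1]", call. = FALSE)
    }
    frac_sum <- frac_sum + ifelse(is.na(f), 0, f)
  }
  n_over <- sum(frac_sum > 1 + overallocation_tol)
  if (n_over > 0) {
    warning(n_over, " cell(s) with crop area fractions summing above 1 ",
            "(reported, not renormalised)", call. = FALSE)
  }
  structure(list(yield = yield, area_fraction = area_fraction,
                 zones = zones, country_ids = country_ids,
                 n_overallocated = n_over),
            class = "crop_raster_stack")
}

#' @export
print.crop_raster_stack <- function(x, ...) {
  cat(sprintf("<crop_raster_stack: %d crops, %d countries, %d x %d cells>\n",
              length(x$yield), length(x$country_ids),
              nrow(x$zones$values), ncol(x$zones$values)))
  invisible(x)
}

.zone_index <- function(stack) {
  z <- stack$zones$values
  z[!is.na(z) & (z < 1 | z > length(stack$country_ids))] <- NA
  z
}

#' Gridded pollination benefit of one crop
#'
#' Per cell: `yield x area_fraction x corrected_price(zone) x dr`, in
#' corrected US$ per hectare of *total* cell area (multiplying by the
#' cultivated fraction moves the harvested-hectare yield onto the common
#' whole-cell reference, so crops can later be summed). Mask semantics:
#' a cell with yield reported but no cultivated-area information is
#' `missing_data` (benefit unknowable, shown separately on maps); a cell
#' with no yield is plain nodata. Cells in a zone without a price are
#' excluded and counted.
#'
#' @param stack A [crop_raster_stack()].
#' @param crop_id Crop to map.
#' @param prices Named numeric vector, corrected US$/ton per country id.
#' @param dr Scalar dependency ratio for the crop.
#' @return A `pv_benefit` object: `values` (a `pv_raster`, NA where
#'   invalid), `missing_data` (logical matrix), `n_unpriced` (cells
#'   excluded for lack of a national price).
#' @export
crop_benefit_map <- function(stack, crop_id, prices, dr) {
  if (!crop_id %in% names(stack$yield)) {
    stop("crop '", crop_id, "' not in stack", call. = FALSE)
  }
  if (dr < 0 || dr > 1) stop("dr must lie in [0, 1]", call. = FALSE)
  y <- stack$yield[[crop_id]]$values
  f <- stack$area_fraction[[crop_id]]$values
  zi <- .zone_index(stack)
  price_cell <- matrix(prices[stack$country_ids[zi]], nrow(y), ncol(y))

  missing_data <- !is.na(y) & is.na(f)
  unpriced <- !is.na(y) & !is.na(f) & is.na(price_cell)
  valid <- !is.na(y) & !is.na(f) & !is.na(price_cell)

  v <- matrix(NA_real_, nrow(y), ncol(y))
  v[valid] <- y[valid] * f[valid] * price_cell[valid] * dr

  ref <- stack$yield[[crop_id]]
  structure(list(values = pv_raster(v, ref$xll, ref$yll, ref$res),
                 missing_data = missing_data,
                 n_unpriced = sum(unpriced),
                 crop_id = crop_id),
            class = "pv_benefit")
}

#' @export
print.pv_benefit <- function(x, ...) {
  cat(sprintf("<pv_benefit%s: %d valid, %d missing-data, %d unpriced cells>\n",
              if (is.null(x$crop_id)) "" else paste0(" [", x$crop_id, "]"),
              sum(!is.na(x$values$values)), sum(x$missing_data), x$n_unpriced))
  invisible(x)
}

#' Total benefit map over all crops
#'
#' Cellwise sum of per-crop benefit maps on a shared lattice. A crop that
#' is invalid in a cell contributes 0 as long as at least one crop is
#' valid there; a cell is nodata only when no crop is valid. Per-crop
#' missing-data masks are not carried into the total (cells with unknowable
#' contributions keep the contributions that are known), so the total is a
#' conservative lower estimate.
#'
#' @param benefit_maps List of `pv_benefit` objects.
#' @return A `pv_benefit` with the summed values and an all-FALSE
#'   missing-data mask.
#' @export
total_benefit_map <- function(benefit_maps) {
  if (length(benefit_maps) == 0) stop("no benefit maps", call. = FALSE)
  .check_lattice(lapply(benefit_maps, `[[`, "values"))
  ref <- benefit_maps[[1]]$values
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  any_valid <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (bm in benefit_maps) {
    v <- bm$values$values
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    any_valid <- any_valid | ok
  }
  acc[!any_valid] <- NA_real_
  structure(list(values = pv_raster(acc, ref$xll, ref$yll, ref$res),
                 missing_data = matrix(FALSE, nrow(acc), ncol(acc)),
                 n_unpriced = sum(vapply(benefit_maps, `[[`, 0, "n_unpriced")),
                 crop_id = NULL),
            class = "pv_benefit")
}

#' Zonal country totals of a benefit map
#'
#' Converts the $/ha map to absolute dollars by multiplying each valid
#' cell by its latitude-dependent spherical cell area and summing within
#' country zones. This is the consistency bridge between the gridded and
#' the national valuation: on rasters whose crop layers re-aggregate to
#' national production, the zonal totals equal the national benefit sums.
#'
#' @param benefit A `pv_benefit`.
#' @param zones `pv_raster` of zone indices on the same lattice.
#' @param country_ids Character vector mapping index to country id.
#' @return Tibble `country_id, total` (corrected US$), with attribute
#'   `n_unzoned`: valid benefit cells lying outside any zone.
#' @export
aggregate_to_country <- function(benefit, zones, country_ids) {
  .check_lattice(list(benefit$values, zones))
  v <- benefit$values$values
  area <- matrix(cell_area(raster_lats(benefit$values), benefit$values$res),
                 nrow(v), ncol(v))
  zi <- zones$values
  valid <- !is.na(v)
  n_unzoned <- sum(valid & is.na(zi))
  if (n_unzoned > 0) {
    warning(n_unzoned, " valid benefit cell(s) outside any country zone",
            call. = FALSE)
  }
  use <- valid & !is.na(zi)
  totals <- vapply(seq_along(country_ids), function(k) {
    sel <- use & zi == k
    sum(v[sel] * area[sel])
  }, 0)
  out <- tibble::tibble(country_id = country_ids, total = totals)
  attr(out, "n_unzoned") <- n_unzoned
  out
}

#' Total benefit maps under all three dependency scenarios
#'
#' Builds lower/median/upper total maps and reports their pairwise Pearson
#' correlations over jointly valid cells — the spatial analogue of the
#' scenario bounds on the national series. Ordering
#' `lower <= median <= upper` holds in every cell.
#'
#' @param stack A [crop_raster_stack()].
#' @param prices Tibble `country_id, crop_id, price` of corrected prices.
#' @param dependency Validated dependency table.
#' @return List: `maps` (named list of `pv_benefit`), `correlations`
#'   (named numeric: `lower_median`, `lower_upper`, `median_upper`).
#' @export
scenario_maps <- function(stack, prices, dependency) {
  dependency <- validate_panel(dependency, "dependency")
  prices <- tibble::as_tibble(prices)
  one_scenario <- function(drc) {
    maps <- lapply(names(stack$yield), function(crop) {
      dr <- dependency[[drc]][match(crop, dependency$crop_id)]
      if (is.na(dr)) stop("crop '", crop, "' missing from dependency table",
                          call. = FALSE)
      p <- prices[prices$crop_id == crop, ]
      pvec <- stats::setNames(p$price, p$country_id)
      crop_benefit_map(stack, crop, pvec, dr)
    })
    total_benefit_map(maps)
  }
  maps <- list(lower = one_scenario("dr_lower"),
               median = one_scenario("dr_median"),
               upper = one_scenario("dr_upper"))
  pair_r <- function(a, b) raster_correlation(a$values, b$values)$r
  list(maps = maps,
       correlations = c(
         lower_median = pair_r(maps$lower, maps$median),
         lower_upper = pair_r(maps$lower, maps$upper),
         median_upper = pair_r(maps$median, maps$upper)))
}

#' Corrected national price table for a map year
#'
#' Convenience builder joining the nominal price panel with correction
#' factors for a single year, yielding the `country_id, crop_id, price`
#' table that [scenario_maps()] and [crop_benefit_map()] consume.
#'
#' @param prices Validated price panel.
#' @param corrections Validated corrections panel.
#' @param year Map year (the spatial snapshot year).
#' @param ppp_enabled Apply the purchasing-power factor (default TRUE).
#' @return Tibble `country_id, crop_id, price` (corrected US$/ton).
#' @export
map_price_table <- function(prices, corrections, year, ppp_enabled = TRUE) {
  prices <- validate_panel(prices, "price")
  corrections <- validate_panel(corrections, "corrections")
  p <- prices[prices$year == year, ]
  k <- corrections[corrections$year == year, ]
  tab <- dplyr::inner_join(p, k, by = c("country_id", "year"))
  ppp <- if (ppp_enabled) tab$ppp_factor else 1
  tibble::tibble(country_id = tab$country_id, crop_id = tab$crop_id,
                 price = corrected_price(tab$price_nominal,
                                         tab$inflation_factor, ppp))
}
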