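# Monetary valuation of the pollination-attributable share of production:
# benefit sums, pollination-weighted quantities, the price signal,
# the staple-crop baseline, scenario bounds and base-year indexing.

.pv_group_col <- function(grouping) {
  switch(grouping,
         global = NULL,
         country = "country_id",
         crop = "crop_id",
         stop("unknown grouping: ", grouping, call. = FALSE))
}

.pv_series <- function(tab, kind, scenario, grouping) {
  tab <- tibble::as_tibble(tab)
  attr(tab, "kind") <- kind
  attr(tab, "scenario") <- scenario
  attr(tab, "grouping") <- grouping
  class(tab) <- c("pv_series", class(tab))
  tab
}

#' @export
print.pv_series <- function(x, ...) {
  cat(sprintf("<valuation series: kind=%s scenario=%s grouping=%s>\n",
              attr(x, "kind"), attr(x, "scenario"), attr(x, "grouping")))
  NextMethod()
}

.dr_column <- function(scenario) {
  if (!scenario %in% c("lower", "median", "upper")) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  paste0("dr_", scenario)
}

# Rows usable in sums: complete (if the flag exists) and all terms present.
.usable <- function(tab, cols) {
  ok <- if ("complete" %in% names(tab)) tab$complete else rep(TRUE, nrow(tab))
  for (col in cols) ok <- ok & !is.na(tab[[col]])
  ok
}

.grouped_sum <- function(tab, term, grouping) {
  gcol <- .pv_group_col(grouping)
  tab$..term <- term
  out <- tab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gcol, "year")))) |>
    dplyr::summarise(value = sum(.data$..term), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(gcol, "year"))))
  if (is.null(gcol)) {
    out <- tibble::tibble(group = "global", year = out$year, value = out$value)
  } else {
    names(out)[names(out) == gcol] <- "group"
  }
  out
}

#' Inflation- and purchasing-power-corrected producer price
#'
#' Multiplies a nominal producer price (US$/ton) by the country-year
#' inflation correction factor (to the reference year) and the
#' purchasing-power-parity factor (1 for the reference country).
#'
#' @param price_nominal Nominal price in US$/ton, `>= 0`.
#' @param inflation_factor,ppp_factor Dimensionless positive factors.
#' @return Corrected price in reference-year, purchasing-power US$/ton.
#' @export
corrected_price <- function(price_nominal, inflation_factor, ppp_factor) {
  if (any(price_nominal < 0, na.rm = TRUE) ||
      any(inflation_factor < 0, na.rm = TRUE) ||
      any(ppp_factor < 0, na.rm = TRUE)) {
    stop("corrected_price: negative input", call. = FALSE)
  }
  price_nominal * inflation_factor * ppp_factor
}

#' Pollination benefit series
#'
#' For every group (globe, country or crop) and year, sums the product
#' `price * quantity * dependency_ratio * inflation_factor * ppp_factor`
#' over all complete rows of the aligned table: the monetary value of the
#' pollination-attributable share of production, in corrected US$.
#' Disabling `ppp_enabled` replaces every purchasing-power factor by 1,
#' giving the uncorrected variant of the series.
#'
#' @param aligned Output of [align_panels()].
#' @param scenario Dependency-ratio scenario: `"lower"`, `"median"` or
#'   `"upper"`.
#' @param grouping `"global"`, `"country"` or `"crop"`.
#' @param ppp_enabled Apply the purchasing-power correction (default TRUE).
#' @return A `pv_series` tibble with columns `group, year, value`.
#' @export
pollination_benefit <- function(aligned, scenario = "median",
                                grouping = "global", ppp_enabled = TRUE) {
  if (nrow(aligned) == 0) stop("empty aligned table", call. = FALSE)
  drc <- .dr_column(scenario)
  use <- .usable(aligned, c("price_nominal", "inflation_factor",
                            "ppp_factor", drc, "quantity"))
  tab <- aligned[use, , drop = FALSE]
  ppp <- if (ppp_enabled) tab$ppp_factor else 1
  term <- tab$price_nominal * tab$quantity * tab[[drc]] *
    tab$inflation_factor * ppp
  out <- .grouped_sum(tab, term, grouping)
  .pv_series(out, "benefit", scenario, grouping)
}

#' Pollination-weighted production quantity series
#'
#' Sums `quantity * dependency_ratio` per group and year: the physical twin
#' of the benefit series, in dependency-weighted tons. With
#' `monetary_corrections = TRUE` each term is additionally multiplied by
#' `inflation_factor * ppp_factor`, reproducing the monetary-corrected
#' variant of the weighted quantity (see the vignette for why the
#' uncorrected form is the default).
#'
#' @inheritParams pollination_benefit
#' @param monetary_corrections Multiply the tonnage terms by the inflation
#'   and purchasing-power factors (default FALSE).
#' @return A `pv_series` tibble with columns `group, year, value`.
#' @export
weighted_quantity <- function(aligned, scenario = "median",
                              grouping = "global",
                              monetary_corrections = FALSE) {
  if (nrow(aligned) == 0) stop("empty aligned table", call. = FALSE)
  drc <- .dr_column(scenario)
  use <- .usable(aligned, c("quantity", drc))
  tab <- aligned[use, , drop = FALSE]
  term <- tab$quantity * tab[[drc]]
  if (monetary_corrections) {
    term <- term * tab$inflation_factor * tab$ppp_factor
  }
  out <- .grouped_sum(tab, term, grouping)
  .pv_series(out, "weighted_quantity", scenario, grouping)
}

#' Price signal: benefit per weighted ton
#'
#' Divides the benefit series by the weighted-quantity series, yielding the
#' implicit average corrected producer price of pollination-dependent
#' output (US$/ton). By construction `benefit = signal * quantity` holds
#' exactly wherever the signal is defined. Years with zero weighted
#' quantity get `value = NA` and `undefined = TRUE` rather than being
#' dropped.
#'
#' @param benefit,quantity `pv_series` objects with the same grouping,
#'   scenario and year coverage.
#' @return A `pv_series` with columns `group, year, value, undefined`.
#' @export
price_signal <- function(benefit, quantity) {
  for (at in c("grouping", "scenario")) {
    if (!identical(attr(benefit, at), attr(quantity, at))) {
      stop("price_signal: benefit and quantity differ in ", at, call. = FALSE)
    }
  }
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(benefit), v = "value"),
    dplyr::rename(tibble::as_tibble(quantity), q = "value"),
    by = c("group", "year"))
  if (nrow(joined) != nrow(benefit) || nrow(joined) != nrow(quantity)) {
    stop("price_signal: year coverage differs between series", call. = FALSE)
  }
  out <- tibble::tibble(
    group = joined$group, year = joined$year,
    value = ifelse(joined$q == 0, NA_real_, joined$v / joined$q),
    undefined = joined$q == 0)
  .pv_series(out, "price_signal", attr(benefit, "scenario"),
             attr(benefit, "grouping"))
}

#' Staple-crop baseline series
#'
#' Applies the valuation machinery to a set of pollination-independent
#' staple crops with the dependency ratio replaced by 1: total tonnage,
#' total corrected production value, and their ratio (the staple price
#' series), for comparison against the pollination-dependent series.
#'
#' @inheritParams pollination_benefit
#' @param staples Character vector of staple crop ids; default `NULL` uses
#'   the `is_staple` flag of the dependency table carried by the aligned
#'   table.
#' @return A list of three `pv_series`: `quantity` (tons), `value`
#'   (corrected US$) and `price` (US$/ton, with `undefined` flags).
#' @export
staple_baseline <- function(aligned, staples = NULL, grouping = "global") {
  sel <- if (is.null(staples)) aligned$is_staple %in% TRUE
         else aligned$crop_id %in% staples
  tab <- aligned[sel, , drop = FALSE]
  if (nrow(tab) == 0) stop("no staple rows in aligned table", call. = FALSE)
  tab$dr_lower <- tab$dr_median <- tab$dr_upper <- 1

  value <- pollination_benefit(tab, "median", grouping)
  attr(value, "kind") <- "production_value"
  quantity <- weighted_quantity(tab, "median", grouping)
  attr(quantity, "kind") <- "production_quantity"
  price <- price_signal(value, quantity)
  attr(price, "kind") <- "price"
  list(quantity = quantity, value = value, price = price)
}

#' Index a series to a base year
#'
#' Divides every value by the group's value in `base_year`, so that all
#' series equal exactly 1 in the base year and are directly comparable.
#' Idempotent: indexing an indexed series changes nothing.
#'
#' @param series A `pv_series`.
#' @param base_year Base year (default 1993).
#' @return The indexed `pv_series`.
#' @export
index_to_base <- function(series, base_year = 1993) {
  tab <- tibble::as_tibble(series)
  base <- tab[tab$year == base_year, c("group", "value")]
  if (nrow(base) == 0) stop("base year ", base_year, " not present",
                            call. = FALSE)
  names(base)[2] <- "..base"
  if (any(is.na(base$..base) | base$..base == 0)) {
    stop("base year value missing or zero for group(s): ",
         paste(base$group[is.na(base$..base) | base$..base == 0],
               collapse = ", "), call. = FALSE)
  }
  missing_base <- setdiff(unique(tab$group), base$group)
  if (length(missing_base) > 0) {
    stop("base year ", base_year, " not present for group(s): ",
         paste(missing_base, collapse = ", "), call. = FALSE)
  }
  tab <- dplyr::left_join(tab, base, by = "group")
  tab$value <- tab$value / tab$..base
  tab$..base <- NULL
  .pv_series(tab, attr(series, "kind"), attr(series, "scenario"),
             attr(series, "grouping"))
}

#' Benefit series under all three dependency scenarios
#'
#' Runs [pollination_benefit()] with the lower, median and upper
#' dependency-ratio columns. The three series bracket the valuation
#' uncertainty inherited from the dependency literature and satisfy
#' `lower <= median <= upper` at every point.
#'
#' @inheritParams pollination_benefit
#' @return Named list of three `pv_series`: `lower`, `median`, `upper`.
#' @export
scenario_bounds <- function(aligned, grouping = "global", ppp_enabled = TRUE) {
  out <- lapply(c(lower = "lower", median = "median", upper = "upper"),
                function(sc) pollination_benefit(aligned, sc, grouping,
                                                 ppp_enabled))
  out
}
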