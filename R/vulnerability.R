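# National vulnerability indicators, country linear trends and the
# relative-change comparison of benefits against the agricultural economy.

#' Pollination benefit as a share of GDP
#'
#' The first vulnerability indicator: the portion of a country's GDP that
#' is attributable to pollination. Ratios above 1 are arithmetically
#' possible when the underlying production and macroeconomic statistics
#' disagree; they are returned as-is but flagged as data inconsistencies.
#'
#' @param benefit Pollination benefit, corrected US$ per year.
#' @param gdp GDP in the same corrected units.
#' @return A tibble with columns `value` (the ratio) and `flag`
#'   (`"ok"`, `"inconsistent"` for ratios above 1, `"undefined"` for zero
#'   GDP).
#' @export
gdp_dependency <- function(benefit, gdp) {
  value <- unname(ifelse(gdp == 0, NA_real_, benefit / gdp))
  flag <- dplyr::case_when(
    gdp == 0 ~ "undefined",
    value > 1 ~ "inconsistent",
    .default = "ok")
  tibble::tibble(value = value, flag = flag)
}

#' Pollination benefit as a share of agricultural GDP
#'
#' The second vulnerability indicator: the dependency of the agricultural
#' economy on pollination, `benefit / (gdp * ag_share)`. Equals
#' [gdp_dependency()] when agriculture is the whole economy.
#'
#' @inheritParams gdp_dependency
#' @param ag_share Agricultural share of GDP, in \[0, 1\].
#' @return A tibble with columns `value` and `flag` as in
#'   [gdp_dependency()].
#' @export
ag_gdp_dependency <- function(benefit, gdp, ag_share) {
  denom <- gdp * ag_share
  value <- unname(ifelse(denom == 0, NA_real_, benefit / denom))
  flag <- dplyr::case_when(
    denom == 0 ~ "undefined",
    value > 1 ~ "inconsistent",
    .default = "ok")
  tibble::tibble(value = value, flag = flag)
}

#' Country-year vulnerability table
#'
#' Joins a per-country benefit series with the macro panel and computes
#' both vulnerability indicators for every country-year. The global row of
#' the table (grouping `"GLOBAL"`) aggregates as a ratio of sums: total
#' benefit over total (agricultural) GDP.
#'
#' @param benefit A `pv_series` with grouping `"country"`.
#' @param macro A validated macro panel (see [validate_panel()]).
#' @param include_global Append a `"GLOBAL"` ratio-of-sums row per year.
#' @return Tibble with columns `country_id, year, gdp_dependency,
#'   ag_gdp_dependency, flag_gdp, flag_ag`.
#' @export
vulnerability_table <- function(benefit, macro, include_global = TRUE) {
  if (!identical(attr(benefit, "grouping"), "country")) {
    stop("benefit series must have grouping = 'country'", call. = FALSE)
  }
  macro <- validate_panel(macro, "macro")
  tab <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(benefit), country_id = "group"),
    macro, by = c("country_id", "year"))

  g <- gdp_dependency(tab$value, tab$gdp)
  a <- ag_gdp_dependency(tab$value, tab$gdp, tab$ag_share)
  out <- tibble::tibble(
    country_id = tab$country_id, year = tab$year,
    gdp_dependency = g$value, ag_gdp_dependency = a$value,
    flag_gdp = g$flag, flag_ag = a$flag)

  if (include_global) {
    glob <- tab |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(benefit = sum(.data$value),
                       ag_gdp = sum(.data$gdp * .data$ag_share),
                       gdp = sum(.data$gdp),
                       .groups = "drop")
    gg <- gdp_dependency(glob$benefit, glob$gdp)
    ga <- ag_gdp_dependency(glob$benefit, glob$ag_gdp, 1)
    out <- dplyr::bind_rows(out, tibble::tibble(
      country_id = "GLOBAL", year = glob$year,
      gdp_dependency = gg$value, ag_gdp_dependency = ga$value,
      flag_gdp = gg$flag, flag_ag = ga$flag))
  }
  out
}

#' Ordinary least-squares trend of a yearly series
#'
#' Slope and intercept of value regressed on calendar year.
#'
#' @param years Integer vector of years (at least 2 distinct).
#' @param values Numeric vector, same length.
#' @return A one-row tibble: `slope` (units/yr), `intercept`, `n_years`.
#' @export
linear_trend <- function(years, values) {
  ok <- !is.na(values) & !is.na(years)
  years <- years[ok]; values <- values[ok]
  if (length(unique(years)) < 2) {
    stop("linear_trend: need at least 2 distinct years", call. = FALSE)
  }
  fit <- stats::lm(values ~ years)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_years = length(years))
}

#' Per-country linear trends of a series
#'
#' Fits [linear_trend()] within each country over its available years
#' (countries entering or leaving the window keep their shorter span,
#' reported in `n_years`). Countries with fewer than 2 observed years are
#' dropped.
#'
#' @param series A `pv_series` with grouping `"country"`, or any tibble
#'   with columns `group` (or `country_id`), `year`, `value`.
#' @return Tibble with columns `country_id, slope, intercept, n_years`.
#' @export
country_trends <- function(series) {
  tab <- tibble::as_tibble(series)
  if ("group" %in% names(tab)) names(tab)[names(tab) == "group"] <- "country_id"
  tab <- tab[!is.na(tab$value), , drop = FALSE]
  tab |>
    dplyr::group_by(.data$country_id) |>
    dplyr::filter(dplyr::n_distinct(.data$year) >= 2) |>
    dplyr::reframe(linear_trend(.data$year, .data$value))
}

#' Pearson correlation between two sets of country trend slopes
#'
#' Correlates slopes over the intersection of countries, after removing an
#' explicit exclusion list (outlier handling is deliberately manual).
#'
#' @param trends_a,trends_b Tibbles with columns `country_id, slope` (as
#'   produced by [country_trends()]).
#' @param exclude Character vector of country ids to drop before
#'   correlating.
#' @return List with `r`, `n`, `excluded` and `flag` (`"ok"` or
#'   `"zero_variance"`, in which case `r` is `NA`).
#' @export
trend_correlation <- function(trends_a, trends_b, exclude = character()) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(trends_a), "country_id", a = "slope"),
    dplyr::select(tibble::as_tibble(trends_b), "country_id", b = "slope"),
    by = "country_id")
  joined <- joined[!joined$country_id %in% exclude, , drop = FALSE]
  if (nrow(joined) < 3) {
    stop("trend_correlation: fewer than 3 common countries after exclusion",
         call. = FALSE)
  }
  if (stats::sd(joined$a) == 0 || stats::sd(joined$b) == 0) {
    return(list(r = NA_real_, n = nrow(joined), excluded = exclude,
                flag = "zero_variance"))
  }
  list(r = stats::cor(joined$a, joined$b), n = nrow(joined),
       excluded = exclude, flag = "ok")
}

#' Relative change of a series between two years
#'
#' `value(y1) / value(y0) - 1`: 0 means unchanged, 1 means a 100% increase
#' relative to the first year. A zero or missing starting value makes the
#' change undefined; such groups are flagged for exclusion from
#' comparative plots rather than reported as infinite.
#'
#' @param series A `pv_series` or tibble with `group, year, value`.
#' @param y0,y1 Comparison years (defaults 1993 and 2009).
#' @return Tibble with columns `group, change, flag` (`"ok"` or
#'   `"undefined"`).
#' @export
relative_change <- function(series, y0 = 1993, y1 = 2009) {
  tab <- tibble::as_tibble(series)
  if ("country_id" %in% names(tab) && !"group" %in% names(tab)) {
    names(tab)[names(tab) == "country_id"] <- "group"
  }
  w <- tidyr::pivot_wider(tab[tab$year %in% c(y0, y1), c("group", "year", "value")],
                          names_from = "year", values_from = "value")
  c0 <- as.character(y0); c1 <- as.character(y1)
  if (!all(c(c0, c1) %in% names(w))) {
    stop("relative_change: year ", setdiff(c(c0, c1), names(w))[1],
         " not present", call. = FALSE)
  }
  bad <- is.na(w[[c0]]) | w[[c0]] == 0 | is.na(w[[c1]])
  tibble::tibble(
    group = w$group,
    change = ifelse(bad, NA_real_, w[[c1]] / w[[c0]] - 1),
    flag = ifelse(bad, "undefined", "ok"))
}

#' Regression of benefit changes on agricultural-economy changes
#'
#' OLS of the relative change in pollination benefit on the relative
#' change in agricultural production value across countries, fitted both
#' with and without an explicit outlier list, together with a plot-ready
#' scatter table weighted by agricultural economy size.
#'
#' @param change_x,change_y Tibbles with columns `group, change` (see
#'   [relative_change()]); x is the agricultural economy, y the benefit.
#' @param weights Optional tibble `group, weight` (agricultural economy
#'   size) for the scatter table.
#' @param exclude Country ids treated as outliers for the refit.
#' @return List: `r_squared`, `r_squared_excluding`, `n`, `n_excluding`,
#'   `table` (columns `group, change_x, change_y, weight, excluded`).
#' @export
change_regression <- function(change_x, change_y, weights = NULL,
                              exclude = character()) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(change_x), "group", change_x = "change"),
    dplyr::select(tibble::as_tibble(change_y), "group", change_y = "change"),
    by = "group")
  joined <- joined[!is.na(joined$change_x) & !is.na(joined$change_y), ,
                   drop = FALSE]
  if (nrow(joined) < 3) {
    stop("change_regression: fewer than 3 usable countries", call. = FALSE)
  }
  if (is.null(weights)) {
    joined$weight <- 1
  } else {
    w <- dplyr::select(tibble::as_tibble(weights), "group", "weight")
    joined <- dplyr::left_join(joined, w, by = "group")
  }
  joined$excluded <- joined$group %in% exclude

  r2 <- function(d) {
    # suppressed: summary.lm warns on numerically perfect fits
    suppressWarnings(
      summary(stats::lm(change_y ~ change_x, data = d))$r.squared)
  }
  kept <- joined[!joined$excluded, , drop = FALSE]
  list(
    r_squared = r2(joined),
    r_squared_excluding = if (nrow(kept) >= 3) r2(kept) else NA_real_,
    n = nrow(joined),
    n_excluding = nrow(kept),
    table = joined)
}
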