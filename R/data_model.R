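# Panel schemas, validation and joins shared by every pipeline stage.

.pv_schemas <- list(
  production = list(
    required = c("country_id", "crop_id", "year", "quantity"),
    key      = c("country_id", "crop_id", "year"),
    numeric  = c("year", "quantity")
  ),
  price = list(
    required = c("country_id", "crop_id", "year", "price_nominal"),
    key      = c("country_id", "crop_id", "year"),
    numeric  = c("year", "price_nominal")
  ),
  corrections = list(
    required = c("country_id", "year", "inflation_factor", "ppp_factor"),
    key      = c("country_id", "year"),
    numeric  = c("year", "inflation_factor", "ppp_factor")
  ),
  macro = list(
    required = c("country_id", "year", "gdp", "ag_share"),
    optional = "beehives",
    key      = c("country_id", "year"),
    numeric  = c("year", "gdp", "ag_share", "beehives")
  ),
  dependency = list(
    required = c("crop_id", "dr_lower", "dr_median", "dr_upper", "is_staple"),
    key      = "crop_id",
    numeric  = c("dr_lower", "dr_median", "dr_upper")
  )
)

#' Panel schema names
#'
#' The five comma-separated-value schemas understood by [read_panel()] and
#' [write_panel()]: crop production quantities, nominal producer prices,
#' inflation/purchasing-power correction factors, macroeconomic series
#' (GDP, agricultural GDP share, beehive counts) and the per-crop
#' pollination dependency table.
#'
#' @return Character vector of schema names.
#' @export
panel_schemas <- function() names(.pv_schemas)

#' Validate a panel table against one of the five schemas
#'
#' Checks required columns, numeric parseability, key uniqueness and the
#' domain invariants of the schema: quantities and prices non-negative and
#' finite; correction factors strictly positive; `ag_share` in \[0, 1\];
#' dependency ratios ordered `0 <= dr_lower <= dr_median <= dr_upper <= 1`
#' with staple crops pollination-independent (`dr_median == 0`).
#'
#' @param x A data frame.
#' @param schema One of [panel_schemas()].
#' @return The validated table as a tibble, with extra columns dropped
#'   (after a warning) and key columns coerced to character/integer.
#' @export
validate_panel <- function(x, schema = c("production", "price", "corrections",
                                         "macro", "dependency")) {
  schema <- match.arg(schema)
  sc <- .pv_schemas[[schema]]
  x <- tibble::as_tibble(x)

  missing_cols <- setdiff(sc$required, names(x))
  if (length(missing_cols) > 0) {
    stop("schema '", schema, "': missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(sc$required, sc$optional)
  extra <- setdiff(names(x), keep)
  if (length(extra) > 0) {
    warning("schema '", schema, "': ignoring extra column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    x <- x[, intersect(keep, names(x)), drop = FALSE]
  }

  for (col in intersect(sc$numeric, names(x))) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "")
      if (length(bad) > 0) {
        stop("schema '", schema, "': unparseable numeric in column '", col,
             "' at row(s) ", paste(utils::head(bad, 10), collapse = ", "),
             call. = FALSE)
      }
      x[[col]] <- parsed
    }
  }
  if ("year" %in% names(x)) x$year <- as.integer(x$year)
  for (col in intersect(c("country_id", "crop_id"), names(x))) {
    x[[col]] <- as.character(x[[col]])
  }
  if ("is_staple" %in% names(x)) x$is_staple <- .as_flag(x$is_staple)

  dup <- duplicated(x[, sc$key, drop = FALSE])
  if (any(dup)) {
    keys <- do.call(paste, c(x[dup, sc$key, drop = FALSE], sep = "/"))
    stop("schema '", schema, "': duplicate key(s): ",
         paste(unique(utils::head(keys, 10)), collapse = ", "), call. = FALSE)
  }

  .check_schema_invariants(x, schema)
  x
}

.as_flag <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  tolower(trimws(as.character(v))) %in% c("true", "t", "1", "yes")
}

.check_schema_invariants <- function(x, schema) {
  fail <- function(...) stop("schema '", schema, "': ", ..., call. = FALSE)
  nonneg <- function(col) {
    v <- x[[col]]
    if (any(!is.finite(v))) fail("non-finite values in '", col, "'")
    if (any(v < 0)) fail("negative values in '", col, "'")
  }
  switch(schema,
    production = nonneg("quantity"),
    price = nonneg("price_nominal"),
    corrections = {
      if (any(!is.finite(x$inflation_factor)) || any(x$inflation_factor <= 0))
        fail("inflation_factor must be finite and > 0")
      if (any(!is.finite(x$ppp_factor)) || any(x$ppp_factor <= 0))
        fail("ppp_factor must be finite and > 0")
    },
    macro = {
      nonneg("gdp")
      if (any(x$ag_share < 0 | x$ag_share > 1, na.rm = TRUE))
        fail("ag_share must lie in [0, 1]")
      if ("beehives" %in% names(x) && any(x$beehives < 0, na.rm = TRUE))
        fail("beehives must be non-negative")
    },
    dependency = {
      dr <- x[, c("dr_lower", "dr_median", "dr_upper")]
      if (any(!is.finite(as.matrix(dr)))) fail("non-finite dependency ratio")
      if (any(dr < 0 | dr > 1)) fail("dependency ratios must lie in [0, 1]")
      bad <- x$dr_lower > x$dr_median | x$dr_median > x$dr_upper
      if (any(bad))
        fail("dependency ratios not ordered (lower <= median <= upper) for crop(s): ",
             paste(x$crop_id[bad], collapse = ", "))
      staple_dep <- x$is_staple & x$dr_median > 0
      if (any(staple_dep))
        fail("staple crop(s) with non-zero median dependency: ",
             paste(x$crop_id[staple_dep], collapse = ", "))
    }
  )
  invisible(x)
}

#' Read a validated panel from CSV
#'
#' Reads a UTF-8 CSV with a header row and validates it against one of the
#' five documented schemas (see [panel_schemas()] and [validate_panel()]).
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_panel
#' @return A validated tibble.
#' @examples
#' dep <- read_panel(system.file("extdata", "example_dependency.csv",
#'                               package = "pollvalue"), "dependency")
#' prod <- read_panel(system.file("extdata", "example_production.csv",
#'                                package = "pollvalue"), "production")
#' @export
read_panel <- function(path, schema = c("production", "price", "corrections",
                                        "macro", "dependency")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8", check.names = FALSE)
  validate_panel(x, schema)
}

#' Write a panel to CSV
#'
#' The inverse of [read_panel()]: validates, then writes a header-row CSV
#' so that `read_panel(write_panel(x, f), schema)` round-trips exactly.
#'
#' @param x A data frame conforming to `schema`.
#' @param path Output file path.
#' @inheritParams validate_panel
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path, schema = c("production", "price",
                                            "corrections", "macro",
                                            "dependency")) {
  schema <- match.arg(schema)
  x <- validate_panel(x, schema)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Join production, prices, corrections and dependency ratios
#'
#' Builds the analysis table that the valuation stage sums over: one row per
#' (country, crop, year) present in the production panel, carrying the
#' nominal price, inflation and purchasing-power factors and the three
#' dependency ratio columns. Rows that lack a price or a correction factor
#' (the analogue of reporting gaps in national statistics) are counted and
#' flagged `complete = FALSE`; by default they are retained in the table but
#' excluded from all valuation sums. With `impute = "country-mean"` a
#' missing price is replaced by the country-year mean nominal price over the
#' crops that do report one.
#'
#' @param production,prices,corrections,dependency Validated panels (see
#'   [validate_panel()]).
#' @param impute Gap policy for missing prices: `"none"` (default; flagged
#'   and excluded) or `"country-mean"`.
#' @return A tibble with one row per production record, columns
#'   `country_id, crop_id, year, quantity, price_nominal, inflation_factor,
#'   ppp_factor, dr_lower, dr_median, dr_upper, is_staple, complete`, and a
#'   `coverage` attribute (`list(n_production, n_complete, n_excluded,
#'   n_missing_price, n_missing_correction, n_missing_dependency)`).
#' @export
align_panels <- function(production, prices, corrections, dependency,
                         impute = c("none", "country-mean")) {
  impute <- match.arg(impute)
  production <- validate_panel(production, "production")
  prices <- validate_panel(prices, "price")
  corrections <- validate_panel(corrections, "corrections")
  dependency <- validate_panel(dependency, "dependency")

  if (length(intersect(unique(production$year), unique(prices$year))) == 0) {
    stop("no overlap between production and price years", call. = FALSE)
  }

  tab <- production |>
    dplyr::left_join(prices, by = c("country_id", "crop_id", "year")) |>
    dplyr::left_join(corrections, by = c("country_id", "year")) |>
    dplyr::left_join(dependency, by = "crop_id")

  missing_price <- is.na(tab$price_nominal)
  if (impute == "country-mean" && any(missing_price)) {
    tab <- tab |>
      dplyr::group_by(.data$country_id, .data$year) |>
      dplyr::mutate(price_nominal = ifelse(
        is.na(.data$price_nominal),
        mean(.data$price_nominal, na.rm = TRUE),
        .data$price_nominal)) |>
      dplyr::ungroup()
    tab$price_nominal[is.nan(tab$price_nominal)] <- NA_real_
    missing_price <- is.na(tab$price_nominal)
  }
  missing_corr <- is.na(tab$inflation_factor) | is.na(tab$ppp_factor)
  missing_dep <- is.na(tab$dr_median)
  tab$complete <- !(missing_price | missing_corr | missing_dep)

  attr(tab, "coverage") <- list(
    n_production = nrow(tab),
    n_complete = sum(tab$complete),
    n_excluded = sum(!tab$complete),
    n_missing_price = sum(missing_price),
    n_missing_correction = sum(missing_corr),
    n_missing_dependency = sum(missing_dep)
  )
  tab
}

#' Join coverage statistics of an aligned table
#'
#' @param aligned Output of [align_panels()].
#' @return The `coverage` attribute: a list of row counts.
#' @export
alignment_coverage <- function(aligned) {
  cov <- attr(aligned, "coverage")
  if (is.null(cov)) stop("not an aligned table (no coverage attribute)",
                         call. = FALSE)
  cov
}
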