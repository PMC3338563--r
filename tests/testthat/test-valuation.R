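test_that("corrected_price is the plain product of its three factors", {
  expect_equal(corrected_price(100, 1.2, 1.5), 180)
  expect_equal(corrected_price(100, 1, 1), 100)
  expect_equal(corrected_price(0, 2.3, 0.7), 0)
  expect_error(corrected_price(-1, 1, 1), "negative")
})

test_that("benefit, weighted quantity and price signal match hand sums", {
  p <- hand_panel()
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  b <- pollination_benefit(aligned, "median", "global")
  expect_equal(b$value, 200 * 50 * 0.65 + 100 * 10 * 0.05) # 6550
  q <- weighted_quantity(aligned, "median", "global")
  expect_equal(q$value, 50 * 0.65 + 10 * 0.05) # 33
  s <- price_signal(b, q)
  expect_equal(s$value, 6550 / 33)
  expect_false(any(s$undefined))

  # zero dependency kills the benefit everywhere
  zero_dep <- p$dependency
  zero_dep[, c("dr_lower", "dr_median", "dr_upper")] <- 0
  aligned0 <- align_panels(p$production, p$prices, p$corrections, zero_dep)
  expect_equal(pollination_benefit(aligned0, "median", "global")$value, 0)
})

test_that("grouped sums equal the naive triple-loop oracle", {
  p <- random_panels(5, 8, 4, seed = 101)
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  for (sc in c("lower", "median", "upper")) {
    oracle <- brute_force_benefit(p$production, p$prices, p$corrections,
                                  p$dependency, paste0("dr_", sc))
    got <- pollination_benefit(aligned, sc, "global")
    expect_equal(got$value, unname(oracle), tolerance = 1e-9)

    oq <- brute_force_benefit(p$production, p$prices, p$corrections,
                              p$dependency, paste0("dr_", sc),
                              weight_only = TRUE)
    gq <- weighted_quantity(aligned, sc, "global")
    expect_equal(gq$value, unname(oq), tolerance = 1e-9)
  }
  # per-country grouping agrees with filtering the panel per country
  bc <- pollination_benefit(aligned, "median", "country")
  for (co in unique(p$production$country_id)) {
    sub <- brute_force_benefit(
      p$production[p$production$country_id == co, ],
      p$prices, p$corrections, p$dependency)
    expect_equal(bc$value[bc$group == co], unname(sub), tolerance = 1e-9)
  }
})

test_that("monetary-corrected weighted quantity applies inf and ppp", {
  p <- random_panels(3, 3, 2, seed = 9)
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  q_plain <- weighted_quantity(aligned, "median", "global")
  q_corr <- weighted_quantity(aligned, "median", "global",
                              monetary_corrections = TRUE)
  oracle <- sapply(sort(unique(aligned$year)), function(yr) {
    rows <- aligned[aligned$year == yr, ]
    sum(rows$quantity * rows$dr_median * rows$inflation_factor *
          rows$ppp_factor)
  })
  expect_equal(q_corr$value, oracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(q_plain$value, q_corr$value)))
})

test_that("price signal flags years with zero weighted quantity", {
  p <- hand_panel()
  two_years <- lapply(p[c("production", "prices")], function(d) {
    d2 <- d; d2$year <- 2001L
    rbind(d, d2)
  })
  two_years$production$quantity[two_years$production$year == 2001] <- 0
  corr <- rbind(p$corrections, transform(p$corrections, year = 2001L))
  aligned <- align_panels(two_years$production, two_years$prices, corr,
                          p$dependency)
  b <- pollination_benefit(aligned, "median", "global")
  q <- weighted_quantity(aligned, "median", "global")
  s <- price_signal(b, q)
  expect_true(s$undefined[s$year == 2001])
  expect_true(is.na(s$value[s$year == 2001]))
  expect_false(s$undefined[s$year == 2000])
})

test_that("staple baseline is the dr = 1 machinery on the staple set", {
  dep <- tibble::tibble(
    crop_id = c("wheat", "fruit"),
    dr_lower = c(0, 0.6), dr_median = c(0, 0.6), dr_upper = c(0, 0.6),
    is_staple = c(TRUE, FALSE))
  production <- tibble::tibble(country_id = "AAA",
                               crop_id = c("wheat", "fruit"),
                               year = 2000L, quantity = c(20, 5))
  prices <- tibble::tibble(country_id = "AAA",
                           crop_id = c("wheat", "fruit"),
                           year = 2000L, price_nominal = c(150, 800))
  corr <- tibble::tibble(country_id = "AAA", year = 2000L,
                         inflation_factor = 1, ppp_factor = 1)
  aligned <- align_panels(production, prices, corr, dep)
  base <- staple_baseline(aligned)
  expect_equal(base$value$value, 150 * 20) # 3000
  expect_equal(base$quantity$value, 20)
  expect_equal(base$price$value, 150)

  # definitional equality: value == pollination_benefit with dr forced to 1
  p <- random_panels(4, 5, 3, seed = 77)
  p$dependency$is_staple <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  p$dependency[p$dependency$is_staple,
               c("dr_lower", "dr_median", "dr_upper")] <- 0
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  base <- staple_baseline(aligned)
  forced <- aligned[aligned$is_staple, ]
  forced$dr_median <- 1
  expect_equal(base$value$value,
               pollination_benefit(forced, "median", "global")$value,
               tolerance = 1e-12)
  expect_error(staple_baseline(aligned, staples = "no_such_crop"),
               "no staple rows")
})

test_that("base-year indexing normalises to 1 and is idempotent", {
  s <- pollvalue:::.pv_series(
    tibble::tibble(group = "global", year = 1993:1995, value = c(2, 4, 6)),
    "benefit", "median", "global")
  idx <- index_to_base(s, 1993)
  expect_equal(idx$value, c(1, 2, 3))
  expect_identical(idx$value[idx$year == 1993], 1)
  expect_equal(index_to_base(idx, 1993)$value, idx$value)
  expect_error(index_to_base(s, 1990), "not present")
  s0 <- s; s0$value[1] <- 0
  expect_error(index_to_base(s0, 1993), "zero")
})

test_that("scenario bounds are ordered and collapse when ratios collapse", {
  p <- random_panels(6, 6, 5, seed = 13)
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  for (grouping in c("global", "country", "crop")) {
    b <- scenario_bounds(aligned, grouping)
    expect_true(all(b$lower$value <= b$median$value + 1e-12))
    expect_true(all(b$median$value <= b$upper$value + 1e-12))
  }
  collapsed <- p$dependency
  collapsed$dr_lower <- collapsed$dr_upper <- collapsed$dr_median
  ac <- align_panels(p$production, p$prices, p$corrections, collapsed)
  bc <- scenario_bounds(ac, "global")
  expect_equal(bc$lower$value, bc$median$value)
  expect_equal(bc$median$value, bc$upper$value)
  zero_low <- p$dependency
  zero_low$dr_lower <- 0
  az <- align_panels(p$production, p$prices, p$corrections, zero_low)
  expect_true(all(pollination_benefit(az, "lower", "global")$value == 0))
})

test_that("benefit is additive over disjoint country sets", {
  p <- random_panels(6, 4, 3, seed = 19)
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  countries <- unique(aligned$country_id)
  set_a <- countries[1:3]
  va <- pollination_benefit(aligned[aligned$country_id %in% set_a, ],
                            "median", "global")
  vb <- pollination_benefit(aligned[!aligned$country_id %in% set_a, ],
                            "median", "global")
  vall <- pollination_benefit(aligned, "median", "global")
  expect_equal(va$value + vb$value, vall$value, tolerance = 1e-12)
})

test_that("disabling ppp equals forcing every ppp factor to 1", {
  p <- random_panels(5, 4, 3, seed = 31)
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  no_ppp <- pollination_benefit(aligned, "median", "country",
                                ppp_enabled = FALSE)
  forced <- aligned
  forced$ppp_factor <- 1
  expect_identical(no_ppp$value,
                   pollination_benefit(forced, "median", "country")$value)
})

test_that("sums are stable under row permutation", {
  p <- random_panels(8, 8, 5, seed = 41)
  aligned <- align_panels(p$production, p$prices, p$corrections,
                          p$dependency)
  set.seed(1)
  shuffled <- aligned[sample.int(nrow(aligned)), ]
  attr(shuffled, "coverage") <- attr(aligned, "coverage")
  a <- pollination_benefit(aligned, "median", "global")$value
  b <- pollination_benefit(shuffled, "median", "global")$value
  expect_equal(a, b, tolerance = 1e-9)
})
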