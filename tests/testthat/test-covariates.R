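test_that("relative humidity follows the Magnus formula", {
  expect_equal(relative_humidity(25, 25), 100)
  # independent evaluation of the saturation vapour pressure ratio
  magnus <- function(td, t) {
    100 * exp(17.625 * td / (243.04 + td)) / exp(17.625 * t / (243.04 + t))
  }
  expect_equal(relative_humidity(25, 20), magnus(20, 25),
               tolerance = 1e-12)
  expect_equal(relative_humidity(0, -10), magnus(-10, 0),
               tolerance = 1e-12)
  # fixed dewpoint, rising temperature: strictly decreasing RH
  rh <- relative_humidity(seq(10, 35, by = 0.5), 5)
  expect_true(all(diff(rh) < 0))
  expect_warning(out <- relative_humidity(10, 12), "clamped")
  expect_equal(out, 100)
  expect_error(relative_humidity(NA, 5), "finite")
})

test_that("ICE metric arithmetic, bounds and antisymmetry", {
  expect_equal(ice(1000, 0, 1000), 1)
  expect_equal(ice(300, 300, 900), 0)
  expect_equal(ice(200, 500, 1000), -0.3)
  set.seed(131)
  for (i in 1:25) {
    tot <- sample(100:10000, 1)
    a <- sample(0:tot, 1); p <- sample(0:(tot - a), 1)
    v <- ice(a, p, tot)
    expect_true(v >= -1 && v <= 1)
    expect_equal(ice(p, a, tot), -v, tolerance = 1e-15)
  }
  expect_warning(v0 <- ice(0, 0, 0), "zero")
  expect_true(is.na(v0))
  expect_error(ice(-1, 0, 10), "non-negative")
  expect_error(ice(8, 8, 10), "exceed")
})

test_that("ICE quartiles orient Q1 to the most advantaged extreme", {
  expect_equal(as.character(ice_quartiles(c(0.9, 0.5, -0.5, -0.9))),
               c("Q1", "Q2", "Q3", "Q4"))
  expect_true(all(ice_quartiles(rep(0.2, 8)) == "Q1"))
  # rank oracle: for 4k distinct values, the top k are Q1, next k Q2, ...
  set.seed(141)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    v <- runif(4 * k, -1, 1)
    labs <- ice_quartiles(v)
    rk <- rank(-v)  # 1 = most advantaged
    oracle <- paste0("Q", ceiling(rk / k))
    expect_equal(as.character(labs), oracle)
  }
  expect_error(ice_quartiles(c(1, 2, 3)), "at least 4")
})

test_that("area-weighted aggregation is a weighted mean per zone", {
  grid <- tibble::tibble(cell_id = c("c1", "c2"), value = c(10, 20))
  w <- tibble::tibble(cell_id = c("c1", "c2"), zone_id = "z1",
                      weight = c(1, 3))
  expect_equal(area_weighted_mean(grid, w)$value, 17.5)
  # constant field: every zone gets the constant
  grid2 <- tibble::tibble(cell_id = paste0("c", 1:6), value = 4.2)
  w2 <- tibble::tibble(cell_id = paste0("c", 1:6),
                       zone_id = rep(c("z1", "z2"), 3),
                       weight = runif(6, 0.1, 2))
  expect_true(all(area_weighted_mean(grid2, w2)$value == 4.2))
  # weight rescaling leaves results unchanged
  w3 <- dplyr::mutate(w2, weight = weight * 7.3)
  expect_equal(area_weighted_mean(grid2, w3)$value,
               area_weighted_mean(grid2, w2)$value, tolerance = 1e-12)
  wz <- tibble::tibble(cell_id = "c1", zone_id = "z9", weight = 0)
  expect_error(area_weighted_mean(grid, wz), "zero total weight")
})

test_that("ICD-10 codes map to the diagnosis blocks", {
  suppressMessages({
    expect_equal(as.character(classify_icd10("F10.10")), "substance")
    expect_equal(as.character(classify_icd10("F32.9")), "mood")
    expect_equal(as.character(classify_icd10("F41.1")), "anxiety")
    expect_equal(as.character(classify_icd10("F20")), "other_mbd")
    expect_equal(as.character(classify_icd10("G30")), "excluded")
    expect_equal(as.character(classify_icd10(c("f19", "F39", "F49", "F99",
                                               "F09"))),
                 c("substance", "mood", "anxiety", "other_mbd",
                   "other_mbd"))
    expect_equal(as.character(classify_icd10(c("", "F1", "10F"))),
                 rep("excluded", 3))
  })
})

make_toy_records <- function(n = 400, seed = 151) {
  set.seed(seed)
  tibble::tibble(
    admission_date = as.Date("2016-01-01") +
      sample(0:729, n, replace = TRUE),
    zip5 = sample(c("27001", "27002", "27003"), n, replace = TRUE),
    icd10_code = sample(c("F10.1", "F32", "F41.9", "F60", "G44"), n,
                        replace = TRUE),
    age_years = sample(0:95, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}

toy_crosswalk <- tibble::tibble(
  zip5 = c("27001", "27002", "27003", "27003"),
  zone_id = c("Z1", "Z2", "Z2", "Z3"),
  weight = c(1, 1, 0.3, 0.7)
)

test_that("count aggregation conserves totals and fills empty days", {
  rec <- make_toy_records()
  suppressMessages(
    panel <- aggregate_counts(rec, toy_crosswalk,
                              date_range = as.Date(c("2016-01-01",
                                                     "2017-12-31")))
  )
  n_retained <- sum(classify_icd10(rec$icd10_code) != "excluded")
  expect_equal(sum(panel$count), n_retained)
  # every zone-day present exactly once
  expect_equal(nrow(panel), 3 * 731)
  expect_true(all(panel$count >= 0))
  # one-to-many zip resolved to the largest weight: 27003 -> Z3
  suppressMessages(
    p3 <- aggregate_counts(rec[rec$zip5 == "27003", ], toy_crosswalk,
                           date_range = as.Date(c("2016-01-01",
                                                  "2017-12-31")))
  )
  expect_equal(sum(p3$count[p3$zone_id == "Z2"]), 0)
})

test_that("subgroup filters partition the total counts", {
  rec <- make_toy_records(600)
  dr <- as.Date(c("2016-01-01", "2017-12-31"))
  suppressMessages({
    total <- aggregate_counts(rec, toy_crosswalk, date_range = dr)
    ages <- lapply(list(c(0, 25), c(26, 49), c(50, 64), c(65, Inf)),
                   function(ar) {
                     aggregate_counts(rec, toy_crosswalk, date_range = dr,
                                      age_range = ar)
                   })
    sexes <- lapply(c("male", "female"), function(sx) {
      aggregate_counts(rec, toy_crosswalk, date_range = dr, sex = sx)
    })
    groups <- lapply(c("substance", "mood", "anxiety", "other_mbd"),
                     function(gp) {
                       aggregate_counts(rec, toy_crosswalk, date_range = dr,
                                        icd_group = gp)
                     })
  })
  agg <- function(lst) Reduce(`+`, lapply(lst, function(p) p$count))
  expect_equal(agg(ages), total$count)
  expect_equal(agg(sexes), total$count)
  expect_equal(agg(groups), total$count)
})

test_that("published regional visit counts sum to the state totals", {
  chk <- check_region_totals()
  expect_true(all(chk$matches))
  expect_equal(chk$region_sum, chk$state_total)
})

test_that("ice_table labels quartiles from the computed metrics", {
  zones <- tibble::tibble(
    zone_id = paste0("Z", 1:8),
    income_adv = c(800, 650, 500, 350, 250, 150, 80, 20),
    income_dis = c(50, 100, 200, 300, 400, 500, 600, 700),
    income_total = 1000,
    race_adv = c(900, 800, 700, 600, 400, 300, 200, 100),
    race_dis = c(50, 100, 200, 300, 500, 600, 700, 800),
    race_total = 1000
  )
  tab <- ice_table(zones)
  expect_true(all(tab$ice_income >= -1 & tab$ice_income <= 1))
  expect_equal(as.character(tab$income_quartile),
               paste0("Q", rep(1:4, each = 2)))
  expect_equal(as.character(tab$race_quartile),
               paste0("Q", rep(1:4, each = 2)))
})
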