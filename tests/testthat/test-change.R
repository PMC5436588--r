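years4 <- c(a = 1950, b = 1970, c = 1990, d = 2010)

toy_table <- function(nfc_a, nfc_d, extra = NULL) {
  n <- length(nfc_a)
  base <- data.frame(cell = rep(seq_len(n), 2),
                     period = rep(c("a", "d"), each = n),
                     NFC = c(nfc_a, nfc_d))
  if (!is.null(extra)) base <- cbind(base, extra)
  base
}

test_that("change rate is the NFC difference per decade", {
  tab <- toy_table(0.5, 0.3)
  ch <- change_table(tab, "a", "d", years4)
  expect_equal(ch$d_nfc, -0.2)
  expect_equal(ch$change_rate, -0.2 / 6, tolerance = 1e-12)
  expect_equal(change_table(toy_table(0.4, 0.4), "a", "d", years4)$change_rate, 0)
  expect_error(change_table(tab, "a", "z", years4), "period")
  # raw and relative variants
  expect_equal(change_table(tab, "a", "d", years4, rate = "raw")$change_rate, -0.2)
  expect_equal(change_table(tab, "a", "d", years4, rate = "relative")$change_rate,
               -0.4)
})

test_that("change records match an independent spreadsheet-style recomputation", {
  sim <- small_sim()
  tab <- sim$cell_table
  scn <- sim$scenario
  yrs <- period_years_of(scn)
  ch <- change_table(tab, scn$periods[1], scn$periods[4], yrs)
  a <- tab[tab$period == scn$periods[1], ]
  d <- tab[tab$period == scn$periods[4], ]
  d <- d[match(a$cell, d$cell), ]
  expect_equal(ch$change_rate, (d$NFC - a$NFC) / 6)
  expect_equal(ch$d_SRL_main, d$SRL_main - a$SRL_main)
})

test_that("simple regression reproduces exact fits and rejects degenerate input", {
  x <- 1:4
  # exact fits make summary.lm grumble about perfection; that is the point
  r <- suppressWarnings(simple_regression(x, 2 * x))
  expect_equal(r$slope, 2)
  expect_equal(r$adj_r_squared, 100)
  # zero-covariance sample: slope and R2 exactly zero
  x0 <- c(-1, 1, -1, 1); y0 <- c(-1, -1, 1, 1)
  r0 <- simple_regression(x0, y0)
  expect_equal(r0$slope, 0)
  expect_equal(r0$r_squared, 0)
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "constant")
})

test_that("regression summaries match the normal-equations oracle", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(50); y <- 0.3 * x + rnorm(50)
    got <- simple_regression(x, y)
    want <- ols_oracle(x, y)
    for (f in c("slope", "intercept", "adj_r_squared", "f", "p")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
    }
  }
})

test_that("indicator power ranks indicators and handles degenerate columns", {
  set.seed(8)
  n <- 400
  d <- data.frame(cell = 1:n, period_pair = "a:d",
                  change_rate = rnorm(n),
                  d_SRL_main = rnorm(n), d_DNR_main = rnorm(n),
                  d_NON_main = rnorm(n), d_MND_main = rnorm(n),
                  d_SRL_secondary = rnorm(n), d_DNR_secondary = rnorm(n),
                  d_NON_secondary = rnorm(n), d_MND_secondary = 0)
  d$change_rate <- 0.8 * d$d_SRL_main + rnorm(n, 0, 0.3)
  expect_message(ip <- indicator_power(d), "degenerate")
  expect_equal(nrow(ip), 7)  # MND_secondary skipped
  top <- ip[which.max(ip$adj_r_squared), ]
  expect_equal(paste(top$indicator, top$class), "SRL main")
  # duplicated indicator gives identical rows
  d2 <- d
  d2$d_NON_main <- d2$d_SRL_main
  ip2 <- indicator_power(d2)
  expect_equal(ip2$adj_r_squared[ip2$indicator == "NON" & ip2$class == "main"],
               ip2$adj_r_squared[ip2$indicator == "SRL" & ip2$class == "main"])
})

test_that("variation partition identity holds and degenerate groups behave", {
  set.seed(31)
  n <- 300
  mk <- function() rnorm(n)
  d <- data.frame(change_rate = mk(),
                  d_SRL_main = mk(), d_DNR_main = mk(), d_NON_main = mk(),
                  d_MND_main = mk(), d_SRL_secondary = mk(),
                  d_DNR_secondary = mk(), d_NON_secondary = mk(),
                  d_MND_secondary = mk())
  d$change_rate <- 0.9 * d$d_SRL_main + 0.2 * d$d_DNR_main + rnorm(n, 0, 0.5)
  vp <- variation_partition(d)
  expect_equal(vp$unique_main + vp$unique_secondary + vp$shared,
               vp$adj_r2_combined, tolerance = 1e-10)
  # secondary group pure noise: its unique component is ~0
  expect_lt(abs(vp$unique_secondary), 3)
  expect_gt(vp$unique_main, 20)
  # identical main and secondary groups: all signal shared
  d3 <- d
  for (ind in c("SRL", "DNR", "NON", "MND")) {
    d3[[paste0("d_", ind, "_secondary")]] <- d3[[paste0("d_", ind, "_main")]]
  }
  vp3 <- suppressWarnings(variation_partition(d3))
  expect_equal(vp3$shared, vp3$adj_r2_combined, tolerance = 1)
  expect_lt(abs(vp3$unique_main), 1)
  # all-constant group: intercept-only convention, identity still exact
  d4 <- d
  for (ind in c("SRL", "DNR", "NON", "MND")) d4[[paste0("d_", ind, "_secondary")]] <- 1
  vp4 <- variation_partition(d4)
  expect_equal(vp4$adj_r2_secondary, 0)
  expect_equal(vp4$unique_main + vp4$unique_secondary + vp4$shared,
               vp4$adj_r2_combined, tolerance = 1e-10)
})

test_that("NFC-vs-rate regression detects coupling and exact nulls", {
  set.seed(77)
  n <- 200
  nfc1 <- runif(n, 0.1, 0.9)
  # rate exactly orthogonal to initial NFC by construction
  raw <- rnorm(n)
  rate0 <- residuals(lm(raw ~ nfc1))
  tab <- data.frame(cell = rep(1:n, 2), period = rep(c("a", "d"), each = n),
                    NFC = c(nfc1, nfc1 + rate0 * 6))
  r0 <- nfc_vs_rate_slope(tab, "a", "d", years4)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  # exact linear coupling: R2 = 100%
  tab2 <- data.frame(cell = rep(1:n, 2), period = rep(c("a", "d"), each = n),
                     NFC = c(nfc1, nfc1 + (0.2 * nfc1 - 0.1) * 6))
  r2 <- suppressWarnings(nfc_vs_rate_slope(tab2, "a", "d", years4))
  expect_equal(r2$r_squared, 100, tolerance = 1e-8)
  expect_equal(r2$slope, 0.2, tolerance = 1e-10)
})
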