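test_that("intrinsic water-use efficiency is assimilation per conductance", {
  expect_equal(wue_i(15, 0.3), 50)
  expect_equal(wue_i(0, 0.3), 0)
  expect_error(wue_i(15, 0), "positive")
})

test_that("seasonality CV matches the hand-computed n-1 form and scales", {
  x <- c(rep(10, 6), rep(20, 6))
  expect_equal(seasonality_cv(x), 100 * sqrt(300 / 11) / 15)
  expect_equal(seasonality_cv(x), 34.82, tolerance = 1e-3)
  expect_equal(seasonality_cv(rep(7, 12)), 0)
  expect_error(seasonality_cv(x - 15), "undefined CV")
  expect_error(seasonality_cv(1:11), "12 monthly")
  # scale invariance for positive scalings
  expect_equal(seasonality_cv(3.7 * x), seasonality_cv(x))
})

test_that("percent change is signed and scale-invariant", {
  expect_equal(percent_change(10, 20), -50)
  expect_equal(percent_change(23, 20), 15)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(-3 * 10, -3 * 20), percent_change(10, 20))
  expect_error(percent_change(1, 0), "nonzero")
})

test_that("Bonferroni division reproduces the study threshold", {
  expect_identical(bonferroni_alpha(0.05, 25), 0.002)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
})

test_that("gas-phase contribution is the conductance ratio within (0, 100]", {
  expect_equal(gias_contribution(1.0, 0.2), 20)
  expect_equal(gias_contribution(0.3, 0.3), 100)
  expect_equal(gias_contribution(1e12, 0.2), 0, tolerance = 1e-9)
  expect_error(gias_contribution(0.1, 0.2), "inconsistent")
})

test_that("correlation matrix matches a covariance-formula oracle", {
  set.seed(41)
  d <- data.frame(a = rnorm(11), b = rnorm(11))
  d$c <- 2 * d$a + 1          # perfectly linear pair
  res <- correlation_matrix(d, c("a"), c("b", "c"))
  r_oracle <- sum((d$a - mean(d$a)) * (d$b - mean(d$b))) /
    sqrt(sum((d$a - mean(d$a))^2) * sum((d$b - mean(d$b))^2))
  expect_equal(res$r[res$y == "b"], r_oracle)
  t_oracle <- r_oracle * sqrt(9) / sqrt(1 - r_oracle^2)
  expect_equal(res$p[res$y == "b"], 2 * pt(-abs(t_oracle), 9))
  expect_equal(res$r[res$y == "c"], 1)
  expect_equal(res$r_squared[res$y == "c"], 1)

  # symmetric in its arguments, r bounded
  swapped <- correlation_matrix(d, c("b"), c("a"))
  expect_equal(res$r[res$y == "b"], swapped$r[1])
  expect_true(all(abs(res$r) <= 1))

  # degenerate columns flagged, not numbered
  d$z <- 5
  resz <- correlation_matrix(d, "a", "z")
  expect_equal(resz$flag, "zero_variance")
  expect_true(is.na(resz$r))

  # log transform option
  d$pos <- exp(d$a)
  reslog <- correlation_matrix(d, "a", "pos",
                               transforms = list(pos = "log"))
  expect_equal(reslog$r, 1)
})

test_that("dehydration comparison separates distinct true responses", {
  set.seed(55)
  mk <- function(acc, true_change_pct, n = 5, sd_pct = 2) {
    ww <- 20 + rnorm(n, sd = 0.001)
    dh <- ww * (1 + true_change_pct / 100) + rnorm(n, sd = 20 * sd_pct / 100)
    rbind(data.frame(accession_id = acc, treatment = "well_watered",
                     replicate = 1:n, An = ww),
          data.frame(accession_id = acc, treatment = "dehydrated",
                     replicate = 1:n, An = dh))
  }
  tab <- rbind(mk("A1", -50), mk("A2", -20))
  res <- dehydration_comparison(tab, "An", alpha_adjusted = 0.002)
  expect_equal(nrow(res), 2)
  # mean of 5 replicate changes with sd 2%: allow a ~3 SE statistical band
  expect_equal(res$mean_pct[res$accession_id == "A1"], -50, tolerance = 0.06)
  expect_equal(res$mean_pct[res$accession_id == "A2"], -20, tolerance = 0.15)
  expect_equal(res$differs_from[res$accession_id == "A1"], "A2")
  expect_equal(res$differs_from[res$accession_id == "A2"], "A1")

  # identical arms: zero change, no significant pairs
  same <- rbind(
    data.frame(accession_id = "B1", treatment = "well_watered",
               replicate = 1:5, An = c(18, 19, 20, 21, 22)),
    data.frame(accession_id = "B1", treatment = "dehydrated",
               replicate = 1:5, An = c(18, 19, 20, 21, 22)),
    data.frame(accession_id = "B2", treatment = "well_watered",
               replicate = 1:5, An = c(15, 16, 17, 18, 19)),
    data.frame(accession_id = "B2", treatment = "dehydrated",
               replicate = 1:5, An = c(15, 16, 17, 18, 19)))
  res2 <- dehydration_comparison(same, "An")
  expect_equal(res2$mean_pct, c(0, 0))
  expect_equal(res2$differs_from, c("", ""))

  # single replicate: SE undefined flag
  single <- rbind(
    data.frame(accession_id = "C1", treatment = "well_watered",
               replicate = 1, An = 20),
    data.frame(accession_id = "C1", treatment = "dehydrated",
               replicate = 1, An = 15))
  res3 <- dehydration_comparison(single, "An")
  expect_true(is.na(res3$se_pct))

  # missing arm excluded with a warning
  expect_warning(
    dehydration_comparison(rbind(tab, data.frame(accession_id = "A3",
                                                 treatment = "well_watered",
                                                 replicate = 1:5, An = 20)),
                           "An"),
    "lacks a treatment arm")
})
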