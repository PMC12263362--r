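test_that("relative risk is exp(z * log OR per SD)", {
  expect_equal(relative_risk(0, log(1.56)), 1)
  expect_equal(relative_risk(1, log(1.56)), 1.56)
  expect_equal(relative_risk(1.2816, log(1.56)), 1.768107,
               tolerance = 1e-6)
  expect_error(relative_risk(NA, 0.4), "finite")
})

test_that("combined relative risk is the ancestry-weighted mean", {
  rr <- matrix(c(2, 1), 1, 2, dimnames = list(NULL, c("EUR", "AFR")))
  q <- matrix(c(0.6, 0.4), 1, 2, dimnames = list(NULL, c("EUR", "AFR")))
  expect_equal(combine_relative_risk(rr, q), 1.6)
  expect_equal(combine_relative_risk(rr, q, scale = "log"),
               exp(0.6 * log(2)))
  q1 <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("EUR", "AFR")))
  expect_equal(combine_relative_risk(rr, q1), 2)
  rr_c <- matrix(c(1.3, 1.3), 1, 2, dimnames = list(NULL, c("EUR", "AFR")))
  expect_equal(combine_relative_risk(rr_c, q), 1.3)
})

test_that("category mean relative risk matches the truncated-normal
          integral", {
  b <- log(1.56)
  expect_equal(category_rr(0.2, 0.7, 0), 1)
  expect_equal(category_rr(0, 1, b), exp(b^2 / 2))
  # numerical-integration oracle over the truncated normal
  oracle <- integrate(function(z) exp(b * z - z^2 / 2) / sqrt(2 * pi),
                      qnorm(0.9), 40, rel.tol = 1e-10)$value / 0.1
  expect_equal(category_rr(0.9, 1, b), oracle, tolerance = 1e-8)
  expect_equal(category_rr(0.9, 1, b), 2.2226, tolerance = 1e-4)
  expect_error(category_rr(0.5, 0.5, b), "bin")
})

test_that("risk categories partition the percentile scale with correct
          shares", {
  rc <- risk_categories(c(0, 0.3, 0.7, 0.9, 1), log(1.56),
                        labels = c("low", "standard", "moderate", "high"))
  expect_equal(sum(rc$share), 1)
  expect_equal(rc$share, c(0.3, 0.4, 0.2, 0.1))
  expect_true(all(diff(rc$rr) > 0))
  expect_error(risk_categories(c(0, 0.5, 0.9), 0.4), "breaks")
})

test_that("incidence recalibration preserves the population constraint
          exactly", {
  lt <- toy_life(0.01, 0.002)
  # hand example: w = (0.5, 0.5), RR = (1, 3), I_pop = 0.01
  cats <- structure(data.frame(label = c("a", "b"), p_lo = c(0, 0.5),
                               p_hi = c(0.5, 1), share = c(0.5, 0.5),
                               rr = c(1, 3)),
                    class = c("risk_categories", "data.frame"))
  rec <- recalibrate_incidence(lt, cats)
  expect_equal(unname(rec$incidence[1, ]), c(0.005, 0.015))
  expect_equal(drop(rec$incidence %*% cats$share), lt$incidence)

  # single category with RR = 1, and equal RRs, reproduce I_pop
  one <- structure(data.frame(label = "all", p_lo = 0, p_hi = 1, share = 1,
                              rr = 1),
                   class = c("risk_categories", "data.frame"))
  expect_equal(unname(recalibrate_incidence(lt, one)$incidence[, 1]),
               lt$incidence)
  eq <- structure(data.frame(label = c("a", "b"), p_lo = c(0, 0.6),
                             p_hi = c(0.6, 1), share = c(0.6, 0.4),
                             rr = c(2.5, 2.5)),
                  class = c("risk_categories", "data.frame"))
  expect_equal(unname(recalibrate_incidence(lt, eq)$incidence[, 1]),
               lt$incidence)
})

test_that("recalibration constraint holds at machine precision over random
          partitions and relative risks", {
  set.seed(14)
  lt <- gen_life_table()
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    breaks <- sort(c(0, runif(k - 1), 1))
    rc <- risk_categories(breaks, runif(1, 0.1, 0.9))
    rc$rr <- rc$rr * exp(rnorm(k, 0, 0.2))  # perturb off the normal form
    rec <- recalibrate_incidence(lt, rc)
    expect_lt(max(abs(drop(rec$incidence %*% rc$share) - lt$incidence)),
              1e-12)
  }
})

test_that("recalibrated incidence reaching 1 is an error naming age and
          category", {
  lt <- toy_life(0.5, 0)
  cats <- structure(data.frame(label = c("lo", "hi"), p_lo = c(0, 0.9),
                               p_hi = c(0.9, 1), share = c(0.9, 0.1),
                               rr = c(0.1, 10)),
                    class = c("risk_categories", "data.frame"))
  expect_error(recalibrate_incidence(lt, cats), "age 40.*hi")
})

test_that("cumulative absolute risk matches closed forms and the direct
          summation oracle", {
  # zero incidence
  lt0 <- toy_life(0, 0.01)
  one <- structure(data.frame(label = "all", p_lo = 0, p_hi = 1, share = 1,
                              rr = 1),
                   class = c("risk_categories", "data.frame"))
  expect_equal(max(cumulative_absolute_risk(recalibrate_incidence(lt0, one),
                                            "all", 40, 10)$ar), 0)
  # m = 0: AR = 1 - (1 - h)^T
  lt1 <- toy_life(0.01, 0)
  ar1 <- cumulative_absolute_risk(recalibrate_incidence(lt1, one), "all",
                                  40, 10)
  expect_equal(ar1$ar[10], 1 - 0.99^10, tolerance = 1e-12)
  # competing mortality: direct summation oracle sum (0.98 * 0.99)^u * 0.01
  lt2 <- toy_life(0.01, 0.02)
  ar2 <- cumulative_absolute_risk(recalibrate_incidence(lt2, one), "all",
                                  40, 10)
  expect_equal(ar2$ar[10], sum(0.01 * (0.99 * 0.98)^(0:9)),
               tolerance = 1e-12)
  expect_true(all(diff(ar2$ar) > 0))
  expect_true(all(diff(ar2$p_nd) < 0) && all(diff(ar2$survival) < 0))
  expect_error(cumulative_absolute_risk(recalibrate_incidence(lt2, one),
                                        "all", 20, 10), "grid")
})

test_that("absolute risk is monotone in horizon, mortality and relative
          risk", {
  lt <- gen_life_table()
  one <- structure(data.frame(label = "all", p_lo = 0, p_hi = 1, share = 1,
                              rr = 1),
                   class = c("risk_categories", "data.frame"))
  rec <- recalibrate_incidence(lt, one)
  ar <- cumulative_absolute_risk(rec, "all", 50, 30)$ar
  expect_true(all(diff(ar) >= 0))
  # higher competing mortality lowers risk pointwise
  lt_hi_m <- gen_life_table(mortality_at_50 = 0.02)
  ar_hi_m <- cumulative_absolute_risk(recalibrate_incidence(lt_hi_m, one),
                                      "all", 50, 30)$ar
  expect_true(all(ar_hi_m <= ar))
  # risk is nondecreasing in z (hence in RR)
  risks <- vapply(c(-2, -1, 0, 1, 2), function(z)
    ten_year_risk(z, log_or_per_sd = log(1.56), life = lt, age = 50)$risk,
    numeric(1))
  expect_true(all(diff(risks) > 0))
})

test_that("ten-year risk of an average individual equals the population
          value and the full chain matches a brute-force recomputation", {
  lt <- gen_life_table()
  one <- structure(data.frame(label = "all", p_lo = 0, p_hi = 1, share = 1,
                              rr = 1),
                   class = c("risk_categories", "data.frame"))
  pop <- cumulative_absolute_risk(recalibrate_incidence(lt, one), "all",
                                  50, 10)$ar[10]
  expect_equal(ten_year_risk(rr = 1, life = lt, age = 50)$risk, pop,
               tolerance = 1e-12)

  # end-to-end brute-force oracle at the 90th percentile
  b <- log(1.56)
  z <- qnorm(0.9)
  rr <- exp(b * z)
  inc <- lt$incidence * rr / exp(b^2 / 2)
  i0 <- match(50, lt$age)
  pnd <- 1; s <- 1; ar <- 0
  for (u in 0:9) {
    ar <- ar + pnd * s * inc[i0 + u]
    pnd <- pnd * (1 - lt$mortality_other[i0 + u])
    s <- s * (1 - inc[i0 + u])
  }
  expect_equal(ten_year_risk(z, log_or_per_sd = b, life = lt,
                             age = 50)$risk,
               ar, tolerance = 1e-12)
})

test_that("multi-panel ten-year risk uses ancestry-weighted relative risk
          and normalizer", {
  lt <- gen_life_table()
  b <- log(1.56)
  z <- c(EUR = 1, AFR = -0.5)
  q <- c(EUR = 0.6, AFR = 0.4)
  out <- ten_year_risk(z, proportions = q, log_or_per_sd = b, life = lt,
                       age = 50)
  expect_equal(out$rr, 0.6 * exp(b) + 0.4 * exp(-0.5 * b))
  expect_equal(out$mean_rr, exp(b^2 / 2))
})

test_that("risk-equivalent age has the population fixed point at the
          reference age and is monotone in risk", {
  lt <- gen_life_table()
  b <- log(1.56)
  ref <- risk_equivalent_age(rr = 1, life = lt, reference_age = 50)
  expect_identical(ref$age, 50)
  expect_false(ref$clamped)
  ages <- vapply(c(0.5, 1, 1.5, 2), function(z)
    risk_equivalent_age(z, log_or_per_sd = b, life = lt)$age, numeric(1))
  expect_true(all(diff(ages) < 0))
  expect_true(all(ages < 50))
  # far below-average risk on a rising table never reaches the threshold
  low <- risk_equivalent_age(-8, log_or_per_sd = b, life = toy_life(
    incidence = 0.001, mortality = 0, ages = 40:60), reference_age = 50)
  expect_true(low$clamped)
})

test_that("risk-equivalent age agrees with a fine grid-search oracle on a
          linear-incidence table", {
  ages <- 30:80
  lt <- life_table("lin", ages, incidence = 1e-4 * (ages - 25),
                   mortality_other = rep(0.005, length(ages)))
  b <- log(2)   # one-SD individual carries RR = 2
  got <- risk_equivalent_age(1, log_or_per_sd = b, life = lt,
                             reference_age = 50)
  # oracle: 10-year risk at integer ages, linear interpolation, 0.01 grid
  grid_ages <- 30:70
  risks <- vapply(grid_ages, function(a)
    ten_year_risk(1, log_or_per_sd = b, life = lt, age = a)$risk,
    numeric(1))
  thr <- ten_year_risk(0, log_or_per_sd = 0, life = lt, age = 50)$risk
  fine <- seq(30, 70, by = 0.01)
  rf <- approx(grid_ages, risks, xout = fine)$y
  oracle <- fine[which(rf >= thr - 1e-12)[1]]
  expect_lt(abs(got$age - oracle), 0.011)
  expect_lt(got$age, 50)
})
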