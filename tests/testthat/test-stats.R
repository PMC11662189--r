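test_that("weekly aggregation averages features and rounds mood", {
  d <- as.Date("2020-03-16") + 0:6
  f <- data.frame(participant = "P01", date = d, location_variance = -9,
                  homestay = 0.6)
  e <- data.frame(participant = "P01", date = d,
                  fatigue = c(1, 1, 2, 2, 2, 3, 3), depressed = 2,
                  manic = 1, irritability = 1)
  w <- weekly_aggregate(f, e)
  expect_equal(w$location_variance, -9)
  expect_equal(w$fatigue, 2)  # rounded mean category of (1,1,2,2,2,3,3)
  # a participant with only 3 valid days is excluded
  f3 <- f[1:3, ]; e3 <- e[1:3, ]
  w3 <- weekly_aggregate(f3, e3)
  expect_equal(nrow(w3), 0)
  expect_equal(attr(w3, "excluded"), "P01")
})

test_that("polyserial estimate is near zero under independence", {
  set.seed(51)
  x <- rnorm(10000)
  y <- sample(1:5, 10000, replace = TRUE)
  ps <- polyserial_cor(x, y)
  expect_lt(abs(ps$rho), 0.03)
  expect_gt(ps$p_value, 0.01)
})

test_that("polyserial recovers a planted latent correlation of 0.5", {
  set.seed(52)
  n <- 5000
  x <- rnorm(n)
  latent <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  y <- findInterval(latent, c(-1.2, -0.3, 0.5, 1.4)) + 1
  ps <- polyserial_cor(x, y)
  expect_lt(abs(ps$rho - 0.5), 0.03)
  expect_lt(ps$p_value, 1e-10)
})

test_that("polyserial approaches Pearson in the many-category limit", {
  set.seed(53)
  x <- rnorm(4000)
  y <- as.integer(cut(x, quantile(x, seq(0, 1, length.out = 26)),
                      include.lowest = TRUE))
  ps <- polyserial_cor(x, y)
  expect_lt(abs(ps$rho - 1), 0.02)  # latent here is x itself
})

test_that("polyserial is affine-invariant in x and flips sign", {
  set.seed(54)
  x <- rnorm(2000)
  y <- findInterval(0.6 * x + 0.8 * rnorm(2000), c(-0.5, 0.5)) + 1
  r0 <- polyserial_cor(x, y)$rho
  expect_equal(polyserial_cor(3 * x + 10, y)$rho, r0, tolerance = 1e-6)
  expect_equal(polyserial_cor(-x, y)$rho, -r0, tolerance = 1e-6)
})

test_that("a constant ordinal margin is reported as undefined", {
  ps <- polyserial_cor(rnorm(100), rep(3, 100))
  expect_true(is.na(ps$rho))
})

test_that("day-pair construction counts pairs like brute force", {
  d <- as.Date("2020-03-01") + 0:179
  parts <- data.frame(participant = "P01", age = 40, sex = 1, group = "MDD")
  f <- data.frame(participant = "P01", date = d, location_variance = rnorm(180),
                  normalized_entropy = runif(180), homestay = runif(180))
  e <- data.frame(participant = "P01", date = d, fatigue = 2, depressed = 2,
                  manic = 1, irritability = 1)
  pairs <- build_day_pairs(f, e, parts)
  expect_equal(nrow(pairs), 179)
  # one missing day breaks pairing on both sides
  e2 <- e[-90, ]
  pairs2 <- build_day_pairs(f, e2, parts)
  expect_equal(nrow(pairs2), 177)
  # random missingness: independent enumeration oracle
  set.seed(55)
  keep <- runif(180) > 0.08
  e3 <- e[keep, ]
  pairs3 <- build_day_pairs(f, e3, parts)
  brute <- sum(vapply(seq_len(179), function(i)
    keep[i] && keep[i + 1], TRUE))
  expect_equal(nrow(pairs3), brute)
})

test_that("reversing day order negates the delta terms exactly", {
  set.seed(56)
  d <- as.Date("2020-03-01") + 0:29
  parts <- data.frame(participant = "P01", age = 40, sex = 0, group = "BP")
  f <- data.frame(participant = "P01", date = d, location_variance = rnorm(30),
                  normalized_entropy = runif(30), homestay = runif(30))
  e <- data.frame(participant = "P01", date = d, fatigue = sample(1:5, 30, TRUE),
                  depressed = 2, manic = 1, irritability = 1)
  fwd <- build_day_pairs(f, e, parts)
  rev_f <- f; rev_f$date <- rev(d); rev_e <- e; rev_e$date <- rev(d)
  bwd <- build_day_pairs(rev_f, rev_e, parts)
  expect_equal(sort(bwd$d_homestay), sort(-fwd$d_homestay))
  expect_equal(sort(bwd$d_fatigue), sort(-fwd$d_fatigue))
})

test_that("GEE with independence equals OLS on a single cluster", {
  set.seed(57)
  d <- data.frame(y = rnorm(80), x1 = rnorm(80), x2 = runif(80), id = "a")
  g <- gee_ar1(y ~ x1 + x2, d, id = "id", corstr = "independence")
  o <- lm(y ~ x1 + x2, d)
  expect_equal(unname(coef(g)), unname(coef(o)), tolerance = 1e-10)
})

test_that("the lag GEE recovers a planted delta coefficient", {
  pairs <- make_pairs(n_part = 40, n_pairs = 170, beta = 0.5, seed = 58)
  fit <- fit_lag_model(pairs, "feature_to_mood", outcome = "depressed",
                       predictor = "homestay")
  expect_lt(abs(fit$delta$beta - 0.5), 2 * fit$delta$se)
  expect_lt(fit$delta$p, 0.05)
  expect_gt(fit$alpha, 0.1)  # picked up the AR(1) residual correlation
})

test_that("delta-term inference tolerates participant-level outcome offsets", {
  pairs <- make_pairs(n_part = 30, n_pairs = 80, beta = 0.4, seed = 59)
  off <- ave(rnorm(nrow(pairs)), pairs$participant, FUN = function(z) z[1])
  pairs2 <- pairs
  pairs2$depressed_2 <- pairs2$depressed_2 + 3 * off
  f1 <- fit_lag_model(pairs, "feature_to_mood", "depressed", "homestay")
  f2 <- fit_lag_model(pairs2, "feature_to_mood", "depressed", "homestay")
  expect_lt(abs(f1$delta$beta - f2$delta$beta),
            2 * (f1$delta$se + f2$delta$se))
})

test_that("small day-pair tables are refused", {
  pairs <- make_pairs(n_part = 1, n_pairs = 5)
  expect_error(fit_lag_model(pairs, "feature_to_mood", "depressed",
                             "homestay"), "at least")
})

test_that("Fisher-z sample sizes match the published anchors", {
  expect_equal(fisher_required_n(0.5, 0.05, 0.80), 29L)
  expect_equal(fisher_required_n(0.5, 0.05, 0.90), 38L)
  expect_equal(fisher_required_n(0.99, 0.05, 0.80), 4L)
})

test_that("Fisher-z power matches its anchors and limits", {
  expect_equal(round(fisher_power(0.364, 45, 0.05), 2), 0.70)
  expect_gt(fisher_power(0.2, 5000, 0.05), 0.999)
  expect_lt(abs(fisher_power(0.5, 29, 0.05) - 0.80), 0.005)
})

test_that("required n and power are mutually consistent", {
  for (rho in c(0.2, 0.364, 0.5, 0.7)) {
    for (pw in c(0.8, 0.9)) {
      n <- fisher_required_n(rho, 0.05, pw)
      # round-to-nearest sits within one unit of the exact inversion
      n_star <- 4
      while (fisher_power(rho, n_star, 0.05) < pw) n_star <- n_star + 1
      expect_lte(abs(n - n_star), 1)
      expect_gte(fisher_power(rho, n, 0.05), pw - 0.02)
      expect_lt(fisher_power(rho, n - 1, 0.05), pw)
    }
  }
})
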