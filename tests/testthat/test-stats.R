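test_that("winsorization caps the upper tail at the 95th percentile", {
  expect_equal(winsorize_upper(rep(3, 20)), rep(3, 20))
  x <- as.numeric(1:100)
  w <- winsorize_upper(x)
  cap <- quantile(x, 0.95, names = FALSE, type = 1)
  expect_equal(max(w), cap)
  expect_equal(w[x <= cap], x[x <= cap])
  expect_true(all(w[x > cap] == cap))
  # weak monotonicity preserved
  expect_true(all(diff(w) >= 0))
  expect_error(winsorize_upper(numeric()), "empty")
})

test_that("winsorization is idempotent", {
  set.seed(83)
  for (rep in 1:20) {
    x <- rexp(sample(10:200, 1)) * 10
    w <- winsorize_upper(x)
    expect_equal(winsorize_upper(w), w, tolerance = 1e-12)
  }
})

test_that("power transforms reduce to their defining special cases", {
  x <- c(0.5, 1, 2, 5)
  expect_equal(apply_power_transform(x, 1, "box_cox"), x - 1)
  expect_equal(apply_power_transform(x, 0, "box_cox"), log(x))
  expect_error(apply_power_transform(c(-1, 2), 0.5, "box_cox"),
               "yeo_johnson")
  # Yeo-Johnson agrees with Box-Cox on x + 1 for positive values
  expect_equal(apply_power_transform(x, 0.5, "yeo_johnson"),
               apply_power_transform(x + 1, 0.5, "box_cox"),
               tolerance = 1e-12)
  # and is defined for negatives
  expect_true(all(is.finite(apply_power_transform(c(-3, -0.1, 0, 2), 0.7,
                                                  "yeo_johnson"))))
})

test_that("lambda search recovers the log-normal normalizing transform", {
  set.seed(89)
  x <- exp(rnorm(10000))
  fit <- fit_power_transform(x, "box_cox")
  expect_lt(abs(fit$lambda), 0.1)
  # identity data prefers lambda near 1
  y <- rnorm(5000, mean = 20, sd = 1)
  fit2 <- fit_power_transform(y, "box_cox")
  expect_lt(abs(fit2$lambda - 1), 0.5)
})

test_that("lambda search agrees with the established reference fitter", {
  skip_if_not_installed("car")
  set.seed(97)
  x <- rgamma(2000, shape = 2, scale = 3)
  ours <- fit_power_transform(x, "box_cox")
  ref <- car::powerTransform(x, family = "bcPower")
  expect_equal(ours$lambda, unname(ref$lambda), tolerance = 0.02)
  yj <- rnorm(2000)^3
  ours_yj <- fit_power_transform(yj, "yeo_johnson")
  ref_yj <- car::powerTransform(yj, family = "yjPower")
  expect_equal(ours_yj$lambda, unname(ref_yj$lambda), tolerance = 0.02)
})

test_that("the normality gate chooses Pearson or Spearman appropriately", {
  set.seed(101)
  x <- seq(1, 20, length.out = 50) + rnorm(50, 0, 0.01)
  r <- gated_correlation(x, x + rnorm(50, 0, 1e-6))
  expect_equal(r$estimate, 1, tolerance = 1e-4)
  r2 <- gated_correlation(x, -x)
  expect_equal(r2$estimate, -1, tolerance = 1e-6)
  # heavy-tailed inputs flip the gate to Spearman nearly always
  methods <- vapply(1:100, function(s) {
    set.seed(s)
    xx <- stats::rcauchy(200)
    yy <- xx + stats::rcauchy(200)
    gated_correlation(xx, yy)$method
  }, character(1))
  expect_gte(mean(methods == "spearman"), 0.95)
  expect_error(gated_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(gated_correlation(1:3, 1:3), "4")
})

test_that("the gate and estimate are symmetric in their arguments", {
  set.seed(103)
  for (rep in 1:10) {
    x <- rexp(40)
    y <- 0.5 * x + rnorm(40)
    a <- gated_correlation(x, y)
    b <- gated_correlation(y, x)
    expect_equal(a$method, b$method)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  }
})

test_that("BY adjustment reproduces hand-computed and reference values", {
  expect_equal(by_adjust(0.03), 0.03)
  # c(3) = 11/6; BH-adjusted (0.01, 0.02, 0.03) are all 0.03; times 11/6
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(by_adjust(c(0.2, NA, 0.01)),
               c(stats::p.adjust(c(0.2, 0.01), "BY")[1], NA,
                 stats::p.adjust(c(0.2, 0.01), "BY")[2]))
})

test_that("BY matches the reference implementation and dominates BH", {
  set.seed(107)
  for (rep in 1:300) {
    m <- sample(1:40, 1)
    p <- runif(m)
    ours <- by_adjust(p)
    expect_equal(ours, stats::p.adjust(p, method = "BY"), tolerance = 1e-12)
    expect_equal(ours, oracle_by_adjust(p), tolerance = 1e-12)
    expect_true(all(ours >= stats::p.adjust(p, method = "BH") - 1e-12))
    # monotone in sorted order
    expect_true(all(diff(ours[order(p)]) >= -1e-12))
  }
})
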