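test_that("component fits reproduce closed-form least-squares solutions", {
  set.seed(19)
  x <- rnorm(30); m <- 0.4 + 1.1 * x + rnorm(30)
  y <- -0.2 + 0.7 * x + 0.9 * m + rnorm(30)
  tot <- fit_total_effect(x, y)
  expect_equal(tot$c, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  expect_equal(tot$beta1, unname(coef(lm(y ~ x))[1]), tolerance = 1e-10)
  fm <- fit_mediator_model(x, m)
  fy <- fit_outcome_model(x, m, y)
  lm_m <- lm(m ~ x); lm_y <- lm(y ~ x + m)
  expect_equal(fm$a, unname(coef(lm_m)[2]), tolerance = 1e-10)
  expect_equal(fm$se_a, coef(summary(lm_m))[2, 2], tolerance = 1e-10)
  expect_equal(fy$c_prime, unname(coef(lm_y)[2]), tolerance = 1e-10)
  expect_equal(fy$b, unname(coef(lm_y)[3]), tolerance = 1e-10)
  expect_equal(fy$se_b, coef(summary(lm_y))[3, 2], tolerance = 1e-10)
  # rank deficiency is reported, not silently absorbed
  expect_error(fit_outcome_model(x, 2 * x + 1, y), "rank-deficient")
})

test_that("an exactly determined triad is decomposed without error", {
  set.seed(8)
  d <- make_exact_triad(n = 20, a = 2, b = 3, c_prime = 1)
  res <- mediate_loop(d$x, d$m, d$y, n_boot = 200, seed = 1)
  expect_equal(res$acme, 6, tolerance = 1e-8)
  expect_equal(res$ade, 1, tolerance = 1e-8)
  expect_equal(res$te, 7, tolerance = 1e-8)
  expect_equal(res$c, 7, tolerance = 1e-8)
  expect_lt(max(abs(residuals(res, "outcome"))), 1e-8)
})

test_that("effect identities hold exactly in the linear case", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    x <- rnorm(n)
    m <- rnorm(n, 0.5 * x)
    y <- rnorm(n, 0.3 * x - 0.8 * m)
    res <- mediate_loop(x, m, y, n_boot = 100, seed = i)
    expect_equal(res$te, res$acme + res$ade, tolerance = 1e-10)
    expect_equal(res$c, res$a * res$b + res$c_prime, tolerance = 1e-10)
    expect_equal(res$acme, res$a * res$b, tolerance = 1e-10)
    expect_equal(unname(coef(res)["te"]), res$te)
  }
})

test_that("bootstrap intervals are reproducible under a seed and respond to
           the confidence level", {
  set.seed(3)
  x <- rnorm(60); m <- 0.8 * x + rnorm(60); y <- 0.5 * m + rnorm(60)
  r1 <- mediate_loop(x, m, y, n_boot = 400, seed = 7)
  r2 <- mediate_loop(x, m, y, n_boot = 400, seed = 7)
  expect_identical(r1$acme_ci, r2$acme_ci)
  expect_identical(r1$acme_p, r2$acme_p)
  wide <- mediate_loop(x, m, y, n_boot = 400, seed = 7, ci_level = 0.99)
  expect_lte(wide$acme_ci[1], r1$acme_ci[1])
  expect_gte(wide$acme_ci[2], r1$acme_ci[2])
  # p-values are floored by the resample count
  expect_gte(r1$acme_p, 2 / (400 + 1))
  expect_error(mediate_loop(x, m, y, n_boot = 10), "n_boot")
})

test_that("the Sobel standard error follows the delta-method formula", {
  expect_equal(sobel_se(a = 2, b = 1, se_a = 0.3, se_b = 0.2),
               sqrt(0.3^2 * 1^2 + 0.2^2 * 2^2), tolerance = 1e-12)
  expect_equal(sobel_se(1, 1, 0, 0), 0)
  ci95 <- sobel_ci(0.5, 0.1, 0.95)
  ci99 <- sobel_ci(0.5, 0.1, 0.99)
  expect_equal(ci95, 0.5 + qnorm(c(0.025, 0.975)) * 0.1, tolerance = 1e-12)
  expect_lt(ci99[1], ci95[1])
  expect_gt(ci99[2], ci95[2])
})

test_that("the Sobel SE tracks the bootstrap spread on a large sample", {
  set.seed(101)
  n <- 1000
  x <- rnorm(n); m <- 0.6 * x + rnorm(n); y <- 0.5 * x + 0.7 * m + rnorm(n)
  res <- mediate_loop(x, m, y, n_boot = 1000, seed = 5)
  expect_lt(abs(res$sobel_se - res$boot_sd["acme"]) / res$boot_sd["acme"],
            0.15)
})

test_that("spline models capture a cubic dose-response that a line misses", {
  set.seed(55)
  n <- 300
  x <- runif(n, -1.5, 1.5)
  m <- x^3 + rnorm(n, sd = 0.1)
  fm_s <- fit_mediator_model(x, m, kind = "spline")
  fm_l <- fit_mediator_model(x, m, kind = "linear")
  grid <- seq(-1.4, 1.4, length.out = 50)
  rmse <- function(f) sqrt(mean((f$predict(grid) - grid^3)^2))
  expect_lt(rmse(fm_s), 0.05)
  expect_gt(rmse(fm_l), 0.2)
  # on truly linear data the spline route agrees with the linear estimate
  m2 <- 1.3 * x + rnorm(n, sd = 0.3)
  y2 <- 0.4 * x + 0.8 * m2 + rnorm(n, sd = 0.3)
  r_lin <- mediate_loop(x, m2, y2, n_boot = 150, seed = 2)
  r_spl <- mediate_loop(x, m2, y2, kind_m = "spline", kind_y = "spline",
                        n_boot = 150, seed = 2)
  expect_equal(r_spl$acme, r_lin$acme, tolerance = 0.1)
  expect_equal(r_spl$te, r_lin$te, tolerance = 0.1)
})

test_that("the sensitivity curve passes through the point estimate at rho = 0
           and is monotone in the confounding", {
  set.seed(12)
  x <- rnorm(100); m <- 0.9 * x + rnorm(100)
  y <- 0.3 * x + 0.6 * m + rnorm(100)
  res <- mediate_loop(x, m, y, n_boot = 150, seed = 1)
  s <- sensitivity(res)
  at0 <- s$acme_at_rho[which.min(abs(s$rho_grid))]
  expect_equal(at0, res$acme, tolerance = 1e-10)
  expect_equal(s$acme0, res$acme, tolerance = 1e-10)
  expect_true(all(diff(s$acme_at_rho) < 0) || all(diff(s$acme_at_rho) > 0))
  # the curve crosses zero where the adjusted ACME changes sign
  if (!is.na(s$rho_zero)) {
    f <- approxfun(s$rho_grid, s$acme_at_rho)
    expect_lt(abs(f(s$rho_zero)), 0.02)
  }
  r_spl <- mediate_loop(x, m, y, kind_m = "spline", n_boot = 150, seed = 1)
  expect_error(sensitivity(r_spl), "linear case only")
})

test_that("sensitivity recovers a planted confounding correlation", {
  # with b = 0 and correlated disturbances, the naive ACME is pure
  # confounding, so the curve should vanish near the planted rho
  set.seed(31)
  n <- 4000
  rho <- 0.5
  x <- rnorm(n)
  z <- rnorm(n)                      # shared confounder
  e2 <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
  e3 <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
  m <- 1.0 * x + e2
  y <- 0.4 * x + 0 * m + e3
  res <- mediate_loop(x, m, y, n_boot = 150, seed = 9)
  s <- sensitivity(res)
  expect_equal(s$rho_zero, cor(e2, e3), tolerance = 0.1)
})

test_that("print, summary, confint and plot methods behave", {
  set.seed(6)
  d <- make_exact_triad(n = 25)
  res <- mediate_loop(d$x, d$m, d$y, n_boot = 150, seed = 4,
                      loop = c("miR-1", "Tf1", "GeneA"))
  out <- capture.output(print(res))
  expect_true(any(grepl("ACME", out)))
  expect_true(any(grepl("miR-1", out)))
  sout <- capture.output(print(summary(res)))
  expect_true(any(grepl("Sobel", sout)))
  ci <- confint(res)
  expect_equal(rownames(ci), c("acme", "ade", "te"))
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  pdf(NULL)
  expect_invisible(plot(res))
  s <- sensitivity(res)
  expect_invisible(plot(s))
  dev.off()
  expect_equal(nrow(sensitivity_table(s)), length(s$rho_grid))
})
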