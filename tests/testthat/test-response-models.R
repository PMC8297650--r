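# RSA, Fv/Fm, increase rates, linear yields, hyperbolic fits.

test_that("RSA formula matches hand arithmetic and rejects bad input", {
  expect_equal(rsa(0.5, 0.5), 0)
  expect_equal(rsa(0.5, 0.0), 100)
  expect_equal(rsa(0.8, 0.2), 75)
  expect_error(rsa(0, 0.1), "positive")
  # invariant under common rescaling of both absorbances
  expect_equal(rsa(0.8, 0.2), rsa(8, 2))
})

test_that("Fv/Fm matches hand arithmetic and flags the healthy range", {
  expect_equal(fv_fm(300, 1500), 0.8)
  expect_equal(fv_fm(0, 1200), 1.0)
  expect_error(fv_fm(1600, 1500), "f0")
  expect_equal(fv_fm_status(c(0.82, 0.825, 0.83, 0.7)),
               c("normal", "normal", "normal", "stressed"))
})

test_that("increase rate sign convention and scale invariance", {
  expect_equal(increase_rate(5, 5), 0)
  expect_equal(increase_rate(10, 5), 100)
  expect_lt(increase_rate(4, 5), 0)
  expect_equal(increase_rate(6, 5), increase_rate(60, 50))
  expect_error(increase_rate(1, 0), "control")
})

test_that("linear yield fit equals the closed-form normal equations", {
  set.seed(4)
  x <- runif(40, 0, 100)
  y <- 0.03 * x + 2 + rnorm(40, 0, 0.3)
  fit <- fit_linear_yield(x, y)
  oracle <- ols_oracle_(x, y)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-9)
})

test_that("linear fit: noiseless line exact, constant response flat", {
  x <- seq(1, 10)
  fit <- fit_linear_yield(x, 2 * x + 5)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  flat <- fit_linear_yield(x, rep(3, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0)
  expect_error(fit_linear_yield(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_linear_yield(rep(2, 5), 1:5), "degenerate")
})

test_that("noisy linear recovery lands within 3 standard errors", {
  set.seed(11)
  x <- runif(100, 0, 120)
  g <- 0.05
  y <- g * x + 4 + rnorm(100, 0, 0.5)
  fit <- fit_linear_yield(x, y)
  expect_lt(abs(fit$slope - g) / fit$slope_se, 3)
})

test_that("hyperbolic fits recover noiseless generating parameters", {
  x <- seq(2, 130, length.out = 40)
  for (form in c("F1", "F2", "F3")) {
    a <- if (form == "F2") 60 else 400
    b <- 20
    y <- hyperbolic_response(form, x, a, b)
    f <- fit_hyperbolic(x, y, form = form)
    expect_true(f$converged)
    expect_equal(f$a, a, tolerance = 1e-6)
    expect_equal(f$b, b, tolerance = 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
})

test_that("fitting the wrong hyperbolic form gives strictly worse R2", {
  x <- seq(2, 130, length.out = 40)
  y <- hyperbolic_response("F1", x, 400, 20)
  right <- fit_hyperbolic(x, y, form = "F1")
  wrong <- fit_hyperbolic(x, y, form = "F2")
  expect_gt(right$r2, wrong$r2)
})

test_that("noisy hyperbolic recovery improves with sample size", {
  recover <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 5, 130)
    y <- hyperbolic_response("F2", x, 60, 20) * (1 + rnorm(n, 0, 0.05))
    f <- fit_hyperbolic(x, y, form = "F2")
    abs(c(f$a - 60, f$b - 20) / c(60, 20))
  }
  err_small <- rowMeans(sapply(1:5, function(s) recover(30, s)))
  err_large <- rowMeans(sapply(1:5, function(s) recover(300, s)))
  expect_lt(err_large[1], err_small[1])
  expect_lt(err_large[2], err_small[2])
  # 5% noise, n = 60: median over 3 seeds within 10% of truth
  est <- sapply(1:3, function(s) {
    set.seed(s)
    x <- runif(60, 5, 130)
    y <- hyperbolic_response("F2", x, 60, 20) * (1 + rnorm(60, 0, 0.05))
    f <- fit_hyperbolic(x, y, form = "F2")
    c(f$a, f$b)
  })
  expect_lt(abs(median(est[1, ]) - 60) / 60, 0.10)
  expect_lt(abs(median(est[2, ]) - 20) / 20, 0.10)
})

test_that("F3 rejects non-positive doses; R2 definition is honoured", {
  expect_error(fit_hyperbolic(c(0, 1, 2), c(1, 2, 3), form = "F3"),
               "positive")
  x <- seq(2, 100, length.out = 30)
  set.seed(2)
  y <- hyperbolic_response("F2", x, 50, 15) + rnorm(30, 0, 2)
  f <- fit_hyperbolic(x, y, form = "F2")
  yhat <- hyperbolic_response("F2", x, f$a, f$b)
  r2_indep <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(f$r2, r2_indep, tolerance = 1e-9)
})

test_that("yield report lays out stages x positions with both model columns", {
  mk <- function(stage, pos, r2)
    structure(list(slope = 1, intercept = 0, r2 = r2, n = 10,
                   position_class = pos, stage = stage),
              class = "yield_fit")
  mkh <- function(stage, pos, r2)
    structure(list(form = "F2", a = 1, b = 1, r2 = r2, n = 10,
                   converged = TRUE, position_class = pos, stage = stage),
              class = "eq_hyperbolic_fit")
  lin <- list(TFC = list(), TPC = list())
  nl <- list(TFC = list(), TPC = list())
  for (st in c("14DAT", "28DAT")) for (po in c("upper", "middle", "lower")) {
    key <- paste(st, po, sep = ".")
    lin$TFC[[key]] <- mk(st, po, 1)
    lin$TPC[[key]] <- mk(st, po, 1)
    nl$TFC[[key]] <- mkh(st, po, 1)
    nl$TPC[[key]] <- mkh(st, po, 1)
  }
  tab <- yield_report(lin, nl)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("linear_regression_TFC", "linear_regression_TPC",
                    "nonlinear_regression_TFC", "nonlinear_regression_TPC")
                  %in% names(tab)))
  expect_true(all(tab$linear_regression_TFC == 1))
})
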