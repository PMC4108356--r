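test_that("log-likelihood equals an independent term-by-term sum", {
  x <- mixed_sample()
  ml <- 0.82; sl <- 0.66
  # oracle: per-term logs written out directly from the model definition
  pmf <- function(t) pnorm((log(t) - ml) / sl) -
    ifelse(t > 1, pnorm((log(t - 1) - ml) / sl), 0)
  surv <- function(t) ifelse(t == 0, 1, 1 - pnorm((log(t) - ml) / sl))
  oracle <- sum(log(pmf(c(2, 3, 1, 5, 2)))) +      # complete
    log(surv(4)) + log(surv(0)) + log(surv(6)) +   # right-censored
    log(surv(2)) + log(surv(0))                    # left-censored at l - 1
  expect_equal(fire_loglik(x, ml, sl, stationary = FALSE), oracle,
               tolerance = 1e-10)

  # stationary mode adds a -log(mean interval) penalty per left-censored
  # observation; oracle mean from an independent brute-force survival sum
  mu <- brute_mean(ml, sl)
  expect_equal(fire_loglik(x, ml, sl, stationary = TRUE),
               oracle - 2 * log(mu), tolerance = 1e-6)
})

test_that("single observations contribute the documented amounts", {
  one <- data.frame(length = 2L, status = "complete")
  two <- rbind(one, one)  # fitting needs 2+ completes; loglik does not
  expect_equal(fire_loglik(one, 0.82, 0.66), log(0.3167522),
               tolerance = 1e-5)
  expect_equal(fire_loglik(one, 0.82, 0.66), -1.1496, tolerance = 1e-4)
  # a right-censored observation of length 0 contributes exactly 0
  rc0 <- data.frame(length = c(2L, 0L),
                    status = c("complete", "right_censored"))
  expect_identical(fire_loglik(rc0, 0.82, 0.66),
                   fire_loglik(one, 0.82, 0.66))
  expect_equal(fire_loglik(two, 0.82, 0.66),
               2 * fire_loglik(one, 0.82, 0.66))
})

test_that("degenerate and invalid samples are rejected or flagged", {
  expect_error(fire_loglik(data.frame(length = integer(0),
                                      status = character(0)), 1, 1),
               "empty")
  allcens <- data.frame(length = c(0L, 0L), status = "right_censored")
  expect_error(fire_loglik(allcens, 1, 1), "informative")
  expect_error(fire_fit(data.frame(length = 3L, status = "complete")),
               "at least 2 complete")
  expect_error(fire_fit(data.frame(length = c(2, -1),
                                   status = "complete")),
               "non-negative")
  expect_error(fire_fit(data.frame(length = c(2, 2),
                                   status = c("complete", "oops"))),
               "status")
  # identical complete intervals: sdlog collapses below the bin width
  # and the fit is flagged degenerate
  fit <- fire_fit(rep(3, 25))
  expect_true(fit$degenerate)
  expect_lt(unname(coef(fit)[["sdlog"]]), 0.1)
})

test_that("maximum likelihood recovers parameters from complete samples", {
  set.seed(101)
  x <- rfireint(5000, 0.82, 0.66)
  fit <- fire_fit(x)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(coef(fit)[["meanlog"]] - 0.82), 0.05)
  expect_lt(abs(coef(fit)[["sdlog"]] - 0.66), 0.05)
  # deterministic: same sample, same fit
  expect_identical(coef(fire_fit(x)), coef(fit))
})

test_that("estimation bias shrinks as the sample grows", {
  err <- sapply(c(500, 5000), function(n) {
    set.seed(202)
    reps <- replicate(8, {
      x <- rfireint(n, 1.19, 0.91)
      coef(fire_fit(x))
    })
    sqrt(mean((reps["meanlog", ] - 1.19)^2))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("fit on censored window samples stays close to the truth", {
  set.seed(33)
  x <- simulate_intervals(1500, 12, 0.90, 0.80)
  fit <- fire_fit(x)
  expect_lt(abs(coef(fit)[["meanlog"]] - 0.90), 0.08)
  expect_lt(abs(coef(fit)[["sdlog"]] - 0.80), 0.08)
  # the naive left-censored convention lands visibly higher on meanlog
  fit_naive <- fire_fit(x, stationary = FALSE)
  expect_gt(coef(fit_naive)[["meanlog"]], coef(fit)[["meanlog"]])
})

test_that("fitted object carries descriptors, counts and diagnostics", {
  set.seed(404)
  x <- simulate_intervals(400, 12, 0.82, 0.66)
  fit <- fire_fit(x)
  expect_s3_class(fit, "firefit")
  expect_identical(sum(fit$counts), nrow(x))
  expect_true(all(c(fit$median, fit$mode, fit$turning_point) >= 1))
  d <- fire_descriptors(coef(fit)[["meanlog"]], coef(fit)[["sdlog"]])
  expect_identical(fit$median, d$median)
  expect_identical(fit$turning_point, d$turning_point)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_identical(attr(logLik(fit), "df"), 2L)
})
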