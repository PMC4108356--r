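test_that("identical seeds reproduce burn masks bit for bit", {
  cls <- data.frame(class = "SS", meanlog = 0.82, sdlog = 0.66,
                    fraction = 1)
  g1 <- simulate_history(fire_sim_config(15, 15, cls, years = 12,
                                         burn_in = 20, seed = 31))
  g2 <- simulate_history(fire_sim_config(15, 15, cls, years = 12,
                                         burn_in = 20, seed = 31))
  g3 <- simulate_history(fire_sim_config(15, 15, cls, years = 12,
                                         burn_in = 20, seed = 32))
  expect_identical(g1$burns, g2$burns)
  expect_false(identical(g1$burns, g3$burns))
  expect_identical(attr(g1, "sim_meta")$seed, 31L)
})

test_that("zero-hazard override produces an unburned landscape", {
  cls <- data.frame(class = "SS", meanlog = 0.82, sdlog = 0.66,
                    fraction = 1)
  cfg <- fire_sim_config(8, 8, cls, years = 12, burn_in = 10,
                         hazard_override = 0, seed = 1)
  g <- simulate_history(cfg)
  expect_false(any(g$burns))
  iv <- extract_intervals(g, spacing_m = 500)
  expect_true(all(iv$status == "right_censored" & iv$length == 12L))
  expect_error(fire_fit(iv), "at least 2 complete")
})

test_that("a near-degenerate interval law burns almost periodically", {
  # meanlog in the interior of the (1, 2] bin so the whole-year binning
  # concentrates on a single interval length
  cls <- data.frame(class = "P2", meanlog = log(1.7), sdlog = 0.05,
                    fraction = 1)
  g <- simulate_history(fire_sim_config(30, 30, cls, years = 12,
                                        burn_in = 30, seed = 9))
  iv <- extract_intervals(g, spacing_m = 500)
  comp <- iv$length[iv$status == "complete"]
  expect_gt(length(comp), 500)
  expect_gt(mean(comp == 2), 0.9)
})

test_that("complete intervals from the landscape follow the interval law", {
  cls <- data.frame(class = "SS", meanlog = 0.82, sdlog = 0.66,
                    fraction = 1)
  g <- simulate_history(fire_sim_config(40, 40, cls, years = 12,
                                        burn_in = 50, seed = 17))
  iv <- extract_intervals(g, spacing_m = 500)
  fit <- fire_fit(iv)
  expect_lt(abs(coef(fit)[["meanlog"]] - 0.82), 0.1)
  expect_lt(abs(coef(fit)[["sdlog"]] - 0.66), 0.1)
  ht <- hp_test(iv, fit, B = 150, seed = 4)
  expect_gt(ht$p.value, 0.01)
})

test_that("class strips and explicit class maps label the landscape", {
  cls <- data.frame(class = c("A", "B"), meanlog = c(0.8, 1.8),
                    sdlog = c(0.7, 1.0), fraction = c(0.25, 0.75))
  g <- simulate_history(fire_sim_config(10, 20, cls, years = 12,
                                        burn_in = 10, seed = 2))
  expect_identical(sum(g$land_cover == "A"), 10L * 5L)
  cm <- matrix("B", 10, 20); cm[1:3, ] <- "A"
  g2 <- simulate_history(fire_sim_config(10, 20, cls, class_map = cm,
                                         years = 12, burn_in = 10,
                                         seed = 2))
  expect_identical(g2$land_cover, cm)
  expect_error(fire_sim_config(10, 20, cls[1, ], years = 12),
               "sum to 1")
})

test_that("record-window point samples mirror the landscape extraction", {
  set.seed(23)
  x <- simulate_intervals(300, 12, 0.82, 0.66)
  expect_identical(attr(x, "record_years"), 12L)
  # one from-origin observation per point
  origin <- x$status == "left_censored" |
    (x$status == "right_censored" & x$length >= 12L)
  expect_identical(sum(origin), 300L)
  # per-point bookkeeping: k fires give k + 1 observations
  k <- table(factor(x$point_id, levels = 1:300))
  burned <- unique(x$point_id[x$status == "left_censored"])
  expect_true(all(k[as.character(burned)] >= 2))
})

test_that("over a long record the complete intervals follow the pmf", {
  # a long window makes the within-window selection of completes negligible,
  # so the pooled complete intervals are draws from the interval pmf itself
  set.seed(24)
  x <- simulate_intervals(200, 400, 0.82, 0.66)
  comp <- x$length[x$status == "complete"]
  expect_gt(length(comp), 10000)
  obs <- tabulate(pmin(comp, 10), nbins = 10)
  p <- dfireint(1:10, 0.82, 0.66)
  p[10] <- p[10] + (1 - sum(p))
  expect_gt(chisq.test(obs, p = p)$p.value, 0.001)
})

test_that("long-run burn frequency approaches the renewal rate", {
  # renewal reward: the long-run fraction of years a cell burns is 1/E[T];
  # agreement tightens as the record grows
  errs <- sapply(c(50, 400), function(N) {
    set.seed(N)
    x <- simulate_intervals(150, N, 0.90, 0.80)
    # count fires directly: a point with k fires has k - 1 completes
    # plus one left-censored observation
    k_total <- sum(x$status == "complete") +
      length(unique(x$point_id[x$status == "left_censored"]))
    abs(k_total / (150 * N) - 1 / fireint_mean(0.90, 0.80))
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05 / fireint_mean(0.90, 0.80))
})
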