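test_that("interval pmf matches published and directly computed values", {
  # Shrub Savanna parameters: two-year interval probability prints as 0.32
  expect_equal(round(dfireint(2, 0.82, 0.66), 2), 0.32)
  expect_equal(dfireint(2, 0.82, 0.66), 0.3167522, tolerance = 1e-6)
  # t = 1 case: lower bin edge collapses to -Inf
  expect_equal(dfireint(1, 0.82, 0.66), pnorm(-0.82 / 0.66),
               tolerance = 1e-12)
  # Dense Woodland three-year interval prints as 0.11
  expect_equal(round(dfireint(3, 1.78, 0.99), 2), 0.11)
  # normalization over the support
  expect_equal(sum(dfireint(1:10000, 0.82, 0.66)), 1, tolerance = 1e-12)
})

test_that("survival distribution matches published values and boundary", {
  expect_equal(round(sfireint(5, 1.78, 0.99), 2), 0.57)
  expect_equal(sfireint(5, 1.78, 0.99), 0.5684, tolerance = 1e-4)
  expect_equal(round(sfireint(10, 1.78, 0.99), 2), 0.30)
  expect_identical(sfireint(0, 0.82, 0.66), 1)
  expect_equal(sfireint(2, 0.82, 0.66),
               1 - pnorm((log(2) - 0.82) / 0.66), tolerance = 1e-12)
  # non-increasing in t
  s <- sfireint(0:60, 0.9, 0.8)
  expect_true(all(diff(s) <= 0))
})

test_that("hazard of burning reproduces published peaks and identities", {
  expect_equal(round(hfireint(4, 0.82, 0.66), 2), 0.42)
  expect_equal(round(hfireint(3, 1.19, 0.91), 2), 0.24)
  expect_equal(round(hfireint(4, 0.93, 0.69), 2), 0.37)
  # hazard(1) = pmf(1) since survival(0) = 1
  expect_equal(hfireint(1, 1.39, 0.92), dfireint(1, 1.39, 0.92))
  # beyond the numerical support horizon the hazard is flagged, not 0/0
  expect_warning(h <- hfireint(1e6, 0.82, 0.1), "support horizon")
  expect_true(is.na(h))
})

test_that("domain errors are raised for invalid ages and parameters", {
  expect_error(dfireint(0, 0.82, 0.66), "integer-valued")
  expect_error(dfireint(2.5, 0.82, 0.66), "integer-valued")
  expect_error(sfireint(-1, 0.82, 0.66), "integer-valued")
  expect_error(hfireint(0, 0.82, 0.66), "integer-valued")
  expect_error(dfireint(2, 0.82, -1), "positive")
  expect_error(dfireint(2, Inf, 1), "finite")
})

test_that("telescoping identity sum f + A holds exactly for all classes", {
  for (i in seq_len(nrow(ref_classes))) {
    ml <- ref_classes$meanlog[i]; sl <- ref_classes$sdlog[i]
    for (Tm in c(1, 7, 33, 100)) {
      expect_equal(sum(dfireint(seq_len(Tm), ml, sl)) + sfireint(Tm, ml, sl),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("discrete product of (1 - hazard) reproduces the survival curve", {
  for (i in c(1, 3, 5)) {
    ml <- ref_classes$meanlog[i]; sl <- ref_classes$sdlog[i]
    tt <- 1:40
    expect_equal(cumprod(1 - hfireint(tt, ml, sl)),
                 sfireint(tt, ml, sl), tolerance = 1e-10)
  }
})

test_that("hazard rises then falls when the turning point exceeds one", {
  for (i in seq_len(nrow(ref_classes))) {
    ml <- ref_classes$meanlog[i]; sl <- ref_classes$sdlog[i]
    h <- hfireint(1:100, ml, sl)
    tp <- fire_descriptors(ml, sl)$turning_point
    expect_gt(tp, 1)
    expect_true(all(diff(h[1:tp]) > 0))
    expect_true(all(diff(h[tp:100]) < 0))
  }
})

test_that("random interval draws follow the binned lognormal law", {
  set.seed(7)
  x <- rfireint(40000, 0.82, 0.66)
  expect_true(all(x >= 1))
  emp <- tabulate(x, nbins = 8) / length(x)
  expect_equal(emp, dfireint(1:8, 0.82, 0.66), tolerance = 0.01)
})

test_that("derived descriptors reproduce every published class row", {
  for (i in seq_len(nrow(ref_classes))) {
    d <- fire_descriptors(ref_classes$meanlog[i], ref_classes$sdlog[i])
    expect_identical(d$median, ref_classes$median[i])
    expect_identical(d$mode, ref_classes$mode[i])
    expect_identical(d$turning_point, ref_classes$turning_point[i])
  }
})

test_that("median ceiling rule is exact at integer boundaries", {
  expect_identical(fire_descriptors(log(4), 0.5)$median, 4L)
  # mode rule is strict: exp(meanlog - sdlog^2) exactly integer bumps up
  sl <- 0.5
  ml <- log(2) + sl^2
  expect_identical(fire_descriptors(ml, sl)$mode, 3L)
})

test_that("mean interval equals the survival-sum brute force", {
  for (i in c(1, 3, 6)) {
    expect_equal(fireint_mean(ref_classes$meanlog[i], ref_classes$sdlog[i]),
                 brute_mean(ref_classes$meanlog[i], ref_classes$sdlog[i]),
                 tolerance = 1e-8)
  }
})
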