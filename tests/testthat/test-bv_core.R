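test_that("CV_T and CV_P follow their definitions on worked values", {
  expect_equal(round_half_up(cv_total(0.420, 0.020), 2), 4.76)
  expect_equal(round_half_up(cv_total(4.45, 0.17), 2), 3.82)
  expect_equal(cv_total(100, 0), 0)
  expect_error(cv_total(0, 1), "non-positive mean")

  expect_equal(cv_within_person(5, 3), 4)
  expect_equal(cv_within_person(9.45, 1.26), sqrt(9.45^2 - 1.26^2))
  expect_warning(cp <- cv_within_person(0, 14.35), "CV_P set to 0")
  expect_equal(cp, 0)
})

test_that("two-sided quantiles are full precision and hit the t-to-z limit", {
  expect_equal(quantile_z(0.95), 1.959964, tolerance = 1e-6)
  expect_equal(quantile_z(0.99), 2.575829, tolerance = 1e-6)
  expect_equal(quantile_z(0.6827), 1.0, tolerance = 1e-3)
  expect_equal(quantile_t(0.95, 2), 4.302653, tolerance = 1e-6)
  expect_equal(quantile_t(0.95, 4), 2.776445, tolerance = 1e-6)
  expect_lt(abs(quantile_t(0.95, 1e7) - quantile_z(0.95)), 1e-6)
  expect_error(quantile_z(1.2), "coverage")
  expect_error(quantile_t(0.95, 0), "df")
})

test_that("prRI_pop reproduces the worked erythrocyte and platelet rows", {
  ery <- bv_profile("erythrocytes", "x 10^12/L", cv_i = 2.80, cv_a = 0.67)
  iv <- round_interval(prri_pop(hsp_estimate(4.45, 0.17, 3), ery), 2)
  expect_equal(iv$rounded, c(4.16, 4.74))
  expect_equal(iv$method, "prRI_pop")
  expect_equal(iv$small_n_factor, sqrt(1 + 1 / 3))

  plt <- bv_profile("platelets", "x 10^9/L", cv_i = 6.40, cv_a = 0.17)
  iv2 <- prri_pop(hsp_estimate(217, 25, 3), plt)
  expect_equal(iv2$lower, 185.56, tolerance = 1e-3)
  expect_equal(iv2$upper, 248.44, tolerance = 1e-3)

  zero <- bv_profile("x", cv_i = 0, cv_a = 0)
  iv3 <- prri_pop(hsp_estimate(5, 0.1, 3), zero)
  expect_equal(c(iv3$lower, iv3$upper), c(5, 5))
  expect_true(iv3$degenerate)
})

test_that("prRI_ind uses the t quantile and keeps negative limits unless clamped", {
  hgb <- hsp_estimate(141, 5, 3, cv_t = 3.36)
  iv <- prri_ind(hgb)
  expect_equal(iv$lower, 117.46, tolerance = 1e-3)
  expect_equal(iv$upper, 164.54, tolerance = 1e-3)
  expect_equal(iv$coverage_z_or_t, quantile_t(0.95, 2))

  leu <- prri_ind(hsp_estimate(4.8, 0.5, 3, cv_t = 9.45))
  expect_equal(round_half_up(c(leu$lower, leu$upper), 2), c(2.55, 7.05),
               tolerance = 1e-3)

  mono <- prri_ind(hsp_estimate(0.3, 0.1, 3, cv_t = 24.24))
  expect_lt(mono$lower, 0)
  mono_c <- prri_ind(hsp_estimate(0.3, 0.1, 3, cv_t = 24.24), clamp = TRUE)
  expect_equal(mono_c$lower, 0)
  expect_true(mono_c$clamped)

  expect_warning(deg <- prri_ind(hsp_estimate(0.04, 0, 3, cv_t = 0)),
                 "degenerate")
  expect_true(deg$degenerate)
  expect_equal(c(deg$lower, deg$upper), c(0.04, 0.04))
  # n = 2 (df = 1) is the smallest usable history
  expect_warning(prri_ind(hsp_estimate(1, 0, 2)), "degenerate")
})

test_that("RCVs reproduce worked values on both bases", {
  leu <- bv_profile("leukocytes", cv_i = 11.10, cv_a = 1.26)
  expect_equal(round_half_up(rcv_pop(leu)$threshold, 2), 30.96)
  hct <- bv_profile("hematocrit", cv_i = 2.80, cv_a = 0.54)
  expect_equal(round_half_up(rcv_pop(hct)$threshold, 2), 7.90)
  expect_equal(rcv_pop(bv_profile("x", cv_i = 0, cv_a = 0))$threshold, 0)

  eos <- hsp_estimate(0.1, 0.0375, 3, cv_t = 37.50)
  expect_equal(round_half_up(rcv_ind(eos)$threshold, 2), 103.94)
  expect_equal(round_half_up(
    rcv_ind(hsp_estimate(1, 0.1, 3, cv_t = 10))$threshold, 2), 27.72)
  expect_warning(na <- rcv_ind(hsp_estimate(0.04, 0, 3, cv_t = 0)),
                 "not applicable")
  expect_equal(na$threshold, 0)
  expect_true(na$not_applicable)
})

test_that("index of individuality supports both variants", {
  expect_equal(index_of_individuality(
    bv_profile("x", cv_i = 10, cv_g = 20, cv_a = 1)), 0.5)
  expect_equal(index_of_individuality(
    bv_profile("x", cv_i = 3, cv_g = 10, cv_a = 4), "noise_adjusted"), 0.5)
  # round trip: CV_G back-computed from a published II returns that II
  leu <- bv_profile("leukocytes", cv_i = 11.10, cv_g = 11.10 / 0.65,
                    cv_a = 1.26)
  expect_equal(index_of_individuality(leu), 0.65)
  expect_error(index_of_individuality(bv_profile("x", cv_i = 1, cv_a = 1)),
               "CV_G")
})

test_that("applicability verdict routes by the CV_A, CV_I and n rules", {
  leu <- bv_profile("leukocytes", cv_i = 11.10, cv_a = 1.26, cv_g = 17.1)
  v <- check_applicability(leu, hsp_estimate(4.8, 0.5, 3))
  expect_false(v$n_ok)
  expect_true(v$cv_a_ok && v$cv_i_ok)
  expect_equal(v$recommended_route, "population")

  eos <- bv_profile("eosinophils", cv_i = 15.00, cv_a = 16.70, cv_g = 62.5)
  v2 <- check_applicability(eos, hsp_estimate(0.1, 0.04, 3))
  expect_false(v2$cv_a_ok)
  expect_equal(v2$recommended_route, "rcv_only")

  ok <- check_applicability(bv_profile("x", cv_i = 10, cv_a = 1, cv_g = 20),
                            hsp_estimate(5, 0.3, 10))
  expect_equal(ok$recommended_route, "individual")

  wide <- check_applicability(bv_profile("x", cv_i = 35, cv_a = 2, cv_g = 40),
                              hsp_estimate(5, 0.3, 10))
  expect_equal(wide$recommended_route, "none")
})

test_that("display rounding is half-up and preserves unrounded limits", {
  iv <- new_iv <- prri_pop(hsp_estimate(4.45, 0.17, 3),
                           bv_profile("e", cv_i = 2.80, cv_a = 0.67))
  r <- round_interval(iv, 2)
  expect_equal(r$rounded, c(4.16, 4.74))
  expect_equal(r$lower, new_iv$lower)
  expect_equal(round_half_up(c(117.46, 164.54), 0), c(117, 165))
  expect_equal(round_half_up(0.5, 0), 1)      # base round() would give 0
  expect_equal(round_half_up(-0.15, 1), -0.2)
  expect_equal(round_half_up(c(0, 0), 2), c(0, 0))
})

test_that("random inputs match independent brute-force algebra", {
  set.seed(11)
  for (i in 1:50) {
    m <- runif(1, 0.01, 500)
    cvi <- runif(1, 0, 30); cva <- runif(1, 0, 10)
    cvt <- runif(1, 0.1, 40); n <- sample(2:12, 1)
    cov <- runif(1, 0.5, 0.999)
    h <- hsp_estimate(m, m * cvt / 100, n)
    p <- bv_profile("x", cv_i = cvi, cv_a = cva)

    ivp <- prri_pop(h, p, cov)
    exp_p <- oracle_prri(m, sqrt(cvi^2 + cva^2), n, oracle_z(cov))
    expect_equal(c(ivp$lower, ivp$upper), exp_p, tolerance = 1e-10)

    ivi <- prri_ind(h, coverage = cov)
    exp_i <- oracle_prri(m, cvt, n, qt(1 - (1 - cov) / 2, n - 1))
    expect_equal(c(ivi$lower, ivi$upper), exp_i, tolerance = 1e-10)

    expect_equal(rcv_pop(p, cov)$threshold,
                 oracle_rcv(sqrt(cvi^2 + cva^2), oracle_z(cov)),
                 tolerance = 1e-10)
    expect_equal(rcv_ind(h, cov)$threshold, oracle_rcv(cvt, oracle_z(cov)),
                 tolerance = 1e-10)

    # interval symmetry about the set point, pre-rounding
    expect_equal((ivp$lower + ivp$upper) / 2, m, tolerance = 1e-12)
    expect_equal((ivi$lower + ivi$upper) / 2, m, tolerance = 1e-12)

    # CV_P / CV_T round trip whenever CV_T >= CV_A
    if (cvt >= cva) {
      cvp <- cv_within_person(cvt, cva)
      expect_equal(sqrt(cvp^2 + cva^2), cvt, tolerance = 1e-10)
    }
  }
})

test_that("interval widths are monotone in CV, HSP and history size", {
  width_pop <- function(cvi, n = 3, m = 10) {
    p <- bv_profile("x", cv_i = cvi, cv_a = 1)
    iv <- prri_pop(hsp_estimate(m, 1, n), p)
    iv$upper - iv$lower
  }
  width_ind <- function(cvt, n = 3, m = 10) {
    iv <- prri_ind(hsp_estimate(m, m * cvt / 100, n))
    iv$upper - iv$lower
  }
  cvs <- seq(1, 25, by = 3)
  expect_true(all(diff(sapply(cvs, width_pop)) > 0))
  expect_true(all(diff(sapply(cvs, width_ind)) > 0))
  ns <- 2:10
  expect_true(all(diff(sapply(ns, function(n) width_pop(10, n))) < 0))
  hs <- c(1, 5, 50, 200)
  expect_true(all(diff(sapply(hs, function(m) width_pop(10, 3, m))) > 0))
  rcvs <- sapply(cvs, function(cv)
    rcv_pop(bv_profile("x", cv_i = cv, cv_a = 1))$threshold)
  expect_true(all(diff(rcvs) > 0))
})

test_that("individual route converges to population route as n grows", {
  cvi <- 7; cva <- 2
  cvt <- sqrt(cvi^2 + cva^2)
  n <- 1e6
  p <- bv_profile("x", cv_i = cvi, cv_a = cva)
  h <- hsp_estimate(10, 10 * cvt / 100, n)
  ivi <- prri_ind(h)
  ivp <- prri_pop(h, p)
  expect_lt(abs(ivi$upper - ivp$upper) / (ivp$upper - 10), 1e-3)
  expect_lt(abs(ivi$lower - ivp$lower) / (10 - ivp$lower), 1e-3)
})

test_that("RCV bases agree when CV_T equals the pooled population CV", {
  cvi <- 9.3; cva <- 2.2
  p <- bv_profile("x", cv_i = cvi, cv_a = cva)
  h <- hsp_estimate(5, 1, 3, cv_t = sqrt(cvi^2 + cva^2))
  expect_equal(rcv_ind(h)$threshold, rcv_pop(p)$threshold,
               tolerance = 1e-12)
})
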