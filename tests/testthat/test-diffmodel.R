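test_that("constant counts give the closed-form intercept-only fit", {
  y <- rep(50L, 8)
  X <- matrix(1, 8, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_nb(y, X)
  expect_equal(unname(coef(f)), log(50), tolerance = 1e-6)
  expect_equal(f$dispersion, 1e-8)  # no overdispersion: lower bound
  expect_true(f$converged)
  expect_lt(f$grad_norm, 1e-4)
})

test_that("the Poisson limit reproduces a Poisson-regression oracle", {
  set.seed(14)
  for (i in 1:5) {
    X <- cbind(1, rep(0:1, each = 10), rnorm(20))
    y <- rpois(20, exp(4 + 0.5 * X[, 2] - 0.2 * X[, 3]))
    f <- fit_nb(y, X, dispersion = 1e-8)
    g <- glm.fit(X, y, family = poisson())
    expect_equal(unname(f$coefficients), unname(g$coefficients),
                 tolerance = 1e-4)
    expect_equal(f$loglik,
                 sum(dpois(y, g$fitted.values, log = TRUE)), tolerance = 1e-6)
  }
})

test_that("fits agree with the MASS negative-binomial implementation", {
  set.seed(27)
  x <- rep(0:1, each = 30)
  y <- rnbinom(60, size = 2, mu = exp(5 + 0.6 * x))
  f <- fit_nb(y, cbind(1, x), cox_reid = FALSE)
  g <- MASS::glm.nb(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
  expect_equal(f$theta, g$theta, tolerance = 1e-2)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("offsets make estimates invariant to global depth scaling", {
  set.seed(5)
  plate <- simulate_plate(24, seed = 16)
  spec <- model_spec(plate)
  sim <- simulate_counts(plate, 6, effects = log(1.5), dispersion = 0.2,
                         seed = 17)
  sf <- size_factors(sim$counts)
  f1 <- fit_nb(sim$counts[2, ], spec$full, sf)
  # multiplying every size factor by a constant shifts only the intercept
  f2 <- fit_nb(sim$counts[2, ], spec$full, 4 * unclass(sf),
               dispersion = f1$dispersion)
  f1b <- fit_nb(sim$counts[2, ], spec$full, sf, dispersion = f1$dispersion)
  expect_equal(unname(f1b$coefficients[spec$treatment_cols]),
               unname(f2$coefficients[spec$treatment_cols]),
               tolerance = 1e-6)
  expect_equal(unname(f2$coefficients[1] - f1b$coefficients[1]), -log(4),
               tolerance = 1e-6)
  # doubling counts together with factors leaves the estimate essentially put
  f3 <- fit_nb(2L * sim$counts[2, ], spec$full, 2 * unclass(sf))
  expect_equal(unname(f1$coefficients[spec$treatment_cols]),
               unname(f3$coefficients[spec$treatment_cols]),
               tolerance = 0.02)
})

test_that("swapping treatment labels flips the estimate's sign", {
  plate <- simulate_plate(16, seed = 23)
  sim <- simulate_counts(plate, 3, effects = 0.4, dispersion = 0.3, seed = 24)
  cov <- plate$covariates
  spec_a <- model_spec(cov)
  cov_swapped <- cov
  cov_swapped$treatment <- ifelse(cov$treatment == "control",
                                  "treated", "control")
  spec_b <- model_spec(cov_swapped)
  ta <- differential_table(sim$counts, spec_a)
  tb <- differential_table(sim$counts, spec_b)
  expect_equal(ta$estimate, -tb$estimate, tolerance = 1e-5)
  expect_equal(ta$p_value, tb$p_value, tolerance = 1e-6)
  # well reordering leaves estimates unchanged
  perm <- sample(16)
  spec_p <- model_spec(cov[perm, , drop = FALSE])
  tp <- differential_table(sim$counts[, perm], spec_p)
  expect_equal(tp$estimate, ta$estimate, tolerance = 1e-6)
})

test_that("the LRT contract holds: nesting, zero statistic, chi-square df", {
  set.seed(31)
  y <- rnbinom(12, size = 4, mu = 100)
  X <- cbind(`(Intercept)` = 1, trt = rep(0:1, each = 6))
  f <- fit_nb(y, X)
  r <- fit_nb(y, X[, 1, drop = FALSE], dispersion = f$dispersion)
  out <- lrt(f, r)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1L)
  expect_equal(out$p_value,
               pchisq(out$statistic, 1, lower.tail = FALSE))
  # identical designs are not nested in the strict sense
  expect_error(lrt(f, f), "fewer coefficients")
  # non-nested designs rejected
  r2 <- fit_nb(y, cbind(z = rnorm(12)), dispersion = f$dispersion)
  expect_error(lrt(f, r2), "not nested")
  # a full model that adds no information: statistic 0, p 1
  f_deg <- fit_nb(y, cbind(a = rep(1, 12), b = rep(2, 12)),
                  dispersion = f$dispersion)
  r_deg <- fit_nb(y, cbind(a = rep(1, 12)), dispersion = f$dispersion)
  deg <- lrt(f_deg, r_deg)
  expect_equal(deg$statistic, 0, tolerance = 1e-8)
  expect_equal(deg$p_value, 1, tolerance = 1e-8)
})

test_that("differential_table reports signed log10 p consistently", {
  plate <- simulate_plate(24, seed = 41)
  sim <- simulate_counts(plate, 10,
                         effects = c(rep(0, 8), log(3), -log(3)),
                         dispersion = 0.15, seed = 42)
  tab <- differential_table(sim$counts, model_spec(plate),
                            size_factors(sim$counts))
  expect_equal(nrow(tab), 10)
  expect_equal(tab$signed_logp,
               sign(tab$estimate) * -log10(pmax(tab$p_value, 1e-300)))
  expect_equal(tab$q_value, p.adjust(tab$p_value, "BH"))
  # planted responders rank top by |signed_logp|
  top2 <- tab$antibody_id[order(-abs(tab$signed_logp))][1:2]
  expect_setequal(top2, c("ab09", "ab10"))
  expect_gt(tab$signed_logp[tab$antibody_id == "ab09"], 0)
  expect_lt(tab$signed_logp[tab$antibody_id == "ab10"], 0)
})

test_that("degenerate all-zero antibodies are flagged, not fitted", {
  plate <- simulate_plate(12, seed = 51)
  sim <- simulate_counts(plate, 3, dispersion = 0.2, seed = 52)
  counts <- sim$counts
  counts[2, ] <- 0L
  tab <- differential_table(counts, model_spec(plate))
  expect_true(tab$degenerate[2])
  expect_true(is.na(tab$p_value[2]))
  expect_false(any(tab$degenerate[-2]))
})

test_that("estimate bias shrinks as wells accumulate", {
  set.seed(61)
  bias <- vapply(c(12, 48, 192), function(n_wells) {
    plate <- simulate_plate(n_wells, seed = n_wells)
    spec <- model_spec(plate)
    est <- replicate(40, {
      sim <- simulate_counts(plate, 12,
                             effects = c(log(2), rep(0, 11)),
                             dispersion = 0.3,
                             seed = sample.int(2^31 - 1, 1))
      f <- fit_nb(sim$counts[1, ], spec$full, size_factors(sim$counts))
      unname(f$coefficients[spec$treatment_cols])
    })
    abs(mean(est) - log(2))
  }, numeric(1))
  expect_lt(bias[3], 0.08)
  expect_lt(bias[3], bias[1] + 0.05)
})
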