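test_that("fixed-effect estimates are scale-equivariant; p-values are not moved", {
  set.seed(5)
  tab <- linear_form_table(beta_group = -0.05)
  f1 <- fit_lmm(tab)
  tab2 <- tab
  tab2$amplitude <- tab2$amplitude * 10
  f2 <- fit_lmm(tab2)
  expect_equal(unname(f2$beta), unname(f1$beta) * 10, tolerance = 1e-6)
  expect_equal(f2$sigma_resid, f1$sigma_resid * 10, tolerance = 1e-6)
  expect_equal(unname(f2$p_value), unname(f1$p_value), tolerance = 1e-6)
})

test_that("swapping group labels flips the sign of the group contrast", {
  set.seed(6)
  tab <- linear_form_table(beta_group = -0.05)
  f1 <- fit_lmm(tab)
  swapped <- tab
  swapped$group <- ifelse(tab$group == "AMD", "Control", "AMD")
  f2 <- fit_lmm(swapped)
  expect_equal(unname(f2$beta["GroupAMD"]), -unname(f1$beta["GroupAMD"]),
               tolerance = 1e-6)
})

test_that("single-group input is a design error and missing rows are dropped with a message", {
  set.seed(7)
  tab <- linear_form_table()
  expect_error(fit_lmm(tab[tab$group == "AMD", ]), "two groups")
  tab$missing[1:10] <- TRUE
  expect_message(f <- fit_lmm(tab), "10 missing ramp row")
  expect_identical(f$n_dropped, 10L)
  expect_identical(f$n_obs, 1390L)
})

test_that("treatment coding makes slower AMD recovery a negative group coefficient", {
  sim <- simulate_cohort_amplitudes(cohort_config(seed = 41))
  f <- fit_lmm(sim$table)
  expect_lt(f$beta["GroupAMD"], 0)
  expect_gt(f$beta["Time"], 0)
  expect_true(f$converged)
  # two-level random intercept is confounded with the fixed group effect:
  # its variance lands on the boundary and is reported as such
  expect_true(f$boundary)
  expect_equal(f$random_intercept_sd, 0, tolerance = 1e-4)
})

test_that("the extended model recovers the age-by-group structure of the generator", {
  sim <- simulate_cohort_amplitudes(cohort_config(seed = 43, n_amd = 40,
                                                  n_control = 40))
  f <- fit_lmm(sim$table, variant = "extended")
  expect_identical(names(f$beta),
                   c("(Intercept)", "Age", "Time", "GroupAMD", "Age:GroupAMD"))
  expect_lt(f$beta["Age"], 0)          # amplitude declines with age
  expect_gt(f$beta["Age:GroupAMD"], 0) # decline attenuated in AMD
})

test_that("marginal F statistics equal squared t statistics with residual df", {
  set.seed(8)
  tab <- linear_form_table(beta_group = -0.05)
  f <- fit_lmm(tab, variant = "extended")
  an <- marginal_anova(f)
  expect_identical(nrow(an), length(f$beta))
  expect_equal(an$f, unname(f$t^2), tolerance = 1e-12)
  expect_true(all(an$df_num == 1L))
  expect_true(all(an$df_den == f$n_obs - length(f$beta)))
  expect_equal(an$p_value, unname(f$p_value), tolerance = 1e-12)
})

test_that("an aliased design is refused with the offending terms named", {
  set.seed(9)
  tab <- linear_form_table()
  tab$age_years <- 75  # constant age aliases Age and Age:Group
  f <- suppressWarnings(fit_lmm(tab, variant = "extended"))
  expect_error(marginal_anova(f), "Age")
})

test_that("information criteria match an independent marginal-likelihood evaluation", {
  set.seed(10)
  tab <- linear_form_table(n_per_group = 3, dark_ms = 100 * (1:8),
                           beta_group = -0.1)
  f <- fit_lmm(tab)
  m <- f$model
  x <- lme4::getME(m, "X")
  z <- as.matrix(lme4::getME(m, "Z"))
  y <- lme4::getME(m, "y")
  n <- length(y)
  v <- f$random_intercept_sd^2 * z %*% t(z) + f$sigma_resid^2 * diag(n)
  r <- y - as.vector(x %*% f$beta)
  ll <- -0.5 * (n * log(2 * pi) +
                  as.numeric(determinant(v, logarithm = TRUE)$modulus) +
                  sum(r * solve(v, r)))
  k <- length(f$beta) + 2  # fixed effects + RE variance + residual variance
  expect_equal(f$log_lik, ll, tolerance = 1e-6)
  expect_equal(f$aic, -2 * ll + 2 * k, tolerance = 1e-6)
  expect_equal(f$bic, -2 * ll + log(n) * k, tolerance = 1e-6)
})

test_that("estimates recover the generating coefficients from the model's own form", {
  set.seed(12)
  truth <- c(0.4, 1e-4, -0.05)
  within <- replicate(25, {
    tab <- linear_form_table(beta0 = truth[1], beta_time = truth[2],
                             beta_group = truth[3], sigma = 0.1)
    f <- fit_lmm(tab)
    all(abs(f$beta - truth) <= 3 * f$se)
  })
  expect_gte(mean(within), 0.8)  # joint 3-SE coverage across 3 coefficients
})

test_that("the subject-level sensitivity refit runs and reports a variance", {
  sim <- simulate_cohort_amplitudes(cohort_config(seed = 44))
  f <- fit_lmm(sim$table, random = "subject")
  expect_true(f$converged)
  expect_gt(f$random_intercept_sd, 0)
})

test_that("fit reports serialize and round-trip through JSON", {
  set.seed(13)
  tab <- linear_form_table(beta_group = -0.05)
  f <- fit_lmm(tab)
  rep0 <- summarize_fit(f)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(rep0, path)
  back <- read_fit_report(path)
  expect_equal(back$aic, rep0$aic, tolerance = 1e-12)
  expect_identical(back$variant, rep0$variant)
  expect_identical(length(back$coefficients), length(rep0$coefficients))
  expect_equal(back$coefficients[[3]]$estimate,
               rep0$coefficients[[3]]$estimate, tolerance = 1e-12)
  expect_identical(back$converged, rep0$converged)
})
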