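# GEE solver, inverse Mills ratio, cluster bootstrap, two-stage Heckman.

test_that("identity GEE with singleton clusters collapses to OLS", {
  set.seed(1)
  n <- 150
  d <- data.frame(child_id = seq_len(n), x = rnorm(n), w = runif(n))
  d$y <- 0.5 + 1.2 * d$x - 0.7 * d$w + rnorm(n)
  fit <- gee_fit(gee_spec(y ~ x + w, corstr = "independence"), d)
  ols <- lm(y ~ x + w, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("probit GEE under independence matches a Fisher-scoring oracle", {
  set.seed(2)
  n <- 400
  d <- data.frame(child_id = seq_len(n), x = rnorm(n))
  d$y <- rbinom(n, 1, pnorm(-0.2 + 0.9 * d$x))
  fit <- gee_fit(gee_spec(y ~ x, link = "probit",
                          corstr = "independence"), d)
  X <- cbind(1, d$x)
  oracle <- fisher_probit(d$y, X)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
})

test_that("the exchangeable correlation is recovered by moments", {
  set.seed(3)
  nc <- 500; k <- 5
  id <- rep(seq_len(nc), each = k)
  b <- rep(rnorm(nc, 0, sqrt(0.4)), each = k)
  x <- rnorm(nc * k)
  d <- data.frame(child_id = id, x = x,
                  y = 1 + 0.8 * x + b + rnorm(nc * k, 0, sqrt(0.6)))
  fit <- gee_fit(gee_spec(y ~ x), d)
  expect_gt(fit$alpha, 0.3)
  expect_lt(fit$alpha, 0.5)
  # both covariance estimates positive semi-definite
  for (V in list(fit$robust_cov, fit$naive_cov)) {
    expect_equal(V, t(V), tolerance = 1e-12)
    expect_true(all(eigen(V, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("gee_fit rejects rank-deficient designs and bad responses", {
  d <- data.frame(child_id = rep(1:10, each = 2), x = rnorm(20))
  d$x2 <- 2 * d$x
  d$y <- rnorm(20)
  expect_error(gee_fit(gee_spec(y ~ x + x2), d), "full column rank")
  expect_error(gee_fit(gee_spec(y ~ x, link = "probit"), d), "binary")
})

test_that("inverse Mills ratio is exact, monotone, and overflow-safe", {
  expect_equal(inverse_mills(0), sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(round(inverse_mills(0), 7), 0.7978846)
  expect_equal(inverse_mills(-2), dnorm(-2) / pnorm(-2), tolerance = 1e-10)
  expect_equal(round(inverse_mills(-2), 4), 2.3732)
  # deep tail: finite, close to -eta
  l40 <- inverse_mills(-40)
  expect_true(is.finite(l40))
  expect_equal(l40, 40.02497, tolerance = 1e-4)
  expect_lt(inverse_mills(8), 1e-10)
  # strictly decreasing and positive on a 1000-point grid
  grid <- seq(-40, 10, length.out = 1000)
  lam <- inverse_mills(grid)
  expect_true(all(lam > 0))
  expect_true(all(diff(lam) < 0))
  # Mills-ratio inequality: lambda(eta) + eta > 0
  expect_true(all(lam + grid > 0))
})

test_that("cluster bootstrap keeps cluster structure and is deterministic", {
  set.seed(4)
  nc <- 60
  d <- data.frame(child_id = rep(seq_len(nc), each = 3), x = rnorm(3 * nc))
  d$y <- 1 + 0.5 * d$x + rep(rnorm(nc, 0, 0.5), each = 3) + rnorm(3 * nc)
  seen <- NULL
  proc <- function(dd) {
    seen <<- c(seen, length(unique(dd$child_id)))
    coef(lm(y ~ x, dd))
  }
  b1 <- suppressWarnings(cluster_bootstrap(proc, d, reps = 30, seed = 5))
  expect_true(all(seen == nc))     # resamples keep the child count
  b2 <- suppressWarnings(cluster_bootstrap(
    function(dd) coef(lm(y ~ x, dd)), d, reps = 30, seed = 5))
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$ci, b2$ci)
  expect_warning(cluster_bootstrap(function(dd) coef(lm(y ~ x, dd)), d,
                                   reps = 20, seed = 1), "fewer than 50")
})

test_that("degenerate zero-variance data give width-zero intervals", {
  d <- data.frame(child_id = rep(1:20, each = 2), x = rep(c(0, 1), 20))
  d$y <- 2 + 3 * d$x                      # exact fit, no noise
  b <- cluster_bootstrap(function(dd) coef(lm(y ~ x, dd)), d, reps = 60,
                         seed = 2)
  expect_equal(unname(b$ci[, 1]), unname(b$ci[, 2]), tolerance = 1e-12)
  expect_equal(unname(b$se), c(0, 0), tolerance = 1e-12)
})

test_that("bootstrap SE approximates the classical SE on independent
           clusters", {
  set.seed(6)
  n <- 500
  d <- data.frame(child_id = seq_len(n), x = rnorm(n))
  d$y <- 1 + 0.8 * d$x + rnorm(n)
  b <- cluster_bootstrap(function(dd) coef(lm(y ~ x, dd)), d, reps = 400,
                         seed = 3)
  classical <- summary(lm(y ~ x, d))$coefficients["x", "Std. Error"]
  expect_lt(abs(b$se[["x"]] - classical) / classical, 0.15)
})

test_that("two-stage correction: structure, determinism and the
           constrained-IMR identity", {
  cfg <- cohort_config(group_sizes = scaled_group_sizes(240), seed = 30)
  sim <- simulate_cohort(cfg, mode = "trajectory_first")
  v <- sim$visits
  v$age_years <- v$age_months / 12
  v$obs01 <- as.integer(v$observed)
  s1 <- gee_spec(obs01 ~ group + site + age_years, link = "probit")
  s2 <- gee_spec(z_obs ~ age_years + I(age_years^2) + group)
  h <- heckman_two_stage(v, s1, s2, bootstrap_reps = 60, seed = 7)
  expect_true(all(h$imr > 0, na.rm = TRUE))
  expect_identical(nrow(h$bootstrap$replicates) + h$bootstrap$failures, 60L)
  expect_true("imr" %in% names(h$stage2_corrected$coefficients))
  expect_false("imr" %in% names(h$stage2_naive$coefficients))
  # naive fit equals an uncorrected GEE on the observed records (the
  # corrected model with the IMR coefficient constrained to zero)
  direct <- gee_fit(s2, v[v$observed, ])
  expect_equal(h$stage2_naive$coefficients, direct$coefficients,
               tolerance = 1e-8)
  # identical seeds reproduce identical bootstrap intervals
  h2 <- heckman_two_stage(v, s1, s2, bootstrap_reps = 60, seed = 7)
  expect_identical(h$bootstrap$ci, h2$bootstrap$ci)
  # table shape: IMR row only in the corrected block
  tab <- heckman_table(h)
  imr_row <- tab[tab$term == "imr", ]
  expect_identical(nrow(imr_row), 1L)
  expect_true(is.na(imr_row$naive_estimate))
  expect_false(is.na(imr_row$corrected_estimate))
})

test_that("under MCAR dropout the IMR coefficient is null", {
  # replicated experiments: the bootstrap interval for the IMR coefficient
  # should cover zero in most replicates
  hits <- 0
  nexp <- 6
  for (r in seq_len(nexp)) {
    cfg <- cohort_config(group_sizes = scaled_group_sizes(280),
                         dropout = list(type = "MCAR", rate = 0.3,
                                        site_effect = 0),
                         seed = 40 + r)
    sim <- simulate_cohort(cfg, mode = "trajectory_first")
    rep_ <- run_growth_evolution(sim, bootstrap_reps = 60, seed = r)
    ci <- rep_$fit$bootstrap$ci["imr", ]
    if (ci[1] <= 0 && ci[2] >= 0) hits <- hits + 1
  }
  expect_gte(hits, nexp - 1)
})

test_that("missing exclusion restriction triggers the identification
           warning", {
  cfg <- cohort_config(group_sizes = scaled_group_sizes(150), seed = 55)
  sim <- simulate_cohort(cfg, mode = "trajectory_first")
  expect_warning(
    run_growth_evolution(sim, stage1_covariates = c("group", "age_years"),
                         bootstrap_reps = 0, seed = 1),
    "exclusion restriction")
})
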