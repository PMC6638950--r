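# Chained-equations imputation, Rubin pooling, Meng-Rubin D3.

test_that("imputation leaves observed cells untouched and is deterministic", {
  cfg <- cohort_config(group_sizes = c(HI = 40, HIL = 40, HEU = 60,
                                       HUU = 60), seed = 8)
  ch <- simulate_cohort(cfg, mode = "state_first")$children
  vars <- setdiff(names(ch), c("child_id", "death_time"))
  i1 <- mice_impute(ch, variables = vars, m = 3, iterations = 4, seed = 2)
  i2 <- mice_impute(ch, variables = vars, m = 3, iterations = 4, seed = 2)
  expect_identical(i1$completed, i2$completed)
  for (k in 1:3) {
    comp <- i1$completed[[k]]
    expect_false(anyNA(comp[vars]))
    for (v in vars) {
      obs <- !is.na(ch[[v]])
      expect_identical(comp[[v]][obs], ch[[v]][obs])
    }
  }
  # different seeds give different draws
  i3 <- mice_impute(ch, variables = vars, m = 3, iterations = 4, seed = 3)
  expect_false(identical(i1$completed, i3$completed))
})

test_that("complete data passes through as m copies", {
  d <- data.frame(a = rnorm(20), b = rbinom(20, 1, 0.5))
  iset <- mice_impute(d, variables = c("a", "b"), m = 4, seed = 1)
  expect_length(iset$completed, 4)
  for (k in 1:4) expect_identical(iset$completed[[k]], d)
})

test_that("MCAR imputation reproduces the observed-cell frequency", {
  set.seed(10)
  n <- 4000
  d <- data.frame(x = rnorm(n), g = factor(sample(c("u", "v", "w"), n,
                                                  replace = TRUE)))
  d$b <- rbinom(n, 1, plogis(0.3 + 0.5 * d$x))
  miss <- runif(n) < 0.10
  truth <- d$b
  d$b[miss] <- NA
  iset <- mice_impute(d, variables = c("x", "g", "b"), m = 5,
                      iterations = 5, seed = 4)
  imputed <- rowMeans(vapply(iset$completed, function(cc) cc$b[miss],
                             numeric(sum(miss))))
  f_obs <- mean(d$b, na.rm = TRUE)
  se <- sqrt(f_obs * (1 - f_obs) / sum(miss))
  expect_lt(abs(mean(imputed) - f_obs), 3 * se)
})

test_that("all-missing variables error; m = 1 pooling warns", {
  d <- data.frame(a = rnorm(5), b = NA_real_)
  expect_error(mice_impute(d, variables = c("a", "b")), "entirely missing")
  expect_warning(p <- pool_rubin(1.2, 0.09), "m = 1")
  expect_identical(p$T, 0.09)
  expect_identical(p$df, Inf)
})

test_that("Rubin's rules match hand arithmetic and scale correctly", {
  p <- pool_rubin(c(1, 1, 1), rep(0.04, 3))
  expect_equal(p$qbar, 1); expect_equal(p$B, 0); expect_equal(p$T, 0.04)
  p2 <- pool_rubin(c(0.9, 1.0, 1.1), rep(0.04, 3))
  expect_equal(p2$B, 0.01)
  expect_equal(p2$T, 0.04 + (4 / 3) * 0.01, tolerance = 1e-12)
  expect_equal(p2$df, 2 * (1 + 0.04 / ((4 / 3) * 0.01))^2)
  # homogeneity: scaling estimates by c scales W, B, T by c^2
  c2 <- 2.5^2
  p3 <- pool_rubin(2.5 * c(0.9, 1.0, 1.1), c2 * rep(0.04, 3))
  expect_equal(p3$W, c2 * p2$W)
  expect_equal(p3$B, c2 * p2$B, tolerance = 1e-12)
  expect_equal(p3$T, c2 * p2$T, tolerance = 1e-12)
  # T >= W always
  for (s in 1:20) {
    set.seed(s)
    pr <- pool_rubin(rnorm(5), runif(5))
    expect_gte(pr$T, pr$W)
  }
})

# minimal fit objects for the pooling contract: gaussian mean model with an
# analytic loglik evaluated on each imputation's own data
mean_fit <- function(y, full) {
  est <- if (full) c(mu = mean(y)) else c(mu = 0)
  ll <- function(par) sum(dnorm(y, par[["mu"]], 1, log = TRUE))
  list(estimate = est, loglik = ll(est), loglik_fun = ll)
}

test_that("Meng-Rubin D3 has the stated degenerate and limit behaviour", {
  set.seed(3)
  y <- rnorm(40, 0.4)
  # m identical completed datasets: dbar_m = dbar_L, r_L = 0, D3 = d/k
  fits_f <- replicate(4, mean_fit(y, TRUE), simplify = FALSE)
  fits_n <- replicate(4, mean_fit(y, FALSE), simplify = FALSE)
  res <- pool_lrt_meng_rubin(fits_f, fits_n, k = 1)
  d <- 2 * (fits_f[[1]]$loglik - fits_n[[1]]$loglik)
  expect_equal(res$dbar_m, res$dbar_L)
  expect_equal(res$r_L, 0)
  expect_equal(res$D3, d / 1)
  # m = 1 chi-square limit: d = 3.84, k = 1 -> D3 = 3.84, p ~ 0.05
  f1 <- list(estimate = c(a = 1), loglik = 1.92,
             loglik_fun = function(p) 1.92)
  n1 <- list(estimate = c(a = 0), loglik = 0,
             loglik_fun = function(p) 0)
  expect_warning(r1 <- pool_lrt_meng_rubin(list(f1), list(n1), k = 1),
                 "m = 1")
  expect_equal(r1$D3, 3.84)
  expect_equal(r1$p_value, pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(round(r1$p_value, 3), 0.05)
})

test_that("D3 matches an independent coding of the published formulas", {
  set.seed(9)
  m <- 3
  ys <- lapply(1:m, function(i) rnorm(30, 0.5) + 0.05 * i)
  fits_f <- lapply(ys, mean_fit, full = TRUE)
  fits_n <- lapply(ys, mean_fit, full = FALSE)
  res <- pool_lrt_meng_rubin(fits_f, fits_n, k = 1)
  # independent reference implementation
  d_i <- sapply(1:m, function(i) 2 * (fits_f[[i]]$loglik -
                                        fits_n[[i]]$loglik))
  mu_bar <- mean(sapply(ys, mean))
  dL_i <- sapply(1:m, function(i) {
    2 * (sum(dnorm(ys[[i]], mu_bar, 1, log = TRUE)) -
           sum(dnorm(ys[[i]], 0, 1, log = TRUE)))
  })
  rL <- max(0, (m + 1) / (1 * (m - 1)) * (mean(d_i) - mean(dL_i)))
  D3 <- mean(dL_i) / (1 * (1 + rL))
  km <- 1 * (m - 1)
  dfden <- if (km > 4) 4 + (km - 4) * (1 + (1 - 2 / km) / rL)^2 else
    (m - 1) * (1 + 1 / 1) * (1 + 1 / rL)^2 / 2
  expect_equal(res$D3, D3, tolerance = 1e-8)
  expect_equal(res$df_den, dfden, tolerance = 1e-8)
  expect_equal(res$p_value, pf(D3, 1, dfden, lower.tail = FALSE),
               tolerance = 1e-8)
  # invariant to reordering imputations
  res_rev <- pool_lrt_meng_rubin(rev(fits_f), rev(fits_n), k = 1)
  expect_equal(res_rev$D3, res$D3)
  expect_equal(res_rev$p_value, res$p_value)
})

test_that("pooled LRT is calibrated under a null effect with MAR
           missingness", {
  # gaussian outcome, null covariate effect, MAR missingness in the
  # covariate; the pooled test should reject at about the nominal 5% level
  set.seed(77)
  nrep <- 120
  n <- 120
  rejections <- 0
  for (r in seq_len(nrep)) {
    w <- rnorm(n)
    x <- rnorm(n, 0.5 * w)
    y <- 0.3 * w + rnorm(n)          # x has no effect
    xm <- x
    xm[runif(n) < plogis(-2 + w)] <- NA   # MAR given observed w
    d <- data.frame(y = y, w = w, x = xm)
    iset <- mice_impute(d, variables = c("y", "w", "x"), m = 3,
                        iterations = 3, seed = r)
    gauss_fit <- function(dd, full) {
      X <- if (full) cbind(1, dd$w, dd$x) else cbind(1, dd$w)
      b <- qr.solve(X, dd$y)
      s2 <- mean((dd$y - X %*% b)^2)
      nm <- if (full) c("b0", "bw", "bx", "ls") else c("b0", "bw", "ls")
      est <- setNames(c(b, log(s2)), nm)
      ll <- function(p) {
        mu <- X %*% p[-length(p)]
        sum(dnorm(dd$y, mu, sqrt(exp(p[[length(p)]])), log = TRUE))
      }
      list(estimate = est, loglik = ll(est), loglik_fun = ll)
    }
    ff <- lapply(iset$completed, gauss_fit, full = TRUE)
    fn <- lapply(iset$completed, gauss_fit, full = FALSE)
    res <- suppressMessages(pool_lrt_meng_rubin(ff, fn, k = 1))
    if (res$p_value < 0.05) rejections <- rejections + 1
  }
  # exact binomial 99.5% band around 5% at 120 replications
  band <- qbinom(c(0.0025, 0.9975), nrep, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})

test_that("imputation sets serialize to a CSV directory with manifest", {
  d <- data.frame(a = c(1, NA, 3, 4, 2, NA, 5, 1), b = rnorm(8))
  iset <- mice_impute(d, variables = c("a", "b"), m = 2, iterations = 2,
                      seed = 6)
  dir <- file.path(tempfile(), "imps")
  write_imputation_set(iset, dir)
  expect_setequal(list.files(dir),
                  c("imputation_01.csv", "imputation_02.csv",
                    "manifest.json"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$m, 2L)
  back <- read.csv(file.path(dir, "imputation_01.csv"))
  expect_equal(back$a, iset$completed[[1]]$a)
})
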