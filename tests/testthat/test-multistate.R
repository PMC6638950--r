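# The three-state panel likelihood, its building blocks, fitting and
# summaries.

test_that("generators have the illness-death structure", {
  p <- random_msm_params(1)
  for (b in 1:3) {
    Q <- build_generator(p, band = b)
    expect_equal(rowSums(Q), rep(0, 3), tolerance = 1e-12)
    expect_identical(Q[3, ], rep(0, 3))          # death absorbing
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
  # published scale: log q0 = ln 0.0372 gives 0.0372/month on 1->2
  p2 <- msm_params(matrix(c(log(0.0372), rep(-20, 11)), 4, 3, byrow = TRUE))
  expect_equal(build_generator(p2, band = 1)[1, 2], 0.0372)
  # proportional-intensity contract: beta = ln 2 doubles only its transition
  p3 <- msm_params(p$log_q0, beta = list(q12 = c(x = log(2))))
  Q0 <- build_generator(p, band = 1)
  Q1 <- build_generator(p3, x = c(x = 1), band = 1)
  expect_equal(Q1[1, 2], 2 * Q0[1, 2])
  expect_equal(Q1[2, 1], Q0[2, 1])
  expect_equal(Q1[2, 3], Q0[2, 3])
})

test_that("transition probabilities agree with closed forms and an ODE
           oracle", {
  expect_identical(transition_probability(matrix(0, 3, 3), 5), diag(3))
  p <- random_msm_params(2)
  Q <- build_generator(p, band = 2)
  expect_identical(transition_probability(Q, 0), diag(3))
  P <- transition_probability(Q, 3.7)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-10)
  expect_true(all(P >= 0 & P <= 1))
  # 2-state collapse: q12 = a only, P11 = exp(-a dt)
  Qa <- matrix(0, 3, 3); Qa[1, 2] <- 0.3; diag(Qa) <- -rowSums(Qa)
  expect_equal(transition_probability(Qa, 2.5)[1, 1], exp(-0.3 * 2.5),
               tolerance = 1e-12)
  # Runge-Kutta oracle: integrate P' = P Q
  skip_if_not_installed("deSolve")
  deriv <- function(t, y, parms) list(as.vector(matrix(y, 3, 3) %*% Q))
  sol <- deSolve::ode(y = as.vector(diag(3)), times = c(0, 2.5),
                      func = deriv, parms = NULL, method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  Pode <- matrix(sol[2, -1], 3, 3)
  expect_equal(transition_probability(Q, 2.5), Pode, tolerance = 1e-8)
})

test_that("interval probabilities multiply across band boundaries", {
  p <- random_msm_params(3)
  # within one band: equals the constant-intensity matrix
  expect_equal(interval_probability(p, NULL, 13, 20),
               transition_probability(build_generator(p, band = 3), 7))
  # (4, 8] crossing 6 months, 2-state collapse: product of exponentials
  lq <- matrix(-30, 4, 3); lq[1, ] <- log(c(0.05, 0.02, 0.01))
  pc <- msm_params(lq)
  expect_equal(interval_probability(pc, NULL, 4, 8)[1, 1],
               exp(-2 * 0.05) * exp(-2 * 0.02), tolerance = 1e-10)
  # 3-band crossing against a fine-grained discretization oracle
  Pfine <- diag(3)
  grid <- seq(4, 40, by = 0.01)
  for (j in seq_len(length(grid) - 1)) {
    b <- findInterval(grid[j] + 1e-9, c(0, 6, 12, 60))
    Pfine <- Pfine %*%
      transition_probability(build_generator(p, band = b), 0.01)
  }
  expect_equal(interval_probability(p, NULL, 4, 40), Pfine,
               tolerance = 1e-6)
  # Chapman-Kolmogorov within a band
  P1 <- interval_probability(p, NULL, 14, 22)
  P2 <- interval_probability(p, NULL, 22, 31)
  expect_equal(P1 %*% P2, interval_probability(p, NULL, 14, 31),
               tolerance = 1e-8)
})

test_that("panel log-likelihood has the stated closed-form special cases", {
  # all panel observations equal to the previous state, Q = 0
  lqz <- matrix(-Inf, 4, 3)
  pz <- msm_params(lqz)
  d <- data.frame(child_id = rep("a", 3), age_months = c(3, 6, 9),
                  state = 1L, obs_type = "panel")
  expect_equal(panel_loglik(d, pz), 0)
  # 2-state collapse q12 = a: pair (1 at 0) -> (1 at t) gives -a t
  lq <- matrix(-Inf, 4, 3); lq[1, ] <- log(0.07)
  pa <- msm_params(lq)
  d2 <- data.frame(child_id = "a", age_months = c(2, 10), state = 1L,
                   obs_type = "panel")
  expect_equal(panel_loglik(d2, pa), -0.07 * 8, tolerance = 1e-10)
  # zero-probability observed transition: -Inf with a diagnostic, no error
  d3 <- data.frame(child_id = "a", age_months = c(2, 10), state = c(1L, 2L),
                   obs_type = "panel")
  ll <- panel_loglik(d3, pz)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "diagnostic"), "zero-probability")
})

test_that("panel log-likelihood matches the brute-force oracle", {
  skip_if_not_installed("Matrix")
  toy <- toy_panel()
  for (s in 1:20) {
    p <- random_msm_params(100 + s)
    expect_equal(panel_loglik(toy, p), brute_loglik(toy, p),
                 tolerance = 1e-8)
  }
})

test_that("exact-death handling reduces to the panel form without deaths", {
  toy <- toy_panel()
  alive <- toy[toy$state != 3, ]
  lq <- matrix(log(0.03), 4, 3); lq[c(2, 4), ] <- -Inf  # no death
  p <- msm_params(lq)
  expect_equal(panel_loglik(alive, p), brute_loglik(alive, p),
               tolerance = 1e-10)
})

test_that("fitting recovers parameters and is stable to init perturbation", {
  cfg <- cohort_config(group_sizes = scaled_group_sizes(800),
                       true_beta = list(q12 = c(groupHIL = log(3))),
                       dropout = list(type = "MCAR", rate = 0.2),
                       covariate_missing_rate = 0, seed = 71)
  sim <- simulate_cohort(cfg, mode = "state_first")
  pan <- cohort_to_panel(sim)
  fit <- fit_msm(pan, model_spec = list(q12 = "group"))
  expect_identical(fit$convergence, 0L)
  expect_true(fit$covariance_ok)
  # covariance symmetric positive semi-definite
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # the configured aHR of 3 on 1->2 for HIL is recovered within Wald bounds
  hr <- hazard_ratios(fit)
  row <- hr[hr$transition == "q12" & hr$term == "groupHIL", ]
  expect_gt(row$upper, 3); expect_lt(row$lower, 3)
  # refits from perturbed inits reach the same maximum
  init2 <- fit$estimate + 0.5 * rep(c(1, -1), length.out =
                                      length(fit$estimate))
  fit2 <- fit_msm(pan, model_spec = list(q12 = "group"), init = init2)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-4)
  # nested model cannot beat the full model
  fit0 <- fit_msm(pan)
  expect_lte(fit0$loglik, fit$loglik + 1e-6)
})

test_that("never-observed transitions are fixed at zero, fit completes", {
  cfg <- cohort_config(group_sizes = c(HI = 40, HIL = 40, HEU = 40,
                                       HUU = 40),
                       true_Q = rbind(q12 = c(0.03, 0.01, 0.007),
                                      q13 = c(0, 0, 0),
                                      q21 = c(0.08, 0.06, 0.04),
                                      q23 = c(0, 0, 0)),
                       true_beta = list(),
                       dropout = list(type = "MCAR", rate = 0.1),
                       seed = 3)
  sim <- simulate_cohort(cfg, mode = "state_first")
  expect_true(all(is.na(sim$children$death_time)))
  fit <- fit_msm(cohort_to_panel(sim))
  expect_false(any(c("q13", "q23") %in% fit$free_transitions))
  expect_true(all(c("q12", "q21") %in% fit$free_transitions))
  expect_identical(unname(fit$params$log_q0["q13", 1]), -Inf)
})

test_that("hazard ratio and intensity summaries apply the stated formulas", {
  # hand-built fit object: one transition, one covariate
  bands <- age_bands()
  est <- c("q12.(0,6]" = log(0.0372), "q12.(6,12]" = log(0.0116),
           "q12.(12,60]" = log(0.0068), "q12.x" = log(2))
  V <- diag(c(0.377, 0.3, 0.137, 0.1)^2)
  dimnames(V) <- list(names(est), names(est))
  fit <- structure(list(estimate = est, covariance = V,
                        covariance_ok = TRUE,
                        model_spec = list(q12 = "x", q13 = character(0),
                                          q21 = character(0),
                                          q23 = character(0)),
                        free_transitions = "q12", bands = bands),
                   class = "msm_fit")
  hr <- hazard_ratios(fit)
  expect_equal(hr$aHR, 2)
  expect_equal(hr$lower, exp(log(2) - 1.96 * 0.1), tolerance = 1e-12)
  expect_equal(round(hr$lower, 3), 1.644)
  expect_equal(round(hr$upper, 3), 2.433)
  it <- intensity_summary(fit)
  expect_equal(it$per1000pm, c(37.2, 11.6, 6.8))
  # log-scale interval consistent with the published asymmetric bounds
  expect_equal(it$lower[1], 37.2 * exp(-1.96 * 0.377), tolerance = 1e-9)
  expect_equal(round(it$lower[1], 1), 17.8)
  expect_equal(round(it$upper[1], 1), 77.9)
  # beta = 0 gives aHR 1 with CI containing 1
  fit$estimate["q12.x"] <- 0
  hr0 <- hazard_ratios(fit)
  expect_equal(hr0$aHR, 1)
  expect_true(hr0$lower < 1 && hr0$upper > 1)
})

test_that("recoding a binary covariate flips the hazard ratio", {
  cfg <- cohort_config(group_sizes = c(HI = 60, HIL = 60, HEU = 60,
                                       HUU = 60),
                       true_beta = list(q12 = c(sexfemale = log(2))),
                       dropout = list(type = "MCAR", rate = 0),
                       covariate_missing_rate = 0, seed = 41)
  sim <- simulate_cohort(cfg, mode = "state_first")
  pan <- cohort_to_panel(sim)
  pan$female <- as.integer(pan$sex == "female")
  pan$male <- 1L - pan$female
  f1 <- fit_msm(pan, model_spec = list(q12 = "female"))
  f2 <- fit_msm(pan, model_spec = list(q12 = "male"))
  b1 <- f1$estimate["q12.female"]
  b2 <- f2$estimate["q12.male"]
  expect_equal(unname(b1), -unname(b2), tolerance = 1e-3)
})

test_that("fitted models serialize to JSON and back", {
  toy <- toy_panel()
  fit <- fit_msm(toy)
  f <- tempfile(fileext = ".json")
  write_msm_fit(fit, f)
  back <- read_msm_fit(f)
  expect_equal(back$estimate, fit$estimate)
  expect_equal(back$loglik, fit$loglik)
  expect_identical(back$covariance_ok, fit$covariance_ok)
  expect_equal(back$params$log_q0, fit$params$log_q0)
})

test_that("panel CSV validation catches malformed input", {
  toy <- toy_panel()
  f <- tempfile(fileext = ".csv")
  write.csv(toy, f, row.names = FALSE)
  expect_silent(read_panel_csv(f))
  bad <- toy
  bad$age_months[2] <- bad$age_months[1]      # ties within child
  expect_error(validate_panel(bad), "strictly increasing")
  bad2 <- toy
  bad2$obs_type[bad2$state != 3][1] <- "exact_death"
  expect_error(validate_panel(bad2), "state 3")
})
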