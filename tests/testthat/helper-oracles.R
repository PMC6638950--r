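# Shared fixtures and independent oracles.

# a single LMS reference row with analytically convenient parameters
fixture_lms_row <- function(L = 0.4, M = 10, S = 0.12) {
  row <- data.frame(index = "WAZ", sex = "male", key = 12,
                    L = L, M = M, S = S)
  row$sd3neg <- inverse_lms(-3, L, M, S)
  row$sd2neg <- inverse_lms(-2, L, M, S)
  row$sd2pos <- inverse_lms(2, L, M, S)
  row$sd3pos <- inverse_lms(3, L, M, S)
  row
}

# random valid three-state parameters on the default bands
random_msm_params <- function(seed) {
  set.seed(seed)
  msm_params(matrix(log(stats::runif(12, 0.002, 0.12)), 4, 3))
}

# brute-force panel log-likelihood, written independently of the package's
# aggregated evaluator: per-pair band splitting with Matrix::expm on the
# full 3x3 generator
brute_loglik <- function(data, params) {
  cuts <- params$bands$cuts
  pmat <- function(x, t1, t2) {
    P <- diag(3)
    bounds <- sort(unique(c(t1, t2, cuts[cuts > t1 & cuts < t2])))
    for (j in seq_len(length(bounds) - 1)) {
      a <- bounds[j]; b <- bounds[j + 1]
      band <- findInterval(a + 1e-9, cuts, left.open = FALSE)
      band <- min(max(band, 1), params$bands$n)
      Q <- build_generator(params, x, band)
      P <- P %*% as.matrix(Matrix::expm((b - a) * Matrix::Matrix(Q)))
    }
    P
  }
  ll <- 0
  for (id in unique(data$child_id)) {
    d <- data[data$child_id == id, ]
    d <- d[order(d$age_months), ]
    d <- d[!is.na(d$state), ]
    if (nrow(d) < 2) next
    for (j in 2:nrow(d)) {
      t1 <- d$age_months[j - 1]; t2 <- d$age_months[j]
      s1 <- d$state[j - 1]; s2 <- d$state[j]
      P <- pmat(NULL, t1, t2)
      if (d$obs_type[j] == "exact_death") {
        band2 <- min(max(findInterval(t2, cuts, left.open = TRUE), 1),
                     params$bands$n)
        Q2 <- build_generator(params, NULL, band2)
        ll <- ll + log(P[s1, 1] * Q2[1, 3] + P[s1, 2] * Q2[2, 3])
      } else {
        ll <- ll + log(P[s1, s2])
      }
    }
  }
  ll
}

# ten-child toy panel with all transition types, including an exact death
toy_panel <- function() {
  set.seed(42)
  rows <- list()
  states <- list(c(1, 1, 2, 1), c(1, 2, 2, 3), c(1, 1, 1, 1), c(1, 2, 1, 2),
                 c(1, 1, 2, 2), c(2, 1, 1, 3), c(1, 2, 3), c(1, 1, 1),
                 c(2, 2, 1, 1), c(1, 1, 1, 2))
  times <- list(c(3, 6, 9, 15), c(3, 9, 15, 21.5), c(6, 12, 24, 36),
                c(3, 6, 12, 18), c(6, 18, 30, 42), c(3, 6, 9, 13.2),
                c(6, 12, 17.8), c(12, 24, 48), c(3, 9, 15, 27),
                c(6, 24, 42, 54))
  for (i in seq_along(states)) {
    s <- states[[i]]
    rows[[i]] <- data.frame(
      child_id = sprintf("T%02d", i), age_months = times[[i]], state = s,
      obs_type = ifelse(s == 3, "exact_death", "panel"))
  }
  do.call(rbind, rows)
}

# independently coded Fisher-scoring probit maximum likelihood
fisher_probit <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pnorm(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- dnorm(eta)^2 / (mu * (1 - mu))
    score <- crossprod(X, (y - mu) * dnorm(eta) / (mu * (1 - mu)))
    step <- solve(crossprod(X, X * w), score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# scaled default four-group design used in recovery experiments
scaled_group_sizes <- function(n_total) {
  gs <- c(HI = 69, HIL = 141, HEU = 205, HUU = 196)
  round(gs * n_total / sum(gs))
}
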