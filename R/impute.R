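# Multiple imputation by chained equations, Rubin's rules, and the
# Meng-Rubin pooled likelihood-ratio statistic (D3) used for variable
# selection in multiply imputed multi-state fits.

#' Chained-equations multiple imputation
#'
#' Gibbs-style fully conditional specification: each incomplete variable is
#' regressed on all other modelled variables; continuous variables are
#' imputed by Bayesian linear regression draws (posterior draws of
#' coefficients and residual variance), binary variables by logistic draws,
#' and factors with more than two levels by multinomial draws.  `m`
#' independent chains are run for `iterations` sweeps each.  Anthropometric
#' outcome columns must be excluded by the caller (they are modelled, not
#' imputed, downstream).
#'
#' @param data Data frame; only columns named in `variables` are imputed,
#'   all of them are used as predictors.
#' @param variables Columns entering the imputation model (default: all
#'   columns with any missing value plus all complete columns except
#'   obvious identifiers).
#' @param m Number of imputations (default 10).
#' @param iterations Chained-equation sweeps per imputation (default 10).
#' @param seed Integer seed.
#' @param pmm Use predictive mean matching (5 donors) instead of Bayesian
#'   draws for continuous variables.
#' @return Object of class `imputation_set`: list of `m` completed data
#'   frames plus the specification.
#' @export
mice_impute <- function(data, variables = NULL, m = 10, iterations = 10,
                        seed = 1L, pmm = FALSE) {
  if (is.null(variables)) {
    variables <- setdiff(names(data), c("child_id", "age_months"))
  }
  stopifnot(m >= 1, iterations >= 1, all(variables %in% names(data)))
  incomplete <- variables[vapply(data[variables], anyNA, logical(1))]
  rates <- vapply(data[variables], function(v) mean(is.na(v)), numeric(1))
  if (any(rates >= 1))
    stop("variable(s) entirely missing: ",
         paste(variables[rates >= 1], collapse = ", "))
  if (any(rates > 0.5))
    warning("variable(s) over 50% missing: ",
            paste(variables[rates > 0.5], collapse = ", "))
  completed <- vector("list", m)
  if (!length(incomplete)) {
    for (k in seq_len(m)) completed[[k]] <- data
  } else {
    for (k in seq_len(m)) {
      set.seed(child_seed(seed, k))
      completed[[k]] <- fcs_chain(data, variables, incomplete, iterations,
                                  pmm)
    }
  }
  structure(list(completed = completed, m = m, iterations = iterations,
                 variables = variables, incomplete = incomplete,
                 seed = as.integer(seed), pmm = pmm),
            class = "imputation_set")
}

# one chained-equations chain
fcs_chain <- function(data, variables, incomplete, iterations, pmm) {
  work <- data
  miss_idx <- lapply(incomplete, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- incomplete
  # initial fill: random draws from the observed cells
  for (v in incomplete) {
    obs <- data[[v]][!is.na(data[[v]])]
    work[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                       replace = TRUE)
  }
  for (it in seq_len(iterations)) {
    for (v in incomplete) {
      idx <- miss_idx[[v]]
      preds <- setdiff(variables, v)
      X <- stats::model.matrix(stats::reformulate(preds, intercept = TRUE),
                               work)
      yobs <- data[[v]][-idx]
      Xobs <- X[-idx, , drop = FALSE]
      Xmis <- X[idx, , drop = FALSE]
      # drop aliased columns for a full-rank conditional model
      qr_ <- qr(Xobs)
      keep <- qr_$pivot[seq_len(qr_$rank)]
      Xobs <- Xobs[, keep, drop = FALSE]
      Xmis <- Xmis[, keep, drop = FALSE]
      work[[v]][idx] <- impute_one(data[[v]], yobs, Xobs, Xmis, pmm)
    }
  }
  work
}

impute_one <- function(y_full, yobs, Xobs, Xmis, pmm) {
  if (is.numeric(y_full) && length(unique(yobs)) > 2) {
    bayes_lm_draw(yobs, Xobs, Xmis, pmm)
  } else if (is.factor(y_full) && nlevels(y_full) > 2) {
    drop_ic <- colnames(Xobs) %in% "(Intercept)"
    dfo <- as.data.frame(Xobs[, !drop_ic, drop = FALSE])
    names(dfo) <- paste0("V", seq_len(ncol(dfo)))
    dfm <- as.data.frame(Xmis[, !drop_ic, drop = FALSE])
    names(dfm) <- names(dfo)
    dfo$.y <- yobs
    fit <- suppressWarnings(nnet::multinom(.y ~ ., data = dfo,
                                           trace = FALSE, maxit = 200))
    p <- stats::predict(fit, newdata = dfm, type = "probs")
    if (is.null(dim(p))) p <- rbind(p)
    lv <- fit$lev
    draw <- apply(p, 1, function(pr) sample(lv, 1, prob = pr))
    factor(draw, levels = levels(y_full))
  } else {
    # binary (numeric 0/1, logical, or 2-level factor): logistic draws
    yb <- if (is.factor(y_full)) as.integer(yobs == levels(y_full)[2])
          else as.numeric(yobs)
    fit <- ridge_logit(yb, Xobs)
    eta <- drop(Xmis %*% fit)
    draw01 <- stats::rbinom(nrow(Xmis), 1, stats::plogis(eta))
    if (is.factor(y_full)) factor(levels(y_full)[draw01 + 1],
                                  levels = levels(y_full))
    else if (is.logical(y_full)) as.logical(draw01)
    else draw01
  }
}

# Bayesian linear regression draws (or predictive mean matching)
bayes_lm_draw <- function(yobs, Xobs, Xmis, pmm) {
  n <- length(yobs); p <- ncol(Xobs)
  XtX <- crossprod(Xobs)
  R <- tryCatch(chol(XtX), error = function(e) chol(XtX + diag(1e-6, p)))
  bhat <- backsolve(R, forwardsolve(t(R), crossprod(Xobs, yobs)))
  res <- yobs - drop(Xobs %*% bhat)
  df <- max(n - p, 1)
  sig2 <- sum(res^2) / stats::rchisq(1, df)
  bstar <- bhat + backsolve(R, stats::rnorm(p)) * sqrt(sig2)
  mu_mis <- drop(Xmis %*% bstar)
  if (pmm) {
    mu_obs <- drop(Xobs %*% bstar)
    vapply(mu_mis, function(mv) {
      d <- abs(mu_obs - mv)
      donors <- order(d)[seq_len(min(5, n))]
      yobs[sample(donors, 1)]
    }, numeric(1))
  } else {
    mu_mis + stats::rnorm(nrow(Xmis), 0, sqrt(sig2))
  }
}

# logistic scoring with a small ridge, stabilising perfect separation
ridge_logit <- function(y, X, lambda = 1e-4, maxit = 50) {
  p <- ncol(X)
  beta <- rep(0, p)
  warned <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, p)
    g <- crossprod(X, y - mu) - lambda * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) { warned <- TRUE; break }
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
    if (max(abs(beta)) > 30 && !warned) {
      warning("near-separation in a conditional imputation model; ",
              "ridge-stabilised fit used")
      warned <- TRUE
      lambda <- 1e-2
    }
  }
  beta
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf(
    "Imputation set: m = %d, %d iterations, %d incomplete variable(s)\n",
    x$m, x$iterations, length(x$incomplete)))
  invisible(x)
}

#' Write / read an imputation set as CSVs plus a JSON manifest
#'
#' @param iset An `imputation_set`.
#' @param dir Output directory (created).
#' @export
write_imputation_set <- function(iset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(iset$m))
    utils::write.csv(iset$completed[[k]],
                     file.path(dir, sprintf("imputation_%02d.csv", k)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(m = iset$m, iterations = iset$iterations, seed = iset$seed,
         variables = iset$variables, incomplete = iset$incomplete,
         pmm = iset$pmm),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Rubin's rules for pooling scalar estimates
#'
#' `qbar` the mean estimate; `W` the mean within-imputation variance; `B`
#' the between-imputation sample variance; total `T = W + (1 + 1/m) B`;
#' small-sample degrees of freedom `(m - 1)(1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates Numeric vector of m point estimates.
#' @param variances Numeric vector of m squared standard errors.
#' @return Object of class `pooled_estimate` with fields `qbar, W, B, T, df,
#'   se`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m, all(variances >= 0))
  qbar <- mean(estimates)
  W <- mean(variances)
  if (m == 1) {
    warning("m = 1: between-imputation variance undefined; total = within")
    out <- list(qbar = qbar, W = W, B = NA_real_, T = W, df = Inf,
                se = sqrt(W), m = m)
  } else {
    B <- stats::var(estimates)
    Tt <- W + (1 + 1 / m) * B
    df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
    out <- list(qbar = qbar, W = W, B = B, T = Tt, df = df, se = sqrt(Tt),
                m = m)
  }
  structure(out, class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate: %.4f (se %.4f), W = %.5f, B = %s, T = %.5f, df = %.1f\n",
    x$qbar, x$se, x$W, ifelse(is.na(x$B), "NA", sprintf("%.5f", x$B)), x$T,
    x$df))
  invisible(x)
}

#' Pool a likelihood-ratio test across imputations (Meng-Rubin D3)
#'
#' `dbar_m` is the mean of the per-imputation LR statistics
#' `2 (ll_full - ll_null)` at their own MLEs; parameters are then pooled by
#' averaging across imputations on the estimation scale, and `dbar_L` is the
#' mean LR statistic re-evaluated at the pooled parameters on each completed
#' dataset.  The relative increase in variance is
#' `r_L = ((m + 1) / (k (m - 1))) (dbar_m - dbar_L)` (clipped at 0), the
#' pooled statistic `D3 = dbar_L / (k (1 + r_L))`, referred to an
#' `F(k, df_den)` distribution with
#' `df_den = 4 + (k(m-1) - 4)(1 + (1 - 2/(k(m-1)))/r_L)^2` when
#' `k (m - 1) > 4`, else `df_den = (m-1)(1 + 1/k)(1 + 1/r_L)^2 / 2`.
#'
#' @param full_fits,null_fits Lists of m fitted models; each must carry
#'   `estimate` (named numeric) `loglik` (numeric) and `loglik_fun`
#'   (re-evaluation at arbitrary parameters on that imputation's data), as
#'   [fit_msm()] objects do.
#' @param k Number of parameter constraints tested.
#' @return Object of class `pooled_lrt` with fields `dbar_m, dbar_L, r_L,
#'   D3, df_num, df_den, p_value`.
#' @export
pool_lrt_meng_rubin <- function(full_fits, null_fits, k) {
  m <- length(full_fits)
  stopifnot(m >= 1, length(null_fits) == m, k >= 1)
  d_i <- vapply(seq_len(m), function(i) {
    2 * (full_fits[[i]]$loglik - null_fits[[i]]$loglik)
  }, numeric(1))
  dbar_m <- mean(d_i)
  if (m == 1) {
    warning("m = 1: D3 reduces to d/k against F(k, Inf) (chi-square / k)")
    D3 <- dbar_m / k
    p <- stats::pchisq(dbar_m, df = k, lower.tail = FALSE)
    return(structure(list(dbar_m = dbar_m, dbar_L = dbar_m, r_L = 0,
                          D3 = D3, df_num = k, df_den = Inf, p_value = p,
                          m = m, clipped = FALSE),
                     class = "pooled_lrt"))
  }
  pool_par <- function(fits) {
    np <- length(fits[[1]]$estimate)
    P <- matrix(vapply(fits, function(f) f$estimate, numeric(np)),
                nrow = np)
    setNames(rowMeans(P), names(fits[[1]]$estimate))
  }
  th_full <- pool_par(full_fits)
  th_null <- pool_par(null_fits)
  dL_i <- vapply(seq_len(m), function(i) {
    2 * (full_fits[[i]]$loglik_fun(th_full) -
           null_fits[[i]]$loglik_fun(th_null))
  }, numeric(1))
  dbar_L <- mean(dL_i)
  r_raw <- ((m + 1) / (k * (m - 1))) * (dbar_m - dbar_L)
  clipped <- r_raw < 0
  if (clipped)
    message("Meng-Rubin r_L negative (", signif(r_raw, 3),
            "); clipped at 0")
  r_L <- max(r_raw, 0)
  D3 <- dbar_L / (k * (1 + r_L))
  km <- k * (m - 1)
  df_den <- if (r_L == 0) Inf
    else if (km > 4) 4 + (km - 4) * (1 + (1 - 2 / km) / r_L)^2
    else (m - 1) * (1 + 1 / k) * (1 + 1 / r_L)^2 / 2
  p <- if (is.finite(df_den)) stats::pf(D3, k, df_den, lower.tail = FALSE)
       else stats::pchisq(k * D3, df = k, lower.tail = FALSE)
  structure(list(dbar_m = dbar_m, dbar_L = dbar_L, r_L = r_L, D3 = D3,
                 df_num = k, df_den = df_den, p_value = p, m = m,
                 clipped = clipped),
            class = "pooled_lrt")
}

#' @export
print.pooled_lrt <- function(x, ...) {
  cat(sprintf(
    "Meng-Rubin pooled LRT: D3 = %.4f on (%d, %.1f) df, p = %.4g (r_L = %.3f)\n",
    x$D3, x$df_num, x$df_den, x$p_value, x$r_L))
  invisible(x)
}
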