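# Generalized estimating equations (identity and probit links, independence
# or exchangeable working correlation, cluster-robust sandwich covariance)
# and the two-stage Heckman correction for informative missingness of
# longitudinal growth outcomes, with cluster bootstrap.

#' Specify a GEE model
#'
#' @param formula Model formula (response on the left).
#' @param id Name of the cluster (child) id column.
#' @param link `"identity"` or `"probit"`.
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param maxit,tol Iteration control.
#' @return Object of class `gee_spec`.
#' @export
gee_spec <- function(formula, id = "child_id",
                     link = c("identity", "probit"),
                     corstr = c("exchangeable", "independence"),
                     maxit = 50, tol = 1e-10) {
  structure(list(formula = stats::as.formula(formula), id = id,
                 link = match.arg(link), corstr = match.arg(corstr),
                 maxit = maxit, tol = tol),
            class = "gee_spec")
}

#' Fit a marginal model by generalized estimating equations
#'
#' Iterated weighted least squares on the GEE score with a moment-based
#' update of the exchangeable correlation from standardized Pearson
#' residuals; robust (sandwich) covariance clustered on the id.  With an
#' identity link, independence correlation, and singleton clusters the
#' estimates collapse to ordinary least squares; with a probit link under
#' independence they solve the probit maximum-likelihood score.
#'
#' @param spec A [gee_spec()].
#' @param data Data frame containing the response, covariates and id.
#' @return Object of class `gee_fit`: `coefficients`, `robust_cov`,
#'   `naive_cov`, `alpha` (exchangeable correlation), `phi` (dispersion),
#'   `converged`, `n_clusters`, `n_obs`.
#' @export
gee_fit <- function(spec, data) {
  rownames(data) <- NULL
  mf <- stats::model.frame(spec$formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(spec$formula, mf)
  if (qr(X)$rank < ncol(X))
    stop("design matrix not of full column rank")
  rows <- as.numeric(rownames(mf))
  id <- data[[spec$id]][rows]
  if (anyNA(id)) stop("missing cluster id")
  ord <- order(match(id, unique(id)))
  y <- y[ord]; X <- X[ord, , drop = FALSE]; id <- id[ord]
  if (length(unique(id)) < 2) stop("need at least 2 clusters")
  if (spec$link == "probit" && !all(y %in% c(0, 1)))
    stop("probit link requires a binary 0/1 response")

  p <- ncol(X)
  n <- length(y)
  cl <- split(seq_len(n), factor(id, levels = unique(id)))
  sizes <- lengths(cl)
  # initial values from the independence (GLM) fit
  beta <- if (spec$link == "identity") {
    stats::lm.fit(X, y)$coefficients
  } else {
    suppressWarnings(stats::glm.fit(X, y,
      family = stats::binomial("probit"))$coefficients)
  }
  beta[is.na(beta)] <- 0
  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (it in seq_len(spec$maxit)) {
    eta <- drop(X %*% beta)
    if (spec$link == "identity") {
      mu <- eta; dmu <- rep(1, n); vfun <- rep(1, n)
    } else {
      mu <- stats::pnorm(eta); dmu <- stats::dnorm(eta)
      vfun <- pmax(mu * (1 - mu), 1e-10)
    }
    r <- (y - mu) / sqrt(vfun)
    phi <- sum(r^2) / (n - p)
    if (spec$corstr == "exchangeable") {
      npair <- sum(sizes * (sizes - 1)) / 2
      if (npair > p) {
        ss <- vapply(cl, function(ix) {
          ri <- r[ix]
          (sum(ri)^2 - sum(ri^2)) / 2
        }, numeric(1))
        alpha <- sum(ss) / (phi * (npair - p))
        amax <- 1 / (max(sizes) - 1 + 1e-12)
        alpha <- min(max(alpha, -0.99 * amax), 0.99)
      } else alpha <- 0
    }
    # assemble the estimating equations cluster by cluster using the
    # closed-form exchangeable inverse R^-1 = (I - a/(1+(k-1)a) J)/(1-a)
    A <- matrix(0, p, p)
    g <- numeric(p)
    for (ix in cl) {
      k <- length(ix)
      Di <- X[ix, , drop = FALSE] * dmu[ix]
      si <- sqrt(vfun[ix])
      ri <- y[ix] - mu[ix]
      if (spec$corstr == "independence" || k == 1 || alpha == 0) {
        U <- Di / (si^2)
        gi <- crossprod(U, ri)
        Ai <- crossprod(U, Di)
      } else {
        Ds <- Di / si
        rs <- ri / si
        f <- alpha / (1 + (k - 1) * alpha)
        # V^-1 x = (x - f * sum(x) 1)/(1-alpha) on the variance-scaled side
        Vr <- (rs - f * sum(rs)) / (1 - alpha)
        VD <- (Ds - matrix(f * colSums(Ds), k, p, byrow = TRUE)) /
          (1 - alpha)
        gi <- crossprod(Ds, Vr)
        Ai <- crossprod(Ds, VD)
      }
      A <- A + Ai
      g <- g + drop(gi)
    }
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step)) {
      if (spec$corstr == "exchangeable") {
        warning("singular working covariance; falling back to independence")
        spec$corstr <- "independence"; alpha <- 0
        next
      }
      stop("singular estimating-equation derivative")
    }
    beta <- beta + drop(step)
    if (max(abs(step)) < spec$tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(step)) < 1e-6) converged <- TRUE
  if (!converged)
    stop("GEE did not converge after ", spec$maxit,
         " iterations (last step ", signif(max(abs(step)), 3), ")")
  # final quantities at the solution
  eta <- drop(X %*% beta)
  if (spec$link == "identity") {
    mu <- eta; dmu <- rep(1, n); vfun <- rep(1, n)
  } else {
    mu <- stats::pnorm(eta); dmu <- stats::dnorm(eta)
    vfun <- pmax(mu * (1 - mu), 1e-10)
  }
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    k <- length(ix)
    Di <- X[ix, , drop = FALSE] * dmu[ix]
    si <- sqrt(vfun[ix])
    ri <- y[ix] - mu[ix]
    if (spec$corstr == "independence" || k == 1 || alpha == 0) {
      gi <- crossprod(Di / (si^2), ri)
      Ai <- crossprod(Di / (si^2), Di)
    } else {
      Ds <- Di / si
      rs <- ri / si
      f <- alpha / (1 + (k - 1) * alpha)
      Vr <- (rs - f * sum(rs)) / (1 - alpha)
      VD <- (Ds - matrix(f * colSums(Ds), k, p, byrow = TRUE)) / (1 - alpha)
      gi <- crossprod(Ds, Vr)
      Ai <- crossprod(Ds, VD)
    }
    A <- A + Ai
    M <- M + tcrossprod(drop(gi))
  }
  Ainv <- solve(A)
  robust <- Ainv %*% M %*% Ainv
  robust <- (robust + t(robust)) / 2
  naive <- Ainv * phi
  names(beta) <- colnames(X)
  dimnames(robust) <- dimnames(naive) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, robust_cov = robust,
                 naive_cov = naive, alpha = alpha, phi = phi,
                 converged = converged, iterations = it,
                 n_clusters = length(cl), n_obs = n, spec = spec),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit (%s link, %s correlation)\n", x$spec$link,
              x$spec$corstr))
  cat(sprintf("  %d observations in %d clusters; alpha = %.3f, phi = %.3f\n",
              x$n_obs, x$n_clusters, x$alpha, x$phi))
  se <- sqrt(diag(x$robust_cov))
  tab <- cbind(estimate = x$coefficients, robust_se = se,
               p = 2 * stats::pnorm(-abs(x$coefficients / se)))
  print(round(tab, 4))
  invisible(x)
}

#' Coefficient table for a GEE fit
#'
#' @param fit A `gee_fit`.
#' @return Data frame `term, estimate, se, lower, upper, p` using the robust
#'   covariance.
#' @export
gee_coef_table <- function(fit) {
  se <- sqrt(diag(fit$robust_cov))
  est <- fit$coefficients
  data.frame(term = names(est), estimate = unname(est), se = se,
             lower = unname(est) - 1.96 * se,
             upper = unname(est) + 1.96 * se,
             p = 2 * stats::pnorm(-abs(est / se)), row.names = NULL)
}

#' Inverse Mills ratio
#'
#' `lambda(eta) = phi(eta) / Phi(eta)`, evaluated on the log scale so that
#' deeply negative linear predictors (where `lambda ~ -eta`) do not
#' overflow.
#'
#' @param eta Numeric vector of probit linear predictors.
#' @return Positive numeric vector.
#' @export
inverse_mills <- function(eta) {
  exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE))
}

#' Cluster bootstrap of an estimation procedure
#'
#' Resamples clusters (children) with replacement — always the original
#' number of clusters, all records of a resampled child moving together —
#' and re-runs `procedure` on each replicate.  Percentile 95% intervals and
#' two-sided bootstrap p-values `2 min(fraction <= 0, fraction >= 0)` per
#' coefficient.
#'
#' @param procedure Function taking a data frame and returning a named
#'   numeric coefficient vector.
#' @param data Data frame with the cluster id column.
#' @param id Cluster id column name.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return Object of class `cluster_boot`: `replicates` (reps x p matrix),
#'   `ci` (percentile bounds), `p_value`, `se`, `failures`.
#' @export
cluster_bootstrap <- function(procedure, data, id = "child_id", reps = 500,
                              seed = 1L) {
  if (reps < 50) warning("fewer than 50 bootstrap replicates: ",
                         "percentile intervals are unstable")
  ids <- unique(data[[id]])
  nid <- length(ids)
  rows_by_id <- split(seq_len(nrow(data)), factor(data[[id]], levels = ids))
  out <- NULL
  failures <- 0L
  set.seed(seed)
  for (r in seq_len(reps)) {
    pick <- sample.int(nid, nid, replace = TRUE)
    idx <- unlist(rows_by_id[pick], use.names = FALSE)
    boot <- data[idx, , drop = FALSE]
    # resampled children must stay distinct clusters
    boot[[id]] <- rep(seq_along(pick), lengths(rows_by_id)[pick])
    co <- tryCatch(procedure(boot), error = function(e) NULL)
    if (is.null(co)) { failures <- failures + 1L; next }
    if (is.null(out)) out <- matrix(NA_real_, reps, length(co),
                                    dimnames = list(NULL, names(co)))
    out[r, names(co)] <- co
  }
  if (failures > 0.05 * reps)
    stop("more than 5% of bootstrap replicates failed (", failures, "/",
         reps, ")")
  ok <- stats::complete.cases(out)
  B <- out[ok, , drop = FALSE]
  ci <- apply(B, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  pv <- apply(B, 2, function(b) min(1, 2 * min(mean(b <= 0), mean(b >= 0))))
  structure(list(replicates = B, ci = t(ci), p_value = pv,
                 se = apply(B, 2, stats::sd), failures = failures,
                 reps = reps),
            class = "cluster_boot")
}

#' Two-stage Heckman correction for informative outcome missingness
#'
#' Stage 1: probit GEE for the per-scheduled-visit indicator that the
#' outcome (z-score) was observed, on all scheduled pre-death visits.
#' The inverse Mills ratio `lambda = phi(eta) / Phi(eta)` is evaluated at
#' each observed record's stage-1 linear predictor.  Stage 2: identity-link
#' GEE for the z-score on observed records, fitted with and without
#' `imr` as a covariate; the corrected model's uncertainty comes from a
#' cluster bootstrap re-running both stages per replicate (the IMR is a
#' generated regressor, so model-based standard errors are invalid).
#'
#' @param data Visit-level data frame including the observation indicator,
#'   the outcome, all covariates, and the cluster id.
#' @param stage1 A [gee_spec()] for the observation indicator (probit).
#' @param stage2 A [gee_spec()] for the outcome (identity); `imr` is
#'   appended for the corrected fit.
#' @param bootstrap_reps Bootstrap replicates (0 skips the bootstrap;
#'   point estimates and model-based fits are still returned).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `heckman_fit`: `stage1`, `imr` (per observed
#'   record), `stage2_naive`, `stage2_corrected`, `bootstrap` (or NULL).
#' @export
heckman_two_stage <- function(data, stage1, stage2, bootstrap_reps = 500,
                              seed = 1L) {
  stopifnot(inherits(stage1, "gee_spec"), inherits(stage2, "gee_spec"))
  if (stage1$link != "probit") stop("stage 1 must use the probit link")
  if (stage2$link != "identity") stop("stage 2 must use the identity link")
  s1_terms <- attr(stats::terms(stage1$formula), "term.labels")
  s2_terms <- attr(stats::terms(stage2$formula), "term.labels")
  if (!length(setdiff(s1_terms, s2_terms)))
    warning("no exclusion restriction: every stage-1 covariate also ",
            "appears in stage 2; identification rests on nonlinearity only")
  run <- function(d) {
    rownames(d) <- NULL
    s1 <- gee_fit(stage1, d)
    mf1 <- stats::model.frame(stage1$formula, d, na.action = stats::na.omit)
    X1 <- stats::model.matrix(stage1$formula, mf1)
    eta <- drop(X1 %*% s1$coefficients)
    lam <- rep(NA_real_, nrow(d))
    lam[as.numeric(rownames(mf1))] <- inverse_mills(eta)
    d$imr <- lam
    resp1 <- all.vars(stage1$formula)[1]
    obs <- d[[resp1]] == 1 & !is.na(d$imr)
    dobs <- d[obs, , drop = FALSE]
    f2c <- stats::update(stage2$formula, . ~ . + imr)
    spec2c <- stage2; spec2c$formula <- f2c
    s2n <- gee_fit(stage2, dobs)
    s2c <- gee_fit(spec2c, dobs)
    list(s1 = s1, s2n = s2n, s2c = s2c, dobs = dobs)
  }
  fits <- run(data)
  boot <- NULL
  if (bootstrap_reps > 0) {
    boot <- cluster_bootstrap(function(d) run(d)$s2c$coefficients,
                              data, id = stage2$id, reps = bootstrap_reps,
                              seed = seed)
  }
  structure(list(stage1 = fits$s1,
                 imr = fits$dobs$imr,
                 stage2_naive = fits$s2n,
                 stage2_corrected = fits$s2c,
                 bootstrap = boot),
            class = "heckman_fit")
}

#' @export
print.heckman_fit <- function(x, ...) {
  cat("Two-stage Heckman GEE correction\n")
  cat(sprintf("  stage 1 (probit): %d records, %d clusters\n",
              x$stage1$n_obs, x$stage1$n_clusters))
  cat(sprintf("  stage 2 (identity): %d observed records\n",
              x$stage2_corrected$n_obs))
  co <- x$stage2_corrected$coefficients
  if (!is.null(x$bootstrap)) {
    tab <- cbind(estimate = co,
                 boot_se = x$bootstrap$se[names(co)],
                 lower = x$bootstrap$ci[names(co), 1],
                 upper = x$bootstrap$ci[names(co), 2],
                 p = x$bootstrap$p_value[names(co)])
  } else {
    tab <- cbind(estimate = co,
                 robust_se = sqrt(diag(x$stage2_corrected$robust_cov)))
  }
  print(round(tab, 4))
  invisible(x)
}

#' Serialize a Heckman fit to JSON
#'
#' Coefficients and robust standard errors for both stages, plus the
#' bootstrap standard errors, percentile intervals and p-values for the
#' corrected model when a bootstrap was run.
#'
#' @param fit A `heckman_fit`.
#' @param path Output path.
#' @export
write_heckman_fit <- function(fit, path) {
  blk <- function(g) list(coefficients = as.list(g$coefficients),
                          robust_se = as.list(sqrt(diag(g$robust_cov))),
                          alpha = g$alpha, n_obs = g$n_obs,
                          n_clusters = g$n_clusters)
  obj <- list(stage1 = blk(fit$stage1),
              stage2_naive = blk(fit$stage2_naive),
              stage2_corrected = blk(fit$stage2_corrected))
  if (!is.null(fit$bootstrap)) {
    b <- fit$bootstrap
    obj$bootstrap <- list(reps = b$reps, failures = b$failures,
                          se = as.list(b$se),
                          ci_lower = as.list(b$ci[, 1]),
                          ci_upper = as.list(b$ci[, 2]),
                          p_value = as.list(b$p_value))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Side-by-side comparison table for a Heckman fit
#'
#' Side-by-side coefficient blocks for the uncorrected marginal model
#' (robust model-based inference) and the IMR-corrected model (bootstrap
#' inference when available).
#'
#' @param fit A `heckman_fit`.
#' @return Data frame with `term` and paired
#'   `coef/se/lower/upper/p` blocks.
#' @export
heckman_table <- function(fit) {
  naive <- gee_coef_table(fit$stage2_naive)
  corr <- gee_coef_table(fit$stage2_corrected)
  if (!is.null(fit$bootstrap)) {
    b <- fit$bootstrap
    corr$se <- unname(b$se[corr$term])
    corr$lower <- unname(b$ci[corr$term, 1])
    corr$upper <- unname(b$ci[corr$term, 2])
    corr$p <- unname(b$p_value[corr$term])
  }
  names(naive)[-1] <- paste0("naive_", names(naive)[-1])
  names(corr)[-1] <- paste0("corrected_", names(corr)[-1])
  merge(naive, corr, by = "term", all = TRUE, sort = FALSE)
}
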