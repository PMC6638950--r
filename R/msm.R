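# Three-state illness-death model with recovery:
#   1 = healthy, 2 = malnourished, 3 = dead (absorbing)
# Allowed transitions 1->2, 1->3, 2->1, 2->3; piecewise-constant baseline
# intensities on age bands; proportional-intensity covariate effects.

MSM_TRANSITIONS <- c("q12", "q13", "q21", "q23")
MSM_FROM <- c(q12 = 1L, q13 = 1L, q21 = 2L, q23 = 2L)
MSM_TO   <- c(q12 = 2L, q13 = 3L, q21 = 1L, q23 = 3L)

#' Age bands for piecewise-constant intensities
#'
#' Default bands (0,6], (6,12], (12,60] months; the last band is treated as
#' open-ended to the right so late observation times remain usable.
#'
#' @param cuts Increasing numeric cut points, first element the origin.
#' @return Object describing the bands.
#' @export
age_bands <- function(cuts = c(0, 6, 12, 60)) {
  stopifnot(is.numeric(cuts), length(cuts) >= 2, all(diff(cuts) > 0))
  structure(list(cuts = cuts, n = length(cuts) - 1L,
                 labels = paste0("(", cuts[-length(cuts)], ",", cuts[-1], "]")),
            class = "age_bands")
}

# band containing time t (bands are (lo, hi]); t beyond the last cut maps to
# the last band
band_of <- function(bands, t) {
  b <- findInterval(t, bands$cuts, left.open = TRUE, rightmost.closed = FALSE)
  pmin(pmax(b, 1L), bands$n)
}

# duration of (t1, t2] inside band b (last band open-ended)
band_overlap <- function(bands, b, t1, t2) {
  lo <- bands$cuts[b]
  hi <- if (b == bands$n) Inf else bands$cuts[b + 1L]
  pmax(0, pmin(t2, hi) - pmax(t1, lo))
}

#' Construct multi-state model parameters
#'
#' @param log_q0 4 x nband numeric matrix of log baseline intensities per
#'   month, rows `q12, q13, q21, q23`, columns the age bands; `-Inf` encodes
#'   a structurally zero (fixed) intensity.
#' @param beta Named list per transition of named covariate log-hazard
#'   coefficients (may be empty).
#' @param bands An [age_bands()] object.
#' @return Object of class `msm_params`.
#' @export
msm_params <- function(log_q0, beta = NULL, bands = age_bands()) {
  log_q0 <- as.matrix(log_q0)
  if (nrow(log_q0) != 4L || ncol(log_q0) != bands$n)
    stop("log_q0 must be 4 x ", bands$n)
  rownames(log_q0) <- MSM_TRANSITIONS
  colnames(log_q0) <- bands$labels
  if (is.null(beta)) beta <- setNames(vector("list", 4), MSM_TRANSITIONS)
  beta <- beta[MSM_TRANSITIONS]
  names(beta) <- MSM_TRANSITIONS
  structure(list(log_q0 = log_q0, beta = beta, bands = bands),
            class = "msm_params")
}

#' Transition intensity generator for one band and covariate vector
#'
#' Builds the 3x3 generator Q with
#' `q_rs = exp(log_q0[rs, band] + beta[rs] . x)` on the allowed transitions,
#' zero elsewhere, diagonal minus the row sum; the death row is zero.
#'
#' @param params An [msm_params()] object.
#' @param x Named numeric covariate vector (values for every name appearing
#'   in `params$beta`); may be `NULL` when no covariates are modelled.
#' @param band Band index.
#' @return 3x3 generator matrix.
#' @export
build_generator <- function(params, x = NULL, band = 1L) {
  Q <- matrix(0, 3, 3)
  for (tr in MSM_TRANSITIONS) {
    eta <- params$log_q0[tr, band]
    b <- params$beta[[tr]]
    if (length(b)) {
      if (is.null(x) || !all(names(b) %in% names(x)))
        stop("covariate values missing for transition ", tr)
      eta <- eta + sum(b * x[names(b)])
    }
    Q[MSM_FROM[tr], MSM_TO[tr]] <- exp(eta)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an interval of constant intensities
#'
#' `P(dt) = expm(dt * Q)` computed by uniformization (Poisson-weighted power
#' series of the stochastic matrix `I + Q/lambda`), which is numerically
#' robust for any generator.
#'
#' @param Q Square generator matrix (rows sum to 0, non-negative
#'   off-diagonals).
#' @param dt Non-negative elapsed time.
#' @return Stochastic matrix of the same dimension.
#' @export
transition_probability <- function(Q, dt) {
  stopifnot(dt >= 0, nrow(Q) == ncol(Q))
  n <- nrow(Q)
  if (dt == 0) return(diag(n))
  lambda <- max(-diag(Q))
  if (lambda <= 0) return(diag(n))
  A <- diag(n) + Q / lambda
  mu <- lambda * dt
  # truncate where the Poisson tail is negligible
  kmax <- max(20, ceiling(mu + 12 * sqrt(mu) + 12))
  P <- diag(n) * exp(-mu)
  term <- diag(n)
  w <- exp(-mu)
  for (k in seq_len(kmax)) {
    term <- term %*% A
    w <- w * mu / k
    P <- P + w * term
    if (w < 1e-17 && k > mu) break
  }
  # guard rounding
  P[P < 0] <- 0
  P / rowSums(P)
}

# Closed-form matrix exponential of the live-state 2x2 block, vectorised.
# For A = [[-(q12+q13), q12], [q21, -(q21+q23)]] the eigenvalues are real
# (the discriminant is a sum of squares plus a product of non-negative
# rates), so with m = tr(A)/2 and h = sqrt(disc)/2,
#   expm(A dt) = e^{m dt} [ cosh(h dt) I + (sinh(h dt)/h) (A - m I) ],
# a form uniformly valid as h -> 0 via sinh(x)/x -> 1.
# Inputs are vectors of length n; returns list of 4 vectors (p11,p12,p21,p22).
expm_live <- function(q12, q13, q21, q23, dt) {
  a11 <- -(q12 + q13); a22 <- -(q21 + q23)
  m <- (a11 + a22) / 2
  dg <- (a11 - a22) / 2
  h <- sqrt(dg * dg + q12 * q21)
  x <- h * dt
  shx <- dt * (1 + x * x / 6)        # sinh(h dt)/h, series for small x
  big <- x > 1e-5
  if (any(big)) shx[big] <- sinh(x[big]) / h[big]
  E <- exp(m * dt)
  ch <- E * cosh(x)
  sh <- E * shx
  list(p11 = ch + sh * dg, p12 = sh * q12,
       p21 = sh * q21, p22 = ch - sh * dg)
}

# per-transition intensity vectors for every band, given unique covariate
# rows; returns list q[[tr]][band, xrow]
intensity_grid <- function(params, Xu) {
  nx <- if (is.null(Xu)) 1L else nrow(Xu)
  out <- list()
  for (tr in MSM_TRANSITIONS) {
    b <- params$beta[[tr]]
    eta <- if (length(b) && !is.null(Xu)) as.numeric(Xu[, names(b), drop = FALSE] %*% b)
           else rep(0, nx)
    out[[tr]] <- exp(outer(params$log_q0[tr, ], eta, "+"))  # nband x nx
  }
  out
}

#' Interval transition probability under age-band inhomogeneity
#'
#' Ordered product of constant-intensity transition matrices over the
#' maximal sub-intervals of `(t_start, t_end]` on which the age band is
#' constant (covariates are held at their interval-start values).
#'
#' @inheritParams build_generator
#' @param t_start,t_end Interval endpoints in months, `t_start < t_end`.
#' @return 3x3 transition probability matrix.
#' @export
interval_probability <- function(params, x = NULL, t_start, t_end) {
  stopifnot(t_start < t_end)
  bands <- params$bands
  P <- diag(3)
  for (b in seq_len(bands$n)) {
    d <- band_overlap(bands, b, t_start, t_end)
    if (d > 0) P <- P %*% transition_probability(build_generator(params, x, b), d)
  }
  P
}

# ---- panel data --------------------------------------------------------------

#' Read a panel dataset from CSV
#'
#' Schema `child_id,age_months,state,obs_type,<covariates...>` with
#' `obs_type` in `{panel, exact_death}`.
#'
#' @param path CSV path.
#' @return Data frame validated by [validate_panel()].
#' @export
read_panel_csv <- function(path) {
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_panel_csv
#' @param data Panel data frame to validate.
#' @export
validate_panel <- function(data) {
  need <- c("child_id", "age_months", "state", "obs_type")
  if (!all(need %in% names(data)))
    stop("panel data must have columns ", paste(need, collapse = ", "))
  if (!all(data$obs_type %in% c("panel", "exact_death")))
    stop("obs_type must be 'panel' or 'exact_death'")
  # death state known only at a visit (obs_type "panel" with state 3) is a
  # permitted encoding; exact_death always implies state 3
  if (any(data$obs_type == "exact_death" & data$state != 3L, na.rm = TRUE))
    stop("obs_type 'exact_death' requires state 3")
  ord <- order(data$child_id, data$age_months)
  data <- data[ord, , drop = FALSE]
  bad <- unlist(tapply(data$age_months, data$child_id,
                       function(t) any(diff(t) <= 0)))
  if (any(bad))
    stop("times must be strictly increasing within child: ",
         paste(utils::head(names(bad)[bad], 5), collapse = ", "))
  dead_not_last <- unlist(tapply(data$state, data$child_id, function(s) {
    w <- which(!is.na(s) & s == 3L)
    length(w) && any(w < length(s))
  }))
  if (any(dead_not_last)) stop("state 3 must be terminal within child")
  data
}

# Aggregate a panel dataset for fast repeated likelihood evaluation.
# Consecutive observation pairs within child are grouped by
# (t1, t2, s1, s2, death flag, covariate pattern) with multiplicity counts.
msm_prepare <- function(data, covariates = character()) {
  data <- validate_panel(data)
  term_map <- list()
  if (length(covariates)) {
    form <- stats::reformulate(covariates)
    mf <- stats::model.frame(form, data, na.action = stats::na.pass)
    X0 <- stats::model.matrix(form, mf)
    asg <- attr(X0, "assign")
    X <- X0[, asg > 0, drop = FALSE]
    # raw term name -> expanded design-matrix column names (factor dummies)
    labs <- attr(stats::terms(form), "term.labels")
    for (j in seq_along(labs))
      term_map[[labs[j]]] <- colnames(X0)[asg == j]
  } else X <- NULL

  id <- data$child_id
  n <- nrow(data)
  first <- !duplicated(id)
  prev <- c(FALSE, id[-1] == id[-n])          # row has a predecessor
  i2 <- which(prev)
  i1 <- i2 - 1L
  ok <- !is.na(data$state[i1]) & !is.na(data$state[i2])
  # pairs starting at a missing state are re-anchored at the previous
  # non-missing observation of the same child
  if (any(!ok)) {
    keep <- !is.na(data$state)
    idx <- which(keep)
    idk <- id[keep]
    p2 <- idx[c(FALSE, idk[-1] == idk[-length(idk)])]
    p1 <- idx[which(c(FALSE, idk[-1] == idk[-length(idk)])) - 1L]
    i1 <- p1; i2 <- p2
    ok <- rep(TRUE, length(i1))
  }
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(X)) {
    Xp <- X[i1, , drop = FALSE]
    if (anyNA(Xp)) {
      cc <- stats::complete.cases(Xp)
      i1 <- i1[cc]; i2 <- i2[cc]; Xp <- Xp[cc, , drop = FALSE]
    }
    pat <- apply(Xp, 1, paste, collapse = "\r")
    xkey <- match(pat, unique(pat))
    Xu <- Xp[match(seq_len(max(xkey)), xkey), , drop = FALSE]
  } else {
    xkey <- rep(1L, length(i1))
    Xu <- NULL
  }
  tab <- data.frame(t1 = data$age_months[i1], t2 = data$age_months[i2],
                    s1 = data$state[i1], s2 = data$state[i2],
                    death = data$obs_type[i2] == "exact_death",
                    xkey = xkey)
  drop_self <- tab$s1 == 3L
  if (any(drop_self)) {
    tab <- tab[!drop_self, , drop = FALSE]
  }
  key <- do.call(paste, c(tab, sep = "\r"))
  agg <- tab[!duplicated(key), , drop = FALSE]
  agg$count <- as.vector(table(factor(key, levels = key[!duplicated(key)])))
  # unique (t1, t2, xkey) intervals shared across rows
  ikey <- paste(agg$t1, agg$t2, agg$xkey, sep = "\r")
  agg$interval <- match(ikey, unique(ikey))
  ints <- agg[!duplicated(agg$interval), c("t1", "t2", "xkey"), drop = FALSE]
  # parameter-independent structures for the hot likelihood path: band
  # durations per unique interval, and flat index vectors per row type
  bands <- age_bands()
  D <- vapply(seq_len(bands$n), function(b)
    band_overlap(bands, b, ints$t1, ints$t2), numeric(nrow(ints)))
  D <- matrix(D, nrow = nrow(ints))
  nd <- !agg$death
  pick <- integer(sum(nd))                       # live-cell column, 0 = to-death
  s1n <- agg$s1[nd]; s2n <- agg$s2[nd]
  pick[s2n != 3L] <- (s1n[s2n != 3L] - 1L) * 2L + s2n[s2n != 3L]
  structure(list(rows = agg, intervals = ints, Xu = Xu,
                 covariates = covariates, term_map = term_map,
                 D = D, bands_cached = bands,
                 nd_rows = which(nd), nd_iv = agg$interval[nd],
                 nd_pick = pick, nd_from = s1n, nd_count = agg$count[nd],
                 dd_rows = which(!nd), dd_iv = agg$interval[!nd],
                 dd_b2 = band_of(bands, agg$t2[!nd]),
                 dd_xk = agg$xkey[!nd], dd_from = agg$s1[!nd],
                 dd_count = agg$count[!nd],
                 n_children = length(unique(id)),
                 n_pairs = length(i1),
                 observed = transition_counts(tab)),
            class = "msm_prepared")
}

# direct state-change counts between consecutive observations (crude, used
# for identifiability screening and initial values)
transition_counts <- function(tab) {
  cnt <- setNames(numeric(4), MSM_TRANSITIONS)
  cnt["q12"] <- sum(tab$s1 == 1 & tab$s2 == 2)
  cnt["q21"] <- sum(tab$s1 == 2 & tab$s2 == 1)
  cnt["q13"] <- sum(tab$s1 == 1 & tab$s2 == 3)
  cnt["q23"] <- sum(tab$s1 == 2 & tab$s2 == 3)
  cnt
}

#' Panel log-likelihood of the three-state model
#'
#' Sums, over consecutive observation pairs, the log interval transition
#' probability for panel records, and for exactly observed deaths the log of
#' `sum_k P[s1, k](t1, t2) q_k3(t2)` over the live states `k` — the state
#' just before a known death time is unknown.  A zero-probability observed
#' transition yields `-Inf` with a diagnostic attribute, not an error.
#'
#' @param data Panel data frame (see [read_panel_csv()]) or an internal
#'   prepared object.
#' @param params An [msm_params()] object.
#' @param covariates Character vector of covariate column names used by
#'   `params$beta` (ignored when `data` is already prepared).
#' @return Log-likelihood (scalar), `-Inf` if any observed transition has
#'   probability zero.
#' @export
panel_loglik <- function(data, params, covariates = character()) {
  prep <- if (inherits(data, "msm_prepared")) data
          else msm_prepare(data, covariates)
  need <- unique(unlist(lapply(params$beta, names)))
  if (length(need) && !all(need %in% colnames(prep$Xu)))
    stop("covariate columns missing from the prepared design: ",
         paste(setdiff(need, colnames(prep$Xu)), collapse = ", "))
  bands <- params$bands
  same_bands <- identical(bands$cuts, prep$bands_cached$cuts)
  ints <- prep$intervals
  ni <- nrow(ints)
  D <- if (same_bands) prep$D else
    vapply(seq_len(bands$n), function(b)
      band_overlap(bands, b, ints$t1, ints$t2), numeric(ni))
  D <- matrix(D, nrow = ni)
  q <- intensity_grid(params, prep$Xu)   # q[[tr]]: nband x nx
  xk <- ints$xkey
  # live-block product across band segments
  p11 <- rep(1, ni); p12 <- rep(0, ni); p21 <- rep(0, ni); p22 <- rep(1, ni)
  for (b in seq_len(bands$n)) {
    d <- D[, b]
    act <- d > 0
    if (!any(act)) next
    E <- expm_live(q$q12[b, xk[act]], q$q13[b, xk[act]],
                   q$q21[b, xk[act]], q$q23[b, xk[act]], d[act])
    n11 <- p11[act] * E$p11 + p12[act] * E$p21
    n12 <- p11[act] * E$p12 + p12[act] * E$p22
    n21 <- p21[act] * E$p11 + p22[act] * E$p21
    n22 <- p21[act] * E$p12 + p22[act] * E$p22
    p11[act] <- n11; p12[act] <- n12; p21[act] <- n21; p22[act] <- n22
  }
  live <- cbind(p11, p12, p21, p22)
  p <- numeric(nrow(prep$rows))
  if (length(prep$nd_rows)) {
    pick <- prep$nd_pick
    iv <- prep$nd_iv
    pl <- numeric(length(pick))
    direct <- pick > 0L
    pl[direct] <- live[cbind(iv[direct], pick[direct])]
    if (any(!direct)) {   # panel-observed death: complement of the live row
      from1 <- prep$nd_from[!direct] == 1L
      pl[!direct] <- 1 - ifelse(from1,
                                p11[iv[!direct]] + p12[iv[!direct]],
                                p21[iv[!direct]] + p22[iv[!direct]])
    }
    p[prep$nd_rows] <- pl
  }
  if (length(prep$dd_rows)) {
    b2 <- if (same_bands) prep$dd_b2 else
      band_of(bands, prep$rows$t2[prep$dd_rows])
    iv <- prep$dd_iv
    q13 <- q$q13[cbind(b2, prep$dd_xk)]
    q23 <- q$q23[cbind(b2, prep$dd_xk)]
    from1 <- prep$dd_from == 1L
    P1 <- numeric(length(iv)); P2 <- numeric(length(iv))
    P1[from1] <- p11[iv[from1]]; P2[from1] <- p12[iv[from1]]
    P1[!from1] <- p21[iv[!from1]]; P2[!from1] <- p22[iv[!from1]]
    p[prep$dd_rows] <- P1 * q13 + P2 * q23
  }
  bad <- p <= 0 | !is.finite(p)
  if (any(bad)) {
    off <- which(bad)[1]
    rows <- prep$rows
    ll <- -Inf
    attr(ll, "diagnostic") <- sprintf(
      "zero-probability transition: state %d at t=%g -> state %d at t=%g",
      rows$s1[off], rows$t1[off], rows$s2[off], rows$t2[off])
    return(ll)
  }
  sum(prep$rows$count * log(p))
}

# ---- parameter vector <-> structured params ---------------------------------

# layout: for each free transition, nband log-q0 entries then its betas
msm_skeleton <- function(model_spec, bands, free_transitions) {
  nm <- character(0)
  for (tr in free_transitions) {
    nm <- c(nm, paste0(tr, ".", bands$labels))
    covs <- model_spec[[tr]]
    if (length(covs)) nm <- c(nm, paste0(tr, ".", covs))
  }
  nm
}

msm_unflatten <- function(par, model_spec, bands, free_transitions) {
  log_q0 <- matrix(-Inf, 4, bands$n,
                   dimnames = list(MSM_TRANSITIONS, bands$labels))
  beta <- setNames(vector("list", 4), MSM_TRANSITIONS)
  i <- 1L
  for (tr in free_transitions) {
    log_q0[tr, ] <- par[i:(i + bands$n - 1L)]
    i <- i + bands$n
    covs <- model_spec[[tr]]
    if (length(covs)) {
      beta[[tr]] <- setNames(par[i:(i + length(covs) - 1L)], covs)
      i <- i + length(covs)
    }
  }
  msm_params(log_q0, beta, bands)
}

# crude occurrence/exposure initial log-intensities per band
crude_init <- function(prep, bands, free_transitions, model_spec) {
  rows <- prep$rows
  expo <- matrix(0, 2, bands$n)   # person-time by from-state x band
  for (b in seq_len(bands$n)) {
    d <- band_overlap(bands, b, rows$t1, rows$t2) * rows$count
    expo[1, b] <- sum(d[rows$s1 == 1])
    expo[2, b] <- sum(d[rows$s1 == 2])
  }
  cnt <- array(0, c(4, bands$n), dimnames = list(MSM_TRANSITIONS, NULL))
  mid <- (rows$t1 + rows$t2) / 2
  bmid <- band_of(bands, mid)
  for (tr in MSM_TRANSITIONS) {
    hit <- rows$s1 == MSM_FROM[tr] & rows$s2 == MSM_TO[tr]
    for (b in seq_len(bands$n))
      cnt[tr, b] <- sum(rows$count[hit & bmid == b])
  }
  par <- numeric(0)
  for (tr in free_transitions) {
    rate <- pmax(cnt[tr, ] / pmax(expo[MSM_FROM[tr], ], 1e-8), 1e-4)
    par <- c(par, log(rate))
    par <- c(par, rep(0, length(model_spec[[tr]])))
  }
  par
}

#' Fit the three-state model to interval-censored panel data
#'
#' Maximises [panel_loglik()] by quasi-Newton (BFGS) with numerical
#' derivatives, starting from crude occurrence/exposure rates (floored at
#' 1e-4/month) and zero covariate effects.  Transitions never directly
#' observed in the data are fixed at intensity zero and excluded from
#' estimation.  The covariance is the inverse of the numerically
#' differentiated observed information; a singular information matrix is
#' reported, never silently inverted.
#'
#' @param data Panel data frame (`child_id, age_months, state, obs_type`,
#'   covariate columns).
#' @param model_spec Named list per transition (`q12, q13, q21, q23`) of
#'   covariate column names; omitted transitions get no covariates.
#' @param bands An [age_bands()] object.
#' @param init Optional named initial parameter vector (flat scale:
#'   log-intensities and betas).
#' @param fixed_zero Character vector of transitions to force to intensity
#'   zero in addition to the never-observed ones.
#' @param control Passed to [stats::optim()] (sensible defaults applied).
#' @return Object of class `msm_fit`: estimates, covariance, log-likelihood,
#'   convergence information and a re-evaluation closure for pooling.
#' @export
fit_msm <- function(data, model_spec = list(), bands = age_bands(),
                    init = NULL, fixed_zero = character(),
                    control = list()) {
  model_spec <- model_spec[intersect(names(model_spec), MSM_TRANSITIONS)]
  for (tr in MSM_TRANSITIONS)
    if (is.null(model_spec[[tr]])) model_spec[[tr]] <- character(0)
  covs <- unique(unlist(model_spec))
  prep <- if (inherits(data, "msm_prepared")) data else msm_prepare(data, covs)
  # raw covariate names -> design-matrix columns (factor dummies expand)
  model_spec <- lapply(model_spec, function(v) {
    unlist(lapply(v, function(nm) {
      if (!is.null(prep$term_map[[nm]])) prep$term_map[[nm]]
      else if (!is.null(prep$Xu) && nm %in% colnames(prep$Xu)) nm
      else stop("unknown covariate '", nm, "'")
    }), use.names = FALSE)
  })
  for (tr in MSM_TRANSITIONS)
    if (is.null(model_spec[[tr]])) model_spec[[tr]] <- character(0)

  obs <- prep$observed
  free <- setdiff(MSM_TRANSITIONS[obs > 0], fixed_zero)
  if (!length(free)) stop("no estimable transitions: nothing observed")
  nm <- msm_skeleton(model_spec, bands, free)
  p0 <- crude_init(prep, bands, free, model_spec)
  names(p0) <- nm
  if (!is.null(init)) {
    if (length(init) != length(p0)) stop("init has wrong length; expected ",
                                         length(p0), " (", paste(nm, collapse = ", "), ")")
    p0[] <- init
  }
  negll <- function(par) {
    ll <- panel_loglik(prep, msm_unflatten(par, model_spec, bands, free))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  if (!is.finite(panel_loglik(prep, msm_unflatten(p0, model_spec, bands, free)))) {
    p0[seq_along(p0)] <- pmax(p0, log(1e-4))  # pull degenerate inits up
    if (negll(p0) >= 1e10)
      stop("log-likelihood not finite at initial values")
  }
  # box constraints: intensities in [1e-6, 5]/month on the log scale (an
  # intensity at the lower bound is effectively zero and unidentified);
  # covariate effects in +/-25
  is_q0 <- grepl("\\.\\(", nm)
  lower <- ifelse(is_q0, log(1e-6), -25)
  upper <- ifelse(is_q0, log(5), 25)
  # forward-difference gradient: half the evaluations of optim's internal
  # central differences, ample accuracy for a likelihood this smooth
  gradll <- function(par) {
    f0 <- negll(par)
    eps <- 1e-7 * pmax(abs(par), 1)
    vapply(seq_along(par), function(j) {
      pj <- par
      pj[j] <- pj[j] + eps[j]
      (negll(pj) - f0) / eps[j]
    }, numeric(1))
  }
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e7), control)
  opt <- stats::optim(pmax(pmin(p0, upper), lower), negll, gr = gradll,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = ctrl)
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll, gr = gradll, method = "L-BFGS-B",
                         lower = lower, upper = upper, control = ctrl)
    if (opt2$value < opt$value) opt <- opt2
  }
  boundary <- opt$par <= lower + 1e-4 | opt$par >= upper - 1e-4
  H <- stats::optimHess(opt$par, negll)
  V <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  ok_idx <- which(!boundary)
  Vsub <- tryCatch(solve(H[ok_idx, ok_idx, drop = FALSE]),
                   error = function(e) NULL)
  cov_ok <- !is.null(Vsub) && all(is.finite(Vsub)) && all(diag(Vsub) > 0)
  if (cov_ok) {
    Vsub <- (Vsub + t(Vsub)) / 2
    V[ok_idx, ok_idx] <- Vsub
  }
  params <- msm_unflatten(opt$par, model_spec, bands, free)
  structure(list(
    params = params,
    estimate = setNames(opt$par, nm),
    covariance = if (cov_ok) V else NULL,
    boundary = setNames(boundary, nm),
    covariance_ok = cov_ok,
    loglik = -opt$value,
    convergence = opt$convergence,
    counts = opt$counts,
    model_spec = model_spec,
    free_transitions = free,
    bands = bands,
    n_children = prep$n_children,
    n_pairs = prep$n_pairs,
    loglik_fun = function(par) {
      panel_loglik(prep, msm_unflatten(par, model_spec, bands, free))
    }),
    class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Three-state panel Markov model fit\n")
  cat(sprintf("  children: %d   observation pairs: %d\n",
              x$n_children, x$n_pairs))
  cat(sprintf("  log-likelihood: %.4f   convergence code: %d\n",
              x$loglik, x$convergence))
  cat("  free transitions:", paste(x$free_transitions, collapse = ", "), "\n")
  se <- if (x$covariance_ok) sqrt(diag(x$covariance)) else rep(NA_real_,
                                                               length(x$estimate))
  print(round(cbind(estimate = x$estimate, se = se), 4))
  invisible(x)
}

#' Hazard ratios with Wald intervals
#'
#' `aHR = exp(beta)` per covariate and transition, 95% CI
#' `exp(beta +/- 1.96 se)`, two-sided Wald p-value.
#'
#' @param fit An `msm_fit`.
#' @return Data frame `transition, term, aHR, lower, upper, p`.
#' @export
hazard_ratios <- function(fit) {
  if (!fit$covariance_ok) stop("covariance unavailable for this fit")
  se <- sqrt(diag(fit$covariance))
  nm <- names(fit$estimate)
  is_beta <- !grepl("\\.\\(", nm)   # band entries carry "(lo,hi]" labels
  out <- data.frame(transition = sub("\\..*$", "", nm[is_beta]),
                    term = sub("^q[0-9]+\\.", "", nm[is_beta]),
                    est = fit$estimate[is_beta],
                    se = se[is_beta])
  out$aHR <- exp(out$est)
  out$lower <- exp(out$est - 1.96 * out$se)
  out$upper <- exp(out$est + 1.96 * out$se)
  out$p <- 2 * stats::pnorm(-abs(out$est / out$se))
  rownames(out) <- NULL
  out[, c("transition", "term", "aHR", "lower", "upper", "p")]
}

#' Transition intensities per 1000 person-months
#'
#' Baseline (covariates at reference / supplied values) intensities with
#' log-scale delta-method 95% intervals:
#' `1000 q exp(+/- 1.96 se(log q))`, guaranteeing positive asymmetric bounds.
#'
#' @param fit An `msm_fit`.
#' @param x Optional named covariate vector at which to evaluate (default:
#'   reference, all zero).
#' @return Data frame `transition, band, per1000pm, lower, upper`.
#' @export
intensity_summary <- function(fit, x = NULL) {
  if (!fit$covariance_ok) stop("covariance unavailable for this fit")
  nm <- names(fit$estimate)
  out <- list()
  for (tr in fit$free_transitions) {
    covs <- fit$model_spec[[tr]]
    for (b in seq_len(fit$bands$n)) {
      lab <- paste0(tr, ".", fit$bands$labels[b])
      cvec <- as.numeric(nm == lab)
      if (length(covs) && !is.null(x)) {
        xv <- x[covs]; xv[is.na(xv)] <- 0
        cvec[match(paste0(tr, ".", covs), nm)] <- xv
      }
      est <- sum(cvec * fit$estimate)
      act <- which(cvec != 0)
      se <- sqrt(drop(t(cvec[act]) %*%
                        fit$covariance[act, act, drop = FALSE] %*%
                        cvec[act]))
      qv <- exp(est)
      degenerate <- qv * 1000 < 1e-8
      out[[length(out) + 1]] <- data.frame(
        transition = tr, band = fit$bands$labels[b],
        per1000pm = 1000 * qv,
        lower = 1000 * qv * exp(-1.96 * se),
        upper = 1000 * qv * exp(1.96 * se),
        degenerate = degenerate)
    }
  }
  do.call(rbind, out)
}

#' Serialize / restore a fitted model as JSON
#'
#' The re-evaluation closure is not serialized; a restored fit supports
#' summaries but not Meng-Rubin re-evaluation.
#'
#' @param fit An `msm_fit`.
#' @param path Output JSON path.
#' @export
write_msm_fit <- function(fit, path) {
  obj <- list(estimate = as.list(fit$estimate),
              covariance = fit$covariance,
              covariance_ok = fit$covariance_ok,
              loglik = fit$loglik,
              convergence = fit$convergence,
              model_spec = fit$model_spec,
              free_transitions = fit$free_transitions,
              band_cuts = fit$bands$cuts,
              n_children = fit$n_children, n_pairs = fit$n_pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_msm_fit
#' @export
read_msm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- age_bands(obj$band_cuts)
  est <- unlist(obj$estimate)
  spec <- lapply(obj$model_spec, function(v) as.character(unlist(v)))
  fit <- list(estimate = est,
              covariance = if (obj$covariance_ok) as.matrix(obj$covariance) else NULL,
              covariance_ok = obj$covariance_ok,
              loglik = obj$loglik, convergence = obj$convergence,
              model_spec = spec,
              free_transitions = obj$free_transitions,
              bands = bands,
              n_children = obj$n_children, n_pairs = obj$n_pairs,
              params = msm_unflatten(est, spec, bands, obj$free_transitions),
              loglik_fun = NULL)
  class(fit) <- "msm_fit"
  fit
}
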