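# Synthetic cohort generator: emulates a four-group pediatric HIV cohort
# (HI, HIL infected; HEU, HUU uninfected) followed to 60 months with
# scheduled visits, malnutrition states observed only at visits, exact death
# times, covariate missingness, and outcome-dependent (MNAR) dropout.

#' Configuration of a synthetic growth cohort
#'
#' Defaults encode the study conditions the generator emulates: group sizes
#' (69, 141, 205, 196) for HI, HIL, HEU, HUU; 3-monthly visits to 24 months
#' then 6-monthly to 60 for infected children, 6-monthly for uninfected;
#' age bands (0,6], (6,12], (12,60]; baseline intensities per month set to
#' the published per-1000-person-month scale for the underweight analysis
#' (healthy->malnourished 37.2/11.6/6.8, healthy->death 9.6/20.1/0.3,
#' malnourished->death 35.3/84.0/6.0); recovery intensities (not published)
#' fixed at 80/60/40 per 1000 pm; group hazard effects on the onset
#' transition; a quadratic mean z trajectory in age (years) with child random
#' intercepts; probit MNAR dropout loading -0.7 on the current z; and 10%
#' covariate missingness (missing at random given group and site).
#'
#' @param group_sizes Named counts for HI, HIL, HEU, HUU.
#' @param true_Q 4 x 3 matrix of baseline intensities per month (rows
#'   `q12, q13, q21, q23`, columns the age bands).
#' @param true_beta Named list per transition of log hazard ratios on
#'   child-level design columns (e.g. `groupHI`).
#' @param bands An [age_bands()] object.
#' @param dropout Dropout model: `type` one of `"MCAR"`, `"MAR"`, `"MNAR"`;
#'   `rate` (MCAR), `intercept`/`z_slope` (MNAR probit on current z),
#'   `intercept`/`group_shift` (MAR probit on group).  `site_effect` shifts
#'   the missingness probit for the LH clinic under MAR and MNAR: clinic
#'   affects attendance but not growth, providing the selection model's
#'   exclusion restriction.
#' @param covariate_missing_rate Average fraction of missing covariate cells.
#' @param growth Trajectory model: intercept, linear and quadratic age terms
#'   (age in years), named group offsets, `sd_child` random intercept SD and
#'   `sd_resid` residual SD.
#' @param seed Integer seed; child-level streams are derived from it so that
#'   subsetting a cohort leaves retained children's data unchanged.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(
    group_sizes = c(HI = 69, HIL = 141, HEU = 205, HUU = 196),
    true_Q = rbind(q12 = c(0.0372, 0.0116, 0.0068),
                   q13 = c(0.0096, 0.0201, 0.0003),
                   q21 = c(0.0800, 0.0600, 0.0400),
                   q23 = c(0.0353, 0.0840, 0.0060)),
    true_beta = list(q12 = c(groupHI = log(3.3), groupHIL = log(4.3),
                             groupHUU = log(0.7))),
    bands = age_bands(),
    dropout = list(type = "MNAR", intercept = -0.5, z_slope = -0.7,
                   rate = 0.2, group_shift = 0.3, site_effect = 0.6),
    covariate_missing_rate = 0.10,
    growth = list(intercept = -0.30, age_lin = 0.84, age_quad = -0.16,
                  group_offsets = c(HI = -0.30, HIL = -0.60, HEU = 0,
                                    HUU = 0.27),
                  sd_child = 0.9, sd_resid = 0.7),
    seed = 1L) {
  stopifnot(all(group_sizes >= 0),
            nrow(true_Q) == 4, ncol(true_Q) == bands$n,
            all(true_Q >= 0),
            dropout$type %in% c("MCAR", "MAR", "MNAR"),
            is.null(dropout$rate) ||
              (dropout$rate >= 0 && dropout$rate <= 1),
            covariate_missing_rate >= 0, covariate_missing_rate <= 1)
  rownames(true_Q) <- MSM_TRANSITIONS
  grids <- list(
    infected = c(seq(3, 24, by = 3), seq(30, 60, by = 6)),
    uninfected = seq(6, 60, by = 6))
  if (any(unlist(lapply(grids, function(g) any(diff(g) <= 0)))))
    stop("visit ages must be strictly increasing")
  structure(list(group_sizes = group_sizes, visit_grid = grids,
                 true_Q = true_Q, true_beta = true_beta, bands = bands,
                 dropout = dropout,
                 covariate_missing_rate = covariate_missing_rate,
                 growth = growth, t_max = 60, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one continuous-time Markov path with piecewise-constant rates
#'
#' Sojourns within a band are exponential with rate `-q_rr`; the next state
#' is chosen with probability `q_rs / -q_rr`; a sojourn crossing a band
#' boundary is re-drawn from the boundary with the new band's rates
#' (memorylessness).  State 3 is absorbing.
#'
#' @param Q_list List of 3x3 generators, one per age band.
#' @param bands An [age_bands()] object.
#' @param t0 Entry time (months).
#' @param t_max Administrative end of follow-up.
#' @param state0 Initial state.
#' @return Data frame `time, state` starting at `(t0, state0)`, one row per
#'   jump, ending at absorption or `t_max`.
#' @export
simulate_ctmc_path <- function(Q_list, bands, t0 = 0, t_max = 60,
                               state0 = 1L) {
  stopifnot(length(Q_list) == bands$n)
  p <- ctmc_path_fast(Q_list, bands, t0, t_max, state0)
  data.frame(time = p$time, state = p$state)
}

# allocation-light core of the path sampler
ctmc_path_fast <- function(Q_list, bands, t0, t_max, state0) {
  t <- t0; s <- state0
  times <- numeric(16); states <- integer(16)
  times[1] <- t0; states[1] <- state0
  k <- 1L
  cuts <- bands$cuts
  nb <- bands$n
  while (t < t_max && s != 3L) {
    b <- findInterval(t + 1e-12, cuts, left.open = TRUE)
    b <- if (b < 1L) 1L else if (b > nb) nb else b
    hi <- if (b == nb) t_max else min(cuts[b + 1L], t_max)
    Q <- Q_list[[b]]
    rate <- -Q[s, s]
    if (rate <= 0) { t <- hi; next }   # no exit in this band
    dt <- stats::rexp(1, rate)
    if (t + dt > hi) { t <- hi; next }
    t <- t + dt
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample.int(3L, 1, prob = probs)
    k <- k + 1L
    if (k > length(times)) {
      times <- c(times, numeric(length(times)))
      states <- c(states, integer(length(states)))
    }
    times[k] <- t; states[k] <- s
  }
  list(time = times[seq_len(k)], state = states[seq_len(k)])
}

# state of a path at given times (right-continuous step function)
path_state_at <- function(path, at) {
  idx <- findInterval(at, path$time)
  out <- rep(NA_integer_, length(at))
  ok <- idx >= 1
  out[ok] <- path$state[idx[ok]]
  out
}

# categorical draw helper
rcat <- function(n, probs, labels) {
  labels[sample.int(length(labels), n, replace = TRUE, prob = probs)]
}

# child-level covariates with marginal frequencies on the scale of the
# motivating cohort's baseline table
simulate_children <- function(groups) {
  n <- length(groups)
  infected <- groups %in% c("HI", "HIL")
  data.frame(
    group = factor(groups, levels = c("HEU", "HI", "HIL", "HUU")),
    sex = factor(rcat(n, c(0.471, 0.529), c("male", "female")),
                 levels = c("male", "female")),
    site = factor(rcat(n, c(0.489, 0.229, 0.282), c("MCH", "LH", "EHC")),
                  levels = c("MCH", "LH", "EHC")),
    sgag = stats::rbinom(n, 1, ifelse(infected, 0.095, 0.052)),
    small_birth = stats::rbinom(n, 1, 0.034),
    hospitalization = stats::rbinom(n, 1, ifelse(infected, 0.45, 0.035)),
    water = stats::rbinom(n, 1, 0.566),
    electricity = stats::rbinom(n, 1, 0.926),
    mother_edu = factor(rcat(n, c(0.231, 0.579, 0.190),
                             c("higher", "secondary", "primary")),
                        levels = c("higher", "secondary", "primary")),
    mother_occupation = factor(rcat(n, c(0.40, 0.15, 0.45),
                                    c("paid", "student", "housewife")),
                               levels = c("paid", "student", "housewife")),
    marital = factor(rcat(n, c(0.650, 0.023, 0.327),
                          c("married", "cohabitation", "single")),
                     levels = c("married", "cohabitation", "single")),
    stringsAsFactors = FALSE)
}

# per-visit time-varying covariates (group-dependent marginals), as plain
# vectors for fast assembly
simulate_visit_covariates <- function(group, nvisit) {
  infected <- group %in% c("HI", "HIL")
  list(
    chronic = stats::rbinom(nvisit, 1, if (infected) 0.06 else 0.005),
    diarrhea = stats::rbinom(nvisit, 1, if (infected) 0.25 else 0.04),
    cd4_low = stats::rbinom(nvisit, 1, if (infected) 0.55 else 0.11),
    general_signs = stats::rbinom(nvisit, 1, if (infected) 0.22 else 0.10),
    anemia = rcat(nvisit,
                  if (infected) c(0.42, 0.22, 0.36) else c(0.13, 0.05, 0.82),
                  c("mild", "modsev", "none")))
}

# per-transition intensity multipliers exp(beta . x) from child covariates
child_multipliers <- function(children, true_beta) {
  X <- stats::model.matrix(~ group + sex + site + sgag + small_birth +
                             hospitalization + water + electricity,
                           children)
  out <- matrix(1, nrow(children), 4,
                dimnames = list(NULL, MSM_TRANSITIONS))
  for (tr in names(true_beta)) {
    b <- true_beta[[tr]]
    if (!length(b)) next
    if (!all(names(b) %in% colnames(X)))
      stop("true_beta names must be design columns; unknown: ",
           paste(setdiff(names(b), colnames(X)), collapse = ", "))
    out[, tr] <- exp(as.numeric(X[, names(b), drop = FALSE] %*% b))
  }
  out
}

child_seed <- function(seed, i) {
  (as.integer(seed) %% 599999L) * 3001L + 7L * i
}

#' Simulate a cohort with known ground truth
#'
#' Two modes. `state_first` samples the three-state path of each child
#' directly from the configured intensities (used for multistate parameter
#' recovery); visit states are read off the path, death times are exact, and
#' malnutrition is observed only at visits (interval censoring).
#' `trajectory_first` samples a continuous z-score trajectory (quadratic in
#' age with child random intercepts) and derives states by thresholding at
#' -2; death hazards follow the configured band intensities given the
#' current state (used for end-to-end pipeline and Heckman validation).
#' Dropout makes scheduled pre-death visits unobserved: MCAR with a constant
#' rate, MAR via a probit on group, or MNAR via a probit on the current
#' (possibly unobserved) z.  In `state_first` mode the MNAR probit uses the
#' state-implied z surrogate (-0.5 healthy, -2.5 malnourished).  Child-level
#' covariate cells are set missing at random given group and site at the
#' configured average rate.
#'
#' @param config A [cohort_config()].
#' @param mode `"state_first"` or `"trajectory_first"`.
#' @return Object of class `sim_cohort`: `children` (covariates, death time,
#'   group), `visits` (scheduled age, observed flag, true and observed
#'   state/z), `paths` (true jump times, `state_first` only), `config`.
#' @export
simulate_cohort <- function(config,
                            mode = c("state_first", "trajectory_first")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(names(config$group_sizes)))
    stop("group_sizes must be a named vector (HI, HIL, HEU, HUU)")
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  if (!n) stop("empty cohort: all group sizes are zero")
  set.seed(config$seed)
  children <- simulate_children(groups)
  children$child_id <- sprintf("C%05d", seq_len(n))
  mult <- child_multipliers(children, config$true_beta)
  grids <- config$visit_grid
  gw <- config$growth

  visit_rows <- vector("list", n)
  path_rows <- vector("list", n)
  death_time <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    set.seed(child_seed(config$seed, i))
    infected <- groups[i] %in% c("HI", "HIL")
    grid <- if (infected) grids$infected else grids$uninfected
    if (mode == "state_first") {
      Q_list <- lapply(seq_len(config$bands$n), function(b) {
        Q <- matrix(0, 3, 3)
        for (tr in MSM_TRANSITIONS)
          Q[MSM_FROM[tr], MSM_TO[tr]] <- config$true_Q[tr, b] * mult[i, tr]
        diag(Q) <- -rowSums(Q)
        Q
      })
      path <- ctmc_path_fast(Q_list, config$bands, 0, config$t_max, 1L)
      path_rows[[i]] <- list(child_id = rep(children$child_id[i],
                                            length(path$time)),
                             time = path$time, state = path$state)
      d3 <- match(3L, path$state)
      if (!is.na(d3)) death_time[i] <- path$time[d3]
      state <- path_state_at(path, grid)
      z_true <- rep(NA_real_, length(grid))
    } else {
      a_yr <- grid / 12
      b_i <- stats::rnorm(1, 0, gw$sd_child)
      mu <- gw$intercept + gw$age_lin * a_yr + gw$age_quad * a_yr^2 +
        gw$group_offsets[[groups[i]]] + b_i
      z_true <- mu + stats::rnorm(length(grid), 0, gw$sd_resid)
      # death hazard from the band intensities given the current smooth state
      death_time[i] <- simulate_death_time(
        function(t) {
          yt <- t / 12
          zt <- gw$intercept + gw$age_lin * yt + gw$age_quad * yt^2 +
            gw$group_offsets[[groups[i]]] + b_i
          b <- band_of(config$bands, pmax(t, 1e-9))
          tri <- ifelse(zt < -2, 4L, 2L)   # q23 else q13 row
          config$true_Q[cbind(tri, b)] * mult[i, tri]
        }, config$t_max)
      state <- classify_state(z_true, alive = TRUE)
    }
    alive <- is.na(death_time[i]) | grid < death_time[i]
    grid_a <- grid[alive]
    state_a <- state[alive]
    z_a <- z_true[alive]
    nv <- length(grid_a)
    # dropout: per-visit probability of being unobserved
    drp <- config$dropout
    site_sh <- if (is.null(drp$site_effect)) 0 else
      drp$site_effect * (children$site[i] == "LH")
    p_miss <- switch(drp$type,
      MCAR = rep(drp$rate, nv),
      MAR = stats::pnorm(drp$intercept + site_sh +
                           drp$group_shift * as.numeric(infected)),
      MNAR = {
        zz <- if (mode == "trajectory_first") z_a
              else ifelse(state_a == 2L, -2.5, -0.5)
        stats::pnorm(drp$intercept + site_sh + drp$z_slope * zz)
      })
    observed <- stats::runif(nv) >= p_miss
    vc <- simulate_visit_covariates(groups[i], nv)
    visit_rows[[i]] <- c(list(
      child_id = rep(children$child_id[i], nv),
      age_months = grid_a,
      observed = observed,
      state_true = state_a,
      state_obs = ifelse(observed, state_a, NA_integer_),
      z_true = z_a,
      z_obs = ifelse(observed, z_a, NA_real_)),
      vc)
  }
  children$death_time <- death_time
  cols <- names(visit_rows[[which(vapply(visit_rows, function(v)
    length(v$child_id), integer(1)) > 0)[1]]])
  visits <- as.data.frame(lapply(setNames(cols, cols), function(cl)
    unlist(lapply(visit_rows, `[[`, cl), use.names = FALSE)))
  visits$anemia <- factor(visits$anemia, levels = c("none", "mild", "modsev"))
  visits <- merge(visits, children, by = "child_id", sort = FALSE)
  visits <- visits[order(visits$child_id, visits$age_months), ]
  rownames(visits) <- NULL
  children <- apply_covariate_missingness(children, config)
  paths <- NULL
  if (mode == "state_first")
    paths <- data.frame(
      child_id = unlist(lapply(path_rows, `[[`, "child_id"),
                        use.names = FALSE),
      time = unlist(lapply(path_rows, `[[`, "time"), use.names = FALSE),
      state = unlist(lapply(path_rows, `[[`, "state"), use.names = FALSE))
  structure(list(children = children, visits = visits, paths = paths,
                 mode = mode, config = config),
            class = "sim_cohort")
}

# piecewise-constant-hazard death time by fine-grid inversion (0.25-month
# steps); NA if no death before t_max
simulate_death_time <- function(hazard_fun, t_max, step = 0.25) {
  tg <- seq(0, t_max, by = step)
  h <- hazard_fun(tg[-length(tg)] + step / 2)
  H <- cumsum(h * step)
  u <- stats::rexp(1)
  if (u > H[length(H)]) return(NA_real_)
  k <- which(H >= u)[1]
  tg[k] + step * (if (k == 1) u / H[1] else (u - H[k - 1]) / (H[k] - H[k - 1])) - step
}

# MAR covariate missingness given group and site, averaging the configured
# cell rate
apply_covariate_missingness <- function(children, config) {
  rate <- config$covariate_missing_rate
  if (rate <= 0) return(children)
  cols <- c("water", "electricity", "mother_edu", "mother_occupation",
            "marital", "sgag", "small_birth")
  base <- stats::qlogis(rate)
  infected <- children$group %in% c("HI", "HIL")
  shift <- 0.35 * infected + 0.2 * (children$site == "LH") - 0.275
  for (cl in cols) {
    p <- stats::plogis(base + shift)
    miss <- stats::runif(nrow(children)) < p
    children[[cl]][miss] <- NA
  }
  children
}

#' Panel dataset from a simulated cohort
#'
#' Observed visit states become panel records; deaths become exact-death
#' records at the true death time.  Child-level covariates are carried on
#' every record.
#'
#' @param cohort A `sim_cohort`.
#' @param use_true_states Use the true state at every scheduled visit
#'   (ignoring dropout); default `FALSE` (observed records only).
#' @return Panel data frame for [fit_msm()].
#' @export
cohort_to_panel <- function(cohort, use_true_states = FALSE) {
  v <- cohort$visits
  st <- if (use_true_states) v$state_true else v$state_obs
  keep <- !is.na(st)
  pan <- data.frame(child_id = v$child_id[keep],
                    age_months = v$age_months[keep],
                    state = st[keep],
                    obs_type = "panel",
                    v[keep, c("group", "sex", "site", "sgag", "small_birth",
                              "hospitalization", "water", "electricity",
                              "chronic", "diarrhea", "cd4_low", "anemia")])
  ch <- cohort$children
  dead <- ch[!is.na(ch$death_time), ]
  if (nrow(dead)) {
    lastcov <- pan[!duplicated(pan$child_id, fromLast = TRUE), ]
    dd <- data.frame(child_id = dead$child_id,
                     age_months = dead$death_time,
                     state = 3L, obs_type = "exact_death")
    dd <- merge(dd, lastcov[, setdiff(names(lastcov),
                                      c("age_months", "state", "obs_type"))],
                by = "child_id", all.x = TRUE)
    dd <- dd[!is.na(dd$group), names(pan)]
    pan <- rbind(pan, dd)
  }
  pan <- pan[order(pan$child_id, pan$age_months), ]
  # a death at or before the last observed visit time would break
  # monotonicity (cannot happen in simulation output, guards real data)
  rownames(pan) <- NULL
  nvis <- table(pan$child_id)
  pan[pan$child_id %in% names(nvis)[nvis >= 2], ]
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic growth cohort (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  children: %d   scheduled visits: %d   observed: %d\n",
              nrow(x$children), nrow(x$visits), sum(x$visits$observed)))
  cat(sprintf("  deaths: %d\n", sum(!is.na(x$children$death_time))))
  print(table(x$children$group))
  invisible(x)
}
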