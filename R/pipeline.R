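# Cohort-level orchestration: covariate recoding, descriptive tables,
# variable selection, and the two analysis arms (multi-state incidence with
# MI pooling; Heckman-corrected growth evolution).

#' Recode raw clinical covariates to analysis categories
#'
#' Applies the cohort's recoding dictionary: marital status collapsed to
#' married / cohabitation / single-divorced-widow; household income split at
#' 100,000 CFA francs; CD4 split at 25% (strictly below); hemoglobin to
#' anemia classes by the 2011 WHO age-dependent cutoffs (severe below
#' 7 g/dl at any age; otherwise not anemic at or above 11 g/dl before 24
#' months and 10 g/dl from 24 months, mild/moderate below that); systemic
#' involvement if any of fever, jaundice, hepatomegaly, adenopathy,
#' parotitis; small-for-gestational-age-and-gender when the
#' gestational-age-and-sex-adjusted birth-weight Z is below -2; small birth
#' size when any birth length Z is below -2.
#'
#' @param raw Data frame; recognised columns (all optional):
#'   `marital_raw`, `income_fcfa`, `cd4_percent`, `hemoglobin`,
#'   `age_months`, `fever`, `jaundice`, `hepatomegaly`, `adenopathy`,
#'   `parotitis`, `birth_weight_z_ga`, `birth_length_z`.
#' @return `raw` with derived columns `marital`, `income`, `cd4_cat`,
#'   `anemia`, `general_signs`, `sgag`, `small_birth` (those whose inputs
#'   are present).
#' @export
recode_covariates <- function(raw) {
  out <- raw
  if ("marital_raw" %in% names(raw)) {
    known <- c("married", "cohabitation", "single", "divorced", "widow")
    bad <- which(!is.na(raw$marital_raw) & !(raw$marital_raw %in% known))
    if (length(bad))
      stop("unknown marital codes in rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    out$marital <- factor(
      ifelse(raw$marital_raw %in% c("single", "divorced", "widow"),
             "single_divorced_widow", raw$marital_raw),
      levels = c("married", "cohabitation", "single_divorced_widow"))
  }
  if ("income_fcfa" %in% names(raw))
    out$income <- factor(ifelse(raw$income_fcfa < 100000, "<100k",
                                ">=100k"),
                         levels = c(">=100k", "<100k"))
  if ("cd4_percent" %in% names(raw))
    out$cd4_cat <- factor(ifelse(raw$cd4_percent < 25, "<25", ">=25"),
                          levels = c(">=25", "<25"))
  if (all(c("hemoglobin", "age_months") %in% names(raw))) {
    hb <- raw$hemoglobin
    none_cut <- ifelse(raw$age_months < 24, 11, 10)
    out$anemia <- factor(
      ifelse(hb < 7, "severe",
             ifelse(hb >= none_cut, "none", "mild_moderate")),
      levels = c("none", "mild_moderate", "severe"))
  }
  signs <- intersect(c("fever", "jaundice", "hepatomegaly", "adenopathy",
                       "parotitis"), names(raw))
  if (length(signs))
    out$general_signs <- as.integer(
      rowSums(raw[signs] == 1, na.rm = TRUE) > 0 &
        rowSums(!is.na(raw[signs])) > 0)
  if ("birth_weight_z_ga" %in% names(raw))
    out$sgag <- as.integer(raw$birth_weight_z_ga < -2)
  if ("birth_length_z" %in% names(raw))
    out$small_birth <- as.integer(raw$birth_length_z < -2)
  out
}

#' Descriptive tables for a child-level cohort summary
#'
#' Per-group counts and percentages, deaths and loss to follow-up, the
#' "experienced malnutrition at least once" flags per index (with per-group
#' chi-square comparisons, Fisher's exact test when any expected cell is
#' below 5), and the same flags restricted to deceased children.
#' Percentages use the non-missing denominator of each flag.
#'
#' @param children Child-level data frame with columns `group`, and any of
#'   `sex`, `status` (`compliant` / `deceased` / `not_compliant`) or logical
#'   `died`, `ever_underweight`, `ever_stunted`, `ever_wasted` (logical,
#'   NA = unknown).
#' @return List of data frames: `groups`, `overall`, `malnutrition`,
#'   `among_deceased`.
#' @export
describe_cohort <- function(children) {
  stopifnot("group" %in% names(children))
  n <- nrow(children)
  grp <- table(children$group)
  groups <- data.frame(group = names(grp), n = as.integer(grp),
                       pct = 100 * as.integer(grp) / n)
  died <- if ("died" %in% names(children)) children$died
          else children$status == "deceased"
  overall <- data.frame(measure = "n_children", value = n, pct = 100)
  add <- function(tab, measure, num, den) {
    rbind(tab, data.frame(measure = measure, value = num,
                          pct = 100 * num / den))
  }
  if (!is.null(died)) overall <- add(overall, "deceased",
                                     sum(died, na.rm = TRUE), n)
  if ("sex" %in% names(children))
    overall <- add(overall, "female",
                   sum(children$sex == "female", na.rm = TRUE), n)
  if ("status" %in% names(children))
    overall <- add(overall, "ltfu",
                   sum(children$status == "not_compliant", na.rm = TRUE), n)
  flags <- c(ever_underweight = "ever_underweight",
             ever_stunted = "ever_stunted", ever_wasted = "ever_wasted")
  flags <- flags[flags %in% names(children)]
  mal <- NULL; mald <- NULL
  for (f in flags) {
    v <- children[[f]]
    ok <- !is.na(v)
    tabgf <- table(children$group[ok], factor(v[ok], c(FALSE, TRUE)))
    p <- tryCatch({
      if (any(suppressWarnings(stats::chisq.test(tabgf))$expected < 5))
        stats::fisher.test(tabgf, simulate.p.value = TRUE, B = 2000)$p.value
      else stats::chisq.test(tabgf)$p.value
    }, error = function(e) NA_real_)
    mal <- rbind(mal, data.frame(
      index = f, n = sum(ok), ever = sum(v[ok]),
      pct = 100 * sum(v[ok]) / sum(ok), group_p = p))
    if (!is.null(died)) {
      okd <- ok & died
      mald <- rbind(mald, data.frame(
        index = f, n_deceased = sum(okd), ever = sum(v[okd]),
        pct = 100 * sum(v[okd]) / sum(okd)))
    }
  }
  list(groups = groups, overall = overall, malnutrition = mal,
       among_deceased = mald)
}

#' Backward variable selection with an entry screen
#'
#' Univariable screen at `entry_p` (strictly below, following the usual
#' epidemiological convention), then backward elimination: at each step the
#' largest-p variable above `retention_p` is a removal candidate; before
#' removal its pairwise interactions with the retained variables are tested
#' and significant ones retained (protecting both main effects).  Emits a
#' full decision trace.
#'
#' @param candidates Character vector of candidate terms.
#' @param fit_engine Function `(terms) -> named p-value vector`, one entry
#'   per term (adjusted for the others); interaction terms are passed as
#'   `"a:b"`.  Engines unable to test a given interaction may return `NA`
#'   for it.
#' @param entry_p Univariable screening threshold (default 0.25).
#' @param retention_p Multivariable retention threshold (default 0.05).
#' @param interactions Test pairwise interactions before each removal.
#' @return List `selected` (final terms), `trace` (decision data frame).
#' @export
select_variables <- function(candidates, fit_engine, entry_p = 0.25,
                             retention_p = 0.05, interactions = TRUE) {
  stopifnot(entry_p > 0, entry_p < 1, retention_p > 0,
            entry_p >= retention_p)
  trace <- data.frame(step = integer(), action = character(),
                      term = character(), p = numeric())
  note <- function(step, action, term, p) {
    trace <<- rbind(trace, data.frame(step = step, action = action,
                                      term = term, p = p))
  }
  step <- 0L
  kept <- character()
  for (v in candidates) {
    step <- step + 1L
    p <- unname(fit_engine(v)[v])
    note(step, if (!is.na(p) && p < entry_p) "screen_keep" else
      "screen_drop", v, p)
    if (!is.na(p) && p < entry_p) kept <- c(kept, v)
  }
  if (!length(kept)) {
    warning("no candidate passed the univariable screen; ",
            "returning the intercept-only specification")
    return(list(selected = character(), trace = trace))
  }
  protected <- character()
  current <- kept
  repeat {
    droppable <- setdiff(current, protected)
    droppable <- droppable[!grepl(":", droppable)]
    if (!length(droppable)) break
    ps <- fit_engine(current)
    pd <- ps[droppable]
    pd <- pd[!is.na(pd)]
    if (!length(pd) || max(pd) < retention_p) break
    v <- names(pd)[which.max(pd)]
    step <- step + 1L
    found_int <- character()
    if (interactions) {
      partners <- setdiff(current[!grepl(":", current)], v)
      for (w in partners) {
        iterm <- paste(v, w, sep = ":")
        pint <- tryCatch(unname(fit_engine(c(current, iterm))[iterm]),
                         error = function(e) NA_real_)
        note(step, "interaction_test", iterm, pint)
        if (!is.na(pint) && pint < retention_p)
          found_int <- c(found_int, iterm)
      }
    }
    if (length(found_int)) {
      current <- c(current, found_int)
      protected <- union(protected,
                         c(v, unlist(strsplit(found_int, ":"))))
      note(step, "keep_with_interaction", v, max(pd))
    } else {
      current <- setdiff(current, v)
      note(step, "remove", v, max(pd))
    }
  }
  list(selected = current, trace = trace)
}

#' Meng-Rubin selection engine over multiply imputed panels
#'
#' Builds a `fit_engine` for [select_variables()] from a list of completed
#' panel datasets: each candidate term's p-value is the Meng-Rubin pooled
#' likelihood ratio comparing the model with all supplied terms on the
#' chosen transition against the model without that term.  Interaction
#' terms (`"a:b"`) are supported through the design-matrix expansion.
#'
#' @param panels List of m completed panel data frames.
#' @param transition Transition carrying the candidate covariates
#'   (default `"q12"`).
#' @param bands Age bands.
#' @return Function `(terms) -> named p-value vector`.
#' @export
mi_msm_engine <- function(panels, transition = "q12", bands = age_bands()) {
  force(panels); force(transition); force(bands)
  function(terms) {
    spec <- setNames(list(terms), transition)
    full <- lapply(panels, fit_msm, model_spec = spec, bands = bands)
    p <- setNames(rep(NA_real_, length(terms)), terms)
    for (v in terms) {
      null_spec <- setNames(list(setdiff(terms, v)), transition)
      nulls <- lapply(panels, fit_msm, model_spec = null_spec,
                      bands = bands)
      k <- length(full[[1]]$estimate) - length(nulls[[1]]$estimate)
      if (k < 1) next
      p[v] <- suppressMessages(
        pool_lrt_meng_rubin(full, nulls, k))$p_value
    }
    p
  }
}

# Rubin-pooled coefficient table across a list of msm fits sharing one spec
pool_msm_fits <- function(fits) {
  nm <- names(fits[[1]]$estimate)
  est <- vapply(fits, function(f) f$estimate[nm], numeric(length(nm)))
  var <- vapply(fits, function(f) {
    if (f$covariance_ok) diag(f$covariance)[nm] else rep(NA_real_,
                                                         length(nm))
  }, numeric(length(nm)))
  est <- matrix(est, nrow = length(nm))
  var <- matrix(var, nrow = length(nm))
  # per-coefficient pooling over the imputations where the coefficient is
  # identified (boundary / unidentified parameters carry NA variance)
  out <- lapply(seq_along(nm), function(j) {
    ok <- is.finite(est[j, ]) & is.finite(var[j, ])
    if (!any(ok))
      return(structure(list(qbar = mean(est[j, ]), W = NA_real_,
                            B = NA_real_, T = NA_real_, df = NA_real_,
                            se = NA_real_, m = 0L),
                       class = "pooled_estimate"))
    if (sum(ok) == 1) suppressWarnings(pool_rubin(est[j, ok], var[j, ok]))
    else pool_rubin(est[j, ok], var[j, ok])
  })
  names(out) <- nm
  out
}

#' Multi-state incidence analysis across multiple imputations
#'
#' Classifies (or takes) panel states for the chosen index, imputes missing
#' child-level covariates by chained equations, fits the three-state model
#' on each completed dataset, pools coefficients by Rubin's rules, and
#' reports hazard-ratio and per-1000-person-month intensity tables.  An
#' optional Meng-Rubin pooled likelihood-ratio test compares the fitted
#' model against the model without `test_term`.
#'
#' @param cohort A `sim_cohort` (or any list with `children` and `visits`
#'   shaped like one).
#' @param model_spec Covariates per transition as in [fit_msm()].
#' @param m Imputations (default 10).
#' @param iterations Chained-equation sweeps (default 10).
#' @param bands Age bands.
#' @param seed Integer seed.
#' @param test_term Optional raw covariate name for a pooled LRT (dropped
#'   from every transition in the null model).
#' @return List of class `msm_report`: `pooled` (coefficient table),
#'   `hazard_ratios`, `intensities`, `lrt` (or NULL), `fits`.
#' @export
run_retardation_analysis <- function(cohort, model_spec = list(q12 = "group"),
                                     m = 10, iterations = 10,
                                     bands = age_bands(), seed = 1L,
                                     test_term = NULL) {
  children <- cohort$children
  impvars <- setdiff(names(children), c("child_id", "death_time"))
  iset <- mice_impute(children, variables = impvars, m = m,
                      iterations = iterations, seed = seed)
  covnames <- unique(unlist(model_spec))
  fits <- vector("list", m)
  fits_null <- if (!is.null(test_term)) vector("list", m) else NULL
  for (k in seq_len(m)) {
    ch_k <- iset$completed[[k]]
    coh_k <- cohort
    keep <- setdiff(names(cohort$visits), setdiff(names(ch_k), "child_id"))
    coh_k$visits <- merge(cohort$visits[keep], ch_k, by = "child_id",
                          sort = FALSE)
    coh_k$children <- ch_k
    coh_k$children$death_time <- children$death_time
    pan <- cohort_to_panel(coh_k)
    fits[[k]] <- fit_msm(pan, model_spec, bands = bands)
    if (!is.null(test_term)) {
      null_spec <- lapply(model_spec, function(v) setdiff(v, test_term))
      fits_null[[k]] <- fit_msm(pan, null_spec, bands = bands)
    }
  }
  pooled <- pool_msm_fits(fits)
  ptab <- data.frame(
    term = names(pooled),
    estimate = vapply(pooled, function(p) p$qbar, numeric(1)),
    se = vapply(pooled, function(p) p$se, numeric(1)),
    df = vapply(pooled, function(p) p$df, numeric(1)))
  tq <- stats::qt(0.975, pmax(ptab$df, 1))
  ptab$lower <- ptab$estimate - tq * ptab$se
  ptab$upper <- ptab$estimate + tq * ptab$se
  ptab$p <- 2 * stats::pt(-abs(ptab$estimate / ptab$se), pmax(ptab$df, 1))
  rownames(ptab) <- NULL
  is_beta <- !grepl("\\.\\(", ptab$term)
  hr <- ptab[is_beta, ]
  hr$aHR <- exp(hr$estimate)
  hr$aHR_lower <- exp(hr$lower)
  hr$aHR_upper <- exp(hr$upper)
  intens <- ptab[!is_beta, ]
  intens$per1000pm <- 1000 * exp(intens$estimate)
  intens$per1000pm_lower <- 1000 * exp(intens$estimate - 1.96 * intens$se)
  intens$per1000pm_upper <- 1000 * exp(intens$estimate + 1.96 * intens$se)
  lrt <- NULL
  if (!is.null(test_term)) {
    k_con <- length(fits[[1]]$estimate) - length(fits_null[[1]]$estimate)
    lrt <- pool_lrt_meng_rubin(fits, fits_null, k = k_con)
  }
  structure(list(pooled = ptab, hazard_ratios = hr, intensities = intens,
                 lrt = lrt, fits = fits, m = m, seed = seed),
            class = "msm_report")
}

#' Growth-evolution analysis with and without the Heckman correction
#'
#' Builds the per-scheduled-visit observation indicator and the observed
#' z-score for the chosen index from a cohort's visit table, then runs the
#' two-stage Heckman GEE with age entering the outcome model as
#' age + age^2 (age in years).
#'
#' @param cohort A `sim_cohort` (`visits` must carry `observed` and
#'   `z_obs`).
#' @param stage1_covariates,stage2_covariates Character vectors of raw
#'   covariate names (stage 2 gets `age_years + I(age_years^2)` prepended).
#' @param bootstrap_reps Cluster-bootstrap replicates for the corrected
#'   model (0 to skip).
#' @param seed Integer seed.
#' @return List of class `growth_report`: `fit` (a `heckman_fit`), `table`
#'   (naive-vs-corrected comparison), `data` (analysis table).
#' @export
run_growth_evolution <- function(cohort,
                                 stage1_covariates = c("group", "site",
                                                       "age_years"),
                                 stage2_covariates = c("group"),
                                 bootstrap_reps = 500, seed = 1L) {
  v <- cohort$visits
  v$age_years <- v$age_months / 12
  v$z <- v$z_obs
  v$obs01 <- as.integer(v$observed)
  f1 <- stats::reformulate(stage1_covariates, response = "obs01")
  f2 <- stats::reformulate(c("age_years", "I(age_years^2)",
                             stage2_covariates), response = "z")
  fit <- heckman_two_stage(
    v,
    stage1 = gee_spec(f1, id = "child_id", link = "probit",
                      corstr = "exchangeable"),
    stage2 = gee_spec(f2, id = "child_id", link = "identity",
                      corstr = "exchangeable"),
    bootstrap_reps = bootstrap_reps, seed = seed)
  structure(list(fit = fit, table = heckman_table(fit), data = v),
            class = "growth_report")
}

#' Child-level summary flags from a cohort's visits
#'
#' Collapses a visit table to one row per child with ever-malnourished
#' flags (from observed states or z-scores), vital status, and loss to
#' follow-up (no observed visit for over 12 months before the end of
#' follow-up).
#'
#' @param cohort A `sim_cohort`.
#' @return Child-level data frame suitable for [describe_cohort()].
#' @export
summarize_children <- function(cohort) {
  v <- cohort$visits
  ch <- cohort$children
  agg <- do.call(rbind, lapply(split(v, v$child_id), function(d) {
    obs <- d[d$observed, , drop = FALSE]
    gaps <- diff(c(obs$age_months, 60))
    data.frame(child_id = d$child_id[1],
               ever_mal = if (nrow(obs)) any(obs$state_obs == 2L) else NA,
               ltfu = if (nrow(obs)) max(gaps) > 12 else TRUE)
  }))
  out <- merge(ch, agg, by = "child_id", sort = FALSE)
  out$died <- !is.na(out$death_time)
  out$status <- ifelse(out$died, "deceased",
                       ifelse(out$ltfu, "not_compliant", "compliant"))
  out$ever_underweight <- out$ever_mal
  out
}
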