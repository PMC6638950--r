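#' LMS Z-score
#'
#' Box-Cox (LMS) Z-score of a measurement against reference parameters
#' `L` (power), `M` (median) and `S` (coefficient of variation), as used by
#' the WHO 2006 child growth standards:
#' \deqn{z = \frac{(y/M)^L - 1}{L S}}
#' with the continuous limit \eqn{z = \log(y/M)/S} as \eqn{L \to 0}.
#'
#' @param y Measurement (kg or cm), positive. Vectorised.
#' @param L Box-Cox power (dimensionless).
#' @param M Reference median, positive, same units as `y`.
#' @param S Reference coefficient of variation, positive.
#' @return Numeric vector of Z-scores.
#' @examples
#' lms_zscore(11, L = 1e-12, M = 10, S = 0.1)  # ~ log(1.1)/0.1
#' @export
lms_zscore <- function(y, L, M, S) {
  n <- max(length(y), length(L), length(M), length(S))
  y <- rep_len(y, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  bad <- !is.na(y) & (y <= 0 | M <= 0 | S <= 0)
  if (any(bad))
    stop("invalid measurement or reference: y, M and S must be positive")
  # |L| <= 1e-8 switches to the log branch; the two agree to O(L) there
  z <- ifelse(abs(L) > 1e-8,
              (exp(L * log(y / M)) - 1) / (L * S),
              log(y / M) / S)
  z
}

#' Inverse LMS transform
#'
#' Measurement value at a given Z-score for reference parameters (L, M, S).
#' Used to build reference bounds and test fixtures.
#'
#' @param z Z-score.
#' @inheritParams lms_zscore
#' @return Measurement value.
#' @export
inverse_lms <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) > 1e-8, M * (1 + L * S * z)^(1 / L), M * exp(S * z))
}

#' Restricted (WHO-adjusted) Z-score tails
#'
#' For the weight-based indices (WAZ, WLZ) the WHO convention linearises the
#' Z-scale beyond +/-3 SD using the reference +/-2 and +/-3 SD bounds, so that
#' extreme weights map to finite, interpretable scores:
#' above +3, `3 + (y - sd3pos)/(sd3pos - sd2pos)`; below -3,
#' `-3 + (y - sd3neg)/(sd2neg - sd3neg)`.  Length-for-age is returned
#' unchanged.
#'
#' @param z Z-score from [lms_zscore()].
#' @param y The raw measurement.
#' @param row A list or one-row data frame with `sd2pos`, `sd3pos`,
#'   `sd2neg`, `sd3neg` reference bounds.
#' @param index One of `"WAZ"`, `"LAZ"`, `"WLZ"`.
#' @return Adjusted Z-score.
#' @export
restricted_zscore <- function(z, y, row, index) {
  index <- match.arg(toupper(index), c("WAZ", "LAZ", "WLZ"))
  if (index == "LAZ") return(z)
  n <- length(z)
  sd3pos <- rep_len(row$sd3pos, n); sd2pos <- rep_len(row$sd2pos, n)
  sd3neg <- rep_len(row$sd3neg, n); sd2neg <- rep_len(row$sd2neg, n)
  dpos <- sd3pos - sd2pos
  dneg <- sd2neg - sd3neg
  if (any(!is.na(dpos) & dpos <= 0) || any(!is.na(dneg) & dneg <= 0))
    stop("degenerate reference bounds: sd3 and sd2 limits coincide")
  out <- z
  hi <- !is.na(z) & z > 3
  lo <- !is.na(z) & z < -3
  out[hi] <- 3 + (y[hi] - sd3pos[hi]) / dpos[hi]
  out[lo] <- -3 + (y[lo] - sd3neg[lo]) / dneg[lo]
  out
}

#' Classify a visit into the three-state space
#'
#' Maps a Z-score for the chosen index into the panel state space:
#' 1 = healthy, 2 = malnourished, 3 = dead.  Malnutrition is a strict
#' `z < -2`; a score of exactly -2 is healthy.  Death dominates regardless of
#' any Z value.  An alive visit with no Z value for the index gets `NA`:
#' such records are missing outcomes (they enter the selection model, not the
#' panel likelihood).
#'
#' @param z Numeric vector of Z-scores for the chosen index (may contain NA).
#' @param alive Logical vector, `FALSE` for death records.
#' @return Integer vector of states in `{1, 2, 3}` with `NA` for missing
#'   alive outcomes.
#' @export
classify_state <- function(z, alive) {
  n <- max(length(z), length(alive))
  z <- rep_len(z, n); alive <- rep_len(alive, n)
  state <- ifelse(!alive, 3L, ifelse(is.na(z), NA_integer_,
                                     ifelse(z < -2, 2L, 1L)))
  as.integer(state)
}

# ---- reference tables --------------------------------------------------------

#' Synthetic LMS reference table
#'
#' A smooth, internally consistent stand-in for the WHO-2006 LMS reference,
#' with the same schema as a WHO CSV export
#' (`index,sex,key,L,M,S,sd3neg,sd2neg,sd2pos,sd3pos`), so that examples and
#' tests run self-contained.  The L, M and S curves are smooth functions of
#' age (WAZ, LAZ; key = completed months 0..60) or recumbent length
#' (WLZ; key = cm on a 1 mm grid) chosen to be anthropometrically plausible;
#' they are synthetic and must not be used for clinical scoring.  The
#' +/-2 and +/-3 SD bounds are derived from (L, M, S) by [inverse_lms()], so
#' the table satisfies the self-consistency invariant by construction.
#'
#' @param wlz_step Grid step (cm) for the WLZ length key; default 0.1.
#' @return Data frame with the schema above, both sexes, all three indices.
#' @export
synthetic_lms_table <- function(wlz_step = 0.1) {
  age <- 0:60
  rows <- list()
  for (sex in c("male", "female")) {
    fem <- sex == "female"
    # weight-for-age: newborn ~3.3 kg rising to ~18-19 kg at 60 months
    M <- (3.35 - 0.12 * fem) + 9.2 * (1 - exp(-age / 13)) + 0.115 * age
    L <- 0.15 + 0.2 * exp(-age / 20)
    S <- 0.125 + 0.015 * exp(-age / 30) - 0.005 * fem
    rows[[length(rows) + 1]] <-
      data.frame(index = "WAZ", sex = sex, key = age, L = L, M = M, S = S)
    # length-for-age: ~49.9 cm at birth to ~110 cm at 60 months; L = 1
    M <- (49.9 - 0.7 * fem) + 42 * (1 - exp(-age / 17)) + 0.22 * age
    L <- rep(1, length(age))
    S <- 0.035 + 0.0001 * age
    rows[[length(rows) + 1]] <-
      data.frame(index = "LAZ", sex = sex, key = age, L = L, M = M, S = S)
    # weight-for-length on a length grid (cm)
    len <- seq(45, 110, by = wlz_step)
    M <- (2.4 - 0.05 * fem) + 0.13 * (len - 45) + 0.00185 * (len - 45)^2
    L <- rep(-0.35, length(len))
    S <- 0.085 + 0.0002 * (len - 45) - 0.003 * fem
    rows[[length(rows) + 1]] <-
      data.frame(index = "WLZ", sex = sex, key = round(len, 1),
                 L = L, M = M, S = S)
  }
  tab <- do.call(rbind, rows)
  tab$sd3neg <- inverse_lms(-3, tab$L, tab$M, tab$S)
  tab$sd2neg <- inverse_lms(-2, tab$L, tab$M, tab$S)
  tab$sd2pos <- inverse_lms(2, tab$L, tab$M, tab$S)
  tab$sd3pos <- inverse_lms(3, tab$L, tab$M, tab$S)
  rownames(tab) <- NULL
  tab
}

#' Read an LMS reference table from CSV
#'
#' Accepts the schema `index,sex,key,L,M,S,sd3neg,sd2neg,sd2pos,sd3pos`
#' (a WHO CSV export reshaped to long form, or [synthetic_lms_table()]
#' written out).  Validates positivity, bound ordering, and the
#' self-consistency of the bounds with (L, M, S) to relative tolerance 1e-6.
#'
#' @param path CSV file path.
#' @return Validated LMS table data frame.
#' @export
read_lms_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lms_table(tab)
}

#' @rdname read_lms_table
#' @param tab An LMS table data frame to validate in place.
#' @export
validate_lms_table <- function(tab) {
  need <- c("index", "sex", "key", "L", "M", "S",
            "sd3neg", "sd2neg", "sd2pos", "sd3pos")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("LMS table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$S <= 0) || any(tab$M <= 0))
    stop("LMS table: M and S must be positive")
  ord <- with(tab, sd3neg < sd2neg & sd2neg < M & M < sd2pos & sd2pos < sd3pos)
  if (any(!ord))
    stop("LMS table: bounds must satisfy sd3neg < sd2neg < M < sd2pos < sd3pos")
  for (zb in c(-3, -2, 2, 3)) {
    col <- c(`-3` = "sd3neg", `-2` = "sd2neg", `2` = "sd2pos",
             `3` = "sd3pos")[as.character(zb)]
    ref <- inverse_lms(zb, tab$L, tab$M, tab$S)
    if (any(abs(tab[[col]] - ref) / ref > 1e-6))
      stop("LMS table: ", col, " inconsistent with (L, M, S)")
  }
  tab$index <- toupper(tab$index)
  tab
}

# nearest-row lookup within one index/sex block; WAZ/LAZ key by completed
# months (floor), WLZ key by length rounded to the table's mm grid
lms_lookup <- function(tab, index, sex, key) {
  block <- tab[tab$index == index & tab$sex == sex, , drop = FALSE]
  if (!nrow(block)) return(rep(NA_integer_, length(key)))
  wanted <- if (index == "WLZ") round(key, 1) else floor(key)
  idx <- match(round(wanted, 6), round(block$key, 6))
  out <- rep(NA_integer_, length(key))
  ok <- !is.na(idx)
  out[ok] <- as.integer(rownames(block))[idx[ok]]
  out
}

#' Compute WAZ, LAZ and WLZ for a measurement table
#'
#' Per-record reference lookup (completed months for the age-keyed indices,
#' nearest 1 mm for weight-for-length), LMS Z-score, restricted-tail
#' adjustment, and implausibility flags.  Missing measurements and keys
#' outside the reference range yield `NA` scores with a warning, never a
#' failure.
#'
#' @param measures Data frame with columns `child_id`, `age_months`, `sex`
#'   (`"male"`/`"female"`), `weight_kg`, `length_cm`, `alive` (logical).
#' @param table Validated LMS table (see [read_lms_table()]).
#' @param restrict Apply the WHO restricted-tail adjustment to the
#'   weight-based indices (default `TRUE`).
#' @param flag_limit Absolute Z beyond which a score is flagged implausible
#'   (default 6); flagged scores are retained.
#' @return `measures` with added columns `waz`, `laz`, `wlz` and logical
#'   `implausible`.
#' @export
compute_zscores <- function(measures, table, restrict = TRUE, flag_limit = 6) {
  stopifnot(all(c("child_id", "age_months", "sex", "alive") %in%
                  names(measures)))
  rownames(table) <- seq_len(nrow(table))
  n <- nrow(measures)
  out <- measures
  out$waz <- out$laz <- out$wlz <- rep(NA_real_, n)
  if (!n) {
    out$implausible <- logical(0)
    return(out)
  }
  w <- if ("weight_kg" %in% names(measures)) measures$weight_kg else rep(NA_real_, n)
  l <- if ("length_cm" %in% names(measures)) measures$length_cm else rep(NA_real_, n)
  spec <- list(WAZ = list(y = w, key = measures$age_months),
               LAZ = list(y = l, key = measures$age_months),
               WLZ = list(y = w, key = l))
  dropped <- 0L
  for (index in names(spec)) {
    y <- spec[[index]]$y
    key <- spec[[index]]$key
    col <- tolower(index)
    for (sex in c("male", "female")) {
      sel <- which(measures$sex == sex & measures$alive &
                     !is.na(y) & !is.na(key))
      if (!length(sel)) next
      rows <- lms_lookup(table, index, sex, key[sel])
      ok <- !is.na(rows)
      dropped <- dropped + sum(!ok)
      if (!any(ok)) next
      sub <- table[rows[ok], ]
      z <- lms_zscore(y[sel][ok], sub$L, sub$M, sub$S)
      if (restrict)
        z <- restricted_zscore(z, y[sel][ok], sub, index)
      out[[col]][sel[ok]] <- z
    }
  }
  if (dropped > 0)
    warning(dropped, " measurement(s) outside the reference key range; ",
            "scores set to NA")
  zmat <- cbind(out$waz, out$laz, out$wlz)
  out$implausible <- apply(abs(zmat) > flag_limit, 1, any, na.rm = TRUE)
  out
}
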