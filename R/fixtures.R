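# Synthetic child-level reconstruction of the marginal counts of the
# motivating four-group pediatric HIV cohort (611 children, Cameroon,
# 2007-2015).  Only the margins are faithful: group sizes, sex, vital
# status, follow-up status, and the ever-malnourished counts per index
# overall, per group and among deceased children.  The joint arrangement of
# flags within the margins is synthetic.

#' Synthetic child-level table reproducing published cohort margins
#'
#' One row per child (n = 611) with `group` (HI 69, HIL 141, HEU 205,
#' HUU 196), `sex` (323 female), `status` (317 compliant, 66 deceased,
#' 228 not compliant), `died`, and ever-malnourished flags:
#' `ever_underweight` (168 of 607 non-missing; 32 of the 62 deceased with
#' the flag observed), `ever_stunted` (369 of 605; 38 of 60 deceased),
#' `ever_wasted` (256 of 605; 16 of 60 deceased).  Feeding this table to
#' [describe_cohort()] reproduces the published descriptive percentages
#' (11.3% HI, 10.8% deceased, 52.9% female, 27.7% / 61.0% / 42.3% ever
#' underweight / stunted / wasted, 51.6% / 63.3% / 26.7% among deceased).
#'
#' @return Child-level data frame for [describe_cohort()].
#' @export
cohort_margins_fixture <- function() {
  grp <- c(HI = 69L, HIL = 141L, HEU = 205L, HUU = 196L)
  female <- c(HI = 42L, HIL = 75L, HEU = 108L, HUU = 98L)
  deceased <- c(HI = 13L, HIL = 44L, HEU = 6L, HUU = 3L)
  not_compliant <- c(HI = 21L, HIL = 22L, HEU = 99L, HUU = 86L)
  # per-index: yes counts per group; missing flags (all assigned to HIL
  # deaths, a synthetic choice); yes counts among deceased per group
  idx <- list(
    ever_underweight = list(yes = c(HI = 24L, HIL = 88L, HEU = 41L,
                                    HUU = 15L),
                            na_hil_dead = 4L,
                            dead_yes = c(HI = 6L, HIL = 24L, HEU = 1L,
                                         HUU = 1L)),
    ever_stunted = list(yes = c(HI = 47L, HIL = 115L, HEU = 124L,
                                HUU = 83L),
                        na_hil_dead = 6L,
                        dead_yes = c(HI = 8L, HIL = 27L, HEU = 2L,
                                     HUU = 1L)),
    ever_wasted = list(yes = c(HI = 32L, HIL = 68L, HEU = 91L, HUU = 65L),
                       na_hil_dead = 6L,
                       dead_yes = c(HI = 3L, HIL = 11L, HEU = 1L,
                                    HUU = 1L)))
  rows <- lapply(names(grp), function(g) {
    n <- grp[[g]]
    d <- data.frame(
      child_id = sprintf("%s%04d", g, seq_len(n)),
      group = factor(g, levels = names(grp)),
      sex = rep(c("female", "male"),
                c(female[[g]], n - female[[g]])),
      died = rep(c(TRUE, FALSE), c(deceased[[g]], n - deceased[[g]])))
    d$status <- "compliant"
    d$status[d$died] <- "deceased"
    alive_idx <- which(!d$died)
    d$status[alive_idx[seq_len(not_compliant[[g]])]] <- "not_compliant"
    for (f in names(idx)) {
      yes <- idx[[f]]$yes[[g]]
      dyes <- idx[[f]]$dead_yes[[g]]
      nna <- if (g == "HIL") idx[[f]]$na_hil_dead else 0L
      v <- rep(FALSE, n)
      dead_idx <- which(d$died)
      live_idx <- which(!d$died)
      v[dead_idx[seq_len(dyes)]] <- TRUE                  # deceased, ever
      v[live_idx[seq_len(yes - dyes)]] <- TRUE            # alive, ever
      if (nna > 0) v[rev(dead_idx)[seq_len(nna)]] <- NA   # unobserved
      d[[f]] <- v
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
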