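# Questionnaire-derived outcome variables and the dyad-level analysis table.

#' Liking composite
#'
#' Arithmetic mean of the three liking items (each on the 0-8 scale).
#'
#' @param items numeric vector (or matrix with 3 columns) of item scores.
#' @return Composite score(s).
#' @export
composite_liking <- function(items) {
  m <- if (is.matrix(items) || is.data.frame(items)) as.matrix(items) else
    matrix(items, nrow = 1)
  if (ncol(m) != 3) stop_input("liking composite expects 3 items")
  if (any(m < 0 | m > 8, na.rm = TRUE))
    stop_input("liking items must be on the 0-8 scale")
  out <- rowMeans(m)
  if (length(out) == 1) out[[1]] else out
}

#' Cronbach's alpha
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 -
#'   \frac{\sum_i s_i^2}{s_{total}^2}\right)}
#' with sample variances (denominator n - 1). An optional 95% confidence
#' interval uses the classical F-distribution method.
#'
#' @param item_matrix n x k numeric matrix (respondents x items).
#' @param ci logical; also return the 95% CI.
#' @return List with \code{alpha}, optionally \code{ci}; \code{alpha} is NA
#'   with a warning when the total-score variance is zero.
#' @export
cronbach_alpha <- function(item_matrix, ci = FALSE) {
  m <- as.matrix(item_matrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_input("need >= 2 respondents and >= 2 items")
  vt <- var(rowSums(m))
  if (vt < 1e-14) {
    warning("total-score variance is zero; alpha undefined")
    return(list(alpha = NA_real_))
  }
  a <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
  out <- list(alpha = a)
  if (ci) {
    # Feldt's F-based interval
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- stats::qf(0.975, df1, df2); fu <- stats::qf(0.025, df1, df2)
    out$ci <- c(lower = 1 - (1 - a) * fl, upper = 1 - (1 - a) * fu)
  }
  out
}

#' Money-sharing ratio
#'
#' Money offered to the other participant relative to money spent on a
#' friend, capped at 1. A friend amount of 0 gives 0 when nothing is offered
#' and the cap (1) otherwise.
#'
#' @param other_eur,friend_eur amounts in [0, 30].
#' @return Proportion in [0, 1].
#' @export
money_ratio <- function(other_eur, friend_eur) {
  if (any(other_eur < 0 | friend_eur < 0)) stop_input("amounts must be >= 0")
  if (any(other_eur > 30 | friend_eur > 30)) stop_input("amounts must be <= 30")
  out <- ifelse(friend_eur == 0, ifelse(other_eur == 0, 0, 1),
                pmin(other_eur / friend_eur, 1))
  out
}

#' Helping ratio
#'
#' Willingness to help the other participant relative to general helping
#' willingness (both on the 1-4 scale), capped at 1.
#'
#' @param help_other,help_general integers in 1-4.
#' @return Proportion in [0, 1].
#' @export
helping_ratio <- function(help_other, help_general) {
  if (any(help_other < 1 | help_other > 4 | help_general < 1 | help_general > 4))
    stop_input("helping items must be on the 1-4 scale")
  pmin(help_other / help_general, 1)
}

#' Grand-mean centering
#'
#' @param values numeric vector.
#' @return Values minus their mean (mean of the output is 0).
#' @export
grand_mean_center <- function(values) {
  if (length(values) == 0) stop_input("empty input")
  values - mean(values, na.rm = TRUE)
}

#' Score a per-participant outcome table
#'
#' Computes the Liking composites at both time points, the prosociality
#' ratios and keeps IOS, per participant.
#'
#' @param outcomes per-participant table as produced by
#'   \code{\link{generate_cohort}} (columns liking1_1..3, liking2_1..3, ios,
#'   money_other_eur, money_friend_eur, help_other, help_general).
#' @return The table with added liking1, liking2, money_ratio, help_ratio.
#' @export
score_outcomes <- function(outcomes) {
  outcomes$liking1 <- composite_liking(outcomes[, c("liking1_1", "liking1_2", "liking1_3")])
  outcomes$liking2 <- composite_liking(outcomes[, c("liking2_1", "liking2_2", "liking2_3")])
  outcomes$money_ratio <- money_ratio(outcomes$money_other_eur,
                                      outcomes$money_friend_eur)
  outcomes$help_ratio <- helping_ratio(outcomes$help_other,
                                       outcomes$help_general)
  outcomes
}

#' Build the dyad-level analysis dataset
#'
#' One row per dyad: synchrony averaged across the two intervals per ROI
#' pair and phase (columns \code{syn_<pair>_<phase>}), social outcomes
#' (Liking 2 composite, IOS, prosociality ratios) summed across both dyad
#' members, the Liking 1 composite sum as baseline, and the relative
#' laughter durations (lbmp, lbfi). Dyads with a missing member are dropped
#' with a reason recorded in the \code{"dropped"} attribute.
#'
#' @param outcomes scored per-participant table (see
#'   \code{\link{score_outcomes}}).
#' @param synchrony long synchrony table from \code{\link{dyad_synchrony}}.
#' @param behavior per-dyad behavior table from \code{\link{dyad_behavior}}.
#' @param ground_truth optional per-dyad table whose condition labels are
#'   joined in.
#' @return Data frame, one row per dyad.
#' @export
build_dyad_dataset <- function(outcomes, synchrony, behavior,
                               ground_truth = NULL) {
  if (!"liking2" %in% names(outcomes)) outcomes <- score_outcomes(outcomes)
  dyads <- unique(outcomes$dyad_id)
  dropped <- character(0)
  rows <- list()
  for (d in dyads) {
    sub <- outcomes[outcomes$dyad_id == d, ]
    if (nrow(sub) != 2) {
      dropped <- c(dropped, sprintf("%s: %d member(s)", d, nrow(sub)))
      next
    }
    row <- list(dyad_id = d,
                liking1_sum = sum(sub$liking1),
                liking2_sum = sum(sub$liking2),
                ios_sum = sum(sub$ios),
                money_ratio_sum = sum(sub$money_ratio),
                help_ratio_sum = sum(sub$help_ratio))
    syn <- synchrony[synchrony$dyad_id == d, ]
    for (pp in unique(synchrony$roi_pair)) {
      for (ph in unique(synchrony$phase)) {
        v <- syn$wtc_value[syn$roi_pair == pp & syn$phase == ph]
        row[[paste0("syn_", pp, "_", ph)]] <-
          if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }
    }
    b <- behavior[behavior$dyad_id == d, ]
    if (nrow(b) == 1) {
      for (cn in setdiff(names(b), "dyad_id")) row[[cn]] <- b[[cn]]
    }
    if (!is.null(ground_truth)) {
      g <- ground_truth[ground_truth$dyad_id == d, ]
      if (nrow(g) == 1)
        for (cn in intersect(c("cell", "laughter", "social", "kappa"), names(g)))
          row[[cn]] <- g[[cn]]
    }
    rows[[length(rows) + 1]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}
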