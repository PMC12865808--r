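# Synthetic questionnaire outcomes with known structural paths.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate outcome variables from a linear structural model
#'
#' Implements the two-equation structure used downstream by the mediation
#' module: \code{mediator* = a * treatment + e1} (unless a mediator vector is
#' supplied, in which case it is passed through) and
#' \code{outcome_raw = c' * treatment + b * mediator + e2}, with independent
#' Gaussian noise per outcome variable. The raw linear outcomes are returned
#' alongside instrument-scaled versions: a Liking-like composite on 0-8, a
#' bonding (IOS-like) score on 1-7, and two prosociality ratios on [0, 1],
#' each produced by shifting the raw outcome to the instrument's midpoint and
#' clipping to its range.
#'
#' @param sp a \code{\link{structural_params}}.
#' @param treatment numeric vector (one value per dyad).
#' @param mediator optional numeric vector; if \code{NULL} it is generated
#'   from the a-path.
#' @param seed integer seed.
#' @param scales named list of instrument anchors; see defaults.
#' @return Data frame with mediator, *_raw linear outcomes and scaled
#'   liking, bonding, money_ratio, help_ratio columns.
#' @export
generate_outcomes <- function(sp, treatment, mediator = NULL, seed = 1L,
                              scales = list(liking_base = 5.5, bonding_base = 3,
                                            ratio_base = 0.6, ratio_slope = 0.25)) {
  n <- length(treatment)
  if (!is.null(mediator) && length(mediator) != n)
    stop_input("`treatment` and `mediator` must have the same length")
  with_seed(seed, {
    if (is.null(mediator))
      mediator <- sp$a_path * treatment + rnorm(n, 0, sp$sd_mediator_noise)
    lin <- function() sp$c_prime * treatment + sp$b_path * mediator +
      rnorm(n, 0, sp$sd_outcome_noise)
    liking_raw <- lin()
    bonding_raw <- lin()
    money_raw <- lin()
    help_raw <- lin()
    data.frame(
      treatment = treatment,
      mediator = mediator,
      liking_raw = liking_raw,
      bonding_raw = bonding_raw,
      money_raw = money_raw,
      help_raw = help_raw,
      liking = clip(scales$liking_base + liking_raw, 0, 8),
      bonding = clip(scales$bonding_base + bonding_raw, 1, 7),
      money_ratio = clip(scales$ratio_base + scales$ratio_slope * money_raw, 0, 1),
      help_ratio = clip(scales$ratio_base + scales$ratio_slope * help_raw, 0, 1)
    )
  })
}
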