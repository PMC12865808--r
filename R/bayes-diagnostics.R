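# Convergence diagnostics and prior/posterior predictive checks.

#' Rank-normalized split R-hat
#'
#' Chains are split in half, draws are rank-normalized (normal scores of
#' pooled ranks), and the classic potential-scale-reduction factor is
#' computed; the reported value is the maximum of the bulk statistic and the
#' same statistic on folded (|x - median|) draws, which is sensitive to both
#' location and scale disagreement.
#'
#' @param chains_matrix iterations x chains matrix of draws for one
#'   parameter (>= 2 chains).
#' @return R-hat value; NA when within-chain variance is zero (constant
#'   parameter).
#' @export
rhat <- function(chains_matrix) {
  m <- as.matrix(chains_matrix)
  if (ncol(m) < 2) stop_input("need >= 2 chains")
  niter <- nrow(m)
  half <- floor(niter / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(niter - half + 1):niter, , drop = FALSE])
  if (all(apply(split, 2, var) < 1e-300)) return(NA_real_)
  rhat_basic <- function(sm) {
    n <- nrow(sm); c <- ncol(sm)
    W <- mean(apply(sm, 2, var))
    B <- n * var(colMeans(sm))
    if (W < 1e-300) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  znorm <- function(sm) {
    r <- rank(sm, ties.method = "average")
    z <- qnorm((r - 3 / 8) / (length(sm) + 1 / 4))
    matrix(z, nrow(sm), ncol(sm))
  }
  bulk <- rhat_basic(znorm(split))
  folded <- rhat_basic(znorm(abs(split - median(split))))
  max(bulk, folded, na.rm = TRUE)
}

#' Prior predictive check
#'
#' Simulates responses from the prior: coefficients and SDs are drawn from
#' their priors, data are simulated from the Gaussian likelihood on the
#' model's design, and the distribution of the replicate means is compared
#' with the observed mean.
#'
#' @param formula,data,priors as in \code{\link{fit_hierarchical}}.
#' @param n_draws number of prior draws (default 1000).
#' @param seed integer seed.
#' @return List: \code{rep_means} (vector), \code{observed_mean},
#'   \code{percentile} of the observed mean among replicate means, and the
#'   resolved priors.
#' @export
prior_predictive <- function(formula, data, priors = NULL, n_draws = 1000,
                             seed = 1L) {
  d <- build_design(formula, data)
  pr <- resolve_priors(priors, d$y)
  P <- ncol(d$X)
  b_mean <- c(pr$intercept_mean, rep(0, P - 1))
  b_sd <- c(pr$intercept_sd, rep(pr$beta_sd, P - 1))
  n <- length(d$y)
  G <- if (!is.null(d$group)) nlevels(d$group) else 0
  rep_means <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
    beta <- rnorm(P, b_mean, b_sd)
    sigma <- pr$sigma_fixed %||% abs(rnorm(1, 0, pr$sigma_sd))
    mu <- drop(d$X %*% beta)
    if (G > 0) {
      tau <- abs(rnorm(1, 0, pr$tau_sd))
      mu <- mu + rnorm(G, 0, tau)[as.integer(d$group)]
    }
    mean(mu + rnorm(n, 0, sigma))
  }, 0))
  list(rep_means = rep_means, observed_mean = mean(d$y),
       percentile = mean(rep_means < mean(d$y)), priors = pr)
}

#' Posterior predictive check
#'
#' Simulates one replicated dataset per posterior draw and reports where the
#' observed mean falls within the distribution of replicated means.
#' Deterministic given the fit and the seed.
#'
#' @param fit a \code{posterior_summary} from \code{\link{fit_hierarchical}}.
#' @param n_rep number of posterior draws to use (default: all).
#' @param seed integer seed.
#' @return List: \code{rep_means}, \code{observed_mean}, \code{percentile}.
#' @export
posterior_predictive <- function(fit, n_rep = NULL, seed = 1L) {
  draws <- fit$draws
  n_rep <- min(n_rep %||% nrow(draws), nrow(draws))
  use <- seq_len(n_rep)
  bcols <- colnames(fit$X)
  n <- length(fit$y)
  has_group <- !is.null(fit$group)
  rep_means <- with_seed(seed, vapply(use, function(i) {
    beta <- draws[i, bcols]
    sigma <- if ("sigma" %in% colnames(draws)) draws[i, "sigma"] else
      fit$priors$sigma_fixed
    mu <- drop(fit$X %*% beta)
    if (has_group) {
      tau <- draws[i, "sd_u"]
      mu <- mu + rnorm(nlevels(fit$group), 0, tau)[as.integer(fit$group)]
    }
    mean(mu + rnorm(n, 0, sigma))
  }, 0))
  list(rep_means = rep_means, observed_mean = mean(fit$y),
       percentile = mean(rep_means < mean(fit$y)))
}
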