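# Bayesian mediation at the dyad level:
#   M = a0 + a T + gamma C + e1,   Y = b0 + c' T + b M + delta C + e2.
# Both regressions are conjugate normal-inverse-gamma problems, so the joint
# posterior is sampled exactly (no MCMC error): sigma^2 from its marginal
# inverse-gamma, coefficients from their conditional multivariate normal.
# Per draw: ACME = a*b, ADE = c', total = c' + a*b (exact linear identity).

# exact posterior draws for y = X beta + eps under
# beta | sigma^2 ~ N(0, sigma^2 v0 I), sigma^2 ~ IG(a0, b0)
conjugate_lm_draws <- function(X, y, n_draws, v0 = 1e6, a0 = 0.01, b0 = 0.01) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  prec_n <- XtX + diag(1 / v0, p)
  Vn <- solve(prec_n)
  mn <- drop(Vn %*% crossprod(X, y))
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (sum(y^2) - drop(t(mn) %*% prec_n %*% mn))
  sig2 <- 1 / rgamma(n_draws, shape = an, rate = bn)
  R <- chol(Vn)
  Zm <- matrix(rnorm(n_draws * p), n_draws, p)
  beta <- sweep(Zm %*% R, 1, sqrt(sig2), "*")
  beta <- sweep(beta, 2, mn, "+")
  colnames(beta) <- colnames(X)
  list(beta = beta, sigma2 = sig2, mean = mn)
}

#' Equal-tailed credible interval
#'
#' Posterior quantiles \code{((1-level)/2, 1-(1-level)/2)} with the
#' linear-interpolation quantile definition (type 7).
#'
#' @param draws numeric vector of posterior draws (>= 100 recommended).
#' @param level interval mass (default 0.95); \code{level = 1} gives the
#'   range.
#' @return Named numeric: lower, upper.
#' @export
eti <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  q <- quantile(draws, probs = c(a, 1 - a), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Bayesian mediation model
#'
#' Jointly samples the mediator and outcome regressions (exact conjugate
#' posterior draws) and summarizes the average causal mediation effect
#' (ACME = a*b), the average direct effect (ADE = c'), the total effect
#' (c' + a*b; the identity total = ADE + ACME holds exactly per draw in this
#' linear Gaussian model) and the proportion mediated (ACME/total, with
#' near-zero-total draws excluded from the ratio and counted).
#'
#' @param dyad_data data frame, one row per dyad.
#' @param treatment,mediator,outcome column names.
#' @param covariates optional character vector of co-predictor columns
#'   entered in both equations (e.g. the social-context indicator when the
#'   treatment is a laughter variable).
#' @param n_draws posterior draws (default 4000).
#' @param seed integer seed.
#' @param prop_tol draws with |total| below this are excluded from the
#'   proportion-mediated ratio.
#' @param v0 prior variance scale of the conjugate coefficient prior
#'   (relative to sigma^2); the default is effectively flat.
#' @return Object of class \code{mediation_result} with a \code{summary}
#'   data frame (mean and 95% ETI for acme, ade, total, prop_mediated and
#'   the paths a, b, c'), the \code{draws}, \code{n_dyads} and the excluded
#'   fraction for the ratio.
#' @export
fit_mediation <- function(dyad_data, treatment, mediator, outcome,
                          covariates = NULL, n_draws = 4000, seed = 1L,
                          prop_tol = 1e-6, v0 = 1e6) {
  cols <- c(treatment, mediator, outcome, covariates)
  miss <- setdiff(cols, names(dyad_data))
  if (length(miss)) stop_input("column(s) not found: ", paste(miss, collapse = ", "))
  dat <- dyad_data[complete.cases(dyad_data[, cols]), cols, drop = FALSE]
  n <- nrow(dat)
  if (n < 10)
    stop_input("only ", n, " complete dyads; mediation needs at least 10 — ",
               "collect more dyads or check for missing synchrony values")
  Tv <- as.numeric(dat[[treatment]])
  Mv <- as.numeric(dat[[mediator]])
  Yv <- as.numeric(dat[[outcome]])
  if (sd(Mv) < 1e-12) stop_input("mediator is constant; paths are unidentified")
  Cm <- if (length(covariates))
    as.matrix(sapply(dat[covariates], as.numeric)) else NULL
  Xm <- cbind(`(Intercept)` = 1, treatment = Tv, Cm)
  Xy <- cbind(`(Intercept)` = 1, treatment = Tv, mediator = Mv, Cm)
  dr <- with_seed(seed, {
    m_fit <- conjugate_lm_draws(Xm, Mv, n_draws, v0 = v0)
    y_fit <- conjugate_lm_draws(Xy, Yv, n_draws, v0 = v0)
    list(a = m_fit$beta[, "treatment"],
         b = y_fit$beta[, "mediator"],
         c_prime = y_fit$beta[, "treatment"],
         sigma_m = sqrt(m_fit$sigma2), sigma_y = sqrt(y_fit$sigma2))
  })
  acme <- dr$a * dr$b
  ade <- dr$c_prime
  total <- ade + acme
  ok <- abs(total) > prop_tol
  prop <- acme[ok] / total[ok]
  summ <- function(x) c(mean = mean(x), eti(x))
  sm <- rbind(acme = summ(acme), ade = summ(ade), total = summ(total),
              prop_mediated = if (any(ok))
                c(mean = median(prop), eti(prop)) else c(NA, NA, NA),
              a = summ(dr$a), b = summ(dr$b), c_prime = summ(dr$c_prime))
  structure(list(
    summary = data.frame(effect = rownames(sm), sm, row.names = NULL,
                         check.names = FALSE),
    draws = data.frame(a = dr$a, b = dr$b, c_prime = dr$c_prime,
                       acme = acme, ade = ade, total = total),
    n_dyads = n,
    prop_excluded_fraction = mean(!ok),
    treatment = treatment, mediator = mediator, outcome = outcome,
    covariates = covariates, seed = seed),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Bayesian mediation: %s -> %s -> %s (n = %d dyads)\n",
              x$treatment, x$mediator, x$outcome, x$n_dyads))
  s <- x$summary
  s[, -1] <- round(s[, -1], 4)
  print(s, row.names = FALSE)
  if (x$prop_excluded_fraction > 0)
    cat(sprintf("  proportion mediated: %.1f%% of draws excluded (|total| ~ 0)\n",
                100 * x$prop_excluded_fraction))
  invisible(x)
}

#' Mediation grid over treatments, mediators and outcomes
#'
#' Fits one mediation model per (treatment x mediator x outcome) cell and
#' summarizes which cells' ACME, ADE or mediator-to-outcome (b) path ETIs
#' exclude zero. Per-cell failures are logged and skipped.
#'
#' @param dyad_data data frame, one row per dyad.
#' @param treatments,mediator_columns,outcomes character vectors of columns.
#' @param covariates passed to \code{\link{fit_mediation}}.
#' @param ... further arguments to \code{\link{fit_mediation}}.
#' @return Data frame with one row per cell: effect means, ETI bounds and
#'   logical \code{acme_excl0}, \code{ade_excl0}, \code{b_excl0}; failed
#'   cells carry the error message in \code{error}.
#' @export
mediation_grid <- function(dyad_data, treatments, mediator_columns, outcomes,
                           covariates = NULL, ...) {
  rows <- list()
  for (tr in treatments) for (md in mediator_columns) for (oc in outcomes) {
    res <- tryCatch(
      fit_mediation(dyad_data, tr, md, oc, covariates = covariates, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        treatment = tr, mediator = md, outcome = oc,
        acme = NA, acme_lower = NA, acme_upper = NA,
        ade = NA, ade_lower = NA, ade_upper = NA,
        b = NA, b_lower = NA, b_upper = NA,
        acme_excl0 = NA, ade_excl0 = NA, b_excl0 = NA,
        error = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    s <- res$summary
    g <- function(eff) unlist(s[s$effect == eff, c("mean", "lower", "upper")])
    ac <- g("acme"); ad <- g("ade"); b <- g("b")
    excl0 <- function(v) unname(v["lower"] > 0 | v["upper"] < 0)
    rows[[length(rows) + 1]] <- data.frame(
      treatment = tr, mediator = md, outcome = oc,
      acme = ac["mean"], acme_lower = ac["lower"], acme_upper = ac["upper"],
      ade = ad["mean"], ade_lower = ad["lower"], ade_upper = ad["upper"],
      b = b["mean"], b_lower = b["lower"], b_upper = b["upper"],
      acme_excl0 = excl0(ac), ade_excl0 = excl0(ad), b_excl0 = excl0(b),
      error = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
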