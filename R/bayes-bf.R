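# Bayes factors for nested and non-nested Gaussian model comparisons.
#
# Two routes:
#  * "marginal": the exact marginal likelihood. Coefficients and random
#    intercepts are Gaussian and integrate analytically; the remaining one-
#    or two-dimensional integral over the half-normal SD priors is evaluated
#    by adaptive quadrature around the Laplace mode. Deterministic.
#  * "savage_dickey": for a single dropped coefficient, the ratio of prior
#    to posterior density at zero, with the posterior density estimated from
#    MCMC draws (kernel density); Monte Carlo error from between-chain
#    variability.

# log N(y; X b_mean, sigma^2 I + tau^2 ZZ' + X S0 X') via Woodbury, given
# precomputed cross-products. sigma > 0; tau >= 0 (0 when no random term).
make_loglik_fun <- function(X, y, group, b_mean, b_sd) {
  A <- X %*% diag(b_sd, ncol(X))
  r <- y - drop(X %*% b_mean)
  n <- length(y)
  if (!is.null(group)) {
    Z <- model.matrix(~ 0 + group)
    G12 <- crossprod(A, Z)
    G22 <- crossprod(Z)
    w2 <- drop(crossprod(Z, r))
  }
  G11 <- crossprod(A)
  w1 <- drop(crossprod(A, r))
  rr <- sum(r^2)
  p <- ncol(A)
  function(sigma, tau = 0) {
    if (!is.null(group) && tau > 0) {
      G <- rbind(cbind(G11, tau * G12),
                 cbind(tau * t(G12), tau^2 * G22))
      w <- c(w1, tau * w2)
    } else {
      G <- G11
      w <- w1
    }
    k <- length(w)
    M <- diag(k) + G / sigma^2
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- n * 2 * log(sigma) + 2 * sum(log(diag(ch)))
    v <- backsolve(ch, forwardsolve(t(ch), w))
    quad <- (rr - sum(w * v) / sigma^2) / sigma^2
    -0.5 * (n * log(2 * pi) + logdet + quad)
  }
}

log_halfnormal <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

# trapezoid log-integral of exp(logf) over a grid
log_trapez <- function(logf, x) {
  dx <- diff(x)
  lw <- log(dx / 2) + pmax(logf[-1], logf[-length(logf)]) +
    log1p(exp(-abs(logf[-1] - logf[-length(logf)])))
  mx <- max(lw)
  mx + log(sum(exp(lw - mx)))
}

#' Log marginal likelihood of a Gaussian linear model
#'
#' Integrates the coefficients (and random intercepts) analytically and the
#' SD parameters by quadrature on the log scale around the posterior mode.
#' With a fixed residual SD and no random term the result is fully
#' closed-form.
#'
#' @param formula,data,priors as in \code{\link{fit_hierarchical}}.
#' @param grid_points quadrature points per dimension (default 61 / 41).
#' @return Log marginal likelihood (scalar).
#' @export
log_marginal <- function(formula, data, priors = NULL, grid_points = NULL) {
  d <- build_design(formula, data)
  pr <- resolve_priors(priors, d$y)
  P <- ncol(d$X)
  b_mean <- c(pr$intercept_mean, rep(0, P - 1))
  b_sd <- c(pr$intercept_sd, rep(pr$beta_sd, P - 1))
  if (colnames(d$X)[1] != "(Intercept)") {
    b_mean <- rep(0, P); b_sd <- rep(pr$beta_sd, P)
  }
  ll <- make_loglik_fun(d$X, d$y, d$group, b_mean, b_sd)
  has_group <- !is.null(d$group)
  if (!is.null(pr$sigma_fixed) && !has_group)
    return(ll(pr$sigma_fixed))

  sy <- sd(d$y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  if (!has_group) {
    gp <- grid_points %||% 61
    f <- function(ls) ll(exp(ls)) + log_halfnormal(exp(ls), pr$sigma_sd) + ls
    opt <- optim(log(sy), function(t) -f(t), method = "Brent",
                 lower = log(sy) - 12, upper = log(5 * pr$sigma_sd) + 2)
    h <- sqrt(1 / max(numeric_neg_hessian_1d(f, opt$par), 1e-4))
    grid <- seq(opt$par - 8 * h, opt$par + 8 * h, length.out = gp)
    return(log_trapez(vapply(grid, f, 0), grid))
  }
  gp <- grid_points %||% 41
  if (!is.null(pr$sigma_fixed)) {
    f <- function(lt) ll(pr$sigma_fixed, exp(lt)) +
      log_halfnormal(exp(lt), pr$tau_sd) + lt
    opt <- optim(log(sy / 2), function(t) -f(t), method = "Brent",
                 lower = log(sy) - 14, upper = log(5 * pr$tau_sd) + 2)
    h <- sqrt(1 / max(numeric_neg_hessian_1d(f, opt$par), 1e-4))
    grid <- seq(opt$par - 8 * h, opt$par + 8 * h, length.out = 61)
    return(log_trapez(vapply(grid, f, 0), grid))
  }
  f2 <- function(th) ll(exp(th[1]), exp(th[2])) +
    log_halfnormal(exp(th[1]), pr$sigma_sd) +
    log_halfnormal(exp(th[2]), pr$tau_sd) + sum(th)
  opt <- optim(c(log(sy), log(sy / 2)), function(t) -f2(t))
  hs <- vapply(1:2, function(j) {
    e <- c(0, 0); e[j] <- 1e-3
    max((2 * opt$value - (-f2(opt$par + e)) - (-f2(opt$par - e))) / 1e-6 * -1,
        1e-4)
  }, 0)
  hs <- sqrt(1 / hs)
  g1 <- seq(opt$par[1] - 7 * hs[1], opt$par[1] + 7 * hs[1], length.out = gp)
  g2 <- seq(opt$par[2] - 7 * hs[2], opt$par[2] + 7 * hs[2], length.out = gp)
  lf <- outer(g1, g2, Vectorize(function(a, b) f2(c(a, b))))
  # iterated trapezoid
  inner <- apply(lf, 1, function(row) log_trapez(row, g2))
  log_trapez(inner, g1)
}

numeric_neg_hessian_1d <- function(f, x, h = 1e-3) {
  -(f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

#' Bayes factor between two Gaussian models
#'
#' BF10 in favour of \code{full} over \code{null}. Method \code{"auto"}
#' picks Savage-Dickey when \code{null} is nested in \code{full} with exactly
#' one dropped coefficient (and the same random structure), and the exact
#' marginal-likelihood route otherwise. \code{bf10 * bf01 = 1} holds exactly
#' for the marginal route.
#'
#' @param full,null model formulas.
#' @param data data frame.
#' @param priors a \code{\link{ds_priors}}; the same priors (resolved on the
#'   full model's response) are used for both models.
#' @param method \code{"auto"}, \code{"savage_dickey"} or \code{"marginal"}.
#' @param ... passed to \code{\link{fit_hierarchical}} for Savage-Dickey.
#' @return Object of class \code{bf_result}: \code{bf10}, \code{log_bf10},
#'   \code{method}, \code{mc_error} (0 for the deterministic marginal
#'   route), and the dropped terms.
#' @export
bayes_factor <- function(full, null, data, priors = NULL,
                         method = c("auto", "savage_dickey", "marginal"),
                         ...) {
  method <- match.arg(method)
  df_full <- build_design(full, data)
  df_null <- build_design(null, data)
  dropped <- setdiff(colnames(df_full$X), colnames(df_null$X))
  nested <- all(colnames(df_null$X) %in% colnames(df_full$X)) &&
    identical(df_full$group_name, df_null$group_name)
  if (method == "auto")
    method <- if (nested && length(dropped) == 1) "savage_dickey" else "marginal"
  if (method == "savage_dickey" && (!nested || length(dropped) != 1))
    stop_input("savage_dickey needs a nested null dropping exactly one coefficient")
  if (length(dropped) == 0 && identical(deparse(full), deparse(null)))
    return(structure(list(bf10 = 1, log_bf10 = 0, method = "identical",
                          mc_error = 0, dropped = character(0)),
                     class = "bf_result"))
  pr <- resolve_priors(priors, df_full$y)
  if (method == "marginal") {
    l1 <- log_marginal(full, data, pr)
    l0 <- log_marginal(null, data, pr)
    return(structure(list(bf10 = exp(l1 - l0), log_bf10 = l1 - l0,
                          method = "marginal", mc_error = 0,
                          dropped = dropped), class = "bf_result"))
  }
  fit <- fit_hierarchical(full, data, priors = pr, ...)
  dr <- fit$draws[, dropped]
  prior0 <- dnorm(0, 0, pr$beta_sd)
  dens0 <- function(x) {
    dd <- density(x, n = 512, from = -4 * sd(x), to = 4 * sd(x))
    approx(dd$x, dd$y, xout = 0, rule = 2)$y
  }
  post0 <- dens0(dr)
  nch <- dim(fit$chain_array)[2]
  per_chain <- vapply(seq_len(nch), function(ch)
    prior0 / dens0(fit$chain_array[, ch, dropped]), 0)
  structure(list(bf10 = prior0 / post0, log_bf10 = log(prior0 / post0),
                 method = "savage_dickey",
                 mc_error = sd(per_chain) / sqrt(nch),
                 dropped = dropped, fit = fit), class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (log = %.3f), method = %s, mc_error = %.3g\n",
              x$bf10, x$log_bf10, x$method, x$mc_error))
  if (length(x$dropped))
    cat("  terms dropped in null:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Sequential Bayes-factor monitoring
#'
#' Implements the sequential stopping rule: accrual starts at
#' \code{start_n_per_condition} dyads per condition and continues until the
#' Bayes factor for full vs null crosses \code{upper} (support for the full
#' model) or drops below \code{lower} (support for the null), or the stream
#' ends ("resources exhausted"). Either a precomputed \code{trajectory} of
#' BF values is monitored, or the BF is recomputed (marginal route) at each
#' accrual step on the growing dataset.
#'
#' @param full,null model formulas (ignored when \code{trajectory} given).
#' @param data data frame ordered by accrual (one row per dyad).
#' @param trajectory optional numeric vector of BF10 values per step.
#' @param start_n_per_condition minimum dyads per condition before testing.
#' @param upper,lower stopping thresholds (defaults 5 and 0.20).
#' @param condition_col column defining conditions (for the start rule).
#' @param priors,step BF priors; accrual step size in dyads.
#' @return List: \code{decision} (\code{"support-full"},
#'   \code{"support-null"} or \code{"resources exhausted"}), \code{stop_at}
#'   (step index or n), and the BF \code{trajectory} data frame.
#' @export
sequential_monitor <- function(full = NULL, null = NULL, data = NULL,
                               trajectory = NULL,
                               start_n_per_condition = 20,
                               upper = 5, lower = 0.20,
                               condition_col = "cell", priors = NULL,
                               step = 1) {
  decide <- function(bf) {
    if (bf > upper) "support-full" else if (bf < lower) "support-null" else NA
  }
  if (!is.null(trajectory)) {
    for (i in seq_along(trajectory)) {
      dec <- decide(trajectory[i])
      if (!is.na(dec))
        return(list(decision = dec, stop_at = i,
                    trajectory = data.frame(step = seq_len(i),
                                            bf10 = trajectory[seq_len(i)])))
    }
    return(list(decision = "resources exhausted", stop_at = length(trajectory),
                trajectory = data.frame(step = seq_along(trajectory),
                                        bf10 = trajectory)))
  }
  if (is.null(data)) stop_input("supply either a trajectory or data")
  conds <- if (condition_col %in% names(data)) data[[condition_col]] else
    rep("all", nrow(data))
  counts <- function(n) min(table(conds[seq_len(n)])[unique(conds)], na.rm = TRUE)
  ns <- seq(1, nrow(data), by = step)
  if (ns[length(ns)] != nrow(data)) ns <- c(ns, nrow(data))
  traj <- data.frame(n = integer(0), bf10 = numeric(0))
  for (n in ns) {
    if (counts(n) < start_n_per_condition) next
    bf <- bayes_factor(full, null, data[seq_len(n), , drop = FALSE],
                       priors = priors, method = "marginal")$bf10
    traj <- rbind(traj, data.frame(n = n, bf10 = bf))
    dec <- decide(bf)
    if (!is.na(dec))
      return(list(decision = dec, stop_at = n, trajectory = traj))
  }
  list(decision = "resources exhausted",
       stop_at = if (nrow(traj)) traj$n[nrow(traj)] else NA_integer_,
       trajectory = traj)
}
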