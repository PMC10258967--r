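## Four-group uniform/Beta mixture on paired P values.
##
## Null margins are Uniform(0,1); non-null margins are Beta(a, 1) with
## a in (0, 1) (density a * p^(a-1), monotone decreasing), one shape per
## population shared by its two non-null groups. Groups: 00 (null in
## both), 10 (associated in population 1 only), 01, 11 (both).

ALPHA_LO <- 1e-3
ALPHA_HI <- 1 - 1e-6

log_beta1 <- function(p, a) log(a) + (a - 1) * log(p)

# Weighted MLE of the Beta(a,1) first shape: a = sum(w) / (-sum(w log p)).
beta_shape_mle <- function(w, logp) {
  s <- sum(w)
  if (s <= 0) return(0.5)
  min(max(-s / sum(w * logp), ALPHA_LO), ALPHA_HI)
}

# One EM run of the full four-group model from a given start.
em_four_group <- function(lp1, lp2, pi0, a1, a2, tol, max_iter) {
  n <- length(lp1)
  pi <- pi0
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    lf1 <- log(a1) + (a1 - 1) * lp1
    lf2 <- log(a2) + (a2 - 1) * lp2
    lg <- cbind(log(pi[1L]),
                log(pi[2L]) + lf1,
                log(pi[3L]) + lf2,
                log(pi[4L]) + lf1 + lf2)
    mx <- pmax(lg[, 1L], lg[, 2L], lg[, 3L], lg[, 4L])
    pr <- exp(lg - mx)
    denom <- rowSums(pr)
    ll <- sum(mx + log(denom))
    if (ll < ll_old - 1e-8 * max(1, abs(ll_old))) {
      stop("em_four_group: log-likelihood decreased (", ll_old, " -> ", ll, ")")
    }
    r <- pr / denom
    pi <- pmax(colMeans(r), 1e-12)
    pi <- pi / sum(pi)
    a1 <- beta_shape_mle(r[, 2L] + r[, 4L], lp1)
    a2 <- beta_shape_mle(r[, 3L] + r[, 4L], lp2)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(pi = pi, alpha1 = a1, alpha2 = a2, loglik = ll,
       iters = iter, converged = iter < max_iter, trace = trace)
}

# Two-group (null/non-null) mixture EM on one margin; the independence
# null factorizes into two of these.
em_two_group <- function(lp, q0, a0, tol, max_iter) {
  q <- q0; a <- a0
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    l1 <- log(q) + log(a) + (a - 1) * lp
    l0 <- log(1 - q)
    mx <- pmax(l0, l1)
    denom <- exp(l0 - mx) + exp(l1 - mx)
    ll <- sum(mx + log(denom))
    r1 <- exp(l1 - mx) / denom
    q <- min(max(mean(r1), 1e-12), 1 - 1e-12)
    a <- beta_shape_mle(r1, lp)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(q = q, alpha = a, loglik = ll)
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Fit the four-group mixture model to paired P values
#'
#' Maximizes the mixture likelihood over the four group proportions and
#' the two Beta shapes by EM (tolerance `tol` on the log-likelihood,
#' `n_restarts` random restarts, best kept), then refits under the
#' independence null (the probability of being non-null in each
#' population is independent, so `pi11 = q1 * q2`) and performs a
#' 1-degree-of-freedom likelihood-ratio test of trans-ethnic genetic
#' overlap. P values should come from approximately independent SNPs.
#'
#' @param p1,p2 aligned P-value vectors in (0, 1].
#' @param tol EM log-likelihood tolerance (default `1e-6`).
#' @param max_iter maximum EM iterations per restart (default 2000).
#' @param n_restarts random restarts, seeded 0 .. n-1 (default 5).
#' @return list of class `four_group_fit`: `pi` (named `pi00`, `pi10`,
#'   `pi01`, `pi11`), `alpha1`, `alpha2`, `loglik`, `loglik_null`,
#'   `lrt_stat`, `p_lrt`, `shared_prop` (`pi11 / (pi10 + pi01 + pi11)`).
#' @export
fit_four_group <- function(p1, p2, tol = 1e-6, max_iter = 2000L,
                           n_restarts = 5L) {
  if (length(p1) != length(p2) || length(p1) == 0L) {
    stop("fit_four_group: p1 and p2 must be non-empty and aligned")
  }
  if (any(p1 <= 0 | p1 > 1 | p2 <= 0 | p2 > 1)) {
    stop("fit_four_group: P values must lie in (0, 1]")
  }
  lp1 <- log(pmin(p1, 1 - 1e-16))
  lp2 <- log(pmin(p2, 1 - 1e-16))
  best <- NULL
  for (s in seq_len(n_restarts) - 1L) {
    start <- with_preserved_seed(s, {
      # symmetric starts (equal specific-group mass, one shared Beta
      # shape) so that swapping the two P vectors mirrors the EM path
      spec <- stats::runif(1, 0.01, 0.1)
      pi0 <- c(stats::runif(1, 0.7, 0.95), spec, spec,
               stats::runif(1, 0.01, 0.1))
      list(pi = pi0 / sum(pi0), a = stats::runif(1, 0.1, 0.9))
    })
    fit <- em_four_group(lp1, lp2, start$pi, start$a, start$a,
                         tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best) || !is.finite(best$loglik)) {
    stop("fit_four_group: no restart converged to a finite log-likelihood")
  }
  # independence null factorizes into two marginal two-group mixtures
  null1 <- em_two_group(lp1, sum(best$pi[c(2L, 4L)]), best$alpha1, tol, max_iter)
  null2 <- em_two_group(lp2, sum(best$pi[c(3L, 4L)]), best$alpha2, tol, max_iter)
  ll_null <- null1$loglik + null2$loglik
  if (ll_null > best$loglik) {
    # the independence solution lies inside the full model: restart the
    # full EM from it so the full fit can never fall below the null
    q1 <- min(max(null1$q, 1e-6), 1 - 1e-6)
    q2 <- min(max(null2$q, 1e-6), 1 - 1e-6)
    pi_ind <- c((1 - q1) * (1 - q2), q1 * (1 - q2), (1 - q1) * q2, q1 * q2)
    refit <- em_four_group(lp1, lp2, pi_ind, null1$alpha, null2$alpha,
                           tol, max_iter)
    if (refit$loglik > best$loglik) best <- refit
  }
  if (ll_null > best$loglik + 1e-6) {
    stop("fit_four_group: null fit exceeds full fit (",
         ll_null, " > ", best$loglik, "); optimization failure")
  }
  lrt <- max(0, 2 * (best$loglik - ll_null))
  pi <- stats::setNames(best$pi, c("pi00", "pi10", "pi01", "pi11"))
  nonnull <- sum(pi[c("pi10", "pi01", "pi11")])
  structure(list(
    pi = pi, alpha1 = best$alpha1, alpha2 = best$alpha2,
    loglik = best$loglik, loglik_null = ll_null,
    null_q = c(q1 = null1$q, q2 = null2$q),
    lrt_stat = lrt,
    p_lrt = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
    shared_prop = if (nonnull > 0) unname(pi["pi11"] / nonnull) else NA_real_,
    converged = best$converged, iters = best$iters
  ), class = "four_group_fit")
}

#' Likelihood-ratio test of trans-ethnic genetic overlap
#'
#' Compares the full four-group fit against the independence null
#' (`pi11 = q1 * q2`); the statistic `2 * (l_full - l_null)` is referred
#' to a chi-squared distribution with 1 degree of freedom. The test is
#' already computed by [fit_four_group()]; this accessor re-derives it
#' from a fit.
#'
#' @param fit a `four_group_fit`.
#' @return list with `stat` and `p`.
#' @export
lrt_overlap <- function(fit) {
  stopifnot(inherits(fit, "four_group_fit"))
  list(stat = fit$lrt_stat, p = fit$p_lrt)
}

#' @export
print.four_group_fit <- function(x, ...) {
  cat(sprintf(
    "four-group fit: pi = (%.3f, %.3f, %.3f, %.3f), alpha = (%.3f, %.3f)\n",
    x$pi[1L], x$pi[2L], x$pi[3L], x$pi[4L], x$alpha1, x$alpha2))
  cat(sprintf("  shared proportion = %.1f%%, LRT = %.1f, P = %.3g\n",
              100 * x$shared_prop, x$lrt_stat, x$p_lrt))
  invisible(x)
}
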