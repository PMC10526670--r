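# From-scratch survival and association statistics: Kaplan-Meier
# product-limit estimation, the two-sample log-rank test, Cox proportional
# hazards with Efron tie handling, Spearman rank correlation, and
# expression dichotomization. Implemented directly (no dependency on the
# survival package) so that unit tests can check them against an
# independent reference implementation.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators: 1 = death, 0 = censored. Censored
#'   subjects leave the risk set after their time.
#' @return Object of class `km_curve` with fields `time` (ordered distinct
#'   event times), `n_risk`, `n_event` and `surv` (S(t), non-increasing,
#'   with S(0) = 1 implicit).
#' @export
km_estimate <- function(time, event) {
  check_flag(is.numeric(time) && length(time) >= 1L && all(is.finite(time)) &&
               all(time > 0), "time", "must be positive and finite")
  check_flag(length(event) == length(time) && all(event %in% c(0, 1)),
             "event", "must be 0/1, one per subject")
  dt <- sort(unique(time[event == 1]))
  n_risk <- vapply(dt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(dt, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = dt, n_risk = n_risk, n_event = n_event, surv = surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d event times; S(last) = %.4f\n",
              length(x$time), if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at time t
#'
#' Right-continuous step-function evaluation: S(t) is the estimate at the
#' largest event time not exceeding `t` (1 before the first event, the
#' last estimate beyond the last event time). Five-year overall survival is
#' `survival_at(curve, 60)` with time in months.
#'
#' @param curve A [km_estimate()] result.
#' @param t Non-negative time(s).
#' @return Survival probabilities in `[0, 1]`, one per element of `t`.
#' @export
survival_at <- function(curve, t) {
  check_flag(inherits(curve, "km_curve"), "curve", "must be a km_curve")
  check_flag(is.numeric(t) && all(t >= 0), "t", "must be non-negative")
  vapply(t, function(tt) {
    k <- sum(curve$time <= tt)
    if (k == 0L) 1 else curve$surv[k]
  }, numeric(1))
}

#' Two-sample log-rank test
#'
#' At each distinct event time the observed number of deaths in group `a`
#' is compared with its hypergeometric expectation given the pooled risk
#' set; `chi_square = (O_a - E_a)^2 / V` with the standard hypergeometric
#' variance summed over event times, and the p-value comes from the
#' chi-square distribution with one degree of freedom. The statistic is
#' invariant under relabeling of the two groups.
#'
#' @param time,event Pooled follow-up times and 0/1 event indicators.
#' @param group Two-level group labels, one per subject.
#' @return Object of class `logrank_result`: `chi_square`, `p_value`,
#'   `observed` and `expected` (named per group), `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  check_flag(is.numeric(time) && length(time) >= 2L && all(time > 0),
             "time", "must be positive, length >= 2")
  check_flag(length(event) == length(time) && all(event %in% c(0, 1)),
             "event", "must be 0/1")
  group <- as.character(group)
  lev <- sort(unique(group))
  check_flag(length(lev) == 2L, "group", "must have exactly two levels")
  if (sum(event) == 0) stop("no events in either group", call. = FALSE)

  dt <- sort(unique(time[event == 1]))
  in_a <- group == lev[1]
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1j <- sum(at_risk & in_a)
    d_j <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & in_a)
    O <- O + d1j
    E <- E + d_j * n1j / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1j / n_j) * (1 - n1j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  obs <- setNames(c(O, sum(event) - O), lev)
  exp_ <- setNames(c(E, sum(event) - E), lev)
  structure(list(chi_square = chi, p_value = p, observed = obs,
                 expected = exp_, n = table(group)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi-square = %.4g on 1 df, p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Cox proportional hazards fit
#'
#' Maximizes the partial likelihood with Efron handling of tied event
#' times by damped Newton iterations (step-halving when a step would
#' decrease the partial log-likelihood). Standard errors come from the
#' inverse observed information; `converged` is set when the gradient
#' max-norm falls below `tol` (1e-8). Monotone divergence of a coefficient
#' (|beta| > 15) triggers a separation warning and `converged = FALSE`.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param x Covariate vector or matrix (one column per covariate); every
#'   covariate needs at least two distinct values.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @return Object of class `cox_result`: `beta`, `hr = exp(beta)`, `se`,
#'   `ci95` (matrix with columns lower/upper, hazard-ratio scale),
#'   `p_value` (Wald), `loglik` (null and fitted), `converged`, `iter`.
#' @export
cox_fit <- function(time, event, x, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  check_flag(is.numeric(time) && all(time > 0), "time", "must be positive")
  check_flag(length(event) == length(time) && all(event %in% c(0, 1)),
             "event", "must be 0/1")
  check_flag(nrow(X) == length(time), "x", "must have one row per subject")
  if (sum(event) == 0) stop("no events; cannot fit", call. = FALSE)
  distinct <- apply(X, 2L, function(v) length(unique(v)))
  if (any(distinct < 2L)) {
    stop("constant covariate: needs >= 2 distinct values", call. = FALSE)
  }
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  beta <- rep(0, p)
  ll0 <- cox_partial(time, event, X, beta)$loglik
  ll <- ll0
  converged <- FALSE
  warned <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    q <- cox_partial(time, event, X, beta)
    if (max(abs(q$grad)) < tol) {
      converged <- TRUE
      ll <- q$loglik
      break
    }
    step <- tryCatch(solve(q$info, q$grad), error = function(e) NULL)
    if (is.null(step)) break
    # damped Newton: halve the step until the log-likelihood improves
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      llc <- cox_partial(time, event, X, cand)$loglik
      if (llc >= q$loglik - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll <- llc
    if (any(abs(beta) > 15)) {
      warning("possible separation: a coefficient diverged", call. = FALSE)
      warned <- TRUE
      break
    }
  }
  q <- cox_partial(time, event, X, beta)
  if (!warned && max(abs(q$grad)) < tol) converged <- TRUE
  cov <- tryCatch(solve(q$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov))
  zc <- stats::qnorm(0.975)
  ci <- cbind(lower = exp(beta - zc * se), upper = exp(beta + zc * se))
  rownames(ci) <- colnames(X)
  pval <- 2 * pnorm(-abs(beta / se))
  structure(list(beta = setNames(beta, colnames(X)),
                 hr = setNames(exp(beta), colnames(X)),
                 se = setNames(se, colnames(X)), ci95 = ci,
                 p_value = setNames(pval, colnames(X)),
                 loglik = c(null = ll0, fitted = q$loglik),
                 converged = converged, iter = iter),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result>\n")
  for (nm in names(x$beta)) {
    cat(sprintf("  %s: HR = %.4g (95%% CI %.4g-%.4g), beta = %.4g, p = %.3g\n",
                nm, x$hr[nm], x$ci95[nm, "lower"], x$ci95[nm, "upper"],
                x$beta[nm], x$p_value[nm]))
  }
  cat(sprintf("  converged: %s (%d iterations)\n", x$converged, x$iter))
  invisible(x)
}

# Efron partial log-likelihood, gradient and observed information.
cox_partial <- function(time, event, X, beta) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  theta <- exp(eta)
  ord <- order(time, decreasing = TRUE)   # accumulate risk sets going back
  t_s <- time[ord]; e_s <- event[ord]
  X_s <- X[ord, , drop = FALSE]; th_s <- theta[ord]; eta_s <- eta[ord]

  loglik <- 0
  grad <- rep(0, p)
  info <- matrix(0, p, p)
  S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
  i <- 1L
  n <- length(t_s)
  while (i <= n) {
    # add everyone tied at this time to the risk set
    j <- i
    while (j <= n && t_s[j] == t_s[i]) j <- j + 1L
    idx <- i:(j - 1L)
    for (k in idx) {
      S0 <- S0 + th_s[k]
      S1 <- S1 + th_s[k] * X_s[k, ]
      S2 <- S2 + th_s[k] * tcrossprod(X_s[k, ])
    }
    dead <- idx[e_s[idx] == 1]
    d <- length(dead)
    if (d > 0) {
      Sd0 <- sum(th_s[dead])
      Sd1 <- colSums(X_s[dead, , drop = FALSE] * th_s[dead])
      Sd2 <- matrix(0, p, p)
      for (k in dead) Sd2 <- Sd2 + th_s[k] * tcrossprod(X_s[k, ])
      loglik <- loglik + sum(eta_s[dead])
      for (l in seq_len(d) - 1L) {
        w <- l / d
        R0 <- S0 - w * Sd0
        R1 <- S1 - w * Sd1
        R2 <- S2 - w * Sd2
        loglik <- loglik - log(R0)
        mu <- R1 / R0
        grad <- grad - mu
        info <- info + R2 / R0 - tcrossprod(mu)
      }
      grad <- grad + colSums(X_s[dead, , drop = FALSE])
    }
    i <- j
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks use midranks for ties; rho is the Pearson correlation of the two
#' rank vectors, and the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return `list(rho = <[-1,1]>, p_value = <[0,1]>)`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch between x and y", call. = FALSE)
  }
  check_flag(length(x) >= 3L, "x", "needs length >= 3")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Dichotomize expression values into low/high groups
#'
#' \describe{
#'   \item{median}{high iff value > sample median; values equal to the
#'     median go to low (deterministic).}
#'   \item{cutoff}{high iff value > `cutoff`.}
#'   \item{youden}{threshold chosen by [youden_cutoff()] against the
#'     supplied binary `outcomes`; high iff value >= that cutoff (higher
#'     score = worse outcome orientation).}
#' }
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @param method `"median"`, `"cutoff"` or `"youden"`.
#' @param cutoff Numeric threshold for `method = "cutoff"`.
#' @param outcomes Binary outcomes for `method = "youden"`.
#' @return Character vector of `"low"`/`"high"`, one per value.
#' @export
dichotomize <- function(values, method = c("median", "cutoff", "youden"),
                        cutoff = NULL, outcomes = NULL) {
  method <- match.arg(method)
  check_flag(is.numeric(values) && length(values) >= 2L, "values",
             "needs >= 2 numeric values")
  if (length(unique(values)) < 2L) {
    stop("all values identical; cannot dichotomize", call. = FALSE)
  }
  high <- switch(method,
    median = values > median(values),
    cutoff = {
      check_flag(is.numeric(cutoff) && length(cutoff) == 1L, "cutoff",
                 "must be a single number")
      values > cutoff
    },
    youden = {
      check_flag(!is.null(outcomes), "outcomes",
                 "required for method = 'youden'")
      yc <- youden_cutoff(values, outcomes)
      values >= yc$cutoff
    }
  )
  ifelse(high, "high", "low")
}
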