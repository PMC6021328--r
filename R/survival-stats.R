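# From-scratch survival machinery: inclusion filtering, Kaplan-Meier
# product-limit estimation with the "smallest t with S(t) <= 0.5" median,
# k-group log-rank with hypergeometric variance, Cox proportional hazards by
# Newton-Raphson on the Breslow partial likelihood, and forward stepwise
# selection gated by univariate significance.

#' Survival-analysis inclusion filter
#'
#' Excludes deaths within the first `min_os` months after surgery and
#' censored patients with less than `min_followup` months of follow-up;
#' records with missing survival data are excluded with reason `"missing"`.
#'
#' @param records data.frame with columns `os_months` and `event`
#'   (1 = death).
#' @param min_os deaths with `os_months <= min_os` are excluded
#'   (reason `early_death`).
#' @param min_followup censored records with `os_months < min_followup` are
#'   excluded (reason `short_followup`).
#' @return list with `included` and `excluded` (the latter with a `reason`
#'   column).
#' @export
apply_inclusion_filter <- function(records, min_os = 1, min_followup = 18) {
  stopifnot(all(c("os_months", "event") %in% names(records)))
  dt <- as.data.table(records)
  rsn <- rep(NA_character_, nrow(dt))
  miss <- is.na(dt$os_months) | is.na(dt$event)
  rsn[miss] <- "missing"
  early <- !miss & dt$event == 1 & dt$os_months <= min_os
  rsn[early] <- "early_death"
  short <- !miss & dt$event == 0 & dt$os_months < min_followup
  rsn[short] <- "short_followup"
  excl <- dt[!is.na(rsn)]
  excl[, reason := rsn[!is.na(rsn)]]
  list(included = dt[is.na(rsn)], excluded = excl[])
}

#' Kaplan-Meier product-limit fit
#'
#' @param times event/censoring times (>= 0).
#' @param events event indicator (1 = event, 0 = censored).
#' @return a `km_fit`: data.table over distinct event times with columns
#'   time, n_risk, n_event, n_censor, surv, plus attributes n/events/
#'   censored. `S(0) = 1` and the estimate is non-increasing.
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events),
            all(is.finite(times)), all(times >= 0),
            all(events %in% c(0, 1)))
  ut <- sort(unique(times))
  n <- length(times)
  tab <- data.table(time = ut)
  tab[, n_risk := vapply(time, function(t) sum(times >= t), 0)]
  tab[, n_event := vapply(time, function(t) sum(times == t & events == 1), 0)]
  tab[, n_censor := vapply(time, function(t) sum(times == t & events == 0), 0)]
  tab[, surv := cumprod(1 - n_event / n_risk)]
  out <- tab[n_event > 0]
  setattr(out, "class", c("km_fit", class(out)))
  setattr(out, "n", n)
  setattr(out, "events", sum(events == 1))
  setattr(out, "censored", sum(events == 0))
  out
}

#' Kaplan-Meier median survival
#'
#' The smallest event time `t` with `S(t) <= 0.5`; `NA` ("not reached") when
#' the curve never drops to 0.5.
#'
#' @param fit a [km_fit()].
#' @return median in the time unit of the fit, or `NA_real_`.
#' @export
km_median <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  hit <- fit[surv <= 0.5 + 1e-12]
  if (!nrow(hit)) NA_real_ else hit$time[1]
}

#' k-group log-rank test
#'
#' Standard observed-minus-expected log-rank: at each distinct event time
#' the per-group expected events and the hypergeometric variance-covariance
#' are accumulated; the statistic is the quadratic form over `k - 1` groups
#' and the p-value comes from the chi-square upper tail with `k - 1` df.
#'
#' @param times event/censoring times.
#' @param events event indicator (1 = event).
#' @param group group labels; every level must contain at least one
#'   subject.
#' @return list with `chisq`, `df`, `p`, `observed`, `expected` (named per
#'   group), class `logrank_test`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (nlevels(group) < 2) stop("log-rank needs >= 2 groups")
  cnt <- table(group)
  if (any(cnt == 0))
    stop("log-rank: group with zero subjects: ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  k <- nlevels(group)
  ut <- sort(unique(times[events == 1]))
  O <- as.numeric(table(group[events == 1]))
  E <- numeric(k); V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- times >= t
    nj <- sum(at_risk)
    dj <- sum(times == t & events == 1)
    nij <- as.numeric(table(group[at_risk]))
    E <- E + dj * nij / nj
    if (nj > 1) {
      f <- dj * (nj - dj) / (nj - 1)
      V <- V + f * (diag(nij / nj, k) - tcrossprod(nij / nj))
    }
  }
  idx <- seq_len(k - 1)
  d <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- tryCatch(drop(t(d) %*% solve(Vi, d)),
                    error = function(e) {
                      # singular covariance (e.g. no events): statistic 0
                      0
                    })
  if (!is.finite(chisq) || chisq < 0) chisq <- 0
  p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  structure(list(chisq = chisq, df = k - 1, p = p,
                 observed = setNames(O, levels(group)),
                 expected = setNames(E, levels(group)),
                 n = length(times)),
            class = "logrank_test")
}

#' Pairwise log-rank tests for k > 2 groups
#'
#' @inheritParams logrank_test
#' @return data.table with group1, group2, chisq, p.
#' @export
pairwise_logrank <- function(times, events, group) {
  group <- as.factor(group)
  lv <- levels(group)
  out <- list()
  for (i in seq_len(length(lv) - 1)) for (j in seq(i + 1, length(lv))) {
    sel <- group %in% lv[c(i, j)]
    lr <- logrank_test(times[sel], events[sel], droplevels(group[sel]))
    out[[length(out) + 1L]] <- data.table(group1 = lv[i], group2 = lv[j],
                                          chisq = lr$chisq, p = lr$p)
  }
  rbindlist(out)
}

# Breslow partial log-likelihood, gradient and Hessian for covariate matrix
# X (n x p), times, events. Risk sets handled by sorting on descending time.
.cox_lgh <- function(beta, X, times, events) {
  n <- nrow(X); p <- ncol(X)
  ord <- order(-times)
  Xo <- X[ord, , drop = FALSE]
  to <- times[ord]; ev <- events[ord]
  if (p == 0) {
    nrisk <- seq_len(n)
    ll <- sum(vapply(which(ev == 1), function(i)
      -log(max(which(to == to[i]))), 0))
    return(list(ll = ll, grad = numeric(0), hess = matrix(0, 0, 0)))
  }
  eta <- drop(Xo %*% beta)
  eta <- pmin(eta, 500)                       # guard overflow
  th <- exp(eta)
  cth <- cumsum(th)                            # sum over risk set (time >= t)
  cx <- apply(Xo * th, 2, cumsum)              # n x p
  cxx <- matrix(0, n, p * (p + 1) / 2)
  idx <- 0L
  for (a in seq_len(p)) for (b in a:p) {
    idx <- idx + 1L
    cxx[, idx] <- cumsum(Xo[, a] * Xo[, b] * th)
  }
  ll <- 0; g <- numeric(p); H <- matrix(0, p, p)
  ev_idx <- which(ev == 1)
  for (i in ev_idx) {
    # risk set = all with time >= to[i]; in descending order that is 1..j
    j <- max(which(to == to[i]))
    S0 <- cth[j]
    S1 <- cx[j, ]
    ll <- ll + eta[i] - log(S0)
    g <- g + Xo[i, ] - S1 / S0
    idx <- 0L
    S2 <- matrix(0, p, p)
    for (a in seq_len(p)) for (b in a:p) {
      idx <- idx + 1L
      S2[a, b] <- S2[b, a] <- cxx[j, idx]
    }
    H <- H + S2 / S0 - tcrossprod(S1 / S0)
  }
  list(ll = ll, grad = g, hess = -H)
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving, iterating to gradient max-norm below `tol`. Hazard ratios carry
#' Wald 95% confidence intervals and p-values. Deterministic given input
#' order.
#'
#' @param times event/censoring times.
#' @param events event indicator (1 = event); at least one event required.
#' @param X numeric covariate matrix (n x p) with column names.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations; non-convergence is an error
#'   reporting the last gradient norm.
#' @return a `cox_fit`: coefficients, se, hr, ci_lo, ci_hi, z, p per
#'   covariate, plus loglik (fitted), loglik_null, iterations and a
#'   `separation` flag (diverging coefficient magnitude).
#' @export
cox_fit <- function(times, events, X, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(times), length(times) == length(events))
  if (sum(events == 1) < 1) stop("Cox fit requires >= 1 event")
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  ll0 <- .cox_lgh(numeric(p), X, times, events)$ll
  if (p == 0)
    return(structure(list(coef = numeric(), se = numeric(), hr = numeric(),
                          ci_lo = numeric(), ci_hi = numeric(),
                          z = numeric(), p = numeric(), loglik = ll0,
                          loglik_null = ll0, iterations = 0L,
                          separation = FALSE, n = length(times),
                          n_events = sum(events == 1)),
                     class = "cox_fit"))
  beta <- numeric(p)
  cur <- .cox_lgh(beta, X, times, events)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    gn <- max(abs(cur$grad))
    if (gn < tol) break
    # separation / boundary drift: coefficient diverging, loglik flat
    if (any(abs(beta) > 15)) break
    if (iter > max_iter) {
      if (gn < 1e-4) break   # loglik converged, gradient at float noise
      stop("Cox fit did not converge in ", max_iter,
           " iterations (gradient max-norm ", format(gn), ")")
    }
    step <- tryCatch(solve(-cur$hess, cur$grad), error = function(e)
      solve(-cur$hess + diag(1e-8, p), cur$grad))
    new_beta <- beta + step
    nxt <- .cox_lgh(new_beta, X, times, events)
    halvings <- 0L
    while ((!is.finite(nxt$ll) || nxt$ll < cur$ll) && halvings < 30) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- .cox_lgh(new_beta, X, times, events)
      halvings <- halvings + 1L
    }
    stalled <- abs(nxt$ll - cur$ll) < 1e-12 * (abs(cur$ll) + 1)
    beta <- new_beta; cur <- nxt
    if (stalled && max(abs(cur$grad)) < 1e-4) break
  }
  separation <- any(abs(beta) > 15)
  se <- sqrt(diag(tryCatch(solve(-cur$hess), error = function(e)
    matrix(NA_real_, p, p))))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  q <- qnorm(0.975)
  structure(list(coef = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 hr = setNames(exp(beta), colnames(X)),
                 ci_lo = setNames(exp(beta - q * se), colnames(X)),
                 ci_hi = setNames(exp(beta + q * se), colnames(X)),
                 z = setNames(z, colnames(X)),
                 p = setNames(pv, colnames(X)),
                 loglik = cur$ll, loglik_null = ll0,
                 iterations = iter, separation = separation,
                 n = length(times), n_events = sum(events == 1)),
            class = "cox_fit")
}

# dummy-code one categorical variable (first level = reference)
.dummy_code <- function(v, name) {
  f <- droplevels(as.factor(v))
  if (nlevels(f) < 2) return(NULL)
  m <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0(name, "=", levels(f)[-1])
  rownames(m) <- NULL
  m
}

.design_for <- function(records, vars) {
  cols <- lapply(vars, function(v) {
    x <- records[[v]]
    if (is.numeric(x)) matrix(x, ncol = 1, dimnames = list(NULL, v))
    else .dummy_code(x, v)
  })
  do.call(cbind, cols[!vapply(cols, is.null, TRUE)])
}

#' Forward stepwise Cox selection gated by univariate significance
#'
#' Candidates are first gated by a univariate test (log-rank across a
#' categorical candidate's categories; univariate Cox Wald test for numeric
#' candidates) at `gate_p`. Gated candidates enter by forward selection on
#' the likelihood-ratio test at `entry_p`, ties broken by the larger
#' likelihood improvement. Records missing a value of a variable are
#' dropped for the models involving it (complete-case per step, counts
#' logged in the path). If nothing passes the gate a null model is returned
#' with a warning.
#'
#' @param records data.frame with `os_months`, `event` and the candidate
#'   columns.
#' @param candidates character vector of candidate column names.
#' @param gate_p univariate inclusion threshold.
#' @param entry_p forward-entry LRT threshold.
#' @return list with `fit` (final [cox_fit()] on complete cases of the
#'   selected variables), `selected`, `gate` (univariate p per candidate)
#'   and `path` (data.table log of each entry step).
#' @export
stepwise_cox <- function(records, candidates, gate_p = 0.05,
                         entry_p = 0.05) {
  dt <- as.data.table(records)
  stopifnot(all(c("os_months", "event") %in% names(dt)),
            all(candidates %in% names(dt)))
  gate <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (v in candidates) {
    ok <- !is.na(dt[[v]]) & !is.na(dt$os_months) & !is.na(dt$event)
    d <- dt[ok]
    gate[v] <- if (is.numeric(dt[[v]])) {
      f <- cox_fit(d$os_months, d$event,
                   matrix(d[[v]], ncol = 1, dimnames = list(NULL, v)))
      f$p[[1]]
    } else {
      if (length(unique(d[[v]])) < 2) 1
      else logrank_test(d$os_months, d$event, d[[v]])$p
    }
  }
  pool <- candidates[gate < gate_p]
  if (!length(pool)) {
    if (length(candidates))
      warning("no candidate passed the univariate gate; returning null model")
    return(list(fit = cox_fit(dt$os_months, dt$event,
                              matrix(numeric(0), nrow(dt), 0)),
                selected = character(), gate = gate, path = data.table()))
  }
  selected <- character()
  path <- list()
  repeat {
    remaining <- setdiff(pool, selected)
    if (!length(remaining)) break
    best <- NULL
    for (v in remaining) {
      vars <- c(selected, v)
      ok <- complete.cases(dt[, c("os_months", "event", vars), with = FALSE])
      d <- dt[ok]
      X1 <- .design_for(d, vars)
      if (is.null(X1)) next
      f1 <- cox_fit(d$os_months, d$event, X1)
      f0 <- if (length(selected)) {
        X0 <- .design_for(d, selected)
        cox_fit(d$os_months, d$event, X0)
      } else cox_fit(d$os_months, d$event, matrix(numeric(0), nrow(d), 0))
      df <- length(f1$coef) - length(f0$coef)
      lrt <- 2 * (f1$loglik - f0$loglik)
      pv <- pchisq(lrt, df = max(df, 1), lower.tail = FALSE)
      cand <- list(var = v, p = pv, lrt = lrt, n = nrow(d), df = df)
      if (is.null(best) || pv < best$p ||
          (pv == best$p && lrt > best$lrt)) best <- cand
    }
    if (is.null(best) || best$p >= entry_p) break
    selected <- c(selected, best$var)
    path[[length(path) + 1L]] <- as.data.table(best)
  }
  ok <- complete.cases(dt[, c("os_months", "event", selected),
                          with = FALSE])
  d <- dt[ok]
  X <- if (length(selected)) .design_for(d, selected)
  else matrix(numeric(0), nrow(d), 0)
  fit <- cox_fit(d$os_months, d$event, X)
  list(fit = fit, selected = selected, gate = gate,
       path = if (length(path)) rbindlist(path) else data.table())
}
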