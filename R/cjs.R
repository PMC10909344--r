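#' Collapse capture histories to per-group sufficient statistics
#'
#' The CJS likelihood conditions on first capture, so never-detected
#' individuals carry no information and are dropped.  The remaining
#' histories are tabulated per infection group into counts over the distinct
#' nonzero detection patterns, with the first and last detection occasion of
#' each pattern precomputed.
#'
#' @param ch A `capture_history` (from [build_capture_histories()] or
#'   [read_capture_histories()]).
#' @return List with `histories` (H x T 0/1 matrix of distinct patterns),
#'   `first`, `last` (occasion indices per pattern), `count_infected`,
#'   `count_uninfected`, `n_bouts`, `n_dropped` (never-detected
#'   individuals).
#' @export
collapse_histories <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  det <- ch$detections
  T <- ncol(det)
  if (T < 2L)
    stop("CJS requires at least two sampling bouts", call. = FALSE)
  ever <- rowSums(det) > 0
  n_dropped <- sum(!ever)
  det <- det[ever, , drop = FALSE]
  grp <- ch$infected[ever]
  key <- as.vector(det %*% 2^(seq_len(T) - 1))
  ukey <- sort(unique(key))
  hist_mat <- t(vapply(ukey,
                       function(k) as.integer(bitwAnd(k %/% 2^(seq_len(T) - 1), 1)),
                       integer(T)))
  idx <- match(key, ukey)
  count_inf <- tabulate(idx[grp], nbins = length(ukey))
  count_uninf <- tabulate(idx[!grp], nbins = length(ukey))
  first <- apply(hist_mat, 1L, function(h) which(h == 1L)[1])
  last <- apply(hist_mat, 1L, function(h) max(which(h == 1L)))
  # per-history counts of detections / misses strictly after first capture
  # up to the last capture: together with `last` these are sufficient for
  # the time-constant likelihood
  n_seen <- integer(nrow(hist_mat))
  for (h in seq_len(nrow(hist_mat))) {
    if (last[h] > first[h])
      n_seen[h] <- sum(hist_mat[h, (first[h] + 1L):last[h]])
  }
  n_miss <- (last - first) - n_seen
  list(histories = hist_mat, first = first, last = last,
       n_seen = n_seen, n_miss = n_miss,
       count_infected = count_inf, count_uninfected = count_uninf,
       n_bouts = T, n_dropped = n_dropped)
}

# log-likelihood of the distinct histories for one group, given phi and the
# group's detection probability p, with analytic gradient.  chi[t] is the
# probability an animal alive at occasion t is never detected afterwards.
cjs_group_loglik <- function(stats, counts, phi, p, gradient = FALSE) {
  T <- stats$n_bouts
  chi <- numeric(T); chi[T] <- 1
  dchi_dphi <- numeric(T); dchi_dp <- numeric(T)
  for (t in (T - 1L):1L) {
    chi[t] <- (1 - phi) + phi * (1 - p) * chi[t + 1L]
    if (gradient) {
      dchi_dphi[t] <- -1 + (1 - p) * chi[t + 1L] +
        phi * (1 - p) * dchi_dphi[t + 1L]
      dchi_dp[t] <- -phi * chi[t + 1L] + phi * (1 - p) * dchi_dp[t + 1L]
    }
  }
  l <- stats$last
  span <- l - stats$first
  ll <- sum(counts * (log(chi[l]) + span * log(phi) +
                        stats$n_seen * log(p) + stats$n_miss * log1p(-p)))
  if (!gradient) return(list(loglik = ll))
  d_phi <- sum(counts * (dchi_dphi[l] / chi[l] + span / phi))
  d_p <- sum(counts * (dchi_dp[l] / chi[l] + stats$n_seen / p -
                         stats$n_miss / (1 - p)))
  list(loglik = ll, d_phi = d_phi, d_p = d_p)
}

#' Negative log-likelihood of the two-group CJS model
#'
#' Model structure: one apparent-survival probability phi shared by both
#' groups and constant over time, and one time-constant detection
#' probability per infection group.  Parameters are on the logit scale so
#' the optimizer works on an unconstrained interior space.
#'
#' @param params Numeric vector `(logit phi, logit p_infected,
#'   logit p_uninfected)`.
#' @param stats Sufficient statistics from [collapse_histories()].
#' @return The negative log-likelihood (a single non-negative number).
#' @export
cjs_negative_log_likelihood <- function(params, stats) {
  phi <- stats::plogis(params[1])
  p_inf <- stats::plogis(params[2])
  p_uninf <- stats::plogis(params[3])
  -(cjs_group_loglik(stats, stats$count_infected, phi, p_inf)$loglik +
      cjs_group_loglik(stats, stats$count_uninfected, phi, p_uninf)$loglik)
}

# analytic gradient of the negative log-likelihood on the logit scale
cjs_negloglik_gradient <- function(params, stats) {
  phi <- stats::plogis(params[1])
  p_inf <- stats::plogis(params[2])
  p_uninf <- stats::plogis(params[3])
  gi <- cjs_group_loglik(stats, stats$count_infected, phi, p_inf,
                         gradient = TRUE)
  gu <- cjs_group_loglik(stats, stats$count_uninfected, phi, p_uninf,
                         gradient = TRUE)
  # chain rule: d logit^{-1}(x)/dx = q(1-q)
  -c((gi$d_phi + gu$d_phi) * phi * (1 - phi),
     gi$d_p * p_inf * (1 - p_inf),
     gu$d_p * p_uninf * (1 - p_uninf))
}

#' Fit the Cormack-Jolly-Seber model with infection-group detection
#'
#' Maximum-likelihood fit of phi(.) p(infection group) by quasi-Newton
#' optimization on the logit scale, starting from all logits zero, with a
#' fixed set of alternative starting points tried when the gradient norm at
#' the optimum exceeds `1e-6`.  With no recapture at all the model is not
#' estimable and the fit is returned unconverged with `NA` estimates rather
#' than raising.
#'
#' Individuals first captured at the final bout contribute a likelihood
#' factor of one; they are counted but carry no information, so
#' `n_histories_used` reports only histories first detected before the last
#' bout.  At five bouts with survival near one, absolute phi and p are only
#' weakly identified, but the between-group difference in p — the bias
#' diagnostic — is identified.
#'
#' @param ch A `capture_history`, or sufficient statistics from
#'   [collapse_histories()].
#' @return A `cjs_fit` object: `phi_hat`, `p_infected`, `p_uninfected`,
#'   `delta_p` (= `p_infected - p_uninfected`), `log_likelihood`,
#'   `converged`, `n_histories_used`.
#' @export
fit_cjs <- function(ch) {
  stats_ <- if (inherits(ch, "capture_history")) collapse_histories(ch) else ch
  counts <- stats_$count_infected + stats_$count_uninfected
  n_det <- rowSums(stats_$histories)
  n_used <- sum(counts[stats_$first < stats_$n_bouts])
  has_recapture <- any(counts > 0 & n_det >= 2)
  has_inf <- sum(stats_$count_infected) > 0
  has_uninf <- sum(stats_$count_uninfected) > 0
  if (!has_recapture) {
    return(new_cjs_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                       FALSE, n_used))
  }
  starts <- list(c(0, 0, 0), c(2, -2, -2), c(-1, 1, 1), c(3, -3, 0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      cjs_optimize(s, stats_),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$converged) {
      best <- fit
      break
    }
  }
  if (is.null(best)) {
    return(new_cjs_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                       FALSE, n_used))
  }
  par <- best$par
  p_inf <- if (has_inf) stats::plogis(par[2]) else NA_real_
  p_uninf <- if (has_uninf) stats::plogis(par[3]) else NA_real_
  new_cjs_fit(stats::plogis(par[1]), p_inf, p_uninf, -best$value,
              best$converged, n_used)
}

# quasi-Newton fit followed by Newton polishing with the analytic gradient;
# logits are kept inside [-20, 20] (a probability saturation far beyond any
# estimable precision) so boundary cases terminate cleanly.
cjs_optimize <- function(start, stats_, logit_cap = 20, tol = 1e-6) {
  fit <- stats::optim(start, cjs_negative_log_likelihood,
                      gr = cjs_negloglik_gradient, stats = stats_,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- pmin(pmax(fit$par, -logit_cap), logit_cap)
  for (it in 1:25) {
    g <- cjs_negloglik_gradient(par, stats_)
    # coordinates pinned at the saturation cap are effectively flat; polish
    # only the free ones so a boundary phi cannot stall the Newton steps
    free <- abs(par) < logit_cap
    if (!any(free) || sqrt(sum(g[free]^2)) < tol / 10) break
    H <- tryCatch(
      stats::optimHess(par, cjs_negative_log_likelihood,
                       gr = cjs_negloglik_gradient, stats = stats_),
      error = function(e) NULL)
    step_free <- if (is.null(H)) NULL else
      tryCatch(solve(H[free, free, drop = FALSE], g[free]),
               error = function(e) NULL)
    if (is.null(step_free)) step_free <- g[free]  # gradient fallback
    step <- numeric(length(par))
    step[free] <- step_free
    new_par <- pmin(pmax(par - step, -logit_cap), logit_cap)
    if (cjs_negative_log_likelihood(new_par, stats_) >
        cjs_negative_log_likelihood(par, stats_) + 1e-12) {
      # damp until the objective stops increasing
      for (d in 1:20) {
        step <- step / 2
        new_par <- pmin(pmax(par - step, -logit_cap), logit_cap)
        if (cjs_negative_log_likelihood(new_par, stats_) <=
            cjs_negative_log_likelihood(par, stats_)) break
      }
    }
    if (max(abs(new_par - par)) < 1e-12) { par <- new_par; break }
    par <- new_par
  }
  g <- cjs_negloglik_gradient(par, stats_)
  # a parameter pinned at the saturation cap has an effectively flat
  # direction; its residual gradient component is not a convergence failure
  free <- abs(par) < logit_cap
  list(par = par, value = cjs_negative_log_likelihood(par, stats_),
       converged = sqrt(sum(g[free]^2)) < tol)
}

new_cjs_fit <- function(phi, p_inf, p_uninf, loglik, converged, n_used) {
  structure(list(
    phi_hat = phi,
    p_infected = p_inf,
    p_uninfected = p_uninf,
    delta_p = p_inf - p_uninf,
    log_likelihood = loglik,
    converged = converged,
    n_histories_used = n_used
  ), class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("Cormack-Jolly-Seber fit (phi(.), p(infection group))\n")
  cat(sprintf("  phi = %.4f   p_infected = %.4f   p_uninfected = %.4f\n",
              x$phi_hat, x$p_infected, x$p_uninfected))
  cat(sprintf("  delta_p = %+.5f   logLik = %.3f   converged: %s (n = %d)\n",
              x$delta_p, x$log_likelihood, x$converged, x$n_histories_used))
  invisible(x)
}

#' Serialize a CJS fit to JSON
#'
#' @param fit A `cjs_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cjs_json <- function(fit, path) {
  stopifnot(inherits(fit, "cjs_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
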