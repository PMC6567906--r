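#' Fit a two-component Gaussian mixture to log ISG scores
#'
#' EM fit of a univariate two-component Gaussian mixture, intended for the
#' bimodal log10 ISG score distribution. The first restart is initialised
#' from a 2-means split of the data; subsequent restarts draw random
#' component centres. The best converged restart by log-likelihood wins.
#' Components are relabelled so component 1 is the low-mean (IFN-low) and
#' component 2 the high-mean (IFN-high) component.
#'
#' Component standard deviations are floored at `sd_floor`; a restart is
#' discarded as degenerate when a component retains fewer than two expected
#' observations (a component collapsed onto a point). If every restart is
#' degenerate the fit errors.
#'
#' @param log_scores Numeric vector (>= 10 finite values) of log10 ISG
#'   scores. A zero or negative score must be handled upstream; `NA` or
#'   non-finite values are an error.
#' @param n_restarts Number of EM restarts (default 10).
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param seed Optional integer seed for reproducible restarts.
#' @param sd_floor Lower bound for component standard deviations
#'   (default 1e-4).
#' @return Object of class `ifn_mixture`: list with `weights`, `means`,
#'   `sds` (each length 2, low then high), `log_likelihood`, `n_iterations`,
#'   `converged`, `posterior` (n x 2 matrix, column 2 = IFN-high),
#'   `loglik_trace` and the input `data`.
#' @export
fit_mixture_em <- function(log_scores, n_restarts = 10, tol = 1e-8,
                           max_iter = 500, seed = NULL, sd_floor = 1e-4) {
  if (any(!is.finite(log_scores))) {
    stop("log scores must all be finite (log of a zero score?)",
         call. = FALSE)
  }
  n <- length(log_scores)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  inits <- vector("list", n_restarts)
  km <- stats::kmeans(log_scores, centers = 2, nstart = 5)
  inits[[1]] <- list(
    mu = as.numeric(km$centers),
    sigma = vapply(1:2, function(k) {
      s <- stats::sd(log_scores[km$cluster == k])
      if (!is.finite(s) || s < sd_floor) max(stats::sd(log_scores) / 10, sd_floor) else s
    }, numeric(1)),
    w = as.numeric(table(factor(km$cluster, levels = 1:2))) / n
  )
  if (n_restarts > 1) {
    for (r in 2:n_restarts) {
      mu <- sample(log_scores, 2)
      inits[[r]] <- list(
        mu = mu,
        sigma = rep(max(stats::sd(log_scores), sd_floor), 2),
        w = c(0.5, 0.5)
      )
    }
  }

  best <- NULL
  for (init in inits) {
    fit <- em_once(log_scores, init, tol, max_iter, sd_floor)
    if (fit$degenerate) next
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts collapsed to degenerate solutions", call. = FALSE)
  }

  ord <- order(best$mu)
  structure(
    list(
      weights = best$w[ord],
      means = best$mu[ord],
      sds = best$sigma[ord],
      log_likelihood = best$log_likelihood,
      n_iterations = best$n_iterations,
      converged = best$converged,
      posterior = best$posterior[, ord, drop = FALSE],
      loglik_trace = best$trace,
      data = log_scores
    ),
    class = "ifn_mixture"
  )
}

# one EM run; responsibilities computed on the log scale for stability
em_once <- function(x, init, tol, max_iter, sd_floor) {
  n <- length(x)
  mu <- init$mu; sigma <- pmax(init$sigma, sd_floor); w <- init$w
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  post <- matrix(0.5, n, 2)
  repeat {
    iter <- iter + 1
    logd <- cbind(
      log(w[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE),
      log(w[2]) + stats::dnorm(x, mu[2], sigma[2], log = TRUE)
    )
    m <- pmax(logd[, 1], logd[, 2])
    lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m))
    ll <- sum(lse)
    trace <- c(trace, ll)
    post <- exp(logd - lse)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    nk <- colSums(post)
    if (any(nk < 2)) {
      return(list(degenerate = TRUE))
    }
    w <- nk / n
    mu <- colSums(post * x) / nk
    sigma <- sqrt(pmax(
      colSums(post * (outer(x, mu, "-"))^2) / nk, sd_floor^2
    ))
  }
  nk <- colSums(post)
  list(
    degenerate = any(nk < 2), w = w, mu = mu, sigma = sigma,
    log_likelihood = trace[length(trace)], n_iterations = iter,
    converged = converged, posterior = post, trace = trace
  )
}

#' @export
print.ifn_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture on log10 ISG scores (n = ",
      length(x$data), ")\n", sep = "")
  cat(sprintf("  IFN-low : weight %.3f, mean %.3f, sd %.3f\n",
              x$weights[1], x$means[1], x$sds[1]))
  cat(sprintf("  IFN-high: weight %.3f, mean %.3f, sd %.3f\n",
              x$weights[2], x$means[2], x$sds[2]))
  cat(sprintf("  logLik %.3f after %d iterations (%s)\n", x$log_likelihood,
              x$n_iterations, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @rdname fit_mixture_em
#' @param x,object An `ifn_mixture` fit.
#' @param ... Unused.
#' @export
tidy.ifn_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("IFN-low", "IFN-high"),
    weight = x$weights, mean = x$means, sd = x$sds
  )
}

#' @rdname fit_mixture_em
#' @export
glance.ifn_mixture <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood, n_iterations = x$n_iterations,
    converged = x$converged, n = length(x$data)
  )
}

#' Classify samples from a fitted mixture
#'
#' A sample is IFN-high when its posterior probability of the high
#' component strictly exceeds `cutoff` (default 0.5); a posterior exactly
#' at the cutoff is IFN-low.
#'
#' @param fit An `ifn_mixture` from [fit_mixture_em()].
#' @param cutoff Posterior probability cutoff (default 0.5).
#' @return Character vector (`"IFN-high"` / `"IFN-low"`), one per
#'   observation in the fit.
#' @export
classify_mixture <- function(fit, cutoff = 0.5) {
  stopifnot(inherits(fit, "ifn_mixture"))
  if (!fit$converged) {
    stop("mixture fit did not converge; refusing to classify", call. = FALSE)
  }
  ifelse(fit$posterior[, 2] > cutoff, "IFN-high", "IFN-low")
}

#' Concordance between threshold and mixture classifications
#'
#' Cross-tabulates the threshold rule (ISG-positive / ISG-negative) against
#' the mixture classification (IFN-high / IFN-low) over the same samples
#' and lists the discordant sample ids.
#'
#' @param threshold_calls Named logical vector (`TRUE` = ISG-positive),
#'   names are sample ids.
#' @param mixture_calls Named character vector (`"IFN-high"` / `"IFN-low"`)
#'   over the same sample ids.
#' @return Object of class `concordance_table`: list with `table` (2 x 2
#'   counts), `discordant` (tibble `sample_id`, `threshold_call`,
#'   `mixture_call`) and `n`.
#' @export
concordance <- function(threshold_calls, mixture_calls) {
  if (is.null(names(threshold_calls)) || is.null(names(mixture_calls)) ||
      !setequal(names(threshold_calls), names(mixture_calls))) {
    stop("threshold and mixture calls must be named over the same samples",
         call. = FALSE)
  }
  mixture_calls <- mixture_calls[names(threshold_calls)]
  thr <- factor(ifelse(threshold_calls, "ISG-positive", "ISG-negative"),
                levels = c("ISG-negative", "ISG-positive"))
  mix <- factor(mixture_calls, levels = c("IFN-low", "IFN-high"))
  tab <- table(threshold = thr, mixture = mix)
  disc <- tibble::tibble(
    sample_id = names(threshold_calls),
    threshold_call = as.character(thr),
    mixture_call = as.character(mix)
  ) |>
    dplyr::filter(
      (.data$threshold_call == "ISG-positive") !=
        (.data$mixture_call == "IFN-high")
    )
  structure(
    list(table = tab, discordant = disc, n = length(threshold_calls)),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  print(x$table)
  cat(nrow(x$discordant), "discordant of", x$n, "samples\n")
  invisible(x)
}
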