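#' Fit a univariate Gaussian mixture to eigenvector coefficients
#'
#' Expectation-maximization fit of a k-component Gaussian mixture to pooled
#' per-bin eigenvector (EV) coefficients.  The genome-wide EV distribution
#' of lymphoid Hi-C maps is tri-modal — fully active (A), fully inactive (B)
#' and an intermediate population — and the k = 3 fit is the basis of the
#' A/I/B compartment thresholds (see [mixture_intersections()]).
#'
#' Initialization is deterministic: component means at the
#' 1/(k+1), ..., k/(k+1) quantiles of the data, equal weights, pooled
#' standard deviation.  If a component degenerates (vanishing variance or
#' weight) the fit restarts from a jittered initialization, up to 5 times
#' (jitter drawn from the seeded RNG), then errors.
#'
#' @param values numeric vector of EV coefficients (NAs dropped); at least
#'   10 k finite values required.
#' @param k number of components.
#' @param seed integer seed for degeneracy restarts (the base fit itself is
#'   deterministic).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return object of class `gaussian_mixture`: list with `components`
#'   (data.frame `weight`, `mean`, `sd`, sorted by mean), `k`,
#'   `log_likelihood`, `bic` (p ln n - 2 lnL with p = 3k - 1), `n`,
#'   `iterations`, `converged`, and the fitted `data`.
#' @seealso [bic_scan()], [mixture_intersections()], [call_compartments()]
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, -0.6, 0.1), rnorm(300, 0.6, 0.1))
#' fit <- fit_gaussian_mixture(x, k = 2)
#' coef(fit)
#' @export
fit_gaussian_mixture <- function(values, k = 3L, seed = 1L, tol = 1e-8,
                                 max_iter = 1000L) {
  x <- values[is.finite(values)]
  n <- length(x)
  k <- as.integer(k)
  if (n < 10L * k)
    stop(sprintf("need at least %d finite values for k = %d, got %d",
                 10L * k, k, n))
  if (k == 1L) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(.new_mixture(data.frame(weight = 1, mean = mu, sd = sigma),
                        k, ll, n, 0L, TRUE, x))
  }
  if (stats::sd(x) == 0)
    stop("EM degenerate: data has zero variance")
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  init_mu <- as.numeric(stats::quantile(x, (1:k) / (k + 1)))
  init_sd <- rep(stats::sd(x), k)
  for (attempt in 0:5) {
    mu <- if (attempt == 0) init_mu
          else sort(init_mu + stats::rnorm(k, 0, 0.1 * stats::sd(x)))
    fit <- .em_run(x, rep(1 / k, k), mu, init_sd, tol, max_iter)
    if (!is.null(fit))
      return(.new_mixture(fit$components, k, fit$ll, n, fit$iter,
                          fit$converged, x))
  }
  stop("EM degenerate after 5 restarts (a component collapsed)")
}

.em_run <- function(x, w, mu, sigma, tol, max_iter) {
  n <- length(x)
  k <- length(w)
  weighted_logdens <- function(w, mu, sigma) {
    logd <- matrix(0, n, k)
    for (j in seq_len(k))
      logd[, j] <- log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE)
    logd
  }
  logsumexp_rows <- function(logd) {
    mx <- logd[, 1]
    for (j in 2:k) mx <- pmax(mx, logd[, j])
    mx + log(rowSums(exp(logd - mx)))
  }
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    logd <- weighted_logdens(w, mu, sigma)
    lse <- logsumexp_rows(logd)
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8 * n)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * outer(x, mu, `-`)^2) / nk)
    if (any(sigma < 1e-8)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ll <- sum(logsumexp_rows(weighted_logdens(w, mu, sigma)))
  ord <- order(mu)
  list(components = data.frame(weight = w[ord], mean = mu[ord],
                               sd = sigma[ord]),
       ll = ll, iter = iter, converged = converged)
}

.new_mixture <- function(components, k, ll, n, iter, converged, x) {
  p <- 3L * k - 1L
  structure(list(components = components, k = k, log_likelihood = ll,
                 bic = p * log(n) - 2 * ll, n = n, iterations = iter,
                 converged = converged, data = x),
            class = "gaussian_mixture")
}

# Seeded RNG scope that restores the caller's generator state on exit.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' @export
print.gaussian_mixture <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian mixture, k = %d (n = %d, BIC = %.2f%s)\n",
              x$k, x$n, x$bic,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$components, digits))
  invisible(x)
}

#' @export
summary.gaussian_mixture <- function(object, ...) {
  print(object)
  cat(sprintf("log-likelihood %.4f in %d EM iterations\n",
              object$log_likelihood, object$iterations))
  if (object$k == 3) {
    th <- mixture_intersections(object)
    cat(sprintf("intersection thresholds: IV1 = %.4f, IV2 = %.4f\n",
                th$iv1, th$iv2))
  }
  invisible(object)
}

#' @export
coef.gaussian_mixture <- function(object, ...) {
  m <- as.matrix(object$components)
  rownames(m) <- paste0("comp", seq_len(object$k))
  m
}

#' @export
logLik.gaussian_mixture <- function(object, ...) {
  structure(object$log_likelihood, df = 3L * object$k - 1L,
            nobs = object$n, class = "logLik")
}

#' Posterior component membership of a fitted mixture
#' @param object a `gaussian_mixture`.
#' @param newdata values to classify (defaults to the fitted data).
#' @param type `"posterior"` for the n x k responsibility matrix,
#'   `"class"` for the maximum-posterior component index (by ascending
#'   component mean).
#' @param ... unused.
#' @return matrix or integer vector.
#' @export
predict.gaussian_mixture <- function(object, newdata = NULL,
                                     type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else as.numeric(newdata)
  co <- object$components
  logd <- vapply(seq_len(object$k), function(j)
    log(co$weight[j]) + stats::dnorm(x, co$mean[j], co$sd[j], log = TRUE),
    numeric(length(x)))
  logd <- matrix(logd, nrow = length(x))
  mx <- apply(logd, 1, max)
  post <- exp(logd - (mx + log(rowSums(exp(logd - mx)))))
  if (type == "posterior") post else max.col(post)
}

#' Simulate draws from a fitted mixture
#' @param object a `gaussian_mixture`.
#' @param nsim number of draws.
#' @param seed optional seed (caller RNG state restored).
#' @param ... unused.
#' @return numeric vector of length `nsim`.
#' @export
simulate.gaussian_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    rng <- .local_rng(seed)
    on.exit(rng$restore())
  }
  co <- object$components
  comp <- sample.int(object$k, nsim, replace = TRUE, prob = co$weight)
  stats::rnorm(nsim, co$mean[comp], co$sd[comp])
}

#' @export
plot.gaussian_mixture <- function(x, breaks = 60, ...) {
  graphics::hist(x$data, breaks = breaks, freq = FALSE,
                 main = sprintf("Gaussian mixture, k = %d", x$k),
                 xlab = "eigenvector coefficient", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 512)
  co <- x$components
  for (j in seq_len(x$k))
    graphics::lines(xs, co$weight[j] * stats::dnorm(xs, co$mean[j], co$sd[j]),
                    col = j + 1)
  graphics::lines(xs, rowSums(vapply(seq_len(x$k), function(j)
    co$weight[j] * stats::dnorm(xs, co$mean[j], co$sd[j]),
    numeric(length(xs)))), lwd = 2)
  invisible(x)
}

#' BIC scan over mixture sizes
#'
#' Fits mixtures for each k in `k_range` and selects the k minimizing
#' BIC = p ln(n) - 2 lnL with p = 3k - 1 free parameters; ties break toward
#' smaller k.  Failed fits are skipped with a warning.
#'
#' @inheritParams fit_gaussian_mixture
#' @param k_range integer vector of component counts (default 1:10).
#' @return list with `table` (data.frame `k`, `bic`), `k` (selected),
#'   `models` (fitted `gaussian_mixture` objects, named by k).
#' @export
bic_scan <- function(values, k_range = 1:10, seed = 1L, tol = 1e-8,
                     max_iter = 1000L) {
  fits <- list()
  for (k in k_range) {
    fit <- tryCatch(fit_gaussian_mixture(values, k, seed, tol, max_iter),
                    error = function(e) {
                      warning(sprintf("k = %d skipped: %s", k,
                                      conditionMessage(e)))
                      NULL
                    })
    if (!is.null(fit)) fits[[as.character(k)]] <- fit
  }
  if (length(fits) == 0) stop("all mixture fits failed")
  tab <- data.frame(k = as.integer(names(fits)),
                    bic = vapply(fits, `[[`, 0, "bic"))
  rownames(tab) <- NULL
  sel <- tab$k[order(tab$bic, tab$k)][1]
  list(table = tab, k = sel, models = fits)
}

#' Compartment thresholds from density intersections
#'
#' For a three-component mixture sorted by mean, IV2 is the point in
#' (mu1, mu2) where the weighted densities of the low (B) and middle (I)
#' components are equal, and IV1 the analogous point in (mu2, mu3) for the
#' middle and high (A) components.  Equating two weighted Gaussian log
#' densities gives a quadratic in x; the root inside the open interval
#' between the two means is taken.  If no root falls in the interval the
#' sd-weighted midpoint (sd_b * mu_a + sd_a * mu_b) / (sd_a + sd_b) is used
#' with a warning.
#'
#' @param model a `gaussian_mixture` with k = 3.
#' @return object of class `compartment_thresholds`: list(iv1, iv2, source).
#' @export
mixture_intersections <- function(model) {
  if (!inherits(model, "gaussian_mixture") || model$k != 3L)
    stop("a k = 3 gaussian_mixture is required")
  co <- model$components
  iv2 <- .pair_intersection(co$weight[1], co$mean[1], co$sd[1],
                            co$weight[2], co$mean[2], co$sd[2])
  iv1 <- .pair_intersection(co$weight[2], co$mean[2], co$sd[2],
                            co$weight[3], co$mean[3], co$sd[3])
  compartment_thresholds(iv1, iv2, source = "model")
}

# Root of w_a N(x; mu_a, s_a) = w_b N(x; mu_b, s_b) inside (mu_a, mu_b).
.pair_intersection <- function(wa, mua, sa, wb, mub, sb) {
  fallback <- (sb * mua + sa * mub) / (sa + sb)
  if (mua == mub) return(fallback)
  lo <- min(mua, mub); hi <- max(mua, mub)
  # log equality: (x-mua)^2/sa^2 - (x-mub)^2/sb^2 = 2 log(wa sb / (wb sa))
  a2 <- 1 / sa^2 - 1 / sb^2
  a1 <- -2 * mua / sa^2 + 2 * mub / sb^2
  a0 <- mua^2 / sa^2 - mub^2 / sb^2 - 2 * log(wa * sb / (wb * sa))
  roots <- if (abs(a2) < 1e-14) {
    if (abs(a1) < 1e-14) numeric() else -a0 / a1
  } else {
    disc <- a1^2 - 4 * a2 * a0
    if (disc < 0) numeric()
    else (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  }
  roots <- roots[roots > lo & roots < hi]
  if (length(roots) == 0) {
    warning("no density intersection between component means; using sd-weighted midpoint")
    return(fallback)
  }
  roots[1]
}

#' Compartment-call thresholds
#' @param iv1 A/I boundary (upper intersection value).
#' @param iv2 I/B boundary (lower intersection value); must be < `iv1`.
#' @param source provenance label (e.g. "model", "consensus").
#' @return object of class `compartment_thresholds`.
#' @export
compartment_thresholds <- function(iv1, iv2, source = "manual") {
  if (!is.finite(iv1) || !is.finite(iv2)) stop("thresholds must be finite")
  if (iv2 >= iv1) stop("iv2 must be below iv1")
  if (iv1 >= 1 || iv2 <= -1)
    warning("thresholds outside (-1, 1): EV coefficients are scaled to [-1, 1]")
  structure(list(iv1 = iv1, iv2 = iv2, source = source),
            class = "compartment_thresholds")
}

#' @export
print.compartment_thresholds <- function(x, ...) {
  cat(sprintf("compartment thresholds (%s): IV1 = %.4f (A/I), IV2 = %.4f (I/B)\n",
              x$source, x$iv1, x$iv2))
  invisible(x)
}

#' Consensus thresholds across replicate mixture fits
#'
#' Averages the per-replicate intersection values; the mean IV1 and IV2
#' across all replicates of a reference data set serve as the standard
#' calling thresholds.
#'
#' @param models non-empty list of k = 3 `gaussian_mixture` fits, or of
#'   `compartment_thresholds`.
#' @return a [compartment_thresholds()] with source "consensus".
#' @export
consensus_thresholds <- function(models) {
  if (length(models) == 0) stop("empty model list")
  ths <- lapply(models, function(m)
    if (inherits(m, "compartment_thresholds")) m else mixture_intersections(m))
  compartment_thresholds(mean(vapply(ths, `[[`, 0, "iv1")),
                         mean(vapply(ths, `[[`, 0, "iv2")),
                         source = "consensus")
}
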