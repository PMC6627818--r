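#' Fit a univariate normal mixture by expectation-maximization
#'
#' Maximum-likelihood fit of a G-component Gaussian mixture to a numeric
#' vector, with either a shared variance across components (`model = "E"`) or
#' component-specific variances (`model = "V"`). Initialization assigns
#' observations to components by splitting at sample quantiles; `n_restarts`
#' additional starts jitter the split points, and the best log-likelihood
#' wins. Restarts use an internal RNG stream (seeded, caller's RNG state
#' untouched), so fits are reproducible.
#'
#' @param x Numeric observations.
#' @param G Number of components (>= 1).
#' @param model `"E"` (equal variance) or `"V"` (unequal variance).
#' @param n_restarts Number of jittered restarts beyond the plain quantile
#'   start.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed Internal seed for restart jitter.
#' @return List with `mean`, `sd`, `weight` (each length G, sorted by mean),
#'   `loglik`, `bic` (2*loglik - npar*log(n); larger is better), `G`, `model`,
#'   `n`, `converged`.
#' @export
fit_normal_mixture <- function(x, G, model = c("V", "E"), n_restarts = 5,
                               max_iter = 500, tol = 1e-8, seed = 1) {
  model <- match.arg(model)
  x <- as.numeric(x)
  n <- length(x)
  if (n < G) stop("need at least G observations")
  sx <- stats::sd(x)
  if (G == 1 || sx == 0) {
    mu <- mean(x); sdv <- max(sx, 0)
    ll <- if (sdv == 0) Inf else sum(stats::dnorm(x, mu, sdv, log = TRUE))
    npar <- 2
    return(list(mean = mu, sd = sdv, weight = 1, loglik = ll,
                bic = if (is.finite(ll)) 2 * ll - npar * log(n) else Inf,
                G = 1L, model = model, n = n, converged = TRUE))
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  sd_floor <- max(1e-6 * sx, 1e-12)
  starts <- c(list(seq(0, 1, length.out = G + 1)),
              lapply(seq_len(n_restarts), function(i) {
                p <- sort(stats::runif(G - 1, 0.05, 0.95))
                c(0, p, 1)
              }))
  best <- NULL
  for (qs in starts) {
    init <- mixture_init(x, qs, model, sd_floor)
    fit <- em_iterate(x, init, model, max_iter, tol, sd_floor)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik))
      best <- fit
  }
  ord <- order(best$mean)
  npar <- (G - 1) + G + if (model == "E") 1 else G
  # a component collapsed onto the variance floor (or onto < 2 effective
  # observations) means the likelihood is diverging, not converging: such a
  # fit is singular and must not compete on BIC
  singular <- any(best$sd <= sd_floor * 1.01) || any(best$weight * n < 2)
  list(mean = best$mean[ord], sd = best$sd[ord], weight = best$weight[ord],
       loglik = best$loglik,
       bic = if (singular) -Inf else 2 * best$loglik - npar * log(n),
       G = as.integer(G), model = model, n = n, converged = best$converged,
       singular = singular)
}

mixture_init <- function(x, qprobs, model, sd_floor) {
  G <- length(qprobs) - 1
  br <- stats::quantile(x, qprobs, names = FALSE)
  br[1] <- -Inf; br[G + 1] <- Inf
  grp <- cut(x, unique(br), labels = FALSE, include.lowest = TRUE)
  # collapse of duplicate breaks can drop groups; re-seed empties from spread
  mu <- tapply(x, grp, mean)
  mu <- as.numeric(mu)
  if (length(mu) < G)
    mu <- seq(min(x), max(x), length.out = G)
  sdv <- rep(max(stats::sd(x) / G, sd_floor), G)
  list(mean = mu, sd = sdv, weight = rep(1 / G, G))
}

em_iterate <- function(x, par, model, max_iter, tol, sd_floor) {
  n <- length(x); G <- length(par$mean)
  ll_old <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step, in log space for stability
    lc <- vapply(seq_len(G), function(k)
      log(par$weight[k]) + stats::dnorm(x, par$mean[k], par$sd[k], log = TRUE),
      numeric(n))
    m <- apply(lc, 1, max)
    ls <- m + log(rowSums(exp(lc - m)))
    ll <- sum(ls)
    z <- exp(lc - ls)
    # M step
    nk <- colSums(z)
    nk <- pmax(nk, 1e-10)
    par$weight <- nk / n
    par$mean <- colSums(z * x) / nk
    if (model == "E") {
      s2 <- sum(z * (outer(x, par$mean, "-")^2)) / n
      par$sd <- rep(max(sqrt(s2), sd_floor), G)
    } else {
      s2 <- colSums(z * (outer(x, par$mean, "-")^2)) / nk
      par$sd <- pmax(sqrt(s2), sd_floor)
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  list(mean = par$mean, sd = par$sd, weight = par$weight, loglik = ll_old,
       converged = converged)
}

#' Estimate standard metabolic rate as the lowest mixture component
#'
#' Fits univariate normal mixtures with 1 to `G_max` components (both equal-
#' and unequal-variance families) to the mass-standardized MO2 values recorded
#' at one temperature, selects the fit by BIC (ties favour fewer components),
#' and returns the mean of the lowest-mean component as the SMR. Components
#' with mixing weight below `min_weight` are not eligible to be the SMR
#' component, which protects the estimate from spurious one-observation
#' clusters in the left tail.
#'
#' The rationale: during a trial the fish's MO2 is a mixture of quiescent
#' readings at SMR and elevated readings from handling stress and spontaneous
#' activity; the lowest normal component captures the quiescent mode.
#'
#' @param x QC-passed mass-standardized MO2 values at one temperature,
#'   mg O2 kg^-1 h^-1.
#' @param G_max Maximum number of mixture components considered.
#' @param min_weight Minimum mixing weight for the SMR component.
#' @param min_obs Minimum number of observations required.
#' @param temperature Optional temperature label used in error messages.
#' @param seed Internal seed for EM restarts.
#' @return An object of class `smr_fit`: `smr`, `G`, `model`, `components`
#'   (data frame mean/sd/weight), `bic` (all candidates), `loglik`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(140, 50, 2), rnorm(60, 90, 5))
#' fit <- estimate_smr(x)
#' fit$smr   # ~50
#' @export
estimate_smr <- function(x, G_max = 4, min_weight = 0.05, min_obs = 10,
                         temperature = NULL, seed = 1) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < min_obs)
    stop(sprintf(
      "too few MO2 observations (%d < %d)%s to estimate SMR", length(x),
      min_obs,
      if (is.null(temperature)) "" else sprintf(" at %g C", temperature)))
  cand <- list()
  for (G in seq_len(G_max)) {
    for (model in if (G == 1) "E" else c("E", "V")) {
      key <- sprintf("%s%d", model, G)
      cand[[key]] <- tryCatch(
        fit_normal_mixture(x, G, model, seed = seed),
        error = function(e) NULL)
    }
  }
  cand <- Filter(function(f) !is.null(f) && is.finite(f$bic), cand)
  if (length(cand) == 0) {   # degenerate data (e.g. all identical)
    best <- fit_normal_mixture(x, 1)
  } else {
    bics <- vapply(cand, `[[`, numeric(1), "bic")
    gs <- vapply(cand, `[[`, integer(1), "G")
    ord <- order(-bics, gs)   # ties favour fewer components
    best <- cand[[ord[1]]]
  }
  eligible <- best$weight >= min_weight
  if (!any(eligible)) eligible <- best$weight == max(best$weight)
  smr <- min(best$mean[eligible])
  structure(list(
    smr = smr, G = best$G, model = best$model,
    components = data.frame(mean = best$mean, sd = best$sd,
                            weight = best$weight),
    bic = if (length(cand)) vapply(cand, `[[`, numeric(1), "bic") else
      c(E1 = best$bic),
    loglik = best$loglik, n = best$n, min_weight = min_weight,
    temperature = temperature), class = "smr_fit")
}

#' @export
print.smr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<smr_fit> SMR = %.*g mg O2/kg/h (n = %d%s)\n", digits, x$smr,
              x$n,
              if (is.null(x$temperature)) "" else
                sprintf(", %g C", x$temperature)))
  cat(sprintf("  selected mixture: %d component(s), %s-variance, BIC %.2f\n",
              x$G, if (x$model == "E") "equal" else "unequal", max(x$bic)))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("    comp %d: mean %.*g, sd %.*g, weight %.3f\n", i, digits,
                comp$mean[i], digits, comp$sd[i], comp$weight[i]))
  invisible(x)
}

#' @export
coef.smr_fit <- function(object, ...) {
  c(smr = object$smr)
}

#' @export
summary.smr_fit <- function(object, ...) {
  print(object)
  cat("  BIC over candidate mixtures:\n")
  print(round(sort(object$bic, decreasing = TRUE), 2))
  invisible(object)
}

#' @export
logLik.smr_fit <- function(object, ...) {
  structure(object$loglik, df = NA, class = "logLik")
}

#' Low-quantile SMR estimate
#'
#' Simple quantile-based SMR estimator: the q-th quantile of the MO2 values.
#' Used as an independent sanity check on the mixture estimator, not as the
#' primary method.
#'
#' @param x MO2 values.
#' @param q Quantile in (0, 0.5].
#' @return The q-th sample quantile.
#' @export
smr_quantile <- function(x, q = 0.2) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) == 0) stop("no observations")
  if (q <= 0 || q > 0.5) stop("q must be in (0, 0.5]")
  unname(stats::quantile(x, q))
}
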