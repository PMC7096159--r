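# --- Bell-Evans mixture fitting by EM --------------------------------------

# weighted negative log-likelihood of one Bell-Evans component,
# parameterized as theta = (log k0, log x_dagger)
component_nll <- function(theta, forces, w, loading_rate, kBT) {
  k0 <- exp(theta[1]); x <- exp(theta[2])
  if (!is.finite(k0) || !is.finite(x) || k0 <= 0 || x <= 0) return(1e12)
  b <- x / kBT
  ll <- log(k0) - log(loading_rate) + b * forces +
    (k0 / (b * loading_rate)) * (1 - exp(b * forces))
  v <- -sum(w * ll)
  if (!is.finite(v)) 1e12 else v
}

# moment-style initial guess for one component from a force subsample:
# the Bell-Evans distribution has spread ~ (kBT/x) * pi/sqrt(6) and mode
# at (kBT/x) log(x r / k0 kBT)
init_component <- function(forces, loading_rate, kBT) {
  s <- max(sd(forces), 1)
  m <- max(median(forces), 1)
  x <- kBT * (pi / sqrt(6)) / s
  x <- min(max(x, 1e-3), 10)
  k0 <- (x * loading_rate / kBT) * exp(-m * x / kBT)
  k0 <- min(max(k0, 1e-300), 1e6)
  c(log(k0), log(x))
}

em_bell_evans <- function(forces, loading_rate, n_components, kBT,
                          theta0, w0, max_iter = 200, tol = 1e-8,
                          fixed_components = FALSE) {
  n <- length(forces)
  theta <- theta0
  w <- w0
  loglik_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step in log space
    lp <- vapply(seq_len(n_components), function(c) {
      k0 <- exp(theta[[c]][1]); x <- exp(theta[[c]][2]); b <- x / kBT
      log(w[c]) + log(k0) - log(loading_rate) + b * forces +
        (k0 / (b * loading_rate)) * (1 - exp(b * forces))
    }, numeric(n))
    lp <- matrix(lp, nrow = n)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    loglik <- sum(lse)
    resp <- exp(lp - lse)
    # M-step
    w <- pmax(colMeans(resp), 1e-12)
    w <- w / sum(w)
    if (!fixed_components) {
      for (c in seq_len(n_components)) {
        opt <- optim(theta[[c]], component_nll, forces = forces,
                     w = resp[, c], loading_rate = loading_rate, kBT = kBT,
                     method = "Nelder-Mead",
                     control = list(maxit = 60, reltol = 1e-10))
        theta[[c]] <- opt$par
      }
    }
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) < tol * (abs(loglik) + 1)) {
      converged <- TRUE
      break
    }
    loglik_old <- loglik
  }
  list(theta = theta, weights = w, log_likelihood = loglik,
       converged = converged, n_iter = iter)
}

new_mixture_fit <- function(em, loading_rate, kBT, n, note = NULL) {
  comp <- map(seq_along(em$theta), function(c) {
    k0 <- exp(em$theta[[c]][1]); x <- exp(em$theta[[c]][2])
    tibble(k0 = k0, x_dagger = x, kBT = kBT, weight = em$weights[c],
           modal_force = as.numeric(modal_force(
             bell_evans_params(k0, x, kBT), loading_rate)))
  })
  comp <- arrange(bind_rows(comp), .data$modal_force)
  k <- nrow(comp)
  structure(list(components = comp,
                 n_components = k,
                 loading_rate = loading_rate,
                 log_likelihood = em$log_likelihood,
                 bic = (3 * k - 1) * log(n) - 2 * em$log_likelihood,
                 n = n,
                 converged = em$converged,
                 degenerate = isTRUE(note == "degenerate")),
            class = "pg_mixture_fit")
}

#' Fit a Bell-Evans mixture to rupture forces
#'
#' Maximum-likelihood fit of a 1- to 3-component mixture of Bell-Evans
#' rupture-force distributions (constant loading rate) to raw forces, by
#' expectation-maximization with multiple quantile-split starts. Fitting
#' is bin-free: histograms are only a visualization. When `n_components`
#' is `NULL` the order (1, 2 or 3) is selected by BIC.
#'
#' @param forces Rupture forces, pN (>= 50 values).
#' @param loading_rate Loading rate at which the forces were recorded,
#'   pN/s; per-event rates are typically collapsed to their median.
#' @param n_components 1, 2 or 3, or `NULL` for BIC selection.
#' @param n_starts Number of EM multi-starts.
#' @param seed Integer seed (start randomization), for determinism.
#' @param kBT Thermal energy, pN nm.
#' @param max_iter,tol EM stopping rule.
#' @return Object of class `pg_mixture_fit`; see [tidy.pg_mixture_fit()].
#' @examples
#' f <- sample_rupture_forces(bell_evans_params(1e-3, 0.4), 1e4, 200, seed = 2)
#' fit_mixture(f, 1e4, n_components = 1)
#' @export
fit_mixture <- function(forces, loading_rate, n_components = NULL,
                        n_starts = 10, seed = 1, kBT = KBT_300K,
                        max_iter = 200, tol = 1e-8) {
  forces <- forces[is.finite(forces)]
  pg_assert(length(forces) >= 50, "need at least 50 rupture forces")
  pg_assert(length(loading_rate) == 1 && loading_rate > 0,
            "loading_rate must be a single positive number")
  if (sd(forces) < 1e-9) {
    em <- list(theta = list(init_component(forces + c(-1, 1), loading_rate,
                                           kBT)),
               weights = 1, log_likelihood = NA_real_, converged = FALSE)
    return(new_mixture_fit(em, loading_rate, kBT, length(forces),
                           note = "degenerate"))
  }
  if (is.null(n_components)) {
    fits <- map(1:3, function(k)
      fit_mixture(forces, loading_rate, n_components = k,
                  n_starts = n_starts, seed = seed, kBT = kBT,
                  max_iter = max_iter, tol = tol))
    return(fits[[which.min(map_dbl(fits, function(f) f$bic))]])
  }
  pg_assert(n_components %in% 1:3, "n_components must be 1, 2 or 3")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    # quantile split of the sorted forces into n_components groups, with
    # jittered boundaries after the first start
    q <- seq(0, 1, length.out = n_components + 1)
    if (s > 1) {
      q[-c(1, length(q))] <- pmin(pmax(
        q[-c(1, length(q))] + runif(n_components - 1, -0.15, 0.15),
        0.05), 0.95)
    }
    cuts <- quantile(forces, q)
    grp <- cut(forces, unique(c(-Inf, cuts[-c(1, length(cuts))], Inf)),
               labels = FALSE)
    theta0 <- map(seq_len(n_components), function(c) {
      g <- forces[grp == min(c, max(grp))]
      if (length(g) < 5) g <- forces
      init_component(g, loading_rate, kBT)
    })
    w0 <- rep(1 / n_components, n_components)
    em <- em_bell_evans(forces, loading_rate, n_components, kBT,
                        theta0, w0, max_iter = max_iter, tol = tol)
    if (is.null(best) || em$log_likelihood > best$log_likelihood) best <- em
  }
  new_mixture_fit(best, loading_rate, kBT, length(forces))
}

#' @export
print.pg_mixture_fit <- function(x, ...) {
  cat(sprintf("<pg_mixture_fit> %d component(s), n = %d, r = %.3g pN/s\n",
              x$n_components, x$n, x$loading_rate))
  cat(sprintf("  log-likelihood %.2f, BIC %.2f, converged: %s%s\n",
              x$log_likelihood, x$bic, x$converged,
              if (x$degenerate) " [degenerate input]" else ""))
  print(as.data.frame(x$components), digits = 4)
  invisible(x)
}

#' Tidy a Bell-Evans mixture fit
#'
#' @param x A `pg_mixture_fit`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `k0`,
#'   `x_dagger`, `kBT`, `weight`, `modal_force`, ordered by modal force.
#' @export
tidy.pg_mixture_fit <- function(x, ...) {
  mutate(x$components, component = seq_len(nrow(x$components)),
         .before = 1)
}

#' One-row summary of a Bell-Evans mixture fit
#'
#' @inheritParams tidy.pg_mixture_fit
#' @return One-row tibble: `n_components`, `n`, `loading_rate`,
#'   `log_likelihood`, `bic`, `converged`, `degenerate`.
#' @export
glance.pg_mixture_fit <- function(x, ...) {
  tibble(n_components = x$n_components, n = x$n,
         loading_rate = x$loading_rate,
         log_likelihood = x$log_likelihood, bic = x$bic,
         converged = x$converged, degenerate = x$degenerate)
}

#' Mixture density of a fitted model
#'
#' @param fit A `pg_mixture_fit`.
#' @param force Forces (pN) at which to evaluate the fitted density.
#' @return Density values, 1/pN.
#' @export
mixture_density <- function(fit, force) {
  out <- numeric(length(force))
  for (c in seq_len(fit$n_components)) {
    p <- fit$components[c, ]
    out <- out + p$weight *
      bell_evans_pdf(force, bell_evans_params(p$k0, p$x_dagger, p$kBT),
                     fit$loading_rate)
  }
  out
}

mixture_loglik <- function(forces, components, weights, loading_rate) {
  lp <- vapply(seq_len(nrow(components)), function(c) {
    p <- components[c, ]
    log(weights[c]) +
      bell_evans_pdf(forces, bell_evans_params(p$k0, p$x_dagger, p$kBT),
                     loading_rate, log = TRUE)
  }, numeric(length(forces)))
  lp <- matrix(lp, nrow = length(forces))
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Compare a free triple fit against a fixed 1SA+3SA combination
#'
#' Evaluates a tetravalent (4SA) rupture-force sample under (a) a freely
#' fitted three-component Bell-Evans mixture and (b) the fixed components
#' of previously fitted monovalent (1SA) and trivalent (3SA) spots with
#' only the mixing weights refit. If 4SA events really are the union of
#' the 1SA and 3SA processes, the two descriptions should be nearly
#' equally likely.
#'
#' @param forces_4SA Rupture forces from the tetravalent spot, pN.
#' @param fit_1SA,fit_3SA Converged `pg_mixture_fit` objects.
#' @param seed,n_starts Passed to the free [fit_mixture()].
#' @return List: `free_fit` (pg_mixture_fit), `combined_components`,
#'   `combined_weights`, `combined_loglik`, `free_loglik`,
#'   `delta_loglik_per_obs` (free minus combined, per observation).
#' @export
compare_mixture_vs_fixed_combination <- function(forces_4SA, fit_1SA,
                                                 fit_3SA, seed = 1,
                                                 n_starts = 10) {
  pg_assert(length(forces_4SA) > 0, "empty force list")
  pg_assert(inherits(fit_1SA, "pg_mixture_fit") &&
              inherits(fit_3SA, "pg_mixture_fit"),
            "fit_1SA and fit_3SA must be pg_mixture_fit objects")
  pg_assert(fit_1SA$converged && fit_3SA$converged,
            "prior fits must have converged")
  comp <- bind_rows(fit_1SA$components, fit_3SA$components)
  r <- fit_1SA$loading_rate
  k <- nrow(comp)
  # weight-only EM with the pooled fixed components
  theta <- map(seq_len(k), function(c)
    c(log(comp$k0[c]), log(comp$x_dagger[c])))
  em <- em_bell_evans(forces_4SA, r, k, comp$kBT[1], theta,
                      rep(1 / k, k), fixed_components = TRUE)
  free_fit <- fit_mixture(forces_4SA, r, n_components = min(k, 3),
                          seed = seed, n_starts = n_starts)
  list(free_fit = free_fit,
       combined_components = comp,
       combined_weights = em$weights,
       combined_loglik = em$log_likelihood,
       free_loglik = free_fit$log_likelihood,
       delta_loglik_per_obs =
         (free_fit$log_likelihood - em$log_likelihood) / length(forces_4SA))
}
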