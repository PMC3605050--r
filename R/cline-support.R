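#' Profile log-likelihood of one cline parameter
#'
#' Fixes `term` at `value`, re-optimizes all other free parameters (warm
#' started from the ML estimates), and returns the profiled log-likelihood.
#'
#' @param fit A [fit_cline()] result.
#' @param term Name of a free parameter.
#' @param value Value at which to pin it.
#' @return The profile log-likelihood (nats).
#' @export
profile_loglik <- function(fit, term, value) {
  if (!inherits(fit, "cline_fit")) abort("`fit` must be a `cline_fit` object.")
  if (!term %in% fit$free) {
    abort(paste0("`", term, "` is not a free parameter of this fit."))
  }
  spec <- list(free = setdiff(fit$free, term),
               fixed = c(setNames(value, term), fit$fixed),
               tail_left = fit$params$tail_left,
               tail_right = fit$params$tail_right)
  if (length(spec$free) == 0) {
    return(loglik_impl(fit$data, assemble_params(numeric(0), spec)))
  }
  bounds <- cline_param_bounds(fit$data$distance)
  lower <- bounds$lower[spec$free]
  upper <- bounds$upper[spec$free]
  start <- unlist(fit$params[spec$free])
  start <- pmin(pmax(start, lower), upper)
  negll <- function(par) {
    names(par) <- spec$free
    -loglik_impl(fit$data, assemble_params(par, spec))
  }
  res <- tryCatch(
    optim(start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(res)) return(-negll(start))
  -res$value
}

#' 2-log-likelihood support limits
#'
#' For each requested free parameter, finds the nearest point on each side
#' of the ML estimate where the profile log-likelihood has dropped by `drop`
#' units (2 by default, analogous to a 95% confidence interval). The search
#' bisects between the estimate and the optimizer's box bound; a side on
#' which the profile never drops by `drop` within the box is reported at the
#' bound and flagged unbounded.
#'
#' @param fit A [fit_cline()] result.
#' @param terms Free parameters to profile (default: all).
#' @param drop Log-likelihood drop defining the limits (default 2).
#' @param tol Bisection tolerance, in log-likelihood units.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `lower_bounded`, `upper_bounded`.
#' @export
cline_support <- function(fit, terms = fit$free, drop = 2, tol = 1e-3) {
  if (!inherits(fit, "cline_fit")) abort("`fit` must be a `cline_fit` object.")
  bad <- setdiff(terms, fit$free)
  if (length(bad) > 0) {
    abort(paste0("not free in this fit: ", paste(bad, collapse = ", "), "."))
  }
  bounds <- cline_param_bounds(fit$data$distance)
  purrr::map_dfr(terms, function(term) {
    est <- fit$params[[term]]
    lo <- support_side(fit, term, est, bounds$lower[[term]], drop, tol)
    hi <- support_side(fit, term, est, bounds$upper[[term]], drop, tol)
    tibble(term = term, estimate = est,
           lower = lo$limit, upper = hi$limit,
           lower_bounded = lo$bounded, upper_bounded = hi$bounded)
  })
}

# bisection for the point where the profile drops by `drop`, between the ML
# estimate (drop 0) and one box bound
support_side <- function(fit, term, est, bound, drop, tol) {
  if (abs(bound - est) < 1e-12) {
    return(list(limit = est, bounded = TRUE))
  }
  drop_at <- function(v) fit$logLik - profile_loglik(fit, term, v)
  if (drop_at(bound) < drop) {
    return(list(limit = bound, bounded = FALSE))
  }
  inner <- est
  outer <- bound
  mid <- (inner + outer) / 2
  for (i in 1:60) {
    mid <- (inner + outer) / 2
    d <- drop_at(mid)
    if (abs(d - drop) <= tol) break
    if (d < drop) inner <- mid else outer <- mid
    if (abs(outer - inner) < 1e-9 * max(1, abs(est))) break
  }
  list(limit = mid, bounded = TRUE)
}
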