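#' Validate a per-population cline dataset
#'
#' A cline dataset is a data frame with one row per sampled population:
#' `distance` (transect position, km), `n` (allele copies sampled, twice the
#' diploid sample size), and `k` (count of focal-allele copies). A
#' `population` label column is kept if present, otherwise one is created.
#' At least three populations with `n > 0` are required for any fit;
#' positions need not be unique or sorted.
#'
#' @param data A data frame with columns `distance` (alias `x` accepted),
#'   `n`, `k`, and optionally `population` and `locus`.
#' @return A validated tibble with columns `population`, `distance`, `n`, `k`.
#' @export
as_cline_data <- function(data) {
  data <- as_tibble(data)
  if (!"distance" %in% names(data) && "x" %in% names(data)) {
    data <- dplyr::rename(data, distance = "x")
  }
  missing_cols <- setdiff(c("distance", "n", "k"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cline data is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  if (nrow(data) == 0) abort("cline data is empty.")
  check_positions(data$distance)
  if (anyNA(data$n) || anyNA(data$k) ||
      any(data$n < 0) || any(data$n != round(data$n)) ||
      any(data$k != round(data$k))) {
    abort("`n` and `k` must be non-negative integers.")
  }
  bad <- which(data$k < 0 | data$k > data$n)
  if (length(bad) > 0) {
    abort(paste0("`k` must satisfy 0 <= k <= n; violated in row(s) ",
                 paste(bad, collapse = ", "), "."))
  }
  if (!"population" %in% names(data)) {
    data$population <- sprintf("P%02d", seq_len(nrow(data)))
  }
  dplyr::relocate(data, "population", "distance", "n", "k")
}

#' Binomial log-likelihood of a cline dataset
#'
#' Independent binomial sampling per population: each population contributes
#' `dbinom(k, n, p, log = TRUE)` where `p` is [cline_frequency()] at its
#' position, clamped to `[1e-9, 1 - 1e-9]` so the log-likelihood stays
#' finite when the model frequency sits exactly on 0 or 1. The binomial
#' coefficient is included, so the value is a true log-probability (nats).
#'
#' @param data A cline dataset (see [as_cline_data()]).
#' @param params A [cline_params()] object.
#' @return The log-likelihood (a single number, nats).
#' @export
cline_loglik <- function(data, params) {
  data <- as_cline_data(data)
  loglik_impl(data, params)
}

# internal: assumes validated data (hot path for the optimizer)
loglik_impl <- function(data, params, eps = 1e-9) {
  p <- cline_frequency(data$distance, params)
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(dbinom(data$k, data$n, p, log = TRUE))
}

# box bounds used by the optimizer and by profile-likelihood searches;
# span-relative so fits are equivariant under a shift of all positions
cline_param_bounds <- function(x) {
  span <- diff(range(x))
  if (span <= 0) span <- max(abs(x), 1)
  list(
    lower = c(center = min(x) - span, width = 0.01,
              theta_left = 1e-3, theta_right = 1e-3,
              z_left = 0, z_right = 0, p_left = 0, p_right = 0),
    upper = c(center = max(x) + span, width = 10 * span,
              theta_left = 1, theta_right = 1,
              z_left = span, z_right = span, p_left = 1, p_right = 1)
  )
}

build_model_spec <- function(model, fixed) {
  par_names <- cline_par_names()
  if (length(fixed) > 0 &&
      (is.null(names(fixed)) || !all(names(fixed) %in% par_names))) {
    abort(paste0("`fixed` must be a named list with names among: ",
                 paste(par_names, collapse = ", "), "."))
  }
  if (model == "sigmoid") {
    defaults <- list(theta_left = 1, theta_right = 1, z_left = 0,
                     z_right = 0, p_left = 0, p_right = 1)
    fixed <- modifyList(defaults, as.list(fixed))
  }
  fixed_vec <- unlist(fixed)
  free <- setdiff(par_names, names(fixed_vec))
  if (length(free) == 0) abort("at least one parameter must be free.")
  list(free = free, fixed = fixed_vec,
       tail_left = model == "tails", tail_right = model == "tails")
}

assemble_params <- function(free_values, spec) {
  v <- c(free_values, spec$fixed)
  new_cline_params(as.list(v[cline_par_names()]),
                   tail_left = spec$tail_left, tail_right = spec$tail_right)
}

# data-driven starting point for the optimizer: put the centre where the
# empirical frequency crosses halfway between the end frequencies
heuristic_start <- function(data, bounds) {
  ok <- data$n > 0
  x <- data$distance[ok]
  freq <- data$k[ok] / data$n[ok]
  ord <- order(x)
  x <- x[ord]; freq <- freq[ord]
  m <- length(x)
  head_idx <- seq_len(max(1, floor(m / 4)))
  tail_idx <- seq(m - max(1, floor(m / 4)) + 1, m)
  p_l <- mean(freq[head_idx]); p_r <- mean(freq[tail_idx])
  mid <- (p_l + p_r) / 2
  ctr <- x[which.min(abs(freq - mid))]
  span <- diff(range(x)); if (span <= 0) span <- 1
  st <- c(center = ctr, width = span / 4, theta_left = 0.9,
          theta_right = 0.9, z_left = span / 10, z_right = span / 10,
          p_left = p_l, p_right = p_r)
  pmin(pmax(st, bounds$lower), bounds$upper)
}

#' Fit a geographic cline by maximum likelihood
#'
#' Maximizes the binomial likelihood of [cline_loglik()] over the free
#' parameters with bounded (L-BFGS-B) local optimization from `n_starts`
#' starting points: one data-driven heuristic start plus Latin-hypercube
#' draws over the parameter box. The box is span-relative:
#' `center` in `[min x - span, max x + span]`, `width` in `[0.01, 10 span]`,
#' `z` in `[0, span]`, `theta` in `[1e-3, 1]`, `p` in `[0, 1]`.
#'
#' Two model families are available. `model = "tails"` is the
#' eight-parameter model (sigmoid centre plus exponential tails, all eight
#' parameters free by default). `model = "sigmoid"` is the two-parameter
#' model: tails disabled, `theta = 1`, `z = 0`, and the asymptotic
#' frequencies fixed (0 and 1 by default), leaving only `center` and `width`
#' free. Any parameter can additionally be pinned through `fixed`.
#'
#' @param data A cline dataset (see [as_cline_data()]).
#' @param model `"tails"` (eight-parameter) or `"sigmoid"` (two-parameter).
#' @param fixed Named list of parameters to hold at fixed values.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed controlling the Latin-hypercube starts; the fit
#'   is a pure function of `(data, model, fixed, n_starts, seed)`.
#' @param locus Optional locus label stored in the result.
#' @return An object of class `cline_fit`: the ML `cline_params`, the
#'   log-likelihood `logLik`, free/fixed parameter information, optimizer
#'   diagnostics (`n_converged`, `boundary`), and the data.
#' @examples
#' truth <- cline_params(center = 50, width = 8)
#' zone <- simulate_zone(truth, positions = seq(30, 70, length.out = 15),
#'                       n_alleles = 40, seed = 7)
#' fit <- fit_cline(zone, model = "sigmoid", n_starts = 5)
#' glance(fit)
#' @export
fit_cline <- function(data, model = c("tails", "sigmoid"), fixed = list(),
                      n_starts = 20, seed = 1L, locus = NULL) {
  model <- match.arg(model)
  if (!is.numeric(n_starts) || n_starts < 1) abort("`n_starts` must be >= 1.")
  locus <- locus %||% attr(data, "locus", exact = TRUE)
  data <- as_cline_data(data)
  if (sum(data$n > 0) < 3) {
    abort("a cline fit needs at least 3 populations with n > 0.")
  }
  spec <- build_model_spec(model, fixed)
  bounds <- cline_param_bounds(data$distance)
  lower <- bounds$lower[spec$free]
  upper <- bounds$upper[spec$free]

  negll <- function(par) {
    names(par) <- spec$free
    -loglik_impl(data, assemble_params(par, spec))
  }

  starts <- list(heuristic_start(data, bounds)[spec$free])
  n_lhs <- n_starts - 1L
  if (n_lhs > 0) {
    lhs_draws <- withr::with_seed(as.integer(seed), {
      lhs::randomLHS(n_lhs, length(spec$free))
    })
    for (i in seq_len(n_lhs)) {
      starts[[i + 1L]] <- lower + lhs_draws[i, ] * (upper - lower)
    }
  }

  best <- NULL
  n_converged <- 0L
  for (st in starts) {
    res <- tryCatch(
      optim(st, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) n_converged <- n_converged + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(paste0("no optimizer start produced a finite log-likelihood (",
                 length(starts), " starts tried)."))
  }

  par_hat <- best$par
  names(par_hat) <- spec$free
  at_bound <- spec$free[par_hat <= lower + 1e-8 * pmax(1, abs(lower)) |
                          par_hat >= upper - 1e-8 * pmax(1, abs(upper))]
  degenerate <- all(data$k == 0) || all(data$k == data$n)
  if (degenerate) {
    warn("all populations are fixed for one allele; frequency estimates sit on the boundary.")
  }

  structure(
    list(params = assemble_params(par_hat, spec),
         logLik = -best$value,
         model = model, free = spec$free, fixed = spec$fixed,
         data = data, locus = locus,
         n_starts = n_starts, seed = as.integer(seed),
         n_converged = n_converged, converged = n_converged > 0,
         boundary = at_bound, degenerate = degenerate),
    class = "cline_fit"
  )
}

#' Fit one cline per locus
#'
#' Splits a long table (one row per population and locus) by its `locus`
#' column and fits each locus with [fit_cline()].
#'
#' @param data A data frame with columns `locus`, `distance`, `n`, `k`.
#' @param ... Passed on to [fit_cline()].
#' @return A named list of `cline_fit` objects.
#' @export
fit_clines <- function(data, ...) {
  data <- as_tibble(data)
  if (!"locus" %in% names(data)) {
    abort("`data` must have a `locus` column; use `fit_cline()` for a single locus.")
  }
  split(data, data$locus) |>
    purrr::imap(function(d, nm) fit_cline(dplyr::select(d, -"locus"),
                                          locus = nm, ...))
}

#' @export
print.cline_fit <- function(x, ...) {
  cat("<cline_fit>", if (!is.null(x$locus)) paste0("locus: ", x$locus),
      sprintf("model: %s (%d free parameters)", x$model, length(x$free)),
      sprintf("logLik: %.4f | populations: %d | converged starts: %d/%d",
              x$logLik, nrow(x$data), x$n_converged, x$n_starts),
      sep = "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
logLik.cline_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$free),
            nobs = sum(object$data$n > 0), class = "logLik")
}

#' @describeIn fit_cline Tidy the parameter estimates; with
#'   `support = TRUE`, adds 2-log-likelihood support limits for the free
#'   parameters (see [cline_support()]).
#' @param x A `cline_fit` object.
#' @param support Add profile-likelihood support limits?
#' @export
tidy.cline_fit <- function(x, support = FALSE, ...) {
  nms <- cline_par_names()
  out <- tibble(term = nms,
                estimate = unlist(x$params[nms], use.names = FALSE),
                free = nms %in% x$free)
  if (isTRUE(support)) {
    out <- dplyr::left_join(out, cline_support(x), by = c("term", "estimate"))
  }
  out
}

#' @describeIn fit_cline One-row model summary.
#' @export
glance.cline_fit <- function(x, ...) {
  tibble(logLik = x$logLik, df = length(x$free),
         n_populations = sum(x$data$n > 0), n_alleles = sum(x$data$n),
         model = x$model, converged = x$converged,
         n_boundary = length(x$boundary))
}

#' Likelihood-ratio test of nested cline models
#'
#' Compares a full fit against a reduced fit whose free parameters are a
#' strict subset of the full model's (for example the eight-parameter tails
#' model against the two-parameter sigmoid model, 6 d.f.). The deviance
#' `D = 2 (lnL_full - lnL_reduced)` is clipped at zero (optimizer noise can
#' leave the constrained optimum marginally above the free one) and compared
#' to a chi-square distribution with d.f. equal to the number of extra free
#' parameters.
#'
#' @param fit_full,fit_reduced `cline_fit` objects on the same data.
#' @return A tibble with columns `statistic` (D), `df`, `p.value`.
#' @export
lrt_nested <- function(fit_full, fit_reduced) {
  if (!inherits(fit_full, "cline_fit") || !inherits(fit_reduced, "cline_fit")) {
    abort("`fit_full` and `fit_reduced` must be `cline_fit` objects.")
  }
  extra <- setdiff(fit_full$free, fit_reduced$free)
  if (!all(fit_reduced$free %in% fit_full$free) || length(extra) == 0) {
    abort("`fit_reduced` must be nested in `fit_full` (its free parameters a strict subset).")
  }
  D <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  df <- length(extra)
  tibble(statistic = D, df = df,
         p.value = pchisq(D, df, lower.tail = FALSE))
}

#' @describeIn fit_cline Predicted allele frequencies at new positions.
#' @param object A `cline_fit` object.
#' @param newdata Optional data frame with a `distance` column (defaults to
#'   the fitted data).
#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$distance else newdata$distance
  check_positions(x)
  tibble(distance = x, .fitted = cline_frequency(x, object$params))
}
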