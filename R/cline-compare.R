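#' Log-likelihood of one locus's data under another locus's cline shape
#'
#' Builds a composite parameter vector taking the six shape parameters
#' (`center`, `width`, `theta_*`, `z_*`) from `shape` and the asymptotic
#' frequencies (`p_left`, `p_right`) from `fit`, then evaluates the binomial
#' log-likelihood of `fit`'s data at that vector. Nothing is re-optimized by
#' default: only the six shape parameters differ between the free and the
#' constrained model, so the comparison carries 6 degrees of freedom.
#' `reoptimize_p = TRUE` instead re-fits the two nuisance frequencies under
#' the pinned shape (a sensitivity analysis, not the default test).
#'
#' @param fit An eight-parameter [fit_cline()] result for the data locus.
#' @param shape A `cline_params` object or `cline_fit` supplying the shape.
#' @param reoptimize_p Re-optimize `p_left`/`p_right` under the pinned
#'   shape?
#' @return The constrained log-likelihood (nats).
#' @export
constrained_loglik <- function(fit, shape, reoptimize_p = FALSE) {
  if (!inherits(fit, "cline_fit")) abort("`fit` must be a `cline_fit` object.")
  if (inherits(shape, "cline_fit")) shape <- shape$params
  if (!inherits(shape, "cline_params")) {
    abort("`shape` must be a `cline_params` or `cline_fit` object.")
  }
  miss <- setdiff(cline_shape_names(), names(shape))
  if (length(miss) > 0) {
    abort(paste0("`shape` is missing parameter(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  comp <- shape
  comp$p_left <- fit$params$p_left
  comp$p_right <- fit$params$p_right
  if (!reoptimize_p) {
    return(loglik_impl(fit$data, comp))
  }
  negll <- function(p) {
    comp$p_left <- p[1]
    comp$p_right <- p[2]
    -loglik_impl(fit$data, comp)
  }
  res <- optim(c(comp$p_left, comp$p_right), negll, method = "L-BFGS-B",
               lower = c(0, 0), upper = c(1, 1))
  -res$value
}

#' Cline-shape deviance for one ordered pair of loci
#'
#' `D = max(0, 2 (lnL_i - lnL_constrained))`, where `lnL_i` is the freely
#' estimated log-likelihood of locus *i* and the constrained value pins
#' locus *i*'s six shape parameters to locus *j*'s ML estimates (keeping
#' locus *i*'s own asymptotic frequencies; see [constrained_loglik()]). The
#' statistic is ordered: `compare_pair(i, j)` and `compare_pair(j, i)`
#' generally differ.
#'
#' @param fit_i Eight-parameter fit providing the data (and `p_left`,
#'   `p_right`).
#' @param fit_j Eight-parameter fit providing the shape.
#' @inheritParams constrained_loglik
#' @return The deviance `D` (a single non-negative number).
#' @export
compare_pair <- function(fit_i, fit_j, reoptimize_p = FALSE) {
  if (!inherits(fit_i, "cline_fit") || !inherits(fit_j, "cline_fit")) {
    abort("`fit_i` and `fit_j` must be `cline_fit` objects.")
  }
  if (fit_i$model != "tails" || fit_j$model != "tails") {
    abort("cline-shape comparisons require eight-parameter (`model = \"tails\"`) fits.")
  }
  max(0, 2 * (fit_i$logLik -
                constrained_loglik(fit_i, fit_j, reoptimize_p = reoptimize_p)))
}

#' Bonferroni-corrected chi-square threshold for cline-shape tests
#'
#' For `m` markers compared in all ordered pairs, the family-wise level
#' `alpha_family` is split over `m (m - 1)` tests (configurable through
#' `divisor`), and the critical deviance is the upper `alpha_per_test`
#' quantile of the chi-square distribution with `df` degrees of freedom.
#' With 10 markers and `alpha_family = 0.05` this gives
#' `alpha_per_test ~= 0.00056` and a critical D of about 23.85 at 6 d.f.
#'
#' @param m Number of markers (>= 2).
#' @param alpha_family Family-wise significance level.
#' @param df Degrees of freedom of each test (6: the shape parameters).
#' @param divisor Number of tests the level is split over; defaults to the
#'   number of ordered pairs `m * (m - 1)`.
#' @return A tibble with columns `m`, `n_tests`, `alpha_family`,
#'   `alpha_per_test`, `df`, `critical_D`.
#' @export
bonferroni_critical_d <- function(m, alpha_family = 0.05, df = 6,
                                  divisor = NULL) {
  if (!is.numeric(m) || m < 2) abort("`m` must be >= 2 markers.")
  divisor <- divisor %||% (m * (m - 1))
  alpha_per_test <- alpha_family / divisor
  tibble(m = m, n_tests = divisor, alpha_family = alpha_family,
         alpha_per_test = alpha_per_test, df = df,
         critical_D = qchisq(alpha_per_test, df, lower.tail = FALSE))
}

#' All ordered pairwise cline-shape comparisons
#'
#' Fills the ordered-pair deviance matrix `D[i, j]` (data from marker *i*,
#' shape from marker *j*; see [compare_pair()]) over every pair of markers,
#' and flags as significantly different in shape the pairs whose deviance
#' reaches the Bonferroni-corrected chi-square threshold of
#' [bonferroni_critical_d()]. The matrix is not symmetrized.
#'
#' @param fits A named list of eight-parameter `cline_fit` objects (>= 2).
#' @inheritParams bonferroni_critical_d
#' @inheritParams constrained_loglik
#' @return An object of class `cline_comparison` with elements `markers`,
#'   `D` (matrix), `significant` (logical matrix), `df`, `alpha_family`,
#'   `alpha_per_test`, `critical_D`, `n_tests`.
#' @examples
#' truth <- cline_params(center = 50, width = 8)
#' zone <- simulate_zone(list(A = truth, B = truth),
#'                       positions = seq(30, 70, length.out = 12),
#'                       n_alleles = 60, seed = 3)
#' fits <- fit_clines(zone, n_starts = 5)
#' cmp <- compare_clines(fits)
#' tidy(cmp)
#' @export
compare_clines <- function(fits, alpha_family = 0.05, df = 6,
                           divisor = NULL, reoptimize_p = FALSE) {
  if (!is.list(fits) || length(fits) < 2) {
    abort("`fits` must be a list of at least 2 `cline_fit` objects.")
  }
  markers <- names(fits) %||% purrr::map_chr(fits, function(f) f$locus %||% "")
  if (is.null(names(fits))) {
    if (any(markers == "") || anyDuplicated(markers)) {
      markers <- paste0("locus", seq_along(fits))
    }
    names(fits) <- markers
  }
  m <- length(fits)
  D <- matrix(0, m, m, dimnames = list(data = markers, shape = markers))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      D[i, j] <- compare_pair(fits[[i]], fits[[j]],
                              reoptimize_p = reoptimize_p)
    }
  }
  crit <- bonferroni_critical_d(m, alpha_family = alpha_family, df = df,
                                divisor = divisor)
  structure(
    list(markers = markers, D = D, significant = D >= crit$critical_D,
         df = df, alpha_family = alpha_family,
         alpha_per_test = crit$alpha_per_test,
         critical_D = crit$critical_D, n_tests = crit$n_tests),
    class = "cline_comparison"
  )
}

#' @export
print.cline_comparison <- function(x, ...) {
  cat(sprintf(
    "<cline_comparison> %d markers, %d ordered tests, df = %d\nalpha per test = %.3g, critical D = %.2f\n",
    length(x$markers), x$n_tests, x$df, x$alpha_per_test, x$critical_D))
  print(round(x$D, 2), ...)
  invisible(x)
}

#' @describeIn compare_clines Long tibble of ordered-pair deviances.
#' @param x A `cline_comparison` object.
#' @export
tidy.cline_comparison <- function(x, ...) {
  tidyr::expand_grid(data_marker = x$markers, shape_marker = x$markers) |>
    dplyr::mutate(
      D = purrr::map2_dbl(.data$data_marker, .data$shape_marker,
                          function(i, j) x$D[i, j]),
      significant = purrr::map2_lgl(.data$data_marker, .data$shape_marker,
                                    function(i, j) x$significant[i, j]))
}

#' @describeIn compare_clines One-row summary of the comparison family.
#' @export
glance.cline_comparison <- function(x, ...) {
  off <- x$significant & !diag(length(x$markers))
  tibble(n_markers = length(x$markers), n_tests = x$n_tests, df = x$df,
         alpha_family = x$alpha_family, alpha_per_test = x$alpha_per_test,
         critical_D = x$critical_D, n_significant = sum(off))
}

#' Serialize a cline-shape comparison
#'
#' Writes the ordered-pair deviance matrix as TSV (markers in rows, stable
#' order) and/or a JSON summary holding the matrix plus the correction
#' settings.
#'
#' @param x A `cline_comparison` object.
#' @param tsv,json Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_comparison <- function(x, tsv = NULL, json = NULL) {
  if (!inherits(x, "cline_comparison")) {
    abort("`x` must be a `cline_comparison` object.")
  }
  if (!is.null(tsv)) {
    df <- as.data.frame(x$D)
    df <- cbind(marker = rownames(x$D), df)
    readr::write_tsv(df, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(markers = x$markers, D = x$D, df = x$df,
           alpha_family = x$alpha_family, alpha_per_test = x$alpha_per_test,
           critical_D = x$critical_D, n_tests = x$n_tests,
           significant = x$significant),
      json, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(x)
}
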