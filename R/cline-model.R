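#' Cline shape parameters
#'
#' Container for the eight parameters that define one locus's spatial
#' allele-frequency curve across a hybrid zone: a central sigmoid of width
#' `width` centred at `center`, optional exponential tails on either side
#' (decay-rate ratios `theta_*`, junction offsets `z_*`), and asymptotic
#' allele frequencies `p_left` / `p_right` at the two ends of the transect.
#'
#' The scaled curve rises from 0 to 1; `p_left > p_right` represents a
#' descending cline acting on the same ascending canonical form. Setting
#' `tails` to `"none"` selects the pure two-parameter sigmoid model
#' explicitly rather than through limiting parameter values.
#'
#' @param center Transect position of the maximum allele-frequency gradient
#'   (km).
#' @param width Cline width (km); the inverse of the maximum slope of the
#'   scaled curve. Must be positive.
#' @param theta_left,theta_right Exponential decay-rate ratios for the left
#'   and right tails, each in (0, 1]. At 1 the tail is slope-continuous with
#'   the central sigmoid.
#' @param z_left,z_right Distances (km, >= 0) from `center` to the left and
#'   right tail junctions.
#' @param p_left,p_right Asymptotic allele frequencies (each in [0, 1]) on
#'   the left and right ends of the transect.
#' @param tails Which exponential tails are active: `"both"` (default),
#'   `"left"`, `"right"`, or `"none"` (pure sigmoid).
#'
#' @return An object of class `cline_params`.
#' @examples
#' pars <- cline_params(center = 50, width = 8)
#' scaled_cline(50, pars)          # 0.5 at the centre
#' cline_frequency(c(30, 50, 70), pars)
#' @export
cline_params <- function(center, width, theta_left = 1, theta_right = 1,
                         z_left = 0, z_right = 0, p_left = 0, p_right = 1,
                         tails = c("both", "left", "right", "none")) {
  tails <- match.arg(tails)
  vals <- list(center = center, width = width,
               theta_left = theta_left, theta_right = theta_right,
               z_left = z_left, z_right = z_right,
               p_left = p_left, p_right = p_right)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a single finite number."))
    }
  }
  if (width <= 0) abort("`width` must satisfy width > 0 (km).")
  if (theta_left <= 0 || theta_left > 1) {
    abort("`theta_left` must satisfy 0 < theta_left <= 1.")
  }
  if (theta_right <= 0 || theta_right > 1) {
    abort("`theta_right` must satisfy 0 < theta_right <= 1.")
  }
  if (z_left < 0) abort("`z_left` must satisfy z_left >= 0 (km).")
  if (z_right < 0) abort("`z_right` must satisfy z_right >= 0 (km).")
  if (p_left < 0 || p_left > 1) abort("`p_left` must satisfy 0 <= p_left <= 1.")
  if (p_right < 0 || p_right > 1) {
    abort("`p_right` must satisfy 0 <= p_right <= 1.")
  }
  new_cline_params(vals, tail_left = tails %in% c("both", "left"),
                   tail_right = tails %in% c("both", "right"))
}

# fast internal constructor: `vals` is a named list of the eight parameters,
# already validated (or coming from the optimizer, whose box bounds enforce
# the same constraints)
new_cline_params <- function(vals, tail_left = TRUE, tail_right = TRUE) {
  structure(c(vals, list(tail_left = tail_left, tail_right = tail_right)),
            class = "cline_params")
}

#' @export
print.cline_params <- function(x, ...) {
  tails <- if (x$tail_left && x$tail_right) "both" else
    if (x$tail_left) "left" else if (x$tail_right) "right" else "none"
  cat("<cline_params> tails:", tails, "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.cline_params <- function(x, ...) {
  nms <- cline_par_names()
  tibble(term = nms, value = unlist(x[nms], use.names = FALSE))
}

cline_par_names <- function() {
  c("center", "width", "theta_left", "theta_right",
    "z_left", "z_right", "p_left", "p_right")
}

cline_shape_names <- function() cline_par_names()[1:6]

check_positions <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be a vector of finite transect positions (km).")
  }
}

#' Scaled cline curve
#'
#' Evaluates the scaled (0 to 1) cline at transect positions `x`: a logistic
#' sigmoid `1 / (1 + exp(-4 (x - center) / width))` inside the central
#' region, replaced beyond the junctions at `center - z_left` and
#' `center + z_right` by exponential tails whose decay rate is `theta_side`
#' times the log-slope of the sigmoid at the junction. The curve is
#' continuous everywhere, non-decreasing in `x`, has slope `1 / width` at
#' `center`, and is slope-continuous at a junction exactly when that side's
#' `theta` is 1.
#'
#' @param x Numeric vector of transect positions (km).
#' @param params A [cline_params()] object.
#' @return Numeric vector of scaled frequencies in (0, 1).
#' @seealso [cline_frequency()] for the curve on the allele-frequency scale.
#' @export
scaled_cline <- function(x, params) {
  if (!inherits(params, "cline_params")) {
    abort("`params` must be a `cline_params` object.")
  }
  check_positions(x)
  ctr <- params$center
  w <- params$width
  s <- plogis4(x, ctr, w)
  if (params$tail_left) {
    xl <- ctr - params$z_left
    lam <- (4 / w) / (1 + exp(-4 * params$z_left / w))
    idx <- x < xl
    if (any(idx)) {
      s[idx] <- plogis4(xl, ctr, w) *
        exp(params$theta_left * lam * (x[idx] - xl))
    }
  }
  if (params$tail_right) {
    xr <- ctr + params$z_right
    lam <- (4 / w) / (1 + exp(-4 * params$z_right / w))
    idx <- x > xr
    if (any(idx)) {
      s[idx] <- 1 - (1 - plogis4(xr, ctr, w)) *
        exp(-params$theta_right * lam * (x[idx] - xr))
    }
  }
  # keep the open interval (0, 1) representable: far in the tails the
  # double-precision result would otherwise round to exactly 0 or 1
  pmin(pmax(s, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

plogis4 <- function(x, center, width) {
  1 / (1 + exp(-4 * (x - center) / width))
}

#' Cline on the allele-frequency scale
#'
#' Affine rescaling of [scaled_cline()] between the asymptotic allele
#' frequencies: `p_left + (p_right - p_left) * scaled_cline(x)`. A
#' descending cline has `p_left > p_right`; `p_left == p_right` gives a flat
#' cline.
#'
#' @inheritParams scaled_cline
#' @return Numeric vector of allele frequencies, each between
#'   `min(p_left, p_right)` and `max(p_left, p_right)`.
#' @export
cline_frequency <- function(x, params) {
  params$p_left + (params$p_right - params$p_left) * scaled_cline(x, params)
}

#' Tabulate a cline curve
#'
#' Convenience grid evaluation used by plotting code and scripts.
#'
#' @inheritParams scaled_cline
#' @param from,to Range of transect positions (km).
#' @param n Number of grid points.
#' @return A tibble with columns `distance`, `scaled`, `frequency`.
#' @export
cline_curve <- function(params, from, to, n = 201) {
  x <- seq(from, to, length.out = n)
  tibble(distance = x,
         scaled = scaled_cline(x, params),
         frequency = cline_frequency(x, params))
}
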