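#' Identify the locus columns of a genotype panel
#'
#' A genotype panel is a wide tibble with one row per individual: an `id`
#' column, optional `population`, a grouping column (typically `group`, the
#' ecotype), and one column per locus holding the focal-allele dosage (0, 1,
#' 2, or `NA` for missing).
#' @noRd
panel_loci <- function(panel, loci = NULL, group_col = "group") {
  loci <- loci %||% setdiff(names(panel),
                            c("id", "population", group_col))
  if (length(loci) == 0) abort("no locus columns found in `panel`.")
  for (lc in loci) {
    v <- panel[[lc]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      abort(paste0("locus `", lc,
                   "` must contain dosages 0/1/2 or NA only."))
    }
  }
  loci
}

#' Focal-allele frequencies by group
#'
#' Per locus and group: `sum(dosage) / (2 * number genotyped)`, with missing
#' genotypes excluded from numerator and denominator. A group with no
#' genotyped individuals at a locus yields `NA`, not zero.
#'
#' @param panel A genotype panel (see [read_genotype_panel()] or
#'   [simulate_ecotype_panel()]): wide tibble with dosage columns.
#' @param by Name of the grouping column (default `"group"`).
#' @param loci Locus columns (default: every non-metadata column).
#' @return A tibble with columns `by`, `locus`, `n_genotyped`, `freq`.
#' @export
allele_frequencies <- function(panel, by = "group", loci = NULL) {
  panel <- as_tibble(panel)
  if (!by %in% names(panel)) {
    abort(paste0("grouping column `", by, "` not found in `panel`."))
  }
  loci <- panel_loci(panel, loci, group_col = by)
  panel |>
    dplyr::select(dplyr::all_of(c(by, loci))) |>
    tidyr::pivot_longer(dplyr::all_of(loci), names_to = "locus",
                        values_to = "dosage") |>
    dplyr::group_by(.data[[by]], .data$locus) |>
    dplyr::summarise(
      n_genotyped = sum(!is.na(.data$dosage)),
      freq = ifelse(.data$n_genotyped > 0,
                    sum(.data$dosage, na.rm = TRUE) / (2 * .data$n_genotyped),
                    NA_real_),
      .groups = "drop")
}

# Weir & Cockerham (1984) theta for one biallelic locus and r = 2 groups.
# n: diploid sample sizes, p: focal-allele frequencies, h: observed
# heterozygote proportions. Returns NA when the locus is monomorphic
# overall (a + b + c = 0).
wc_theta <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

#' Between-group F_ST (Weir-Cockerham theta)
#'
#' Weir and Cockerham's theta for exactly two groups (here, the two
#' ecotypes, pooling populations within ecotype), computed per locus from
#' diploid dosage data. Theta is 1 exactly when the two groups are fixed
#' for alternate alleles, about 0 (possibly slightly negative) with no
#' differentiation, and `NA` when the locus is monomorphic overall or a
#' group has fewer than two genotyped individuals.
#'
#' @inheritParams allele_frequencies
#' @param group_col Name of the column holding the two group labels.
#' @return A tibble with columns `locus`, `n_1`, `n_2`, `freq_1`, `freq_2`,
#'   `fst` (groups in sorted label order).
#' @examples
#' panel <- simulate_ecotype_panel(freq_a = 1, freq_b = 0,
#'                                 n_a = 267, n_b = 107, seed = 1)
#' fst_between_groups(panel)   # fixed difference: theta = 1
#' @export
fst_between_groups <- function(panel, group_col = "group", loci = NULL) {
  panel <- as_tibble(panel)
  if (!group_col %in% names(panel)) {
    abort(paste0("grouping column `", group_col, "` not found in `panel`."))
  }
  groups <- sort(unique(panel[[group_col]]))
  if (length(groups) != 2) {
    abort("F_ST requires exactly two groups.")
  }
  loci <- panel_loci(panel, loci, group_col = group_col)
  purrr::map_dfr(loci, function(lc) {
    stats_by_group <- purrr::map(groups, function(g) {
      d <- panel[[lc]][panel[[group_col]] == g]
      d <- d[!is.na(d)]
      list(n = length(d),
           p = if (length(d) > 0) sum(d) / (2 * length(d)) else NA_real_,
           h = if (length(d) > 0) mean(d == 1) else NA_real_)
    })
    n <- purrr::map_dbl(stats_by_group, "n")
    p <- purrr::map_dbl(stats_by_group, "p")
    h <- purrr::map_dbl(stats_by_group, "h")
    fst <- if (any(n < 2)) NA_real_ else wc_theta(n, p, h)
    tibble(locus = lc, n_1 = n[1], n_2 = n[2],
           freq_1 = p[1], freq_2 = p[2], fst = fst)
  })
}

#' Genetic map distance from F2 recombinant counts
#'
#' Converts a count of recombinant F2 individuals into a map distance under
#' the single-recombinant-gamete convention: each recombinant individual is
#' taken to carry exactly one recombinant gamete, so the recombination
#' fraction is `r = n_recombinant / (2 * n_individuals)`. Map functions:
#' `direct` (100 r, the default), `haldane` (-50 ln(1 - 2r)), `kosambi`
#' (25 ln((1 + 2r) / (1 - 2r))). Haldane and Kosambi require `r < 0.5`.
#'
#' @param n_recombinant Number of recombinant individuals.
#' @param n_individuals Number of F2 individuals scored.
#' @param map_function `"direct"`, `"haldane"`, or `"kosambi"`.
#' @return A one-row tibble with columns `n_individuals`, `n_recombinant`,
#'   `r`, `map_function`, `cM`.
#' @examples
#' map_distance(79, 359)        # ~11 cM
#' @export
map_distance <- function(n_recombinant, n_individuals,
                         map_function = c("direct", "haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (!is.numeric(n_recombinant) || !is.numeric(n_individuals) ||
      n_individuals <= 0 || n_recombinant < 0 ||
      n_recombinant > n_individuals ||
      n_recombinant != round(n_recombinant) ||
      n_individuals != round(n_individuals)) {
    abort("counts must satisfy 0 <= n_recombinant <= n_individuals (integers).")
  }
  r <- n_recombinant / (2 * n_individuals)
  if (map_function != "direct" && r >= 0.5) {
    abort(paste0("the ", map_function,
                 " map function is only defined for r < 0.5 (got r = ",
                 signif(r, 4), ")."))
  }
  cM <- switch(map_function,
               direct = 100 * r,
               haldane = -50 * log(1 - 2 * r),
               kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
  tibble(n_individuals = n_individuals, n_recombinant = n_recombinant,
         r = r, map_function = map_function, cM = cM)
}

#' Exact test of a 2 x K contingency table
#'
#' Fisher's exact test for genotype-phenotype association and
#' allelic-imbalance tables. For 2 x 2 tables the two-sided p-value uses the
#' point-probability rule on the conditional hypergeometric distribution.
#' Wider tables use exact conditional enumeration when the table is small
#' (total count at most `exact_limit`) and seeded Monte-Carlo resampling of
#' the conditional null otherwise, with the replicate count reported. A
#' table with a zero margin carries no information; it yields p = 1 with a
#' warning.
#'
#' @param x A 2 x K matrix (or data frame) of non-negative integer counts,
#'   K in 2..4.
#' @param exact_limit Largest total count for which a K > 2 table is
#'   enumerated exactly.
#' @param B Monte-Carlo replicates for large tables.
#' @param seed Seed for the Monte-Carlo path.
#' @return A one-row tibble with columns `p.value`, `method`, `n_sim`
#'   (`NA` unless Monte-Carlo).
#' @export
fisher_exact <- function(x, exact_limit = 500, B = 1e5, seed = 1L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x))) {
    abort("`x` must contain non-negative integer counts.")
  }
  if (nrow(x) != 2 || !ncol(x) %in% 2:4) {
    abort("`x` must be a 2 x K table with K in 2..4.")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warn("table has a zero margin; p = 1 by convention.")
    return(tibble(p.value = 1, method = "degenerate", n_sim = NA_integer_))
  }
  if (ncol(x) == 2 || sum(x) <= exact_limit) {
    p <- stats::fisher.test(x)$p.value
    return(tibble(p.value = min(p, 1), method = "exact", n_sim = NA_integer_))
  }
  p <- withr::with_seed(as.integer(seed), {
    stats::fisher.test(x, simulate.p.value = TRUE, B = as.integer(B))$p.value
  })
  tibble(p.value = p, method = "monte-carlo", n_sim = as.integer(B))
}

#' Convert flower-colour phenotypes to a genotype-coded cline dataset
#'
#' Codes each individual's colour category as a focal-allele dosage --
#' red = 2 (homozygous), red-orange and orange = 1 (heterozygous),
#' yellow = 0 -- and tallies per population `k = sum(dosage)` and
#' `n = 2 * individuals`, producing a cline dataset on the same footing as a
#' SNP so the phenotypic cline can be fit and compared with marker clines.
#'
#' @param data A data frame with one row per individual: columns
#'   `population`, `color`, and optionally `distance` (constant within a
#'   population, carried through).
#' @param color_col Name of the colour column.
#' @return A cline dataset tibble (columns `population`, `distance` if
#'   supplied, `n`, `k`).
#' @export
phenotype_to_cline_counts <- function(data, color_col = "color") {
  data <- as_tibble(data)
  if (!"population" %in% names(data)) {
    abort("`data` must have a `population` column.")
  }
  if (!color_col %in% names(data)) {
    abort(paste0("colour column `", color_col, "` not found."))
  }
  coding <- c(red = 2, `red-orange` = 1, orange = 1, yellow = 0)
  cols <- as.character(data[[color_col]])
  bad <- setdiff(unique(cols), names(coding))
  if (length(bad) > 0) {
    abort(paste0("unrecognized colour categor",
                 if (length(bad) > 1) "ies: " else "y: ",
                 paste(bad, collapse = ", "),
                 ". Valid labels: ", paste(names(coding), collapse = ", "), "."))
  }
  data$`..dosage` <- unname(coding[cols])
  grp_cols <- intersect(c("population", "distance"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(n = 2L * dplyr::n(),
                     k = as.integer(sum(.data$`..dosage`)),
                     .groups = "drop")
}
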