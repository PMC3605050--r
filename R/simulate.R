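#' Simulate allele counts along a hybrid-zone transect
#'
#' Draws per-population allele counts under the same sampling model the
#' cline likelihood assumes: at each transect position, `k` focal alleles
#' out of `n` sampled copies are drawn binomially with probability
#' [cline_frequency()] under the true parameters. One dataset is produced
#' per locus; the output is a pure function of `(params, positions,
#' n_alleles, seed)`.
#'
#' @param params A [cline_params()] object, or a named list of them (one
#'   per locus).
#' @param positions Numeric vector of transect positions (km), one per
#'   population.
#' @param n_alleles Allele copies sampled per population (scalar or one
#'   value per population); twice the diploid sample size.
#' @param seed Integer seed; recorded in the output's `seed` attribute.
#' @return A tibble with columns `locus`, `population`, `distance`, `n`,
#'   `k`, with attributes `seed` and `true_params`.
#' @examples
#' truth <- cline_params(center = 50, width = 8)
#' simulate_zone(truth, positions = seq(34, 66, length.out = 9),
#'               n_alleles = 80, seed = 1)
#' @export
simulate_zone <- function(params, positions, n_alleles, seed = 1L) {
  if (inherits(params, "cline_params")) params <- list(locus1 = params)
  if (!is.list(params) || !all(purrr::map_lgl(params, inherits,
                                              "cline_params"))) {
    abort("`params` must be a `cline_params` object or a named list of them.")
  }
  if (is.null(names(params)) || any(names(params) == "")) {
    names(params) <- paste0("locus", seq_along(params))
  }
  check_positions(positions)
  n_pop <- length(positions)
  if (length(n_alleles) == 1L) n_alleles <- rep(n_alleles, n_pop)
  if (length(n_alleles) != n_pop || anyNA(n_alleles) ||
      any(n_alleles < 0) || any(n_alleles != round(n_alleles))) {
    abort("`n_alleles` must be non-negative integers, one per population (or a scalar).")
  }
  out <- withr::with_seed(as.integer(seed), {
    purrr::imap_dfr(params, function(pr, nm) {
      p <- cline_frequency(positions, pr)
      tibble(locus = nm,
             population = sprintf("P%02d", seq_len(n_pop)),
             distance = positions,
             n = as.integer(n_alleles),
             k = rbinom(n_pop, as.integer(n_alleles), p))
    })
  })
  attr(out, "seed") <- as.integer(seed)
  attr(out, "true_params") <- params
  out
}

#' Simulate two fixed-ecotype genotype panels
#'
#' Draws diploid genotypes under Hardy-Weinberg proportions at each group's
#' allele frequency, emulating the reference-panel design of a hybrid-zone
#' study (by default 267 individuals in group `a` and 107 in group `b`, the
#' red- and yellow-ecotype panel sizes).
#'
#' @param freq_a,freq_b Focal-allele frequency in each group; scalars or
#'   equal-length (optionally named) vectors, one entry per locus.
#' @param n_a,n_b Diploid individuals per group.
#' @param group_labels Length-2 character vector of group labels.
#' @param seed Integer seed; recorded in the output's `seed` attribute.
#' @return A genotype panel tibble: `id`, `population`, `group`, one dosage
#'   column per locus.
#' @export
simulate_ecotype_panel <- function(freq_a, freq_b, n_a = 267, n_b = 107,
                                   group_labels = c("a", "b"), seed = 1L) {
  if (length(freq_a) != length(freq_b)) {
    abort("`freq_a` and `freq_b` must have the same length (one entry per locus).")
  }
  if (any(freq_a < 0 | freq_a > 1) || any(freq_b < 0 | freq_b > 1)) {
    abort("allele frequencies must lie in [0, 1].")
  }
  if (length(group_labels) != 2) abort("`group_labels` must have length 2.")
  loci <- names(freq_a) %||% paste0("L", seq_along(freq_a))
  withr::with_seed(as.integer(seed), {
    draw <- function(n, freqs, label) {
      g <- purrr::map(freqs, function(f) rbinom(n, 2L, f))
      names(g) <- loci
      dplyr::bind_cols(
        tibble(id = paste0(label, "_", seq_len(n)),
               population = label, group = label),
        as_tibble(g))
    }
    out <- dplyr::bind_rows(draw(n_a, freq_a, group_labels[1]),
                            draw(n_b, freq_b, group_labels[2]))
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Simulate a two-locus F2 intercross
#'
#' Each F2 individual receives two gametes from F1 parents heterozygous at
#' both loci in coupling phase; each gamete is recombinant with probability
#' `r`. An individual is classified recombinant when it carries at least
#' one recombinant gamete (at small `r`, almost always exactly one, the
#' convention under which `r = recombinants / 2N`).
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @param n Number of F2 individuals.
#' @param seed Integer seed.
#' @return A list with elements `counts` (one-row tibble: `n_individuals`,
#'   `n_recombinant`, `n_recombinant_gametes`, `seed`) and `genotypes`
#'   (tibble with per-individual dosages `locus1`, `locus2` and
#'   `n_recombinant_gametes`).
#' @export
simulate_f2 <- function(r = 0.11, n = 359, seed = 1L) {
  if (!is.numeric(r) || r < 0 || r > 0.5) {
    abort("`r` must lie in [0, 0.5].")
  }
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  withr::with_seed(as.integer(seed), {
    gamete <- function() {
      rec <- rbinom(n, 1L, r)                   # 1 = recombinant gamete
      a1 <- rbinom(n, 1L, 0.5)                  # allele at locus 1 (1 = focal)
      a2 <- ifelse(rec == 1L, 1L - a1, a1)      # coupling phase
      list(rec = rec, a1 = a1, a2 = a2)
    }
    g1 <- gamete()
    g2 <- gamete()
    rec_gametes <- g1$rec + g2$rec
    genotypes <- tibble(
      id = sprintf("F2_%03d", seq_len(n)),
      locus1 = g1$a1 + g2$a1,
      locus2 = g1$a2 + g2$a2,
      n_recombinant_gametes = as.integer(rec_gametes))
    counts <- tibble(
      n_individuals = as.integer(n),
      n_recombinant = as.integer(sum(rec_gametes >= 1L)),
      n_recombinant_gametes = as.integer(sum(rec_gametes)),
      seed = as.integer(seed))
    list(counts = counts, genotypes = genotypes)
  })
}
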