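toy_panel <- function() {
  tibble::tibble(
    id = paste0("i", 1:8),
    population = rep(c("west", "east"), each = 4),
    group = rep(c("A", "B"), each = 4),
    L1 = c(2, 2, 1, 1, 0, 0, 1, 1),
    L2 = c(2, 2, 2, 2, 0, 0, 0, 0))
}

test_that("allele frequencies pool dosages and exclude missing genotypes", {
  panel <- toy_panel()
  af <- allele_frequencies(panel)
  expect_equal(af$freq[af$group == "A" & af$locus == "L1"], 0.75)
  expect_equal(af$freq[af$group == "B" & af$locus == "L2"], 0)

  all2 <- tibble::tibble(id = c("a", "b"), group = "g", L = c(2, 2))
  expect_equal(allele_frequencies(all2)$freq, 1)
  mix <- tibble::tibble(id = c("a", "b", "c"), group = "g", L = c(2, 1, 0))
  expect_equal(allele_frequencies(mix)$freq, 0.5)

  miss <- tibble::tibble(id = c("a", "b", "c"), group = c("g", "g", "h"),
                         L = c(2, NA, NA))
  af <- allele_frequencies(miss)
  expect_equal(af$freq[af$group == "g"], 1)      # NA dropped from both sides
  expect_true(is.na(af$freq[af$group == "h"]))   # all-missing group: NA, not 0

  expect_error(allele_frequencies(dplyr::mutate(toy_panel(), L1 = L1 + 5)),
               "0/1/2")
})

test_that("a 267 vs 107 panel fixed for alternate alleles has frequencies (1, 0) and F_ST exactly 1", {
  panel <- tibble::tibble(
    id = as.character(1:374), population = "p",
    group = rep(c("red", "yellow"), c(267, 107)),
    M = rep(c(2, 0), c(267, 107)))
  af <- allele_frequencies(panel)
  expect_equal(af$freq[af$group == "red"], 1)
  expect_equal(af$freq[af$group == "yellow"], 0)
  expect_identical(fst_between_groups(panel)$fst, 1)
})

test_that("Weir-Cockerham theta matches a spreadsheet-style component oracle", {
  panel <- toy_panel()
  got <- fst_between_groups(panel)
  # L1: group A dosages 2,2,1,1 -> p = 0.75, het = 0.5; B mirrored
  expect_equal(got$fst[got$locus == "L1"],
               wc_theta_oracle(c(4, 4), c(0.75, 0.25), c(0.5, 0.5)),
               tolerance = 1e-10)
  expect_equal(got$fst[got$locus == "L2"],
               wc_theta_oracle(c(4, 4), c(1, 0), c(0, 0)),
               tolerance = 1e-10)
})

test_that("theta is invariant to group order and allele relabelling, and near zero without differentiation", {
  panel <- toy_panel()
  base <- fst_between_groups(panel)$fst
  swapped <- dplyr::mutate(panel, group = ifelse(group == "A", "B", "A"))
  expect_equal(fst_between_groups(swapped)$fst, base, tolerance = 1e-12)
  relabelled <- dplyr::mutate(panel, L1 = 2 - L1, L2 = 2 - L2)
  expect_equal(fst_between_groups(relabelled)$fst, base, tolerance = 1e-12)

  ident <- tibble::tibble(id = as.character(1:12), group = rep(c("A", "B"), each = 6),
                          L = rep(c(2, 1, 1, 1, 0, 0), 2))
  th <- fst_between_groups(ident)$fst
  expect_lt(abs(th), 0.1)
  expect_lte(th, 0)   # identical counts: estimator is non-positive

  mono <- tibble::tibble(id = as.character(1:8), group = rep(c("A", "B"), each = 4),
                         L = rep(2, 8))
  expect_true(is.na(fst_between_groups(mono)$fst))
  expect_error(fst_between_groups(dplyr::mutate(toy_panel(), group = "one")),
               "exactly two")
})

test_that("theta rises towards 1 as simulated groups approach fixation for alternate alleles", {
  deltas <- c(0.2, 0.35, 0.5)
  thetas <- purrr::map_dbl(seq_along(deltas), function(i) {
    panel <- simulate_ecotype_panel(0.5 + deltas[i], 0.5 - deltas[i],
                                    n_a = 400, n_b = 400, seed = 100 + i)
    fst_between_groups(panel)$fst
  })
  expect_true(all(diff(thetas) > 0))
  expect_gt(thetas[3], 0.8)
})

test_that("map distances follow the stated map functions and their ordering", {
  direct <- map_distance(79, 359)
  expect_equal(direct$r, 79 / 718)
  expect_equal(direct$cM, 11.0, tolerance = 1e-3)

  expect_equal(map_distance(0, 100, "direct")$cM, 0)
  expect_equal(map_distance(0, 100, "haldane")$cM, 0)
  expect_equal(map_distance(0, 100, "kosambi")$cM, 0)

  # r = 0.11: haldane closed form -50 ln(0.78)
  hal <- map_distance(22, 100, "haldane")
  expect_equal(hal$cM, -50 * log(0.78), tolerance = 1e-12)

  for (rec in c(10, 30, 49)) {
    d <- map_distance(rec, 50, "direct")$cM
    k <- map_distance(rec, 50, "kosambi")$cM
    h <- map_distance(rec, 50, "haldane")$cM
    expect_true(d <= k && k <= h)
  }

  expect_error(map_distance(50, 50, "haldane"), "r < 0.5")
  expect_error(map_distance(50, 50, "kosambi"), "r < 0.5")
  expect_equal(map_distance(50, 50, "direct")$cM, 50)
  expect_error(map_distance(-1, 10), "n_recombinant")
})

test_that("exact tests match hypergeometric enumeration and honour invariances", {
  # [[3,0],[0,3]]: 2 of the 20 equally likely conditional tables are as extreme
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2, 2))$p.value, 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p.value, 1)
  expect_equal(fisher_exact(rbind(c(4, 2, 1), c(4, 2, 1)))$p.value, 1)

  m <- rbind(c(8, 2, 5), c(1, 7, 3))
  expect_equal(fisher_exact(m[, c(3, 1, 2)])$p.value,
               fisher_exact(m)$p.value, tolerance = 1e-12)
  expect_equal(fisher_exact(m[c(2, 1), ])$p.value,
               fisher_exact(m)$p.value, tolerance = 1e-12)

  expect_warning(res <- fisher_exact(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_equal(res$p.value, 1)

  big <- rbind(c(400, 300, 200), c(250, 350, 300))
  mc <- fisher_exact(big, exact_limit = 100, B = 2e4, seed = 5)
  expect_equal(mc$method, "monte-carlo")
  expect_equal(mc$n_sim, 20000L)
  expect_identical(mc$p.value,
                   fisher_exact(big, exact_limit = 100, B = 2e4, seed = 5)$p.value)
  expect_error(fisher_exact(rbind(c(1, 2), c(3, -1))), "non-negative")
})

test_that("flower-colour categories code to heterozygote-equivalent cline counts", {
  reds <- tibble::tibble(population = "p1", color = rep("red", 3))
  out <- phenotype_to_cline_counts(reds)
  expect_equal(out$k, 6L)
  expect_equal(out$n, 6L)

  one_each <- tibble::tibble(population = "p1",
                             color = c("red", "orange", "yellow"))
  expect_equal(phenotype_to_cline_counts(one_each)$k, 3L)

  withr::local_seed(12)
  cats <- c("red", "red-orange", "orange", "yellow")
  multi <- tibble::tibble(
    population = sample(paste0("p", 1:4), 60, replace = TRUE),
    distance = NA_real_, color = sample(cats, 60, replace = TRUE))
  multi$distance <- as.numeric(factor(multi$population)) * 3
  out <- phenotype_to_cline_counts(multi)
  coding <- c(red = 2, `red-orange` = 1, orange = 1, yellow = 0)
  for (p in unique(multi$population)) {
    rows <- multi[multi$population == p, ]
    expect_equal(out$k[out$population == p],
                 as.integer(sum(coding[rows$color])))
    expect_equal(out$n[out$population == p], 2L * nrow(rows))
  }
  expect_s3_class(as_cline_data(dplyr::rename(out, x = distance)), "tbl_df")

  expect_error(phenotype_to_cline_counts(
    tibble::tibble(population = "p", color = "blue")), "blue")
})
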