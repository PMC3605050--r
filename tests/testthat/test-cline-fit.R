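test_that("the binomial log-likelihood matches hand and brute-force computation", {
  # one population, n = 2, k = 1, model frequency exactly 0.5
  d1 <- tibble::tibble(distance = 0, n = 2L, k = 1L)
  pars <- cline_params(center = 0, width = 5, p_left = 0, p_right = 1)
  expect_equal(cline_loglik(d1, pars), log(0.5), tolerance = 1e-12)

  # three populations against independent term-by-term summation
  d3 <- tibble::tibble(distance = c(-4, 1, 7), n = c(10L, 14L, 8L),
                       k = c(2L, 7L, 8L))
  pars <- cline_params(center = 0.5, width = 6, theta_left = 0.7,
                       theta_right = 0.9, z_left = 2, z_right = 1,
                       p_left = 0.05, p_right = 0.95)
  expect_equal(cline_loglik(d3, pars),
               brute_force_loglik(d3, cline_frequency(d3$distance, pars)),
               tolerance = 1e-12)

  # epsilon clamp keeps the likelihood finite at boundary frequencies
  dg <- tibble::tibble(distance = -1e4, n = 2L, k = 1L)
  expect_true(is.finite(cline_loglik(dg, pars)))

  expect_error(cline_loglik(tibble::tibble(distance = numeric(),
                                           n = integer(), k = integer()),
                            pars), "empty")
})

test_that("the log-likelihood ignores population order and n = 0 rows", {
  pars <- cline_params(center = 10, width = 8, p_left = 0.1, p_right = 0.9)
  d <- tibble::tibble(distance = c(2, 8, 14, 20), n = c(20L, 30L, 10L, 24L),
                      k = c(3L, 12L, 8L, 21L))
  expect_equal(cline_loglik(d[sample(4), ], pars), cline_loglik(d, pars))
  d0 <- dplyr::bind_rows(d, tibble::tibble(distance = 11, n = 0L, k = 0L))
  expect_equal(cline_loglik(d0, pars), cline_loglik(d, pars))

  fit_a <- fit_cline(d, model = "sigmoid", n_starts = 5)
  fit_b <- fit_cline(d0, model = "sigmoid", n_starts = 5)
  expect_equal(fit_a$logLik, fit_b$logLik, tolerance = 1e-6)
  expect_equal(fit_a$params$center, fit_b$params$center, tolerance = 1e-4)
})

test_that("the two-parameter fit matches an exhaustive grid search on a toy dataset", {
  d <- toy_cline_data()
  fit <- fit_cline(d, model = "sigmoid", n_starts = 8)
  grid <- grid_search_sigmoid(d, seq(-2, 22, by = 0.05), seq(0.1, 30, by = 0.05))
  expect_gte(fit$logLik, grid$logLik - 0.01)
  expect_equal(fit$params$center, grid$center, tolerance = 0.06)
})

test_that("maximum-likelihood estimates shift with the transect origin", {
  d <- toy_cline_data()
  fit0 <- fit_cline(d, model = "sigmoid", n_starts = 8)
  d_shift <- dplyr::mutate(d, distance = distance + 137)
  fit1 <- fit_cline(d_shift, model = "sigmoid", n_starts = 8)
  expect_equal(fit1$params$center, fit0$params$center + 137, tolerance = 1e-3)
  expect_equal(fit1$params$width, fit0$params$width, tolerance = 1e-3)
  expect_equal(fit1$logLik, fit0$logLik, tolerance = 1e-5)
})

test_that("the eight-parameter model never fits worse than the nested two-parameter model", {
  truth <- cline_params(center = 50, width = 8, tails = "none")
  zone <- simulate_zone(truth, positions = seq(34, 66, length.out = 20),
                        n_alleles = 60, seed = 5)
  d <- dplyr::select(zone, -locus)
  fit2 <- fit_cline(d, model = "sigmoid", n_starts = 8)
  fit8 <- fit_cline(d, model = "tails", n_starts = 15)
  expect_gte(fit8$logLik, fit2$logLik - 1e-4)

  lrt <- lrt_nested(fit8, fit2)
  expect_equal(lrt$df, 6)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p.value, chisq6_upper_tail(lrt$statistic), tolerance = 1e-8)
})

test_that("fits are reproducible and recover the simulated centre within its support interval", {
  truth <- cline_params(center = 50, width = 8, tails = "none")
  zone <- simulate_zone(truth, positions = seq(34, 66, length.out = 30),
                        n_alleles = 200, seed = 11)
  d <- dplyr::select(zone, -locus)
  fit <- fit_cline(d, model = "sigmoid", n_starts = 8, seed = 2)
  refit <- fit_cline(d, model = "sigmoid", n_starts = 8, seed = 2)
  expect_identical(tidy(fit), tidy(refit))
  sup <- cline_support(fit, "center")
  expect_gte(50, sup$lower)
  expect_lte(50, sup$upper)
})

test_that("support intervals contain the estimate, drop by 2 units, and narrow with sample size", {
  truth <- cline_params(center = 50, width = 8, tails = "none")
  zone <- simulate_zone(truth, positions = seq(34, 66, length.out = 25),
                        n_alleles = 40, seed = 3)
  d <- dplyr::select(zone, -locus)
  fit <- fit_cline(d, model = "sigmoid", n_starts = 8)
  sup <- cline_support(fit)
  expect_true(all(sup$lower <= sup$estimate & sup$estimate <= sup$upper))

  # at the returned limits the profile has dropped by 2.0 +/- 0.05
  for (i in seq_len(nrow(sup))) {
    for (lim in c(sup$lower[i], sup$upper[i])) {
      drop <- fit$logLik - profile_loglik(fit, sup$term[i], lim)
      expect_equal(drop, 2, tolerance = 0.05)
    }
  }

  d_big <- dplyr::mutate(d, n = 2L * n, k = 2L * k)
  fit_big <- fit_cline(d_big, model = "sigmoid", n_starts = 8)
  sup_big <- cline_support(fit_big, "center")
  sup_c <- sup[sup$term == "center", ]
  expect_lt(sup_big$upper - sup_big$lower, sup_c$upper - sup_c$lower)
})

test_that("degenerate and invalid datasets are handled as specified", {
  d_fixed <- tibble::tibble(distance = c(0, 5, 10), n = c(10L, 10L, 10L),
                            k = c(10L, 10L, 10L))
  expect_warning(fit <- fit_cline(d_fixed, model = "sigmoid", n_starts = 4),
                 "boundary")
  expect_true(fit$degenerate)

  expect_error(fit_cline(tibble::tibble(distance = c(0, 1), n = c(4L, 4L),
                                        k = c(1L, 2L))),
               "at least 3")
  expect_error(as_cline_data(tibble::tibble(distance = 1, n = 4L, k = 5L)),
               "0 <= k <= n")
  expect_error(fit_cline(toy_cline_data(), fixed = list(bogus = 1)), "named")
  expect_error(lrt_nested(fit, fit), "nested")
})
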