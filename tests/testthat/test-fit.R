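test_that("noise-free linear children are recovered to six decimals", {
  set.seed(51)
  dat <- tibble::tibble(A = rnorm(100), B = rnorm(100))
  dat$C <- 2 - 1.25 * dat$A + 0.75 * dat$B + rnorm(100, sd = 1e-9)
  g <- bn_dag(c("A", "B", "C"),
              tibble::tibble(from = c("A", "B"), to = "C"))
  fit <- fit_network(g, dat)
  expect_equal(unname(fit$locals$C$coefficients["A"]), -1.25,
               tolerance = 1e-6)
  expect_equal(unname(fit$locals$C$coefficients["B"]), 0.75,
               tolerance = 1e-6)
  expect_equal(fit$locals$C$intercept, 2, tolerance = 1e-6)
})

test_that("ground-truth coefficients are recovered within two standard errors", {
  truth <- cached_truth("total_pa")
  cfg <- ground_truth_config("total_pa")
  co <- sample_cohort(truth, 333, seed = 77)
  fit <- fit_network(truth$graph, co)
  tt <- tidy(fit)
  ref <- dplyr::rename(cfg$coefficients, true_coef = coef, se_ref = se)
  merged <- dplyr::inner_join(tt, ref,
                              by = c("child" = "to", "parent" = "from"))
  expect_identical(nrow(merged), nrow(ref))
  # CRP-on-BMI slope near 0.093, depression-on-insomnia log-odds near 1.0
  crp <- merged[merged$child == "logcrp", ]
  expect_lt(abs(crp$estimate - 0.093), 2 * crp$se)
  dep <- merged[merged$child == "Depression", ]
  expect_lt(abs(dep$estimate - 1.000), 2 * dep$se)
  # at most a couple of the 18 coefficients outside 2 fitted SEs (seeded)
  outside <- sum(abs(merged$estimate - merged$true_coef) > 2 * merged$se)
  expect_lte(outside, 2)
})

test_that("the activity-deconstruction refit reproduces the sedentary slope", {
  truth2 <- cached_truth("mvpa_sedentary")
  co <- sample_cohort(truth2, 333, seed = 78)
  fit <- fit_network(truth2$graph, co)
  sed <- tidy(fit)
  row <- sed[sed$child == "Sedentary" & sed$parent == "MVPA", ]
  expect_lt(abs(row$estimate - (-1.788)), 2 * row$se)
})

test_that("coefficient report merges strengths and keeps the full edge row set", {
  truth <- cached_truth("total_pa")
  co <- sample_cohort(truth, 333, seed = 79)
  fit <- fit_network(truth$graph, co)
  gs <- list(truth$graph, truth$graph)
  st <- arc_strengths(gs)
  rep1 <- coefficient_report(fit, st)
  expect_identical(nrow(rep1), nrow(truth$graph$edges))
  expect_true(all(rep1$strength == 1))
  expect_true(all(rep1$se > 0))
  expect_identical(rep1, dplyr::arrange(rep1, child, parent))
  # edges missing from the strength table warn and get NA
  st0 <- arc_strengths(list(bn_dag(truth$graph$nodes)))
  st0 <- st0[st0$from == "BMI" & st0$to == "loginsulin", ]
  expect_warning(rep2 <- coefficient_report(fit, st0), "missing")
  expect_true(anyNA(rep2$strength))
  # empty network -> empty table
  fit0 <- fit_network(bn_dag(truth$graph$nodes), co)
  expect_identical(nrow(coefficient_report(fit0)), 0L)
})

test_that("refitting reproduces the maximized local likelihood totals", {
  truth <- cached_truth("total_pa")
  co <- sample_cohort(truth, 200, seed = 80)
  rep1 <- network_bic(truth$graph, co, label = "truth")
  # independent total: per-node lm/glm logLik via stats::logLik at ML scale
  total <- 0
  for (node in truth$graph$nodes) {
    pa <- parents(truth$graph, node)
    f <- stats::as.formula(paste(node, "~",
                                 if (length(pa)) paste(pa, collapse = "+")
                                 else "1"))
    if (node %in% c("Smoke", "Insomnia", "Depression", "Arthritis")) {
      m <- stats::glm(f, data = co, family = stats::binomial())
      total <- total + as.numeric(stats::logLik(m))
    } else {
      m <- stats::lm(f, data = co)
      s2 <- mean(stats::residuals(m)^2)
      total <- total + sum(stats::dnorm(co[[node]], stats::fitted(m),
                                        sqrt(s2), log = TRUE))
    }
  }
  expect_equal(rep1$logLik, total, tolerance = 1e-6)
})

test_that("fitting errors on separation and singular designs", {
  set.seed(91)
  dat <- tibble::tibble(A = rbinom(80, 1, 0.5))
  dat$B <- dat$A                       # perfectly separated child
  g <- bn_dag(c("A", "B"), tibble::tibble(from = "A", to = "B"))
  expect_error(fit_network(g, dat), class = "behavnet_separation_error")
  dat2 <- tibble::tibble(A = rnorm(80))
  dat2$B <- 2 * dat2$A
  dat2$C <- rnorm(80)
  g2 <- bn_dag(c("A", "B", "C"),
               tibble::tibble(from = c("A", "B"), to = "C"))
  expect_error(fit_network(g2, dat2), class = "behavnet_singular_error")
})
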