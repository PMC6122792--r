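test_that("schema variants carry the expected variables and constraints", {
  s1 <- cohort_schema("total_pa")
  expect_identical(nrow(s1), 19L)
  expect_true(all(c("PA", "BMI", "loginsulin", "logcrp") %in% s1$name))
  s2 <- cohort_schema("mvpa_sedentary")
  expect_identical(nrow(s2), 20L)
  expect_true(all(c("MVPA", "Sedentary") %in% s2$name))
  expect_false("PA" %in% s2$name)
  expect_setequal(s1$name[s1$kind == "binary"],
                  c("Smoke", "Insomnia", "Depression", "Arthritis"))
  # log transform is restricted to continuous variables
  bad <- s1
  bad$transform[bad$name == "Smoke"] <- "natural_log"
  expect_error(behavnet:::validate_schema(bad), "natural_log")
})

test_that("tier blacklist forbids sink parents, root children, and CG violations", {
  s <- cohort_schema("total_pa")
  bl <- default_blacklist(s)
  expect_true(all(paste("QOLp", setdiff(s$name, "QOLp")) %in%
                    paste(bl$from, bl$to)))
  expect_true(all(paste(setdiff(s$name, "Age"), "Age") %in%
                    paste(bl$from, bl$to)))
  # continuous -> binary pairs all present
  expect_true(all(paste("BMI", c("Smoke", "Insomnia", "Depression",
                                 "Arthritis")) %in% paste(bl$from, bl$to)))
  extra <- tibble::tibble(from = "Smoke", to = "BMI")
  bl2 <- default_blacklist(s, extra)
  expect_true(any(bl2$from == "Smoke" & bl2$to == "BMI"))
  expect_error(default_blacklist(s, tibble::tibble(from = "Zz", to = "Age")),
               "unknown")
})

test_that("calibration reproduces hand-derived intercepts and residuals", {
  truth <- cached_truth("total_pa")
  # parentless node: intercept = target mean, residual = target sd
  age <- truth$locals$Age
  expect_equal(age$intercept, 63)
  expect_equal(age$residual_sd, 6.9)
  # log-CRP residual: sqrt(target_var - slope^2 * Var(BMI)) ~= 0.97
  crp <- truth$locals$logcrp
  w <- behavnet:::obesity_weight()
  target_sd <- w * 1.07 + (1 - w) * 1.05
  expect_equal(crp$residual_sd, sqrt(target_sd^2 - 0.093^2 * 4.9^2),
               tolerance = 0.02)
  # depression intercept solves the marginal prevalence equation exactly
  dep <- truth$locals$Depression
  implied <- 0.288 * plogis(dep$intercept + 1.0) +
    0.712 * plogis(dep$intercept)
  expect_equal(implied, 0.408, tolerance = 1e-6)
})

test_that("calibration errors when a marginal target is infeasible", {
  cfg <- ground_truth_config("total_pa")
  squeezed <- cfg
  squeezed$target_marginals$sd[squeezed$target_marginals$node == "logcrp"] <-
    0.05  # far below what the BMI slope alone explains
  expect_error(calibrate_network(squeezed),
               class = "behavnet_calibration_error")
})

test_that("sampling is deterministic and stable under node addition", {
  truth <- cached_truth("total_pa")
  a <- sample_cohort(truth, 100, seed = 9)
  b <- sample_cohort(truth, 100, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(truth, 100, seed = 10)))
  # per-node substreams: a node's draws do not depend on the rest of the
  # network's node set
  solo <- bn_fit(bn_dag("Age"), list(Age = truth$locals$Age), n = 333)
  expect_identical(sample_cohort(solo, 100, seed = 9)$Age, a$Age)
})

test_that("large-sample marginals hit the published targets", {
  truth <- cached_truth("total_pa")
  cfg <- ground_truth_config("total_pa")
  co <- sample_cohort(truth, 100000, seed = 2)
  marg <- cfg$target_marginals
  for (i in seq_len(nrow(marg))) {
    row <- marg[i, ]
    mom <- behavnet:::target_moments(row)
    obs <- mean(co[[row$node]])
    if (row$dist == "bernoulli") {
      expect_lt(abs(obs - row$prevalence), 0.005)
    } else {
      expect_lt(abs(obs - mom$mean), abs(mom$mean) * 0.01 + 1e-9)
    }
  }
  expect_lt(abs(mean(co$BMI) - 31.1), 0.1)
  expect_lt(abs(sd(co$BMI) - 4.9), 0.1)
  expect_lt(abs(mean(co$Arthritis) - 0.564), 0.01)
  # binary columns are exactly 0/1, and nothing is missing
  expect_true(all(co$Smoke %in% c(0, 1)))
  expect_false(anyNA(co))
})

test_that("marginal validation flags a shifted column and passes self-samples", {
  truth <- cached_truth("total_pa")
  cfg <- ground_truth_config("total_pa")
  co <- sample_cohort(truth, 50000, seed = 4)
  rep1 <- validate_marginals(co, cfg)
  expect_false(any(rep1$flag))
  co$QOLp <- co$QOLp + 10 * 18.7
  rep2 <- validate_marginals(co, cfg)
  expect_true(rep2$flag[rep2$node == "QOLp"])
  expect_identical(sum(rep2$flag), 1L)
})

test_that("replicate means of QOLp at n=333 spread per the CLT", {
  truth <- cached_truth("total_pa")
  means <- vapply(1:200, function(s)
    mean(sample_cohort(truth, 333, seed = 1000 + s)$QOLp), numeric(1))
  # SD of the replicate means should be near 18.7 / sqrt(333); chi-square
  # bounds for 200 replicates give about +/-10%
  expect_equal(sd(means), 18.7 / sqrt(333), tolerance = 0.12)
})

test_that("a residual-floor network with zero slopes is constant at intercepts", {
  g <- bn_dag(c("A", "B"), tibble::tibble(from = "A", to = "B"))
  net <- bn_fit(g, list(
    A = cpd_linear("A", intercept = 3, residual_sd = 1e-12),
    B = cpd_linear("B", "A", intercept = -2, coefficients = c(A = 0),
                   residual_sd = 1e-12)), n = 10)
  co <- sample_cohort(net, 50, seed = 1)
  expect_equal(unique(round(co$A, 6)), 3)
  expect_equal(unique(round(co$B, 6)), -2)
})

test_that("the activity-deconstruction variant calibrates and samples", {
  truth2 <- cached_truth("mvpa_sedentary")
  co <- sample_cohort(truth2, 50000, seed = 6)
  expect_lt(abs(mean(co$MVPA) - 17.5), 0.4)
  expect_lt(abs(mean(co$Sedentary) - 471), 2)
  expect_true(all(co$MVPA > 0))
  expect_true(all(co$Alcohol > 0))
  rep2 <- validate_marginals(co, ground_truth_config("mvpa_sedentary"))
  expect_false(any(rep2$flag))
})
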