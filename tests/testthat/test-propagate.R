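test_that("vacuous evidence recovers the marginal with a near-zero delta", {
  truth <- cached_truth("total_pa")
  res <- propagate(truth, "QOLp",
                   evidence_interval("BMI", -Inf, Inf),
                   evidence_interval("Age", -Inf, Inf),
                   min_accepted = 30000, batch_size = 30000, seed = 4)
  expect_lt(abs(res$delta), 0.5)
  expect_lt(abs(res$mean_a - 66.2), 0.5)
  expect_false(res$low_precision)
})

test_that("evidence on a marginally independent variable does not move the outcome", {
  truth <- cached_truth("total_pa")
  res <- propagate(truth, "QOLp",
                   evidence_quantile("Neighborhood", above = 0.75),
                   evidence_quantile("Neighborhood", below = 0.25),
                   min_accepted = 20000, batch_size = 100000, seed = 5)
  expect_lt(abs(res$delta), 0.6)
})

test_that("degenerate and unsatisfiable queries raise clean errors", {
  truth <- cached_truth("total_pa")
  expect_error(propagate(truth, "BMI",
                         evidence_interval("BMI", 30, Inf),
                         evidence_interval("BMI", -Inf, 30)),
               "degenerate")
  expect_error(propagate(truth, "QOLp",
                         evidence_interval("BMI", 500, 600),
                         evidence_interval("BMI", -Inf, Inf),
                         min_accepted = 100, batch_size = 5000,
                         max_batches = 2, seed = 1),
               class = "behavnet_rejection_error")
})

test_that("quantile evidence is resolved against the sampled marginal", {
  truth <- cached_truth("total_pa")
  ref <- sample_cohort(truth, 100000, substream_seed(9, "marginal"))
  q3 <- quantile(ref$Sleep2, 0.75, names = FALSE)
  ev <- behavnet:::resolve_evidence(
    list(evidence_quantile("Sleep2", above = 0.75)), ref)[[1]]
  expect_equal(ev$lo, q3)
  expect_identical(ev$hi, Inf)
})

test_that("propagation is deterministic given the seed", {
  truth <- cached_truth("total_pa")
  a <- propagate(truth, "loginsulin", evidence_interval("BMI", 30, Inf),
                 evidence_interval("BMI", -Inf, 30),
                 min_accepted = 20000, batch_size = 60000, seed = 12)
  b <- propagate(truth, "loginsulin", evidence_interval("BMI", 30, Inf),
                 evidence_interval("BMI", -Inf, 30),
                 min_accepted = 20000, batch_size = 60000, seed = 12)
  expect_identical(a$delta, b$delta)
})

test_that("evidence beyond a node's Markov blanket no longer moves it", {
  truth <- cached_truth("total_pa")
  # log-CRP's blanket is just BMI: fixing a narrow BMI band, additionally
  # conditioning on depression must leave the CRP mean unchanged
  blanket <- evidence_interval("BMI", 30, 33)
  res <- propagate(truth, "logcrp",
                   list(blanket),
                   list(blanket, evidence_category("Depression", 1)),
                   min_accepted = 10000, batch_size = 200000, seed = 6)
  mc_noise <- 4 * sqrt(res$sd_a^2 / res$accepted_a +
                         res$sd_b^2 / res$accepted_b)
  expect_lt(abs(res$delta), mc_noise)
})

test_that("the shipped YAML preset mirrors the built-in query table", {
  path <- system.file("extdata", "intervention_queries.yaml",
                      package = "behavnet")
  expect_true(nzchar(path))
  from_yaml <- read_queries_yaml(path)
  built_in <- intervention_queries("total_pa")
  expect_identical(nrow(from_yaml), 9L)
  expect_identical(from_yaml$outcome, built_in$outcome)
  expect_identical(from_yaml$label, built_in$label)
  # predicate-by-predicate equivalence
  for (i in seq_len(nrow(from_yaml))) {
    expect_equal(from_yaml$condition_a[[i]], built_in$condition_a[[i]],
                 info = paste("row", i))
    expect_equal(from_yaml$condition_b[[i]], built_in$condition_b[[i]],
                 info = paste("row", i))
  }
})
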