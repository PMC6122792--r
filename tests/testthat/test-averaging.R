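make_graph <- function(...) {
  ed <- list(...)
  bn_dag(c("A", "B", "C"),
         if (length(ed))
           tibble::tibble(from = vapply(ed, `[`, "", 1),
                          to = vapply(ed, `[`, "", 2))
         else NULL)
}

test_that("arc and direction strengths count occurrences correctly", {
  gs <- list(make_graph(c("A", "B")), make_graph(c("A", "B")))
  st <- arc_strengths(gs)
  g1 <- function(a, b, col) st[[col]][st$from == a & st$to == b]
  expect_equal(g1("A", "B", "strength"), 1)
  expect_equal(g1("A", "B", "direction"), 1)
  expect_equal(g1("B", "A", "strength"), 1)
  expect_equal(g1("B", "A", "direction"), 0)
  # half each way
  gs2 <- list(make_graph(c("A", "B")), make_graph(c("B", "A")))
  st2 <- arc_strengths(gs2)
  expect_equal(st2$direction[st2$from == "A" & st2$to == "B"], 0.5)
  # 2 of 3 graphs, always oriented A -> B
  gs3 <- list(make_graph(c("A", "B")), make_graph(c("A", "B")), make_graph())
  st3 <- arc_strengths(gs3)
  expect_equal(st3$strength[st3$from == "A" & st3$to == "B"], 2 / 3)
  expect_equal(st3$direction[st3$from == "A" & st3$to == "B"], 1)
  expect_equal(st3$strength[st3$from == "A" & st3$to == "C"], 0)
  expect_equal(st3$direction[st3$from == "A" & st3$to == "C"], 0)
})

test_that("direction strengths of the two orientations sum to one", {
  set.seed(23)
  gs <- replicate(30, random_dag(5, 0.4), simplify = FALSE)
  st <- arc_strengths(gs)
  pos <- st[st$strength > 0, ]
  rev_dir <- st$direction[match(paste(pos$to, pos$from),
                                paste(st$from, st$to))]
  expect_equal(pos$direction + rev_dir, rep(1, nrow(pos)))
  # mean directed edge count identity
  expect_equal(sum(st$strength * st$direction),
               mean(vapply(gs, function(g) nrow(g$edges), numeric(1))))
})

test_that("threshold selection separates a clearly bimodal strength set", {
  t1 <- significance_threshold(c(1, 1, 0, 0))
  expect_gt(t1, 0)
  expect_lte(t1, 1)
  expect_identical(sum(c(1, 1, 0, 0) >= t1), 2L)
})

test_that("threshold selection matches the direct L1 integration oracle", {
  set.seed(29)
  for (i in 1:30) {
    s <- switch(1 + i %% 3,
                round(runif(20), 2),
                c(rep(0, 10), round(rbeta(8, 5, 1), 2)),
                rep(round(runif(1), 2), 7))
    expect_equal(significance_threshold(s), threshold_oracle(s),
                 info = paste("case", i))
  }
})

test_that("identical bootstrap structures average to themselves", {
  g <- make_graph(c("A", "B"), c("B", "C"))
  avg <- averaged_network(replicate(10, g, simplify = FALSE))
  expect_identical(dplyr::arrange(avg$graph$edges, from),
                   dplyr::arrange(g$edges, from))
  # an unreachable override threshold empties the graph
  avg2 <- averaged_network(replicate(10, g, simplify = FALSE),
                           threshold_override = 1.01)
  expect_identical(nrow(avg2$graph$edges), 0L)
})

test_that("raising the threshold never adds arcs", {
  set.seed(37)
  gs <- replicate(40, random_dag(5, 0.35), simplify = FALSE)
  th <- seq(0.1, 1, by = 0.1)
  counts <- vapply(th, function(t)
    nrow(averaged_network(gs, threshold_override = t)$graph$edges),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  for (t in c(0.3, 0.7)) {
    avg <- averaged_network(gs, threshold_override = t)
    kept <- tidy(avg)
    expect_true(all(kept$strength >= t))
    expect_false(is.null(topo_sort(avg$graph)))
  }
})

test_that("exact direction ties resolve and the result stays acyclic", {
  gs <- list(make_graph(c("A", "B")), make_graph(c("B", "A")))
  avg <- averaged_network(gs, threshold_override = 0.5)
  expect_identical(nrow(avg$graph$edges), 1L)
  expect_false(is.null(topo_sort(avg$graph)))
  # lexicographic preference when both orientations are admissible
  expect_identical(avg$graph$edges$from, "A")
})

test_that("a forced identity resample reproduces the single-data fit", {
  dat <- chain_data(300, slope = 4, seed = 3)
  bl <- tibble::tibble(from = "B", to = "A")
  gs <- bootstrap_structures(dat, B = 1, blacklist = bl, seed = 1,
                             resample_fn = function(n, r) seq_len(n))
  direct <- hill_climb(dat, blacklist = bl)
  expect_identical(gs[[1]]$edges, direct$edges)
})

test_that("spurious edges on independent columns are unstable", {
  set.seed(41)
  dat <- tibble::tibble(A = rnorm(120), B = rnorm(120), C = rnorm(120))
  gs <- bootstrap_structures(dat, B = 40, seed = 2)
  st <- arc_strengths(gs)
  expect_true(all(st$strength < 0.5))
})
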