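test_that("DAG construction validates endpoints, cycles, duplicates", {
  g <- bn_dag(c("A", "B", "C"),
              tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  expect_identical(topo_sort(g), c("A", "B", "C"))
  expect_error(bn_dag(c("A", "B"), tibble::tibble(from = "A", to = "Z")),
               "not in node set")
  expect_error(bn_dag(c("A", "B"),
                      tibble::tibble(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
  expect_error(bn_dag(c("A", "B"), tibble::tibble(from = "A", to = "A")),
               "self-loop")
})

test_that("Markov blankets match the published survivor-network statements", {
  g <- fig_graph("total_pa")
  expect_setequal(markov_blanket(g, "loginsulin"),
                  c("BMI", "PA", "Age", "Sleep2"))
  expect_setequal(markov_blanket(g, "logcrp"), "BMI")
  expect_setequal(markov_blanket(g, "BMI"),
                  c("Smoke", "Arthritis", "Sleep2", "QOLp", "loginsulin",
                    "logcrp"))
  # isolated variables have empty blankets
  expect_identical(markov_blanket(g, "Neighborhood"), character(0))
  edgeless <- bn_dag(g$nodes)
  expect_identical(markov_blanket(edgeless, "BMI"), character(0))
  expect_error(markov_blanket(g, "NotAVariable"), "NotAVariable")
})

test_that("Markov blanket membership is symmetric", {
  set.seed(42)
  for (i in 1:25) {
    g <- random_dag(6, 0.35)
    for (a in g$nodes) {
      for (b in markov_blanket(g, a)) {
        expect_true(a %in% markov_blanket(g, b))
      }
    }
  }
})

test_that("d-separation reproduces the sleep-hub conditional independence", {
  g <- fig_graph("total_pa")
  expect_true(d_separated(g, c("Insomnia", "Depression", "QOLm"),
                          c("BMI", "PA", "QOLp", "loginsulin", "logcrp"),
                          c("Sleep2", "Arthritis")))
  # and it fails without the arthritis pathway blocked
  expect_false(d_separated(g, c("Depression"), c("BMI"), c("Sleep2")))
  expect_false(d_separated(bn_dag(c("A", "B"),
                                  tibble::tibble(from = "A", to = "B")),
                           "A", "B", character(0)))
  expect_error(d_separated(g, "BMI", "BMI", character(0)), "disjoint")
})

test_that("d-separation is symmetric in its two sets", {
  set.seed(7)
  for (i in 1:30) {
    g <- random_dag(6, 0.3)
    picks <- sample(g$nodes, 4)
    A <- picks[1]; B <- picks[2]; C <- picks[3:4]
    expect_identical(d_separated(g, A, B, C), d_separated(g, B, A, C))
  }
})

test_that("d-separation agrees with brute-force path enumeration", {
  set.seed(11)
  for (i in 1:150) {
    nn <- sample(4:7, 1)
    g <- random_dag(nn, 0.35)
    picks <- sample(g$nodes, min(nn, 4))
    A <- picks[1]; B <- picks[2]
    C <- if (length(picks) > 2) picks[-(1:2)][seq_len(sample(0:2, 1))]
         else character(0)
    expect_identical(d_separated(g, A, B, C),
                     d_separated_oracle(g, A, B, C),
                     info = paste("graph", i))
  }
})

test_that("factorization prints the canonical product of local terms", {
  g <- fig_graph("total_pa")
  f <- factorization(g)
  expect_match(f, "P(loginsulin|BMI)", fixed = TRUE)
  expect_match(f, "P(PA|Age,Sleep2,loginsulin)", fixed = TRUE)
  expect_match(f, "P(TumorStage)", fixed = TRUE)
  g2 <- fig_graph("mvpa_sedentary")
  expect_match(factorization(g2), "P(Sedentary|Arthritis,MVPA)", fixed = TRUE)
  expect_identical(factorization(bn_dag(c("A", "B"))), "P(A)\u22c5P(B)")
})

test_that("max in-degree matches the published structure and edge cases", {
  expect_identical(max_in_degree(fig_graph("total_pa")), 3L)
  expect_identical(max_in_degree(bn_dag(c("A", "B"))), 0L)
  g <- bn_dag(c("A", "B", "C", "D", "E"),
              tibble::tibble(from = c("A", "B", "C", "D"), to = "E"))
  expect_identical(max_in_degree(g), 4L)
})

test_that("acyclicity agrees with igraph DAG detection on random graphs", {
  set.seed(3)
  for (i in 1:40) {
    nb <- sample(3:6, 1)
    nodes <- LETTERS[1:nb]
    pairs <- expand.grid(from = nodes, to = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    ed <- pairs[stats::runif(nrow(pairs)) < 0.3, ]
    ig <- igraph::graph_from_data_frame(ed, vertices = nodes)
    ours <- !is.null(topo_sort(list(nodes = nodes,
                                    edges = tibble::as_tibble(ed))))
    expect_identical(ours, igraph::is_dag(ig))
  }
})

test_that("node isolation strips exactly the incident edges", {
  g <- fig_graph("total_pa")
  g1 <- isolate_node(g, "Sleep1")
  expect_identical(nrow(g$edges) - nrow(g1$edges), 3L)
  expect_false("Sleep1" %in% c(g1$edges$from, g1$edges$to))
  g2 <- isolate_node(g, "Sleep2")
  expect_identical(nrow(g$edges) - nrow(g2$edges), 5L)
  # already isolated: identity
  g3 <- isolate_node(g, "Neighborhood")
  expect_identical(g3$edges, g$edges)
  expect_error(isolate_node(g, "nope"), "nope")
})

test_that("edge deletion requires an existing edge", {
  g <- fig_graph("total_pa")
  g1 <- delete_edge(g, "BMI", "loginsulin")
  expect_identical(nrow(g1$edges), nrow(g$edges) - 1L)
  expect_error(delete_edge(g, "loginsulin", "BMI"),
               class = "behavnet_unknown_edge")
})
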