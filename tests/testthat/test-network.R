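mk_calls <- function(..., medium = "fresh") {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(metabolite = r[1], species = r[2], direction = r[3],
               medium = medium, stringsAsFactors = FALSE)
  }))
}

test_that("fresh-medium prediction applies the producer!=consumer rule", {
  calls <- mk_calls(
    c("X", "A", "secreted"), c("X", "B", "consumed"), c("X", "C", "consumed"),
    c("Y", "A", "secreted"), c("Y", "A", "consumed"),
    c("Z", "A", "secreted"),
    c("W", "B", "consumed"))
  pred <- predict_fresh_crossfeeding(calls)
  # X: one producer, two consumers; Y excluded (same single species);
  # Z/W lack a partner
  expect_equal(pred$metabolite, "X")
  expect_equal(pred$interaction_type, "one-to-many")
  expect_equal(pred$n_consumers, 2)
})

test_that("interaction types partition by producer/consumer set sizes", {
  calls <- mk_calls(
    c("m11", "A", "secreted"), c("m11", "B", "consumed"),
    c("m1n", "A", "secreted"), c("m1n", "B", "consumed"),
    c("m1n", "C", "consumed"),
    c("mn1", "A", "secreted"), c("mn1", "B", "secreted"),
    c("mn1", "C", "consumed"),
    c("mnn", "A", "secreted"), c("mnn", "B", "secreted"),
    c("mnn", "C", "consumed"), c("mnn", "D", "consumed"))
  pred <- predict_fresh_crossfeeding(calls)
  types <- setNames(pred$interaction_type, pred$metabolite)
  expect_equal(types[["m11"]], "one-to-one")
  expect_equal(types[["m1n"]], "one-to-many")
  expect_equal(types[["mn1"]], "many-to-one")
  expect_equal(types[["mnn"]], "many-to-many")
  # the four counts partition the cross-fed metabolites
  expect_equal(sum(table(pred$interaction_type)), nrow(pred))
})

test_that("spent network requires secretion by the producer of the medium", {
  fresh <- mk_calls(c("X", "P", "secreted"), c("Y", "Q", "secreted"))
  spent <- mk_calls(c("X", "C", "consumed"), c("Y", "C", "consumed"),
                    medium = "spent:P")
  edges <- build_spent_network(fresh, spent)
  # Y consumed in P's medium but secreted only by Q: no edge
  expect_equal(nrow(edges), 1)
  expect_equal(edges$producer, "P")
  expect_equal(edges$consumer, "C")
  expect_equal(edges$metabolite, "X")
  # self-feeding excluded
  spent_self <- mk_calls(c("X", "P", "consumed"), medium = "spent:P")
  expect_equal(nrow(build_spent_network(fresh, spent_self)), 0)
  # unknown producer id rejected
  bad <- mk_calls(c("X", "C", "consumed"), medium = "spent:ZZ")
  expect_error(build_spent_network(fresh, bad, known_producers = c("P", "Q")),
               "unknown producer")
  expect_error(build_spent_network(fresh, mk_calls(c("X", "C", "consumed"),
                                                   medium = "fresh")),
               "non-spent")
})

test_that("goods and scores match hand enumeration on a toy network", {
  edges <- data.frame(
    producer   = c("A", "A", "B", "B", "C"),
    consumer   = c("B", "C", "C", "C", "A"),
    metabolite = c("x", "x", "y", "z", "z"),
    consumed_mM = NA_real_, stringsAsFactors = FALSE)
  gs <- goods_and_scores(edges)
  s <- gs$summaries
  expect_equal(s$good_class[s$metabolite == "x"], "public")   # B and C
  expect_equal(s$good_class[s$metabolite == "y"], "private")  # C only
  expect_equal(s$good_class[s$metabolite == "z"], "public")   # C and A
  sc <- gs$scores
  expect_equal(sc$n_consumed[sc$species == "C"], 3)
  expect_equal(sc$n_secreted[sc$species == "A"], 2)
  expect_equal(sc$ratio[sc$species == "C"], 3 / 1)
  expect_equal(sc$ratio[sc$species == "A"], 1 / 2)
  # bookkeeping invariants
  expect_equal(sum(sc$n_consumed), nrow(edges))
  expect_equal(sum(sc$n_secreted), nrow(edges))
  expect_equal(sum(s$n_edges), nrow(edges))
})

test_that("pure producers score 0 and pure consumers are flagged", {
  edges <- data.frame(producer = "A", consumer = "B", metabolite = "x",
                      consumed_mM = NA_real_)
  sc <- goods_and_scores(edges)$scores
  expect_equal(sc$ratio[sc$species == "A"], 0)
  expect_true(is.na(sc$ratio[sc$species == "B"]))
})

test_that("Fisher enrichment p equals exhaustive enumeration (3,1,1,3)", {
  # hand case: two-sided p = 34/70
  expect_equal(oracle_fisher_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  summaries <- data.frame(
    metabolite = sprintf("m%d", 1:8),
    producers = "A", consumers = c(rep("B,C", 4), rep("B", 4)),
    n_producers = 1, n_consumers = c(rep(2, 4), rep(1, 4)),
    interaction_type = "one-to-many",
    good_class = c(rep("public", 4), rep("private", 4)),
    compound_class = c(rep("acid", 3), "amine", "acid", rep("amine", 3)),
    n_edges = 1, stringsAsFactors = FALSE)
  st <- network_statistics(summaries, enrich_class = "acid")
  expect_equal(st$enrichment$p, 34 / 70, tolerance = 1e-7)
})

test_that("stats::fisher.test agrees with enumeration for all tables N<=30", {
  worst <- 0
  for (N in 2:30) {
    for (r1 in 1:(N - 1)) {
      for (c1 in 1:(N - 1)) {
        lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
        for (a in lo:hi) {
          b <- r1 - a; c <- c1 - a; d <- N - r1 - c1 + a
          p1 <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
          p2 <- oracle_fisher_p(a, b, c, d)
          worst <- max(worst, abs(p1 - p2))
        }
      }
    }
  }
  expect_lt(worst, 1e-7)
})

test_that("covariate correlation is exact on proportional data and guarded", {
  summaries <- data.frame(
    metabolite = c("x", "y", "z"),
    producers = "D",
    consumers = c("A,B,C", "B,C", "C"),
    n_producers = 1, n_consumers = c(3, 2, 1),
    interaction_type = "one-to-many",
    good_class = c("public", "public", "private"),
    compound_class = NA_character_, n_edges = 1, stringsAsFactors = FALSE)
  # counts: A=1, B=2, C=3
  cov <- c(A = 2, B = 4, C = 6)
  st <- network_statistics(summaries, species_covariate = cov)
  expect_equal(st$covariate$r, 1)
  expect_error(network_statistics(summaries,
                                  species_covariate = c(A = 1, B = 1, C = 1)),
               "zero-variance")
  expect_error(network_statistics(summaries,
                                  species_covariate = c(A = 1, B = 2)),
               ">= 3 species")
})

test_that("graphml export round-trips nodes and edge attributes", {
  edges <- data.frame(producer = c("A", "B"), consumer = c("B", "C"),
                      metabolite = c("x", "y"), consumed_mM = c(1.5, NA))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(edges, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$metabolite, c("x", "y"))
})
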