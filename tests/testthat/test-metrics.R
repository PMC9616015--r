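test_that("tie counting uses the ordered-pair convention", {
  expect_equal(countTies(graph_with_edges(135, 1684)), 3368L)
  expect_equal(countTies(matrix(0L, 4, 4,
                                dimnames = list(letters[1:4],
                                                letters[1:4]))), 0L)
  expect_equal(countTies(complete_matrix(4)), 12L)
})

test_that("density and average degree recompute the comparison-table values", {
  # each (n, ordered ties) pair printed in the cross-network tables must
  # reproduce the printed density (3 dp) and average degree (2 dp)
  cases <- list(
    list(n = 135, ties = 3368, density = 0.186, avg = 24.95),
    list(n = 86,  ties = 1728, density = 0.236, avg = 20.09),
    list(n = 75,  ties = 1950, density = 0.351, avg = 26.00),
    list(n = 135, ties = 2102, density = 0.116, avg = 15.57),
    list(n = 86,  ties = 1026, density = 0.140, avg = 11.93),
    list(n = 75,  ties = 1056, density = 0.190, avg = 14.08))
  for (cs in cases) {
    m <- graph_with_edges(cs$n, cs$ties / 2)
    expect_equal(countTies(m), cs$ties)
    expect_equal(round(tieDensity(m), 3), cs$density)
    expect_equal(round(averageDegree(m), 2), cs$avg)
  }
  expect_equal(tieDensity(complete_matrix(6)), 1.0)
  expect_equal(averageDegree(matrix(0L, 3, 3,
                                    dimnames = list(letters[1:3],
                                                    letters[1:3]))), 0)
  expect_error(tieDensity(matrix(0L, 1, 1, dimnames = list("a", "a"))),
               "undefined")
})

test_that("isolate and active-organization summaries round as in the tables", {
  pad_isolates <- function(m, k) {
    n <- nrow(m) + k
    ids <- sprintf("o%03d", seq_len(n))
    out <- matrix(0L, n, n, dimnames = list(ids, ids))
    out[seq_len(nrow(m)), seq_len(nrow(m))] <- m
    out
  }
  m <- pad_isolates(graph_with_edges(132, 1051), 3)  # 135 orgs, 3 isolates
  s <- isolateSummary(m)
  expect_equal(s$isolates, 3L)
  expect_equal(s$active, 132L)
  expect_equal(s$active_pct, 98L)

  m2 <- pad_isolates(graph_with_edges(80, 513), 6)   # 86 orgs, 6 isolates
  s2 <- isolateSummary(m2)
  expect_equal(s2$active, 80L)
  expect_equal(s2$active_pct, 93L)

  s3 <- isolateSummary(complete_matrix(7))
  expect_equal(s3$isolates, 0L)
  expect_equal(s3$active_pct, 100L)
})

test_that("degree centrality matches row sums and normalizes by n-1", {
  n <- 9
  m <- star_matrix(n)
  dc <- degreeCentrality(m)
  expect_equal(dc$normalized_degree[dc$org_id == "o01"], 1.0)
  iso <- rbind(cbind(m, 0L), 0L)
  rownames(iso) <- colnames(iso) <- sprintf("o%02d", 1:(n + 1))
  dci <- degreeCentrality(iso)
  expect_equal(dci$degree[dci$org_id == sprintf("o%02d", n + 1)], 0L)
  set.seed(11)
  for (rep in 1:10) {
    r <- rand_sym_matrix(15, runif(1, 0.1, 0.6))
    dcr <- degreeCentrality(r)
    expect_equal(stats::setNames(dcr$degree, dcr$org_id)[rownames(r)],
                 naive_degrees(r))
    expect_equal(sum(dcr$degree), countTies(r))  # handshake
  }
})

test_that("degree centralization hits the star and regular closed forms", {
  for (n in c(3, 5, 12)) {
    expect_equal(degreeCentralization(star_matrix(n)), 1.0)
    expect_equal(degreeCentralization(cycle_matrix(n)), 0.0)
    expect_equal(degreeCentralization(complete_matrix(n)), 0.0)
  }
  expect_error(degreeCentralization(complete_matrix(2)), "undefined")
})

test_that("all metrics agree with naive-loop oracles on 200 random graphs", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(3:20, 1)
    m <- rand_sym_matrix(n, runif(1, 0.05, 0.8))
    expect_identical(countTies(m), naive_ties(m))
    expect_equal(tieDensity(m), naive_density(m))
    expect_equal(averageDegree(m), naive_avg_degree(m))
    expect_equal(isolateSummary(m)$isolates, naive_isolates(m))
    expect_equal(degreeCentralization(m), naive_centralization(m))
  }
})

test_that("degree and density also match an independent graph library", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    m <- rand_sym_matrix(n, runif(1, 0.1, 0.7))
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    expect_equal(unname(sort(degreeCentrality(m)$degree)),
                 unname(sort(igraph::degree(g))))
    expect_equal(tieDensity(m), igraph::edge_density(g))
  }
})

test_that("centralization stays within [0,1] on every graph with up to 5 nodes", {
  for (n in 3:5) {
    for (m in all_graphs(n)) {
      cz <- degreeCentralization(m)
      expect_gte(cz, 0)
      expect_lte(cz, 1)
    }
  }
})

test_that("adding an edge never decreases density or average degree", {
  set.seed(77)
  for (rep in 1:20) {
    m <- rand_sym_matrix(10, 0.3)
    free <- which(upper.tri(m) & m == 0L)
    if (!length(free)) next
    pick <- sample(free, 1)
    m2 <- m
    m2[pick] <- 1L
    m2 <- naive_symmetrize(m2)
    expect_gte(tieDensity(m2), tieDensity(m))
    expect_gte(averageDegree(m2), averageDegree(m))
  }
})

test_that("the ranked centrality table annotates and orders deterministically", {
  sv <- generateSurvey(syntheticConfig(n_orgs = 40L, seed = 12L))
  adj <- adjacencyFromMatrix(sv$truth@contact)
  top <- topCentral(adj, sv$roster, k = 10L)
  expect_equal(nrow(top), 10L)
  expect_true(all(diff(top$degree) <= 0))
  expect_identical(top$gatekeeper,
                   vapply(orgTasks(sv$roster)[top$org_id],
                          function(v) "gatekeeper" %in% v, TRUE,
                          USE.NAMES = FALSE))
  # k = n returns the full table
  expect_equal(nrow(topCentral(adj, sv$roster, k = 40L)), 40L)
  # a planted hub of degree n-1 is ranked first
  m <- adjMatrix(adj)
  m["org005", ] <- 1L; m[, "org005"] <- 1L; diag(m) <- 0L
  top1 <- topCentral(adjacencyFromMatrix(m), sv$roster, k = 1L)
  expect_equal(top1$org_id, "org005")
  expect_equal(top1$normalized_degree, 1.0)
})

test_that("metric panels satisfy the arithmetic identities", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    adj <- adjacencyFromMatrix(rand_sym_matrix(n, runif(1, 0.1, 0.5)))
    p <- metricsPanel(adj)
    expect_equal(p@density * n * (n - 1), p@ties_ordered)
    expect_equal(p@avg_degree * n, p@ties_ordered)
    expect_equal(p@active_orgs + p@isolates, p@n_orgs)
    expect_equal(p@ties_ordered %% 2, 0)
  }
})
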