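test_that("co-occurrence edges follow the count threshold definition", {
  n <- 100
  A <- matrix(0L, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  A[1:30, "A"] <- 1L; A[1:30, "B"] <- 1L      # co-present in 30
  A[31:35, "C"] <- 1L; A[31:35, "A"] <- 1L    # co-present in 5 only
  net <- build_cooccurrence_network(pm_from_matrix(A), min_node_prev = 0.01,
                                    min_edge_count = 10)
  e <- net$edges[u == "A" & v == "B"]
  expect_equal(e$count, 30)
  expect_equal(e$support, 0.3)
  expect_false(any(net$edges$u == "C" | net$edges$v == "C"))
  # never co-present: no edge
  B <- matrix(0L, n, 2, dimnames = list(NULL, c("X", "Y")))
  B[1:20, "X"] <- 1L; B[21:40, "Y"] <- 1L
  net2 <- build_cooccurrence_network(pm_from_matrix(B), min_edge_count = 1)
  expect_equal(nrow(net2$edges), 0L)
  # node prevalence floor removes rare conditions
  net3 <- build_cooccurrence_network(pm_from_matrix(A), min_node_prev = 0.1,
                                     min_edge_count = 10)
  expect_false("C" %in% net3$nodes$condition)
})

test_that("degree centrality matches closed forms and the brute-force oracle", {
  # path A-B-C
  M <- matrix(0L, 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  M[1:20, c("A", "B")] <- 1L
  M[21:40, c("B", "C")] <- 1L
  net <- build_cooccurrence_network(pm_from_matrix(M), min_edge_count = 5)
  expect_equal(net$centrality[["B"]], 1)
  expect_equal(net$centrality[["A"]], 0.5)
  # complete graph on 4 nodes
  K <- matrix(1L, 30, 4, dimnames = list(NULL, letters[1:4]))
  netk <- build_cooccurrence_network(pm_from_matrix(K), min_edge_count = 5)
  expect_true(all(netk$centrality == 1))
  # isolated node scores zero (D present only in rows where others are absent)
  M2 <- rbind(cbind(M, D = 0L),
              matrix(c(0L, 0L, 0L, 1L), 10, 4, byrow = TRUE,
                     dimnames = list(NULL, c("A", "B", "C", "D"))))
  net2 <- build_cooccurrence_network(pm_from_matrix(M2), min_edge_count = 5)
  expect_equal(net2$centrality[["D"]], 0)
  # random graphs vs oracle (and igraph when available)
  set.seed(41)
  for (i in 1:100) {
    nv <- sample(3:30, 1)
    nodes <- paste0("n", seq_len(nv))
    ne <- sample(0:(nv * (nv - 1) / 2), 1)
    all_pairs <- t(utils::combn(nodes, 2))
    pick <- all_pairs[sample(nrow(all_pairs), min(ne, nrow(all_pairs))), ,
                      drop = FALSE]
    fake <- structure(list(
      nodes = data.table::data.table(condition = nodes),
      edges = data.table::data.table(u = pick[, 1], v = pick[, 2])),
      class = "comorbidity_network")
    got <- degree_centrality(fake)
    expect_equal(got, oracle_degree_centrality(nodes, fake$edges))
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::sample_gnp(25, 0.2)
    igraph::V(g)$name <- paste0("v", 1:25)
    el <- igraph::as_edgelist(g)
    fake <- structure(list(
      nodes = data.table::data.table(condition = paste0("v", 1:25)),
      edges = data.table::data.table(u = el[, 1], v = el[, 2])),
      class = "comorbidity_network")
    expect_equal(unname(degree_centrality(fake)[paste0("v", 1:25)]),
                 unname(igraph::degree(g) / 24))
  }
})

test_that("edge sets are invariant to participant and column permutation", {
  set.seed(42)
  M <- matrix(rbinom(600, 1, 0.3), 100, 6,
              dimnames = list(NULL, paste0("c", 1:6)))
  net <- build_cooccurrence_network(pm_from_matrix(M), min_edge_count = 5)
  Mp <- M[sample(nrow(M)), sample(ncol(M))]
  netp <- build_cooccurrence_network(pm_from_matrix(Mp), min_edge_count = 5)
  key <- function(n) sort(paste(pmin(n$edges$u, n$edges$v),
                                pmax(n$edges$u, n$edges$v)))
  expect_identical(key(net), key(netp))
})

test_that("characteristic conditions implement the dual-control logic", {
  mk <- function(conds, window) {
    structure(list(
      nodes = data.table::data.table(condition = conds),
      edges = data.table::data.table(u = character(0), v = character(0)),
      n = 100, window = window, cohort = NA), class = "comorbidity_network")
  }
  wlabs <- c("15-20 before", "10-15 before")
  cohort <- list(mk(c("A", "B", "C"), wlabs[1]), mk(c("A", "B"), wlabs[2]))
  control <- list(mk("B", wlabs[1]), mk("B", wlabs[2]))
  names(cohort) <- names(control) <- wlabs
  cc <- characteristic_conditions(cohort, control,
                                  disease_characteristic = "C",
                                  mwu_significant = "A")
  # A and C are cohort-only in window 1 -> new; A re-occurs in window 2
  expect_equal(cc[window == wlabs[1] & condition == "A", status], "new")
  expect_equal(cc[window == wlabs[2] & condition == "A", status], "re-occurring")
  # B is in the control net -> never characteristic
  expect_false("B" %in% cc$condition)
  # C is characteristic of the control disease too -> not validated
  expect_false(cc[condition == "C", validated])
  expect_true(cc[window == wlabs[1] & condition == "A", validated])
  expect_true(cc[condition == "A", mwu_overlap][1])
  # missing control window is skipped with a warning
  expect_warning(characteristic_conditions(cohort, control[1]), "skipped")
})

test_that("null cohorts yield few characteristic conditions per window", {
  set.seed(43)
  n <- 1000; p <- 40
  prevs <- runif(p, 0.005, 0.2)
  reps <- 20
  frac <- numeric(reps)
  for (r in seq_len(reps)) {
    A <- matrix(rbinom(n * p, 1, rep(prevs, each = n)), n, p,
                dimnames = list(NULL, paste0("c", 1:p)))
    B <- matrix(rbinom(n * p, 1, rep(prevs, each = n)), n, p,
                dimnames = list(NULL, paste0("c", 1:p)))
    na <- build_cooccurrence_network(pm_from_matrix(A))
    nb <- build_cooccurrence_network(pm_from_matrix(B))
    cc <- characteristic_conditions(list(w = na), list(w = nb))
    frac[r] <- nrow(cc) / p
  }
  expect_lt(mean(frac), 0.05)
})

test_that("Bayesian network learner recovers a chain and stays empty on noise", {
  set.seed(44)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  y <- ifelse(runif(n) < 0.9, x, 1 - x)
  z <- ifelse(runif(n) < 0.9, y, 1 - y)
  M <- cbind(X = x, Y = y, Z = z)
  fit <- learn_bayesian_network(M, seed = 1)
  skel <- unique(t(apply(as.matrix(fit$edges[, .(from, to)]), 1, sort)))
  skel <- paste(skel[, 1], skel[, 2])
  expect_setequal(skel, c("X Y", "Y Z"))
  # independent columns: empty graph in most seeds
  empties <- 0L
  for (s in 1:30) {
    M0 <- matrix(rbinom(n * 4, 1, 0.3), n, 4,
                 dimnames = list(NULL, paste0("V", 1:4)))
    f0 <- learn_bayesian_network(M0, seed = s)
    empties <- empties + (nrow(f0$edges) == 0L)
  }
  expect_gte(empties / 30, 0.9)
  # BIC penalty dominates at tiny n: near-orthogonal balanced columns give a
  # log-likelihood gain (~0.2 nats) far below the log(10)/2 ~ 1.15 penalty
  Mt <- cbind(A = rep(c(1L, 0L), each = 5),
              B = c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L),
              C = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  ft <- learn_bayesian_network(Mt, seed = 1, prevalence_floor = 0)
  expect_equal(nrow(ft$edges), 0L)
  expect_error(learn_bayesian_network(M[, 1, drop = FALSE]), "2 columns")
})

test_that("network export writes edge list and GraphML", {
  M <- matrix(0L, 50, 2, dimnames = list(NULL, c("A", "B")))
  M[1:20, ] <- 1L
  net <- build_cooccurrence_network(pm_from_matrix(M), min_edge_count = 5)
  tmp <- withr::local_tempdir()
  export_network(net, path_csv = file.path(tmp, "e.csv"),
                 path_graphml = file.path(tmp, "e.graphml"))
  expect_true(file.exists(file.path(tmp, "e.csv")))
  gml <- readLines(file.path(tmp, "e.graphml"))
  expect_true(any(grepl("edge source", gml)))
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::read_graph(file.path(tmp, "e.graphml"), format = "graphml")
    expect_equal(igraph::gsize(g), nrow(net$edges))
  }
})
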