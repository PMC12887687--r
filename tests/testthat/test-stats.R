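test_that("Mann-Whitney U statistic and exact p match stated examples", {
  r <- mann_whitney_binary(c(1, 1, 1, 0), c(0, 0, 0, 0))
  expect_equal(r$U, 14)
  # identical groups: no difference
  expect_equal(mann_whitney_binary(c(0, 1, 1), c(0, 1, 1))$p, 1)
  expect_equal(mann_whitney_binary(rep(2, 4), rep(2, 5))$p, 1)
  # fully separated 5 vs 5: exact enumeration gives 2/choose(10,5)
  r <- mann_whitney_binary(rep(1, 5), rep(0, 5))
  expect_equal(r$U, 25)
  expect_equal(r$p, 2 / choose(10, 5))
})

test_that("exact p equals the combn enumeration oracle for small samples with ties", {
  set.seed(31)
  for (i in 1:40) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- sample(0:2, n1, TRUE); b <- sample(0:2, n2, TRUE)
    got <- mann_whitney_binary(a, b)
    if (length(unique(c(a, b))) == 1L) {
      expect_equal(got$p, 1)
    } else {
      expect_equal(got$p, oracle_mwu_exact(a, b), tolerance = 1e-12)
    }
  }
})

test_that("large-sample path agrees with wilcox.test and swapping groups", {
  set.seed(32)
  a <- rbinom(300, 1, 0.3); b <- rbinom(280, 1, 0.2)
  got <- mann_whitney_binary(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # U(a,b) + U(b,a) = n*m and p invariant under swap
  swp <- mann_whitney_binary(b, a)
  expect_equal(got$U + swp$U, length(a) * length(b))
  expect_equal(got$p, swp$p, tolerance = 1e-12)
})

test_that("vectorized binary-column path equals the scalar path", {
  set.seed(33)
  A <- matrix(rbinom(200 * 8, 1, runif(8, 0.05, 0.5)[rep(1:8, each = 200)]),
              200, 8, dimnames = list(NULL, paste0("c", 1:8)))
  B <- matrix(rbinom(250 * 8, 1, 0.2), 250, 8,
              dimnames = list(NULL, paste0("c", 1:8)))
  res <- compare_prevalence(pm_from_matrix(A), pm_from_matrix(B),
                            prevalence_floor = 0)
  for (j in res$condition) {
    ref <- mann_whitney_binary(A[, j], B[, j], exact_limit = 0)
    expect_equal(res[condition == j, U], ref$U)
    expect_equal(res[condition == j, p], ref$p, tolerance = 1e-12)
  }
})

test_that("bonferroni and BH adjustments follow their closed forms", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 5), 1)
  expect_equal(bonferroni_adjust(c(0.001, 0.02), 2), c(0.002, 0.04))
  expect_error(bonferroni_adjust(0.1, 0), "m")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "m")
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.04, 0.001)), c(0.04, 0.002))
  # order equivariance
  set.seed(34)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_equal(bonferroni_adjust(p, 25)[perm], bonferroni_adjust(p[perm], 25))
})

test_that("compare_prevalence finds a planted 3x prevalence shift and ranks by p", {
  set.seed(35)
  n <- 1000
  A <- cbind(X = rbinom(n, 1, 0.15), Y = rbinom(n, 1, 0.05),
             Z = rbinom(n, 1, 0.3))
  B <- cbind(X = rbinom(n, 1, 0.05), Y = rbinom(n, 1, 0.05),
             Z = rbinom(n, 1, 0.3))
  res <- compare_prevalence(pm_from_matrix(A), pm_from_matrix(B))
  expect_true("X" %in% res[significant == TRUE, condition])
  expect_false("Y" %in% res[significant == TRUE, condition])
  expect_equal(res$p, sort(res$p))
  expect_lte(nrow(top_conditions(res, 2)), 2)
  # cohort identical to control: nothing significant
  res0 <- compare_prevalence(pm_from_matrix(A), pm_from_matrix(A))
  expect_equal(sum(res0$significant), 0L)
  expect_true(all(res0$p == 1))
})

test_that("compare_prevalence honors the prevalence floor and flags degenerate columns", {
  set.seed(36)
  A <- cbind(rare = rbinom(400, 1, 0.001), none = 0L,
             common = rbinom(400, 1, 0.2))
  B <- cbind(rare = rbinom(400, 1, 0.001), none = 0L,
             common = rbinom(400, 1, 0.2))
  res <- compare_prevalence(pm_from_matrix(A), pm_from_matrix(B),
                            prevalence_floor = 0.005)
  expect_false(any(c("rare", "none") %in% res$condition))
  res2 <- compare_prevalence(pm_from_matrix(A[, "none", drop = FALSE]),
                             pm_from_matrix(B[, "none", drop = FALSE]),
                             prevalence_floor = 0)
  expect_true(res2$degenerate)
  expect_equal(res2$p, 1)
})

test_that("PRS comparisons detect a shifted group and respect the null", {
  set.seed(37)
  sc <- data.table::data.table(
    group = rep(c("AD", "VaD", "control"), each = 1000),
    prs = c(rnorm(1000, 0.5), rnorm(1000, 0.25), rnorm(1000)))
  res <- compare_prs(sc)
  expect_equal(nrow(res), 3L)
  expect_lt(res[group1 == "AD" & group2 == "control", p_adj], 0.05)
  # degenerate constant groups compare as equal
  scc <- data.table::data.table(group = rep(c("AD", "control"), each = 10),
                                prs = 1)
  # VaD is missing from both pairs involving it -> two warnings
  expect_warning(expect_warning(res2 <- compare_prs(scc), "missing group"),
                 "missing group")
  expect_equal(res2[group1 == "AD" & group2 == "control", p], 1)
  # null: three same-distribution groups rarely yield any significance
  hits <- 0L
  for (i in 1:60) {
    sc0 <- data.table::data.table(
      group = rep(c("AD", "VaD", "control"), each = 150), prs = rnorm(450))
    hits <- hits + any(compare_prs(sc0)$p_adj < 0.05)
  }
  expect_lte(hits / 60, 0.15)
})
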