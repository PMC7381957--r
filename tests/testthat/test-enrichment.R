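sets_tbl <- function(...) {
  l <- list(...)
  tibble::tibble(set_id = names(l), description = names(l), genes = unname(l))
}

test_that("ORA reproduces the analytic hypergeometric values", {
  universe <- paste0("g", 1:20)
  sets <- sets_tbl(s1 = paste0("g", 1:5))
  res <- ora(paste0("g", 1:5), sets, universe)
  # all five selected inside the five-member set: p = 1 / C(20, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 6.449e-5, tolerance = 1e-3)
  expect_equal(res$rich_factor, 1)

  # zero overlap: upper tail P(X >= 0) = 1
  res0 <- ora(paste0("g", 6:10), sets_tbl(s1 = paste0("g", 1:3)), universe)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)

  expect_error(ora(character(0), sets, universe), "non-empty")
  expect_error(ora("zz", sets, universe), "subset")
})

test_that("ORA matches full enumeration on small universes", {
  set.seed(31)
  for (trial in 1:20) {
    N <- sample(10:25, 1)
    set_n <- sample(2:6, 1)
    sel_n <- sample(2:6, 1)
    universe <- paste0("g", seq_len(N))
    sets <- sets_tbl(s1 = paste0("g", seq_len(set_n)))
    selected <- sample(universe, sel_n)
    res <- ora(selected, sets, universe)
    expect_equal(res$p, oracle_ora_p(N, set_n, sel_n, res$overlap), tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the standard step-up arithmetic", {
  universe <- paste0("g", 1:30)
  sets <- sets_tbl(a = paste0("g", 1:5), b = paste0("g", 6:10), c = paste0("g", 11:15))
  res <- ora(paste0("g", c(1:4, 6, 11)), sets, universe)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_true(all(res$p_adj >= res$p))
  # BH on (0.01, 0.02, 0.03) over 3 tests gives (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("preranked GSEA has its closed-form extremes", {
  ranked <- tibble::tibble(feature_id = paste0("f", 1:10), score = 10:1)
  # single top-ranked member, weight 0: running sum jumps to 1 immediately
  res <- suppressWarnings(
    gsea_preranked(ranked, sets_tbl(top = "f1", spare = c("f2", "f3")),
                   weight = 0, n_perm = 50, seed = 1)
  )
  expect_equal(unname(res$es[res$set_id == "top"]), 1)
  # direct running-sum enumeration agrees
  in_set <- c(TRUE, rep(FALSE, 9))
  expect_equal(oracle_gsea_es(in_set, 10:1, weight = 0), 1)

  # a set covering the whole ranking is skipped with a warning
  expect_warning(
    gsea_preranked(ranked, sets_tbl(all = paste0("f", 1:10)), n_perm = 10, seed = 1),
    "skipping"
  )
  # a set with no member in the ranking is skipped too
  expect_warning(
    gsea_preranked(ranked, sets_tbl(none = c("zz", "yy")), n_perm = 10, seed = 1),
    "skipping"
  )

  # reversing the ranking negates the unweighted ES
  set.seed(2)
  sets <- sets_tbl(s = sample(ranked$feature_id, 3))
  up <- suppressWarnings(gsea_preranked(ranked, sets, weight = 0, n_perm = 20, seed = 3))
  down <- suppressWarnings(gsea_preranked(
    ranked |> dplyr::mutate(score = -score), sets, weight = 0, n_perm = 20, seed = 3
  ))
  expect_equal(up$es, -down$es)

  expect_error(gsea_preranked(tibble::tibble(feature_id = c("a", "a"), score = 1:2),
                              sets_tbl(s = "a")), "duplicated")
})

test_that("unweighted |ES| is bounded by 1 over random sets", {
  set.seed(17)
  ranked <- tibble::tibble(feature_id = paste0("f", 1:50), score = rnorm(50))
  ess <- vapply(1:1000, function(i) {
    members <- sample(ranked$feature_id, sample(2:20, 1))
    in_set <- ranked$feature_id[order(ranked$score, decreasing = TRUE)] %in% members
    lncreg:::gsea_es(in_set, sort(ranked$score, decreasing = TRUE), weight = 0)
  }, numeric(1))
  expect_true(all(abs(ess) <= 1 + 1e-12))
})

test_that("enrichment scores agree with the reference preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(41)
  scores <- sort(rnorm(60), decreasing = TRUE)
  names(scores) <- paste0("f", 1:60)
  for (trial in 1:10) {
    members <- sample(names(scores), sample(3:15, 1))
    in_set <- names(scores) %in% members
    mine <- lncreg:::gsea_es(in_set, unname(scores), weight = 1)
    ref <- fgsea::calcGseaStat(unname(scores), selectedStats = which(in_set), gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("permutation p-values are reproducible and bounded", {
  set.seed(6)
  ranked <- tibble::tibble(feature_id = paste0("f", 1:40), score = c(rnorm(5, 3), rnorm(35)))
  sets <- sets_tbl(hot = paste0("f", 1:5), cold = paste0("f", 30:35))
  a <- gsea_preranked(ranked, sets, n_perm = 200, seed = 9)
  b <- gsea_preranked(ranked, sets, n_perm = 200, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$p >= 1 / 201 & a$p <= 1))
  expect_lt(a$p[a$set_id == "hot"], 0.05)
})
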