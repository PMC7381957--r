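make_counts <- function(m, groups) {
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  as_expr_tbl(
    tibble::as_tibble(cbind(tibble::tibble(feature_id = paste0("f", seq_len(nrow(m)))),
                            as.data.frame(m))),
    tibble::tibble(sample_id = colnames(m), group = groups)
  )
}

test_that("FPKM matches hand arithmetic and its invariances", {
  # one feature with k=10, L=1000, plus filler bringing the column sum to 1e6
  m <- matrix(c(10, 1e6 - 10), ncol = 1)
  x <- make_counts(cbind(m, m), c("control", "control"))
  fpkm <- compute_fpkm(x, c(f1 = 1000, f2 = 1000))
  expect_equal(fpkm$s1[1], 10) # 10 * 1e9 / (1e3 * 1e6)

  # zero count gives zero FPKM
  x0 <- make_counts(matrix(c(0, 100), ncol = 1), "control")
  expect_equal(compute_fpkm(x0, c(f1 = 500, f2 = 500))$s1[1], 0)

  # doubling every count of a sample leaves its FPKM column unchanged
  m2 <- matrix(rpois(20, 50) + 1, ncol = 2)
  a <- compute_fpkm(make_counts(m2, c("control", "case1")), setNames(rep(100, 10), paste0("f", 1:10)))
  m2[, 2] <- m2[, 2] * 2
  b <- compute_fpkm(make_counts(m2, c("control", "case1")), setNames(rep(100, 10), paste0("f", 1:10)))
  expect_equal(a$s2, b$s2)

  expect_error(compute_fpkm(make_counts(matrix(c(0, 0), ncol = 1), "control"),
                            c(f1 = 100, f2 = 100)), "empty sample")
})

test_that("size factors follow the median-of-ratios closed forms", {
  # identical columns give unit factors
  m <- matrix(rep(c(5, 10, 20), 3), ncol = 3)
  sf <- estimate_size_factors(make_counts(m, rep("control", 3)))
  expect_equal(sf$size_factor, rep(1, 3))

  # single feature, counts (2, 8): ratios to geometric mean 4 are (0.5, 2)
  sf2 <- estimate_size_factors(make_counts(matrix(c(2, 8), ncol = 2), rep("control", 2)))
  expect_equal(sf2$size_factor, c(0.5, 2))

  # doubling one column doubles its factor relative to the others
  set.seed(1)
  m3 <- matrix(rpois(150, 100) + 1, ncol = 3)
  base <- estimate_size_factors(make_counts(m3, rep("control", 3)))
  m3[, 2] <- m3[, 2] * 2
  doubled <- estimate_size_factors(make_counts(m3, rep("control", 3)))
  expect_equal(doubled$size_factor[2] / doubled$size_factor[1],
               2 * base$size_factor[2] / base$size_factor[1], tolerance = 1e-12)

  expect_error(estimate_size_factors(make_counts(matrix(c(0, 1, 1, 0), 2), rep("control", 2))),
               "filter")
})

test_that("the exact test is symmetric and null-calibrated at the Poisson boundary", {
  set.seed(42)
  m <- matrix(rpois(10 * 20, 100), ncol = 10)
  x <- make_counts(m, rep(c("control", "case2"), each = 5))
  res <- nb_exact_test(x, "control", "case2")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # swapping group labels negates log2fc and leaves p unchanged
  swapped <- nb_exact_test(x, "case2", "control")
  expect_equal(swapped$log2fc, -res$log2fc)
  expect_equal(swapped$p_value, res$p_value)

  # equal group sums at equal sizes give p = 1 (symmetric null mode)
  eq <- make_counts(matrix(rep(50, 10 * 3), ncol = 10), rep(c("control", "case2"), each = 5))
  sf1 <- tibble::tibble(sample_id = paste0("s", 1:10), size_factor = rep(1, 10))
  req <- nb_exact_test(eq, "control", "case2", sf1)
  expect_true(all(req$p_value > 0.999))
})

test_that("all-zero features are flagged with p = 1 and zero fold change", {
  m <- rbind(matrix(rpois(10 * 5, 50), ncol = 10), 0)
  x <- make_counts(m, rep(c("control", "case2"), each = 5))
  res <- nb_exact_test(x, "control", "case2")
  expect_true(res$all_zero[6])
  expect_equal(res$p_value[6], 1)
  expect_equal(res$log2fc[6], 0)
})

test_that("call_de applies strict-p and inclusive-fold-change boundaries", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(0.5, -1.0, 2, 1.5),
    p_value = c(0.01, 0.04, 0.05, 0.001)
  )
  called <- call_de(res)
  expect_false("a" %in% called$feature_id) # |lfc| below 1 despite small p
  expect_true("b" %in% called$feature_id)  # boundary |lfc| = 1 passes >=
  expect_false("c" %in% called$feature_id) # p = 0.05 fails strict <
  expect_equal(called$direction[called$feature_id == "b"], "down")
  expect_equal(called$direction[called$feature_id == "d"], "up")
})

test_that("partition_sets computes the disjoint Venn partition", {
  part <- partition_sets(paste0("g", 1:5), paste0("g", 4:8))
  expect_setequal(part$feature_id[part$set_label == "common"], c("g4", "g5"))
  expect_setequal(part$feature_id[part$set_label == "case1_specific"], c("g1", "g2", "g3"))
  expect_setequal(part$feature_id[part$set_label == "case2_specific"], c("g6", "g7", "g8"))
  expect_equal(anyDuplicated(part$feature_id), 0L)

  disjoint <- partition_sets(c("a", "b"), c("c"))
  expect_length(disjoint$feature_id[disjoint$set_label == "common"], 0)
})

test_that("broom-style accessors summarise a differential result", {
  st <- default_study()
  res <- nb_exact_test(st$counts, "control", "case2")
  g <- glance(res)
  expect_equal(g$n_de, nrow(call_de(res)))
  expect_equal(g$group_b, "case2")
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
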