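fixture_regulation <- function() {
  # a common gene regulated by one case1-specific, one case2-specific and
  # one common lncRNA, plus a second gene with trans regulators only
  reg <- tibble::tibble(
    lncrna_id = c("l1", "l2", "l3", "l1", "l4", "l5"),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2"),
    mode = c("cis", "cis", "trans", "trans", "trans", "trans"),
    r = 0.9, p_value = 1e-4
  )
  de <- tibble::tibble(
    feature_id = c("g1", "g2", "l1", "l2", "l3", "l4", "l5"),
    direction = c("up", "down", "up", "up", "down", "up", "down")
  )
  part <- tibble::tibble(
    feature_id = c("g1", "g2", "l1", "l2", "l3", "l4", "l5"),
    set_label = c("common", "case1_specific", "case1_specific", "case2_specific",
                  "common", "common", "common")
  )
  list(reg = reg, de = de, part = part)
}

test_that("the regulation network carries directions, set labels and count labels", {
  fx <- fixture_regulation()
  net <- build_regulation_network(fx$reg, fx$de, fx$part)

  g1 <- net$nodes[net$nodes$id == "g1", ]
  expect_equal(g1$label, "1/2")
  expect_equal(g1$direction, "up")
  expect_equal(g1$set_label, "common")
  g2 <- net$nodes[net$nodes$id == "g2", ]
  expect_equal(g2$label, "3/0")

  # the common gene's three regulators span all three set labels
  regs <- net$edges$source[net$edges$target == "g1"]
  expect_setequal(net$nodes$set_label[match(regs, net$nodes$id)],
                  c("case1_specific", "case2_specific", "common"))

  # edges are lncRNA -> gene with the pair's mode
  expect_true(all(net$edges$relation %in% c("cis", "trans")))
  expect_equal(sum(net$edges$relation == "cis"), 2)

  # un-called feature keeps its edge but has NA direction, with a warning
  expect_warning(
    net2 <- build_regulation_network(fx$reg, fx$de[-3, ], fx$part),
    "without a differential call"
  )
  expect_true(is.na(net2$nodes$direction[net2$nodes$id == "l1"]))
  expect_equal(nrow(net2$edges), nrow(net$edges))
})

test_that("PPI merging validates ids, collapses duplicates and never drops nodes", {
  fx <- fixture_regulation()
  net <- build_regulation_network(fx$reg, fx$de, fx$part)

  expect_identical(merge_ppi(net, tibble::tibble(gene_a = character(),
                                                 gene_b = character())), net)

  ppi <- tibble::tibble(
    gene_a = c("g1", "g2", "g1", "zz"),
    gene_b = c("g2", "g1", "g2", "g1"),
    weight = c(0.5, 0.9, 0.7, 1)
  )
  expect_warning(merged <- merge_ppi(net, ppi), "dropped")
  ppi_edges <- merged$edges[merged$edges$relation == "ppi", ]
  expect_equal(nrow(ppi_edges), 1) # duplicates collapsed
  expect_equal(ppi_edges$weight, 0.9) # keeping the max weight
  expect_gte(nrow(merged$nodes), nrow(net$nodes))
})

test_that("binding networks and localization annotation attach cleanly", {
  calls <- tibble::tibble(
    lncrna_id = c("l1", "l2"), protein_id = c("p1", "p1"),
    prob_svm = c(0.9, 0.8), prob_rf = c(0.7, 0.9), positive = TRUE
  )
  bnet <- build_binding_network(calls, "protein_binding", weight_col = "prob_rf")
  expect_equal(sort(bnet$nodes$kind), c("lncRNA", "lncRNA", "protein"))
  expect_equal(bnet$edges$relation, rep("protein_binding", 2))

  loc <- tibble::tibble(id = "l1", localization = "exosome")
  annotated <- annotate_localization(bnet, loc)
  expect_equal(annotated$nodes$localization[annotated$nodes$id == "l1"], "exosome")
  expect_true(is.na(annotated$nodes$localization[annotated$nodes$id == "l2"]))
})

test_that("tidiers summarise networks", {
  fx <- fixture_regulation()
  net <- build_regulation_network(fx$reg, fx$de, fx$part)
  g <- glance(net)
  expect_equal(g$n_nodes, 7)
  expect_equal(g$n_cis_edges, 2)
  expect_equal(nrow(tidy(net)), 6)
})
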