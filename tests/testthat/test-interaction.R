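test_that("featurization produces normalised k-mer and conjoint-triad blocks", {
  f <- featurize_pair("AAAA", "AAAAA")
  expect_length(f, 256 + 343)
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f[1:256]), 1)
  # A is class 1: triad (1,1,1) carries all protein mass
  expect_equal(unname(f["t111"]), 1)
  expect_equal(sum(f[257:599]), 1)

  # blocks sum to 1 for any long-enough sequence
  set.seed(3)
  g <- featurize_pair(random_rna_str(100), paste(sample(names(lncreg:::CT_CLASSES), 60, TRUE), collapse = ""))
  expect_equal(sum(g[1:256]), 1)
  expect_equal(sum(g[257:599]), 1)
  expect_true(all(g >= 0))

  # too-short sequences give all-zero blocks
  z <- featurize_pair("AC", "KR")
  expect_equal(sum(z), 0)
})

test_that("k-mer frequencies are shift-invariant for periodic sequences", {
  s <- strrep("ACGU", 10)
  rot <- paste0(substr(s, 3, 40), substr(s, 1, 2))
  f1 <- featurize_pair(s, "AAAAA")[1:256]
  f2 <- featurize_pair(rot, "AAAAA")[1:256]
  # same periodic content: identical 4-mer distribution up to edge effects
  expect_equal(sort(names(f1[f1 > 0])), sort(names(f2[f2 > 0])))
  expect_equal(unname(sum(abs(f1 - f2))), 0, tolerance = 0.06)
})

test_that("scorer training is seeded, deterministic and refuses degenerate input", {
  st <- default_study()
  sc1 <- train_scorers(st$labeled_pairs, seed = 11)
  sc2 <- train_scorers(st$labeled_pairs, seed = 11)
  X <- lncreg:::featurize_pairs(st$labeled_pairs$rna_seq[1:5], st$labeled_pairs$protein_seq[1:5])
  expect_equal(lncreg:::score_pairs(sc1, X), lncreg:::score_pairs(sc2, X))

  one_class <- st$labeled_pairs[st$labeled_pairs$interacts, ]
  expect_error(train_scorers(one_class), "both classes")
  few <- st$labeled_pairs[c(1:5, 31:35), ]
  expect_error(train_scorers(few), "at least 20")

  g <- glance(sc1)
  expect_lt(g$rf_oob_error, 0.5) # sanity floor: better than chance on training data
})

test_that("held-out discrimination of planted interaction signal is strong", {
  cfg <- simulation_config(n_labeled_pairs = 45, seed = 314)
  st <- simulate_study(cfg)
  lp <- st$labeled_pairs
  set.seed(99)
  pos <- which(lp$interacts)
  neg <- which(!lp$interacts)
  test_idx <- c(sample(pos, 15), sample(neg, 15))
  train <- lp[-test_idx, ]
  test <- lp[test_idx, ]
  scorers <- train_scorers(train, seed = 15)
  X <- lncreg:::featurize_pairs(test$rna_seq, test$protein_seq)
  pr <- lncreg:::score_pairs(scorers, X)
  # AUROC of the averaged probability
  score <- (pr$prob_svm + pr$prob_rf) / 2
  pos_s <- score[test$interacts]
  neg_s <- score[!test$interacts]
  auroc <- mean(outer(pos_s, neg_s, ">") + 0.5 * outer(pos_s, neg_s, "=="))
  expect_gte(auroc, 0.8)
})

test_that("interaction calls are gated by coexpression and dual thresholds", {
  st <- default_study()
  scorers <- train_scorers(st$labeled_pairs, seed = 2)
  tx_of <- setNames(st$annotation$transcript_id, st$annotation$gene_id)
  gene_seqs <- setNames(st$sequences[tx_of], names(tx_of))

  inter <- st$truth$interacting
  candidates <- tibble::tibble(lncrna_id = inter$lncrna_id, protein_id = inter$gene_id)
  gate_all <- tibble::tibble(lncrna_id = inter$lncrna_id, gene_id = inter$gene_id)

  calls <- call_interactions(candidates, gate_all, gene_seqs, st$proteins, scorers)
  expect_equal(nrow(calls), nrow(inter))
  expect_true(all(calls$positive == (calls$prob_svm > 0.5 & calls$prob_rf > 0.5)))
  # planted interacting pairs carry both signatures: most are called positive
  expect_gte(mean(calls$positive), 0.8)

  # pairs failing the coexpression prerequisite are never scored
  gated_out <- call_interactions(candidates, gate_all[0, ], gene_seqs, st$proteins, scorers)
  expect_equal(nrow(gated_out), 0)

  # non-interacting pairs lack the signatures and score negative
  neg_cand <- tibble::tibble(
    lncrna_id = setdiff(st$annotation$gene_id[st$annotation$biotype == "lncRNA"],
                        inter$lncrna_id)[1:10],
    protein_id = setdiff(names(st$proteins), inter$gene_id)[1:10]
  )
  neg_gate <- tibble::tibble(lncrna_id = neg_cand$lncrna_id, gene_id = neg_cand$protein_id)
  neg_calls <- call_interactions(neg_cand, neg_gate, gene_seqs, st$proteins, scorers)
  expect_lte(mean(neg_calls$positive), 0.2)
})
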