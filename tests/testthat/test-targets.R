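toy_annotation <- function() {
  tibble::tibble(
    transcript_id = c("L1.1", "G1.1", "G2.1", "L2.1", "G3.1"),
    gene_id = c("L1", "G1", "G2", "L2", "G3"),
    biotype = c("lncRNA", "mRNA", "mRNA", "lncRNA", "mRNA"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
    strand = "+",
    start = c(1000, 52000, 300000, 5000, 5000),
    end = c(2000, 53000, 301000, 6000, 6000),
    exon_starts = as.list(c(1000, 52000, 300000, 5000, 5000)),
    exon_ends = as.list(c(2000, 53000, 301000, 6000, 6000)),
    tx_length = 1001L
  )
}

pairs_of <- function(lnc, gene) {
  tibble::tibble(lncrna_id = lnc, gene_id = gene, r = 0.95, p_value = 1e-4)
}

test_that("cis calling uses the nearest-end gap with a strict 100 kb rule", {
  ann <- toy_annotation()
  # spans [1000,2000] and [52000,53000]: 49,999 intervening bases
  cis <- call_cis(pairs_of("L1", "G1"), ann)
  expect_equal(nrow(cis), 1)
  expect_equal(cis$genomic_gap, 49999)
  expect_equal(cis$mode, "cis")

  # overlapping spans have gap 0
  ann2 <- ann
  ann2$start[2] <- 1500
  ann2$end[2] <- 2500
  expect_equal(call_cis(pairs_of("L1", "G1"), ann2)$genomic_gap, 0)

  # a ~298 kb gap is not cis; different chromosomes are never cis
  expect_equal(nrow(call_cis(pairs_of("L1", "G2"), ann)), 0)
  expect_equal(nrow(call_cis(pairs_of("L2", "G1"), ann)), 0)

  # unannotated feature skipped with warning
  expect_warning(res <- call_cis(pairs_of("LX", "G1"), ann), "skipped")
  expect_equal(nrow(res), 0)
})

test_that("trans calling eliminates same-chromosome pairs and demands a passing duplex", {
  ann <- toy_annotation()
  set.seed(12)
  seqs <- setNames(
    vapply(1:5, function(i) random_rna_str(300), character(1)),
    c("L1.1", "G1.1", "G2.1", "L2.1", "G3.1")
  )
  # plant a 25-nt complementary insert between L2 (chr2) and G3 (chr3)
  seg <- substr(seqs[["G3.1"]], 100, 124)
  seqs[["L2.1"]] <- paste0(substr(seqs[["L2.1"]], 1, 49), rna_rc(seg),
                           substr(seqs[["L2.1"]], 75, 300))

  trans <- call_trans(pairs_of("L2", "G3"), ann, seqs)
  expect_equal(nrow(trans), 1)
  expect_equal(trans$mode, "trans")
  expect_gte(trans$site_length, 25)

  # same chromosome: eliminated before scanning even with perfect binding
  seqs2 <- seqs
  seqs2[["L1.1"]] <- paste0(rna_rc(substr(seqs[["G1.1"]], 1, 60)), random_rna_str(100))
  expect_equal(nrow(call_trans(pairs_of("L1", "G1"), ann, seqs2)), 0)

  # different chromosomes without complementarity: not trans
  expect_equal(nrow(call_trans(pairs_of("L1", "G3"), ann, seqs)), 0)

  # missing sequence: skipped with warning
  expect_warning(res <- call_trans(pairs_of("L2", "G3"), ann, seqs[-4]), "missing sequence")
  expect_equal(nrow(res), 0)
})

test_that("cis and trans labels are exclusive over pairs", {
  run <- default_pipeline_run()$result
  reg <- dplyr::bind_rows(run$targets)
  key <- paste(reg$lncrna_id, reg$gene_id)
  modes <- tapply(reg$mode, key, function(m) length(unique(m)))
  expect_true(all(modes == 1))
})

test_that("regulator counts are distinct per mode with 0/0 backfill", {
  reg <- tibble::tibble(
    lncrna_id = c("l1", "l2", "l3", "l4", "l5", "l5", "l1", "l2"),
    gene_id = c(rep("g1", 5), "g1", "g2", "g2"),
    mode = c("trans", "trans", "trans", "cis", "cis", "cis", "trans", "cis")
  )
  counts <- count_regulators(reg, gene_universe = c("g1", "g2", "g3"))
  expect_equal(counts$label[counts$gene_id == "g1"], "3/2") # l5 duplicate counts once
  expect_equal(counts$label[counts$gene_id == "g2"], "1/1")
  expect_equal(counts$label[counts$gene_id == "g3"], "0/0")
})

test_that("end-to-end target recovery meets precision and recall on planted truth", {
  run <- default_pipeline_run()$result
  truth <- run$study$truth
  reg <- run$targets[["case2"]]

  score <- function(called, planted) {
    tp <- nrow(dplyr::semi_join(called, planted, by = c("lncrna_id", "gene_id")))
    c(recall = tp / nrow(planted), precision = tp / max(1, nrow(called)))
  }
  cis <- score(reg[reg$mode == "cis", ], truth$cis_pairs)
  trans <- score(reg[reg$mode == "trans", ], truth$trans_pairs)
  expect_gte(cis[["recall"]], 0.8)
  expect_gte(cis[["precision"]], 0.8)
  expect_gte(trans[["recall"]], 0.8)
  expect_gte(trans[["precision"]], 0.8)

  # planted in-degrees are recovered for recovered pairs
  rec <- dplyr::semi_join(reg, dplyr::bind_rows(truth$cis_pairs[1:2], truth$trans_pairs[1:2]),
                          by = c("lncrna_id", "gene_id"))
  counts <- count_regulators(rec)
  planted_deg <- dplyr::bind_rows(truth$cis_pairs[1:2], truth$trans_pairs[1:2]) |>
    dplyr::semi_join(rec, by = c("lncrna_id", "gene_id")) |>
    dplyr::count(gene_id)
  joined <- dplyr::inner_join(counts, planted_deg, by = "gene_id")
  expect_equal(joined$n_trans + joined$n_cis, joined$n)
})
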