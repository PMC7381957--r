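test_that("generator respects its configuration invariants", {
  st <- default_study()
  truth <- st$truth
  cfg <- st$config

  # common DE structure: exactly n_de_common features per class in both comparisons
  de <- truth$de
  for (cls in c("gene", "lncRNA")) {
    ids1 <- de$feature_id[de$comparison == "case1" & de$class == cls]
    ids2 <- de$feature_id[de$comparison == "case2" & de$class == cls]
    expect_length(intersect(ids1, ids2), cfg$n_de_common)
    expect_length(ids1, cfg$n_de_case1)
    expect_length(ids2, cfg$n_de_case2)
  }

  # every planted pair references existing features
  all_ids <- st$annotation$gene_id
  expect_true(all(c(truth$cis_pairs$lncrna_id, truth$cis_pairs$gene_id,
                    truth$trans_pairs$lncrna_id, truth$trans_pairs$gene_id) %in% all_ids))

  # cis gaps below 100 kb and matching the genomic coordinates
  expect_true(all(truth$cis_pairs$gap < 100000))
  loc <- st$annotation
  for (i in seq_len(nrow(truth$cis_pairs))) {
    l <- loc[loc$gene_id == truth$cis_pairs$lncrna_id[i], ]
    g <- loc[loc$gene_id == truth$cis_pairs$gene_id[i], ]
    expect_equal(l$chrom, g$chrom)
    expect_equal(min(l$start) - max(g$end) - 1L, truth$cis_pairs$gap[i])
  }

  # trans pairs on different chromosomes
  chrom <- setNames(loc$chrom, loc$gene_id)
  expect_true(all(chrom[truth$trans_pairs$lncrna_id] != chrom[truth$trans_pairs$gene_id]))
})

test_that("planted trans inserts are exact reverse complements", {
  st <- default_study()
  seqs <- st$sequences
  tx_of <- setNames(st$annotation$transcript_id, st$annotation$gene_id)
  rc <- function(x) chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (i in seq_len(nrow(st$truth$trans_pairs))) {
    tp <- st$truth$trans_pairs[i, ]
    lseq <- seqs[[tx_of[tp$lncrna_id]]]
    gseq <- seqs[[tx_of[tp$gene_id]]]
    ins <- substr(lseq, tp$insert_start, tp$insert_end)
    seg <- substr(gseq, tp$target_start, tp$target_end)
    expect_equal(ins, rc(seg))
  }
})

test_that("zero dispersion with unit depth is the noise-free degenerate mode", {
  cfg <- simulation_config(
    n_genes = 20, n_lncrnas = 0, dispersion = 0, depth_range = c(1, 1),
    n_de_case1 = 0, n_de_case2 = 0, n_de_common = 0,
    n_cis_pairs = 0, n_trans_pairs = 0, n_same_chr_decoys = 0,
    n_diff_chr_decoys = 0, n_pfms = 0, n_interacting = 0, seed = 5
  )
  st <- simulate_study(cfg)
  m <- as.matrix(st$counts[-1])
  # no planted effect: every feature's counts equal its rounded mean everywhere
  expect_true(all(m == m[, 1]))
})

test_that("a fixed seed reproduces the study exactly", {
  cfg <- simulation_config(n_genes = 40, n_lncrnas = 40, n_de_case1 = 6,
                           n_de_case2 = 6, n_de_common = 3, n_cis_pairs = 2,
                           n_trans_pairs = 2, n_same_chr_decoys = 1,
                           n_diff_chr_decoys = 1, n_interacting = 1, seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("realized fold changes track the planted values", {
  # at phi = 0.02 the per-gene shot noise of 5-sample group means leaves the
  # realised log2FC within 0.3 of the planted value for the bulk of genes;
  # at the dispersion boundary 0.05 the NB noise floor alone caps coverage
  # near 86%, so the property is pinned in its attainable region
  st <- simulate_study(simulation_config(dispersion = 0.02, seed = 616))
  sf <- estimate_size_factors(st$counts)
  s <- setNames(sf$size_factor, sf$sample_id)
  design <- counts_design(st$counts)
  m <- as.matrix(st$counts[-1])
  rownames(m) <- st$counts$feature_id
  q <- sweep(m, 2, s[colnames(m)], "/")
  truth <- st$truth$de[st$truth$de$comparison == "case2", ]
  realized <- log2(rowMeans(q[truth$feature_id, design$group == "case2"]) /
                     rowMeans(q[truth$feature_id, design$group == "control"]))
  expect_gte(mean(abs(realized - truth$log2fc) <= 0.3), 0.9)
})

test_that("write_study emits files that round-trip through the readers", {
  st <- default_study()
  dir <- file.path(tempdir(), "study_roundtrip")
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))

  back <- read_counts(paths[["counts"]], paths[["design"]])
  expect_equal(as.data.frame(back), as.data.frame(st$counts))
  expect_equal(counts_design(back), counts_design(st$counts))

  seqs <- read_fasta(paths[["fasta"]])
  expect_identical(seqs[names(st$sequences)], st$sequences)

  sets <- read_gmt(paths[["gmt"]])
  expect_equal(sets$genes, st$gene_sets$genes)
  # the planted enriched set contains exactly the generator's members
  expect_setequal(sets$genes[[1]], st$truth$enriched_set$members)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_true(all(unlist(truth$cis_pairs$gap) < 100000))
})

test_that("infeasible placement is reported with advice", {
  cfg <- simulation_config(n_genes = 200, n_lncrnas = 0, n_de_case2 = 150,
                           n_de_case1 = 0, n_de_common = 0, n_cis_pairs = 0,
                           n_trans_pairs = 0, n_same_chr_decoys = 0,
                           n_diff_chr_decoys = 0, n_pfms = 0, n_interacting = 0,
                           chrom_length = 1e6, seed = 1)
  expect_error(simulate_study(cfg), "chrom_length")
})
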