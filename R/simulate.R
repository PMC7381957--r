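# ---- synthetic study generator ---------------------------------------------
#
# A fully specified synthetic leukocyte-transcriptomics study with planted
# signals: NB counts for a control group and two case populations, planted
# differential features, planted cis/trans coexpression pairs (genomic
# proximity or a reverse-complementary insert), decoy pairs, planted PWM
# motif sites, and planted lncRNA-protein interactions. Every planted
# effect is recorded in a ground-truth object so downstream stages can be
# scored without external data.

RNA_BOX <- "ACGUACGGUCACGGAUCGUA"  # 20-nt signature inserted into interacting lncRNAs
PEP_BOX <- "CCWKDHCEMCWC"          # 12-aa signature inserted into interacting proteins

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
random_protein <- function(n) {
  paste(sample(names(CT_CLASSES), n, replace = TRUE), collapse = "")
}

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

insert_at <- function(seq, what, pos) {
  # overwrite (not splice) so transcript lengths stay fixed
  paste0(substr(seq, 1, pos - 1), what, substr(seq, pos + nchar(what), nchar(seq)))
}

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design: a control group of 5, case population
#' 1 with 2 samples, case population 2 with 5 samples; 12 differential
#' features common to both case-versus-control comparisons; planted fold
#' changes of |log2FC| = 2; planted cis pairs (same chromosome, gap drawn
#' uniformly in [1 kb, 90 kb]) and trans pairs (different chromosomes with a
#' 25-nt reverse-complementary insert); decoy correlated pairs that are
#' same-chromosome distal (> 150 kb) or different-chromosome without an
#' insert; and a toy genome of 6 chromosomes x 2 Mb.
#'
#' @param n_genes,n_lncrnas Numbers of protein-coding genes and lncRNAs.
#' @param group_sizes Named integer vector (control, case1, case2).
#' @param mean_log_mu,sd_log_mu Log-normal baseline mean parameters
#'   (natural-log scale).
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2);
#'   phi = 0 is the degenerate noise-free mode where counts equal their
#'   rounded means.
#' @param n_de_case1,n_de_case2,n_de_common Planted differential feature
#'   counts per feature class (genes and lncRNAs each);
#'   `n_de_common <= min(n_de_case1, n_de_case2)`.
#' @param planted_log2fc Planted |log2 fold change| (>= 1).
#' @param n_cis_pairs,n_trans_pairs Planted regulatory pair counts.
#' @param n_same_chr_decoys,n_diff_chr_decoys Correlated decoy pair counts.
#' @param duplex_insert_len Length of the trans pairs' complementary insert
#'   (> 20 nt).
#' @param latent_sd Standard deviation (natural-log scale) of the shared,
#'   group-centred latent factor planted into correlated pairs.
#' @param depth_range Range of per-sample depth factors, drawn log-uniform.
#' @param n_chromosomes,chrom_length Toy genome layout.
#' @param n_pfms Number of generated RBP position frequency matrices; one
#'   consensus site per PFM is planted into a lncRNA.
#' @param n_interacting Number of planted interacting lncRNA-protein pairs
#'   (taken from the leading cis pairs, which lie in the common set).
#' @param n_labeled_pairs Labelled pairs per class for scorer training.
#' @param n_gene_sets,genes_per_set Gene-set collection layout; one set is
#'   enriched in planted differential genes.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 160, n_lncrnas = 160,
                              group_sizes = c(control = 5, case1 = 2, case2 = 5),
                              mean_log_mu = log(150), sd_log_mu = 1,
                              dispersion = 0.05,
                              n_de_case1 = 24, n_de_case2 = 24, n_de_common = 12,
                              planted_log2fc = 2,
                              n_cis_pairs = 8, n_trans_pairs = 8,
                              n_same_chr_decoys = 3, n_diff_chr_decoys = 3,
                              duplex_insert_len = 25,
                              latent_sd = 0.6,
                              depth_range = c(0.5, 2),
                              n_chromosomes = 6, chrom_length = 2e6,
                              n_pfms = 3,
                              n_interacting = 6,
                              n_labeled_pairs = 30,
                              n_gene_sets = 8, genes_per_set = 25,
                              seed = 20200716) {
  cfg <- as.list(environment())
  if (cfg$n_de_common > min(cfg$n_de_case1, cfg$n_de_case2)) {
    abort("n_de_common must not exceed min(n_de_case1, n_de_case2)")
  }
  if (cfg$duplex_insert_len <= 20) abort("duplex_insert_len must exceed 20")
  if (cfg$planted_log2fc < 0) abort("planted_log2fc must be non-negative")
  if (cfg$dispersion < 0) abort("dispersion must be non-negative")
  n_pairs <- cfg$n_cis_pairs + cfg$n_trans_pairs + cfg$n_same_chr_decoys + cfg$n_diff_chr_decoys
  if (n_pairs > cfg$n_de_case2) {
    abort("planted + decoy pairs exceed the number of case2 differential features")
  }
  if (cfg$n_interacting > cfg$n_cis_pairs) {
    abort("n_interacting must not exceed n_cis_pairs")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# sequential district placement on the toy genome; returns chrom/start for a
# series of jobs with the requested district widths
make_placer <- function(n_chrom, chrom_len) {
  cursor <- rep(10000, n_chrom)
  k <- 0L
  place <- function(width, avoid_chr = NULL) {
    k <<- k + 1L
    order <- ((k - 1L + seq_len(n_chrom) - 1L) %% n_chrom) + 1L
    for (chr in order) {
      if (!is.null(avoid_chr) && chr == avoid_chr) next
      if (cursor[chr] + width < chrom_len - 10000) {
        at <- cursor[chr]
        cursor[chr] <<- cursor[chr] + width
        return(list(chrom = chr, start = at))
      }
    }
    abort("toy genome too small for the requested placements; increase chrom_length or n_chromosomes")
  }
  place
}

# genomic structure for one transcript: 1-3 exons covering tx_len nt
make_exons <- function(start, tx_len) {
  n_ex <- sample(1:3, 1)
  cuts <- sort(sample(seq_len(tx_len - 1), n_ex - 1))
  ex_len <- diff(c(0, cuts, tx_len))
  introns <- if (n_ex > 1) sample(200:2000, n_ex - 1, replace = TRUE) else integer(0)
  s <- integer(n_ex)
  e <- integer(n_ex)
  at <- start
  for (i in seq_len(n_ex)) {
    s[i] <- at
    e[i] <- at + ex_len[i] - 1L
    at <- e[i] + 1L + if (i < n_ex) introns[i] else 0L
  }
  list(starts = s, ends = e)
}

#' Simulate the synthetic study
#'
#' Generates annotation, transcript sequences, NB counts, protein
#' sequences, PFMs, gene sets, a PPI edge list, labelled training pairs for
#' the interaction scorers, and the ground truth of every planted signal.
#' Counts follow k ~ NB(mean = s_j * mu_ij, variance = mu + phi * mu^2)
#' with per-sample depth factors s_j drawn log-uniform from `depth_range`.
#' Planted differential features receive a 2^(+/- planted_log2fc) fold
#' change in their case group(s); planted and decoy correlated pairs share
#' a group-centred latent Gaussian factor on the log-mean scale (so the
#' planted fold changes are undistorted while the within-scope Pearson
#' correlation of a pair exceeds 0.9 in expectation).
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `lnc_study` with elements `annotation`,
#'   `sequences`, `counts`, `proteins`, `pfms`, `gene_sets`, `ppi_edges`,
#'   `labeled_pairs`, `truth` and `config`. `truth` records planted DE
#'   features with signed log2FC per comparison, cis pairs with genomic
#'   gaps, trans pairs with insert coordinates, decoy and independent
#'   pairs, motif sites, interacting pairs, the enriched gene set and the
#'   per-sample depth factors.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  gene_ids <- sprintf("G%03d", seq_len(cfg$n_genes))
  lnc_ids <- sprintf("L%03d", seq_len(cfg$n_lncrnas))

  # ---- planted differential features (per feature class) -------------------
  pick_de <- function(ids) {
    if (length(ids) == 0L) {
      return(list(common = character(0), case1_specific = character(0),
                  case2_specific = character(0)))
    }
    common <- sample(ids, cfg$n_de_common)
    rest <- setdiff(ids, common)
    case1 <- sample(rest, cfg$n_de_case1 - cfg$n_de_common)
    case2 <- sample(setdiff(rest, case1), cfg$n_de_case2 - cfg$n_de_common)
    list(common = common, case1_specific = case1, case2_specific = case2)
  }
  de_g <- pick_de(gene_ids)
  de_l <- pick_de(lnc_ids)
  de_case2_genes <- c(de_g$common, de_g$case2_specific)
  de_case2_lncs <- c(de_l$common, de_l$case2_specific)

  # ---- pair assignment among case2 differential features -------------------
  # common features come first so the leading cis pairs (which also carry the
  # planted lncRNA-protein interactions) fall inside the common set that the
  # interaction stage examines
  n_pairs <- cfg$n_cis_pairs + cfg$n_trans_pairs + cfg$n_same_chr_decoys + cfg$n_diff_chr_decoys
  pair_genes <- c(sample(de_g$common), sample(de_g$case2_specific))[seq_len(n_pairs)]
  pair_lncs <- c(sample(de_l$common), sample(de_l$case2_specific))[seq_len(n_pairs)]
  idx <- 0L
  take <- function(n) {
    out <- seq_len(n) + idx
    idx <<- idx + n
    out
  }
  cis_i <- take(cfg$n_cis_pairs)
  trans_i <- take(cfg$n_trans_pairs)
  sdec_i <- take(cfg$n_same_chr_decoys)
  ddec_i <- take(cfg$n_diff_chr_decoys)

  # ---- sequence lengths ----------------------------------------------------
  tx_len <- c(
    setNames(sample(500:1500, cfg$n_genes, replace = TRUE), gene_ids),
    setNames(sample(300:800, cfg$n_lncrnas, replace = TRUE), lnc_ids)
  )

  # ---- genomic placement ---------------------------------------------------
  place <- make_placer(cfg$n_chromosomes, cfg$chrom_length)
  loc <- list() # feature -> list(chrom, exons)
  place_feature <- function(id, start, chrom) {
    loc[[id]] <<- c(list(chrom = chrom), make_exons(start, tx_len[[id]]))
  }
  cis_gaps <- integer(cfg$n_cis_pairs)
  for (i in seq_along(cis_i)) {
    p <- place(300000)
    g <- pair_genes[cis_i[i]]
    l <- pair_lncs[cis_i[i]]
    place_feature(g, p$start, p$chrom)
    gap <- sample(1000:90000, 1)
    gene_end <- max(loc[[g]]$ends)
    place_feature(l, gene_end + gap + 1L, p$chrom)
    cis_gaps[i] <- gap
  }
  for (i in sdec_i) {
    p <- place(600000)
    g <- pair_genes[i]
    l <- pair_lncs[i]
    place_feature(g, p$start, p$chrom)
    gap <- sample(150000:380000, 1)
    place_feature(l, max(loc[[g]]$ends) + gap + 1L, p$chrom)
  }
  for (i in c(trans_i, ddec_i)) {
    pg <- place(120000)
    place_feature(pair_genes[i], pg$start, pg$chrom)
    pl <- place(120000, avoid_chr = pg$chrom)
    place_feature(pair_lncs[i], pl$start, pl$chrom)
  }
  singles <- setdiff(
    c(de_g$common, de_g$case1_specific, de_g$case2_specific,
      de_l$common, de_l$case1_specific, de_l$case2_specific),
    c(pair_genes, pair_lncs)
  )
  for (id in singles) {
    p <- place(120000)
    place_feature(id, p$start, p$chrom)
  }
  # non-differential features never enter the screens; place them anywhere
  for (id in setdiff(c(gene_ids, lnc_ids), names(loc))) {
    chrom <- sample(cfg$n_chromosomes, 1)
    start <- sample(seq(10000, cfg$chrom_length - 20000), 1)
    place_feature(id, start, chrom)
  }

  all_ids <- c(gene_ids, lnc_ids)
  annotation <- tibble(
    transcript_id = paste0(all_ids, ".1"),
    gene_id = all_ids,
    biotype = rep(c("mRNA", "lncRNA"), c(cfg$n_genes, cfg$n_lncrnas)),
    chrom = map_chr(all_ids, ~ paste0("chr", loc[[.x]]$chrom)),
    strand = sample(c("+", "-"), length(all_ids), replace = TRUE),
    exon_starts = map(all_ids, ~ loc[[.x]]$starts),
    exon_ends = map(all_ids, ~ loc[[.x]]$ends)
  ) |>
    mutate(
      start = map_int(.data$exon_starts, ~ as.integer(min(.x))),
      end = map_int(.data$exon_ends, ~ as.integer(max(.x))),
      tx_length = as.integer(tx_len[all_ids])
    ) |>
    select("transcript_id", "gene_id", "biotype", "chrom", "strand",
           "start", "end", "exon_starts", "exon_ends", "tx_length")

  # ---- sequences and planted inserts ---------------------------------------
  seqs <- setNames(map_chr(all_ids, ~ random_rna(tx_len[[.x]])), all_ids)
  L <- cfg$duplex_insert_len
  trans_truth <- vector("list", cfg$n_trans_pairs)
  for (i in seq_along(trans_i)) {
    g <- pair_genes[trans_i[i]]
    l <- pair_lncs[trans_i[i]]
    tpos <- sample(seq_len(tx_len[[g]] - L + 1L), 1)
    lpos <- sample(seq_len(tx_len[[l]] - L + 1L), 1)
    seg <- substr(seqs[[g]], tpos, tpos + L - 1L)
    seqs[[l]] <- insert_at(seqs[[l]], rna_revcomp(seg), lpos)
    trans_truth[[i]] <- tibble(
      lncrna_id = l, gene_id = g,
      insert_start = lpos, insert_end = lpos + L - 1L,
      target_start = tpos, target_end = tpos + L - 1L,
      insert_len = L
    )
  }

  # ---- proteins and interaction planting -----------------------------------
  proteins <- setNames(map_chr(gene_ids, ~ random_protein(sample(150:300, 1))), gene_ids)
  inter_i <- cis_i[seq_len(cfg$n_interacting)]
  for (i in inter_i) {
    l <- pair_lncs[i]
    g <- pair_genes[i]
    for (rep in 1:3) {
      seqs[[l]] <- insert_at(seqs[[l]], RNA_BOX,
                             sample(seq_len(tx_len[[l]] - nchar(RNA_BOX) + 1L), 1))
      proteins[[g]] <- insert_at(proteins[[g]], PEP_BOX,
                                 sample(seq_len(nchar(proteins[[g]]) - nchar(PEP_BOX) + 1L), 1))
    }
  }
  interacting <- tibble(lncrna_id = pair_lncs[inter_i], gene_id = pair_genes[inter_i])

  # ---- PWMs and motif planting ---------------------------------------------
  pfm_w <- 8L
  pfms <- map(seq_len(cfg$n_pfms), function(i) {
    cons <- sample(c("A", "C", "G", "U"), pfm_w, replace = TRUE)
    m <- matrix(5, 4, pfm_w, dimnames = list(c("A", "C", "G", "U"), NULL))
    m[cbind(match(cons, rownames(m)), seq_len(pfm_w))] <- 85
    list(rbp_id = sprintf("RBP%02d", i), pfm = m, consensus = paste(cons, collapse = ""))
  })
  # plant motif sites in differential, non-pair lncRNAs: the motif stage
  # scans differential lncRNAs, and pair lncRNAs must keep their inserts
  de_lncs_all <- c(de_l$common, de_l$case1_specific, de_l$case2_specific)
  host_pool <- setdiff(de_lncs_all, pair_lncs)
  if (length(host_pool) < cfg$n_pfms) host_pool <- setdiff(lnc_ids, pair_lncs)
  motif_hosts <- sample(host_pool, cfg$n_pfms)
  motif_truth <- map(seq_len(cfg$n_pfms), function(i) {
    host <- motif_hosts[i]
    pos <- sample(seq_len(tx_len[[host]] - pfm_w + 1L), 1)
    seqs[[host]] <<- insert_at(seqs[[host]], pfms[[i]]$consensus, pos)
    tibble(rbp_id = pfms[[i]]$rbp_id, lncrna_id = host, position = pos)
  }) |> bind_rows()
  pfm_tbl <- tibble(rbp_id = map_chr(pfms, "rbp_id"), pfm = map(pfms, "pfm"))

  # ---- expression model ----------------------------------------------------
  gs <- cfg$group_sizes
  sample_ids <- c(
    paste0("ctrl_", seq_len(gs[["control"]])),
    paste0("case1_", seq_len(gs[["case1"]])),
    paste0("case2_", seq_len(gs[["case2"]]))
  )
  groups <- rep(c("control", "case1", "case2"), gs)
  n_samp <- length(sample_ids)
  design <- tibble(sample_id = sample_ids, group = groups)

  lmu <- rnorm(length(all_ids), cfg$mean_log_mu, cfg$sd_log_mu)
  names(lmu) <- all_ids
  # pair members get a solidly expressed baseline so their correlation is
  # not drowned by shot noise
  pair_members <- unique(c(pair_genes, pair_lncs))
  lmu[pair_members] <- rnorm(length(pair_members), log(300), 0.3)

  direction <- setNames(sample(c(1, -1), length(all_ids), replace = TRUE), all_ids)
  # pair members share a direction so the planted shift reinforces the pair
  for (i in seq_len(n_pairs)) {
    direction[pair_lncs[i]] <- direction[pair_genes[i]]
  }

  de_tbl <- bind_rows(
    tibble(feature_id = c(de_g$common, de_l$common), comparison = "case1"),
    tibble(feature_id = c(de_g$common, de_l$common), comparison = "case2"),
    tibble(feature_id = c(de_g$case1_specific, de_l$case1_specific), comparison = "case1"),
    tibble(feature_id = c(de_g$case2_specific, de_l$case2_specific), comparison = "case2")
  ) |>
    mutate(
      class = ifelse(.data$feature_id %in% gene_ids, "gene", "lncRNA"),
      log2fc = cfg$planted_log2fc * direction[.data$feature_id]
    )

  effect <- matrix(0, length(all_ids), n_samp, dimnames = list(all_ids, sample_ids))
  for (r in seq_len(nrow(de_tbl))) {
    cols <- groups == de_tbl$comparison[r]
    effect[de_tbl$feature_id[r], cols] <- de_tbl$log2fc[r] * log(2)
  }

  # group-centred latent factors for correlated (planted + decoy) pairs;
  # centring acts on the multiplicative factor (divide by the group mean of
  # exp(sd * z)) so each group's expected count mean — and hence the planted
  # fold change — is preserved exactly
  latent_i <- c(cis_i, trans_i, sdec_i, ddec_i)
  for (i in latent_i) {
    z <- cfg$latent_sd * rnorm(n_samp)
    for (g in unique(groups)) {
      z[groups == g] <- z[groups == g] - log(mean(exp(z[groups == g])))
    }
    effect[pair_genes[i], ] <- effect[pair_genes[i], ] + z
    effect[pair_lncs[i], ] <- effect[pair_lncs[i], ] + z
  }

  s_j <- exp(runif(n_samp, log(cfg$depth_range[1]), log(cfg$depth_range[2])))
  mu <- exp(sweep(effect, 1, lmu[all_ids], "+"))
  mu_scaled <- sweep(mu, 2, s_j, "*")
  counts <- if (cfg$dispersion == 0) {
    round(mu_scaled)
  } else {
    matrix(rnbinom(length(mu_scaled), mu = mu_scaled, size = 1 / cfg$dispersion),
           nrow(mu_scaled), dimnames = dimnames(mu_scaled))
  }
  counts_tbl <- as_expr_tbl(tibble::as_tibble(counts, rownames = "feature_id"), design)

  # ---- gene sets (one enriched in case2 differential genes) ----------------
  set_size <- min(cfg$genes_per_set, cfg$n_genes)
  sets <- map(seq_len(cfg$n_gene_sets), function(i) {
    if (i == 1L) {
      members <- unique(c(
        sample(de_case2_genes, min(15, length(de_case2_genes))),
        sample(gene_ids, max(0, set_size - 15))
      ))
    } else {
      members <- sample(gene_ids, set_size)
    }
    tibble(set_id = sprintf("SET%02d", i),
           description = ifelse(i == 1L, "planted enriched pathway", "random pathway"),
           genes = list(members))
  }) |> bind_rows()

  # ---- PPI edges among differential genes ----------------------------------
  de_genes_all <- unique(c(de_g$common, de_g$case1_specific, de_g$case2_specific))
  ppi <- if (length(de_genes_all) >= 2L) {
    as_tibble(t(combn(de_genes_all, 2)), .name_repair = ~ c("gene_a", "gene_b")) |>
      slice_sample(n = min(60, choose(length(de_genes_all), 2))) |>
      mutate(weight = round(runif(n(), 0.4, 1), 3))
  } else {
    tibble(gene_a = character(), gene_b = character(), weight = numeric())
  }

  # ---- labelled pairs for scorer training ----------------------------------
  lp <- cfg$n_labeled_pairs
  make_labeled <- function(n, rna_box, pep_box) {
    tibble(
      rna_seq = map_chr(seq_len(n), ~ {
        s <- random_rna(sample(300:800, 1))
        if (rna_box) for (k in 1:3) s <- insert_at(s, RNA_BOX, sample(nchar(s) - 24, 1))
        s
      }),
      protein_seq = map_chr(seq_len(n), ~ {
        s <- random_protein(sample(150:300, 1))
        if (pep_box) for (k in 1:3) s <- insert_at(s, PEP_BOX, sample(nchar(s) - 14, 1))
        s
      })
    )
  }
  labeled_pairs <- bind_rows(
    make_labeled(lp, TRUE, TRUE) |> mutate(interacts = TRUE),
    make_labeled(ceiling(lp / 3), FALSE, FALSE) |> mutate(interacts = FALSE),
    make_labeled(ceiling(lp / 3), TRUE, FALSE) |> mutate(interacts = FALSE),
    make_labeled(ceiling(lp / 3), FALSE, TRUE) |> mutate(interacts = FALSE)
  )

  # ---- independent decoy pairs (no latent, no shift) -----------------------
  free_lncs <- setdiff(lnc_ids, c(de_l$common, de_l$case1_specific, de_l$case2_specific))
  free_genes <- setdiff(gene_ids, de_genes_all)
  independent <- if (length(free_lncs) > 0L && length(free_genes) > 0L) {
    tibble(
      lncrna_id = sample(free_lncs, 40, replace = length(free_lncs) < 40),
      gene_id = sample(free_genes, 40, replace = length(free_genes) < 40)
    )
  } else {
    tibble(lncrna_id = character(), gene_id = character())
  }

  truth <- list(
    de = de_tbl,
    cis_pairs = tibble(
      lncrna_id = pair_lncs[cis_i], gene_id = pair_genes[cis_i], gap = cis_gaps
    ),
    trans_pairs = bind_rows(trans_truth),
    same_chr_decoys = tibble(lncrna_id = pair_lncs[sdec_i], gene_id = pair_genes[sdec_i]),
    diff_chr_decoys = tibble(lncrna_id = pair_lncs[ddec_i], gene_id = pair_genes[ddec_i]),
    independent_pairs = independent,
    motif_sites = motif_truth,
    interacting = interacting,
    enriched_set = list(set_id = "SET01", members = sets$genes[[1]]),
    depth_factors = tibble(sample_id = sample_ids, s = s_j),
    dispersion = cfg$dispersion
  )

  # transcript-id keyed copies for sequence consumers
  names(seqs) <- paste0(all_ids, ".1")
  structure(
    list(
      annotation = annotation, sequences = seqs, counts = counts_tbl,
      proteins = proteins, pfms = pfm_tbl, gene_sets = sets, ppi_edges = ppi,
      labeled_pairs = labeled_pairs, truth = truth, config = cfg
    ),
    class = "lnc_study"
  )
}

#' @export
print.lnc_study <- function(x, ...) {
  cfg <- x$config
  cat("<lnc_study> ", cfg$n_genes, " genes + ", cfg$n_lncrnas, " lncRNAs, ",
      sum(cfg$group_sizes), " samples (control=", cfg$group_sizes[["control"]],
      ", case1=", cfg$group_sizes[["case1"]], ", case2=", cfg$group_sizes[["case2"]],
      ")\n  planted: ", nrow(x$truth$cis_pairs), " cis, ",
      nrow(x$truth$trans_pairs), " trans pairs, ",
      cfg$n_de_common, " common DE per class\n", sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits every input the pipeline reads: GTF annotation, transcript FASTA,
#' counts and design TSVs, protein FASTA, gene sets (GMT), PFMs
#' (JASPAR-style), a PPI edge TSV and the ground truth as JSON. All files
#' round-trip through the package's readers.
#'
#' @param study `lnc_study` from [simulate_study()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "lnc_study"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", outdir))
  }
  paths <- c(
    gtf = file.path(outdir, "annotation.gtf"),
    fasta = file.path(outdir, "transcripts.fa"),
    counts = file.path(outdir, "counts.tsv"),
    design = file.path(outdir, "design.tsv"),
    proteins = file.path(outdir, "proteins.fa"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    pfm = file.path(outdir, "rbp_pfms.txt"),
    ppi = file.path(outdir, "ppi_edges.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_gtf(study$annotation, paths[["gtf"]])
  write_fasta(study$sequences, paths[["fasta"]])
  write_counts(study$counts, paths[["counts"]], paths[["design"]])
  write_fasta(study$proteins, paths[["proteins"]])
  write_gmt(study$gene_sets, paths[["gmt"]])
  write_pfm(study$pfms, paths[["pfm"]])
  readr::write_tsv(study$ppi_edges, paths[["ppi"]], progress = FALSE)
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
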