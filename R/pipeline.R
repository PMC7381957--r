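# ---- end-to-end pipeline ----------------------------------------------------

#' Pipeline configuration
#'
#' Collects every stage threshold with the analysis defaults: DE filter
#' p < 0.05 and |log2FC| >= 1; coexpression |r| > 0.8 and p < 0.05; cis gap
#' < 100 kb; trans duplex site > 20 paired nt with energy cutoff 50 model
#' units; dual interaction probability > 0.5; PWM relative score >= 0.8.
#'
#' @param outdir Output directory for all stage files.
#' @param seed Global seed; per-stage seeds are derived from it by hashing
#'   the stage name, so a stage re-run in isolation reproduces its output.
#' @param simulation `simulation_config()` describing the synthetic study,
#'   or `NULL` together with `study` to analyse an existing study object.
#' @param comparisons Named list of case groups to compare against control.
#' @param alpha,min_lfc DE thresholds.
#' @param r_min,coexpr_alpha Coexpression thresholds.
#' @param scope Coexpression sample scope.
#' @param max_gap Cis distance cutoff (nt).
#' @param min_site,energy Duplex binding thresholds.
#' @param prob_threshold Dual interaction-probability cutoff.
#' @param pwm_threshold PWM relative-score cutoff.
#' @param gsea_n_perm Preranked GSEA permutations.
#' @param max_bulge,max_extend Duplex scanner extension settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            simulation = simulation_config(),
                            comparisons = c("case1", "case2"),
                            alpha = 0.05, min_lfc = 1,
                            r_min = 0.8, coexpr_alpha = 0.05,
                            scope = "case_plus_control",
                            max_gap = 100000,
                            min_site = 21, energy = 50,
                            prob_threshold = 0.5,
                            pwm_threshold = 0.8,
                            gsea_n_perm = 1000,
                            max_bulge = 1, max_extend = 60) {
  stopifnot(alpha > 0, alpha <= 1, min_lfc >= 0, r_min >= 0, r_min < 1,
            max_gap > 0, min_site > 0, pwm_threshold >= 0, pwm_threshold <= 1,
            prob_threshold >= 0, prob_threshold <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `simulation` block
#' holds [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$group_sizes)) sim_args$group_sizes <- unlist(sim_args$group_sizes)
  y$simulation <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, y)
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — simulate, differential
#' expression per comparison, Venn partition, hierarchical clustering,
#' coexpression screen, cis/trans target calling, lncRNA-protein
#' interaction scoring, RBP motif scanning, enrichment (ORA + preranked
#' GSEA), and network assembly — writing every result as TSV (networks also
#' as GraphML/SIF) under `config$outdir`, plus a `manifest.json` listing
#' all outputs with md5 checksums. Identical config + seed reproduces
#' identical outputs byte for byte.
#'
#' @param config A [pipeline_config()] object.
#' @param study Optional pre-built [simulate_study()] object; by default
#'   the study is simulated from `config$simulation` (with the pipeline's
#'   derived stage seed overriding the simulation seed).
#' @param resume Skip stages whose output files already exist, reading
#'   them back instead of recomputing (default FALSE).
#' @return A list of all stage results (invisibly also written to disk),
#'   including `manifest`.
#' @export
run_pipeline <- function(config, study = NULL, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  p <- function(...) file.path(out, paste0(...))
  run_stage <- function(name, files, compute, reader = NULL) {
    if (resume && !is.null(reader) && all(file.exists(files))) {
      inform(paste0("[", name, "] resumed from existing output"))
      return(reader(files))
    }
    withr::with_seed(stage_seed(config$seed, name), compute())
  }
  read_tsvs <- function(files) map(files, readr::read_tsv, show_col_types = FALSE)

  # -- simulate ---------------------------------------------------------------
  if (is.null(study)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    study <- simulate_study(sim_cfg)
  }
  write_study(study, file.path(out, "study"))
  ann <- study$annotation
  lengths <- setNames(as.numeric(ann$tx_length), ann$gene_id)
  biotype <- setNames(ann$biotype, ann$gene_id)
  gene_seqs <- setNames(study$sequences, ann$gene_id[match(names(study$sequences), ann$transcript_id)])

  counts <- study$counts
  size_factors <- estimate_size_factors(counts)
  fpkm <- compute_fpkm(counts, lengths)

  # -- differential expression -----------------------------------------------
  de <- list(); de_calls <- list()
  for (cmp in config$comparisons) {
    res <- run_stage(
      paste0("de_", cmp), p("de_", cmp, ".tsv"),
      compute = function() {
        r <- nb_exact_test(counts, "control", cmp, size_factors)
        readr::write_tsv(r, p("de_", cmp, ".tsv"), progress = FALSE)
        r
      },
      reader = function(f) read_tsvs(f)[[1]]
    )
    de[[cmp]] <- res
    de_calls[[cmp]] <- call_de(res, config$alpha, config$min_lfc)
  }

  # -- Venn partition ---------------------------------------------------------
  partition <- partition_sets(de_calls[[1]]$feature_id, de_calls[[2]]$feature_id) |>
    mutate(class = ifelse(biotype[.data$feature_id] == "lncRNA", "lncRNA", "gene"))
  readr::write_tsv(partition, p("partition.tsv"), progress = FALSE)

  # -- clustering of differential profiles ------------------------------------
  de_ids <- unique(c(de_calls[[1]]$feature_id, de_calls[[2]]$feature_id))
  cluster <- NULL
  if (length(de_ids) >= 2L) {
    sub <- log2(expr_matrix(fpkm)[de_ids, , drop = FALSE] + 1)
    sample_tree <- upgma(correlation_distance(sub, axis = "samples"))
    feature_tree <- upgma(correlation_distance(sub, axis = "features"))
    export_heatmap(sub, feature_tree, sample_tree, p("heatmap.cdt.tsv"))
    cluster <- list(sample_tree = sample_tree, feature_tree = feature_tree)
  }

  # -- coexpression screen ----------------------------------------------------
  coexpr <- list()
  for (cmp in config$comparisons) {
    lncs <- de_calls[[cmp]]$feature_id[biotype[de_calls[[cmp]]$feature_id] == "lncRNA"]
    genes <- de_calls[[cmp]]$feature_id[biotype[de_calls[[cmp]]$feature_id] == "mRNA"]
    pairs <- if (length(lncs) > 0 && length(genes) > 0) {
      correlate_pairs(fpkm, lncs, genes, case_group = cmp, scope = config$scope)
    } else {
      tibble(lncrna_id = character(), gene_id = character(), r = numeric(),
             p_value = numeric(), n_samples = integer())
    }
    passing <- filter_pairs(pairs, config$r_min, config$coexpr_alpha)
    readr::write_tsv(passing, p("coexpr_", cmp, ".tsv"), progress = FALSE)
    coexpr[[cmp]] <- passing
  }

  # -- cis/trans target prediction (duplex scans cached across comparisons) ---
  all_pairs <- bind_rows(coexpr) |> distinct(.data$lncrna_id, .data$gene_id, .keep_all = TRUE)
  trans_all <- call_trans(all_pairs, ann, study$sequences,
                          min_len = config$min_site, energy_cutoff = config$energy,
                          max_bulge = config$max_bulge, max_extend = config$max_extend)
  targets <- list()
  for (cmp in config$comparisons) {
    cis <- call_cis(coexpr[[cmp]], ann, config$max_gap)
    trans <- trans_all |>
      semi_join(coexpr[[cmp]], by = c("lncrna_id", "gene_id"))
    reg <- bind_rows(cis, trans)
    readr::write_tsv(reg, p("targets_", cmp, ".tsv"), progress = FALSE)
    readr::write_tsv(count_regulators(reg), p("regulators_", cmp, ".tsv"), progress = FALSE)
    targets[[cmp]] <- reg
  }

  # -- lncRNA-protein interaction scoring -------------------------------------
  scorers <- run_stage("rpi_train", character(0), compute = function() {
    train_scorers(study$labeled_pairs, seed = stage_seed(config$seed, "rpi_train"))
  })
  common_lncs <- partition$feature_id[partition$set_label == "common" & partition$class == "lncRNA"]
  common_genes <- partition$feature_id[partition$set_label == "common" & partition$class == "gene"]
  candidates <- tidyr::expand_grid(lncrna_id = common_lncs, protein_id = common_genes)
  coexpr_union <- bind_rows(coexpr) |> distinct(.data$lncrna_id, .data$gene_id)
  interactions <- run_stage(
    "rpi", p("interactions.tsv"),
    compute = function() {
      calls <- call_interactions(candidates, coexpr_union, gene_seqs, study$proteins,
                                 scorers, config$prob_threshold)
      readr::write_tsv(calls, p("interactions.tsv"), progress = FALSE)
      calls
    },
    reader = function(f) read_tsvs(f)[[1]]
  )

  # -- RBP motif scanning -----------------------------------------------------
  de_lncs <- de_ids[biotype[de_ids] == "lncRNA"]
  motif_hits <- run_stage(
    "rbpscan", p("motif_hits.tsv"),
    compute = function() {
      hits <- scan_motifs_all(gene_seqs[de_lncs], study$pfms, threshold = config$pwm_threshold)
      readr::write_tsv(hits, p("motif_hits.tsv"), progress = FALSE)
      hits
    },
    reader = function(f) read_tsvs(f)[[1]]
  )

  # -- enrichment -------------------------------------------------------------
  gene_universe <- ann$gene_id[ann$biotype == "mRNA"]
  enrichment <- list()
  for (cmp in config$comparisons) {
    sel <- intersect(de_calls[[cmp]]$feature_id, gene_universe)
    if (length(sel) > 0) {
      res <- ora(sel, study$gene_sets, gene_universe)
      readr::write_tsv(res, p("ora_", cmp, ".tsv"), progress = FALSE)
      enrichment[[paste0("ora_", cmp)]] <- res
    }
  }
  ranked <- de[[config$comparisons[[length(config$comparisons)]]]] |>
    filter(.data$feature_id %in% gene_universe) |>
    select("feature_id", score = "log2fc")
  gsea <- suppressWarnings(gsea_preranked(
    ranked, study$gene_sets, n_perm = config$gsea_n_perm,
    seed = stage_seed(config$seed, "gsea")
  ))
  readr::write_tsv(gsea, p("gsea.tsv"), progress = FALSE)
  enrichment$gsea <- gsea

  # -- networks ---------------------------------------------------------------
  reg_all <- bind_rows(targets) |>
    distinct(.data$lncrna_id, .data$gene_id, .data$mode, .keep_all = TRUE)
  networks <- list()
  if (nrow(reg_all) > 0) {
    net <- build_regulation_network(reg_all, bind_rows(de_calls), partition)
    # PPI edges touching genes outside the regulation network are irrelevant
    # here; pre-filter so merge_ppi's unknown-id warning stays meaningful
    ppi_known <- study$ppi_edges |>
      filter(.data$gene_a %in% net$nodes$id, .data$gene_b %in% net$nodes$id)
    net <- merge_ppi(net, ppi_known)
    write_network(net, p("network.graphml"), "graphml")
    write_network(net, p("network.sif"), "sif")
    networks$regulation <- net
  }
  if (nrow(interactions) > 0 && any(interactions$positive)) {
    bnet <- build_binding_network(interactions[interactions$positive, ],
                                  relation = "protein_binding", weight_col = "prob_rf")
    write_network(bnet, p("binding.graphml"), "graphml")
    networks$binding <- bnet
  }

  # -- manifest ---------------------------------------------------------------
  files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("lncreg")),
    seed = config$seed,
    files = tibble(
      path = sub(paste0("^", out, "/?"), "", files),
      md5 = unname(tools::md5sum(files))
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")

  invisible(list(
    study = study, size_factors = size_factors, fpkm = fpkm,
    de = de, de_calls = de_calls, partition = partition, cluster = cluster,
    coexpr = coexpr, targets = targets, scorers = scorers,
    interactions = interactions, motif_hits = motif_hits,
    enrichment = enrichment, networks = networks, manifest = manifest
  ))
}
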