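# Session-level cache for expensive shared fixtures: the default synthetic
# study and a full pipeline run over it. Built once per test session.

.fixtures <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study(simulation_config())
  }
  .fixtures$study
}

# a reduced but complete study + pipeline run used by stage-level tests;
# small enough to keep the suite fast
small_pipeline_run <- function() {
  if (is.null(.fixtures$small_run)) {
    out <- file.path(tempdir(), "lncreg_small_run")
    cfg <- pipeline_config(
      outdir = out, seed = 7L,
      simulation = simulation_config(
        n_genes = 70, n_lncrnas = 70,
        n_de_case1 = 10, n_de_case2 = 10, n_de_common = 5,
        n_cis_pairs = 3, n_trans_pairs = 3,
        n_same_chr_decoys = 1, n_diff_chr_decoys = 1,
        n_interacting = 2, n_labeled_pairs = 21,
        n_gene_sets = 5, genes_per_set = 15
      ),
      gsea_n_perm = 200
    )
    .fixtures$small_run <- list(config = cfg, result = run_pipeline(cfg))
  }
  .fixtures$small_run
}

# full pipeline over the default study, shared by targets/pipeline/acceptance
default_pipeline_run <- function() {
  if (is.null(.fixtures$default_run)) {
    out <- file.path(tempdir(), "lncreg_default_run")
    cfg <- pipeline_config(outdir = out, seed = 1L)
    .fixtures$default_run <- list(
      config = cfg,
      result = run_pipeline(cfg, study = default_study())
    )
  }
  .fixtures$default_run
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
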