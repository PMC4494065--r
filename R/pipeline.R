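# Orchestration: run the simulator and the full analysis pipeline
# (quantify -> normalize -> diffexpr -> variants) from one configuration.

#' Run the simulator and write its outputs
#'
#' Writes the design, the panel (FASTA + annotation), the simulated count
#' table, the ground-truth tables and (optionally) per-library FASTQ files
#' to `out_dir`, plus a manifest TSV listing every file with its MD5
#' checksum. Deterministic under a fixed config seed.
#'
#' @param panel A `gene_panel` (default: the synthetic 80-gene panel built
#'   with the config seed).
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param reads Also simulate FASTQ libraries (default FALSE: counts only).
#' @return Tibble manifest (`file`, `md5`), invisibly; files on disk.
#' @export
run_simulate <- function(config = sim_config(), out_dir,
                         panel = simulate_panel(config$seed),
                         reads = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  design <- make_design()
  readr::write_tsv(design, file.path(out_dir, "design.tsv"))
  write_panel(panel, file.path(out_dir, "panel.fasta"),
              file.path(out_dir, "panel_annotation.tsv"))
  sim <- simulate_counts(panel, design, config)
  write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(sim$truth$effects, file.path(out_dir, "truth_effects.tsv"))
  readr::write_tsv(sim$truth$variants, file.path(out_dir, "truth_variants.tsv"))
  readr::write_tsv(sim$truth$editing, file.path(out_dir, "truth_editing.tsv"))
  if (reads) {
    simulate_reads(panel, design, config, file.path(out_dir, "fastq"))
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = tools::md5sum(files)
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Run the analysis pipeline end to end
#'
#' Stages run in order quantify (skipped when a precomputed count table is
#' supplied) -> normalize -> differential expression -> variants (skipped
#' when no pileups are available). Any stage error aborts with the stage
#' name.
#'
#' @param panel A `gene_panel`.
#' @param design Design tibble.
#' @param counts Long count tibble (`gene_id`, `library_id`, `count`), or
#'   NULL to quantify `fastq_manifest`.
#' @param fastq_manifest Tibble with `library_id` and `path` (used when
#'   `counts` is NULL, and for pileups when `pileups` is NULL).
#' @param pileups Optional precomputed pileup tibble for the variant stage.
#' @param alpha BY-FDR level.
#' @param k k-mer length for quantification.
#' @param ci_z,threshold Variant-score parameters.
#' @param pseudo Pseudocount for the log transform.
#' @return List with `counts`, `expression`, `de` (an `oxphos_de`),
#'   `de_summary`, and `variants` (an `oxphos_variants` or NULL).
#' @export
run_pipeline <- function(panel, design, counts = NULL,
                         fastq_manifest = NULL, pileups = NULL,
                         alpha = 0.01, k = 31L, ci_z = 1.96, threshold = 1,
                         pseudo = 0.5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  index <- NULL
  if (is.null(counts)) {
    if (is.null(fastq_manifest)) {
      stop("either counts or fastq_manifest must be supplied")
    }
    index <- stage("quantify", build_index(panel, k))
    counts <- stage("quantify", quantify_libraries(fastq_manifest, index))
  }
  message("pipeline: counts stage: ", length(unique(counts$gene_id)),
          " genes x ", length(unique(counts$library_id)), " libraries")
  expr <- stage("normalize",
                log_transform(expression_index(counts, panel), pseudo = pseudo))
  de <- stage("diffexpr", run_diffexpr(expr, design, panel, alpha = alpha))
  de_summary <- stage("diffexpr", summarize_by_complex(de, panel))
  variants <- NULL
  if (is.null(pileups) && !is.null(fastq_manifest)) {
    if (is.null(index)) index <- stage("variants", build_index(panel, k))
    pileups <- stage("variants", dplyr::bind_rows(
      purrr::map(seq_len(nrow(fastq_manifest)), function(i) {
        build_pileup(fastq_manifest$path[i], panel, index,
                     library_id = fastq_manifest$library_id[i])
      })))
  }
  if (!is.null(pileups) && nrow(pileups) > 0) {
    variants <- stage("variants",
                      call_variants(pileups, panel, design, ci_z = ci_z,
                                    threshold = threshold))
  }
  list(counts = counts, expression = expr, de = de,
       de_summary = de_summary, variants = variants)
}
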