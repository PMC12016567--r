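#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or equivalent list) with sections
#' `inputs` (paths per assay per condition), `params` (optional parameter
#' overrides per module), `output_dir` and `seed`. Unknown keys are
#' rejected; every referenced input path must exist.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  allowed_top <- c("inputs", "params", "output_dir", "seed",
                   "condition_labels")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key: %s", unknown[1]))
  }
  if (is.null(config$inputs)) abort("missing config section: inputs")
  if (is.null(config$output_dir)) abort("missing config key: output_dir")
  required <- list(
    c("hic", "cond1", "matrix"), c("hic", "cond1", "bins"),
    c("hic", "cond2", "matrix"), c("hic", "cond2", "bins"),
    c("ctcf", "cond1"), c("ctcf", "cond2"),
    c("atac", "cond1"), c("atac", "cond2"),
    c("genes"), c("counts"))
  for (keys in required) {
    v <- purrr::pluck(config$inputs, !!!as.list(keys))
    key_name <- paste(c("inputs", keys), collapse = ".")
    if (is.null(v)) abort(sprintf("missing config key: %s", key_name))
    if (!file.exists(v)) abort(sprintf("input path does not exist (%s): %s",
                                       key_name, v))
  }
  known_params <- c("tads", "classify", "expression", "boundary")
  unknown <- setdiff(names(config$params), known_params)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key: params.%s", unknown[1]))
  }
  config$seed <- config$seed %||% 1L
  config
}

#' Run the full two-condition classification pipeline
#'
#' Reads both conditions' binned Hi-C matrices, CTCF and ATAC peak sets,
#' gene models and the count table; calls TADs and boundaries per
#' condition via the directionality index; selects CTCF-supported boundary
#' alterations; calls differential expression; and classifies candidate
#' enhancer-gene pairs under both mechanisms. All intermediate artifacts
#' (DI tracks, TAD/boundary BEDs, reorganization events, expression table,
#' pair table, summary JSON and a run manifest) are written to
#' `output_dir`.
#'
#' @param config Path to a YAML config or a config list, see
#'   [read_run_config()].
#' @return A `pair_result` (invisibly also written to disk), with the
#'   per-condition TAD sets attached as attributes.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  pt <- cfg$params$tads %||% list()
  pb <- cfg$params$boundary %||% list()
  pe <- cfg$params$expression %||% list()

  map1 <- read_contact_map(cfg$inputs$hic$cond1$matrix,
                           cfg$inputs$hic$cond1$bins)
  map2 <- read_contact_map(cfg$inputs$hic$cond2$matrix,
                           cfg$inputs$hic$cond2$bins)
  ctcf1 <- read_peaks(cfg$inputs$ctcf$cond1, condition = "cond1", assay = "CTCF")
  ctcf2 <- read_peaks(cfg$inputs$ctcf$cond2, condition = "cond2", assay = "CTCF")
  atac1 <- read_peaks(cfg$inputs$atac$cond1, condition = "cond1", assay = "ATAC")
  atac2 <- read_peaks(cfg$inputs$atac$cond2, condition = "cond2", assay = "ATAC")
  genes <- read_gene_models(cfg$inputs$genes)
  counts <- readr::read_tsv(cfg$inputs$counts, col_types = readr::cols(),
                            progress = FALSE)

  di1 <- directionality_index(map1, window_bp = pt$window_bp %||% 2e6)
  di2 <- directionality_index(map2, window_bp = pt$window_bp %||% 2e6)
  tads1 <- call_tads(di1, t_sd = pt$t_sd %||% 0.5,
                     min_size_bins = pt$min_size_bins %||% 3)
  tads2 <- call_tads(di2, t_sd = pt$t_sd %||% 0.5,
                     min_size_bins = pt$min_size_bins %||% 3)
  reorg <- classify_reorganization(tads1, tads2,
                                   tol_bins = pb$tol_bins %||% 1,
                                   ro_min = pb$ro_min %||% 0.8,
                                   shift_max = pb$shift_max %||% 5)

  lengths <- genes$exonic_length[match(counts$gene_id, genes$gene_id)]
  if (anyNA(lengths)) abort("count table contains gene ids absent from the gene models")
  expr <- call_degs(counts, lengths,
                    dispersion = pe$dispersion %||% 0.1,
                    fc_min = pe$fc_min %||% 2.0,
                    fdr_max = pe$fdr_max %||% 0.05,
                    rpkm_min = pe$rpkm_min %||% 1.0,
                    rpkm_rule = pe$rpkm_rule %||% "any_sample")

  result <- classify_pairs(tads1, tads2, ctcf1, ctcf2, atac1, atac2, genes,
                           expr, params = cfg$params$classify %||% list())

  out <- function(f) file.path(cfg$output_dir, f)
  write_bedgraph(di1$di, map1$bins, out("di_cond1.bedgraph"))
  write_bedgraph(di2$di, map2$bins, out("di_cond2.bedgraph"))
  write_tads_bed(tads1, out("tads_cond1.bed"))
  write_tads_bed(tads2, out("tads_cond2.bed"))
  readr::write_tsv(reorg, out("reorg_events.tsv"))
  readr::write_tsv(result$events, out("boundary_events.tsv"))
  readr::write_tsv(as_tibble(expr), out("expression.tsv"))
  readr::write_tsv(result$pairs, out("pairs.tsv"))
  jsonlite::write_json(as.list(result$summary), out("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tadreorg")),
    config_hash = rlang::hash(cfg), seed = cfg$seed,
    row_counts = list(tads_cond1 = nrow(tads1), tads_cond2 = nrow(tads2),
                      reorg_events = nrow(reorg),
                      boundary_events = nrow(result$events),
                      expression = nrow(expr), pairs = nrow(result$pairs)))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  attr(result, "tads1") <- tads1
  attr(result, "tads2") <- tads2
  attr(result, "reorg") <- reorg
  attr(result, "expression") <- expr
  result
}

write_tads_bed <- function(tads, path) {
  write_bed(tibble(chrom = tads$chrom, start = tads$start, end = tads$end,
                   name = tads$tad_id, score = 0, strand = "."), path)
}
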