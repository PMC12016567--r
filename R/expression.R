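#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson-Oshlack): the
#' reference sample is the one whose upper quartile is closest to the mean
#' upper quartile; genes with a zero count in either sample of a comparison
#' are excluded; M and A values are doubly trimmed at `trim_m` / `trim_a`;
#' each factor is `2^(inverse-variance weighted mean M)`; factors are
#' rescaled to geometric mean 1. Computation is delegated to
#' [edgeR::calcNormFactors()].
#'
#' @param counts Gene-by-sample count tibble (first column `gene_id`) or
#'   numeric matrix.
#' @param trim_m Trim fraction for M values (log ratios).
#' @param trim_a Trim fraction for A values (absolute intensities).
#' @return Named numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  cm <- as_count_matrix(counts)
  if (ncol(cm$mat) < 2L) abort("TMM needs at least two samples")
  lib <- colSums(cm$mat)
  if (any(lib == 0)) {
    abort(sprintf("sample with zero library size: %s",
                  paste(colnames(cm$mat)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(cm$mat, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(as.numeric(f), colnames(cm$mat))
}

as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    gene_id <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    return(list(mat = counts, gene_id = gene_id))
  }
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  num <- counts[setdiff(names(counts), "gene_id")]
  mat <- as.matrix(num)
  rownames(mat) <- counts$gene_id
  list(mat = mat, gene_id = counts$gene_id)
}

#' Reads per kilobase of exonic length per million mapped reads
#'
#' `rpkm = count * 1e9 / (effective_lib_size * exonic_length)` with
#' `effective_lib_size = lib_size * tmm_factor`.
#'
#' @param counts Count tibble (`gene_id` + sample columns) or matrix.
#' @param exonic_length Exonic length in bp per gene (recycled by position;
#'   all lengths must be >= 1).
#' @param factors Optional TMM factors (default: computed with
#'   [tmm_factors()] when two or more samples are present, else 1).
#' @return Tibble with `gene_id` and one RPKM column per sample.
#' @export
rpkm_matrix <- function(counts, exonic_length, factors = NULL) {
  cm <- as_count_matrix(counts)
  if (any(exonic_length < 1)) abort("exonic lengths must be >= 1")
  lib <- colSums(cm$mat)
  if (is.null(factors)) {
    factors <- if (ncol(cm$mat) >= 2L) tmm_factors(counts) else
      setNames(1, colnames(cm$mat))
  }
  eff <- lib * factors[colnames(cm$mat)]
  if (any(eff == 0)) abort("zero effective library size")
  r <- sweep(cm$mat * 1e9 / exonic_length, 2, eff, "/")
  out <- as_tibble(r)
  out$gene_id <- cm$gene_id
  select(out, "gene_id", dplyr::everything())
}

#' Flag low-abundance genes by RPKM
#'
#' With the default rule a gene is flagged when its RPKM is below
#' `threshold` in at least one sample (the literal filtering rule); the
#' `"all_samples"` alternative keeps on/off genes and only flags genes low
#' everywhere.
#'
#' @param rpkm Tibble from [rpkm_matrix()].
#' @param threshold RPKM threshold.
#' @param rule `"any_sample"` (default) or `"all_samples"`.
#' @return Logical vector, `TRUE` = low abundance, one per gene.
#' @export
low_abundance_filter <- function(rpkm, threshold = 1.0,
                                 rule = c("any_sample", "all_samples")) {
  rule <- match.arg(rule)
  mat <- as.matrix(rpkm[setdiff(names(rpkm), "gene_id")])
  low <- mat < threshold
  if (rule == "any_sample") apply(low, 1, any) else apply(low, 1, all)
}

#' Call differentially expressed genes between two conditions
#'
#' Counts are TMM-normalized, transformed to RPKM for the low-abundance
#' filter, and tested with a fixed-dispersion negative-binomial exact test
#' ([edgeR::exactTest()]) on the genes passing the filter; the fixed
#' dispersion replaces tagwise estimation because a one-sample-per-condition
#' design has no replicate structure to estimate it from. FDR is
#' Benjamini-Hochberg over tested genes. A gene is flagged `up` when its
#' fold change (condition 2 over condition 1) is at least `fc_min` with
#' `fdr < fdr_max`, `down` for the reciprocal, else `none`.
#'
#' @param counts Count tibble (`gene_id` + one column per sample).
#' @param exonic_length Exonic length in bp per gene (for RPKM).
#' @param conditions Character vector assigning each sample column to one of
#'   exactly two condition labels, in order; replicate columns are pooled by
#'   summation. Default: each column is its own condition.
#' @param dispersion Negative-binomial dispersion for the exact test.
#' @param fc_min Linear-scale fold-change threshold (applied in either
#'   direction).
#' @param fdr_max FDR threshold.
#' @param rpkm_min Low-abundance RPKM threshold.
#' @param rpkm_rule Low-abundance rule, see [low_abundance_filter()].
#' @return An `expression_result` tibble: `gene_id`, one `rpkm_*` column per
#'   condition, `log2_fc`, `p_value`, `fdr`, `low_abundance`, `deg_flag`.
#' @export
call_degs <- function(counts, exonic_length, conditions = NULL,
                      dispersion = 0.1, fc_min = 2.0, fdr_max = 0.05,
                      rpkm_min = 1.0, rpkm_rule = "any_sample") {
  cm <- as_count_matrix(counts)
  samples <- colnames(cm$mat)
  if (is.null(conditions)) conditions <- samples
  if (length(conditions) != ncol(cm$mat)) {
    abort("conditions must name one condition per sample column")
  }
  levels <- unique(conditions)
  if (length(levels) != 2L) abort("exactly two conditions are required")
  pooled <- vapply(levels, function(l) {
    rowSums(cm$mat[, conditions == l, drop = FALSE])
  }, numeric(nrow(cm$mat)))
  colnames(pooled) <- levels
  rownames(pooled) <- cm$gene_id

  factors <- tmm_factors(pooled)
  rpkm <- rpkm_matrix(pooled, exonic_length, factors)
  low <- low_abundance_filter(rpkm, rpkm_min, rpkm_rule)

  keep <- which(!low)
  log2_fc <- rep(NA_real_, nrow(pooled))
  p <- rep(NA_real_, nrow(pooled))
  if (length(keep) > 0L) {
    d <- edgeR::DGEList(counts = pooled[keep, , drop = FALSE],
                        group = factor(levels, levels = levels),
                        norm.factors = as.numeric(factors))
    et <- edgeR::exactTest(d, pair = levels, dispersion = dispersion)
    log2_fc[keep] <- et$table$logFC
    p[keep] <- et$table$PValue
  }
  fdr <- rep(NA_real_, nrow(pooled))
  fdr[keep] <- p.adjust(p[keep], method = "BH")
  deg_flag <- rep("none", nrow(pooled))
  deg_flag[!is.na(fdr) & fdr < fdr_max & log2_fc >= log2(fc_min)] <- "up"
  deg_flag[!is.na(fdr) & fdr < fdr_max & log2_fc <= -log2(fc_min)] <- "down"

  out <- tibble(gene_id = cm$gene_id)
  for (l in levels) out[[paste0("rpkm_", l)]] <- rpkm[[l]]
  out$log2_fc <- log2_fc
  out$p_value <- p
  out$fdr <- fdr
  out$low_abundance <- low
  out$deg_flag <- deg_flag
  structure(out, conditions = levels,
            class = c("expression_result", class(out)))
}

#' One-row summary of an expression result
#'
#' @param x An `expression_result`.
#' @param ... Unused.
#' @return Tibble with gene counts per category.
#' @export
glance.expression_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_low_abundance = sum(x$low_abundance),
         n_tested = sum(!is.na(x$fdr)),
         n_up = sum(x$deg_flag == "up"), n_down = sum(x$deg_flag == "down"))
}
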