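# Independent oracles and small fixture builders used across the suite.

# O(n*m) all-pairs interval intersection with symmetric expansion of `a`.
brute_force_overlap <- function(a, b, tolerance = 0) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- max(a$start[i] - tolerance, 0)
      e <- a$end[i] + tolerance
      if (a$chrom[i] == b$chrom[j] && s < b$end[j] && b$start[j] < e) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer()))
  }
  m <- do.call(rbind, out)
  dplyr::arrange(tibble::tibble(idx_a = m[, 1], idx_b = m[, 2]),
                 idx_a, idx_b)
}

# Hand-coded trimmed-mean-of-M-values factors (Robinson-Oshlack): doubly
# trimmed weighted mean of log ratios against the upper-quartile reference,
# rescaled to geometric mean 1.
tmm_oracle <- function(mat, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(mat)
  f75 <- apply(mat, 2, function(x) quantile(x, p = 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, nO, refc, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    f <- 2^(sum(logR[keep] / v[keep], na.rm = TRUE) /
              sum(1 / v[keep], na.rm = TRUE))
    if (is.na(f) || !is.finite(f)) 1 else f
  }
  f <- vapply(seq_len(ncol(mat)), function(k) {
    one_factor(mat[, k], lib[k], mat[, ref], lib[ref])
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(mat))
}

# Upper-tail binomial probability by direct summation of the pmf.
binom_tail_oracle <- function(k, size, prob) {
  if (k > size) return(0)
  sum(dbinom(seq(k, size), size, prob))
}

# Fully independent re-check of the printed pair criteria over the full
# cross product of candidate genes x peaks x events. Takes the classifier's
# *inputs* (events from step 1, expression, peaks, TADs) and re-derives the
# pair table with plain loops and arithmetic.
brute_force_pairs <- function(events, genes, expr, atac1, atac2, tads1,
                              tads2, resolution,
                              promoter_halfwidth = 2000,
                              search_radius = 1e6,
                              mech1_max_dist = 20000,
                              mech2_max_dist = 1e5,
                              between_tol_bins = 1,
                              mech2_rule = "novel_boundary_activates") {
  overlaps_any <- function(chrom, s, e, peaks) {
    any(peaks$chrom == chrom & peaks$start < e & s < peaks$end)
  }
  tad_at <- function(tads, chrom, pos) {
    hit <- which(tads$chrom == chrom & tads$start <= pos & pos < tads$end)
    if (length(hit)) tads$tad_id[hit[1]] else NA
  }
  rows <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ex <- expr[expr$gene_id == g$gene_id, ]
    if (nrow(ex) == 0L || ex$deg_flag == "none") next
    ps <- max(g$tss - promoter_halfwidth, 0); pe <- g$tss + promoter_halfwidth
    near <- any(events$chrom == g$chrom &
                  events$boundary_bp + 1 > ps - search_radius &
                  events$boundary_bp < pe + search_radius)
    if (!near) next
    if (!overlaps_any(g$chrom, ps, pe, atac1)) next
    if (!overlaps_any(g$chrom, ps, pe, atac2)) next
    for (pi in seq_len(nrow(atac1))) {
      pk <- atac1[pi, ]
      if (pk$chrom != g$chrom) next
      if (!overlaps_any(pk$chrom, pk$start, pk$end, atac2)) next
      mid <- (pk$start + pk$end) / 2
      dist <- abs(mid - g$tss)
      if (pk$start < pe && ps < pk$end) next   # promoter peak, not distal
      peak_bin <- floor(mid / resolution) + 1
      tss_bin <- floor(g$tss / resolution) + 1
      lo <- min(peak_bin, tss_bin) - between_tol_bins
      hi <- max(peak_bin, tss_bin) + between_tol_bins
      for (ei in seq_len(nrow(events))) {
        ev <- events[ei, ]
        if (ev$chrom != g$chrom || ev$bin < lo || ev$bin > hi) next
        # mechanism 1
        if (dist > 0 && dist < mech1_max_dist) {
          dir <- if (ev$change == "gained" && ex$deg_flag == "down") {
            "deactivation"
          } else if (ev$change == "lost" && ex$deg_flag == "up") {
            "activation"
          } else NA
          if (!is.na(dir)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              gene_id = g$gene_id, mechanism = 1L,
              role = if (ex$deg_flag == "up") "oncogene" else "suppressor",
              direction = dir, chrom = g$chrom,
              peak_start = pk$start, peak_end = pk$end,
              boundary_bp = ev$boundary_bp, event_change = ev$change,
              distance_bp = dist)
          }
        }
        # mechanism 2
        if (dist > 0 && dist < mech2_max_dist) {
          t1g <- tad_at(tads1, g$chrom, g$tss)
          t1p <- tad_at(tads1, g$chrom, mid)
          t2g <- tad_at(tads2, g$chrom, g$tss)
          t2p <- tad_at(tads2, g$chrom, mid)
          same1 <- !is.na(t1g) && !is.na(t1p) && t1g == t1p
          same2 <- !is.na(t2g) && !is.na(t2p) && t2g == t2p
          if (xor(same1, same2)) {
            dir <- if (mech2_rule == "novel_boundary_activates") {
              if (ev$change == "gained" && ex$deg_flag == "up") "activation"
              else if (ev$change == "lost" && ex$deg_flag == "down") "deactivation"
              else NA
            } else {
              if (ev$change == "gained" && ex$deg_flag == "down") "deactivation"
              else if (ev$change == "lost" && ex$deg_flag == "up") "activation"
              else NA
            }
            if (!is.na(dir)) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                gene_id = g$gene_id, mechanism = 2L,
                role = if (ex$deg_flag == "up") "oncogene" else "suppressor",
                direction = dir, chrom = g$chrom,
                peak_start = pk$start, peak_end = pk$end,
                boundary_bp = ev$boundary_bp, event_change = ev$change,
                distance_bp = dist)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene_id = character(), mechanism = integer(),
                          role = character(), direction = character(),
                          chrom = character(), peak_start = double(),
                          peak_end = double(), boundary_bp = double(),
                          event_change = character(),
                          distance_bp = double()))
  }
  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(rows)),
                 gene_id, mechanism, distance_bp, peak_start)
}

# Tiny FASTA writer for GC tests.
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

# Minimal GTF with one gene per row of `genes` plus explicit exon rows.
# `exons` is a list (per gene) of matrices with 1-based inclusive columns.
write_test_gtf <- function(path, genes, exons) {
  lines <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    at <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_id)
    lines <- c(lines, paste(g$chrom, "test", "gene", g$start, g$end, ".",
                            g$strand, ".", at, sep = "\t"))
    ex <- exons[[g$gene_id]]
    if (!is.null(ex)) {
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, paste(g$chrom, "test", "exon", ex[k, 1], ex[k, 2],
                                ".", g$strand, ".", at, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  path
}

# A fabricated di_track from bare DI values on one chromosome.
fake_di_track <- function(di, chrom = "chrT", resolution = 40000) {
  n <- length(di)
  out <- tibble::tibble(bin = seq_len(n), chrom = chrom,
                        start = (seq_len(n) - 1) * resolution,
                        end = seq_len(n) * resolution,
                        A = NA_real_, B = NA_real_, E = NA_real_, di = di)
  structure(out, resolution = resolution,
            class = c("di_track", class(out)))
}

# A fabricated tad_set from local half-open bin spans.
fake_tad_set <- function(spans, chrom = "chrT", resolution = 40000) {
  out <- tibble::tibble(
    tad_id = sprintf("%s_tad%03d", chrom, seq_len(nrow(spans))),
    chrom = chrom, start_bin = spans$start_bin, end_bin = spans$end_bin,
    start = (spans$start_bin - 1) * resolution,
    end = (spans$end_bin - 1) * resolution,
    span_bp = (spans$end_bin - spans$start_bin) * resolution)
  structure(out, resolution = resolution,
            class = c("tad_set", class(out)))
}

# Two-condition NB count fixture with planted up/down genes.
nb_counts <- function(n_null, n_up, n_down, fc = 8, mu = 500, disp = 0.1,
                      seed = 101) {
  withr::with_seed(seed, {
    n <- n_null + n_up + n_down
    mu2 <- c(rep(mu, n_null), rep(mu * fc, n_up), rep(mu / fc, n_down))
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      cond1 = rnbinom(n, mu = mu, size = 1 / disp),
      cond2 = rnbinom(n, mu = mu2, size = 1 / disp))
  })
}
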