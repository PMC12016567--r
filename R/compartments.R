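#' A/B compartment eigenvector of a contact map
#'
#' Per chromosome the cis matrix is smoothed ([smooth_map()]), transformed
#' to observed/expected, restricted to bins with nonzero raw coverage, and
#' converted to a Pearson correlation matrix (main diagonal excluded from
#' the correlations). The first eigenvector (largest-magnitude eigenvalue)
#' scores each bin; the sign is fixed so that positive-score bins have the
#' higher mean gene density (or GC content with `orientation = "gc"`).
#' Positive scores are labeled A, negative B; uncovered bins are NA.
#'
#' @param map A `contact_map` (typically 100-kb bins).
#' @param h Smoothing half-span in bins.
#' @param orientation `"gene_density"` or `"gc"`.
#' @param genes Gene models (required for gene-density orientation).
#' @param genome FASTA path or `DNAStringSet` (required for GC orientation).
#' @return A `compartment_track` tibble with `bin`, `chrom`, `start`, `end`,
#'   `score`, `label`.
#' @export
compartment_eigenvector <- function(map, h = 1,
                                    orientation = c("gene_density", "gc"),
                                    genes = NULL, genome = NULL) {
  orientation <- match.arg(orientation)
  if (orientation == "gene_density" && is.null(genes)) {
    abort("gene models are required for gene-density orientation")
  }
  if (orientation == "gc" && is.null(genome)) {
    abort("a genome FASTA is required for GC orientation")
  }
  raw <- map
  sm <- smooth_map(map, h)
  oe <- observed_expected(sm)
  bins <- map$bins
  out <- imap(oe, function(O, chrom) {
    sel <- bins[bins$chrom == chrom, ]
    n <- nrow(O)
    score <- rep(NA_real_, n)
    covered <- which(Matrix::rowSums(as.matrix(raw$cis[[chrom]])) > 0)
    if (length(covered) < 3L) {
      warn(sprintf("fewer than 3 covered bins on %s: compartment scores NA", chrom))
      return(tibble(bin = sel$bin, chrom = chrom, start = sel$start,
                    end = sel$end, score = score))
    }
    Oc <- O[covered, covered, drop = FALSE]
    diag(Oc) <- NA   # exclude the main diagonal from the correlations
    C <- suppressWarnings(cor(Oc, use = "pairwise.complete.obs"))
    if (all(is.na(C[upper.tri(C)]))) {
      warn(sprintf("degenerate correlation matrix on %s: compartment scores NA",
                   chrom))
      return(tibble(bin = sel$bin, chrom = chrom, start = sel$start,
                    end = sel$end, score = score))
    }
    C[is.na(C)] <- 0
    diag(C) <- 1
    eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
    k <- which.max(abs(eig$values))
    score[covered] <- eig$vectors[, k]
    tibble(bin = sel$bin, chrom = chrom, start = sel$start, end = sel$end,
           score = score)
  }) |> list_rbind()

  ref <- orientation_reference(out, orientation, genes, genome, map$resolution)
  out <- out |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      ok <- !is.na(g$score)
      if (any(ok)) {
        r <- ref[match(paste(key$chrom, g$start), names(ref))]
        pos <- mean(r[ok & g$score > 0], na.rm = TRUE)
        neg <- mean(r[ok & g$score < 0], na.rm = TRUE)
        if (!is.na(pos) && !is.na(neg) && neg > pos) g$score <- -g$score
      }
      g$chrom <- key$chrom
      g
    }) |> list_rbind() |>
    mutate(label = case_when(is.na(.data$score) ~ NA_character_,
                             .data$score > 0 ~ "A",
                             .data$score < 0 ~ "B",
                             TRUE ~ NA_character_)) |>
    select("bin", "chrom", "start", "end", "score", "label") |>
    arrange(.data$bin)
  structure(out, resolution = map$resolution,
            class = c("compartment_track", class(out)))
}

# Per-bin orientation reference: TSS count or GC fraction, named by
# "chrom start".
orientation_reference <- function(track, orientation, genes, genome, res) {
  if (orientation == "gene_density") {
    ref <- map_dbl(seq_len(nrow(track)), function(i) {
      sum(genes$chrom == track$chrom[i] & genes$tss >= track$start[i] &
            genes$tss < track$end[i])
    })
  } else {
    ref <- gc_content(track[, c("chrom", "start", "end")], genome)
  }
  setNames(ref, paste(track$chrom, track$start))
}

#' Assign A/B compartment labels to TADs
#'
#' Each TAD takes the overlap-weighted mean eigenvector score of the
#' compartment bins it intersects: mean > 0 is A, mean < 0 is B, a mean of
#' exactly 0 (or no scored bins) is NA.
#'
#' @param track A `compartment_track`.
#' @param tads A `tad_set` (resolutions may differ; intersection is by bp).
#' @return `tads` with added `compartment_score` and `compartment` columns.
#' @export
assign_tad_compartments <- function(track, tads) {
  scores <- map_dbl(seq_len(nrow(tads)), function(i) {
    sel <- track$chrom == tads$chrom[i] & track$end > tads$start[i] &
      track$start < tads$end[i] & !is.na(track$score)
    if (!any(sel)) return(NA_real_)
    w <- pmin(track$end[sel], tads$end[i]) - pmax(track$start[sel], tads$start[i])
    sum(track$score[sel] * w) / sum(w)
  })
  tads$compartment_score <- scores
  tads$compartment <- case_when(is.na(scores) ~ NA_character_,
                                scores > 0 ~ "A", scores < 0 ~ "B",
                                TRUE ~ NA_character_)
  tads
}

#' Maximal same-label compartment segments
#'
#' Contiguous bins sharing a label are merged; NA bins break runs.
#'
#' @param track A `compartment_track`.
#' @return Tibble with `chrom`, `start`, `end`, `label`, `length_bp`,
#'   `n_bins`.
#' @export
compartment_segments <- function(track) {
  track |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      g <- arrange(g, .data$start)
      lab <- replace_na_chr(g$label, "NA")
      r <- rle(lab)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      seg <- tibble(chrom = key$chrom, start = g$start[starts],
                    end = g$end[ends], label = r$values,
                    n_bins = r$lengths)
      seg[seg$label != "NA", ]
    }) |> list_rbind() |>
    mutate(length_bp = .data$end - .data$start) |>
    arrange(.data$chrom, .data$start)
}

#' Summarize compartment segment lengths per label
#'
#' @param segments Output of [compartment_segments()].
#' @return Tibble per label with counts and length quantiles (bp).
#' @export
compartment_segment_summary <- function(segments) {
  segments |>
    group_by(.data$label) |>
    summarise(n_segments = dplyr::n(),
              total_bp = sum(.data$length_bp),
              median_bp = stats::median(.data$length_bp),
              q25_bp = quantile(.data$length_bp, 0.25),
              q75_bp = quantile(.data$length_bp, 0.75),
              .groups = "drop")
}

#' Compare compartment tracks between two conditions
#'
#' Computed over bins labeled in both tracks.
#'
#' @param track1,track2 `compartment_track` tibbles on the same bin table.
#' @return A `compartment_comparison` list with `label_agreement` (fraction
#'   of co-labeled bins with equal label) and `score_correlation` (Pearson
#'   r of eigenvector scores).
#' @export
compare_compartments <- function(track1, track2) {
  if (nrow(track1) != nrow(track2) ||
      !all(track1$bin == track2$bin)) {
    abort("compartment tracks are not on the same bin table")
  }
  ok <- !is.na(track1$label) & !is.na(track2$label)
  if (!any(ok)) abort("no bins labeled in both tracks")
  structure(list(
    label_agreement = mean(track1$label[ok] == track2$label[ok]),
    score_correlation = cor(track1$score[ok], track2$score[ok]),
    n_bins = sum(ok)
  ), class = "compartment_comparison")
}

#' @export
print.compartment_comparison <- function(x, ...) {
  cat(sprintf("compartment_comparison: agreement %.3f, score r = %.3f over %d bins\n",
              x$label_agreement, x$score_correlation, x$n_bins))
  invisible(x)
}

#' @rdname compare_compartments
#' @param x A `compartment_comparison`.
#' @param ... Unused.
#' @export
glance.compartment_comparison <- function(x, ...) {
  tibble(label_agreement = x$label_agreement,
         score_correlation = x$score_correlation, n_bins = x$n_bins)
}
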