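#' Compare boundary sets between two conditions
#'
#' Boundaries are matched greedily by nearest distance within `tol_bins`
#' (each boundary matched at most once, closest pairs first). Unmatched
#' condition-2 boundaries are gained, unmatched condition-1 boundaries lost.
#'
#' @param b1,b2 `boundary_set` tibbles from [boundaries_of()] at the same
#'   resolution.
#' @param tol_bins Matching tolerance in bins.
#' @return A `boundary_diff` object with elements `shared` (tibble of
#'   matched pairs), `gained`, `lost`, `shared_fraction_1`,
#'   `shared_fraction_2`.
#' @export
compare_boundaries <- function(b1, b2, tol_bins = 1) {
  res1 <- attr(b1, "resolution"); res2 <- attr(b2, "resolution")
  if (!is.null(res1) && !is.null(res2) && res1 != res2) {
    abort("boundary sets have different resolutions")
  }
  matched <- greedy_match(b1, b2, tol_bins)
  shared <- matched$pairs
  lost <- b1[!seq_len(nrow(b1)) %in% shared$i1, c("chrom", "bin", "start", "end")]
  gained <- b2[!seq_len(nrow(b2)) %in% shared$i2, c("chrom", "bin", "start", "end")]
  structure(list(
    shared = shared,
    gained = as_tibble(gained),
    lost = as_tibble(lost),
    shared_fraction_1 = if (nrow(b1) == 0) NA_real_ else nrow(shared) / nrow(b1),
    shared_fraction_2 = if (nrow(b2) == 0) NA_real_ else nrow(shared) / nrow(b2),
    tol_bins = tol_bins,
    resolution = res1 %||% res2
  ), class = "boundary_diff")
}

# Greedy nearest-first matching of boundary bins within tol (per chromosome).
greedy_match <- function(b1, b2, tol_bins) {
  empty <- tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                  distance = integer(), i1 = integer(), i2 = integer())
  if (nrow(b1) == 0L || nrow(b2) == 0L) return(list(pairs = empty))
  cand <- inner_join(
    mutate(as_tibble(b1)[, c("chrom", "bin")], i1 = dplyr::row_number()),
    mutate(as_tibble(b2)[, c("chrom", "bin")], i2 = dplyr::row_number()),
    by = "chrom", suffix = c("1", "2"), relationship = "many-to-many") |>
    mutate(distance = abs(.data$bin1 - .data$bin2)) |>
    filter(.data$distance <= tol_bins) |>
    arrange(.data$distance, .data$chrom, .data$bin1, .data$bin2)
  used1 <- logical(nrow(b1)); used2 <- logical(nrow(b2))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i1 <- cand$i1[k]; i2 <- cand$i2[k]
    if (!used1[i1] && !used2[i2]) {
      keep[k] <- TRUE; used1[i1] <- TRUE; used2[i2] <- TRUE
    }
  }
  pairs <- cand[keep, c("chrom", "bin1", "bin2", "distance", "i1", "i2")]
  list(pairs = arrange(pairs, .data$chrom, .data$bin1))
}

#' @export
print.boundary_diff <- function(x, ...) {
  cat(sprintf(
    "boundary_diff: %d shared, %d lost, %d gained (shared fractions %.3f / %.3f)\n",
    nrow(x$shared), nrow(x$lost), nrow(x$gained),
    x$shared_fraction_1, x$shared_fraction_2))
  invisible(x)
}

#' Tidy a boundary comparison into one row per boundary
#'
#' @param x A `boundary_diff`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `bin`, `status` (shared/lost/gained) and the
#'   matched partner bin for shared boundaries.
#' @export
tidy.boundary_diff <- function(x, ...) {
  bind_rows(
    tibble(chrom = x$shared$chrom, bin = x$shared$bin1,
           partner_bin = x$shared$bin2, status = "shared"),
    tibble(chrom = x$lost$chrom, bin = x$lost$bin,
           partner_bin = NA_integer_, status = "lost"),
    tibble(chrom = x$gained$chrom, bin = x$gained$bin,
           partner_bin = NA_integer_, status = "gained")
  ) |> arrange(.data$chrom, .data$bin)
}

#' One-row summary of a boundary comparison
#'
#' @param x A `boundary_diff`.
#' @param ... Unused.
#' @return Tibble with counts and shared fractions.
#' @export
glance.boundary_diff <- function(x, ...) {
  tibble(n_shared = nrow(x$shared), n_lost = nrow(x$lost),
         n_gained = nrow(x$gained),
         shared_fraction_1 = x$shared_fraction_1,
         shared_fraction_2 = x$shared_fraction_2)
}

#' Classify TAD reorganization events between two conditions
#'
#' A condition-1 TAD whose span reciprocally overlaps (>= `ro_min`) the
#' union span of two or more condition-2 TADs, with a gained boundary
#' strictly inside it, is a *separation*; the mirror case (condition-2 TAD
#' covering several condition-1 TADs with a lost internal boundary) is a
#' *fusion*. Boundaries matched at a distance in `(tol_bins, shift_max]`
#' whose flanking TADs are otherwise conserved are *shifts*. Events are
#' disjoint in their defining boundaries.
#'
#' @param tads1,tads2 `tad_set` tibbles at the same resolution.
#' @param tol_bins Boundary-sharing tolerance in bins.
#' @param ro_min Minimum reciprocal overlap for fusion/separation.
#' @param shift_max Maximum shift distance in bins; larger moves count as
#'   independent gain + loss.
#' @return Tibble of events: `kind` (fusion/separation/shift), `chrom`,
#'   `boundary_bin` (condition-2 bin for separations/shifts, condition-1 for
#'   fusions), `boundary_bp` (bin midpoint), `tad1_id`, `tad2_ids`, and for
#'   shifts `from_bin`/`to_bin`.
#' @export
classify_reorganization <- function(tads1, tads2, tol_bins = 1, ro_min = 0.8,
                                    shift_max = 5) {
  res1 <- attr(tads1, "resolution"); res2 <- attr(tads2, "resolution")
  if (!is.null(res1) && !is.null(res2) && res1 != res2) {
    abort("TAD sets have different resolutions")
  }
  res <- res1 %||% res2
  b1 <- boundaries_of(tads1); b2 <- boundaries_of(tads2)
  diff <- compare_boundaries(b1, b2, tol_bins)

  sep <- split_events(tads1, tads2, diff$gained, ro_min, kind = "separation")
  fus <- split_events(tads2, tads1, diff$lost, ro_min, kind = "fusion")

  used <- c(paste(sep$chrom, sep$boundary_bin), paste(fus$chrom, fus$boundary_bin))
  shift_pairs <- greedy_match(b1, b2, shift_max)$pairs |>
    filter(.data$distance > tol_bins,
           !paste(.data$chrom, .data$bin1) %in% used,
           !paste(.data$chrom, .data$bin2) %in% used)
  shifts <- shift_pairs[flanks_conserved(shift_pairs, tads1, tads2,
                                         tol_bins, shift_max), ]
  shift_ev <- tibble(
    kind = rep("shift", nrow(shifts)), chrom = shifts$chrom,
    boundary_bin = shifts$bin2, from_bin = shifts$bin1, to_bin = shifts$bin2,
    tad1_id = NA_character_, tad2_ids = NA_character_)

  out <- bind_rows(sep, fus, shift_ev)
  if (nrow(out) == 0L) {
    out <- tibble(kind = character(), chrom = character(),
                  boundary_bin = integer(), from_bin = integer(),
                  to_bin = integer(), tad1_id = character(),
                  tad2_ids = character())
  }
  out |>
    mutate(boundary_bp = (.data$boundary_bin - 0.5) * res) |>
    arrange(.data$chrom, .data$boundary_bin, .data$kind)
}

# Parent TADs of `tads_whole` split into >=2 `tads_parts` TADs with an
# altered boundary strictly inside: the separation/fusion engine.
split_events <- function(tads_whole, tads_parts, altered, ro_min, kind) {
  empty <- tibble(kind = character(), chrom = character(),
                  boundary_bin = integer(), tad1_id = character(),
                  tad2_ids = character())
  if (nrow(tads_whole) == 0L || nrow(tads_parts) == 0L || nrow(altered) == 0L) {
    return(empty)
  }
  out <- list()
  for (i in seq_len(nrow(tads_whole))) {
    T <- tads_whole[i, ]
    parts <- tads_parts[tads_parts$chrom == T$chrom &
                          tads_parts$start_bin < T$end_bin &
                          tads_parts$end_bin > T$start_bin, ]
    if (nrow(parts) < 2L) next
    u_start <- min(parts$start_bin); u_end <- max(parts$end_bin)
    ov <- min(T$end_bin, u_end) - max(T$start_bin, u_start)
    if (ov / (T$end_bin - T$start_bin) < ro_min) next
    if (ov / (u_end - u_start) < ro_min) next
    inside <- altered[altered$chrom == T$chrom &
                        altered$bin > T$start_bin &
                        altered$bin < T$end_bin - 1L, ]
    if (nrow(inside) == 0L) next
    out[[length(out) + 1L]] <- tibble(
      kind = kind, chrom = T$chrom, boundary_bin = inside$bin,
      tad1_id = T$tad_id, tad2_ids = paste(parts$tad_id, collapse = ","))
  }
  if (length(out) == 0L) empty else list_rbind(out)
}

# Shift sanity check: the TADs flanking the moved boundary keep their outer
# edges in both conditions (matched within the same shift_max radius that
# defines boundary correspondence), or are absent in both.
flanks_conserved <- function(pairs, tads1, tads2, tol_bins, shift_max) {
  if (nrow(pairs) == 0L) return(logical(0))
  edge <- function(tads, chrom, bin, side) {
    tt <- tads[tads$chrom == chrom, ]
    if (side == "left") {
      cand <- tt[tt$end_bin - 1L >= bin - tol_bins & tt$start_bin < bin, ]
      if (nrow(cand) == 0L) NA_integer_ else max(cand$start_bin)
    } else {
      cand <- tt[tt$start_bin <= bin + tol_bins & tt$end_bin - 1L > bin, ]
      if (nrow(cand) == 0L) NA_integer_ else max(cand$end_bin)
    }
  }
  vapply(seq_len(nrow(pairs)), function(k) {
    ch <- pairs$chrom[k]
    l1 <- edge(tads1, ch, pairs$bin1[k], "left")
    l2 <- edge(tads2, ch, pairs$bin2[k], "left")
    r1 <- edge(tads1, ch, pairs$bin1[k], "right")
    r2 <- edge(tads2, ch, pairs$bin2[k], "right")
    ok_left <- (is.na(l1) && is.na(l2)) ||
      (!is.na(l1) && !is.na(l2) && abs(l1 - l2) <= shift_max)
    ok_right <- (is.na(r1) && is.na(r2)) ||
      (!is.na(r1) && !is.na(r2) && abs(r1 - r2) <= shift_max)
    ok_left && ok_right
  }, TRUE)
}

#' Gene density and GC content of TAD inner versus border regions
#'
#' Border regions are boundary bins extended by `border_flank_bins` on each
#' side; inner regions are the remaining TAD bins. Gene density is the TSS
#' count per Mb of region length.
#'
#' @param tads A `tad_set`.
#' @param genes Gene models from [read_gene_models()].
#' @param genome Optional FASTA path or `DNAStringSet` for GC content.
#' @param border_flank_bins Border half-width in bins.
#' @return Tibble with one row per `region_class` (inner/border):
#'   `length_mb`, `n_tss`, `gene_density_per_mb`, `gc_fraction` (NA without
#'   a genome).
#' @export
region_class_stats <- function(tads, genes, genome = NULL,
                               border_flank_bins = 1) {
  res <- attr(tads, "resolution")
  regions <- list(inner = tibble(chrom = character(), start = double(),
                                 end = double()),
                  border = tibble(chrom = character(), start = double(),
                                  end = double()))
  bounds <- boundaries_of(tads)
  for (ch in unique(tads$chrom)) {
    tt <- tads[tads$chrom == ch, ]
    tad_bins <- unique(unlist(map2(tt$start_bin, tt$end_bin - 1L, seq)))
    bb <- bounds$bin[bounds$chrom == ch]
    border_bins <- unique(unlist(map(bb, function(b)
      seq(max(b - border_flank_bins, 1L), b + border_flank_bins))))
    inner_bins <- setdiff(tad_bins, border_bins)
    regions$inner <- bind_rows(regions$inner, bins_to_intervals(ch, inner_bins, res))
    regions$border <- bind_rows(regions$border, bins_to_intervals(ch, border_bins, res))
  }
  imap(regions, function(iv, cls) {
    len <- sum(iv$end - iv$start)
    n_tss <- if (nrow(iv) == 0L) 0L else sum(map_int(seq_len(nrow(genes)), function(g) {
      as.integer(any(iv$chrom == genes$chrom[g] & iv$start <= genes$tss[g] &
                       genes$tss[g] < iv$end))
    }))
    gc <- NA_real_
    if (!is.null(genome) && nrow(iv) > 0L) {
      gcs <- gc_content(iv, genome)
      w <- iv$end - iv$start
      gc <- sum(gcs * w, na.rm = TRUE) / sum(w[!is.na(gcs)])
    }
    tibble(region_class = cls, length_mb = len / 1e6, n_tss = n_tss,
           gene_density_per_mb = if (len > 0) n_tss / (len / 1e6) else 0,
           gc_fraction = gc)
  }) |> list_rbind()
}

# Merge consecutive local bin indices into bp intervals.
bins_to_intervals <- function(chrom, bins, res) {
  if (length(bins) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  bins <- sort(bins)
  grp <- cumsum(c(1, diff(bins) != 1))
  tibble(chrom = chrom,
         start = tapply(bins, grp, min) |> as.numeric(),
         end = tapply(bins, grp, max) |> as.numeric()) |>
    mutate(start = (.data$start - 1) * res, end = .data$end * res)
}
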