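#' CTCF-supported boundary alteration events
#'
#' A boundary gained in condition 2 is retained only when a
#' condition-2-specific CTCF peak (one with no condition-1 CTCF peak within
#' `tol_bp`) lies within `tol_bp` of the boundary bin; lost boundaries
#' mirror this with condition-1-specific peaks. Boundary and CTCF change
#' therefore always agree in direction.
#'
#' @param bdiff A `boundary_diff` from [compare_boundaries()].
#' @param ctcf1,ctcf2 CTCF peak tibbles for the two conditions.
#' @param tol_bp Overlap tolerance in bp (default one 40-kb bin).
#' @return Tibble of events: `chrom`, `bin`, `boundary_bp` (bin midpoint),
#'   `change`, `ctcf_change` (always equal to `change`).
#' @export
ctcf_boundary_events <- function(bdiff, ctcf1, ctcf2, tol_bp = 40000) {
  res <- bdiff$resolution
  one_side <- function(boundaries, specific_peaks, change) {
    if (nrow(boundaries) == 0L || nrow(specific_peaks) == 0L) {
      return(tibble(chrom = character(), bin = integer(),
                    boundary_bp = double(), change = character(),
                    ctcf_change = character()))
    }
    hits <- interval_overlap(boundaries, specific_peaks, tolerance = tol_bp)
    b <- boundaries[unique(hits$idx_a), ]
    tibble(chrom = b$chrom, bin = b$bin,
           boundary_bp = (b$start + b$end) / 2,
           change = change, ctcf_change = change)
  }
  gained <- one_side(bdiff$gained, specific_peaks(ctcf2, ctcf1, tol_bp), "gained")
  lost <- one_side(bdiff$lost, specific_peaks(ctcf1, ctcf2, tol_bp), "lost")
  bind_rows(gained, lost) |> arrange(.data$chrom, .data$bin)
}

# Peaks of `a` with no peak of `b` within tol_bp.
specific_peaks <- function(a, b, tol_bp) {
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  hits <- interval_overlap(a, b, tolerance = tol_bp)
  a[!seq_len(nrow(a)) %in% hits$idx_a, ]
}

#' Candidate genes near CTCF-supported boundary alterations
#'
#' A gene is retained iff it is differentially expressed, its promoter
#' (TSS +/- `promoter_halfwidth`) lies within `search_radius` of some
#' event's boundary, and the promoter overlaps an ATAC peak in *both*
#' conditions (consistent promoter accessibility).
#'
#' @param events Events from [ctcf_boundary_events()].
#' @param genes Gene models from [read_gene_models()].
#' @param expr An `expression_result` from [call_degs()].
#' @param atac1,atac2 ATAC peak tibbles for the two conditions.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @param search_radius Maximum promoter-to-boundary distance in bp.
#' @return Gene tibble with `tss`, `promoter_start`, `promoter_end`,
#'   `log2_fc`, `fdr`, `deg_flag` columns.
#' @export
candidate_genes <- function(events, genes, expr, atac1, atac2,
                            promoter_halfwidth = 2000,
                            search_radius = 1e6) {
  g <- genes |>
    inner_join(as_tibble(expr)[, c("gene_id", "log2_fc", "fdr", "deg_flag")],
               by = "gene_id") |>
    filter(.data$deg_flag != "none") |>
    mutate(promoter_start = pmax(.data$tss - promoter_halfwidth, 0),
           promoter_end = .data$tss + promoter_halfwidth)
  if (nrow(g) == 0L || nrow(events) == 0L) return(g[0, ])
  prom <- tibble(chrom = g$chrom, start = g$promoter_start,
                 end = g$promoter_end)
  ev <- tibble(chrom = events$chrom, start = events$boundary_bp,
               end = events$boundary_bp + 1)
  near <- unique(interval_overlap(prom, ev, tolerance = search_radius)$idx_a)
  acc1 <- unique(interval_overlap(prom, atac1, tolerance = 0)$idx_a)
  acc2 <- unique(interval_overlap(prom, atac2, tolerance = 0)$idx_a)
  g[intersect(intersect(near, acc1), acc2), ]
}

# ATAC peaks accessible in both conditions: peaks of `atac1` that overlap
# some peak of `atac2` (coordinates taken from the first set).
both_accessible_peaks <- function(atac1, atac2) {
  if (nrow(atac1) == 0L || nrow(atac2) == 0L) return(atac1[0, ])
  hits <- interval_overlap(atac1, atac2, tolerance = 0)
  atac1[sort(unique(hits$idx_a)), ]
}

pair_tibble <- function() {
  tibble(gene_id = character(), gene_name = character(),
         mechanism = integer(), role = character(), direction = character(),
         chrom = character(), peak_start = double(), peak_end = double(),
         boundary_bp = double(), event_change = character(),
         distance_bp = double(), log2_fc = double(), fdr = double())
}

# Shared geometry for both mechanisms: both-condition-accessible,
# promoter-distal peaks near the TSS of each candidate gene.
distal_peaks_for_gene <- function(gene, peaks, max_dist, promoter_halfwidth) {
  p <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(p) == 0L) return(p)
  mid <- (p$start + p$end) / 2
  dist <- abs(mid - gene$tss)
  distal <- !(p$start < gene$tss + promoter_halfwidth &
                p$end > gene$tss - promoter_halfwidth)
  out <- p[dist < max_dist & distal, , drop = FALSE]
  out$peak_mid <- mid[dist < max_dist & distal]
  out$distance_bp <- dist[dist < max_dist & distal]
  out
}

# Does an event boundary fall between two positions, at bin resolution with
# a +/- `tol_bins` slack? Boundaries are bins, so betweenness is assessed on
# bin indices with the same one-bin tolerance used for boundary matching.
boundary_between <- function(event_bin, pos1, pos2, res, tol_bins = 1) {
  b1 <- floor(pos1 / res) + 1
  b2 <- floor(pos2 / res) + 1
  lo <- pmin(b1, b2) - tol_bins
  hi <- pmax(b1, b2) + tol_bins
  event_bin >= lo & event_bin <= hi
}

# TAD id containing a chromosome-local bp position (NA when outside TADs).
tad_of <- function(tads, chrom, pos) {
  hit <- tads$chrom == chrom & tads$start <= pos & pos < tads$end
  if (any(hit)) tads$tad_id[which(hit)[1]] else NA_character_
}

#' Mechanism-1 (intra-TAD, loop alteration) candidate pairs
#'
#' For each candidate gene, emits a pair for every ATAC peak that is
#' accessible in both conditions, promoter-distal, closer than `max_dist`
#' to the TSS, and separated from the TSS by an event boundary (at bin
#' resolution, +/- `between_tol_bins`), when the direction rule holds: a
#' gained boundary with a down-regulated gene gives a deactivation pair, a
#' lost boundary with an up-regulated gene an activation pair.
#'
#' @param cands Candidate genes from [candidate_genes()].
#' @param events Events from [ctcf_boundary_events()].
#' @param atac1,atac2 ATAC peak tibbles.
#' @param resolution Bin width in bp of the boundary bins.
#' @param max_dist Maximum peak-to-TSS distance in bp (default 20 kb).
#' @param promoter_halfwidth Promoter half-width in bp.
#' @param between_tol_bins Bin tolerance for the betweenness test.
#' @return A candidate-pair tibble (see [classify_pairs()]).
#' @export
classify_mechanism1 <- function(cands, events, atac1, atac2, resolution,
                                max_dist = 20000, promoter_halfwidth = 2000,
                                between_tol_bins = 1) {
  peaks <- both_accessible_peaks(atac1, atac2)
  out <- list()
  for (i in seq_len(nrow(cands))) {
    gene <- cands[i, ]
    pk <- distal_peaks_for_gene(gene, peaks, max_dist, promoter_halfwidth)
    if (nrow(pk) == 0L) next
    ev <- events[events$chrom == gene$chrom, , drop = FALSE]
    for (k in seq_len(nrow(pk))) {
      between <- ev[boundary_between(ev$bin, pk$peak_mid[k], gene$tss,
                                     resolution, between_tol_bins), ,
                    drop = FALSE]
      for (e in seq_len(nrow(between))) {
        dir <- mech1_direction(between$change[e], gene$deg_flag)
        if (is.na(dir)) next
        out[[length(out) + 1L]] <- tibble(
          gene_id = gene$gene_id, gene_name = gene$gene_name,
          mechanism = 1L,
          role = if (gene$deg_flag == "up") "oncogene" else "suppressor",
          direction = dir, chrom = gene$chrom,
          peak_start = pk$start[k], peak_end = pk$end[k],
          boundary_bp = between$boundary_bp[e],
          event_change = between$change[e],
          distance_bp = pk$distance_bp[k],
          log2_fc = gene$log2_fc, fdr = gene$fdr)
      }
    }
  }
  if (length(out) == 0L) pair_tibble() else list_rbind(out)
}

mech1_direction <- function(change, deg_flag) {
  if (change == "gained" && deg_flag == "down") "deactivation"
  else if (change == "lost" && deg_flag == "up") "activation"
  else NA_character_
}

#' Mechanism-2 (inter-TAD, TAD reorganization) candidate pairs
#'
#' Pairs require a both-condition-accessible, promoter-distal peak within
#' `max_dist` of the TSS such that peak and TSS lie in the same TAD in
#' exactly one condition (fusion/separation geometry), with an associated
#' event boundary in the peak-TSS window. The direction rule is
#' configurable: under `"novel_boundary_activates"` (the default) a gained
#' boundary with an up-regulated gene gives an activation pair and a lost
#' boundary with a down-regulated gene a deactivation pair; the
#' `"novel_boundary_insulates"` preset swaps the two (a lost boundary
#' fusing two TADs activates the gene), matching fusion-driven activation
#' case studies.
#'
#' @inheritParams classify_mechanism1
#' @param tads1,tads2 `tad_set` tibbles for the two conditions.
#' @param max_dist Maximum peak-to-TSS distance in bp (default 100 kb).
#' @param rule Direction-rule preset.
#' @return A candidate-pair tibble (see [classify_pairs()]).
#' @export
classify_mechanism2 <- function(cands, events, atac1, atac2, tads1, tads2,
                                resolution, max_dist = 1e5,
                                promoter_halfwidth = 2000,
                                between_tol_bins = 1,
                                rule = c("novel_boundary_activates",
                                         "novel_boundary_insulates")) {
  rule <- match.arg(rule)
  peaks <- both_accessible_peaks(atac1, atac2)
  out <- list()
  for (i in seq_len(nrow(cands))) {
    gene <- cands[i, ]
    pk <- distal_peaks_for_gene(gene, peaks, max_dist, promoter_halfwidth)
    if (nrow(pk) == 0L) next
    ev <- events[events$chrom == gene$chrom, , drop = FALSE]
    tss_tad1 <- tad_of(tads1, gene$chrom, gene$tss)
    tss_tad2 <- tad_of(tads2, gene$chrom, gene$tss)
    for (k in seq_len(nrow(pk))) {
      same1 <- !is.na(tss_tad1) &&
        identical(tad_of(tads1, gene$chrom, pk$peak_mid[k]), tss_tad1)
      same2 <- !is.na(tss_tad2) &&
        identical(tad_of(tads2, gene$chrom, pk$peak_mid[k]), tss_tad2)
      if (same1 == same2) next   # co-membership must change between conditions
      between <- ev[boundary_between(ev$bin, pk$peak_mid[k], gene$tss,
                                     resolution, between_tol_bins), ,
                    drop = FALSE]
      for (e in seq_len(nrow(between))) {
        dir <- mech2_direction(between$change[e], gene$deg_flag, rule)
        if (is.na(dir)) next
        out[[length(out) + 1L]] <- tibble(
          gene_id = gene$gene_id, gene_name = gene$gene_name,
          mechanism = 2L,
          role = if (gene$deg_flag == "up") "oncogene" else "suppressor",
          direction = dir, chrom = gene$chrom,
          peak_start = pk$start[k], peak_end = pk$end[k],
          boundary_bp = between$boundary_bp[e],
          event_change = between$change[e],
          distance_bp = pk$distance_bp[k],
          log2_fc = gene$log2_fc, fdr = gene$fdr)
      }
    }
  }
  if (length(out) == 0L) pair_tibble() else list_rbind(out)
}

mech2_direction <- function(change, deg_flag, rule) {
  if (rule == "novel_boundary_activates") {
    if (change == "gained" && deg_flag == "up") "activation"
    else if (change == "lost" && deg_flag == "down") "deactivation"
    else NA_character_
  } else {
    if (change == "gained" && deg_flag == "down") "deactivation"
    else if (change == "lost" && deg_flag == "up") "activation"
    else NA_character_
  }
}

#' Classify candidate enhancer-gene pairs from prepared inputs
#'
#' Runs the three analysis steps on in-memory objects: CTCF-supported
#' boundary events, candidate-gene selection, and mechanism-1/2 pair
#' classification. Output order is deterministic (gene, then distance).
#'
#' @param tads1,tads2 `tad_set` tibbles for conditions 1 and 2.
#' @param ctcf1,ctcf2,atac1,atac2 Peak tibbles per condition.
#' @param genes Gene models.
#' @param expr An `expression_result`.
#' @param params Optional list overriding defaults: `ctcf_tol_bp`,
#'   `boundary_tol_bins`, `promoter_halfwidth`, `search_radius`,
#'   `mech1_max_dist`, `mech2_max_dist`, `between_tol_bins`, `mech2_rule`.
#' @return A `pair_result` list: `pairs` (candidate-pair tibble), `events`,
#'   `candidates`, and `summary` (counts per mechanism and role).
#' @export
classify_pairs <- function(tads1, tads2, ctcf1, ctcf2, atac1, atac2, genes,
                           expr, params = list()) {
  p <- utils::modifyList(list(
    ctcf_tol_bp = 40000, boundary_tol_bins = 1, promoter_halfwidth = 2000,
    search_radius = 1e6, mech1_max_dist = 20000, mech2_max_dist = 1e5,
    between_tol_bins = 1, mech2_rule = "novel_boundary_activates"), params)
  res <- attr(tads1, "resolution") %||% attr(tads2, "resolution")
  bdiff <- compare_boundaries(boundaries_of(tads1), boundaries_of(tads2),
                              tol_bins = p$boundary_tol_bins)
  events <- ctcf_boundary_events(bdiff, ctcf1, ctcf2, tol_bp = p$ctcf_tol_bp)
  cands <- candidate_genes(events, genes, expr, atac1, atac2,
                           promoter_halfwidth = p$promoter_halfwidth,
                           search_radius = p$search_radius)
  pairs <- bind_rows(
    classify_mechanism1(cands, events, atac1, atac2, resolution = res,
                        max_dist = p$mech1_max_dist,
                        promoter_halfwidth = p$promoter_halfwidth,
                        between_tol_bins = p$between_tol_bins),
    classify_mechanism2(cands, events, atac1, atac2, tads1, tads2,
                        resolution = res, max_dist = p$mech2_max_dist,
                        promoter_halfwidth = p$promoter_halfwidth,
                        between_tol_bins = p$between_tol_bins,
                        rule = p$mech2_rule)) |>
    distinct() |>
    arrange(.data$gene_id, .data$mechanism, .data$distance_bp,
            .data$peak_start)
  structure(list(pairs = pairs, events = events, candidates = cands,
                 summary = pair_summary(pairs), params = p),
            class = "pair_result")
}

#' Count candidate pairs per mechanism and role
#'
#' Genes are counted once per (mechanism, role); a gene supported by
#' several peaks still counts once.
#'
#' @param pairs A candidate-pair tibble.
#' @return Tibble with `mech1_onco`, `mech1_supp`, `mech2_onco`,
#'   `mech2_supp`.
#' @export
pair_summary <- function(pairs) {
  cnt <- function(mech, role) {
    dplyr::n_distinct(pairs$gene_id[pairs$mechanism == mech &
                                      pairs$role == role])
  }
  tibble(mech1_onco = cnt(1L, "oncogene"), mech1_supp = cnt(1L, "suppressor"),
         mech2_onco = cnt(2L, "oncogene"), mech2_supp = cnt(2L, "suppressor"))
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("pair_result: %d pairs (%d events, %d candidate genes)\n",
              nrow(x$pairs), nrow(x$events), nrow(x$candidates)))
  print(x$summary)
  invisible(x)
}

#' @rdname classify_pairs
#' @param x A `pair_result`.
#' @param ... Unused.
#' @export
tidy.pair_result <- function(x, ...) x$pairs

#' @rdname classify_pairs
#' @export
glance.pair_result <- function(x, ...) {
  bind_cols(x$summary, tibble(n_pairs = nrow(x$pairs),
                              n_events = nrow(x$events),
                              n_candidates = nrow(x$candidates)))
}
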