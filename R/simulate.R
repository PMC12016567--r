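#' Scenario specification for the two-condition simulator
#'
#' A scenario fixes everything the simulator needs: chromosome sizes and
#' resolution, the condition-1 TAD layout (built from a repeating cycle of
#' TAD sizes), the planted reorganization events, the planted enhancer-gene
#' pairs and decoys, sequencing depth, distance-decay exponent, within-TAD
#' contact enrichment, expression parameters, and the seed. All simulator
#' outputs are fully determined by the spec (which includes the seed).
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param resolution Bin width in bp.
#' @param tad_size_cycle TAD sizes in bins, recycled along each chromosome
#'   to build the condition-1 layout.
#' @param events Tibble of planted events: `chrom`, `kind`
#'   (fusion/separation/shift), `bin` (the altered boundary bin; for shifts
#'   the condition-1 bin) and `shift_by` (bins, shifts only).
#' @param pairs Tibble of planted pairs and decoys: `gene_id`, `chrom`,
#'   `event_bin`, `mechanism` (1 or 2), `expected` (logical: decoys are
#'   FALSE), `violation` (NA or one of distance/accessibility/deg/
#'   direction), `deg_direction` (up/down/none).
#' @param depth_per_chrom Expected total cis read pairs per chromosome.
#' @param decay_exponent Power-law exponent of contact decay with distance.
#' @param block_enrichment Within-TAD contact multiplier.
#' @param n_null_genes Background genes with no planted fold change.
#' @param base_mean Baseline expression mean count.
#' @param planted_fc Planted linear fold change for DEG genes.
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param mech2_rule Direction preset the planted mechanism-2 expression
#'   changes follow (see [classify_mechanism2()]).
#' @param seed Integer seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(chrom_sizes = c(chrS1 = 2e7, chrS2 = 2e7),
                          resolution = 40000,
                          tad_size_cycle = c(10, 17, 8, 18, 11, 9, 17, 12),
                          events = NULL, pairs = NULL,
                          depth_per_chrom = 1e5, decay_exponent = 1.0,
                          block_enrichment = 3.0, n_null_genes = 42,
                          base_mean = 500, planted_fc = 8,
                          nb_dispersion = 0.1,
                          mech2_rule = "novel_boundary_activates",
                          seed = 42) {
  n_bins <- setNames(ceiling(chrom_sizes / resolution), names(chrom_sizes))
  layout1 <- lapply(n_bins, function(n) layout_breakpoints(n, tad_size_cycle))
  spec <- structure(list(
    chrom_sizes = chrom_sizes, resolution = resolution,
    n_bins = n_bins, layout1 = layout1,
    events = events %||% tibble(chrom = character(), kind = character(),
                                bin = integer(), shift_by = integer()),
    pairs = pairs %||% tibble(gene_id = character(), chrom = character(),
                              event_bin = integer(), mechanism = integer(),
                              expected = logical(), violation = character(),
                              deg_direction = character()),
    depth_per_chrom = depth_per_chrom, decay_exponent = decay_exponent,
    block_enrichment = block_enrichment, n_null_genes = n_null_genes,
    base_mean = base_mean, planted_fc = planted_fc,
    nb_dispersion = nb_dispersion, mech2_rule = mech2_rule, seed = seed
  ), class = "scenario_spec")
  validate_scenario(spec)
  spec
}

# TAD partition breakpoints: TAD k spans [v[k], v[k+1]); includes 1 and
# n_bins + 1. A short trailing TAD is merged into its neighbor.
layout_breakpoints <- function(n_bins, sizes) {
  v <- 1L
  k <- 1L
  while (tail(v, 1) <= n_bins) {
    v <- c(v, tail(v, 1) + sizes[(k - 1L) %% length(sizes) + 1L])
    k <- k + 1L
  }
  v[length(v)] <- n_bins + 1L
  if (length(v) > 2L && diff(tail(v, 2)) < 3L) v <- v[-(length(v) - 1L)]
  as.integer(v)
}

validate_scenario <- function(spec) {
  ev <- spec$events
  if (nrow(ev) == 0L) return(invisible(spec))
  for (ch in unique(ev$chrom)) {
    bins <- sort(ev$bin[ev$chrom == ch])
    if (any(diff(bins) < 6L)) abort("overlapping planted events (boundaries closer than 6 bins)")
    if (any(bins < 4L) || any(bins > spec$n_bins[[ch]] - 3L)) {
      abort("planted event boundary outside chromosome bounds")
    }
  }
  invisible(spec)
}

# Run code under a derived seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a block-structured cis contact map
#'
#' The expected count of bin pair (i, j) is proportional to
#' `(|i - j| + 1)^(-decay_exponent)` times `block_enrichment` when the two
#' bins share a TAD; counts are independent Poisson draws normalized so the
#' expected total per chromosome is `depth_per_chrom`.
#'
#' @param layout Named list (per chromosome) of TAD partition breakpoints
#'   in bins (`c(1, ..., n_bins + 1)`).
#' @param chrom_sizes,resolution Genome geometry.
#' @param depth_per_chrom Expected cis read pairs per chromosome.
#' @param decay_exponent,block_enrichment Decay and block parameters.
#' @param seed Integer seed (reproducible output).
#' @return A `contact_map`.
#' @export
simulate_contact_map <- function(layout, chrom_sizes, resolution,
                                 depth_per_chrom = 1e5, decay_exponent = 1.0,
                                 block_enrichment = 3.0, seed = 1) {
  bins <- make_bins(chrom_sizes, resolution)
  nb <- chrom_nbins(bins)
  cis <- with_seed(seed, {
    out <- lapply(names(nb), function(ch) {
      n <- nb[[ch]]
      tad_id <- tad_membership(layout[[ch]], n)
      D <- abs(outer(seq_len(n), seq_len(n), "-"))
      W <- (D + 1)^(-decay_exponent)
      same <- outer(tad_id, tad_id, function(a, b) !is.na(a) & !is.na(b) & a == b)
      W <- W * ifelse(same, block_enrichment, 1)
      up <- upper.tri(W, diag = TRUE)
      p <- W[up] / sum(W[up])
      counts <- rpois(length(p), lambda = depth_per_chrom * p)
      M <- matrix(0, n, n)
      M[up] <- counts
      M + t(M) - diag(diag(M))
    })
    names(out) <- names(nb)
    out
  })
  new_contact_map(bins, lapply(cis, function(m) Matrix::Matrix(m, sparse = TRUE)))
}

# TAD index per bin given partition breakpoints (every bin belongs to one).
tad_membership <- function(breakpoints, n_bins) {
  findInterval(seq_len(n_bins), breakpoints)
}

#' Simulate a matched pair of condition contact maps with planted events
#'
#' The condition-2 layout is the condition-1 layout with the spec's events
#' applied: fusions remove the named boundary, separations insert it,
#' shifts move it by `shift_by` bins. Both maps are simulated with
#' [simulate_contact_map()] under seeds derived from the spec seed.
#'
#' @param spec A [scenario_spec()].
#' @return List with `map1`, `map2` and `truth`, a manifest recording the
#'   layouts, per-condition boundary bins, and the planted events.
#' @export
simulate_condition_pair <- function(spec) {
  layout2 <- apply_events(spec$layout1, spec$events)
  map1 <- simulate_contact_map(spec$layout1, spec$chrom_sizes,
                               spec$resolution, spec$depth_per_chrom,
                               spec$decay_exponent, spec$block_enrichment,
                               seed = spec$seed)
  map2 <- simulate_contact_map(layout2, spec$chrom_sizes, spec$resolution,
                               spec$depth_per_chrom, spec$decay_exponent,
                               spec$block_enrichment, seed = spec$seed + 1000L)
  truth <- list(
    layout1 = spec$layout1, layout2 = layout2,
    boundaries1 = layout_boundary_bins(spec$layout1),
    boundaries2 = layout_boundary_bins(layout2),
    events = spec$events, resolution = spec$resolution
  )
  list(map1 = map1, map2 = map2, truth = truth)
}

apply_events <- function(layout1, events) {
  layout2 <- layout1
  for (k in seq_len(nrow(events))) {
    ch <- events$chrom[k]; b <- events$bin[k]
    v <- layout2[[ch]]
    if (events$kind[k] == "fusion") {
      if (!b %in% v) abort("fusion event at a bin that is not a boundary")
      v <- setdiff(v, b)
    } else if (events$kind[k] == "separation") {
      if (b %in% v) abort("separation event at an existing boundary")
      v <- sort(c(v, b))
    } else if (events$kind[k] == "shift") {
      if (!b %in% v) abort("shift event at a bin that is not a boundary")
      v <- sort(c(setdiff(v, b), b + events$shift_by[k]))
    } else abort(sprintf("unknown event kind: %s", events$kind[k]))
    layout2[[ch]] <- as.integer(v)
  }
  layout2
}

# Boundary bins of a layout, matching the boundaries_of() convention:
# every TAD start bin plus the last bin of the chromosome-final TAD.
layout_boundary_bins <- function(layout) {
  lapply(layout, function(v) {
    c(head(v, -1), tail(v, 1) - 1L)
  })
}

#' Simulate CTCF/ATAC peaks, gene models and expression counts for a
#' scenario
#'
#' CTCF peaks are placed at every TAD boundary, present only in the
#' condition(s) whose layout contains that boundary. Each planted pair
#' contributes a gene (promoter ATAC peaks in both conditions) and an
#' enhancer ATAC peak at the mechanism's geometry; counts are
#' negative-binomial with the planted fold change in the direction the
#' active mechanism rule requires. Decoys violate exactly one criterion
#' each (distance, accessibility, DEG status, or direction); null genes
#' are scattered background with no fold change.
#'
#' @param spec A [scenario_spec()].
#' @param truth Truth manifest from [simulate_condition_pair()].
#' @return List with peak tibbles `ctcf1`, `ctcf2`, `atac1`, `atac2`, gene
#'   models `genes`, count tibble `counts` (columns `cond1`, `cond2`), and
#'   `truth_pairs` (expected pairs and decoy annotations).
#' @export
simulate_regulome <- function(spec, truth) {
  res <- spec$resolution
  ctcf <- function(bound) {
    list_rbind(imap(bound, function(bins, ch) {
      mid <- (bins - 0.5) * res
      tibble(chrom = ch, start = pmax(mid - 200, 0), end = mid + 200,
             name = sprintf("%s_ctcf_%d", ch, bins), score = 10,
             strand = ".")
    })) |> arrange(.data$chrom, .data$start)
  }
  ctcf1 <- ctcf(truth$boundaries1)
  ctcf2 <- ctcf(truth$boundaries2)

  geom <- pair_geometry(spec)
  genes <- geom$genes
  # background genes: evenly spaced TSSs away from planted loci
  null_genes <- null_gene_models(spec, genes)
  genes <- bind_rows(genes, null_genes) |> arrange(.data$chrom, .data$start)

  prom <- tibble(chrom = genes$chrom, start = pmax(genes$tss - 300, 0),
                 end = genes$tss + 300,
                 name = paste0(genes$gene_id, "_prom"), score = 5,
                 strand = ".")
  enh <- geom$enhancers
  atac1 <- bind_rows(prom, enh[enh$in_cond1, names(prom)]) |>
    arrange(.data$chrom, .data$start)
  atac2 <- bind_rows(prom, enh[enh$in_cond2, names(prom)]) |>
    arrange(.data$chrom, .data$start)

  mu1 <- rep(spec$base_mean, nrow(genes))
  fc <- setNames(rep(1, nrow(genes)), genes$gene_id)
  dirs <- setNames(geom$truth_pairs$deg_direction, geom$truth_pairs$gene_id)
  fc[names(dirs)[dirs == "up"]] <- spec$planted_fc
  fc[names(dirs)[dirs == "down"]] <- 1 / spec$planted_fc
  mu2 <- mu1 * fc[genes$gene_id]
  counts <- with_seed(spec$seed + 2000L, {
    tibble(gene_id = genes$gene_id,
           cond1 = rnbinom(nrow(genes), mu = mu1, size = 1 / spec$nb_dispersion),
           cond2 = rnbinom(nrow(genes), mu = mu2, size = 1 / spec$nb_dispersion))
  })
  list(ctcf1 = ctcf1, ctcf2 = ctcf2, atac1 = atac1, atac2 = atac2,
       genes = genes, counts = counts,
       truth_pairs = geom$truth_pairs)
}

# Gene/enhancer geometry for every planted pair and decoy. Anchors are the
# start bp of the event's boundary bin; mechanism 1 places TSS and enhancer
# 8 kb either side of it (16 kb apart), mechanism 2 uses 45 kb (90 kb
# apart) so that TAD membership is robust to one-bin boundary-call error.
pair_geometry <- function(spec) {
  res <- spec$resolution
  genes <- list(); enh <- list(); tp <- list()
  for (k in seq_len(nrow(spec$pairs))) {
    pr <- spec$pairs[k, ]
    anchor <- (pr$event_bin - 1) * res
    off <- if (pr$mechanism == 1L) 8000 else 45000
    viol <- pr$violation
    tss <- anchor + off
    enh_mid <- anchor - off
    if (!is.na(viol) && viol == "distance") {
      enh_mid <- anchor - (if (pr$mechanism == 1L) 30000 else 150000)
    }
    if (!is.na(viol) && viol == "direction" && pr$mechanism == 1L) {
      # same-side geometry: boundary not between peak and TSS at TAD scale
      tss <- anchor + 70000
      enh_mid <- anchor + 55000
    }
    gid <- pr$gene_id
    genes[[k]] <- tibble(
      gene_id = gid, gene_name = gid, chrom = pr$chrom, strand = "+",
      start = tss, end = tss + 5000, tss = tss, exonic_length = 2000)
    enh[[k]] <- tibble(
      chrom = pr$chrom, start = enh_mid - 400, end = enh_mid + 400,
      name = paste0(gid, "_enh"), score = 8, strand = ".",
      in_cond1 = TRUE,
      in_cond2 = is.na(viol) || viol != "accessibility")
    tp[[k]] <- mutate(pr, tss = tss, enhancer_mid = enh_mid)
  }
  list(genes = if (length(genes)) list_rbind(genes) else
         tibble(gene_id = character(), gene_name = character(),
                chrom = character(), strand = character(), start = double(),
                end = double(), tss = double(), exonic_length = double()),
       enhancers = if (length(enh)) list_rbind(enh) else
         tibble(chrom = character(), start = double(), end = double(),
                name = character(), score = double(), strand = character(),
                in_cond1 = logical(), in_cond2 = logical()),
       truth_pairs = if (length(tp)) list_rbind(tp) else spec$pairs)
}

null_gene_models <- function(spec, planted) {
  n <- spec$n_null_genes
  if (n == 0L) {
    return(planted[0, ])
  }
  chroms <- rep(names(spec$chrom_sizes), length.out = n)
  out <- list()
  for (k in seq_len(n)) {
    ch <- chroms[k]
    pos <- round(spec$chrom_sizes[[ch]] * (k + 0.5) / (n + 2))
    # keep background promoters clear of planted loci so a null promoter
    # peak can never stand in as an enhancer of a planted gene
    # 250 kb: planted TSSs sit up to 70 kb from their anchor and mechanism-2
    # scans 100 kb around them, so this keeps null promoters out of reach
    anchors <- (spec$events$bin[spec$events$chrom == ch] - 1) * spec$resolution
    while (any(planted$chrom == ch & abs(planted$tss - pos) < 20000) ||
           any(abs(anchors - pos) < 250000)) {
      pos <- pos + 50000
    }
    gid <- sprintf("null%03d", k)
    out[[k]] <- tibble(gene_id = gid, gene_name = gid, chrom = ch,
                       strand = "+", start = pos, end = pos + 5000,
                       tss = pos, exonic_length = 2000)
  }
  list_rbind(out)
}

#' Fully simulated two-condition scenario
#'
#' Convenience wrapper running [simulate_condition_pair()] and
#' [simulate_regulome()].
#'
#' @param spec A [scenario_spec()].
#' @return List with `map1`, `map2`, the regulome elements and `truth`
#'   (manifest including `truth_pairs`).
#' @export
simulate_scenario <- function(spec) {
  cp <- simulate_condition_pair(spec)
  reg <- simulate_regulome(spec, cp$truth)
  truth <- cp$truth
  truth$truth_pairs <- reg$truth_pairs
  c(list(map1 = cp$map1, map2 = cp$map2, truth = truth),
    reg[c("ctcf1", "ctcf2", "atac1", "atac2", "genes", "counts")])
}

#' The default planted-truth scenario
#'
#' Two 20-Mb chromosomes at 40-kb bins with within-TAD enrichment 3, decay
#' exponent 1 and 1e5 cis pairs per chromosome. Sixteen planted events
#' carry 4 expected mechanism-1 pairs, 4 expected mechanism-2 pairs and 8
#' one-violation decoys; 42 null genes give 50 decoy/background genes in
#' total.
#'
#' @param seed Integer seed.
#' @return A [scenario_spec()].
#' @export
default_scenario <- function(seed = 42) {
  # events sit at layout breakpoints (fusions, merging TAD pairs of about
  # 20 bins) or at midpoints of the large 17-18-bin TADs (separations,
  # leaving halves of 8-9 bins) of the default size cycle; bins chosen on
  # that fixed layout, >= 6 bins apart and away from the chromosome edges
  # where flank truncation degrades the directionality index.
  events <- tibble(
    chrom = rep(c("chrS1", "chrS2"), each = 8),
    kind = c("separation", "fusion", "separation", "fusion",
             "separation", "separation", "separation", "separation",
             "separation", "fusion", "separation", "fusion",
             "separation", "fusion", "separation", "separation"),
    bin = c(147L, 205L, 184L, 409L, 286L, 351L, 388L, 427L,
            147L, 205L, 184L, 409L, 286L, 65L, 351L, 427L),
    shift_by = NA_integer_
  )
  pairs <- tibble(
    gene_id = c("gene_m1_deact_a", "gene_m1_act_a", "gene_m2_act_a",
                "gene_m2_deact_a", "decoy_m1_dist", "decoy_m1_acc",
                "decoy_m1_deg", "decoy_m1_dir",
                "gene_m1_deact_b", "gene_m1_act_b", "gene_m2_act_b",
                "gene_m2_deact_b", "decoy_m2_dist", "decoy_m2_acc",
                "decoy_m2_deg", "decoy_m2_dir"),
    chrom = rep(c("chrS1", "chrS2"), each = 8),
    event_bin = c(147L, 205L, 184L, 409L, 286L, 351L, 388L, 427L,
                  147L, 205L, 184L, 409L, 286L, 65L, 351L, 427L),
    mechanism = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L,
                  1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L),
    expected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    violation = c(NA, NA, NA, NA, "distance", "accessibility", "deg",
                  "direction",
                  NA, NA, NA, NA, "distance", "accessibility", "deg",
                  "direction"),
    deg_direction = c("down", "up", "up", "down", "down", "down", "none",
                      "up",
                      "down", "up", "up", "down", "up", "down", "none",
                      "down")
  )
  scenario_spec(events = events, pairs = pairs, seed = seed)
}

#' Scenario with a chosen number of each reorganization event type
#'
#' Events are assigned deterministically to the condition-1 layout:
#' fusions and shifts take existing internal boundaries, separations split
#' large TADs at their midpoint, all spaced at least 6 bins apart.
#'
#' @param n_fusion,n_separation,n_shift Event counts.
#' @param shift_by Shift distance in bins.
#' @param seed Integer seed.
#' @param ... Passed to [scenario_spec()].
#' @return A [scenario_spec()].
#' @export
event_scenario <- function(n_fusion = 10, n_separation = 10, n_shift = 10,
                           shift_by = 3L, seed = 7, ...) {
  base <- scenario_spec(seed = seed, ...)
  # fusion/shift candidates: internal breakpoints, small merged spans first
  # so fused TADs stay compact enough for reliable re-detection
  cand_bound <- list_rbind(imap(base$layout1, function(v, ch) {
    sizes <- diff(v)
    k <- seq(2, length(v) - 1)
    tibble(chrom = ch, bin = as.integer(v[k]),
           merged = sizes[k - 1] + sizes[k])
  })) |>
    filter(.data$bin > 54, .data$bin < map_dbl(.data$chrom, ~ base$n_bins[[.x]]) - 54) |>
    arrange(.data$merged, .data$chrom, .data$bin)
  # separation candidates: midpoints of large TADs, so both halves carry
  # enough bins for the directionality index to resolve them
  cand_sep <- list_rbind(imap(base$layout1, function(v, ch) {
    sizes <- diff(v)
    big <- which(sizes >= 16)
    tibble(chrom = ch, bin = as.integer(v[big] + floor(sizes[big] / 2)))
  })) |>
    filter(.data$bin > 54, .data$bin < map_dbl(.data$chrom, ~ base$n_bins[[.x]]) - 54)
  # shift candidates: boundaries whose right-hand TAD is large, so the
  # moved boundary still flanks a well-resolved domain
  cand_shift <- list_rbind(imap(base$layout1, function(v, ch) {
    sizes <- diff(v)
    k <- which(sizes >= 14)
    k <- k[k > 1]
    tibble(chrom = ch, bin = as.integer(v[k]))
  })) |>
    filter(.data$bin > 54, .data$bin < map_dbl(.data$chrom, ~ base$n_bins[[.x]]) - 54)
  used <- tibble(chrom = character(), bin = integer())
  # 12-bin exclusion zone keeps events out of each other's TADs
  take <- function(cand, n, kind, shift) {
    got <- 0L; rows <- list()
    for (i in seq_len(nrow(cand))) {
      if (got == n) break
      ok <- !any(used$chrom == cand$chrom[i] & abs(used$bin - cand$bin[i]) < 12L)
      if (ok) {
        rows[[length(rows) + 1L]] <- tibble(chrom = cand$chrom[i],
                                            kind = kind, bin = cand$bin[i],
                                            shift_by = shift)
        used <<- bind_rows(used, cand[i, c("chrom", "bin")])
        got <- got + 1L
      }
    }
    if (got < n) abort(sprintf("layout too small for %d %s events", n, kind))
    list_rbind(rows)
  }
  ev <- bind_rows(
    take(cand_bound, n_fusion, "fusion", NA_integer_),
    take(cand_shift, n_shift, "shift", as.integer(shift_by)),
    take(cand_sep, n_separation, "separation", NA_integer_))
  scenario_spec(events = ev, seed = seed, ...)
}

#' Simulate a compartment-structured contact map
#'
#' Bins carry planted A/B labels; expected counts are the power-law decay
#' times `compartment_enrichment` when two bins share a label, so the
#' Pearson correlation of the observed/expected matrix has the plaid
#' pattern compartment calling relies on.
#'
#' @param labels Character vector of planted labels ("A"/"B"), one per bin,
#'   single chromosome.
#' @param chrom Chromosome name.
#' @param resolution Bin width in bp.
#' @param depth Expected total cis pairs.
#' @param decay_exponent Power-law decay exponent.
#' @param compartment_enrichment Same-label contact multiplier.
#' @param seed Integer seed.
#' @return List with `map` (a `contact_map`) and `labels`.
#' @export
simulate_compartment_map <- function(labels, chrom = "chrC",
                                     resolution = 100000, depth = 2e5,
                                     decay_exponent = 0.5,
                                     compartment_enrichment = 2.0,
                                     seed = 1) {
  n <- length(labels)
  chrom_sizes <- setNames(n * resolution, chrom)
  bins <- make_bins(chrom_sizes, resolution)
  M <- with_seed(seed, {
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    W <- (D + 1)^(-decay_exponent)
    same <- outer(labels, labels, "==")
    W <- W * ifelse(same, compartment_enrichment, 1)
    up <- upper.tri(W, diag = TRUE)
    p <- W[up] / sum(W[up])
    counts <- rpois(length(p), depth * p)
    M <- matrix(0, n, n)
    M[up] <- counts
    M + t(M) - diag(diag(M))
  })
  cis <- setNames(list(Matrix::Matrix(M, sparse = TRUE)), chrom)
  list(map = new_contact_map(bins, cis), labels = labels)
}

#' Write a simulated scenario to pipeline input files
#'
#' Emits the formats the pipeline reads: HiC-Pro triplet matrix + bins BED
#' per condition, narrowPeak files for CTCF and ATAC, a GTF of gene
#' models, a count TSV, and a JSON truth manifest.
#'
#' @param sim Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_scenario_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix1 = file.path(dir, "cond1.matrix"),
    bins1 = file.path(dir, "cond1_abs.bed"),
    matrix2 = file.path(dir, "cond2.matrix"),
    bins2 = file.path(dir, "cond2_abs.bed"),
    ctcf1 = file.path(dir, "ctcf_cond1.narrowPeak"),
    ctcf2 = file.path(dir, "ctcf_cond2.narrowPeak"),
    atac1 = file.path(dir, "atac_cond1.narrowPeak"),
    atac2 = file.path(dir, "atac_cond2.narrowPeak"),
    genes = file.path(dir, "genes.gtf"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.json"))
  write_contact_map(sim$map1, paths$matrix1, paths$bins1)
  write_contact_map(sim$map2, paths$matrix2, paths$bins2)
  for (nm in c("ctcf1", "ctcf2", "atac1", "atac2")) {
    write_narrowpeak(sim[[nm]], paths[[nm]])
  }
  write_gtf(sim$genes, paths$genes)
  readr::write_tsv(sim$counts, paths$counts)
  truth <- sim$truth
  truth$events <- as.data.frame(truth$events)
  truth$truth_pairs <- as.data.frame(truth$truth_pairs)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  df <- data.frame(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE),
    name = if (n) replace_na_chr(peaks$name) else character(),
    score = 0, strand = ".",
    signal = if ("score" %in% names(peaks)) replace_na_chr(as.character(peaks$score), "0") else "0",
    p = -1, q = -1, summit = -1)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

write_gtf <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    # internal 0-based half-open -> GTF 1-based inclusive
    lines <- c(lines,
               paste(g$chrom, "sim", "gene", g$start + 1, g$end, ".",
                     g$strand, ".", attrs, sep = "\t"),
               paste(g$chrom, "sim", "exon", g$start + 1,
                     g$start + g$exonic_length, ".", g$strand, ".", attrs,
                     sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
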