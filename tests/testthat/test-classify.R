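# A hand-built locus: one chromosome, 40-kb bins, a boundary gained in
# condition 2 at bin 26 (separation of a [21,31) TAD), plus peaks and an
# expression table, small enough to reason through by hand.
peak_row <- function(chrom, start, end, name = "p") {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 score = 1, strand = ".")
}

locus <- function() {
  res <- 40000
  anchor <- 25 * res                      # start of boundary bin 26
  tads1 <- fake_tad_set(tibble::tibble(start_bin = c(1L, 21L),
                                       end_bin = c(21L, 31L)), "chrL", res)
  tads2 <- fake_tad_set(tibble::tibble(start_bin = c(1L, 21L, 26L),
                                       end_bin = c(21L, 26L, 31L)), "chrL", res)
  ctcf1 <- peak_row("chrL", c(0, 20 * res), c(400, 20 * res + 400))
  ctcf2 <- dplyr::bind_rows(ctcf1, peak_row("chrL", anchor - 200, anchor + 200))
  gene_tss <- anchor + 8000
  genes <- tibble::tibble(gene_id = "gX", gene_name = "gX", chrom = "chrL",
                          strand = "+", start = gene_tss, end = gene_tss + 5000,
                          tss = gene_tss, exonic_length = 2000)
  prom <- peak_row("chrL", gene_tss - 300, gene_tss + 300, "prom")
  enh <- peak_row("chrL", anchor - 8400, anchor - 7600, "enh")
  atac <- dplyr::bind_rows(prom, enh)
  expr_down <- structure(tibble::tibble(gene_id = "gX", log2_fc = -3,
                                        fdr = 1e-6, deg_flag = "down"),
                         class = c("expression_result", "tbl_df", "tbl",
                                   "data.frame"))
  list(res = res, anchor = anchor, tads1 = tads1, tads2 = tads2,
       ctcf1 = ctcf1, ctcf2 = ctcf2, genes = genes, atac1 = atac,
       atac2 = atac, expr = expr_down)
}

events_of <- function(l, tol_bp = 40000) {
  bdiff <- compare_boundaries(boundaries_of(l$tads1), boundaries_of(l$tads2))
  ctcf_boundary_events(bdiff, l$ctcf1, l$ctcf2, tol_bp = tol_bp)
}

test_that("boundary events require condition-specific CTCF support", {
  l <- locus()
  ev <- events_of(l)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$change, "gained")
  expect_equal(ev$ctcf_change, "gained")
  expect_equal(ev$bin, 26L)

  # CTCF peak present in both conditions: boundary change is discarded
  l2 <- locus()
  l2$ctcf1 <- dplyr::bind_rows(l2$ctcf1,
                               peak_row("chrL", l2$anchor - 190, l2$anchor + 210))
  expect_equal(nrow(events_of(l2)), 0L)

  # no CTCF at all
  l3 <- locus()
  l3$ctcf1 <- l3$ctcf1[0, ]; l3$ctcf2 <- l3$ctcf2[0, ]
  expect_equal(nrow(events_of(l3)), 0L)
})

test_that("candidate genes need DEG status, proximity and accessibility", {
  l <- locus()
  ev <- events_of(l)
  cands <- candidate_genes(ev, l$genes, l$expr, l$atac1, l$atac2)
  expect_equal(cands$gene_id, "gX")

  # not differentially expressed
  e_none <- l$expr; e_none$deg_flag <- "none"
  expect_equal(nrow(candidate_genes(ev, l$genes, e_none, l$atac1, l$atac2)), 0L)

  # promoter accessible in only one condition
  expect_equal(nrow(candidate_genes(ev, l$genes, l$expr,
                                    l$atac1[l$atac1$name != "prom", ],
                                    l$atac2)), 0L)

  # promoter 0.5 Mb from the event still qualifies
  lfar <- locus()
  lfar$genes$tss <- lfar$anchor + 5e5
  lfar$genes$start <- lfar$genes$tss; lfar$genes$end <- lfar$genes$tss + 5000
  prom_far <- peak_row("chrL", lfar$genes$tss - 300, lfar$genes$tss + 300)
  lfar$atac1 <- dplyr::bind_rows(lfar$atac1, prom_far)
  lfar$atac2 <- lfar$atac1
  expect_equal(nrow(candidate_genes(events_of(lfar), lfar$genes, lfar$expr,
                                    lfar$atac1, lfar$atac2)), 1L)
})

test_that("mechanism 1 pairs follow geometry and direction rules", {
  l <- locus()
  ev <- events_of(l)
  cands <- candidate_genes(ev, l$genes, l$expr, l$atac1, l$atac2)
  pairs <- classify_mechanism1(cands, ev, l$atac1, l$atac2, l$res)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$direction, "deactivation")
  expect_equal(pairs$role, "suppressor")
  expect_lt(pairs$distance_bp, 20000)

  # same geometry but an up-regulated gene: direction rule fails
  e_up <- l$expr; e_up$deg_flag <- "up"; e_up$log2_fc <- 3
  cands_up <- candidate_genes(ev, l$genes, e_up, l$atac1, l$atac2)
  expect_equal(nrow(classify_mechanism1(cands_up, ev, l$atac1, l$atac2, l$res)),
               0L)

  # peak too far for mechanism 1
  l25 <- locus()
  l25$atac1$start[l25$atac1$name == "enh"] <- l25$anchor - 25400
  l25$atac1$end[l25$atac1$name == "enh"] <- l25$anchor - 24600
  l25$atac2 <- l25$atac1
  ev25 <- events_of(l25)
  c25 <- candidate_genes(ev25, l25$genes, l25$expr, l25$atac1, l25$atac2)
  expect_equal(nrow(classify_mechanism1(c25, ev25, l25$atac1, l25$atac2,
                                        l25$res)), 0L)

  # promoter-overlapping peaks are not distal enhancers
  lprom <- locus()
  lprom$atac1 <- lprom$atac1[lprom$atac1$name == "prom", ]
  lprom$atac2 <- lprom$atac1
  evp <- events_of(lprom)
  cp <- candidate_genes(evp, lprom$genes, lprom$expr, lprom$atac1, lprom$atac2)
  expect_equal(nrow(classify_mechanism1(cp, evp, lprom$atac1, lprom$atac2,
                                        lprom$res)), 0L)
})

test_that("mechanism 2 requires a TAD co-membership change and its rule table", {
  l <- locus()
  # move the enhancer to 45 kb upstream: mechanism-2 range, other TAD in
  # condition 2 only
  l$atac1$start[l$atac1$name == "enh"] <- l$anchor - 45400
  l$atac1$end[l$atac1$name == "enh"] <- l$anchor - 44600
  l$atac2 <- l$atac1
  ev <- events_of(l)
  e_up <- l$expr; e_up$deg_flag <- "up"; e_up$log2_fc <- 3
  cands <- candidate_genes(ev, l$genes, e_up, l$atac1, l$atac2)

  # default preset: gained boundary + up gene -> activation
  p_def <- classify_mechanism2(cands, ev, l$atac1, l$atac2, l$tads1, l$tads2,
                               l$res)
  expect_equal(nrow(p_def), 1L)
  expect_equal(p_def$direction, "activation")
  expect_equal(p_def$mechanism, 2L)

  # alternate preset rejects that combination and accepts the mirrored one
  expect_equal(nrow(classify_mechanism2(cands, ev, l$atac1, l$atac2,
                                        l$tads1, l$tads2, l$res,
                                        rule = "novel_boundary_insulates")),
               0L)
  cands_down <- candidate_genes(ev, l$genes, l$expr, l$atac1, l$atac2)
  p_alt <- classify_mechanism2(cands_down, ev, l$atac1, l$atac2, l$tads1,
                               l$tads2, l$res,
                               rule = "novel_boundary_insulates")
  expect_equal(p_alt$direction, "deactivation")

  # same TAD in both conditions: no mechanism-2 pair
  p_same <- classify_mechanism2(cands, ev, l$atac1, l$atac2, l$tads1,
                                l$tads1, l$res)
  expect_equal(nrow(p_same), 0L)
})

test_that("classification is invariant to the input ordering of rows", {
  spec <- default_scenario(seed = 2)
  sim <- simulate_scenario(spec)
  t1 <- call_tads(directionality_index(sim$map1))
  t2 <- call_tads(directionality_index(sim$map2))
  expr <- call_degs(sim$counts,
                    sim$genes$exonic_length[match(sim$counts$gene_id,
                                                  sim$genes$gene_id)])
  res <- classify_pairs(t1, t2, sim$ctcf1, sim$ctcf2, sim$atac1, sim$atac2,
                        sim$genes, expr)
  withr::with_seed(3, {
    shuf <- function(df) df[sample(nrow(df)), ]
    res2 <- classify_pairs(t1, t2, shuf(sim$ctcf1), shuf(sim$ctcf2),
                           shuf(sim$atac1), shuf(sim$atac2),
                           shuf(sim$genes), expr)
  })
  expect_equal(res$pairs, res2$pairs)
  expect_equal(res$summary, res2$summary)
  expect_equal(tidy(res), res$pairs)
  expect_equal(glance(res)$n_pairs, nrow(res$pairs))
})
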