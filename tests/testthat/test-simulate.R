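small_spec <- function(seed = 5, events = NULL, pairs = NULL) {
  scenario_spec(chrom_sizes = c(chrS1 = 8e6), depth_per_chrom = 5e4,
                n_null_genes = 6, events = events, pairs = pairs,
                seed = seed)
}

test_that("the simulator is fully determined by spec and seed", {
  s1 <- simulate_contact_map(small_spec()$layout1, c(chrS1 = 8e6), 40000,
                             5e4, 1, 3, seed = 17)
  s2 <- simulate_contact_map(small_spec()$layout1, c(chrS1 = 8e6), 40000,
                             5e4, 1, 3, seed = 17)
  expect_identical(cis_matrix(s1, "chrS1"), cis_matrix(s2, "chrS1"))
  s3 <- simulate_contact_map(small_spec()$layout1, c(chrS1 = 8e6), 40000,
                             5e4, 1, 3, seed = 18)
  expect_false(identical(cis_matrix(s1, "chrS1"), cis_matrix(s3, "chrS1")))

  spec <- default_scenario(seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_scenario_files(simulate_scenario(spec), d1)
  p2 <- write_scenario_files(simulate_scenario(spec), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
})

test_that("without block enrichment no planted boundaries are recoverable", {
  spec <- small_spec()
  flat <- simulate_contact_map(spec$layout1, spec$chrom_sizes, 40000,
                               1e5, 1, block_enrichment = 1, seed = 6)
  tads <- suppressWarnings(call_tads(directionality_index(flat)))
  planted <- setdiff(spec$layout1$chrS1, c(1, max(spec$layout1$chrS1)))
  called <- boundaries_of(tads)$bin
  hits <- mean(vapply(planted, function(b) any(abs(called - b) <= 1), TRUE))
  expect_lt(hits, 0.5)
  # interior DI carries no direction signal
  di <- directionality_index(flat)
  interior <- di$di[60:140]
  enr <- simulate_contact_map(spec$layout1, spec$chrom_sizes, 40000,
                              1e5, 1, block_enrichment = 3, seed = 6)
  di_e <- directionality_index(enr)
  expect_lt(max(abs(interior)), max(abs(di_e$di[60:140])))
})

test_that("planted events reshape the condition-2 layout as declared", {
  spec <- small_spec()
  v <- spec$layout1$chrS1
  sep_bin <- v[4] + 9L   # inside the 18-bin TAD
  ev <- tibble::tibble(chrom = "chrS1",
                       kind = c("separation", "fusion", "shift"),
                       bin = c(sep_bin, v[2], v[6]),
                       shift_by = c(NA_integer_, NA_integer_, 3L))
  spec2 <- small_spec(events = ev)
  cp <- simulate_condition_pair(spec2)
  l2 <- cp$truth$layout2$chrS1
  expect_true(sep_bin %in% l2)
  expect_false(v[2] %in% l2)
  expect_false(v[6] %in% l2)
  expect_true((v[6] + 3L) %in% l2)

  # zero events: boundary sharing is essentially complete
  cp0 <- simulate_condition_pair(small_spec(seed = 12))
  b1 <- boundaries_of(call_tads(directionality_index(cp0$map1)))
  b2 <- boundaries_of(call_tads(directionality_index(cp0$map2)))
  d <- compare_boundaries(b1, b2)
  expect_gte(d$shared_fraction_1, 0.75)

  # a planted separation is recovered as a separation event
  cp1 <- simulate_condition_pair(small_spec(events = ev[1, ], seed = 19))
  t1 <- call_tads(directionality_index(cp1$map1))
  t2 <- call_tads(directionality_index(cp1$map2))
  reorg <- classify_reorganization(t1, t2)
  expect_true(any(reorg$kind == "separation" &
                    abs(reorg$boundary_bin - sep_bin) <= 1))
})

test_that("event validation rejects colliding or out-of-range boundaries", {
  bad <- tibble::tibble(chrom = "chrS1", kind = c("separation", "separation"),
                        bin = c(100L, 103L), shift_by = NA_integer_)
  expect_error(small_spec(events = bad), "overlapping")
  edge <- tibble::tibble(chrom = "chrS1", kind = "separation", bin = 2L,
                         shift_by = NA_integer_)
  expect_error(small_spec(events = edge), "outside")
  nonb <- tibble::tibble(chrom = "chrS1", kind = "fusion", bin = 100L,
                         shift_by = NA_integer_)
  expect_error(simulate_condition_pair(small_spec(events = nonb)),
               "not a boundary")
})

test_that("the regulome couples peaks and counts to the planted truth", {
  spec <- default_scenario(seed = 3)
  sim <- simulate_scenario(spec)
  tp <- sim$truth$truth_pairs

  # CTCF peaks exist exactly at each condition's boundaries
  expect_equal(nrow(sim$ctcf1),
               sum(lengths(sim$truth$boundaries1)))
  expect_equal(nrow(sim$ctcf2),
               sum(lengths(sim$truth$boundaries2)))

  # accessibility decoys lack their enhancer in condition 2 only
  acc <- tp[!is.na(tp$violation) & tp$violation == "accessibility", ]
  for (g in acc$gene_id) {
    expect_true(any(sim$atac1$name == paste0(g, "_enh")))
    expect_false(any(sim$atac2$name == paste0(g, "_enh")))
  }

  # planted deactivation genes drop, activation genes rise, >= 4-fold
  cts <- sim$counts
  for (k in seq_len(nrow(tp))) {
    fc <- (cts$cond2[cts$gene_id == tp$gene_id[k]] + 1) /
      (cts$cond1[cts$gene_id == tp$gene_id[k]] + 1)
    if (tp$deg_direction[k] == "down") expect_lt(fc, 1)
    if (tp$deg_direction[k] == "up") expect_gt(fc, 1)
  }

  # emitted files parse back through the readers without warnings
  d <- withr::local_tempdir()
  paths <- write_scenario_files(sim, d)
  expect_no_warning({
    pk <- read_peaks(paths$ctcf1)
    at <- read_peaks(paths$atac2, format = "narrowPeak")
    gm <- read_gene_models(paths$genes)
    mp <- read_contact_map(paths$matrix1, paths$bins1)
  })
  expect_equal(nrow(gm), nrow(sim$genes))
  expect_equal(total_cis_pairs(mp), total_cis_pairs(sim$map1))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(sort(truth$truth_pairs$gene_id), sort(tp$gene_id))
})
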