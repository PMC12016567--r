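test_that("directionality index follows the signed chi-square form", {
  # two bins contacting only each other: bin 1 sees all mass downstream,
  # bin 2 upstream
  bins <- make_bins(c(chrA = 80000), 40000)
  M <- matrix(c(0, 20, 20, 0), 2, 2)
  di <- directionality_index(new_contact_map(bins, list(chrA = M)),
                             window_bp = 40000)
  # bin 1: A = 0, B = 20 -> E = 10, DI = +((0-10)^2/10 + (20-10)^2/10) = 20
  expect_equal(di$di[1], 20)
  expect_equal(di$di[2], -20)

  # symmetric flanks cancel exactly
  M3 <- matrix(10, 3, 3)
  di3 <- directionality_index(new_contact_map(make_bins(c(chrA = 120000), 40000),
                                              list(chrA = M3)),
                              window_bp = 40000)
  expect_equal(di3$di[2], 0)
  # empty flanks give DI = 0, not NaN
  Mz <- matrix(0, 3, 3)
  diz <- directionality_index(new_contact_map(make_bins(c(chrA = 120000), 40000),
                                              list(chrA = Mz)))
  expect_equal(diz$di, c(0, 0, 0))
})

test_that("DI equals the closed form and flank sums match direct summation", {
  set.seed(21)
  n <- 60
  M <- matrix(rpois(n * n, 4), n, n); M <- M + t(M)
  map <- new_contact_map(make_bins(c(chrA = n * 40000), 40000),
                         list(chrA = M))
  w <- 10
  di <- directionality_index(map, window_bp = w * 40000)
  for (i in sample(n, 15)) {
    A <- sum(M[i, max(i - w, 1):max(i - 1, 1)][seq_len(min(w, i - 1))])
    B <- if (i < n) sum(M[i, (i + 1):min(i + w, n)]) else 0
    expect_equal(di$A[i], A)
    expect_equal(di$B[i], B)
    E <- (A + B) / 2
    want <- if (A + B == 0 || A == B) 0 else
      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    expect_equal(di$di[i], want, tolerance = 1e-12)
  }
})

test_that("reversing bin order negates the DI track", {
  set.seed(22)
  n <- 50
  M <- matrix(rpois(n * n, 3), n, n); M <- M + t(M)
  bins <- make_bins(c(chrA = n * 40000), 40000)
  di_f <- directionality_index(new_contact_map(bins, list(chrA = M)),
                               window_bp = 8 * 40000)
  di_r <- directionality_index(new_contact_map(bins, list(chrA = M[n:1, n:1])),
                               window_bp = 8 * 40000)
  expect_equal(di_r$di, -rev(di_f$di))
})

test_that("the run automaton turns DI sign runs into TADs", {
  di <- fake_di_track(c(5, 5, -5, -5))
  tads <- call_tads(di, t_sd = 0.5, min_size_bins = 3)
  expect_equal(nrow(tads), 1L)
  expect_equal(tads$start_bin, 1L)
  expect_equal(tads$end_bin, 5L)     # covers all four bins, half-open

  expect_warning(t0 <- call_tads(fake_di_track(rep(0, 10))), "all-zero")
  expect_equal(nrow(t0), 0L)

  # two (+run, -run) blocks give two adjacent TADs sharing the junction
  di2 <- fake_di_track(c(5, 5, -5, -5, 5, 5, -5, -5))
  t2 <- call_tads(di2, min_size_bins = 3)
  expect_equal(nrow(t2), 2L)
  expect_equal(t2$end_bin[1], t2$start_bin[2])
  b <- boundaries_of(t2)
  expect_equal(nrow(b), 3L)          # junction deduplicated

  # neutral gap between runs is spanned by the TAD
  di3 <- fake_di_track(c(5, 0, 0, -5, -5))
  t3 <- call_tads(di3)
  expect_equal(t3$start_bin, 1L)
  expect_equal(t3$end_bin, 6L)
})

test_that("TAD calls are invariant to scaling counts by a positive constant", {
  spec <- scenario_spec(chrom_sizes = c(chrS1 = 6e6), seed = 13)
  m <- simulate_contact_map(spec$layout1, spec$chrom_sizes, spec$resolution,
                            4e4, 1, 3, seed = 13)
  m3 <- m
  m3$cis <- lapply(m$cis, function(x) x * 3)
  t1 <- call_tads(directionality_index(m))
  t2 <- call_tads(directionality_index(m3))
  expect_equal(t1$start_bin, t2$start_bin)
  expect_equal(t1$end_bin, t2$end_bin)
})

test_that("boundaries use the TAD start bin and last inside bin", {
  tads <- fake_tad_set(tibble::tibble(start_bin = 10L, end_bin = 20L))
  b <- boundaries_of(tads)
  expect_equal(b$bin, c(10L, 19L))
  expect_equal(b$provenance, c("tad_start", "tad_end"))

  adj <- fake_tad_set(tibble::tibble(start_bin = c(10L, 20L),
                                     end_bin = c(20L, 30L)))
  expect_equal(boundaries_of(adj)$bin, c(10L, 20L, 29L))

  empty <- fake_tad_set(tibble::tibble(start_bin = integer(),
                                       end_bin = integer()))
  expect_equal(nrow(boundaries_of(empty)), 0L)
})

test_that("region stats separate TAD inner from border bins", {
  tads <- fake_tad_set(tibble::tibble(start_bin = 1L, end_bin = 26L),
                       resolution = 40000)
  genes <- tibble::tibble(gene_id = "g1", gene_name = "g1", chrom = "chrT",
                          strand = "+", start = 480000, end = 500000,
                          tss = 480000, exonic_length = 1000)
  st <- region_class_stats(tads, genes)
  inner <- st[st$region_class == "inner", ]
  # 25 TAD bins, borders at bins 1 and 25 +/- 1 -> inner = bins 3..23 (21 bins)
  expect_equal(inner$length_mb, 21 * 0.04)
  expect_equal(inner$n_tss, 1L)   # TSS at 480 kb = bin 13
  expect_equal(inner$gene_density_per_mb, 1 / (21 * 0.04))
  expect_true(is.na(inner$gc_fraction))

  st0 <- region_class_stats(tads, genes[0, ])
  expect_true(all(st0$gene_density_per_mb == 0))

  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(chrT = strrep("GC", 520000)), fa)
  stg <- region_class_stats(tads, genes, genome = fa)
  expect_equal(stg$gc_fraction, c(1, 1))
})
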