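#' Directionality index of a contact map
#'
#' For each bin the upstream contact sum `A` (bins `[i - w, i)`), the
#' downstream sum `B` (bins `(i, i + w]`) and `E = (A + B) / 2` are computed
#' within a fixed flank of `window_bp`, truncated at chromosome edges. The
#' directionality index is the signed chi-square-like statistic
#' `sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`, 0 where `A + B = 0`.
#'
#' @param map A `contact_map` (typically 40-kb bins).
#' @param window_bp Flank width in bp (default 2 Mb).
#' @return A `di_track` tibble with `bin`, `chrom`, `start`, `end`, `A`,
#'   `B`, `E`, `di`.
#' @export
directionality_index <- function(map, window_bp = 2e6) {
  if (window_bp < map$resolution) abort("window_bp must be >= the bin width")
  w <- floor(window_bp / map$resolution)
  bins <- map$bins
  tracks <- imap(map$cis, function(m, chrom) {
    M <- as.matrix(m)
    n <- nrow(M)
    A <- numeric(n); B <- numeric(n)
    # cumulative sums along each row give O(1) flank sums
    CS <- cbind(0, t(apply(M, 1, cumsum)))
    for (i in seq_len(n)) {
      lo <- max(i - w, 1L); hi <- min(i + w, n)
      A[i] <- CS[i, i] - CS[i, lo]            # columns [lo, i-1]
      B[i] <- CS[i, hi + 1] - CS[i, i + 1]    # columns [i+1, hi]
    }
    E <- (A + B) / 2
    di <- ifelse(A + B == 0 | A == B, 0,
                 sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
    sel <- bins[bins$chrom == chrom, ]
    tibble(bin = sel$bin, chrom = chrom, start = sel$start, end = sel$end,
           A = A, B = B, E = E, di = di)
  })
  out <- list_rbind(tracks)
  structure(out, resolution = map$resolution,
            class = c("di_track", class(out)))
}

#' Call TADs from a directionality-index track
#'
#' Bins are labeled downstream-biased (`di >= t`), upstream-biased
#' (`di <= -t`) or neutral, with `t = t_sd * SD` of the nonzero DI values on
#' that chromosome. A TAD spans from the first bin of a downstream-biased
#' run to the last bin of the next upstream-biased run; shorter TADs than
#' `min_size_bins` are discarded. This deterministic run automaton stands in
#' for the original HMM-based segmentation: it is parameter-light and its
#' output is directly checkable against planted truth.
#'
#' @param di A `di_track` from [directionality_index()].
#' @param t_sd Threshold multiplier on the per-chromosome SD of nonzero DI.
#' @param min_size_bins Minimum TAD size in bins.
#' @return A `tad_set` tibble with `tad_id`, `chrom`, `start_bin`,
#'   `end_bin` (half-open, local 1-based bin units within the chromosome),
#'   `start`, `end` (bp) and `span_bp`. TADs are disjoint and sorted.
#' @export
call_tads <- function(di, t_sd = 0.5, min_size_bins = 3) {
  res <- attr(di, "resolution")
  tads <- di |>
    group_by(.data$chrom) |>
    group_map(function(g, key) {
      x <- g$di
      nz <- x[x != 0]
      if (length(nz) == 0L) {
        warn(sprintf("all-zero DI on %s: no TADs called", key$chrom))
        return(NULL)
      }
      t <- t_sd * sd(nz)
      if (is.na(t) || t == 0) t <- t_sd * abs(nz[1])   # degenerate: <2 distinct values
      state <- ifelse(x >= t, 1L, ifelse(x <= -t, -1L, 0L))
      spans <- run_automaton(state)
      if (nrow(spans) == 0L) return(NULL)
      spans$chrom <- key$chrom
      spans$start <- g$start[spans$start_bin]
      spans$end <- g$end[spans$end_bin]
      spans$end_bin <- spans$end_bin + 1L   # half-open in bin units
      spans
    }) |> list_rbind()
  if (is.null(tads) || nrow(tads) == 0L) {
    tads <- tibble(chrom = character(), start_bin = integer(),
                   end_bin = integer(), start = double(), end = double())
  }
  tads <- tads |>
    filter(.data$end_bin - .data$start_bin >= min_size_bins) |>
    mutate(span_bp = .data$end - .data$start) |>
    arrange(.data$chrom, .data$start_bin) |>
    mutate(tad_id = sprintf("%s_tad%03d", .data$chrom,
                            stats::ave(rep(1, dplyr::n()), .data$chrom,
                                       FUN = cumsum)), .before = 1)
  structure(tads, resolution = res, class = c("tad_set", class(tads)))
}

# Runs of +1 / -1 states: a TAD opens at the first bin of a +1 run and
# closes at the last bin of the next -1 run. Returns closed bin spans
# (1-based, inclusive).
run_automaton <- function(state) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  open_start <- NA_integer_
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1L && is.na(open_start)) {
      open_start <- starts[k]
    } else if (r$values[k] == -1L && !is.na(open_start)) {
      out[[length(out) + 1L]] <- c(open_start, ends[k])
      open_start <- NA_integer_
    }
  }
  if (length(out) == 0L) {
    return(tibble(start_bin = integer(), end_bin = integer()))
  }
  m <- do.call(rbind, out)
  tibble(start_bin = m[, 1], end_bin = m[, 2])
}

#' Boundary bins of a TAD set
#'
#' Each TAD contributes its start bin and its last inside bin
#' (`end_bin - 1`); where two TADs are adjacent the junction yields a single
#' boundary (the start bin of the downstream TAD).
#'
#' @param tads A `tad_set`.
#' @return A `boundary_set` tibble with `chrom`, `bin` (local 1-based),
#'   `start`, `end` (bp of the boundary bin) and `provenance`
#'   (`tad_start`/`tad_end`), deduplicated and sorted.
#' @export
boundaries_of <- function(tads) {
  res <- attr(tads, "resolution")
  if (nrow(tads) == 0L) {
    out <- tibble(chrom = character(), bin = integer(), start = double(),
                  end = double(), provenance = character())
    return(structure(out, resolution = res,
                     class = c("boundary_set", class(out))))
  }
  starts <- tibble(chrom = tads$chrom, bin = tads$start_bin,
                   provenance = "tad_start")
  # skip the end boundary when another TAD starts exactly at end_bin
  junction <- paste(tads$chrom, tads$end_bin) %in%
    paste(tads$chrom, tads$start_bin)
  ends <- tibble(chrom = tads$chrom[!junction],
                 bin = tads$end_bin[!junction] - 1L,
                 provenance = "tad_end")
  out <- bind_rows(starts, ends) |>
    mutate(start = (.data$bin - 1) * res, end = .data$start + res) |>
    distinct(.data$chrom, .data$bin, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$bin) |>
    select("chrom", "bin", "start", "end", "provenance")
  structure(out, resolution = res, class = c("boundary_set", class(out)))
}
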