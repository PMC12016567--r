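#' Call significant cis interactions
#'
#' Bin pairs at distances of at least `min_dist_bins` are partitioned into
#' up to `n_distance_strata` equal-occupancy distance strata (contiguous
#' distance ranges carrying roughly equal total counts). The expected
#' contact probability of a stratum is its count sum divided by (possible
#' pair count x total cis reads); the per-pair p-value is the upper-tail
#' binomial probability of the observed count given that expectation, and
#' q-values are Benjamini-Hochberg over all tested pairs (pairs with at
#' least one read). Pairs are retained iff `read_count >= min_count`
#' (i.e. read count above 2 with the defaults), `p <= p_max` and
#' `q <= q_max`, and returned sorted by read count, descending.
#'
#' @param map A `contact_map` (typically 10-kb bins).
#' @param n_distance_strata Number of equal-occupancy distance strata.
#' @param min_count Minimum read count (default 3).
#' @param p_max,q_max Significance thresholds (applied jointly).
#' @param min_dist_bins Minimum pair distance in bins (excludes adjacent-bin
#'   self-ligation artifacts).
#' @return An `interaction_calls` tibble: `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`, `binA`, `binB` (global bin ids),
#'   `distance_bp`, `read_count`, `p_value`, `q_value`, `kind`.
#' @export
call_cis_significant <- function(map, n_distance_strata = 100, min_count = 3,
                                 p_max = 0.01, q_max = 0.01,
                                 min_dist_bins = 2) {
  res <- map$resolution
  n_cis <- total_cis_pairs(map)
  empty <- interaction_tibble()
  if (n_cis == 0) return(empty)

  # per-distance totals (counts and possible pairs), pooled over chromosomes
  per_chrom <- imap(map$cis, function(m, chrom) {
    M <- as.matrix(m)
    n <- nrow(M)
    if (n <= min_dist_bins) return(NULL)
    idx <- which(upper.tri(M), arr.ind = TRUE)
    d <- idx[, 2] - idx[, 1]
    keep <- d >= min_dist_bins
    tibble(chrom = chrom, i = idx[keep, 1], j = idx[keep, 2],
           d = d[keep], count = M[idx[keep, , drop = FALSE]])
  })
  pairs <- list_rbind(keep(per_chrom, Negate(is.null)))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)

  strata <- distance_strata(pairs, n_distance_strata)
  pairs$stratum <- strata$stratum_of[as.character(pairs$d)]
  pairs <- left_join(pairs, strata$table, by = "stratum")
  pairs$p_exp <- pairs$stratum_count / (pairs$stratum_pairs * n_cis)

  tested <- pairs[pairs$count >= 1, ]
  if (nrow(tested) == 0L) return(empty)
  tested$p_value <- pbinom(tested$count - 1, size = round(n_cis),
                           prob = tested$p_exp, lower.tail = FALSE)
  tested$q_value <- p.adjust(tested$p_value, method = "BH")
  calls <- tested[tested$count >= min_count & tested$p_value <= p_max &
                    tested$q_value <= q_max, ]
  finish_calls(calls, map, kind = "cis")
}

# Equal-occupancy contiguous distance strata. Returns the stratum id per
# distance and a per-stratum table of count sums and possible-pair counts.
distance_strata <- function(pairs, n_strata) {
  by_d <- pairs |>
    group_by(.data$d) |>
    summarise(count = sum(.data$count), n_pairs = dplyr::n(), .groups = "drop") |>
    arrange(.data$d)
  total <- sum(by_d$count)
  if (total == 0) {
    stratum <- rep(1L, nrow(by_d))
  } else {
    target <- total / min(n_strata, nrow(by_d))
    cum <- cumsum(by_d$count)
    stratum <- pmin(floor((cum - 1e-9) / target) + 1L, n_strata)
    stratum <- cummax(stratum)
  }
  by_d$stratum <- stratum
  table <- by_d |>
    group_by(.data$stratum) |>
    summarise(stratum_count = sum(.data$count),
              stratum_pairs = sum(.data$n_pairs), .groups = "drop")
  list(stratum_of = setNames(stratum, by_d$d), table = table)
}

#' Call significant trans interactions
#'
#' All possible inter-chromosomal bin pairs share a single uniform expected
#' contact probability `1 / n_possible_trans_pairs`; p-values are upper-tail
#' binomial given the total trans read count, with Benjamini-Hochberg
#' q-values over tested (nonzero) pairs and the same retention filters as
#' [call_cis_significant()].
#'
#' @inheritParams call_cis_significant
#' @return An `interaction_calls` tibble (see [call_cis_significant()]).
#' @export
call_trans_significant <- function(map, min_count = 3, p_max = 0.01,
                                   q_max = 0.01) {
  empty <- interaction_tibble()
  if (nrow(map$trans) == 0L) return(empty)
  n_trans <- total_trans_pairs(map)
  nb <- chrom_nbins(map$bins)
  total_bins <- sum(nb)
  n_possible <- (total_bins^2 - sum(nb^2)) / 2
  p_t <- 1 / n_possible
  tested <- map$trans[map$trans$count >= 1, ]
  tested$p_value <- pbinom(tested$count - 1, size = round(n_trans),
                           prob = p_t, lower.tail = FALSE)
  tested$q_value <- p.adjust(tested$p_value, method = "BH")
  calls <- tested[tested$count >= min_count & tested$p_value <= p_max &
                    tested$q_value <= q_max, ]
  if (nrow(calls) == 0L) return(empty)
  calls <- rename(calls, chrom = "chrom1", i = "bin1", j = "bin2")
  calls$chromB <- calls$chrom2
  finish_calls(calls, map, kind = "trans")
}

interaction_tibble <- function() {
  tibble(chromA = character(), startA = double(), endA = double(),
         chromB = character(), startB = double(), endB = double(),
         binA = integer(), binB = integer(), distance_bp = double(),
         read_count = double(), p_value = double(), q_value = double(),
         kind = character())
}

finish_calls <- function(calls, map, kind) {
  if (nrow(calls) == 0L) return(interaction_tibble())
  bins <- map$bins
  first_bin <- tapply(bins$bin, bins$chrom, min)
  chromA <- calls$chrom
  chromB <- if (kind == "cis") calls$chrom else calls$chromB
  ga <- calls$i + first_bin[chromA] - 1L
  gb <- calls$j + first_bin[chromB] - 1L
  out <- tibble(
    chromA = chromA,
    startA = bins$start[ga], endA = bins$end[ga],
    chromB = chromB,
    startB = bins$start[gb], endB = bins$end[gb],
    binA = as.integer(ga), binB = as.integer(gb),
    distance_bp = if (kind == "cis") (calls$j - calls$i) * map$resolution
      else NA_real_,
    read_count = calls$count,
    p_value = calls$p_value, q_value = calls$q_value,
    kind = kind)
  arrange(out, desc(.data$read_count), .data$binA, .data$binB)
}

#' Count interaction calls shared between two call sets
#'
#' Pair identity is an exact (binA, binB) match after canonical ordering.
#'
#' @param calls1,calls2 `interaction_calls` tibbles at the same resolution.
#' @return Tibble with `shared_cis` and `shared_trans` counts.
#' @export
shared_interactions <- function(calls1, calls2) {
  key <- function(x) {
    a <- pmin(x$binA, x$binB); b <- pmax(x$binA, x$binB)
    paste(x$kind, x$chromA, x$chromB, a, b)
  }
  w1 <- max(calls1$endA - calls1$startA, 0)
  w2 <- max(calls2$endA - calls2$startA, 0)
  if (nrow(calls1) > 0 && nrow(calls2) > 0 && w1 != w2) {
    abort("interaction call sets are at different resolutions")
  }
  shared <- intersect(key(calls1), key(calls2))
  tibble(shared_cis = sum(startsWith(shared, "cis")),
         shared_trans = sum(startsWith(shared, "trans")))
}
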