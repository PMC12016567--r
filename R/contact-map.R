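#' Contact map container
#'
#' A `contact_map` holds binned Hi-C counts: one symmetric cis count matrix
#' per chromosome (sparse storage, local bin indices) and a tibble of
#' inter-chromosomal pair counts. Counts are raw; matrix balancing, if any,
#' is assumed to have happened upstream.
#'
#' @param bins A [make_bins()] bin table.
#' @param cis Named list (by chromosome) of symmetric count matrices.
#' @param trans Tibble with `chrom1`, `chrom2`, `bin1`, `bin2`, `count`
#'   (local, 1-based bin indices within each chromosome).
#' @return An object of class `contact_map`.
#' @export
new_contact_map <- function(bins, cis, trans = NULL) {
  nb <- chrom_nbins(bins)
  stopifnot(all(names(cis) %in% names(nb)))
  for (chrom in names(cis)) {
    m <- cis[[chrom]]
    stopifnot(nrow(m) == nb[[chrom]], ncol(m) == nb[[chrom]])
  }
  if (is.null(trans)) {
    trans <- tibble(chrom1 = character(), chrom2 = character(),
                    bin1 = integer(), bin2 = integer(), count = double())
  }
  structure(list(bins = bins, resolution = bin_resolution(bins),
                 chrom_sizes = attr(bins, "chrom_sizes"),
                 cis = cis, trans = trans),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact_map: %d chromosome(s), resolution %s bp, %s cis / %s trans pairs\n",
    length(x$cis), format(x$resolution, big.mark = ","),
    format(total_cis_pairs(x), big.mark = ","),
    format(total_trans_pairs(x), big.mark = ",")))
  invisible(x)
}

#' Total cis and trans counts of a contact map
#'
#' @param map A `contact_map`.
#' @return Sum of stored cis (respectively trans) counts.
#' @export
total_cis_pairs <- function(map) {
  sum(map_dbl(map$cis, function(m) {
    m <- as.matrix(m)
    (sum(m) + sum(diag(m))) / 2   # unique pairs: upper triangle + diagonal
  }))
}

#' @rdname total_cis_pairs
#' @export
total_trans_pairs <- function(map) sum(map$trans$count)

#' Dense cis matrix for one chromosome
#'
#' @param map A `contact_map`.
#' @param chrom Chromosome name.
#' @return Base dense symmetric matrix of counts.
#' @export
cis_matrix <- function(map, chrom) {
  if (!chrom %in% names(map$cis)) abort(sprintf("no cis matrix for %s", chrom))
  as.matrix(map$cis[[chrom]])
}

# Build a symmetric sparse matrix from (i, j, x) triplets (any orientation;
# duplicates summed).
sym_sparse <- function(i, j, x, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  up <- Matrix::sparseMatrix(i = lo, j = hi, x = x, dims = c(n, n))
  up + Matrix::t(up) - Matrix::Diagonal(n, Matrix::diag(up))
}

#' Read a binned contact map from HiC-Pro style triplet files
#'
#' The matrix file has lines `binA binB count` with 1-based bin ids; the
#' accompanying bins file is a BED with the bin id in column 4. Supply
#' either `bins_path` or `chrom_sizes` + `resolution`.
#'
#' @param matrix_path Triplet matrix file.
#' @param bins_path BED file of bins (chrom, start, end, id).
#' @param chrom_sizes Named vector of chromosome sizes (alternative to
#'   `bins_path`).
#' @param resolution Bin width in bp (required with `chrom_sizes`).
#' @return A [new_contact_map()] object. Intra-chromosomal entries go to the
#'   symmetric cis store (diagonal kept); inter-chromosomal entries to the
#'   trans store.
#' @export
read_contact_map <- function(matrix_path, bins_path = NULL,
                             chrom_sizes = NULL, resolution = NULL) {
  stopifnot(file.exists(matrix_path))
  if (!is.null(bins_path)) {
    bed <- readr::read_tsv(bins_path, col_names = c("chrom", "start", "end", "id"),
                           col_types = "cddd", progress = FALSE)
    bed <- arrange(bed, .data$id)
    resolution <- max(bed$end - bed$start)
    sizes <- bed |> group_by(.data$chrom) |>
      summarise(size = max(.data$end), .groups = "drop")
    chrom_sizes <- setNames(sizes$size, sizes$chrom)
    # preserve the file's chromosome order
    chrom_sizes <- chrom_sizes[unique(bed$chrom)]
  }
  if (is.null(chrom_sizes) || is.null(resolution)) {
    abort("supply bins_path, or chrom_sizes together with resolution")
  }
  bins <- make_bins(chrom_sizes, resolution)

  trip <- readr::read_tsv(matrix_path, col_names = c("i", "j", "count"),
                          col_types = "ddd", progress = FALSE)
  n <- nrow(bins)
  if (nrow(trip) > 0) {
    if (any(trip$i < 1 | trip$i > n | trip$j < 1 | trip$j > n)) {
      abort("bin id out of range for the bin table")
    }
    if (any(trip$count != round(trip$count)) || any(trip$count < 0)) {
      abort("counts must be non-negative integers")
    }
  }
  chrom_of <- bins$chrom
  first_bin <- tapply(bins$bin, bins$chrom, min)[unique(bins$chrom)]
  ci <- chrom_of[trip$i]; cj <- chrom_of[trip$j]
  nb <- chrom_nbins(bins)

  cis <- lapply(names(nb), function(chrom) {
    sel <- which(ci == chrom & cj == chrom)
    off <- first_bin[[chrom]] - 1L
    if (length(sel) == 0L) {
      Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                           dims = c(nb[[chrom]], nb[[chrom]]))
    } else {
      sym_sparse(trip$i[sel] - off, trip$j[sel] - off, trip$count[sel],
                 nb[[chrom]])
    }
  })
  names(cis) <- names(nb)

  sel <- which(ci != cj)
  trans <- if (length(sel) == 0L) NULL else {
    swap <- match(ci[sel], names(nb)) > match(cj[sel], names(nb))
    a <- ifelse(swap, trip$j[sel], trip$i[sel])
    b <- ifelse(swap, trip$i[sel], trip$j[sel])
    tibble(chrom1 = chrom_of[a], chrom2 = chrom_of[b],
           bin1 = as.integer(a - (first_bin[chrom_of[a]] - 1L)),
           bin2 = as.integer(b - (first_bin[chrom_of[b]] - 1L)),
           count = trip$count[sel]) |>
      group_by(.data$chrom1, .data$chrom2, .data$bin1, .data$bin2) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  new_contact_map(bins, cis, trans)
}

#' Write a contact map as HiC-Pro style triplet + bins files
#'
#' @param map A `contact_map`.
#' @param matrix_path,bins_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_contact_map <- function(map, matrix_path, bins_path) {
  bins <- map$bins
  readr::write_tsv(
    data.frame(chrom = bins$chrom,
               start = format(bins$start, scientific = FALSE, trim = TRUE),
               end = format(bins$end, scientific = FALSE, trim = TRUE),
               id = bins$bin),
    bins_path, col_names = FALSE)
  first_bin <- tapply(bins$bin, bins$chrom, min)
  rows <- list()
  for (chrom in names(map$cis)) {
    m <- as.matrix(map$cis[[chrom]])
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      off <- first_bin[[chrom]] - 1L
      rows[[length(rows) + 1L]] <-
        data.frame(i = idx[, 1] + off, j = idx[, 2] + off,
                   count = m[idx])
    }
  }
  if (nrow(map$trans) > 0) {
    off1 <- first_bin[map$trans$chrom1] - 1L
    off2 <- first_bin[map$trans$chrom2] - 1L
    rows[[length(rows) + 1L]] <-
      data.frame(i = map$trans$bin1 + off1, j = map$trans$bin2 + off2,
                 count = map$trans$count)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), count = double())
  out <- out[order(out$i, out$j), , drop = FALSE]
  readr::write_tsv(out, matrix_path, col_names = FALSE)
  invisible(matrix_path)
}

# Mean over the (2h+1)^2 window truncated at the edges, via summed-area table.
box_mean <- function(M, h) {
  n <- nrow(M); m <- ncol(M)
  S <- matrix(0, n + 1, m + 1)
  S[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(n) - h, 1); r2 <- pmin(seq_len(n) + h, n)
  c1 <- pmax(seq_len(m) - h, 1); c2 <- pmin(seq_len(m) + h, m)
  W <- S[cbind(rep(r2 + 1, m), rep(c2 + 1, each = n))] -
    S[cbind(rep(r1, m), rep(c2 + 1, each = n))] -
    S[cbind(rep(r2 + 1, m), rep(c1, each = n))] +
    S[cbind(rep(r1, m), rep(c1, each = n))]
  matrix(W, n, m) / outer(r2 - r1 + 1, c2 - c1 + 1)
}

#' Smooth the cis matrices of a contact map
#'
#' Each entry is replaced by the mean of the `(2h+1) x (2h+1)` window around
#' it, truncated at the matrix edges (mean over available cells). `h = 0` is
#' the identity.
#'
#' @param map A `contact_map`.
#' @param h Window half-span in bins.
#' @return A `contact_map` with smoothed cis matrices (trans unchanged).
#' @export
smooth_map <- function(map, h = 1) {
  stopifnot(is.numeric(h), length(h) == 1L, h >= 0)
  if (h == 0) return(map)
  map$cis <- lapply(map$cis, function(m) box_mean(as.matrix(m), h))
  map
}

# Mean count at each diagonal offset of a symmetric matrix (offset 0 first).
diagonal_means <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(numeric())
  d <- abs(row(M) - col(M))
  as.numeric(tapply(M, d, mean))
}

#' Distance-decay profile of a contact map
#'
#' @param map A `contact_map`.
#' @return Tibble with `chrom`, `distance` (bins, offset 0 included) and
#'   `mean_count`, the mean count over all bin pairs at that offset.
#' @export
distance_decay <- function(map) {
  imap(map$cis, function(m, chrom) {
    dm <- diagonal_means(as.matrix(m))
    tibble(chrom = chrom, distance = seq_along(dm) - 1, mean_count = dm)
  }) |> list_rbind()
}

#' Observed/expected transform of cis matrices
#'
#' Divides each entry by the mean count at its diagonal offset on that
#' chromosome; offsets with zero mean yield 0.
#'
#' @param map A `contact_map`.
#' @return Named list (by chromosome) of dense O/E matrices.
#' @export
observed_expected <- function(map) {
  lapply(map$cis, function(m) {
    M <- as.matrix(m)
    n <- nrow(M)
    if (n == 0L) return(M)
    dm <- diagonal_means(M)
    E <- matrix(dm[abs(row(M) - col(M)) + 1], n, n)
    out <- ifelse(E > 0, M / E, 0)
    matrix(out, n, n)
  })
}
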