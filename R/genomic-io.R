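#' Read a BED or narrowPeak file into a peak tibble
#'
#' All coordinates in the package are 0-based, half-open (BED convention).
#' Chromosome names are taken verbatim; set `harmonize_chr = TRUE` to add a
#' "chr" prefix to names that lack one (inputs from different portals mix
#' conventions).
#'
#' @param path Path to a tab-separated BED3/BED6 or ENCODE narrowPeak file.
#' @param format One of `"auto"`, `"bed"`, `"narrowPeak"`. `"auto"` treats
#'   10-column files as narrowPeak and anything else as BED.
#' @param condition,assay Optional labels stored as columns (e.g. condition
#'   name and `"CTCF"`/`"ATAC"`).
#' @param harmonize_chr Add a `"chr"` prefix where missing.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (plus `condition`/`assay` when given), sorted by
#'   (`chrom`, `start`). For narrowPeak input `score` holds the signalValue
#'   column; the summit offset is ignored (peaks are treated as intervals).
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak"),
                       condition = NULL, assay = NULL, harmonize_chr = FALSE) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    out <- tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character())
    return(finish_peaks(out, condition, assay, harmonize_chr))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                  bad[1]))
  }
  if (format == "auto") {
    format <- if (all(ncol == 10L)) "narrowPeak" else "bed"
  }
  col <- function(k, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else default, "")
  }
  start <- suppressWarnings(as.numeric(col(2L)))
  end <- suppressWarnings(as.numeric(col(3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d: invalid start/end", bad[1]))
  }
  score <- if (format == "narrowPeak") {
    suppressWarnings(as.numeric(col(7L)))   # signalValue
  } else {
    suppressWarnings(as.numeric(col(5L)))
  }
  out <- tibble(
    chrom = col(1L), start = start, end = end,
    name = col(4L),
    score = score,
    strand = ifelse(col(6L) %in% c("+", "-"), col(6L), ".")
  )
  finish_peaks(out, condition, assay, harmonize_chr)
}

finish_peaks <- function(peaks, condition, assay, harmonize_chr) {
  if (harmonize_chr) {
    peaks$chrom <- ifelse(startsWith(peaks$chrom, "chr"),
                          peaks$chrom, paste0("chr", peaks$chrom))
  }
  if (!is.null(condition)) peaks$condition <- condition
  if (!is.null(assay)) peaks$assay <- assay
  arrange(peaks, .data$chrom, .data$start)
}

#' Write intervals as a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  df <- data.frame(
    chrom = intervals$chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(intervals)) replace_na_chr(intervals$name) else rep(".", n),
    score = if ("score" %in% names(intervals)) ifelse(is.na(intervals$score), 0, intervals$score) else rep(0, n),
    strand = if ("strand" %in% names(intervals)) replace_na_chr(intervals$strand) else rep(".", n)
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

replace_na_chr <- function(x, fill = ".") ifelse(is.na(x), fill, x)

#' Read gene models from a GTF file
#'
#' Parses `gene` and `exon` features. GTF 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention (start shifted by
#' -1, end preserved). The exonic length is the length of the union of a
#' gene's exons; genes with no exon rows fall back to the span length with a
#' warning.
#'
#' @param path Path to a GTF file with `gene_id` attributes.
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `exonic_length`. The TSS is the span
#'   start for `+` genes and `end - 1` for `-` genes (0-based).
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (!"gene_id" %in% names(meta)) abort("GTF lacks gene_id attributes")
  if (!"type" %in% names(meta)) abort("GTF lacks feature types")

  genes <- meta[meta$type == "gene", , drop = FALSE]
  exons <- meta[meta$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0L) {
    # Some annotations carry only exon rows; synthesize gene spans.
    if (nrow(exons) == 0L) abort("GTF contains neither gene nor exon features")
    genes <- exons |>
      group_by(.data$gene_id) |>
      summarise(seqnames = first(.data$seqnames), start = min(.data$start),
                end = max(.data$end), strand = first(.data$strand),
                gene_name = if ("gene_name" %in% names(exons)) first(.data$gene_name) else first(.data$gene_id),
                .groups = "drop")
    genes$type <- "gene"
  }
  exon_len <- c()
  if (nrow(exons) > 0L) {
    egr <- GenomicRanges::GRanges(exons$seqnames,
                                  IRanges::IRanges(exons$start, exons$end))
    red <- GenomicRanges::reduce(GenomicRanges::split(egr, exons$gene_id))
    exon_len <- vapply(red, function(g) sum(IRanges::width(g)), 0)
  }

  gene_name <- if ("gene_name" %in% names(genes)) {
    ifelse(is.na(genes$gene_name), genes$gene_id, genes$gene_name)
  } else {
    genes$gene_id
  }
  start0 <- genes$start - 1L   # GTF -> 0-based half-open
  end0 <- genes$end
  strand <- as.character(genes$strand)
  no_exon <- !(genes$gene_id %in% names(exon_len))
  if (any(no_exon)) {
    warn(sprintf("%d gene(s) without exon features; exonic length falls back to span length",
                 sum(no_exon)))
  }
  exonic_length <- ifelse(no_exon, end0 - start0,
                          unname(exon_len[genes$gene_id]))
  tibble(
    gene_id = genes$gene_id,
    gene_name = gene_name,
    chrom = as.character(genes$seqnames),
    strand = strand,
    start = as.numeric(start0),
    end = as.numeric(end0),
    tss = ifelse(strand == "-", as.numeric(end0) - 1, as.numeric(start0)),
    exonic_length = as.numeric(exonic_length)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param resolution Bin width in bp.
#' @return A `bin_table`: a tibble with columns `bin` (1-based global index,
#'   ordered by chromosome then start), `chrom`, `start`, `end`, carrying
#'   `resolution` and `chrom_sizes` attributes. The last bin of each
#'   chromosome may be short.
#' @export
make_bins <- function(chrom_sizes, resolution) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) > 0)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("chrom_sizes must be a named vector")
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    abort("resolution must be a positive number")
  }
  if (any(chrom_sizes <= 0)) abort("zero-length chromosome in chrom_sizes")
  bins <- imap(as.list(chrom_sizes), function(size, chrom) {
    n <- ceiling(size / resolution)
    start <- (seq_len(n) - 1) * resolution
    tibble(chrom = chrom, start = start,
           end = pmin(start + resolution, size))
  }) |> list_rbind()
  bins <- mutate(bins, bin = dplyr::row_number(), .before = 1)
  structure(bins, resolution = resolution,
            chrom_sizes = chrom_sizes,
            class = c("bin_table", class(bins)))
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins, %d chromosome(s), resolution %s bp\n",
              nrow(x), length(attr(x, "chrom_sizes")),
              format(attr(x, "resolution"), big.mark = ",")))
  NextMethod()
}

bin_resolution <- function(bins) attr(bins, "resolution")

# Map base positions to global bin indices on one chromosome.
bin_index_at <- function(bins, chrom, pos) {
  res <- bin_resolution(bins)
  offset <- match(chrom, bins$chrom)
  if (any(is.na(offset))) abort("position on a chromosome absent from the bin table")
  offset + pmin(floor(pos / res), chrom_nbins(bins)[chrom] - 1)
}

chrom_nbins <- function(bins) {
  tab <- table(bins$chrom)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out[unique(bins$chrom)]
}

#' Report overlapping interval pairs with a symmetric tolerance
#'
#' Pair `(i, j)` is reported iff interval `i` of `a`, expanded by `tolerance`
#' bp on each side, intersects interval `j` of `b`. Both inputs use 0-based
#' half-open coordinates.
#'
#' @param a,b Tibbles with `chrom`, `start`, `end`.
#' @param tolerance Non-negative expansion in bp applied to `a`.
#' @return Tibble with columns `idx_a`, `idx_b` (row indices into `a`, `b`).
#' @export
interval_overlap <- function(a, b, tolerance = 0) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    abort("tolerance must be a non-negative number")
  }
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(idx_a = integer(), idx_b = integer()))
  }
  gra <- GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(pmax(a$start - tolerance, 0) + 1,
                              a$end + tolerance))
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  tibble(idx_a = S4Vectors::queryHits(hits),
         idx_b = S4Vectors::subjectHits(hits)) |>
    arrange(.data$idx_a, .data$idx_b)
}

#' GC fraction of intervals from a genome FASTA
#'
#' Computes (G + C) / (A + C + G + T) per interval; N bases are excluded
#' from the denominator and an all-N interval yields `NA`.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions, one per interval.
#' @export
gc_content <- function(intervals, genome) {
  seqs <- if (is(genome, "DNAStringSet")) genome else {
    stopifnot(file.exists(genome))
    Biostrings::readDNAStringSet(genome)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(intervals$chrom), names(seqs))
  if (length(missing) > 0L) {
    abort(sprintf("chromosome(s) absent from FASTA: %s",
                  paste(missing, collapse = ", ")))
  }
  vapply(seq_len(nrow(intervals)), function(i) {
    s <- Biostrings::subseq(seqs[[intervals$chrom[i]]],
                            start = intervals$start[i] + 1,
                            end = intervals$end[i])
    freq <- Biostrings::alphabetFrequency(s)
    acgt <- sum(freq[c("A", "C", "G", "T")])
    if (acgt == 0) NA_real_ else sum(freq[c("G", "C")]) / acgt
  }, 0)
}

#' Write per-bin values as a bedGraph track
#'
#' One line per bin with a non-missing value; values survive a write/read
#' round trip to 6 decimal places.
#'
#' @param values Numeric vector aligned to `bins` (NA bins are skipped).
#' @param bins A [make_bins()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, bins, path) {
  if (length(values) != nrow(bins)) {
    abort(sprintf("length(values) = %d does not match the bin table (%d bins)",
                  length(values), nrow(bins)))
  }
  keep <- !is.na(values)
  df <- data.frame(
    chrom = bins$chrom[keep],
    start = format(bins$start[keep], scientific = FALSE, trim = TRUE),
    end = format(bins$end[keep], scientific = FALSE, trim = TRUE),
    value = sprintf("%.6f", values[keep])
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph track back onto a bin table
#'
#' @param path bedGraph file written by [write_bedgraph()] (or compatible).
#' @param bins Bin table the track aligns to.
#' @return Numeric vector of length `nrow(bins)` with `NA` for absent bins.
#' @export
read_bedgraph <- function(path, bins) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "cddd", progress = FALSE)
  out <- rep(NA_real_, nrow(bins))
  idx <- match(paste(df$chrom, df$start), paste(bins$chrom, bins$start))
  if (anyNA(idx)) abort("bedGraph line does not align to the bin table")
  out[idx] <- df$value
  out
}
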