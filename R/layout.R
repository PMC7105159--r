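#' Genome layout: chromosome lengths and a fixed-width bin grid
#'
#' A layout holds the ordered chromosomes (name, length in bp) shared by
#' every stage of the pipeline, together with the bin size used to tile
#' them. All coordinates in the package are 0-based, half-open
#' (BED convention).
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp, positive integer-valued).
#' @param bin_size bin width in bp (positive).
#' @return An object of class `genome_layout`.
#' @examples
#' ly <- genome_layout(data.frame(chrom = "chr1", length = 10.5e6), 1e6)
#' nrow(make_bins(ly))  # 11 bins, last truncated to 0.5 Mb
#' @export
genome_layout <- function(chromosomes, bin_size) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names in layout")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (length(bin_size) != 1L || bin_size <= 0) stop("bin_size must be > 0")
  structure(list(
    chromosomes = data.frame(chrom = as.character(chromosomes$chrom),
                             length = as.numeric(chromosomes$length)),
    bin_size = as.numeric(bin_size)
  ), class = "genome_layout")
}

#' Default desk-scale layout
#'
#' Twenty-two pseudo-autosomes with human-like megabase lengths
#' (~2.88 Gb total) tiled at 1 Mb. Sex chromosomes are excluded by
#' design: the healthy reference panel is male while patients are
#' female, so only autosomes are comparable.
#'
#' @param bin_size bin width in bp, default 1 Mb.
#' @param scale multiplier applied to every chromosome length (useful
#'   for small test genomes).
#' @return A `genome_layout`.
#' @export
default_layout <- function(bin_size = 1e6, scale = 1) {
  mb <- c(248, 242, 198, 190, 181, 171, 159, 145, 138, 133, 135,
          133, 114, 107, 102, 90, 83, 80, 59, 64, 47, 51)
  genome_layout(
    data.frame(chrom = paste0("chr", seq_along(mb)),
               length = mb * 1e6 * scale),
    bin_size = bin_size
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.1f Mb total, %.2f Mb bins (%d bins)\n",
              nrow(x$chromosomes), total_length(x) / 1e6,
              x$bin_size / 1e6, nrow(make_bins(x))))
  invisible(x)
}

#' Total genome length of a layout
#' @param layout a `genome_layout`.
#' @return total length in bp.
#' @export
total_length <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$chromosomes$length)
}

#' Tile a layout into half-open bins
#'
#' Bins tile each chromosome in order, `[start, end)`, with the last bin
#' truncated at the chromosome end. Bin order is chromosome-major,
#' position-minor, so bin index and genomic region are in bijection.
#'
#' @param layout a `genome_layout`.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  bs <- layout$bin_size
  pieces <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    starts <- seq(0, by = bs, length.out = ceiling(len / bs))
    data.frame(chrom = layout$chromosomes$chrom[i],
               start = starts,
               end = pmin(starts + bs, len))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# bin indices (1-based, grid order) overlapped by a half-open region
.region_bins <- function(bins, chrom, start, end) {
  which(bins$chrom == chrom & bins$start < end & bins$end > start)
}

# internal: evaluate `code` under a temporary RNG seed, restoring state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}
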