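#' Per-sample bin profile
#'
#' Container for one sample's shallow-WGS signal on a bin grid: raw
#' fragment counts, the per-bin GC fraction, GC-corrected counts, and
#' log2 ratios against a reference panel. Masked-out bins are excluded
#' from every downstream statistic.
#'
#' @param sample_id character scalar.
#' @param layout the `genome_layout` the counts live on.
#' @param raw_counts non-negative integer vector, one per bin.
#' @param gc per-bin GC fraction in `[0, 1]`.
#' @param mask logical per-bin usability flag (default all `TRUE`).
#' @return An object of class `bin_profile`.
#' @export
bin_profile <- function(sample_id, layout, raw_counts, gc = NULL,
                        mask = NULL) {
  bins <- make_bins(layout)
  n <- nrow(bins)
  raw_counts <- as.numeric(raw_counts)
  if (length(raw_counts) != n)
    stop("raw_counts length (", length(raw_counts),
         ") does not match bin grid (", n, ")")
  if (any(raw_counts < 0) || any(raw_counts != floor(raw_counts)))
    stop("raw_counts must be non-negative integers")
  if (!is.null(gc) && length(gc) != n) stop("gc length mismatch")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length mismatch")
  structure(list(
    sample_id = as.character(sample_id),
    layout = layout,
    bins = bins,
    raw_counts = raw_counts,
    gc = gc,
    corrected = NULL,
    log2_ratio = NULL,
    mask = as.logical(mask)
  ), class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("bin_profile '%s': %d bins, %d masked out, total count %s\n",
              x$sample_id, length(x$raw_counts), sum(!x$mask),
              format(sum(x$raw_counts), big.mark = ",")))
  if (!is.null(x$log2_ratio)) cat("  normalized (log2 ratios present)\n")
  invisible(x)
}

.same_grid <- function(a_bins, b_bins) {
  nrow(a_bins) == nrow(b_bins) &&
    all(a_bins$chrom == b_bins$chrom) &&
    all(a_bins$start == b_bins$start) &&
    all(a_bins$end == b_bins$end)
}

#' Assign fragments to bins by midpoint
#'
#' Each fragment goes to exactly one bin: the bin containing its
#' midpoint `floor((start + end) / 2)` under the half-open convention
#' (a midpoint sitting exactly on a bin boundary belongs to the
#' right-hand bin). Fragments on chromosomes absent from the layout, or
#' malformed records (`end <= start`), are skipped and counted.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param layout a `genome_layout`.
#' @return Integer vector of per-bin counts with attribute `skipped`
#'   (number of fragments not assigned). A warning summarizes skips.
#' @export
count_fragments <- function(fragments, layout) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  bins <- make_bins(layout)
  counts <- integer(nrow(bins))

  bad <- fragments$end <= fragments$start
  known <- fragments$chrom %in% layout$chromosomes$chrom
  keep <- !bad & known
  n_skipped <- sum(!keep)
  if (any(bad)) warning(sum(bad), " malformed fragment(s) (end <= start) skipped")
  if (any(!known & !bad)) warning(sum(!known & !bad),
                                  " fragment(s) on unknown chromosomes skipped")

  if (any(keep)) {
    fr <- fragments[keep, , drop = FALSE]
    mid <- floor((fr$start + fr$end) / 2)
    # clamp midpoints beyond the chromosome end into the last bin
    chrlen <- stats::setNames(layout$chromosomes$length,
                              layout$chromosomes$chrom)
    mid <- pmin(mid, chrlen[fr$chrom] - 1)
    bin_in_chrom <- floor(mid / layout$bin_size)
    nbin_per_chrom <- ceiling(layout$chromosomes$length / layout$bin_size)
    offset <- stats::setNames(cumsum(c(0, nbin_per_chrom))[seq_len(nrow(layout$chromosomes))],
                              layout$chromosomes$chrom)
    idx <- offset[fr$chrom] + bin_in_chrom + 1
    tab <- tabulate(idx, nbins = nrow(bins))
    counts <- counts + tab
  }
  attr(counts, "skipped") <- n_skipped
  counts
}

#' Mask unusable bins
#'
#' A bin is masked out when its GC fraction falls outside `gc_range`,
#' or (when a reference panel is supplied) when the median raw count
#' across panel donors is zero. The operation is idempotent: the mask
#' is a pure function of the profile and the rules.
#'
#' @param profile a `bin_profile`.
#' @param panel optional `reference_panel` providing per-bin median
#'   donor counts.
#' @param gc_range usable GC interval, default `c(0.3, 0.7)`.
#' @return The profile with its `mask` updated.
#' @export
mask_bins <- function(profile, panel = NULL, gc_range = c(0.3, 0.7)) {
  stopifnot(inherits(profile, "bin_profile"))
  mask <- rep(TRUE, length(profile$raw_counts))
  if (!is.null(profile$gc))
    mask <- mask & profile$gc >= gc_range[1] & profile$gc <= gc_range[2]
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "reference_panel"))
    if (!.same_grid(profile$bins, panel$bins)) stop("grid mismatch with panel")
    mask <- mask & panel$median_count > 0 & panel$mask
  }
  profile$mask <- mask
  profile
}

#' GC-bias correction of bin counts
#'
#' Fits a smooth curve of count on GC fraction over unmasked bins
#' (local regression via [stats::lowess()]; a per-GC-decile median
#' ratio for inputs too small for a stable fit) and divides it out,
#' rescaling so the corrected mean equals the raw mean. The correction
#' is scale-equivariant: doubling all raw counts doubles the corrected
#' counts.
#'
#' @param profile a `bin_profile` with `gc` set.
#' @param method `"lowess"` (default) or `"decile"`.
#' @param span lowess smoother span.
#' @param min_bins minimum number of unmasked bins required.
#' @return The profile with `corrected` filled in (masked bins `NA`).
#' @export
gc_correct <- function(profile, method = c("lowess", "decile"),
                       span = 0.3, min_bins = 50) {
  stopifnot(inherits(profile, "bin_profile"))
  if (is.null(profile$gc)) stop("profile has no GC track")
  method <- match.arg(method)
  ok <- profile$mask
  if (sum(ok) < min_bins)
    stop("too few unmasked bins for GC correction (", sum(ok),
         " < ", min_bins, ")")
  x <- profile$gc[ok]
  y <- profile$raw_counts[ok]

  if (method == "lowess" && length(unique(x)) >= 10) {
    fit <- stats::lowess(x, y, f = span)
    pred <- stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
  } else {
    # decile-median fallback: expected count per GC decile
    dec <- cut(x, breaks = stats::quantile(x, probs = seq(0, 1, 0.1)),
               include.lowest = TRUE)
    med <- tapply(y, dec, stats::median)
    pred <- as.numeric(med[dec])
  }
  pred <- pmax(pred, 1e-8 * max(1, mean(y)))
  corr <- y / pred
  corr <- corr * mean(y) / mean(corr)

  corrected <- rep(NA_real_, length(profile$raw_counts))
  corrected[ok] <- corr
  profile$corrected <- corrected
  profile
}

#' Depth-normalized log2 ratios against a reference panel
#'
#' Converts GC-corrected counts to per-bin fractions of the sample
#' total and takes `log2(fraction / panel median fraction)`, where both
#' fractions are floored at a small pseudo-count (half the smallest
#' positive panel median fraction) so zero bins at shallow coverage
#' cannot produce `-Inf`. The result is invariant to uniform rescaling
#' of the sample's counts.
#'
#' @param profile a `bin_profile`; if `corrected` is absent the raw
#'   counts are used.
#' @param panel a `reference_panel` on the same grid.
#' @return The profile with `log2_ratio` filled (masked bins `NA`) and
#'   its mask intersected with the panel mask.
#' @export
to_log2_ratio <- function(profile, panel) {
  stopifnot(inherits(profile, "bin_profile"),
            inherits(panel, "reference_panel"))
  if (!.same_grid(profile$bins, panel$bins))
    stop("grid mismatch: profile and panel are on different bin grids")
  mask <- profile$mask & panel$mask
  vals <- if (is.null(profile$corrected)) profile$raw_counts else profile$corrected
  frac <- rep(NA_real_, length(vals))
  frac[mask] <- vals[mask] / sum(vals[mask])
  pc <- panel$pseudo_count
  l2 <- rep(NA_real_, length(vals))
  l2[mask] <- log2(pmax(frac[mask], pc) /
                     pmax(panel$median_fraction[mask], pc))
  profile$mask <- mask
  profile$log2_ratio <- l2
  profile
}
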