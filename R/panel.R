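#' Build a healthy-donor reference panel
#'
#' Summarizes a set of donor bin profiles into the null model for
#' plasma Z-scores: per-bin median fraction (the normalization
#' baseline), per-bin mean and SD of donor log2 ratios, and the full
#' donor-by-bin log2 matrix retained for region (segmented) statistics.
#' Per-bin SDs are floored so that degenerate bins cannot produce
#' infinite Z-scores.
#'
#' @param donor_profiles list of `bin_profile`s on one grid (>= 2).
#' @param run_gc_correct apply [gc_correct()] to donors whose
#'   `corrected` slot is empty (default `TRUE`; skipped for profiles
#'   without a GC track).
#' @param gc_range usable GC interval for the panel mask.
#' @param sd_floor_quantile the SD floor is this quantile of all
#'   positive per-bin SDs (default 0.05); if every SD is zero
#'   (identical donors) a small absolute floor is used.
#' @return An object of class `reference_panel`.
#' @export
build_panel <- function(donor_profiles, run_gc_correct = TRUE,
                        gc_range = c(0.3, 0.7), sd_floor_quantile = 0.05) {
  if (length(donor_profiles) < 2)
    stop("a reference panel needs at least 2 donors")
  stopifnot(all(vapply(donor_profiles, inherits, logical(1), "bin_profile")))
  bins <- donor_profiles[[1]]$bins
  for (p in donor_profiles)
    if (!.same_grid(bins, p$bins)) stop("donor profiles are on different grids")

  if (run_gc_correct)
    donor_profiles <- lapply(donor_profiles, function(p) {
      if (is.null(p$corrected) && !is.null(p$gc)) gc_correct(p) else p
    })

  n <- nrow(bins)
  raw <- vapply(donor_profiles, function(p) p$raw_counts, numeric(n))
  corr <- vapply(donor_profiles, function(p)
    if (is.null(p$corrected)) p$raw_counts else p$corrected, numeric(n))
  gc <- donor_profiles[[1]]$gc

  median_count <- apply(raw, 1, stats::median)
  mask <- median_count > 0
  if (!is.null(gc)) mask <- mask & gc >= gc_range[1] & gc <= gc_range[2]
  for (p in donor_profiles) mask <- mask & p$mask

  frac <- apply(corr, 2, function(x) {
    f <- rep(NA_real_, n); f[mask] <- x[mask] / sum(x[mask]); f
  })
  median_fraction <- apply(frac, 1, stats::median)
  pos <- median_fraction[mask & median_fraction > 0]
  if (!length(pos)) stop("panel has no usable bins")
  pc <- min(pos) / 2

  donor_log2 <- log2(sweep(pmax(frac, pc), 1, pmax(median_fraction, pc), "/"))
  donor_log2[!mask, ] <- NA_real_

  mean_log2 <- rowMeans(donor_log2)
  sd_log2 <- apply(donor_log2, 1, stats::sd)
  pos_sd <- sd_log2[mask & !is.na(sd_log2) & sd_log2 > 0]
  sd_floor <- if (length(pos_sd))
    as.numeric(stats::quantile(pos_sd, sd_floor_quantile)) else 1e-6
  sd_floor <- max(sd_floor, 1e-6)
  sd_log2 <- pmax(sd_log2, sd_floor)

  structure(list(
    version = 1L,
    bins = bins,
    donor_ids = vapply(donor_profiles, function(p) p$sample_id, character(1)),
    n_donors = length(donor_profiles),
    mask = mask,
    median_count = median_count,
    median_fraction = median_fraction,
    pseudo_count = pc,
    mean_log2 = mean_log2,
    sd_log2 = sd_log2,
    sd_floor = sd_floor,
    donor_log2 = donor_log2
  ), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d donors, %d bins (%d masked out), SD floor %.4g\n",
              x$n_donors, nrow(x$bins), sum(!x$mask), x$sd_floor))
  invisible(x)
}

#' Per-bin Z-scores against the panel
#'
#' `Z_i = (log2_i - panel_mean_i) / panel_SD_i` on unmasked bins
#' (masked bins `NA`).
#'
#' @param profile a `bin_profile` normalized with [to_log2_ratio()]
#'   on the panel's grid.
#' @param panel a `reference_panel`.
#' @return Numeric vector of per-bin Z-scores.
#' @export
bin_zscores <- function(profile, panel) {
  stopifnot(inherits(profile, "bin_profile"),
            inherits(panel, "reference_panel"))
  if (is.null(profile$log2_ratio))
    stop("profile is not normalized; run to_log2_ratio() first")
  if (!.same_grid(profile$bins, panel$bins)) stop("grid mismatch")
  z <- (profile$log2_ratio - panel$mean_log2) / panel$sd_log2
  z[!(profile$mask & panel$mask)] <- NA_real_
  z
}

#' Segmented (region) Z-score
#'
#' For a genomic region, the sample's mean log2 ratio over the region's
#' unmasked bins is standardized against the distribution of the same
#' region mean across the panel donors (the donor-projection SD). This
#' absorbs inter-bin correlation, unlike dividing a per-bin SD by
#' `sqrt(n)`. The donor SD is floored at the panel bin-level floor
#' scaled by `1/sqrt(n_bins)`.
#'
#' @param profile a normalized `bin_profile`.
#' @param panel a `reference_panel`.
#' @param region list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return List with `z`, `sample_mean`, `donor_mean`, `donor_sd`,
#'   `n_bins`, and `evaluable`. Regions with no unmasked bins return
#'   `evaluable = FALSE` and `z = NA` (distinct from a Z of 0).
#' @export
region_zscore <- function(profile, panel, region) {
  stopifnot(inherits(profile, "bin_profile"),
            inherits(panel, "reference_panel"))
  if (is.null(profile$log2_ratio))
    stop("profile is not normalized; run to_log2_ratio() first")
  if (!.same_grid(profile$bins, panel$bins)) stop("grid mismatch")
  idx <- .region_bins(profile$bins, region$chrom, region$start, region$end)
  idx <- idx[profile$mask[idx] & panel$mask[idx]]
  if (!length(idx))
    return(list(z = NA_real_, sample_mean = NA_real_, donor_mean = NA_real_,
                donor_sd = NA_real_, n_bins = 0L, evaluable = FALSE))
  m <- mean(profile$log2_ratio[idx])
  md <- colMeans(panel$donor_log2[idx, , drop = FALSE])
  sd_d <- max(stats::sd(md), panel$sd_floor / sqrt(length(idx)))
  list(z = (m - mean(md)) / sd_d,
       sample_mean = m, donor_mean = mean(md), donor_sd = sd_d,
       n_bins = length(idx), evaluable = TRUE)
}

#' Serialize a reference panel to a TSV bundle
#'
#' A single tab-separated file with `#`-prefixed metadata header lines
#' (format version, donor ids, SD floor, pseudo-count) followed by the
#' per-bin table including the donor log2 matrix. Numbers are written
#' at full precision so [load_panel()] round-trips bit-exactly.
#'
#' @param panel a `reference_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    sprintf("#plasmacna_panel_version\t%d", panel$version),
    sprintf("#n_donors\t%d", panel$n_donors),
    sprintf("#donor_ids\t%s", paste(panel$donor_ids, collapse = ",")),
    sprintf("#sd_floor\t%s", num(panel$sd_floor)),
    sprintf("#pseudo_count\t%s", num(panel$pseudo_count))
  ), con)
  tab <- data.frame(chrom = panel$bins$chrom,
                    start = num(panel$bins$start), end = num(panel$bins$end),
                    mask = as.integer(panel$mask),
                    median_count = num(panel$median_count),
                    median_fraction = num(panel$median_fraction),
                    mean_log2 = num(panel$mean_log2),
                    sd_log2 = num(panel$sd_log2),
                    stringsAsFactors = FALSE)
  dl <- panel$donor_log2
  colnames(dl) <- paste0("donor_log2.", seq_len(ncol(dl)))
  tab <- cbind(tab, apply(dl, 2, num))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname save_panel
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- strsplit(sub("^#", "", hdr), "\t")
  meta <- stats::setNames(vapply(meta, `[`, character(1), 2),
                          vapply(meta, `[`, character(1), 1))
  if (is.na(meta["plasmacna_panel_version"]) ||
      as.integer(meta["plasmacna_panel_version"]) != 1L)
    stop("unsupported or missing panel format version in ", path)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dcols <- grep("^donor_log2\\.", names(tab))
  donor_log2 <- as.matrix(tab[, dcols, drop = FALSE])
  dimnames(donor_log2) <- NULL
  structure(list(
    version = 1L,
    bins = data.frame(chrom = tab$chrom, start = tab$start, end = tab$end),
    donor_ids = strsplit(meta[["donor_ids"]], ",")[[1]],
    n_donors = as.integer(meta[["n_donors"]]),
    mask = tab$mask == 1L,
    median_count = tab$median_count,
    median_fraction = tab$median_fraction,
    pseudo_count = as.numeric(meta[["pseudo_count"]]),
    mean_log2 = tab$mean_log2,
    sd_log2 = tab$sd_log2,
    sd_floor = as.numeric(meta[["sd_floor"]]),
    donor_log2 = donor_log2
  ), class = "reference_panel")
}
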