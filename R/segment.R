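#' Segment a per-bin log2 profile into constant-mean pieces
#'
#' CBS-style recursive segmentation, per chromosome: each step places
#' the inner segment (or edge split) maximizing the two-sample
#' t-statistic against the rest of the interval — the circular
#' binary-segmentation statistic, which finds interior events that a
#' plain left/right split misses — and accepts it when a seeded
#' permutation test gives `p < alpha`; accepted splits are recursed.
#' Adjacent segments whose means differ by less than `merge_tol` are
#' merged afterwards. The
#' permutation stream for a candidate interval is keyed on the interval
#' itself, so lowering `alpha` can only remove breakpoints, never add
#' them.
#'
#' @param profile a normalized `bin_profile`, or a numeric vector of
#'   per-bin log2 ratios together with `layout`.
#' @param layout required when `profile` is a bare numeric vector.
#' @param alpha significance level for accepting a split (default
#'   0.01).
#' @param min_seg_bins minimum bins per segment (default 3).
#' @param n_perm permutations per candidate split (default 200).
#' @param merge_tol adjacent segments closer than this in mean log2
#'   are merged (default 0.05).
#' @param max_depth recursion depth cap.
#' @param seed base seed for the permutation streams.
#' @return data.frame of segments: `chrom, start, end, n_bins,
#'   mean_log2` (half-open bp coordinates). Per chromosome the
#'   segments are contiguous in unmasked-bin order and partition the
#'   unmasked bins.
#' @export
segment_profile <- function(profile, layout = NULL, alpha = 0.01,
                            min_seg_bins = 3, n_perm = 200,
                            merge_tol = 0.05, max_depth = 20, seed = 1) {
  if (inherits(profile, "bin_profile")) {
    if (is.null(profile$log2_ratio))
      stop("profile is not normalized; run to_log2_ratio() first")
    bins <- profile$bins
    vals <- profile$log2_ratio
    mask <- profile$mask & !is.na(vals)
  } else {
    if (is.null(layout)) stop("layout required for a bare numeric input")
    bins <- make_bins(layout)
    vals <- as.numeric(profile)
    if (length(vals) != nrow(bins)) stop("value length does not match grid")
    mask <- !is.na(vals)
  }

  out <- list()
  for (ci in seq_along(unique(bins$chrom))) {
    ch <- unique(bins$chrom)[ci]
    idx <- which(bins$chrom == ch & mask)
    if (!length(idx)) {
      warning("chromosome ", ch, " has no usable bins; no segments emitted")
      next
    }
    x <- vals[idx]
    bps <- .rbs(x, min_seg_bins, alpha, n_perm, max_depth,
                seed_key = c(seed, ci))
    segs <- .breaks_to_segments(x, bps)
    segs <- .merge_segments(segs, x, merge_tol)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = bins$start[idx[segs$first]],
      end = bins$end[idx[segs$last]],
      n_bins = segs$last - segs$first + 1L,
      mean_log2 = segs$mean,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(),
                      mean_log2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Candidate boundary pairs (a, b), 0 <= a < b <= n, for the CBS-style
# statistic comparing inner segment (a, b] against the rest of the
# interval. Flanks may be empty; non-empty pieces respect min_bins.
.candidate_pairs <- function(n, min_bins) {
  if (n > 1500) {
    # quadratic pair search is not worth it on very long chromosomes;
    # fall back to plain edge splits (recursion still finds interiors)
    a <- c(rep(0L, n - 1), 1:(n - 1))
    b <- c(1:(n - 1), rep(n, n - 1))
  } else {
    a <- rep(0:n, each = n + 1)
    b <- rep(0:n, times = n + 1)
  }
  inner <- b - a
  left <- a
  right <- n - b
  ok <- inner >= min_bins & inner < n &
    (left == 0 | left >= min_bins) &
    (right == 0 | right >= min_bins)
  list(a = a[ok], b = b[ok])
}

# max |t| between inner segment and the rest, over candidate pairs;
# returns the statistic and (for the observed data) the boundaries
.pair_stat <- function(v, cp, want_argmax = FALSE) {
  n <- length(v)
  S <- c(0, cumsum(v)); S2 <- c(0, cumsum(v^2))
  n_in <- cp$b - cp$a
  n_out <- n - n_in
  sum_in <- S[cp$b + 1] - S[cp$a + 1]
  sum_out <- S[n + 1] - sum_in
  ss_in <- (S2[cp$b + 1] - S2[cp$a + 1]) - sum_in^2 / n_in
  ss_out <- (S2[n + 1] - (S2[cp$b + 1] - S2[cp$a + 1])) - sum_out^2 / n_out
  pooled <- pmax((ss_in + ss_out) / max(n - 2, 1), 1e-12)
  t <- abs(sum_in / n_in - sum_out / n_out) /
    sqrt(pooled * (1 / n_in + 1 / n_out))
  if (!want_argmax) return(max(t))
  k <- which.max(t)
  list(t = t[k], a = cp$a[k], b = cp$b[k])
}

# recursive CBS-style segmentation on a masked-bin vector; each step
# places the inner segment maximizing the two-sample t against the
# rest (a plain edge split when one flank is empty), accepts it by a
# seeded permutation test, and recurses on the resulting pieces.
# Returns sorted breakpoint positions (split after index b).
.rbs <- function(x, min_bins, alpha, n_perm, max_depth, seed_key) {
  recurse <- function(lo, hi, depth) {
    n <- hi - lo + 1
    if (n < 2 * min_bins || depth > max_depth) return(integer(0))
    v <- x[lo:hi]
    cp <- .candidate_pairs(n, min_bins)
    obs <- .pair_stat(v, cp, want_argmax = TRUE)
    # interval-keyed seed: p-value independent of sibling intervals
    iseed <- (abs(seed_key[1]) * 97 + seed_key[2] * 10007 +
                lo * 31 + hi * 17) %% 2147483647
    exceed <- .with_seed(iseed, {
      sum(vapply(seq_len(n_perm), function(p)
        .pair_stat(sample(v), cp) >= obs$t, logical(1)))
    })
    pval <- (1 + exceed) / (n_perm + 1)
    if (pval >= alpha) return(integer(0))
    bps <- sort(unique(c(obs$a, obs$b)))
    bps <- bps[bps > 0 & bps < n]
    bounds <- c(0L, bps, n)
    kids <- unlist(lapply(seq_len(length(bounds) - 1), function(i)
      recurse(lo + bounds[i], lo + bounds[i + 1] - 1, depth + 1)))
    sort(c(lo + bps - 1, kids))
  }
  sort(recurse(1L, length(x), 1L))
}

.breaks_to_segments <- function(x, bps) {
  bounds <- c(0L, bps, length(x))
  first <- bounds[-length(bounds)] + 1L
  last <- bounds[-1]
  data.frame(first = first, last = last,
             mean = vapply(seq_along(first), function(i)
               mean(x[first[i]:last[i]]), numeric(1)))
}

# merge adjacent segments whose means differ by < tol (left to right,
# repeated to a fixed point)
.merge_segments <- function(segs, x, tol) {
  repeat {
    if (nrow(segs) < 2) return(segs)
    d <- abs(diff(segs$mean))
    i <- which(d < tol)
    if (!length(i)) return(segs)
    i <- i[1]
    segs$last[i] <- segs$last[i + 1]
    segs$mean[i] <- mean(x[segs$first[i]:segs$last[i]])
    segs <- segs[-(i + 1), , drop = FALSE]
    rownames(segs) <- NULL
  }
}

#' Exhaustive breakpoint search (test oracle)
#'
#' Finds the globally optimal set of `k_breaks` breakpoints of a short
#' vector by enumerating all placements and minimizing the residual sum
#' of squares around segment means. Intended as an independent check of
#' [segment_profile()] on small instances; quadratic-to-cubic cost.
#'
#' @param x numeric vector (<= 200 values is sensible; tests use <= 30).
#' @param k_breaks number of breakpoints (0, 1 or 2).
#' @param min_seg_bins minimum bins per segment.
#' @return List with `breakpoints` (split-after indices, sorted) and
#'   `rss`.
#' @export
exhaustive_breakpoint_oracle <- function(x, k_breaks, min_seg_bins = 1) {
  n <- length(x)
  stopifnot(k_breaks %in% 0:2, n >= (k_breaks + 1) * min_seg_bins)
  rss <- function(v) sum((v - mean(v))^2)
  if (k_breaks == 0)
    return(list(breakpoints = integer(0), rss = rss(x)))
  best <- list(breakpoints = NULL, rss = Inf)
  if (k_breaks == 1) {
    for (b in min_seg_bins:(n - min_seg_bins)) {
      r <- rss(x[1:b]) + rss(x[(b + 1):n])
      if (r < best$rss) best <- list(breakpoints = b, rss = r)
    }
  } else {
    for (b1 in min_seg_bins:(n - 2 * min_seg_bins)) {
      for (b2 in (b1 + min_seg_bins):(n - min_seg_bins)) {
        r <- rss(x[1:b1]) + rss(x[(b1 + 1):b2]) + rss(x[(b2 + 1):n])
        if (r < best$rss) best <- list(breakpoints = c(b1, b2), rss = r)
      }
    }
  }
  best
}

#' Write / read segments as BED
#'
#' Half-open BED records with `mean_log2` (and `z`, when present) as
#' extra columns after name/score/strand; a `#`-prefixed header line
#' names the columns.
#'
#' @param segments segment data.frame from [segment_profile()],
#'   optionally with a `z` column.
#' @param path file path.
#' @return `path` invisibly; `read_segments_bed()` returns the
#'   segment data.frame.
#' @export
segments_to_bed <- function(segments, path) {
  has_z <- "z" %in% names(segments)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "n_bins", "mean_log2", if (has_z) "z")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(segments)) {
    tab <- data.frame(chrom = segments$chrom,
                      start = format(segments$start, scientific = FALSE, trim = TRUE),
                      end = format(segments$end, scientific = FALSE, trim = TRUE),
                      name = sprintf("seg_%d", seq_len(nrow(segments))),
                      score = 0L, strand = ".",
                      n_bins = segments$n_bins,
                      mean_log2 = sprintf("%.17g", segments$mean_log2))
    if (has_z) tab$z <- sprintf("%.17g", segments$z)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname segments_to_bed
#' @export
read_segments_bed <- function(path) {
  if (!file.exists(path)) stop("segments file not found: ", path)
  lines <- readLines(path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- lines[-1]
  if (!length(body))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(),
                      mean_log2 = numeric()))
  tab <- utils::read.table(text = body, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- hdr
  tab[, setdiff(hdr, c("name", "score", "strand")), drop = FALSE]
}
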