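#' Call CNA regions from a tumor log2 profile
#'
#' Segments an array-like per-bin log2 profile and calls a segment a
#' gain when its mean is at or above `gain_thresh` and a loss at or
#' below `loss_thresh`; neutral segments are dropped and genomically
#' adjacent same-type calls are merged (length-weighted mean log2).
#' Thresholds default to +/- 0.2 log2 units, appropriate for
#' single-copy events at moderate tumor purity.
#'
#' @param tumor_log2 data.frame `chrom,start,end,log2` (one row per
#'   bin, as from [simulate_array_profile()]) or a numeric per-bin
#'   vector with `layout`.
#' @param layout required when `tumor_log2` is a bare vector.
#' @param gain_thresh,loss_thresh call thresholds in log2 units.
#' @param min_seg_bins,alpha,n_perm,merge_tol,seed passed to
#'   [segment_profile()].
#' @return data.frame of calls: `chrom, start, end, type, tumor_log2`
#'   with `type` in `{"gain","loss"}`; zero rows when the profile is
#'   flat.
#' @export
call_tumor_cnas <- function(tumor_log2, layout = NULL, gain_thresh = 0.2,
                            loss_thresh = -0.2, min_seg_bins = 3,
                            alpha = 0.01, n_perm = 200, merge_tol = 0.05,
                            seed = 1) {
  stopifnot(gain_thresh > 0, loss_thresh < 0)
  if (is.data.frame(tumor_log2)) {
    stopifnot(all(c("chrom", "start", "end", "log2") %in% names(tumor_log2)))
    if (is.null(layout)) {
      lens <- tapply(tumor_log2$end, tumor_log2$chrom, max)
      cn <- unique(tumor_log2$chrom)
      layout <- genome_layout(
        data.frame(chrom = cn, length = as.numeric(lens[cn])),
        bin_size = stats::median(tumor_log2$end - tumor_log2$start))
    }
    vals <- tumor_log2$log2
  } else {
    if (is.null(layout)) stop("layout required for a bare numeric input")
    vals <- as.numeric(tumor_log2)
  }
  segs <- segment_profile(vals, layout = layout, alpha = alpha,
                          min_seg_bins = min_seg_bins, n_perm = n_perm,
                          merge_tol = merge_tol, seed = seed)
  segs$type <- ifelse(segs$mean_log2 >= gain_thresh, "gain",
                      ifelse(segs$mean_log2 <= loss_thresh, "loss", NA))
  calls <- segs[!is.na(segs$type), , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      tumor_log2 = numeric(), stringsAsFactors = FALSE))
  # merge genomically adjacent same-type calls
  out <- calls[1, , drop = FALSE]
  if (nrow(calls) > 1) for (i in 2:nrow(calls)) {
    j <- nrow(out)
    if (calls$chrom[i] == out$chrom[j] && calls$type[i] == out$type[j] &&
        calls$start[i] == out$end[j]) {
      w1 <- out$n_bins[j]; w2 <- calls$n_bins[i]
      out$mean_log2[j] <- (out$mean_log2[j] * w1 + calls$mean_log2[i] * w2) /
        (w1 + w2)
      out$end[j] <- calls$end[i]
      out$n_bins[j] <- w1 + w2
    } else out <- rbind(out, calls[i, ])
  }
  res <- data.frame(chrom = out$chrom, start = out$start, end = out$end,
                    type = out$type, tumor_log2 = out$mean_log2,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write / read CNA calls as BED
#'
#' 0-based half-open BED with column 4 = type (`gain`/`loss`), column
#' 5 = `round(1000 * |tumor_log2|)` as the score, column 6 = strand
#' placeholder, and `tumor_log2` as an extra column. `read_cna_bed()`
#' validates the type labels and rejects records that cannot be
#' half-open (`end <= start`), the footprint of 1-based inclusive
#' input.
#'
#' @param calls CNA call data.frame (`chrom,start,end,type,tumor_log2`).
#' @param path file path.
#' @return `path` invisibly; `read_cna_bed()` returns the call
#'   data.frame.
#' @export
write_cna_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\ttype\tscore\tstrand\ttumor_log2", con)
  if (nrow(calls)) {
    tab <- data.frame(chrom = calls$chrom,
                      start = format(calls$start, scientific = FALSE, trim = TRUE),
                      end = format(calls$end, scientific = FALSE, trim = TRUE),
                      type = calls$type,
                      score = round(1000 * abs(calls$tumor_log2)),
                      strand = ".",
                      tumor_log2 = sprintf("%.17g", calls$tumor_log2))
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cna_bed
#' @export
read_cna_bed <- function(path) {
  if (!file.exists(path)) stop("CNA BED file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      tumor_log2 = numeric(), stringsAsFactors = FALSE))
  tab <- utils::read.table(text = body, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("CNA BED needs at least 4 columns (chrom, start, end, type)")
  calls <- data.frame(chrom = tab[[1]], start = as.numeric(tab[[2]]),
                      end = as.numeric(tab[[3]]), type = tab[[4]],
                      tumor_log2 = if (ncol(tab) >= 7) as.numeric(tab[[7]])
                                   else NA_real_,
                      stringsAsFactors = FALSE)
  bad_type <- setdiff(unique(calls$type), c("gain", "loss"))
  if (length(bad_type))
    stop("unknown CNA type label(s): ", paste(bad_type, collapse = ", "),
         " (expected 'gain' or 'loss')")
  if (any(calls$end <= calls$start))
    stop("records with end <= start: input must be 0-based half-open ",
         "(BED); 1-based inclusive coordinates are not accepted")
  calls
}

#' Per-patient CNA burden summary
#'
#' @param calls_per_patient named list of CNA call data.frames, one per
#'   patient (possibly empty list), or a plain integer vector of
#'   per-patient CNA counts.
#' @return List with `per_patient` (data.frame `patient_id, n_cnas`),
#'   `median`, and `range` across patients; empty input gives an empty
#'   summary with `NA` statistics.
#' @export
summarize_cna_burden <- function(calls_per_patient) {
  if (!length(calls_per_patient))
    return(list(per_patient = data.frame(patient_id = character(),
                                         n_cnas = integer()),
                median = NA_real_, range = c(NA_real_, NA_real_)))
  ids <- names(calls_per_patient)
  if (is.null(ids)) ids <- sprintf("patient_%d", seq_along(calls_per_patient))
  counts <- if (is.numeric(calls_per_patient)) as.integer(calls_per_patient)
            else vapply(calls_per_patient, nrow, integer(1))
  list(per_patient = data.frame(patient_id = ids, n_cnas = as.integer(counts),
                                row.names = NULL),
       median = stats::median(counts),
       range = range(counts))
}
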