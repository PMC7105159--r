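.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Intersect tumor CNA regions with plasma segments
#'
#' Any-overlap semantics on half-open coordinates; one output row per
#' (CNA, segment) overlapping pair with the overlap length in bp,
#' ordered by CNA then segment.
#'
#' @param cna_regions data.frame `chrom,start,end,...`.
#' @param plasma_segments data.frame `chrom,start,end,...` (as from
#'   [segment_profile()]).
#' @return data.frame `cna_index, segment_index, chrom, cna_start,
#'   cna_end, seg_start, seg_end, overlap_bp`; zero rows for disjoint
#'   inputs.
#' @export
intersect_regions <- function(cna_regions, plasma_segments) {
  empty <- data.frame(cna_index = integer(), segment_index = integer(),
                      chrom = character(), cna_start = numeric(),
                      cna_end = numeric(), seg_start = numeric(),
                      seg_end = numeric(), overlap_bp = numeric())
  if (!nrow(cna_regions) || !nrow(plasma_segments)) return(empty)
  q <- .as_granges(cna_regions)
  s <- .as_granges(plasma_segments)
  # disjoint chromosome sets are a legitimate empty result, not a
  # user error worth a seqlevel warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  if (!length(hits)) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(q[qh], s[sh]))
  out <- data.frame(cna_index = qh, segment_index = sh,
                    chrom = cna_regions$chrom[qh],
                    cna_start = cna_regions$start[qh],
                    cna_end = cna_regions$end[qh],
                    seg_start = plasma_segments$start[sh],
                    seg_end = plasma_segments$end[sh],
                    overlap_bp = as.numeric(ov))
  out <- out[order(out$cna_index, out$segment_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate one tumor CNA in a plasma sample
#'
#' The tumor-informed detection rule: the segmented Z-score is computed
#' over the CNA's own genomic footprint, the direction of the plasma
#' signal must match the tumor call (gain: positive mean log2; loss:
#' negative), and detection additionally requires the sign-specific
#' tail `Z > z_cut` (gain) or `Z < -z_cut` (loss).
#'
#' @param cna one-row data.frame (or list) with `chrom,start,end,type`
#'   and optionally `tumor_log2`.
#' @param profile normalized plasma `bin_profile`.
#' @param panel `reference_panel`.
#' @param z_cut positive Z threshold (default 1.5).
#' @param footprint `"cna"` (default) scores the CNA's own footprint;
#'   `"max_segment"` scores the overlapping plasma segment with the
#'   largest absolute Z (requires `segments`).
#' @param segments plasma segments, only used for
#'   `footprint = "max_segment"`.
#' @return One-row data.frame: `chrom,start,end,type,tumor_log2,
#'   plasma_z,plasma_mean,n_bins,direction_match,detected,evaluable`.
#' @export
evaluate_cna_in_plasma <- function(cna, profile, panel, z_cut = 1.5,
                                   footprint = c("cna", "max_segment"),
                                   segments = NULL) {
  stopifnot(z_cut > 0)
  footprint <- match.arg(footprint)
  region <- list(chrom = cna$chrom, start = cna$start, end = cna$end)
  if (footprint == "max_segment") {
    if (is.null(segments)) stop("footprint = 'max_segment' needs segments")
    ov <- intersect_regions(as.data.frame(cna, stringsAsFactors = FALSE)[1, ],
                            segments)
    if (nrow(ov)) {
      zs <- vapply(seq_len(nrow(ov)), function(i) {
        r <- region_zscore(profile, panel,
                           list(chrom = ov$chrom[i], start = ov$seg_start[i],
                                end = ov$seg_end[i]))
        if (r$evaluable) abs(r$z) else -Inf
      }, numeric(1))
      if (any(is.finite(zs))) {
        i <- which.max(zs)
        region <- list(chrom = ov$chrom[i], start = ov$seg_start[i],
                       end = ov$seg_end[i])
      }
    }
  }
  rz <- region_zscore(profile, panel, region)
  dir_match <- isTRUE(rz$evaluable) &&
    ((cna$type == "gain" && rz$sample_mean > 0) ||
     (cna$type == "loss" && rz$sample_mean < 0))
  detected <- dir_match &&
    ((cna$type == "gain" && rz$z > z_cut) ||
     (cna$type == "loss" && rz$z < -z_cut))
  data.frame(chrom = cna$chrom, start = cna$start, end = cna$end,
             type = cna$type,
             tumor_log2 = if (!is.null(cna$tumor_log2)) cna$tumor_log2
                          else NA_real_,
             plasma_z = rz$z, plasma_mean = rz$sample_mean,
             n_bins = rz$n_bins,
             direction_match = dir_match, detected = detected,
             evaluable = rz$evaluable, stringsAsFactors = FALSE)
}

#' Tumor-informed detection for one patient
#'
#' Evaluates every CNA called in the patient's tumor against the
#' matched plasma profile; the patient is flagged ctDNA-detected when
#' any CNA passes the direction-matched Z cutoff. Patients whose tumor
#' shows no CNAs yield zero records and a `FALSE` flag: the method is
#' blind to such tumors.
#'
#' @param cna_list CNA call data.frame for the patient's tumor.
#' @param profile normalized plasma `bin_profile`.
#' @param panel `reference_panel`.
#' @param z_cut positive Z threshold (default 1.5).
#' @param patient_id label attached to the records.
#' @param ... passed to [evaluate_cna_in_plasma()].
#' @return List with `records` (data.frame, one row per CNA),
#'   `detected` (any record detected), and `n_unevaluable` (records
#'   without usable bins, excluded from summaries).
#' @export
detect_patient <- function(cna_list, profile, panel, z_cut = 1.5,
                           patient_id = profile$sample_id, ...) {
  if (!nrow(cna_list)) {
    rec <- data.frame(patient_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), type = character(),
                      tumor_log2 = numeric(), plasma_z = numeric(),
                      plasma_mean = numeric(), n_bins = integer(),
                      direction_match = logical(), detected = logical(),
                      evaluable = logical(), stringsAsFactors = FALSE)
    return(list(records = rec, detected = FALSE, n_unevaluable = 0L))
  }
  recs <- do.call(rbind, lapply(seq_len(nrow(cna_list)), function(i)
    evaluate_cna_in_plasma(cna_list[i, ], profile, panel, z_cut, ...)))
  recs <- cbind(patient_id = patient_id, recs, stringsAsFactors = FALSE)
  n_bad <- sum(!recs$evaluable)
  if (n_bad) message(n_bad, " CNA region(s) had no usable bins and were ",
                     "excluded from detection summaries")
  list(records = recs,
       detected = any(recs$detected[recs$evaluable]),
       n_unevaluable = n_bad)
}

#' Percent of the genome altered in plasma
#'
#' 100 times the union length of a patient's detected regions divided
#' by the total layout length; overlapping regions are not double
#' counted.
#'
#' @param records detection records for one patient (as from
#'   [detect_patient()]).
#' @param layout the `genome_layout`.
#' @param patient_id optional label (taken from the records if absent).
#' @return List with `patient_id`, `altered_bp` (union length of
#'   detected regions) and `pct_genome_altered`.
#' @export
percent_genome_altered <- function(records, layout, patient_id = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.null(patient_id))
    patient_id <- if (nrow(records) && "patient_id" %in% names(records))
      records$patient_id[1] else NA_character_
  det <- records[which(records$detected), , drop = FALSE]
  altered <- if (nrow(det)) {
    sum(as.numeric(GenomicRanges::width(
      GenomicRanges::reduce(.as_granges(det)))))
  } else 0
  list(patient_id = patient_id, altered_bp = altered,
       pct_genome_altered = 100 * altered / total_length(layout))
}

#' Donor specificity of a tumor-informed query set
#'
#' Screens healthy-donor profiles against a set of query regions (the
#' CNAs detected in patients): a donor is a false positive when any
#' query region is detected (direction-matched, `|Z| > z_cut`) in that
#' donor. Donors that are members of the panel are evaluated against a
#' panel rebuilt without them (leave-one-out).
#'
#' @param donor_profiles list of donor `bin_profile`s (raw counts; GC
#'   correction and normalization are applied internally).
#' @param query_regions data.frame `chrom,start,end,type`.
#' @param panel optional external `reference_panel`; when `NULL`
#'   (default) leave-one-out panels are built from the donors
#'   themselves.
#' @param z_cut positive Z threshold (default 1.5).
#' @param require_direction require the direction match (default
#'   `TRUE`); when `FALSE` detection is `|Z| > z_cut` alone.
#' @return List with `true_negatives`, `n_donors`, `specificity`, and
#'   `per_donor` (data.frame `donor_id, n_detected, false_positive`).
#' @export
donor_specificity <- function(donor_profiles, query_regions, panel = NULL,
                              z_cut = 1.5, require_direction = TRUE) {
  stopifnot(z_cut > 0)
  n <- length(donor_profiles)
  res <- lapply(seq_len(n), function(d) {
    prof <- donor_profiles[[d]]
    pan <- if (is.null(panel)) build_panel(donor_profiles[-d]) else panel
    if (is.null(prof$corrected) && !is.null(prof$gc))
      prof <- gc_correct(prof)
    prof <- to_log2_ratio(prof, pan)
    if (!nrow(query_regions)) return(0L)
    hits <- vapply(seq_len(nrow(query_regions)), function(i) {
      q <- query_regions[i, ]
      rz <- region_zscore(prof, pan, q)
      if (!rz$evaluable) return(FALSE)
      if (require_direction) {
        (q$type == "gain" && rz$sample_mean > 0 && rz$z > z_cut) ||
          (q$type == "loss" && rz$sample_mean < 0 && rz$z < -z_cut)
      } else abs(rz$z) > z_cut
    }, logical(1))
    sum(hits)
  })
  n_det <- vapply(res, identity, integer(1))
  fp <- n_det > 0
  list(true_negatives = sum(!fp), n_donors = n,
       specificity = if (n) mean(!fp) else NA_real_,
       per_donor = data.frame(
         donor_id = vapply(donor_profiles, function(p) p$sample_id,
                           character(1)),
         n_detected = n_det, false_positive = fp, row.names = NULL))
}

#' Tumor-plasma agreement by linear regression
#'
#' Ordinary least squares of the plasma segmented Z-score on the tumor
#' log2 ratio across detection records, reporting slope, R-squared and
#' the two-sided p-value for zero slope.
#'
#' @param records detection records with finite `plasma_z` and
#'   `tumor_log2`.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
tumor_plasma_agreement <- function(records) {
  ok <- is.finite(records$plasma_z) & is.finite(records$tumor_log2)
  d <- records[ok, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 records with finite values")
  if (nrow(d) == 2)
    warning("only 2 points: R-squared is degenerately 1")
  fit <- stats::lm(plasma_z ~ tumor_log2, data = d)
  # collinear toy inputs trigger summary.lm's perfect-fit warning
  s <- suppressWarnings(summary(fit))
  p <- if (nrow(d) > 2) s$coefficients["tumor_log2", "Pr(>|t|)"]
       else NA_real_
  list(slope = unname(stats::coef(fit)["tumor_log2"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = s$r.squared, p_value = p, n = nrow(d))
}
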