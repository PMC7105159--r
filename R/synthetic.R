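#' Simulate a spatially autocorrelated GC track
#'
#' Produces one GC fraction per bin of the layout, in `[0.3, 0.7]`,
#' spatially autocorrelated at the isochore scale: a mean-reverting
#' (AR(1)) smoothed walk whose correlation decays over roughly
#' `1/(1 - phi)` bins (~10 Mb at the defaults), squashed through tanh
#' so the range constraint always holds. Deterministic for a given
#' seed.
#'
#' @param layout a `genome_layout`.
#' @param seed integer seed.
#' @param phi AR(1) coefficient in `[0, 1)` controlling the
#'   correlation length (default 0.9).
#' @return Numeric vector, one GC fraction per bin.
#' @export
simulate_gc_track <- function(layout, seed = 1, phi = 0.9) {
  stopifnot(phi >= 0, phi < 1)
  bins <- make_bins(layout)
  n <- nrow(bins)
  .with_seed(seed, {
    sd_stat <- 1 / sqrt(1 - phi^2)
    w <- numeric(n)
    e <- stats::rnorm(n)
    w[1] <- e[1] * sd_stat
    for (i in seq_len(n)[-1]) w[i] <- phi * w[i - 1] + e[i]
    w <- w / sd_stat
    0.5 + 0.2 * tanh(w / 2)
  })
}

# smooth unimodal multiplicative GC bias, peak near GC = 0.45,
# normalized to mean 1 so the genome-wide expected depth is preserved
.gc_bias_curve <- function(gc, amplitude) {
  b <- 1 + amplitude * (1 - ((gc - 0.45) / 0.25)^2)
  b <- pmax(b, 0.05)
  b / mean(b)
}

# shared count-drawing path so plasma at tumor_fraction = 0 reproduces
# the donor model exactly under the same seed
.draw_counts <- function(mu, dispersion, seed) {
  .with_seed(seed, {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  })
}

#' Simulate a healthy-donor shallow-WGS bin profile
#'
#' Per-bin fragment counts are drawn from a negative binomial with mean
#' `mean_depth * g(gc)`, where `g` is a smooth unimodal GC-bias curve
#' (peak near GC 0.45) scaled by `gc_bias_amplitude` and normalized to
#' mean 1. `dispersion = 0` gives the Poisson limit
#' (`Var = mu`); otherwise `Var = mu + dispersion * mu^2`.
#'
#' @param layout a `genome_layout`.
#' @param gc_track per-bin GC fractions (see [simulate_gc_track()]).
#' @param mean_depth expected fragments per bin (> 0); the default 30
#'   emulates ~0.1x coverage on megabase bins at desk scale.
#' @param gc_bias_amplitude strength of the multiplicative GC bias
#'   (0 = unbiased).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return A `bin_profile` with raw counts and the GC track attached.
#' @export
simulate_donor_counts <- function(layout, gc_track, mean_depth = 30,
                                  gc_bias_amplitude = 0, dispersion = 0,
                                  seed = 1, sample_id = "donor") {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  bins <- make_bins(layout)
  stopifnot(length(gc_track) == nrow(bins))
  mu <- mean_depth * .gc_bias_curve(gc_track, gc_bias_amplitude)
  counts <- .draw_counts(mu, dispersion, seed)
  bin_profile(sample_id, layout, counts, gc = gc_track)
}

#' Simulate a tumor CNA truth set
#'
#' Places `n_cnas` non-overlapping copy-number-altered regions on the
#' layout, with copy numbers drawn from `copy_numbers` (default
#' `c(1, 3)`: single-copy loss or gain, the typical leiomyoma events).
#' Region boundaries are aligned to the bin grid so that bin-level
#' expectations are exact. `n_cnas = 0` models tumors without CNAs.
#'
#' @param layout a `genome_layout`.
#' @param n_cnas number of regions (>= 0).
#' @param size_range region length range in bp; sizes are drawn
#'   uniformly then rounded to whole bins (minimum one bin).
#' @param copy_numbers admissible integer copy numbers (no 2s).
#' @param tumor_fraction fraction of plasma cfDNA derived from the
#'   tumor, recorded with the truth set.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget before giving up.
#' @return An object of class `sim_truth`: list with `tumor_cnas`
#'   (data.frame `chrom,start,end,type,copy`), `tumor_fraction`, `seed`.
#' @export
simulate_tumor_truth <- function(layout, n_cnas, size_range = c(3e6, 4e7),
                                 copy_numbers = c(1, 3),
                                 tumor_fraction = NA_real_, seed = 1,
                                 max_tries = 1000L) {
  stopifnot(n_cnas >= 0)
  if (any(copy_numbers == 2) || any(copy_numbers < 0) ||
      any(copy_numbers != floor(copy_numbers)))
    stop("copy_numbers must be non-negative integers other than 2")
  bs <- layout$bin_size
  chroms <- layout$chromosomes
  cnas <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), type = character(),
                     copy = numeric(), stringsAsFactors = FALSE)
  if (n_cnas > 0) {
    cnas <- .with_seed(seed, {
      placed <- list()
      tries <- 0
      while (length(placed) < n_cnas) {
        tries <- tries + 1
        if (tries > max_tries)
          stop("could not place ", n_cnas,
               " non-overlapping CNA regions; reduce n_cnas or sizes")
        size <- stats::runif(1, size_range[1], size_range[2])
        size <- max(1, round(size / bs)) * bs
        ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
        clen <- chroms$length[ci]
        if (size > clen) next
        nstart <- floor((clen - size) / bs)
        start <- sample.int(nstart + 1, 1) - 1
        start <- start * bs
        end <- min(start + size, clen)
        overlaps <- vapply(placed, function(p)
          p$chrom == chroms$chrom[ci] && p$start < end && p$end > start,
          logical(1))
        if (any(overlaps)) next
        cp <- if (length(copy_numbers) == 1) copy_numbers
              else sample(copy_numbers, 1)
        placed[[length(placed) + 1]] <- list(chrom = chroms$chrom[ci],
                                             start = start, end = end,
                                             copy = cp)
      }
      do.call(rbind, lapply(placed, function(p)
        data.frame(chrom = p$chrom, start = p$start, end = p$end,
                   type = if (p$copy > 2) "gain" else "loss",
                   copy = p$copy, stringsAsFactors = FALSE)))
    })
    cnas <- cnas[order(match(cnas$chrom, chroms$chrom), cnas$start), ]
    rownames(cnas) <- NULL
  }
  structure(list(tumor_cnas = cnas, tumor_fraction = tumor_fraction,
                 seed = seed), class = "sim_truth")
}

# per-bin copy number implied by a truth set (2 outside CNAs)
.truth_bin_copy <- function(truth, bins) {
  copy <- rep(2, nrow(bins))
  cnas <- truth$tumor_cnas
  if (nrow(cnas)) for (i in seq_len(nrow(cnas))) {
    idx <- .region_bins(bins, cnas$chrom[i], cnas$start[i], cnas$end[i])
    copy[idx] <- cnas$copy[i]
  }
  copy
}

#' Simulate an array-like tumor copy-number profile
#'
#' Per-bin tumor log2 ratio: `log2(copy / 2)` inside truth regions, 0
#' elsewhere, plus Gaussian noise. Emulates the segmented output of a
#' SNP-array platform on the pipeline's bin grid.
#'
#' @param truth a `sim_truth`.
#' @param layout a `genome_layout`.
#' @param noise_sd Gaussian noise SD in log2 units (>= 0).
#' @param seed integer seed.
#' @return data.frame `chrom,start,end,log2` (one row per bin).
#' @export
simulate_array_profile <- function(truth, layout, noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"), noise_sd >= 0)
  bins <- make_bins(layout)
  copy <- .truth_bin_copy(truth, bins)
  base <- ifelse(copy == 0, log2(0.05), log2(copy / 2))  # bounded for copy 0
  noise <- .with_seed(seed, stats::rnorm(nrow(bins), 0, noise_sd))
  cbind(bins, data.frame(log2 = base + noise))
}

#' Simulate a plasma cfDNA bin profile with tumor admixture
#'
#' The expected count in a bin covered by a truth CNA of copy number
#' `c` is scaled by `1 + tumor_fraction * (c/2 - 1)` relative to the
#' healthy-donor baseline; all other parameters follow
#' [simulate_donor_counts()]. With `tumor_fraction = 0` and the same
#' seed the output is identical to the donor model.
#'
#' @param truth a `sim_truth`.
#' @param layout a `genome_layout`.
#' @param gc_track per-bin GC fractions.
#' @param tumor_fraction fraction in `[0, 1]` of plasma DNA derived
#'   from tumor cells.
#' @param mean_depth,gc_bias_amplitude,dispersion,seed,sample_id as in
#'   [simulate_donor_counts()].
#' @return A `bin_profile` with attribute fields recording the truth.
#' @export
simulate_plasma_counts <- function(truth, layout, gc_track, tumor_fraction,
                                   mean_depth = 30, gc_bias_amplitude = 0,
                                   dispersion = 0, seed = 1,
                                   sample_id = "plasma") {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.finite(tumor_fraction) || tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  bins <- make_bins(layout)
  stopifnot(length(gc_track) == nrow(bins))
  copy <- .truth_bin_copy(truth, bins)
  admix <- 1 + tumor_fraction * (copy / 2 - 1)
  mu <- mean_depth * .gc_bias_curve(gc_track, gc_bias_amplitude) * admix
  counts <- .draw_counts(mu, dispersion, seed)
  prof <- bin_profile(sample_id, layout, counts, gc = gc_track)
  prof$tumor_fraction <- tumor_fraction
  prof
}

#' Simulate a two-group clinical cohort (LM / LMS)
#'
#' Gaussian draws truncated at zero for LDH (U/L) and age (years), with
#' defaults matching the study conditions the pipeline models: mean LDH
#' 191 (LM) and 288 (LMS) U/L; mean age 48 and 54 years.
#'
#' @param n_lm,n_lms group sizes (>= 0).
#' @param ldh_means,ldh_sds per-group (LM, LMS) LDH mean and SD in U/L.
#' @param age_means,age_sds per-group age mean and SD in years.
#' @param seed integer seed.
#' @return data.frame `patient_id, diagnosis, ldh, age` with
#'   `diagnosis` in `{"LM", "LMS"}`.
#' @export
simulate_clinical_cohort <- function(n_lm = 9, n_lms = 8,
                                     ldh_means = c(191, 288),
                                     ldh_sds = c(40, 80),
                                     age_means = c(48, 54),
                                     age_sds = c(9, 10), seed = 1) {
  stopifnot(n_lm >= 0, n_lms >= 0, all(ldh_sds >= 0), all(age_sds >= 0))
  rtnorm <- function(n, mean, sd) {
    if (n == 0) return(numeric(0))
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  .with_seed(seed, {
    data.frame(
      patient_id = c(sprintf("LM%02d", seq_len(n_lm)),
                     sprintf("LMS%02d", seq_len(n_lms))),
      diagnosis = c(rep("LM", n_lm), rep("LMS", n_lms)),
      ldh = c(rtnorm(n_lm, ldh_means[1], ldh_sds[1]),
              rtnorm(n_lms, ldh_means[2], ldh_sds[2])),
      age = c(rtnorm(n_lm, age_means[1], age_sds[1]),
              rtnorm(n_lms, age_means[2], age_sds[2])),
      stringsAsFactors = FALSE
    )
  })
}
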