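# shared fixtures, built in code

# small two-chromosome layout: 60 + 40 bins of 1 Mb
tiny_layout <- function() {
  genome_layout(data.frame(chrom = c("chrA", "chrB"),
                           length = c(60e6, 40e6)), bin_size = 1e6)
}

# single-chromosome layout with n bins of 1 Mb
line_layout <- function(n) {
  genome_layout(data.frame(chrom = "chr1", length = n * 1e6), bin_size = 1e6)
}

# a donor cohort plus its panel on a given layout
make_cohort <- function(layout, n_donors = 25, mean_depth = 30, seed = 500,
                        gc_seed = 11, ...) {
  gc <- simulate_gc_track(layout, seed = gc_seed)
  donors <- lapply(seq_len(n_donors), function(i)
    simulate_donor_counts(layout, gc, mean_depth = mean_depth,
                          seed = seed + i,
                          sample_id = sprintf("HD%02d", i), ...))
  list(gc = gc, donors = donors, panel = build_panel(donors))
}

# a normalized plasma profile carrying the given truth
make_plasma <- function(truth, layout, gc, panel, tumor_fraction,
                        mean_depth = 30, seed = 1, sample_id = "pt") {
  p <- simulate_plasma_counts(truth, layout, gc, tumor_fraction,
                              mean_depth = mean_depth, seed = seed,
                              sample_id = sample_id)
  to_log2_ratio(gc_correct(p), panel)
}

# truth set with one CNA at explicit bin-aligned coordinates
manual_truth <- function(chrom, start, end, copy, tumor_fraction = NA) {
  structure(list(
    tumor_cnas = data.frame(chrom = chrom, start = start, end = end,
                            type = ifelse(copy > 2, "gain", "loss"),
                            copy = copy, stringsAsFactors = FALSE),
    tumor_fraction = tumor_fraction, seed = NA_integer_
  ), class = "sim_truth")
}
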