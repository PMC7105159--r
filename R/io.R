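#' Read and write per-bin tracks as TSV
#'
#' Four-column tab-separated files (`chrom, start, end, <value>`) with a
#' `#`-prefixed header line; coordinates 0-based half-open. Used for
#' bin counts, GC tracks and log2-ratio profiles.
#'
#' @param df data.frame whose first three columns are `chrom, start,
#'   end`; remaining columns are written as-is.
#' @param path file path.
#' @param value_col name of the value column for `read_bin_tsv`
#'   validation (optional).
#' @return `path` invisibly; `read_bin_tsv()` returns a data.frame.
#' @export
write_bin_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_tsv
#' @export
read_bin_tsv <- function(path, value_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  tab <- utils::read.table(text = lines[-1], sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- hdr
  if (!is.null(value_col) && !(value_col %in% hdr))
    stop("column '", value_col, "' not found in ", path)
  tab
}

#' Write a simulated truth set as BED
#'
#' Six-column BED: name = `gain`/`loss`, score = integer copy number.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  cn <- truth$tumor_cnas
  if (nrow(cn)) {
    tab <- data.frame(chrom = cn$chrom,
                      start = format(cn$start, scientific = FALSE, trim = TRUE),
                      end = format(cn$end, scientific = FALSE, trim = TRUE),
                      name = cn$type, score = cn$copy, strand = ".")
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read fragment intervals from a BED3 file
#'
#' @param path BED3 file (no header required; `#` lines ignored).
#' @return data.frame `chrom, start, end`.
#' @export
read_fragments_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  tab <- utils::read.table(text = body, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(chrom = tab[[1]], start = as.numeric(tab[[2]]),
             end = as.numeric(tab[[3]]))
}
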