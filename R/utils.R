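# shared validation helpers

abort_input <- function(...) stop(..., call. = FALSE)

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    abort_input(sprintf("'%s' must be a positive integer, got %s", name,
                        paste(format(x), collapse = ",")))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort_input(sprintf("'%s' must lie in [0, 1]", name))
  }
  as.numeric(x)
}

#' Convert 0-based half-open intervals to GRanges
#'
#' All on-disk interval formats in this package are BED-style 0-based
#' half-open; GRanges is 1-based closed. These two helpers do the shift in
#' one place.
#'
#' @param df data.frame with columns chrom, start, end (0-based half-open).
#' @param ... further metadata columns carried through.
#' @return A [GenomicRanges::GRanges].
#' @keywords internal
#' @noRd
bed_to_granges <- function(df) {
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    abort_input(sprintf("malformed interval (end <= start) at record %d: %s:%d-%d",
                        bad, df$chrom[bad], df$start[bad], df$end[bad]))
  }
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}

granges_to_bed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}
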