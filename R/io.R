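# On-disk formats. Interval files are BED-style 0-based half-open
# throughout; bedGraph goes through rtracklayer; the binarized text layout
# mirrors ChromHMM's (header line "tissue<TAB>chrom", then one column per
# mark, one row per bin).

#' @rdname write_formats
#' @param chrom_sizes data.frame (chrom, length).
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(chrom_sizes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' File writers for pipeline artifacts
#'
#' Small writers for the text formats the pipeline emits: chromosome
#' sizes (two-column TSV), BED3/BED4/BED6 intervals, bedGraph tracks,
#' ChromHMM-style binarized calls, state-model JSON and a ChromHMM-shaped
#' emissions table, BED9 browser tracks coloured by state name.
#'
#' @param df a BED-style data.frame (chrom, start, end, ...).
#' @param path output file.
#' @param columns which columns to write after chrom/start/end.
#' @return the path, invisibly.
#' @name write_formats
#' @export
write_bed <- function(df, path, columns = setdiff(names(df),
                                                  c("chrom", "start", "end"))) {
  write.table(df[, c("chrom", "start", "end", columns), drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_formats
#' @param track a [binned_track()].
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$values)
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = seq_len(n) * track$bin_size_bp -
                       track$bin_size_bp + 1L,
                     width = track$bin_size_bp))
  S4Vectors::mcols(gr)$score <- track$values
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_formats
#' @param obs an [observation_matrix()].
#' @export
write_binarized <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(obs$tissue, obs$chromosome, sep = "\t"), con)
  writeLines(paste(obs$marks, collapse = "\t"), con)
  write.table(obs$mat, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_formats
#' @export
read_binarized <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- strsplit(hdr[1], "\t")[[1]]
  marks <- strsplit(hdr[2], "\t")[[1]]
  mat <- as.matrix(read.table(path, skip = 2L, sep = "\t"))
  dimnames(mat) <- NULL
  observation_matrix(mat, marks, tissue = meta[1], chromosome = meta[2])
}

#' @rdname write_formats
#' @param model a [state_model()].
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(K = model$K, pi = model$pi, A = model$A,
                            E = model$E, marks = model$marks,
                            state_names = model$state_names),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_formats
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  state_model(pi = x$pi, A = x$A, E = x$E, marks = x$marks,
              state_names = x$state_names)
}

#' @rdname write_formats
#' @export
write_emissions_table <- function(model, path) {
  df <- data.frame(`State (Emission order)` = seq_len(model$K),
                   model$E, check.names = FALSE)
  colnames(df)[-1] <- model$marks
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_formats
#' @param segmentation data.frame (chrom, start, end, state).
#' @export
write_segmentation_bed <- function(segmentation, path) {
  out <- segmentation[, c("chrom", "start", "end")]
  out$name <- paste0("E", segmentation$state)
  write_bed(out, path)
}

#' @rdname write_formats
#' @param labels data.frame from [label_states()].
#' @export
write_state_track_bed9 <- function(segmentation, labels, path) {
  nm <- labels$name[match(segmentation$state, labels$state)]
  pal <- state_palette()
  out <- data.frame(chrom = segmentation$chrom, start = segmentation$start,
                    end = segmentation$end, name = nm, score = 0L,
                    strand = ".", thickStart = segmentation$start,
                    thickEnd = segmentation$end,
                    itemRgb = unname(pal[nm]), stringsAsFactors = FALSE)
  write_bed(out, path)
}

#' @rdname write_formats
#' @param x data.frame to write with a header.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
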