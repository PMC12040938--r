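#' Published per-tissue tissue-specific EnhA counts
#'
#' The per-tissue counts of tissue-specific strong active enhancers
#' reported for the five sheep reproductive tissues (ovary, oviduct,
#' cervix, cornua uteri, corpus uteri), bundled as a reference table.
#' Their sum is the published 83,980 tissue-specific EnhA total.
#'
#' @return data.frame with columns tissue and count.
#' @export
#' @examples
#' sum(reported_tsr_counts()$count)
reported_tsr_counts <- function() {
  read.table(system.file("extdata", "published_tsr_counts.tsv",
                         package = "chromatlas"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
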