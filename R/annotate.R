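#' Fifteen chromatin-state names and their six functional categories
#'
#' @return data.frame with columns `name` and `category`.
#' @export
state_vocabulary <- function() {
  data.frame(
    name = c("TssA", "TssAHet", "TssBiv",
             "TxFlnk", "TxFlnkWk", "TxFlnkHet",
             "EnhA", "EnhAMe", "EnhAWk", "EnhAHet", "EnhPois",
             "ATAC_Is", "Repr", "ReprWk", "Qui"),
    category = c(rep("promoter", 3),
                 rep("tss_proximal_transcription", 3),
                 rep("enhancer", 5),
                 "atac_island", rep("repressive", 2), "quiescent"),
    stringsAsFactors = FALSE)
}

# fixed browser palette, one colour per state name
state_palette <- function() {
  c(TssA = "255,0,0", TssAHet = "255,69,0", TssBiv = "205,92,92",
    TxFlnk = "0,128,0", TxFlnkWk = "144,238,144", TxFlnkHet = "60,179,113",
    EnhA = "255,195,77", EnhAMe = "255,215,0", EnhAWk = "255,255,0",
    EnhAHet = "218,165,32", EnhPois = "189,183,107",
    ATAC_Is = "0,191,255", Repr = "128,128,128", ReprWk = "192,192,192",
    Qui = "255,255,255")
}

#' Default emission-to-name rule cascade
#'
#' First-match rule table over binarized emission levels (high = emission
#' probability >= 0.5) of the five marks plus the TSS-enrichment flag
#' (enriched = fold >= 2). Cell values: `1` = must be high/enriched,
#' `0` = must be low/not enriched, `-` = either. The final `Qui` row
#' matches everything, making labelling a total function. A `Repr` match
#' is downgraded to `ReprWk` when the state's H3K27me3 emission is below
#' `wk_fraction` (default 0.75) of the maximum H3K27me3 emission across
#' states.
#'
#' The table is versioned and editable: pass a modified copy (or a TSV read
#' with the same columns) to [label_states()].
#'
#' @return data.frame with columns name, H3K4me3, H3K4me1, H3K27ac,
#'   H3K27me3, ATAC, tss; attribute `version`.
#' @export
default_state_rules <- function() {
  txt <- c(
    # name       m3  m1  ac  me3 at  tss
    "TssBiv       1   -   -   1   -   -",
    "TssA         1   -   -   -   1   1",
    "TssAHet      1   -   -   -   0   1",
    "TxFlnk       1   -   -   -   1   0",
    "TxFlnkHet    1   -   -   -   0   0",
    "EnhPois      -   1   -   1   -   -",
    "TxFlnk       -   1   1   -   1   1",
    "EnhA         -   1   1   -   1   0",
    "EnhAHet      -   1   1   -   0   -",
    "EnhAMe       -   1   0   -   1   -",
    "EnhAMe       -   0   1   -   1   -",
    "EnhAHet      -   0   1   -   0   -",
    "TxFlnkWk     -   1   0   -   0   1",
    "EnhAWk       -   1   0   -   0   0",
    "Repr         -   -   -   1   -   -",
    "ATAC_Is      0   0   0   0   1   -",
    "Qui          -   -   -   -   -   -")
  df <- read.table(text = txt, col.names = c("name", "H3K4me3", "H3K4me1",
                                             "H3K27ac", "H3K27me3", "ATAC",
                                             "tss"),
                   colClasses = "character", stringsAsFactors = FALSE)
  attr(df, "version") <- "1"
  df
}

#' TSS-neighbourhood fold enrichment per state
#'
#' For each state, the fraction of its bases lying within +/- `window_bp`
#' of a TSS divided by the fraction of the (segmented) genome within the
#' same windows. Windows are clipped at chromosome ends and merged where
#' genes overlap. A state with no bases near a TSS (or absent entirely)
#' gets fold 0.
#'
#' @param segmentation data.frame (chrom, start, end, state) covering the
#'   binned genome, 0-based half-open.
#' @param tss_set data.frame with chrom and tss columns (non-empty).
#' @param window_bp half-window around each TSS.
#' @param states state indices to report (defaults to those present);
#'   absent states get fold 0.
#' @return named numeric vector of folds indexed by state.
#' @export
tss_enrichment <- function(segmentation, tss_set, window_bp = 2000L,
                           states = sort(unique(segmentation$state))) {
  if (is.null(tss_set) || nrow(tss_set) == 0L) {
    abort_input("TSS set must be non-empty")
  }
  seg_gr <- bed_to_granges(segmentation)
  chrom_ends <- tapply(segmentation$end, segmentation$chrom, max)
  w0 <- pmax(0L, tss_set$tss - window_bp)
  w1 <- pmin(as.integer(chrom_ends[tss_set$chrom]), tss_set$tss + window_bp)
  win <- GenomicRanges::reduce(bed_to_granges(
    data.frame(chrom = tss_set$chrom, start = w0, end = w1)))
  genome_bases <- sum(as.numeric(segmentation$end - segmentation$start))
  win_bases <- sum(as.numeric(GenomicRanges::width(win)))
  genome_frac <- win_bases / genome_bases

  folds <- vapply(states, function(s) {
    gr <- seg_gr[segmentation$state == s]
    tot <- sum(as.numeric(GenomicRanges::width(gr)))
    if (tot == 0) return(0)
    ov <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(gr, win))))
    (ov / tot) / genome_frac
  }, numeric(1))
  names(folds) <- states
  folds
}

#' Name learned states with the 15-label vocabulary
#'
#' Applies the first-match rule cascade of [default_state_rules()] to each
#' state's binarized emission row (high iff emission >= 0.5) and TSS fold
#' (enriched iff fold >= `fold_cut`). Every state receives exactly one
#' name; several states may share a name.
#'
#' @param model a [state_model()] whose `marks` include H3K4me3, H3K4me1,
#'   H3K27ac, H3K27me3 and ATAC.
#' @param tss_folds per-state fold from [tss_enrichment()], aligned with
#'   state indices.
#' @param rules rule table (defaults to [default_state_rules()]).
#' @param emission_cut,fold_cut the high/enriched thresholds.
#' @param wk_fraction a `Repr` match is downgraded to `ReprWk` when its
#'   H3K27me3 emission is below this fraction of the maximum H3K27me3
#'   emission across states.
#' @return data.frame: state (index), name, category.
#' @export
label_states <- function(model, tss_folds, rules = default_state_rules(),
                         emission_cut = 0.5, fold_cut = 2,
                         wk_fraction = 0.75) {
  validate_state_model(model)
  needed <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "ATAC")
  if (!all(needed %in% model$marks)) {
    abort_input("mark_order must include: ", paste(needed, collapse = ", "))
  }
  if (length(tss_folds) != model$K) {
    abort_input("tss_folds must have one entry per state")
  }
  E <- model$E[, needed, drop = FALSE]
  high <- E >= emission_cut
  flags <- cbind(high, tss = tss_folds >= fold_cut)
  colnames(flags) <- c(needed, "tss")
  me3_max <- max(E[, "H3K27me3"])

  names_out <- character(model$K)
  for (k in seq_len(model$K)) {
    for (r in seq_len(nrow(rules))) {
      want <- unlist(rules[r, colnames(flags)])
      ok <- all(want == "-" | (want == "1") == flags[k, ])
      if (ok) {
        nm <- rules$name[r]
        if (nm == "Repr" && E[k, "H3K27me3"] < wk_fraction * me3_max) {
          nm <- "ReprWk"
        }
        names_out[k] <- nm
        break
      }
    }
  }
  vocab <- state_vocabulary()
  data.frame(state = seq_len(model$K), name = names_out,
             category = vocab$category[match(names_out, vocab$name)],
             stringsAsFactors = FALSE)
}

#' Merge one state's intervals across tissues into non-redundant elements
#'
#' Overlapping and book-ended (adjacent) intervals are merged; the count of
#' merged intervals is the state's non-redundant regulatory element total
#' (NRRET). Idempotent.
#'
#' @param intervals data.frame (chrom, start, end), 0-based half-open;
#'   intervals with `end <= start` are an input error.
#' @return list: `merged` (data.frame chrom, start, end, genomically
#'   sorted), `count`.
#' @export
nonredundant_elements <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(list(merged = intervals[, c("chrom", "start", "end")], count = 0L))
  }
  # reduce() merges book-ended neighbours (min.gapwidth = 1) and sorts
  merged <- GenomicRanges::reduce(bed_to_granges(intervals))
  list(merged = granges_to_bed(merged), count = length(merged))
}

#' Per-state and per-category summary statistics
#'
#' Element counts (number of segmentation intervals, summed over tissues),
#' pooled and tissue-averaged mean element sizes, genome coverage fractions
#' (computed per tissue, averaged across tissues), NRRET (cross-tissue
#' merged element count per state), and a six-category rollup. The
#' regulatory-element total counts all non-quiescent intervals over all
#' tissues (per-tissue, before cross-tissue merging).
#'
#' @param segmentations named list (per tissue) of segmentation data.frames
#'   (chrom, start, end, state) covering the binned genome.
#' @param labels data.frame from [label_states()].
#' @return list: `per_state`, `per_category`, `regulatory_element_total`.
#' @export
summarize_states <- function(segmentations, labels) {
  tissues <- names(segmentations)
  states <- labels$state
  per_tissue_cov <- sapply(tissues, function(ts) {
    seg <- segmentations[[ts]]
    tot <- sum(as.numeric(seg$end - seg$start))
    v <- vapply(states, function(s)
      sum(as.numeric(seg$end[seg$state == s] - seg$start[seg$state == s])) / tot,
      numeric(1))
    v
  })
  counts <- vapply(states, function(s)
    sum(vapply(segmentations, function(seg) sum(seg$state == s), integer(1))),
    integer(1))
  bases <- vapply(states, function(s)
    sum(vapply(segmentations, function(seg)
      sum(as.numeric(seg$end[seg$state == s] - seg$start[seg$state == s])),
      numeric(1))), numeric(1))
  mean_size_tissue <- vapply(states, function(s) {
    per <- vapply(segmentations, function(seg) {
      sel <- seg$state == s
      if (!any(sel)) NA_real_ else mean(seg$end[sel] - seg$start[sel])
    }, numeric(1))
    mean(per, na.rm = TRUE)
  }, numeric(1))
  nrret <- vapply(states, function(s) {
    iv <- do.call(rbind, lapply(segmentations, function(seg)
      seg[seg$state == s, c("chrom", "start", "end")]))
    if (is.null(iv) || nrow(iv) == 0L) 0L else nonredundant_elements(iv)$count
  }, integer(1))

  per_state <- data.frame(
    state = states, name = labels$name, category = labels$category,
    element_count = counts,
    mean_size_pooled_bp = ifelse(counts > 0, bases / counts, NA_real_),
    mean_size_tissue_avg_bp = mean_size_tissue,
    genome_coverage = rowMeans(per_tissue_cov),
    nrret = nrret, stringsAsFactors = FALSE)

  per_category <- do.call(rbind, lapply(split(per_state, per_state$category),
                                        function(d) data.frame(
    category = d$category[1],
    element_count = sum(d$element_count),
    mean_size_pooled_bp = sum(d$element_count * d$mean_size_pooled_bp,
                              na.rm = TRUE) / max(sum(d$element_count), 1),
    genome_coverage = sum(d$genome_coverage),
    stringsAsFactors = FALSE)))
  rownames(per_category) <- NULL

  list(per_state = per_state, per_category = per_category,
       regulatory_element_total =
         sum(per_state$element_count[per_state$category != "quiescent"]))
}
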