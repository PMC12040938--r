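#' Extract one named state's intervals per tissue
#'
#' Convenience bridge from labelled segmentations to the per-tissue EnhA
#' interval sets consumed by [build_rrat()]. Intervals of all states
#' carrying the requested name are pooled (several learned states may share
#' a name).
#'
#' @param segmentations named per-tissue list of segmentation data.frames.
#' @param labels data.frame from [label_states()].
#' @param state_name which name to extract (default "EnhA").
#' @return named list (per tissue) of data.frames (chrom, start, end).
#' @export
state_intervals_by_tissue <- function(segmentations, labels,
                                      state_name = "EnhA") {
  sel_states <- labels$state[labels$name == state_name]
  lapply(segmentations, function(seg) {
    seg[seg$state %in% sel_states, c("chrom", "start", "end")]
  })
}

#' Build the cross-tissue EnhA overlap (RRAT) matrix
#'
#' RRAT regions are the merged (including book-ended) union of every
#' tissue's EnhA intervals. A region scores 1 for a tissue iff at least one
#' of that tissue's EnhA intervals overlaps it by >= 1 bp. By construction
#' no row is all-zero; rows are in genomic order.
#'
#' @param enh_by_tissue named list (per tissue) of data.frames
#'   (chrom, start, end, 0-based half-open).
#' @param tissues ordered tissue names (defaults to the list names); every
#'   list name must be one of them.
#' @return list of class `rrat`: `regions` (data.frame), `matrix`
#'   (regions x tissues, 0/1), `tissues`.
#' @export
build_rrat <- function(enh_by_tissue, tissues = names(enh_by_tissue)) {
  if (is.null(names(enh_by_tissue)) ||
      !all(names(enh_by_tissue) %in% tissues)) {
    abort_input("unknown tissue name in EnhA interval sets")
  }
  all_iv <- do.call(rbind, lapply(enh_by_tissue, function(d)
    d[, c("chrom", "start", "end")]))
  if (is.null(all_iv) || nrow(all_iv) == 0L) {
    return(structure(list(
      regions = data.frame(chrom = character(0), start = integer(0),
                           end = integer(0)),
      matrix = matrix(0L, 0, length(tissues),
                      dimnames = list(NULL, tissues)),
      tissues = tissues), class = "rrat"))
  }
  regions_gr <- GenomicRanges::reduce(bed_to_granges(all_iv))
  mat <- matrix(0L, length(regions_gr), length(tissues),
                dimnames = list(NULL, tissues))
  for (ts in names(enh_by_tissue)) {
    d <- enh_by_tissue[[ts]]
    if (nrow(d) == 0L) next
    hit <- GenomicRanges::countOverlaps(regions_gr, bed_to_granges(d)) > 0
    mat[, ts] <- pmax(mat[, ts], as.integer(hit))
  }
  structure(list(regions = granges_to_bed(regions_gr), matrix = mat,
                 tissues = tissues), class = "rrat")
}

#' Classify RRAT regions into the six TSR modules
#'
#' A region present in exactly one tissue goes to that tissue's specific
#' module; a region present in exactly the three uterine tissues goes to
#' `uterine_common`; every other presence pattern is `unassigned`. The
#' result is a partition: each region gets exactly one module.
#'
#' @param rrat from [build_rrat()].
#' @param uterine_tissues the three uterine tissue names (must be among the
#'   RRAT tissues).
#' @return data.frame: chrom, start, end, module.
#' @export
classify_modules <- function(rrat, uterine_tissues) {
  if (!all(uterine_tissues %in% rrat$tissues) ||
      length(uterine_tissues) != 3L) {
    abort_input("uterine_tissues must be three names among the RRAT tissues")
  }
  mat <- rrat$matrix
  n_on <- rowSums(mat)
  module <- rep("unassigned", nrow(mat))
  one <- n_on == 1
  if (any(one)) {
    which_ts <- rrat$tissues[max.col(mat[one, , drop = FALSE])]
    module[one] <- paste0(which_ts, "_specific")
  }
  is_ut <- rrat$tissues %in% uterine_tissues
  ut_all <- rowSums(mat[, is_ut, drop = FALSE]) == 3 &
    rowSums(mat[, !is_ut, drop = FALSE]) == 0
  module[ut_all] <- "uterine_common"
  cbind(rrat$regions, data.frame(module = module, stringsAsFactors = FALSE))
}

#' Link module regions to target genes through shared TADs
#'
#' A gene is linked to a region iff the gene's TSS and the region's
#' midpoint fall inside the same TAD. Regions whose midpoint lies in no
#' TAD get an empty target set and are flagged. TADs must not overlap.
#'
#' @param modules data.frame from [classify_modules()].
#' @param tads data.frame (chrom, start, end, 0-based half-open),
#'   non-overlapping.
#' @param genes data.frame with chrom, tss and name columns.
#' @return list: `targets` (named list, region id `chrom:start-end` ->
#'   character vector of gene names), `no_tad` (region ids outside any TAD).
#' @export
link_targets <- function(modules, tads, genes) {
  tad_gr <- bed_to_granges(tads)
  ov_self <- GenomicRanges::findOverlaps(tad_gr, drop.self = TRUE,
                                         drop.redundant = TRUE)
  if (length(ov_self)) {
    i <- S4Vectors::queryHits(ov_self)[1]
    j <- S4Vectors::subjectHits(ov_self)[1]
    abort_input(sprintf(
      "overlapping TADs: %s:%d-%d and %s:%d-%d",
      tads$chrom[i], tads$start[i], tads$end[i],
      tads$chrom[j], tads$start[j], tads$end[j]))
  }
  ids <- sprintf("%s:%d-%d", modules$chrom, modules$start, modules$end)
  mid <- (modules$start + modules$end) %/% 2L
  mid_gr <- GenomicRanges::GRanges(modules$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1L,
                                                    genes$tss + 1L))
  reg_tad <- GenomicRanges::findOverlaps(mid_gr, tad_gr, select = "first")
  gene_tad <- GenomicRanges::findOverlaps(tss_gr, tad_gr, select = "first")
  targets <- lapply(seq_along(ids), function(i) {
    if (is.na(reg_tad[i])) return(character(0))
    genes$name[!is.na(gene_tad) & gene_tad == reg_tad[i]]
  })
  names(targets) <- ids
  list(targets = targets, no_tad = ids[is.na(reg_tad)])
}

#' Per-module report: counts, targets and expression ranks
#'
#' For every module, the region count; for every linked target gene, the
#' rank of its expression in the module's tissue among all tissues (rank 1
#' = highest), and whether its top tissue matches the module tissue.
#' Uterine-common genes are ranked by their best uterine tissue. Genes
#' missing from the expression table are reported, not fatal.
#'
#' @param modules data.frame from [classify_modules()].
#' @param links from [link_targets()].
#' @param expression genes x tissues matrix (e.g.
#'   [simulate_expression()]).
#' @param uterine_tissues the three uterine names.
#' @return list: `module_counts` (named vector over the six modules +
#'   unassigned), `gene_ranks` (data.frame module, gene, rank,
#'   top_matches), `missing_genes`.
#' @export
module_report <- function(modules, links, expression,
                          uterine_tissues = c("cervix", "cornua_uteri",
                                              "corpus_uteri")) {
  tissues <- colnames(expression)
  all_modules <- c(paste0(tissues, "_specific"), "uterine_common",
                   "unassigned")
  module_counts <- setNames(integer(length(all_modules)), all_modules)
  tab <- table(modules$module)
  module_counts[names(tab)] <- as.integer(tab)

  ids <- sprintf("%s:%d-%d", modules$chrom, modules$start, modules$end)
  rows <- list(); missing <- character(0)
  for (i in seq_along(ids)) {
    mod <- modules$module[i]
    if (mod == "unassigned") next
    gs <- links$targets[[ids[i]]]
    for (g in gs) {
      if (!(g %in% rownames(expression))) {
        missing <- c(missing, g)
        next
      }
      v <- expression[g, ]
      rk <- rank(-v, ties.method = "min")
      ts <- if (mod == "uterine_common") {
        uterine_tissues[which.min(rk[uterine_tissues])]
      } else sub("_specific$", "", mod)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, region = ids[i], gene = g, rank = unname(rk[ts]),
        top_matches = rk[ts] == 1L, stringsAsFactors = FALSE)
    }
  }
  gene_ranks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), region = character(0),
               gene = character(0), rank = integer(0),
               top_matches = logical(0))
  list(module_counts = module_counts, gene_ranks = gene_ranks,
       missing_genes = unique(missing))
}
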