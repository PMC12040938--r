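#' Binned signal track
#'
#' Per-chromosome ordered bin values (raw counts or normalized signal) for
#' one mark, tissue and replicate.
#'
#' @param values numeric vector, one value per bin.
#' @param chrom chromosome name.
#' @param bin_size_bp bin width in bp.
#' @param mark,tissue assay metadata.
#' @param replicate replicate index (NA once replicates are pooled).
#' @return list of class `binned_track`.
#' @export
binned_track <- function(values, chrom, bin_size_bp, mark = NA_character_,
                         tissue = NA_character_, replicate = NA_integer_) {
  structure(list(chrom = chrom, bin_size_bp = as.integer(bin_size_bp),
                 values = as.numeric(values), mark = mark, tissue = tissue,
                 replicate = replicate),
            class = "binned_track")
}

#' Bin reads (intervals) into fixed-width genomic bins
#'
#' Each read is assigned to the bin containing its midpoint; a bin's value
#' is the number of read midpoints it contains. The last partial bin is
#' kept.
#'
#' @param reads data.frame with chrom, start, end (0-based half-open).
#' @param chrom chromosome to bin.
#' @param chrom_length_bp chromosome length.
#' @param bin_size_bp bin width.
#' @param ... metadata passed to [binned_track()].
#' @return a [binned_track()] of counts.
#' @export
bin_reads <- function(reads, chrom, chrom_length_bp, bin_size_bp, ...) {
  n_bins <- as.integer(ceiling(chrom_length_bp / bin_size_bp))
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  if (nrow(r) && any(r$end > chrom_length_bp | r$start < 0)) {
    bad <- which(r$end > chrom_length_bp | r$start < 0)[1L]
    abort_input(sprintf("read %d (%s:%d-%d) lies outside chromosome bounds",
                        bad, chrom, r$start[bad], r$end[bad]))
  }
  counts <- integer(n_bins)
  if (nrow(r)) {
    mid <- (r$start + r$end) %/% 2L
    idx <- pmin(mid %/% bin_size_bp, n_bins - 1L) + 1L
    tab <- tabulate(idx, nbins = n_bins)
    counts <- tab
  }
  binned_track(counts, chrom, bin_size_bp, ...)
}

#' Z-score normalize a track
#'
#' Centers to mean 0 and scales to sample SD 1 (denominator n - 1). A
#' constant track (SD 0) maps to all zeros. Idempotent on non-degenerate
#' input.
#'
#' @param track a [binned_track()] (non-empty).
#' @return the normalized [binned_track()].
#' @export
zscore_track <- function(track) {
  v <- track$values
  if (!length(v)) abort_input("track must be non-empty")
  s <- sd(v)
  track$values <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  track
}

#' Pearson correlation matrix across tracks
#'
#' Tracks are concatenated genome-wide (the caller supplies one track per
#' sample, already spanning the same bins in the same order).
#'
#' @param tracks list of [binned_track()] with identical binning/length.
#' @return symmetric matrix of Pearson r, unit diagonal, labelled
#'   `tissue.mark.replicate`.
#' @export
pairwise_correlation <- function(tracks) {
  lens <- vapply(tracks, function(t) length(t$values), integer(1))
  bins <- vapply(tracks, function(t) t$bin_size_bp, integer(1))
  if (length(unique(lens)) != 1L || length(unique(bins)) != 1L) {
    abort_input("tracks must share binning and genome")
  }
  X <- vapply(tracks, function(t) t$values, numeric(lens[1]))
  colnames(X) <- vapply(tracks, function(t)
    paste(t$tissue, t$mark, t$replicate, sep = "."), character(1))
  r <- cor(X)
  diag(r) <- 1
  r
}

#' PCA over tracks
#'
#' Samples are tracks, features are bins; data are centered per bin
#' before the decomposition.
#'
#' @param tracks list of [binned_track()] (at least 2).
#' @param n_components number of components to retain (at most the number
#'   of tracks).
#' @return list: `scores` (tracks x components), `explained_variance`
#'   (fractions, non-increasing, summing to at most 1).
#' @export
pca_tracks <- function(tracks, n_components = 2L) {
  if (length(tracks) < 2L) abort_input("need at least two tracks")
  if (n_components > length(tracks)) {
    abort_input("n_components exceeds track count")
  }
  X <- t(vapply(tracks, function(t) t$values,
                numeric(length(tracks[[1]]$values))))
  rownames(X) <- vapply(tracks, function(t)
    paste(t$tissue, t$mark, t$replicate, sep = "."), character(1))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)])
}

#' Pool replicate tracks by per-bin count sum
#'
#' @param tracks list of count [binned_track()]s.
#' @return list of pooled tracks, one per (tissue, mark, chrom), replicate
#'   set to NA.
#' @export
pool_replicates <- function(tracks) {
  key <- vapply(tracks, function(t) paste(t$tissue, t$mark, t$chrom, sep = "\r"),
                character(1))
  lapply(split(tracks, factor(key, levels = unique(key))), function(grp) {
    v <- Reduce(`+`, lapply(grp, function(t) t$values))
    t1 <- grp[[1]]
    binned_track(v, t1$chrom, t1$bin_size_bp, t1$mark, t1$tissue, NA_integer_)
  })
}

#' Poisson binarization threshold
#'
#' Smallest integer `c >= 1` with upper-tail probability
#' `P(X >= c | Poisson(lambda)) <= p`.
#'
#' @param lambda Poisson mean (genome-wide mean count per bin).
#' @param p_threshold tail probability cut (ChromHMM-style default 1e-4).
#' @return integer threshold.
#' @export
poisson_threshold <- function(lambda, p_threshold = 1e-4) {
  if (lambda < 0) abort_input("lambda must be non-negative")
  if (lambda == 0) return(1L)
  cc <- 1L
  # P(X >= c) = 1 - P(X <= c-1); walk up from 1 (tail is decreasing in c)
  while (ppois(cc - 1L, lambda, lower.tail = FALSE) > p_threshold) {
    cc <- cc + 1L
  }
  cc
}

#' Binarize a pooled count track against a Poisson background
#'
#' The background rate is estimated as the track-wide mean count per bin
#' (callers estimating a genome-wide rate across chromosomes can pass it
#' via `lambda`). A bin is called 1 iff its count reaches the
#' [poisson_threshold()]; the threshold is at least 1, so all-zero bins are
#' never called.
#'
#' @param track a count [binned_track()] (pooled across replicates).
#' @param p_threshold tail probability cut.
#' @param lambda optional externally estimated background rate.
#' @return a [binned_track()] whose values are 0/1 calls, with attributes
#'   `lambda` and `threshold`.
#' @export
binarize_poisson <- function(track, p_threshold = 1e-4, lambda = NULL) {
  v <- track$values
  if (any(v < 0) || any(v != floor(v))) {
    abort_input("counts must be non-negative integers")
  }
  if (is.null(lambda)) lambda <- mean(v)
  if (is.na(lambda) || lambda == 0) {
    warning("all-zero track: lambda-hat = 0, emitting all-zero calls",
            call. = FALSE)
    calls <- rep(0L, length(v))
    thr <- 1L
  } else {
    thr <- poisson_threshold(lambda, p_threshold)
    calls <- as.integer(v >= thr)
  }
  out <- binned_track(calls, track$chrom, track$bin_size_bp, track$mark,
                      track$tissue, NA_integer_)
  attr(out, "lambda") <- lambda
  attr(out, "threshold") <- thr
  out
}

#' Binarize all marks of all tissues into observation matrices
#'
#' Pools replicates per (tissue, mark), estimates one genome-wide Poisson
#' background per tissue/mark over all chromosomes, binarizes, and
#' assembles per-(tissue, chromosome) bins x marks observation matrices —
#' the HMM input.
#'
#' @param tracks list of count [binned_track()]s (replicate-level).
#' @param marks ordered mark names (column order of the result).
#' @param p_threshold tail probability cut.
#' @return list of [observation_matrix()], one per tissue x chromosome.
#' @export
binarize_tracks <- function(tracks, marks, p_threshold = 1e-4) {
  pooled <- pool_replicates(tracks)
  tissues <- unique(vapply(pooled, function(t) t$tissue, character(1)))
  chroms <- unique(vapply(pooled, function(t) t$chrom, character(1)))
  out <- list()
  for (ts in tissues) {
    # lambda per mark over all chromosomes of this tissue
    calls <- list()
    for (mk in marks) {
      sel <- Filter(function(t) t$tissue == ts && t$mark == mk, pooled)
      if (!length(sel)) abort_input("no tracks for tissue ", ts, " mark ", mk)
      lam <- mean(unlist(lapply(sel, function(t) t$values)))
      calls[[mk]] <- lapply(sel, binarize_poisson,
                            p_threshold = p_threshold, lambda = lam)
      names(calls[[mk]]) <- vapply(sel, function(t) t$chrom, character(1))
    }
    for (ch in chroms) {
      mat <- vapply(marks, function(mk) calls[[mk]][[ch]]$values,
                    numeric(length(calls[[marks[1]]][[ch]]$values)))
      out[[paste(ts, ch, sep = ".")]] <-
        observation_matrix(mat, marks, ts, ch)
    }
  }
  out
}
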