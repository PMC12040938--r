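#' Position weight matrix
#'
#' Per-position base probabilities over (A, C, G, T) with a background
#' distribution. Probabilities are floored at 1e-3 (pseudo-probability) and
#' rows renormalized before log-odds scoring so that mismatches stay
#' finite.
#'
#' @param matrix w x 4 matrix of probabilities, columns A, C, G, T; rows
#'   sum to 1.
#' @param name motif name.
#' @param background length-4 background probabilities (default uniform).
#' @return list of class `pwm`.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) abort_input("PWM must have 4 columns (A,C,G,T)")
  if (max(abs(rowSums(matrix) - 1)) > 1e-9) {
    abort_input("PWM rows must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9) {
    abort_input("background must sum to 1")
  }
  matrix <- pmax(matrix, 1e-3)
  matrix <- matrix / rowSums(matrix)
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = name, width = nrow(matrix), matrix = matrix,
                 background = pmax(as.numeric(background), 1e-3)),
            class = "pwm")
}

#' @rdname pwm
#' @param x a `pwm`.
#' @return `pwm_consensus`: the consensus string (per-position argmax base,
#'   ties to the alphabetically first base).
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[max.col(x$matrix, ties.method = "first")],
        collapse = "")
}

#' Build a sharp PWM from a consensus sequence
#'
#' Each position puts probability `1 - 3 * off` on the consensus base.
#'
#' @param consensus DNA string over A/C/G/T.
#' @param name motif name.
#' @param off per-off-base probability (default 1e-3, the pseudo-probability
#'   floor).
#' @return a [pwm()].
#' @export
consensus_pwm <- function(consensus, name = consensus, off = 1e-3) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort_input("consensus must be over A/C/G/T")
  }
  m <- matrix(off, length(bases), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <-
    1 - 3 * off
  pwm(m, name = name)
}

#' Read / write PWMs in simple matrix text
#'
#' Format: one block per motif — a `>name` header line followed by `w`
#' lines of four whitespace-separated probabilities (A C G T order),
#' blank-line separated.
#'
#' @param path file path.
#' @return `read_pwms`: named list of [pwm()].
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) abort_input("no PWM blocks in ", path)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    nm <- sub("^>\\s*", "", lines[starts[i]])
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    out[[nm]] <- pwm(m, name = nm)
  }
  out
}

#' @rdname read_pwms
#' @param pwms named list of [pwm()].
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    utils::write.table(format(p$matrix, digits = 6), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Scan a sequence with a PWM
#'
#' Window score = sum over positions of `log2(p_i(base) / bg(base))`; a hit
#' is any window scoring at least `score_fraction` times the maximum
#' attainable score. Both strands are scanned; hits are reported with
#' forward-strand offsets (1-based). Windows containing N are skipped.
#'
#' @param sequence DNA string (character or [Biostrings::DNAString]) over
#'   A/C/G/T/N.
#' @param pwm a [pwm()].
#' @param score_fraction fraction of the maximum score required for a hit.
#' @return data.frame: offset, strand ("+"/"-"), score. Empty when the
#'   sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, score_fraction = 0.8) {
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  w <- pwm$width
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < w) return(empty)
  code <- match(strsplit(seq_chr, "")[[1]], c("A", "C", "G", "T"))  # N -> NA
  lo <- log2(pwm$matrix / matrix(pwm$background, w, 4, byrow = TRUE))
  max_score <- sum(apply(lo, 1, max))
  thr <- score_fraction * max_score
  n_win <- n - w + 1L

  score_strand <- function(mat) {
    s <- numeric(n_win)
    for (i in seq_len(w)) s <- s + mat[i, ][code[seq_len(n_win) + i - 1L]]
    s
  }
  fwd <- score_strand(lo)
  # reverse strand: score the reverse complement of each window, which
  # equals scanning with the reverse-complemented PWM on the forward text
  lo_rc <- lo[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
  rev_s <- score_strand(lo_rc)

  fi <- which(!is.na(fwd) & fwd >= thr)
  ri <- which(!is.na(rev_s) & rev_s >= thr)
  hits <- data.frame(offset = c(fi, ri),
                     strand = rep(c("+", "-"), c(length(fi), length(ri))),
                     score = c(fwd[fi], rev_s[ri]))
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# upper-tail hypergeometric p-value for foreground enrichment:
# P(X >= fg_hits) with X ~ Hypergeom(total present, total absent, fg_total)
hyper_p <- function(fg_hits, fg_total, bg_hits, bg_total) {
  phyper(fg_hits - 1, fg_hits + bg_hits,
         (fg_total - fg_hits) + (bg_total - bg_hits), fg_total,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: `q_(i) = min_{j >= i} min(1, m p_(j) / j)`, mapped back to
#' the input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_input("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

rank_results <- function(df) {
  df <- df[order(df$p_value, df$item), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Motif enrichment of foreground vs background sequences
#'
#' The counting unit is presence/absence: a sequence counts once if it
#' contains at least one hit. Per motif, a one-sided hypergeometric
#' upper-tail p-value of foreground presence given pooled presence, BH
#' adjustment across motifs, significance at `q < alpha`, and the top five
#' significant motifs by rank (ascending p, ties broken by name).
#'
#' @param fg_sequences,bg_sequences [Biostrings::DNAStringSet] or character
#'   vectors (both non-empty).
#' @param pwms named list of [pwm()].
#' @param alpha FDR gate.
#' @param score_fraction passed to [scan_pwm()].
#' @return list: `results` (data.frame item, fg_hits, fg_total, bg_hits,
#'   bg_total, p_value, q_value, significant, rank), `top5` (character
#'   vector of up to five significant motif names).
#' @export
motif_enrichment <- function(fg_sequences, bg_sequences, pwms, alpha = 0.05,
                             score_fraction = 0.8) {
  if (!length(fg_sequences) || !length(bg_sequences)) {
    abort_input("foreground and background must be non-empty")
  }
  fg <- as.character(fg_sequences)
  bg <- as.character(bg_sequences)
  present <- function(seqs, p) {
    vapply(seqs, function(s) nrow(scan_pwm(s, p, score_fraction)) > 0,
           logical(1), USE.NAMES = FALSE)
  }
  rows <- lapply(pwms, function(p) {
    if (p$width > max(nchar(c(fg, bg)))) {
      return(data.frame(item = p$name, fg_hits = 0L, fg_total = length(fg),
                        bg_hits = 0L, bg_total = length(bg), p_value = 1))
    }
    fh <- sum(present(fg, p))
    bh <- sum(present(bg, p))
    data.frame(item = p$name, fg_hits = fh, fg_total = length(fg),
               bg_hits = bh, bg_total = length(bg),
               p_value = hyper_p(fh, length(fg), bh, length(bg)))
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  res <- rank_results(res)
  list(results = res,
       top5 = head(res$item[res$significant], 5L))
}

#' Hypergeometric term enrichment of target genes
#'
#' One-sided upper-tail hypergeometric test per term (annotated targets vs
#' annotated universe), BH across tested terms. Terms annotating no
#' universe gene are skipped.
#'
#' @param target_genes character vector, subset of `universe`.
#' @param universe all genes considered.
#' @param term_map data.frame with columns `gene` and `term`.
#' @param alpha FDR gate.
#' @return data.frame: item, fg_hits, fg_total, bg_hits, bg_total, p_value,
#'   q_value, significant, rank (empty for an empty target set).
#' @export
term_enrichment <- function(target_genes, universe, term_map, alpha = 0.05) {
  if (!all(target_genes %in% universe)) {
    abort_input("target genes outside the universe: ",
                paste(head(setdiff(target_genes, universe)), collapse = ", "))
  }
  empty <- data.frame(item = character(0), fg_hits = integer(0),
                      fg_total = integer(0), bg_hits = integer(0),
                      bg_total = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0),
                      rank = integer(0))
  if (!length(target_genes)) return(empty)
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  if (!nrow(tm)) return(empty)
  target_genes <- unique(target_genes)
  n_t <- length(target_genes)
  n_bg <- length(universe) - n_t
  rows <- lapply(split(tm$gene, tm$term), function(g) {
    g <- unique(g)
    fh <- sum(g %in% target_genes)
    data.frame(fg_hits = fh, fg_total = n_t,
               bg_hits = length(g) - fh, bg_total = n_bg,
               p_value = hyper_p(fh, n_t, length(g) - fh, n_bg))
  })
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(item = names(rows), stringsAsFactors = FALSE), res)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  rank_results(res)
}
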