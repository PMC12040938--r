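#' Configuration for the synthetic multi-tissue epigenome generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genome()], [simulate_state_paths()], [simulate_mark_counts()],
#' [simulate_expression()] and [simulate_epigenome()]. The defaults emulate
#' the design of a five-tissue reproductive epigenome study: five tissues
#' (ovary, oviduct and the three uterine compartments), two replicates, four
#' histone marks plus ATAC, and an RNA assay per tissue/replicate — 60
#' libraries in total (see [library_design()]).
#'
#' Counts are Poisson: `background_rate` reads/bin where a mark is absent and
#' `enriched_rate` where present, with per-bin mark presence drawn Bernoulli
#' from the true state's emission probability.
#'
#' @param seed integer seed; every simulation output is a pure function of
#'   the configuration including this seed.
#' @param n_chromosomes,chrom_length_bp genome shape; `chrom_length_bp` must
#'   be divisible by `bin_size_bp`.
#' @param bin_size_bp genomic bin width in bp (200 by convention).
#' @param tissues ordered tissue names; must contain the three uterine names
#'   when `uterine_common_enhancers > 0`.
#' @param uterine_tissues the three names forming the uterine-common module.
#' @param n_replicates replicates per tissue and assay.
#' @param marks ordered epigenomic mark names.
#' @param n_states number of chromatin states in the default true model.
#' @param background_rate,enriched_rate Poisson means (reads/bin) for
#'   mark-absent and mark-present bins; `enriched_rate > background_rate > 0`.
#' @param n_genes,n_tads gene count (genome-wide) and TAD count per
#'   chromosome.
#' @param planted_specific_enhancers_per_tissue,uterine_common_enhancers
#'   numbers of planted EnhA blocks per tissue-specific module and for the
#'   shared uterine module.
#' @param enhancer_block_bp planted block width (bin-aligned).
#' @param tss_exclusion_bp margin from chromosome ends kept free of TSSs.
#' @param tss_promoter_state plant the promoter-like state around every TSS
#'   in all tissues so that promoter states are genuinely TSS-enriched.
#' @param expression_fold,expression_noise_sd,expression_baseline expression
#'   model: genes TAD-linked to a planted enhancer get
#'   `expression_baseline * expression_fold` mean expression in the planted
#'   tissue(s), log-normal noise with `sdlog = expression_noise_sd`.
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' nrow(library_design(cfg))  # 60
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_length_bp = 1500000L,
                             bin_size_bp = 200L,
                             tissues = c("ovary", "oviduct", "cervix",
                                         "cornua_uteri", "corpus_uteri"),
                             uterine_tissues = c("cervix", "cornua_uteri",
                                                 "corpus_uteri"),
                             n_replicates = 2L,
                             marks = c("H3K4me3", "H3K4me1", "H3K27ac",
                                       "H3K27me3", "ATAC"),
                             n_states = 6L,
                             background_rate = 1,
                             enriched_rate = 10,
                             n_genes = 150L,
                             n_tads = 10L,
                             planted_specific_enhancers_per_tissue = 20L,
                             uterine_common_enhancers = 8L,
                             enhancer_block_bp = 2000L,
                             tss_exclusion_bp = 10000L,
                             tss_promoter_state = TRUE,
                             expression_fold = 8,
                             expression_noise_sd = 0.2,
                             expression_baseline = 10) {
  cfg <- list(
    seed = check_positive_int(seed, "seed"),
    n_chromosomes = check_positive_int(n_chromosomes, "n_chromosomes"),
    chrom_length_bp = check_positive_int(chrom_length_bp, "chrom_length_bp"),
    bin_size_bp = check_positive_int(bin_size_bp, "bin_size_bp"),
    tissues = as.character(tissues),
    uterine_tissues = as.character(uterine_tissues),
    n_replicates = check_positive_int(n_replicates, "n_replicates"),
    marks = as.character(marks),
    n_states = check_positive_int(n_states, "n_states"),
    background_rate = background_rate,
    enriched_rate = enriched_rate,
    n_genes = check_positive_int(n_genes, "n_genes"),
    n_tads = check_positive_int(n_tads, "n_tads"),
    planted_specific_enhancers_per_tissue =
      as.integer(planted_specific_enhancers_per_tissue),
    uterine_common_enhancers = as.integer(uterine_common_enhancers),
    enhancer_block_bp = check_positive_int(enhancer_block_bp, "enhancer_block_bp"),
    tss_exclusion_bp = as.integer(tss_exclusion_bp),
    tss_promoter_state = isTRUE(tss_promoter_state),
    expression_fold = expression_fold,
    expression_noise_sd = expression_noise_sd,
    expression_baseline = expression_baseline)
  if (cfg$chrom_length_bp %% cfg$bin_size_bp != 0L) {
    abort_input("chrom_length_bp must be divisible by bin_size_bp")
  }
  if (!(cfg$enriched_rate > cfg$background_rate && cfg$background_rate > 0)) {
    abort_input("need enriched_rate > background_rate > 0")
  }
  if (anyDuplicated(cfg$tissues)) abort_input("duplicate tissue names")
  if (cfg$uterine_common_enhancers > 0 &&
      !all(cfg$uterine_tissues %in% cfg$tissues)) {
    abort_input("tissues must contain the three uterine names when ",
                "uterine_common_enhancers > 0")
  }
  if (cfg$planted_specific_enhancers_per_tissue < 0 ||
      cfg$uterine_common_enhancers < 0) {
    abort_input("planted enhancer counts must be non-negative")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' The 60-library design implied by a configuration
#'
#' One row per sequencing library: each tissue x replicate combination
#' carries every epigenomic mark plus one RNA library. Under the default
#' configuration this is 5 tissues x 2 replicates x (4 histone marks +
#' ATAC + RNA) = 60 libraries.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns tissue, replicate, assay.
#' @export
library_design <- function(config) {
  assays <- c(config$marks, "RNA")
  out <- expand.grid(assay = assays, replicate = seq_len(config$n_replicates),
                     tissue = config$tissues, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("tissue", "replicate", "assay")]
}

#' Default true chromatin-state model for simulation
#'
#' Six states over the five default marks: Qui (nothing), TssA
#' (H3K4me3/H3K27ac/ATAC), TxFlnk (H3K4me3/H3K4me1/ATAC), EnhA
#' (H3K4me1/H3K27ac/ATAC), ATAC_Is (ATAC only) and Repr (H3K27me3 only).
#' Emission probabilities are well separated (0.05/0.95). Transitions are
#' sticky (self-probability 0.9) with off-diagonal mass proportional to
#' stationary weights dominated by Qui; the baseline EnhA stationary mass is
#' deliberately small (0.4%) because EnhA is mainly introduced by planted
#' blocks.
#'
#' @param marks mark names, must include the five defaults.
#' @return A [state_model()] with `state_names` set.
#' @export
default_true_model <- function(marks = c("H3K4me3", "H3K4me1", "H3K27ac",
                                         "H3K27me3", "ATAC")) {
  states <- c("Qui", "TssA", "TxFlnk", "EnhA", "ATAC_Is", "Repr")
  lo <- 0.05; hi <- 0.95
  E <- rbind(
    Qui     = c(lo, lo, lo, lo, lo),
    TssA    = c(hi, lo, hi, lo, hi),
    TxFlnk  = c(hi, hi, lo, lo, hi),
    EnhA    = c(lo, hi, hi, lo, hi),
    ATAC_Is = c(lo, lo, lo, lo, hi),
    Repr    = c(lo, lo, lo, hi, lo))
  colnames(E) <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "ATAC")
  E <- E[, marks, drop = FALSE]
  w <- c(Qui = 0.845, TssA = 0.022, TxFlnk = 0.035, EnhA = 0.004,
         ATAC_Is = 0.028, Repr = 0.066)
  A <- 0.9 * diag(6) + 0.1 * matrix(w, 6, 6, byrow = TRUE)
  state_model(pi = w, A = A, E = E, marks = marks, state_names = states)
}

#' Simulate a genome with genes and TADs
#'
#' Chromosome sizes come from the configuration; genes are placed uniformly
#' at random (TSS at the start on + strand, at end-1 on - strand) outside a
#' margin from chromosome ends; TADs tile each chromosome contiguously
#' without gaps or overlap, with bin-aligned random breakpoints.
#'
#' @param config a [synthetic_config()].
#' @return list of class `genome_model` with elements `chrom_sizes`
#'   (data.frame chrom, length), `genes` (BED6-style data.frame with an
#'   extra `tss` column, 0-based half-open), `tads` (BED3-style data.frame).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    sizes <- data.frame(chrom = chroms, length = config$chrom_length_bp,
                        stringsAsFactors = FALSE)

    # TADs: random bin-aligned breakpoints, min 10 bins per TAD
    bin <- config$bin_size_bp
    n_bins <- config$chrom_length_bp %/% bin
    if (config$n_tads * 10L > n_bins) {
      abort_input("n_tads too large for chromosome length")
    }
    tads <- do.call(rbind, lapply(chroms, function(ch) {
      if (config$n_tads == 1L) {
        cuts <- integer(0)
      } else {
        # sample interior breakpoints keeping every TAD >= 10 bins
        slack <- n_bins - config$n_tads * 10L
        gaps <- stats::rmultinom(1, slack, rep(1, config$n_tads))[, 1]
        cuts <- cumsum(10L + gaps)[-config$n_tads]
      }
      bounds <- c(0L, cuts, n_bins) * bin
      data.frame(chrom = ch, start = bounds[-length(bounds)],
                 end = bounds[-1], stringsAsFactors = FALSE)
    }))

    # genes: chromosome chosen proportional to length, TSS uniform in the
    # allowed interior, body 1-10 kb clamped to chromosome bounds
    margin <- config$tss_exclusion_bp
    gchrom <- sample(chroms, config$n_genes, replace = TRUE)
    tss <- floor(runif(config$n_genes, margin,
                       config$chrom_length_bp - margin))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    glen <- floor(runif(config$n_genes, 1000, 10000))
    gstart <- ifelse(strand == "+", tss, pmax(0, tss - glen + 1))
    gend <- ifelse(strand == "+",
                   pmin(config$chrom_length_bp, tss + glen), tss + 1)
    genes <- data.frame(chrom = gchrom, start = as.integer(gstart),
                        end = as.integer(gend),
                        name = sprintf("gene%03d", seq_len(config$n_genes)),
                        score = 0L, strand = strand, tss = as.integer(tss),
                        stringsAsFactors = FALSE)
    genes <- genes[order(genes$chrom, genes$start), ]
    rownames(genes) <- NULL

    structure(list(chrom_sizes = sizes, genes = genes, tads = tads),
              class = "genome_model")
  })
}

# sample a Markov chain of length n (1-based state indices)
sample_markov <- function(n, pi, A) {
  if (n == 0L) return(integer(0))
  K <- length(pi)
  path <- integer(n)
  cumA <- t(apply(A, 1, cumsum))
  u <- runif(n)
  path[1] <- findInterval(u[1], cumsum(pi), left.open = TRUE) + 1L
  for (t in 2:n) {
    path[t] <- findInterval(u[t], cumA[path[t - 1], ], left.open = TRUE) + 1L
  }
  path
}

#' Simulate per-tissue chromatin-state paths with planted enhancer modules
#'
#' Baseline state paths are sampled per tissue from the true Markov chain.
#' Planted EnhA blocks then overwrite the path with the EnhA state in
#' exactly the designated tissue(s): `planted_specific_enhancers_per_tissue`
#' blocks per tissue for the five tissue-specific modules, and
#' `uterine_common_enhancers` blocks written into all three uterine tissues
#' (and no others). Every block lies fully inside one TAD and blocks are
#' mutually separated by at least two bins so that modules cannot merge.
#' When `tss_promoter_state` is on, a +/-2-bin window around every TSS is
#' set to the promoter-like state in all tissues.
#'
#' @param true_model a [state_model()] with `state_names` including "EnhA"
#'   (and the promoter state name when `tss_promoter_state` is on).
#' @param genome a `genome_model` from [simulate_genome()].
#' @param config a [synthetic_config()].
#' @return list of class `ground_truth`: `true_model`, `state_paths`
#'   (per tissue, per chromosome integer vectors), `planted_enhancers`
#'   (data.frame chrom, start, end, module, id), `enhancer_target_genes`
#'   (named list id -> gene names, same-TAD TSSs), `planted_promoters`.
#' @export
simulate_state_paths <- function(true_model, genome, config) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(genome, "genome_model"))
  validate_state_model(true_model)
  if (max(abs(rowSums(true_model$A) - 1)) > 1e-9) {
    abort_input("transition matrix rows must sum to 1")
  }
  sn <- true_model$state_names
  if (is.null(sn) || !("EnhA" %in% sn)) {
    abort_input("true model must name an 'EnhA' state")
  }
  enh_state <- match("EnhA", sn)
  prom_state <- match("TssA", sn)

  bin <- config$bin_size_bp
  chroms <- genome$chrom_sizes$chrom
  n_bins <- genome$chrom_sizes$length %/% bin
  names(n_bins) <- chroms

  withr::with_seed(config$seed + 1L, {
    paths <- lapply(config$tissues, function(ts) {
      p <- lapply(chroms, function(ch) {
        sample_markov(n_bins[[ch]], true_model$pi, true_model$A)
      })
      names(p) <- chroms
      p
    })
    names(paths) <- config$tissues

    # promoter windows (bins, all tissues)
    prom <- NULL
    if (config$tss_promoter_state && nrow(genome$genes)) {
      if (is.na(prom_state)) abort_input("true model must name a 'TssA' state")
      pb0 <- pmax(0L, genome$genes$tss %/% bin - 2L)
      pb1 <- pmin(n_bins[genome$genes$chrom] - 1L, genome$genes$tss %/% bin + 2L)
      prom <- data.frame(chrom = genome$genes$chrom,
                         start = pb0 * bin, end = (pb1 + 1L) * bin,
                         stringsAsFactors = FALSE)
      for (i in seq_len(nrow(prom))) {
        for (ts in config$tissues) {
          paths[[ts]][[prom$chrom[i]]][(pb0[i]:pb1[i]) + 1L] <- prom_state
        }
      }
    }

    # candidate planting slots: inside a TAD, clear of TSS windows
    block_bins <- ceiling(config$enhancer_block_bp / bin)
    modules <- c(paste0(config$tissues, "_specific"),
                 if (config$uterine_common_enhancers > 0) "uterine_common")
    wanted <- c(rep(config$planted_specific_enhancers_per_tissue,
                    length(config$tissues)),
                if (config$uterine_common_enhancers > 0)
                  config$uterine_common_enhancers)
    names(wanted) <- modules

    occupied <- lapply(chroms, function(ch) logical(n_bins[[ch]]))
    names(occupied) <- chroms
    if (!is.null(prom)) {
      for (i in seq_len(nrow(prom))) {
        occupied[[prom$chrom[i]]][(prom$start[i] %/% bin + 1L):
                                    (prom$end[i] %/% bin)] <- TRUE
      }
    }

    planted <- list(); targets <- list(); idx <- 0L
    tad_of <- genome$tads
    for (m in seq_along(modules)) {
      module <- modules[m]
      for (k in seq_len(wanted[[module]])) {
        placed <- FALSE
        for (try in 1:2000) {
          ti <- sample.int(nrow(tad_of), 1L)
          ch <- tad_of$chrom[ti]
          b0 <- tad_of$start[ti] %/% bin
          b1 <- tad_of$end[ti] %/% bin  # exclusive
          # keep one bin off each TAD edge
          lo <- b0 + 1L; hi <- b1 - 1L - block_bins
          if (hi < lo) next
          s <- sample(lo:hi, 1L)
          span <- (s - 1L):(s + block_bins)  # block + 1-bin guard each side
          span <- span[span >= 0 & span < n_bins[[ch]]]
          if (any(occupied[[ch]][span + 1L])) next
          occupied[[ch]][span + 1L] <- TRUE
          idx <- idx + 1L
          id <- sprintf("enh%03d", idx)
          planted[[idx]] <- data.frame(
            chrom = ch, start = s * bin, end = (s + block_bins) * bin,
            module = module, id = id, stringsAsFactors = FALSE)
          target_tissues <- if (module == "uterine_common") {
            config$uterine_tissues
          } else sub("_specific$", "", module)
          for (ts in target_tissues) {
            paths[[ts]][[ch]][(s:(s + block_bins - 1L)) + 1L] <- enh_state
          }
          g <- genome$genes
          in_tad <- g$chrom == ch & g$tss >= tad_of$start[ti] &
            g$tss < tad_of$end[ti]
          targets[[id]] <- g$name[in_tad]
          placed <- TRUE
          break
        }
        if (!placed) {
          abort_input("requested plantings exceed genome capacity ",
                      sprintf("(module %s, block %d)", module, k))
        }
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 module = character(0), id = character(0))

    structure(list(true_model = true_model, state_paths = paths,
                   planted_enhancers = planted,
                   enhancer_target_genes = targets,
                   planted_promoters = prom,
                   genome = genome, config = config),
              class = "ground_truth")
  })
}

#' Simulate Poisson mark counts from ground-truth state paths
#'
#' For every tissue x replicate x mark x chromosome, per-bin mark presence
#' is drawn Bernoulli from the true state's emission probability, then the
#' read count is Poisson(`enriched_rate`) where present and
#' Poisson(`background_rate`) otherwise. Replicates are independent draws.
#'
#' @param ground_truth from [simulate_state_paths()].
#' @param config a [synthetic_config()].
#' @return flat list of [binned_track()] objects.
#' @export
simulate_mark_counts <- function(ground_truth, config) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  E <- ground_truth$true_model$E
  if (any(E < 0 | E > 1)) abort_input("emission probabilities must be in [0,1]")
  withr::with_seed(config$seed + 2L, {
    tracks <- list()
    for (ts in config$tissues) {
      for (rep_i in seq_len(config$n_replicates)) {
        for (mk in config$marks) {
          m <- match(mk, colnames(E))
          if (is.na(m)) abort_input("mark not in true model: ", mk)
          for (ch in names(ground_truth$state_paths[[ts]])) {
            path <- ground_truth$state_paths[[ts]][[ch]]
            n <- length(path)
            if (n == 0L) {
              cnt <- integer(0)
            } else {
              present <- rbinom(n, 1L, E[path, m])
              cnt <- rpois(n, ifelse(present == 1L, config$enriched_rate,
                                     config$background_rate))
            }
            tracks[[length(tracks) + 1L]] <- binned_track(
              values = cnt, chrom = ch, bin_size_bp = config$bin_size_bp,
              mark = mk, tissue = ts, replicate = rep_i)
          }
        }
      }
    }
    tracks
  })
}

#' Simulate a normalized gene-by-tissue expression table
#'
#' Genes TAD-linked to a planted enhancer get `expression_fold` times the
#' baseline mean in the planted tissue(s) (all three uterine tissues for
#' uterine-common blocks); everything else sits at baseline. Log-normal
#' noise with `sdlog = expression_noise_sd` multiplies every value
#' (`expression_noise_sd = 0` is exactly noiseless).
#'
#' @param gene_set the `genes` data.frame of a `genome_model`.
#' @param ground_truth from [simulate_state_paths()].
#' @param config a [synthetic_config()].
#' @return numeric matrix, genes x tissues.
#' @export
simulate_expression <- function(gene_set, ground_truth, config) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  unknown <- setdiff(unlist(ground_truth$enhancer_target_genes),
                     gene_set$name)
  if (length(unknown)) {
    abort_input("enhancer target genes absent from gene set: ",
                paste(head(unknown), collapse = ", "))
  }
  withr::with_seed(config$seed + 3L, {
    mu <- matrix(config$expression_baseline, nrow(gene_set),
                 length(config$tissues),
                 dimnames = list(gene_set$name, config$tissues))
    pe <- ground_truth$planted_enhancers
    for (i in seq_len(nrow(pe))) {
      gs <- ground_truth$enhancer_target_genes[[pe$id[i]]]
      if (!length(gs)) next
      tts <- if (pe$module[i] == "uterine_common") config$uterine_tissues else
        sub("_specific$", "", pe$module[i])
      mu[gs, tts] <- config$expression_baseline * config$expression_fold
    }
    noise <- if (config$expression_noise_sd > 0) {
      matrix(rlnorm(length(mu), 0, config$expression_noise_sd), nrow(mu))
    } else 1
    mu * noise
  })
}

#' Simulate region sequences with a planted motif
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. In a designated
#' fraction of regions (rounded to the nearest count, chosen uniformly at
#' random) one occurrence of the PWM consensus is inserted at a random
#' offset on a random strand.
#'
#' @param regions data.frame (chrom, start, end, 0-based half-open) naming
#'   the sequences to emit; widths must be >= the motif width for planted
#'   regions.
#' @param pwm a [pwm()] object.
#' @param plant_fraction fraction of regions receiving the consensus.
#' @param config a [synthetic_config()] (seed source).
#' @return list: `sequences` ([Biostrings::DNAStringSet], named
#'   chrom:start-end), `planted` (character vector of planted names).
#' @export
simulate_sequences_with_motifs <- function(regions, pwm, plant_fraction,
                                           config) {
  check_fraction(plant_fraction, "plant_fraction")
  widths <- regions$end - regions$start
  if (any(widths <= 0)) abort_input("regions must have positive width")
  nms <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  withr::with_seed(config$seed + 4L, {
    n <- nrow(regions)
    n_plant <- round(plant_fraction * n)
    plant_idx <- if (n_plant > 0) sample.int(n, n_plant) else integer(0)
    cons <- pwm_consensus(pwm)
    w <- nchar(cons)
    seqs <- vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), widths[i], replace = TRUE),
                 collapse = "")
      if (i %in% plant_idx) {
        if (widths[i] < w) {
          abort_input(sprintf("region %s shorter than motif width %d",
                              nms[i], w))
        }
        off <- sample.int(widths[i] - w + 1L, 1L)
        ins <- if (sample(c(TRUE, FALSE), 1L)) cons else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        substr(s, off, off + w - 1L) <- ins
      }
      s
    }, character(1))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- nms
    list(sequences = dss, planted = nms[sort(plant_idx)])
  })
}

#' One-stop synthetic epigenome
#'
#' Runs [simulate_genome()], [simulate_state_paths()] (with
#' [default_true_model()] unless one is supplied), [simulate_mark_counts()]
#' and [simulate_expression()].
#'
#' @param config a [synthetic_config()].
#' @param true_model optional [state_model()] overriding the default.
#' @return list: `genome`, `truth`, `tracks`, `expression`, `config`.
#' @export
simulate_epigenome <- function(config = synthetic_config(),
                               true_model = default_true_model(config$marks)) {
  genome <- simulate_genome(config)
  truth <- simulate_state_paths(true_model, genome, config)
  tracks <- simulate_mark_counts(truth, config)
  expr <- simulate_expression(genome$genes, truth, config)
  list(genome = genome, truth = truth, tracks = tracks, expression = expr,
       config = config)
}
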