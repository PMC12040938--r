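test_that("genome simulation tiles TADs, bounds genes, and is deterministic", {
  cfg <- synthetic_config(seed = 5, n_chromosomes = 1,
                          chrom_length_bp = 1000000, n_tads = 10,
                          n_genes = 50)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  tads <- g1$tads
  expect_equal(nrow(tads), 10)
  tads <- tads[order(tads$start), ]
  expect_equal(tads$start[1], 0)
  expect_equal(tads$end[10], 1000000)
  expect_equal(tads$start[-1], tads$end[-10])  # contiguous, no overlap

  expect_equal(nrow(g1$genes), 50)
  expect_true(all(g1$genes$tss >= 0 & g1$genes$tss < 1000000))
  # TSS convention: start on + strand, end-1 on - strand
  plus <- g1$genes$strand == "+"
  expect_equal(g1$genes$tss[plus], g1$genes$start[plus])
  expect_equal(g1$genes$tss[!plus], g1$genes$end[!plus] - 1L)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(chrom_length_bp = 1001, bin_size_bp = 200),
               "divisible")
  expect_error(synthetic_config(background_rate = 2, enriched_rate = 1),
               "enriched_rate")
  expect_error(synthetic_config(n_genes = 0), "positive integer")
  expect_error(synthetic_config(tissues = c("a", "b", "c"),
                                uterine_common_enhancers = 1),
               "uterine")
})

test_that("planted enhancers respect modules, TADs and separation", {
  sim <- default_sim()
  cfg <- sim$config
  truth <- sim$truth
  pe <- truth$planted_enhancers
  expect_equal(nrow(pe), 5 * 20 + 8)
  expect_equal(sum(pe$module == "uterine_common"), 8)
  # every block inside exactly one TAD
  tads <- sim$genome$tads
  for (i in seq_len(nrow(pe))) {
    inside <- tads$chrom == pe$chrom[i] & tads$start <= pe$start[i] &
      tads$end >= pe$end[i]
    expect_equal(sum(inside), 1)
  }
  # planted bins carry the EnhA state in every designated tissue; in the
  # other tissues only the (rare) baseline chain can produce EnhA there
  enh <- match("EnhA", truth$true_model$state_names)
  bin <- cfg$bin_size_bp
  contaminated <- 0L
  for (i in seq_len(nrow(pe))) {
    bins <- (pe$start[i] %/% bin + 1):(pe$end[i] %/% bin)
    ts_on <- if (pe$module[i] == "uterine_common") cfg$uterine_tissues else
      sub("_specific$", "", pe$module[i])
    hit_other <- FALSE
    for (ts in cfg$tissues) {
      states <- truth$state_paths[[ts]][[pe$chrom[i]]][bins]
      if (ts %in% ts_on) {
        expect_true(all(states == enh))
      } else if (any(states == enh)) {
        hit_other <- TRUE
      }
    }
    contaminated <- contaminated + hit_other
  }
  # baseline EnhA occupancy is 0.4%, so cross-tissue collisions stay rare
  expect_lte(contaminated / nrow(pe), 0.15)
})

test_that("overfull planting requests fail with a generation error", {
  cfg <- synthetic_config(seed = 1, n_chromosomes = 1,
                          chrom_length_bp = 100000, n_tads = 2,
                          n_genes = 5, planted_specific_enhancers_per_tissue = 50,
                          uterine_common_enhancers = 0)
  g <- simulate_genome(cfg)
  expect_error(simulate_state_paths(default_true_model(), g, cfg),
               "capacity")
})

test_that("an absorbing chain yields a constant baseline path", {
  cfg <- synthetic_config(seed = 2, n_chromosomes = 1,
                          chrom_length_bp = 100000, n_genes = 5,
                          planted_specific_enhancers_per_tissue = 0,
                          uterine_common_enhancers = 0,
                          tss_promoter_state = FALSE)
  m <- state_model(pi = c(1, 0), A = diag(2),
                   E = matrix(c(0.1, 0.9, 0.1, 0.9, 0.1,
                                0.9, 0.1, 0.9, 0.1, 0.9), 2, 5),
                   marks = cfg$marks, state_names = c("Qui", "EnhA"))
  truth <- simulate_state_paths(m, simulate_genome(cfg), cfg)
  for (ts in cfg$tissues) {
    expect_true(all(truth$state_paths[[ts]]$chr1 == 1L))
  }
})

test_that("sampled paths reproduce the transition matrix within 3 MC SE", {
  m <- default_true_model()
  n <- 100000
  path <- withr::with_seed(42, chromatlas:::sample_markov(n, m$pi, m$A))
  expect_equal(length(path), n)
  from <- path[-n]
  to <- path[-1]
  for (i in seq_len(m$K)) {
    n_i <- sum(from == i)
    if (n_i < 200) next
    for (j in seq_len(m$K)) {
      p_hat <- sum(from == i & to == j) / n_i
      se <- sqrt(m$A[i, j] * (1 - m$A[i, j]) / n_i)
      expect_lt(abs(p_hat - m$A[i, j]), 3 * se + 1e-12)
    }
  }
})

test_that("mark counts follow the Bernoulli-Poisson mixture", {
  sim <- default_sim()
  cfg <- sim$config
  # closed form: lambda-bar = p * enriched + (1 - p) * background where p
  # is the path-weighted emission probability of the mark
  E <- sim$truth$true_model$E
  tr <- Filter(function(t) t$tissue == "ovary" && t$replicate == 1,
               sim$tracks)
  for (mk in cfg$marks) {
    vals <- unlist(lapply(Filter(function(t) t$mark == mk, tr),
                          function(t) t$values))
    p <- mean(unlist(lapply(sim$truth$state_paths$ovary,
                            function(path) E[path, mk])))
    lam <- p * cfg$enriched_rate + (1 - p) * cfg$background_rate
    # mixture variance: E[Var] + Var[E]
    v <- p * (cfg$enriched_rate + cfg$enriched_rate^2) +
      (1 - p) * (cfg$background_rate + cfg$background_rate^2) - lam^2
    se <- sqrt(v / length(vals))
    expect_lt(abs(mean(vals) - lam), 3 * se)
  }
})

test_that("zero-emission marks give pure background counts", {
  cfg <- synthetic_config(seed = 9, n_chromosomes = 1,
                          chrom_length_bp = 10000000, n_genes = 5,
                          background_rate = 2, enriched_rate = 8,
                          planted_specific_enhancers_per_tissue = 0,
                          uterine_common_enhancers = 0,
                          tss_promoter_state = FALSE,
                          tissues = "ovary", uterine_tissues = character(0),
                          n_replicates = 1, marks = "H3K4me3")
  m <- state_model(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                   E = matrix(0, 2, 1), marks = "H3K4me3",
                   state_names = c("Qui", "EnhA"))
  truth <- simulate_state_paths(m, simulate_genome(cfg), cfg)
  tracks <- simulate_mark_counts(truth, cfg)
  vals <- tracks[[1]]$values
  expect_equal(length(vals), 50000)
  se <- sqrt(cfg$background_rate / length(vals))
  expect_lt(abs(mean(vals) - cfg$background_rate), 3 * se)
})

test_that("empty state paths give empty tracks", {
  sim <- default_sim()
  truth <- sim$truth
  truth$state_paths <- lapply(truth$state_paths, function(p) list(chr1 = integer(0)))
  tracks <- simulate_mark_counts(truth, sim$config)
  expect_true(all(vapply(tracks, function(t) length(t$values) == 0L,
                         logical(1))))
})

test_that("expression elevates TAD-linked targets in the planted tissue", {
  # sparse planting so that some genes are targets of one module only
  cfg <- synthetic_config(seed = 14, n_chromosomes = 2, n_tads = 20,
                          n_genes = 120,
                          planted_specific_enhancers_per_tissue = 4,
                          uterine_common_enhancers = 2,
                          expression_noise_sd = 0)
  genome <- simulate_genome(cfg)
  truth <- simulate_state_paths(default_true_model(), genome, cfg)
  sim <- list(genome = genome, truth = truth)
  expr <- simulate_expression(genome$genes, truth, cfg)
  pe <- truth$planted_enhancers
  ov <- pe[pe$module == "ovary_specific", ]
  targets <- unique(unlist(truth$enhancer_target_genes[ov$id]))
  # genes can be targets of several modules; keep ovary-only targets
  other <- unique(unlist(truth$enhancer_target_genes[
    pe$id[pe$module != "ovary_specific"]]))
  targets <- setdiff(targets, other)
  expect_gt(length(targets), 0)
  expect_true(all(expr[targets, "ovary"] ==
                    cfg$expression_baseline * cfg$expression_fold))
  expect_true(all(expr[targets, "oviduct"] == cfg$expression_baseline))

  # with log-normal noise at sd 0.2 the planted tissue ranks first in
  # >= 95% of seeds
  g <- targets[1]
  ranks_first <- vapply(1:40, function(s) {
    cfg$seed <- s
    e <- simulate_expression(sim$genome$genes, sim$truth, cfg)
    which.max(e[g, ]) == match("ovary", colnames(e))
  }, logical(1))
  expect_gte(mean(ranks_first), 0.95)
})

test_that("unknown target genes are a generation error", {
  sim <- default_sim()
  truth <- sim$truth
  truth$enhancer_target_genes[[1]] <- c("no_such_gene")
  expect_error(simulate_expression(sim$genome$genes, truth, sim$config),
               "no_such_gene")
})

test_that("motif planting is deterministic and covers the requested fraction", {
  cfg <- synthetic_config(seed = 8)
  regions <- data.frame(chrom = "chr1", start = (0:49) * 1000,
                        end = (0:49) * 1000 + 500)
  p <- consensus_pwm("ACGGTCAT")
  s1 <- simulate_sequences_with_motifs(regions, p, 1, cfg)
  s2 <- simulate_sequences_with_motifs(regions, p, 1, cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_equal(length(s1$planted), 50)
  cons <- "ACGGTCAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  has <- vapply(as.character(s1$sequences), function(s)
    grepl(cons, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), logical(1))
  expect_true(all(has))

  s0 <- simulate_sequences_with_motifs(regions, p, 0, cfg)
  expect_equal(length(s0$planted), 0)

  short <- data.frame(chrom = "chr1", start = 0, end = 5)
  expect_error(simulate_sequences_with_motifs(short, p, 1, cfg), "shorter")
})

test_that("unplanted sequences match the closed-form consensus rate", {
  cfg <- synthetic_config(seed = 21)
  n_regions <- 2000
  width <- 1000
  regions <- data.frame(chrom = "chr1", start = seq_len(n_regions) * 2000,
                        end = seq_len(n_regions) * 2000 + width)
  w <- 8
  p <- consensus_pwm("ACGGTCAT")
  s <- simulate_sequences_with_motifs(regions, p, 0, cfg)
  cons <- "ACGGTCAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  hits <- sum(vapply(as.character(s$sequences), function(x)
    length(gregexpr(cons, x, fixed = TRUE)[[1]][
      gregexpr(cons, x, fixed = TRUE)[[1]] > 0]) +
      length(gregexpr(rc, x, fixed = TRUE)[[1]][
        gregexpr(rc, x, fixed = TRUE)[[1]] > 0]), numeric(1)))
  expected <- n_regions * (width - w + 1) * 2 * 0.25^w
  se <- sqrt(expected)  # Poisson-like count
  expect_lt(abs(hits - expected), 3 * se + 3)
})

test_that("the library design enumerates 60 libraries under defaults", {
  ld <- library_design(synthetic_config())
  expect_equal(nrow(ld), 60)
  expect_equal(length(unique(ld$tissue)), 5)
  expect_setequal(unique(ld$assay),
                  c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "ATAC",
                    "RNA"))
})
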