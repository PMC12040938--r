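five_tissues <- c("ovary", "oviduct", "cervix", "cornua_uteri",
                  "corpus_uteri")
uterine <- c("cervix", "cornua_uteri", "corpus_uteri")

test_that("RRAT regions merge the cross-tissue union and score 1 bp overlaps", {
  enh <- list(ovary = data.frame(chrom = "chr1", start = 0, end = 200),
              oviduct = data.frame(chrom = "chr1", start = 100, end = 300))
  r <- build_rrat(enh, tissues = five_tissues)
  expect_equal(nrow(r$regions), 1)
  expect_equal(r$regions$start, 0)
  expect_equal(r$regions$end, 300)
  expect_equal(unname(r$matrix[1, ]), c(1, 1, 0, 0, 0))

  solo <- build_rrat(list(cervix = data.frame(chrom = "chr2", start = 10,
                                              end = 50)),
                     tissues = five_tissues)
  expect_equal(sum(solo$matrix), 1)
  expect_equal(unname(solo$matrix[1, "cervix"]), 1)

  expect_error(build_rrat(list(foo = data.frame(chrom = "chr1", start = 0,
                                                end = 10)),
                          tissues = five_tissues), "unknown tissue")
})

test_that("RRAT construction is consistent with a brute-force overlap scan", {
  withr::with_seed(19, {
    for (rep_i in 1:10) {
      enh <- lapply(setNames(five_tissues, five_tissues), function(ts) {
        n <- sample(5:30, 1)
        st <- sample(0:20000, n)
        data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = st, end = st + sample(100:800, n, TRUE))
      })
      r <- build_rrat(enh)
      # every input interval overlaps exactly one region
      for (ts in five_tissues) {
        d <- enh[[ts]]
        for (i in seq_len(nrow(d))) {
          n_over <- sum(r$regions$chrom == d$chrom[i] &
                          r$regions$start < d$end[i] &
                          r$regions$end > d$start[i])
          expect_equal(n_over, 1)
        }
      }
      # every region overlaps at least one input; matrix entries match a
      # direct overlap test
      all_iv <- do.call(rbind, enh)
      for (j in seq_len(nrow(r$regions))) {
        hits <- vapply(five_tissues, function(ts) {
          d <- enh[[ts]]
          any(d$chrom == r$regions$chrom[j] & d$start < r$regions$end[j] &
                d$end > r$regions$start[j])
        }, logical(1))
        expect_true(any(hits))
        expect_equal(unname(r$matrix[j, ]), as.integer(hits))
      }
    }
  })
})

test_that("module classification implements the exhaustive pattern rule", {
  regions <- data.frame(chrom = "chr1", start = (0:3) * 1000,
                        end = (0:3) * 1000 + 500)
  mat <- rbind(c(1, 0, 0, 0, 0),
               c(0, 0, 1, 1, 1),
               c(1, 1, 1, 1, 1),
               c(0, 1, 1, 0, 0))
  colnames(mat) <- five_tissues
  rrat <- structure(list(regions = regions, matrix = mat,
                         tissues = five_tissues), class = "rrat")
  mods <- classify_modules(rrat, uterine)
  expect_equal(mods$module, c("ovary_specific", "uterine_common",
                              "unassigned", "unassigned"))
  expect_error(classify_modules(rrat, c("a", "b", "c")), "uterine")
})

test_that("module assignment is a partition invariant to column order", {
  withr::with_seed(29, {
    n <- 200
    mat <- matrix(rbinom(n * 5, 1, 0.4), n, 5,
                  dimnames = list(NULL, five_tissues))
    mat[rowSums(mat) == 0, 1] <- 1L  # RRAT rows are never all-zero
    regions <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                          end = (seq_len(n) - 1) * 1000 + 500)
    rrat <- structure(list(regions = regions, matrix = mat,
                           tissues = five_tissues), class = "rrat")
    mods <- classify_modules(rrat, uterine)
    expect_equal(nrow(mods), n)  # partition: one label per region
    counts <- table(factor(mods$module,
                           c(paste0(five_tissues, "_specific"),
                             "uterine_common", "unassigned")))
    expect_equal(sum(counts), n)

    perm <- c(3, 1, 5, 2, 4)
    rrat2 <- rrat
    rrat2$matrix <- mat[, perm]
    rrat2$tissues <- five_tissues[perm]
    mods2 <- classify_modules(rrat2, uterine)
    expect_equal(mods2$module, mods$module)
  })
})

test_that("target linking requires a shared TAD", {
  tads <- data.frame(chrom = "chr1", start = c(0, 100000),
                     end = c(100000, 200000))
  genes <- data.frame(chrom = "chr1", tss = c(60000, 150000),
                      name = c("gA", "gB"))
  mods <- data.frame(chrom = "chr1", start = c(49000, 190000, 250000),
                     end = c(51000, 191000, 251000),
                     module = "ovary_specific")
  links <- link_targets(mods, tads, genes)
  expect_equal(links$targets[["chr1:49000-51000"]], "gA")
  expect_equal(links$targets[["chr1:190000-191000"]], "gB")
  # region outside all TADs -> empty and flagged
  expect_equal(links$targets[["chr1:250000-251000"]], character(0))
  expect_equal(links$no_tad, "chr1:250000-251000")

  bad_tads <- data.frame(chrom = "chr1", start = c(0, 50000),
                         end = c(100000, 150000))
  expect_error(link_targets(mods, bad_tads, genes), "overlapping TADs")
})

test_that("planted enhancer-gene pairs are recovered through TADs", {
  sim <- default_sim()
  truth <- sim$truth
  pe <- truth$planted_enhancers
  mods <- data.frame(chrom = pe$chrom, start = pe$start, end = pe$end,
                     module = pe$module)
  links <- link_targets(mods, sim$genome$tads, sim$genome$genes)
  ids <- sprintf("%s:%d-%d", pe$chrom, pe$start, pe$end)
  n_pairs <- 0; n_hit <- 0; n_cross <- 0
  tad_of_gene <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sim$genome$genes$chrom,
                           IRanges::IRanges(sim$genome$genes$tss + 1,
                                            sim$genome$genes$tss + 1)),
    chromatlas:::bed_to_granges(sim$genome$tads), select = "first")
  for (i in seq_len(nrow(pe))) {
    want <- truth$enhancer_target_genes[[pe$id[i]]]
    got <- links$targets[[ids[i]]]
    n_pairs <- n_pairs + length(want)
    n_hit <- n_hit + length(intersect(want, got))
    n_cross <- n_cross + length(setdiff(got, want))
  }
  expect_gte(n_hit / n_pairs, 0.95)
  expect_equal(n_cross, 0)
})

test_that("module reports count regions and rank noiseless expression", {
  mods <- data.frame(chrom = "chr1",
                     start = c(0, 1000, 2000, 3000, 4000, 5000, 6000, 7000),
                     end = c(0, 1000, 2000, 3000, 4000, 5000, 6000, 7000) + 500,
                     module = c(rep("ovary_specific", 5),
                                rep("oviduct_specific", 3)))
  links <- list(targets = setNames(
    c(lapply(1:5, function(i) "gA"), lapply(1:3, function(i) "gB")),
    sprintf("chr1:%d-%d", mods$start, mods$end)), no_tad = character(0))
  expr <- matrix(10, 2, 5, dimnames = list(c("gA", "gB"), five_tissues))
  expr["gA", "ovary"] <- 80
  expr["gB", "oviduct"] <- 80
  rep <- module_report(mods, links, expr, uterine)
  expect_equal(unname(rep$module_counts[c("ovary_specific",
                                          "oviduct_specific",
                                          "cervix_specific",
                                          "uterine_common")]),
               c(5, 3, 0, 0))
  expect_true(all(rep$gene_ranks$rank == 1))
  expect_true(all(rep$gene_ranks$top_matches))
  expect_equal(rep$missing_genes, character(0))

  # empty module list: zero counts, no errors
  rep0 <- module_report(mods[0, ], list(targets = list(),
                                        no_tad = character(0)),
                        expr, uterine)
  expect_true(all(rep0$module_counts == 0))
  expect_equal(nrow(rep0$gene_ranks), 0)
})
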