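#' Bundled demonstration PWM library
#'
#' Eight sharp 8-mer motifs: TF01..TF05 are the motifs planted in the five
#' tissue-specific enhancer modules by the synthetic pipeline (in tissue
#' order); TF06..TF08 are never planted and act as decoys.
#'
#' @return named list of [pwm()].
#' @export
default_pwm_library <- function() {
  cons <- c(TF01 = "ACGGTCAT", TF02 = "GATTACAG", TF03 = "CCATGGTC",
            TF04 = "TGACGTCT", TF05 = "GGATCCAA", TF06 = "ATCGATGC",
            TF07 = "CAGTACTG", TF08 = "TTGGCCAT")
  out <- lapply(names(cons), function(nm) consensus_pwm(cons[[nm]], name = nm))
  names(out) <- names(cons)
  out
}

#' Pipeline run configuration
#'
#' Single configuration for the synthetic end-to-end run: simulate ->
#' QC -> binarize -> learn -> decode -> label -> summarize -> TSR ->
#' enrich. Any element can be overridden; `stages` toggles optional
#' stages.
#'
#' @param outdir output directory (created).
#' @param seed master seed; the synthetic configuration inherits it unless
#'   one is supplied.
#' @param synthetic a [synthetic_config()].
#' @param qc_bin_size_bp bin size for the correlation/PCA QC stage (1 kb).
#' @param p_threshold Poisson binarization tail cut.
#' @param n_states states to learn. The default (15) deliberately exceeds
#'   the number of generative states: spare states absorb partial-detection
#'   and stray single-mark patterns instead of forcing rare states (EnhA)
#'   to merge, mirroring how 15-state models are fit over 5 marks in
#'   practice.
#' @param n_restarts,tol,max_iter passed to [learn_model()].
#' @param decode_method `"viterbi"` or `"posterior"`.
#' @param tss_window_bp TSS-enrichment half window.
#' @param alpha FDR gate for enrichment.
#' @param score_fraction PWM hit threshold (fraction of maximum score).
#' @param motif_plant_fraction fraction of foreground module sequences
#'   receiving the module motif.
#' @param n_bg_sequences background sequences per enrichment test.
#' @param write_tracks write per-library bedGraph files (the slowest
#'   artifact; toggle off for quick runs).
#' @param stages named logical vector enabling optional stages (`qc`,
#'   `enrichment`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("chromatlas_run"),
                            seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            qc_bin_size_bp = 1000L,
                            p_threshold = 1e-4,
                            n_states = 15L,
                            n_restarts = 3L, tol = 1e-4, max_iter = 200L,
                            decode_method = "viterbi",
                            tss_window_bp = 2000L,
                            alpha = 0.05,
                            score_fraction = 0.8,
                            motif_plant_fraction = 0.9,
                            n_bg_sequences = 200L,
                            write_tracks = TRUE,
                            stages = c(qc = TRUE, enrichment = TRUE)) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, qc_bin_size_bp = qc_bin_size_bp,
                 p_threshold = p_threshold, n_states = n_states,
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter,
                 decode_method = decode_method,
                 tss_window_bp = tss_window_bp, alpha = alpha,
                 score_fraction = score_fraction,
                 motif_plant_fraction = motif_plant_fraction,
                 n_bg_sequences = n_bg_sequences,
                 write_tracks = isTRUE(write_tracks),
                 stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] arguments; a `synthetic`
#' block overrides [synthetic_config()] arguments.
#'
#' @param path YAML file.
#' @param ... further overrides applied after the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic
  y$synthetic <- NULL
  seed <- if (!is.null(y$seed)) y$seed else 1L
  if (!is.null(syn_args)) {
    if (is.null(syn_args$seed)) syn_args$seed <- seed
    y$synthetic <- do.call(synthetic_config, syn_args)
  }
  args <- modifyList(y, list(...))
  do.call(pipeline_config, args)
}

# aggregate a 200 bp count track into coarser QC bins by summing
aggregate_track <- function(track, out_bin_bp) {
  fac <- out_bin_bp %/% track$bin_size_bp
  n <- length(track$values)
  grp <- (seq_len(n) - 1L) %/% fac
  v <- as.numeric(tapply(track$values, grp, sum))
  binned_track(v, track$chrom, out_bin_bp, track$mark, track$tissue,
               track$replicate)
}

# concatenate per-chromosome tracks of one library genome-wide
concat_library_tracks <- function(tracks) {
  key <- vapply(tracks, function(t)
    paste(t$tissue, t$mark, t$replicate, sep = "."), character(1))
  lapply(split(tracks, factor(key, levels = unique(key))), function(grp) {
    t1 <- grp[[1]]
    binned_track(unlist(lapply(grp, function(t) t$values)), "genome",
                 t1$bin_size_bp, t1$mark, t1$tissue, t1$replicate)
  })
}

recovery_scores <- function(modules, planted, uterine_tissues) {
  if (nrow(planted) == 0L) {
    return(list(recovered_fraction = NA_real_, n_planted_specific = 0L,
                uterine_single_tissue_misclass = 0L,
                n_planted_uterine = 0L))
  }
  mod_gr <- bed_to_granges(modules[, c("chrom", "start", "end")])
  pl_gr <- bed_to_granges(planted[, c("chrom", "start", "end")])
  ov <- GenomicRanges::findOverlaps(pl_gr, mod_gr)
  spec <- planted$module != "uterine_common"
  rec <- logical(nrow(planted))
  ut_bad <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    got <- modules$module[hits]
    rec[i] <- planted$module[i] %in% got
    ut_bad[i] <- !spec[i] && any(grepl("_specific$", got))
  }
  list(recovered_fraction = if (any(spec)) mean(rec[spec]) else NA_real_,
       n_planted_specific = sum(spec),
       uterine_recovered_fraction =
         if (any(!spec)) mean(rec[!spec]) else NA_real_,
       uterine_single_tissue_misclass = sum(ut_bad),
       n_planted_uterine = sum(!spec))
}

#' Run the full synthetic-epigenome pipeline
#'
#' Stages in dependency order: simulate, QC (1 kb correlation + PCA),
#' replicate pooling + Poisson binarization, joint Baum-Welch model
#' learning across tissues, per-tissue decoding and segmentation, state
#' labelling and summaries, RRAT/TSR module calling with TAD target
#' linking, and per-module motif/term enrichment. Artifacts are written
#' under `config$outdir` and checksummed; a JSON and a plain-text report
#' are produced. A stage failure aborts with the stage name and leaves a
#' `FAILED_<stage>` marker next to any partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly also written to
#'   `report.json` / `report.txt`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    seed = config$seed, bin_size_bp = config$synthetic$bin_size_bp,
    qc_bin_size_bp = config$qc_bin_size_bp,
    p_threshold = config$p_threshold, n_states = config$n_states,
    n_restarts = config$n_restarts, decode_method = config$decode_method,
    tss_window_bp = config$tss_window_bp, alpha = config$alpha,
    score_fraction = config$score_fraction))
  files <- character(0)
  t0 <- proc.time()[["elapsed"]]
  stage_times <- list()

  run_stage <- function(name, fun) {
    message(sprintf("[chromatlas] stage %-12s ...", name))
    st <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      file.create(file.path(outdir, paste0("FAILED_", name)))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - st, 2)
    res
  }

  ## simulate -----------------------------------------------------------
  sim <- run_stage("simulate", function() {
    sim <- simulate_epigenome(config$synthetic)
    gdir <- file.path(outdir, "genome")
    dir.create(gdir, showWarnings = FALSE)
    files <<- c(files,
      write_chrom_sizes(sim$genome$chrom_sizes,
                        file.path(gdir, "chrom.sizes")),
      write_bed(sim$genome$genes, file.path(gdir, "genes.bed"),
                columns = c("name", "score", "strand")),
      write_bed(sim$genome$tads, file.path(gdir, "tads.bed"),
                columns = character(0)),
      write_tsv(data.frame(gene = rownames(sim$expression),
                           sim$expression, check.names = FALSE),
                file.path(gdir, "expression.tsv")),
      write_bed(sim$truth$planted_enhancers,
                file.path(gdir, "planted_enhancers.bed")))
    if (config$write_tracks) {
      tdir <- file.path(outdir, "tracks")
      dir.create(tdir, showWarnings = FALSE)
      for (tr in sim$tracks) {
        f <- file.path(tdir, sprintf("%s_rep%d_%s_%s.bedGraph", tr$tissue,
                                     tr$replicate, tr$mark, tr$chrom))
        files <<- c(files, write_bedgraph(tr, f))
      }
    }
    sim
  })
  cfgS <- config$synthetic

  ## qc ------------------------------------------------------------------
  if (isTRUE(config$stages[["qc"]])) {
    report$qc <- run_stage("qc", function() {
      coarse <- lapply(sim$tracks, aggregate_track,
                       out_bin_bp = config$qc_bin_size_bp)
      libs <- concat_library_tracks(coarse)
      zlibs <- lapply(libs, zscore_track)
      cm <- pairwise_correlation(zlibs)
      pc <- pca_tracks(zlibs, n_components = 2L)
      files <<- c(files, write_tsv(
        data.frame(sample = rownames(cm), cm, check.names = FALSE),
        file.path(outdir, "qc_correlation.tsv")))
      list(mean_within_mark_r = {
        marks <- vapply(zlibs, function(t) t$mark, character(1))
        same <- outer(marks, marks, "==") & upper.tri(cm)
        mean(cm[same])
      }, pc1_var = unname(pc$explained_variance[1]))
    })
  }

  ## binarize -------------------------------------------------------------
  obs_list <- run_stage("binarize", function() {
    ol <- binarize_tracks(sim$tracks, cfgS$marks, config$p_threshold)
    bdir <- file.path(outdir, "binarized")
    dir.create(bdir, showWarnings = FALSE)
    for (o in ol) {
      files <<- c(files, write_binarized(
        o, file.path(bdir, sprintf("%s_%s_binary.txt", o$tissue,
                                   o$chromosome))))
    }
    ol
  })

  ## learn ----------------------------------------------------------------
  fit <- run_stage("learn", function() {
    fit <- learn_model(obs_list, K = config$n_states, seed = config$seed,
                       n_restarts = config$n_restarts, tol = config$tol,
                       max_iter = config$max_iter)
    mdir <- file.path(outdir, "model")
    dir.create(mdir, showWarnings = FALSE)
    files <<- c(files,
                write_model_json(fit$model, file.path(mdir, "model.json")),
                write_emissions_table(fit$model,
                                      file.path(mdir, "emissions.txt")))
    fit
  })
  report$learn <- list(loglik = fit$trace[length(fit$trace)],
                       n_iter = fit$n_iter, converged = fit$converged,
                       restart_loglik = fit$restart_loglik)

  ## decode ---------------------------------------------------------------
  segs <- run_stage("decode", function() {
    sdir <- file.path(outdir, "segmentation")
    dir.create(sdir, showWarnings = FALSE)
    segs <- lapply(cfgS$tissues, function(ts) {
      per_chrom <- lapply(Filter(function(o) o$tissue == ts, obs_list),
                          function(o) {
        path <- decode(fit$model, o, method = config$decode_method)
        segment_path(path, cfgS$bin_size_bp, o$chromosome)
      })
      seg <- do.call(rbind, per_chrom)
      rownames(seg) <- NULL
      files <<- c(files, write_segmentation_bed(
        seg, file.path(sdir, paste0(ts, "_segments.bed"))))
      seg
    })
    names(segs) <- cfgS$tissues
    segs
  })

  ## annotate -------------------------------------------------------------
  ann <- run_stage("annotate", function() {
    folds_per_tissue <- vapply(segs, function(seg)
      tss_enrichment(seg, sim$genome$genes, config$tss_window_bp,
                     states = seq_len(config$n_states)),
      numeric(config$n_states))
    folds <- rowMeans(folds_per_tissue)
    labels <- label_states(fit$model, folds)
    summary <- summarize_states(segs, labels)
    adir <- file.path(outdir, "annotation")
    dir.create(adir, showWarnings = FALSE)
    files <<- c(files,
      write_tsv(summary$per_state, file.path(adir, "state_summary.tsv")),
      write_tsv(summary$per_category,
                file.path(adir, "category_summary.tsv")),
      write_tsv(default_state_rules(), file.path(adir, "state_rules.tsv")))
    for (ts in cfgS$tissues) {
      files <<- c(files, write_state_track_bed9(
        segs[[ts]], labels, file.path(adir, paste0(ts, "_states.bed9"))))
    }
    list(labels = labels, summary = summary, tss_folds = folds)
  })
  report$states <- list(
    labels = ann$labels,
    regulatory_element_total = ann$summary$regulatory_element_total,
    per_state = ann$summary$per_state,
    per_category = ann$summary$per_category)

  ## tsr ------------------------------------------------------------------
  tsr <- run_stage("tsr", function() {
    enh <- state_intervals_by_tissue(segs, ann$labels, "EnhA")
    rrat <- build_rrat(enh, tissues = cfgS$tissues)
    modules <- classify_modules(rrat, cfgS$uterine_tissues)
    links <- link_targets(modules, sim$genome$tads, sim$genome$genes)
    rep_mod <- module_report(modules, links, sim$expression,
                             cfgS$uterine_tissues)
    tdir <- file.path(outdir, "tsr")
    dir.create(tdir, showWarnings = FALSE)
    files <<- c(files, write_tsv(
      cbind(rrat$regions, as.data.frame(rrat$matrix)),
      file.path(tdir, "rrat.tsv")))
    for (m in unique(modules$module)) {
      files <<- c(files, write_bed(modules[modules$module == m, ],
                                   file.path(tdir, paste0(m, ".bed")),
                                   columns = "module"))
    }
    files <<- c(files, write_tsv(
      data.frame(region = names(links$targets),
                 genes = vapply(links$targets, paste, character(1),
                                collapse = ",")),
      file.path(tdir, "region_genes.tsv")))
    list(rrat = rrat, modules = modules, links = links, report = rep_mod)
  })
  specific_names <- paste0(cfgS$tissues, "_specific")
  report$tsr <- list(
    module_counts = tsr$report$module_counts,
    specific_total = sum(tsr$report$module_counts[specific_names]),
    target_top_match_fraction =
      if (nrow(tsr$report$gene_ranks)) mean(tsr$report$gene_ranks$top_matches)
      else NA_real_)
  report$recovery <- recovery_scores(tsr$modules,
                                     sim$truth$planted_enhancers,
                                     cfgS$uterine_tissues)

  ## enrichment -----------------------------------------------------------
  if (isTRUE(config$stages[["enrichment"]])) {
    report$enrichment <- run_stage("enrich", function() {
      pwms <- default_pwm_library()
      tissue_motif <- setNames(names(pwms)[seq_along(cfgS$tissues)],
                               cfgS$tissues)
      edir <- file.path(outdir, "enrichment")
      dir.create(edir, showWarnings = FALSE)
      out <- list()
      for (i in seq_along(cfgS$tissues)) {
        ts <- cfgS$tissues[i]
        fg_regions <- tsr$modules[tsr$modules$module ==
                                    paste0(ts, "_specific"),
                                  c("chrom", "start", "end")]
        if (nrow(fg_regions) == 0L) next
        cfg_fg <- cfgS; cfg_fg$seed <- cfgS$seed + 100L + i
        fg <- simulate_sequences_with_motifs(
          fg_regions, pwms[[tissue_motif[[ts]]]],
          config$motif_plant_fraction, cfg_fg)
        cfg_bg <- cfgS; cfg_bg$seed <- cfgS$seed + 200L + i
        bg_regions <- data.frame(chrom = "bg",
                                 start = seq_len(config$n_bg_sequences) * 1000L,
                                 end = seq_len(config$n_bg_sequences) * 1000L +
                                   1000L)
        bg <- simulate_sequences_with_motifs(bg_regions, pwms[[1]], 0, cfg_bg)
        me <- motif_enrichment(fg$sequences, bg$sequences, pwms,
                               alpha = config$alpha,
                               score_fraction = config$score_fraction)
        files <<- c(files, write_tsv(
          me$results, file.path(edir, sprintf("motifs_%s.tsv", ts))))

        # term enrichment on the module's TAD-linked target genes
        ids <- sprintf("%s:%d-%d", fg_regions$chrom, fg_regions$start,
                       fg_regions$end)
        targets <- unique(unlist(tsr$links$targets[ids]))
        te <- NULL
        if (length(targets)) {
          tm <- synthetic_term_map(sim, cfgS)
          te <- term_enrichment(targets, sim$genome$genes$name, tm,
                                alpha = config$alpha)
          files <<- c(files, write_tsv(
            te, file.path(edir, sprintf("terms_%s.tsv", ts))))
        }
        out[[ts]] <- list(
          planted_motif = tissue_motif[[ts]], top5 = me$top5,
          planted_motif_rank =
            me$results$rank[me$results$item == tissue_motif[[ts]]],
          planted_motif_q =
            me$results$q_value[me$results$item == tissue_motif[[ts]]],
          top_term = if (!is.null(te) && nrow(te)) te$item[1] else NA)
      }
      out
    })
  }

  ## report ---------------------------------------------------------------
  report$stage_seconds <- stage_times
  report$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 2)
  report$checksums <- as.list(tools::md5sum(sort(unique(files))))
  names(report$checksums) <- substring(names(report$checksums),
                                       nchar(outdir) + 2L)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(format_report(report), file.path(outdir, "report.txt"))
  invisible(report)
}

# synthetic gene-to-term map: one term per planted module (its target
# genes) plus random decoy terms of similar size
synthetic_term_map <- function(sim, cfgS) {
  truth <- sim$truth
  rows <- list()
  for (mod in unique(truth$planted_enhancers$module)) {
    ids <- truth$planted_enhancers$id[truth$planted_enhancers$module == mod]
    genes <- unique(unlist(truth$enhancer_target_genes[ids]))
    if (length(genes)) {
      rows[[mod]] <- data.frame(gene = genes, term = paste0("T_", mod))
    }
  }
  withr::with_seed(cfgS$seed + 5L, {
    sizes <- vapply(rows, nrow, integer(1))
    for (k in seq_len(3)) {
      n <- max(5L, round(mean(sizes)))
      rows[[paste0("decoy", k)]] <- data.frame(
        gene = sample(sim$genome$genes$name, min(n, nrow(sim$genome$genes))),
        term = paste0("T_random", k))
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

format_report <- function(report) {
  c("chromatlas run report",
    "=====================",
    sprintf("seed: %d", report$parameters$seed),
    sprintf("states learned: %d (log-likelihood %.2f, %d iterations%s)",
            nrow(report$states$labels), report$learn$loglik,
            report$learn$n_iter,
            if (report$learn$converged) "" else ", NOT converged"),
    "",
    "Per-state summary:",
    utils::capture.output(print(report$states$per_state, row.names = FALSE)),
    "",
    sprintf("Regulatory elements (non-quiescent intervals, all tissues): %d",
            report$states$regulatory_element_total),
    "",
    "TSR module counts:",
    utils::capture.output(print(report$tsr$module_counts)),
    sprintf("Five tissue-specific modules total: %d",
            report$tsr$specific_total),
    if (!is.null(report$recovery))
      sprintf("Planted specific-block recovery: %.1f%% (%d blocks); uterine-common misclassified as single-tissue: %d of %d",
              100 * report$recovery$recovered_fraction,
              report$recovery$n_planted_specific,
              report$recovery$uterine_single_tissue_misclass,
              report$recovery$n_planted_uterine),
    "")
}
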