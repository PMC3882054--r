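#' @title End-to-end pipeline orchestration
#' @description Runs the full analysis in the order of a gene-discovery
#'   study: simulate a population, map the locus by shared homozygosity and
#'   a haplotype-window scan, prioritize variants through both filtering
#'   cascades, verify Hardy-Weinberg / segregation statistics, and fit and
#'   compare voltage-clamp gating kinetics.  Every stage is a thin call into
#'   the corresponding module, so stage-by-stage runs and [run_all()] give
#'   identical results under the same seed.
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "map", "prioritize", "stats", "kinetics")

#' Pipeline run configuration
#'
#' @param sim a [sim_config()].
#' @param map list: `max_missing_per_marker`, `min_markers`, optional
#'   `genotypes_vcf` (read genotypes from a file instead of the simulate
#'   stage).
#' @param scan list: `window_size`, `step`, `min_count`.
#' @param kinetics list: per-group time-constant distributions (mean ms, sem
#'   ms, n oocytes), relative current noise, and the fit window.  Group "a"
#'   is the mutant (fast), "b" the wild type (slow).
#' @param seed global seed; every stage derives its own stream from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       map = list(max_missing_per_marker = 0L,
                                  min_markers = 10L),
                       scan = list(window_size = 10L, step = 5L,
                                   min_count = 8L),
                       kinetics = list(mut_tau = 104, mut_sem = 6, mut_n = 18,
                                       wt_tau = 341, wt_sem = 18, wt_n = 13,
                                       noise_frac = 0.02, window_ms = 250),
                       seed = 1L) {
  structure(list(sim = sim, map = map, scan = scan, kinetics = kinetics,
                 seed = seed), class = "run_config")
}

#' Run a single pipeline stage
#'
#' @param stage one of "simulate", "map", "prioritize", "stats", "kinetics".
#' @param config a [run_config()].
#' @param state named list of outputs from earlier stages (as returned by
#'   previous [run_stage()] calls); the simulate stage needs none.
#' @param out_dir optional directory; when given, stage outputs are written
#'   in their interchange formats.
#' @return The stage's outputs (a named list).
#' @export
run_stage <- function(stage, config, state = list(), out_dir = NULL) {
  if (!stage %in% PIPELINE_STAGES)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  seed <- config$seed
  switch(stage,
    simulate = stage_simulate(config, seed, out_dir),
    map = stage_map(config, state, out_dir),
    prioritize = stage_prioritize(config, state),
    stats = stage_stats(config, state),
    kinetics = stage_kinetics(config, seed, out_dir))
}

stage_simulate <- function(config, seed, out_dir) {
  pop <- build_population(config$sim, seed = derive_seed(seed, 1L))
  ped <- pop$pedigree
  cases <- ped$id[ped$phenotype == "affected"]
  controls <- sample_controls(ped, config$sim$n_array_controls,
                              derive_seed(seed, 2L))
  gm <- emit_array_genotypes(pop$haplotypes,
                             error_rate = config$sim$genotyping_error_rate,
                             seed = derive_seed(seed, 3L),
                             samples = c(cases, controls))
  wgs <- emit_wgs_callset(pop, config$sim, seed = derive_seed(seed, 4L))
  if (!is.null(out_dir)) {
    write_vcf(gm, file.path(out_dir, "array_genotypes.vcf"))
    write_ped_map(gm, file.path(out_dir, "array_genotypes"))
    write_vcf(wgs$callset, file.path(out_dir, "wgs_callset.vcf"))
    write_gene_gff3(pop$gene, file.path(out_dir, "toy_gene.gff3"))
    write_cds_fasta(pop$gene, file.path(out_dir, "toy_gene_cds.fasta"))
    utils::write.table(ped, file.path(out_dir, "pedigree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(wgs$truth, file.path(out_dir, "wgs_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(wgs$catalogue, file.path(out_dir, "catalogue.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(pop = pop, array = gm, wgs = wgs, cases = cases, controls = controls)
}

sample_controls <- function(ped, n, seed) {
  set.seed(seed)
  pool <- ped$id[ped$phenotype == "unaffected"]
  sample(pool, min(n, length(pool)))
}

stage_map <- function(config, state, out_dir) {
  if (is.null(state$simulate)) {
    vcf <- config$map$genotypes_vcf
    if (is.null(vcf))
      stop("stage map: no simulate-stage output and no genotypes_vcf in config")
    if (!file.exists(vcf))
      stop("stage map: genotype file not found: ", vcf)
    gm <- read_vcf(vcf)
    cases <- config$map$case_ids
    sim <- NULL
  } else {
    gm <- state$simulate$array
    cases <- state$simulate$cases
    sim <- state$simulate
  }
  segments <- shared_homozygosity_segments(
    gm, cases,
    max_missing_per_marker = config$map$max_missing_per_marker,
    min_markers = config$map$min_markers)
  scan <- NULL
  if (!is.null(sim)) {
    labels <- stats::setNames(
      ifelse(gm$samples %in% cases, "affected", "unaffected"), gm$samples)
    scan <- haplotype_window_scan(sim$pop$haplotypes, labels,
                                  window_size = config$scan$window_size,
                                  step = config$scan$step,
                                  min_count = config$scan$min_count)
  }
  if (!is.null(out_dir)) {
    write_bed(segments, file.path(out_dir, "shared_homozygosity.bed"))
    if (!is.null(scan))
      manhattan_table(scan, file.path(out_dir, "manhattan.tsv"))
  }
  list(segments = segments, scan = scan)
}

stage_prioritize <- function(config, state) {
  if (is.null(state$simulate)) stop("stage prioritize: simulate stage required")
  wgs <- state$simulate$wgs
  rep_a <- cascade_a(wgs$callset, wgs$cohorts$cases, wgs$cohorts$noncarriers,
                     wgs$catalogue, wgs$gene)
  rep_b <- cascade_b(wgs$callset, wgs$cohorts$cases, wgs$cohorts$carriers,
                     wgs$cohorts$noncarriers, wgs$gene)
  list(cascade_a = rep_a, cascade_b = rep_b)
}

stage_stats <- function(config, state) {
  if (is.null(state$simulate)) stop("stage stats: simulate stage required")
  pop <- state$simulate$pop
  ped <- pop$pedigree
  copies <- causal_copies(pop$haplotypes, pop$causal$chrom, pop$causal$pos)
  unaff <- ped$id[ped$phenotype == "unaffected"]
  counts <- c(n_homref = sum(copies[unaff] == 0L),
              n_het = sum(copies[unaff] == 1L),
              n_homalt = sum(copies[unaff] == 2L))
  hwe <- hwe_test(counts["n_homref"], counts["n_het"], counts["n_homalt"])
  freq <- allele_frequency_percent(counts["n_homref"], counts["n_het"],
                                   counts["n_homalt"])
  seg <- check_recessive_segregation(ped, copies)
  carriers <- carrier_frequency_by_group(
    unname(copies[ped$id]),
    ifelse(ped$generation == 0L, "founders", "bred"))
  list(control_counts = counts, hwe = hwe, allele_freq = freq,
       segregation = seg, carrier_table = carriers)
}

stage_kinetics <- function(config, seed, out_dir) {
  k <- config$kinetics
  fit_group <- function(tau_mean, sem, n, stream) {
    set.seed(derive_seed(seed, stream))
    taus_true <- stats::rnorm(n, tau_mean, sem * sqrt(n))
    taus_true <- pmax(taus_true, 5)
    vapply(seq_len(n), function(i) {
      spec <- trace_sim_spec(tau_act = taus_true[i])
      spec$noise_sd <- k$noise_frac * trace_amplitude(spec, 80)
      tr <- simulate_traces(spec, 1L, seed = derive_seed(seed, stream + i))[[1L]]
      fit_activation(tr, voltage_mv = 80, window_ms = k$window_ms)$tau_ms
    }, numeric(1))
  }
  taus_mut <- fit_group(k$mut_tau, k$mut_sem, k$mut_n, 50L)
  taus_wt <- fit_group(k$wt_tau, k$wt_sem, k$wt_n, 100L)
  cmp <- compare_groups(taus_wt, taus_mut)
  iv <- normalize_iv(simulate_traces(trace_sim_spec(), 3L,
                                     seed = derive_seed(seed, 150L)))
  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(group = c(rep("WT", length(taus_wt)),
                           rep("MUT", length(taus_mut))),
                 tau_ms = c(taus_wt, taus_mut)),
      file.path(out_dir, "activation_taus.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(iv, file.path(out_dir, "iv_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(taus_wt = taus_wt, taus_mut = taus_mut, comparison = cmp, iv = iv)
}

#' Run the complete pipeline
#'
#' Executes simulate, map, prioritize, stats and kinetics in order, writes
#' every intermediate file in its interchange format plus a consolidated
#' JSON report, and returns the full run state.  Identical config + seed
#' gives a byte-identical report.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param verbose print stage progress and timings to the console (and to
#'   `run.log` under `out_dir`).
#' @return list of class `run_report`: stage outputs (`simulate`, `map`,
#'   `prioritize`, `stats`, `kinetics`) plus `summary` (the JSON-ready
#'   consolidated report) and `provenance`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_file <- if (!is.null(out_dir)) file.path(out_dir, "run.log") else NULL
  say <- function(...) {
    msg <- sprintf(...)
    if (verbose) message(msg)
    if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  }
  state <- list()
  for (stage in PIPELINE_STAGES) {
    t0 <- proc.time()[["elapsed"]]
    state[[stage]] <- tryCatch(
      run_stage(stage, config, state, out_dir),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    say("stage %-10s done in %.2f s", stage,
        proc.time()[["elapsed"]] - t0)
  }
  summary <- summarize_run(config, state)
  prov <- list(seed = config$seed,
               package_version = as.character(utils::packageVersion("autozyg")))
  if (!is.null(out_dir)) {
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(config_to_json(config), cfg_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    prov$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(c(summary, list(provenance = prov)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(c(state, list(summary = summary, provenance = prov)),
            class = "run_report")
}

config_to_json <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

## the consolidated, JSON-serializable view of a run
summarize_run <- function(config, state) {
  seg <- state$map$segments
  cluster <- state$simulate$wgs$cluster
  hit <- seg[seg$chrom == cluster$chrom &
             seg$start_bp <= min(cluster$genomic_positions) &
             seg$end_bp >= max(cluster$genomic_positions), , drop = FALSE]
  top <- state$map$scan[which.min(state$map$scan$p), ]
  ca <- state$prioritize$cascade_a
  cb <- state$prioritize$cascade_b
  nonsyn <- Filter(function(r) r$class != "synonymous", cb$consequences)
  list(
    mapping = list(
      n_segments = nrow(seg),
      causal_interval = if (nrow(hit)) as.list(hit[1L, ]) else NULL,
      causal_interval_mb = if (nrow(hit)) interval_length_mb(hit[1L, ]) else NA,
      scan_top = list(chrom = top$chrom, mid_bp = top$mid_bp, p = top$p)),
    cascade_a = c(as.list(ca$counts),
                  list(percent_removed_step1 = ca$percent_removed_step1)),
    cascade_b = list(n_survivors = nrow(cb$survivors),
                     breakdown = as.list(cb$breakdown),
                     coding_split = as.list(cb$coding_split),
                     nonsyn_labels = vapply(nonsyn, `[[`, "", "short_label")),
    stats = list(control_counts = as.list(state$stats$control_counts),
                 hwe_p = state$stats$hwe$p,
                 allele_freq_percent = state$stats$allele_freq$percent,
                 segregation_pass = state$stats$segregation$pass),
    kinetics = list(mean_tau_wt = state$kinetics$comparison$mean_a,
                    mean_tau_mut = state$kinetics$comparison$mean_b,
                    fold_ratio = state$kinetics$comparison$fold_ratio,
                    t = state$kinetics$comparison$t,
                    p = state$kinetics$comparison$p))
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("Pipeline run summary\n")
  cat(sprintf("  mapping: %d shared-homozygosity segment(s); causal interval %s (%.2f Mb)\n",
              s$mapping$n_segments,
              if (is.null(s$mapping$causal_interval)) "NOT FOUND" else
                sprintf("%s:%d-%d", s$mapping$causal_interval$chrom,
                        s$mapping$causal_interval$start_bp,
                        s$mapping$causal_interval$end_bp),
              s$mapping$causal_interval_mb))
  cat(sprintf("  cascade A: %d -> %d -> %d -> %d -> %d -> %d (%d%% removed at step 1)\n",
              s$cascade_a$total, s$cascade_a$remaining,
              s$cascade_a$hom_all_cases, s$cascade_a$in_transcribed,
              s$cascade_a$in_orf, s$cascade_a$aa_changing,
              s$cascade_a$percent_removed_step1))
  cat(sprintf("  cascade B: %d survivors (%d intergenic, %d intronic, %d coding); non-syn: %s\n",
              s$cascade_b$n_survivors, s$cascade_b$breakdown$intergenic,
              s$cascade_b$breakdown$intronic, s$cascade_b$breakdown$coding,
              paste(s$cascade_b$nonsyn_labels, collapse = ", ")))
  cat(sprintf("  stats: HWE p = %.3g, allele freq = %.2f%%, segregation %s\n",
              s$stats$hwe_p, s$stats$allele_freq_percent,
              if (s$stats$segregation_pass) "PASS" else "FAIL"))
  cat(sprintf("  kinetics: tau WT %.0f ms vs MUT %.0f ms (x%.1f, t-test p = %.2g)\n",
              s$kinetics$mean_tau_wt, s$kinetics$mean_tau_mut,
              s$kinetics$fold_ratio, s$kinetics$p))
  invisible(x)
}
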