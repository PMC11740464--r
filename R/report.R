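#' Two-group comparisons over several outcomes with FDR control
#'
#' Applies [compare_two_groups()] to each outcome column of a per-neuron (or
#' per-case) table split by a two-level grouping column, then adjusts the p
#' values with Benjamini-Hochberg within the family of outcomes.
#'
#' @param data Data.frame, one row per unit.
#' @param outcomes Character vector of outcome column names.
#' @param group_col Name of the two-level grouping column.
#' @param mode Test mode, see [compare_two_groups()].
#' @return Data.frame with one row per outcome: test, statistic, df, p,
#'   `p_adj`, group labels and sizes.
#' @export
run_group_comparisons <- function(data, outcomes, group_col,
                                  mode = "welch-t") {
  missing_cols <- setdiff(c(outcomes, group_col), names(data))
  if (length(missing_cols))
    stop("columns absent from the table: ",
         paste(missing_cols, collapse = ", "))
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2) stop("`group_col` must have exactly two levels")
  lv <- levels(g)
  rows <- lapply(outcomes, function(oc) {
    a <- data[[oc]][g == lv[1]]; b <- data[[oc]][g == lv[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    cmp <- compare_two_groups(a, b, mode)
    cbind(data.frame(outcome = oc, group_a = lv[1], group_b = lv[2],
                     mean_a = mean(a), mean_b = mean(b)), cmp)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Run the full synthetic pipeline end to end
#'
#' Generates seeded synthetic cohorts under the intact-circuit ("sham") and
#' injured ("tbi") presets, extracts every neuron's summary, analyses the
#' firing response across current levels with a mixed-design ANOVA, and
#' compares AP features between neurons apposed to and away from satellite
#' microglia. Optionally also simulates the network-hyperexcitability latency
#' experiment (sham vs TBI presets) and a 3D stack with satellite and cfos
#' analysis.
#'
#' @param seed Integer master seed; all component seeds derive from it.
#' @param n_per_group Neurons per condition in each cohort.
#' @param components Subset of `c("ephys", "network", "stack")`.
#' @param latency_n Latency sample sizes `c(sham, tbi)`.
#' @return A list of class `satmg_demo` with elements `ephys` (per-cohort
#'   tables, mixed ANOVA tables, AP-feature comparisons), `network` (per-slice
#'   latencies and the group test), `stack` (satellite calls, cfos summary,
#'   Sholl profile of the first microglia), and `seed`.
#' @export
run_demo <- function(seed = 1, n_per_group = 12,
                     components = c("ephys", "network", "stack"),
                     latency_n = c(8, 6)) {
  components <- match.arg(components, several.ok = TRUE)
  dseed <- function(k) (as.integer(seed) %% 100000L) * 17L + k
  out <- list(seed = seed)

  if ("ephys" %in% components) {
    cohorts <- list()
    for (preset in c("sham", "tbi")) {
      cfg <- cohort_config(preset = preset, n_per_group = n_per_group,
                           seed = dseed(if (preset == "sham") 1L else 2L))
      sim <- simulate_cohort(cfg)
      summ <- summarize_cohort(sim$sweep_sets)
      fim <- cohort_fi_matrices(summ)
      amps <- as.numeric(colnames(fim$counts))
      long <- data.frame(
        subject = rep(rownames(fim$counts), times = ncol(fim$counts)),
        group = rep(fim$condition, times = ncol(fim$counts)),
        within = rep(amps, each = nrow(fim$counts)),
        y = as.vector(fim$counts))
      anova_counts <- rm_two_way_anova(long)
      cmp <- run_group_comparisons(
        summ$table[summ$table$included, ],
        outcomes = c("threshold_mV", "ahp_mV", "rise_slope_mV_per_ms",
                     "input_resistance_MOhm"),
        group_col = "condition", mode = "welch-t")
      cohorts[[preset]] <- list(truth = sim$truth, table = summ$table,
                                anova_counts = anova_counts,
                                ap_comparisons = cmp)
    }
    out$ephys <- cohorts
  }

  if ("network" %in% components) {
    presets <- data.frame(
      group = rep(c("sham", "tbi"), times = latency_n),
      t0_mean = rep(c(100, 40), times = latency_n))
    lat <- numeric(nrow(presets))
    set.seed(dseed(3L))
    t0 <- pmax(15, stats::rnorm(nrow(presets), presets$t0_mean, 15))
    for (i in seq_len(nrow(presets))) {
      cfg <- burst_scene_config(duration_s = 200, first_onset_s = t0[i],
                                interval_s = 20, onset_jitter_s = 0.5,
                                seed = dseed(10L + i))
      tr <- simulate_network_trace(cfg)
      ev <- detect_bursts(tr$trace, tr$sample_rate_hz)
      lat[i] <- latency_to_second_burst(ev)$latency_s
    }
    res <- data.frame(group = presets$group, latency_s = lat)
    test <- compare_two_groups(lat[presets$group == "sham"],
                               lat[presets$group == "tbi"], "unpaired-t")
    out$network <- list(latencies = res, test = test)
  }

  if ("stack" %in% components) {
    scene <- stack_scene_config(seed = dseed(4L))
    stk <- render_stack(scene)
    seg_n <- segment_stack(stk$channels$neurons, stk$voxel_um,
                           intensity_threshold = 50, min_size_um3 = 20)
    seg_m <- segment_stack(stk$channels$microglia, stk$voxel_um,
                           intensity_threshold = 50, min_size_um3 = 5)
    calls <- classify_satellites(seg_n, seg_m, stk$truth$microglia,
                                 stk$truth$filaments,
                                 process_radius_um = scene$process_radius_um)
    cf <- cfos_positivity(stk$channels$cfos, seg_n, calls$calls$satellite)
    mg1 <- stk$truth$microglia[1, ]
    sh <- sholl_profile(stk$truth$filaments[[mg1$id]],
                        c(mg1$z_um, mg1$y_um, mg1$x_um), max_radius_um = 20)
    out$stack <- list(truth = stk$truth, satellite = calls, cfos = cf,
                      sholl = sh)
  }
  class(out) <- "satmg_demo"
  out
}

#' @export
print.satmg_demo <- function(x, ...) {
  cat(sprintf("Synthetic pipeline demo (seed %s)\n", x$seed))
  if (!is.null(x$ephys)) {
    for (preset in names(x$ephys)) {
      an <- x$ephys[[preset]]$anova_counts
      cat(sprintf(
        "  %s cohort: group p = %.4g, current x group p = %.4g (AP counts, GG)\n",
        preset, an$p[an$effect == "group"],
        an$p_gg[an$effect == "within_x_group"]))
    }
  }
  if (!is.null(x$network))
    cat(sprintf("  latency sham vs tbi: p = %.4g\n", x$network$test$p))
  if (!is.null(x$stack))
    cat(sprintf("  stack: %.1f%% of neurons have a satellite microglia\n",
                x$stack$satellite$percent_satellite))
  invisible(x)
}

#' Write the report files for a demo (or assembled) analysis
#'
#' Emits per-figure-analog TSV tables plus a machine-readable JSON summary.
#' Output is deterministic for fixed inputs; missing optional sections are
#' simply omitted.
#'
#' @param demo A `satmg_demo` (or a compatible list).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the files written.
#' @export
build_report <- function(demo, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <<- c(files, path)
  }
  summary_json <- list(seed = demo$seed,
                       note = paste("repeated-measures analyses are",
                                    "complete-case; subjects with missing",
                                    "levels are dropped and counted"))

  if (!is.null(demo$ephys)) {
    for (preset in names(demo$ephys)) {
      co <- demo$ephys[[preset]]
      wtsv(co$table, sprintf("neuron_summaries_%s.tsv", preset))
      wtsv(co$anova_counts, sprintf("fi_anova_%s.tsv", preset))
      wtsv(co$ap_comparisons, sprintf("ap_comparisons_%s.tsv", preset))
      an <- co$anova_counts
      summary_json[[paste0("ephys_", preset)]] <- list(
        p_group = an$p[an$effect == "group"],
        p_interaction_gg = an$p_gg[an$effect == "within_x_group"],
        n_dropped = attr(an, "n_dropped"))
    }
  }
  if (!is.null(demo$network)) {
    wtsv(demo$network$latencies, "latency.tsv")
    wtsv(demo$network$test, "latency_test.tsv")
    summary_json$network <- list(p = demo$network$test$p)
  }
  if (!is.null(demo$stack)) {
    wtsv(demo$stack$satellite$calls, "satellite_calls.tsv")
    wtsv(demo$stack$cfos$summary, "cfos_summary.tsv")
    wtsv(demo$stack$sholl, "sholl.tsv")
    summary_json$stack <- list(
      percent_satellite = demo$stack$satellite$percent_satellite)
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "report.json"))
  invisible(files)
}
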