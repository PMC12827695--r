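# End-to-end orchestration: (simulate | read) -> ETS -> dynamics -> frame
# networks -> graph metrics -> NBS -> harmonized group statistics, with
# artifacts written per stage and one master seed.

#' Pipeline run configuration
#'
#' @param input_dir Directory of subject files + metadata.csv (exclusive
#'   with `simulate_spec`).
#' @param simulate_spec A [cohort_spec()] to generate the cohort in place.
#' @param output_dir Directory for artifacts.
#' @param top_fraction High-amplitude frame fraction (default 0.10).
#' @param sparsity_grid Proportional thresholds (default
#'   [default_sparsity_grid()]).
#' @param fc_method `"mean_cofluctuation"` (default) or `"frame_pearson"`.
#' @param nbs An [nbs_config()].
#' @param n_nulls Null graphs per thresholded graph for gamma/lambda/sigma.
#' @param rewires_per_edge Accepted swaps per edge per null.
#' @param units `"frames"` or `"seconds"` for TTD summaries.
#' @param alpha Significance level for FDR / reporting.
#' @param tr_seconds TR attached to series read from disk.
#' @param seed Master seed governing simulation, nulls and permutations.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulate_spec = NULL,
                       output_dir = tempfile("edgedyn_run_"),
                       top_fraction = 0.10,
                       sparsity_grid = default_sparsity_grid(),
                       fc_method = c("mean_cofluctuation", "frame_pearson"),
                       nbs = nbs_config(), n_nulls = 100L,
                       rewires_per_edge = 10L,
                       units = c("frames", "seconds"), alpha = 0.05,
                       tr_seconds = 3.0, seed = 1L) {
  fc_method <- match.arg(fc_method)
  units <- match.arg(units)
  if (is.null(input_dir) == is.null(simulate_spec))
    stop_edgedyn("give exactly one of 'input_dir' or 'simulate_spec'")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop_edgedyn("input_dir does not exist: %s", input_dir)
  if (!is.null(simulate_spec)) stopifnot(inherits(simulate_spec, "cohort_spec"))
  stopifnot(inherits(nbs, "nbs_config"))
  if (top_fraction <= 0 || top_fraction >= 1)
    stop_edgedyn("'top_fraction' must be in (0, 1)")
  structure(list(input_dir = input_dir, simulate_spec = simulate_spec,
                 output_dir = output_dir, top_fraction = top_fraction,
                 sparsity_grid = as.numeric(sparsity_grid),
                 fc_method = fc_method, nbs = nbs,
                 n_nulls = check_count(n_nulls, "n_nulls", 0L),
                 rewires_per_edge = check_count(rewires_per_edge,
                                                "rewires_per_edge", 1L),
                 units = units, alpha = alpha,
                 tr_seconds = check_positive(tr_seconds, "tr_seconds"),
                 seed = check_count(seed, "seed", 0L)),
            class = "run_config")
}

log_stage <- function(stage, subject, ...) {
  extra <- paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                 collapse = " ")
  message(sprintf("[edgedyn] stage=%s subject=%s %s", stage, subject, extra))
}

#' Run the full edge-centric analysis pipeline
#'
#' Stages: `simulate` (or read), `ets`, `dynamics`, `networks`, `metrics`,
#' `nbs`, `stats`. Later stages always compute their prerequisites in
#' memory; `stages` controls which artifacts are written. Everything is
#' deterministic under `config$seed`.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @param quiet Suppress per-stage log lines.
#' @return Invisible list with `dynamics`, `metrics_global`,
#'   `metrics_nodal`, `nbs` (high/low), `stats` (dynamics/global/nodal
#'   tables, correlations), `metadata`, `output_dir`.
#' @export
run_pipeline <- function(config, stages = "all", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "ets", "dynamics", "networks", "metrics",
                  "nbs", "stats")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_edgedyn("unknown stage(s): %s", paste(bad, collapse = ", "))
  say <- if (quiet) function(...) invisible() else log_stage
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  want <- function(s) s %in% stages
  # highest stage requested decides how deep we compute
  depth <- max(match(stages, all_stages))

  # --- input ---------------------------------------------------------
  if (!is.null(config$simulate_spec)) {
    spec <- config$simulate_spec
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
    series <- cohort$series
    metadata <- cohort$metadata
    if (want("simulate")) {
      write_cohort(cohort, file.path(out, "cohort"))
      say("simulate", "-", n = length(series))
    }
  } else {
    inp <- read_cohort(config$input_dir, tr_seconds = config$tr_seconds)
    series <- inp$series
    metadata <- inp$metadata
  }
  groups <- unique(metadata$group)
  if (length(groups) != 2L)
    stop_edgedyn("expected exactly 2 groups, found: %s",
                 paste(groups, collapse = ", "))
  res <- list(metadata = metadata, output_dir = out)
  if (depth < 2L) { write_manifest(config, out); return(invisible(res)) }

  # --- per-subject ETS, dynamics, state FC ---------------------------
  n <- length(series)
  dyn <- vector("list", n)
  stacks <- list(high = NULL, low = NULL)
  edge_idx <- NULL
  for (s in seq_len(n)) {
    id <- metadata$subject_id[s]
    ser <- series[[s]]
    ets <- tryCatch(compute_ets(zscore_series(ser)), error = function(e)
      stop_edgedyn("stage ets failed for subject %s: %s", id,
                   conditionMessage(e)))
    if (is.null(edge_idx)) {
      edge_idx <- ets$edge_index
      stacks$high <- matrix(NA_real_, n, nrow(edge_idx))
      stacks$low <- matrix(NA_real_, n, nrow(edge_idx))
    }
    rss <- compute_rss(ets)
    prof <- event_profile(rss)
    dyn[[s]] <- data.frame(subject_id = id,
                           n_troughs = length(prof$trough_frames),
                           n_peaks = length(prof$peak_frames),
                           mean_peak_amplitude = prof$mean_peak_amplitude,
                           mean_ttd_frames = prof$mean_ttd,
                           mean_ttd_seconds = prof$mean_ttd * ser$tr_seconds,
                           stringsAsFactors = FALSE)
    masks <- split_frames(rss, config$top_fraction)
    for (st in c("high", "low")) {
      fc <- build_state_fc(ets, masks[[st]], method = config$fc_method,
                           raw = ser)
      stacks[[st]][s, ] <- fc$edge_values
    }
    say("ets", id, frames = ncol(ets$data), troughs = length(prof$trough_frames))
  }
  dyn <- do.call(rbind, dyn)
  if (want("dynamics"))
    utils::write.csv(dyn, file.path(out, "dynamics.csv"), row.names = FALSE)
  res$dynamics <- dyn
  roi_labels <- series[[1L]]$roi_labels
  if (depth < 4L) { write_manifest(config, out); return(invisible(res)) }

  # --- graphs + metrics ----------------------------------------------
  if (depth >= 5L) {
    glob_rows <- list(); nod_rows <- list()
    for (s in seq_len(n)) {
      id <- metadata$subject_id[s]
      for (st in c("high", "low")) {
        fcmat <- matrix(0, length(roi_labels), length(roi_labels),
                        dimnames = list(roi_labels, roi_labels))
        fcmat[cbind(edge_idx[, 1L], edge_idx[, 2L])] <- stacks[[st]][s, ]
        fcmat[cbind(edge_idx[, 2L], edge_idx[, 1L])] <- stacks[[st]][s, ]
        gs <- threshold_proportional(fcmat, config$sparsity_grid)
        mt <- metric_table(gs, n_nulls = config$n_nulls,
                           rewires_per_edge = config$rewires_per_edge,
                           seed = config$seed + 1000L * s +
                             (st == "low") * 500L)
        mt$global <- cbind(subject_id = id, state = st, mt$global)
        mt$nodal <- cbind(subject_id = id, state = st, mt$nodal)
        glob_rows[[paste(id, st)]] <- mt$global
        nod_rows[[paste(id, st)]] <- mt$nodal
      }
      say("metrics", id)
    }
    res$metrics_global <- do.call(rbind, glob_rows)
    res$metrics_nodal <- do.call(rbind, nod_rows)
    rownames(res$metrics_global) <- rownames(res$metrics_nodal) <- NULL
    if (want("metrics")) {
      utils::write.csv(res$metrics_global,
                       file.path(out, "global_metrics.csv"), row.names = FALSE)
      utils::write.csv(res$metrics_nodal,
                       file.path(out, "nodal_metrics.csv"), row.names = FALSE)
    }
  }
  if (want("networks")) {
    # state FC stacks as edge-value tables (subjects x edges)
    for (st in c("high", "low")) {
      df <- as.data.frame(stacks[[st]])
      names(df) <- paste(roi_labels[edge_idx[, 1L]],
                         roi_labels[edge_idx[, 2L]], sep = "--")
      utils::write.csv(cbind(subject_id = metadata$subject_id, df),
                       file.path(out, sprintf("state_fc_%s.csv", st)),
                       row.names = FALSE)
    }
  }
  if (depth < 6L) { write_manifest(config, out); return(invisible(res)) }

  # --- NBS ------------------------------------------------------------
  ga <- metadata$group == groups[1L]
  res$nbs <- list()
  for (st in c("high", "low")) {
    cfg <- config$nbs
    cfg$seed <- config$seed + 77L + (st == "low")
    r <- nbs_permutation(stacks[[st]][ga, , drop = FALSE],
                         stacks[[st]][!ga, , drop = FALSE],
                         edge_idx, cfg)
    res$nbs[[st]] <- r
    if (want("nbs")) {
      comps <- lapply(r$components, function(c)
        list(nodes = roi_labels[c$nodes],
             edges = cbind(roi_labels[c$edges[, 1L]],
                           roi_labels[c$edges[, 2L]]),
             size = c$size, p_value = c$p_value))
      jsonlite::write_json(
        list(state = st, tail = cfg$tail, t_threshold = cfg$t_threshold,
             n_permutations = cfg$n_permutations,
             group_a = groups[1L], group_b = groups[2L],
             components = comps),
        file.path(out, sprintf("nbs_%s.json", st)),
        auto_unbox = TRUE, digits = NA)
    }
    say("nbs", "-", state = st, components = length(r$components))
  }
  if (depth < 7L) { write_manifest(config, out); return(invisible(res)) }

  # --- harmonized statistics -----------------------------------------
  grp <- factor(metadata$group, levels = groups)
  feat <- data.frame(mean_peak_amplitude = dyn$mean_peak_amplitude,
                     mean_ttd = if (config$units == "seconds")
                       dyn$mean_ttd_seconds else dyn$mean_ttd_frames)
  res$stats <- list()
  res$stats$dynamics <- group_comparison_table(
    feat, grp, site = metadata$site, fdr = FALSE)
  if (!is.null(res$metrics_global)) {
    auc <- res$metrics_global[res$metrics_global$summary == "AUC", ]
    wide <- data.frame(row.names = metadata$subject_id)
    for (m in c("Cp", "Lp", "gamma", "lambda", "sigma", "Eglob", "Eloc"))
      for (st in c("high", "low"))
        wide[[paste(st, m, sep = "_")]] <-
          auc[[m]][match(paste(metadata$subject_id, st),
                         paste(auc$subject_id, auc$state))]
    wide <- wide[, colSums(is.na(wide)) == 0, drop = FALSE]
    res$stats$global <- group_comparison_table(wide, grp,
                                               site = metadata$site,
                                               fdr = FALSE)
    nod <- res$metrics_nodal[res$metrics_nodal$summary == "AUC", ]
    nwide <- data.frame(row.names = metadata$subject_id)
    for (m in c("Dc", "Bc", "Ne"))
      for (st in c("high", "low"))
        for (r in roi_labels)
          nwide[[paste(st, m, r, sep = "_")]] <-
            nod[[m]][match(paste(metadata$subject_id, st, r),
                           paste(nod$subject_id, nod$state, nod$roi))]
    # nodal metrics: no harmonization, FDR across nodes/metrics
    res$stats$nodal <- group_comparison_table(nwide, grp, site = NULL,
                                              fdr = TRUE,
                                              alpha = config$alpha)
  }
  # Spearman correlations of dynamics with clinical variables
  cors <- list()
  for (v in c("apoe4_count", "mmse", "moca"))
    for (m in names(feat)) {
      cr <- tryCatch(spearman_cor(feat[[m]], metadata[[v]],
                                  labels = c(m, v)),
                     error = function(e) NULL)
      if (!is.null(cr))
        cors[[paste(m, v)]] <- data.frame(metric = m, variable = v,
                                          rho = cr$rho, p = cr$p_value,
                                          n = cr$n, stringsAsFactors = FALSE)
    }
  res$stats$correlations <- do.call(rbind, cors)
  if (!is.null(res$stats$correlations)) {
    rownames(res$stats$correlations) <- NULL
    res$stats$correlations$p_fdr <- fdr_bh(res$stats$correlations$p)$adjusted
  }
  if (want("stats")) {
    utils::write.csv(res$stats$dynamics, file.path(out, "stats_dynamics.csv"),
                     row.names = FALSE)
    if (!is.null(res$stats$global))
      utils::write.csv(res$stats$global, file.path(out, "stats_global.csv"),
                       row.names = FALSE)
    if (!is.null(res$stats$nodal))
      utils::write.csv(res$stats$nodal, file.path(out, "stats_nodal.csv"),
                       row.names = FALSE)
    if (!is.null(res$stats$correlations))
      utils::write.csv(res$stats$correlations,
                       file.path(out, "correlations.csv"), row.names = FALSE)
  }
  say("stats", "-", metrics = length(res$stats))
  write_manifest(config, out)
  invisible(res)
}

write_manifest <- function(config, out) {
  cfg <- unclass(config)
  cfg$simulate_spec <- if (is.null(cfg$simulate_spec)) NULL
                       else unclass(cfg$simulate_spec)
  cfg$nbs <- unclass(cfg$nbs)
  jsonlite::write_json(
    list(package = "edgedyn",
         version = as.character(utils::packageVersion("edgedyn")),
         r_version = R.version.string,
         seed = config$seed,
         config = cfg,
         config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = "")))),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(NULL)
}
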