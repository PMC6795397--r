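#' Pipeline run configuration
#'
#' Bundles every tunable parameter of a contractility run. Exactly one input
#' source must be given: a multi-page TIFF path (`input`) or a
#' [motion_spec()] (`spec`) for a synthetic recording. Every field is echoed
#' into the run manifest so that a run is reconstructible from the manifest
#' alone.
#'
#' @param input path to a multi-page TIFF stack, or `NULL`.
#' @param spec a [motion_spec()] for synthetic input, or `NULL`.
#' @param frame_rate acquisition rate in Hz (required with `input`; taken
#'   from `spec` otherwise).
#' @param piv a [piv_params()].
#' @param convention contractility convention, `"absolute"` or `"signed"`.
#' @param min_prominence,min_separation beat-detection parameters
#'   ([detect_beats()]).
#' @param noise_sigma,n_speckles,speckle_sigma,interpolation synthetic
#'   rendering parameters (ignored with file input).
#' @param tails,variance group-statistics options ([unpaired_t_test()]).
#' @param output_dir directory for result files.
#' @param seed integer seed for all randomness in the run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, spec = NULL, frame_rate = NULL,
                       piv = piv_params(),
                       convention = c("absolute", "signed"),
                       min_prominence = 0.3, min_separation = 0.4,
                       noise_sigma = 0.01, n_speckles = 2000,
                       speckle_sigma = 1.5, interpolation = "bilinear",
                       tails = 2, variance = "pooled",
                       output_dir = ".", seed = 1) {
  convention <- match.arg(convention)
  if (is.null(input) == is.null(spec))
    stopf("exactly one input source required: `input` path or `spec`")
  if (!is.null(spec)) stopifnot(inherits(spec, "motion_spec"))
  if (!is.null(input) && (is.null(frame_rate) || !is_number(frame_rate) ||
                          frame_rate <= 0))
    stopf("file input requires a positive `frame_rate`")
  stopifnot(inherits(piv, "piv_params"))
  structure(list(input = input, spec = spec, frame_rate = frame_rate,
                 piv = piv, convention = convention,
                 min_prominence = min_prominence,
                 min_separation = min_separation,
                 noise_sigma = noise_sigma, n_speckles = n_speckles,
                 speckle_sigma = speckle_sigma,
                 interpolation = interpolation, tails = tails,
                 variance = variance, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_manifest <- function(config, extra = list()) {
  m <- list(
    input = if (is.null(config$input)) NA else config$input,
    synthetic = !is.null(config$spec),
    spec = if (is.null(config$spec)) NULL else unclass(config$spec),
    frame_rate = if (is.null(config$frame_rate)) config$spec$frame_rate
                 else config$frame_rate,
    piv = unclass(config$piv),
    convention = config$convention,
    min_prominence = config$min_prominence,
    min_separation = config$min_separation,
    noise_sigma = config$noise_sigma,
    n_speckles = config$n_speckles,
    speckle_sigma = config$speckle_sigma,
    interpolation = config$interpolation,
    tails = config$tails,
    variance = config$variance,
    seed = config$seed)
  c(m, extra)
}

#' Run the contractility pipeline end to end
#'
#' Video (read or synthesized) to displacement fields to contractility trace
#' to beat metrics, with every product written to `output_dir`:
#' `trace.csv` (t, D, n_valid), `metrics.csv` and `metrics.json` (one row:
#' d_peak, d_mean, t_cycle, t_contract, n_beats), and `manifest.json`
#' recording every parameter and seed. Rerunning with the same configuration
#' produces bit-identical files.
#'
#' @param config a [run_config()].
#' @param verbose emit progress messages to stderr.
#' @return invisibly, a list with `trace` (`contractility_trace`), `metrics`
#'   (`beat_metrics`), `ref_index` and the output `paths`.
#' @export
run_contractility <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$spec)) {
    say("rendering synthetic video (%d frames)", config$spec$n_frames)
    tex <- make_speckle_texture(config$spec$width, config$spec$height,
                                config$n_speckles, config$speckle_sigma,
                                seed = config$seed + 1L)
    stack <- render_beating_video(tex, config$spec, config$noise_sigma,
                                  seed = config$seed,
                                  interpolation = config$interpolation)
  } else {
    say("reading %s", config$input)
    stack <- read_frame_stack(config$input, config$frame_rate)
  }

  say("selecting diastolic reference frame")
  speeds <- consecutive_speed_trace(stack, config$piv)
  ref <- select_reference_frame(stack, config$piv, speeds = speeds)
  say("reference frame %d; computing displacement series", ref)
  fields <- displacement_series(stack, ref, config$piv)
  trace <- contractility_trace(fields, config$convention)
  peaks <- detect_beats(trace, config$min_prominence, config$min_separation)
  metrics <- compute_metrics(trace, peaks)

  paths <- list(trace = file.path(config$output_dir, "trace.csv"),
                metrics_csv = file.path(config$output_dir, "metrics.csv"),
                metrics_json = file.path(config$output_dir, "metrics.json"),
                manifest = file.path(config$output_dir, "manifest.json"))
  write_trace_csv(trace, paths$trace)
  write.csv(as.data.frame(metrics), paths$metrics_csv, row.names = FALSE)
  jsonlite::write_json(
    c(as.list(as.data.frame(metrics)),
      list(per_beat = metrics$per_beat, ref_index = ref)),
    paths$metrics_json, auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(config_manifest(config, list(ref_index = ref)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       na = "null")
  say("done: D_peak = %.4g, T_cycle = %.3f s", metrics$d_peak,
      metrics$t_cycle)
  invisible(list(trace = trace, metrics = metrics, ref_index = ref,
                 paths = paths))
}

read_metrics_table <- function(x, label) {
  if (is.data.frame(x)) return(x)
  if (is.character(x)) {
    rows <- lapply(x, function(p) {
      if (!file.exists(p)) stopf("metrics file not found (%s): %s", label, p)
      read.csv(p)
    })
    return(do.call(rbind, rows))
  }
  stopf("group '%s' must be a data.frame or character vector of metrics files",
        label)
}

#' Compare beat metrics between two groups of recordings
#'
#' For each metric (d_peak, d_mean, t_cycle, t_contract), reports the group
#' means, SEMs and sizes, the percent difference of group b relative to
#' group a, and an unpaired t test. Input is one row of metrics per
#' recording (as written by [run_contractility()] to `metrics.csv`), given
#' as data.frames or vectors of file paths.
#'
#' @param group_a,group_b metrics tables (data.frame) or character vectors
#'   of `metrics.csv` paths, at least 2 recordings each.
#' @param labels length-2 group names for the report.
#' @param tails,variance see [unpaired_t_test()].
#' @param output optional CSV path for the report.
#' @return data.frame with one row per metric: `metric`, `mean_a`, `sem_a`,
#'   `n_a`, `mean_b`, `sem_b`, `n_b`, `percent_difference`, `t`, `df`, `p`,
#'   `tails`.
#' @export
run_group_comparison <- function(group_a, group_b,
                                 labels = c("group_a", "group_b"),
                                 tails = 2, variance = "pooled",
                                 output = NULL) {
  a <- read_metrics_table(group_a, labels[1])
  b <- read_metrics_table(group_b, labels[2])
  if (nrow(a) < 2L) stopf("group '%s' has fewer than 2 recordings", labels[1])
  if (nrow(b) < 2L) stopf("group '%s' has fewer than 2 recordings", labels[2])
  metrics <- intersect(c("d_peak", "d_mean", "t_cycle", "t_contract"),
                       intersect(names(a), names(b)))
  rows <- lapply(metrics, function(m) {
    va <- a[[m]][is.finite(a[[m]])]
    vb <- b[[m]][is.finite(b[[m]])]
    if (length(va) < 2L || length(vb) < 2L || (sd(va) == 0 && sd(vb) == 0)) {
      # identical degenerate groups: difference 0, no evidence against H0
      cmp <- list(mean_a = mean(va), sem_a = group_summary(va)$sem,
                  n_a = length(va), mean_b = mean(vb),
                  sem_b = group_summary(vb)$sem, n_b = length(vb),
                  percent_difference =
                    if (mean(va) != 0) percent_difference(mean(va), mean(vb))
                    else NA_real_,
                  t = if (mean(va) == mean(vb)) 0 else NA_real_,
                  df = NA_real_,
                  p = if (mean(va) == mean(vb)) 1 else NA_real_)
    } else {
      cmp <- unpaired_t_test(va, vb, tails = tails, variance = variance)
    }
    data.frame(metric = m, mean_a = cmp$mean_a, sem_a = cmp$sem_a,
               n_a = cmp$n_a, mean_b = cmp$mean_b, sem_b = cmp$sem_b,
               n_b = cmp$n_b, percent_difference = cmp$percent_difference,
               t = cmp$t, df = cmp$df, p = cmp$p, tails = tails)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  if (!is.null(output)) write.csv(out, output, row.names = FALSE)
  out
}

#' Fold-change report from a Cq table
#'
#' Computes the relative expression of a treated group versus a reference
#' group from a long-format Cq table. When a control assay is present, the
#' full per-sample path is used (dCt per sample, then 2^-ddCt on the group
#' means) and an unpaired t test on the per-sample dCt values is reported;
#' otherwise the target Cq values are treated as already normalized.
#'
#' @param table a Cq data.frame (`sample_id`, `group`, `assay`, `cq`) or a
#'   CSV path.
#' @param reference_group,treated_group group labels to compare.
#' @param target,control assay labels; set `control = NULL` for
#'   already-normalized tables.
#' @param tails,variance see [unpaired_t_test()].
#' @param output optional CSV path for the one-row report.
#' @return one-row data.frame: `reference_group`, `treated_group`,
#'   `mean_dct_reference`, `mean_dct_treated`, `fold_change`,
#'   `percent_difference` (of expression, fold - 1 in percent), `t`, `df`,
#'   `p` (`NA` without per-sample replication).
#' @export
run_expression_report <- function(table, reference_group, treated_group,
                                  target = "target", control = "control",
                                  tails = 2, variance = "pooled",
                                  output = NULL) {
  if (is.character(table)) {
    if (!file.exists(table)) stopf("Cq table not found: %s", table)
    table <- read.csv(table)
  }
  need <- c("sample_id", "group", "assay", "cq")
  if (!is.data.frame(table) || nrow(table) == 0)
    stopf("empty or invalid Cq table")
  bad <- which(!stats::complete.cases(table[intersect(need, names(table))]))
  if (!all(need %in% names(table)))
    stopf("Cq table needs columns %s", paste(need, collapse = ", "))
  if (length(bad))
    stopf("malformed Cq table: missing values in row(s) %s",
          paste(bad, collapse = ", "))

  if (!is.null(control) && control %in% table$assay) {
    d <- normalize_dct(table, target = target, control = control)
  } else {
    t_rows <- table[table$assay == target, ]
    d <- data.frame(sample_id = t_rows$sample_id, group = t_rows$group,
                    dct = t_rows$cq, stringsAsFactors = FALSE)
  }
  for (g in c(reference_group, treated_group))
    if (!g %in% d$group) stopf("group '%s' absent from the Cq table", g)
  dref <- d$dct[d$group == reference_group]
  dtre <- d$dct[d$group == treated_group]
  fold <- fold_change_ddct(dtre, dref)

  if (length(dref) >= 2L && length(dtre) >= 2L &&
      !(sd(dref) == 0 && sd(dtre) == 0)) {
    ht <- unpaired_t_test(dref, dtre, tails = tails, variance = variance)
    tstat <- ht$t; df <- ht$df; p <- ht$p
  } else {
    tstat <- NA_real_; df <- NA_real_; p <- NA_real_
  }
  out <- data.frame(reference_group = reference_group,
                    treated_group = treated_group,
                    mean_dct_reference = mean(dref),
                    mean_dct_treated = mean(dtre),
                    fold_change = fold,
                    percent_difference = 100 * (fold - 1),
                    t = tstat, df = df, p = p)
  if (!is.null(output)) write.csv(out, output, row.names = FALSE)
  out
}
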