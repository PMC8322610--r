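#' Write cohort traces and metadata to a directory
#'
#' One CSV per trial (`P<participant>_<coordination>_<direction>_<trial>.csv`
#' with columns `t_s, head_yaw_deg, trunk_yaw_deg`) plus `metadata.csv`.
#' UTF-8, comma separator, '.' decimal, header row; angles in degrees,
#' times in seconds, errors in meters.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$traces)) {
    utils::write.csv(cohort$traces[[key]][, c("t_s", "head_yaw_deg",
                                              "trunk_yaw_deg")],
                     file.path(dir, paste0(key, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$params, file.path(dir, "params.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read cohort traces and metadata back from a directory
#'
#' @param dir directory written by [write_cohort()].
#' @return List `traces` (named, with identifier columns restored from the
#'   filenames), `metadata`.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$"),
                   c("metadata.csv", "params.csv"))
  traces <- list()
  for (f in files) {
    key <- sub("\\.csv$", "", f)
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    if (length(parts) != 4L) next
    tr <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    tr$participant_id <- parts[1]
    tr$coordination <- parts[2]
    tr$direction <- parts[3]
    tr$trial <- as.integer(parts[4])
    tr$group <- meta$group[match(parts[1], meta$participant_id)]
    traces[[key]] <- tr
  }
  list(traces = traces, metadata = meta)
}

#' Build the long analysis table from aggregated measures and performance
#'
#' Stacks the four study measures (trunk jerk RMS, cross-correlation peak,
#' accuracy, precision) into the long format consumed by [art_anova()] and
#' [posthoc_suite()].
#'
#' @param aggregated output of [aggregate_participant()].
#' @param performance output of [condition_performance()].
#' @return data.frame `participant_id, group, direction, coordination,
#'   measure, value`.
#' @export
build_long_table <- function(aggregated, performance) {
  base <- aggregated[, c("participant_id", "group", "direction",
                         "coordination")]
  long <- rbind(
    cbind(base, measure = "trunk_rms", value = aggregated$trunk_rms),
    cbind(base, measure = "cross_peak", value = aggregated$cross_peak),
    cbind(performance[, names(base)], measure = "accuracy",
          value = performance$accuracy),
    cbind(performance[, names(base)], measure = "precision",
          value = performance$precision)
  )
  rownames(long) <- NULL
  long
}

#' Import a deposited final dataset into the long analysis table
#'
#' Mapping-driven importer for an externally downloaded final dataset (for
#' instance the study deposit on Zenodo, record 10.5281/zenodo.4707477,
#' which must be fetched by the user: nothing is downloaded here). The
#' column mapping names the source columns holding each required field;
#' per-trial tables are aggregated to participant x condition medians.
#'
#' @param path CSV file path.
#' @param column_mapping named list or vector mapping the required fields
#'   `participant_id, group, direction, coordination, measure, value` (or,
#'   for wide per-measure layouts, `measure_cols` = named vector of source
#'   columns per measure) to source column names.
#' @param expected_groups expected group sizes, used only for a warning.
#' @return Long table (see [build_long_table()]).
#' @export
import_final_dataset <- function(path, column_mapping,
                                 expected_groups = c(blind = 10, sighted = 11)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  get_col <- function(field) {
    src <- column_mapping[[field]]
    if (is.null(src) || !src %in% names(raw))
      stop("unmappable column for '", field, "'; available: ",
           paste(names(raw), collapse = ", "))
    raw[[src]]
  }
  if (!is.null(column_mapping$measure_cols)) {
    mc <- column_mapping$measure_cols
    pieces <- lapply(names(mc), function(m) {
      data.frame(participant_id = as.character(get_col("participant_id")),
                 group = as.character(get_col("group")),
                 direction = as.character(get_col("direction")),
                 coordination = as.character(get_col("coordination")),
                 measure = m, value = as.numeric(raw[[mc[[m]]]]),
                 stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, pieces)
  } else {
    long <- data.frame(participant_id = as.character(get_col("participant_id")),
                       group = as.character(get_col("group")),
                       direction = as.character(get_col("direction")),
                       coordination = as.character(get_col("coordination")),
                       measure = as.character(get_col("measure")),
                       value = as.numeric(get_col("value")),
                       stringsAsFactors = FALSE)
  }
  # aggregate per-trial records to participant x condition medians
  key <- with(long, interaction(participant_id, direction, coordination,
                                measure, drop = TRUE))
  if (any(table(key) > 1)) {
    long <- do.call(rbind, lapply(split(long, key), function(cell) {
      cell$value[1] <- stats::median(cell$value, na.rm = TRUE)
      cell[1, ]
    }))
    rownames(long) <- NULL
  }
  counts <- table(unique(long[, c("participant_id", "group")])$group)
  for (g in names(expected_groups)) {
    found <- if (g %in% names(counts)) counts[[g]] else 0
    if (found != expected_groups[[g]])
      warning(sprintf("group '%s': %d participants (expected %d)",
                      g, found, expected_groups[[g]]))
  }
  for (m in unique(long$measure)) {
    sub <- long[long$measure == m, ]
    tab <- table(sub$participant_id,
                 interaction(sub$direction, sub$coordination))
    if (any(tab != 1)) {
      bad <- which(tab != 1, arr.ind = TRUE)
      warning(sprintf("measure '%s': participant %s missing cell %s", m,
                      rownames(tab)[bad[1, 1]], colnames(tab)[bad[1, 2]]))
    }
  }
  long
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> per-trial measures -> participant aggregation + performance
#' -> ART ANOVA and post-hoc suites per measure. When `out_dir` is given,
#' every intermediate artifact is written (traces, metadata, per-trial
#' measures, long table, JSON stats report) together with a manifest
#' echoing all settings, seeds and file digests.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @param measures_settings list of overrides for [trial_measures()].
#' @param posthoc_interaction interaction for [posthoc_suite()].
#' @param n_boot,ci bootstrap settings for post-hoc intervals.
#' @return List `cohort`, `measures`, `aggregated`, `performance`,
#'   `long_table`, `anova` (named by measure), `posthoc` (named by
#'   measure), `manifest`.
#' @export
run_pipeline <- function(spec = cohort_spec(), out_dir = NULL,
                         measures_settings = list(),
                         posthoc_interaction = "group:coordination",
                         n_boot = 2000, ci = FALSE) {
  cohort <- generate_cohort(spec)
  meas <- do.call(cohort_measures,
                  c(list(traces = cohort$traces, metadata = cohort$metadata),
                    measures_settings))
  agg <- aggregate_participant(meas)
  perf <- condition_performance(meas)
  long <- build_long_table(agg, perf)
  measures_names <- unique(long$measure)
  anova_list <- list(); posthoc_list <- list()
  for (m in measures_names) {
    sub <- long[long$measure == m, ]
    anova_list[[m]] <- art_anova(sub)
    posthoc_list[[m]] <- posthoc_suite(sub, posthoc_interaction,
                                       n_boot = n_boot, ci = ci,
                                       seed = spec$rng_seed)
  }
  manifest <- list(
    spec = unclass(spec),
    measures_settings = measures_settings,
    posthoc_interaction = posthoc_interaction,
    n_trials_total = nrow(cohort$metadata),
    n_trials_invalid = sum(!cohort$metadata$valid),
    n_traces = length(cohort$traces),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tdir <- file.path(out_dir, "traces")
    write_cohort(cohort, tdir)
    utils::write.csv(meas, file.path(out_dir, "trial_measures.csv"),
                     row.names = FALSE)
    utils::write.csv(long, file.path(out_dir, "long_table.csv"),
                     row.names = FALSE)
    report <- list(manifest = manifest,
                   anova = anova_list, posthoc = posthoc_list)
    jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(file.path(out_dir, c("trial_measures.csv", "long_table.csv",
                                    "stats_report.json")),
               file.path(tdir, "metadata.csv"))
    manifest$digests <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, measures = meas, aggregated = agg,
       performance = perf, long_table = long, anova = anova_list,
       posthoc = posthoc_list, manifest = manifest)
}
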