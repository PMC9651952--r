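# End-to-end orchestration: simulate -> preprocess -> decode -> rsa ->
# stats, with serialized tables and a hashed manifest for reproducibility.

#' Pipeline run configuration
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials trials per subject.
#' @param seed master seed; per-subject generator seeds are derived from it.
#' @param generator a [generator_config()] used as template (its `seed` is
#'   replaced per subject).
#' @param wavelet a [wavelet_spec()].
#' @param decoder a [decoder_spec()].
#' @param decimate decoding decimation factor (4 ms grid x `decimate`).
#' @param n_perm permutations for the cluster test.
#' @param out output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(n_subjects = 6L, n_trials = 144L, seed = 1L,
                       generator = generator_config(),
                       wavelet = wavelet_spec(), decoder = decoder_spec(),
                       decimate = 10L, n_perm = 1000L, out = "conjrsa-run") {
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 generator = generator, wavelet = wavelet, decoder = decoder,
                 decimate = as.integer(decimate), n_perm = as.integer(n_perm),
                 out = out),
            class = "run_config")
}

#' Simulate a full study for one subject
#'
#' Derives a subject-specific generator seed, draws the design, patterns,
#' epochs and behavior.
#'
#' @param config a [generator_config()] template.
#' @param n_trials trials to generate.
#' @param subject_seed integer seed for this subject.
#' @return list with `design`, `eeg`, `behavior`, `patterns`.
#' @export
simulate_subject <- function(config, n_trials = 144L, subject_seed = 1L) {
  cfg <- config
  cfg$seed <- as.integer(subject_seed)
  design <- generate_design(n_trials, seed = cfg$seed)
  patterns <- plant_patterns(cfg)
  eeg <- simulate_epochs(design, patterns, cfg)
  behavior <- simulate_behavior(design, cfg, trial_amp = attr(eeg, "trial_amp"))
  list(design = design, eeg = eeg, behavior = behavior, patterns = patterns)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Persist / load epochs in the flat-binary + JSON sidecar container
#'
#' `export_epochs()` writes little-endian float64 samples (trial-major,
#' then channel, then sample) to `<path>.dat` and a JSON sidecar
#' `<path>.json` with shape, sampling rate, channel names and epoch times.
#'
#' @param eeg an `epoched_eeg`.
#' @param path file stem (no extension).
#' @return `export_epochs()` the stem invisibly; `import_epochs()` an
#'   `epoched_eeg`.
#' @export
export_epochs <- function(eeg, path) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(eeg$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  side <- list(shape = dim(eeg$data), fs = eeg$fs, channels = eeg$channels,
               scalp = eeg$scalp, times = eeg$times, trial = eeg$trial,
               order = "sample,channel,trial")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname export_epochs
#' @export
import_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(side$shape)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(v) != n)
    stop_conjrsa("epoch payload does not match sidecar shape", "conjrsa_schema_error")
  dat <- aperm(array(v, dim = rev(side$shape)), c(3, 2, 1))
  structure(list(data = dat, times = side$times, channels = side$channels,
                 scalp = side$scalp, fs = side$fs, trial = side$trial),
            class = "epoched_eeg")
}

#' Import external behavioral / design tables
#'
#' Maps deposited trial-by-trial TSV files onto the internal design and
#' behavior schemas through a user-supplied column map. Rows failing
#' validation are dropped and reported.
#'
#' @param path TSV file path.
#' @param kind `"design"` or `"behavior"`.
#' @param column_map named character vector `internal_name = external_name`;
#'   identity for internal exports.
#' @return the validated data.frame, with attribute `dropped` (number of
#'   invalid rows removed).
#' @export
import_external <- function(path, kind = c("design", "behavior"),
                            column_map = NULL) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(df))
    if (length(miss))
      stop_conjrsa(paste("mapped columns absent from file:",
                         paste(miss, collapse = ", ")), "conjrsa_schema_error")
    for (i in seq_along(column_map))
      names(df)[names(df) == column_map[[i]]] <- names(column_map)[i]
  }
  req <- switch(kind,
    design = c("trial", "rule", "stim_high", "stim_low", "tested", "overlap"),
    behavior = c("trial", "rt", "response", "correct", "cutoff"))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_conjrsa(paste("required columns missing:", paste(miss, collapse = ", ")),
                 "conjrsa_schema_error")
  n0 <- nrow(df)
  if (kind == "design") {
    ok <- df$rule %in% task_rules() & df$stim_high %in% task_locations() &
      df$stim_low %in% task_locations() & df$tested %in% c("high", "low")
    df <- df[ok, , drop = FALSE]
    df$overlap <- as.logical(df$overlap)
    if (!"correct_response_high" %in% names(df))
      df$correct_response_high <- mapply(response_for, df$rule, df$stim_high,
                                         USE.NAMES = FALSE)
    if (!"correct_response_low" %in% names(df))
      df$correct_response_low <- mapply(response_for, df$rule, df$stim_low,
                                        USE.NAMES = FALSE)
    if (!"const_high" %in% names(df))
      df$const_high <- constellation_id(df$rule, df$stim_high)
    if (!"const_low" %in% names(df))
      df$const_low <- constellation_id(df$rule, df$stim_low)
  } else {
    ok <- is.na(df$rt) | df$rt <= df$cutoff
    df <- df[ok, , drop = FALSE]
    df$correct <- as.logical(df$correct)
  }
  structure(df, dropped = n0 - nrow(df))
}

#' Run the full pipeline
#'
#' simulate -> artifact rejection -> band power -> decoding -> RSA ->
#' group statistics, writing per-subject design/behavior tables, long-format
#' RSA scores, the behavioral summary, the conjunction interaction cluster
#' table, and a manifest (config echo, seeds, md5 hashes of every output)
#' to `config$out`. Re-running with the same config reproduces all tables
#' bit-identically.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `fits` (per subject `conj_rsa`),
#'   `summary`, `clusters`, `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  fits <- list(); beh <- list(); des <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    sim <- simulate_subject(config$generator, config$n_trials,
                            subject_seed = config$seed + 1000L * s)
    keep <- reject_artifacts(sim$eeg, c(veog = "VEOG", heog = "HEOG"))
    fit <- conjunction_rsa(sim$eeg, sim$design, sim$behavior, keep = keep,
                           wavelet = config$wavelet, decoder = config$decoder,
                           decimate = config$decimate,
                           seed = config$seed + 1000L * s)
    fits[[sid]] <- fit
    d <- sim$design; d$subject <- sid; des[[sid]] <- d
    b <- sim$behavior; b$subject <- sid; beh[[sid]] <- b
    files <- c(files,
               write_tsv(d, file.path(config$out, paste0(sid, "_design.tsv"))),
               write_tsv(b, file.path(config$out, paste0(sid, "_behavior.tsv"))),
               write_tsv(rsa_long(fit$scores, sid),
                         file.path(config$out, paste0(sid, "_rsa.tsv"))))
  }
  designs <- do.call(rbind, des); behavior <- do.call(rbind, beh)
  summ <- behavior_summary(behavior, designs)
  files <- c(files,
             write_tsv(summ$cells, file.path(config$out, "behavior_cells.tsv")),
             write_tsv(summ$anova, file.path(config$out, "behavior_anova.tsv")))
  tab <- score_table(lapply(fits, `[[`, "scores"), model = "conjunction")
  clusters <- cluster_permutation(tab, ~ priority * tested, "prioritylow:tested",
                                  n_perm = config$n_perm, seed = config$seed)
  files <- c(files,
             write_tsv(clusters, file.path(config$out, "conjunction_clusters.tsv")))
  manifest <- list(config = unclass_config(config),
                   files = as.list(tools::md5sum(files)))
  manifest_path <- file.path(config$out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fits = fits, summary = summ, clusters = clusters,
                 manifest_path = manifest_path))
}

# config as plain lists for JSON echo
unclass_config <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_config) else unclass(x)
}

# long-format serialization of an rsa_score
rsa_long <- function(scores, subject) {
  d <- dim(scores$t)
  grid <- expand.grid(trial = scores$designs$trial,
                      time_ms = scores$times,
                      plan = dimnames(scores$t)[[3]],
                      model = dimnames(scores$t)[[4]],
                      stringsAsFactors = FALSE)
  grid$t <- as.vector(scores$t)
  grid$masked <- as.vector(scores$mask)
  grid$subject <- subject
  grid[, c("subject", "trial", "time_ms", "plan", "model", "t", "masked")]
}
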