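#' Pipeline configuration
#'
#' Bundles every stage's options: the simulation protocol, envelope
#' processing options, clustering options and the statistics options. The
#' master seed fixes all stage seeds through a documented derivation
#' (character-code offset of the stage name, see `stage_seed`), so a
#' configuration reproduces a run exactly.
#'
#' @param protocol Simulation protocol from [default_protocol()].
#' @param time_constant_s,causal,window Envelope filter and differentiation
#'   options (see [smooth_envelope()], [differentiate_position()]).
#' @param k Retained components.
#' @param n_init k-means restarts.
#' @param alpha MANOVA significance gate before per-muscle follow-ups.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(protocol = default_protocol(),
                            time_constant_s = 0.020, causal = FALSE,
                            window = 11, k = 3, n_init = 50, alpha = 0.01,
                            seed = 1L) {
  cfg <- list(protocol = protocol, time_constant_s = time_constant_s,
              causal = causal, window = window, k = k, n_init = n_init,
              alpha = alpha, seed = as.integer(seed))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  known <- c("protocol", "time_constant_s", "causal", "window", "k",
             "n_init", "alpha", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stopf("unknown config key(s): %s",
                           paste(extra, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing)) stopf("missing config key(s): %s",
                             paste(missing, collapse = ", "))
  proto_known <- names(default_protocol())
  proto_extra <- setdiff(names(cfg$protocol), proto_known)
  if (length(proto_extra)) stopf("unknown protocol key(s): %s",
                                 paste(proto_extra, collapse = ", "))
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> decompose (PCA and varimax) -> match ->
#' compare, writing every intermediate artifact under `out_dir`
#' (`raw/`, `preprocessed/`, `decomp/`, `match/`, `stats/`) plus a
#' `manifest.json` holding the configuration echo and an MD5 checksum of
#' every artifact file. Rerunning with the same configuration reproduces
#' identical files and checksums; wall-clock timings go to a separate
#' `run.log` that is not checksummed. Figure-eight trials are decomposed
#' one by one; each subject's eight point-to-point movements are
#' concatenated and decomposed as a single movement set.
#'
#' @param config A `pipeline_config` list.
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  say("stage simulate")
  dataset <- clock("simulate", make_dataset(config$protocol))
  write_dataset(dataset, file.path(out_dir, "raw"))

  say("stage preprocess")
  units <- clock("preprocess", preprocess_stage(dataset, config))
  pre_dir <- file.path(out_dir, "preprocessed")
  dir.create(pre_dir, showWarnings = FALSE)
  for (u in units) {
    df <- data.frame(t(u$values), check.names = FALSE)
    utils::write.csv(format(df, digits = 12, trim = TRUE),
                     file.path(pre_dir, paste0(safe_id(u$trial_id), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  say("stage decompose")
  decomp <- clock("decompose", list(
    pca = lapply(units, decompose_trial, flavor = "pca", k = config$k),
    varimax = lapply(units, decompose_trial, flavor = "varimax",
                     k = config$k)))
  dec_dir <- file.path(out_dir, "decomp")
  dir.create(dec_dir, showWarnings = FALSE)
  for (fl in names(decomp)) {
    tab <- do.call(rbind, lapply(decomp[[fl]], function(d) {
      data.frame(trial_id = d$trial_id, flavor = fl,
                 component = seq_len(ncol(d$loadings)),
                 t(d$loadings),
                 variance_explained = d$variance_explained,
                 check.names = FALSE)
    }))
    utils::write.csv(format(tab, digits = 12, trim = TRUE),
                     file.path(dec_dir, paste0("loadings_", fl, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  say("stage match")
  match <- clock("match", list(
    pca = match_components(decomp$pca, "pca",
                           seed = stage_seed(config$seed, "match_pca"),
                           n_init = config$n_init),
    varimax = match_components(decomp$varimax, "varimax",
                               seed = stage_seed(config$seed, "match_vm"),
                               n_init = config$n_init)))
  match_dir <- file.path(out_dir, "match")
  dir.create(match_dir, showWarnings = FALSE)
  for (fl in names(match)) {
    a <- match[[fl]]
    utils::write.csv(format(data.frame(a$provenance, cluster = a$labels,
                                       distance = a$distances),
                            digits = 12, trim = TRUE),
                     file.path(match_dir, paste0("assignment_", fl, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(format(a$conflicts, digits = 12, trim = TRUE),
                     file.path(match_dir, paste0("conflicts_", fl, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  say("stage compare")
  stats_out <- clock("compare", compare_stage(decomp, match, config))
  stats_dir <- file.path(out_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  utils::write.csv(format(stats_out$report, digits = 10, trim = TRUE),
                   file.path(stats_dir, "manova_report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format(stats_out$dispersion, digits = 10, trim = TRUE),
                   file.path(stats_dir, "dispersion.csv"),
                   row.names = FALSE, quote = FALSE)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!basename(files) %in% c("manifest.json", "run.log")]
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- sub(paste0("^", out_dir, "/?"), "", names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("emgsyn")),
    seed = config$seed,
    n_trials = length(dataset$trials),
    n_units = length(units),
    conflicts = list(pca = match$pca$n_conflict_trials,
                     varimax = match$varimax$n_conflict_trials),
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(sprintf("%s: %.3f s", names(timings), unlist(timings)),
             file.path(out_dir, "run.log"))
  invisible(list(manifest = manifest, dataset = dataset, units = units,
                 decomp = decomp, match = match, stats = stats_out))
}

safe_id <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# figure-eight trials preprocessed per movement; each subject's discrete
# movements concatenated (in fixed direction order) into one movement set
preprocess_stage <- function(dataset, config) {
  trials <- dataset$trials
  types <- vapply(trials, function(tr) tr$condition$movement_type, "")
  units <- list()
  for (tr in trials[types == "figure8"]) {
    units[[tr$trial_id]] <- preprocess_trial(
      tr, time_constant_s = config$time_constant_s, causal = config$causal)
  }
  disc <- trials[types == "discrete"]
  if (length(disc)) {
    subj <- vapply(disc, function(tr) tr$subject_id, "")
    for (s in unique(subj)) {
      envs <- lapply(disc[subj == s], preprocess_trial,
                     time_constant_s = config$time_constant_s,
                     causal = config$causal, normalize = FALSE)
      u <- concatenate_envelopes(envs, normalize = TRUE)
      u$trial_id <- sprintf("%s_discrete_set", s)
      u$subject_id <- s
      u$condition <- list(movement_type = "discrete",
                          initial_direction = NA, orientation = NA,
                          plane = disc[[which(subj == s)[1L]]]$condition$plane)
      units[[u$trial_id]] <- u
    }
  }
  units
}

# MANOVA contrasts available in the dataset plus the dispersion ANOVA
compare_stage <- function(decomp, match, config) {
  report <- list()
  for (fl in names(decomp)) {
    a <- match[[fl]]
    meta <- unit_metadata(decomp[[fl]])
    for (contrast in c("direction", "movement_type")) {
      grouping <- switch(contrast,
                         direction = ifelse(meta$movement_type == "figure8",
                                            meta$direction, NA),
                         movement_type = meta$movement_type)
      names(grouping) <- meta$trial_id
      for (cl in 1:3) {
        idx <- which(a$labels == cl)
        gr <- grouping[a$provenance$trial_id[idx]]
        keep <- !is.na(gr)
        if (length(unique(gr[keep])) < 2) next
        X <- a$vectors[idx[keep], , drop = FALSE]
        colnames(X) <- emg_muscles()
        groups <- split.data.frame(X, gr[keep])
        res <- tryCatch(manova_wilks(groups, follow_up = FALSE),
                        error = function(e) NULL)
        if (is.null(res)) next
        report[[length(report) + 1L]] <- data.frame(
          flavor = fl, component = cl, contrast = contrast,
          wilks_lambda = res$wilks_lambda, F = res$f_stat,
          df1 = res$df1, df2 = res$df2, p = res$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(flavor = character(), component = integer(),
               contrast = character(), wilks_lambda = numeric(),
               F = numeric(), df1 = numeric(), df2 = numeric(),
               p = numeric())
  census <- stability_census(match$pca, match$varimax)
  disp <- distance_anova(census$distance_table)
  dispersion <- data.frame(
    term = c("component", "pca_vs_varimax"),
    F = c(disp$main$f_stat, disp$contrast$f_stat),
    df1 = c(disp$main$df1, disp$contrast$df1),
    df2 = c(disp$main$df2, disp$contrast$df2),
    p = c(disp$main$p_value, disp$contrast$p_value),
    stringsAsFactors = FALSE)
  list(report = report, dispersion = dispersion, census = census,
       distance_anova = disp)
}

unit_metadata <- function(decomps) {
  do.call(rbind, lapply(decomps, function(d) {
    data.frame(trial_id = d$trial_id,
               movement_type = d$condition$movement_type %||% NA,
               direction = as.character(d$condition$initial_direction %||% NA),
               stringsAsFactors = FALSE)
  }))
}
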