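# Pipeline orchestration: a single structured configuration drives
# cohort generation (or loading), cleaning, spectral processing,
# connectivity, graph metrics, trajectory statistics and the resilience
# scan, writing every product plus a machine-readable manifest to a run
# directory.

# FNV-1a hash of a character string, as 8 hex digits; used to stamp output
# tables with the configuration that produced them.
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$cohort <- NULL
  cfg$out_dir <- NULL          # a location, not an analysis parameter
  cfg <- strip_classes(cfg)
  cfg$cohort <- if (is.character(config$cohort)) config$cohort else
    strip_classes(unclass(if (inherits(config$cohort, "synthetic_cohort"))
      attr(config$cohort, "config") else config$cohort))
  fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null"))
}

#' Pipeline configuration
#'
#' Bundles the cohort (or cohort directory), the analysis parameters and
#' the stage toggles.  Defaults mirror the reference analysis: 30-s windows
#' with 1/8 stride, costs 5-30\% in 5\% steps, 1,024 bootstrap
#' realizations, 10,000 permutations, 90 removals, LOESS bandwidths
#' 0.01-0.99 with 10-fold cross-validation.
#'
#' @param cohort A \code{\link{cohort_config}}, a \code{synthetic_cohort},
#'   or a path to a cohort directory written by \code{\link{write_cohort}}.
#' @param out_dir Output run directory (created if missing).
#' @param window_s,stride_fraction Sliding-window parameters.
#' @param costs Proportional-threshold grid.
#' @param metrics Scalar network metrics for the trajectory grid.
#' @param n_boot Bootstrap realizations.
#' @param n_p Permutations for maximum-statistics correction.
#' @param loess_grid,k_folds LOESS bandwidth candidates and CV folds.
#' @param max_remove Node removals in the resilience scan.
#' @param resilience_cost Cost at which resilience graphs are thresholded.
#' @param score_maps Optional named list term -> data.frame(node_id, score)
#'   (or a CSV path per term) for score-ranked removal.
#' @param run_resilience,run_stats Stage toggles.
#' @param seed Integer master seed for every stochastic stage.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(cohort, out_dir,
                            window_s = 30, stride_fraction = 1 / 8,
                            costs = default_costs(),
                            metrics = c("global_efficiency",
                                        "local_efficiency"),
                            n_boot = 1024L, n_p = 10000L,
                            loess_grid = seq(0.01, 0.99, by = 0.01),
                            k_folds = 10L, max_remove = 90L,
                            resilience_cost = 0.15, score_maps = NULL,
                            run_resilience = TRUE, run_stats = TRUE,
                            seed = 1L) {
  if (any(costs <= 0 | costs > 1))
    stop("pipeline_config: costs must lie in (0, 1]")
  if (is.character(cohort) && !dir.exists(cohort))
    stop("pipeline_config: cohort directory not found: ", cohort)
  if (is.character(score_maps)) score_maps <- as.list(score_maps)
  if (is.list(score_maps) && !is.null(score_maps)) {
    for (term in names(score_maps)) {
      sm <- score_maps[[term]]
      if (is.character(sm) && !file.exists(sm))
        stop("pipeline_config: score map file for term '", term,
             "' not found: ", sm)
    }
  }
  structure(list(cohort = cohort, out_dir = out_dir, window_s = window_s,
                 stride_fraction = stride_fraction, costs = costs,
                 metrics = metrics, n_boot = as.integer(n_boot),
                 n_p = as.integer(n_p), loess_grid = loess_grid,
                 k_folds = as.integer(k_folds),
                 max_remove = as.integer(max_remove),
                 resilience_cost = resilience_cost,
                 score_maps = score_maps,
                 run_resilience = isTRUE(run_resilience),
                 run_stats = isTRUE(run_stats), seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_cohort <- function(cfg) {
  if (inherits(cfg$cohort, "synthetic_cohort")) return(cfg$cohort)
  if (inherits(cfg$cohort, "cohort_config")) return(generate_cohort(cfg$cohort))
  if (is.character(cfg$cohort)) return(read_cohort(cfg$cohort))
  stop("run_pipeline: unrecognized cohort specification")
}

resolve_score_maps <- function(score_maps) {
  if (is.null(score_maps)) return(NULL)
  out <- list()
  for (term in names(score_maps)) {
    sm <- score_maps[[term]]
    if (is.character(sm)) {
      if (!file.exists(sm))
        stop("run_pipeline: score map file for term '", term,
             "' not found: ", sm)
      sm <- read.csv(sm, stringsAsFactors = FALSE)
    }
    if (!all(c("node_id", "score") %in% names(sm)))
      stop("run_pipeline: score map '", term,
           "' needs columns node_id and score")
    out[[term]] <- sm
  }
  out
}

# Per-subject connectivity matrices for every band: from parcel series if
# present (analytic signal -> sliding windows -> median collapse), else the
# planted weighted matrices stand in for measured connectivity.
subject_connectivity <- function(rec, bands, window_s, stride_fraction) {
  out <- list()
  for (b in names(bands)) {
    if (!is.null(rec$series)) {
      an <- analytic_signal(rec$series[[b]], rec$fs, band = bands[[b]],
                            sample_mask = rec$sample_mask)
      arr <- sliding_window_connectivity(an, window_s = window_s,
                                         stride_fraction = stride_fraction)
      out[[b]] <- collapse_median(arr)
    } else {
      out[[b]] <- connectivity_matrix(rec$planted[[b]], band = bands[[b]])
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- cohort, cleaning, spectral/connectivity,
#' graph metrics over the cost grid, trajectory statistics (Spearman +
#' maximum-statistics correction, robust confirmation and CV LOESS for the
#' strongest cell, bootstrap cloud), and the resilience scan -- and writes
#' metrics.csv, correlations.csv, resilience.csv, cleaning.json and
#' manifest.json (with the config hash and per-file checksums) to the run
#' directory.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the in-memory products: \code{cohort},
#'   \code{metric_matrix}, \code{correlations}, \code{loess}, \code{cloud},
#'   \code{resilience}, \code{cleaning}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- "setup"
  result <- tryCatch({
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stage <- "cohort"
    cohort <- resolve_cohort(config)
    ccfg <- attr(cohort, "config")
    bands <- ccfg$bands
    ages <- vapply(cohort, `[[`, 0, "age")
    score_maps <- resolve_score_maps(config$score_maps)

    stage <- "cleaning"
    cleaning <- NULL
    if (!is.null(cohort[[1L]]$aux)) {
      cohort <- structure(lapply(cohort, clean_subject),
                          config = ccfg, class = "synthetic_cohort")
      cleaning <- lapply(cohort, function(r)
        list(fraction_removed = r$cleaning$fraction_removed,
             events = as.list(r$cleaning$events)))
    }

    stage <- "connectivity"
    conn <- list()
    for (b in names(bands)) conn[[b]] <- vector("list", length(cohort))
    for (s in seq_along(cohort)) {
      sc <- subject_connectivity(cohort[[s]], bands, config$window_s,
                                 config$stride_fraction)
      for (b in names(bands)) conn[[b]][[s]] <- sc[[b]]
    }

    stage <- "graphs"
    M <- metric_grid(conn, costs = config$costs, metrics = config$metrics)

    stage <- "stats"
    correlations <- NULL; lofit <- NULL; cloud <- NULL; robust <- NULL
    if (config$run_stats) {
      correlations <- maxstat_correction(M, ages, n_p = config$n_p,
                                         seed = config$seed)
      top <- which.max(abs(correlations$table$rho))
      top_cell <- correlations$table$cell[top]
      lofit <- tryCatch({
        cv <- loess_cv(ages, M[, top_cell], grid = config$loess_grid,
                       k_folds = config$k_folds, seed = config$seed)
        fit <- loess_fit(ages, M[, top_cell], cv$bandwidth)
        fit$cell <- top_cell
        fit$cv <- cv
        fit
      }, error = function(e) {
        warning("LOESS stage skipped: ", conditionMessage(e))
        NULL
      })
      cloud <- nested_bootstrap(ages, M[, top_cell], n_boot = config$n_boot,
                                seed = config$seed)
      sig <- correlations$table$cell[!is.na(correlations$table$p_c) &
                                       correlations$table$p_c < 0.05]
      if (length(ages) >= 10L)           # bootstrap CI needs n >= 10
        robust <- lapply(stats::setNames(sig, sig), function(cell)
          robust_confirmation(ages, M[, cell], seed = config$seed))
    }

    stage <- "resilience"
    scan <- NULL
    if (config$run_resilience) {
      adj <- lapply(conn, function(lst)
        lapply(lst, threshold_proportional, cost = config$resilience_cost))
      if (is.null(score_maps)) {
        # fixed group-level degree ranking (same order for all subjects)
        mean_deg <- lapply(adj, function(lst)
          Reduce(`+`, lapply(lst, node_degree)) / length(lst))
        orders <- list(degree = rank_nodes(Reduce(`+`, mean_deg)))
      } else {
        orders <- lapply(score_maps, rank_nodes)
      }
      max_rm <- min(config$max_remove, ccfg$n_nodes - 2L)
      scan <- age_resilience_scan(adj, ages, orders, max_remove = max_rm,
                                  n_p = config$n_p, seed = config$seed)
    }

    stage <- "write"
    hash <- config_hash(config)
    write_stamped <- function(df, path) {
      con <- file(path, "w")
      writeLines(sprintf("# config_hash: %s", hash), con)
      write.csv(df, con, row.names = FALSE)
      close(con)
    }
    metric_df <- data.frame(subject_id = rep(names(cohort), ncol(M)),
                            cell = rep(colnames(M), each = nrow(M)),
                            value = as.vector(M))
    write_stamped(metric_df, file.path(config$out_dir, "metrics.csv"))
    if (!is.null(correlations))
      write_stamped(correlations$table,
                    file.path(config$out_dir, "correlations.csv"))
    if (!is.null(scan))
      write_stamped(scan$table, file.path(config$out_dir, "resilience.csv"))
    if (!is.null(cleaning))
      jsonlite::write_json(cleaning,
                           file.path(config$out_dir, "cleaning.json"),
                           auto_unbox = TRUE, digits = NA)
    files <- list.files(config$out_dir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    checksums <- vapply(files, function(f)
      fnv1a(paste(readLines(f, warn = FALSE), collapse = "\n")), "")
    names(checksums) <- basename(files)
    manifest <- list(package_version =
                       as.character(utils::packageVersion("aecnet")),
                     r_version = as.character(getRversion()),
                     seed = config$seed, config_hash = hash,
                     n_subjects = length(cohort),
                     parameters = list(window_s = config$window_s,
                                       stride_fraction = config$stride_fraction,
                                       costs = config$costs,
                                       metrics = config$metrics,
                                       n_boot = config$n_boot,
                                       n_p = config$n_p,
                                       max_remove = config$max_remove),
                     checksums = as.list(checksums))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(cohort = cohort, metric_matrix = M, correlations = correlations,
         loess = lofit, cloud = cloud, robust = robust, resilience = scan,
         cleaning = cleaning, manifest = manifest)
  }, error = function(e) {
    stop("run_pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  invisible(result)
}

#' Write a cohort to a plain-text directory container
#'
#' Container layout: subjects.csv (subject_id, age), meta.json (generator
#' configuration), ground_truth.json (artifact logs), and per subject
#' planted_/series_ CSV matrices plus aux.csv.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Target directory (created if missing).
#' @return Invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  write.csv(subject_table(cohort), file.path(dir, "subjects.csv"),
            row.names = FALSE)
  meta <- unclass(cfg)
  meta$bands <- lapply(cfg$bands, unclass)
  meta$artifact_rates <- as.list(cfg$artifact_rates)   # keep names in JSON
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- lapply(cohort, `[[`, "artifact_log")
  jsonlite::write_json(gt[!vapply(gt, is.null, TRUE)],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (rec in cohort) {
    sdir <- file.path(dir, rec$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (b in names(rec$planted))
      write.csv(rec$planted[[b]], file.path(sdir, paste0("planted_", b, ".csv")),
                row.names = FALSE)
    if (!is.null(rec$series))
      for (b in names(rec$series))
        write.csv(rec$series[[b]], file.path(sdir, paste0("series_", b, ".csv")),
                  row.names = FALSE)
    if (!is.null(rec$aux))
      write.csv(as.data.frame(rec$aux), file.path(sdir, "aux.csv"),
                row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from a directory container
#'
#' @param dir Directory written by \code{\link{write_cohort}}.
#' @return A \code{synthetic_cohort}.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  bands <- lapply(meta$bands, function(b)
    band_definition(b$name, b$f_lo, b$f_hi))
  names(bands) <- vapply(bands, `[[`, "", "name")
  cfg <- cohort_config(n_subjects = meta$n_subjects,
                       age_range = meta$age_range, n_nodes = meta$n_nodes,
                       bands = bands, duration = meta$duration, fs = meta$fs,
                       coupling_strength = meta$coupling_strength,
                       leakage_strength = meta$leakage_strength,
                       age_effect_local = meta$age_effect_local,
                       age_effect_global = meta$age_effect_global,
                       local_band = meta$local_band,
                       global_band = meta$global_band,
                       hub_nodes = meta$hub_nodes,
                       artifact_rates = unlist(meta$artifact_rates),
                       planted_density = meta$planted_density,
                       char_fraction = meta$char_fraction,
                       signals = meta$signals, aux = meta$aux,
                       seed = meta$seed)
  subjects <- read.csv(file.path(dir, "subjects.csv"),
                       stringsAsFactors = FALSE)
  cohort <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sdir <- file.path(dir, subjects$subject_id[i])
    planted <- list()
    for (b in names(bands)) {
      f <- file.path(sdir, paste0("planted_", b, ".csv"))
      if (file.exists(f)) planted[[b]] <- as.matrix(read.csv(f))
    }
    series <- NULL
    sfiles <- list.files(sdir, pattern = "^series_", full.names = TRUE)
    if (length(sfiles)) {
      series <- lapply(sfiles, function(f) as.matrix(read.csv(f)))
      names(series) <- sub("^series_(.*)\\.csv$", "\\1", basename(sfiles))
    }
    aux <- NULL
    if (file.exists(file.path(sdir, "aux.csv")))
      aux <- as.list(read.csv(file.path(sdir, "aux.csv")))
    n_samp <- round(cfg$duration * cfg$fs)
    cohort[[i]] <- structure(list(subject_id = subjects$subject_id[i],
                                  age = subjects$age[i], fs = cfg$fs,
                                  duration = cfg$duration,
                                  n_samples = n_samp, planted = planted,
                                  series = series, aux = aux,
                                  aux_fs = cfg$fs,
                                  sample_mask = if (is.null(series)) NULL else
                                    rep(TRUE, ncol(series[[1L]])),
                                  artifact_log = NULL),
                             class = "subject_record")
  }
  names(cohort) <- subjects$subject_id
  structure(cohort, config = cfg, class = "synthetic_cohort")
}

#' Write synthetic fixtures (cohort, score maps, ground truth) to disk
#'
#' Generates a cohort from the configuration and writes the directory
#' container plus a per-node score map CSV (group-mean degree with seeded
#' noise, term "synthetic-hubness") and a vertex-level map with a
#' vertex-to-node membership table, exercising every external interface.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param dir Target directory.
#' @return Invisibly, a list of the written paths.
#' @export
make_fixtures <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  set.seed(config$seed + 1L)
  band1 <- names(config$bands)[1L]
  deg <- Reduce(`+`, lapply(cohort, function(r)
    node_degree(threshold_proportional(r$planted[[band1]], 0.15))))
  deg <- deg / length(cohort)
  score_map <- data.frame(node_id = seq_len(config$n_nodes),
                          score = deg + rnorm(config$n_nodes, sd = 0.1),
                          term = "synthetic-hubness")
  score_path <- file.path(dir, "score_map.csv")
  write.csv(score_map, score_path, row.names = FALSE)
  vpn <- 4L                                   # vertices per node
  membership <- data.frame(vertex_id = seq_len(vpn * config$n_nodes),
                           node_id = rep(seq_len(config$n_nodes), each = vpn))
  vertex_scores <- data.frame(vertex_id = membership$vertex_id,
                              z = score_map$score[membership$node_id] +
                                rnorm(nrow(membership), sd = 0.05))
  vertex_path <- file.path(dir, "vertex_scores.csv")
  member_path <- file.path(dir, "vertex_membership.csv")
  write.csv(vertex_scores, vertex_path, row.names = FALSE)
  write.csv(membership, member_path, row.names = FALSE)
  invisible(list(cohort_dir = dir, score_map = score_path,
                 vertex_scores = vertex_path, membership = member_path))
}
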