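#' Configuration of an end-to-end granulometry run
#'
#' A single declarative configuration drives the whole pipeline, so a run
#' is reproducible from one artifact (plus its seed in synthetic mode).
#'
#' @param mode `"synthetic"` (generate populations from presets) or
#'   `"from_files"` (read distribution tables).
#' @param presets Character vector of preset entries, each
#'   `"NAME"` or `"NAME:n_reps"` (default 3 replicates); synthetic mode.
#' @param inputs Character vector of table paths; from_files mode.
#' @param seed Master integer seed; required in synthetic mode.
#' @param n_bins,d_min,d_max Synthetic measurement grid (log-spaced).
#' @param total_granules Granules counted per synthetic measurement.
#' @param replicate_jitter_cv Biological replicate jitter (see
#'   [simulate_replicate_set()]).
#' @param prominence_frac Mode-detection threshold for [select_model()].
#' @param alpha Significance level for letter displays.
#' @param alpha_assumption Level for the test-selection gate.
#' @param out_dir Output directory for [render_report()].
#' @param log_level `"quiet"` or `"info"`.
#' @return Validated object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "from_files"),
                       presets = character(), inputs = character(),
                       seed = NA_integer_,
                       n_bins = 300L, d_min = 2, d_max = 60,
                       total_granules = 1e5, replicate_jitter_cv = 0.03,
                       prominence_frac = 0.05,
                       alpha = 0.05, alpha_assumption = 0.05,
                       out_dir = "granulofit_out",
                       log_level = c("quiet", "info")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (mode == "synthetic") {
    if (is.na(seed)) stop("synthetic mode requires a master seed", call. = FALSE)
    if (!length(presets)) stop("synthetic mode requires at least one preset", call. = FALSE)
    parsed <- lapply(presets, function(p) {
      parts <- strsplit(p, ":", fixed = TRUE)[[1L]]
      n_reps <- if (length(parts) > 1L) as.integer(parts[2L]) else 3L
      if (is.na(n_reps) || n_reps < 2L) {
        stop(sprintf("invalid preset entry '%s': replicate count must be an integer >= 2", p),
             call. = FALSE)
      }
      if (!parts[1L] %in% preset_names()) {
        stop(sprintf("unknown preset '%s'; valid presets: %s", parts[1L],
                     paste(preset_names(), collapse = ", ")), call. = FALSE)
      }
      list(name = parts[1L], n_reps = n_reps)
    })
  } else {
    if (!length(inputs)) stop("from_files mode requires at least one input path", call. = FALSE)
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in)) {
      stop("input file(s) not found: ", paste(missing_in, collapse = ", "), call. = FALSE)
    }
    parsed <- list()
  }
  structure(
    list(mode = mode, presets = presets, preset_list = parsed, inputs = inputs,
         seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
         n_bins = as.integer(n_bins), d_min = d_min, d_max = d_max,
         total_granules = total_granules,
         replicate_jitter_cv = replicate_jitter_cv,
         prominence_frac = prominence_frac, alpha = alpha,
         alpha_assumption = alpha_assumption, out_dir = out_dir,
         log_level = log_level),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), f)
  unname(tools::md5sum(f))
}

run_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message(sprintf(...))
}

metric_names <- c("a_mean_diameter", "b_mean_diameter", "b_content_pct",
                  "granules_per_mg")

#' Run the granulometry pipeline end to end
#'
#' Generates (or reads) binned size distributions, decomposes each
#' replicate with [select_model()], derives phenotype metrics, aggregates
#' replicate curves, and compares genotypes per timepoint and metric.
#' Fitting is per biological replicate; genotype-level values are means of
#' per-replicate metrics. Outputs are deterministic given the
#' configuration (and seed in synthetic mode); non-converged fits are
#' reported in the metrics table, never dropped.
#'
#' @param cfg A [run_config()].
#' @return Object of class `granule_run` with fields `config`, `hash`,
#'   `samples` (the analysed distributions), `metrics` (one row per
#'   sample), `aggregates` (per genotype x timepoint
#'   [aggregate_replicates()] curves) and `comparisons` (per timepoint x
#'   metric [compare_groups()] results).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  gpm_info <- list()
  if (cfg$mode == "synthetic") {
    grid <- log_diameter_grid(cfg$n_bins, cfg$d_min, cfg$d_max)
    samples <- list()
    for (i in seq_along(cfg$preset_list)) {
      entry <- cfg$preset_list[[i]]
      spec <- make_preset(entry$name, total_granules = cfg$total_granules,
                          grid = grid,
                          replicate_jitter_cv = cfg$replicate_jitter_cv)
      rs <- simulate_replicate_set(spec, entry$n_reps,
                                   seed = sub_seed(cfg$seed, i))
      run_log(cfg, "simulated %s: %d replicates", entry$name, entry$n_reps)
      for (d in rs$distributions) {
        samples[[length(samples) + 1L]] <- d
        gpm_info[[d$meta$sample_id]] <- list(total_count = spec$total_granules,
                                             mass_mg = d$mass_mg)
      }
    }
  } else {
    samples <- list()
    for (path in cfg$inputs) {
      for (d in read_sizedist_table(path)) {
        if (d$weighting == "number_counts") {
          if (!is.na(d$mass_mg)) {
            gpm_info[[d$meta$sample_id]] <- list(total_count = sum(d$values),
                                                 mass_mg = d$mass_mg)
          }
          d <- number_to_volume(d)
        } else if (!isTRUE(d$normalized)) {
          d <- normalize_percent(d)
        }
        samples[[length(samples) + 1L]] <- d
      }
    }
    run_log(cfg, "read %d sample(s) from %d file(s)", length(samples),
            length(cfg$inputs))
  }

  rows <- lapply(samples, function(d) {
    fit <- select_model(d, cfg$prominence_frac)
    info <- gpm_info[[d$meta$sample_id]]
    metrics <- if (isTRUE(fit$converged)) derive_metrics(fit, info) else NULL
    fit_to_row(fit, metrics, d$meta)
  })
  metrics <- do.call(rbind, rows)

  key <- vapply(samples, function(d) {
    paste(d$meta$genotype, d$meta$timepoint, sep = "\r")
  }, character(1))
  aggregates <- list()
  for (kk in unique(key)) {
    members <- samples[key == kk]
    if (length(members) >= 2L) {
      nm <- paste(members[[1L]]$meta$genotype, members[[1L]]$meta$timepoint, sep = "_")
      aggregates[[nm]] <- aggregate_replicates(replicate_set(members))
    }
  }

  comparisons <- list()
  for (tp in unique(metrics$timepoint)) {
    for (met in metric_names) {
      sub <- metrics[metrics$timepoint == tp & !is.na(metrics[[met]]), ]
      if (!nrow(sub)) next
      grp <- split(sub[[met]], sub$genotype)
      grp <- grp[lengths(grp) >= 2L]
      if (length(grp) < 2L) next
      comparisons[[paste(tp, met, sep = "_")]] <- c(
        compare_groups(grp, alpha = cfg$alpha,
                       alpha_assumption = cfg$alpha_assumption),
        list(timepoint = tp, metric = met))
    }
  }
  for (nm in names(comparisons)) class(comparisons[[nm]]) <- "comparison_result"

  structure(
    list(config = cfg, hash = config_hash(cfg), samples = samples,
         metrics = metrics, aggregates = aggregates,
         comparisons = comparisons),
    class = "granule_run"
  )
}

#' @export
print.granule_run <- function(x, ...) {
  cat(sprintf("<granule_run> %d sample(s), %d aggregate curve(s), %d comparison(s)\n",
              length(x$samples), length(x$aggregates), length(x$comparisons)))
  print(x$metrics)
  invisible(x)
}

provenance_header <- function(run) {
  sprintf("# granulofit %s | config_hash %s | seed %s",
          as.character(utils::packageVersion("granulofit")), run$hash,
          ifelse(is.na(run$config$seed), "none", run$config$seed))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         format(df[[nm]], digits = 15, scientific = FALSE,
                                trim = TRUE))
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "na")
  invisible(path)
}

#' Per-group comparison table of a run
#'
#' @param run A `granule_run`.
#' @return Tibble with one row per (timepoint, metric, group).
#' @export
comparison_table <- function(run) {
  if (!length(run$comparisons)) {
    return(tibble::tibble(timepoint = character(), metric = character(),
                          group = character(), mean = numeric(),
                          se = numeric(), n = integer(),
                          letters = character(), test_used = character(),
                          omnibus_p = numeric()))
  }
  do.call(rbind, lapply(run$comparisons, function(cr) {
    tibble::tibble(timepoint = cr$timepoint, metric = cr$metric,
                   group = cr$group, mean = cr$mean, se = cr$se, n = cr$n,
                   letters = unname(cr$letters), test_used = cr$test_used,
                   omnibus_p = cr$p.value)
  }))
}

#' Pairwise p-value tables of a run
#'
#' @param run A `granule_run`.
#' @return Tibble with one row per (timepoint, metric, group pair).
#' @export
pairwise_table <- function(run) {
  if (!length(run$comparisons)) {
    return(tibble::tibble(timepoint = character(), metric = character(),
                          group1 = character(), group2 = character(),
                          p = numeric()))
  }
  do.call(rbind, lapply(run$comparisons, function(cr) {
    pm <- cr$pairwise
    idx <- which(upper.tri(pm), arr.ind = TRUE)
    tibble::tibble(timepoint = cr$timepoint, metric = cr$metric,
                   group1 = rownames(pm)[idx[, 1L]],
                   group2 = colnames(pm)[idx[, 2L]],
                   p = pm[idx])
  }))
}

aggregate_table <- function(run) {
  if (!length(run$aggregates)) {
    return(tibble::tibble(genotype = character(), timepoint = character(),
                          bin_lower_um = numeric(), bin_upper_um = numeric(),
                          mean = numeric(), se = numeric(), n = integer()))
  }
  do.call(rbind, lapply(run$aggregates, function(ac) {
    e <- ac$grid$edges
    tibble::tibble(genotype = ac$genotype, timepoint = ac$timepoint,
                   bin_lower_um = e[-length(e)], bin_upper_um = e[-1L],
                   mean = ac$mean, se = ac$se, n = ac$n)
  }))
}

#' Write tables and plots of a completed run
#'
#' Writes `metrics.tsv` (one row per sample), `comparisons.tsv` (one row
#' per timepoint x metric x group, with letters) and
#' `aggregate_curves.tsv`, each headed by a provenance comment (package
#' version, configuration hash, seed), plus one distribution plot per
#' timepoint (PNG always; SVG where the graphics device supports it --
#' plotting failures downgrade to warnings, the tables are the contract).
#' Missing values are written as the literal `na`. Pairwise p-value
#' matrices are available via [pairwise_table()].
#'
#' @param run A `granule_run`.
#' @param outdir Output directory (default from the run's configuration);
#'   created if needed.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(run, outdir = run$config$out_dir) {
  stopifnot(inherits(run, "granule_run"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2L) != 0L) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  hdr <- provenance_header(run)
  files <- character()
  f <- file.path(outdir, "metrics.tsv")
  write_tsv_with_header(run$metrics, f, hdr)
  files <- c(files, f)
  f <- file.path(outdir, "comparisons.tsv")
  write_tsv_with_header(comparison_table(run), f, hdr)
  files <- c(files, f)
  f <- file.path(outdir, "aggregate_curves.tsv")
  write_tsv_with_header(aggregate_table(run), f, hdr)
  files <- c(files, f)

  agg <- aggregate_table(run)
  for (tp in unique(agg$timepoint)) {
    sub <- agg[agg$timepoint == tp, ]
    sub$mid <- sqrt(sub$bin_lower_um * sub$bin_upper_um)
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$mid, y = .data$mean,
                                           colour = .data$genotype,
                                           fill = .data$genotype)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           alpha = 0.3, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "Granule diameter (µm)",
                    y = "Relative volume (%)",
                    title = sprintf("Granule size distribution (%s)", tp)) +
      ggplot2::theme_minimal()
    base <- file.path(outdir, sprintf("distribution_%s", tp))
    png_ok <- tryCatch({
      ggplot2::ggsave(paste0(base, ".png"), p, width = 6, height = 4, dpi = 150)
      TRUE
    }, error = function(e) {
      warning("PNG plot failed for timepoint ", tp, ": ", conditionMessage(e))
      FALSE
    })
    if (png_ok) files <- c(files, paste0(base, ".png"))
    svg_ok <- tryCatch({
      grDevices::svg(paste0(base, ".svg"), width = 6, height = 4)
      print(p)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warning("SVG plot failed for timepoint ", tp, ": ", conditionMessage(e))
      FALSE
    })
    if (svg_ok) files <- c(files, paste0(base, ".svg"))
  }
  invisible(files)
}
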