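#' Run the end-to-end rank-selection pipeline from a configuration
#'
#' Reads (or simulates) a target matrix, optionally preprocesses it, runs
#' the rank survey, applies the knee selector, optionally runs PRESS
#' cross-validation, and returns a self-describing report. All randomness is
#' governed by the single `seed` entry, and the report carries no volatile
#' fields, so a rerun with the same configuration is byte-identical.
#'
#' Configuration is a named list or the path of a flat `key = value` file
#' (`#` comments allowed; `A:B` parses as an integer range). Recognised
#' keys: `input`, `format`, `transpose`, `simulate`, `sim_processes`,
#' `sim_genomes`, `sim_exposure_scale`, `sim_no_noise`, `ranks`, `nrun`,
#' `algorithm`, `theta`, `seed`, `min_total_count`, `log_transform`,
#' `pseudo_count`, `normalize_samples`, `normalize_mode`,
#' `variance_filter_keep`, `cv`, `cv_fraction`, `cv_repeats`, `out`, `plot`.
#'
#' @param config named list or file path.
#' @return the report (class `uiknmf_report`), invisibly when written to
#'   `out`; a JSON file is written when `out` is set, an SVG survey plot
#'   when `plot` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  cfg <- utils::modifyList(list(
    input = NULL, format = NULL, transpose = FALSE,
    simulate = FALSE, sim_processes = 10L, sim_genomes = 100L,
    sim_exposure_scale = 1000, sim_no_noise = FALSE,
    ranks = 2:15, nrun = 10L, algorithm = "brunet", theta = 0.5, seed = 1L,
    min_total_count = 0, log_transform = FALSE, pseudo_count = 1,
    normalize_samples = FALSE, normalize_mode = "divide",
    variance_filter_keep = NULL, cv = FALSE, cv_fraction = 0.05,
    cv_repeats = 5L, out = NULL, plot = NULL), config)

  ranks <- as.integer(cfg$ranks)
  if (length(ranks) < 4L || any(diff(ranks) <= 0))
    stop("config error: ranks must be >= 4 strictly increasing values",
         call. = FALSE)
  if (!cfg$algorithm %in% c("brunet", "lee", "nsnmf"))
    stop("config error: unknown algorithm ", cfg$algorithm, call. = FALSE)
  if (is.null(cfg$input) && !isTRUE(cfg$simulate))
    stop("config error: either input or simulate = TRUE is required",
         call. = FALSE)

  V <- if (isTRUE(cfg$simulate)) {
    simulate_catalog(n_processes = cfg$sim_processes,
                     n_genomes = cfg$sim_genomes,
                     exposure_scale = cfg$sim_exposure_scale,
                     poisson_noise = !isTRUE(cfg$sim_no_noise),
                     seed = cfg$seed)$counts
  } else {
    read_target_matrix(cfg$input, cfg$format, transpose = isTRUE(cfg$transpose))
  }
  V <- preprocess_matrix(V, min_total_count = cfg$min_total_count,
                         log_transform = isTRUE(cfg$log_transform),
                         pseudo_count = cfg$pseudo_count,
                         normalize_samples = isTRUE(cfg$normalize_samples),
                         normalize_mode = cfg$normalize_mode,
                         variance_filter_keep = cfg$variance_filter_keep,
                         verbose = FALSE)
  V <- validate_target_matrix(V, "preprocessed input")

  model <- uiknmf(V, ranks = ranks, nrun = cfg$nrun,
                  algorithm = cfg$algorithm, theta = cfg$theta,
                  seed = cfg$seed)
  report <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("uiknmf")),
    seed = as.integer(cfg$seed),
    dataset = list(n_features = nrow(V), n_samples = ncol(V),
                   source = if (isTRUE(cfg$simulate)) "simulated" else cfg$input),
    algorithm = cfg$algorithm, nrun = as.integer(cfg$nrun),
    ranks = ranks,
    rss_curve = model$survey$rss_curve,
    cophenetic_curve = model$survey$cophenetic_curve,
    curve_type = model$knee$curve_type,
    knee_start = model$knee$knee_start,
    knee_end = model$knee$knee_end,
    selected_rank = model$rank)
  if (isTRUE(cfg$cv)) {
    pr <- select_rank_press(V, ranks[ranks <= min(dim(V))],
                            holdout_scheme("random_fraction",
                                           fraction = cfg$cv_fraction,
                                           n_repeats = cfg$cv_repeats,
                                           seed = cfg$seed))
    report$press_curve <- pr$press_curve
    report$press_optimal <- pr$optimal
  }
  class(report) <- "uiknmf_report"

  if (!is.null(cfg$out))
    jsonlite::write_json(unclass(report), cfg$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(cfg$plot)) {
    grDevices::svg(cfg$plot, width = 9, height = 4.5)
    plot(model)
    grDevices::dev.off()
  }
  invisible(report)
}

#' @export
#' @method print uiknmf_report
print.uiknmf_report <- function(x, ...) {
  cat("uikNMF pipeline report (schema ", x$schema_version, ")\n", sep = "")
  cat("  dataset: ", x$dataset$n_features, " x ", x$dataset$n_samples,
      " (", x$dataset$source, ")\n", sep = "")
  cat("  algorithm ", x$algorithm, ", ranks ", min(x$ranks), "-", max(x$ranks),
      ", seed ", x$seed, "\n", sep = "")
  cat("  selected rank: ", x$selected_rank, "\n", sep = "")
  if (!is.null(x$press_optimal))
    cat("  PRESS optimal rank: ", x$press_optimal, "\n", sep = "")
  invisible(x)
}

# flat key = value configuration file; '#' starts a comment, A:B is a range
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L)
      stop("config parse error at line: ", ln, call. = FALSE)
    key <- kv[2L]; val <- trimws(kv[3L])
    val <- gsub('^"|"$', "", val)
    parsed <- if (grepl("^-?[0-9]+:[0-9]+$", val)) {
      ab <- as.integer(strsplit(val, ":", fixed = TRUE)[[1L]])
      seq.int(ab[1L], ab[2L])
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else if (grepl("^-?[0-9.eE+-]+$", val) && !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
    cfg[[key]] <- parsed
  }
  cfg
}
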