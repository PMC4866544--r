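#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`, requires the `yaml` package) or JSON.  See
#' [validate_config()] for the recognized fields.
#'
#' @param path Config file path.
#' @return The configuration as a nested list, with `config_path` recorded.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$config_path <- path
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks paths, ranges and enum values, aggregating all problems instead of
#' failing on the first.
#'
#' Recognized fields: `paths$variant_table`, `paths$association_reads` or
#' `paths$tag_map`, `paths$counts` (tag- or construct-level TSV),
#' `paths$output_dir`, `paths$exclusions` (optional TSV);
#' `analysis$alpha`, `analysis$bh_family`, `analysis$qc_k`,
#' `analysis$min_support`; `simulation` (arguments for [sim_params()]);
#' `seed`.
#'
#' @param config Configuration list from [read_config()] or built in code.
#' @param for_command Which subcommand the config must support
#'   (`"analyze"` needs the analysis inputs, `"simulate"` the simulation
#'   block, `"all"` both the simulation block and analysis options).
#' @return The validated config, invisibly; or an error listing every
#'   problem found.
#' @export
validate_config <- function(config, for_command = c("analyze", "simulate",
                                                    "all")) {
  for_command <- match.arg(for_command)
  errs <- character(0)
  addn <- function(msg) errs <<- c(errs, msg)
  paths <- config$paths
  an <- config$analysis

  need_path <- function(p, label, required = TRUE) {
    if (is.null(p)) {
      if (required) addn(paste0("missing required path: ", label))
    } else if (!file.exists(p)) {
      addn(paste0(label, " does not exist: ", p))
    }
  }
  if (for_command == "analyze") {
    need_path(paths$variant_table, "paths$variant_table")
    need_path(paths$counts, "paths$counts")
    if (is.null(paths$association_reads) && is.null(paths$tag_map))
      addn("one of paths$association_reads or paths$tag_map is required")
    need_path(paths$association_reads, "paths$association_reads",
              required = FALSE)
    need_path(paths$tag_map, "paths$tag_map", required = FALSE)
    need_path(paths$exclusions, "paths$exclusions", required = FALSE)
  }
  if (for_command %in% c("analyze", "all") && is.null(paths$output_dir))
    addn("missing required path: paths$output_dir")
  if (!is.null(an$alpha) && (!is.numeric(an$alpha) || an$alpha <= 0 ||
                             an$alpha >= 1))
    addn("analysis$alpha out of range (0, 1)")
  if (!is.null(an$bh_family) && !an$bh_family %in% c("separate", "combined"))
    addn("analysis$bh_family must be 'separate' or 'combined'")
  if (!is.null(an$qc_k) && (!is.numeric(an$qc_k) || an$qc_k <= 0))
    addn("analysis$qc_k must be positive")
  if (!is.null(an$min_support) && (!is.numeric(an$min_support) ||
                                   an$min_support < 1))
    addn("analysis$min_support must be >= 1")
  if (for_command %in% c("simulate", "all")) {
    ok <- tryCatch({
      do.call(sim_params, sim_args(config))
      TRUE
    }, error = function(e) {
      addn(paste0("simulation block invalid: ", conditionMessage(e)))
      FALSE
    })
    invisible(ok)
  }
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

sim_args <- function(config) {
  args <- config$simulation
  if (is.null(args)) args <- list()
  if (!is.null(args$outlier_replicates))
    args$outlier_replicates <- as.data.frame(args$outlier_replicates)
  if (is.null(args$seed) && !is.null(config$seed)) args$seed <- config$seed
  args
}

#' Run the full analysis pipeline
#'
#' Executes associate -> count -> aggregate -> QC -> log ratios -> t-tests ->
#' BH -> fold change -> correlations -> classification on the inputs named
#' in the config, writing all result tables, a run log (package version,
#' config hash, per-stage row counts) and a verbatim config echo into the
#' output directory.  Re-running on the same inputs and config is
#' bit-identical.
#'
#' @param config Configuration list (see [validate_config()]).
#' @return The [analyze_activity()] result, invisibly, with the output paths
#'   in `attr(, "paths")`.
#' @export
run_pipeline <- function(config) {
  validate_config(config, "analyze")
  paths <- config$paths
  an <- config$analysis
  outdir <- paths$output_dir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  say("mpratag ", as.character(utils::packageVersion("mpratag")))

  echo_path <- file.path(outdir, "config_echo.json")
  jsonlite::write_json(config[setdiff(names(config), "config_path")],
                       echo_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  say("config hash (md5): ", unname(tools::md5sum(echo_path)))

  library <- read_variant_table(paths$variant_table)
  say("variant_library: ", nrow(library), " variant pairs")
  constructs <- build_constructs(library)
  say("constructs: ", nrow(constructs))

  min_support <- if (is.null(an$min_support)) 2L else as.integer(an$min_support)
  if (!is.null(paths$tag_map)) {
    assignments <- read_tag_assignments(paths$tag_map)
    say("tag_map: ", sum(assignments$status == "unique"),
        " unique tags (read from file)")
  } else {
    reads <- read_sequences(paths$association_reads)
    say("association reads: ", length(reads))
    assignments <- associate_tags(reads, constructs,
                                  min_support = min_support)
    say("tag association: ", sum(assignments$status == "unique"), " unique, ",
        sum(assignments$status == "ambiguous"), " ambiguous, ",
        sum(assignments$status == "unassigned"), " unassigned")
  }
  write_tag_assignments(assignments, file.path(outdir, "tag_assignments.tsv"))

  counts <- read_sample_counts(paths$counts)
  say("count rows: ", nrow(counts))
  agg <- if ("construct_id" %in% names(counts)) counts
         else aggregate_by_construct(counts, assignments, constructs)
  say("aggregated rows: ", nrow(agg))

  exclusions <- NULL
  if (!is.null(paths$exclusions)) {
    exclusions <- utils::read.delim(paths$exclusions, sep = "\t",
                                    stringsAsFactors = FALSE)
    say("external exclusions: ", nrow(exclusions))
  }

  res <- analyze_activity(
    agg, constructs,
    alpha = if (is.null(an$alpha)) 0.05 else an$alpha,
    qc_k = if (is.null(an$qc_k)) 3 else an$qc_k,
    exclusions = exclusions,
    bh_family = if (is.null(an$bh_family)) "separate" else an$bh_family)
  say("results: ", nrow(res$results_da), " derived-vs-ancestral tests, ",
      nrow(res$results_nc), " vs-negative-control tests, ",
      sum(res$results_da$significant, na.rm = TRUE), " + ",
      sum(res$results_nc$significant, na.rm = TRUE), " significant")

  written <- write_analysis(res, outdir)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  attr(res, "paths") <- c(written, file.path(outdir, "run_log.txt"), echo_path)
  invisible(res)
}

#' Run the simulate subcommand
#'
#' Builds the synthetic dataset described by the config's `simulation` block
#' and writes it to `paths$output_dir`.
#'
#' @param config Configuration list.
#' @return The written paths, invisibly.
#' @export
run_simulate <- function(config) {
  validate_config(config, "simulate")
  params <- do.call(sim_params, sim_args(config))
  sim <- simulate_library(params)
  ct <- simulate_counts(sim)
  outdir <- if (!is.null(config$paths$output_dir)) config$paths$output_dir
            else "."
  paths <- write_simulation(sim, ct, outdir)
  message("simulated dataset written to ", outdir)
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `analyze` (run the
#' statistics on existing inputs), `all` (simulate, then analyze the
#' simulated data).  Arguments: `--config <file>` (YAML or JSON); `analyze`
#' also accepts `--counts`, `--variants`, `--tag-map`, `--out`, `--alpha`,
#' `--exclusions` overriding the config.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
mpratag_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mpratag <simulate|analyze|all> [--config cfg.{yaml,json}]",
    "  analyze options: --counts F --variants F [--tag-map F] --out DIR",
    "                   [--alpha A] [--exclusions F]", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else list()
  if (!is.null(opts$counts)) cfg$paths$counts <- opts$counts
  if (!is.null(opts$variants)) cfg$paths$variant_table <- opts$variants
  if (!is.null(opts[["tag-map"]])) cfg$paths$tag_map <- opts[["tag-map"]]
  if (!is.null(opts$out)) cfg$paths$output_dir <- opts$out
  if (!is.null(opts$exclusions)) cfg$paths$exclusions <- opts$exclusions
  if (!is.null(opts$alpha)) cfg$analysis$alpha <- as.numeric(opts$alpha)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)

  switch(cmd,
    simulate = run_simulate(cfg),
    analyze = run_pipeline(cfg),
    all = {
      simdir <- file.path(cfg$paths$output_dir, "simulated")
      cfg$paths$output_dir <- cfg$paths$output_dir
      simpaths <- run_simulate(within_paths(cfg, simdir))
      cfg$paths$variant_table <- simpaths[["variants"]]
      cfg$paths$tag_map <- simpaths[["tag_map"]]
      cfg$paths$counts <- simpaths[["counts"]]
      run_pipeline(cfg)
    },
    { message("unknown subcommand: ", cmd, "\n", usage)
      return(invisible(1L)) })
  invisible(0L)
}

within_paths <- function(cfg, outdir) {
  cfg$paths$output_dir <- outdir
  cfg
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
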