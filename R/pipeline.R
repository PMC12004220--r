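#' Configuration for a full pipeline run
#'
#' Collects every stage's parameters plus input/output locations. Either an
#' input matrix (`input_path` + `input_format`) or `simulate = TRUE` (a
#' self-contained demonstration on a simulated dataset) must be given.
#'
#' @param input_path path to a 10x MTX directory or dense TSV, or `NULL`
#'   when simulating.
#' @param input_format `"10x"` or `"tsv"`.
#' @param input_layer layer of a TSV input (`"raw_counts"` or `"lognorm"`).
#' @param simulate logical; simulate the input instead of reading it.
#' @param sim_design a `SimulationDesign` used when `simulate = TRUE`.
#' @param normalize log-normalize raw counts before selection (default
#'   TRUE).
#' @param scale_factor normalization scale factor.
#' @param selection a `SelectionParams`.
#' @param graph a `GraphParams`.
#' @param mcl an `MclParams`.
#' @param min_size,min_cells,min_frac,strict_frac,min_sd module filters;
#'   `min_sd = 0` disables the standard-deviation filter.
#' @param top_fraction module activity score parameter.
#' @param output_dir directory for artifacts (created if needed).
#' @param seed master seed; overrides the selection and simulation seeds so
#'   one value pins the whole run.
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(input_path = NULL, input_format = c("10x", "tsv"),
                       input_layer = "raw_counts",
                       simulate = is.null(input_path),
                       sim_design = simulation_design(),
                       normalize = TRUE, scale_factor = 1e4,
                       selection = selection_params(),
                       graph = graph_params(),
                       mcl = mcl_params(),
                       min_size = 10L, min_cells = 5L, min_frac = 0.2,
                       strict_frac = FALSE, min_sd = 0,
                       top_fraction = 0.05,
                       output_dir = "coexmod_out", seed = 123L) {
  input_format <- match.arg(input_format)
  if (is.null(input_path) && !simulate) {
    stop("either input_path or simulate = TRUE is required")
  }
  seed <- as.integer(seed)
  selection$seed <- seed
  sim_design$seed <- seed
  structure(list(input_path = input_path, input_format = input_format,
                 input_layer = input_layer, simulate = simulate,
                 sim_design = sim_design, normalize = normalize,
                 scale_factor = scale_factor, selection = selection,
                 graph = graph, mcl = mcl, min_size = as.integer(min_size),
                 min_cells = as.integer(min_cells), min_frac = min_frac,
                 strict_frac = strict_frac, min_sd = min_sd,
                 top_fraction = top_fraction, output_dir = output_dir,
                 seed = seed),
            class = "RunConfig")
}

#' Run the full module-detection pipeline and write its artifacts
#'
#' Reads (or simulates) a count matrix, log-normalizes it, selects
#' co-expressed genes by DKNN, builds the neighborhood graph, partitions it
#' with MCL, applies the module filters, scores module activity per cell,
#' and writes: `selected_genes.tsv`, `modules.gmt`, `modules.tsv`,
#' `module_scores.tsv` and a machine-readable `run_report.json` holding the
#' full parameter closure, the DKNN threshold and FDR, module counts and
#' any warnings. The report contains no timestamps, so identical
#' configurations produce byte-identical artifacts.
#'
#' @param config a `RunConfig`.
#' @return invisibly, a list with the `ModuleSet`, the `DknnResult`, the
#'   score matrix and the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  warnings_seen <- character(0)

  m_raw <- if (config$simulate) {
    sim <- simulate_dataset(config$sim_design)
    sim$matrix
  } else if (config$input_format == "10x") {
    read_10x_mtx(config$input_path)
  } else {
    read_dense_tsv(config$input_path, layer = config$input_layer)
  }
  m_work <- if (config$normalize && m_raw$layer == "raw_counts") {
    lognormalize(m_raw, config$scale_factor)
  } else {
    m_raw
  }

  sel <- select_genes(m_work, config$selection)
  if (!length(sel$selected_genes)) {
    stop("no genes selected at FDR ", config$selection$fdr_target)
  }
  ms <- partition_genes(m_work, sel, config$graph, config$mcl)
  diag <- ms$provenance$mcl_diagnostics
  if (!is.null(diag) && !isTRUE(diag$converged)) {
    warnings_seen <- c(warnings_seen,
                       "MCL did not converge within max_iterations")
  }
  n_modules_raw <- length(ms$modules)
  ms <- filter_cluster_size(ms, config$min_size)
  ms <- filter_nb_supporting_cells(ms, m_raw, config$min_cells,
                                   config$min_frac, config$strict_frac)
  if (config$min_sd > 0) {
    ms <- filter_module_sd(ms, m_work, config$min_sd)
  }
  scores <- module_activity_scores(ms, m_work, config$top_fraction)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    selected_genes = file.path(config$output_dir, "selected_genes.tsv"),
    modules_gmt = file.path(config$output_dir, "modules.gmt"),
    modules_tsv = file.path(config$output_dir, "modules.tsv"),
    module_scores = file.path(config$output_dir, "module_scores.tsv"),
    run_report = file.path(config$output_dir, "run_report.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(unlist(paths)), add = TRUE)

  write_dknn_tsv(sel, paths$selected_genes)
  write_modules_gmt(ms, paths$modules_gmt)
  write_modules_tsv(ms, paths$modules_tsv)
  write_scores_tsv(scores, paths$module_scores)

  report <- list(
    package = "coexmod",
    seed = config$seed,
    input = if (config$simulate) {
      list(kind = "simulated", design = unclass(config$sim_design))
    } else {
      list(kind = config$input_format, path = config$input_path)
    },
    parameters = list(
      normalize = config$normalize, scale_factor = config$scale_factor,
      selection = unclass(config$selection), graph = unclass(config$graph),
      mcl = unclass(config$mcl),
      filters = list(min_size = config$min_size,
                     min_cells = config$min_cells,
                     min_frac = config$min_frac,
                     strict_frac = config$strict_frac,
                     min_sd = config$min_sd),
      top_fraction = config$top_fraction),
    results = list(
      n_genes = length(m_work$gene_ids),
      n_cells = length(m_work$cell_ids),
      n_genes_scored = length(sel$gene_ids),
      n_genes_selected = length(sel$selected_genes),
      dknn_threshold = sel$threshold,
      fdr_at_threshold = sel$fdr_at_threshold,
      n_modules_unfiltered = n_modules_raw,
      n_modules = length(ms$modules),
      module_sizes = vapply(ms$modules, length, 0L)),
    warnings = warnings_seen)
  jsonlite::write_json(report, paths$run_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(list(modules = ms, selection = sel, scores = scores,
                 report = report, paths = paths))
}
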