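#' Build a pipeline run configuration
#'
#' A run is either synthetic (a [genome_spec()] drives data generation) or
#' real (paths to peak, annotation and track files). Exactly one of `spec`
#' and `paths` must be supplied. All stage parameters are centralized here
#' and echoed into the run report, so every run is self-describing.
#'
#' @param spec A `genome_spec` for synthetic mode, or the name of an
#'   [example_genome_spec()] design.
#' @param paths Named list for real mode: `peaks`, `genes`, `ip`, `input`,
#'   and optionally `pol2`, `nelf`, `dsif`, `second`.
#' @param outdir Output directory (`NULL`: keep results in memory only).
#' @param seed Integer seed for all stochastic stages.
#' @param depth Tags per simulated track (synthetic mode).
#' @param tag_length,bin_size,scheme Simulation / weighting parameters.
#' @param tracks Track kinds to simulate in synthetic mode.
#' @param funnel Named list of overrides for [run_funnel()] parameters.
#' @return A `run_config` object.
#' @export
run_config <- function(spec = NULL, paths = NULL, outdir = NULL, seed = 1L,
                       depth = 1e5, tag_length = 36L, bin_size = 10L,
                       scheme = "uniform",
                       tracks = c("pol3_ip", "input", "pol2"),
                       funnel = list()) {
  if (is.null(spec) == is.null(paths))
    stop("supply exactly one of `spec` (synthetic mode) or `paths` (real mode)")
  if (is.character(spec)) spec <- example_genome_spec(spec, seed = seed)
  if (!is.null(spec) && !inherits(spec, "genome_spec"))
    stop("`spec` must be a genome_spec or an example design name")
  if (!is.null(paths)) {
    need <- c("peaks", "genes", "ip", "input")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0)
      stop("real mode requires paths: ", paste(miss, collapse = ", "))
  }
  structure(list(mode = if (is.null(spec)) "real" else "synthetic",
                 spec = spec, paths = paths, outdir = outdir,
                 seed = as.integer(seed), depth = depth,
                 tag_length = as.integer(tag_length),
                 bin_size = as.integer(bin_size), scheme = scheme,
                 tracks = tracks, funnel = funnel),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized fields: `mode` (`synthetic`/`real`); for synthetic mode either
#' `design` (an [example_genome_spec()] name) or nothing (defaults to
#' `funnel`); for real mode a `paths` mapping; plus any of `seed`, `depth`,
#' `tag_length`, `bin_size`, `scheme`, `tracks`, `outdir` and a `funnel`
#' mapping of stage-parameter overrides.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mode <- y$mode %||% "synthetic"
  args <- list(outdir = y$outdir, seed = y$seed %||% 1L,
               depth = y$depth %||% 1e5, tag_length = y$tag_length %||% 36L,
               bin_size = y$bin_size %||% 10L, scheme = y$scheme %||% "uniform",
               funnel = y$funnel %||% list())
  if (!is.null(y$tracks)) args$tracks <- unlist(y$tracks)
  if (mode == "synthetic") args$spec <- y$design %||% "funnel"
  else args$paths <- y$paths
  do.call(run_config, args)
}

#' Execute a configured run
#'
#' Runs the stages in order (generate or load inputs, weight tags, build
#' coverage, run the funnel), persists every intermediate artifact when an
#' output directory is configured, and returns a machine-readable report
#' with stage counts, parameters, seeds and the package version. Re-running
#' with the same configuration reproduces all stochastic stages bit-exactly.
#'
#' @param config A `run_config` (or a YAML path understood by
#'   [read_run_config()]).
#' @return A `pipeline_report` list (`counts`, `events`, `params`, `seed`,
#'   `mode`, `version`), invisibly writing `report.json` and artifacts under
#'   `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  if (config$mode == "real") {
    files <- unlist(config$paths)
    missing <- files[!file.exists(files)]
    if (length(missing) > 0)
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }

  if (config$mode == "synthetic") {
    spec <- config$spec
    spec$seed <- config$seed
    genome <- generate_genome(spec)
    cov <- simulate_tracks(genome, tracks = config$tracks,
                           depth = config$depth,
                           tag_length = config$tag_length,
                           bin_size = config$bin_size,
                           scheme = config$scheme, seed = config$seed)
    peaks <- genome$pol3_units
    genes <- genome$genes
    second <- NULL
  } else {
    p <- config$paths
    peaks <- .read_bed_intervals(p$peaks)
    genes <- .read_gene_table(p$genes)
    cov <- list(pol3_ip = read_bedgraph(p$ip), input = read_bedgraph(p$input))
    if (!is.null(p$pol2)) cov$pol2 <- read_bedgraph(p$pol2)
    if (!is.null(p$nelf)) cov$nelf <- read_bedgraph(p$nelf)
    if (!is.null(p$dsif)) cov$dsif <- read_bedgraph(p$dsif)
    second <- if (!is.null(p$second)) .read_bed_intervals(p$second) else NULL
    genome <- NULL
  }

  fargs <- c(list(pol3_peaks = peaks, genes = genes, ip = cov$pol3_ip,
                  input = cov$input, pol2 = cov$pol2, nelf = cov$nelf,
                  dsif = cov$dsif, second_peakset = second),
             config$funnel)
  funnel <- do.call(run_funnel, fargs)

  report <- structure(list(
    mode = config$mode, seed = config$seed,
    counts = as.list(funnel$counts),
    skipped = funnel$skipped,
    params = c(funnel$params,
               list(depth = config$depth, tag_length = config$tag_length,
                    bin_size = config$bin_size, scheme = config$scheme)),
    version = as.character(utils::packageVersion("pol3roadblock"))),
    class = "pipeline_report")
  report$events <- funnel$events

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(genome)) {
      write_genome(genome, file.path(config$outdir, "genome"))
      ts <- attr(cov, "tag_sets")
      for (nm in names(ts))
        write_tags(ts[[nm]], file.path(config$outdir,
                                       paste0("tags_", nm, ".tsv")))
    }
    for (nm in intersect(names(cov), config$tracks))
      write_bedgraph(cov[[nm]], file.path(config$outdir,
                                          paste0(nm, ".bedGraph")))
    write_funnel(funnel, config$outdir)
    validate_report(report)
    jsonlite::write_json(report[setdiff(names(report), "events")],
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    validate_report(report)
  }
  report
}

.read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  nm <- gr$name %||% names(gr)
  if (!is.null(nm)) df$id <- nm
  df
}

.read_gene_table <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) gr <- gr[gr$type == "gene"]
  df <- data.frame(id = gr$ID %||% gr$name %||%
                     sprintf("gene_%03d", seq_along(gr)),
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tes <- ifelse(df$strand == "+", df$end, df$start)
  df
}

# Structural validation of the run report against the shipped JSON schema
# (inst/schema/report_schema.json): required fields and types.
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "pol3roadblock"))
  req <- unlist(schema$required)
  miss <- setdiff(req, names(report))
  if (length(miss) > 0)
    stop("run report is missing required field(s): ",
         paste(miss, collapse = ", "))
  types <- vapply(schema$properties, function(p) p$type, character(1))
  for (nm in names(types)) {
    if (!nm %in% names(report)) next
    ok <- switch(types[[nm]],
                 string = is.character(report[[nm]]),
                 integer = is.numeric(report[[nm]]),
                 object = is.list(report[[nm]]),
                 array = is.list(report[[nm]]) || is.vector(report[[nm]]),
                 TRUE)
    if (!ok) stop("run report field '", nm, "' has the wrong type")
  }
  invisible(TRUE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline run (%s mode, seed %d, pol3roadblock %s)\n",
              x$mode, x$seed, x$version))
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.na(v)) "(skipped)" else format(v)))
  }
  invisible(x)
}
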