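#' Assemble a pipeline configuration
#'
#' Collects every stage's thresholds and paths.  Values echo into the
#' run log and into a config snapshot written next to the outputs, so a
#' run can be reproduced from its artifacts alone.
#'
#' @param fastaPath Input FASTA path.
#' @param taxonomyPath Two-column taxonomy TSV path.
#' @param outDir Output directory (created if absent).
#' @param prefix Output file prefix (default `"curated"`).
#' @param clstrPath Optional pre-computed `.clstr` path; when given the
#'   clustering stage is skipped and the file parsed instead.
#' @param exclusionPath Optional text file with one accession per line to
#'   drop before clustering (the second-pass protocol).
#' @param keywords Header keywords (default [defaultKeywords()]).
#' @param minLength Length threshold in nt (default 150).
#' @param identity Clustering identity threshold (default 0.99).
#' @param bothStrands Cluster considering reverse complements too.
#' @param dominance Curation dominance threshold (default 0.9, strict).
#' @param rankLadder Curation rank ladder (default species, genus,
#'   family).
#' @param flagSpeciesGt Highlight threshold for distinct species count.
#' @param lineWidth FASTA output line width.
#' @param greengenesPrefixes Write taxonomy with Greengenes-style rank
#'   prefixes.
#' @param verbose Emit per-stage messages to stderr (default `TRUE`).
#' @return A named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(fastaPath, taxonomyPath, outDir,
                           prefix = "curated", clstrPath = NULL,
                           exclusionPath = NULL,
                           keywords = defaultKeywords(),
                           minLength = 150L, identity = 0.99,
                           bothStrands = FALSE, dominance = 0.9,
                           rankLadder = c("species", "genus", "family"),
                           flagSpeciesGt = 2L, lineWidth = 80L,
                           greengenesPrefixes = FALSE, verbose = TRUE) {
  structure(list(fastaPath = fastaPath, taxonomyPath = taxonomyPath,
                 outDir = outDir, prefix = prefix, clstrPath = clstrPath,
                 exclusionPath = exclusionPath, keywords = keywords,
                 minLength = as.integer(minLength), identity = identity,
                 bothStrands = bothStrands, dominance = dominance,
                 rankLadder = rankLadder,
                 flagSpeciesGt = as.integer(flagSpeciesGt),
                 lineWidth = as.integer(lineWidth),
                 greengenesPrefixes = greengenesPrefixes,
                 verbose = verbose),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML, with overrides
#'
#' Flag-style overrides win over file values, so a recorded config
#' snapshot re-runs identically while still allowing ad hoc tweaks.
#'
#' @param path YAML file whose keys mirror [pipelineConfig()] arguments.
#' @param overrides Named list of values that replace file values.
#' @return A `pipelineConfig`.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipelineConfig, vals)
}

#' Run the full curation pipeline
#'
#' Stage order: header-keyword filter, length filter, optional
#' exclusion-list removal, clustering (or `.clstr` parsing when a file
#' is supplied), cluster curation, output writing.  Every stage's record
#' counts (in, removed, out) are collected into a machine-readable run
#' summary where counts are conserved: `n_in == n_removed + n_out` per
#' stage, and each stage's `n_out` is the next stage's `n_in`.  The
#' curation stage counts one emitted representative record per kept
#' cluster; collapsed redundant members and discarded clusters are its
#' removals.  Identical config + inputs give byte-identical artifacts
#' (timestamps go to the log only).
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, `list(records=, taxonomy=, report=, summary=,
#'   files=)`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  stage_fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  run_stage <- function(stage, expr)
    tryCatch(expr, error = function(e) stage_fail(stage, e))

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say("reading input: %s", config$fastaPath)
  records <- run_stage("read_fasta", readFastaRecords(config$fastaPath))
  taxmap <- run_stage("read_taxonomy",
                      readTaxonomyMap(config$taxonomyPath))
  summary <- data.frame(stage = character(), n_in = integer(),
                        n_removed = integer(), n_out = integer(),
                        stringsAsFactors = FALSE)
  note <- function(stage, n_in, n_out) {
    summary[nrow(summary) + 1L, ] <<-
      list(stage, n_in, n_in - n_out, n_out)
    say("stage %-16s in=%d removed=%d out=%d", stage, n_in,
        n_in - n_out, n_out)
  }

  fh <- run_stage("filter_headers",
                  filterHeaders(records, config$keywords))
  note("filter_headers", length(records), length(fh$kept))
  fl <- run_stage("filter_length",
                  filterLength(fh$kept, config$minLength))
  note("filter_length", length(fh$kept), length(fl$kept))
  kept <- fl$kept

  if (!is.null(config$exclusionPath)) {
    ids <- readLines(config$exclusionPath)
    ids <- ids[nzchar(ids)]
    ex <- run_stage("apply_exclusion_list",
                    applyExclusionList(kept, ids))
    note("apply_exclusion_list", length(kept), length(ex$kept))
    kept <- ex$kept
  }

  if (!is.null(config$clstrPath)) {
    say("parsing supplied clusters: %s", config$clstrPath)
    clusters <- run_stage("parse_clstr", parseClstr(config$clstrPath))
  } else {
    clusters <- run_stage("greedy_cluster",
                          greedyCluster(kept, config$identity,
                                        config$bothStrands))
  }
  note("cluster", length(kept), length(kept))
  say("%d clusters", length(clusters))

  cur <- run_stage("run_curation",
                   runCuration(clusters, taxmap, kept, config$dominance,
                               config$rankLadder, config$flagSpeciesGt))
  note("curate", length(kept), length(cur$records))

  p <- function(ext) file.path(config$outDir,
                               paste0(config$prefix, ext))
  files <- c(fasta = p(".fasta"), taxonomy = p(".tax.tsv"),
             report = p(".report.tsv"), discards = p(".discards.log"),
             summary = p(".run_summary.tsv"), config = p(".config.yaml"),
             clstr = p(".clstr"))
  writeFastaRecords(cur$records, files[["fasta"]], config$lineWidth)
  writeTaxonomyMap(cur$taxonomy, files[["taxonomy"]],
                   config$greengenesPrefixes)
  writeReportTsv(cur$report, files[["report"]])
  writeDiscardLog(cur$report, files[["discards"]])
  writeRunSummary(summary, files[["summary"]])
  writeClstr(clusters, kept, files[["clstr"]])
  snapshot <- config
  snapshot$packageVersion <-
    as.character(utils::packageVersion("refclust"))
  yaml::write_yaml(unclass(snapshot), files[["config"]])
  say("wrote %d curated records to %s", length(cur$records),
      files[["fasta"]])
  invisible(list(records = cur$records, taxonomy = cur$taxonomy,
                 report = cur$report, summary = summary, files = files))
}
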