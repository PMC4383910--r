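#' Scan replicons for tDNA-targeted genomic islands
#'
#' Runs the whole method in memory: integrase admission, per-tDNA
#' fragment search, side and subsite classification, candidate
#' construction, the seven-filter cascade, tandem-aware resolution,
#' naming and summary statistics.
#'
#' @param replicons Replicon tibble ([read_replicons()] or
#'   [simulate_genome()]).
#' @param features List with `tdnas`, `integrases`, `domains` tibbles
#'   ([read_features()]).
#' @param config An [island_config()], a list of overrides, or a YAML
#'   path.
#' @param serials Optional named strain-serial vector for naming (see
#'   [name_islands()]).
#' @param genomes_scanned Genome count for the summary; defaults to the
#'   number of replicons.
#' @param quiet Suppress progress messages.
#' @return An object of class `island_scan`: a list with `islands`,
#'   `candidates`, `survivors`, `trace`, `hits`, `admitted_integrases`,
#'   `summary`, `config` and input tables. Use [generics::tidy()] for
#'   the island tibble, [generics::glance()] for the one-row summary,
#'   and [ggplot2::autoplot()] for a genome map.
#' @examples
#' sim <- simulate_genome(synthetic_plan(1, "canonical_island"))
#' scan <- scan_islands(sim$replicons, sim, quiet = TRUE)
#' tidy(scan)
#' @export
scan_islands <- function(replicons, features, config = island_config(),
                         serials = NULL, genomes_scanned = NULL,
                         quiet = FALSE) {
  config <- as_island_config(config)
  say <- function(...) if (!quiet) inform(paste0(...))
  tdnas <- features$tdnas
  genomes_scanned <- genomes_scanned %||% nrow(replicons)
  admitted <- admit_integrases(features$integrases, config, quiet = quiet)
  say("Population phase: ", nrow(tdnas), " tDNA(s), ",
      nrow(admitted), "/", nrow(features$integrases),
      " integrase call(s) admitted.")
  hits <- find_fragment_hits(tdnas, replicons, config)
  hits <- classify_fragments(hits, tdnas, replicons, config)
  cand <- build_candidates(hits, tdnas, replicons)
  cand <- classify_subsite(cand, tdnas, replicons, config)
  say("Population phase: ", nrow(hits), " fragment hit(s), ",
      nrow(cand), " candidate island(s).")
  casc <- run_cascade(cand, tdnas, admitted, features$domains,
                      replicons, config)
  if (!quiet) {
    for (i in seq_len(nrow(casc$trace))) {
      say("Filtering phase: ", casc$trace$filter[i], " filter: ",
          casc$trace$entering[i], " entering, ",
          casc$trace$rejected[i], " rejected.")
    }
  }
  islands <- resolve_islands(casc$survivors, admitted, tdnas, replicons,
                             config)
  islands <- name_islands(islands, replicons, serials, config)
  say("Resolution phase: ", nrow(casc$survivors), " survivor(s) -> ",
      nrow(islands), " island(s).")
  structure(list(
    islands = islands,
    candidates = casc$candidates,
    survivors = casc$survivors,
    trace = casc$trace,
    hits = hits,
    admitted_integrases = admitted,
    tdnas = tdnas,
    domains = features$domains,
    replicons = replicons %>% select(-"sequence"),
    summary = summarize_islands(islands, genomes_scanned),
    config = config
  ), class = "island_scan")
}

#' @export
print.island_scan <- function(x, ...) {
  cat("<island_scan>\n")
  cat("  replicons:  ", nrow(x$replicons), "\n")
  cat("  tDNAs:      ", nrow(x$tdnas), "\n")
  cat("  candidates: ", nrow(x$candidates), "\n")
  cat("  islands:    ", nrow(x$islands), "\n")
  if (nrow(x$islands)) {
    cat("  names:      ",
        paste(utils::head(x$islands$name, 8), collapse = ", "),
        if (nrow(x$islands) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an island scan into its island table
#'
#' @param x An `island_scan`.
#' @param ... Unused.
#' @return The island tibble.
#' @export
tidy.island_scan <- function(x, ...) x$islands

#' One-row summary of an island scan
#'
#' @param x An `island_scan`.
#' @param ... Unused.
#' @return The one-row summary tibble of [summarize_islands()].
#' @export
glance.island_scan <- function(x, ...) x$summary

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Run the pipeline from files to an output directory
#'
#' Reads a FASTA and its feature annotations, scans for islands, writes
#' `islands.gff3`, `islands.fna`, `islands.tsv`, `summary.tsv` and a
#' JSON run manifest (configuration snapshot, input digests, per-phase
#' counts), and returns the scan. Outputs are deterministic: identical
#' inputs give byte-identical island GFF3 and summary TSV. Nothing is
#' written when any input fails validation.
#'
#' @param fasta Replicon FASTA path.
#' @param features Feature GFF3 path (or TSV directory).
#' @param outdir Output directory.
#' @param config An [island_config()], overrides list, or YAML path.
#' @param serials Optional named strain-serial vector.
#' @param quiet Suppress progress messages.
#' @return The `island_scan`, invisibly.
#' @export
run_island_pipeline <- function(fasta, features, outdir,
                                config = island_config(), serials = NULL,
                                quiet = FALSE) {
  config <- as_island_config(config)
  replicons <- read_replicons(fasta)
  feats <- read_features(features, replicons)
  scan <- scan_islands(replicons, feats, config, serials = serials,
                       quiet = quiet)
  write_islands(scan$islands, replicons, outdir, summary = scan$summary)
  manifest <- list(
    package = "islandmapr",
    version = as.character(utils::packageVersion("islandmapr")),
    config = unclass(config),
    inputs = list(
      fasta = unname(tools::md5sum(fasta)),
      features = if (dir.exists(features)) {
        as.list(tools::md5sum(list.files(features, full.names = TRUE)))
      } else unname(tools::md5sum(features))
    ),
    counts = list(
      replicons = nrow(replicons),
      tdnas = nrow(feats$tdnas),
      integrase_calls = nrow(feats$integrases),
      integrases_admitted = nrow(scan$admitted_integrases),
      fragment_hits = nrow(scan$hits),
      candidates = nrow(scan$candidates),
      survivors = nrow(scan$survivors),
      islands = nrow(scan$islands)
    ),
    filter_trace = as.list(setNames(scan$trace$rejected,
                                    scan$trace$filter))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(scan)
}

#' Write a synthetic dataset to a fixture directory
#'
#' Materializes [simulate_genome()] output as the same FASTA/GFF3
#' dialects the pipeline reads, plus truth tables and a manifest.
#'
#' @param sim Output of [simulate_genome()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_synthetic <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory '", outdir, "'."))
  }
  write_replicons(sim$replicons, file.path(outdir, "replicons.fna"))
  write_features(sim, file.path(outdir, "features.gff3"), sim$replicons)
  readr::write_tsv(sim$truth$islands,
                   file.path(outdir, "truth_islands.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$decoys,
                   file.path(outdir, "truth_decoys.tsv"), progress = FALSE)
  manifest <- list(
    package = "islandmapr",
    seed = sim$plan$seed,
    topology = sim$plan$topology,
    plants = as.list(table(sim$plan$plants$kind))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
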