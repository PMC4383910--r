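#' Pipeline configuration
#'
#' Collects every numeric threshold of the island search in one validated
#' list. Defaults follow the published search parameters where stated
#' (length bounds 2--200 kb, BLASTN-style seeding with word size 7, gap
#' open 0 and gap extend 2.5 per residue, integron-integrase E-value
#' cutoff 1.2e-24, 3-bp damage allowance at the tDNA 3' end); the
#' remaining knobs (match/mismatch scores, hit score and length floors,
#' subsite windows) are package choices documented in the methods
#' vignette.
#'
#' @param min_len,max_len Accepted island length bounds in bp (inclusive).
#' @param word_size Exact-match seed length in nt for the fragment search.
#' @param match_score,mismatch_score Per-base alignment scores.
#' @param gap_open,gap_extend Affine gap scoring: a k-residue gap costs
#'   `gap_open + k * gap_extend`. `gap_extend` may be fractional.
#' @param min_fragment_len Minimum aligned query span (nt) of a reported
#'   fragment hit.
#' @param min_fragment_score Minimum alignment score of a reported hit.
#' @param integron_evalue_max Integrase calls with an integron-profile
#'   E-value at or below this are classified as integron integrases and
#'   excluded.
#' @param damage_offset Number of bases before the tDNA 3' end up to
#'   which a shortened ("damaged") 3' fragment is still accepted.
#' @param min_peptide_len Minimum peptide length (aa) for reported
#'   six-frame ORFs.
#' @param subsite_a_min,subsite_a_max tDNA-local window, as fractions of
#'   gene length, within which an att crossover is classified as
#'   anticodon-proximal (subsite A); crossovers at or beyond
#'   `subsite_a_max` are subsite J.
#' @param tmrna_site_letter Single-letter integration-site code used for
#'   tmRNA targets in island names.
#'
#' @return A list of class `island_config`.
#' @examples
#' cfg <- island_config()
#' cfg$max_len
#' @export
island_config <- function(min_len = 2000,
                          max_len = 200000,
                          word_size = 7,
                          match_score = 2,
                          mismatch_score = -3,
                          gap_open = 0,
                          gap_extend = 2.5,
                          min_fragment_len = 10,
                          min_fragment_score = 20,
                          integron_evalue_max = 1.2e-24,
                          damage_offset = 3,
                          min_peptide_len = 50,
                          subsite_a_min = 0.30,
                          subsite_a_max = 0.60,
                          tmrna_site_letter = "Z") {
  cfg <- list(
    min_len = as.numeric(min_len), max_len = as.numeric(max_len),
    word_size = as.integer(word_size),
    match_score = as.numeric(match_score),
    mismatch_score = as.numeric(mismatch_score),
    gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
    min_fragment_len = as.integer(min_fragment_len),
    min_fragment_score = as.numeric(min_fragment_score),
    integron_evalue_max = as.numeric(integron_evalue_max),
    damage_offset = as.integer(damage_offset),
    min_peptide_len = as.integer(min_peptide_len),
    subsite_a_min = as.numeric(subsite_a_min),
    subsite_a_max = as.numeric(subsite_a_max),
    tmrna_site_letter = as.character(tmrna_site_letter)
  )
  if (cfg$min_len >= cfg$max_len) {
    abort("`min_len` must be smaller than `max_len`.")
  }
  if (cfg$word_size < 4 || cfg$word_size > 10) {
    abort("`word_size` must be between 4 and 10.")
  }
  if (cfg$damage_offset < 0) abort("`damage_offset` must be >= 0.")
  if (cfg$integron_evalue_max < 0) {
    abort("`integron_evalue_max` must be non-negative.")
  }
  if (!(cfg$subsite_a_min >= 0 && cfg$subsite_a_min < cfg$subsite_a_max &&
        cfg$subsite_a_max <= 1)) {
    abort("subsite windows must satisfy 0 <= a_min < a_max <= 1.")
  }
  if (nchar(cfg$tmrna_site_letter) != 1L) {
    abort("`tmrna_site_letter` must be a single character.")
  }
  structure(cfg, class = "island_config")
}

#' @export
print.island_config <- function(x, ...) {
  cat("<island_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [island_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `island_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  bad <- setdiff(names(vals), names(formals(island_config)))
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(bad, collapse = ", ")))
  }
  do.call(island_config, vals)
}

as_island_config <- function(config) {
  if (inherits(config, "island_config")) return(config)
  if (is.null(config)) return(island_config())
  if (is.character(config) && length(config) == 1L) {
    return(read_config(config))
  }
  if (is.list(config)) return(do.call(island_config, config))
  abort("`config` must be an island_config, a list, or a YAML path.")
}
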