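# Resolution phase: collapse multiple surviving candidates at one tDNA
# into a single island, or recognize a tandem array when every member
# has its own integrase and displaced fragment; then name islands and
# compute run-level summary statistics.

aa_three_to_one <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Sec = "U", Pyl = "O"
)

isotype_letter <- function(isotype, kind, config = island_config()) {
  config <- as_island_config(config)
  vapply(seq_along(isotype), function(i) {
    if (kind[i] == "tmRNA" || isotype[i] == "tmRNA") {
      return(config$tmrna_site_letter)
    }
    iso <- isotype[i]
    if (nchar(iso) == 1L) return(toupper(iso))
    hit <- aa_three_to_one[stringr::str_to_title(iso)]
    if (is.na(hit)) {
      abort(paste0("Cannot map isotype '", iso,
                   "' to a one-letter code."))
    }
    unname(hit)
  }, character(1))
}

round_half_up <- function(x) floor(x + 0.5)

#' Resolve surviving candidates into islands
#'
#' Candidates surviving the cascade are grouped by target tDNA. A group
#' of one yields that island directly. For larger groups, candidates are
#' ordered by the distance of their fragment from the gene (nearest
#' first) and the spanned region is partitioned into consecutive
#' segments, each ending at its own fragment; when every segment also
#' carries its own admitted integrase, the group is a tandem array and
#' each segment becomes an island with a `tandem_index`. Otherwise a
#' single winner is kept: highest fragment score, ties broken by
#' shortest island, then leftmost.
#'
#' @param survivors Survivor tibble from [run_cascade()].
#' @param integrases Admitted integrase tibble.
#' @param tdnas tDNA tibble.
#' @param replicons Replicon tibble.
#' @param config An [island_config()].
#' @return An island tibble: `replicon_id`, `start`, `end`, `strand`,
#'   `length`, `tdna_id`, `isotype`, `kind`, `site_letter`, `subsite`,
#'   `fragment_side`, `damaged`, `tandem_index`, `tandem_size`,
#'   `integrase_count`, `score`, `identities`.
#' @export
resolve_islands <- function(survivors, integrases, tdnas, replicons,
                            config = island_config()) {
  config <- as_island_config(config)
  empty <- tibble(replicon_id = character(), start = integer(),
                  end = integer(), strand = character(), length = numeric(),
                  tdna_id = character(), isotype = character(),
                  kind = character(), site_letter = character(),
                  subsite = character(), fragment_side = character(),
                  damaged = logical(), tandem_index = integer(),
                  tandem_size = integer(), integrase_count = integer(),
                  score = numeric(), identities = integer())
  if (!nrow(survivors)) return(empty)
  as_island <- function(cand, start, end, tandem_index, tandem_size) {
    td <- tdnas[match(cand$tdna_id, tdnas$tdna_id), , drop = FALSE]
    L <- replicons$length[match(cand$replicon_id, replicons$replicon_id)]
    fake <- cand
    fake$island_start <- start
    fake$island_end <- end
    tibble(
      replicon_id = cand$replicon_id,
      start = as.integer(start), end = as.integer(end),
      strand = td$strand,
      length = ivl_length(start, end, L, circular = TRUE),
      tdna_id = cand$tdna_id, isotype = td$isotype, kind = td$kind,
      site_letter = isotype_letter(td$isotype, td$kind, config),
      subsite = cand$subsite, fragment_side = cand$side,
      damaged = cand$damaged,
      tandem_index = tandem_index, tandem_size = tandem_size,
      integrase_count = n_integrases_within(fake, integrases, replicons),
      score = cand$score, identities = cand$identities
    )
  }
  islands <- survivors %>%
    group_by(.data$replicon_id, .data$tdna_id) %>%
    group_split() %>%
    map_dfr(function(grp) {
      if (nrow(grp) == 1L) {
        return(as_island(grp[1, ], grp$island_start[1], grp$island_end[1],
                         NA_integer_, NA_integer_))
      }
      grp <- grp %>% arrange(.data$island_length, .data$island_start)
      L <- replicons$length[match(grp$replicon_id[1],
                                  replicons$replicon_id)]
      # a tandem array must share side, placement and strand, have
      # strictly nested candidate intervals and one fixed tDNA boundary
      moving_end <- length(unique(grp$island_start)) == 1L
      moving_start <- length(unique(grp$island_end)) == 1L
      coherent <- length(unique(grp$side)) == 1L &&
        length(unique(grp$relative_position)) == 1L &&
        length(unique(grp$subject_strand)) == 1L &&
        (moving_end || moving_start) &&
        !anyDuplicated(grp$island_length)
      segments <- NULL
      if (coherent) {
        segments <- map_dfr(seq_len(nrow(grp)), function(k) {
          if (k == 1L) {
            s <- grp$island_start[1]; e <- grp$island_end[1]
          } else if (moving_end) {
            s <- grp$island_end[k - 1]; e <- grp$island_end[k]
          } else {
            s <- grp$island_start[k]; e <- grp$island_start[k - 1]
          }
          tibble(k = k, start = s, end = e)
        })
        seg_cand <- grp
        seg_cand$island_start <- segments$start
        seg_cand$island_end <- segments$end
        n_int <- n_integrases_within(seg_cand, integrases, replicons)
        if (!all(n_int >= 1L)) segments <- NULL
      }
      if (!is.null(segments)) {
        n <- nrow(grp)
        map_dfr(seq_len(n), function(k) {
          as_island(grp[k, ], segments$start[k], segments$end[k],
                    k, n)
        })
      } else {
        win <- grp %>%
          arrange(desc(.data$score), .data$island_length,
                  .data$island_start) %>%
          slice(1)
        as_island(win, win$island_start[1], win$island_end[1],
                  NA_integer_, NA_integer_)
      }
    })
  islands %>% arrange(.data$replicon_id, .data$start)
}

#' Compose an island name
#'
#' The nickname is the uppercase first letter of the genus (a leading
#' "Candidatus" token is skipped) plus the lowercase first two letters
#' of the species, followed by a serial number distinguishing strains
#' that share a nickname; the suffix is the island length in kbp
#' (rounded half away from zero) and a single-letter code for the
#' integration site (the target tRNA isotype, or the configured letter
#' for tmRNA).
#'
#' @param genus,species Organism names; `species` must be non-empty.
#' @param serial Strain serial number (>= 0).
#' @param length_bp Island length in bp.
#' @param isotype Target isotype (one- or three-letter amino-acid code,
#'   or `"tmRNA"`).
#' @param kind `"tRNA"` or `"tmRNA"`.
#' @param config An [island_config()].
#' @return The island name, e.g. `"Eco661_50S"`.
#' @examples
#' name_island("Escherichia", "coli", 661, 49591, "Ser")
#' @export
name_island <- function(genus, species, serial, length_bp,
                        isotype, kind = "tRNA",
                        config = island_config()) {
  if (is.na(species) || !nzchar(species)) {
    abort("`species` is required for island naming.")
  }
  if (is.na(genus) || !nzchar(genus)) {
    abort("`genus` is required for island naming.")
  }
  toks <- strsplit(trimws(genus), "\\s+")[[1]]
  toks <- toks[tolower(toks) != "candidatus"]
  if (!length(toks)) abort("Genus contains only a 'Candidatus' token.")
  nickname <- paste0(toupper(substr(toks[1], 1, 1)),
                     tolower(substr(species, 1, 2)))
  kbp <- round_half_up(length_bp / 1000)
  paste0(nickname, serial, "_", kbp,
         isotype_letter(isotype, kind, config))
}

#' Name a table of islands
#'
#' Applies [name_island()] to every island, taking the organism from
#' its replicon. Serial numbers may be supplied as a named vector
#' (names are replicon ids); otherwise a replicon whose `strain` field
#' is purely numeric uses it, and remaining replicons are numbered in
#' input order within each nickname. A unique `island_id` is added for
#' file output, since distinct islands can share a name.
#'
#' @param islands Island tibble from [resolve_islands()].
#' @param replicons Replicon tibble.
#' @param serials Optional named integer vector of strain serials.
#' @param config An [island_config()].
#' @return `islands` with `name` and `island_id` columns.
#' @export
name_islands <- function(islands, replicons, serials = NULL,
                         config = island_config()) {
  config <- as_island_config(config)
  if (!nrow(islands)) {
    return(islands %>% mutate(name = character(), island_id = character()))
  }
  org <- replicons %>%
    mutate(genus = ifelse(nzchar(.data$genus), .data$genus, "Unknown"),
           species = ifelse(nzchar(.data$species), .data$species, "sp"))
  nick <- vapply(seq_len(nrow(org)), function(i) {
    toks <- strsplit(trimws(org$genus[i]), "\\s+")[[1]]
    toks <- toks[tolower(toks) != "candidatus"]
    paste0(toupper(substr(toks[1], 1, 1)),
           tolower(substr(org$species[i], 1, 2)))
  }, character(1))
  serial <- integer(nrow(org))
  if (!is.null(serials)) {
    m <- serials[org$replicon_id]
    serial <- as.integer(m)
  }
  need <- is.na(serial) | serial == 0L
  numeric_strain <- grepl("^[0-9]+$", org$strain)
  serial[need & numeric_strain] <-
    as.integer(org$strain[need & numeric_strain])
  for (nk in unique(nick)) {
    idx <- which(nick == nk & (is.na(serial) | serial == 0L))
    if (length(idx)) {
      used <- serial[nick == nk & !is.na(serial) & serial > 0L]
      pool <- setdiff(seq_len(length(idx) + length(used)), used)
      serial[idx] <- pool[seq_along(idx)]
    }
  }
  ri <- match(islands$replicon_id, org$replicon_id)
  nm <- vapply(seq_len(nrow(islands)), function(i) {
    name_island(org$genus[ri[i]], org$species[ri[i]], serial[ri[i]],
                islands$length[i], islands$isotype[i], islands$kind[i],
                config)
  }, character(1))
  islands %>%
    mutate(name = nm, island_id = make.unique(nm, sep = "."))
}

#' Mean islands per island-positive genome
#'
#' @param total_islands Total island count.
#' @param positive_genomes Number of genomes with at least one island.
#' @return The mean rounded to two decimals (half away from zero); 0
#'   when there are no positive genomes.
#' @examples
#' islands_per_positive_genome(3919, 1302)
#' @export
islands_per_positive_genome <- function(total_islands, positive_genomes) {
  if (positive_genomes == 0) return(0)
  round_half_up(total_islands / positive_genomes * 100) / 100
}

#' Summary statistics for a set of islands
#'
#' One-row tibble mirroring the usual run report: total islands,
#' genomes with at least one island, mean islands per positive genome
#' (two decimals), damage counts, 3'/5' fragment partition, A/J/NA
#' subsite partition, and tandem-array counts (arrays of size >= 2 and
#' >= 3). The side partition and the subsite partition each sum to the
#' total.
#'
#' @param islands Island tibble.
#' @param genomes_scanned Number of genomes scanned in the run.
#' @return A one-row tibble.
#' @export
summarize_islands <- function(islands, genomes_scanned) {
  pos <- if (nrow(islands)) length(unique(islands$replicon_id)) else 0L
  arrays <- islands %>%
    filter(!is.na(.data$tandem_size)) %>%
    distinct(.data$replicon_id, .data$tdna_id, .data$tandem_size)
  tibble(
    total_islands = nrow(islands),
    genomes_scanned = as.integer(genomes_scanned),
    genomes_with_island = pos,
    mean_islands_per_positive_genome =
      islands_per_positive_genome(nrow(islands), pos),
    islands_damaged = sum(islands$damaged),
    islands_3prime = sum(islands$fragment_side == "three_prime"),
    islands_5prime = sum(islands$fragment_side == "five_prime"),
    islands_A = sum(!is.na(islands$subsite) & islands$subsite == "A"),
    islands_J = sum(!is.na(islands$subsite) & islands$subsite == "J"),
    islands_subsite_na = sum(is.na(islands$subsite)),
    tandem_ge2 = sum(arrays$tandem_size >= 2L),
    tandem_ge3 = sum(arrays$tandem_size >= 3L),
    no_islands = nrow(islands) == 0L
  )
}
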