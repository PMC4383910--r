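# Readers and writers for the on-disk formats.
#
# Internal coordinates are 0-based half-open; every on-disk format is
# 1-based inclusive (GFF3/BLAST convention). On circular replicons a
# feature crossing the origin is represented internally as start > end
# and on disk as two GFF3 rows sharing one ID.

#' Read replicons from a FASTA file
#'
#' Header lines may carry `key=value` tags after the sequence id:
#' `topology` (`circular`/`linear`, default linear), `genus`, `species`,
#' `strain`. Sequences are uppercased; characters outside `ACGTN` are
#' mapped to `N` with a warning.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `replicon_id`, `length`, `topology`,
#'   `genus`, `species`, `strain`, `sequence`.
#' @export
read_replicons <- function(path) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) {
                     abort(paste0("Cannot read FASTA '", path, "': ",
                                  conditionMessage(e)))
                   })
  if (length(seqs) == 0L) abort(paste0("FASTA '", path, "' has no records."))
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate replicon id(s) in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tag <- function(h, key, default = "") {
    m <- regmatches(h, regexpr(paste0("\\b", key, "=\\S+"), h))
    if (length(m) && nzchar(m)) sub(paste0("^", key, "="), "", m) else default
  }
  sequence <- unname(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    warn(paste0("Non-ACGTN characters mapped to N in replicon(s): ",
                paste(ids[bad], collapse = ", ")))
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  if (any(nchar(sequence) < 1L)) abort("Empty sequence record in FASTA.")
  tibble(
    replicon_id = unname(ids),
    length = nchar(sequence),
    topology = vapply(headers, tag, character(1), key = "topology",
                      default = "linear", USE.NAMES = FALSE),
    genus = vapply(headers, tag, character(1), key = "genus",
                   USE.NAMES = FALSE),
    species = vapply(headers, tag, character(1), key = "species",
                     USE.NAMES = FALSE),
    strain = vapply(headers, tag, character(1), key = "strain",
                    USE.NAMES = FALSE),
    sequence = unname(sequence)
  ) %>%
    mutate(topology = ifelse(.data$topology %in% c("circular", "linear"),
                             .data$topology, "linear"))
}

#' Write replicons to FASTA
#'
#' Inverse of [read_replicons()]: organism and topology tags are kept in
#' the headers.
#'
#' @param replicons Replicon tibble.
#' @param path Output FASTA path.
#' @export
write_replicons <- function(replicons, path) {
  hdr <- paste0(replicons$replicon_id,
                " topology=", replicons$topology,
                ifelse(nzchar(replicons$genus),
                       paste0(" genus=", replicons$genus), ""),
                ifelse(nzchar(replicons$species),
                       paste0(" species=", replicons$species), ""),
                ifelse(nzchar(replicons$strain),
                       paste0(" strain=", replicons$strain), ""))
  x <- Biostrings::DNAStringSet(replicons$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3 helpers
# ---------------------------------------------------------------------------

gff_import_tbl <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   abort(paste0("Cannot read GFF3 '", path, "': ",
                                conditionMessage(e)))
                 })
  mc <- as.data.frame(S4Vectors::mcols(gr))
  out <- tibble(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  for (nm in names(mc)) {
    v <- mc[[nm]]
    if (is.list(v)) v <- vapply(v, function(x) {
      if (length(x) == 0) NA_character_ else paste(x, collapse = ",")
    }, character(1))
    out[[nm]] <- as.character(v)
  }
  out
}

# merge two-row origin-wrapping features (same ID) into start > end form
gff_merge_wraps <- function(tbl, replicons) {
  if (!nrow(tbl) || !"ID" %in% names(tbl)) return(tbl)
  dup <- tbl$ID[duplicated(tbl$ID)]
  if (!length(dup)) return(tbl)
  keep <- tbl %>% filter(!.data$ID %in% dup)
  merged <- map_dfr(unique(dup), function(id) {
    rows <- tbl %>% filter(.data$ID == id) %>% arrange(desc(.data$start))
    if (nrow(rows) != 2L) {
      abort(paste0("Feature ID '", id, "' has ", nrow(rows),
                   " GFF3 rows; origin-wrapping features must have 2."))
    }
    L <- replicons$length[match(rows$replicon_id[1], replicons$replicon_id)]
    if (is.na(L) || rows$end[1] != L || rows$start[2] != 0L) {
      abort(paste0("Rows of feature '", id,
                   "' do not form a valid origin wrap."))
    }
    rows$end[1] <- rows$end[2]
    rows[1, , drop = FALSE]
  })
  bind_rows(keep, merged)
}

gff_attr_string <- function(df, attr_cols) {
  apply(df[attr_cols], 1L, function(row) {
    vals <- row[!is.na(row) & nzchar(row)]
    paste(paste0(names(vals), "=", vals), collapse = ";")
  })
}

# write a GFF3 from an internal-coordinate tibble, splitting wraps
gff_write <- function(tbl, path, replicons, source = "islandmapr",
                      type_col = "type", score_col = NULL,
                      attr_cols = character()) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(replicons))) {
    lines <- c(lines, paste("##sequence-region", replicons$replicon_id[i],
                            1L, replicons$length[i]))
  }
  if (nrow(tbl)) {
    rows <- map_dfr(seq_len(nrow(tbl)), function(i) {
      r <- tbl[i, , drop = FALSE]
      L <- replicons$length[match(r$replicon_id, replicons$replicon_id)]
      segs <- ivl_segments(r$start, r$end, L)
      map_dfr(seq_len(nrow(segs)), function(k) {
        r2 <- r
        r2$start <- segs[k, 1]
        r2$end <- segs[k, 2]
        r2
      })
    })
    score <- if (is.null(score_col)) "." else {
      ifelse(is.na(rows[[score_col]]), ".",
             format(rows[[score_col]], trim = TRUE, scientific = FALSE))
    }
    lines <- c(lines, paste(
      rows$replicon_id, source, rows[[type_col]],
      rows$start + 1L, rows$end, score, rows$strand, ".",
      gff_attr_string(rows, attr_cols),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature tables (tDNAs, integrase calls, domain calls)
# ---------------------------------------------------------------------------

empty_tdnas <- function() {
  tibble(tdna_id = character(), replicon_id = character(),
         start = integer(), end = integer(), strand = character(),
         kind = character(), isotype = character(), anticodon = character())
}

empty_integrases <- function() {
  tibble(integrase_id = character(), replicon_id = character(),
         start = integer(), end = integer(), strand = character(),
         subfamily = character(), integron_evalue = numeric(),
         dom_start = integer(), dom_end = integer())
}

empty_domains <- function() {
  tibble(domain_id = character(), replicon_id = character(),
         start = integer(), end = integer(), strand = character(),
         accession = character(), is_integrase = logical())
}

#' Read tDNA, integrase and protein-domain annotations
#'
#' Accepts either a single GFF3 file (feature types `tRNA`/`tmRNA`,
#' `integrase`, `protein_domain`) or a directory holding the tab-separated
#' tables `tdnas.tsv`, `integrases.tsv` and `domains.tsv`. Both dialects
#' use 1-based inclusive coordinates on disk; see the methods vignette
#' for the column definitions. Coordinates are converted to the internal
#' 0-based half-open convention and validated against `replicons`.
#'
#' @param path GFF3 file or directory of TSV tables.
#' @param replicons Replicon tibble from [read_replicons()].
#' @return A list with tibbles `tdnas`, `integrases`, `domains`.
#' @export
read_features <- function(path, replicons) {
  feats <- if (dir.exists(path)) {
    read_features_tsv(path)
  } else {
    read_features_gff(path, replicons)
  }
  validate_features(feats, replicons)
}

read_features_gff <- function(path, replicons) {
  tbl <- gff_import_tbl(path)
  if (!nrow(tbl)) {
    return(list(tdnas = empty_tdnas(), integrases = empty_integrases(),
                domains = empty_domains()))
  }
  if (!"type" %in% names(tbl)) {
    abort("GFF3 file lacks a type column.")
  }
  grab <- function(tbl, col, default = NA_character_) {
    if (col %in% names(tbl)) tbl[[col]] else rep(default, nrow(tbl))
  }
  td <- tbl %>% filter(.data$type %in% c("tRNA", "tmRNA"))
  td <- gff_merge_wraps(td, replicons)
  tdnas <- tibble(
    tdna_id = grab(td, "ID"),
    replicon_id = td$replicon_id,
    start = as.integer(td$start), end = as.integer(td$end),
    strand = td$strand,
    kind = td$type,
    isotype = grab(td, "isotype"),
    anticodon = dplyr::coalesce(grab(td, "anticodon"), "")
  )
  ig <- tbl %>% filter(.data$type == "integrase")
  ig <- gff_merge_wraps(ig, replicons)
  integrases <- tibble(
    integrase_id = grab(ig, "ID"),
    replicon_id = ig$replicon_id,
    start = as.integer(ig$start), end = as.integer(ig$end),
    strand = ig$strand,
    subfamily = dplyr::coalesce(grab(ig, "subfamily"), "generic"),
    integron_evalue = suppressWarnings(as.numeric(grab(ig, "integron_evalue"))),
    dom_start = suppressWarnings(as.integer(grab(ig, "domain_start"))) - 1L,
    dom_end = suppressWarnings(as.integer(grab(ig, "domain_end")))
  )
  dm <- tbl %>% filter(.data$type == "protein_domain")
  dm <- gff_merge_wraps(dm, replicons)
  domains <- tibble(
    domain_id = grab(dm, "ID"),
    replicon_id = dm$replicon_id,
    start = as.integer(dm$start), end = as.integer(dm$end),
    strand = dm$strand,
    accession = dplyr::coalesce(grab(dm, "accession"), ""),
    is_integrase = toupper(dplyr::coalesce(grab(dm, "is_integrase"),
                                           "FALSE")) %in% c("TRUE", "1")
  )
  known <- c("tRNA", "tmRNA", "integrase", "protein_domain")
  other <- setdiff(unique(tbl$type), known)
  if (length(other)) {
    inform(paste0("Ignoring GFF3 feature type(s): ",
                  paste(other, collapse = ", ")))
  }
  list(tdnas = tdnas, integrases = integrases, domains = domains)
}

read_features_tsv <- function(dir) {
  rd <- function(name, required = FALSE) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      if (required) abort(paste0("Missing feature table: ", p))
      return(NULL)
    }
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  td <- rd("tdnas.tsv", required = TRUE)
  need <- c("tdna_id", "replicon_id", "start", "end", "strand", "kind",
            "isotype")
  miss <- setdiff(need, names(td))
  if (length(miss)) {
    abort(paste0("tdnas.tsv lacks column(s): ", paste(miss, collapse = ", ")))
  }
  tdnas <- tibble(
    tdna_id = as.character(td$tdna_id), replicon_id = td$replicon_id,
    start = as.integer(td$start) - 1L, end = as.integer(td$end),
    strand = td$strand, kind = td$kind,
    isotype = as.character(td$isotype),
    anticodon = if ("anticodon" %in% names(td)) {
      dplyr::coalesce(as.character(td$anticodon), "")
    } else ""
  )
  ig <- rd("integrases.tsv")
  integrases <- if (is.null(ig) || !nrow(ig)) empty_integrases() else tibble(
    integrase_id = as.character(ig$integrase_id),
    replicon_id = ig$replicon_id,
    start = as.integer(ig$start) - 1L, end = as.integer(ig$end),
    strand = ig$strand,
    subfamily = as.character(ig$subfamily),
    integron_evalue = if ("integron_evalue" %in% names(ig)) {
      as.numeric(ig$integron_evalue)
    } else NA_real_,
    dom_start = as.integer(ig$domain_start) - 1L,
    dom_end = as.integer(ig$domain_end)
  )
  dm <- rd("domains.tsv")
  domains <- if (is.null(dm) || !nrow(dm)) empty_domains() else tibble(
    domain_id = as.character(dm$domain_id),
    replicon_id = dm$replicon_id,
    start = as.integer(dm$start) - 1L, end = as.integer(dm$end),
    strand = dm$strand,
    accession = as.character(dm$accession),
    is_integrase = as.logical(dm$is_integrase)
  )
  list(tdnas = tdnas, integrases = integrases, domains = domains)
}

validate_features <- function(feats, replicons) {
  check_tbl <- function(tbl, what) {
    if (!nrow(tbl)) return(tbl)
    unknown <- setdiff(unique(tbl$replicon_id), replicons$replicon_id)
    if (length(unknown)) {
      abort(paste0(what, " reference unknown replicon(s): ",
                   paste(unknown, collapse = ", ")))
    }
    idx <- match(tbl$replicon_id, replicons$replicon_id)
    check_interval_bounds(tbl$start, tbl$end, replicons$length[idx],
                          replicons$topology[idx] == "circular", what)
    if (!all(tbl$strand %in% c("+", "-"))) {
      abort(paste0(what, " strand must be '+' or '-'."))
    }
    tbl
  }
  feats$tdnas <- check_tbl(feats$tdnas, "tDNA")
  feats$integrases <- check_tbl(feats$integrases, "integrase")
  feats$domains <- check_tbl(feats$domains, "protein domain")
  td <- feats$tdnas
  if (nrow(td)) {
    if (any(is.na(td$isotype) | !nzchar(td$isotype))) {
      abort(paste0("tDNA(s) lacking mandatory isotype attribute: ",
                   paste(td$tdna_id[is.na(td$isotype) | !nzchar(td$isotype)],
                         collapse = ", ")))
    }
    if (anyDuplicated(td$tdna_id)) abort("Duplicate tDNA id(s).")
    idx <- match(td$replicon_id, replicons$replicon_id)
    len <- ivl_length(td$start, td$end, replicons$length[idx],
                      replicons$topology[idx] == "circular")
    odd <- td$kind == "tRNA" & (len < 60 | len > 120)
    if (any(odd)) {
      warn(paste0("tRNA gene(s) with unusual length (outside 60-120 nt): ",
                  paste(td$tdna_id[odd], collapse = ", ")))
    }
  }
  ig <- feats$integrases
  if (nrow(ig)) {
    if (!all(ig$subfamily %in%
             c("generic", "XerC", "XerD", "XerS", "XerD-like"))) {
      abort("Integrase subfamily must be one of generic, XerC, XerD, XerS, XerD-like.")
    }
    bad <- !is.na(ig$integron_evalue) & ig$integron_evalue < 0
    if (any(bad)) abort("Negative integron E-value(s).")
    has_dom <- !is.na(ig$dom_start) & !is.na(ig$dom_end)
    if (any(has_dom)) {
      idx <- match(ig$replicon_id, replicons$replicon_id)
      ok <- vapply(which(has_dom), function(i) {
        ivl_contains(ig$start[i], ig$end[i], ig$dom_start[i], ig$dom_end[i],
                     replicons$length[idx[i]])
      }, logical(1))
      if (!all(ok)) {
        abort(paste0("Integrase domain interval outside its ORF: ",
                     paste(ig$integrase_id[which(has_dom)[!ok]],
                           collapse = ", ")))
      }
    }
  }
  feats
}

#' Write feature annotations to GFF3
#'
#' Inverse of [read_features()]; round-tripping a feature set through
#' [write_features()] then [read_features()] reproduces the internal
#' intervals exactly.
#'
#' @param features List with `tdnas`, `integrases`, `domains` tibbles.
#' @param path Output GFF3 path.
#' @param replicons Replicon tibble.
#' @export
write_features <- function(features, path, replicons) {
  td <- features$tdnas %>%
    mutate(type = .data$kind, ID = .data$tdna_id) %>%
    select("replicon_id", "start", "end", "strand", "type", "ID",
           "isotype", "anticodon")
  ig <- features$integrases %>%
    mutate(type = "integrase", ID = .data$integrase_id,
           subfamily = .data$subfamily,
           integron_evalue = ifelse(is.na(.data$integron_evalue), NA,
                                    format(.data$integron_evalue,
                                           scientific = TRUE, trim = TRUE)),
           domain_start = as.character(.data$dom_start + 1L),
           domain_end = as.character(.data$dom_end)) %>%
    select("replicon_id", "start", "end", "strand", "type", "ID",
           "subfamily", "integron_evalue", "domain_start", "domain_end")
  dm <- features$domains %>%
    mutate(type = "protein_domain", ID = .data$domain_id,
           is_integrase = ifelse(.data$is_integrase, "TRUE", "FALSE")) %>%
    select("replicon_id", "start", "end", "strand", "type", "ID",
           "accession", "is_integrase")
  all <- bind_rows(td, ig, dm)
  attr_cols <- setdiff(names(all),
                       c("replicon_id", "start", "end", "strand", "type"))
  gff_write(all, path, replicons, type_col = "type", attr_cols = attr_cols)
}

# ---------------------------------------------------------------------------
# Island outputs
# ---------------------------------------------------------------------------

#' Write accepted islands to an output directory
#'
#' Emits `islands.gff3` (1-based coordinates; origin-wrapping islands
#' become two rows sharing an ID), `islands.fna` (one FASTA record per
#' island) and `islands.tsv` (the island table). Re-reading the GFF3
#' with [read_islands()] reproduces the internal intervals exactly.
#'
#' @param islands Island tibble (see [resolve_islands()]).
#' @param replicons Replicon tibble.
#' @param outdir Output directory, created if needed.
#' @param summary Optional one-row summary tibble written as
#'   `summary.tsv`.
#' @return The output directory, invisibly.
#' @export
write_islands <- function(islands, replicons, outdir, summary = NULL) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory '", outdir, "'."))
  }
  gtab <- islands %>%
    mutate(type = "genomic_island", ID = .data$island_id, Name = .data$name,
           target_tdna = .data$tdna_id,
           tandem_index = ifelse(is.na(.data$tandem_index), NA,
                                 as.character(.data$tandem_index)),
           tandem_size = ifelse(is.na(.data$tandem_size), NA,
                                as.character(.data$tandem_size)),
           damaged = ifelse(.data$damaged, "TRUE", "FALSE")) %>%
    select("replicon_id", "start", "end", "strand", "type", "score",
           "ID", "Name", "target_tdna", "isotype", "kind", "site_letter",
           "subsite", "fragment_side", "damaged", "tandem_index",
           "tandem_size", "integrase_count", "identities")
  attr_cols <- setdiff(names(gtab),
                       c("replicon_id", "start", "end", "strand", "type",
                         "score"))
  gff_write(gtab, file.path(outdir, "islands.gff3"), replicons,
            type_col = "type", score_col = "score", attr_cols = attr_cols)
  seqs <- if (nrow(islands)) {
    vapply(seq_len(nrow(islands)), function(i) {
      s <- replicons$sequence[match(islands$replicon_id[i],
                                    replicons$replicon_id)]
      ivl_seq(s, islands$start[i], islands$end[i])
    }, character(1))
  } else character()
  x <- Biostrings::DNAStringSet(seqs)
  if (nrow(islands)) {
    names(x) <- paste0(islands$island_id, " ", islands$replicon_id, ":",
                       islands$start + 1, "-", islands$end)
  }
  Biostrings::writeXStringSet(x, file.path(outdir, "islands.fna"),
                              width = 70L)
  readr::write_tsv(islands, file.path(outdir, "islands.tsv"),
                   progress = FALSE)
  if (!is.null(summary)) {
    readr::write_tsv(summary, file.path(outdir, "summary.tsv"),
                     progress = FALSE)
  }
  invisible(outdir)
}

#' Read an island GFF3 back into a tibble
#'
#' @param path `islands.gff3` written by [write_islands()].
#' @param replicons Replicon tibble (needed to rejoin origin-wrapping
#'   islands).
#' @return Island tibble with internal 0-based half-open coordinates.
#' @export
read_islands <- function(path, replicons) {
  tbl <- gff_import_tbl(path)
  if (!nrow(tbl)) {
    return(tibble(island_id = character(), name = character(),
                  replicon_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  length = numeric(), tdna_id = character(),
                  isotype = character(), kind = character(),
                  site_letter = character(), subsite = character(),
                  fragment_side = character(), damaged = logical(),
                  tandem_index = integer(), tandem_size = integer(),
                  integrase_count = integer(), score = numeric(),
                  identities = integer()))
  }
  tbl <- gff_merge_wraps(tbl, replicons)
  idx <- match(tbl$replicon_id, replicons$replicon_id)
  grab <- function(col) {
    if (col %in% names(tbl)) tbl[[col]] else rep(NA_character_, nrow(tbl))
  }
  tibble(
    island_id = grab("ID"),
    name = grab("Name"),
    replicon_id = tbl$replicon_id,
    start = as.integer(tbl$start), end = as.integer(tbl$end),
    strand = tbl$strand,
    length = ivl_length(as.integer(tbl$start), as.integer(tbl$end),
                        replicons$length[idx],
                        replicons$topology[idx] == "circular"),
    tdna_id = grab("target_tdna"),
    isotype = grab("isotype"),
    kind = grab("kind"),
    site_letter = grab("site_letter"),
    subsite = grab("subsite"),
    fragment_side = grab("fragment_side"),
    damaged = toupper(grab("damaged")) == "TRUE",
    tandem_index = suppressWarnings(as.integer(grab("tandem_index"))),
    tandem_size = suppressWarnings(as.integer(grab("tandem_size"))),
    integrase_count = suppressWarnings(as.integer(grab("integrase_count"))),
    score = suppressWarnings(as.numeric(grab("score"))),
    identities = suppressWarnings(as.integer(grab("identities")))
  ) %>% arrange(.data$replicon_id, .data$start)
}
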