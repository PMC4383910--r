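# Seeded synthetic replicons with planted, truth-annotated islands and
# per-filter decoys.
#
# Plants are laid out left to right with background margins between
# them. Background is i.i.d. with configurable GC and is scrubbed of
# every word_size-mer occurring in any tDNA template or filler (either
# strand), so the only alignment seeds in a synthetic replicon are the
# planted copies. Every planted fragment is flanked by filler windows
# chosen so that no extension past the planted boundary can score
# positive, making truth endpoints exact.

# Fixed synthetic 76-nt tDNA-like templates, one per isotype letter
# (Z = tmRNA). Pairwise disjoint in 7-mer content, including reverse
# complements, which the test suite asserts.
.tdna_templates <- c(
  S = "GATAGTCGTTCGCCTCCAATTTATCAAGAACTTCTCTTCGGCAGTGCTACGTCTTGGATGCAGCTGACCTCCGCCA",
  L = "CTAAGGACAGGCCGGGGGAGGGTTACTTGCACGCGGGAACTGATGCGTCTGCTCCAGCCGCATTAACAGAACGCCA",
  G = "TCAGGCCACATGAGTCGCTCGAGTACCGTCGAATAAGTGAGGGACGTTAAGGTTCTGATTGTCAGTGAGATAGCCA",
  M = "CACAGACCCCCTGAATGTATAATGATTTTGAAATCGAATTAGGGTCCAACAGTTCTCAACGCGACCTGAGACGCCA",
  R = "TTTTCATCTACTATAGCGATGTCGCCAAGTCAGGGCAGTCATCCCGCCGCGGTGAACTAAGCCAGCCATAGCGCCA",
  K = "CATCTGCAGTAATCTGCGTTTATAACCGTTTTACTAGAGGAGGGGCATCGAGTCTGTAATTGCACACCACGCGCCA",
  V = "GTCCGGCAATGCGCCTAAAGTATCAGGAAGACCACACAGATCAGATGTACGTAAAGTCACACTGCAAGAGAGGCCA",
  T = "ATGTCCGTGGAGACGAGACAACTCTACAGTGTAGCCTTTTTCCGTAGGGTTCAGAGGGGTTGCTAACAATTTGCCA",
  P = "TAGGGCTATGCATTGGACTGCGCGCGGAATTTCACATAACGAACCCACTACGCCATCGACCGGTTTGTTCGTGCCA",
  A = "GCCAGTACCCCTTTTAACTGAAGTGGATTATTACGTTAGTGACACAAAAATACGGCCGAGAGATCGATGACGGCCA",
  Z = "TTACCGTTCTAGGTGTGTCTGGCCCCGGGTGCGTCCATGATCGGGGGCCGGCAGGAACATTTGGGAATAGATGCCA"
)

#' Synthetic tDNA template sequence
#'
#' @param isotype One-letter isotype code (`"Z"` is the tmRNA template).
#' @return The 76-nt template string.
#' @export
tdna_template <- function(isotype) {
  if (!isotype %in% names(.tdna_templates)) {
    abort(paste0("No synthetic template for isotype '", isotype,
                 "'; available: ",
                 paste(names(.tdna_templates), collapse = ", ")))
  }
  unname(.tdna_templates[isotype])
}

plant_kinds <- c("canonical_island", "decoy_no_integrase",
                 "decoy_wrong_orientation", "decoy_wrong_side",
                 "decoy_internal_fragment", "decoy_short", "decoy_long",
                 "decoy_fragment_in_domain", "decoy_fragment_in_tdna",
                 "tandem_array")

designed_filter_of <- c(
  decoy_no_integrase = "integrase",
  decoy_fragment_in_domain = "cds",
  decoy_fragment_in_tdna = "tdna",
  decoy_short = "length", decoy_long = "length",
  decoy_internal_fragment = "internal",
  decoy_wrong_side = "configuration",
  decoy_wrong_orientation = "orientation"
)

#' Specify one plant for a synthetic replicon
#'
#' @param kind One of the plant kinds: `canonical_island`,
#'   `tandem_array`, or one `decoy_*` class per filter (see the methods
#'   vignette for the decoy taxonomy).
#' @param isotype One-letter template isotype; assigned automatically
#'   when `NA`.
#' @param strand Strand of the planted gene.
#' @param crossover tDNA-local crossover position, as a fraction of
#'   gene length (0 < crossover < 1) or an absolute position in nt.
#' @param island_length Planted island length in bp (per member for
#'   tandem arrays).
#' @param damaged Plant a 3'-damaged fragment (shortened by the damage
#'   offset).
#' @param array_size Number of members for `tandem_array`.
#' @return A one-row tibble.
#' @export
plant_spec <- function(kind, isotype = NA_character_, strand = "+",
                       crossover = 0.5, island_length = NULL,
                       damaged = FALSE, array_size = 3L) {
  kind <- match.arg(kind, plant_kinds)
  if (is.null(island_length)) {
    island_length <- switch(kind,
                            decoy_short = 1500,
                            decoy_long = 201000,
                            tandem_array = 8000,
                            10000)
  }
  if (!strand %in% c("+", "-")) abort("Plant strand must be '+' or '-'.")
  tibble(kind = kind, isotype = isotype, strand = strand,
         crossover = crossover, island_length = as.numeric(island_length),
         damaged = damaged, array_size = as.integer(array_size))
}

#' Plan a synthetic replicon
#'
#' @param seed Integer seed; generation is deterministic given the plan.
#' @param plants A tibble of [plant_spec()] rows, or a character vector
#'   of plant kinds.
#' @param topology `"linear"` or `"circular"`.
#' @param gc Background GC fraction.
#' @param margin Background bp between plants and at the ends.
#' @param replicon_id,genus,species,strain Identity of the replicon.
#' @return A list of class `synthetic_plan`.
#' @export
synthetic_plan <- function(seed, plants, topology = "linear", gc = 0.5,
                           margin = 400L, replicon_id = "syn1",
                           genus = "Synthia", species = "arenosa",
                           strain = "1") {
  if (is.character(plants)) {
    plants <- map_dfr(plants, plant_spec)
  }
  if (!nrow(plants)) abort("A synthetic plan needs at least one plant.")
  if (!all(plants$kind %in% plant_kinds)) {
    abort("Unknown plant kind(s) in plan.")
  }
  free <- setdiff(names(.tdna_templates), plants$isotype)
  need <- which(is.na(plants$isotype))
  if (length(need) > length(free)) {
    abort(paste0("Too many plants for the available templates (max ",
                 length(.tdna_templates), " per replicon)."))
  }
  plants$isotype[need] <- free[seq_along(need)]
  if (anyDuplicated(plants$isotype)) {
    abort("Each plant in a replicon must use a distinct template isotype.")
  }
  bad <- plants$crossover <= 0 |
    (plants$crossover >= 1 & plants$crossover >= 76)
  if (any(bad)) abort("Crossover must fall strictly inside the gene.")
  structure(list(seed = as.integer(seed), plants = plants,
                 topology = match.arg(topology, c("linear", "circular")),
                 gc = gc, margin = as.integer(margin),
                 replicon_id = replicon_id, genus = genus,
                 species = species, strain = strain),
            class = "synthetic_plan")
}

# --------------------------------------------------------------------------
# internals
# --------------------------------------------------------------------------

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b), 1, paste0, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

template_kmer_flags <- function(word) {
  seqs <- c(.tdna_templates, .flank_filler, .host_filler)
  keys <- unlist(lapply(seqs, function(tp) {
    c(kmer_keys(tp, word), kmer_keys(revcomp_chr(tp), word))
  }))
  flags <- logical(4^word)
  flags[keys[!is.na(keys)] + 1L] <- TRUE
  flags
}

kmer_keys <- function(seq, word) {
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(b)
  if (n < word) return(integer(0))
  key <- numeric(n - word + 1L)
  for (k in 0:(word - 1L)) {
    key <- key + b[(1L + k):(n - word + 1L + k)] * 4^(word - 1L - k)
  }
  key
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# On circular replicons the word windows crossing the origin (which the
# linear scrub never sees) are cleaned here. A changed base is accepted
# only if every window covering it -- on the ring and on the line -- is
# clean, so the fix cannot re-break windows the scrub already settled.
# The origin region is always background margin, so its positions are
# redrawable.
fix_origin_windows <- function(seqstr, mask, flags, word, gc) {
  n <- nchar(seqstr)
  chars <- strsplit(seqstr, "")[[1]]
  flagged <- function(s0) {
    idx <- ((s0:(s0 + word - 1L)) %% n) + 1L
    k <- kmer_keys(paste(chars[idx], collapse = ""), word)
    length(k) == 1L && !is.na(k) && flags[k + 1L]
  }
  pos_ok <- function(p0) {  # 0-based position
    all(!vapply((p0 - word + 1L):p0, function(s0) flagged(s0 %% n),
                logical(1)))
  }
  wrap_starts <- (n - word + 1L):(n - 1L)
  for (it in 1:50) {
    bad <- Filter(flagged, wrap_starts)
    if (!length(bad)) return(paste(chars, collapse = ""))
    s0 <- bad[[1]]
    pos0 <- (s0:(s0 + word - 1L)) %% n
    pos0 <- pos0[mask[pos0 + 1L]]
    fixed <- FALSE
    for (p0 in rev(pos0)) {
      orig <- chars[p0 + 1L]
      for (cand in sample(setdiff(c("A", "C", "G", "T"), orig))) {
        chars[p0 + 1L] <- cand
        if (pos_ok(p0)) { fixed <- TRUE; break }
      }
      if (fixed) break
      chars[p0 + 1L] <- orig
    }
    if (!fixed) return(NULL)
  }
  NULL
}

# random stop-free ORF (table 11) of len bases (multiple of 3, >= 12),
# built codon by codon so that it contains no template/filler word
random_orf <- function(len, flags, word) {
  ncod <- len %/% 3L
  sense <- sense_codons()
  cods <- character(ncod)
  cods[1] <- "ATG"
  ctx_clean <- function(i) {
    ctx <- paste(cods[max(1L, i - 3L):i], collapse = "")
    keys <- kmer_keys(ctx, word)
    !length(keys) || !any(flags[keys + 1L])
  }
  i <- 2L
  steps <- 0L
  while (i < ncod) {
    steps <- steps + 1L
    if (steps > 50L * ncod) abort("Could not build a clean ORF.")
    placed <- FALSE
    for (cand in sample(sense)) {
      cods[i] <- cand
      if (ctx_clean(i)) { placed <- TRUE; break }
    }
    if (placed) i <- i + 1L else { cods[i] <- ""; i <- max(2L, i - 1L) }
  }
  repeat {
    cods[ncod] <- "TAA"
    if (ctx_clean(ncod)) break
    # re-randomize the penultimate codon until the stop fits cleanly
    for (cand in sample(sense)) {
      cods[ncod - 1L] <- cand
      if (ctx_clean(ncod - 1L)) break
    }
  }
  paste(cods, collapse = "")
}

chars_of <- function(s) strsplit(s, "")[[1]]

rev_str <- function(s) paste(rev(chars_of(s)), collapse = "")

# Fixed filler sequences, 7-mer disjoint (with reverse complements)
# from every template and from each other. Windows of .flank_filler
# flank planted fragments; .host_filler forms the 5' body of the
# host-gene decoy. Both are included in the scrub word set, so they
# never arise in background sequence.
.flank_filler <- "CGGTTTTGGTTGGGCACAACTGACGATCCTATACGGGCAGCCTTGAAAAAAGTGGGGTCGTAGGTCGTACTGATCAATCGACAAGCGTGCTCTGCTTGCGGAGTAGCGCGGTCTCGACTGTTCCGGAACGCATACTCGCAGGTGGGTGCCTACTTGAGAGTATTCCAGAATACGACGCTCAACACCGGCATTTTTTGGAATGAACGTCAGGTATGCAAAGCTCTCTCTCTGTTTGAGCGCGACGGAACCAAACTTGACGGTTCCAAGGAGTCGTATCGAGAGGATGTCTGATGTTCTATCGCTCAGTTGGATAATGCTGCGAGTCAGAATGCCTTGGTCCATTGACAACGACGTTTCCTGGACTCAGCCTCGCAGGCGGACTTTTGGCGTGGCGAAGGGA"
.host_filler <- "CAGTAAATGTGATATGACAAACACACGATCTAGCCTGGTCGCTTTATTTCATTAGGACCTTGTACACGTTATCGACGTGCATGACCCTTGATCCTGCATTTCGATAACGCGGTAAATAGCAAGACTCTATGCCAAAGCACCCCGGTAGAAGCGGCGCAAGACTTCATGATGTAGACATAGTCTTAGCACGTGCTTAGAGCAGGACGCGTGTCCGATTAACTCTTTTCTGAATCTAGGCGGGGTGGCACACAACCCAGGTTACGAATTTGGAGCCTCATTTCCTTACTTCTTGGGGCAGGCAGGTTATTGTAGATAATTTCCGGTATAAGATTTACTGGAGTGTGGAAGTATATAGCTATTAGCGCAGAATCTGGATGAAGTCAACCCTTCAAGAGGACCC"

# how many of the four bases x leave the word x+six (or six+x) outside
# the scrub word set; junctions facing background need at least two so
# the scrub can always pick a clean adjacent base
n_clean_pre <- function(six, flags, word) {
  sum(vapply(c("A", "C", "G", "T"), function(x) {
    !flags[kmer_keys(paste0(x, six), word) + 1L]
  }, logical(1)))
}
n_clean_suf <- function(six, flags, word) {
  sum(vapply(c("A", "C", "G", "T"), function(x) {
    !flags[kmer_keys(paste0(six, x), word) + 1L]
  }, logical(1)))
}

# Choose a filler window that is extension-safe against the given
# template continuation: no anchored alignment of the continuation
# against the window scores positive (so seed extension stops exactly
# at the planted boundary), preferring windows that leave the deepest
# deficit for paths traversing the whole window. `cont` reads away
# from the fragment boundary, first character adjacent. Returns the
# window as inserted into the cassette (`side` names the side of the
# fragment it sits on); its background-facing boundary must leave the
# scrub at least two clean junction bases. Deterministic.
pick_flank <- function(cont, config, flags, side = c("right", "left"),
                       flank_len = 24L) {
  side <- match.arg(side)
  word <- config$word_size
  filler <- .flank_filler
  cont <- substr(cont, 1L, 36L)
  if (!nzchar(cont)) return("")
  best <- NULL
  best_end <- Inf
  for (o in 0:(nchar(filler) - flank_len)) {
    w <- substr(filler, o + 1L, o + flank_len)
    # a left flank is inserted as the reverse complement of a filler
    # window, so its words stay inside the scrub word set under every
    # orientation transform
    ins <- if (side == "right") w else revcomp_chr(w)
    away <- if (side == "right") ins else rev_str(ins)
    feasible <- if (side == "right") {
      n_clean_suf(substr(ins, flank_len - word + 2L, flank_len),
                  flags, word) >= 2L
    } else {
      n_clean_pre(substr(ins, 1L, word - 1L), flags, word) >= 2L
    }
    if (!feasible) next
    sc <- cpp_ext_score(cont, away, config$match_score,
                        config$mismatch_score,
                        config$gap_open, config$gap_extend)
    if (sc$max_all <= 0 && sc$max_end < best_end) {
      best <- ins
      best_end <- sc$max_end
    }
  }
  if (is.null(best)) {
    abort("No extension-safe flank window found for a planted fragment.")
  }
  best
}

# Host-gene 5' body: a window of .host_filler whose junction with the
# template 3' part is extension-safe in both directions and whose
# background-facing 5' boundary leaves the scrub clean junction bases.
pick_host_prefix <- function(template, cross, config, flags) {
  word <- config$word_size
  cont <- rev_str(substr(template, max(1L, cross - 35L), cross))
  depth <- min(cross, 36L)
  best <- NULL
  best_end <- Inf
  for (o in 0:(nchar(.host_filler) - cross)) {
    prefix <- substr(.host_filler, o + 1L, o + cross)
    if (n_clean_pre(substr(prefix, 1L, word - 1L), flags, word) < 2L) next
    w <- substr(rev_str(prefix), 1L, depth)
    sc <- cpp_ext_score(cont, w, config$match_score, config$mismatch_score,
                        config$gap_open, config$gap_extend)
    if (sc$max_all <= 0 && sc$max_end < best_end) {
      best <- prefix
      best_end <- sc$max_end
    }
  }
  if (is.null(best)) {
    abort("No extension-safe host prefix found.")
  }
  best
}

# one plant cassette in local coordinates. Returns the cassette string
# ('?' marks background to fill), feature tables, protected spans and
# truth rows, all 0-based half-open local.
build_cassette <- function(plant, flags, word, config) {
  damage_offset <- config$damage_offset
  template <- tdna_template(plant$isotype)
  L <- nchar(template)
  cross <- if (plant$crossover < 1) {
    as.integer(round(plant$crossover * L))
  } else as.integer(plant$crossover)
  if (cross < 10L || cross > L - 10L) {
    abort("Crossover leaves too short a fragment to detect.")
  }
  kind <- plant$kind
  want_orf <- TRUE
  orf_len <- if (plant$island_length < 2500) 600L else 900L
  s1 <- 100L
  frag_seq <- substr(template, cross + 1L, L)
  frag_q <- c(cross, L)
  if (kind == "decoy_wrong_side") {
    frag_seq <- substr(template, 1L, cross)
    frag_q <- c(0L, cross)
  } else if (kind == "decoy_internal_fragment") {
    a <- max(2L, as.integer(round(0.25 * L)))
    b <- min(L - damage_offset - 2L, a + 40L)
    frag_seq <- substr(template, a + 1L, b)
    frag_q <- c(a, b)
  } else if (plant$damaged) {
    frag_seq <- substr(template, cross + 1L, L - damage_offset)
    frag_q <- c(cross, L - damage_offset)
  }
  flen <- nchar(frag_seq)
  # extension-safe filler windows flank the fragment wherever the gene
  # sequence continues beyond the planted copy, so seed extensions stop
  # exactly at the planted boundary
  flank_l <- if (frag_q[1] > 0L) {
    pick_flank(rev_str(substr(template, 1L, frag_q[1])), config, flags,
               side = "left")
  } else ""
  flank_r <- if (frag_q[2] < L) {
    pick_flank(substr(template, frag_q[2] + 1L, L), config, flags,
               side = "right")
  } else ""
  frag_unit <- paste0(flank_l, frag_seq, flank_r)
  frag_off_in_unit <- nchar(flank_l)
  if (kind == "decoy_wrong_orientation") {
    frag_unit <- revcomp_chr(frag_unit)
    frag_off_in_unit <- nchar(flank_r)
  }
  n_members <- if (kind == "tandem_array") plant$array_size else 1L
  host <- kind == "decoy_fragment_in_tdna"
  # member layout: s1 bg, ORF, s2 bg, fragment unit (fragment last);
  # for the host decoy the fragment is embedded as the 3' part of a
  # planted full-length tDNA
  parts <- list(list(type = "gene", seq = template))
  for (m in seq_len(n_members)) {
    # island spans (gene end, fragment end]; solve the s2 spacer so the
    # planted length is exact
    frag_tail <- if (host) {
      cross + (L - frag_q[1])
    } else {
      flen + frag_off_in_unit  # flank window preceding the fragment
    }
    s2 <- as.integer(plant$island_length) - s1 -
      (if (want_orf) orf_len else 0L) - frag_tail
    if (s2 < 20L) abort("island_length too small for the cassette layout.")
    parts[[length(parts) + 1L]] <- list(type = "bg", len = s1)
    if (want_orf) {
      parts[[length(parts) + 1L]] <-
        list(type = "orf", seq = random_orf(orf_len, flags, word),
             member = m)
    }
    parts[[length(parts) + 1L]] <- list(type = "bg", len = s2)
    if (host) {
      parts[[length(parts) + 1L]] <-
        list(type = "hostgene", seq = NULL, member = m)
    } else {
      parts[[length(parts) + 1L]] <-
        list(type = "frag", seq = frag_unit, member = m)
    }
  }
  list(parts = parts, template_len = L, cross = cross, frag_q = frag_q,
       frag_off_in_unit = frag_off_in_unit, frag_len = flen,
       want_orf = want_orf, host = host,
       n_members = n_members, kind = kind)
}

#' Generate a synthetic replicon with planted islands and decoys
#'
#' Deterministic under the plan seed: the same plan produces the same
#' sequence, feature tables and truth table. Canonical and in-bounds
#' tandem plants are recorded in `truth$islands` with the exact island
#' interval expected from the endpoint convention; every decoy (and any
#' out-of-bounds canonical plant) is recorded in `truth$decoys` with
#' the filter designed to reject it.
#'
#' @param plan A [synthetic_plan()].
#' @param config An [island_config()]; supplies the damage offset, the
#'   seed word length used for background scrubbing, the subsite
#'   windows used for expected-subsite annotation and the length bounds
#'   used to decide which plants are expected islands.
#' @return A list with `replicons`, `tdnas`, `integrases`, `domains`
#'   (the tibbles [read_features()] would produce), `truth` (list of
#'   `islands` and `decoys` tibbles), `protected` (matrix of planted
#'   fixed-sequence spans, for diagnostics) and `plan`.
#' @export
simulate_genome <- function(plan, config = island_config()) {
  config <- as_island_config(config)
  stopifnot(inherits(plan, "synthetic_plan"))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  }, add = TRUE)
  flags <- template_kmer_flags(config$word_size)
  for (attempt in 0:19) {
    set.seed((plan$seed + 7919L * attempt) %% .Machine$integer.max)
    sim <- simulate_once(plan, config, flags)
    if (!is.null(sim)) return(sim)
  }
  abort("Synthetic generation failed to converge; try another seed.")
}

crossover_nt <- function(crossover, L) {
  if (crossover < 1) as.integer(round(crossover * L)) else
    as.integer(crossover)
}

simulate_once <- function(plan, config, flags) {
  word <- config$word_size
  # Host-gene decoys mix filler and template sequence, and the host is
  # itself a query: its junction words must be scrubbed from background
  # too. Hosts are fixed before anything random is generated so that
  # ORFs and background are cleaned against the full word set.
  host_seqs <- vector("list", nrow(plan$plants))
  for (pi in seq_len(nrow(plan$plants))) {
    if (plan$plants$kind[pi] == "decoy_fragment_in_tdna") {
      tpl <- tdna_template(plan$plants$isotype[pi])
      cross <- crossover_nt(plan$plants$crossover[pi], nchar(tpl))
      host_seqs[[pi]] <- paste0(
        pick_host_prefix(tpl, cross, config, flags),
        substr(tpl, cross + 1L, nchar(tpl)))
    }
  }
  for (hs in host_seqs) {
    if (!is.null(hs)) {
      keys <- c(kmer_keys(hs, word), kmer_keys(revcomp_chr(hs), word))
      flags[keys[!is.na(keys)] + 1L] <- TRUE
    }
  }
  margin <- plan$margin
  plants <- plan$plants
  chunks <- character(0)   # assembled cassette strings with '?' bg
  tdnas <- list(); integrases <- list(); domains <- list()
  truth_islands <- list(); truth_decoys <- list()
  protected <- list()      # absolute spans of planted fixed sequence
  offset <- 0L
  add_chunk <- function(s) {
    chunks[[length(chunks) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }
  add_chunk(strrep("?", margin))
  for (pi in seq_len(nrow(plants))) {
    plant <- plants[pi, , drop = FALSE]
    plant_id <- paste0("p", pi)
    cas <- build_cassette(plant, flags, word, config)
    L <- cas$template_len
    # materialize parts into one cassette string with local features
    loc <- 0L
    segs <- character(0)
    feat_local <- list()
    put <- function(s) {
      segs <<- c(segs, s)
      loc <<- loc + nchar(s)
    }
    for (p in cas$parts) {
      if (p$type == "bg") {
        put(strrep("?", p$len))
      } else if (p$type == "gene") {
        feat_local[[length(feat_local) + 1L]] <-
          list(what = "gene", start = loc, end = loc + nchar(p$seq))
        put(p$seq)
      } else if (p$type == "orf") {
        feat_local[[length(feat_local) + 1L]] <-
          list(what = "orf", start = loc, end = loc + nchar(p$seq),
               member = p$member)
        put(p$seq)
      } else if (p$type == "frag") {
        fs <- loc + cas$frag_off_in_unit
        feat_local[[length(feat_local) + 1L]] <-
          list(what = "frag", start = fs, end = fs + cas$frag_len,
               unit_start = loc, unit_end = loc + nchar(p$seq),
               member = p$member)
        put(p$seq)
      } else if (p$type == "hostgene") {
        # full-length decoy tDNA whose 3' part is the planted fragment;
        # its 5' body is an extension-safe host-filler window, so the
        # hit starts exactly at the planted crossover
        hseq <- host_seqs[[pi]]
        feat_local[[length(feat_local) + 1L]] <-
          list(what = "hostgene", start = loc, end = loc + L,
               frag_start = loc + cas$cross, frag_end = loc + L,
               member = p$member)
        put(hseq)
      }
    }
    cassette <- paste(segs, collapse = "")
    clen <- nchar(cassette)
    # mirror the whole cassette for minus-strand plants
    minus <- plant$strand == "-"
    if (minus) {
      qm <- chartr("?", "N", cassette)   # keep placeholders intact
      cassette <- chartr("N", "?", revcomp_chr(qm))
      feat_local <- lapply(feat_local, function(f) {
        f2 <- f
        f2$start <- clen - f$end
        f2$end <- clen - f$start
        if (!is.null(f$frag_start)) {
          f2$frag_start <- clen - f$frag_end
          f2$frag_end <- clen - f$frag_start
        }
        if (!is.null(f$unit_start)) {
          f2$unit_start <- clen - f$unit_end
          f2$unit_end <- clen - f$unit_start
        }
        f2
      })
    }
    base <- offset
    add_chunk(cassette)
    add_chunk(strrep("?", margin))
    # emit features in absolute coordinates
    strand <- plant$strand
    gene <- Filter(function(f) f$what == "gene", feat_local)[[1]]
    td_id <- paste0("td_", plant_id)
    tdnas[[length(tdnas) + 1L]] <- tibble(
      tdna_id = td_id, replicon_id = plan$replicon_id,
      start = base + gene$start, end = base + gene$end, strand = strand,
      kind = ifelse(plant$isotype == "Z", "tmRNA", "tRNA"),
      isotype = ifelse(plant$isotype == "Z", "tmRNA", plant$isotype),
      anticodon = ifelse(plant$isotype == "Z", "", "NNN")
    )
    protected[[length(protected) + 1L]] <- c(base + gene$start,
                                             base + gene$end)
    for (f in feat_local) {
      if (f$what == "orf") {
        ig_id <- paste0("ig_", plant_id, "_", f$member)
        # the no-integrase decoy carries an excluded call (Xer or
        # integron-like), exercising the admission step
        sub <- "generic"; ev <- NA_real_
        if (plant$kind == "decoy_no_integrase") {
          if (stats::runif(1) < 0.5) sub <- "XerD" else ev <- 1e-30
        }
        integrases[[length(integrases) + 1L]] <- tibble(
          integrase_id = ig_id, replicon_id = plan$replicon_id,
          start = base + f$start, end = base + f$end,
          strand = strand, subfamily = sub, integron_evalue = ev,
          dom_start = base + f$start + 30L, dom_end = base + f$end - 30L
        )
        domains[[length(domains) + 1L]] <- tibble(
          domain_id = paste0("dom_", ig_id),
          replicon_id = plan$replicon_id,
          start = base + f$start + 30L, end = base + f$end - 30L,
          strand = strand, accession = "PF00589", is_integrase = TRUE
        )
      } else if (f$what == "frag") {
        protected[[length(protected) + 1L]] <- c(base + f$unit_start,
                                                 base + f$unit_end)
        if (plant$kind == "decoy_fragment_in_domain") {
          domains[[length(domains) + 1L]] <- tibble(
            domain_id = paste0("dom_", plant_id),
            replicon_id = plan$replicon_id,
            start = base + f$start - 5L, end = base + f$end + 5L,
            strand = strand, accession = "PF13356", is_integrase = FALSE
          )
        }
      } else if (f$what == "hostgene") {
        protected[[length(protected) + 1L]] <- c(base + f$start,
                                                 base + f$end)
        host_iso <- "G"
        tdnas[[length(tdnas) + 1L]] <- tibble(
          tdna_id = paste0("td_", plant_id, "_host"),
          replicon_id = plan$replicon_id,
          start = base + f$start, end = base + f$end, strand = strand,
          kind = "tRNA", isotype = host_iso, anticodon = "NNN"
        )
      }
    }
    # truth bookkeeping
    frag_feats <- Filter(function(f) f$what %in% c("frag", "hostgene"),
                         feat_local)
    members <- order(vapply(frag_feats, function(f) f$member %||% 1L,
                            integer(1)))
    frag_feats <- frag_feats[members]
    expected_island <- plant$kind %in% c("canonical_island",
                                         "tandem_array") &&
      plant$island_length >= config$min_len &&
      plant$island_length <= config$max_len
    p_cross <- cas$frag_q[1] / L
    subsite_exp <- if (plant$isotype == "Z") {
      NA_character_
    } else if (p_cross >= config$subsite_a_min &&
               p_cross < config$subsite_a_max) "A" else "J"
    if (expected_island) {
      n <- cas$n_members
      for (k in seq_len(n)) {
        f <- frag_feats[[k]]
        fe <- if (is.null(f$frag_end)) f$end else f$frag_end
        fs0 <- if (is.null(f$frag_start)) f$start else f$frag_start
        if (strand == "+") {
          s_prev <- if (k == 1L) gene$end else {
            fp <- frag_feats[[k - 1L]]
            if (is.null(fp$frag_end)) fp$end else fp$frag_end
          }
          iv <- c(base + s_prev, base + fe)
        } else {
          s_prev <- if (k == 1L) gene$start else {
            fp <- frag_feats[[k - 1L]]
            if (is.null(fp$frag_start)) fp$start else fp$frag_start
          }
          iv <- c(base + fs0, base + s_prev)
        }
        truth_islands[[length(truth_islands) + 1L]] <- tibble(
          replicon_id = plan$replicon_id,
          start = iv[1], end = iv[2],
          length = iv[2] - iv[1],
          tdna_id = td_id, side = "three_prime",
          damaged = plant$damaged,
          tandem_index = if (n > 1L) k else NA_integer_,
          tandem_size = if (n > 1L) n else NA_integer_,
          subsite = subsite_exp
        )
      }
    } else {
      f <- frag_feats[[1L]]
      fs0 <- if (is.null(f$frag_start)) f$start else f$frag_start
      fe <- if (is.null(f$frag_end)) f$end else f$frag_end
      df <- unname(designed_filter_of[plant$kind])
      if (is.na(df)) df <- "length"  # out-of-bounds canonical/tandem plant
      truth_decoys[[length(truth_decoys) + 1L]] <- tibble(
        plant_id = plant_id, kind = plant$kind, tdna_id = td_id,
        designed_filter = df,
        frag_start = base + fs0, frag_end = base + fe,
        subject_strand = if (plant$kind == "decoy_wrong_orientation") {
          flip_strand(strand)
        } else strand
      )
    }
  }
  # on a circle the displacement side is read from the shorter arc, so
  # every planted island must span at most half the replicon; pad with
  # background if needed
  if (plan$topology == "circular") {
    max_island <- max(plan$plants$island_length *
                        ifelse(plan$plants$kind == "tandem_array",
                               plan$plants$array_size, 1))
    need <- 2L * as.integer(max_island) + 2L * margin - offset
    if (need > 0L) add_chunk(strrep("?", need))
  }
  seqstr <- paste(chunks, collapse = "")
  Ltot <- nchar(seqstr)
  chars <- strsplit(seqstr, "")[[1]]
  mask <- chars == "?"
  chars[mask] <- random_bases(sum(mask), plan$gc)
  seqstr <- cpp_scrub(paste(chars, collapse = ""), mask, flags,
                      config$word_size, rep(-1L, length(chars)))
  if (plan$topology == "circular") {
    seqstr <- fix_origin_windows(seqstr, mask, flags, config$word_size,
                                 plan$gc)
    if (is.null(seqstr)) return(NULL)
  }
  # final verification: every template word occurrence lies inside a
  # planted template copy (including words crossing the origin of a
  # circular replicon)
  vseq <- if (plan$topology == "circular") {
    paste0(seqstr, substr(seqstr, 1L, config$word_size - 1L))
  } else seqstr
  keys <- kmer_keys(vseq, config$word_size)
  hit <- which(!is.na(keys) & flags[keys + 1L]) - 1L  # 0-based starts
  if (length(hit)) {
    prot <- do.call(rbind, protected)
    ok <- vapply(hit, function(h) {
      h < Ltot - config$word_size + 1L &&
        any(prot[, 1] <= h & h + config$word_size <= prot[, 2])
    }, logical(1))
    if (!all(ok)) {
      if (isTRUE(getOption("islandmapr.sim_debug"))) {
        inform(paste0("Unprotected template word(s) at: ",
                      paste(utils::head(hit[!ok], 10), collapse = ", ")))
      }
      if (!isTRUE(getOption("islandmapr.sim_skip_verify"))) return(NULL)
    }
  }
  replicons <- tibble(
    replicon_id = plan$replicon_id, length = Ltot,
    topology = plan$topology, genus = plan$genus,
    species = plan$species, strain = plan$strain, sequence = seqstr
  )
  bind0 <- function(lst, empty) if (length(lst)) bind_rows(lst) else empty
  list(
    replicons = replicons,
    tdnas = bind0(tdnas, empty_tdnas()),
    integrases = bind0(integrases, empty_integrases()),
    domains = bind0(domains, empty_domains()),
    protected = do.call(rbind, protected),
    truth = list(
      islands = bind0(truth_islands, tibble(
        replicon_id = character(), start = integer(), end = integer(),
        length = numeric(), tdna_id = character(), side = character(),
        damaged = logical(), tandem_index = integer(),
        tandem_size = integer(), subsite = character())),
      decoys = bind0(truth_decoys, tibble(
        plant_id = character(), kind = character(), tdna_id = character(),
        designed_filter = character(), frag_start = integer(),
        frag_end = integer(), subject_strand = character()))
    ),
    plan = plan
  )
}

# --------------------------------------------------------------------------
# transforms used by the invariance tests
# --------------------------------------------------------------------------

#' Rotate a circular synthetic dataset
#'
#' Moves the origin of a circular replicon by `offset` bases; all
#' feature tables and the truth table are shifted accordingly
#' (intervals crossing the new origin adopt the start > end wraparound
#' convention). Recovered island sets must be invariant under this
#' transform.
#'
#' @param sim Output of [simulate_genome()] (single circular replicon).
#' @param offset Rotation in bp.
#' @return A transformed copy of `sim`.
#' @export
rotate_synthetic <- function(sim, offset) {
  stopifnot(sim$replicons$topology[1] == "circular",
            nrow(sim$replicons) == 1L)
  L <- sim$replicons$length[1]
  offset <- offset %% L
  s <- sim$replicons$sequence[1]
  sim$replicons$sequence[1] <-
    paste0(substr(s, L - offset + 1L, L), substr(s, 1L, L - offset))
  shift_tbl <- function(tbl, cols = c("start", "end")) {
    if (!nrow(tbl)) return(tbl)
    for (i in seq_len(nrow(tbl))) {
      iv <- ivl_shift(tbl[[cols[1]]][i], tbl[[cols[2]]][i], offset, L)
      tbl[[cols[1]]][i] <- as.integer(iv[1])
      tbl[[cols[2]]][i] <- as.integer(iv[2])
    }
    tbl
  }
  sim$tdnas <- shift_tbl(sim$tdnas)
  sim$integrases <- shift_tbl(sim$integrases)
  sim$integrases <- shift_tbl(sim$integrases, c("dom_start", "dom_end"))
  sim$domains <- shift_tbl(sim$domains)
  sim$truth$islands <- shift_tbl(sim$truth$islands)
  sim$truth$decoys <- shift_tbl(sim$truth$decoys,
                                c("frag_start", "frag_end"))
  sim
}

#' Reverse-complement a synthetic dataset
#'
#' Mirrors the replicon and every feature and truth interval; strands
#' flip. Recovered island sets must mirror exactly under this
#' transform.
#'
#' @param sim Output of [simulate_genome()] (single replicon).
#' @return A transformed copy of `sim`.
#' @export
revcomp_synthetic <- function(sim) {
  stopifnot(nrow(sim$replicons) == 1L)
  L <- sim$replicons$length[1]
  sim$replicons$sequence[1] <- revcomp_chr(sim$replicons$sequence[1])
  mirror_tbl <- function(tbl, cols = c("start", "end"),
                         strand_col = "strand") {
    if (!nrow(tbl)) return(tbl)
    for (i in seq_len(nrow(tbl))) {
      iv <- ivl_mirror(tbl[[cols[1]]][i], tbl[[cols[2]]][i], L)
      tbl[[cols[1]]][i] <- as.integer(iv[1])
      tbl[[cols[2]]][i] <- as.integer(iv[2])
    }
    if (!is.null(strand_col) && strand_col %in% names(tbl)) {
      tbl[[strand_col]] <- flip_strand(tbl[[strand_col]])
    }
    tbl
  }
  sim$tdnas <- mirror_tbl(sim$tdnas)
  sim$integrases <- mirror_tbl(sim$integrases)
  sim$integrases <- mirror_tbl(sim$integrases, c("dom_start", "dom_end"),
                               strand_col = NULL)
  sim$domains <- mirror_tbl(sim$domains)
  sim$truth$islands <- mirror_tbl(sim$truth$islands, strand_col = NULL)
  sim$truth$decoys <- mirror_tbl(sim$truth$decoys,
                                 c("frag_start", "frag_end"),
                                 strand_col = "subject_strand")
  sim
}

#' Compare called islands against a synthetic truth table
#'
#' An island counts as recovered only when its replicon and both
#' endpoints match the truth exactly (and, for tandem members, the
#' tandem index and size match). The decoy report checks, for every
#' designed decoy, that its candidate was rejected and -- when the
#' filters are evaluated in isolation -- that exactly the designed
#' filter fails.
#'
#' @param scan An `island_scan` from [scan_islands()].
#' @param truth The `truth` element of [simulate_genome()] output.
#' @return A list: `recall` (exact-endpoint recall), `precision`,
#'   `n_truth`, `n_called`, and `decoys`, a tibble with one row per
#'   designed decoy (`found`, `rejected`, `failed_filters`, `clean`).
#' @export
truth_compare <- function(scan, truth) {
  islands <- scan$islands
  key <- function(d, idx = TRUE) {
    k <- paste(d$replicon_id, d$start, d$end, sep = ":")
    if (idx && "tandem_index" %in% names(d)) {
      k <- paste(k, dplyr::coalesce(as.character(d$tandem_index), "-"),
                 dplyr::coalesce(as.character(d$tandem_size), "-"),
                 sep = ":")
    }
    k
  }
  t_keys <- key(truth$islands)
  c_keys <- if (nrow(islands)) key(islands) else character(0)
  recovered <- sum(t_keys %in% c_keys)
  recall <- if (length(t_keys)) recovered / length(t_keys) else 1
  precision <- if (length(c_keys)) {
    sum(c_keys %in% t_keys) / length(c_keys)
  } else 1
  cand <- scan$candidates
  pass_cols <- paste0("pass_", island_filter_names)
  decoys <- map_dfr(seq_len(nrow(truth$decoys)), function(i) {
    d <- truth$decoys[i, , drop = FALSE]
    hit <- cand %>%
      filter(.data$tdna_id == d$tdna_id,
             .data$s_start == d$frag_start, .data$s_end == d$frag_end,
             .data$subject_strand == d$subject_strand)
    if (!nrow(hit)) {
      return(tibble(plant_id = d$plant_id, kind = d$kind,
                    designed_filter = d$designed_filter, found = FALSE,
                    rejected = NA, failed_filters = NA_character_,
                    clean = FALSE))
    }
    hit <- hit[1, , drop = FALSE]
    fails <- island_filter_names[!vapply(pass_cols, function(cl) {
      hit[[cl]]
    }, logical(1))]
    tibble(plant_id = d$plant_id, kind = d$kind,
           designed_filter = d$designed_filter, found = TRUE,
           rejected = !hit$accepted,
           failed_filters = paste(fails, collapse = ","),
           clean = identical(fails, d$designed_filter))
  })
  list(recall = recall, precision = precision,
       n_truth = length(t_keys), n_called = length(c_keys),
       decoys = decoys)
}
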