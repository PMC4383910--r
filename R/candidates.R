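#' Build candidate islands from classified fragment hits
#'
#' The interval between a tDNA and each of its fragment hits is a
#' candidate island. In tDNA-local orientation, a fragment lying
#' downstream of the gene yields the island `(tDNA 3' end, fragment
#' distal end]`, and a fragment lying upstream yields `[fragment
#' proximal start, tDNA 5' start)`; the island therefore includes the
#' displaced att copy and excludes the intact gene, so excision plus
#' rejoining leaves exactly one intact tDNA. Intervals are mapped back
#' to forward-strand coordinates; on circular replicons the shorter arc
#' consistent with the displacement side is taken.
#'
#' @param hits Classified hit tibble from [classify_fragments()].
#' @param tdnas tDNA tibble.
#' @param replicons Replicon tibble.
#' @return A candidate tibble: hit columns plus `candidate_id`,
#'   `island_start`, `island_end` (0-based half-open, `start > end`
#'   marking an origin wrap), `island_length` and `relative_position`
#'   (`downstream`/`upstream`, in gene orientation).
#' @export
build_candidates <- function(hits, tdnas, replicons) {
  if (!nrow(hits)) {
    return(hits %>% mutate(candidate_id = character(),
                           island_start = integer(),
                           island_end = integer(),
                           island_length = numeric(),
                           relative_position = character()))
  }
  res <- map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    td <- tdnas[match(h$tdna_id, tdnas$tdna_id), , drop = FALSE]
    rep_idx <- match(td$replicon_id, replicons$replicon_id)
    L <- replicons$length[rep_idx]
    circular <- replicons$topology[rep_idx] == "circular"
    ov <- ivl_overlap_bp(td$start, td$end, h$s_start, h$s_end, L)
    if (ov > 0) {
      abort(paste0("Fragment hit overlaps its own tDNA locus ('",
                   td$tdna_id, "'); self-hits must be removed upstream."))
    }
    # candidate intervals for both displacement sides, gene-oriented
    if (td$strand == "+") {
      down <- c(td$end %% L, h$s_end)        # (tDNA 3' end, frag distal]
      up <- c(h$s_start, td$start)           # [frag proximal, tDNA 5')
    } else {
      down <- c(h$s_start, td$start)
      up <- c(td$end %% L, h$s_end)
    }
    fix <- function(iv) {
      s <- iv[1] %% L
      e <- iv[2]
      if (e == 0L) e <- L
      c(s, e)
    }
    down <- fix(down); up <- fix(up)
    len_down <- ivl_length(down[1], down[2], L, circular = TRUE)
    len_up <- ivl_length(up[1], up[2], L, circular = TRUE)
    if (!circular) {
      # exactly one side is geometrically possible on a linear replicon
      frag_after <- h$s_start >= td$end
      pos_fwd <- if (frag_after) "after" else "before"
      relpos <- if ((pos_fwd == "after") == (td$strand == "+")) {
        "downstream"
      } else {
        "upstream"
      }
    } else {
      relpos <- if (len_down <= len_up) "downstream" else "upstream"
    }
    iv <- if (relpos == "downstream") down else up
    len <- if (relpos == "downstream") len_down else len_up
    tibble(h, island_start = as.integer(iv[1]),
           island_end = as.integer(iv[2]),
           island_length = len, relative_position = relpos)
  })
  res %>%
    mutate(candidate_id = paste0(.data$tdna_id, ":", .data$s_start, "-",
                                 .data$s_end, ":", .data$subject_strand)) %>%
    relocate("candidate_id")
}

#' Classify the att crossover subsite (A or J)
#'
#' The recombination crossover of a tDNA-targeted island falls either in
#' the anticodon-loop-encoding region (subsite A) or towards the 3' end
#' of the gene, in the T-loop / acceptor-stem junction region (subsite
#' J; the two 3' subsites are hard to distinguish and are reported
#' together). The crossover position is taken as the fragment's
#' proximal query boundary: the query start for a 3' fragment, the
#' query end for a 5' fragment. Crossovers within
#' `[subsite_a_min, subsite_a_max)` of the gene length are A, at or
#' beyond `subsite_a_max` are J, and below `subsite_a_min`
#' (an unexpected acceptor-stem-proximal crossover) are J with a
#' warning. tmRNA targets get `NA`.
#'
#' @param candidates Candidate tibble from [build_candidates()].
#' @param tdnas tDNA tibble.
#' @param replicons Replicon tibble.
#' @param config An [island_config()].
#' @return `candidates` with a `subsite` column (`"A"`, `"J"` or `NA`).
#' @export
classify_subsite <- function(candidates, tdnas, replicons,
                             config = island_config()) {
  config <- as_island_config(config)
  if (!nrow(candidates)) {
    return(candidates %>% mutate(subsite = character()))
  }
  idx <- match(candidates$tdna_id, tdnas$tdna_id)
  rep_idx <- match(tdnas$replicon_id[idx], replicons$replicon_id)
  L <- ivl_length(tdnas$start[idx], tdnas$end[idx],
                  replicons$length[rep_idx],
                  replicons$topology[rep_idx] == "circular")
  crossover <- ifelse(candidates$side == "three_prime",
                      candidates$q_start, candidates$q_end)
  p <- crossover / L
  subsite <- ifelse(p >= config$subsite_a_min & p < config$subsite_a_max,
                    "A", "J")
  subsite[!candidates$side %in% c("five_prime", "three_prime")] <-
    NA_character_
  is_tmrna <- tdnas$kind[idx] == "tmRNA"
  if (any(is_tmrna & !is.na(subsite))) {
    inform("Subsite classification not applicable to tmRNA targets; NA.")
  }
  subsite[is_tmrna] <- NA_character_
  low <- !is.na(subsite) & p < config$subsite_a_min
  if (any(low)) {
    warn(paste0("Crossover unexpectedly close to the acceptor stem ",
                "(5' of the anticodon window) for candidate(s): ",
                paste(candidates$candidate_id[low], collapse = ", "),
                "; classified J."))
  }
  candidates %>% mutate(subsite = subsite)
}
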