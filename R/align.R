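# Fragment search: each tDNA is aligned against its own replicon with a
# BLASTN-style seeded local search (exact word seeds, anchored affine-gap
# extension), and an exhaustive Smith-Waterman/Gotoh oracle is provided
# for validating the search on small instances.

#' Exact local alignment oracle
#'
#' Full Smith-Waterman dynamic programming with Gotoh affine gaps under
#' the configured scoring (a k-residue gap costs
#' `gap_open + k * gap_extend`). Quadratic in time and memory; intended
#' as a brute-force reference for the seeded search, not for genome-scale
#' use.
#'
#' @param a,b DNA strings (each at most 5000 nt).
#' @param config An [island_config()] supplying the scoring.
#' @return A one-row tibble with `score`, `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open spans of the optimal local alignment)
#'   and `identities`. Score 0 with empty spans when no positive-scoring
#'   alignment exists.
#' @examples
#' local_align_oracle("ACGTACGT", "ACGTTACGT", island_config())
#' @export
local_align_oracle <- function(a, b, config = island_config()) {
  config <- as_island_config(config)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > 5000 || nchar(b) > 5000) {
    abort("local_align_oracle is limited to sequences of at most 5000 nt.")
  }
  res <- cpp_sw_local(a, b, config$match_score, config$mismatch_score,
                      config$gap_open, config$gap_extend)
  tibble(score = res$score,
         a_start = res$a_start, a_end = res$a_end,
         b_start = res$b_start, b_end = res$b_end,
         identities = res$identities)
}

# gene-orientation sequence of one tDNA
tdna_sequence <- function(tdna_row, replicons) {
  s <- replicons$sequence[match(tdna_row$replicon_id,
                                replicons$replicon_id)]
  g <- ivl_seq(s, tdna_row$start, tdna_row$end)
  if (tdna_row$strand == "-") revcomp_chr(g) else g
}

#' Find displaced tDNA fragments by seeded local alignment
#'
#' Each tDNA (in gene orientation) is used as a query against both
#' strands of its source replicon. Seeds are exact `word_size`-mers;
#' each seed is extended in both directions by anchored dynamic
#' programming under the configured scoring, so a reported hit is the
#' best local alignment containing its seed word. The hit at the tDNA's
#' own locus is removed, hits below the score or length floors are
#' dropped, and hits whose subject intervals overlap by more than 50%
#' are collapsed to the higher-scoring one (ties to the leftmost).
#' Output is deterministic, ordered by subject coordinate.
#'
#' @param tdnas tDNA tibble ([read_features()]).
#' @param replicons Replicon tibble ([read_replicons()]).
#' @param config An [island_config()].
#' @return A tibble with one row per hit: `tdna_id`, `replicon_id`,
#'   `q_start`, `q_end` (tDNA-local 0-based half-open span, 5'->3' of
#'   the gene), `s_start`, `s_end` (forward-strand replicon interval,
#'   `start > end` marking an origin wrap), `subject_strand`, `score`,
#'   `identities`.
#' @export
find_fragment_hits <- function(tdnas, replicons, config = island_config()) {
  config <- as_island_config(config)
  map_dfr(seq_len(nrow(tdnas)), function(i) {
    td <- tdnas[i, , drop = FALSE]
    rep_idx <- match(td$replicon_id, replicons$replicon_id)
    L <- replicons$length[rep_idx]
    circular <- replicons$topology[rep_idx] == "circular"
    query <- tdna_sequence(td, replicons)
    qlen <- nchar(query)
    if (qlen < config$word_size) {
      warn(paste0("tDNA '", td$tdna_id, "' is shorter than the seed word;",
                  " no fragment search performed."))
      return(NULL)
    }
    subject <- replicons$sequence[rep_idx]
    ext <- 0L
    if (circular) {
      ext <- min(L, 2L * qlen + 64L)
      subject <- paste0(subject, substr(replicons$sequence[rep_idx], 1, ext))
    }
    raw <- cpp_seed_extend(query, subject, config$word_size,
                           config$match_score, config$mismatch_score,
                           config$gap_open, config$gap_extend,
                           config$min_fragment_score,
                           config$min_fragment_len)
    if (!nrow(raw)) return(NULL)
    # the query is in gene orientation, so a "same"-sense hit means the
    # fragment reads 5'->3' on the forward strand regardless of the
    # gene's own strand
    raw <- as_tibble(raw) %>%
      mutate(subject_strand = ifelse(.data$sense == "same", "+", "-"))
    # canonicalize hits found in the appended origin extension
    raw <- raw %>% filter(.data$s_start < L)
    if (circular && nrow(raw)) {
      wrap <- raw$s_end > L
      raw$s_end[wrap] <- raw$s_end[wrap] - L
    }
    raw <- raw %>%
      distinct(.data$q_start, .data$q_end, .data$s_start, .data$s_end,
               .data$subject_strand, .keep_all = TRUE)
    # remove self-alignments: the exact self-hit and any other hit of
    # the gene onto (part of) its own locus, on either strand
    self_ov <- vapply(seq_len(nrow(raw)), function(k) {
      ivl_overlap_bp(raw$s_start[k], raw$s_end[k], td$start, td$end, L) > 0
    }, logical(1))
    raw <- raw[!self_ov, , drop = FALSE]
    if (!nrow(raw)) return(NULL)
    # redundancy: subject intervals overlapping > 50% keep best scorer
    ord <- order(-raw$score, raw$s_start, raw$s_end)
    raw <- raw[ord, , drop = FALSE]
    keep <- logical(nrow(raw))
    for (k in seq_len(nrow(raw))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- ivl_overlap_bp(raw$s_start[k], raw$s_end[k],
                             raw$s_start[j], raw$s_end[j], L)
        lk <- ivl_length(raw$s_start[k], raw$s_end[k], L, TRUE)
        lj <- ivl_length(raw$s_start[j], raw$s_end[j], L, TRUE)
        if (ov > 0.5 * min(lk, lj)) { ok <- FALSE; break }
      }
      keep[k] <- ok
    }
    raw[keep, , drop = FALSE] %>%
      transmute(tdna_id = td$tdna_id, replicon_id = td$replicon_id,
                q_start = .data$q_start, q_end = .data$q_end,
                s_start = .data$s_start, s_end = .data$s_end,
                subject_strand = .data$subject_strand,
                score = .data$score, identities = .data$identities) %>%
      arrange(.data$s_start, .data$s_end)
  })
}

#' Classify fragment hits by tDNA side and damage
#'
#' A hit is a 5' fragment when its query span starts at the gene's first
#' base, and a 3' fragment when its query span ends within
#' `damage_offset` bases of the gene's last base -- the allowance for
#' islands whose displaced fragment carries a small deletion just
#' upstream of the discriminator, so that alignments stop short of the
#' 3' terminus. A 3' fragment ending before the terminus is flagged
#' `damaged`. Everything else is `internal`.
#'
#' @param hits Fragment-hit tibble from [find_fragment_hits()].
#' @param tdnas tDNA tibble.
#' @param replicons Replicon tibble.
#' @param config An [island_config()].
#' @return `hits` with columns `side` (`five_prime`, `three_prime`,
#'   `internal`) and `damaged` added.
#' @export
classify_fragments <- function(hits, tdnas, replicons,
                               config = island_config()) {
  config <- as_island_config(config)
  if (!nrow(hits)) {
    return(hits %>% mutate(side = character(), damaged = logical()))
  }
  idx <- match(hits$tdna_id, tdnas$tdna_id)
  rep_idx <- match(tdnas$replicon_id[idx], replicons$replicon_id)
  L <- ivl_length(tdnas$start[idx], tdnas$end[idx],
                  replicons$length[rep_idx],
                  replicons$topology[rep_idx] == "circular")
  side <- ifelse(hits$q_start == 0L, "five_prime",
                 ifelse(hits$q_end >= L - config$damage_offset,
                        "three_prime", "internal"))
  hits %>%
    mutate(side = side,
           damaged = side == "three_prime" & .data$q_end < L)
}
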