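# The filter cascade. Each filter is a pure predicate of one candidate
# and its context, so the accepted set is the conjunction of the seven
# predicates and is independent of evaluation order; the cascade applies
# them in the canonical order (integrase, CDS, tDNA, length, internal,
# configuration, orientation) to produce the attrition trace.

island_filter_names <- c("integrase", "cds", "tdna", "length",
                         "internal", "configuration", "orientation")

replicon_len_of <- function(candidates, replicons) {
  replicons$length[match(candidates$replicon_id, replicons$replicon_id)]
}

#' Integrase filter
#'
#' A candidate island must contain or overlap at least one admitted
#' integrase open reading frame (>= 1 bp overlap with the ORF interval;
#' an integrase straddling the island boundary counts).
#'
#' @param candidates Candidate tibble.
#' @param integrases Admitted integrase tibble ([admit_integrases()]).
#' @param replicons Replicon tibble.
#' @return Logical vector, one element per candidate.
#' @export
filter_integrase <- function(candidates, integrases, replicons) {
  n_integrases_within(candidates, integrases, replicons) >= 1L
}

n_integrases_within <- function(candidates, integrases, replicons) {
  L <- replicon_len_of(candidates, replicons)
  vapply(seq_len(nrow(candidates)), function(i) {
    ig <- integrases[integrases$replicon_id == candidates$replicon_id[i], ,
                     drop = FALSE]
    if (!nrow(ig)) return(0L)
    sum(vapply(seq_len(nrow(ig)), function(j) {
      ivl_overlap_bp(candidates$island_start[i], candidates$island_end[i],
                     ig$start[j], ig$end[j], L[i]) > 0
    }, logical(1)))
  }, integer(1))
}

#' CDS (conserved-domain) filter
#'
#' True tDNAs and their island-split fragments should not overlap
#' conserved portions of protein-coding genes. A candidate fails when
#' its fragment hit interval or its query tDNA interval overlaps a
#' projected Pfam domain, except that integrase-domain overlaps are
#' allowed (some integrase genes are known to extend across attP).
#'
#' @inheritParams filter_integrase
#' @param domains Domain-call tibble.
#' @param tdnas tDNA tibble.
#' @export
filter_cds <- function(candidates, domains, tdnas, replicons) {
  L <- replicon_len_of(candidates, replicons)
  dm <- domains[!domains$is_integrase, , drop = FALSE]
  vapply(seq_len(nrow(candidates)), function(i) {
    d <- dm[dm$replicon_id == candidates$replicon_id[i], , drop = FALSE]
    if (!nrow(d)) return(TRUE)
    td <- tdnas[match(candidates$tdna_id[i], tdnas$tdna_id), , drop = FALSE]
    !any(vapply(seq_len(nrow(d)), function(j) {
      ivl_overlap_bp(candidates$s_start[i], candidates$s_end[i],
                     d$start[j], d$end[j], L[i]) > 0 ||
        ivl_overlap_bp(td$start, td$end, d$start[j], d$end[j], L[i]) > 0
    }, logical(1)))
  }, logical(1))
}

#' tDNA filter
#'
#' Fragment hits that fall fully within an annotated full-length tDNA
#' are rejected: such "fragments" are simply conserved gene sequence,
#' not displaced att copies. Containment, not mere overlap, is
#' required, so hits abutting a gene end survive.
#'
#' @inheritParams filter_cds
#' @export
filter_tdna <- function(candidates, tdnas, replicons) {
  L <- replicon_len_of(candidates, replicons)
  vapply(seq_len(nrow(candidates)), function(i) {
    td <- tdnas[tdnas$replicon_id == candidates$replicon_id[i], ,
                drop = FALSE]
    if (!nrow(td)) return(TRUE)
    !any(vapply(seq_len(nrow(td)), function(j) {
      ivl_contains(td$start[j], td$end[j],
                   candidates$s_start[i], candidates$s_end[i], L[i])
    }, logical(1)))
  }, logical(1))
}

#' Length filter
#'
#' Accepted islands must be between `min_len` and `max_len` (inclusive;
#' defaults 2 kb and 200 kb). Legitimate giants -- symbiosis islands in
#' the hundreds of kb -- are knowingly lost here.
#'
#' @inheritParams filter_integrase
#' @param config An [island_config()].
#' @export
filter_length <- function(candidates, config = island_config()) {
  config <- as_island_config(config)
  candidates$island_length >= config$min_len &
    candidates$island_length <= config$max_len
}

#' Internal-fragment filter
#'
#' Integration splits off tDNA end fragments, so a candidate whose
#' fragment is internal to the full gene is rejected. Damaged 3'
#' fragments (ending within the damage allowance of the terminus) pass.
#'
#' @inheritParams filter_integrase
#' @export
filter_internal <- function(candidates) {
  candidates$side %in% c("five_prime", "three_prime")
}

#' Configuration filter
#'
#' Integration displaces the fragment to one specific side: a 3'
#' fragment must lie downstream of the gene and a 5' fragment upstream
#' (in gene orientation). Candidates with the opposite arrangement are
#' rejected. Candidates without an end-fragment side (internal hits,
#' handled by [filter_internal()]) are vacuously passed here so that
#' each filter tests exactly one property.
#'
#' @inheritParams filter_integrase
#' @export
filter_configuration <- function(candidates) {
  ifelse(candidates$side == "three_prime",
         candidates$relative_position == "downstream",
         ifelse(candidates$side == "five_prime",
                candidates$relative_position == "upstream",
                TRUE))
}

#' Orientation filter
#'
#' The displaced fragment must lie in the same orientation as its tDNA.
#' Opposite-orientation candidates are rejected; because true island
#' signatures are never opposite-oriented, the rejection rate of this
#' late filter estimates the false-positive load among surviving
#' candidates.
#'
#' @inheritParams filter_cds
#' @export
filter_orientation <- function(candidates, tdnas) {
  candidates$subject_strand ==
    tdnas$strand[match(candidates$tdna_id, tdnas$tdna_id)]
}

#' Run the full filter cascade
#'
#' Evaluates all seven filter predicates for every candidate (each
#' predicate is a pure function of the candidate and its context, so
#' the accepted set does not depend on evaluation order), derives the
#' sequential attrition trace in canonical filter order, and returns
#' survivors.
#'
#' @param candidates Candidate tibble from [build_candidates()] (with
#'   `side`/`subsite` columns from [classify_fragments()] and
#'   [classify_subsite()]).
#' @param tdnas,integrases,domains Context tibbles; `integrases` must
#'   already be admitted ([admit_integrases()]).
#' @param replicons Replicon tibble.
#' @param config An [island_config()].
#' @return A list with `candidates` (input plus `pass_*` logical
#'   columns, `n_integrases`, `accepted`), `survivors` (accepted
#'   subset) and `trace` (tibble `filter`, `entering`, `rejected` in
#'   cascade order).
#' @export
run_cascade <- function(candidates, tdnas, integrases, domains, replicons,
                        config = island_config()) {
  config <- as_island_config(config)
  if (!nrow(candidates)) {
    cand <- candidates %>%
      mutate(n_integrases = integer(), pass_integrase = logical(),
             pass_cds = logical(), pass_tdna = logical(),
             pass_length = logical(), pass_internal = logical(),
             pass_configuration = logical(), pass_orientation = logical(),
             accepted = logical())
    trace <- tibble(filter = island_filter_names,
                    entering = 0L, rejected = 0L)
    return(list(candidates = cand, survivors = cand, trace = trace))
  }
  n_int <- n_integrases_within(candidates, integrases, replicons)
  cand <- candidates %>%
    mutate(n_integrases = n_int,
           pass_integrase = n_int >= 1L,
           pass_cds = filter_cds(candidates, domains, tdnas, replicons),
           pass_tdna = filter_tdna(candidates, tdnas, replicons),
           pass_length = filter_length(candidates, config),
           pass_internal = filter_internal(candidates),
           pass_configuration = filter_configuration(candidates),
           pass_orientation = filter_orientation(candidates, tdnas))
  pass_cols <- paste0("pass_", island_filter_names)
  cand$accepted <- Reduce(`&`, lapply(pass_cols, function(cl) cand[[cl]]))
  alive <- rep(TRUE, nrow(cand))
  entering <- rejected <- integer(length(island_filter_names))
  for (k in seq_along(island_filter_names)) {
    entering[k] <- sum(alive)
    fails <- alive & !cand[[pass_cols[k]]]
    rejected[k] <- sum(fails)
    alive <- alive & !fails
  }
  trace <- tibble(filter = island_filter_names,
                  entering = entering, rejected = rejected)
  list(candidates = cand, survivors = cand[cand$accepted, , drop = FALSE],
       trace = trace)
}

#' Per-candidate filter status in cascade order
#'
#' Long-format view of the cascade: for every candidate and filter,
#' `pass`, `fail`, or `not-evaluated` (a filter after the candidate's
#' first sequential failure).
#'
#' @param candidates The `candidates` tibble returned by
#'   [run_cascade()].
#' @return A tibble `candidate_id`, `filter`, `status`.
#' @export
filter_status <- function(candidates) {
  pass_cols <- paste0("pass_", island_filter_names)
  map_dfr(seq_len(nrow(candidates)), function(i) {
    passes <- unname(vapply(pass_cols, function(cl) candidates[[cl]][i],
                            logical(1)))
    first_fail <- match(FALSE, passes)
    status <- ifelse(passes, "pass", "fail")
    if (!is.na(first_fail) && first_fail < length(passes)) {
      status[(first_fail + 1L):length(status)] <- "not-evaluated"
    }
    tibble(candidate_id = candidates$candidate_id[i],
           filter = island_filter_names, status = status)
  })
}
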