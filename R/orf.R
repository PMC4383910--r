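#' Six-frame stop-to-stop open reading frames
#'
#' Translates each replicon in all six frames (translation table 11
#' stop codons TAA, TAG, TGA) and reports every maximal stop-free run
#' with peptide length at or above `min_peptide_len`. Sequence ends act
#' as run boundaries on linear replicons; on circular replicons frames
#' wrap across the origin. Codons containing an ambiguous base are
#' treated as sense codons (translated X), which keeps ORFs intact.
#'
#' @param replicons Replicon tibble from [read_replicons()].
#' @param min_peptide_len Minimum peptide length in amino acids.
#' @return A tibble with columns `replicon_id`, `start`, `end` (0-based
#'   half-open DNA interval of the codons, forward strand, `start > end`
#'   marking an origin wrap), `strand`, `frame` (1--3 within strand) and
#'   `peptide_length`.
#' @export
six_frame_orfs <- function(replicons, min_peptide_len = 50) {
  stops <- c("TAA", "TAG", "TGA")
  map_dfr(seq_len(nrow(replicons)), function(ri) {
    seq <- replicons$sequence[ri]
    L <- nchar(seq)
    circular <- replicons$topology[ri] == "circular"
    out <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp_chr(seq)
      for (off in 0:2) {
        if (circular) {
          # scan the doubled sequence: runs crossing the origin continue
          # codon by codon into the second copy. The run at scan start
          # (not preceded by a stop) is the tail of an origin-crossing
          # run reported elsewhere, so it is dropped; runs are capped at
          # one circumference of codons.
          s2 <- paste0(s, s)
          n_cod <- (2L * L - off) %/% 3L
          if (n_cod < 1) next
          starts <- off + 3L * (seq_len(n_cod) - 1L)  # 0-based codon starts
          cod <- substring(s2, starts + 1L, starts + 3L)
          is_stop <- cod %in% stops
          max_cod <- max(1L, L %/% 3L)
          if (!any(is_stop)) {
            runs <- data.frame(first = 1L, len = max_cod)
          } else {
            runs <- orf_runs(is_stop)
            if (!is_stop[1]) runs <- runs[runs$first != 1L, , drop = FALSE]
            runs <- runs[starts[runs$first] < L, , drop = FALSE]
            runs$len <- pmin(runs$len, max_cod)
          }
        } else {
          n_cod <- (L - off) %/% 3L
          if (n_cod < 1) next
          starts <- off + 3L * (seq_len(n_cod) - 1L)
          cod <- substring(s, starts + 1L, starts + 3L)
          is_stop <- cod %in% stops
          runs <- orf_runs(is_stop)
        }
        if (!nrow(runs)) next
        runs <- runs[runs$len >= min_peptide_len, , drop = FALSE]
        if (!nrow(runs)) next
        a <- starts[runs$first] %% L
        b <- (a + 3L * runs$len) %% L
        b[b == 0L] <- L
        # map strand-local coordinates back to the forward strand
        if (strand == "-") {
          tmp <- L - b
          b <- L - a
          a <- tmp
          a[a == L] <- 0L
          b[b == 0L] <- L
        }
        out[[length(out) + 1L]] <- tibble(
          replicon_id = replicons$replicon_id[ri],
          start = as.integer(a), end = as.integer(b),
          strand = strand, frame = off + 1L,
          peptide_length = as.integer(runs$len)
        )
      }
    }
    bind_rows(out)
  }) %>% arrange(.data$replicon_id, .data$start, .data$strand, .data$frame)
}

# maximal stop-free runs in a logical stop vector; returns first codon
# index (1-based into the scanned codon series) and run length
orf_runs <- function(is_stop) {
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(first = firsts[keep], len = r$lengths[keep])
}
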