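# Topology-aware interval arithmetic.
#
# All internal coordinates are 0-based, half-open, on the forward strand.
# On circular replicons an interval with start > end wraps across the
# origin; its two linear segments are [start, L) and [0, end).

ivl_length <- function(start, end, replicon_len, circular = FALSE) {
  wrap <- start > end
  if (any(wrap & !circular)) {
    abort("Wraparound interval (start > end) on a linear replicon.")
  }
  ifelse(wrap, replicon_len - start + end, end - start)
}

# decompose into a matrix of linear [start, end) segments
ivl_segments <- function(start, end, replicon_len) {
  if (start > end) {
    rbind(c(start, replicon_len), c(0, end))
  } else {
    rbind(c(start, end))
  }
}

# overlap in bp between two (possibly wrapping) intervals; scalar
ivl_overlap_bp <- function(s1, e1, s2, e2, replicon_len) {
  a <- ivl_segments(s1, e1, replicon_len)
  b <- ivl_segments(s2, e2, replicon_len)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      tot <- tot + max(0, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
    }
  }
  tot
}

# is [s2, e2) fully contained in [s1, e1)?  scalar
ivl_contains <- function(s1, e1, s2, e2, replicon_len) {
  inner <- ivl_length(s2, e2, replicon_len, circular = TRUE)
  ivl_overlap_bp(s1, e1, s2, e2, replicon_len) == inner && inner > 0
}

# extract the sequence of a (possibly wrapping) interval
ivl_seq <- function(sequence, start, end) {
  L <- nchar(sequence)
  if (start > end) {
    paste0(substr(sequence, start + 1, L), substr(sequence, 1, end))
  } else {
    substr(sequence, start + 1, end)
  }
}

# shift an interval by `offset` (mod L), preserving its length
ivl_shift <- function(start, end, offset, replicon_len) {
  len <- ivl_length(start, end, replicon_len, circular = TRUE)
  s <- (start + offset) %% replicon_len
  e <- s + len
  if (e > replicon_len) e <- e - replicon_len
  if (e == 0) e <- replicon_len
  c(s, e)
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, ""), function(ch) {
           paste(rev(ch), collapse = "")
         }, character(1)))
}

# mirror an interval under reverse-complementation of the whole replicon
ivl_mirror <- function(start, end, replicon_len) {
  len <- ivl_length(start, end, replicon_len, circular = TRUE)
  e <- (replicon_len - start) %% replicon_len
  if (e == 0) e <- replicon_len
  s <- e - len
  if (s < 0) s <- s + replicon_len
  if (s == replicon_len) s <- 0
  c(s, e)
}

flip_strand <- function(strand) ifelse(strand == "+", "-", "+")

check_interval_bounds <- function(start, end, replicon_len, circular,
                                  what = "feature") {
  bad <- start < 0 | end < 0 | start > replicon_len | end > replicon_len |
    start == end
  if (any(bad)) {
    abort(paste0("Out-of-bounds or empty ", what, " interval(s): ",
                 paste(which(bad), collapse = ", ")))
  }
  wrap <- start > end
  if (any(wrap & !circular)) {
    abort(paste0("Wraparound ", what,
                 " interval(s) on a linear replicon: ",
                 paste(which(wrap & !circular), collapse = ", ")))
  }
  invisible(TRUE)
}
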