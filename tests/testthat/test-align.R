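test_that("oracle reproduces hand-computed local alignments", {
  cfg <- island_config()
  expect_equal(local_align_oracle("ACGT", "ACGT", cfg)$score, 8)
  expect_equal(local_align_oracle("AAAA", "TTTT", cfg)$score, 0)
  # 1-nt insertion: 8 matches at +2 minus one gap residue at 2.5
  r <- local_align_oracle("ACGTACGT", "ACGTTACGT", cfg)
  expect_equal(r$score, 13.5)
  expect_equal(r$identities, 8L)
  expect_equal(local_align_oracle("", "ACGT", cfg)$score, 0)
})

test_that("a planted exact copy of the tDNA 3' end is found precisely", {
  set.seed(21)
  tpl <- tdna_template("S")
  L <- nchar(tpl)
  # scrubbed background so the only seeds are the planted copies
  flags <- islandmapr:::template_kmer_flags(7)
  bg <- function(n) {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    islandmapr:::cpp_scrub(s, rep(TRUE, n), flags, 7L, rep(-1L, n))
  }
  seq <- paste0(bg(200), tpl, bg(5000), substr(tpl, L - 19, L), bg(200))
  reps <- tibble::tibble(replicon_id = "r1", length = nchar(seq),
                         topology = "linear", genus = "", species = "",
                         strain = "", sequence = seq)
  td <- toy_tdna(start = 200L, end = 200L + L)
  hits <- find_fragment_hits(td, reps)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$q_start, L - 20L)
  expect_equal(hits$q_end, L)
  expect_equal(hits$identities, 20L)
  expect_equal(hits$s_start, 200L + L + 5000L)
  expect_equal(hits$score, 40)
})

test_that("a replicon containing only the tDNA yields no hits", {
  tpl <- tdna_template("L")
  reps <- tibble::tibble(replicon_id = "r1", length = nchar(tpl),
                         topology = "linear", genus = "", species = "",
                         strain = "", sequence = tpl)
  td <- toy_tdna(start = 0L, end = nchar(tpl))
  expect_equal(nrow(find_fragment_hits(td, reps)), 0L)
})

test_that("seeded search equals the oracle when a seeded copy is planted", {
  set.seed(77)
  cfg <- island_config()
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    q <- paste(sample(bases, sample(40:80, 1), replace = TRUE),
               collapse = "")
    # plant a copy of an interior query window, with up to 2 mutations
    # spaced so an exact 7-mer run survives
    L <- nchar(q)
    a <- sample(1:10, 1)
    b <- L - sample(1:10, 1)
    copy <- strsplit(substr(q, a, b), "")[[1]]
    if (i %% 3 == 0 && length(copy) > 30) {
      copy[10] <- sample(setdiff(bases, copy[10]), 1)
    }
    subject <- paste0(
      paste(sample(bases, 150, replace = TRUE), collapse = ""),
      paste(copy, collapse = ""),
      paste(sample(bases, 150, replace = TRUE), collapse = ""))
    res <- islandmapr:::cpp_seed_extend(q, subject, cfg$word_size,
                                        cfg$match_score,
                                        cfg$mismatch_score,
                                        cfg$gap_open, cfg$gap_extend,
                                        0, 1L)
    fwd <- res[res$sense == "same", , drop = FALSE]
    oracle <- local_align_oracle(q, subject, cfg)
    expect_true(nrow(fwd) >= 1L)
    expect_equal(max(fwd$score), oracle$score, info = paste("case", i))
    # no same-sense hit ever beats the exhaustive optimum
    expect_true(all(fwd$score <= oracle$score + 1e-9))
  }
})

test_that("hit scores never exceed the oracle on unstructured pairs", {
  set.seed(99)
  cfg <- island_config()
  for (i in 1:20) {
    q <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    res <- islandmapr:::cpp_seed_extend(q, s, cfg$word_size,
                                        cfg$match_score,
                                        cfg$mismatch_score,
                                        cfg$gap_open, cfg$gap_extend,
                                        0, 1L)
    # each orientation is bounded by its own exhaustive optimum
    fwd_ora <- local_align_oracle(q, s, cfg)$score
    rc_ora <- local_align_oracle(islandmapr:::revcomp_chr(q), s,
                                 cfg)$score
    fwd <- res[res$sense == "same", , drop = FALSE]
    rc <- res[res$sense == "opposite", , drop = FALSE]
    if (nrow(fwd)) expect_true(all(fwd$score <= fwd_ora + 1e-9))
    if (nrow(rc)) expect_true(all(rc$score <= rc_ora + 1e-9))
  }
})

test_that("reverse-complementing the replicon mirrors hits exactly", {
  sim <- simulate_genome(synthetic_plan(31, dplyr::bind_rows(
    plant_spec("canonical_island"),
    plant_spec("decoy_wrong_orientation"))))
  h1 <- find_fragment_hits(sim$tdnas, sim$replicons)
  rv <- revcomp_synthetic(sim)
  h2 <- find_fragment_hits(rv$tdnas, rv$replicons)
  L <- sim$replicons$length
  m <- h2 %>%
    mutate(s_start2 = L - .data$s_end, s_end2 = L - .data$s_start,
           strand2 = ifelse(.data$subject_strand == "+", "-", "+")) %>%
    arrange(.data$s_start2)
  h1 <- arrange(h1, .data$s_start)
  expect_equal(h1$s_start, m$s_start2)
  expect_equal(h1$s_end, m$s_end2)
  expect_equal(h1$subject_strand, m$strand2)
  expect_equal(h1$score, m$score)
  expect_equal(h1$q_start, m$q_start)
})

test_that("fragment sides and damage classify per the 3' allowance", {
  reps <- toy_replicon()
  td <- toy_tdna()  # 76 nt
  hits <- dplyr::bind_rows(
    toy_hit(q_start = 0L, q_end = 35L),
    toy_hit(q_start = 40L, q_end = 73L),
    toy_hit(q_start = 20L, q_end = 60L),
    toy_hit(q_start = 40L, q_end = 76L)
  )[, c("tdna_id", "replicon_id", "q_start", "q_end", "s_start",
        "s_end", "subject_strand", "score", "identities")]
  cl <- classify_fragments(hits, td, reps)
  expect_equal(cl$side, c("five_prime", "three_prime", "internal",
                          "three_prime"))
  expect_equal(cl$damaged, c(FALSE, TRUE, FALSE, FALSE))
})
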