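toy_rep <- function(seq, topology = "linear") {
  tibble::tibble(replicon_id = "r", length = nchar(seq),
                 topology = topology, genus = "", species = "",
                 strain = "", sequence = seq)
}

test_that("stop-to-stop ORFs match hand translation", {
  o <- six_frame_orfs(toy_rep("ATGAAATAA"), min_peptide_len = 2)
  fwd1 <- dplyr::filter(o, strand == "+", frame == 1)
  expect_equal(fwd1$start, 0L)
  expect_equal(fwd1$end, 6L)
  expect_equal(fwd1$peptide_length, 2L)  # MK
})

test_that("an all-stop frame yields no ORFs", {
  o <- six_frame_orfs(toy_rep("TAATAGTGA"), min_peptide_len = 1)
  expect_false(any(o$strand == "+" & o$frame == 1))
})

test_that("ORFs are strand-symmetric on random sequences", {
  set.seed(41)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rc <- islandmapr:::revcomp_chr(s)
    a <- six_frame_orfs(toy_rep(s), min_peptide_len = 5)
    b <- six_frame_orfs(toy_rep(rc), min_peptide_len = 5)
    L <- nchar(s)
    mirrored <- dplyr::tibble(start = L - b$end, end = L - b$start,
                              strand = ifelse(b$strand == "+", "-", "+"),
                              peptide_length = b$peptide_length) %>%
      dplyr::arrange(start, strand)
    orig <- dplyr::select(a, start, end, strand, peptide_length) %>%
      dplyr::arrange(start, strand)
    expect_equal(orig$start, mirrored$start)
    expect_equal(orig$end, mirrored$end)
    expect_equal(orig$peptide_length, mirrored$peptide_length)
  }
})

test_that("ORF intervals are disjoint within each frame and strand", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  o <- six_frame_orfs(toy_rep(s), min_peptide_len = 1)
  for (grp in split(o, paste(o$strand, o$frame))) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1) {
      expect_true(all(grp$start[-1] >= grp$end[-nrow(grp)]))
    }
  }
})

test_that("ORFs wrap the origin on circular replicons", {
  # 30 nt, divisible by 3; one stop in frame 1 at position 12
  s <- paste0(strrep("AAA", 4), "TAA", strrep("AAA", 5))
  o <- six_frame_orfs(toy_rep(s, topology = "circular"),
                      min_peptide_len = 1)
  f1 <- dplyr::filter(o, strand == "+", frame == 1)
  # a single run wrapping from after the stop around to before it
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$start, 15L)
  expect_equal(f1$end, 12L)   # start > end marks the origin wrap
  expect_equal(f1$peptide_length, 9L)
})
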