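test_that("island naming follows the nickname/serial/kbp/site scheme", {
  expect_equal(name_island("Escherichia", "coli", 661, 49591, "Ser"),
               "Eco661_50S")
  expect_equal(name_island("Candidatus Foo", "bar", 1, 2000, "Gly"),
               "Fba1_2G")
  # kbp rounds half away from zero
  expect_equal(name_island("Vibrio", "cholerae", 2, 2499, "K"),
               "Vch2_2K")
  expect_equal(name_island("Vibrio", "cholerae", 2, 2500, "K"),
               "Vch2_3K")
  expect_equal(name_island("Bacillus", "subtilis", 3, 12000, "tmRNA",
                           kind = "tmRNA"),
               "Bsu3_12Z")
  expect_error(name_island("Escherichia", "", 1, 1000, "S"), "species")
})

test_that("serials come from numeric strains or input order per nickname", {
  reps <- dplyr::bind_rows(
    toy_replicon(),
    dplyr::mutate(toy_replicon(), replicon_id = "r2", strain = "x"),
    dplyr::mutate(toy_replicon(), replicon_id = "r3", strain = "x"))
  islands <- tibble::tibble(
    replicon_id = c("r1", "r2", "r3"), start = 0L, end = 5000L,
    strand = "+", length = 5000, tdna_id = "t", isotype = "S",
    kind = "tRNA", site_letter = "S", subsite = "A",
    fragment_side = "three_prime", damaged = FALSE,
    tandem_index = NA_integer_, tandem_size = NA_integer_,
    integrase_count = 1L, score = 40, identities = 20L)
  nm <- name_islands(islands, reps)
  expect_equal(nm$name, c("Eco661_5S", "Eco1_5S", "Eco2_5S"))
  expect_false(anyDuplicated(nm$island_id) > 0)
})

test_that("multiple survivors at one tDNA resolve to the best single island", {
  reps <- toy_replicon()
  td <- toy_tdna()
  ig <- toy_integrase(2000, 2900)
  hits <- dplyr::bind_rows(
    toy_hit(s_start = 6076L, s_end = 6096L, score = 40),
    toy_hit(q_start = 44L, s_start = 9076L, s_end = 9096L, score = 30))
  cand <- build_candidates(hits, td, reps) %>%
    dplyr::mutate(subsite = "A")
  # outer segment (6096, 9096] holds no integrase: no tandem
  isl <- resolve_islands(cand, ig, td, reps)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$end, 6096L)         # higher score wins
  expect_true(is.na(isl$tandem_index))
  # tie on score: the shorter island wins
  hits2 <- dplyr::mutate(hits, score = 40)
  cand2 <- build_candidates(hits2, td, reps) %>%
    dplyr::mutate(subsite = "A")
  isl2 <- resolve_islands(cand2, ig, td, reps)
  expect_equal(isl2$end, 6096L)
})

test_that("tandem arrays need an integrase in every segment", {
  reps <- toy_replicon()
  td <- toy_tdna()
  hits <- dplyr::bind_rows(
    toy_hit(s_start = 6076L, s_end = 6096L, score = 40),
    toy_hit(s_start = 11076L, s_end = 11096L, score = 40))
  cand <- build_candidates(hits, td, reps) %>%
    dplyr::mutate(subsite = "A")
  both <- dplyr::bind_rows(toy_integrase(2000, 2900, id = "i1"),
                           toy_integrase(8000, 8900, id = "i2"))
  isl <- resolve_islands(cand, both, td, reps)
  expect_equal(nrow(isl), 2L)
  expect_equal(isl$tandem_index, c(1L, 2L))
  expect_equal(isl$tandem_size, c(2L, 2L))
  expect_equal(isl$start, c(1076L, 6096L))
  expect_equal(isl$end, c(6096L, 11096L))
  # islands do not overlap
  expect_true(isl$end[1] <= isl$start[2])
  # with only the inner integrase the group collapses to one island
  isl2 <- resolve_islands(cand, toy_integrase(2000, 2900), td, reps)
  expect_equal(nrow(isl2), 1L)
  expect_true(is.na(isl2$tandem_index))
})

test_that("summary statistics partition correctly", {
  sim <- simulate_genome(mixed_plan(12, n_decoys = 2))
  scan <- scan_sim(sim)
  sm <- scan$summary
  expect_equal(sm$islands_3prime + sm$islands_5prime, sm$total_islands)
  expect_equal(sm$islands_A + sm$islands_J + sm$islands_subsite_na,
               sm$total_islands)
  expect_equal(sm$mean_islands_per_positive_genome,
               islands_per_positive_genome(sm$total_islands,
                                           sm$genomes_with_island))
  empty <- summarize_islands(scan$islands[0, ], 5)
  expect_equal(empty$total_islands, 0L)
  expect_equal(empty$mean_islands_per_positive_genome, 0)
  expect_true(empty$no_islands)
})
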