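test_that("tDNA templates are pairwise 7-mer disjoint, both strands", {
  tpls <- vapply(names(islandmapr:::.tdna_templates), tdna_template,
                 character(1))
  fillers <- c(islandmapr:::.flank_filler, islandmapr:::.host_filler)
  kmers <- function(s) {
    n <- nchar(s)
    substring(s, 1:(n - 6), 7:n)
  }
  sets <- lapply(c(tpls, fillers), function(s) {
    unique(c(kmers(s), kmers(islandmapr:::revcomp_chr(s))))
  })
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j) expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
  }
  # no template shares a word with its own reverse complement
  for (tp in tpls) {
    expect_length(intersect(kmers(tp),
                            kmers(islandmapr:::revcomp_chr(tp))), 0)
  }
})

test_that("generation is byte-identical under the same seed", {
  plan <- mixed_plan(2, n_decoys = 3)
  a <- simulate_genome(plan)
  b <- simulate_genome(plan)
  expect_identical(a$replicons$sequence, b$replicons$sequence)
  expect_identical(a$truth, b$truth)
  expect_identical(a$integrases, b$integrases)
})

test_that("a canonical plant is recovered at the exact truth interval", {
  sim <- simulate_genome(synthetic_plan(
    42, plant_spec("canonical_island", crossover = 0.7,
                   island_length = 10000)))
  scan <- scan_sim(sim)
  expect_equal(nrow(scan$islands), 1L)
  expect_equal(scan$islands$start, sim$truth$islands$start)
  expect_equal(scan$islands$end, sim$truth$islands$end)
  expect_equal(scan$islands$length, 10000)
  tc <- truth_compare(scan, sim$truth)
  expect_equal(tc$recall, 1)
  expect_equal(tc$precision, 1)
})

test_that("each decoy class is rejected by exactly its designed filter", {
  plants <- dplyr::bind_rows(lapply(decoy_kinds, plant_spec))
  sim <- simulate_genome(synthetic_plan(7, plants))
  scan <- scan_sim(sim)
  expect_equal(nrow(scan$islands), 0L)
  tc <- truth_compare(scan, sim$truth)
  expect_equal(nrow(tc$decoys), length(decoy_kinds))
  expect_true(all(tc$decoys$found))
  expect_true(all(tc$decoys$rejected))
  expect_true(all(tc$decoys$clean),
              info = paste(tc$decoys$kind, tc$decoys$failed_filters,
                           collapse = "; "))
})

test_that("damaged fragments are recovered and flagged", {
  sim <- simulate_genome(synthetic_plan(
    15, plant_spec("canonical_island", damaged = TRUE, crossover = 0.5)))
  scan <- scan_sim(sim)
  expect_equal(nrow(scan$islands), 1L)
  expect_true(scan$islands$damaged)
  expect_equal(scan$islands$fragment_side, "three_prime")
  expect_equal(scan$islands$end, sim$truth$islands$end)
})

test_that("tandem arrays come back with member indices", {
  sim <- simulate_genome(synthetic_plan(
    25, plant_spec("tandem_array", array_size = 3)))
  scan <- scan_sim(sim)
  expect_equal(nrow(scan$islands), 3L)
  expect_equal(scan$islands$tandem_index, 1:3)
  expect_equal(scan$islands$tandem_size, rep(3L, 3))
  tc <- truth_compare(scan, sim$truth)
  expect_equal(tc$recall, 1)
})

test_that("truth comparison is strict about endpoints", {
  sim <- simulate_genome(synthetic_plan(42, "canonical_island"))
  scan <- scan_sim(sim)
  shifted <- scan
  shifted$islands$end <- shifted$islands$end + 1L
  tc <- truth_compare(shifted, sim$truth)
  expect_equal(tc$recall, 0)
})

test_that("infeasible plans fail before any output", {
  expect_error(synthetic_plan(1, character(0)), "at least one")
  expect_error(
    simulate_genome(synthetic_plan(
      1, plant_spec("canonical_island", island_length = 500))),
    "island_length")
  expect_error(
    synthetic_plan(1, dplyr::bind_rows(
      plant_spec("canonical_island", isotype = "S"),
      plant_spec("decoy_short", isotype = "S"))),
    "distinct template")
})
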