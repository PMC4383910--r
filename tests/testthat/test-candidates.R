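test_that("candidate intervals follow the endpoint convention", {
  reps <- toy_replicon()
  td <- toy_tdna(1000L, 1076L)
  # 3' fragment downstream: island excludes the gene, includes the copy
  cand <- build_candidates(toy_hit(s_start = 6076L, s_end = 6096L),
                           td, reps)
  expect_equal(cand$island_start, 1076L)
  expect_equal(cand$island_end, 6096L)
  expect_equal(cand$island_length, 5020)
  expect_equal(cand$relative_position, "downstream")
  # 5' fragment upstream: [fragment start, gene start)
  cand2 <- build_candidates(
    toy_hit(q_start = 0L, q_end = 20L, s_start = 300L, s_end = 320L,
            side = "five_prime"), td, reps)
  expect_equal(cand2$island_start, 300L)
  expect_equal(cand2$island_end, 1000L)
  expect_equal(cand2$relative_position, "upstream")
})

test_that("a fragment overlapping its own tDNA locus is an error", {
  reps <- toy_replicon()
  td <- toy_tdna(1000L, 1076L)
  expect_error(
    build_candidates(toy_hit(s_start = 1050L, s_end = 1090L), td, reps),
    "own tDNA locus")
})

test_that("minus-strand construction mirrors the plus-strand islands", {
  sim <- simulate_genome(synthetic_plan(17, plant_spec(
    "canonical_island", strand = "-", crossover = 0.6)))
  scan <- scan_sim(sim)
  expect_equal(nrow(scan$islands), 1L)
  expect_equal(scan$islands$start, sim$truth$islands$start)
  expect_equal(scan$islands$end, sim$truth$islands$end)
  # and the mirrored genome gives the mirrored island
  rv <- revcomp_synthetic(sim)
  scan2 <- scan_sim(rv)
  expect_equal(scan2$islands$start, rv$truth$islands$start)
  expect_equal(scan2$islands$end, rv$truth$islands$end)
})

test_that("circular replicons take the shorter arc and wrap cleanly", {
  sim <- simulate_genome(synthetic_plan(19, plant_spec(
    "canonical_island", island_length = 4000), topology = "circular"))
  truth <- sim$truth$islands
  # rotate so the island body crosses the origin
  rot <- rotate_synthetic(sim, sim$replicons$length - truth$start - 1500L)
  scan <- scan_sim(rot)
  expect_equal(nrow(scan$islands), 1L)
  expect_true(scan$islands$start > scan$islands$end)
  expect_equal(scan$islands$start, rot$truth$islands$start)
  expect_equal(scan$islands$end, rot$truth$islands$end)
  expect_equal(scan$islands$length, 4000)
})

test_that("subsite classification uses the anticodon window", {
  cfg <- island_config()
  reps <- toy_replicon()
  td <- toy_tdna()  # L = 76; A window = [22.8, 45.6)
  mk <- function(q_start, q_end, side) {
    dplyr::mutate(build_candidates(
      toy_hit(q_start = q_start, q_end = q_end),
      td, reps), side = side, damaged = FALSE)
  }
  c1 <- classify_subsite(mk(34L, 76L, "three_prime"), td, reps, cfg)
  expect_equal(c1$subsite, "A")     # 0.45 L: anticodon-proximal
  c2 <- classify_subsite(mk(65L, 76L, "three_prime"), td, reps, cfg)
  expect_equal(c2$subsite, "J")     # 0.85 L: T/acceptor junction
  c3 <- NULL
  expect_warning(c3 <- classify_subsite(mk(10L, 76L, "three_prime"),
                                        td, reps, cfg),
                 "acceptor")
  expect_equal(c3$subsite, "J")
  tdz <- dplyr::mutate(td, kind = "tmRNA", isotype = "tmRNA")
  c4 <- suppressMessages(
    classify_subsite(mk(34L, 76L, "three_prime"), tdz, reps, cfg))
  expect_true(is.na(c4$subsite))
})
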