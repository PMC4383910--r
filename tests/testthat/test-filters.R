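# Filters are exercised on hand-built candidates (boundary arithmetic)
# and on synthetic decoys (one class per filter; see test-simulate.R
# for the designed-filter isolation property).

mk_cand <- function(..., td = toy_tdna(), reps = toy_replicon()) {
  cand <- build_candidates(toy_hit(...), td, reps)
  dplyr::mutate(cand, subsite = "A")
}

test_that("integrase filter requires >= 1 bp ORF overlap", {
  reps <- toy_replicon()
  cand <- mk_cand()  # island [1076, 6096)
  inside <- toy_integrase(2000, 2900)
  straddle <- toy_integrase(6000, 6900)   # crosses the island end
  outside <- toy_integrase(8000, 8900)
  abutting <- toy_integrase(6096, 6900)   # zero overlap
  expect_true(filter_integrase(cand, inside, reps))
  expect_true(filter_integrase(cand, straddle, reps))
  expect_false(filter_integrase(cand, outside, reps))
  expect_false(filter_integrase(cand, abutting, reps))
})

test_that("CDS filter spares integrase domains but not others", {
  reps <- toy_replicon()
  td <- toy_tdna()
  cand <- mk_cand()  # fragment at [6076, 6096)
  dom <- function(s, e, integrase) {
    tibble::tibble(domain_id = "d", replicon_id = "r1", start = s,
                   end = e, strand = "+", accession = "PFX",
                   is_integrase = integrase)
  }
  expect_false(filter_cds(cand, dom(6080L, 6200L, FALSE), td, reps))
  expect_true(filter_cds(cand, dom(6080L, 6200L, TRUE), td, reps))
  expect_true(filter_cds(cand, dom(7000L, 7200L, FALSE), td, reps))
  # the query tDNA interval is protected too
  expect_false(filter_cds(cand, dom(1040L, 1200L, FALSE), td, reps))
})

test_that("tDNA filter rejects containment but not mere overlap", {
  reps <- toy_replicon()
  td <- dplyr::bind_rows(
    toy_tdna(),
    dplyr::mutate(toy_tdna(6000L, 6076L), tdna_id = "t2"))
  contained <- mk_cand(s_start = 6010L, s_end = 6050L, td = td[1, ])
  overlapping <- mk_cand(s_start = 6050L, s_end = 6100L, td = td[1, ])
  free <- mk_cand(s_start = 7000L, s_end = 7040L, td = td[1, ])
  expect_false(filter_tdna(contained, td, reps))
  expect_true(filter_tdna(overlapping, td, reps))
  expect_true(filter_tdna(free, td, reps))
})

test_that("length filter bounds are inclusive", {
  cfg <- island_config()
  lens <- c(1999, 2000, 2001, 199999, 200000, 200001, 611000)
  cand <- tibble::tibble(island_length = lens)
  expect_equal(filter_length(cand, cfg),
               c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("internal and configuration filters read side and placement", {
  cand <- tibble::tibble(
    side = c("internal", "three_prime", "three_prime", "five_prime",
             "five_prime"),
    relative_position = c("downstream", "downstream", "upstream",
                          "upstream", "downstream"))
  expect_equal(filter_internal(cand), c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(filter_configuration(cand), c(TRUE, TRUE, FALSE, TRUE,
                                             FALSE))
})

test_that("orientation filter compares fragment and gene strands", {
  td <- dplyr::bind_rows(toy_tdna(),
                         dplyr::mutate(toy_tdna(strand = "-"),
                                       tdna_id = "t2"))
  cand <- tibble::tibble(tdna_id = c("t1", "t1", "t2", "t2"),
                         subject_strand = c("+", "-", "-", "+"))
  expect_equal(filter_orientation(cand, td), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("the accepted set is independent of filter order", {
  sim <- simulate_genome(mixed_plan(3, n_decoys = 4))
  scan <- scan_sim(sim)
  cand <- scan$candidates
  pass_cols <- paste0("pass_", islandmapr:::island_filter_names)
  set.seed(8)
  for (i in 1:10) {
    ord <- sample(pass_cols)
    surv <- cand
    for (cl in ord) surv <- surv[surv[[cl]], , drop = FALSE]
    expect_setequal(surv$candidate_id, scan$survivors$candidate_id)
  }
})

test_that("the attrition trace is internally consistent", {
  sim <- simulate_genome(mixed_plan(4, n_decoys = 4))
  scan <- scan_sim(sim)
  tr <- scan$trace
  expect_equal(tr$entering[-1], (tr$entering - tr$rejected)[-nrow(tr)])
  expect_equal(tr$entering[1], nrow(scan$candidates))
  expect_equal(tr$entering[nrow(tr)] - tr$rejected[nrow(tr)],
               nrow(scan$survivors))
})

test_that("filter status marks filters after the first failure", {
  sim <- simulate_genome(synthetic_plan(6, "decoy_no_integrase"))
  scan <- scan_sim(sim)
  st <- filter_status(scan$candidates)
  one <- st[st$candidate_id == scan$candidates$candidate_id[1], ]
  expect_equal(one$status[one$filter == "integrase"], "fail")
  expect_true(all(one$status[-1] == "not-evaluated"))
  expect_equal(nrow(one), 7L)
})
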