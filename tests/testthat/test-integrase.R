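test_that("Xer subfamilies and integron-like calls are excluded", {
  calls <- dplyr::bind_rows(
    toy_integrase(100, 800, id = "ok"),
    toy_integrase(900, 1600, subfamily = "XerD", id = "xer"),
    toy_integrase(1700, 2400, evalue = 1.0e-24, id = "integron_at"),
    toy_integrase(2500, 3200, evalue = 1.2e-24, id = "integron_eq"),
    toy_integrase(3300, 4000, evalue = 1.0e-20, id = "weak_integron")
  )
  adm <- admit_integrases(calls, island_config(), quiet = TRUE)
  # the threshold is inclusive: a hit at the cutoff is integron-like
  expect_setequal(adm$integrase_id, c("ok", "weak_integron"))
})

test_that("admission is idempotent and order-preserving", {
  calls <- dplyr::bind_rows(
    toy_integrase(100, 800, id = "a"),
    toy_integrase(900, 1600, subfamily = "XerC", id = "b"),
    toy_integrase(1700, 2400, id = "c")
  )
  once <- admit_integrases(calls, quiet = TRUE)
  twice <- admit_integrases(once, quiet = TRUE)
  expect_identical(once, twice)
  expect_equal(once$integrase_id, c("a", "c"))
})

test_that("negative E-values are an input error", {
  calls <- toy_integrase(1, 700, evalue = -1)
  expect_error(admit_integrases(calls, quiet = TRUE), "Negative")
})
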