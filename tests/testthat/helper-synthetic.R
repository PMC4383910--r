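suppressPackageStartupMessages(library(dplyr))

# Shared builders for synthetic fixtures. Everything is generated in
# code at test time; nothing is read from disk except what the tests
# themselves write to tempdirs.

decoy_kinds <- c("decoy_no_integrase", "decoy_wrong_orientation",
                 "decoy_wrong_side", "decoy_internal_fragment",
                 "decoy_short", "decoy_long",
                 "decoy_fragment_in_domain", "decoy_fragment_in_tdna")

# a compact mixed plan: one canonical island, a tandem array, and a
# rotating subset of decoy classes
mixed_plan <- function(seed, n_decoys = 3, topology = "linear",
                       strand = "+", damaged = FALSE) {
  picks <- decoy_kinds[(seq_len(n_decoys) + seed) %% length(decoy_kinds) + 1]
  plants <- dplyr::bind_rows(
    plant_spec("canonical_island", strand = strand, damaged = damaged,
               crossover = if (seed %% 2) 0.5 else 0.7,
               island_length = 6000),
    plant_spec("tandem_array", array_size = 2 + seed %% 2,
               island_length = 5000),
    dplyr::bind_rows(lapply(picks, function(k) {
      plant_spec(k, island_length = switch(k, decoy_short = 1500,
                                           decoy_long = 201000, 6000))
    }))
  )
  synthetic_plan(seed, plants, topology = topology, margin = 300L)
}

scan_sim <- function(sim, ...) {
  suppressWarnings(scan_islands(sim$replicons, sim, quiet = TRUE, ...))
}

# minimal single-replicon tibble for hand-built candidate tests
toy_replicon <- function(len = 300000L, topology = "linear") {
  tibble::tibble(replicon_id = "r1", length = len, topology = topology,
                 genus = "Escherichia", species = "coli", strain = "661",
                 sequence = strrep("A", min(len, 1000L)))
}

toy_tdna <- function(start = 1000L, end = 1076L, strand = "+",
                     kind = "tRNA", isotype = "S") {
  tibble::tibble(tdna_id = "t1", replicon_id = "r1",
                 start = start, end = end, strand = strand, kind = kind,
                 isotype = isotype, anticodon = "NNN")
}

# a classified hit row compatible with build_candidates()/filters
toy_hit <- function(q_start = 38L, q_end = 76L, s_start = 6076L,
                    s_end = 6096L, strand = "+", side = "three_prime",
                    damaged = FALSE, score = 40) {
  tibble::tibble(tdna_id = "t1", replicon_id = "r1",
                 q_start = q_start, q_end = q_end,
                 s_start = s_start, s_end = s_end,
                 subject_strand = strand, score = score,
                 identities = as.integer(q_end - q_start),
                 side = side, damaged = damaged)
}

toy_integrase <- function(start, end, strand = "+", subfamily = "generic",
                          evalue = NA_real_, id = "i1") {
  tibble::tibble(integrase_id = id, replicon_id = "r1",
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, subfamily = subfamily,
                 integron_evalue = evalue,
                 dom_start = as.integer(start + 10L),
                 dom_end = as.integer(end - 10L))
}
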