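#' Admit island-capable integrase calls
#'
#' Integrase genes mark true islands, but two tyrosine-recombinase
#' subclasses must be excluded first: the host Xer proteins (XerC, XerD,
#' XerS, XerD-like), which act at dif sites and are not island-borne,
#' and integron integrases, which mobilize cassettes rather than
#' canonical islands. A call is admitted when its subfamily is `generic`
#' and its integron-profile E-value is either absent or above
#' `config$integron_evalue_max` (a hit at or below the cutoff is a
#' stronger match to the integron profile and is excluded).
#'
#' The operation is idempotent and order-preserving; exclusions are
#' reported as messages with machine-parsable reason codes.
#'
#' @param integrases Integrase-call tibble (see [read_features()]).
#' @param config An [island_config()].
#' @param quiet Suppress exclusion messages.
#' @return The admitted subset of `integrases`.
#' @examples
#' calls <- tibble::tibble(
#'   integrase_id = c("i1", "i2", "i3"),
#'   replicon_id = "r1", start = c(100L, 900L, 1700L),
#'   end = c(800L, 1600L, 2400L), strand = "+",
#'   subfamily = c("generic", "XerD", "generic"),
#'   integron_evalue = c(NA, NA, 1e-30),
#'   dom_start = NA_integer_, dom_end = NA_integer_
#' )
#' admit_integrases(calls, island_config(), quiet = TRUE)
#' @export
admit_integrases <- function(integrases, config = island_config(),
                             quiet = FALSE) {
  config <- as_island_config(config)
  if (!nrow(integrases)) return(integrases)
  if (any(!is.na(integrases$integron_evalue) &
          integrases$integron_evalue < 0)) {
    abort("Negative integron E-value(s) in integrase calls.")
  }
  is_xer <- integrases$subfamily != "generic"
  is_integron <- !is.na(integrases$integron_evalue) &
    integrases$integron_evalue <= config$integron_evalue_max
  admitted <- !is_xer & !is_integron
  if (!quiet && any(!admitted)) {
    reasons <- ifelse(is_xer,
                      paste0("XER_SUBFAMILY:", integrases$subfamily),
                      "INTEGRON_EVALUE_AT_OR_BELOW_CUTOFF")
    inform(paste0("Excluded integrase call(s): ",
                  paste(paste0(integrases$integrase_id[!admitted], " [",
                               reasons[!admitted], "]"),
                        collapse = "; ")))
  }
  integrases[admitted, , drop = FALSE]
}
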