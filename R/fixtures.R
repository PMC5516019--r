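# Shipped reference system: sevoflurane binding to the open Kv1.2 channel.
# Twelve docking-resolved sites (four each at the S4S5 linker, the S6P-helix
# interface of adjacent subunits, and the extracellular face), with
# restrained-FEP work values for single occupancy everywhere and double
# occupancy at all but the extracellular-face sites. The reservoir excess
# chemical potential of sevoflurane in water is -0.1 kcal/mol.

#' Reference affinity table: sevoflurane on Kv1.2
#'
#' Restrained-FEP inputs for the twelve sevoflurane sites of the open Kv1.2
#' pore domain, shipped with the package. Use with
#' `ligand_reservoir(excess_mu = -0.1)`.
#'
#' @return An [affinity_table()] with 12 sites, 8 of which carry a level-2
#'   (doubly-occupied) entry.
#' @examples
#' tbl <- kv12_affinity_table()
#' max_occupancy(tbl)
#' @export
kv12_affinity_table <- function() {
  read_affinity_table(system.file("extdata", "kv12_sevoflurane_affinity.tsv",
                                  package = "multibind", mustWork = TRUE))
}

#' Reference symmetry classes: the 4-fold Kv1.2 tetramer
#'
#' @return A [symmetry_classes()] grouping the twelve sites into the three
#'   distinguishable regions (S4S5 linker, S6P-helix interface,
#'   extracellular face).
#' @export
kv12_symmetry_classes <- function() {
  read_symmetry_classes(system.file("extdata", "kv12_symmetry_classes.tsv",
                                    package = "multibind", mustWork = TRUE))
}

#' Per-step reversible work values for the doubly-occupied Kv1.2 sites
#'
#' The level-2 work values of [kv12_affinity_table()] are two-step
#' compositions: coupling of the first ligand to the vacant site (`w1`)
#' followed by coupling of a second ligand to the pre-occupied site
#' (`w2_given_1`). This table carries the individual steps and their errors,
#' for use with [compose_two_step_work()].
#'
#' @return Data frame with columns `site_id`, `w1`, `e1`, `w2_given_1`,
#'   `e2`.
#' @export
kv12_fep_steps <- function() {
  data.frame(
    site_id = c("S01", "S02", "S03", "S04", "S09", "S10", "S11", "S12"),
    w1 = c(-4.5, -4.7, -5.0, -3.8, -6.4, -7.5, -6.7, -5.6),
    e1 = c(0.2, 0.2, 0.2, 0.3, 0.2, 0.0, 0.3, 0.3),
    w2_given_1 = c(-3.6, -4.3, -3.8, -3.3, -4.0, -5.2, -7.0, -6.1),
    e2 = c(0.2, 0.2, 0.3, 0.4, 0.3, 0.2, 0.3, 0.3),
    stringsAsFactors = FALSE
  )
}
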