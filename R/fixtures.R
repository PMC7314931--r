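fixture_checksums <- c(
  language_nodes.tsv = "a5ad1d6e57f2345095acc021e53f03a4",
  dfc_group_reference.tsv = "be365b381768a8cbec13afcc128a697d",
  topology_group_reference.tsv = "8259c48588fcb58a2fd9b5ce34593a3c"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dynfc")
  if (p == "") abort(paste0("packaged fixture ", file, " not found"))
  sum <- unname(tools::md5sum(p))
  if (!identical(sum, unname(fixture_checksums[[file]]))) {
    abort(paste0("fixture ", file, " checksum mismatch"))
  }
  p
}

read_fixture_tsv <- function(file) {
  tibble::as_tibble(utils::read.table(fixture_path(file), sep = "\t",
                                      header = TRUE, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' Packaged language-network node table
#'
#' The 17 language-network nodes (7 found from the Broca seed, 10 from the
#' Wernicke seed) with their originating seed, cluster size, Brodmann area,
#' peak t and peak MNI coordinate. Real-data users can supply this table
#' directly and skip the node-identification stage.
#'
#' @return tibble with 17 rows: `node`, `seed`, `cluster_size`, `ba`,
#'   `peak_t`, `x`, `y`, `z`.
#' @export
language_node_table <- function() {
  read_fixture_tsv("language_nodes.tsv")
}

#' Packaged reference tables
#'
#' Returns the three packaged reference tables: the 17-row node table, the
#' 22-row per-state edge-comparison reference (group means, SDs,
#' permutation p and Cohen's d), and the 16-row (4 metrics x 4 states)
#' topology-comparison reference. Checksums are verified on read.
#'
#' @return list with elements `nodes`, `dfc`, `topology`.
#' @export
load_fixtures <- function() {
  list(nodes = language_node_table(),
       dfc = read_fixture_tsv("dfc_group_reference.tsv"),
       topology = read_fixture_tsv("topology_group_reference.tsv"))
}
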