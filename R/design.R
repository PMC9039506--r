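#' Enumerate the grafting experimental design
#'
#' Builds the full sample sheet of the heterografting experiment: all four
#' scion/rootstock combinations of the two species (`Csa/Csa`, `Csa/Cmo`,
#' `Cmo/Csa`, `Cmo/Cmo`), two tissues (first leaf of the scion, root of the
#' rootstock), two conditions (control and 6-h chilling) and `replicates`
#' biological replicates. Sample ids follow the
#' `scion_rootstock.tissue.condition.repN` convention used by all writers.
#'
#' @param replicates Number of biological replicates per sample group.
#' @return A tibble with one row per sample: `scion`, `rootstock`, `tissue`,
#'   `condition`, `replicate`, `heterograft` (logical), `resident` (species
#'   whose transcripts natively populate the tissue) and `sample_id`.
#' @examples
#' graft_design()
#' @export
graft_design <- function(replicates = 3) {
  stopifnot(is.numeric(replicates), replicates >= 1)
  tidyr::expand_grid(
    scion = SPECIES,
    rootstock = SPECIES,
    tissue = TISSUES,
    condition = CONDITIONS,
    replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(
      heterograft = .data$scion != .data$rootstock,
      resident = resident_species(.data$scion, .data$rootstock, .data$tissue),
      sample_id = sample_key(.data$scion, .data$rootstock, .data$tissue,
                             .data$condition, .data$replicate)
    )
}

sample_key <- function(scion, rootstock, tissue, condition, replicate) {
  sprintf("%s_%s.%s.%s.rep%d", scion, rootstock, tissue, condition,
          as.integer(replicate))
}

#' Simulation configuration
#'
#' Bundles and validates the tunable parameters of the synthetic-data
#' generator. The same config plus the same seed reproduces every generated
#' artifact exactly.
#'
#' @param n_pairs Number of homolog pairs (one transcript per species each).
#' @param transcript_length Transcript length in bases.
#' @param divergence_rate Per-base substitution rate between the two species'
#'   homologs, in (0, 1). Must satisfy
#'   `divergence_rate * transcript_length >= 1` so each pair carries at least
#'   one expected diagnostic site.
#' @param read_length Read length in bases (default 150, the short-read
#'   convention the mobility screen is built around).
#' @param depth Mean sequenced reads per expressed transcript per sample.
#' @param error_rate Per-base sequencing error probability in \[0, 1).
#' @param n_replicates Biological replicates per sample group.
#' @param seed Integer seed controlling all generator randomness.
#' @return A validated list of class `sim_config`.
#' @examples
#' sim_config(n_pairs = 10, depth = 20, seed = 1)
#' @export
sim_config <- function(n_pairs = 30,
                       transcript_length = 1000,
                       divergence_rate = 0.01,
                       read_length = 150,
                       depth = 20,
                       error_rate = 0,
                       n_replicates = 3,
                       seed = 1) {
  counts <- c(n_pairs = n_pairs, transcript_length = transcript_length,
              read_length = read_length, depth = depth,
              n_replicates = n_replicates)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    abort("all counts in sim_config() must be finite and >= 1")
  }
  if (!is.finite(divergence_rate) || divergence_rate < 0 || divergence_rate >= 1) {
    abort("`divergence_rate` must lie in [0, 1)")
  }
  if (!is.finite(error_rate) || error_rate < 0 || error_rate >= 1) {
    abort("`error_rate` must lie in [0, 1)")
  }
  if (read_length > transcript_length) {
    abort("`read_length` cannot exceed `transcript_length`")
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      transcript_length = as.integer(transcript_length),
      divergence_rate = divergence_rate,
      read_length = as.integer(read_length),
      depth = depth,
      error_rate = error_rate,
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
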