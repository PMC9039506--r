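#' Write homolog references to FASTA and a pair-map TSV
#'
#' Emits one FASTA per species plus a two-column tab-separated pair map
#' (species-A id, species-B id), the interchange format consumed by
#' [read_homolog_references()].
#'
#' @param refs Reference table from [make_homolog_references()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths (fasta_a, fasta_b, pair_map).
#' @export
write_reference_fasta <- function(refs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa_a <- file.path(dir, sprintf("refs_%s.fasta", refs$species_a[[1]]))
  fa_b <- file.path(dir, sprintf("refs_%s.fasta", refs$species_b[[1]]))
  pm <- file.path(dir, "pair_map.tsv")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(refs$seq_a, refs$id_a)), fa_a)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(refs$seq_b, refs$id_b)), fa_b)
  readr::write_tsv(dplyr::select(refs, "id_a", "id_b"), pm)
  invisible(c(fasta_a = fa_a, fasta_b = fa_b, pair_map = pm))
}

#' Read homolog references from FASTA files and a pair map
#'
#' @param fasta_a,fasta_b FASTA paths for the two species.
#' @param pair_map TSV with columns `id_a`, `id_b`.
#' @param species Species names of the A and B files.
#' @return A reference tibble in the [make_homolog_references()] layout.
#' @export
read_homolog_references <- function(fasta_a, fasta_b, pair_map,
                                    species = SPECIES) {
  a <- Biostrings::readDNAStringSet(fasta_a)
  b <- Biostrings::readDNAStringSet(fasta_b)
  pm <- readr::read_tsv(pair_map, show_col_types = FALSE)
  assert_columns(pm, c("id_a", "id_b"), "pair_map")
  tibble(
    pair = seq_len(nrow(pm)),
    species_a = species[[1]], id_a = pm$id_a,
    seq_a = as.character(a[pm$id_a]),
    species_b = species[[2]], id_b = pm$id_b,
    seq_b = as.character(b[pm$id_b])
  )
}

#' Write simulated reads to one FASTQ per sample
#'
#' @param reads Read table from [simulate_graft_reads()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_reads_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(split(reads, reads$sample_id), function(s) {
    path <- file.path(dir, paste0(s$sample_id[[1]], ".fastq"))
    x <- Biostrings::DNAStringSet(setNames(s$sequence, s$read_id))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(s$sequence))))
    path
  })
  invisible(paths)
}

#' Read per-sample FASTQ files back into a read table
#'
#' File names must follow the `scion_rootstock.tissue.condition.repN.fastq`
#' convention written by [write_reads_fastq()].
#'
#' @param paths FASTQ file paths.
#' @return A read table in the [simulate_graft_reads()] layout.
#' @export
read_reads_fastq <- function(paths) {
  purrr::map_dfr(paths, function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    sample_id <- sub("\\.fastq$", "", basename(p))
    meta <- parse_sample_key(sample_id)
    dplyr::bind_cols(
      tibble(sample_id = sample_id),
      meta,
      tibble(read_id = names(x), sequence = as.character(x))
    )
  })
}

parse_sample_key <- function(key) {
  parts <- stringr::str_match(
    key, "^([A-Za-z]+)_([A-Za-z]+)\\.([a-z]+)\\.([a-z]+)\\.rep(\\d+)$")
  if (any(is.na(parts[, 1]))) {
    abort(sprintf("sample key(s) not in scion_rootstock.tissue.condition.repN form: %s",
                  paste(key[is.na(parts[, 1])], collapse = ", ")))
  }
  tibble(scion = parts[, 2], rootstock = parts[, 3], tissue = parts[, 4],
         condition = parts[, 5], replicate = as.integer(parts[, 6]))
}

#' Write a long feature table as a features-by-samples TSV matrix
#'
#' @param df Long table from the generators (`expression` or `intensity`).
#' @param path Output TSV path.
#' @param id_col,value_col Feature id and abundance columns.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(df, path, id_col = "gene",
                                 value_col = "fpkm") {
  wide <- df |>
    dplyr::select(dplyr::all_of(c(id_col, "sample_id", value_col))) |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = dplyr::all_of(value_col))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a features-by-samples TSV matrix into the long layout
#'
#' Column names must follow the sample-key convention; see
#' [parse_sample_key()] internals.
#'
#' @param path TSV path written by [write_feature_matrix()].
#' @param id_col,value_col Names for the feature id and abundance columns.
#' @return A long tibble with design columns recovered from the sample keys.
#' @export
read_feature_matrix <- function(path, id_col = "gene", value_col = "fpkm") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-1, names_to = "sample_id",
                        values_to = value_col)
  names(long)[[1]] <- id_col
  dplyr::bind_cols(long[id_col], parse_sample_key(long$sample_id),
                   long[c("sample_id", value_col)])
}

#' Write a network edge list as SIF and as TSV
#'
#' SIF rows are `source <interaction-type> target`; the TSV adds the
#' correlation sign column.
#'
#' @param edges Edge table from [build_network()].
#' @param sif,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(edges, sif = NULL, tsv = NULL) {
  out <- character()
  if (!is.null(sif)) {
    writeLines(sprintf("%s\t%s\t%s", edges$source, edges$type, edges$target),
               sif)
    out <- c(out, sif = sif)
  }
  if (!is.null(tsv)) {
    readr::write_tsv(edges, tsv)
    out <- c(out, tsv = tsv)
  }
  invisible(out)
}

#' Flatten mobility calls for TSV export
#'
#' Expands the per-replicate count list column into a comma-separated string
#' so the call table round-trips through plain TSV.
#'
#' @param calls Mobility calls from [call_mobile_transcripts()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_mobility_table <- function(calls, path) {
  flat <- calls |>
    dplyr::mutate(replicate_reads = purrr::map_chr(
      .data$replicate_reads, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}
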