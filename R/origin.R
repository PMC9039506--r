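#' Find species-diagnostic sites on a homolog pair
#'
#' The two species' homologous transcripts are alignment-free by construction
#' (no indels), so a diagnostic site is simply a position where their bases
#' differ and neither is `N`. These sites are what make per-read
#' species-of-origin assignment possible: a read covering at least one of
#' them betrays which species it was transcribed in.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings over `A C G T N`.
#' @return A tibble with 0-based `position`, `allele_a` and `allele_b`,
#'   ascending by position. Empty for identical sequences.
#' @examples
#' find_diagnostic_sites("ACGT", "ACCT")
#' @export
find_diagnostic_sites <- function(seq_a, seq_b) {
  stopifnot(length(seq_a) == 1, length(seq_b) == 1)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort(paste("homolog sequences have unequal lengths; align them upstream",
                "before diagnostic-site discovery"))
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(c(a, b)), c(DNA_BASES, "N"))
  if (length(bad) > 0) {
    abort(sprintf("unexpected base(s) in homolog pair: %s",
                  paste(bad, collapse = ", ")))
  }
  keep <- a != b & a != "N" & b != "N"
  tibble(position = which(keep) - 1L, allele_a = a[keep], allele_b = b[keep])
}

# diagnostic sites for every pair in a reference table
pair_diagnostic_sites <- function(refs) {
  purrr::map_dfr(seq_len(nrow(refs)), function(i) {
    find_diagnostic_sites(refs$seq_a[[i]], refs$seq_b[[i]]) |>
      dplyr::mutate(pair = refs$pair[[i]], .before = 1)
  })
}

#' Assign one read to its species of origin
#'
#' Locates the read on a homolog pair by scanning every offset of both
#' homologs for a match with at most `max_mismatch` mismatches, then reads
#' out the alleles at the diagnostic sites the read covers. The verdict is
#' `origin_a`/`origin_b` when all covered informative sites carry one
#' species' alleles, `ambiguous` when sites conflict, `uninformative` when
#' the read covers no diagnostic site, and `unmapped` when the read fits
#' neither homolog within tolerance. A covered site whose read base matches
#' neither allele is treated as a sequencing error and excluded from the
#' vote.
#'
#' This is the transparent per-read reference routine; the pipeline-scale
#' caller [call_mobile_transcripts()] uses a seed-indexed implementation of
#' the same rule.
#'
#' @param read Read sequence (length at most the transcript length).
#' @param seq_a,seq_b The homolog pair.
#' @param sites Diagnostic sites from [find_diagnostic_sites()]; recomputed
#'   when omitted.
#' @param max_mismatch Maximum mismatches tolerated when locating the read.
#' @return A list with `origin` (one of `origin_a`, `origin_b`, `ambiguous`,
#'   `uninformative`, `unmapped`) and `offset` (0-based placement, `NA` if
#'   unmapped).
#' @export
assign_read_origin <- function(read, seq_a, seq_b, sites = NULL,
                               max_mismatch = 1) {
  if (nchar(read) > nchar(seq_a)) {
    abort("read is longer than the transcript")
  }
  if (is.null(sites)) sites <- find_diagnostic_sites(seq_a, seq_b)
  rl <- nchar(read)
  offsets <- 0:(nchar(seq_a) - rl)
  win_a <- substr(rep(seq_a, length(offsets)), offsets + 1L, offsets + rl)
  win_b <- substr(rep(seq_b, length(offsets)), offsets + 1L, offsets + rl)
  mm_a <- count_mismatches(rep(read, length(offsets)), win_a)
  mm_b <- count_mismatches(rep(read, length(offsets)), win_b)
  mm <- pmin(mm_a, mm_b)
  if (min(mm) > max_mismatch) {
    return(list(origin = "unmapped", offset = NA_integer_))
  }
  offset <- offsets[[which.min(mm)]]
  covered <- sites[sites$position >= offset & sites$position < offset + rl, ]
  if (nrow(covered) == 0) {
    return(list(origin = "uninformative", offset = offset))
  }
  base <- substr(rep(read, nrow(covered)),
                 covered$position - offset + 1L,
                 covered$position - offset + 1L)
  votes_a <- sum(base == covered$allele_a)
  votes_b <- sum(base == covered$allele_b)
  origin <- if (votes_a > 0 && votes_b == 0) "origin_a"
  else if (votes_b > 0 && votes_a == 0) "origin_b"
  else if (votes_a > 0 && votes_b > 0) "ambiguous"
  else "uninformative"
  list(origin = origin, offset = offset)
}

# --- pipeline-scale origin assignment -------------------------------------
#
# Reads are located with a pigeonhole seed index: a read with at most
# max_mismatch mismatches against its source window must match at least one
# of (max_mismatch + 1) disjoint seeds exactly, so exact seed lookup against
# all reference windows yields a complete candidate set, which is then
# verified by full-length mismatch counting against both homologs.

seed_index <- function(refs, read_length, n_seeds) {
  seed_len <- read_length %/% n_seeds
  tx <- reference_transcripts(refs)
  L <- nchar(tx$sequence[[1]])
  offsets <- 0:(L - read_length)
  purrr::map_dfr(seq_len(n_seeds), function(slot) {
    start <- offsets + (slot - 1L) * seed_len
    purrr::map_dfr(seq_len(nrow(tx)), function(i) {
      tibble(
        slot = slot,
        seed = substr(rep(tx$sequence[[i]], length(start)),
                      start + 1L, start + seed_len),
        pair = tx$pair[[i]],
        offset = offsets
      )
    })
  }) |>
    dplyr::distinct(.data$slot, .data$seed, .data$pair, .data$offset)
}

# returns one row per read: pair, offset, origin class, origin species,
# origin transcript
assign_reads_bulk <- function(reads, refs, max_mismatch = 1) {
  stopifnot(nrow(reads) > 0)
  rl <- nchar(reads$sequence[[1]])
  n_seeds <- max_mismatch + 1L
  idx <- seed_index(refs, rl, n_seeds)
  seed_len <- rl %/% n_seeds

  rd <- tibble(.read = seq_len(nrow(reads)), sequence = reads$sequence)
  candidates <- purrr::map_dfr(seq_len(n_seeds), function(slot) {
    rd |>
      dplyr::mutate(slot = slot,
                    seed = substr(.data$sequence, (slot - 1L) * seed_len + 1L,
                                  slot * seed_len)) |>
      dplyr::inner_join(idx, by = c("slot", "seed"),
                        relationship = "many-to-many")
  }) |>
    dplyr::distinct(.data$.read, .data$sequence, .data$pair, .data$offset)

  if (nrow(candidates) > 0) {
    seq_a <- setNames(refs$seq_a, refs$pair)[as.character(candidates$pair)]
    seq_b <- setNames(refs$seq_b, refs$pair)[as.character(candidates$pair)]
    win_a <- substr(seq_a, candidates$offset + 1L, candidates$offset + rl)
    win_b <- substr(seq_b, candidates$offset + 1L, candidates$offset + rl)
    candidates$mm <- pmin(count_mismatches(candidates$sequence, win_a),
                          count_mismatches(candidates$sequence, win_b))
    located <- candidates |>
      dplyr::filter(.data$mm <= max_mismatch) |>
      dplyr::arrange(.data$.read, .data$mm, .data$pair, .data$offset) |>
      dplyr::distinct(.data$.read, .keep_all = TRUE)
  } else {
    located <- tibble(.read = integer(), sequence = character(),
                      pair = integer(), offset = integer(), mm = integer())
  }

  sites <- pair_diagnostic_sites(refs)
  votes <- located |>
    dplyr::inner_join(sites, by = "pair", relationship = "many-to-many") |>
    dplyr::filter(.data$position >= .data$offset,
                  .data$position < .data$offset + rl) |>
    dplyr::mutate(base = substr(.data$sequence,
                                .data$position - .data$offset + 1L,
                                .data$position - .data$offset + 1L)) |>
    dplyr::group_by(.data$.read) |>
    dplyr::summarise(votes_a = sum(.data$base == .data$allele_a),
                     votes_b = sum(.data$base == .data$allele_b),
                     .groups = "drop")

  located |>
    dplyr::left_join(votes, by = ".read") |>
    dplyr::mutate(
      votes_a = dplyr::coalesce(.data$votes_a, 0L),
      votes_b = dplyr::coalesce(.data$votes_b, 0L),
      origin = dplyr::case_when(
        votes_a > 0 & votes_b == 0 ~ "origin_a",
        votes_b > 0 & votes_a == 0 ~ "origin_b",
        votes_a > 0 & votes_b > 0 ~ "ambiguous",
        TRUE ~ "uninformative"
      )
    ) |>
    dplyr::right_join(rd[".read"], by = ".read") |>
    dplyr::mutate(origin = dplyr::coalesce(.data$origin, "unmapped")) |>
    dplyr::left_join(
      dplyr::select(refs, "pair", "species_a", "id_a", "species_b", "id_b"),
      by = "pair"
    ) |>
    dplyr::mutate(
      origin_species = dplyr::case_when(
        origin == "origin_a" ~ .data$species_a,
        origin == "origin_b" ~ .data$species_b,
        TRUE ~ NA_character_
      ),
      origin_transcript = dplyr::case_when(
        origin == "origin_a" ~ .data$id_a,
        origin == "origin_b" ~ .data$id_b,
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::arrange(.data$.read) |>
    dplyr::select(".read", "pair", "offset", "origin", "origin_species",
                  "origin_transcript")
}

#' Call graft-mobile transcripts from origin-assigned reads
#'
#' Assigns every read in every sample to its species of origin, then calls a
#' transcript mobile into a heterograft tissue when (i) at least `min_reads`
#' origin-assigned foreign reads are found summed over replicates, (ii) the
#' transcript is detected in at least `min_replicates` replicates, and
#' (iii) the matched homograft background — reads of the destination tissue's
#' own-species homograft, same tissue and condition, that are nevertheless
#' assigned to the foreign species — does not exceed `max_background`. The
#' background veto screens out transcripts whose apparent mobility could be a
#' mapping artifact: such artifacts are systematic and produce background
#' counts on the scale of the resident sequencing depth. The default
#' `max_background = 1` tolerates the occasional single read whose only
#' covered diagnostic site was flipped to the foreign allele by a sequencing
#' error (expected well below one per transcript at typical depths and error
#' rates) while still vetoing anything systematic; set it to 0 for a strict
#' zero-tolerance screen. Ambiguous, uninformative and unmapped reads never
#' contribute to counts.
#'
#' @param reads Read table from [simulate_graft_reads()] (or
#'   [read_reads_fastq()]): sample metadata plus `sequence`.
#' @param refs Homolog reference table.
#' @param min_reads Minimum total foreign reads over replicates.
#' @param min_replicates Minimum replicates with at least one foreign read.
#' @param max_background Maximum tolerated homograft background count
#'   (default 1; see Details).
#' @param max_mismatch Mismatch tolerance when locating reads.
#' @param design Sample sheet used to check that every heterograft tissue has
#'   its matched homograft background sample; defaults to the samples present
#'   in `reads`.
#' @return A tibble of mobility calls, one row per (transcript, destination
#'   graft, tissue, condition) with at least one foreign read: `transcript`,
#'   `origin`, `scion`, `rootstock`, `tissue`, `condition`,
#'   `replicate_reads` (list column of per-replicate counts), `reads_total`,
#'   `n_replicates_detected`, `background_reads`, `is_mobile`.
#' @export
call_mobile_transcripts <- function(reads, refs, min_reads = 5,
                                    min_replicates = 2, max_background = 1,
                                    max_mismatch = 1, design = NULL) {
  assert_columns(reads, c("scion", "rootstock", "tissue", "condition",
                          "replicate", "sequence"), "reads")
  if (is.null(design)) {
    design <- dplyr::distinct(reads, .data$scion, .data$rootstock,
                              .data$tissue, .data$condition, .data$replicate)
  }
  hets <- design |>
    dplyr::filter(.data$scion != .data$rootstock) |>
    dplyr::distinct(.data$scion, .data$rootstock, .data$tissue,
                    .data$condition) |>
    dplyr::mutate(resident = resident_species(.data$scion, .data$rootstock,
                                              .data$tissue))
  missing_bg <- hets |>
    dplyr::anti_join(
      design |> dplyr::filter(.data$scion == .data$rootstock),
      by = c(resident = "scion", "tissue", "condition")
    )
  if (nrow(missing_bg) > 0) {
    m <- missing_bg[1, ]
    abort(sprintf(
      "missing homograft background sample %s/%s %s %s required for heterograft %s/%s",
      m$resident, m$resident, m$tissue, m$condition, m$scion, m$rootstock))
  }

  empty_calls <- tibble(
    transcript = character(), origin = character(), scion = character(),
    rootstock = character(), tissue = character(), condition = character(),
    replicate_reads = list(), reads_total = integer(),
    n_replicates_detected = integer(), background_reads = integer(),
    is_mobile = logical()
  )
  if (nrow(reads) == 0) return(empty_calls)

  assigned <- dplyr::bind_cols(
    reads[c("scion", "rootstock", "tissue", "condition", "replicate")],
    assign_reads_bulk(reads, refs, max_mismatch = max_mismatch)
  ) |>
    dplyr::filter(!is.na(.data$origin_species)) |>
    dplyr::mutate(resident = resident_species(.data$scion, .data$rootstock,
                                              .data$tissue))

  n_rep <- max(design$replicate)
  foreign <- assigned |>
    dplyr::filter(.data$scion != .data$rootstock,
                  .data$origin_species != .data$resident) |>
    dplyr::count(.data$origin_transcript, .data$origin_species, .data$scion,
                 .data$rootstock, .data$tissue, .data$condition,
                 .data$replicate, name = "reads")
  if (nrow(foreign) == 0) return(empty_calls)

  background <- assigned |>
    dplyr::filter(.data$scion == .data$rootstock,
                  .data$origin_species != .data$resident) |>
    dplyr::count(.data$origin_transcript, homograft = .data$scion,
                 .data$tissue, .data$condition, name = "background_reads")

  foreign |>
    dplyr::group_by(.data$origin_transcript, .data$origin_species,
                    .data$scion, .data$rootstock, .data$tissue,
                    .data$condition) |>
    dplyr::summarise(
      replicate_reads = list({
        v <- integer(n_rep)
        v[.data$replicate] <- .data$reads
        v
      }),
      reads_total = sum(.data$reads),
      n_replicates_detected = dplyr::n_distinct(.data$replicate),
      .groups = "drop"
    ) |>
    dplyr::mutate(resident = resident_species(.data$scion, .data$rootstock,
                                              .data$tissue)) |>
    dplyr::left_join(background,
                     by = c("origin_transcript", resident = "homograft",
                            "tissue", "condition")) |>
    dplyr::mutate(
      background_reads = dplyr::coalesce(.data$background_reads, 0L),
      is_mobile = .data$reads_total >= min_reads &
        .data$n_replicates_detected >= min_replicates &
        .data$background_reads <= max_background
    ) |>
    dplyr::select(transcript = "origin_transcript", origin = "origin_species",
                  "scion", "rootstock", "tissue", "condition",
                  "replicate_reads", "reads_total", "n_replicates_detected",
                  "background_reads", "is_mobile") |>
    dplyr::arrange(.data$transcript, .data$scion, .data$rootstock,
                   .data$tissue, .data$condition)
}
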