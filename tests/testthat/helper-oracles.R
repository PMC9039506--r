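# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. These deliberately share no code with
# the package internals.

oracle_diff_sites <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  out <- list()
  for (i in seq_along(a)) {
    if (a[i] != b[i] && a[i] != "N" && b[i] != "N") {
      out[[length(out) + 1]] <- list(position = i - 1L, allele_a = a[i],
                                     allele_b = b[i])
    }
  }
  dplyr::bind_rows(out)
}

oracle_hamming <- function(x, y) {
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
}

# exhaustive per-read origin assignment: every offset of every pair
oracle_assign_read <- function(read, refs, max_mismatch = 1) {
  rl <- nchar(read)
  best <- NULL
  for (i in seq_len(nrow(refs))) {
    for (off in 0:(nchar(refs$seq_a[i]) - rl)) {
      wa <- substring(refs$seq_a[i], off + 1, off + rl)
      wb <- substring(refs$seq_b[i], off + 1, off + rl)
      mm <- min(oracle_hamming(read, wa), oracle_hamming(read, wb))
      if (mm <= max_mismatch &&
          (is.null(best) || mm < best$mm ||
           (mm == best$mm && (refs$pair[i] < best$pair ||
                              (refs$pair[i] == best$pair && off < best$off))))) {
        best <- list(pair = refs$pair[i], off = off, mm = mm)
      }
    }
  }
  if (is.null(best)) {
    return(list(origin = "unmapped", pair = NA, offset = NA))
  }
  i <- which(refs$pair == best$pair)
  sites <- oracle_diff_sites(refs$seq_a[i], refs$seq_b[i])
  votes_a <- 0; votes_b <- 0
  if (nrow(sites) > 0) {
    for (r in seq_len(nrow(sites))) {
      p <- sites$position[r]
      if (p >= best$off && p < best$off + rl) {
        base <- substring(read, p - best$off + 1, p - best$off + 1)
        if (base == sites$allele_a[r]) votes_a <- votes_a + 1
        if (base == sites$allele_b[r]) votes_b <- votes_b + 1
      }
    }
  }
  origin <- if (votes_a > 0 && votes_b == 0) "origin_a"
  else if (votes_b > 0 && votes_a == 0) "origin_b"
  else if (votes_a > 0 && votes_b > 0) "ambiguous"
  else "uninformative"
  list(origin = origin, pair = best$pair, offset = best$off)
}

# exclusive Venn region counts by inclusion-exclusion over superset
# intersections (the package counts memberships directly)
oracle_venn_regions <- function(sets) {
  k <- length(sets)
  nm <- names(sets)
  masks <- 1:(2^k - 1)
  inter_size <- function(mask) {
    members <- nm[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    length(Reduce(intersect, sets[members]))
  }
  vapply(masks, function(mask) {
    total <- 0
    for (sup in masks) {
      if (bitwAnd(sup, mask) == mask) {
        extra <- sum(bitwAnd(sup, 2^(seq_len(k) - 1)) > 0) -
          sum(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
        total <- total + (-1)^extra * inter_size(sup)
      }
    }
    total
  }, numeric(1)) |>
    stats::setNames(masks)
}

# closed-form hypergeometric upper tail via binomial coefficients
oracle_hyper_tail <- function(set_hits, bg_hits, bg_size, set_size) {
  ks <- set_hits:min(bg_hits, set_size)
  sum(choose(bg_hits, ks) * choose(bg_size - bg_hits, set_size - ks)) /
    choose(bg_size, set_size)
}

# Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force direction from a set of mobility destinations
oracle_direction <- function(origin, dest_scions, dest_rootstocks) {
  as_scion <- any(dest_scions == origin)
  as_rootstock <- any(dest_rootstocks == origin)
  if (as_scion && as_rootstock) "bidirectional"
  else if (as_scion) "scion_to_rootstock"
  else "rootstock_to_scion"
}

# small shared fixtures ------------------------------------------------------

tiny_refs <- function(n_pairs = 5, transcript_length = 300,
                      divergence_rate = 0.02, depth = 10, error_rate = 0,
                      seed = 11, ...) {
  cfg <- sim_config(n_pairs = n_pairs, transcript_length = transcript_length,
                    divergence_rate = divergence_rate, depth = depth,
                    error_rate = error_rate, seed = seed, ...)
  list(config = cfg, refs = make_homolog_references(cfg))
}

swap_ref_species <- function(refs) {
  dplyr::tibble(
    pair = refs$pair,
    species_a = refs$species_b, id_a = refs$id_b, seq_a = refs$seq_b,
    species_b = refs$species_a, id_b = refs$id_a, seq_b = refs$seq_a
  )
}

# mobility-call fixture used by direction/classification tests
manual_call <- function(transcript, origin, scion, rootstock, tissue,
                        condition, is_mobile = TRUE) {
  dplyr::tibble(transcript = transcript, origin = origin, scion = scion,
                rootstock = rootstock, tissue = tissue, condition = condition,
                is_mobile = is_mobile)
}
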