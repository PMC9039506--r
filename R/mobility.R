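#' Classify the movement direction of mobile transcripts
#'
#' For each transcript of origin species S that is mobile under one
#' condition, the set of heterograft destinations determines its direction:
#' found only in tissue of the graft where S is the scion (so the foreign
#' tissue is on the rootstock side) gives `scion_to_rootstock`; found only
#' where S is the rootstock gives `rootstock_to_scion`; found in both
#' reciprocal grafts gives `bidirectional`. Direction is defined relative to
#' the transcript's origin, aggregating over the destination side's tissues,
#' so one transcript gets one direction per condition.
#'
#' @param calls Mobility-call table from [call_mobile_transcripts()] (rows
#'   with `is_mobile = FALSE` are ignored), or any tibble with `transcript`,
#'   `origin`, `scion`, `rootstock`, `tissue`, `condition` columns describing
#'   mobility events.
#' @param condition Condition to classify (`"control"` or `"chilling"`);
#'   `NULL` classifies each condition present.
#' @param species Restrict to transcripts of one origin species (`NULL` for
#'   all).
#' @return A tibble `transcript`, `species`, `condition`, `direction`.
#' @export
assign_direction <- function(calls, condition = NULL, species = NULL) {
  assert_columns(calls, c("transcript", "origin", "scion", "rootstock",
                          "tissue", "condition"), "calls")
  mobile <- calls
  if ("is_mobile" %in% names(mobile)) {
    mobile <- dplyr::filter(mobile, .data$is_mobile)
  }
  if (!is.null(condition)) {
    cond <- condition
    mobile <- dplyr::filter(mobile, .data$condition %in% cond)
  }
  if (!is.null(species)) {
    sp <- species
    mobile <- dplyr::filter(mobile, .data$origin %in% sp)
  }
  corrupt <- resident_species(mobile$scion, mobile$rootstock,
                              mobile$tissue) == mobile$origin
  if (any(corrupt)) {
    abort(sprintf(
      "corrupt mobility call(s): transcript %s recorded as mobile into its own species' tissue",
      paste(unique(mobile$transcript[corrupt]), collapse = ", ")))
  }
  mobile |>
    dplyr::group_by(transcript = .data$transcript, species = .data$origin,
                    condition = .data$condition) |>
    dplyr::summarise(
      down = any(.data$species == .data$scion),
      up = any(.data$species == .data$rootstock),
      .groups = "drop"
    ) |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$down & .data$up ~ "bidirectional",
      .data$down ~ "scion_to_rootstock",
      .data$up ~ "rootstock_to_scion"
    )) |>
    dplyr::select("transcript", "species", "condition", "direction") |>
    dplyr::arrange(.data$transcript, .data$condition)
}

#' Classify mobile transcripts by their chilling response
#'
#' Compares the direction records of the two conditions over the union of
#' transcripts mobile in at least one of them: mobile under chilling only is
#' `chilling_induced`; mobile under control only is `chilling_reduced`;
#' mobile under both with different directions is `direction_changed`; with
#' the same direction, `direction_maintained`. The four categories are
#' mutually exclusive and exhaustive.
#'
#' @param directions_control,directions_chilling Direction records from
#'   [assign_direction()] for the control and chilling condition.
#' @return A tibble `transcript`, `species`, `category`.
#' @export
classify_condition_response <- function(directions_control,
                                        directions_chilling) {
  assert_columns(directions_control, c("transcript", "species", "direction"),
                 "directions_control")
  assert_columns(directions_chilling, c("transcript", "species", "direction"),
                 "directions_chilling")
  dplyr::full_join(
    dplyr::select(directions_control, "transcript", "species",
                  control = "direction"),
    dplyr::select(directions_chilling, "transcript", "species",
                  chilling = "direction"),
    by = c("transcript", "species")
  ) |>
    dplyr::mutate(category = dplyr::case_when(
      is.na(.data$control) ~ "chilling_induced",
      is.na(.data$chilling) ~ "chilling_reduced",
      .data$control != .data$chilling ~ "direction_changed",
      TRUE ~ "direction_maintained"
    )) |>
    dplyr::select("transcript", "species", "category") |>
    dplyr::arrange(.data$transcript)
}

#' Summarize direction classes as counts and percentages
#'
#' Tallies direction records and reports each class as a percentage of the
#' total, rounded half-up to one decimal (the convention under which e.g.
#' 3324 of 3500 prints as 95.0). Accepts either one row per transcript (a
#' [assign_direction()] output) or pre-tallied counts in an `n` column.
#'
#' @param directions A tibble with a `direction` column, optionally
#'   pre-counted via an `n` column.
#' @return A tibble `direction`, `n`, `percent`, ordered by decreasing count.
#' @examples
#' summarize_directions(tibble::tibble(
#'   direction = c("scion_to_rootstock", "rootstock_to_scion", "bidirectional"),
#'   n = c(3324, 40, 136)
#' ))
#' @export
summarize_directions <- function(directions) {
  assert_columns(directions, "direction", "directions")
  counts <- if ("n" %in% names(directions)) {
    directions |>
      dplyr::group_by(.data$direction) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  } else {
    dplyr::count(directions, .data$direction)
  }
  total <- sum(counts$n)
  if (total < 1) abort("no direction records to summarize")
  counts |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / total, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
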