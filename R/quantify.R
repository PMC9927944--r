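#' Normalize barcode counts by library size and apply the low-count cutoff
#'
#' Counts are scaled to a common depth, offset by a pseudocount and log2
#' transformed: `value = log2(count / library_size * scale + pseudocount)`.
#' Low normalized values behave like Poisson shot noise rather than signal,
#' so cells below the lower-end cutoff are flagged for removal. The cutoff
#' is strict at the boundary: a value exactly equal to `cutoff` is retained,
#' values strictly below it are not.
#'
#' @param counts Long tibble with columns `barcode`, `library`, `count`
#'   (non-negative integers).
#' @param scale Counts-per-`scale` normalization constant (default 1e6).
#' @param pseudocount Added before the log (default 1).
#' @param cutoff Lower-end threshold on the normalized value (default 0.5).
#' @return A tibble with the input columns plus `library_size`, `normalized`
#'   and `retained`.
#' @examples
#' counts <- tibble::tibble(barcode = c("b1", "b2"), library = "pDNA",
#'                          count = c(0L, 100L))
#' normalize_counts(counts, scale = 1e4)
#' @export
normalize_counts <- function(counts, scale = 1e6, pseudocount = 1,
                             cutoff = 0.5) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("barcode", "library", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative", call. = FALSE)
  sizes <- counts |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(library_size = sum(.data$count), .groups = "drop")
  zero <- sizes$library[sizes$library_size == 0]
  if (length(zero)) {
    stop("library has zero total counts: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  counts |>
    dplyr::left_join(sizes, by = "library") |>
    dplyr::mutate(
      normalized = log2(.data$count / .data$library_size * scale + pseudocount),
      retained = .data$normalized >= cutoff
    )
}

#' Per-barcode reporter activity from paired cDNA/pDNA libraries
#'
#' Activity is the log2 ratio of output to input abundance for each barcode:
#' the normalized cDNA value minus the normalized value of the matching
#' plasmid (pDNA) library. A barcode contributes an activity only where it
#' survived the low-count cutoff in both members of the pair.
#'
#' @param normalized Output of [normalize_counts()] covering both libraries.
#' @param pairing Named character vector or two-column data frame mapping
#'   each cDNA library to its pDNA partner (`cdna`, `pdna`).
#' @return A tibble with `barcode`, `cdna_library`, `pdna_library`,
#'   `activity`.
#' @export
compute_activity <- function(normalized, pairing) {
  if (is.character(pairing) && !is.null(names(pairing))) {
    pairing <- tibble::tibble(cdna = names(pairing), pdna = unname(pairing))
  }
  pairing <- tibble::as_tibble(pairing)
  stopifnot(all(c("cdna", "pdna") %in% names(pairing)))
  libs <- unique(normalized$library)
  cdna_like <- setdiff(libs, pairing$pdna)
  orphan <- setdiff(cdna_like, pairing$cdna)
  if (length(orphan)) {
    stop("cDNA library with no declared pDNA partner: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  missing_lib <- setdiff(c(pairing$cdna, pairing$pdna), libs)
  if (length(missing_lib)) {
    stop("pairing refers to absent libraries: ",
         paste(missing_lib, collapse = ", "), call. = FALSE)
  }
  purrr::pmap(pairing, function(cdna, pdna, ...) {
    c_tab <- normalized |>
      dplyr::filter(.data$library == cdna, .data$retained) |>
      dplyr::select("barcode", cdna_value = "normalized")
    p_tab <- normalized |>
      dplyr::filter(.data$library == pdna, .data$retained) |>
      dplyr::select("barcode", pdna_value = "normalized")
    dplyr::inner_join(c_tab, p_tab, by = "barcode") |>
      dplyr::transmute(
        barcode = .data$barcode,
        cdna_library = cdna,
        pdna_library = pdna,
        activity = .data$cdna_value - .data$pdna_value
      )
  }) |>
    dplyr::bind_rows()
}

#' Aggregate barcode activities to fragments and apply the barcode filter
#'
#' Activities are ascribed to fragments through the barcode dictionary.
#' When several cDNA replicates contribute activities for the same barcode
#' they are pooled by averaging at the barcode level (`pool = "pooled"`,
#' the default) so each barcode counts once; `pool = "per_replicate"` keeps
#' every (barcode, replicate) activity as a separate observation. Fragments
#' with fewer than `min_barcodes` activity-bearing barcodes are flagged as
#' failing the filter and are excluded from downstream testing.
#'
#' @param activity Output of [compute_activity()].
#' @param map Barcode dictionary: an `mpra_barcode_map` or a tibble with
#'   `barcode` and `fragment_id`.
#' @param min_barcodes Minimum activity-bearing barcodes a fragment needs
#'   (default 12).
#' @param pool `"pooled"` or `"per_replicate"` (see above).
#' @return A tibble of class `mpra_fragment_summary`: `fragment_id`,
#'   `n_barcodes`, `mean_activity`, `sd_activity`, `passed_filter`, and an
#'   `activities` list-column. Activities whose barcode is absent from the
#'   dictionary are dropped and reported via the `n_unmapped` attribute.
#' @export
aggregate_fragments <- function(activity, map, min_barcodes = 12L,
                                pool = c("pooled", "per_replicate")) {
  pool <- match.arg(pool)
  entries <- if (inherits(map, "mpra_barcode_map")) map$entries else
    tibble::as_tibble(map)
  activity <- tibble::as_tibble(activity)
  mapped <- dplyr::inner_join(activity,
                              entries[, c("barcode", "fragment_id")],
                              by = "barcode")
  n_unmapped <- nrow(activity) - nrow(mapped)
  if (n_unmapped > 0L) {
    message(n_unmapped, " activity record(s) had barcodes absent from the ",
            "dictionary and were excluded")
  }
  if (pool == "pooled") {
    mapped <- mapped |>
      dplyr::group_by(.data$fragment_id, .data$barcode) |>
      dplyr::summarise(activity = mean(.data$activity), .groups = "drop")
  }
  out <- mapped |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::summarise(
      n_barcodes = if (pool == "pooled") dplyr::n() else
        dplyr::n_distinct(.data$barcode),
      mean_activity = mean(.data$activity),
      sd_activity = stats::sd(.data$activity),
      activities = list(.data$activity),
      .groups = "drop"
    ) |>
    dplyr::mutate(passed_filter = .data$n_barcodes >= min_barcodes) |>
    dplyr::relocate("activities", .after = "passed_filter") |>
    dplyr::arrange(.data$fragment_id)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "min_barcodes") <- as.integer(min_barcodes)
  class(out) <- c("mpra_fragment_summary", class(out))
  out
}
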