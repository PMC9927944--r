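#' Build the barcode-to-fragment dictionary from association reads
#'
#' Each read pair of the association library carries the random barcode tag
#' on one mate and the fragment sequence on the other. Reads are assigned to
#' the catalog fragment whose sequence matches the fragment segment with at
#' most `max_mismatch` substitutions (unique best hit wins; ties are
#' discarded). Barcodes observed with more than one fragment are kept only
#' if a single fragment accounts for at least `purity` of their reads;
#' otherwise they are quarantined as ambiguous. Barcode matching itself is
#' exact: the tags are random sequences with no truth to correct towards.
#'
#' @param reads A tibble with columns `read1` (barcode mate) and `read2`
#'   (fragment mate), e.g. from [read_fastq_pair()], or a length-2 character
#'   vector of FASTQ paths.
#' @param catalog An `mpra_catalog` / fragment tibble with `fragment_id` and
#'   `sequence` columns.
#' @param barcode_length Barcode tag length in bases (default 16).
#' @param max_mismatch Maximum substitutions tolerated in the fragment
#'   segment (default 2).
#' @param min_reads Minimum supporting reads for a barcode to be kept.
#' @param purity Minimum fraction of a barcode's reads that must support its
#'   top fragment (default 0.9).
#' @param barcode_start,fragment_start 1-based offsets of the barcode and
#'   fragment segments within their mates.
#' @return An object of class `mpra_barcode_map`: a list with `entries`
#'   (tibble `barcode`, `fragment_id`, `reads`), `ambiguous` (tibble
#'   `barcode`, `n_fragments`, `reads`), and a `summary` of skipped /
#'   unmatched read counts.
#' @examples
#' catalog <- tibble::tibble(fragment_id = c("f1", "f2"),
#'                           sequence = c("ACGTACGT", "TTTTCCCC"))
#' reads <- tibble::tibble(
#'   read1 = c("AAAACCCCGGGGTTTT", "AAAACCCCGGGGTTTT"),
#'   read2 = c("ACGTACGT", "ACGTACGT"))
#' build_barcode_map(reads, catalog, barcode_length = 16)
#' @export
build_barcode_map <- function(reads, catalog,
                              barcode_length = 16L,
                              max_mismatch = 2L,
                              min_reads = 1L,
                              purity = 0.9,
                              barcode_start = 1L,
                              fragment_start = 1L) {
  if (is.character(reads) && length(reads) == 2L) {
    reads <- read_fastq_pair(reads[[1]], reads[[2]])
  }
  reads <- tibble::as_tibble(reads)
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  cat_seq <- catalog$sequence
  cat_id <- catalog$fragment_id
  frag_lens <- sort(unique(nchar(cat_seq)))

  bc_end <- barcode_start + barcode_length - 1L
  min_frag_end <- fragment_start + min(frag_lens) - 1L
  malformed <- nchar(reads$read1) < bc_end | nchar(reads$read2) < min_frag_end
  n_malformed <- sum(malformed)
  reads <- reads[!malformed, , drop = FALSE]

  barcode <- substr(reads$read1, barcode_start, bc_end)
  # exact lookup per fragment length, then Hamming rescue for the leftovers
  assigned <- rep(NA_character_, nrow(reads))
  for (L in frag_lens) {
    idx_L <- which(nchar(cat_seq) == L)
    lut <- stats::setNames(cat_id[idx_L], cat_seq[idx_L])
    seg <- substr(reads$read2, fragment_start, fragment_start + L - 1L)
    hit <- lut[seg]
    assigned[is.na(assigned) & !is.na(hit)] <- hit[is.na(assigned) & !is.na(hit)]
  }
  if (max_mismatch > 0L && anyNA(assigned)) {
    todo <- which(is.na(assigned))
    for (L in frag_lens) {
      idx_L <- which(nchar(cat_seq) == L)
      mat <- seq_char_matrix(cat_seq[idx_L])
      seg <- substr(reads$read2[todo], fragment_start, fragment_start + L - 1L)
      # distinct read segments only; fan the verdict back out
      uniq <- unique(seg)
      verdict <- vapply(uniq, function(s) {
        if (nchar(s) < L) return(NA_character_)
        d <- hamming_to_all(s, mat)
        best <- min(d)
        if (best > max_mismatch || sum(d == best) != 1L) return(NA_character_)
        cat_id[idx_L][which.min(d)]
      }, character(1))
      hit <- verdict[match(seg, uniq)]
      assigned[todo][!is.na(hit)] <- hit[!is.na(hit)]
      todo <- which(is.na(assigned))
      if (!length(todo)) break
    }
  }
  n_unmatched <- sum(is.na(assigned))

  pairs <- tibble::tibble(barcode = barcode[!is.na(assigned)],
                          fragment_id = assigned[!is.na(assigned)])
  tallied <- dplyr::count(pairs, .data$barcode, .data$fragment_id, name = "reads")
  per_bc <- tallied |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      total_reads = sum(.data$reads),
      n_fragments = dplyr::n(),
      top_fragment = .data$fragment_id[which.max(.data$reads)],
      top_reads = max(.data$reads),
      .groups = "drop"
    )
  keep <- per_bc$n_fragments == 1L |
    (per_bc$top_reads / per_bc$total_reads >= purity)
  entries <- per_bc[keep, ] |>
    dplyr::transmute(barcode = .data$barcode,
                     fragment_id = .data$top_fragment,
                     reads = .data$top_reads) |>
    dplyr::filter(.data$reads >= min_reads) |>
    dplyr::arrange(.data$barcode)
  ambiguous <- per_bc[!keep, ] |>
    dplyr::transmute(barcode = .data$barcode,
                     n_fragments = .data$n_fragments,
                     reads = .data$total_reads) |>
    dplyr::arrange(.data$barcode)

  structure(
    list(entries = entries,
         ambiguous = ambiguous,
         summary = list(n_read_pairs = length(barcode) + n_malformed,
                        n_malformed = n_malformed,
                        n_unmatched = n_unmatched,
                        barcode_length = as.integer(barcode_length),
                        max_mismatch = as.integer(max_mismatch),
                        min_reads = as.integer(min_reads),
                        purity = purity)),
    class = "mpra_barcode_map"
  )
}

#' @export
print.mpra_barcode_map <- function(x, ...) {
  cat("<mpra_barcode_map>\n")
  cat("  barcodes mapped:   ", nrow(x$entries), "\n")
  cat("  ambiguous barcodes:", nrow(x$ambiguous), "\n")
  cat("  fragments observed:", dplyr::n_distinct(x$entries$fragment_id), "\n")
  cat("  unmatched reads:   ", x$summary$n_unmatched,
      " (of ", x$summary$n_read_pairs, " pairs, ",
      x$summary$n_malformed, " malformed)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a barcode map into its entries table
#' @param x An `mpra_barcode_map`.
#' @param ... Unused.
#' @return A tibble with one row per unambiguous barcode.
#' @method tidy mpra_barcode_map
#' @export
tidy.mpra_barcode_map <- function(x, ...) x$entries

#' One-row summary of a barcode map
#' @param x An `mpra_barcode_map`.
#' @param ... Unused.
#' @method glance mpra_barcode_map
#' @export
glance.mpra_barcode_map <- function(x, ...) {
  tibble::tibble(
    n_barcodes = nrow(x$entries),
    n_ambiguous = nrow(x$ambiguous),
    n_fragments_observed = dplyr::n_distinct(x$entries$fragment_id),
    n_read_pairs = x$summary$n_read_pairs,
    n_unmatched = x$summary$n_unmatched
  )
}

#' Barcodes-per-fragment statistics for a dictionary
#'
#' Summarizes how barcodes distribute over fragments and what fraction of
#' fragments clear the minimum-barcode filter used downstream. When a
#' catalog is supplied, fragments with zero observed barcodes are included
#' in the denominator.
#'
#' @param map An `mpra_barcode_map` or an entries tibble with `barcode` and
#'   `fragment_id` columns.
#' @param min_barcodes Barcode count a fragment needs to survive filtering
#'   (default 12).
#' @param catalog Optional catalog tibble; adds unobserved fragments with
#'   zero barcodes.
#' @return A one-row tibble: `n_barcodes`, `n_fragments_observed`,
#'   `frac_fragments_ge_min`, and a `distribution` list-column holding the
#'   per-fragment barcode counts.
#' @export
map_statistics <- function(map, min_barcodes = 12L, catalog = NULL) {
  entries <- if (inherits(map, "mpra_barcode_map")) map$entries else
    tibble::as_tibble(map)
  dist <- dplyr::count(entries, .data$fragment_id, name = "n_barcodes")
  if (!is.null(catalog)) {
    missing_frags <- setdiff(catalog$fragment_id, dist$fragment_id)
    if (length(missing_frags)) {
      dist <- dplyr::bind_rows(
        dist, tibble::tibble(fragment_id = missing_frags, n_barcodes = 0L))
    }
  }
  dist <- dplyr::arrange(dist, .data$fragment_id)
  n_frag <- nrow(dist)
  tibble::tibble(
    n_barcodes = nrow(entries),
    n_fragments_observed = sum(dist$n_barcodes > 0L),
    frac_fragments_ge_min = if (n_frag == 0L) 0 else
      mean(dist$n_barcodes >= min_barcodes),
    min_barcodes = as.integer(min_barcodes),
    distribution = list(dist)
  )
}
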