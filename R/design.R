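#' Design parameters for variant-centered MPRA fragments
#'
#' Bundles the geometry and guard-rail settings used when turning a variant
#' set into an oligo catalog. The defaults reproduce the common design of a
#' 137 bp variable region with the tested variant at its center, flanked by
#' 68 reference bases on each side. Adaptor sequences are placeholders for
#' PCR/cloning arms; synthesis vendors supply their own.
#'
#' @param fragment_length Length in bp of the variable region for an SNV
#'   (must equal `2 * flank + 1` for single-base variants).
#' @param flank Number of reference bases on each side of the centered variant.
#' @param adaptor_5p,adaptor_3p Adaptor DNA appended to each oligo.
#' @param max_variants_per_window Guard against combinatorial explosion: a
#'   window holding more than this many variants is an error rather than a
#'   silent `2^k` blow-up.
#' @param strict_snv If `TRUE` (default) only single-base ref/alt alleles are
#'   accepted, so every variable region has exactly `fragment_length` bases.
#'   With `FALSE`, indel alleles are substituted by reference span and the
#'   region length may differ from `fragment_length`.
#' @return A list of class `mpra_design_params`.
#' @examples
#' design_params()
#' @export
design_params <- function(fragment_length = 137L,
                          flank = 68L,
                          adaptor_5p = "ACTGGCCGCTTGACG",
                          adaptor_3p = "CACTGCGGCTCCTGC",
                          max_variants_per_window = 6L,
                          strict_snv = TRUE) {
  fragment_length <- as.integer(fragment_length)
  flank <- as.integer(flank)
  if (fragment_length <= 0L || flank < 0L) {
    stop("fragment_length must be positive and flank non-negative", call. = FALSE)
  }
  if (fragment_length != 2L * flank + 1L) {
    stop("fragment_length must equal 2 * flank + 1 for a centered SNV ",
         "(got ", fragment_length, " vs 2*", flank, "+1)", call. = FALSE)
  }
  assert_dna(c(adaptor_5p, adaptor_3p), "adaptor")
  structure(
    list(fragment_length = fragment_length,
         flank = flank,
         adaptor_5p = adaptor_5p,
         adaptor_3p = adaptor_3p,
         max_variants_per_window = as.integer(max_variants_per_window),
         strict_snv = isTRUE(strict_snv)),
    class = "mpra_design_params"
  )
}

#' Validate and normalize a variant table
#'
#' Accepts a data frame with columns `id`, `chrom`, `pos` (1-based), `ref`
#' and `alt` (comma-separated alternates) and returns a tibble sorted by
#' position with a list-column `alts`.
#'
#' @param variants A data frame of variants.
#' @return A tibble with one row per variant.
#' @export
as_variant_table <- function(variants) {
  variants <- tibble::as_tibble(variants)
  need <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols)) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(variants$id)) {
    stop("variant ids must be unique", call. = FALSE)
  }
  if (any(variants$pos < 1L)) stop("variant pos must be >= 1", call. = FALSE)
  if (any(!nzchar(variants$ref))) stop("ref allele must be non-empty", call. = FALSE)
  variants <- dplyr::mutate(
    variants,
    pos = as.integer(.data$pos),
    alts = strsplit(as.character(.data$alt), ",", fixed = TRUE)
  )
  bad <- purrr::map2_lgl(variants$alts, variants$ref,
                         function(a, r) any(a == r) || length(a) == 0L)
  if (any(bad)) {
    stop("every alt must be non-empty and differ from ref (offending: ",
         paste(variants$id[bad], collapse = ", "), ")", call. = FALSE)
  }
  dplyr::arrange(variants, .data$chrom, .data$pos)
}

#' Enumerate all allele combinations for variants sharing a fragment window
#'
#' Takes the variants that co-occur inside one fragment window and returns
#' the full Cartesian product over \{ref\} union alts for each variant, so a
#' window with k biallelic variants yields `2^k` assignments. Order is
#' deterministic: variants by position, reference allele first, then
#' alternates in their declared order; the first variant varies slowest.
#'
#' @param variants A variant table (see [as_variant_table()]) restricted to
#'   one window.
#' @return A tibble with one row per combination: `combo` (1-based index),
#'   `alleles` (list-column of named character vectors, names are variant
#'   ids), and `is_reference`.
#' @examples
#' v <- tibble::tibble(id = c("v1", "v2"), chrom = "chr1",
#'                     pos = c(100L, 120L), ref = c("A", "G"),
#'                     alt = c("T", "C"))
#' enumerate_allele_combinations(v)
#' @export
enumerate_allele_combinations <- function(variants) {
  variants <- as_variant_table(variants)
  check_allele_collisions(variants)
  allele_sets <- purrr::map2(variants$ref, variants$alts, function(r, a) c(r, a))
  names(allele_sets) <- variants$id
  # expand.grid varies the first factor fastest; reverse to make the first
  # (leftmost) variant vary slowest, then restore column order
  grid <- expand.grid(rev(allele_sets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(allele_sets)), drop = FALSE]
  refs <- stats::setNames(variants$ref, variants$id)
  assignments <- purrr::map(seq_len(nrow(grid)), function(i) {
    a <- unlist(grid[i, , drop = TRUE])
    stats::setNames(as.character(a), names(allele_sets))
  })
  tibble::tibble(
    combo = seq_along(assignments),
    alleles = assignments,
    is_reference = purrr::map_lgl(assignments, function(a) all(a == refs[names(a)]))
  )
}

# Error if two variants' reference spans overlap (their alleles would collide
# on the same base).
check_allele_collisions <- function(variants) {
  if (nrow(variants) < 2L) return(invisible(variants))
  starts <- variants$pos
  ends <- variants$pos + nchar(variants$ref) - 1L
  for (i in seq_len(nrow(variants) - 1L)) {
    for (j in seq(i + 1L, nrow(variants))) {
      if (starts[j] <= ends[i] && starts[i] <= ends[j]) {
        stop("alleles of variants ", variants$id[i], " and ", variants$id[j],
             " collide on overlapping reference bases", call. = FALSE)
      }
    }
  }
  invisible(variants)
}

#' Build variant-centered MPRA fragments
#'
#' For every variant, defines the window that places it at the center of a
#' `fragment_length` bp variable region and emits one fragment per allele
#' combination over all variants overlapping that window (including the
#' all-reference fragment). Substitutions are applied to the forward-strand
#' reference slice.
#'
#' @param variants A variant table (columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`), or anything [as_variant_table()] accepts.
#' @param reference A single reference sequence as a character string, or a
#'   named character vector / `Biostrings::DNAStringSet` keyed by contig.
#' @param params A [design_params()] object.
#' @return A tibble with one row per fragment: `fragment_id`, `chrom`,
#'   `window_start`/`window_end` (0-based half-open), `center_variant`,
#'   `combo`, `alleles` (list-column of named allele vectors),
#'   `allele_label`, `variant_sites` (list-column of ids whose allele
#'   differs from reference), `n_variant_sites`, `is_reference`, `sequence`.
#' @examples
#' ref <- paste(rep("ACGT", 250), collapse = "")
#' v <- tibble::tibble(id = "v1", chrom = "ref", pos = 500L, ref = "T", alt = "A")
#' frags <- build_fragments(v, ref)
#' nchar(frags$sequence)
#' @export
build_fragments <- function(variants, reference, params = design_params()) {
  stopifnot(inherits(params, "mpra_design_params"))
  variants <- as_variant_table(variants)
  reference <- as_reference(reference)
  if (params$strict_snv) {
    not_snv <- nchar(variants$ref) != 1L |
      purrr::map_lgl(variants$alts, function(a) any(nchar(a) != 1L))
    if (any(not_snv)) {
      stop("strict SNV mode: non single-base alleles for ",
           paste(variants$id[not_snv], collapse = ", "),
           "; use design_params(strict_snv = FALSE)", call. = FALSE)
    }
  }
  flank <- params$flank
  out <- purrr::map(seq_len(nrow(variants)), function(i) {
    center <- variants[i, ]
    contig <- reference[[center$chrom]]
    if (is.null(contig)) {
      stop("reference has no contig named '", center$chrom, "'", call. = FALSE)
    }
    w_start <- center$pos - 1L - flank              # 0-based
    w_end <- center$pos - 1L + nchar(center$ref) + flank
    if (w_start < 0L || w_end > nchar(contig)) {
      stop("window for variant ", center$id, " [", w_start, ", ", w_end,
           ") extends past the reference ends", call. = FALSE)
    }
    in_window <- variants$chrom == center$chrom &
      variants$pos + nchar(variants$ref) - 1L > w_start &
      variants$pos <= w_end                          # 1-based span overlap
    window_variants <- variants[in_window, ]
    if (nrow(window_variants) > params$max_variants_per_window) {
      stop("window centered on ", center$id, " holds ",
           nrow(window_variants), " variants (limit ",
           params$max_variants_per_window,
           "); raise max_variants_per_window to proceed", call. = FALSE)
    }
    slice <- substr(contig, w_start + 1L, w_end)
    assert_dna(slice, paste0("reference window of ", center$id))
    check_ref_alleles(window_variants, contig)
    combos <- enumerate_allele_combinations(window_variants)
    refs <- stats::setNames(window_variants$ref, window_variants$id)
    seqs <- purrr::map_chr(combos$alleles, function(a) {
      substitute_alleles(slice, w_start, window_variants, a)
    })
    sites <- purrr::map(combos$alleles, function(a) {
      names(a)[a != refs[names(a)]]
    })
    tibble::tibble(
      fragment_id = paste0(center$id, "_c", sprintf("%02d", combos$combo)),
      chrom = center$chrom,
      window_start = w_start,
      window_end = w_end,
      center_variant = center$id,
      combo = combos$combo,
      alleles = combos$alleles,
      allele_label = purrr::map_chr(combos$alleles, function(a) {
        paste(paste0(names(a), ":", a), collapse = ";")
      }),
      variant_sites = sites,
      n_variant_sites = lengths(sites),
      is_reference = combos$is_reference,
      sequence = seqs
    )
  })
  dplyr::bind_rows(out)
}

# Apply allele substitutions to a window slice. Substitutions are applied
# right-to-left so earlier coordinates stay valid when alleles change length.
substitute_alleles <- function(slice, w_start, window_variants, alleles) {
  ord <- order(window_variants$pos, decreasing = TRUE)
  for (k in ord) {
    v_id <- window_variants$id[k]
    allele <- alleles[[v_id]]
    rel <- window_variants$pos[k] - w_start        # 1-based within slice
    ref_len <- nchar(window_variants$ref[k])
    before <- if (rel > 1L) substr(slice, 1L, rel - 1L) else ""
    after <- substr(slice, rel + ref_len, nchar(slice))
    slice <- paste0(before, allele, after)
  }
  slice
}

check_ref_alleles <- function(window_variants, contig) {
  observed <- substr(rep(contig, nrow(window_variants)),
                     window_variants$pos,
                     window_variants$pos + nchar(window_variants$ref) - 1L)
  bad <- observed != window_variants$ref
  if (any(bad)) {
    stop("declared ref allele does not match the reference sequence for ",
         paste(window_variants$id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  if (!is.character(reference)) {
    stop("reference must be a character vector or DNAStringSet", call. = FALSE)
  }
  if (is.null(names(reference))) {
    if (length(reference) != 1L) {
      stop("an unnamed reference must hold exactly one sequence", call. = FALSE)
    }
    # single unnamed contig matches any chrom label
    return(structure(as.list(rep(unname(reference), 1L)),
                     class = "mpra_reference", single = TRUE))
  }
  structure(as.list(reference), class = "mpra_reference", single = FALSE)
}

#' @export
`[[.mpra_reference` <- function(x, name) {
  if (isTRUE(attr(x, "single"))) return(unclass(x)[[1L]])
  unclass(x)[[name]]
}

#' Collapse duplicate fragments and attach adaptors
#'
#' Fragments whose variable-region sequences are identical (windows of
#' nearby variants can produce the same string) are collapsed to a single
#' catalog entry; the merged fragments' identities are retained in a
#' `provenance` list-column. Full oligo sequences are formed by flanking the
#' variable region with the design adaptors.
#'
#' @param fragments Output of [build_fragments()].
#' @param params A [design_params()] object (supplies the adaptors).
#' @return A tibble of class `mpra_catalog`: one row per unique sequence
#'   with `fragment_id` (the first contributing fragment's id), `sequence`,
#'   `oligo`, the representative fragment's design columns, `n_merged` and
#'   `provenance` (list-column of merged fragment rows).
#' @export
dedupe_and_catalog <- function(fragments, params = design_params()) {
  stopifnot(inherits(params, "mpra_design_params"))
  fragments <- tibble::as_tibble(fragments)
  groups <- split(seq_len(nrow(fragments)),
                  factor(fragments$sequence, levels = unique(fragments$sequence)))
  rows <- purrr::map(groups, function(idx) {
    rep_row <- fragments[idx[1L], ]
    rep_row$n_merged <- length(idx)
    rep_row$provenance <- list(fragments[idx, c("fragment_id", "center_variant",
                                                "allele_label", "is_reference")])
    rep_row
  })
  catalog <- dplyr::bind_rows(rows)
  catalog$oligo <- paste0(params$adaptor_5p, catalog$sequence, params$adaptor_3p)
  class(catalog) <- c("mpra_catalog", class(catalog))
  catalog
}
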