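# Small fixture builders used across test files.

# A fixed deterministic 1 kb reference (no RNG involvement).
fixed_reference <- function(length = 1000L, chrom = "refA") {
  bases <- c("A", "C", "G", "T")
  stats::setNames(paste(bases[(seq_len(length) * 7L) %% 4L + 1L],
                        collapse = ""), chrom)
}

ref_base_at <- function(reference, pos) {
  substr(unname(reference[1]), pos, pos)
}

# One isolated biallelic SNV centered in the fixture reference.
isolated_snv <- function(reference = fixed_reference(), pos = 500L,
                         id = "v1") {
  r <- ref_base_at(reference, pos)
  tibble::tibble(id = id, chrom = names(reference)[1], pos = pos,
                 ref = r, alt = setdiff(c("A", "C", "G", "T"), r)[1])
}

# k SNVs spaced 'gap' bases apart starting at 'start'.
spaced_snvs <- function(reference, k, start, gap, prefix = "v") {
  pos <- start + (seq_len(k) - 1L) * gap
  refs <- vapply(pos, function(p) ref_base_at(reference, p), character(1))
  tibble::tibble(
    id = paste0(prefix, seq_len(k)),
    chrom = names(reference)[1],
    pos = as.integer(pos),
    ref = refs,
    alt = vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                 character(1))
  )
}

# Long count table for a set of barcodes with given pDNA/cDNA counts.
toy_counts <- function(barcodes, pdna, cdna, cdna_lib = "cDNA_1") {
  dplyr::bind_rows(
    tibble::tibble(barcode = barcodes, library = "pDNA",
                   count = as.integer(pdna)),
    tibble::tibble(barcode = barcodes, library = cdna_lib,
                   count = as.integer(cdna))
  )
}

toy_pairing <- function(cdna_lib = "cDNA_1") {
  tibble::tibble(cdna = cdna_lib, pdna = "pDNA")
}

# Fragment summaries built directly from activity vectors.
summaries_from_activities <- function(acts, min_barcodes = 12L) {
  out <- tibble::tibble(
    fragment_id = names(acts),
    n_barcodes = lengths(acts),
    mean_activity = vapply(acts, mean, numeric(1)),
    sd_activity = vapply(acts, stats::sd, numeric(1)),
    passed_filter = lengths(acts) >= min_barcodes,
    activities = unname(acts)
  )
  class(out) <- c("mpra_fragment_summary", class(out))
  out
}

# Minimal two-fragment design (test vs reference) for one window.
two_fragment_design <- function(center = "v1") {
  tibble::tibble(
    fragment_id = c("fref", "falt"),
    center_variant = center,
    is_reference = c(TRUE, FALSE),
    n_variant_sites = c(0L, 1L),
    variant_sites = list(character(0), center)
  )
}
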