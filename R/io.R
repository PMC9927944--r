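# Readers and writers for the plain-text formats the pipeline exchanges.
# FASTA/FASTQ go through Biostrings; VCF input goes through vcfR.

#' Read a reference sequence from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (one element per contig).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  toupper(seqs)
}

#' Write a reference sequence to FASTA
#' @param reference Named character vector of sequences.
#' @param path Output path.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  names(x) <- names(reference) %||% paste0("contig", seq_along(reference))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read candidate variants from a VCF file
#'
#' Parses a (possibly multi-allelic) VCF with vcfR and returns the variant
#' table the design stage consumes. INFO is carried along as an opaque
#' annotation string.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A variant tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `annotations`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                                         stringsAsFactors = FALSE))
  out <- tibble::tibble(
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    annotations = fix$INFO %||% NA_character_
  )
  if (any(is.na(out$id) | out$id == ".")) {
    idx <- which(is.na(out$id) | out$id == ".")
    out$id[idx] <- paste0(out$chrom[idx], ":", out$pos[idx])
  }
  as_variant_table(out)
}

#' Write a variant table as a minimal VCF
#' @param variants A variant table.
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  variants <- as_variant_table(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mpravar",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$chrom, variants$pos, variants$id,
                  variants$ref, variants$alt)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write the oligo catalog as FASTA plus a TSV manifest
#'
#' The FASTA holds full oligo sequences (adaptors included) under the
#' fragment id; the manifest records the window, allele assignment and
#' reference flag for each catalog entry. Rerunning the design on the same
#' inputs reproduces both files byte for byte.
#'
#' @param catalog Output of [dedupe_and_catalog()].
#' @param out_prefix Path prefix; writes `<prefix>.fa` and `<prefix>_manifest.tsv`.
#' @return Invisibly, the two paths written.
#' @export
write_catalog <- function(catalog, out_prefix) {
  fa_path <- paste0(out_prefix, ".fa")
  tsv_path <- paste0(out_prefix, "_manifest.tsv")
  x <- Biostrings::DNAStringSet(catalog$oligo)
  names(x) <- catalog$fragment_id
  Biostrings::writeXStringSet(x, fa_path, width = 80L)
  manifest <- tibble::tibble(
    fragment_id = catalog$fragment_id,
    chrom = catalog$chrom,
    window_start = catalog$window_start,
    window_end = catalog$window_end,
    center_variant = catalog$center_variant,
    allele_assignment = catalog$allele_label,
    n_variant_sites = catalog$n_variant_sites,
    is_reference = catalog$is_reference,
    n_merged = catalog$n_merged,
    sequence = catalog$sequence
  )
  readr::write_tsv(manifest, tsv_path)
  invisible(c(fasta = fa_path, manifest = tsv_path))
}

#' Read a catalog manifest written by [write_catalog()]
#'
#' Rebuilds the `alleles` and `variant_sites` list-columns by comparing each
#' fragment's allele assignment against the reference fragment of its window.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with the design columns needed downstream.
#' @export
read_catalog_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  parse_label <- function(lbl) {
    if (is.na(lbl) || !nzchar(lbl)) return(stats::setNames(character(0), character(0)))
    parts <- strsplit(strsplit(lbl, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  }
  m$alleles <- purrr::map(m$allele_assignment, parse_label)
  ref_alleles <- list()
  for (i in which(m$is_reference)) {
    ref_alleles[[m$center_variant[i]]] <- m$alleles[[i]]
  }
  m$variant_sites <- purrr::map2(m$alleles, m$center_variant, function(a, cv) {
    r <- ref_alleles[[cv]]
    if (is.null(r)) return(names(a))
    names(a)[a != r[names(a)]]
  })
  m
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1,r2 Paths to the two mates (plain or gzipped FASTQ).
#' @return A tibble with columns `read1`, `read2` (sequences as strings).
#' @export
read_fastq_pair <- function(r1, r2) {
  a <- Biostrings::readDNAStringSet(r1, format = "fastq")
  b <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(a) != length(b)) {
    stop("mates have different read counts (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  tibble::tibble(read1 = unname(as.character(a)),
                 read2 = unname(as.character(b)))
}

#' Write a read-pair tibble as two FASTQ files
#' @param reads Tibble with `read1`, `read2` columns.
#' @param r1,r2 Output paths.
#' @export
write_fastq_pair <- function(reads, r1, r2) {
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("read%06d", seq_along(seqs))
    quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  }
  write_one(reads$read1, r1)
  write_one(reads$read2, r2)
  invisible(c(r1 = r1, r2 = r2))
}

#' Read a long-format barcode count table
#'
#' @param path TSV with columns `barcode`, `library`, `count`.
#' @return A tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(barcode = "c", library = "c",
                                          count = "i"))
}

#' Write a long-format barcode count table
#' @param counts Tibble with `barcode`, `library`, `count`.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts[, c("barcode", "library", "count")], path)
  invisible(path)
}

#' Read / write the barcode-to-fragment dictionary
#' @param path TSV with columns `barcode`, `fragment_id` (and optionally
#'   `reads`).
#' @return A tibble.
#' @export
read_barcode_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_barcode_map_tsv
#' @param map A barcode map (entries tibble or `mpra_barcode_map`).
#' @export
write_barcode_map_tsv <- function(map, path) {
  entries <- if (inherits(map, "mpra_barcode_map")) map$entries else map
  readr::write_tsv(entries, path)
  invisible(path)
}

#' Read a phased haplotype matrix from TSV
#'
#' @param path TSV whose header row holds variant ids and whose body holds
#'   0/1 alleles, one haplotype per line.
#' @return An integer matrix, haplotypes x variants, with variant ids as
#'   column names.
#' @export
read_haplotypes_tsv <- function(path) {
  m <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
  storage.mode(m) <- "integer"
  as_haplotype_matrix(m)
}

#' @rdname read_haplotypes_tsv
#' @param h A haplotype matrix.
#' @export
write_haplotypes_tsv <- function(h, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(h)), path)
  invisible(path)
}
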