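#' Simulation profiles for synthetic MPRA libraries
#'
#' The `"default"` profile is a desk-scale study: negative-binomially
#' dispersed plasmid counts, Gaussian per-barcode activity noise of 0.3
#' log2 units, and about 25 barcodes per fragment so that essentially all
#' fragments clear the 12-barcode filter. The `"full_scale"` profile keeps
#' the same noise model but draws roughly 900 barcodes per fragment, the
#' regime of a full-size library (~1.5 million barcodes over ~1,600
#' fragments).
#'
#' @param name `"default"` or `"full_scale"`.
#' @param ... Named overrides for individual profile fields.
#' @return A list of generator settings.
#' @export
sim_profile <- function(name = c("default", "full_scale"), ...) {
  name <- match.arg(name)
  p <- list(
    mean_barcodes = 25,          # Poisson mean of barcodes per fragment
    pdna_mean = 60,              # NB mean plasmid count per barcode
    dispersion = 0.1,            # NB dispersion (size = 1/dispersion)
    sigma = 0.3,                 # per-barcode activity noise, log2 units
    mu0 = 0,                     # baseline fragment activity, log2 units
    n_cdna = 1L,                 # cDNA replicate libraries
    assoc_reads_per_barcode = 3L,
    error_rate = 0,              # substitution rate in association reads
    barcode_length = 16L
  )
  if (name == "full_scale") p$mean_barcodes <- 936
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop("unknown profile field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(overrides)] <- overrides
  p
}

#' Simulate a reference region and a set of common variants
#'
#' Draws a uniform-random DNA sequence and places biallelic SNVs on it. Most
#' variants are spaced at least `min_spacing` apart (isolated windows); a
#' configurable fraction is planted within one flank of an already-placed
#' variant so that the design stage must emit combinatorial allele
#' fragments. Output is byte-identical for a given seed.
#'
#' @param length Region length in bp (default 58 kb, an intron-sized locus).
#' @param n_variants Number of variants (default 336).
#' @param seed Integer seed.
#' @param chrom Contig name for the synthetic region.
#' @param min_spacing Minimum distance between isolated variants (default
#'   150 bp, wider than one fragment window).
#' @param frac_close Fraction of variants placed 10-60 bp from an isolated
#'   variant to create shared windows (default 0.15).
#' @param flank Flank size the design stage will use; bounds placement so no
#'   window is clipped.
#' @return A list with `reference` (named character vector) and `variants`
#'   (a variant tibble).
#' @examples
#' reg <- sim_region(length = 2000, n_variants = 5, seed = 7)
#' reg$variants
#' @export
sim_region <- function(length = 58000L, n_variants = 336L, seed = 1L,
                       chrom = "chrS", min_spacing = 150L,
                       frac_close = 0.15, flank = 68L) {
  if (n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                      collapse = "")
    n_close <- round(frac_close * n_variants)
    n_anchor <- n_variants - n_close
    lo <- flank + 70L                 # keep neighbours' windows un-clipped too
    hi <- length - flank - 70L
    span_needed <- (n_anchor - 1L) * min_spacing
    slack <- (hi - lo) - span_needed
    if (n_anchor < 1L || slack < 0L) {
      stop("infeasible spacing: ", n_anchor, " isolated variants at spacing ",
           min_spacing, " do not fit in ", length, " bp", call. = FALSE)
    }
    extra <- if (n_anchor > 1L) {
      sort(sample.int(slack + 1L, n_anchor, replace = TRUE) - 1L)
    } else sample.int(slack + 1L, 1L) - 1L
    anchors <- lo + extra + (seq_len(n_anchor) - 1L) * min_spacing
    positions <- anchors
    if (n_close > 0L) {
      taken <- new.env(parent = emptyenv())
      for (p in positions) assign(as.character(p), TRUE, envir = taken)
      close_pos <- integer(0)
      attempts <- 0L
      while (length(close_pos) < n_close) {
        attempts <- attempts + 1L
        if (attempts > 50L * n_close) {
          stop("infeasible spacing: could not place clustered variants",
               call. = FALSE)
        }
        anchor <- anchors[sample.int(n_anchor, 1L)]
        cand <- anchor + sample(c(-1L, 1L), 1L) * sample(10:60, 1L)
        key <- as.character(cand)
        if (cand < lo || cand > hi || !is.null(taken[[key]])) next
        assign(key, TRUE, envir = taken)
        close_pos <- c(close_pos, cand)
      }
      positions <- c(positions, close_pos)
    }
    positions <- sort(positions)
    refs <- substring(sequence, positions, positions)
    alts <- vapply(refs, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1), USE.NAMES = FALSE)
    variants <- tibble::tibble(
      id = sprintf("sv%04d", seq_along(positions)),
      chrom = chrom,
      pos = as.integer(positions),
      ref = refs,
      alt = alts
    )
    list(reference = stats::setNames(sequence, chrom),
         variants = as_variant_table(variants))
  })
}

#' Simulate MPRA libraries with known allelic effects
#'
#' Given a fragment design and a table of true per-variant allelic effects
#' (log2 units, additive across the variant alleles a fragment carries),
#' generates everything the downstream pipeline consumes: a barcode
#' dictionary, paired association reads, and per-barcode pDNA/cDNA count
#' tables. Plasmid counts are negative binomial; cDNA counts are Poisson
#' around `pdna_count * 2^(mu0 + sum(delta) + N(0, sigma))`, so the expected
#' per-barcode log2 activity equals the fragment's true activity.
#'
#' @param design Fragment table from [build_fragments()] (or a deduplicated
#'   catalog) with `fragment_id`, `sequence` and `variant_sites` columns.
#' @param effects Tibble with `variant` and `delta` (log2 allelic effect);
#'   variants not listed have effect 0. `NULL` means a global null.
#' @param profile Generator settings from [sim_profile()].
#' @param seed Integer seed; output is byte-identical per seed.
#' @return A list: `barcode_map` (truth tibble `barcode`, `fragment_id`),
#'   `reads` (tibble `read1` barcode mate, `read2` fragment mate), `counts`
#'   (long tibble over libraries `pDNA`, `cDNA_1`, ...), `pairing` (cDNA to
#'   pDNA), and `truth` (per-fragment true activity and the effect table).
#' @export
sim_mpra_libraries <- function(design, effects = NULL,
                               profile = sim_profile(), seed = 1L) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("fragment_id", "sequence", "variant_sites") %in% names(design)))
  delta <- stats::setNames(numeric(0), character(0))
  if (!is.null(effects) && nrow(effects)) {
    delta <- stats::setNames(effects$delta, effects$variant)
  }
  true_activity <- vapply(design$variant_sites, function(vs) {
    profile$mu0 + sum(delta[intersect(vs, names(delta))])
  }, numeric(1))

  withr::with_seed(seed, {
    n_frag <- nrow(design)
    n_bc <- pmax(1L, stats::rpois(n_frag, profile$mean_barcodes))
    n_total <- sum(n_bc)
    if (n_total > 0.25 * 4^profile$barcode_length) {
      stop("barcode space exhausted: ", n_total, " tags requested from a ",
           profile$barcode_length, " bp space", call. = FALSE)
    }
    barcodes <- unique(random_dna(n_total, profile$barcode_length))
    guard <- 0L
    while (length(barcodes) < n_total) {
      guard <- guard + 1L
      if (guard > 100L) stop("barcode space exhausted", call. = FALSE)
      barcodes <- unique(c(barcodes,
                           random_dna(n_total - length(barcodes),
                                      profile$barcode_length)))
    }
    frag_of_bc <- rep(design$fragment_id, times = n_bc)
    act_of_bc <- rep(true_activity, times = n_bc)
    barcode_map <- tibble::tibble(barcode = barcodes, fragment_id = frag_of_bc)

    pdna <- stats::rnbinom(n_total, mu = profile$pdna_mean,
                           size = 1 / profile$dispersion)
    counts <- tibble::tibble(barcode = barcodes, library = "pDNA",
                             count = as.integer(pdna))
    pairing <- tibble::tibble(cdna = character(0), pdna = character(0))
    for (r in seq_len(profile$n_cdna)) {
      noise <- stats::rnorm(n_total, 0, profile$sigma)
      mu_cdna <- pdna * 2^(act_of_bc + noise)
      cdna <- stats::rpois(n_total, lambda = mu_cdna)
      lib <- paste0("cDNA_", r)
      counts <- dplyr::bind_rows(
        counts,
        tibble::tibble(barcode = barcodes, library = lib,
                       count = as.integer(cdna)))
      pairing <- dplyr::bind_rows(pairing,
                                  tibble::tibble(cdna = lib, pdna = "pDNA"))
    }

    n_reads <- profile$assoc_reads_per_barcode
    read1 <- rep(barcodes, each = n_reads)
    read2 <- rep(design$sequence[match(frag_of_bc, design$fragment_id)],
                 each = n_reads)
    if (profile$error_rate > 0) {
      read2 <- apply_seq_errors(read2, profile$error_rate)
    }
    list(
      barcode_map = barcode_map,
      reads = tibble::tibble(read1 = read1, read2 = read2),
      counts = counts,
      pairing = pairing,
      truth = list(
        effects = tibble::tibble(variant = names(delta),
                                 delta = unname(delta)),
        fragment_activity = tibble::tibble(fragment_id = design$fragment_id,
                                           true_activity = true_activity,
                                           n_barcodes = n_bc)
      )
    )
  })
}

# Random substitutions at a fixed per-base rate; draws stay inside the
# caller's seeded RNG stream.
apply_seq_errors <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < rate)
    if (!length(hits)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[hits] <- vapply(chars[hits],
                          function(b) sample(setdiff(bases, b), 1L),
                          character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate block-structured phased haplotypes
#'
#' Generates a 0/1 haplotype matrix with independent LD blocks. Within a
#' block, every column is the block's anchor column with entries flipped
#' independently at rate `(1 - sqrt(r2)) / 2`, which gives an expected
#' allelic correlation of `sqrt(r2)` (so pairwise r-squared around the
#' target) for 0.5-frequency alleles; across blocks columns are
#' independent.
#'
#' @param n_haplotypes Number of haplotype rows (default 200).
#' @param blocks Data frame with `n_variants` and `r2` (target within-block
#'   r-squared) per block.
#' @param seed Integer seed; output is byte-identical per seed.
#' @param maf Allele frequency of the anchor draws (default 0.5).
#' @return Integer matrix with columns named `b<block>v<index>`.
#' @examples
#' h <- sim_haplotypes(100, tibble::tibble(n_variants = c(3, 4), r2 = 0.9),
#'                     seed = 3)
#' colnames(h)
#' @export
sim_haplotypes <- function(n_haplotypes = 200L, blocks, seed = 1L, maf = 0.5) {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("n_variants", "r2") %in% names(blocks)))
  if (any(blocks$r2 < 0 | blocks$r2 > 1)) {
    stop("target r2 must lie in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    cols <- list()
    for (b in seq_len(nrow(blocks))) {
      anchor <- stats::rbinom(n_haplotypes, 1L, maf)
      if (length(unique(anchor)) == 1L) anchor[1L] <- 1L - anchor[1L]
      flip_p <- (1 - sqrt(blocks$r2[b])) / 2
      for (j in seq_len(blocks$n_variants[b])) {
        col <- if (j == 1L) anchor else {
          flips <- stats::rbinom(n_haplotypes, 1L, flip_p)
          as.integer(xor(anchor, flips))
        }
        if (length(unique(col)) == 1L) col[1L] <- 1L - col[1L]
        cols[[paste0("b", b, "v", j)]] <- col
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- NULL
    as_haplotype_matrix(m)
  })
}

#' Run the count-to-call pipeline on one set of MPRA libraries
#'
#' Convenience wrapper chaining [normalize_counts()], [compute_activity()],
#' [aggregate_fragments()] and [test_fragments()] with the standard
#' defaults. Accepts the list returned by [sim_mpra_libraries()] or the
#' individual pieces.
#'
#' @param counts Long count tibble, or a [sim_mpra_libraries()] result list
#'   (in which case `pairing` and `map` are taken from it).
#' @param design Fragment design table.
#' @param pairing,map See [compute_activity()] and [aggregate_fragments()].
#' @param scale,pseudocount,cutoff,min_barcodes,alpha,variant Pipeline
#'   settings with the standard defaults.
#' @return A list with `normalized`, `activity`, `summaries` and `results`.
#' @export
run_mpra_pipeline <- function(counts, design, pairing = NULL, map = NULL,
                              scale = 1e6, pseudocount = 1, cutoff = 0.5,
                              min_barcodes = 12L, alpha = 0.05,
                              variant = "student") {
  if (is.list(counts) && !is.data.frame(counts) &&
      all(c("counts", "pairing", "barcode_map") %in% names(counts))) {
    pairing <- pairing %||% counts$pairing
    map <- map %||% counts$barcode_map
    counts <- counts$counts
  }
  normalized <- normalize_counts(counts, scale = scale,
                                 pseudocount = pseudocount, cutoff = cutoff)
  activity <- compute_activity(normalized, pairing)
  summaries <- aggregate_fragments(activity, map, min_barcodes = min_barcodes)
  results <- test_fragments(summaries, design, alpha = alpha,
                            variant = variant)
  list(normalized = normalized, activity = activity,
       summaries = summaries, results = results)
}
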