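# Independent oracles used to cross-check the implementation. These are
# written from the textbook definitions and deliberately share no code with
# the package internals.

# Enumerate all allele tuples for a list of per-variant allele sets by
# counting in mixed radix (no expand.grid).
oracle_allele_tuples <- function(allele_sets) {
  ks <- lengths(allele_sets)
  n <- prod(ks)
  out <- vector("list", n)
  for (idx in seq_len(n) - 1L) {
    rem <- idx
    tuple <- character(length(ks))
    # last variant varies fastest
    for (v in rev(seq_along(ks))) {
      tuple[v] <- allele_sets[[v]][rem %% ks[v] + 1L]
      rem <- rem %/% ks[v]
    }
    out[[idx + 1L]] <- stats::setNames(tuple, names(allele_sets))
  }
  out
}

# Character-by-character substitution of SNV alleles into a window slice.
oracle_substitute <- function(ref_seq, w_start0, positions, alleles) {
  chars <- strsplit(substr(ref_seq, w_start0 + 1L,
                           w_start0 + 137L), "", fixed = TRUE)[[1]]
  for (k in seq_along(positions)) {
    chars[positions[k] - w_start0] <- alleles[k]
  }
  paste(chars, collapse = "")
}

# Pooled-variance two-sample two-tailed t-test from the closed form.
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Welch two-sample t-test from the closed form.
oracle_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  se2 <- var(x) / n1 + var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-locus LD statistics straight from the four haplotype counts.
oracle_ld_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p11 <- n11 / n
  p1 <- (n11 + n10) / n
  q1 <- (n11 + n01) / n
  D <- p11 - p1 * q1
  r2 <- D^2 / (p1 * (1 - p1) * q1 * (1 - q1))
  Dmax <- if (D >= 0) min(p1 * (1 - q1), (1 - p1) * q1) else
    min(p1 * q1, (1 - p1) * (1 - q1))
  list(D = D, r2 = r2, Dprime = if (D == 0) 0 else D / Dmax)
}

# Turn haplotype counts into an explicit 0/1 matrix with two columns.
haps_from_counts <- function(n11, n10, n01, n00) {
  cbind(
    a = rep(c(1L, 1L, 0L, 0L), times = c(n11, n10, n01, n00)),
    b = rep(c(1L, 0L, 1L, 0L), times = c(n11, n10, n01, n00))
  )
}

# Direct log-CPM-style normalization formula for cross-checking.
oracle_normalize <- function(count, lib_size, scale, pseudocount) {
  log2(count / lib_size * scale + pseudocount)
}
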