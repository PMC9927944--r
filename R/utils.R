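# Internal helpers shared across modules.

# Split fixed-width DNA strings into a character matrix (rows = sequences).
seq_char_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

# Hamming distance between one string and each row of a pre-split matrix.
hamming_to_all <- function(segment, mat) {
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  if (length(chars) != ncol(mat)) {
    stop("segment length does not match catalog sequence length", call. = FALSE)
  }
  rowSums(mat != matrix(chars, nrow = nrow(mat), ncol = ncol(mat), byrow = TRUE))
}

random_dna <- function(n, length, bases = c("A", "C", "G", "T")) {
  vapply(seq_len(n),
         function(i) paste(sample(bases, length, replace = TRUE), collapse = ""),
         character(1))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT base found in ", what, call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
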