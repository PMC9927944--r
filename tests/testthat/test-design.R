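test_that("allele combinations cover the full Cartesian product", {
  ref <- fixed_reference()

  v1 <- isolated_snv(ref)
  expect_equal(nrow(enumerate_allele_combinations(v1)), 2L)

  v2 <- spaced_snvs(ref, 2, start = 500L, gap = 20L)
  expect_equal(nrow(enumerate_allele_combinations(v2)), 4L)

  # 3 biallelic variants: identical to a brute-force enumeration oracle
  v3 <- spaced_snvs(ref, 3, start = 500L, gap = 20L)
  combos <- enumerate_allele_combinations(v3)
  expect_equal(nrow(combos), 8L)
  sets <- purrr::map2(v3$ref, v3$alt, c)
  names(sets) <- v3$id
  oracle <- oracle_allele_tuples(sets)
  got <- purrr::map_chr(combos$alleles, paste, collapse = "")
  want <- purrr::map_chr(oracle, paste, collapse = "")
  expect_setequal(got, want)
  # exactly one all-reference assignment
  expect_equal(sum(combos$is_reference), 1L)

  # a multi-allelic variant contributes (1 + n_alts) choices
  vm <- v2
  vm$alt[1] <- paste(setdiff(c("A", "C", "G", "T"), vm$ref[1])[1:2],
                     collapse = ",")
  expect_equal(nrow(enumerate_allele_combinations(vm)), 6L)
})

test_that("overlapping variants are rejected with the colliding pair named", {
  ref <- fixed_reference()
  v <- tibble::tibble(
    id = c("a", "b"), chrom = "refA", pos = c(500L, 500L),
    ref = c(ref_base_at(ref, 500), ref_base_at(ref, 500)),
    alt = c("A", "C")
  )
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                  character(1))
  expect_error(enumerate_allele_combinations(v), "a.*b|collide")
})

test_that("an isolated SNV yields a 137 bp fragment with 68 bp flanks", {
  ref <- fixed_reference()
  v <- isolated_snv(ref, pos = 500L)
  frags <- build_fragments(v, ref)
  expect_equal(nrow(frags), 2L)
  expect_true(all(nchar(frags$sequence) == 137L))
  # variant base sits at 0-based offset 68
  ref_frag <- frags[frags$is_reference, ]
  alt_frag <- frags[!frags$is_reference, ]
  expect_equal(substr(ref_frag$sequence, 69, 69), v$ref)
  expect_equal(substr(alt_frag$sequence, 69, 69), v$alt)
  # flanks are the untouched reference sequence
  expect_equal(substr(alt_frag$sequence, 1, 68),
               substr(unname(ref), 500 - 68, 499))
  expect_equal(substr(alt_frag$sequence, 70, 137),
               substr(unname(ref), 501, 500 + 68))
  expect_equal(ref_frag$window_start, 500L - 1L - 68L)
  expect_equal(ref_frag$window_end, 500L + 68L)
})

test_that("windows clipped by the reference ends are an error", {
  ref <- fixed_reference()
  v <- isolated_snv(ref, pos = 30L)
  expect_error(build_fragments(v, ref), "extends past")
  v2 <- isolated_snv(ref, pos = 990L, id = "v2")
  expect_error(build_fragments(v2, ref), "extends past")
})

test_that("shared windows produce combinatorial fragments matching a substitution oracle", {
  ref <- fixed_reference()
  v <- spaced_snvs(ref, 2, start = 490L, gap = 20L)
  frags <- build_fragments(v, ref)
  # each of the two windows yields 2^2 fragments
  expect_equal(as.vector(table(frags$center_variant)), c(4L, 4L))
  for (i in seq_len(nrow(frags))) {
    f <- frags[i, ]
    alleles <- f$alleles[[1]]
    expected <- oracle_substitute(unname(ref), f$window_start,
                                  v$pos[match(names(alleles), v$id)],
                                  unname(alleles))
    expect_identical(f$sequence, expected)
  }
})

test_that("k isolated SNVs give exactly 2k fragments", {
  for (seed in 1:3) {
    reg <- sim_region(length = 20000, n_variants = 10 + seed, seed = seed,
                      frac_close = 0)
    frags <- build_fragments(reg$variants, reg$reference)
    expect_equal(nrow(frags), 2L * nrow(reg$variants))
  }
})

test_that("non-reference fragments differ from reference exactly at substituted sites", {
  reg <- sim_region(length = 8000, n_variants = 12, seed = 11,
                    frac_close = 0.3)
  frags <- build_fragments(reg$variants, reg$reference)
  pos_of <- stats::setNames(reg$variants$pos, reg$variants$id)
  for (cv in unique(frags$center_variant)) {
    w <- frags[frags$center_variant == cv, ]
    ref_seq <- w$sequence[w$is_reference]
    for (i in which(!w$is_reference)) {
      a <- strsplit(ref_seq, "")[[1]]
      b <- strsplit(w$sequence[i], "")[[1]]
      diff_pos <- w$window_start[i] + which(a != b)   # 1-based genome coords
      expect_setequal(diff_pos, unname(pos_of[w$variant_sites[[i]]]))
    }
  }
})

test_that("guard rails: window variant limit and ref-allele mismatches error", {
  ref <- fixed_reference()
  v7 <- spaced_snvs(ref, 7, start = 470L, gap = 9L)
  expect_error(build_fragments(v7, ref), "max_variants_per_window")

  v <- isolated_snv(ref, pos = 500L)
  v$ref <- setdiff(c("A", "C", "G", "T"), ref_base_at(ref, 500))[1]
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_error(build_fragments(v, ref), "does not match")
})

test_that("deduplication collapses identical sequences and is idempotent", {
  ref <- fixed_reference()
  v <- isolated_snv(ref)
  frags <- build_fragments(v, ref)
  doubled <- dplyr::bind_rows(frags, frags)
  catalog <- dedupe_and_catalog(doubled)
  expect_equal(nrow(catalog), 2L)
  expect_true(all(catalog$n_merged == 2L))
  expect_equal(nrow(catalog$provenance[[1]]), 2L)

  again <- dedupe_and_catalog(catalog)
  expect_equal(again$sequence, catalog$sequence)
  expect_equal(again$fragment_id, catalog$fragment_id)

  # oligos contain the variable region as an exact substring
  expect_true(all(mapply(grepl, catalog$sequence, catalog$oligo,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("catalog size equals a set-of-strings oracle on random variant sets", {
  sizes <- c(5, 24, 50)
  for (k in seq_along(sizes)) {
    seed <- c(5, 17, 29)[k]
    n <- sizes[k]
    reg <- sim_region(length = 30000, n_variants = n, seed = seed,
                      frac_close = 0.2)
    frags <- build_fragments(reg$variants, reg$reference)
    catalog <- dedupe_and_catalog(frags)
    expect_equal(nrow(catalog), length(unique(frags$sequence)))
  }
})

test_that("design output is byte-identical across reruns", {
  reg <- sim_region(length = 10000, n_variants = 15, seed = 23,
                    frac_close = 0.2)
  run_once <- function(dir) {
    frags <- build_fragments(reg$variants, reg$reference)
    catalog <- dedupe_and_catalog(frags)
    write_catalog(catalog, file.path(dir, "cat"))
    c(fa = unname(tools::md5sum(file.path(dir, "cat.fa"))),
      tsv = unname(tools::md5sum(file.path(dir, "cat_manifest.tsv"))))
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  expect_identical(run_once(d1), run_once(d2))
})
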