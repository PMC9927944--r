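test_that("region simulation is byte-deterministic per seed", {
  a <- sim_region(length = 5000, n_variants = 8, seed = 12)
  b <- sim_region(length = 5000, n_variants = 8, seed = 12)
  expect_identical(a, b)
  c <- sim_region(length = 5000, n_variants = 8, seed = 13)
  expect_false(identical(a$reference, c$reference))
})

test_that("isolated variants design to 2k fragments; clustered windows to 2^k", {
  reg <- sim_region(length = 10000, n_variants = 10, seed = 2, frac_close = 0)
  frags <- build_fragments(reg$variants, reg$reference)
  expect_equal(nrow(frags), 20L)

  # force a window with 3 variants: anchor plus two planted neighbours
  reg2 <- sim_region(length = 6000, n_variants = 4, seed = 6, frac_close = 0)
  v <- reg2$variants
  anchor <- v[2, ]
  ref_chr <- unname(reg2$reference[1])
  mk_neighbour <- function(offset, id) {
    p <- anchor$pos + offset
    r <- substr(ref_chr, p, p)
    tibble::tibble(id = id, chrom = anchor$chrom, pos = p, ref = r,
                   alt = setdiff(c("A", "C", "G", "T"), r)[1])
  }
  v3 <- dplyr::bind_rows(anchor, mk_neighbour(15L, "nb1"),
                         mk_neighbour(-20L, "nb2"))
  frags3 <- build_fragments(v3, reg2$reference)
  per_window <- table(frags3$center_variant)
  expect_true(all(per_window == 8L))
})

test_that("library simulation is deterministic and internally consistent", {
  reg <- sim_region(length = 6000, n_variants = 6, seed = 1, frac_close = 0)
  frags <- build_fragments(reg$variants, reg$reference)
  s1 <- sim_mpra_libraries(frags, profile = sim_profile(), seed = 99)
  s2 <- sim_mpra_libraries(frags, profile = sim_profile(), seed = 99)
  expect_identical(s1, s2)
  # no barcode collisions across fragments
  expect_equal(anyDuplicated(s1$barcode_map$barcode), 0L)
  # every fragment received at least one barcode
  expect_setequal(unique(s1$barcode_map$fragment_id), frags$fragment_id)
})

test_that("null libraries produce mean activities near zero", {
  reg <- sim_region(length = 12000, n_variants = 15, seed = 14,
                    frac_close = 0)
  frags <- build_fragments(reg$variants, reg$reference)
  sim <- sim_mpra_libraries(frags, NULL,
                            sim_profile(mean_barcodes = 40, pdna_mean = 200),
                            seed = 15)
  out <- run_mpra_pipeline(sim, frags)
  ok <- out$results[out$results$status == "ok", ]
  # effects (differences of means) have SE ~ sigma * sqrt(2/40) ~ 0.07
  se <- 3 * 0.3 * sqrt(2 / 40)
  expect_true(all(abs(ok$effect) < 3 * se))
})

test_that("barcodes-per-fragment counts track the configured Poisson draw", {
  reg <- sim_region(length = 40000, n_variants = 100, seed = 41,
                    frac_close = 0)
  frags <- build_fragments(reg$variants, reg$reference)
  sim <- sim_mpra_libraries(frags, profile = sim_profile(), seed = 42)
  n_bc <- sim$truth$fragment_activity$n_barcodes
  lambda <- sim_profile()$mean_barcodes
  # sup distance between the empirical CDF and the Poisson CDF
  grid <- 0:60
  emp <- ecdf(n_bc)(grid)
  theo <- ppois(grid, lambda)
  expect_lt(max(abs(emp - theo)), 0.1)
  # the default profile keeps nearly all fragments above the barcode filter
  expect_gt(mean(n_bc >= 12), 0.98)
})

test_that("haplotype blocks hit their target r2 and respect bounds", {
  blocks <- tibble::tibble(n_variants = c(4, 3), r2 = c(1, 0.9))
  h1 <- sim_haplotypes(120, blocks, seed = 30)
  h2 <- sim_haplotypes(120, blocks, seed = 30)
  expect_identical(h1, h2)
  # target r2 = 1: all columns of block 1 identical (up to label flips)
  b1 <- h1[, paste0("b1v", 1:4)]
  agree <- abs(cor(b1))
  expect_true(all(agree > 0.999))
  # cross-block columns are near-independent at this sample size
  cross <- abs(cor(h1[, "b1v1"], h1[, "b2v1"]))
  expect_lt(cross, 0.35)
  expect_error(sim_haplotypes(50, tibble::tibble(n_variants = 2, r2 = 1.2)),
               "\\[0, 1\\]")
})

test_that("infeasible variant spacing is rejected", {
  expect_error(sim_region(length = 1000, n_variants = 50, seed = 1,
                          frac_close = 0),
               "infeasible")
})

test_that("every emitted file round-trips through the pipeline readers", {
  dir <- withr::local_tempdir()
  reg <- sim_region(length = 6000, n_variants = 6, seed = 20,
                    frac_close = 0.2)
  frags <- build_fragments(reg$variants, reg$reference)
  catalog <- dedupe_and_catalog(frags)
  sim <- sim_mpra_libraries(catalog, profile = sim_profile(), seed = 21)

  expect_no_warning({
    write_reference_fasta(reg$reference, file.path(dir, "ref.fa"))
    ref_back <- read_reference_fasta(file.path(dir, "ref.fa"))
    write_variants_vcf(reg$variants, file.path(dir, "var.vcf"))
    var_back <- read_variants_vcf(file.path(dir, "var.vcf"))
    write_catalog(catalog, file.path(dir, "cat"))
    manifest_back <- read_catalog_manifest(file.path(dir, "cat_manifest.tsv"))
    write_fastq_pair(sim$reads, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
    reads_back <- read_fastq_pair(file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
    write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
    counts_back <- read_counts_tsv(file.path(dir, "counts.tsv"))
    write_barcode_map_tsv(sim$barcode_map, file.path(dir, "map.tsv"))
    map_back <- read_barcode_map_tsv(file.path(dir, "map.tsv"))
  })
  expect_identical(unname(ref_back), unname(reg$reference))
  expect_equal(var_back$pos, reg$variants$pos)
  expect_equal(var_back$ref, reg$variants$ref)
  expect_equal(nrow(manifest_back), nrow(catalog))
  expect_identical(reads_back$read1, sim$reads$read1)
  expect_equal(counts_back$count, sim$counts$count)
  expect_equal(map_back$barcode, sim$barcode_map$barcode)

  # manifest round-trip preserves the variant-difference annotation
  sites_want <- purrr::map(catalog$variant_sites, sort)
  sites_got <- purrr::map(
    manifest_back$variant_sites[match(catalog$fragment_id,
                                      manifest_back$fragment_id)], sort)
  expect_equal(sites_got, sites_want)

  # haplotype matrix TSV round-trip
  h <- sim_haplotypes(40, tibble::tibble(n_variants = 3, r2 = 0.8), seed = 9)
  write_haplotypes_tsv(h, file.path(dir, "haps.tsv"))
  expect_identical(read_haplotypes_tsv(file.path(dir, "haps.tsv")), h)
})

test_that("the full-scale profile only changes the barcode regime", {
  p <- sim_profile("full_scale")
  d <- sim_profile()
  expect_gt(p$mean_barcodes, 900)
  expect_equal(p$sigma, d$sigma)
  expect_error(sim_profile(nonsense = 1), "unknown profile")
})
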