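#' Coerce to a 0/1 haplotype matrix
#'
#' @param x Matrix or data frame of phased alleles, haplotypes in rows and
#'   variants in columns, coded 0 (reference) / 1 (alternate). Column names
#'   are variant ids.
#' @return An integer matrix with validated entries.
#' @export
as_haplotype_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) {
    stop("haplotype entries must be 0 or 1", call. = FALSE)
  }
  if (nrow(m) < 2L) stop("need at least 2 haplotypes", call. = FALSE)
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("v", seq_len(ncol(m)))
  }
  m
}

#' Two-locus linkage disequilibrium from phased haplotypes
#'
#' Computes the classical two-locus statistics directly from haplotype
#' frequencies: `D = p11 - p1 * q1` (covariance of carrying the alternate
#' allele at both loci), `r2 = D^2 / (p1 (1-p1) q1 (1-q1))`, and `D' = D /
#' Dmax` where `Dmax = min(p1 (1-q1), (1-p1) q1)` for positive D and
#' `min(p1 q1, (1-p1)(1-q1))` for negative D.
#'
#' @param h Haplotype matrix (see [as_haplotype_matrix()]).
#' @param i,j Column indices or variant ids.
#' @return One-row tibble: `variant_i`, `variant_j`, `D`, `Dprime`, `r2`.
#' @examples
#' h <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' ld_pair(h, "a", "b")
#' @export
ld_pair <- function(h, i, j) {
  h <- as_haplotype_matrix(h)
  x <- h[, i]
  y <- h[, j]
  id_i <- if (is.character(i)) i else colnames(h)[i]
  id_j <- if (is.character(j)) j else colnames(h)[j]
  p1 <- mean(x)
  q1 <- mean(y)
  if (p1 %in% c(0, 1) || q1 %in% c(0, 1)) {
    stop("undefined LD: locus ",
         if (p1 %in% c(0, 1)) id_i else id_j,
         " is monomorphic", call. = FALSE)
  }
  p11 <- mean(x == 1L & y == 1L)
  D <- p11 - p1 * q1
  r2 <- D^2 / (p1 * (1 - p1) * q1 * (1 - q1))
  Dmax <- if (D >= 0) min(p1 * (1 - q1), (1 - p1) * q1) else
    min(p1 * q1, (1 - p1) * (1 - q1))
  Dprime <- if (D == 0) 0 else D / Dmax
  tibble::tibble(variant_i = id_i, variant_j = id_j,
                 D = D, Dprime = Dprime, r2 = r2)
}

#' All pairwise LD statistics for a haplotype matrix
#'
#' @param h Haplotype matrix.
#' @return Tibble with one row per unordered polymorphic pair.
#' @export
ld_matrix <- function(h) {
  h <- as_haplotype_matrix(h)
  poly <- colnames(h)[colMeans(h) > 0 & colMeans(h) < 1]
  if (length(poly) < 2L) {
    return(tibble::tibble(variant_i = character(), variant_j = character(),
                          D = numeric(), Dprime = numeric(), r2 = numeric()))
  }
  pairs <- utils::combn(poly, 2L)
  purrr::map(seq_len(ncol(pairs)),
             function(k) ld_pair(h, pairs[1L, k], pairs[2L, k])) |>
    dplyr::bind_rows()
}

#' Group variants by linkage to seed (lead) SNPs
#'
#' Each seed SNP starts a group; seeds whose mutual r-squared exceeds the
#' threshold are merged into one group. Every other variant joins the group
#' of the seed with which its r-squared is highest, provided that r-squared
#' strictly exceeds the threshold; variants clearing it with no seed (or
#' monomorphic in the panel) are left ungrouped. Groups are numbered by the
#' column order of their first seed, so output is deterministic.
#'
#' @param h Haplotype matrix.
#' @param seeds Character vector of seed variant ids (must be columns of `h`).
#' @param r2_min Strict r-squared threshold (default 0.70).
#' @return A tibble with one row per variant: `variant`, `is_seed`, `group`
#'   (e.g. `"grp-1"`, `NA` when ungrouped), `best_seed`, `r2_best`.
#' @export
group_by_ld <- function(h, seeds, r2_min = 0.70) {
  # strict threshold, with an epsilon so that r2 values equal to the
  # threshold up to floating error (e.g. exact duplicates at r2_min = 1)
  # are treated as exceeding it
  exceeds <- function(r2, thr) r2 > thr - 1e-12
  h <- as_haplotype_matrix(h)
  missing_seeds <- setdiff(seeds, colnames(h))
  if (length(missing_seeds)) {
    stop("seed variant(s) absent from the haplotype matrix: ",
         paste(missing_seeds, collapse = ", "), call. = FALSE)
  }
  seeds <- unique(seeds)
  ids <- colnames(h)
  r2_fn <- function(a, b) {
    pa <- mean(h[, a]); pb <- mean(h[, b])
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
    D <- mean(h[, a] == 1L & h[, b] == 1L) - pa * pb
    D^2 / (pa * (1 - pa) * pb * (1 - pb))
  }
  # union-find over seeds: merge seeds in mutual LD above the threshold
  parent <- seq_along(seeds)
  find <- function(k) { while (parent[k] != k) k <- parent[k]; k }
  if (length(seeds) > 1L) {
    for (a in seq_len(length(seeds) - 1L)) {
      for (b in seq(a + 1L, length(seeds))) {
        r2 <- r2_fn(seeds[a], seeds[b])
        if (!is.na(r2) && exceeds(r2, r2_min)) {
          parent[find(b)] <- find(a)
        }
      }
    }
  }
  roots <- vapply(seq_along(seeds), find, integer(1))
  group_of_seed <- stats::setNames(
    paste0("grp-", match(roots, sort(unique(roots)))), seeds)

  rows <- purrr::map(ids, function(v) {
    if (v %in% seeds) {
      return(tibble::tibble(variant = v, is_seed = TRUE,
                            group = group_of_seed[[v]],
                            best_seed = v, r2_best = 1))
    }
    r2s <- vapply(seeds, function(s) r2_fn(v, s), numeric(1))
    if (all(is.na(r2s)) || !exceeds(max(r2s, na.rm = TRUE), r2_min)) {
      return(tibble::tibble(variant = v, is_seed = FALSE,
                            group = NA_character_,
                            best_seed = NA_character_,
                            r2_best = if (all(is.na(r2s))) NA_real_ else
                              max(r2s, na.rm = TRUE)))
    }
    best <- which.max(r2s)  # earliest seed wins ties
    tibble::tibble(variant = v, is_seed = FALSE,
                   group = group_of_seed[[seeds[best]]],
                   best_seed = seeds[best], r2_best = r2s[best])
  })
  dplyr::bind_rows(rows)
}

#' Prioritize MPRA hits by linkage to lead GWAS SNPs
#'
#' Joins the per-variant allele-specific activity calls with LD group
#' membership and partitions variants into four strata: lead SNPs with
#' significant activity, variants linked (grouped) to a lead SNP with
#' significant activity, significant variants with no lead linkage, and the
#' rest.
#'
#' @param calls Per-variant summary from [summarize_variants()].
#' @param groups LD grouping from [group_by_ld()].
#' @param leads Character vector of lead SNP ids.
#' @return A tibble sorted by stratum: `variant`, `any_significant`,
#'   `is_lead`, `group`, `linked_to_lead`, `stratum`.
#' @export
prioritize_variants <- function(calls, groups, leads) {
  lead_groups <- unique(groups$group[groups$variant %in% leads &
                                       !is.na(groups$group)])
  merged <- calls |>
    dplyr::full_join(groups, by = "variant") |>
    dplyr::mutate(
      any_significant = dplyr::coalesce(.data$any_significant, FALSE),
      is_lead = .data$variant %in% leads,
      linked_to_lead = !is.na(.data$group) & .data$group %in% lead_groups &
        !.data$is_lead,
      stratum = dplyr::case_when(
        .data$is_lead & .data$any_significant ~ "lead & significant",
        .data$linked_to_lead & .data$any_significant ~ "linked & significant",
        .data$any_significant ~ "significant only",
        TRUE ~ "not significant"
      )
    )
  merged |>
    dplyr::arrange(factor(.data$stratum,
                          levels = c("lead & significant",
                                     "linked & significant",
                                     "significant only",
                                     "not significant")),
                   .data$variant) |>
    dplyr::select("variant", "any_significant", "is_lead", "group",
                  "linked_to_lead", "best_seed", "r2_best", "stratum",
                  dplyr::any_of(c("n_significant", "significant_single",
                                  "best_p", "best_effect")))
}
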