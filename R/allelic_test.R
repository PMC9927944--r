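#' Two-sample t-test of one fragment's activities against its reference
#'
#' Compares the barcode activities of a variant-carrying fragment with those
#' of the all-reference fragment from the same window using a two-tailed
#' two-sample t-test. `variant = "student"` (the default) pools variances;
#' `variant = "welch"` uses the Welch correction for unequal variances.
#'
#' @param test_activities,ref_activities Numeric vectors of per-barcode
#'   activities.
#' @param alpha Significance level (default 0.05).
#' @param variant `"student"` or `"welch"`.
#' @return One-row tibble: `n_test`, `n_ref`, `effect` (mean test minus mean
#'   reference, log2 units), `statistic`, `df`, `p_value`, `significant`.
#' @examples
#' test_fragment(c(1.0, 1.2, 0.8), c(0.5, 0.7, 0.6))
#' @export
test_fragment <- function(test_activities, ref_activities, alpha = 0.05,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(test_activities) < 2L || length(ref_activities) < 2L) {
    stop("each side needs at least 2 activities for a t-test", call. = FALSE)
  }
  effect <- mean(test_activities) - mean(ref_activities)
  if (stats::sd(test_activities) == 0 && stats::sd(ref_activities) == 0) {
    # degenerate: both groups constant; equal means give t = 0, p = 1
    statistic <- if (effect == 0) 0 else sign(effect) * Inf
    p <- if (effect == 0) 1 else 0
    df <- length(test_activities) + length(ref_activities) - 2
  } else {
    fit <- stats::t.test(test_activities, ref_activities,
                         var.equal = (variant == "student"),
                         alternative = "two.sided")
    statistic <- unname(fit$statistic)
    df <- unname(fit$parameter)
    p <- fit$p.value
  }
  tibble::tibble(
    n_test = length(test_activities),
    n_ref = length(ref_activities),
    effect = effect,
    statistic = statistic,
    df = df,
    p_value = p,
    significant = p < alpha
  )
}

#' Allele-specific activity tests for every non-reference fragment
#'
#' For each fragment window, tests each variant-carrying fragment's barcode
#' activities against the window's all-reference fragment. Fragments on
#' either side of a comparison that failed the minimum-barcode filter yield
#' a withheld row (`status = "insufficient barcodes"`) rather than a test.
#'
#' @param summaries An `mpra_fragment_summary` (from [aggregate_fragments()]).
#' @param design Fragment design table carrying `fragment_id`,
#'   `center_variant`, `is_reference`, `n_variant_sites` and `variant_sites`
#'   ([build_fragments()] output, a deduplicated catalog, or a manifest read
#'   back with [read_catalog_manifest()]).
#' @param alpha Significance level for the raw p-value (default 0.05).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param fdr If `TRUE`, adds a Benjamini-Hochberg `q_value` column; the
#'   `significant` flag still uses the raw p-value.
#' @return A tibble of class `mpra_diff` with one row per non-reference
#'   fragment: ids, `status`, barcode counts, `effect`, `statistic`,
#'   `p_value`, `significant`, `n_variant_sites`, `variant_sites`.
#' @export
test_fragments <- function(summaries, design, alpha = 0.05,
                           variant = c("student", "welch"), fdr = FALSE) {
  variant <- match.arg(variant)
  design <- tibble::as_tibble(design)
  need <- c("fragment_id", "center_variant", "is_reference", "n_variant_sites")
  stopifnot(all(need %in% names(design)))
  if (!"variant_sites" %in% names(design)) {
    design$variant_sites <- vector("list", nrow(design))
  }
  s_lut <- stats::setNames(seq_len(nrow(summaries)), summaries$fragment_id)

  rows <- design |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::group_split(.data$center_variant) |>
    purrr::map(function(frags) {
      cv <- frags$center_variant[[1]]
      ref_row <- design[design$center_variant == cv & design$is_reference, ]
      purrr::map(seq_len(nrow(frags)), function(k) {
        f <- frags[k, ]
        ref_id <- if (nrow(ref_row)) ref_row$fragment_id[[1]] else NA_character_
        base <- tibble::tibble(
          fragment_id = f$fragment_id,
          reference_fragment_id = ref_id,
          center_variant = cv,
          n_variant_sites = f$n_variant_sites,
          variant_sites = f$variant_sites
        )
        si <- s_lut[f$fragment_id]
        ri <- if (is.na(ref_id)) NA_integer_ else s_lut[ref_id]
        ok <- !is.na(si) && !is.na(ri) &&
          summaries$passed_filter[si] && summaries$passed_filter[ri]
        if (!ok) {
          reason <- if (is.na(ref_id) || is.na(ri)) "missing reference" else
            "insufficient barcodes"
          return(dplyr::bind_cols(base, tibble::tibble(
            status = reason,
            n_test = if (is.na(si)) 0L else summaries$n_barcodes[si],
            n_ref = if (is.na(ri)) 0L else summaries$n_barcodes[ri],
            effect = NA_real_, statistic = NA_real_, df = NA_real_,
            p_value = NA_real_, significant = FALSE)))
        }
        res <- test_fragment(summaries$activities[[si]],
                             summaries$activities[[ri]],
                             alpha = alpha, variant = variant)
        dplyr::bind_cols(base, tibble::tibble(status = "ok"), res)
      }) |> dplyr::bind_rows()
    })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$fragment_id)
  if (fdr) {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  attr(out, "alpha") <- alpha
  attr(out, "variant") <- variant
  class(out) <- c("mpra_diff", class(out))
  out
}

#' Summarize allele-specific activity evidence per variant
#'
#' A fragment that tests significant implicates every variant whose allele
#' differs from reference in that fragment; constructs are classed by how
#' many such variants they carry (single / double / triple / higher).
#' Single-variant evidence is reported separately so variants can be
#' prioritized on unconfounded constructs.
#'
#' @param results An `mpra_diff` tibble from [test_fragments()].
#' @param design The fragment design table used for testing (to check that
#'   every result fragment is known).
#' @param alpha Significance level; defaults to the level stored on
#'   `results`.
#' @return A tibble with one row per variant: `variant`, `n_fragments`,
#'   `n_significant`, `any_significant`, `significant_single` (significant
#'   in a single-variant construct), `construct_classes` (classes of the
#'   significant constructs), `best_p`, `best_effect`.
#' @export
summarize_variants <- function(results, design, alpha = NULL) {
  alpha <- alpha %||% attr(results, "alpha") %||% 0.05
  design <- tibble::as_tibble(design)
  unknown <- setdiff(results$fragment_id, design$fragment_id)
  if (length(unknown)) {
    stop("results reference fragments absent from the design: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  tested <- results |> dplyr::filter(.data$status == "ok")
  long <- tested |>
    dplyr::mutate(construct_class = construct_class(.data$n_variant_sites)) |>
    dplyr::select("fragment_id", "variant_sites", "construct_class",
                  "effect", "p_value", "significant") |>
    tidyr::unnest_longer("variant_sites", values_to = "variant")
  long |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n_fragments = dplyr::n(),
      n_significant = sum(.data$significant),
      any_significant = any(.data$significant),
      significant_single = any(.data$significant &
                                 .data$construct_class == "single"),
      construct_classes = list(sort(unique(
        .data$construct_class[.data$significant]))),
      best_p = min(.data$p_value),
      best_effect = .data$effect[which.min(.data$p_value)],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$variant)
}

construct_class <- function(n_sites) {
  dplyr::case_when(
    n_sites == 1L ~ "single",
    n_sites == 2L ~ "double",
    n_sites == 3L ~ "triple",
    TRUE ~ "higher"
  )
}

#' Count significant reporter constructs by class
#'
#' Tallies how many tested fragments ("reporter constructs") with
#' significant allele-specific activity carried one, two or three variant
#' alleles. `by = "window"` counts windows with at least one significant
#' fragment instead, classing each window by its significant fragment with
#' the fewest variant sites.
#'
#' @param results An `mpra_diff` tibble.
#' @param by `"fragment"` (default) or `"window"`.
#' @return A tibble with `construct_class` and `n`.
#' @export
construct_class_counts <- function(results, by = c("fragment", "window")) {
  by <- match.arg(by)
  sig <- results |>
    dplyr::filter(.data$status == "ok", .data$significant) |>
    dplyr::mutate(construct_class = construct_class(.data$n_variant_sites))
  if (by == "window") {
    sig <- sig |>
      dplyr::group_by(.data$center_variant) |>
      dplyr::slice_min(.data$n_variant_sites, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  sig |>
    dplyr::count(.data$construct_class, name = "n") |>
    dplyr::arrange(factor(.data$construct_class,
                          levels = c("single", "double", "triple", "higher")))
}

#' Tidy / summarize allele-specific test results
#' @param x An `mpra_diff` tibble.
#' @param ... Unused.
#' @method tidy mpra_diff
#' @export
tidy.mpra_diff <- function(x, ...) {
  tibble::as_tibble(x)[, c("fragment_id", "reference_fragment_id",
                           "center_variant", "status", "n_test", "n_ref",
                           "effect", "statistic", "p_value", "significant",
                           "n_variant_sites")]
}

#' @rdname tidy.mpra_diff
#' @method glance mpra_diff
#' @export
glance.mpra_diff <- function(x, ...) {
  tested <- x[x$status == "ok", ]
  tibble::tibble(
    n_fragments = nrow(x),
    n_tested = nrow(tested),
    n_significant = sum(tested$significant),
    alpha = attr(x, "alpha"),
    variant = attr(x, "variant")
  )
}
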