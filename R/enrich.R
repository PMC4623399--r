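category_members <- function(category_map, category, universe) {
  stopifnot(is.data.frame(category_map))
  if (!category %in% category_map$category) {
    abort(paste0("category not in map: ", category),
          class = "energyomics_domain_error")
  }
  feats <- unique(category_map$feature_id[category_map$category == category])
  dropped <- setdiff(feats, universe)
  if (length(dropped) > 0) {
    warn(sprintf("%d mapped feature(s) of '%s' absent from the universe; dropped.",
                 length(dropped), category))
  }
  members <- intersect(feats, universe)
  if (length(members) == 0) {
    abort(paste0("category has no members in the analyzed universe: ",
                 category),
          class = "energyomics_domain_error")
  }
  members
}

#' Fisher's exact test for category overrepresentation
#'
#' One-sided (upper-tail hypergeometric) test of whether differentially
#' expressed features are overrepresented in a functional category relative
#' to the background of all tested features, via the 2 x 2 table
#' category/non-category x DE/non-DE.
#'
#' @param data Data frame with columns `feature_id` and logical `de`; the
#'   rows define the universe.
#' @param category_map Two-column data frame `feature_id`, `category`
#'   (hierarchical bin labels joined by `.`; a feature may map to several
#'   categories).
#' @param category Category label to test.
#' @return One-row tibble: `category`, `n_in`, `n_out`, `de_in`, `de_out`,
#'   `fisher_p`.
#' @export
fisher_overrep <- function(data, category_map, category) {
  stopifnot(is.data.frame(data),
            all(c("feature_id", "de") %in% names(data)))
  members <- category_members(category_map, category, data$feature_id)
  in_cat <- data$feature_id %in% members
  tab <- table(factor(in_cat, levels = c(TRUE, FALSE)),
               factor(data$de, levels = c(TRUE, FALSE)))
  p <- fisher.test(tab, alternative = "greater")$p.value
  tibble::tibble(category = category,
                 n_in = sum(in_cat), n_out = sum(!in_cat),
                 de_in = sum(in_cat & data$de),
                 de_out = sum(!in_cat & data$de),
                 fisher_p = p)
}

#' Wilcoxon rank-sum test for a category's expression shift
#'
#' Two-sided rank-sum test of the log2 fold changes of category members
#' against all non-members. The exact null distribution is used for
#' categories of up to `exact_max_n` members when the data are tie-free;
#' larger categories (or ties) use the normal approximation with tie
#' correction. Direction is the sign of the member-vs-complement median
#' difference.
#'
#' @param data Data frame with columns `feature_id` and `log2fc`.
#' @param category_map,category As in [fisher_overrep()].
#' @param exact_max_n Largest category size for the exact branch (default 10).
#' @return One-row tibble: `category`, `n_in`, `n_out`, `statistic` (rank-sum
#'   W), `wilcoxon_p`, `median_log2fc`, `median_shift`, `direction`.
#' @export
wilcoxon_shift <- function(data, category_map, category, exact_max_n = 10) {
  stopifnot(is.data.frame(data),
            all(c("feature_id", "log2fc") %in% names(data)))
  members <- category_members(category_map, category, data$feature_id)
  in_cat <- data$feature_id %in% members
  v_in <- data$log2fc[in_cat]
  v_out <- data$log2fc[!in_cat]
  if (length(v_out) == 0) {
    abort("category equals the universe; no complement to compare against.",
          class = "energyomics_domain_error")
  }
  has_ties <- anyDuplicated(c(v_in, v_out)) > 0
  use_exact <- length(v_in) <= exact_max_n && !has_ties
  fit <- suppressWarnings(
    wilcox.test(v_in, v_out, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  shift <- median(v_in) - median(v_out)
  tibble::tibble(category = category,
                 n_in = length(v_in), n_out = length(v_out),
                 statistic = unname(fit$statistic),
                 wilcoxon_p = fit$p.value,
                 median_log2fc = median(v_in),
                 median_shift = shift,
                 direction = dplyr::case_when(shift > 0 ~ "up",
                                              shift < 0 ~ "down",
                                              .default = "none"))
}

#' Joint Fisher/Wilcoxon enrichment over all categories
#'
#' Runs [fisher_overrep()] and [wilcoxon_shift()] for every category in the
#' map and flags categories significant at `alpha` (default raw P < 0.01 on
#' either test, no multiple-testing correction — the PageMan-style
#' convention; set `adjust = "BH"` to correct each test family instead).
#'
#' @param data Data frame with `feature_id`, `de` (logical) and `log2fc`.
#' @param category_map Two-column feature-to-bin map.
#' @param alpha Significance threshold (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param timepoint Optional label copied into the result (for assembling
#'   per-timepoint matrices).
#' @return Tibble, one row per category, with both test p-values, the median
#'   member log2fc, the shift direction and a `significant` flag.
#' @export
enrich_categories <- function(data, category_map, alpha = 0.01,
                              adjust = c("none", "BH"), timepoint = NA) {
  adjust <- match.arg(adjust)
  cats <- unique(category_map$category)
  res <- purrr::map_dfr(cats, function(cc) {
    f <- fisher_overrep(data, category_map, cc)
    w <- wilcoxon_shift(data, category_map, cc)
    dplyr::bind_cols(f, dplyr::select(w, -"category", -"n_in", -"n_out"))
  })
  if (adjust == "BH") {
    res$fisher_p <- bh_fdr(res$fisher_p)
    res$wilcoxon_p <- bh_fdr(pmin(pmax(res$wilcoxon_p, .Machine$double.xmin), 1))
  }
  res |>
    dplyr::mutate(timepoint = timepoint,
                  significant = .data$fisher_p < alpha |
                    .data$wilcoxon_p < alpha) |>
    dplyr::relocate("timepoint")
}

#' Category-by-timepoint enrichment matrix
#'
#' Condenses per-timepoint enrichment results into a categories x timepoints
#' table of median log2 fold changes, with a parallel significance-flag
#' column per timepoint — the tabular equivalent of a condensed PageMan
#' false-color display.
#'
#' @param results Row-bound [enrich_categories()] outputs with distinct
#'   `timepoint` labels.
#' @return Tibble: `category`, one `log2fc_<t>` and one `sig_<t>` column per
#'   timepoint.
#' @export
enrichment_matrix <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("category", "timepoint", "median_log2fc", "significant")
                %in% names(results)))
  results |>
    dplyr::select("category", "timepoint", "median_log2fc", "significant") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("median_log2fc", "significant"),
                       names_glue = "{ifelse(.value == 'median_log2fc', 'log2fc', 'sig')}_{timepoint}")
}

#' Synthetic functional-category map
#'
#' Assigns features at random to `n_bins` equally sized hierarchical bins
#' (`bin.1` ... `bin.k`) — a synthetic stand-in for a MapMan/PageMan-style
#' ontology, which is user-supplied data in real analyses.
#'
#' @param feature_ids Character vector of features to bin.
#' @param n_bins Number of bins (default 20).
#' @param seed RNG seed.
#' @return Two-column tibble `feature_id`, `category`.
#' @export
gen_category_map <- function(feature_ids, n_bins = 20, seed = 1L) {
  stopifnot(n_bins >= 1, length(feature_ids) >= n_bins)
  set.seed(as.integer(seed))
  shuffled <- sample(feature_ids)
  tibble::tibble(
    feature_id = shuffled,
    category = paste0("bin.", rep_len(seq_len(n_bins), length(shuffled)))
  ) |>
    dplyr::arrange(.data$feature_id)
}
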