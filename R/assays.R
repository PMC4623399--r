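ENERGY_ANALYTES <- c("ATP", "ADP", "NADP+", "NADPH")

#' Internal-standard / fresh-weight normalization of GC-MS peak heights
#'
#' Each metabolite peak height is divided by the ribitol (internal standard)
#' peak height of the same run and by the fresh weight of the extracted
#' tissue: `value = peak_height / ribitol_height / fresh_weight`, a relative
#' response per gram fresh weight.
#'
#' @param records Data frame with columns `peak_height`, `ribitol_height`
#'   (> 0) and `fresh_weight` (g, > 0).
#' @return `records` as a tibble with a `value` column appended.
#' @examples
#' normalize_gcms(tibble::tibble(metabolite = "sucrose", peak_height = 1000,
#'                               ribitol_height = 500, fresh_weight = 0.05))
#' @export
normalize_gcms <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("peak_height", "ribitol_height", "fresh_weight"),
                          names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(records$ribitol_height <= 0 | records$fresh_weight <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive ribitol height or fresh weight in record(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "energyomics_record_error")
  }
  tibble::as_tibble(records) |>
    dplyr::mutate(value = .data$peak_height / .data$ribitol_height /
                    .data$fresh_weight)
}

#' Scale values relative to a reference group mean
#'
#' Divides every value by the mean of the reference group (by default wild
#' type at 0 h) computed separately for each analyte, so the reference group
#' averages exactly 1. Metabolites whose reference mean is zero are flagged
#' and their scaled values set to missing.
#'
#' @param data Data frame with `value` plus grouping columns.
#' @param by Column(s) defining the analyte (default `"metabolite"`).
#' @param ref Named list selecting the reference group, default
#'   `list(genotype = "WT", timepoint = "0h")`.
#' @return `data` with `rel_value` appended (reference mean maps to 1) and a
#'   logical `ref_flagged` column marking analytes with zero reference mean.
#' @export
relative_to_reference_group <- function(data, by = "metabolite",
                                        ref = list(genotype = "WT",
                                                   timepoint = "0h")) {
  stopifnot(is.data.frame(data), "value" %in% names(data))
  in_ref <- rep(TRUE, nrow(data))
  for (col in names(ref)) in_ref <- in_ref & data[[col]] == ref[[col]]
  data <- tibble::as_tibble(data)
  data$.in_ref <- in_ref
  out <- data |>
    dplyr::mutate(
      .ref_mean = mean(.data$value[.data$.in_ref]),
      ref_flagged = !is.na(.data$.ref_mean) & .data$.ref_mean == 0,
      rel_value = dplyr::if_else(.data$ref_flagged, NA_real_,
                                 .data$value / .data$.ref_mean),
      .by = dplyr::all_of(by)
    )
  if (any(out$ref_flagged)) {
    warn(sprintf("%d analyte group(s) have zero reference mean; values set to NA.",
                 dplyr::n_distinct(out[out$ref_flagged, by])))
  }
  dplyr::select(out, -".in_ref", -".ref_mean")
}

#' Energy-status ratios and sums from an ATP/ADP/NADP(H) panel
#'
#' From replicate measurements of ATP, ADP, NADP+ and NADPH (nmol per g
#' fresh weight) derives, per genotype x timepoint x replicate: ATP/ADP,
#' ATP + ADP, NADPH/NADP+, NADP+ + NADPH and ATP/NADPH. Ratios are taken on
#' per-replicate values (preserving replicate-level variance for SD), then
#' typically summarized with [summarize_assay()]. A zero-denominator
#' replicate yields a missing ratio for that replicate only.
#'
#' @param panel Long data frame: `analyte` (one of ATP, ADP, NADP+, NADPH),
#'   `genotype`, `timepoint`, `replicate`, `value`.
#' @param ratio_of_means If `TRUE`, compute ratios of group means instead of
#'   per-replicate ratios (one row per genotype x timepoint).
#' @return Long tibble: `genotype`, `timepoint`, `replicate`, `analyte`
#'   (derived quantity name), `value`.
#' @export
derive_energy_ratios <- function(panel, ratio_of_means = FALSE) {
  stopifnot(is.data.frame(panel))
  bad <- setdiff(unique(panel$analyte), ENERGY_ANALYTES)
  if (length(bad) > 0) {
    abort(paste0("unknown analyte(s): ", paste(bad, collapse = ", "),
                 "; expected ", paste(ENERGY_ANALYTES, collapse = ", ")),
          class = "energyomics_domain_error")
  }
  grp <- if (ratio_of_means) c("genotype", "timepoint")
         else c("genotype", "timepoint", "replicate")
  wide <- panel |>
    dplyr::summarise(value = mean(.data$value),
                     .by = dplyr::all_of(c(grp, "analyte"))) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  safe_div <- function(num, den) dplyr::if_else(den == 0, NA_real_, num / den)
  wide |>
    dplyr::mutate(
      `ATP/ADP` = safe_div(.data$ATP, .data$ADP),
      `ATP+ADP` = .data$ATP + .data$ADP,
      `NADPH/NADP+` = safe_div(.data$NADPH, .data$`NADP+`),
      `NADP++NADPH` = .data$`NADP+` + .data$NADPH,
      `ATP/NADPH` = safe_div(.data$ATP, .data$NADPH)
    ) |>
    dplyr::select(-dplyr::all_of(ENERGY_ANALYTES)) |>
    tidyr::pivot_longer(-dplyr::all_of(grp), names_to = "analyte",
                        values_to = "value")
}

#' Replicate summary (mean, SD, SE, n)
#'
#' @param data Long data frame with a `value` column.
#' @param by Grouping columns.
#' @return One row per group with `n`, `mean`, `sd`, `se`.
#' @export
summarize_assay <- function(data, by = c("analyte", "genotype", "timepoint")) {
  stopifnot(is.data.frame(data))
  data |>
    dplyr::summarise(n = sum(!is.na(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     se = .data$sd / sqrt(.data$n),
                     .by = dplyr::all_of(intersect(by, names(data))))
}

#' Two-sample t-test with significance stars
#'
#' Welch's unequal-variance t-test by default (`var_equal = FALSE`); the
#' pooled-variance Student test is available since with n = 3 per group the
#' two can differ appreciably. Stars follow the usual convention: `*` for
#' p < 0.05, `**` for p < 0.01.
#'
#' @param a,b Numeric vectors of replicate values for the two groups.
#' @param var_equal Pool the variances (classical Student test)?
#' @param two_tailed Two-sided alternative (default) or upper-tailed.
#' @return One-row tibble: `t`, `df`, `p`, `stars`.
#' @examples
#' two_sample_t(c(10, 11, 9), c(20, 21, 19), var_equal = TRUE)
#' @export
two_sample_t <- function(a, b, var_equal = FALSE, two_tailed = TRUE) {
  fit <- t.test(a, b, var.equal = var_equal,
                alternative = if (two_tailed) "two.sided" else "greater")
  p <- unname(fit$p.value)
  tibble::tibble(t = unname(fit$statistic), df = unname(fit$parameter),
                 p = p, stars = star_string(p))
}

star_string <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Per-analyte group contrasts across a long assay table
#'
#' Runs [two_sample_t()] for each analyte (and any further stratification
#' columns) between two levels of a grouping column, e.g. OE vs WT within
#' each timepoint.
#'
#' @param data Long data frame with a `value` column.
#' @param group_col Column naming the two groups (default `"genotype"`).
#' @param levels Character vector of length 2: groups compared as
#'   `levels[2]` vs `levels[1]` (t > 0 means the second is larger).
#' @param by Stratification columns (default analyte and timepoint).
#' @param var_equal Passed to [two_sample_t()].
#' @return One row per stratum: means of both groups, `t`, `df`, `p`, `stars`.
#' @export
compare_groups <- function(data, group_col = "genotype",
                           levels = c("WT", "OE"),
                           by = c("analyte", "metabolite", "timepoint"),
                           var_equal = FALSE) {
  stopifnot(is.data.frame(data), "value" %in% names(data))
  by <- intersect(by, names(data))
  data |>
    dplyr::filter(.data[[group_col]] %in% levels, !is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d[[group_col]] == levels[1]]
      b <- d$value[d[[group_col]] == levels[2]]
      res <- two_sample_t(b, a, var_equal = var_equal)
      dplyr::bind_cols(tibble::tibble(mean_ref = mean(a), mean_alt = mean(b)),
                       res)
    }) |>
    dplyr::ungroup()
}

#' Relative expression by the comparative threshold (delta-delta-Ct) method
#'
#' Per target gene: the replicate-level delta-Ct is `ct_target -
#' ct_reference` (reference gene playing the Actin-2 role); `ddct` is the
#' mean delta-Ct of the treatment group minus that of the control group, and
#' the relative fold change is `2^-ddct`. Relative abundances (group means of
#' `2^-dCt`) are rescaled so the maximum across the compared groups is 1.
#' Significance comes from a two-tailed paired t-test on per-replicate
#' delta-Ct pairs, pairing replicates by index; unequal replicate counts are
#' an error.
#'
#' @param records Data frame with columns `gene` (optional; one test per
#'   gene), `group` (`"treatment"` / `"control"`), `replicate`, `ct_target`,
#'   `ct_reference`. Ct values outside 10-40 cycles trigger a warning.
#' @return Tibble, one row per gene: `ddct`, `fold`, `rel_treatment`,
#'   `rel_control`, `t`, `df`, `p`, `stars`.
#' @examples
#' rec <- tibble::tibble(group = rep(c("treatment", "control"), each = 3),
#'                       replicate = rep(1:3, 2),
#'                       ct_target = c(25, 25, 25, 27, 27, 27),
#'                       ct_reference = 20)
#' ddct_relative_expression(rec) # fold = 4
#' @export
ddct_relative_expression <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("group", "replicate", "ct_target", "ct_reference"),
                          names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cts <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(cts))) {
    abort("Ct values must be finite.", class = "energyomics_domain_error")
  }
  if (any(cts < 10 | cts > 40)) {
    warn("Ct values outside the typical 10-40 cycle range.")
  }
  if (!"gene" %in% names(records)) records$gene <- "target"
  records |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference) |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      trt <- d |> dplyr::filter(.data$group == "treatment") |>
        dplyr::arrange(.data$replicate)
      ctl <- d |> dplyr::filter(.data$group == "control") |>
        dplyr::arrange(.data$replicate)
      if (nrow(trt) != nrow(ctl)) {
        abort("paired delta-delta-Ct test needs equal replicate counts per group.",
              class = "energyomics_domain_error")
      }
      ddct <- mean(trt$dct) - mean(ctl$dct)
      rel <- 2^(-c(treatment = mean(trt$dct), control = mean(ctl$dct)))
      rel <- rel / max(rel)
      diffs <- trt$dct - ctl$dct
      if (sd(diffs) == 0) {
        t_stat <- NA_real_; df <- length(diffs) - 1; p <- NA_real_
      } else {
        fit <- t.test(trt$dct, ctl$dct, paired = TRUE)
        t_stat <- unname(fit$statistic); df <- unname(fit$parameter)
        p <- unname(fit$p.value)
      }
      tibble::tibble(ddct = ddct, fold = 2^(-ddct),
                     rel_treatment = rel[["treatment"]],
                     rel_control = rel[["control"]],
                     t = t_stat, df = df, p = p, stars = star_string(p))
    }) |>
    dplyr::ungroup()
}
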