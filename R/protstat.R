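PROTEIN_TIERS <- c(1.2, 1.33, 1.5)

#' Filter iTRAQ protein identifications
#'
#' Keeps proteins with an unused ProtScore of at least `min_unused` and at
#' least `min_peptides` peptides at >= 95 % confidence — both boundaries
#' inclusive. Defaults are the conventional identification cutoffs (1.3
#' unused score, two peptides).
#'
#' @param records Data frame with columns `unused_score`, `n_peptides_95`.
#' @param min_unused Minimum unused ProtScore (default 1.3).
#' @param min_peptides Minimum peptide count at >= 95 % confidence (default 2).
#' @return The filtered tibble.
#' @export
filter_identifications <- function(records, min_unused = 1.3,
                                   min_peptides = 2) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("unused_score", "n_peptides_95"), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(records) |>
    dplyr::filter(.data$unused_score >= min_unused,
                  .data$n_peptides_95 >= min_peptides)
}

#' One-sample t-test of replicate ratios against an assumed fold change
#'
#' `t = (mean(ratios) - mu0) / (s / sqrt(n))` with `s` the sample standard
#' deviation (n - 1 denominator); the one-tailed p-value is the upper-tail
#' Student-t probability at `n - 1` degrees of freedom for `tail = "upper"`
#' (testing up-regulation beyond `mu0`), the lower tail for
#' `tail = "lower"`. With four replicate ratios the test has 3 degrees of
#' freedom.
#'
#' Zero-variance input is degenerate: `t` and `p` are returned as `NA` with
#' `degenerate = TRUE`, and such proteins are never called significant.
#'
#' @param ratios Numeric vector of replicate abundance ratios (> 0).
#' @param mu0 Assumed null fold change (e.g. 1.2, 1.33 or 1.5).
#' @param tail `"upper"` or `"lower"`.
#' @return One-row tibble: `mean_ratio`, `sd`, `df`, `t`, `p_one_tailed`,
#'   `degenerate`.
#' @examples
#' one_sample_t(c(1.3, 1.4, 1.5, 1.6), mu0 = 1.2) # t = 3.873
#' @export
one_sample_t <- function(ratios, mu0, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (any(ratios <= 0)) {
    abort("replicate ratios must be positive.",
          class = "energyomics_domain_error")
  }
  n <- length(ratios)
  if (n < 2) abort("need at least two replicate ratios.")
  m <- mean(ratios)
  s <- sd(ratios)
  if (s == 0) {
    inform(sprintf("zero-variance ratios (all %.4g): degenerate t-test.", m))
    return(tibble::tibble(mean_ratio = m, sd = 0, df = n - 1,
                          t = NA_real_, p_one_tailed = NA_real_,
                          degenerate = TRUE))
  }
  tval <- (m - mu0) / (s / sqrt(n))
  p <- pt(tval, df = n - 1, lower.tail = (tail == "lower"))
  tibble::tibble(mean_ratio = m, sd = s, df = n - 1, t = tval,
                 p_one_tailed = p, degenerate = FALSE)
}

#' Tiered differential-abundance calls for iTRAQ protein ratios
#'
#' For each protein the four replicate OE/WT ratios are tested against each
#' assumed fold-change tier `mu0` in `tiers` (defaults 1.2, 1.33, 1.5): the
#' protein is called `up` at a tier when its mean ratio exceeds `mu0` and the
#' upper-tailed one-sample t-test against `mu0` gives `p < alpha`. For
#' suppression, with `down = "reciprocal"` (default) the mean must fall below
#' `1/mu0` with the lower-tailed test against `1/mu0` significant —
#' symmetric on the log scale; `down = "lower_tail"` instead tests the lower
#' tail against `mu0` itself. No multiple-testing correction is applied
#' across proteins: each is judged at raw `p < alpha`, matching common
#' practice for tiered iTRAQ screens (interpret tallies accordingly).
#'
#' @param records Data frame with `protein_id` and the four ratio columns
#'   `ratio_r1` ... `ratio_r4`.
#' @param alpha Per-protein significance level (default 0.05).
#' @param tiers Assumed null fold changes.
#' @param down `"reciprocal"` or `"lower_tail"` (see above).
#' @return Tibble of class `protein_de`, one row per protein x tier:
#'   `protein_id`, `mean_ratio`, `sd`, `df`, `tier`, `t_up`, `p_up`,
#'   `t_down`, `p_down`, `call`.
#' @export
call_protein_de <- function(records, alpha = 0.05, tiers = PROTEIN_TIERS,
                            down = c("reciprocal", "lower_tail")) {
  down <- match.arg(down)
  stopifnot(is.data.frame(records))
  ratio_cols <- paste0("ratio_r", 1:4)
  missing_cols <- setdiff(c("protein_id", ratio_cols), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rmat <- as.matrix(records[ratio_cols])
  if (any(rmat <= 0)) {
    abort("replicate ratios must be positive.",
          class = "energyomics_domain_error")
  }
  n <- ncol(rmat)
  m <- rowMeans(rmat)
  s <- apply(rmat, 1, sd)
  base <- tibble::tibble(protein_id = records$protein_id,
                         mean_ratio = m, sd = s, df = n - 1)
  purrr::map_dfr(tiers, function(mu0) {
    mu0_down <- if (down == "reciprocal") 1 / mu0 else mu0
    t_up <- (m - mu0) / (s / sqrt(n))
    t_down <- (m - mu0_down) / (s / sqrt(n))
    p_up <- pt(t_up, df = n - 1, lower.tail = FALSE)
    p_down <- pt(t_down, df = n - 1, lower.tail = TRUE)
    degenerate <- s == 0
    t_up[degenerate] <- t_down[degenerate] <- NA_real_
    p_up[degenerate] <- p_down[degenerate] <- NA_real_
    call <- rep("ns", length(m))
    ok <- !degenerate
    call[ok & m > mu0 & p_up < alpha] <- "up"
    call[ok & m < mu0_down & p_down < alpha] <- "down"
    dplyr::mutate(base, tier = mu0, t_up = t_up, p_up = p_up,
                  t_down = t_down, p_down = p_down, call = call)
  }) -> out
  structure(out, class = c("protein_de", class(out)),
            alpha = alpha, down = down)
}
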