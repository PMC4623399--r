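#' Benjamini-Hochberg FDR q-values
#'
#' Step-up multiple-testing adjustment: for ascending p-values the q-value of
#' the i-th is `min over j >= i of p_(j) * m / j`, mapped back to input
#' order. Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.8))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1] with no missing values.",
          class = "energyomics_domain_error")
  }
  p.adjust(p, method = "BH")
}

#' Library-size-normalized fold change between two libraries
#'
#' `FC = (y / N2) / (x / N1)`, the ratio of normalized abundances (equivalent
#' to the RPKM ratio, since gene length cancels within a gene). Genes absent
#' from one library get sentinel values so extinction events still pass a
#' fold-change filter: `Inf` when `x = 0, y > 0`, `0` when `y = 0, x > 0`,
#' and `1` when both counts are zero.
#'
#' @inheritParams ac_two_sided_p
#' @return Numeric vector of fold changes (second library over first).
#' @examples
#' fold_change(100, 400, 1e7, 1e7) # 4
#' fold_change(1300, 0, 1e7, 1e7)  # 0: extinguished in library 2
#' @export
fold_change <- function(x, y, n1, n2) {
  fc <- (y / n2) / (x / n1)
  fc[x == 0 & y > 0] <- Inf
  fc[y == 0 & x > 0] <- 0
  fc[x == 0 & y == 0] <- 1
  fc
}

#' Differential-expression calls for a two-library contrast
#'
#' Runs the exact two-library Poisson test on every gene, adjusts p-values by
#' Benjamini-Hochberg, computes library-size-normalized fold changes, and
#' calls a gene `up` when `q <= alpha` and `FC > fc_threshold`, `down` when
#' `q <= alpha` and `FC < 1/fc_threshold`, and `ns` otherwise. The defaults
#' are the genome-wide thresholds FDR <= 0.001 and fold change > 2; organellar
#' contrasts are typically rerun with `fc_threshold = 1.5`.
#'
#' Genes with zero counts in both libraries are undetected rather than
#' non-significant: they are excluded from testing (and from the BH family);
#' their number is kept in the `n_undetected` attribute.
#'
#' @param data Data frame with one row per gene and columns `gene_id` plus
#'   the two count columns named by `x` and `y`.
#' @param n1,n2 Total clean read counts of the libraries behind `x` and `y`.
#' @param alpha FDR significance level (default 0.001).
#' @param fc_threshold Fold-change threshold, usually 2 or 1.5.
#' @param x,y Names of the count columns for libraries 1 and 2 (defaults
#'   `"wt"` and `"oe"`).
#' @param upper_tail_includes_y Passed to [ac_two_sided_p()].
#' @return A tibble of class `de_results` with columns `gene_id`, `x`, `y`,
#'   `fc`, `log2fc`, `p`, `q`, `call` and attributes `alpha`, `fc_threshold`,
#'   `n1`, `n2`, `n_undetected`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), wt = c(50L, 100L),
#'                          oe = c(800L, 100L))
#' call_de_table(counts, n1 = 1e7, n2 = 1e7)
#' @export
call_de_table <- function(data, n1, n2, alpha = 0.001, fc_threshold = 2,
                          x = "wt", y = "oe",
                          upper_tail_includes_y = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("gene_id", x, y), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (alpha <= 0 || fc_threshold <= 0) {
    abort("`alpha` and `fc_threshold` must be positive.")
  }
  xs <- data[[x]]
  ys <- data[[y]]
  detected <- xs + ys > 0
  res <- tibble::tibble(gene_id = data$gene_id[detected],
                        x = xs[detected], y = ys[detected])
  res$fc <- fold_change(res$x, res$y, n1, n2)
  res$log2fc <- log2(res$fc)
  res$p <- ac_two_sided_p(res$x, res$y, n1, n2,
                          upper_tail_includes_y = upper_tail_includes_y)
  res$q <- bh_fdr(res$p)
  res$call <- dplyr::case_when(
    res$q <= alpha & res$fc > fc_threshold ~ "up",
    res$q <= alpha & res$fc < 1 / fc_threshold ~ "down",
    .default = "ns"
  )
  structure(res,
            class = c("de_results", class(res)),
            alpha = alpha, fc_threshold = fc_threshold,
            n1 = n1, n2 = n2, n_undetected = sum(!detected))
}
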