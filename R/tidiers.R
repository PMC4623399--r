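#' Tidy and summarize differential-expression results
#'
#' `tidy()` returns the per-gene table as a plain tibble; `glance()` gives a
#' one-row summary of the contrast (features tested, up/down calls,
#' thresholds, undetected genes).
#'
#' @param x A `de_results` object from [call_de_table()].
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.de_results <- function(x, ...) {
  tibble::as_tibble(unclass_results(x))
}

#' @rdname tidy.de_results
#' @exportS3Method generics::glance
glance.de_results <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x),
                 n_up = sum(x$call == "up"),
                 n_down = sum(x$call == "down"),
                 n_undetected = attr(x, "n_undetected"),
                 alpha = attr(x, "alpha"),
                 fc_threshold = attr(x, "fc_threshold"))
}

#' Tidy and summarize tiered protein test results
#'
#' `tidy()` returns the per-protein-per-tier table as a plain tibble;
#' `glance()` gives one row per tier with up/down call counts.
#'
#' @param x A `protein_de` object from [call_protein_de()].
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.protein_de <- function(x, ...) {
  tibble::as_tibble(unclass_results(x))
}

#' @rdname tidy.protein_de
#' @exportS3Method generics::glance
glance.protein_de <- function(x, ...) {
  out <- de_summary_counts(x, by = "tier")
  out$alpha <- attr(x, "alpha")
  out
}

unclass_results <- function(x) {
  class(x) <- setdiff(class(x), c("de_results", "protein_de",
                                  "gene_type_summary"))
  attr(x, "alpha") <- NULL
  attr(x, "fc_threshold") <- NULL
  attr(x, "n1") <- NULL
  attr(x, "n2") <- NULL
  attr(x, "n_undetected") <- NULL
  attr(x, "down") <- NULL
  x
}

#' @export
print.de_results <- function(x, ...) {
  cat(sprintf(
    "Two-library exact Poisson DE contrast: %d genes tested (FDR <= %g, FC > %g)\n",
    nrow(x), attr(x, "alpha"), attr(x, "fc_threshold")))
  cat(sprintf("  up: %d   down: %d   undetected (excluded): %d\n",
              sum(x$call == "up"), sum(x$call == "down"),
              attr(x, "n_undetected")))
  print(tidy(x), ...)
  invisible(x)
}
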