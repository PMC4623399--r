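COMPARTMENTS <- c("nuclear", "mitochondrial", "chloroplast")
GENE_TYPES <- c("protein_coding", "pre_tRNA", "rRNA", "snRNA", "snoRNA",
                "miRNA", "other_RNA", "pseudogene", "TE")
COMPARTMENT_LABELS <- c(nuclear = "Chr1-5", mitochondrial = "ATMG",
                        chloroplast = "ATCG")

#' RPKM expression values per gene per library
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = 1e9 * C / (N * L)` with `C` the reads on the gene, `N` the
#' library's total mappable reads and `L` the gene length in bp. `N` is each
#' library's own total — typically larger than the column sum, since it
#' includes reads mapped outside the annotated gene set.
#'
#' @param counts Data frame with a `gene_id` column and one integer count
#'   column per library.
#' @param annot Gene annotation: data frame with columns `gene_id`,
#'   `compartment`, `gene_type`, `length_bp`. Every gene in `counts` must be
#'   annotated.
#' @param lib_sizes Named numeric vector of total mappable reads, names
#'   matching the count columns. Defaults to the `library_sizes` attribute of
#'   `counts` if present, else (with a warning) to the column sums.
#' @return Long tibble: `gene_id`, `library`, `count`, `length_bp`, `rpkm`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", wt = 100L, oe = 50L)
#' annot <- tibble::tibble(gene_id = "g1", compartment = "nuclear",
#'                         gene_type = "protein_coding", length_bp = 1000L)
#' compute_rpkm(counts, annot, lib_sizes = c(wt = 1e7, oe = 1e7))
#' @export
compute_rpkm <- function(counts, annot, lib_sizes = NULL) {
  stopifnot(is.data.frame(counts), is.data.frame(annot))
  count_cols <- setdiff(names(counts), "gene_id")
  if (is.null(lib_sizes)) lib_sizes <- attr(counts, "library_sizes")
  if (is.null(lib_sizes)) {
    warn("`lib_sizes` not supplied; using column sums as library totals.")
    lib_sizes <- colSums(counts[count_cols])
  }
  if (!all(count_cols %in% names(lib_sizes))) {
    abort("`lib_sizes` must carry a named total for every count column.")
  }
  if (any(lib_sizes[count_cols] <= 0)) {
    abort("library totals must be positive.",
          class = "energyomics_domain_error")
  }
  orphans <- setdiff(counts$gene_id, annot$gene_id)
  if (length(orphans) > 0) {
    abort(paste0("genes without annotation: ",
                 paste(head(orphans, 5), collapse = ", "),
                 if (length(orphans) > 5) sprintf(" (+%d more)", length(orphans) - 5)),
          class = "energyomics_annotation_error")
  }
  counts |>
    tidyr::pivot_longer(dplyr::all_of(count_cols),
                        names_to = "library", values_to = "count") |>
    dplyr::left_join(dplyr::select(annot, "gene_id", "length_bp"),
                     by = "gene_id") |>
    dplyr::mutate(
      rpkm = 1e9 * .data$count /
        (unname(lib_sizes[.data$library]) * .data$length_bp)
    )
}

#' Flag expressed genes
#'
#' A gene is expressed when its count reaches `min_count` in at least one
#' library. The threshold is explicit because detection criteria vary between
#' studies; the default of one read is the most permissive.
#'
#' @param expr Long expression tibble from [compute_rpkm()] (needs `gene_id`,
#'   `count`).
#' @param min_count Minimum count in at least one library (default 1).
#' @return `expr` with a logical `expressed` column (constant per gene).
#' @export
detect_expressed <- function(expr, min_count = 1) {
  stopifnot(is.data.frame(expr), min_count >= 0)
  expr |>
    dplyr::mutate(expressed = any(.data$count >= min_count),
                  .by = "gene_id")
}

#' Expressed-gene summary by compartment and gene type
#'
#' Cross-tabulates expressed genes by genome of origin (nuclear = Chr1-5,
#' mitochondrial = ATMG, chloroplast = ATCG) and gene type, with a `Total`
#' column and a `Total expressed genes` margin row. When `expr` is keyed by
#' transcript id the tallies are transcript-level.
#'
#' @param expr Expression tibble; rows with `expressed == FALSE` are dropped
#'   (if no `expressed` column, every gene counts).
#' @param annot Annotation covering all expressed genes.
#' @return Tibble with one row per compartment plus the margin row; attribute
#'   `total_expressed_genes` holds the grand total.
#' @export
summarize_gene_types <- function(expr, annot) {
  stopifnot(is.data.frame(expr), is.data.frame(annot))
  bad <- setdiff(unique(annot$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    abort(paste0("unknown compartment label(s): ", paste(bad, collapse = ", ")),
          class = "energyomics_annotation_error")
  }
  if ("expressed" %in% names(expr)) expr <- dplyr::filter(expr, .data$expressed)
  genes <- dplyr::distinct(expr, .data$gene_id) |>
    dplyr::inner_join(annot, by = "gene_id")
  tab <- genes |>
    dplyr::count(.data$compartment, .data$gene_type) |>
    tidyr::pivot_wider(names_from = "gene_type", values_from = "n",
                       values_fill = 0L)
  for (gt in GENE_TYPES) if (!gt %in% names(tab)) tab[[gt]] <- 0L
  for (cp in COMPARTMENTS) {
    if (!cp %in% tab$compartment) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(compartment = cp))
    }
  }
  tab[is.na(tab)] <- 0L
  tab <- tab[match(COMPARTMENTS, tab$compartment), c("compartment", GENE_TYPES)]
  tab$compartment <- unname(COMPARTMENT_LABELS[tab$compartment])
  tab$Total <- rowSums(tab[GENE_TYPES])
  margin <- tibble::tibble(compartment = "Total expressed genes")
  for (gt in c(GENE_TYPES, "Total")) margin[[gt]] <- sum(tab[[gt]])
  out <- dplyr::bind_rows(tab, margin) |>
    dplyr::relocate("Total", .after = "compartment")
  structure(out, total_expressed_genes = margin$Total,
            class = c("gene_type_summary", class(out)))
}

#' Split an expression table by genome of origin
#'
#' @param expr Expression tibble with `gene_id`.
#' @param annot Annotation with `gene_id` and `compartment`.
#' @return Named list of tibbles (`nuclear`, `mitochondrial`, `chloroplast`),
#'   a disjoint and exhaustive partition of the rows of `expr`.
#' @export
partition_by_compartment <- function(expr, annot) {
  stopifnot(is.data.frame(expr), is.data.frame(annot))
  joined <- dplyr::left_join(expr,
                             dplyr::select(annot, "gene_id", "compartment"),
                             by = "gene_id")
  if (anyNA(joined$compartment)) {
    abort("some genes in `expr` have no compartment annotation.",
          class = "energyomics_annotation_error")
  }
  out <- lapply(setNames(COMPARTMENTS, COMPARTMENTS), function(cp) {
    joined |>
      dplyr::filter(.data$compartment == cp) |>
      dplyr::select(-"compartment")
  })
  out
}
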