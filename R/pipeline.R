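#' Up/down tallies of differential-expression calls
#'
#' Counts `up` and `down` calls, optionally per stratum (e.g. per protein
#' tier or per contrast label), in the shape of a bar-chart summary of DE
#' features per comparison.
#'
#' @param results Data frame with a `call` column (`up`/`down`/`ns`).
#' @param by Optional stratification columns present in `results` (e.g.
#'   `"tier"`); defaults to any of `contrast`, `tier`, `timepoint` found.
#' @return Tibble with the stratification columns plus `n_up`, `n_down`,
#'   `n_tested`.
#' @export
de_summary_counts <- function(results, by = NULL) {
  stopifnot(is.data.frame(results), "call" %in% names(results))
  by <- by %||% intersect(c("contrast", "tier", "timepoint"), names(results))
  results |>
    dplyr::summarise(n_up = sum(.data$call == "up"),
                     n_down = sum(.data$call == "down"),
                     n_tested = dplyr::n(),
                     .by = dplyr::all_of(by))
}

#' Cross-omic correlation of transcript and protein fold changes
#'
#' Joins transcript- and protein-level log2 fold changes on a shared feature
#' id and reports their correlation; Spearman's rank correlation is the
#' default since the two layers live on different scales.
#'
#' @param transcripts Data frame with the id column and `log2fc`.
#' @param proteins Data frame with the id column and a log2 fold-change
#'   column (`log2fc`, or `mean_ratio` which is log2-transformed).
#' @param by Shared id column (default `"gene_id"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble: `estimate`, `n`, `p`, `method`.
#' @export
transcript_protein_correlation <- function(transcripts, proteins,
                                           by = "gene_id",
                                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(transcripts), is.data.frame(proteins))
  prot <- tibble::as_tibble(proteins)
  if (!"log2fc" %in% names(prot)) {
    if (!"mean_ratio" %in% names(prot)) {
      abort("`proteins` needs a `log2fc` or `mean_ratio` column.")
    }
    prot$log2fc <- log2(prot$mean_ratio)
  }
  joined <- dplyr::inner_join(
    dplyr::select(transcripts, dplyr::all_of(by), t_log2fc = "log2fc"),
    dplyr::select(prot, dplyr::all_of(by), p_log2fc = "log2fc"),
    by = by
  ) |>
    dplyr::filter(is.finite(.data$t_log2fc), is.finite(.data$p_log2fc))
  if (nrow(joined) < 3) abort("fewer than 3 matched features.")
  fit <- suppressWarnings(cor.test(joined$t_log2fc, joined$p_log2fc,
                                   method = method, exact = FALSE))
  tibble::tibble(estimate = unname(fit$estimate), n = nrow(joined),
                 p = fit$p.value, method = method)
}

#' Confusion matrix of DE calls against simulation truth
#'
#' @param de A [call_de_table()] result (or any table with `gene_id` and
#'   `call`).
#' @param truth Truth table with `gene_id`/`protein_id` and `true_status`.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `realized_fdr`, `power`.
#' @export
confusion_vs_truth <- function(de, truth) {
  id <- intersect(c("gene_id", "protein_id"), intersect(names(de),
                                                        names(truth)))[1]
  if (is.na(id)) abort("no shared id column between `de` and `truth`.")
  joined <- dplyr::inner_join(de, truth, by = id)
  called <- joined$call %in% c("up", "down")
  changed <- joined$true_status == "changed"
  tp <- sum(called & changed); fp <- sum(called & !changed)
  fn <- sum(!called & changed); tn <- sum(!called & !changed)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 realized_fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
                 power = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

write_tsv_out <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name), progress = FALSE)
}

#' Run the full synthetic tri-omic pipeline
#'
#' Generates a complete synthetic experiment from a [sim_config()] (or a
#' YAML/JSON config path), then runs every analysis stage: RPKM
#' quantification and expressed-gene summary, the exact two-library Poisson
#' DE test at both the genome-wide (FC > 2) and organellar (FC > 1.5)
#' thresholds, identification filtering plus tiered protein t-tests, GC-MS
#' normalization with reference-group scaling and OE-vs-WT contrasts,
#' energy-panel ratios and contrasts, delta-delta-Ct qPCR quantification,
#' and Fisher/Wilcoxon category enrichment over a synthetic bin map. All
#' stage outputs are written as TSV into `out_dir` together with a
#' machine-readable `summary.json`, a truth-aware confusion matrix and a
#' plain-text run log; outputs are byte-reproducible for a fixed config
#' seed.
#'
#' @param config A [sim_config()] or path to a YAML/JSON config file.
#' @param out_dir Output directory (created if missing).
#' @param alpha,fc_thresholds Transcript DE thresholds (FDR level and the
#'   two fold-change tiers).
#' @param protein_alpha Per-protein significance level.
#' @param n_bins Number of synthetic enrichment bins.
#' @return Invisibly, a list of all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir,
                         alpha = 0.001, fc_thresholds = c(2, 1.5),
                         protein_alpha = 0.05, n_bins = 20) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), parent = e)
    })
  }

  sim <- stage("simulate", {
    list(rna = gen_counts(config), prot = gen_itraq(config),
         metab = gen_metabolites(config), energy = gen_energy_panel(config),
         qpcr = gen_qpcr(config))
  })
  write_tsv_out(sim$rna$counts, out_dir, "counts.tsv")
  write_tsv_out(sim$rna$annotation, out_dir, "annotation.tsv")
  write_tsv_out(sim$rna$truth, out_dir, "truth.tsv")
  write_tsv_out(sim$prot$records, out_dir, "proteins.tsv")

  expr <- stage("quantify", {
    compute_rpkm(sim$rna$counts, sim$rna$annotation,
                 lib_sizes = config$library_sizes) |>
      detect_expressed()
  })
  write_tsv_out(expr, out_dir, "rpkm.tsv")
  gts <- stage("quantify", summarize_gene_types(expr, sim$rna$annotation))
  write_tsv_out(gts, out_dir, "summary.tsv")

  n1 <- config$library_sizes[["wt"]]
  n2 <- config$library_sizes[["oe"]]
  de <- stage("detest", {
    lapply(setNames(fc_thresholds, paste0("fc", fc_thresholds)),
           function(thr) call_de_table(sim$rna$counts, n1, n2,
                                       alpha = alpha, fc_threshold = thr))
  })
  for (nm in names(de)) write_tsv_out(de[[nm]], out_dir,
                                      paste0("de_", nm, ".tsv"))
  confusion <- stage("detest", confusion_vs_truth(de[[1]], sim$rna$truth))
  write_tsv_out(confusion, out_dir, "confusion.tsv")

  prot_de <- stage("protstat", {
    filter_identifications(sim$prot$records) |>
      call_protein_de(alpha = protein_alpha)
  })
  write_tsv_out(prot_de, out_dir, "protein_de.tsv")

  assays <- stage("assays", {
    metab <- normalize_gcms(sim$metab) |>
      relative_to_reference_group()
    list(metab = metab,
         metab_contrasts = compare_groups(metab),
         energy_ratios = derive_energy_ratios(sim$energy),
         energy_contrasts = compare_groups(
           dplyr::bind_rows(sim$energy[c("analyte", "genotype", "timepoint",
                                         "replicate", "value")],
                            derive_energy_ratios(sim$energy))),
         qpcr = ddct_relative_expression(sim$qpcr))
  })
  write_tsv_out(assays$metab, out_dir, "assays_normalized.tsv")
  write_tsv_out(assays$metab_contrasts, out_dir, "assay_contrasts.tsv")
  write_tsv_out(assays$energy_ratios, out_dir, "energy_ratios.tsv")
  write_tsv_out(assays$energy_contrasts, out_dir, "energy_contrasts.tsv")
  write_tsv_out(assays$qpcr, out_dir, "qpcr_ddct.tsv")

  enr <- stage("enrich", {
    bins <- gen_category_map(de[[1]]$gene_id, n_bins = n_bins,
                             seed = config$seed + 907L)
    d1 <- de[[1]]
    edata <- tibble::tibble(feature_id = d1$gene_id,
                            de = d1$call != "ns",
                            log2fc = pmax(pmin(d1$log2fc, 20), -20))
    enrich_categories(edata, bins)
  })
  write_tsv_out(enr, out_dir, "enrichment.tsv")

  summary_json <- list(
    seed = config$seed,
    thresholds = list(alpha = alpha, fc = fc_thresholds,
                      protein_alpha = protein_alpha),
    total_expressed_genes = attr(gts, "total_expressed_genes"),
    de_counts = lapply(de, function(d) as.list(de_summary_counts(d))),
    protein_counts = as.list(
      tidyr::pivot_wider(de_summary_counts(prot_de, by = "tier"),
                         names_from = "tier",
                         values_from = c("n_up", "n_down", "n_tested"))),
    confusion = as.list(confusion),
    n_significant_categories = sum(enr$significant)
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(
    paste0("energyomics version: ",
           as.character(utils::packageVersion("energyomics"))),
    paste0("seed: ", config$seed),
    paste0("alpha: ", alpha),
    paste0("fc_thresholds: ", paste(fc_thresholds, collapse = ", ")),
    paste0("protein_alpha: ", protein_alpha)
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(sim = sim, expression = expr, gene_type_summary = gts,
                 de = de, confusion = confusion, protein_de = prot_de,
                 assays = assays, enrichment = enr))
}
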