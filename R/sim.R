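SEED_OFFSETS <- c(counts = 101L, itraq = 211L, metabolites = 307L,
                  qpcr = 401L, energy = 503L)

default_metabolite_means <- function() {
  base <- c(sucrose = 12, glucose = 8, fructose = 6,
            malate = 20, fumarate = 15, succinate = 2)
  time_mult <- c("0h" = 1, "1h" = 1.5, "8h" = 2)
  sugars <- c("sucrose", "glucose", "fructose")
  grid <- tidyr::expand_grid(metabolite = names(base),
                             genotype = c("WT", "OE"),
                             timepoint = names(time_mult))
  grid |>
    dplyr::mutate(
      group_mean = unname(base[.data$metabolite]) *
        dplyr::if_else(.data$metabolite %in% sugars,
                       unname(time_mult[.data$timepoint]), 1) *
        dplyr::if_else(.data$genotype == "OE" &
                         .data$metabolite %in% c("malate", "fumarate"),
                       1.5, 1)
    )
}

default_energy_means <- function() {
  # synthetic nmol/g FW group means: OE line richer in ATP (hence ATP/NADPH)
  # at every timepoint, NADP(H) slightly depleted, mirroring a high-energy
  # phenotype; invented values for simulation, not measurements.
  tibble::tribble(
    ~analyte, ~genotype, ~"0h", ~"1h", ~"8h",
    "ATP",    "WT",  18, 30, 34,
    "ATP",    "OE",  26, 42, 48,
    "ADP",    "WT",   8, 10, 11,
    "ADP",    "OE",  11, 14, 15,
    "NADP+",  "WT",  14, 12, 12,
    "NADP+",  "OE",  11, 11, 11,
    "NADPH",  "WT",  10, 11, 12,
    "NADPH",  "OE",   9, 10,  9
  ) |>
    tidyr::pivot_longer(c("0h", "1h", "8h"), names_to = "timepoint",
                        values_to = "group_mean")
}

#' Configuration for the tri-omic synthetic experiment
#'
#' Bundles every knob of the generators with defaults mirroring the study
#' design being emulated: a wild-type and an overexpression library of 1e7
#' mappable reads each over 23,250 nuclear + 126 mitochondrial + 96
#' chloroplast genes; 2,611 candidate proteins quantified as 4 replicate
#' OE/WT ratios (2 biological x 2 technical, treated as 4 independent
#' replicates); triplicate metabolite, energy-panel and qPCR measurements.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   from `seed` plus a fixed offset, so adding one generator never perturbs
#'   another.
#' @param n_genes_by_compartment Named integer vector
#'   (`nuclear`/`mitochondrial`/`chloroplast`).
#' @param library_sizes Named numeric vector `c(wt =, oe =)` of mappable
#'   reads per library.
#' @param gene_length_range Interval (bp) for uniform gene-length sampling;
#'   the default 300-3000 spans typical transcript lengths.
#' @param rpkm_log_mean,rpkm_log_sd Natural-log mean/sd of the lognormal
#'   per-gene RPKM distribution.
#' @param frac_de Fraction of genes with a true fold change.
#' @param log2_effects True log2 fold changes cycled over the changed genes.
#' @param overdispersion Gamma-mixing variance for optional extra-Poisson
#'   noise (0 = pure Poisson, the model the exact test assumes).
#' @param n_proteins Number of simulated proteins before identification
#'   filtering.
#' @param protein_ratio_noise_sd Natural-log sd of replicate protein ratios.
#' @param frac_protein_changed Fraction of proteins with a true ratio != 1.
#' @param protein_true_ratios True ratios cycled over changed proteins.
#' @param frac_low_confidence Fraction of proteins failing the
#'   identification filter (low unused score or < 2 peptides).
#' @param metabolite_group_means Data frame `metabolite`, `genotype`,
#'   `timepoint`, `group_mean`; `NULL` for the built-in synthetic panel.
#' @param metabolite_cv Coefficient of variation of metabolite replicates.
#' @param n_reps Metabolite/energy replicates per group (default 3).
#' @param energy_group_means Data frame `analyte`, `genotype`, `timepoint`,
#'   `group_mean` (nmol/g FW); `NULL` for the built-in synthetic panel.
#' @param energy_cv CV of energy-panel replicates.
#' @param qpcr_fold_changes Named vector of designed treatment/control fold
#'   changes per target gene.
#' @param qpcr_ct_noise_sd Additive Ct noise (cycles).
#' @param qpcr_n_reps qPCR replicates per sample (default 3).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_by_compartment = c(nuclear = 23250L,
                                                  mitochondrial = 126L,
                                                  chloroplast = 96L),
                       library_sizes = c(wt = 1e7, oe = 1e7),
                       gene_length_range = c(300L, 3000L),
                       rpkm_log_mean = 2, rpkm_log_sd = 1.5,
                       frac_de = 0.1, log2_effects = c(-2, 2),
                       overdispersion = 0,
                       n_proteins = 2611L,
                       protein_ratio_noise_sd = 0.1,
                       frac_protein_changed = 0.2,
                       protein_true_ratios = c(2, 0.5),
                       frac_low_confidence = 0.16,
                       metabolite_group_means = NULL,
                       metabolite_cv = 0.15, n_reps = 3L,
                       energy_group_means = NULL, energy_cv = 0.12,
                       qpcr_fold_changes = c(AtPAP2 = 8, cox1 = 2,
                                             atp6_2 = 0.125),
                       qpcr_ct_noise_sd = 0.1, qpcr_n_reps = 3L) {
  cfg <- list(seed = as.integer(seed),
              n_genes_by_compartment = n_genes_by_compartment,
              library_sizes = library_sizes,
              gene_length_range = gene_length_range,
              rpkm_log_mean = rpkm_log_mean, rpkm_log_sd = rpkm_log_sd,
              frac_de = frac_de, log2_effects = log2_effects,
              overdispersion = overdispersion,
              n_proteins = as.integer(n_proteins),
              protein_ratio_noise_sd = protein_ratio_noise_sd,
              frac_protein_changed = frac_protein_changed,
              protein_true_ratios = protein_true_ratios,
              frac_low_confidence = frac_low_confidence,
              metabolite_group_means = metabolite_group_means %||%
                default_metabolite_means(),
              metabolite_cv = metabolite_cv, n_reps = as.integer(n_reps),
              energy_group_means = energy_group_means %||%
                default_energy_means(),
              energy_cv = energy_cv,
              qpcr_fold_changes = qpcr_fold_changes,
              qpcr_ct_noise_sd = qpcr_ct_noise_sd,
              qpcr_n_reps = as.integer(qpcr_n_reps))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(n_genes_by_compartment <= 0) || n_proteins <= 0 ||
        n_reps <= 0 || qpcr_n_reps <= 0) {
      abort("all feature and replicate counts must be > 0.",
            class = "energyomics_config_error")
    }
    if (any(library_sizes <= 0)) {
      abort("library sizes must be positive.",
            class = "energyomics_config_error")
    }
    if (frac_de < 0 || frac_de > 1 ||
        frac_protein_changed < 0 || frac_protein_changed > 1 ||
        frac_low_confidence < 0 || frac_low_confidence > 1) {
      abort("fractions must lie in [0, 1].",
            class = "energyomics_config_error")
    }
    if (gene_length_range[1] < 1 || diff(gene_length_range) < 0) {
      abort("gene lengths must be >= 1 bp.",
            class = "energyomics_config_error")
    }
    if (protein_ratio_noise_sd < 0 || metabolite_cv < 0 || energy_cv < 0 ||
        qpcr_ct_noise_sd < 0 || overdispersion < 0) {
      abort("noise parameters must be non-negative.",
            class = "energyomics_config_error")
    }
    if (any(protein_true_ratios <= 0) || any(qpcr_fold_changes <= 0)) {
      abort("true ratios and fold changes must be positive.",
            class = "energyomics_config_error")
    }
  })
  invisible(cfg)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Scalar fields of the file override [sim_config()] defaults; tabular
#' fields (`metabolite_group_means`, `energy_group_means`) may be given as
#' lists of columns.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (tab in c("metabolite_group_means", "energy_group_means")) {
    if (!is.null(raw[[tab]])) raw[[tab]] <- tibble::as_tibble(raw[[tab]])
  }
  for (vec in c("n_genes_by_compartment", "library_sizes",
                "qpcr_fold_changes")) {
    if (!is.null(raw[[vec]])) raw[[vec]] <- unlist(raw[[vec]])
  }
  do.call(sim_config, raw)
}

gene_type_probs <- list(
  nuclear = c(protein_coding = 0.924, pre_tRNA = 0, rRNA = 0.0001,
              snRNA = 0.0006, snoRNA = 0.0008, miRNA = 0.0028,
              other_RNA = 0.0146, pseudogene = 0.0158, TE = 0.0407),
  mitochondrial = c(protein_coding = 0.96, pre_tRNA = 0.016, rRNA = 0.024,
                    snRNA = 0, snoRNA = 0, miRNA = 0, other_RNA = 0,
                    pseudogene = 0, TE = 0),
  chloroplast = c(protein_coding = 0.906, pre_tRNA = 0.01, rRNA = 0.084,
                  snRNA = 0, snoRNA = 0, miRNA = 0, other_RNA = 0,
                  pseudogene = 0, TE = 0)
)

#' Simulate two-library RNA-seq counts with spike-in fold changes
#'
#' Per gene g an expression level RPKM_g is drawn lognormally and converted
#' to the expected read count of library l as
#' `lambda_{g,l} = N_l * L_g * RPKM_g / 1e9` — the inverse of the RPKM
#' equation, so quantification round-trips exactly at infinite depth. Counts
#' are `x_g ~ Poisson(lambda_{g,wt})` and
#' `y_g ~ Poisson(lambda_{g,oe} * 2^delta_g)` with `delta_g` the gene's true
#' log2 effect (0 for nulls); a `floor(frac_de * n)` subset of genes, taken
#' as the first in a shuffled order, receives effects cycled from
#' `log2_effects`. With `overdispersion > 0` each gene's rates are scaled by
#' a Gamma multiplier of unit mean and variance `overdispersion`
#' (Gamma-mixed Poisson) to study robustness to extra-Poisson noise.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (tibble `gene_id`, `wt`, `oe`; attribute
#'   `library_sizes`), `annotation` (`gene_id`, `compartment`, `gene_type`,
#'   `length_bp`), `truth` (`gene_id`, `compartment`, `true_status`,
#'   `true_log2fc`).
#' @export
gen_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["counts"]])
  comp_n <- config$n_genes_by_compartment
  compartment <- rep(names(comp_n), comp_n)
  n <- length(compartment)
  prefix <- c(nuclear = "ATN", mitochondrial = "ATM", chloroplast = "ATC")
  gene_id <- paste0(prefix[compartment],
                    "G", formatC(unlist(lapply(comp_n, seq_len)),
                                 width = 5, flag = "0"))
  gene_type <- unlist(lapply(names(comp_n), function(cp) {
    sample(GENE_TYPES, comp_n[[cp]], replace = TRUE,
           prob = gene_type_probs[[cp]])
  }))
  length_bp <- sample(seq(config$gene_length_range[1],
                          config$gene_length_range[2]), n, replace = TRUE)
  rpkm <- rlnorm(n, config$rpkm_log_mean, config$rpkm_log_sd)

  delta <- numeric(n)
  n_de <- floor(config$frac_de * n)
  shuffled <- sample.int(n)
  de_idx <- shuffled[seq_len(n_de)]
  if (n_de > 0) delta[de_idx] <- rep_len(config$log2_effects, n_de)

  lam_wt <- config$library_sizes[["wt"]] * length_bp * rpkm / 1e9
  lam_oe <- config$library_sizes[["oe"]] * length_bp * rpkm / 1e9 * 2^delta
  if (config$overdispersion > 0) {
    shp <- 1 / config$overdispersion
    lam_wt <- lam_wt * stats::rgamma(n, shape = shp, rate = shp)
    lam_oe <- lam_oe * stats::rgamma(n, shape = shp, rate = shp)
  }
  counts <- tibble::tibble(gene_id = gene_id,
                           wt = rpois(n, lam_wt), oe = rpois(n, lam_oe))
  attr(counts, "library_sizes") <- config$library_sizes
  list(
    counts = counts,
    annotation = tibble::tibble(gene_id = gene_id, compartment = compartment,
                                gene_type = gene_type,
                                length_bp = length_bp),
    truth = tibble::tibble(gene_id = gene_id, compartment = compartment,
                           true_status = dplyr::if_else(delta != 0,
                                                        "changed", "null"),
                           true_log2fc = delta)
  )
}

#' Simulate iTRAQ protein quantification records
#'
#' Each protein carries four replicate OE/WT ratios
#' `r * exp(epsilon)`, `epsilon ~ Normal(0, protein_ratio_noise_sd^2)`, with
#' true ratio `r = 1` for nulls and values cycled from
#' `protein_true_ratios` for a `floor(frac_protein_changed * n)` shuffled
#' subset. Unused ProtScores and >= 95 %-confidence peptide counts are drawn
#' so that about `frac_low_confidence` of proteins fail the identification
#' filter (score < 1.3 or < 2 peptides).
#'
#' @param config A [sim_config()].
#' @return List with `records` (tibble `protein_id`, `unused_score`,
#'   `n_peptides_95`, `ratio_r1` ... `ratio_r4`) and `truth`
#'   (`protein_id`, `true_status`, `true_ratio`).
#' @export
gen_itraq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["itraq"]])
  n <- config$n_proteins
  protein_id <- sprintf("PROT%05d", seq_len(n))
  true_ratio <- rep(1, n)
  n_chg <- floor(config$frac_protein_changed * n)
  shuffled <- sample.int(n)
  chg_idx <- shuffled[seq_len(n_chg)]
  if (n_chg > 0) true_ratio[chg_idx] <- rep_len(config$protein_true_ratios,
                                                n_chg)
  fails <- runif(n) < config$frac_low_confidence
  unused_score <- ifelse(fails & runif(n) < 0.5,
                         runif(n, 0.3, 1.29),
                         1.3 + stats::rexp(n, rate = 1 / 6))
  n_peptides_95 <- ifelse(fails & unused_score >= 1.3,
                          sample(0:1, n, replace = TRUE),
                          2L + rpois(n, 4))
  ratios <- true_ratio *
    exp(matrix(rnorm(4 * n, 0, config$protein_ratio_noise_sd), ncol = 4))
  records <- tibble::tibble(protein_id = protein_id,
                            unused_score = unused_score,
                            n_peptides_95 = as.integer(n_peptides_95))
  for (k in 1:4) records[[paste0("ratio_r", k)]] <- ratios[, k]
  list(records = records,
       truth = tibble::tibble(protein_id = protein_id,
                              true_status = dplyr::if_else(true_ratio != 1,
                                                           "changed", "null"),
                              true_ratio = true_ratio))
}

#' Simulate a GC-MS metabolite panel with raw normalization fields
#'
#' Replicate values are `group_mean * (1 + Normal(0, cv))`; each replicate
#' also gets a ribitol internal-standard peak height and a fresh weight
#' (around 50 mg) and its raw `peak_height` is back-computed as
#' `value * ribitol_height * fresh_weight`, so [normalize_gcms()] recovers
#' the simulated value and the normalization path is exercised end to end.
#'
#' @param config A [sim_config()].
#' @return Tibble: `assay_type`, `metabolite`, `genotype`, `timepoint`,
#'   `replicate`, `peak_height`, `ribitol_height`, `fresh_weight`,
#'   `true_value` (the group mean).
#' @export
gen_metabolites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["metabolites"]])
  grid <- config$metabolite_group_means |>
    tidyr::expand_grid(replicate = seq_len(config$n_reps))
  m <- nrow(grid)
  value <- grid$group_mean * (1 + rnorm(m, 0, config$metabolite_cv))
  ribitol <- rlnorm(m, log(5e4), 0.05)
  fw <- runif(m, 0.045, 0.055)
  tibble::tibble(assay_type = "gcms",
                 metabolite = grid$metabolite,
                 genotype = grid$genotype,
                 timepoint = grid$timepoint,
                 replicate = grid$replicate,
                 peak_height = value * ribitol * fw,
                 ribitol_height = ribitol,
                 fresh_weight = fw,
                 true_value = grid$group_mean)
}

#' Simulate an ATP/ADP/NADP(H) energy panel
#'
#' Triplicate nmol/g FW values per analyte x genotype x timepoint, as
#' `group_mean * (1 + Normal(0, energy_cv))`.
#'
#' @param config A [sim_config()].
#' @return Tibble: `analyte`, `genotype`, `timepoint`, `replicate`, `value`,
#'   `true_value`.
#' @export
gen_energy_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["energy"]])
  grid <- config$energy_group_means |>
    tidyr::expand_grid(replicate = seq_len(config$n_reps))
  tibble::tibble(analyte = grid$analyte, genotype = grid$genotype,
                 timepoint = grid$timepoint, replicate = grid$replicate,
                 value = grid$group_mean *
                   (1 + rnorm(nrow(grid), 0, config$energy_cv)),
                 true_value = grid$group_mean)
}

#' Simulate triplicate qPCR Ct values with designed fold changes
#'
#' For each target gene with designed treatment/control fold `f`, reference
#' (internal-control) Ct values sit near 20 cycles and control-target Ct
#' near 24; the treatment target Ct is shifted by `-log2(f)` so that the
#' delta-delta-Ct estimate of fold change recovers `f` exactly at zero
#' noise. Additive Normal noise of sd `qpcr_ct_noise_sd` cycles is applied
#' to every well.
#'
#' @param config A [sim_config()].
#' @return Tibble: `gene`, `group`, `replicate`, `ct_target`,
#'   `ct_reference`, `true_fold`.
#' @export
gen_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["qpcr"]])
  folds <- config$qpcr_fold_changes
  grid <- tidyr::expand_grid(gene = names(folds),
                             group = c("treatment", "control"),
                             replicate = seq_len(config$qpcr_n_reps))
  m <- nrow(grid)
  shift <- ifelse(grid$group == "treatment",
                  -log2(unname(folds[grid$gene])), 0)
  tibble::tibble(gene = grid$gene, group = grid$group,
                 replicate = grid$replicate,
                 ct_target = 24 + shift + rnorm(m, 0, config$qpcr_ct_noise_sd),
                 ct_reference = 20 + rnorm(m, 0, config$qpcr_ct_noise_sd),
                 true_fold = unname(folds[grid$gene]))
}
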