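test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(library_sizes = c(wt = 0, oe = 1e6)),
               class = "energyomics_config_error")
  expect_error(sim_config(frac_de = 1.2), class = "energyomics_config_error")
  expect_error(sim_config(gene_length_range = c(0, 100)),
               class = "energyomics_config_error")
  expect_error(sim_config(protein_ratio_noise_sd = -0.1),
               class = "energyomics_config_error")
  expect_error(sim_config(metabolite_cv = -1),
               class = "energyomics_config_error")
  expect_error(sim_config(n_genes_by_compartment = c(nuclear = 0L,
                                                     mitochondrial = 5L,
                                                     chloroplast = 5L)),
               class = "energyomics_config_error")
})

test_that("every generator is deterministic given the seed, and streams are independent", {
  cfg <- small_config(seed = 99)
  expect_identical(gen_counts(cfg), gen_counts(cfg))
  expect_identical(gen_itraq(cfg), gen_itraq(cfg))
  expect_identical(gen_metabolites(cfg), gen_metabolites(cfg))
  expect_identical(gen_energy_panel(cfg), gen_energy_panel(cfg))
  expect_identical(gen_qpcr(cfg), gen_qpcr(cfg))
  # interleaving other generators does not perturb a stream
  a <- gen_counts(cfg)
  invisible(gen_itraq(cfg)); invisible(gen_qpcr(cfg))
  expect_identical(gen_counts(cfg), a)
})

test_that("truth bookkeeping matches the configured changed fraction", {
  cfg <- small_config(seed = 2, frac_de = 0.25, frac_protein_changed = 0.3)
  sim <- gen_counts(cfg)
  n <- nrow(sim$truth)
  expect_equal(sum(sim$truth$true_status == "changed"), floor(0.25 * n))
  expect_equal(nrow(sim$counts), n)
  expect_setequal(sim$truth$gene_id, sim$annotation$gene_id)
  prot <- gen_itraq(cfg)
  expect_equal(sum(prot$truth$true_status == "changed"),
               floor(0.3 * cfg$n_proteins))
  none <- gen_counts(small_config(seed = 2, frac_de = 0))
  expect_true(all(none$truth$true_status == "null"))
  expect_true(all(none$truth$true_log2fc == 0))
})

test_that("simulated counts follow the configured Poisson rates", {
  # 10,000 null genes at lambda = 100: LLN bound 3 / sqrt(100 * 10000)
  cfg <- sim_config(seed = 31,
                    n_genes_by_compartment = c(nuclear = 9900L,
                                               mitochondrial = 60L,
                                               chloroplast = 40L),
                    library_sizes = c(wt = 1e7, oe = 1e7),
                    frac_de = 0, rpkm_log_sd = 0)
  sim <- gen_counts(cfg)
  lambda <- 1e7 * sim$annotation$length_bp * exp(cfg$rpkm_log_mean) / 1e9
  z <- c(sim$counts$wt / lambda, sim$counts$oe / lambda)
  expect_lt(abs(mean(z) - 1), 3 / sqrt(mean(lambda) * length(z)) * 2)
  # variance/mean ratio near 1 for Poisson
  expect_equal(var(sim$counts$wt - lambda) / mean(lambda), 1,
               tolerance = 0.1)
})

test_that("protein ratios carry the designed signal and noise", {
  cfg <- sim_config(seed = 13, n_proteins = 10000L, frac_protein_changed = 0,
                    protein_ratio_noise_sd = 0.2)
  prot <- gen_itraq(cfg)
  lr <- log(as.matrix(prot$records[paste0("ratio_r", 1:4)]))
  expect_lt(abs(mean(lr)), 3 * 0.2 / sqrt(length(lr)))
  expect_equal(sd(as.vector(lr)), 0.2, tolerance = 0.02)
  # zero noise, all-null: every replicate ratio is exactly 1
  noiseless <- gen_itraq(sim_config(seed = 13, n_proteins = 50L,
                                    frac_protein_changed = 0,
                                    protein_ratio_noise_sd = 0))
  expect_true(all(as.matrix(noiseless$records[paste0("ratio_r", 1:4)]) == 1))
  # identification filter fails roughly the configured fraction
  cfg2 <- sim_config(seed = 13, n_proteins = 10000L,
                     frac_low_confidence = 0.16)
  rec2 <- gen_itraq(cfg2)$records
  kept <- nrow(filter_identifications(rec2))
  expect_lt(abs((1 - kept / 10000) - 0.16), 0.02)
})

test_that("metabolite replicates realize the configured CV and normalization fields", {
  cfg <- sim_config(seed = 5, metabolite_cv = 0.2, n_reps = 10000L)
  met <- dplyr::filter(gen_metabolites(cfg), metabolite == "sucrose",
                       genotype == "WT", timepoint == "0h")
  value <- met$peak_height / met$ribitol_height / met$fresh_weight
  expect_lt(abs(sd(value) / mean(value) - 0.2), 0.01)
  expect_equal(mean(value), met$true_value[1], tolerance = 0.01)
  # cv = 0: normalized replicates equal the group mean exactly
  met0 <- gen_metabolites(sim_config(seed = 5, metabolite_cv = 0))
  expect_equal(met0$peak_height / met0$ribitol_height / met0$fresh_weight,
               met0$true_value, tolerance = 1e-12)
})

test_that("qPCR generator round-trips designed fold changes through ddCt", {
  # zero noise: exact recovery
  q0 <- gen_qpcr(sim_config(seed = 3, qpcr_ct_noise_sd = 0))
  res0 <- ddct_relative_expression(q0)
  truth <- dplyr::distinct(q0, gene, true_fold)
  expect_equal(res0$fold[match(truth$gene, res0$gene)], truth$true_fold)
  # 0.1-Ct noise: sd of ddCt is 0.1 * sqrt(4/3), fold within 3 sd on log2 scale
  qn <- gen_qpcr(sim_config(seed = 17, qpcr_ct_noise_sd = 0.1))
  resn <- ddct_relative_expression(qn)
  truthn <- dplyr::distinct(qn, gene, true_fold)
  tol <- 3 * 0.1 * sqrt(2 * 2 / 3)
  expect_true(all(abs(log2(resn$fold[match(truthn$gene, resn$gene)]) -
                        log2(truthn$true_fold)) < tol))
})
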