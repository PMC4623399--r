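test_that("GC-MS normalization is the ribitol/fresh-weight quotient", {
  rec <- tibble::tibble(metabolite = c("sucrose", "zero"),
                        peak_height = c(1000, 0),
                        ribitol_height = c(500, 500),
                        fresh_weight = c(0.05, 0.05))
  out <- normalize_gcms(rec)
  expect_equal(out$value, c(40, 0))
  # doubling fresh weight halves the value
  out2 <- normalize_gcms(dplyr::mutate(rec, fresh_weight = fresh_weight * 2))
  expect_equal(out2$value, out$value / 2)
  expect_error(normalize_gcms(dplyr::mutate(rec, ribitol_height = 0)),
               class = "energyomics_record_error")
  expect_error(normalize_gcms(dplyr::mutate(rec, fresh_weight = -1)),
               class = "energyomics_record_error")
})

test_that("reference-group scaling maps the reference mean to one", {
  d <- tidyr::expand_grid(metabolite = c("m1", "m2"),
                          genotype = c("WT", "OE"),
                          timepoint = c("0h", "1h"),
                          replicate = 1:3) |>
    dplyr::mutate(value = 10)
  # all-equal data: everything becomes 1
  out <- relative_to_reference_group(d)
  expect_true(all(out$rel_value == 1))
  # OE mean double the WT reference: OE values scale to 2
  d2 <- dplyr::mutate(d, value = dplyr::if_else(genotype == "OE", 20, 10))
  out2 <- relative_to_reference_group(d2)
  expect_true(all(out2$rel_value[out2$genotype == "OE"] == 2))
  ref_rows <- out2$genotype == "WT" & out2$timepoint == "0h"
  expect_equal(mean(out2$rel_value[ref_rows]), 1)
  # scale equivariance: scaling all values by k leaves rel_value unchanged
  out3 <- relative_to_reference_group(dplyr::mutate(d2, value = value * 7.3))
  expect_equal(out3$rel_value, out2$rel_value)
  # zero reference mean flags the metabolite
  d4 <- dplyr::mutate(d2, value = dplyr::if_else(
    metabolite == "m1" & genotype == "WT" & timepoint == "0h", 0, value))
  expect_warning(out4 <- relative_to_reference_group(d4), "zero reference")
  expect_true(all(is.na(out4$rel_value[out4$metabolite == "m1"])))
  expect_false(anyNA(out4$rel_value[out4$metabolite == "m2"]))
})

test_that("energy ratios and sums match per-replicate arithmetic", {
  panel <- tidyr::expand_grid(analyte = c("ATP", "ADP", "NADP+", "NADPH"),
                              genotype = "WT", timepoint = "0h",
                              replicate = 1:3) |>
    dplyr::mutate(value = dplyr::case_when(analyte == "ATP" ~ 40,
                                           analyte == "ADP" ~ 40,
                                           analyte == "NADP+" ~ 5,
                                           analyte == "NADPH" ~ 10))
  der <- derive_energy_ratios(panel)
  val <- function(a) unique(der$value[der$analyte == a])
  expect_equal(val("ATP/ADP"), 1)
  expect_equal(val("ATP/NADPH"), 4)
  expect_equal(val("ATP+ADP"), 80)
  expect_equal(val("NADPH/NADP+"), 2)
  expect_equal(val("NADP++NADPH"), 15)
  # random fixture: sums equal component-wise addition per replicate
  set.seed(6)
  rnd <- tidyr::expand_grid(analyte = c("ATP", "ADP", "NADP+", "NADPH"),
                            genotype = c("WT", "OE"),
                            timepoint = c("0h", "8h"), replicate = 1:3) |>
    dplyr::mutate(value = runif(dplyr::n(), 1, 50))
  der2 <- derive_energy_ratios(rnd) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  wide <- tidyr::pivot_wider(rnd, names_from = "analyte",
                             values_from = "value")
  expect_equal(der2$`ATP+ADP`, wide$ATP + wide$ADP)
  expect_equal(der2$`ATP/ADP`, wide$ATP / wide$ADP)
  # zero denominator: that replicate's ratio is missing, others survive
  z <- dplyr::mutate(panel, value = dplyr::if_else(
    analyte == "ADP" & replicate == 2, 0, value))
  derz <- derive_energy_ratios(z)
  atp_adp <- derz[derz$analyte == "ATP/ADP", ]
  expect_true(is.na(atp_adp$value[atp_adp$replicate == 2]))
  expect_false(anyNA(atp_adp$value[atp_adp$replicate != 2]))
  expect_error(derive_energy_ratios(dplyr::mutate(panel, analyte = "GTP")),
               class = "energyomics_domain_error")
})

test_that("two-sample t matches hand arithmetic and the reference implementation", {
  res <- two_sample_t(c(10, 11, 9), c(20, 21, 19), var_equal = TRUE)
  expect_equal(res$t, -12.24745, tolerance = 1e-6)
  expect_equal(res$p, 2.5e-4, tolerance = 2e-2)
  expect_equal(res$stars, "**")
  # swapping groups flips the sign, same p
  swap <- two_sample_t(c(20, 21, 19), c(10, 11, 9), var_equal = TRUE)
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
  # identical groups: t = 0, p = 1, no star
  same <- two_sample_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")
  # Welch default agrees with stats::t.test across random fixtures
  set.seed(10)
  for (k in 1:20) {
    a <- rnorm(3, 10, 2); b <- rnorm(3, 12, 1)
    mine <- two_sample_t(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("compare_groups runs the contrast per analyte and timepoint", {
  set.seed(12)
  d <- tidyr::expand_grid(analyte = c("ATP", "ADP"),
                          genotype = c("WT", "OE"),
                          timepoint = c("0h", "8h"), replicate = 1:3) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 20, 2) +
                    (genotype == "OE" & analyte == "ATP") * 15)
  out <- compare_groups(d)
  expect_equal(nrow(out), 4)
  atp <- dplyr::filter(out, analyte == "ATP")
  expect_true(all(atp$p < 0.05))
  expect_true(all(atp$t > 0))      # OE larger than WT
  expect_true(all(atp$stars != ""))
})

test_that("ddCt quantification matches its defining arithmetic", {
  mk <- function(dct_trt, dct_ctl, gene = "g") {
    tibble::tibble(gene = gene,
                   group = rep(c("treatment", "control"),
                               c(length(dct_trt), length(dct_ctl))),
                   replicate = c(seq_along(dct_trt), seq_along(dct_ctl)),
                   ct_target = 20 + c(dct_trt, dct_ctl),
                   ct_reference = 20)
  }
  # delta-Ct 5 vs 7: ddCt = -2, fold = 4, treatment is the maximum (1)
  res <- ddct_relative_expression(mk(c(5, 5, 5), c(7, 7, 7)))
  expect_equal(res$ddct, -2)
  expect_equal(res$fold, 4)
  expect_equal(res$rel_treatment, 1)
  expect_equal(res$rel_control, 0.25)
  # all Ct equal: fold 1, degenerate paired test flagged NA
  flat <- ddct_relative_expression(mk(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(flat$fold, 1)
  expect_true(is.na(flat$p))
  # paired test agrees with stats::t.test on noisy replicates
  set.seed(19)
  trt <- rnorm(3, 5, 0.2); ctl <- rnorm(3, 7, 0.2)
  noisy <- ddct_relative_expression(mk(trt, ctl))
  ref <- t.test(trt, ctl, paired = TRUE)
  expect_equal(noisy$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(noisy$p, ref$p.value, tolerance = 1e-9)
  # unpaired replicate counts are an error
  expect_error(ddct_relative_expression(mk(c(5, 5), c(7, 7, 7))),
               class = "energyomics_domain_error")
  # implausible Ct values warn
  expect_warning(ddct_relative_expression(
    dplyr::mutate(mk(c(5, 5, 5), c(7, 7, 7)), ct_reference = 5)),
    "10-40")
})
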