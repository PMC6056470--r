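two_class_spec <- function(n = 2e4, sd = 0.25, delta = 1) {
  # thymocytes and mTECs with CD45/EpCAM means straddling the default
  # threshold (10^2.5) by delta standard deviations in total
  m <- default_population_spec("P10")$marker_means
  m["thymocyte", "CD45"] <- 2.5 + delta * sd / 2
  m["thymocyte", "EpCAM"] <- 2.5 - delta * sd / 2
  m["mTEC", "CD45"] <- 2.5 - delta * sd / 2
  m["mTEC", "EpCAM"] <- 2.5 + delta * sd / 2
  population_spec(c(thymocyte = n, cTEC_outer = 0, cTEC_inner = 0, mTEC = n),
                  survival = c(thymocyte = 1, cTEC_outer = 1,
                               cTEC_inner = 1, mTEC = 1),
                  marker_means = m, marker_sd = sd)
}

test_that("dissociation survival draws behave binomially", {
  spec <- population_spec(
    c(thymocyte = 500, cTEC_outer = 100, cTEC_inner = 100, mTEC = 200),
    survival = c(thymocyte = 1, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1)
  )
  ev <- dissociate(spec, seed = 1)
  expect_equal(nrow(ev), 900)
  expect_equal(as.vector(table(ev$true_class)[thymometry:::CELL_CLASSES]),
               c(500, 100, 100, 200))

  spec0 <- population_spec(
    c(thymocyte = 500, cTEC_outer = 100, cTEC_inner = 100, mTEC = 200),
    survival = c(thymocyte = 1, cTEC_outer = 0, cTEC_inner = 0, mTEC = 0)
  )
  ev0 <- dissociate(spec0, seed = 1)
  expect_true(all(ev0$true_class == "thymocyte"))

  spec5 <- population_spec(
    c(thymocyte = 1e6, cTEC_outer = 0, cTEC_inner = 0, mTEC = 0),
    survival = c(thymocyte = 0.5, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1)
  )
  n <- nrow(dissociate(spec5, seed = 7))
  ci <- qbinom(c(5e-4, 1 - 5e-4), 1e6, 0.5)
  expect_gte(n, ci[1])
  expect_lte(n, ci[2])

  # determinism
  expect_identical(dissociate(spec, seed = 3), dissociate(spec, seed = 3))
})

test_that("well-separated classes gate exactly to their hidden labels", {
  spec <- population_spec(
    c(thymocyte = 5000, cTEC_outer = 300, cTEC_inner = 300, mTEC = 400),
    survival = c(thymocyte = 1, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1),
    marker_sd = 0.05
  )
  ev <- dissociate(spec, seed = 2)
  g <- gate(ev)
  expect_equal(g$counts[["thymocyte"]], 5000)
  expect_equal(g$counts[["tec"]], 1000)
  expect_equal(g$counts[["ly51_pos"]], 600)
  expect_equal(g$counts[["uea1_pos"]], 400)
  expect_equal(g$ti_flow, 5)
  expect_equal(g$ly51_uea1_ratio, 1.5)
})

test_that("gate misclassification matches the Gaussian-overlap oracle", {
  n <- 2e4
  spec <- two_class_spec(n = n, sd = 0.25, delta = 1)
  ev <- dissociate(spec, seed = 11)
  g <- gate(ev)
  # each quadrant collects correctly gated cells of its own class plus
  # double-misclassified cells of the opposite class; both markers are
  # independent Gaussians offset delta/2 sds from the threshold
  p_ok <- pnorm(0.5)^2
  p_swap <- pnorm(-0.5)^2
  expected <- n * (p_ok + p_swap)
  mc_sd <- sqrt(n * (p_ok * (1 - p_ok) + p_swap * (1 - p_swap)))
  for (cls in c("thymocyte", "tec")) {
    expect_lt(abs(g$counts[[cls]] - expected), 3 * mc_sd)
  }
})

test_that("a 0.1% TEC fraction corresponds to a flow TI of 1000", {
  spec <- population_spec(
    c(thymocyte = 99900, cTEC_outer = 0, cTEC_inner = 0, mTEC = 100),
    survival = c(thymocyte = 1, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1),
    marker_sd = 0.05
  )
  g <- gate(dissociate(spec, seed = 5))
  expect_equal(g$counts[["tec"]] / g$n_events, 0.001)
  expect_lt(abs(g$ti_flow - 1000) / 1000, 0.01)
  expect_equal(g$ti_flow, 999)  # counts form: (1 - f)/f
})

test_that("zero TEC events are flagged in gating", {
  spec <- population_spec(
    c(thymocyte = 100, cTEC_outer = 0, cTEC_inner = 0, mTEC = 0)
  )
  g <- gate(dissociate(spec, seed = 1))
  expect_true(g$tec_zero)
  expect_true(is.na(g$ti_flow))
})

test_that("bulk expression is a linear composition of class counts", {
  spec <- population_spec(
    c(thymocyte = 0, cTEC_outer = 0, cTEC_inner = 0, mTEC = 1000),
    survival = c(thymocyte = 1, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1)
  )
  bw <- bulk_expression(spec, source = "whole_organ")
  expect_equal(bw[["Foxn1"]], 1000)  # single class: count x unit level
  expect_equal(bw[["Psmb11"]], 0)

  # adding thymocytes leaves TEC-exclusive gene levels unchanged
  spec2 <- population_spec(
    c(thymocyte = 5e6, cTEC_outer = 0, cTEC_inner = 0, mTEC = 1000),
    survival = spec$survival
  )
  bw2 <- bulk_expression(spec2, source = "whole_organ")
  expect_equal(bw2[["Foxn1"]], bw[["Foxn1"]])
  expect_equal(bw2[["Epcam"]], bw[["Epcam"]])

  # exact linearity in counts
  spec3 <- population_spec(3 * spec2$counts, survival = spec$survival)
  expect_equal(bulk_expression(spec3, source = "whole_organ"), 3 * bw2)

  # hand-computed two-class mixture
  mix <- population_spec(
    c(thymocyte = 0, cTEC_outer = 10, cTEC_inner = 0, mTEC = 20),
    survival = c(thymocyte = 1, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1)
  )
  bmix <- bulk_expression(mix, source = "whole_organ")
  expect_equal(bmix[["Cxcl12"]], 10 * 1.5 + 20 * 0)
  expect_equal(bmix[["Foxn1"]], 30)
})

test_that("ratio fold changes cancel exactly for co-localized gene pairs", {
  spec <- default_population_spec("P10")
  bw <- bulk_expression(spec, source = "whole_organ")
  bp <- bulk_expression(spec, source = "purified_TEC")
  # both strictly cortical: the class-specific loss cancels
  expect_equal(ratio_fold_change(bw, bp, "Psmb11", "Prss16"), 1)
  # uniform survival across all TEC classes: fold = 1 for any TEC pair
  u <- population_spec(spec$counts,
                       survival = c(thymocyte = 1, cTEC_outer = 0.3,
                                    cTEC_inner = 0.3, mTEC = 0.3))
  bwu <- bulk_expression(u, source = "whole_organ")
  bpu <- bulk_expression(u, source = "purified_TEC")
  for (gpair in list(c("Cxcl12", "Foxn1"), c("Ccl25", "Epcam"),
                     c("Dll4", "Foxn1"))) {
    expect_equal(ratio_fold_change(bwu, bpu, gpair[1], gpair[2]), 1)
  }
})

test_that("asymmetric survival matches the closed-form fold oracle", {
  # cortical gene over pan-TEC gene, equal counts, unit expression:
  # fold = (s_c + s_m) / (2 s_c)
  expr <- expression_spec(rbind(
    Foxn1  = c(thymocyte = 0, cTEC_outer = 1, cTEC_inner = 0, mTEC = 1),
    Cxcl12 = c(0, 1, 0, 0),
    Ccl25  = c(0, 1, 0, 0),
    Psmb11 = c(0, 1, 0, 0),
    Prss16 = c(0, 1, 0, 0),
    Dll4   = c(0, 1, 0, 1),
    Epcam  = c(0, 1, 1, 1)
  ))
  s_c <- 0.05; s_m <- 0.5
  spec <- population_spec(
    c(thymocyte = 0, cTEC_outer = 1000, cTEC_inner = 0, mTEC = 1000),
    survival = c(thymocyte = 1, cTEC_outer = s_c, cTEC_inner = s_c, mTEC = s_m)
  )
  bw <- bulk_expression(spec, expr, source = "whole_organ")
  bp <- bulk_expression(spec, expr, source = "purified_TEC")
  expect_equal(ratio_fold_change(bw, bp, "Cxcl12", "Foxn1"),
               (s_c + s_m) / (2 * s_c))
  expect_equal(ratio_fold_change(bw, bp, "Cxcl12", "Foxn1"), 5.5)
})

test_that("flow/true TI ratio equals thymocyte over TEC-weighted survival", {
  spec <- default_population_spec("P10")
  tec_classes <- c("cTEC_outer", "cTEC_inner", "mTEC")
  ti_true <- spec$counts[["thymocyte"]] / sum(spec$counts[tec_classes])
  s_tec <- sum(spec$counts[tec_classes] * spec$survival[tec_classes]) /
    sum(spec$counts[tec_classes])
  expected <- spec$survival[["thymocyte"]] / s_tec
  ratios <- vapply(1:3, function(s) {
    g <- gate(dissociate(spec, seed = s, scale = 0.01))
    g$ti_flow / ti_true
  }, numeric(1))
  expect_lt(abs(mean(ratios) - expected) / expected, 0.05)
  # ties to reconcile: the TI-based correction factor inverts TEC recovery
  r <- reconcile(ti_true, ti_true * expected, 1000)
  expect_equal(1 / r$recovery_rate, expected, tolerance = 1e-12)
})

test_that("preferential cortical loss depresses the gated Ly51/UEA1 ratio", {
  spec <- default_population_spec("P10")  # s_cTEC < s_mTEC
  true_ratio <- sum(spec$counts[c("cTEC_outer", "cTEC_inner")]) /
    spec$counts[["mTEC"]]
  gated <- vapply(1:20, function(s) {
    gate(dissociate(spec, seed = s, scale = 0.002))$ly51_uea1_ratio
  }, numeric(1))
  expect_true(all(gated <= true_ratio))
})

test_that("recovery timelines are flat for static specs and fall as mTECs emerge", {
  base_counts <- c(thymocyte = 5e4, cTEC_outer = 500, cTEC_inner = 500,
                   mTEC = 100)
  surv1 <- c(thymocyte = 1, cTEC_outer = 1, cTEC_inner = 1, mTEC = 1)
  static <- replicate(3, population_spec(base_counts, survival = surv1,
                                         marker_sd = 0.05),
                      simplify = FALSE)
  tl <- recovery_timeline(static, seed = 2)
  expect_equal(length(unique(tl$ti_flow)), 1)
  expect_equal(length(unique(tl$ly51_uea1_ratio)), 1)

  # ablation recovery: mTEC numbers rise, cTEC numbers static
  rising <- lapply(c(100, 400, 1600), function(m) {
    population_spec(replace(base_counts, "mTEC", m), survival = surv1,
                    marker_sd = 0.05)
  })
  tlr <- recovery_timeline(rising, seed = 2)
  expect_true(all(diff(tlr$ly51_uea1_ratio) < 0))

  expect_error(recovery_timeline(static[1], seed = 1), "2 time points")
})

test_that("Epcam normalization keeps expression tables finite", {
  spec <- default_population_spec("P10")
  lv <- bulk_expression(spec, source = "purified_TEC", normalize = TRUE)
  expect_true(all(is.finite(lv)))
  expect_equal(lv[["Epcam"]], 1)
})
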