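test_that("configuration validation enforces the variant contracts", {
  expect_error(mechanics_params(Fa = -1), "Fa")
  expect_error(simulation_config("base", genotype = "nope"), "genotype")
  # base and asym variants force isotropic adhesion
  cfg <- simulation_config("base", mechanics = mechanics_params(Fa = 3, Fb = 1))
  expect_identical(cfg$mechanics$Fa, cfg$mechanics$Fb)
  # selective adhesion defaults to the 4:1 ratio
  cfg <- simulation_config("selective_adhesion")
  expect_identical(cfg$mechanics$Fa / cfg$mechanics$Fb, 4)
  # asymmetric division needs p0 >= 1/2: a regulation whose p0 falls below
  # the threshold is rejected with the constraint named
  weak <- ovol_regulation(pmin = 0.3, pT = 0.05)
  expect_error(simulation_config("asym_division", lineage = weak),
               "p0 >= 1/2")
  expect_silent(simulation_config("base", lineage = weak))
})

test_that("effective rates reduce to the Ovol regulation at zero signal", {
  reg <- ovol_regulation()
  fb <- signal_feedback(k_alpha = 2, k_beta = 20, s_half = 0.5)
  for (ct in c("C0", "C1", "C2", "C3")) {
    expect_equal(effective_rates(ct, reg, 0, fb, "signal"),
                 ovol_modulate(reg))
    expect_equal(effective_rates(ct, reg, 7, fb, "base"),
                 ovol_modulate(reg))
  }
})

test_that("saturating feedback has the correct limits and monotonicity", {
  reg <- ovol_regulation()
  fb <- signal_feedback(k_alpha = 2, k_beta = 20, s_half = 0.5)
  # s -> infinity: d2 saturates at dDKO + sigma_c alpha (1 + k_alpha) + xi beta
  d2_inf <- reg$dDKO + reg$sigma_c * reg$alpha * (1 + fb$k_alpha) +
    reg$xi * reg$beta
  expect_equal(effective_rates("C2", reg, 1e9, fb, "signal")$d2, d2_inf,
               tolerance = 1e-6)
  # d2 strictly increasing, p0/v0 strictly decreasing in s
  ss <- c(0, 0.1, 0.5, 2, 10)
  d2s <- vapply(ss, function(s) effective_rates("C2", reg, s, fb, "signal")$d2,
                numeric(1))
  p0s <- vapply(ss, function(s) effective_rates("C0", reg, s, fb, "signal")$p0,
                numeric(1))
  v0s <- vapply(ss, function(s) effective_rates("C0", reg, s, fb, "signal")$v0,
                numeric(1))
  expect_true(all(diff(d2s) > 0))
  expect_true(all(diff(p0s) < 0))
  expect_true(all(diff(v0s) < 0))
  expect_error(signal_feedback(k_alpha = -1), "gains")
})

test_that("the initial tissue is a relaxed basal monolayer", {
  set.seed(91)
  # a single cell rests on the membrane
  tis <- init_tissue(1, 1, n_elements = 8, relax_steps = 150,
                     periodic_xy = FALSE, domain = c(20, 20, 20))
  expect_identical(nrow(tis$cell), 1L)
  expect_true(all(tis$cell$cell_type == 0L))
  expect_lt(min(tis$pos[, 3]), mechanics_params()$membrane_cutoff)
  # a grid monolayer: all basal, thickness under 1.5 cell diameters
  tis <- init_tissue(4, 4, n_elements = 8, relax_steps = 150)
  expect_true(all(tis$cell$cell_type == 0L))
  cz <- tissue_cells(tis)$z
  expect_lt(max(cz) - min(cz), 1.5 * mechanics_params()$cell_diameter)
  expect_error(init_tissue(10, 10, domain = c(8, 8, 40)), "domain too small")
})

test_that("runs are reproducible and capped", {
  cfg <- simulation_config("asym_division", duration = 15, nx = 3, ny = 3,
                           n_elements = 6)
  r1 <- suppressWarnings(run_simulation(cfg, seed = 11))
  r2 <- suppressWarnings(run_simulation(cfg, seed = 11))
  expect_identical(r1$events, r2$events) # identical event logs
  expect_identical(r1$tissue$pos, r2$tissue$pos) # bit-identical state
  r3 <- suppressWarnings(run_simulation(cfg, seed = 12))
  expect_false(identical(r1$tissue$pos, r3$tissue$pos))
  # the cell cap triggers a clean early stop with partial outputs
  cfg2 <- cfg
  cfg2$duration <- 60 # long enough for the 3x3 sheet to outgrow the cap
  cfg2$max_cells <- 10
  expect_warning(r4 <- run_simulation(cfg2, seed = 11), "cap")
  expect_true(r4$early_stop)
  expect_gt(nrow(r4$snapshots), 0)
})

test_that("the sweep relabels the adhesion axis and classifies outcomes", {
  cfg <- simulation_config("selective_adhesion", duration = 6, nx = 3, ny = 3,
                           n_elements = 5, snapshot_every = 6)
  out <- suppressWarnings(sweep_parameter(cfg, "Fa_over_Fb", c(1, 4),
                                          seeds = 1))
  expect_identical(nrow(out), 2L)
  expect_true(all(out$pattern %in%
    c("stratified", "mixed", "salt_pepper", "compact", "cavity")))
  expect_error(sweep_parameter(cfg, "no_such_axis", 1), "axis")
})

test_that("pattern classification flags cavities and purity", {
  set.seed(92)
  # hand-built tissue: pure basal layer below a pure granular layer
  mk <- function(zs, type0) {
    n <- 25
    cx <- rep((1:5 - 0.5) * 4, 5); cy <- rep((1:5 - 0.5) * 4, each = 5)
    purrr::map_dfr(seq_along(zs), function(i)
      tibble::tibble(cell = seq_len(n) + (i - 1) * n, x = cx, y = cy,
                     z = zs[i], type = type0[i]))
  }
  df <- mk(c(2, 6), c("C0", "C3"))
  el <- tibble::tibble(element_id = seq_len(nrow(df)), cell_id = df$cell,
                       element_type = "interior", x = df$x, y = df$y, z = df$z)
  cl <- tibble::tibble(cell_id = df$cell, cell_type = df$type,
                       cycle_clock = 0, cycle_length = 24, n_target = 1,
                       growth_interval = Inf, next_growth = Inf,
                       removal_state = 0L, next_shrink = Inf, birth_time = 0)
  tis <- new_tissue(el, cl, c(20, 20, 20), periodic_xy = TRUE)
  cls <- classify_pattern(tis)
  expect_identical(cls$pattern, "stratified")
  expect_equal(cls$max_ir, 0)
  # a floating layer with an empty gap below reads as a cavity
  df2 <- mk(c(2, 14), c("C0", "C3"))
  el2 <- el; el2$z <- df2$z
  tis2 <- new_tissue(el2, cl, c(20, 20, 20), periodic_xy = TRUE)
  expect_identical(classify_pattern(tis2)$pattern, "cavity")
})

test_that("broom-style accessors summarise runs", {
  cfg <- simulation_config("base", duration = 10, nx = 3, ny = 3,
                           n_elements = 5, snapshot_every = 5)
  run <- suppressWarnings(run_simulation(cfg, seed = 3))
  td <- tidy(run)
  expect_true(all(c("time", "type", "cells") %in% names(td)))
  gl <- glance(run)
  expect_identical(gl$variant, "base")
  expect_identical(gl$total, nrow(run$tissue$cell))
  # plots build without error
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(plot_tissue(run$tissue), "ggplot")
})
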