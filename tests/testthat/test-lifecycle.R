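mp <- mechanics_params()

# a single isolated cell with a controllable element count
one_cell_tissue <- function(n_el = 5, n_target = 10, type = "C0",
                            next_growth = 0, clock = 0, cycle = 24) {
  pos <- sweep(matrix(runif(3 * n_el, -1, 1), n_el, 3), 2, c(15, 15, 5), `+`)
  el <- tibble::tibble(element_id = seq_len(n_el), cell_id = 1L,
                       element_type = "interior",
                       x = pos[, 1], y = pos[, 2], z = abs(pos[, 3]))
  cl <- tibble::tibble(cell_id = 1L, cell_type = type, cycle_clock = clock,
                       cycle_length = cycle, n_target = n_target,
                       growth_interval = cycle / (n_target - n_el),
                       next_growth = next_growth, removal_state = 0L,
                       next_shrink = Inf, birth_time = 0)
  new_tissue(el, cl, c(30, 30, 30), periodic_xy = FALSE)
}

test_that("growth adds elements on schedule up to the target count", {
  set.seed(21)
  tis <- one_cell_tissue(n_el = 5, n_target = 10)
  # over one cycle the count goes from initial to target exactly
  gi <- tis$cell$growth_interval[1]
  for (tick in seq(0, 24, by = gi)) {
    tis$time <- tick
    tis <- grow_cell(tis, 1L, tick, mp)
  }
  expect_identical(nrow(tis$pos), 10L)
  # at target: no further additions
  tis <- grow_cell(tis, 1L, 100, mp)
  expect_identical(nrow(tis$pos), 10L)
  # placement contract: a new element lands within sigma of the centroid
  set.seed(22)
  tis2 <- one_cell_tissue(n_el = 5, n_target = 10)
  cen <- colMeans(tis2$pos)
  tis2 <- grow_cell(tis2, 1L, 0, mp)
  expect_lt(sqrt(sum((tis2$pos[6, ] - cen)^2)), mp$sigma)
})

test_that("division decisions follow the lineage probabilities", {
  set.seed(31)
  # certainty cases
  for (i in 1:5) {
    ev <- decide_division("C0", p0 = 1, p1 = 0.2, variant = "base")
    expect_identical(ev$daughter_types, c("C0", "C0"))
    ev <- decide_division("C0", p0 = 1, p1 = 0.2, variant = "asym_division")
    expect_identical(ev$daughter_types, c("C0", "C0"))
    # p0 = 1/2 in the asymmetric variant: every division is asymmetric
    ev <- decide_division("C0", p0 = 0.5, p1 = 0.2, variant = "asym_division")
    expect_identical(ev$mode, "asymmetric")
  }
  expect_error(decide_division("C2", 0.5, 0.2), "C0 and C1")
  # binomial sampling bound: 10,000 base-variant draws at p0 = 0.7
  set.seed(32)
  renew <- replicate(10000, identical(
    decide_division("C0", 0.7, 0.2, "base")$daughter_types, c("C0", "C0")))
  expect_lt(abs(mean(renew) - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  # C1 exit: both daughters C2 on the 1 - p1 branch
  set.seed(33)
  d <- replicate(2000, decide_division("C1", 0.7, 0.25)$daughter_types[1])
  expect_lt(abs(mean(d == "C1") - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
  expect_true(all(d %in% c("C1", "C2")))
})

test_that("division planes have the stated orientations", {
  set.seed(34)
  for (i in 1:50) {
    ev <- decide_division("C0", 0.6, 0.2, "asym_division")
    if (ev$mode == "asymmetric") {
      # plane parallel to the membrane: normal within 15 degrees of vertical
      expect_gt(abs(ev$plane_normal[3]), cos(15 * pi / 180) - 1e-9)
    } else {
      expect_lt(abs(ev$plane_normal[3]), sin(15 * pi / 180) + 1e-9)
    }
    nrm <- decide_division("C0", 1, 0.2, "base")$plane_normal
    # symmetric: plane perpendicular to the membrane (normal horizontal)
    expect_lt(abs(nrm[3]), sin(15 * pi / 180) + 1e-9)
  }
})

test_that("division partitions conserve elements and order daughters by height", {
  set.seed(41)
  for (i in 1:20) {
    tis <- one_cell_tissue(n_el = 10, n_target = 10, clock = 24)
    ev <- decide_division("C0", 0.5, 0.2, "asym_division")
    res <- divide_cell(tis, 1L, ev, lifecycle_params(), now = 24)
    expect_identical(nrow(res$tissue$pos), 10L) # conserved
    cl <- res$tissue$cell
    expect_setequal(cl$cell_type, c(0L, 1L))
    # the daughter with greater mean z carries the differentiated type
    mz <- vapply(cl$cell_id, function(id)
      mean(res$tissue$pos[res$tissue$el_cell == id, 3]), numeric(1))
    expect_identical(cl$cell_type[which.max(mz)], 1L)
    # balanced partition: each daughter gets at least floor(n/2) - 1
    nd <- table(res$tissue$el_cell)
    expect_true(all(nd >= 4))
    # clocks reset
    expect_true(all(cl$cycle_clock == 0))
  }
})

test_that("symmetric daughters separate roughly parallel to the membrane", {
  set.seed(42)
  angles <- replicate(30, {
    tis <- one_cell_tissue(n_el = 10, n_target = 10, clock = 24)
    ev <- decide_division("C0", 1, 0.2, "base")
    res <- divide_cell(tis, 1L, ev, lifecycle_params(), now = 24)
    cen <- vapply(res$tissue$cell$cell_id, function(id)
      colMeans(res$tissue$pos[res$tissue$el_cell == id, , drop = FALSE]),
      numeric(3))
    sep <- cen[, 1] - cen[, 2]
    abs(sep[3]) / sqrt(sum(sep^2))
  })
  # separation vector mostly horizontal (plane perpendicular to membrane)
  expect_lt(median(angles), sin(30 * pi / 180))
})

test_that("maturation hazard matches the exponential waiting time", {
  lc1 <- lifecycle_params(maturation_stages = 1) # memoryless limit
  # d2 = 0: never transitions
  set.seed(51)
  tis <- one_cell_tissue(type = "C2")
  for (i in 1:50) {
    res <- differentiate_mature(tis, 1L, d2_eff = 0, dt = 1, lc1)
    expect_false(res$transitioned)
  }
  # empirical rate within 3 sigma of the hazard over many draws
  set.seed(52)
  d2 <- 0.2; dt <- 0.5
  hits <- replicate(4000, {
    t2 <- one_cell_tissue(type = "C2")
    differentiate_mature(t2, 1L, d2, dt, lc1)$transitioned
  })
  p_true <- 1 - exp(-d2 * dt)
  expect_lt(abs(mean(hits) - p_true), 3 * sqrt(p_true * (1 - p_true) / 4000))
  expect_error(differentiate_mature(one_cell_tissue(type = "C1"), 1L, d2, dt),
               "C2")
})

test_that("staged maturation keeps the mean residence at 1/d2", {
  # k stages at rate k*d2 each: mean conversion time 1/d2, spread 1/sqrt(k)
  set.seed(53)
  d2 <- 0.1; dt <- 0.25
  waits <- function(lc) replicate(600, {
    t2 <- one_cell_tissue(type = "C2")
    t_el <- 0
    repeat {
      t_el <- t_el + dt
      r <- differentiate_mature(t2, 1L, d2, dt, lc)
      t2 <- r$tissue
      if (r$transitioned || t_el > 400) break
    }
    t_el
  })
  w4 <- waits(lifecycle_params(maturation_stages = 4))
  expect_lt(abs(mean(w4) - 1 / d2), 3 * (1 / d2 / 2) / sqrt(600))
  # narrower spread than the memoryless rule
  expect_lt(sd(w4), 0.75 * (1 / d2))
})

test_that("granular removal deletes one element per tick until the cell goes", {
  set.seed(61)
  lc <- lifecycle_params(removal_interval = 6)
  n0 <- 8
  tis <- one_cell_tissue(n_el = n0, n_target = 10, type = "C3",
                         clock = 30, cycle = 24)
  tick <- 6 / n0
  counts <- integer(0)
  t <- 30
  for (k in 1:(n0 + 1)) {
    res <- remove_granular(tis, 1L, t, lc)
    tis <- res$tissue
    counts <- c(counts, sum(tis$el_cell == 1L))
    if (res$cell_removed) break
    t <- t + tick
  }
  expect_true(all(diff(counts) <= 0)) # monotone shrinkage
  expect_identical(counts[length(counts)], 0L) # deleted after n ticks
  expect_false(1L %in% tis$cell$cell_id)
  # a granular cell before its lifetime is untouched
  tis2 <- one_cell_tissue(type = "C3", clock = 3, cycle = 24)
  res <- remove_granular(tis2, 1L, 3, lc)
  expect_identical(sum(res$tissue$el_cell == 1L), 5L)
  # removal never applies to earlier stages
  expect_error(remove_granular(one_cell_tissue(type = "C1"), 1L, 50, lc), "C3")
})

test_that("lineage stages only move forward in simulation", {
  cfg <- simulation_config("asym_division", duration = 30, nx = 3, ny = 3,
                           n_elements = 6)
  run <- suppressWarnings(run_simulation(cfg, seed = 5))
  ev <- run$events
  # differentiation events only ever announce forward transitions, and
  # division offspring never regress below the parent stage
  stage <- function(x) match(x, c("C0", "C1", "C2", "C3"))
  div <- ev[ev$event %in% c("divide_sym", "divide_asym"), ]
  expect_true(nrow(div) > 0)
  parts <- strsplit(div$detail, "->|\\+")
  expect_true(all(vapply(parts, function(k) {
    k <- stage(k)
    all(k[-1] >= k[1]) && max(k[-1]) - k[1] <= 1 # forward only, one step
  }, logical(1))))
})

test_that("agent-level division outcomes match the lineage coefficients", {
  # run a base-variant tissue and compare the realised self-renewal
  # fraction among C0 divisions with p0
  cfg <- simulation_config("base", duration = 48, nx = 5, ny = 5,
                           n_elements = 6)
  run <- suppressWarnings(run_simulation(cfg, seed = 7))
  p0 <- ovol_modulate(cfg$lineage)$p0
  div <- run$events[run$events$event == "divide_sym", ]
  div <- div[startsWith(div$detail, "C0->"), ]
  renew <- mean(div$detail == "C0->C0+C0")
  n <- nrow(div)
  expect_gt(n, 20)
  expect_lt(abs(renew - p0), 3 * sqrt(p0 * (1 - p0) / n))
})
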