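mp <- mechanics_params()

test_that("intracellular spring force follows Hooke's law", {
  o <- c(0, 0, 0)
  at <- function(r) c(r, 0, 0)
  expect_equal(intra_pair_force(at(mp$r0), o, mp), c(0, 0, 0))
  f <- intra_pair_force(at(mp$r0 + 1), o, mp)
  expect_equal(sqrt(sum(f^2)), mp$mu_spring)
  expect_lt(f[1], 0) # stretched spring pulls back toward the partner
  # antisymmetry
  ri <- c(1, 2, 3); rj <- c(4, 6, 3)
  expect_equal(intra_pair_force(ri, rj, mp), -intra_pair_force(rj, ri, mp))
})

test_that("pair forces are the negative gradients of their potentials", {
  set.seed(7)
  h <- 1e-6
  num_grad <- function(fun, ri) vapply(1:3, function(k) {
    e <- c(0, 0, 0); e[k] <- h
    (fun(ri + e) - fun(ri - e)) / (2 * h)
  }, numeric(1))
  for (i in 1:10) {
    rj <- runif(3, -1, 1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    ri <- rj + dir * runif(1, 2.5, 4.5) # around the spring rest length
    g <- num_grad(function(r) intra_pair_potential(r, rj, mp), ri)
    f <- intra_pair_force(ri, rj, mp)
    expect_equal(f, -g, tolerance = 1e-5)
    ri <- rj + dir * runif(1, 0.95 * mp$sigma, 0.9 * mp$inter_cutoff)
    g <- num_grad(function(r) inter_pair_potential(r, rj, TRUE, mp), ri)
    f <- inter_pair_force(ri, rj, TRUE, mp)
    expect_equal(f, -g, tolerance = 1e-5)
  }
})

test_that("intercellular potential honours its landmarks", {
  o <- c(0, 0, 0)
  at <- function(r) c(r, 0, 0)
  # potential zero at the equilibrium separation sigma
  expect_equal(inter_pair_potential(at(mp$sigma), o, TRUE, mp), 0)
  # force zero at the potential minimum 2^(1/6) sigma
  f <- inter_pair_force(at(2^(1 / 6) * mp$sigma), o, TRUE, mp)
  expect_equal(f, c(0, 0, 0), tolerance = 1e-12)
  # exactly zero beyond the cutoff
  expect_equal(inter_pair_force(at(mp$inter_cutoff + 1e-9), o, TRUE, mp),
               c(0, 0, 0))
  expect_gt(abs(inter_pair_force(at(mp$inter_cutoff - 0.1), o, TRUE, mp)[1]), 0)
  # selective strength is linear: Fa = 4 Fb gives a 4x same-class force
  mp2 <- mechanics_params(Fa = 2, Fb = 0.5)
  fs <- inter_pair_force(at(2.5), o, TRUE, mp2)
  fx <- inter_pair_force(at(2.5), o, FALSE, mp2)
  expect_equal(fs, 4 * fx)
})

test_that("membrane attraction applies only to adherent basal elements in range", {
  # basal adherent element inside the cutoff: unit-magnitude downward pull
  e <- list(x = 0, y = 0, z = mp$membrane_cutoff / 2,
            element_type = "membrane_adherent", cell_type = "C0")
  expect_equal(external_force(e, 0, mp), c(0, 0, -mp$eps_external))
  e$z <- mp$membrane_cutoff * 1.5
  expect_equal(external_force(e, 0, mp), c(0, 0, 0))
  # suprabasal cells never feel the membrane
  e <- list(x = 0, y = 0, z = 1, element_type = "interior", cell_type = "C1")
  expect_equal(external_force(e, 0, mp), c(0, 0, 0))
  e <- list(x = 0, y = 0, z = 1, element_type = "membrane_adherent",
            cell_type = "C2")
  expect_equal(external_force(e, 0, mp), c(0, 0, 0))
})

test_that("force assembly matches the all-pairs oracle", {
  set.seed(11)
  for (periodic in c(TRUE, FALSE)) {
    tis <- random_test_tissue(k = 6, m = 9, periodic = periodic)
    tis <- .update_element_types(tis)
    fa <- assemble_forces(tis, mp)
    aclass <- ifelse(tis$cell$cell_type[match(tis$el_cell, tis$cell$cell_id)] == 0, 0,
              ifelse(tis$cell$cell_type[match(tis$el_cell, tis$cell$cell_id)] <= 2, 1, 2))
    ref <- oracle_forces(tis$pos, tis$el_cell, aclass, tis$el_type, mp,
                         tis$domain[1], tis$domain[2], periodic)
    expect_equal(fa$forces, ref, tolerance = 1e-10)
    # the pair-list path agrees with the fused path
    idx <- neighbor_index(tis$pos, mp, tis$domain, periodic)
    fa2 <- assemble_forces(tis, mp, index = idx)
    expect_equal(fa2$forces, fa$forces, tolerance = 1e-12)
    # Newton's third law: internal forces cancel (no membrane term for
    # elements off the membrane; zero the adherent flags to isolate pairs)
    tis$el_type[] <- 0L
    fa3 <- assemble_forces(tis, mp)
    expect_equal(colSums(fa3$forces), c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("two isolated cells beyond the cutoff do not interact", {
  set.seed(3)
  mk <- function(cenx) {
    p <- sweep(matrix(runif(15, -1.5, 1.5), 5, 3), 2, c(cenx, 15, 15), `+`)
    p
  }
  box <- c(60, 30, 30)
  p1 <- mk(10); p2 <- mk(10 + mp$inter_cutoff + 5)
  el <- tibble::tibble(element_id = 1:10, cell_id = rep(1:2, each = 5),
                       element_type = "interior",
                       x = c(p1[, 1], p2[, 1]), y = c(p1[, 2], p2[, 2]),
                       z = c(p1[, 3], p2[, 3]))
  cl <- tibble::tibble(cell_id = 1:2, cell_type = "C1", cycle_clock = 0,
                       cycle_length = 24, n_target = 5, growth_interval = 4.8,
                       next_growth = Inf, removal_state = 0L,
                       next_shrink = Inf, birth_time = 0)
  both <- new_tissue(el, cl, box, periodic_xy = FALSE)
  f_both <- assemble_forces(both, mp)$forces
  one <- new_tissue(el[1:5, ], cl[1, ], box, periodic_xy = FALSE)
  f_one <- assemble_forces(one, mp)$forces
  expect_equal(f_both[1:5, ], f_one, tolerance = 1e-12)
})

test_that("position updates follow the overdamped scheme", {
  pos <- matrix(c(0, 0, 5), 1, 3)
  # zero force, no noise: frozen
  st <- step_positions(pos, matrix(0, 1, 3), mechanics_params(noise_amp = 0))
  expect_identical(st$pos, pos)
  # drift term: displacement = mobility * F * dt
  f <- matrix(c(2, 0, 0), 1, 3)
  st <- step_positions(pos, f, mechanics_params(noise_amp = 0))
  expect_equal(st$pos[1, 1], 2 * mechanics_params()$dt_mech)
  # oversized displacement triggers halving until the bound fits
  f <- matrix(c(1e4, 0, 0), 1, 3)
  st <- step_positions(pos, f, mechanics_params(noise_amp = 0))
  expect_gt(st$n_halvings, 0)
  expect_lte(abs(st$pos[1, 1] - pos[1, 1]), mechanics_params()$sigma / 2)
  expect_lt(st$dt_taken, mechanics_params()$dt_mech)
})

test_that("cross-cell attraction relaxes toward the potential minimum", {
  mpq <- mechanics_params(noise_amp = 0)
  r_start <- 1.5 * mpq$sigma
  el <- tibble::tibble(element_id = 1:2, cell_id = 1:2,
                       element_type = "interior",
                       x = c(10, 10 + r_start), y = 10, z = 10)
  cl <- tibble::tibble(cell_id = 1:2, cell_type = "C1", cycle_clock = 0,
                       cycle_length = 24, n_target = 1, growth_interval = Inf,
                       next_growth = Inf, removal_state = 0L,
                       next_shrink = Inf, birth_time = 0)
  tis <- new_tissue(el, cl, c(40, 20, 20), periodic_xy = FALSE)
  seps <- numeric(250)
  for (k in 1:250) {
    fa <- assemble_forces(tis, mpq)
    tis$pos <- step_positions(tis$pos, fa$forces, mpq)$pos
    seps[k] <- abs(diff(tis$pos[, 1]))
  }
  expect_true(all(diff(seps) < 1e-12)) # monotone approach
  expect_equal(seps[250], 2^(1 / 6) * mpq$sigma, tolerance = 1e-3)
})

test_that("noiseless relaxation is a descent of the potential energy", {
  set.seed(5)
  # gradient flow descends for time steps below the local curvature bound
  mpq <- mechanics_params(noise_amp = 0, dt_mech = 0.02)
  tis <- random_test_tissue(k = 1, m = 10, periodic = FALSE)
  tis$el_type[] <- 0L
  energies <- numeric(40)
  for (k in 1:40) {
    fa <- assemble_forces(tis, mpq)
    energies[k] <- fa$energy
    tis$pos <- step_positions(tis$pos, fa$forces, mpq)$pos
  }
  expect_true(all(diff(energies) <= 1e-9))
  # and the kernel energy agrees with the independent bookkeeping
  aclass <- rep(1, nrow(tis$pos))
  eref <- oracle_energy(tis$pos, tis$el_cell, aclass, tis$el_type, mpq,
                        tis$domain[1], tis$domain[2], FALSE)
  expect_equal(assemble_forces(tis, mpq)$energy, eref, tolerance = 1e-10)
})

test_that("a relaxed single cell is roughly spherical at its preferred size", {
  set.seed(9)
  tis <- init_tissue(1, 1, n_elements = 10, relax_steps = 300,
                     periodic_xy = FALSE, domain = c(30, 30, 30))
  rel <- sweep(tis$pos, 2, colMeans(tis$pos))
  ev <- eigen(crossprod(rel) / nrow(rel), symmetric = TRUE,
              only.values = TRUE)$values
  # asphericity: spread of the gyration eigenvalues stays moderate
  expect_lt(max(ev) / max(min(ev), 1e-9), 6)
  # preferred size: radius of gyration near the spring rest length scale
  expect_lt(sqrt(sum(ev)), 1.5 * mechanics_params()$r0)
})

test_that("identical seeds give bit-identical trajectories", {
  roll <- function() {
    set.seed(123)
    tis <- random_test_tissue(k = 3, m = 6)
    for (k in 1:20) {
      fa <- assemble_forces(tis, mp)
      tis$pos <- step_positions(tis$pos, fa$forces, mp)$pos
    }
    tis$pos
  }
  expect_identical(roll(), roll())
})
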