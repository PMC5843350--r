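# tabular cell records for metric tests
cells_df <- function(x, y, z, type) tibble::tibble(x = x, y = y, z = z,
                                                   cell_type = type)

test_that("slice rasterization assigns modal layer codes", {
  dom <- c(40, 40)
  # only basal cells: all pixels code 0
  cx <- rep((1:10 - 0.5) * 4, 10); cy <- rep((1:10 - 0.5) * 4, each = 10)
  img <- rasterize_slice(cells_df(cx, cy, 1, "C0"), 0, 4, dom)
  expect_true(all(img$img == 0L))
  expect_false(any(img$mask))
  # C1 and C2 map to the same spinous code
  img1 <- rasterize_slice(cells_df(cx, cy, 1, "C1"), 0, 4, dom)
  img2 <- rasterize_slice(cells_df(cx, cy, 1, "C2"), 0, 4, dom)
  expect_identical(img1$img, img2$img)
  expect_true(all(img1$img == 1L))
  # modal tie in a pixel resolves to the lowest code
  tie <- cells_df(c(2, 2), c(2, 2.2), c(1, 1), c("C3", "C0"))
  img <- rasterize_slice(tie, 0, 4, dom)
  expect_identical(img$img[1, 1], 0L)
  # out-of-window cells are excluded; empty slice is fully masked
  img <- rasterize_slice(cells_df(cx, cy, 10, "C0"), 0, 4, dom)
  expect_true(all(img$mask))
  expect_true(is.na(sharpness_index(img)))
  # empty pixels are filled from the nearest occupied pixel, mask retained
  one <- rasterize_slice(cells_df(2, 2, 1, "C3"), 0, 4, dom)
  expect_true(all(one$img == 2L))
  expect_identical(sum(!one$mask), 1L)
})

test_that("the Sharpness Index matches its literal definition", {
  # constant image: extreme polarization, SI = 1 exactly
  for (v in 0:2) expect_identical(sharpness_index(matrix(v, 10, 10)), 1)
  # oracle equivalence on 1000 random 10x10 label images, exact
  set.seed(81)
  for (i in 1:1000) {
    img <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    expect_identical(sharpness_index(img), oracle_si(img))
  }
})

test_that("Sharpness Index bounds and band patterns", {
  set.seed(82)
  sis <- replicate(200, sharpness_index(
    matrix(sample(0:2, 100, replace = TRUE), 10, 10)))
  expect_true(all(sis >= -3 & sis <= 1))
  # period-2 alternating 0/2 columns: central differences skip one column,
  # so the pattern registers as perfectly smooth (the two-pixel stencil
  # reads equal values) — frozen from the loop oracle
  alt2 <- matrix(rep(c(0L, 2L), 5)[col(matrix(0, 10, 10))], 10, 10)
  expect_identical(oracle_si(alt2), 1)
  expect_identical(sharpness_index(alt2), 1)
  # period-4 banding 0,0,2,2,...: every interior pixel sees one full jump
  # across the two-pixel stencil in one direction; the loop oracle gives
  # 1 - 4/2 = -1 on this pattern
  alt4 <- matrix(rep(c(0L, 0L, 2L, 2L), 3)[col(matrix(0, 10, 10))][1:100], 10, 10)
  expect_identical(sharpness_index(alt4), oracle_si(alt4))
  expect_identical(sharpness_index(alt4), -1)
  # a two-band image (half 0, half 2) is sharper than the period-4 bands
  band <- matrix(0L, 10, 10); band[, 6:10] <- 2L
  expect_identical(sharpness_index(band), oracle_si(band))
  expect_gt(sharpness_index(band), sharpness_index(alt4))
  # SI = 1 iff all interior central differences vanish
  expect_lt(sharpness_index(band), 1)
})

test_that("Isolation Ratio identities", {
  # one connected chain: perfect self-aggregation
  chain <- cells_df(seq(0, 49) * 2, 0, 0, "C2")
  expect_identical(isolation_ratio(chain, "spinous", cell_diameter = 4), 0)
  # two equal distant clusters: 1/2 regardless of tie-break
  two <- cells_df(c(0, 1, 100, 101), 0, 0, "C3")
  expect_identical(isolation_ratio(two, "granular", cell_diameter = 4), 0.5)
  # n mutually distant singletons: (n - 1)/n
  n <- 7
  singles <- cells_df(seq_len(n) * 100, 0, 0, "C0")
  expect_equal(isolation_ratio(singles, "basal", cell_diameter = 4),
               (n - 1) / n)
  # no cell of the type: undefined
  expect_true(is.na(isolation_ratio(chain, "granular")))
  # rigid motion invariance (translation + rotation about z)
  set.seed(83)
  pts <- matrix(rnorm(60, sd = 6), 20, 3)
  df0 <- cells_df(pts[, 1], pts[, 2], pts[, 3], "C1")
  th <- 0.7; Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  pr <- pts %*% Rz + matrix(c(5, -3, 2), 20, 3, byrow = TRUE)
  df1 <- cells_df(pr[, 1], pr[, 2], pr[, 3], "C1")
  expect_identical(isolation_ratio(df0, "spinous", 4),
                   isolation_ratio(df1, "spinous", 4))
})

test_that("Ripley's K matches its definition and flags aggregation", {
  A <- 100 * 100
  # all points coincident: K(r) = A for any r > 0
  co <- cells_df(rep(50, 6), rep(50, 6), 1, "C0")
  k <- ripley_k(co, 0, 4, radii = c(0.5, 2), domain = c(100, 100))
  expect_true(all(k$K == A))
  # two tight clumps: K at short range far above the CSR parabola
  cl <- cells_df(c(rnorm(20, 25, 0.5), rnorm(20, 75, 0.5)),
                 c(rnorm(20, 25, 0.5), rnorm(20, 75, 0.5)), 1, "C0")
  k <- ripley_k(cl, 0, 4, radii = 3, domain = c(100, 100))
  expect_gt(k$K, pi * 9)
  # fewer than two points: undefined
  expect_true(is.na(ripley_k(cells_df(1, 1, 1, "C0"), 0, 4, 3,
                             domain = c(100, 100))$K))
})

test_that("Ripley's K is calibrated on complete spatial randomness", {
  # homogeneous Poisson pattern on a periodic square: K(r) ~ pi r^2
  set.seed(84)
  L <- 100; n <- 200; radii <- c(5, 10, 15, 20, 25)
  ks <- replicate(100, {
    df <- cells_df(runif(n, 0, L), runif(n, 0, L), 1, "C0")
    ripley_k(df, 0, 4, radii, domain = c(L, L), periodic_xy = TRUE)$K
  })
  rel <- rowMeans(ks) / (pi * radii^2)
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("cell counts group the spinous compartment", {
  df <- cells_df(1:10, 1, 1, rep(c("C0", "C1", "C2", "C3", "C2"), 2))
  ct <- count_cells(df)
  expect_identical(ct$C0, 2L); expect_identical(ct$C2, 4L)
  expect_identical(ct$C1_C2, ct$C1 + ct$C2)
  expect_identical(ct$total, 10L)
  empty <- count_cells(cells_df(numeric(), numeric(), numeric(), character()))
  expect_true(all(unlist(empty) == 0L))
})

test_that("metrics reports aggregate slices, isolation and counts", {
  set.seed(85)
  tis <- random_test_tissue(k = 8, m = 6, box = c(30, 30, 30),
                            types = rep(0:3, 2))
  mr <- metrics_report(tis, cell_diameter = 4)
  expect_s3_class(mr$slices, "tbl_df")
  expect_identical(nrow(mr$isolation), 3L)
  expect_identical(mr$counts$total, 8L)
  expect_true(all(mr$slices$si[!is.na(mr$slices$si)] <= 1))
  glanced <- glance(mr)
  expect_identical(glanced$total, 8L)
})
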