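#' Tissue state of the subcellular element model
#'
#' An `epistrat_tissue` bundles the discrete mechanical state: an `n x 3`
#' element position matrix (micrometres; positions are kept unwrapped, the
#' minimum-image convention is applied inside the force and rasterization
#' kernels), the element-to-cell map, per-element types (`interior` /
#' `membrane_adherent`), and a per-cell record of lineage stage and cycle
#' clocks. The basement membrane is the plane `z = 0`.
#'
#' `new_tissue()` assembles a tissue from tabular element and cell records
#' (the snapshot format); [init_tissue()] builds the standard starting
#' condition, a relaxed basal monolayer.
#'
#' @param elements a data frame with columns `element_id`, `cell_id`,
#'   `element_type`, `x`, `y`, `z`.
#' @param cells a data frame with columns `cell_id`, `cell_type` (one of
#'   `"C0".."C3"` or integer codes 0-3), `cycle_clock`, `cycle_length`,
#'   `n_target`, `growth_interval`, `next_growth`, `removal_state`,
#'   `next_shrink`, `birth_time`.
#' @param domain extents `c(Lx, Ly, Lz)` in \eqn{\mu}m.
#' @param periodic_xy lateral periodicity flag.
#' @param time simulation time (hours).
#' @return an `epistrat_tissue` object.
#' @export
new_tissue <- function(elements, cells, domain, periodic_xy = TRUE, time = 0) {
  stopifnot(is.data.frame(elements), is.data.frame(cells))
  ct <- cells$cell_type
  if (is.character(ct) || is.factor(ct))
    ct <- match(as.character(ct), c("C0", "C1", "C2", "C3")) - 1L
  if (anyNA(ct) || any(ct < 0L | ct > 3L))
    abort("`cell_type` must be C0..C3 (or codes 0-3)")
  et <- elements$element_type
  if (is.character(et) || is.factor(et))
    et <- as.integer(as.character(et) == "membrane_adherent")
  if (!all(elements$cell_id %in% cells$cell_id))
    abort("every element must belong to a listed cell")
  pos <- cbind(elements$x, elements$y, elements$z)
  if (!all(is.finite(pos))) abort("element positions must be finite")
  cellrec <- data.frame(
    cell_id = as.integer(cells$cell_id),
    cell_type = as.integer(ct),
    cycle_clock = cells$cycle_clock,
    cycle_length = cells$cycle_length,
    n_target = as.integer(cells$n_target),
    growth_interval = cells$growth_interval,
    next_growth = cells$next_growth,
    removal_state = as.integer(cells$removal_state),
    next_shrink = cells$next_shrink,
    birth_time = cells$birth_time,
    mat_stage = if (is.null(cells[["mat_stage"]]))
      integer(length(cells$cell_id)) else as.integer(cells[["mat_stage"]])
  )
  structure(list(pos = pos,
                 el_cell = as.integer(elements$cell_id),
                 el_type = as.integer(et),
                 el_id = as.integer(elements$element_id),
                 cell = cellrec,
                 domain = as.numeric(domain),
                 periodic_xy = isTRUE(periodic_xy),
                 time = time,
                 next_cell_id = max(as.integer(cells$cell_id), 0L) + 1L,
                 next_el_id = max(as.integer(elements$element_id), 0L) + 1L),
            class = "epistrat_tissue")
}

#' @export
print.epistrat_tissue <- function(x, ...) {
  cat("<epistrat_tissue> t =", format(x$time), "h;",
      nrow(x$cell), "cells,", nrow(x$pos), "elements;",
      "domain", paste(round(x$domain, 1), collapse = " x "), "um",
      if (x$periodic_xy) "(periodic x-y)" else "", "\n")
  counts <- table(factor(x$cell$cell_type, levels = 0:3,
                         labels = c("C0", "C1", "C2", "C3")))
  print(counts)
  invisible(x)
}

#' @export
as_tibble.epistrat_tissue <- function(x, ...) {
  pos <- x$pos
  tibble(
    element_id = x$el_id,
    cell_id = x$el_cell,
    cell_type = c("C0", "C1", "C2", "C3")[
      x$cell$cell_type[match(x$el_cell, x$cell$cell_id)] + 1L],
    element_type = ifelse(x$el_type == 1L, "membrane_adherent", "interior"),
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
}

#' Per-cell summary table
#'
#' @param tissue an `epistrat_tissue`.
#' @return a tibble with one row per cell: lineage stage, element count,
#'   centroid coordinates and cycle bookkeeping.
#' @export
tissue_cells <- function(tissue) {
  stopifnot(inherits(tissue, "epistrat_tissue"))
  cen <- .cell_centroids(tissue)
  cl <- tissue$cell
  idx <- match(cl$cell_id, as.integer(rownames(cen)))
  tibble(
    cell_id = cl$cell_id,
    cell_type = c("C0", "C1", "C2", "C3")[cl$cell_type + 1L],
    n_elements = as.integer(tabulate(match(tissue$el_cell, cl$cell_id),
                                     nbins = nrow(cl))),
    x = cen[idx, 1], y = cen[idx, 2], z = cen[idx, 3],
    cycle_clock = cl$cycle_clock,
    removal_state = ifelse(cl$removal_state == 1L, "shrinking", "none")
  )
}

# centroid matrix (rownames = cell id) on unwrapped coordinates
.cell_centroids <- function(tissue) {
  f <- factor(tissue$el_cell)
  out <- rowsum(tissue$pos, f) / as.vector(table(f))
  rownames(out) <- levels(f)
  out
}

# membrane-adherent flags: for basal cells, the elements in the lower half
# of the cell (below its centroid) are the adherent subset
.update_element_types <- function(tissue) {
  idx <- match(tissue$el_cell, tissue$cell$cell_id)
  ns <- tabulate(idx, nbins = nrow(tissue$cell))
  zsum <- numeric(nrow(tissue$cell))
  zacc <- rowsum(tissue$pos[, 3], idx)
  zsum[as.integer(rownames(zacc))] <- zacc
  cz <- (zsum / pmax(ns, 1L))[idx]
  ct <- tissue$cell$cell_type[idx]
  tissue$el_type <- as.integer(ct == 0L & tissue$pos[, 3] <= cz)
  tissue
}

# reflecting boundaries: the basement membrane at z = 0 is impenetrable,
# as is the domain top
.reflect_z <- function(pos, Lz) {
  z <- pos[, 3]
  z <- abs(z)
  over <- z > Lz
  z[over] <- 2 * Lz - z[over]
  pos[, 3] <- z
  pos
}

#' Initialize a basal monolayer
#'
#' Builds the standard starting tissue: an `nx x ny` grid of basal (C0)
#' cells resting on the basement membrane, one cell diameter apart, each a
#' cluster of `n_elements` elements relaxed (noise off) to mechanical
#' quasi-equilibrium before `t = 0`. Cycle clocks are staggered uniformly
#' over one cycle length so divisions are asynchronous; the layout is
#' deterministic given the session RNG state.
#'
#' @param nx,ny basal grid size (cells).
#' @param n_elements elements per mature cell.
#' @param cycle_length cell-cycle length (hours).
#' @param params an [mechanics_params()] object.
#' @param domain optional extents `c(Lx, Ly, Lz)`; defaults to
#'   `nx * cell_diameter` by `ny * cell_diameter` laterally and `8` cell
#'   diameters high.
#' @param periodic_xy lateral periodicity (default `TRUE`).
#' @param relax_steps deterministic relaxation steps before `t = 0`.
#' @param granular_lifetime granular lifetime (hours) stored as the C3
#'   "cycle length".
#' @return an `epistrat_tissue`.
#' @examples
#' set.seed(1)
#' tis <- init_tissue(2, 2, n_elements = 6, relax_steps = 40)
#' tis
#' @export
init_tissue <- function(nx = 10, ny = 10, n_elements = 10,
                        cycle_length = 24, params = mechanics_params(),
                        domain = NULL, periodic_xy = TRUE,
                        relax_steps = 150, granular_lifetime = 24) {
  d <- params$cell_diameter
  if (is.null(domain)) domain <- c(nx * d, ny * d, 8 * d)
  if (nx * d > domain[1] + 1e-9 || ny * d > domain[2] + 1e-9)
    abort("domain too small for the requested basal grid")
  n_cells <- nx * ny
  centers <- cbind(
    x = rep((seq_len(nx) - 0.5) * domain[1] / nx, times = ny),
    y = rep((seq_len(ny) - 0.5) * domain[2] / ny, each = nx),
    z = d / 2
  )
  pos <- matrix(0, n_cells * n_elements, 3)
  el_cell <- rep(seq_len(n_cells), each = n_elements)
  for (i in seq_len(n_cells)) {
    off <- matrix(runif(3 * n_elements, -0.4 * d, 0.4 * d), n_elements, 3)
    pos[el_cell == i, ] <- sweep(off, 2, centers[i, ], `+`)
  }
  pos <- .reflect_z(pos, domain[3])
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    cell_type = 0L,
    cycle_clock = runif(n_cells, 0, cycle_length),
    cycle_length = cycle_length,
    n_target = as.integer(n_elements),
    growth_interval = cycle_length / max(1, ceiling(n_elements / 2)),
    next_growth = Inf, # already at target size
    removal_state = 0L,
    next_shrink = Inf,
    birth_time = 0,
    mat_stage = 0L
  )
  tissue <- structure(list(pos = pos, el_cell = el_cell,
                           el_type = rep(0L, nrow(pos)),
                           el_id = seq_len(nrow(pos)),
                           cell = cells, domain = as.numeric(domain),
                           periodic_xy = isTRUE(periodic_xy), time = 0,
                           next_cell_id = n_cells + 1L,
                           next_el_id = nrow(pos) + 1L),
                      class = "epistrat_tissue")
  tissue <- .update_element_types(tissue)
  # deterministic relaxation (noise off) to mechanical quasi-equilibrium
  relax_params <- params
  relax_params$noise_amp <- 0
  for (k in seq_len(relax_steps)) {
    fa <- assemble_forces(tissue, relax_params)
    st <- step_positions(tissue$pos, fa$forces, relax_params)
    tissue$pos <- .reflect_z(st$pos, tissue$domain[3])
  }
  .update_element_types(tissue)
}
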