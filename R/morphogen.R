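#' Calcium morphogen grid
#'
#' The extracellular calcium field `s` lives on a regular 3D grid
#' superimposed on the tissue domain and evolves by reaction-diffusion
#'
#' \deqn{\partial s/\partial t = \nabla\cdot(D \nabla s) + f(c_2, c_3) - d_s s}
#'
#' with secretion source \eqn{f = \delta_{s1} c_2 + \delta_{s2} c_3}
#' (mature spinous and granular cells secrete; granular cells twice as
#' fast by default), first-order decay `ds_decay`, and a local diffusivity
#' reduced by element crowding (see [local_diffusivity()]). The
#' discretization is a conservative second-order central-difference flux
#' form with forward-Euler substeps; with uniform diffusivity it reduces
#' to the plain Laplacian form.
#'
#' @param domain tissue extents `c(Lx, Ly, Lz)` (\eqn{\mu}m).
#' @param h grid spacing (\eqn{\mu}m).
#' @param Ds_base baseline diffusivity (\eqn{\mu}m\eqn{^2}/hour).
#' @param ds_decay decay rate (1/hour).
#' @param delta_s1 secretion rate per mature spinous (C2) cell (units/hour).
#' @param delta_s2 secretion rate per granular (C3) cell (default
#'   `2 * delta_s1`).
#' @param dt_pde PDE substep (hours); defaults to 90% of the stability
#'   bound `h^2 / (6 Ds_base)`.
#' @param periodic_xy lateral periodicity (zero-flux top and bottom).
#' @return an `epistrat_morphogen_grid` with the concentration array `s`.
#' @export
morphogen_grid <- function(domain, h = 2.5, Ds_base = 360, ds_decay = 9,
                           delta_s1 = 1, delta_s2 = 2 * delta_s1,
                           dt_pde = 0.9 * h^2 / (6 * Ds_base),
                           periodic_xy = TRUE) {
  if (h <= 0) abort("grid spacing `h` must be > 0")
  if (Ds_base <= 0 || ds_decay < 0 || delta_s1 < 0 || delta_s2 < 0)
    abort("diffusivity must be > 0 and rates >= 0")
  dims <- pmax(2L, as.integer(ceiling(domain / h)))
  if (dt_pde > h^2 / (6 * Ds_base) + 1e-12)
    abort(sprintf(
      "PDE substep dt_pde = %g violates the stability bound h^2/(6 D) = %g",
      dt_pde, h^2 / (6 * Ds_base)))
  structure(list(s = array(0, dims), h = h, dims = dims,
                 Ds_base = Ds_base, ds_decay = ds_decay,
                 delta_s1 = delta_s1, delta_s2 = delta_s2,
                 dt_pde = dt_pde, periodic_xy = isTRUE(periodic_xy),
                 domain = as.numeric(domain), n_clipped = 0),
            class = "epistrat_morphogen_grid")
}

# voxel index (1-based triples) of positions, wrapped laterally and
# clamped to the boundary voxels otherwise
.voxel_of <- function(pos, grid) {
  idx <- matrix(0L, nrow(pos), 3)
  for (k in 1:3) {
    x <- pos[, k]
    if (grid$periodic_xy && k <= 2) x <- x %% grid$domain[k]
    i <- floor(x / grid$h) + 1L
    idx[, k] <- pmin(pmax(i, 1L), grid$dims[k])
  }
  idx
}

#' Secretion source field
#'
#' Each element of a mature spinous (C2) cell deposits
#' `delta_s1 / (elements in the cell)` per hour into its containing voxel,
#' and each element of a granular (C3) cell `delta_s2 / (elements)`, so
#' the per-cell totals equal the lineage-model production
#' `delta_s1 * #C2 + delta_s2 * #C3` exactly. Elements outside the domain
#' are clamped to the boundary voxel.
#'
#' @param tissue an `epistrat_tissue`.
#' @param grid an [morphogen_grid()].
#' @return an array of per-voxel source rates (units/hour) with attribute
#'   `total` (the deposited mass rate).
#' @export
deposit_secretion <- function(tissue, grid) {
  src <- array(0, grid$dims)
  ct <- tissue$cell$cell_type[match(tissue$el_cell, tissue$cell$cell_id)]
  sel <- which(ct %in% c(2L, 3L))
  if (length(sel)) {
    n_el <- tabulate(match(tissue$el_cell, tissue$cell$cell_id),
                     nbins = nrow(tissue$cell))
    per_el <- ifelse(ct[sel] == 2L, grid$delta_s1, grid$delta_s2) /
      n_el[match(tissue$el_cell[sel], tissue$cell$cell_id)]
    vox <- .voxel_of(tissue$pos[sel, , drop = FALSE], grid)
    lin <- vox[, 1] + grid$dims[1] * (vox[, 2] - 1L + grid$dims[2] * (vox[, 3] - 1L))
    acc <- rowsum(per_el, lin)
    src[as.integer(rownames(acc))] <- acc
  }
  attr(src, "total") <- sum(src)
  src
}

#' Crowding-dependent diffusivity field
#'
#' The diffusivity of a voxel is the baseline divided by its element count
#' (crowded voxels slow diffusion), averaged over the voxel itself and its
#' first-degree (face) neighbors. Empty voxels use a count floor of 1, so
#' the field never exceeds `Ds_base` and stays strictly positive.
#'
#' @param grid an [morphogen_grid()].
#' @param counts per-voxel element counts (array matching `grid$dims`);
#'   computed from `tissue` when supplied instead.
#' @param tissue optional `epistrat_tissue` used to tabulate counts.
#' @return an array of per-voxel diffusivities (\eqn{\mu}m\eqn{^2}/hour).
#' @export
local_diffusivity <- function(grid, counts = NULL, tissue = NULL) {
  if (is.null(counts)) {
    counts <- array(0L, grid$dims)
    if (!is.null(tissue) && nrow(tissue$pos)) {
      vox <- .voxel_of(tissue$pos, grid)
      lin <- vox[, 1] + grid$dims[1] * (vox[, 2] - 1L + grid$dims[2] * (vox[, 3] - 1L))
      tab <- table(lin)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  if (any(counts < 0)) abort("element counts must be >= 0")
  dv <- grid$Ds_base / pmax(counts, 1)
  # mean over self + face neighbors, wrapping laterally when periodic
  shift <- function(a, dim, by) {
    idx <- lapply(dim(a), seq_len)
    n <- dim(a)[dim]
    src <- seq_len(n) - by
    if (grid$periodic_xy && dim <= 2) src <- ((src - 1) %% n) + 1
    else src <- pmin(pmax(src, 1), n) # replicate edge (zero-flux analogue)
    idx[[dim]] <- src
    do.call(`[`, c(list(a), idx))
  }
  acc <- dv
  for (d in 1:3) acc <- acc + shift(dv, d, 1L) + shift(dv, d, -1L)
  acc / 7
}

#' Advance the morphogen field
#'
#' Runs `n_substeps` forward-Euler updates of the reaction-diffusion
#' equation in conservative flux form with face-averaged diffusivities.
#' The runtime stability bound `dt_pde <= h^2 / (6 max D)` is checked;
#' negative concentrations are clipped to zero and counted.
#'
#' @param grid an [morphogen_grid()].
#' @param source per-voxel source rates (from [deposit_secretion()]), or
#'   `NULL` for none.
#' @param diffusivity per-voxel diffusivity (from [local_diffusivity()]),
#'   or `NULL` for the uniform baseline.
#' @param n_substeps number of Euler substeps.
#' @return the grid with updated `s` and accumulated `n_clipped`.
#' @export
step_field <- function(grid, source = NULL, diffusivity = NULL,
                       n_substeps = 1L) {
  stopifnot(inherits(grid, "epistrat_morphogen_grid"))
  if (is.null(source)) source <- array(0, grid$dims)
  if (is.null(diffusivity)) diffusivity <- array(grid$Ds_base, grid$dims)
  dmax <- max(diffusivity)
  if (grid$dt_pde > grid$h^2 / (6 * dmax) + 1e-12)
    abort(sprintf(
      "PDE substep dt_pde = %g violates the stability bound h^2/(6 max D) = %g",
      grid$dt_pde, grid$h^2 / (6 * dmax)))
  out <- .step_field_cpp(as.vector(grid$s), as.vector(diffusivity),
                         as.vector(source), grid$ds_decay, grid$dt_pde,
                         as.integer(n_substeps), grid$h,
                         grid$dims[1], grid$dims[2], grid$dims[3],
                         grid$periodic_xy)
  grid$s <- array(out$s, grid$dims)
  grid$n_clipped <- grid$n_clipped + out$n_clipped
  grid
}

#' Sample the field at a cell
#'
#' The local signal level of a cell is the unweighted mean of the
#' concentration over the voxels containing its elements.
#'
#' @param tissue an `epistrat_tissue`.
#' @param grid an [morphogen_grid()].
#' @param cell_id one or more cell ids (default: all cells).
#' @return a named numeric vector of local signal levels.
#' @export
sample_field <- function(tissue, grid, cell_id = tissue$cell$cell_id) {
  vox <- .voxel_of(tissue$pos, grid)
  lin <- vox[, 1] + grid$dims[1] * (vox[, 2] - 1L + grid$dims[2] * (vox[, 3] - 1L))
  vals <- grid$s[lin]
  out <- vapply(cell_id, function(id) {
    sel <- tissue$el_cell == id
    if (!any(sel)) return(NA_real_)
    mean(vals[sel])
  }, numeric(1))
  names(out) <- as.character(cell_id)
  out
}
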