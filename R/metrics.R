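#' Rasterize a horizontal tissue slice
#'
#' Cells whose centroid lies in `[z, z + thickness)` are binned into an
#' `n_px x n_px` pixel image over the lateral domain. Each pixel carries
#' the modal layer code among the centroids it contains — 0 basal (C0),
#' 1 spinous (C1 and C2 share the code), 2 granular (C3) — with modal ties
#' resolved to the lowest code. Pixels without a centroid are filled from
#' the nearest occupied pixel but stay flagged in the `mask`; an empty
#' slice yields an all-masked image.
#'
#' @param cells a data frame of cell records with columns `x`, `y`, `z`,
#'   `cell_type` (an `epistrat_tissue` is accepted and summarised via
#'   [tissue_cells()]).
#' @param z slice floor (\eqn{\mu}m).
#' @param thickness slice thickness (\eqn{\mu}m; about one cell diameter).
#' @param domain lateral extents `c(Lx, Ly)` (\eqn{\mu}m).
#' @param n_px pixels per side (default 10).
#' @return an `epistrat_slice_image`: integer `img` (`n_px x n_px`),
#'   logical `mask` (`TRUE` where no centroid fell), `z`, `thickness`.
#' @export
rasterize_slice <- function(cells, z, thickness, domain = NULL, n_px = 10L) {
  if (inherits(cells, "epistrat_tissue")) {
    if (is.null(domain)) domain <- cells$domain[1:2]
    cells <- tissue_cells(cells)
  }
  if (is.null(domain)) abort("`domain` (Lx, Ly) is required with tabular input")
  if (thickness <= 0) abort("`thickness` must be > 0")
  sel <- cells$z >= z & cells$z < z + thickness
  img <- matrix(NA_integer_, n_px, n_px)
  mask <- matrix(TRUE, n_px, n_px)
  if (any(sel)) {
    code <- .layer_code(match(cells$cell_type[sel], c("C0", "C1", "C2", "C3")) - 1L)
    px <- pmin(pmax(floor((cells$x[sel] %% domain[1]) / domain[1] * n_px) + 1L, 1L), n_px)
    py <- pmin(pmax(floor((cells$y[sel] %% domain[2]) / domain[2] * n_px) + 1L, 1L), n_px)
    for (lin in unique(px + n_px * (py - 1L))) {
      hit <- (px + n_px * (py - 1L)) == lin
      tab <- tabulate(code[hit] + 1L, nbins = 3L)
      img[lin] <- which.max(tab) - 1L # which.max takes the lowest code on ties
      mask[lin] <- FALSE
    }
    if (any(mask)) {
      occ <- which(!mask, arr.ind = TRUE)
      emp <- which(mask, arr.ind = TRUE)
      for (k in seq_len(nrow(emp))) {
        d2 <- (occ[, 1] - emp[k, 1])^2 + (occ[, 2] - emp[k, 2])^2
        img[emp[k, 1], emp[k, 2]] <- img[occ[which.min(d2), 1], occ[which.min(d2), 2]]
      }
    }
  }
  structure(list(img = img, mask = mask, z = z, thickness = thickness),
            class = "epistrat_slice_image")
}

#' Sharpness Index of a slice image
#'
#' One minus the mean squared central differences of the pixel labels over
#' the interior of the image (the boundary ring is excluded):
#'
#' \deqn{SI = 1 - \frac{1}{2\,\#(I)} \sum_{(x,y)\in I}
#'   (g(x{+}1,y)-g(x{-}1,y))^2 + (g(x,y{+}1)-g(x,y{-}1))^2}
#'
#' `SI = 1` corresponds to an extremely polarized (constant-label) slice;
#' with labels in `{0, 1, 2}` the value is bounded below by `-3`. Masked
#' (filled) pixels are excluded from the interior sum but still provide
#' neighbor values; an image with no valid interior pixels gives `NA`.
#'
#' @param img an `epistrat_slice_image`, or a bare integer matrix of labels.
#' @return the Sharpness Index (scalar), or `NA_real_` if undefined.
#' @examples
#' sharpness_index(matrix(1L, 10, 10)) # constant image: exactly 1
#' @export
sharpness_index <- function(img) {
  mask <- NULL
  if (inherits(img, "epistrat_slice_image")) { mask <- img$mask; img <- img$img }
  if (!is.matrix(img)) abort("`img` must be a matrix or slice image")
  n <- nrow(img); m <- ncol(img)
  if (n < 3 || m < 3) return(NA_real_)
  if (is.null(mask)) mask <- matrix(FALSE, n, m)
  if (anyNA(img)) return(NA_real_)
  ix <- 2:(n - 1); iy <- 2:(m - 1)
  gx <- img[ix + 1, iy, drop = FALSE] - img[ix - 1, iy, drop = FALSE]
  gy <- img[ix, iy + 1, drop = FALSE] - img[ix, iy - 1, drop = FALSE]
  valid <- !mask[ix, iy, drop = FALSE]
  nI <- sum(valid)
  if (nI == 0) return(NA_real_)
  1 - sum((gx^2 + gy^2)[valid]) / (2 * nI)
}

#' Isolation Ratio of a cell type
#'
#' Cells of the type are grouped into clusters by centroid adjacency (two
#' cells touch when their centroid distance is at most `touch_factor` cell
#' diameters). The target cluster is the largest one; among equally large
#' clusters the one whose mean height is closest to the type's overall mean
#' height (its expected layer band) wins. The Isolation Ratio is the
#' fraction of the type's cells outside the target cluster: 0 means perfect
#' self-aggregation.
#'
#' @param cells a data frame with `x`, `y`, `z`, `cell_type` (or an
#'   `epistrat_tissue`).
#' @param cell_type the type to assess (`"C0"`..`"C3"`, or a layer name
#'   `"basal"`, `"spinous"`, `"granular"` grouping C1+C2).
#' @param cell_diameter cell diameter (\eqn{\mu}m) setting the adjacency
#'   scale.
#' @param touch_factor adjacency threshold in cell diameters.
#' @param domain,periodic_xy lateral extents and periodicity for
#'   minimum-image distances (taken from the tissue when one is supplied).
#' @return the Isolation Ratio in `[0, 1]`, or `NA_real_` when no cell of
#'   the type is present.
#' @export
isolation_ratio <- function(cells, cell_type, cell_diameter = 5,
                            touch_factor = 1.2, domain = NULL,
                            periodic_xy = FALSE) {
  if (inherits(cells, "epistrat_tissue")) {
    domain <- cells$domain
    periodic_xy <- cells$periodic_xy
    cells <- tissue_cells(cells)
  }
  types <- switch(cell_type,
                  basal = "C0", spinous = c("C1", "C2"), granular = "C3",
                  cell_type)
  sel <- cells$cell_type %in% types
  n <- sum(sel)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  xyz <- cbind(cells$x[sel], cells$y[sel], cells$z[sel])
  if (periodic_xy && !is.null(domain)) {
    dx <- outer(xyz[, 1], xyz[, 1], `-`)
    dy <- outer(xyz[, 2], xyz[, 2], `-`)
    dz <- outer(xyz[, 3], xyz[, 3], `-`)
    dx <- dx - domain[1] * round(dx / domain[1])
    dy <- dy - domain[2] * round(dy / domain[2])
    dmat <- stats::as.dist(sqrt(dx^2 + dy^2 + dz^2))
  } else {
    dmat <- dist(xyz)
  }
  # single-linkage cut at the touch threshold == connected components
  comp <- cutree(hclust(dmat, method = "single"),
                 h = touch_factor * cell_diameter)
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1) {
    band <- mean(xyz[, 3])
    zdist <- vapply(big, function(k) abs(mean(xyz[comp == k, 3]) - band),
                    numeric(1))
    big <- big[which.min(zdist)]
  }
  (n - max(sizes)) / n
}

#' Per-slice Ripley's K function
#'
#' The second-order statistic of the lateral point pattern of cell
#' centroids in a slice:
#' \deqn{K(r) = \frac{A}{n(n-1)} \sum_{i \neq j} 1[d_{ij} \le r]}
#' with `A` the slice area. Under complete spatial randomness
#' `K(r) = pi r^2`; clustering inflates K at short range. Distances use
#' the minimum image on periodic domains (which need no edge correction);
#' no edge correction is applied otherwise.
#'
#' @param cells a data frame with `x`, `y`, `z` (or an `epistrat_tissue`);
#'   filter by `cell_type` beforehand to analyse one type.
#' @param z,thickness slice window `[z, z + thickness)`.
#' @param radii radii at which to evaluate K (\eqn{\mu}m).
#' @param domain lateral extents `c(Lx, Ly)`.
#' @param periodic_xy minimum-image distances when `TRUE`.
#' @return a tibble with columns `r`, `K`, `n` (points in the slice);
#'   `K` is `NA` when fewer than 2 points fall in the slice.
#' @export
ripley_k <- function(cells, z, thickness, radii, domain = NULL,
                     periodic_xy = FALSE) {
  if (inherits(cells, "epistrat_tissue")) {
    domain <- cells$domain[1:2]
    periodic_xy <- cells$periodic_xy
    cells <- tissue_cells(cells)
  }
  if (is.null(domain)) abort("`domain` (Lx, Ly) is required with tabular input")
  sel <- cells$z >= z & cells$z < z + thickness
  n <- sum(sel)
  if (n < 2)
    return(tibble(r = radii, K = NA_real_, n = n))
  A <- domain[1] * domain[2]
  dx <- outer(cells$x[sel], cells$x[sel], `-`)
  dy <- outer(cells$y[sel], cells$y[sel], `-`)
  if (periodic_xy) {
    dx <- dx - domain[1] * round(dx / domain[1])
    dy <- dy - domain[2] * round(dy / domain[2])
  }
  dmat <- sqrt(dx^2 + dy^2)
  diag(dmat) <- Inf
  K <- vapply(radii, function(r) A * sum(dmat <= r) / (n * (n - 1)), numeric(1))
  tibble(r = radii, K = K, n = n)
}

#' Per-type cell counts
#'
#' @param cells a data frame with a `cell_type` column (or an
#'   `epistrat_tissue`).
#' @return a one-row tibble with counts `C0`, `C1`, `C2`, `C3`, the grouped
#'   spinous count `C1_C2`, and `total`.
#' @export
count_cells <- function(cells) {
  if (inherits(cells, "epistrat_tissue")) cells <- tissue_cells(cells)
  tab <- table(factor(cells$cell_type, levels = c("C0", "C1", "C2", "C3")))
  tibble(C0 = as.integer(tab["C0"]), C1 = as.integer(tab["C1"]),
         C2 = as.integer(tab["C2"]), C3 = as.integer(tab["C3"]),
         C1_C2 = as.integer(tab["C1"] + tab["C2"]),
         total = as.integer(sum(tab)))
}

#' Stratification metrics report
#'
#' Slices the tissue into one-cell-diameter-thick horizontal slices,
#' rasterizes each into a 10x10 label image, and reports the per-slice
#' Sharpness Index together with the per-layer Isolation Ratio and cell
#' counts.
#'
#' @param tissue an `epistrat_tissue`.
#' @param cell_diameter slice thickness and adjacency scale (\eqn{\mu}m).
#' @param n_px pixels per image side.
#' @param touch_factor Isolation Ratio adjacency threshold (diameters).
#' @return an `epistrat_metrics` list of tibbles: `slices` (`z`, `si`,
#'   `n_cells`), `isolation` (`layer`, `ir`), `counts`, and `time`.
#' @export
metrics_report <- function(tissue, cell_diameter = 5, n_px = 10L,
                           touch_factor = 1.2) {
  cells <- tissue_cells(tissue)
  zmax <- if (nrow(cells)) max(cells$z) else 0
  floors <- seq(0, max(zmax, cell_diameter), by = cell_diameter)
  slices <- purrr::map_dfr(floors, function(z0) {
    simg <- rasterize_slice(cells, z0, cell_diameter,
                            domain = tissue$domain[1:2], n_px = n_px)
    tibble(z = z0, si = sharpness_index(simg),
           n_cells = sum(cells$z >= z0 & cells$z < z0 + cell_diameter))
  })
  isolation <- purrr::map_dfr(c("basal", "spinous", "granular"), function(ly)
    tibble(layer = ly,
           ir = isolation_ratio(cells, ly, cell_diameter, touch_factor,
                                domain = tissue$domain,
                                periodic_xy = tissue$periodic_xy)))
  structure(list(slices = slices, isolation = isolation,
                 counts = count_cells(cells), time = tissue$time),
            class = "epistrat_metrics")
}

#' @export
print.epistrat_metrics <- function(x, ...) {
  cat("<epistrat_metrics> t =", format(x$time), "h\n")
  cat("counts:", paste(names(x$counts), unlist(x$counts), sep = "=",
                       collapse = " "), "\n")
  cat("median slice SI:", format(median(x$slices$si, na.rm = TRUE)), "\n")
  cat("isolation:", paste(x$isolation$layer, round(x$isolation$ir, 3),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}
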