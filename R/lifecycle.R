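#' Lifecycle parameters
#'
#' Timing constants of the discrete cell lifecycle. Basal (C0) and
#' proliferative spinous (C1) cells divide once their cycle clock reaches
#' `cycle_length` and they have grown back to `n_target` elements. Granular
#' (C3) cells live for `granular_lifetime` hours (tied to the lineage
#' removal rate as `ln 2 / d3` so agent-level removal matches the
#' population model), then shrink: one element is deleted per tick over
#' `removal_interval` hours until the cell disappears.
#'
#' @param cycle_length cell-cycle length of C0/C1 cells (hours).
#' @param n_target element count of a fully grown cell.
#' @param removal_interval duration of granular shrinkage (hours).
#' @param granular_lifetime granular lifetime before shrink onset (hours).
#' @param maturation_stages number of internal maturation stages a mature
#'   spinous cell passes through before turning granular. Each stage is
#'   left at rate `maturation_stages * d2`, so the mean residence time is
#'   exactly `1/d2` (matching the population model's flux `d2 c2` at
#'   steady state) while the conversion-age spread narrows as
#'   `1/sqrt(stages)`; `1` recovers the memoryless per-step hazard.
#' @param div_angle_tol angular jitter of division-plane normals (degrees;
#'   "roughly" parallel/perpendicular).
#' @return a validated `epistrat_lifecycle_params` list.
#' @export
lifecycle_params <- function(cycle_length = 24, n_target = 10,
                             removal_interval = 6,
                             granular_lifetime = log(2) / (log(2) / 30),
                             maturation_stages = 8,
                             div_angle_tol = 15) {
  if (cycle_length <= 0 || removal_interval <= 0 || granular_lifetime <= 0)
    abort("lifecycle durations must be > 0")
  if (n_target < 2) abort("`n_target` must be >= 2")
  if (div_angle_tol < 0 || div_angle_tol > 45)
    abort("`div_angle_tol` must be in [0, 45] degrees")
  if (maturation_stages < 1) abort("`maturation_stages` must be >= 1")
  structure(list(cycle_length = cycle_length, n_target = as.integer(n_target),
                 removal_interval = removal_interval,
                 granular_lifetime = granular_lifetime,
                 maturation_stages = as.integer(maturation_stages),
                 div_angle_tol = div_angle_tol),
            class = "epistrat_lifecycle_params")
}

#' Grow a cell by one element
#'
#' Cells regain volume after division by adding one element near the cell
#' centroid (uniform offset shorter than half the element equilibrium
#' separation) whenever the growth schedule is due, until the target count
#' is reached. The schedule advances by `cycle_length / (target - initial)`
#' so a daughter is back at full size by its next division.
#'
#' @param tissue an `epistrat_tissue`.
#' @param cell_id the cell to grow.
#' @param now current time (hours).
#' @param params an [mechanics_params()] (for the placement scale).
#' @return the updated tissue (invisibly unchanged when no growth is due).
#' @export
grow_cell <- function(tissue, cell_id, now, params = mechanics_params()) {
  i <- match(cell_id, tissue$cell$cell_id)
  if (is.na(i)) abort(sprintf("unknown cell %s", cell_id))
  rec <- tissue$cell[i, ]
  if (rec$removal_state != 0L) return(tissue)
  n_now <- sum(tissue$el_cell == cell_id)
  if (now < rec$next_growth || n_now >= rec$n_target) return(tissue)
  cen <- colMeans(tissue$pos[tissue$el_cell == cell_id, , drop = FALSE])
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  newpos <- cen + dir * runif(1, 0.05, 0.5) * params$sigma
  tissue$pos <- rbind(tissue$pos, newpos)
  tissue$el_cell <- c(tissue$el_cell, as.integer(cell_id))
  tissue$el_type <- c(tissue$el_type, 0L)
  tissue$el_id <- c(tissue$el_id, as.integer(tissue$next_el_id))
  tissue$next_el_id <- as.integer(tissue$next_el_id + 1L)
  tissue$cell$next_growth[i] <- if (n_now + 1L >= rec$n_target) Inf else
    rec$next_growth + rec$growth_interval
  tissue
}

#' Decide the mode and fates of a division
#'
#' For a basal (C0) cell in the base variant, division is always symmetric:
#' self-renewal (two C0) with probability `p0`, symmetric differentiation
#' (two C1) otherwise. In variants with asymmetric division the C0 division
#' is asymmetric (one C0 + one C1, plane parallel to the membrane) with
#' probability `2(1 - p0)` and symmetric self-renewal with probability
#' `2 p0 - 1`, which preserves the expected offspring composition of the
#' lineage model (expected C0 daughters per division = `2 p0` either way);
#' this requires `p0 >= 1/2` (probabilities are clamped at runtime when a
#' signal feedback pushes the effective `p0` below 1/2, in which case some
#' divisions become fully differentiative). A C1 cell stays proliferative
#' (two C1) with probability `p1` and exits the cycle (two C2) otherwise.
#'
#' @param cell_type `"C0"` or `"C1"` (codes 0/1 accepted).
#' @param p0,p1 effective division probabilities.
#' @param variant one of `"base"`, `"asym_division"`, `"selective_adhesion"`,
#'   `"signal"`.
#' @param tol angular jitter for the plane normal (degrees).
#' @return an `epistrat_division_event` list with `mode`, `plane_normal`
#'   and `daughter_types`.
#' @export
decide_division <- function(cell_type, p0, p1, variant = "base", tol = 15) {
  ct <- if (is.character(cell_type)) match(cell_type, c("C0", "C1")) - 1L
        else as.integer(cell_type)
  if (is.na(ct) || !ct %in% c(0L, 1L)) abort("only C0 and C1 cells divide")
  asym_on <- variant %in% c("asym_division", "selective_adhesion", "signal")
  if (ct == 0L) {
    if (asym_on) {
      p_asym <- min(1, max(0, 2 * (1 - p0)))
      if (runif(1) < p_asym) {
        mode <- "asymmetric"; daughters <- c("C0", "C1")
      } else {
        mode <- "symmetric"; daughters <- c("C0", "C0")
      }
      # clamped regime (p0 < 1/2): the non-asymmetric remainder is zero,
      # so the branch above always fires and composition follows 2p0 < 1
    } else {
      mode <- "symmetric"
      daughters <- if (runif(1) < p0) c("C0", "C0") else c("C1", "C1")
    }
  } else {
    mode <- "symmetric"
    daughters <- if (runif(1) < p1) c("C1", "C1") else c("C2", "C2")
  }
  normal <- .division_normal(mode, tol)
  structure(list(mode = mode, plane_normal = normal,
                 daughter_types = daughters),
            class = "epistrat_division_event")
}

# division-plane normal: symmetric divisions have a plane roughly
# perpendicular to the membrane (normal roughly horizontal); asymmetric
# divisions a plane roughly parallel (normal roughly vertical)
.division_normal <- function(mode, tol = 15) {
  phi <- runif(1, 0, 2 * pi)
  tilt <- runif(1, -tol, tol) * pi / 180
  if (mode == "asymmetric") {
    c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
  } else {
    c(cos(tilt) * cos(phi), cos(tilt) * sin(phi), sin(tilt))
  }
}

#' Execute a division event
#'
#' Splits the parent's elements by signed distance to the division plane
#' through the centroid. In asymmetric mode the daughter farther from the
#' basement membrane (greater mean z) receives the differentiated type and
#' the lower daughter stays basal. Daughters' cycle clocks restart at zero
#' and their growth schedules are reinitialized so they regrow to the
#' target count over one cycle. Degenerate partitions (an empty side) are
#' retried with a jittered plane up to 5 times.
#'
#' @param tissue an `epistrat_tissue`.
#' @param cell_id the dividing cell.
#' @param event an `epistrat_division_event` from [decide_division()].
#' @param lifecycle an [lifecycle_params()] object.
#' @param now current time (hours).
#' @return list with the updated `tissue` and `daughter_ids`.
#' @export
divide_cell <- function(tissue, cell_id, event, lifecycle = lifecycle_params(),
                        now = tissue$time) {
  i <- match(cell_id, tissue$cell$cell_id)
  if (is.na(i)) abort(sprintf("unknown cell %s", cell_id))
  sel <- which(tissue$el_cell == cell_id)
  if (length(sel) < 2L) abort("cannot divide a cell with fewer than 2 elements")
  rel <- sweep(tissue$pos[sel, , drop = FALSE], 2,
               colMeans(tissue$pos[sel, , drop = FALSE]))
  normal <- event$plane_normal
  upper <- NULL
  for (try in 1:5) {
    d <- as.vector(rel %*% normal)
    # partition by signed distance; ranks break ties so the split is
    # balanced (each daughter gets at least floor(n/2) elements)
    upper <- rank(d, ties.method = "first") > length(d) / 2
    if (any(upper) && any(!upper)) break
    upper <- NULL
    normal <- normal + rnorm(3, sd = 0.1)
    normal <- normal / sqrt(sum(normal^2))
  }
  if (is.null(upper)) abort("degenerate division partition")

  daughters <- event$daughter_types
  if (event$mode == "asymmetric") {
    # daughter with greater mean z differentiates; order types accordingly
    mz_up <- mean(tissue$pos[sel[upper], 3])
    mz_lo <- mean(tissue$pos[sel[!upper], 3])
    daughters <- if (mz_up >= mz_lo) c("C1", "C0") else c("C0", "C1")
  }
  type_code <- function(x) match(x, c("C0", "C1", "C2", "C3")) - 1L

  id_up <- as.integer(tissue$next_cell_id)
  id_lo <- as.integer(tissue$next_cell_id + 1L)
  tissue$next_cell_id <- as.integer(tissue$next_cell_id + 2L)
  tissue$el_cell[sel[upper]] <- id_up
  tissue$el_cell[sel[!upper]] <- id_lo

  mk <- function(id, type, n_init) {
    remaining <- max(lifecycle$n_target - n_init, 0L)
    gi <- if (remaining > 0) lifecycle$cycle_length / remaining else Inf
    clen <- if (type_code(type) == 3L) lifecycle$granular_lifetime else
      lifecycle$cycle_length
    data.frame(cell_id = as.integer(id), cell_type = type_code(type),
               cycle_clock = 0,
               cycle_length = clen, n_target = lifecycle$n_target,
               growth_interval = gi,
               next_growth = if (is.finite(gi)) now + gi else Inf,
               removal_state = 0L, next_shrink = Inf, birth_time = now,
               mat_stage = 0L)
  }
  tissue$cell <- rbind(tissue$cell[-i, ],
                       mk(id_up, daughters[1], sum(upper)),
                       mk(id_lo, daughters[2], sum(!upper)))
  rownames(tissue$cell) <- NULL
  list(tissue = tissue, daughter_ids = c(id_up, id_lo))
}

#' Mature spinous to granular transition
#'
#' A mature spinous (C2) cell progresses through
#' `lifecycle$maturation_stages` internal stages, leaving each with
#' per-step hazard `1 - exp(-stages * d2_eff * dt)`; completing the last
#' stage converts the cell to granular. The mean residence time is
#' `1/d2_eff` for any stage count — the discrete counterpart of the
#' lineage flux `d2 c2` — and a single stage recovers the memoryless
#' per-step hazard. In the signal variant `d2_eff` has been raised by the
#' local calcium level before the call. On transition the granular
#' lifetime clock starts at zero.
#'
#' @param tissue an `epistrat_tissue`.
#' @param cell_id a C2 cell.
#' @param d2_eff effective differentiation rate (1/hour).
#' @param dt lifecycle step (hours).
#' @param lifecycle an [lifecycle_params()] object.
#' @return list with the updated `tissue` and logical `transitioned`.
#' @export
differentiate_mature <- function(tissue, cell_id, d2_eff, dt,
                                 lifecycle = lifecycle_params()) {
  i <- match(cell_id, tissue$cell$cell_id)
  if (is.na(i) || tissue$cell$cell_type[i] != 2L)
    abort("`cell_id` must name a C2 cell")
  if (d2_eff < 0) abort("`d2_eff` must be >= 0")
  k <- lifecycle$maturation_stages
  hit <- FALSE
  if (runif(1) < 1 - exp(-k * d2_eff * dt)) {
    stage <- tissue$cell$mat_stage[i] + 1L
    if (stage >= k) {
      hit <- TRUE
      tissue$cell$cell_type[i] <- 3L
      tissue$cell$mat_stage[i] <- 0L
      tissue$cell$cycle_clock[i] <- 0
      tissue$cell$cycle_length[i] <- lifecycle$granular_lifetime
      tissue$cell$next_growth[i] <- Inf
    } else {
      tissue$cell$mat_stage[i] <- stage
    }
  }
  list(tissue = tissue, transitioned = hit)
}

#' Granular shrinkage and removal
#'
#' When a granular cell's lifetime clock reaches its cycle length it enters
#' the shrinking state: one element is deleted per tick (tick =
#' `removal_interval / element count at onset`) until none remain, at which
#' point the cell is removed from the tissue.
#'
#' @param tissue an `epistrat_tissue`.
#' @param cell_id a C3 cell.
#' @param now current time (hours).
#' @param lifecycle an [lifecycle_params()] object.
#' @return list with the updated `tissue`, `n_removed` elements deleted in
#'   this call, and logical `cell_removed`.
#' @export
remove_granular <- function(tissue, cell_id, now,
                            lifecycle = lifecycle_params()) {
  i <- match(cell_id, tissue$cell$cell_id)
  if (is.na(i) || tissue$cell$cell_type[i] != 3L)
    abort("`cell_id` must name a C3 cell")
  rec <- tissue$cell[i, ]
  n_removed <- 0L
  if (rec$removal_state == 0L) {
    if (rec$cycle_clock < rec$cycle_length) return(
      list(tissue = tissue, n_removed = 0L, cell_removed = FALSE))
    n_now <- sum(tissue$el_cell == cell_id)
    tissue$cell$removal_state[i] <- 1L
    tick <- lifecycle$removal_interval / max(n_now, 1L)
    tissue$cell$next_shrink[i] <- now
    tissue$cell$growth_interval[i] <- tick # reuse slot for the shrink tick
  }
  repeat {
    i <- match(cell_id, tissue$cell$cell_id)
    if (now < tissue$cell$next_shrink[i]) break
    sel <- which(tissue$el_cell == cell_id)
    if (length(sel) == 0L) break
    # delete the element farthest from the centroid (outside-in shrinkage)
    cen <- colMeans(tissue$pos[sel, , drop = FALSE])
    far <- sel[which.max(rowSums(sweep(tissue$pos[sel, , drop = FALSE], 2, cen)^2))]
    tissue$pos <- tissue$pos[-far, , drop = FALSE]
    tissue$el_cell <- tissue$el_cell[-far]
    tissue$el_type <- tissue$el_type[-far]
    tissue$el_id <- tissue$el_id[-far]
    n_removed <- n_removed + 1L
    tissue$cell$next_shrink[i] <- tissue$cell$next_shrink[i] +
      tissue$cell$growth_interval[i]
    if (length(sel) == 1L) break
  }
  cell_removed <- !any(tissue$el_cell == cell_id)
  if (cell_removed) {
    tissue$cell <- tissue$cell[tissue$cell$cell_id != cell_id, ]
    rownames(tissue$cell) <- NULL
  }
  list(tissue = tissue, n_removed = n_removed, cell_removed = cell_removed)
}
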