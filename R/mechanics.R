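#' Mechanical parameters of the subcellular element model
#'
#' Each cell is a cluster of point elements. Elements of the same cell
#' interact through a harmonic spring potential
#' \eqn{V_{intra} = \mu (r - r_0)^2 / 2}; elements of different cells through
#' a Lennard-Jones-type potential
#' \eqn{V_{inter} = F_{a,b}\,\epsilon ((\sigma/r)^{12} - (\sigma/r)^6)}
#' whose strength multiplier is `Fa` for cells of the same adhesion class
#' (basal / spinous / granular) and `Fb` across classes, truncated to exactly
#' zero beyond `inter_cutoff` (two cell diameters). Membrane-adherent
#' elements of basal cells additionally feel a constant-magnitude pull
#' toward the basement membrane, \eqn{V_{ext} = \epsilon_{ext} |r_i|},
#' within `membrane_cutoff` (half a cell diameter). Element positions follow
#' overdamped Langevin dynamics
#' \eqn{dY = M F \, dt + \eta \sqrt{dt}\, \xi} with mobility `M`, noise
#' amplitude `eta` and standard-normal `xi`; `noise_amp = 0` recovers the
#' deterministic gradient flow.
#'
#' Units: micrometres and hours. The energy, spring and adhesion scales are
#' calibrated package defaults (chosen so that a relaxed cell is roughly
#' spherical with diameter near `cell_diameter` and tissues relax on the
#' hour scale), not literature measurements.
#'
#' @param mu_spring intracellular spring constant (force/\eqn{\mu}m).
#' @param r0 spring rest length (\eqn{\mu}m).
#' @param eps Lennard-Jones energy scale.
#' @param sigma equilibrium separation where the intercellular potential is
#'   zero (\eqn{\mu}m).
#' @param Fa,Fb same-class / cross-class adhesion strength multipliers.
#' @param cell_diameter nominal packing diameter of a cell in tissue
#'   (\eqn{\mu}m): the centroid spacing of a relaxed monolayer. Sets the
#'   initial grid spacing, the metric slice thickness and cluster
#'   adjacency scales.
#' @param cluster_diameter diameter of the relaxed element cluster itself
#'   (\eqn{\mu}m, measured once from the default 10-element cell); the
#'   interaction cutoffs follow this scale: intercellular adhesion is cut
#'   at two cluster diameters and the membrane pull at half of one.
#' @param inter_cutoff intercellular interaction cutoff (\eqn{\mu}m,
#'   default two cell diameters).
#' @param eps_external strength of the basement-membrane attraction.
#' @param membrane_cutoff range of the membrane attraction (\eqn{\mu}m,
#'   default half a cell diameter).
#' @param f_clamp ceiling on the magnitude of a single intercellular pair
#'   force; deep core overlaps (transient after division) are resolved at
#'   bounded speed instead of exploding. Evaluations at separations below
#'   `0.05 sigma` are additionally clamped to that floor and counted.
#' @param mobility inverse friction (\eqn{\mu}m per unit force per hour).
#' @param noise_amp stochastic displacement scale (\eqn{\mu}m
#'   hour\eqn{^{-1/2}}).
#' @param dt_mech mechanics time step (hours).
#' @return a validated `epistrat_mechanics_params` list.
#' @examples
#' mp <- mechanics_params()
#' inter_pair_force(c(0, 0, 0), c(2.5, 0, 0), same_type = TRUE, mp)
#' @export
mechanics_params <- function(mu_spring = 5, r0 = 3,
                             eps = 1, sigma = 2, Fa = 1, Fb = 1,
                             cell_diameter = 4,
                             cluster_diameter = 3,
                             inter_cutoff = 2 * cluster_diameter,
                             eps_external = 3,
                             membrane_cutoff = cluster_diameter / 2,
                             f_clamp = 15,
                             mobility = 1, noise_amp = 0.1,
                             dt_mech = 0.02) {
  if (Fa < 0 || Fb < 0) abort("adhesion strengths `Fa`, `Fb` must be >= 0")
  if (sigma <= 0) abort("`sigma` must be > 0")
  if (inter_cutoff <= sigma)
    abort("`inter_cutoff` must exceed the equilibrium separation `sigma`")
  if (membrane_cutoff <= 0 || dt_mech <= 0 || mobility <= 0)
    abort("cutoffs, `mobility` and `dt_mech` must be > 0")
  if (mu_spring < 0 || r0 <= 0 || eps < 0 || eps_external < 0 || noise_amp < 0)
    abort("mechanical constants must be non-negative (r0 > 0)")
  if (f_clamp <= 0) abort("`f_clamp` must be > 0")
  structure(list(mu_spring = mu_spring, r0 = r0, eps = eps, sigma = sigma,
                 Fa = Fa, Fb = Fb, cell_diameter = cell_diameter,
                 cluster_diameter = cluster_diameter,
                 inter_cutoff = inter_cutoff, eps_external = eps_external,
                 membrane_cutoff = membrane_cutoff, f_clamp = f_clamp,
                 mobility = mobility,
                 noise_amp = noise_amp, dt_mech = dt_mech),
            class = "epistrat_mechanics_params")
}

#' Pairwise forces and potentials
#'
#' Reference scalar implementations of the three interaction laws, returning
#' the force on the element at `ri` exerted by the element at `rj` (or by
#' the basement membrane). These are the contracts the vectorised assembly
#' kernel must honour; [assemble_forces()] is the fast path.
#'
#' @param ri,rj positions (numeric 3-vectors, \eqn{\mu}m).
#' @param params an [mechanics_params()] object.
#' @return a numeric 3-vector (force), or a scalar for the `*_potential`
#'   functions.
#' @export
intra_pair_force <- function(ri, rj, params) {
  d <- ri - rj
  r <- sqrt(sum(d^2))
  if (r < 1e-12) abort("coincident elements: jitter positions before force evaluation")
  -params$mu_spring * (r - params$r0) * d / r
}

#' @rdname intra_pair_force
#' @export
intra_pair_potential <- function(ri, rj, params) {
  r <- sqrt(sum((ri - rj)^2))
  params$mu_spring * (r - params$r0)^2 / 2
}

#' @rdname intra_pair_force
#' @param same_type `TRUE` if the two cells share an adhesion class (then
#'   `Fa` applies), `FALSE` across classes (`Fb`).
#' @export
inter_pair_force <- function(ri, rj, same_type, params) {
  d <- ri - rj
  r <- sqrt(sum(d^2))
  if (r <= 0) abort("`ri` and `rj` must be distinct")
  if (r > params$inter_cutoff) return(c(0, 0, 0))
  reval <- max(r, 0.05 * params$sigma)
  Fab <- if (isTRUE(same_type)) params$Fa else params$Fb
  sr6 <- (params$sigma / reval)^6
  fmag <- Fab * params$eps * (12 * sr6^2 - 6 * sr6) / reval
  fmag <- sign(fmag) * min(abs(fmag), params$f_clamp)
  fmag * d / r
}

#' @rdname intra_pair_force
#' @export
inter_pair_potential <- function(ri, rj, same_type, params) {
  r <- sqrt(sum((ri - rj)^2))
  if (r > params$inter_cutoff) return(0)
  Fab <- if (isTRUE(same_type)) params$Fa else params$Fb
  sr6 <- (params$sigma / max(r, 0.05 * params$sigma))^6
  Fab * params$eps * (sr6^2 - sr6)
}

#' @rdname intra_pair_force
#' @param element a one-row element record with fields `x`, `y`, `z`,
#'   `element_type` (`"membrane_adherent"` or `"interior"`) and `cell_type`;
#'   alternatively a numeric 3-vector position of a basal membrane-adherent
#'   element.
#' @param membrane_z height of the basement membrane plane (\eqn{\mu}m).
#' @export
external_force <- function(element, membrane_z = 0, params = mechanics_params()) {
  if (is.numeric(element)) {
    z <- element[3]; adherent <- TRUE
  } else {
    z <- element$z
    adherent <- identical(element$element_type, "membrane_adherent") &&
      identical(as.character(element$cell_type), "C0")
  }
  r <- z - membrane_z
  if (!adherent || abs(r) > params$membrane_cutoff || abs(r) < 1e-12)
    return(c(0, 0, 0))
  c(0, 0, -params$eps_external * sign(r))
}

#' Neighbor index for short-range force assembly
#'
#' Builds the candidate pair list by spatial binning at a resolution of at
#' least the interaction cutoff (plus a Verlet skin, so the list stays valid
#' while no element has moved more than half the skin). Every element pair
#' within `inter_cutoff` is guaranteed to be listed.
#'
#' @param pos an `n x 3` position matrix.
#' @param params an [mechanics_params()] object.
#' @param domain domain extents `c(Lx, Ly, Lz)` (\eqn{\mu}m).
#' @param periodic_xy lateral periodicity flag.
#' @param skin Verlet skin width (\eqn{\mu}m).
#' @return an `epistrat_neighbor_index` with the 0-based pair matrix.
#' @export
neighbor_index <- function(pos, params, domain, periodic_xy = TRUE, skin = 1) {
  pairs <- .build_pairs_cpp(pos, params$inter_cutoff + skin,
                            domain[1], domain[2], periodic_xy)
  structure(list(pairs = pairs, skin = skin, ref_pos = pos,
                 cutoff = params$inter_cutoff + skin),
            class = "epistrat_neighbor_index")
}

# does `pos` still lie within the index's validity envelope?
.index_valid <- function(index, pos) {
  if (nrow(pos) != nrow(index$ref_pos)) return(FALSE)
  max_disp2 <- max(rowSums((pos - index$ref_pos)^2))
  max_disp2 <= (index$skin / 2)^2
}

#' Assemble forces on every element
#'
#' Sums intracellular spring forces (all element pairs of a cell),
#' intercellular selective Lennard-Jones forces over the neighbor index, and
#' the basement-membrane attraction on membrane-adherent elements of basal
#' cells. Internal pairwise forces are antisymmetric, so their total is the
#' zero vector.
#'
#' @param tissue an `epistrat_tissue` (see [init_tissue()]).
#' @param params an [mechanics_params()] object.
#' @param index optional [neighbor_index()]; when supplied (and still
#'   valid for the positions) forces are summed over its candidate pair
#'   list, otherwise a fused neighbor-search kernel is used. Both paths
#'   produce identical forces.
#' @return a list with `forces` (n x 3 matrix), `energy`, `n_clamped` and
#'   `n_coincident`.
#' @export
assemble_forces <- function(tissue, params, index = NULL) {
  pos <- tissue$pos
  aclass <- .layer_code(tissue$cell$cell_type[match(tissue$el_cell, tissue$cell$cell_id)])
  adherent <- as.integer(tissue$el_type == 1L)
  if (!is.null(index)) {
    if (!.index_valid(index, pos))
      index <- neighbor_index(pos, params, tissue$domain, tissue$periodic_xy)
    out <- .assemble_forces_cpp(pos, tissue$el_cell, as.integer(aclass), adherent,
                                index$pairs,
                                params$mu_spring, params$r0,
                                params$eps, params$sigma, params$Fa, params$Fb,
                                params$inter_cutoff, params$f_clamp,
                                params$eps_external, params$membrane_cutoff,
                                tissue$domain[1], tissue$domain[2],
                                tissue$periodic_xy)
    out$index <- index
    return(out)
  }
  .compute_forces_cpp(pos, tissue$el_cell, as.integer(aclass), adherent,
                      params$mu_spring, params$r0,
                      params$eps, params$sigma, params$Fa, params$Fb,
                      params$inter_cutoff, params$f_clamp,
                      params$eps_external, params$membrane_cutoff,
                      tissue$domain[1], tissue$domain[2],
                      tissue$periodic_xy)
}

#' Advance element positions one overdamped step
#'
#' Euler-Maruyama update `Y <- Y + M F dt + eta sqrt(dt) xi`. If any
#' displacement would exceed `sigma/2` the step is retried at half the time
#' step (forces held fixed) until it fits; the time actually advanced is
#' returned so a driver can consume the remainder with fresh forces.
#'
#' @param pos `n x 3` position matrix.
#' @param forces `n x 3` force matrix.
#' @param params an [mechanics_params()] object.
#' @param noise optional pre-drawn `n x 3` standard-normal matrix (draws
#'   from the session RNG when `NULL` and `noise_amp > 0`).
#' @param dt time step (hours); defaults to `params$dt_mech`.
#' @return list with the updated `pos`, the time `dt_taken` actually
#'   advanced, and `n_halvings`.
#' @export
step_positions <- function(pos, forces, params, noise = NULL,
                           dt = params$dt_mech, consume_all = FALSE) {
  if (dt <= 0) abort("`dt` must be > 0")
  n <- nrow(pos)
  if (is.null(noise)) {
    noise <- if (params$noise_amp > 0) matrix(rnorm(3L * n), n, 3L)
             else matrix(0, n, 3L)
  }
  drift <- params$mobility * forces
  bound2 <- (params$sigma / 2)^2
  halvings <- 0L
  advance <- function(step_dt, xi) {
    disp <- drift * step_dt + params$noise_amp * sqrt(step_dt) * xi
    k <- 0L
    while (n > 0L && max(rowSums(disp^2)) > bound2 && k < 20L) {
      step_dt <- step_dt / 2
      disp <- drift * step_dt + params$noise_amp * sqrt(step_dt) * xi
      k <- k + 1L
    }
    if (k >= 20L)
      warn("mechanics step reduced 20 times without satisfying the displacement bound")
    list(disp = disp, dt = step_dt, k = k)
  }
  first <- advance(dt, noise)
  pos <- pos + first$disp
  taken <- first$dt
  halvings <- first$k
  if (consume_all && halvings > 0L) {
    # consume the remainder of the step with the same force field, in
    # displacement-bounded chunks with fresh noise per chunk
    while (taken < dt - 1e-12) {
      xi <- if (params$noise_amp > 0) matrix(rnorm(3L * n), n, 3L)
            else matrix(0, n, 3L)
      nxt <- advance(dt - taken, xi)
      pos <- pos + nxt$disp
      taken <- taken + nxt$dt
      halvings <- halvings + nxt$k
      if (nxt$k >= 20L) break
    }
  }
  list(pos = pos, dt_taken = taken, n_halvings = halvings)
}
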