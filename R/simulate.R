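#' Calcium feedback on effective Ovol levels
#'
#' In the signal variant the local calcium level `s` feeds back on the
#' lineage through saturating Hill-type multipliers on the effective Ovol
#' levels: in mature spinous cells calcium stimulates Ovol1, raising the
#' differentiation rate (`alpha_eff = alpha (1 + k_alpha s/(s_half + s))`),
#' and in basal cells it is permissive to Ovol2, lowering self-renewal and
#' proliferation (`beta_eff = beta (1 + k_beta s/(s_half + s))`). The
#' multipliers are bounded, monotone in `s`, and reduce to no feedback at
#' `s = 0`.
#'
#' @param k_alpha gain of calcium on Ovol1 in C2 cells (dimensionless).
#' @param k_beta gain of calcium on Ovol2 in C0 cells.
#' @param s_half half-saturation calcium level (field units).
#' @return a validated `epistrat_signal_feedback` list.
#' @export
signal_feedback <- function(k_alpha = 4, k_beta = 40, s_half = 0.03) {
  if (k_alpha < 0 || k_beta < 0) abort("feedback gains must be >= 0")
  if (s_half <= 0) abort("`s_half` must be > 0")
  structure(list(k_alpha = k_alpha, k_beta = k_beta, s_half = s_half),
            class = "epistrat_signal_feedback")
}

#' Effective lineage rates for a cell
#'
#' Composes the Ovol regulation with the calcium feedback: outside the
#' signal variant the genotype's Ovol levels give the rates directly; in
#' the signal variant the local signal raises the effective Ovol1 of C2
#' cells (raising `d2`) and the effective Ovol2 of C0 cells (lowering `v0`
#' and `p0`). At `s = 0` the output equals [ovol_modulate()] exactly.
#'
#' @param cell_type `"C0".."C3"` (or codes 0-3).
#' @param reg an [ovol_regulation()] with the genotype's levels.
#' @param local_signal local calcium level (>= 0).
#' @param feedback an [signal_feedback()] object.
#' @param variant the model variant.
#' @return an [lineage_params()] with the effective rates.
#' @export
effective_rates <- function(cell_type, reg, local_signal = 0,
                            feedback = signal_feedback(),
                            variant = "base") {
  if (local_signal < 0) abort("`local_signal` must be >= 0")
  if (!identical(variant, "signal")) return(ovol_modulate(reg))
  ct <- if (is.character(cell_type)) match(cell_type, c("C0", "C1", "C2", "C3")) - 1L
        else as.integer(cell_type)
  hill <- local_signal / (feedback$s_half + local_signal)
  alpha <- reg$alpha * (if (ct == 2L) 1 + feedback$k_alpha * hill else 1)
  beta <- reg$beta * (if (ct == 0L) 1 + feedback$k_beta * hill else 1)
  ovol_modulate(reg, alpha = alpha, beta = beta)
}

#' Simulation configuration
#'
#' Assembles and validates the full configuration of a multiscale run. The
#' four variants are nested, each adding one mechanism: `base` has lineage
#' dynamics only (isotropic adhesion `Fa = Fb`, symmetric divisions);
#' `asym_division` adds asymmetric basal divisions; `selective_adhesion`
#' adds differential adhesion (`Fa > Fb`, default ratio 4); `signal` adds
#' the calcium feedback.
#'
#' @param variant one of `"base"`, `"asym_division"`, `"selective_adhesion"`,
#'   `"signal"`.
#' @param genotype a genotype name from [genotype_presets()].
#' @param duration simulated hours.
#' @param nx,ny initial basal grid (cells).
#' @param n_elements elements per mature cell.
#' @param domain optional `c(Lx, Ly, Lz)` (\eqn{\mu}m).
#' @param periodic_xy lateral periodicity.
#' @param snapshot_every snapshot/metrics cadence (hours).
#' @param max_cells cap on the live cell count; exceeding it ends the run
#'   early with partial outputs.
#' @param lineage an [ovol_regulation()] (genotype levels are applied on
#'   top of its weights).
#' @param mechanics an [mechanics_params()].
#' @param lifecycle an [lifecycle_params()].
#' @param morphogen a list of [morphogen_grid()] arguments (signal variant).
#' @param feedback an [signal_feedback()].
#' @return a validated `epistrat_config` list.
#' @examples
#' cfg <- simulation_config("asym_division", duration = 24, nx = 4, ny = 4)
#' @export
simulation_config <- function(variant = c("base", "asym_division",
                                          "selective_adhesion", "signal"),
                              genotype = "WT", duration = 120,
                              nx = 10, ny = 10, n_elements = 10,
                              domain = NULL, periodic_xy = TRUE,
                              snapshot_every = 12, max_cells = 2000,
                              lineage = ovol_regulation(),
                              mechanics = mechanics_params(),
                              lifecycle = lifecycle_params(n_target = n_elements),
                              morphogen = list(),
                              feedback = signal_feedback()) {
  variant <- match.arg(variant)
  presets <- genotype_presets()
  if (!genotype %in% presets$genotype)
    abort(sprintf("unknown genotype `%s` (use one of %s)", genotype,
                  paste(presets$genotype, collapse = ", ")))
  if (duration < 0) abort("`duration` must be >= 0")
  if (nx < 1 || ny < 1) abort("`nx`, `ny` must be >= 1")
  stopifnot(inherits(lineage, "epistrat_ovol_regulation"),
            inherits(mechanics, "epistrat_mechanics_params"),
            inherits(lifecycle, "epistrat_lifecycle_params"),
            inherits(feedback, "epistrat_signal_feedback"))
  gt <- presets[presets$genotype == genotype, ]
  lineage$alpha <- gt$alpha
  lineage$beta <- gt$beta
  if (variant %in% c("base", "asym_division")) {
    mechanics$Fb <- mechanics$Fa # isotropic adhesion in the first two variants
  } else if (mechanics$Fa == mechanics$Fb &&
             identical(mechanics$Fa, mechanics_params()$Fa)) {
    mechanics$Fa <- 2 # default selective ratio Fa = 4 Fb
    mechanics$Fb <- 0.5
  }
  if (variant != "base") {
    p0 <- ovol_modulate(lineage)$p0
    if (p0 < 0.5)
      abort(sprintf(paste0(
        "asymmetric division requires p0 >= 1/2 (2 p0 - 1 would be negative); ",
        "genotype %s gives p0 = %.3f"), genotype, p0))
  }
  if (is.null(domain))
    domain <- c(nx, ny, 8) * mechanics$cell_diameter
  structure(list(variant = variant, genotype = genotype, duration = duration,
                 nx = nx, ny = ny, n_elements = as.integer(n_elements),
                 domain = as.numeric(domain), periodic_xy = isTRUE(periodic_xy),
                 snapshot_every = snapshot_every, max_cells = max_cells,
                 lineage = lineage, mechanics = mechanics,
                 lifecycle = lifecycle, morphogen = morphogen,
                 feedback = feedback),
            class = "epistrat_config")
}

# per-cell local signal levels (zero outside the signal variant)
.cell_signals <- function(tissue, grid) {
  if (is.null(grid)) return(setNames(rep(0, nrow(tissue$cell)),
                                     tissue$cell$cell_id))
  sample_field(tissue, grid)
}

#' Run a multiscale simulation
#'
#' Executes the event loop of the multiscale model: each step advances the
#' mechanics (force assembly and overdamped position update), then the
#' lifecycle (granular removal, then divisions, then growth, with
#' signal-modulated effective rates sampled at decision time), then — in
#' the signal variant — deposits secretion and advances the morphogen
#' field. Runs are bit-reproducible for a given seed and configuration.
#'
#' @param config an [simulation_config()].
#' @param seed integer RNG seed; ignored when `reseed = FALSE` (the session
#'   RNG state is used as-is, e.g. when resuming from a snapshot whose
#'   stream state has been restored).
#' @param progress print occasional progress lines.
#' @param init optional `epistrat_tissue` to start from (a snapshot);
#'   defaults to a fresh relaxed basal monolayer. `duration` then counts
#'   from the snapshot time.
#' @param init_grid optional [morphogen_grid()] accompanying `init`.
#' @param reseed call `set.seed(seed)` before the run (default).
#' @return an `epistrat_run` with the final `tissue`, the morphogen `grid`
#'   (signal variant), a `snapshots` tibble of per-type counts over time,
#'   per-snapshot `metrics`, the `events` log, and bookkeeping fields.
#' @examples
#' \donttest{
#' cfg <- simulation_config("asym_division", duration = 24, nx = 4, ny = 4,
#'                          n_elements = 6)
#' run <- run_simulation(cfg, seed = 1)
#' run$snapshots
#' }
#' @export
run_simulation <- function(config, seed = 1, progress = FALSE,
                           init = NULL, init_grid = NULL, reseed = TRUE) {
  stopifnot(inherits(config, "epistrat_config"))
  if (reseed) set.seed(as.integer(seed))
  mech <- config$mechanics
  lcp <- config$lifecycle
  reg <- config$lineage
  fb <- config$feedback
  signal_on <- config$variant == "signal"
  base_rates <- ovol_modulate(reg)

  if (is.null(init)) {
    tissue <- init_tissue(config$nx, config$ny, n_elements = config$n_elements,
                          cycle_length = lcp$cycle_length, params = mech,
                          domain = config$domain,
                          periodic_xy = config$periodic_xy,
                          granular_lifetime = lcp$granular_lifetime)
  } else {
    stopifnot(inherits(init, "epistrat_tissue"))
    tissue <- init
  }
  grid <- init_grid
  n_pde_sub <- 0L
  if (signal_on) {
    if (is.null(grid))
      grid <- do.call(morphogen_grid,
                      c(list(domain = config$domain,
                             periodic_xy = config$periodic_xy),
                        config$morphogen))
    n_pde_sub <- max(1L, as.integer(round(mech$dt_mech / grid$dt_pde)))
  }

  t0_run <- tissue$time
  dt <- mech$dt_mech
  n_steps <- max(1L, as.integer(ceiling(config$duration / dt)))
  ev_time <- numeric(0); ev_what <- character(0)
  ev_cell <- integer(0); ev_detail <- character(0)
  snaps <- list()
  metrics <- list()
  next_snap <- 0
  early_stop <- FALSE
  log_event <- function(time, what, cell_id, detail = "") {
    k <- length(ev_time) + 1L
    ev_time[k] <<- time; ev_what[k] <<- what
    ev_cell[k] <<- as.integer(cell_id); ev_detail[k] <<- detail
  }

  last_snap <- -Inf
  take_snapshot <- function() {
    mr <- metrics_report(tissue, cell_diameter = mech$cell_diameter)
    metrics[[length(metrics) + 1L]] <<- mr
    snaps[[length(snaps) + 1L]] <<- cbind(tibble(time = tissue$time), mr$counts)
    last_snap <<- tissue$time
  }
  take_snapshot()
  next_snap <- t0_run + config$snapshot_every

  for (step in seq_len(n_steps)) {
    now <- tissue$time

    ## -- mechanics substep: one force assembly per step; the update
    ## consumes the full dt in displacement-bounded chunks (compiled)
    fa <- assemble_forces(tissue, mech)
    st <- .step_update_cpp(tissue$pos, fa$forces, mech$mobility,
                           mech$noise_amp, dt, mech$sigma / 2)
    if (st$dt_taken < dt - 1e-9)
      warn("mechanics step could not satisfy the displacement bound")
    tissue$pos <- .reflect_z(st$pos, tissue$domain[3])
    tissue$time <- now + dt
    tissue$cell$cycle_clock <- tissue$cell$cycle_clock + dt

    ## -- local signal levels (decision-time sampling)
    sig <- .cell_signals(tissue, grid)

    ## -- lifecycle, fixed order: removal > division > growth
    # granular shrinkage / removal (batched element deletion)
    now_t <- tissue$time
    enter <- which(tissue$cell$cell_type == 3L &
                     tissue$cell$removal_state == 0L &
                     tissue$cell$cycle_clock >= tissue$cell$cycle_length)
    if (length(enter)) {
      n_el_now <- tabulate(match(tissue$el_cell, tissue$cell$cell_id),
                           nbins = nrow(tissue$cell))
      tissue$cell$removal_state[enter] <- 1L
      tissue$cell$growth_interval[enter] <-
        lcp$removal_interval / pmax(n_el_now[enter], 1L) # shrink tick
      tissue$cell$next_shrink[enter] <- now_t
    }
    due <- which(tissue$cell$removal_state == 1L &
                   tissue$cell$next_shrink <= now_t)
    if (length(due)) {
      drop_el <- integer(0)
      cen_all <- .cell_centroids(tissue)
      for (k in due) {
        id <- tissue$cell$cell_id[k]
        sel <- which(tissue$el_cell == id)
        if (length(sel)) {
          cen <- cen_all[match(as.character(id), rownames(cen_all)), ]
          far <- sel[which.max(rowSums(
            sweep(tissue$pos[sel, , drop = FALSE], 2, cen)^2))]
          drop_el <- c(drop_el, far)
          log_event(now_t, "shrink", id, "1")
        }
        tissue$cell$next_shrink[k] <- tissue$cell$next_shrink[k] +
          tissue$cell$growth_interval[k]
      }
      if (length(drop_el)) {
        tissue$pos <- tissue$pos[-drop_el, , drop = FALSE]
        tissue$el_cell <- tissue$el_cell[-drop_el]
        tissue$el_type <- tissue$el_type[-drop_el]
        tissue$el_id <- tissue$el_id[-drop_el]
      }
      gone <- setdiff(tissue$cell$cell_id[tissue$cell$removal_state == 1L],
                      tissue$el_cell)
      if (length(gone)) {
        for (id in gone) log_event(now_t, "remove", id)
        tissue$cell <- tissue$cell[!tissue$cell$cell_id %in% gone, ]
        rownames(tissue$cell) <- NULL
      }
    }

    # per-cell effective rates, vectorised (signal variant composes the
    # calcium feedback with the Ovol regulation; see effective_rates())
    cl <- tissue$cell
    if (signal_on) {
      s_loc <- unname(sig[match(cl$cell_id, as.integer(names(sig)))])
      s_loc[is.na(s_loc)] <- 0
      hill <- s_loc / (fb$s_half + s_loc)
      a_eff <- reg$alpha * ifelse(cl$cell_type == 2L, 1 + fb$k_alpha * hill, 1)
      b_eff <- reg$beta * ifelse(cl$cell_type == 0L, 1 + fb$k_beta * hill, 1)
      rv_p0 <- reg$pmin + reg$pT / (1 + reg$lam * a_eff + reg$mu_reg * b_eff)
      rv_v0 <- reg$vmin + reg$vT / (1 + reg$omega * a_eff + reg$chi * b_eff)
      rv_d2 <- reg$dDKO + reg$sigma_c * a_eff + reg$xi * reg$beta
    } else {
      n_cl <- nrow(cl)
      rv_p0 <- rep(base_rates$p0, n_cl)
      rv_v0 <- rep(base_rates$v0, n_cl)
      rv_d2 <- rep(base_rates$d2, n_cl)
    }

    # divisions (C0/C1 due and fully grown)
    n_el_by_cell <- tabulate(match(tissue$el_cell, tissue$cell$cell_id),
                             nbins = nrow(tissue$cell))
    for (k in which(cl$cell_type %in% c(0L, 1L) & n_el_by_cell >= cl$n_target)) {
      id <- cl$cell_id[k]
      v <- if (cl$cell_type[k] == 0L) rv_v0[k] else base_rates$v1
      # divide at the mean inter-division time implied by the lineage
      # rate, so agent-level event rates match the ODE coefficients
      cycle_eff <- if (v > 0) 1 / v else Inf
      if (cl$cycle_clock[k] < cycle_eff) next
      ev <- decide_division(cl$cell_type[k], rv_p0[k], base_rates$p1,
                            variant = config$variant, tol = lcp$div_angle_tol)
      res <- divide_cell(tissue, id, ev, lcp, now = tissue$time)
      tissue <- res$tissue
      log_event(tissue$time,
                if (ev$mode == "asymmetric") "divide_asym" else "divide_sym",
                id, paste0(c("C0", "C1")[cl$cell_type[k] + 1L], "->",
                           paste(ev$daughter_types, collapse = "+")))
    }

    # C2 -> C3 staged maturation hazard (vectorised over mature cells)
    c2_rows <- which(cl$cell_type == 2L)
    c2_rows <- c2_rows[cl$cell_id[c2_rows] %in% tissue$cell$cell_id]
    if (length(c2_rows)) {
      k_st <- lcp$maturation_stages
      adv <- runif(length(c2_rows)) < 1 - exp(-k_st * rv_d2[c2_rows] * dt)
      if (any(adv)) {
        ids <- cl$cell_id[c2_rows][adv]
        rows <- match(ids, tissue$cell$cell_id)
        stage <- tissue$cell$mat_stage[rows] + 1L
        done <- stage >= k_st
        tissue$cell$mat_stage[rows] <- ifelse(done, 0L, stage)
        if (any(done)) {
          dr <- rows[done]
          tissue$cell$cell_type[dr] <- 3L
          tissue$cell$cycle_clock[dr] <- 0
          tissue$cell$cycle_length[dr] <- lcp$granular_lifetime
          tissue$cell$next_growth[dr] <- Inf
          for (id in ids[done]) log_event(tissue$time, "differentiate", id)
        }
      }
    }

    # growth by element addition
    due_grow <- tissue$cell$cell_id[tissue$cell$removal_state == 0L &
                                      tissue$time >= tissue$cell$next_growth]
    for (id in due_grow) tissue <- grow_cell(tissue, id, tissue$time, mech)

    tissue <- .update_element_types(tissue)

    ## -- morphogen substep
    if (signal_on) {
      src <- deposit_secretion(tissue, grid)
      Dfield <- local_diffusivity(grid, tissue = tissue)
      grid <- step_field(grid, src, Dfield, n_substeps = n_pde_sub)
    }

    ## -- snapshots / cap
    if (tissue$time + 1e-9 >= next_snap) {
      take_snapshot()
      next_snap <- next_snap + config$snapshot_every
      if (progress)
        message(sprintf("t = %6.1f h: %d cells, %d elements", tissue$time,
                        nrow(tissue$cell), nrow(tissue$pos)))
    }
    if (nrow(tissue$cell) > config$max_cells) {
      warn(sprintf("cell cap (%d) exceeded at t = %.1f h; stopping early",
                   config$max_cells, tissue$time))
      early_stop <- TRUE
      break
    }
  }
  if (tissue$time > last_snap + 1e-9) take_snapshot() # final state

  structure(list(config = config, seed = as.integer(seed), tissue = tissue,
                 grid = grid,
                 snapshots = dplyr::bind_rows(snaps),
                 metrics = metrics,
                 events = tibble(time = ev_time, event = ev_what,
                                 cell_id = ev_cell, detail = ev_detail),
                 early_stop = early_stop),
            class = "epistrat_run")
}

#' @export
print.epistrat_run <- function(x, ...) {
  cat("<epistrat_run>", x$config$variant, "variant,", x$config$genotype,
      "genotype, seed", x$seed, if (x$early_stop) "(stopped early)", "\n")
  print(x$tissue)
  invisible(x)
}

# fraction of slices whose dominant layer purity reaches `purity`
.slice_purity <- function(tissue, cell_diameter) {
  cells <- tissue_cells(tissue)
  if (!nrow(cells)) return(tibble(z = numeric(), purity = numeric()))
  floors <- seq(0, max(cells$z), by = cell_diameter)
  purrr::map_dfr(floors, function(z0) {
    sel <- cells$z >= z0 & cells$z < z0 + cell_diameter
    if (!any(sel)) return(tibble(z = z0, purity = NA_real_, n = 0L))
    code <- .layer_code(match(cells$cell_type[sel], c("C0", "C1", "C2", "C3")) - 1L)
    tibble(z = z0, purity = max(tabulate(code + 1L, 3L)) / sum(sel),
           n = sum(sel))
  })
}

# coarse occupancy check for internal cavities: fraction of empty
# cell-diameter voxels lying below the top of their own column. Element
# positions (not centroids) define occupancy — ten elements per cell
# fill space, so sound tissue reads as solid while real holes remain.
.cavity_fraction <- function(tissue, cell_diameter) {
  cells <- tissue_cells(tissue)
  if (!nrow(cells) || !nrow(tissue$pos)) return(0)
  nx <- max(1L, as.integer(round(tissue$domain[1] / cell_diameter)))
  ny <- max(1L, as.integer(round(tissue$domain[2] / cell_diameter)))
  px <- tissue$pos[, 1]; py <- tissue$pos[, 2]; pz <- tissue$pos[, 3]
  ix <- pmin(pmax(floor((px %% tissue$domain[1]) / cell_diameter) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((py %% tissue$domain[2]) / cell_diameter) + 1L, 1L), ny)
  iz <- pmax(floor(pz / cell_diameter) + 1L, 1L)
  nz <- max(iz)
  occ <- array(FALSE, c(nx, ny, nz))
  occ[cbind(ix, iy, iz)] <- TRUE
  tops <- apply(occ, c(1, 2), function(col) if (any(col)) max(which(col)) else 0L)
  interior <- 0L; empty <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (tops[i, j] < 1L) next
    interior <- interior + tops[i, j]
    empty <- empty + sum(!occ[i, j, seq_len(tops[i, j])])
  }
  if (interior == 0L) 0 else empty / interior
}

#' Classify the spatial outcome of a run
#'
#' Rule-based version of the visual pattern classes used to map the
#' adhesion sweep: `stratified` requires dominant-layer purity of at least
#' `purity` in at least `purity_frac` of the occupied slices, an Isolation
#' Ratio of at most `ir_max` for every layer, and no internal cavity;
#' otherwise runs are labelled `cavity` (occupancy holes), `salt_pepper`
#' (strong intermixing, median slice SI below `si_saltpepper`), `compact`
#' (tissue squeezed well below its expected height) or `mixed`.
#'
#' @param run an `epistrat_run` (or an `epistrat_tissue`).
#' @param purity,purity_frac slice-purity thresholds.
#' @param ir_max Isolation Ratio ceiling per layer.
#' @param cavity_max tolerated empty-voxel fraction below the tissue top.
#' @param si_saltpepper median-SI boundary between salt-pepper and mixed.
#' @param compact_frac height fraction below which the tissue is compact.
#' @return a one-row tibble: `pattern`, `median_si`, `max_ir`,
#'   `purity_ok_frac`, `cavity_frac`, `height`, `expected_height`.
#' @export
classify_pattern <- function(run, purity = 0.7, purity_frac = 0.7,
                             ir_max = 0.1, cavity_max = 0.1,
                             si_saltpepper = 0.3, compact_frac = 0.6) {
  tissue <- if (inherits(run, "epistrat_run")) run$tissue else run
  d <- if (inherits(run, "epistrat_run")) run$config$mechanics$cell_diameter else 5
  mr <- metrics_report(tissue, cell_diameter = d)
  pur <- .slice_purity(tissue, d)
  pur <- pur[pur$n > 0, ]
  purity_ok <- if (nrow(pur)) mean(pur$purity >= purity) else 0
  max_ir <- max(mr$isolation$ir, na.rm = TRUE)
  cav <- .cavity_fraction(tissue, d)
  cells <- tissue_cells(tissue)
  height <- if (nrow(cells)) max(cells$z) else 0
  expected <- nrow(cells) / (tissue$domain[1] * tissue$domain[2] / d^2) * d
  med_si <- median(mr$slices$si, na.rm = TRUE)
  pattern <- if (cav > cavity_max) "cavity"
    else if (purity_ok >= purity_frac && max_ir <= ir_max) "stratified"
    else if (is.finite(med_si) && med_si < si_saltpepper) "salt_pepper"
    else if (height < compact_frac * expected) "compact"
    else "mixed"
  tibble(pattern = pattern, median_si = med_si, max_ir = max_ir,
         purity_ok_frac = purity_ok, cavity_frac = cav,
         height = height, expected_height = expected)
}

#' Parameter sweep with pattern classification
#'
#' Runs replicate simulations along one configuration axis and classifies
#' each outcome with [classify_pattern()]. The special axis `"Fa_over_Fb"`
#' rescales the same-class adhesion strength `Fa = value * Fb` at fixed
#' `Fb`.
#'
#' @param config an [simulation_config()] template.
#' @param axis a configuration field name (e.g. `"Fa_over_Fb"`,
#'   `"duration"`, or a mechanics field).
#' @param values values to sweep.
#' @param seeds seeds per value (replicates).
#' @return a tibble with one row per (value, seed) carrying the
#'   classification columns.
#' @export
sweep_parameter <- function(config, axis, values, seeds = 1:3) {
  stopifnot(inherits(config, "epistrat_config"))
  purrr::map_dfr(values, function(v) {
    cfg <- config
    if (identical(axis, "Fa_over_Fb")) {
      cfg$mechanics$Fa <- v * cfg$mechanics$Fb
    } else if (axis %in% names(cfg$mechanics)) {
      cfg$mechanics[[axis]] <- v
    } else if (axis %in% names(cfg)) {
      cfg[[axis]] <- v
    } else abort(sprintf("unknown sweep axis `%s`", axis))
    purrr::map_dfr(seeds, function(s) {
      run <- run_simulation(cfg, seed = s)
      cbind(tibble(!!axis := v, seed = s), classify_pattern(run))
    })
  })
}
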