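#' Load a simulation configuration from YAML
#'
#' Reads a structured text configuration and builds a validated
#' [simulation_config()]. Top-level keys select the variant, genotype,
#' duration, geometry and seed; the sections `lineage`, `mechanics`,
#' `lifecycle`, `morphogen` and `feedback` override individual parameters
#' of the corresponding constructors. Absent fields take package defaults;
#' unknown keys are rejected with the offending name.
#'
#' @param path path to a YAML file.
#' @return a list with the validated `config` and the `seed` (if given).
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("variant: base\nduration: 24\nnx: 4\nny: 4", f)
#' load_config(f)$config$variant
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_keys <- c("variant", "genotype", "duration", "nx", "ny", "n_elements",
                "domain", "periodic_xy", "snapshot_every", "max_cells", "seed")
  section_keys <- c("lineage", "mechanics", "lifecycle", "morphogen", "feedback")
  unknown <- setdiff(names(raw), c(top_keys, section_keys))
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  check_section <- function(name, allowed) {
    sec <- raw[[name]]
    if (is.null(sec)) return(list())
    bad <- setdiff(names(sec), allowed)
    if (length(bad))
      abort(sprintf("unknown key(s) in [%s]: %s", name,
                    paste(bad, collapse = ", ")))
    sec
  }
  lin <- check_section("lineage", setdiff(names(formals(ovol_regulation)), "base"))
  mec <- check_section("mechanics", names(formals(mechanics_params)))
  lif <- check_section("lifecycle", names(formals(lifecycle_params)))
  mor <- check_section("morphogen", setdiff(names(formals(morphogen_grid)),
                                            c("domain", "periodic_xy")))
  fdb <- check_section("feedback", names(formals(signal_feedback)))
  args <- raw[intersect(names(raw), setdiff(top_keys, "seed"))]
  args$lineage <- do.call(ovol_regulation, lin)
  args$mechanics <- do.call(mechanics_params, mec)
  if (!is.null(raw$n_elements) && is.null(lif$n_target))
    lif$n_target <- raw$n_elements
  args$lifecycle <- do.call(lifecycle_params, lif)
  args$morphogen <- mor
  args$feedback <- do.call(signal_feedback, fdb)
  config <- do.call(simulation_config, args)
  list(config = config, seed = raw$seed)
}

#' Write and read tissue snapshots
#'
#' A snapshot is a pair of plain-text CSV tables sharing a path prefix:
#' `<prefix>_elements.csv` (element id, owning cell, element type and
#' position at full precision) and `<prefix>_cells.csv` (per-cell lineage
#' stage and cycle bookkeeping), plus `<prefix>_meta.yaml` (domain,
#' periodicity, time and, optionally, the serialized RNG state so a run
#' can be resumed bit-identically). Reading a snapshot reproduces element
#' positions, types, clocks and field values exactly.
#'
#' @param tissue an `epistrat_tissue`.
#' @param prefix path prefix for the snapshot files.
#' @param grid optional [morphogen_grid()] written to `<prefix>_grid.txt`.
#' @param save_rng serialize `.Random.seed` into the metadata.
#' @return `write_snapshot()` returns the prefix invisibly;
#'   `read_snapshot()` returns a list with `tissue`, `grid` (or `NULL`)
#'   and `rng_state` (or `NULL`).
#' @export
write_snapshot <- function(tissue, prefix, grid = NULL, save_rng = FALSE) {
  stopifnot(inherits(tissue, "epistrat_tissue"))
  el <- as.data.frame(as_tibble(tissue))
  utils::write.csv(format(el, digits = 17, trim = TRUE, scientific = TRUE),
                   paste0(prefix, "_elements.csv"), row.names = FALSE,
                   quote = FALSE)
  cl <- tissue$cell
  cl$cell_type <- c("C0", "C1", "C2", "C3")[cl$cell_type + 1L]
  utils::write.csv(format(cl, digits = 17, trim = TRUE, scientific = FALSE),
                   paste0(prefix, "_cells.csv"), row.names = FALSE,
                   quote = FALSE)
  # numeric metadata goes through text at full precision (YAML would
  # round doubles and break bit-identical resumption)
  meta <- list(schema = "epistrat-snapshot-1",
               domain = format(tissue$domain, digits = 17, trim = TRUE),
               periodic_xy = tissue$periodic_xy,
               time = format(tissue$time, digits = 17, trim = TRUE),
               next_cell_id = tissue$next_cell_id,
               next_el_id = tissue$next_el_id)
  if (save_rng) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    meta$rng_state <- get(".Random.seed", envir = globalenv())
  }
  yaml::write_yaml(meta, paste0(prefix, "_meta.yaml"))
  if (!is.null(grid)) write_field(grid, paste0(prefix, "_grid.txt"))
  invisible(prefix)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(prefix) {
  fe <- paste0(prefix, "_elements.csv")
  fc <- paste0(prefix, "_cells.csv")
  fm <- paste0(prefix, "_meta.yaml")
  for (f in c(fe, fc, fm)) if (!file.exists(f))
    abort(sprintf("missing snapshot file: %s", f))
  el <- utils::read.csv(fe)
  cl <- utils::read.csv(fc)
  meta <- yaml::read_yaml(fm)
  for (col in c("cycle_clock", "cycle_length", "growth_interval",
                "next_growth", "next_shrink", "birth_time"))
    cl[[col]] <- as.numeric(cl[[col]])
  tissue <- new_tissue(el, cl, domain = as.numeric(unlist(meta$domain)),
                       periodic_xy = isTRUE(meta$periodic_xy),
                       time = as.numeric(meta$time))
  tissue$next_cell_id <- as.integer(meta$next_cell_id)
  tissue$next_el_id <- as.integer(meta$next_el_id)
  fg <- paste0(prefix, "_grid.txt")
  grid <- if (file.exists(fg)) read_field(fg) else NULL
  rng <- if (!is.null(meta$rng_state)) as.integer(unlist(meta$rng_state)) else NULL
  list(tissue = tissue, grid = grid, rng_state = rng)
}

#' Plain-text morphogen field dumps
#'
#' Writes the 3D concentration array as a text file: a header with
#' dimensions, spacing and origin, followed by one voxel value per line in
#' column-major order, at full precision.
#'
#' @param grid an [morphogen_grid()].
#' @param path output path.
#' @return `write_field()` the path invisibly; `read_field()` the grid.
#' @export
write_field <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# epistrat-field-1",
               paste("dims", paste(grid$dims, collapse = " ")),
               paste("spacing", format(grid$h, digits = 17)),
               paste("origin 0 0 0"),
               paste("Ds_base", format(grid$Ds_base, digits = 17)),
               paste("ds_decay", format(grid$ds_decay, digits = 17)),
               paste("delta_s1", format(grid$delta_s1, digits = 17)),
               paste("delta_s2", format(grid$delta_s2, digits = 17)),
               paste("dt_pde", format(grid$dt_pde, digits = 17)),
               paste("periodic_xy", as.integer(grid$periodic_xy)),
               paste("domain", paste(format(grid$domain, digits = 17),
                                     collapse = " "))), con)
  writeLines(format(as.vector(grid$s), digits = 17, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# epistrat-field"))
    abort(sprintf("%s: not an epistrat field dump (line 1)", path))
  hdr <- list()
  i <- 2L
  while (i <= length(lines) && grepl("^[a-zA-Z]", lines[i])) {
    parts <- strsplit(lines[i], " +")[[1]]
    hdr[[parts[1]]] <- as.numeric(parts[-1])
    i <- i + 1L
  }
  dims <- as.integer(hdr$dims)
  vals <- as.numeric(lines[i:length(lines)])
  if (length(vals) != prod(dims))
    abort(sprintf("%s: expected %d voxel values, found %d (line %d onward)",
                  path, prod(dims), length(vals), i))
  grid <- morphogen_grid(domain = hdr$domain, h = hdr$spacing,
                         Ds_base = hdr$Ds_base, ds_decay = hdr$ds_decay,
                         delta_s1 = hdr$delta_s1, delta_s2 = hdr$delta_s2,
                         dt_pde = hdr$dt_pde,
                         periodic_xy = hdr$periodic_xy == 1)
  grid$s <- array(vals, dims)
  grid
}

#' Run manifest
#'
#' A structured-text record sufficient to reproduce a run: the fully
#' resolved configuration, the seed, the package version and wall-clock
#' times.
#'
#' @param run an `epistrat_run`.
#' @param path optional output path (YAML); when `NULL` the manifest list
#'   is returned without writing.
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(run, path = NULL) {
  stopifnot(inherits(run, "epistrat_run"))
  cfg <- run$config
  flatten <- function(x) {
    if (inherits(x, "epistrat_ovol_regulation")) x$base <- flatten(x$base)
    if (is.list(x)) lapply(unclass(x), flatten) else x
  }
  man <- list(schema = "epistrat-manifest-1",
              package_version = as.character(utils::packageVersion("epistrat")),
              seed = run$seed,
              early_stop = run$early_stop,
              final_time = run$tissue$time,
              config = flatten(cfg))
  if (!is.null(path)) {
    yaml::write_yaml(man, path)
    return(invisible(man))
  }
  man
}
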