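#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a lineage trajectory
#'
#' @param x an `epistrat_lineage_sim`.
#' @param ... unused.
#' @return a long tibble with columns `t`, `compartment`, `cells`.
#' @export
tidy.epistrat_lineage_sim <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), c("c0", "c1", "c2", "c3"),
                      names_to = "compartment", values_to = "cells")
}

#' @rdname tidy.epistrat_lineage_sim
#' @return for `glance()`: a one-row tibble with the final populations and
#'   the effective rates used.
#' @export
glance.epistrat_lineage_sim <- function(x, ...) {
  last <- x[nrow(x), ]
  p <- attr(x, "params")
  tibble(t_end = last$t, c0 = last$c0, c1 = last$c1, c2 = last$c2,
         c3 = last$c3, total = last$c0 + last$c1 + last$c2 + last$c3,
         p0 = p$p0, v0 = p$v0, d2 = p$d2)
}

#' Tidy a simulation run
#'
#' @param x an `epistrat_run`.
#' @param ... unused.
#' @return a long tibble of per-type counts over snapshot times.
#' @export
tidy.epistrat_run <- function(x, ...) {
  tidyr::pivot_longer(x$snapshots, c("C0", "C1", "C2", "C3", "C1_C2"),
                      names_to = "type", values_to = "cells")
}

#' @rdname tidy.epistrat_run
#' @return for `glance()`: a one-row tibble with the final counts, median
#'   slice Sharpness Index, the worst per-layer Isolation Ratio and run
#'   bookkeeping.
#' @export
glance.epistrat_run <- function(x, ...) {
  mr <- x$metrics[[length(x$metrics)]]
  cbind(tibble(variant = x$config$variant, genotype = x$config$genotype,
               seed = x$seed, t_end = x$tissue$time,
               early_stop = x$early_stop),
        mr$counts,
        tibble(median_si = median(mr$slices$si, na.rm = TRUE),
               max_ir = max(mr$isolation$ir, na.rm = TRUE)))
}

#' Tidy a metrics report
#'
#' @param x an `epistrat_metrics`.
#' @param ... unused.
#' @return the per-slice tibble (`z`, `si`, `n_cells`).
#' @export
tidy.epistrat_metrics <- function(x, ...) x$slices

#' @rdname tidy.epistrat_metrics
#' @export
glance.epistrat_metrics <- function(x, ...) {
  cbind(tibble(time = x$time,
               median_si = median(x$slices$si, na.rm = TRUE),
               max_ir = max(x$isolation$ir, na.rm = TRUE)),
        x$counts)
}
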