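# Independent reference implementations used as oracles. These are written
# as literal loops over the defining formulas and deliberately share no
# code with the package kernels.

# all-pairs force assembly: spring within cells, truncated Lennard-Jones
# between cells (with the same short-range clamps the model defines),
# constant membrane pull on adherent elements
oracle_forces <- function(pos, cell, aclass, adherent, p, Lx, Ly, periodic) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  mimg <- function(d, L) if (periodic) d - L * round(d / L) else d
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- pos[i, ] - pos[j, ]
    d[1] <- mimg(d[1], Lx); d[2] <- mimg(d[2], Ly)
    r <- sqrt(sum(d^2))
    if (r < 1e-12) next
    if (cell[i] == cell[j]) {
      F[i, ] <- F[i, ] - p$mu_spring * (r - p$r0) * d / r
    } else if (r <= p$inter_cutoff) {
      re <- max(r, 0.05 * p$sigma)
      Fab <- if (aclass[i] == aclass[j]) p$Fa else p$Fb
      fmag <- Fab * p$eps * (12 * (p$sigma / re)^12 - 6 * (p$sigma / re)^6) / re
      fmag <- sign(fmag) * min(abs(fmag), p$f_clamp)
      F[i, ] <- F[i, ] + fmag * d / r
    }
  }
  for (i in seq_len(n)) {
    if (adherent[i] == 1L && abs(pos[i, 3]) <= p$membrane_cutoff &&
        abs(pos[i, 3]) > 1e-12)
      F[i, 3] <- F[i, 3] - p$eps_external * sign(pos[i, 3])
  }
  F
}

# literal evaluation of the Sharpness Index definition on a full image
oracle_si <- function(img) {
  n <- nrow(img); m <- ncol(img)
  tot <- 0; cnt <- 0
  for (x in 2:(n - 1)) for (y in 2:(m - 1)) {
    tot <- tot + (img[x + 1, y] - img[x - 1, y])^2 +
      (img[x, y + 1] - img[x, y - 1])^2
    cnt <- cnt + 1
  }
  1 - tot / (2 * cnt)
}

# total potential energy of a configuration (for gradient-flow checks)
oracle_energy <- function(pos, cell, aclass, adherent, p, Lx, Ly, periodic) {
  n <- nrow(pos)
  E <- 0
  mimg <- function(d, L) if (periodic) d - L * round(d / L) else d
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d[1] <- mimg(d[1], Lx); d[2] <- mimg(d[2], Ly)
    r <- sqrt(sum(d^2))
    if (cell[i] == cell[j]) {
      E <- E + p$mu_spring * (r - p$r0)^2 / 2
    } else if (r <= p$inter_cutoff) {
      re <- max(r, 0.05 * p$sigma)
      Fab <- if (aclass[i] == aclass[j]) p$Fa else p$Fb
      E <- E + Fab * p$eps * ((p$sigma / re)^12 - (p$sigma / re)^6)
    }
  }
  for (i in seq_len(n))
    if (adherent[i] == 1L && abs(pos[i, 3]) <= p$membrane_cutoff)
      E <- E + p$eps_external * abs(pos[i, 3])
  E
}

# random small tissue for kernel tests: k cells of m elements each
random_test_tissue <- function(k = 5, m = 10, box = c(30, 30, 30),
                               types = NULL, periodic = TRUE) {
  pos <- NULL; cellv <- NULL
  for (c in seq_len(k)) {
    cen <- runif(3, 5, box - 5)
    pos <- rbind(pos, sweep(matrix(runif(3 * m, -3, 3), m, 3), 2, cen, `+`))
    cellv <- c(cellv, rep(c, m))
  }
  if (is.null(types)) types <- sample(0:3, k, replace = TRUE)
  el <- tibble::tibble(element_id = seq_len(nrow(pos)), cell_id = cellv,
                       element_type = "interior",
                       x = pos[, 1], y = pos[, 2], z = abs(pos[, 3]))
  cl <- tibble::tibble(cell_id = seq_len(k),
                       cell_type = c("C0", "C1", "C2", "C3")[types + 1L],
                       cycle_clock = 0, cycle_length = 24, n_target = m,
                       growth_interval = 4.8, next_growth = Inf,
                       removal_state = 0L, next_shrink = Inf, birth_time = 0)
  new_tissue(el, cl, domain = box, periodic_xy = periodic)
}
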