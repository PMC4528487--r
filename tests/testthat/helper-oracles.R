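# Independent brute-force oracles used across the suite.

# toroidal distance as the minimum over the 9 periodic images
brute_toroidal <- function(a, b, extent) {
  if (length(extent) == 1) extent <- c(extent, extent)
  shifts <- expand.grid(sx = -1:1, sy = -1:1)
  min(apply(shifts, 1, function(s) {
    sqrt(sum((a - (b + s * extent))^2))
  }))
}

# exhaustive all-sites contact scan (coarse-grains the position like the
# implementation contract states, then checks every centre)
brute_contacts <- function(position, radius, world) {
  d <- world$cell_diameter
  position <- wrap_position(round(wrap_position(position, world$extent)),
                            world$extent)
  hits <- NULL
  for (row in seq_len(world$n_rows)) {
    for (col in seq_len(world$n_cols)) {
      if (world$state[row, col] == "dead") next
      ctr <- c((col - 0.5) * d, (row - 0.5) * d)
      dd <- brute_toroidal(position, ctr, world$extent)
      if (dd <= radius)
        hits <- rbind(hits, data.frame(row = row - 1L, col = col - 1L,
                                       distance = dd))
    }
  }
  if (is.null(hits)) data.frame(row = integer(), col = integer(),
                                distance = numeric())
  else hits[order(hits$row, hits$col), ]
}

# toroidal nearest-neighbour distances among a set of sites (0-based row/col)
nn_distances <- function(sites, cell_diameter, extent) {
  n <- nrow(sites)
  pts <- cbind((sites[, "col"] + 0.5) * cell_diameter,
               (sites[, "row"] + 0.5) * cell_diameter)
  vapply(seq_len(n), function(i) {
    d <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pts[i, 1] - pts[j, 1]; dx <- dx - extent[1] * round(dx / extent[1])
      dy <- pts[i, 2] - pts[j, 2]; dy <- dy - extent[2] * round(dy / extent[2])
      d <- min(d, sqrt(dx^2 + dy^2))
    }
    d
  }, numeric(1))
}

# Clark-Evans aggregation index: mean nearest-neighbour distance over the
# expectation 0.5/sqrt(density) under complete spatial randomness
clark_evans <- function(sites, cell_diameter, extent) {
  rho <- nrow(sites) / prod(extent)
  mean(nn_distances(sites, cell_diameter, extent)) / (0.5 / sqrt(rho))
}

# infected site list (0-based) from a finished engine run, via a fresh
# short run that exposes the grid is not available; instead experiments
# sample sites directly where needed.

# small helper: run a growth-only simulation and return the timecourse
grow_only <- function(cfg, seed) {
  cfg$seed <- seed
  cfg$n_ctl <- 0L
  run_simulation(cfg)
}
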