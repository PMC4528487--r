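#' Construct a tissue world
#'
#' A static lattice of cells on a torus. Site `(row, col)` (0-based) has its
#' centre at `((col + 0.5) * d, (row + 0.5) * d)` where `d` is the cell
#' diameter; the extent per axis is the number of sites times `d`, and all
#' positions wrap. This is the in-memory container the spatial queries
#' ([cells_in_contact()], [nearest_infected()]) operate on.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param cell_diameter Cell diameter (lattice pitch), um.
#' @param state Optional character matrix (`n_rows` x `n_cols`) of site
#'   states among `"non_susceptible"`, `"susceptible"`, `"infected"`,
#'   `"dead"`; defaults to all susceptible.
#' @return An object of class `tissue_world`.
#' @examples
#' w <- tissue_world(8, 8)
#' w$state[3, 4] <- "infected"
#' nearest_infected(c(0, 0), w)
#' @export
tissue_world <- function(n_rows = 320L, n_cols = 320L, cell_diameter = 10,
                         state = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.null(state)) {
    state <- matrix("susceptible", n_rows, n_cols)
  } else {
    stopifnot(is.matrix(state), nrow(state) == n_rows, ncol(state) == n_cols)
    bad <- setdiff(unique(as.vector(state)),
                   c("non_susceptible", "susceptible", "infected", "dead"))
    if (length(bad)) stop("unknown cell states: ", paste(bad, collapse = ", "))
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_diameter = cell_diameter,
                 extent = c(x = n_cols * cell_diameter,
                            y = n_rows * cell_diameter),
                 state = state),
            class = "tissue_world")
}

#' Wrap a position onto the torus
#'
#' @param position Numeric 2-vector (x, y) in um.
#' @param extent Extent per axis, um: a scalar (square domain) or length-2
#'   vector (x, y).
#' @return The congruent position with each coordinate in `[0, extent)`.
#' @examples
#' wrap_position(c(3205, -1), 3200)
#' @export
wrap_position <- function(position, extent) {
  if (any(!is.finite(position))) stop("position must be finite")
  if (any(!is.finite(extent)) || any(extent <= 0)) stop("extent must be positive")
  if (length(extent) == 1) extent <- rep(extent, length(position))
  position - extent * floor(position / extent)
}

#' Toroidal (minimum-image) Euclidean distance
#'
#' @param a,b Positions in um (wrapped or not; they are wrapped internally).
#' @inheritParams wrap_position
#' @return Distance in um under the minimum-image convention.
#' @examples
#' toroidal_distance(c(0, 0), c(3199, 0), 3200)  # 1, across the seam
#' @export
toroidal_distance <- function(a, b, extent) {
  if (length(extent) == 1) extent <- rep(extent, length(a))
  d <- wrap_position(a, extent) - wrap_position(b, extent)
  d <- d - extent * round(d / extent)
  sqrt(sum(d^2))
}

# centres of all sites as a list of x/y matrices matching world$state layout
site_centres <- function(world) {
  d <- world$cell_diameter
  list(x = outer(rep(1, world$n_rows), (seq_len(world$n_cols) - 0.5) * d),
       y = outer((seq_len(world$n_rows) - 0.5) * d, rep(1, world$n_cols)))
}

# toroidal distance from a single point to every site centre (matrix)
dist_to_centres <- function(position, world) {
  ctr <- site_centres(world)
  ex <- world$extent[["x"]]; ey <- world$extent[["y"]]
  dx <- ctr$x - position[1]; dx <- dx - ex * round(dx / ex)
  dy <- ctr$y - position[2]; dy <- dy - ey * round(dy / ey)
  sqrt(dx^2 + dy^2)
}

#' Sites in contact with a position
#'
#' The agent position is first coarse-grained to the nearest 1 um (the
#' contact-detection resolution); every site whose centre lies within
#' `contact_radius` of that coarse-grained point (toroidal metric) is in
#' contact. Dead sites are excluded: they are no longer scannable.
#'
#' @param position Numeric 2-vector (x, y), um (wrapped internally).
#' @param contact_radius Contact radius, um.
#' @param world A [tissue_world()].
#' @return A data.frame with 0-based `row`, `col` and `distance` (um),
#'   ordered by (row, col).
#' @export
cells_in_contact <- function(position, contact_radius, world) {
  stopifnot(contact_radius > 0)
  position <- wrap_position(round(wrap_position(position, world$extent)),
                            world$extent)
  dd <- dist_to_centres(position, world)
  hit <- which(dd <= contact_radius & world$state != "dead", arr.ind = TRUE)
  out <- data.frame(row = hit[, 1] - 1L, col = hit[, 2] - 1L,
                    distance = dd[hit])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Nearest living infected site
#'
#' Returns the infected site (conjugated or not; never dead) minimising the
#' toroidal distance to `position`; ties are broken on the smaller
#' `(row, col)` for determinism.
#'
#' @inheritParams cells_in_contact
#' @return `NULL` if no infected site exists, else a list with `site`
#'   (0-based `c(row, col)`) and `distance` (um).
#' @export
nearest_infected <- function(position, world) {
  position <- wrap_position(position, world$extent)
  inf <- which(world$state == "infected", arr.ind = TRUE)
  if (nrow(inf) == 0) return(NULL)
  dd <- dist_to_centres(position, world)
  di <- dd[inf]
  ord <- order(di, inf[, 1], inf[, 2])
  best <- ord[1]
  list(site = c(row = unname(inf[best, 1]) - 1L,
                col = unname(inf[best, 2]) - 1L),
       distance = as.numeric(di[best]))
}

#' @export
print.tissue_world <- function(x, ...) {
  tab <- table(factor(x$state, levels = c("non_susceptible", "susceptible",
                                          "infected", "dead")))
  cat(sprintf("tissue_world: %d x %d sites, %g um cells (%g x %g um)\n",
              x$n_rows, x$n_cols, x$cell_diameter,
              x$extent[["x"]], x$extent[["y"]]))
  print(tab)
  invisible(x)
}
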