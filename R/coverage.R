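#' Lipid-to-protein ratio implied by a bound-protein footprint
#'
#' How many lipid head groups one bound protein occludes: the footprint
#' area divided by the area per head group, rounded to the nearest
#' integer per leaflet, then multiplied by the number of leaflets
#' counted. The canonical hairpin footprint of about 10 x 2 nm^2 at 0.75
#' nm^2 per head group gives 27 lipids per leaflet, i.e. 1 protein : 54
#' lipids counting both leaflets.
#'
#' @param length,width Footprint dimensions, nm (defaults 10 and 2).
#' @param area_per_lipid Area per head group, nm^2 (default 0.75).
#' @param leaflets_counted Leaflets included in the total (default 2).
#' @return One-row tibble with `per_leaflet_ratio`, `total_ratio`
#'   (integers) and the unrounded `per_leaflet_exact`.
#' @export
#' @examples
#' lipids_per_protein()  # 27 per leaflet, 54 total
lipids_per_protein <- function(length = 10, width = 2,
                               area_per_lipid = 0.75,
                               leaflets_counted = 2L) {
  stopifnot(length > 0, width > 0, area_per_lipid > 0, leaflets_counted >= 1)
  exact <- length * width / area_per_lipid
  per <- as.integer(round(exact))
  tibble(per_leaflet_ratio = per,
         total_ratio = per * as.integer(leaflets_counted),
         per_leaflet_exact = exact,
         footprint_nm2 = length * width,
         area_per_lipid = area_per_lipid)
}

#' Random sequential adsorption of rectangles in a periodic box
#'
#' Rectangles are inserted one at a time at uniformly random positions
#' (and orientations, unless `oriented`) in a periodic square box; an
#' insertion overlapping any placed rectangle (separating-axis test
#' against periodic images) is rejected. The process stops after
#' `max_failures` consecutive rejections. This is an exploratory tool
#' for surface-coverage intuition; literature coverage limits for
#' adsorbing particles come from richer models, so no equality with any
#' particular reference value is implied.
#'
#' @param box_side Periodic box side, nm.
#' @param length,width Rectangle dimensions, nm (must fit in the box).
#' @param oriented If TRUE all rectangles are axis-aligned.
#' @param max_failures Consecutive-failure stop rule (>= 1000).
#' @param seed Integer seed; identical seeds give identical placements.
#' @return List with `coverage` (fraction of the box area), `n_placed`
#'   and `placements` (tibble: `x`, `y`, `angle` in radians).
#' @export
rsa_coverage <- function(box_side, length, width, oriented = FALSE,
                         max_failures = 5000L, seed = 1L) {
  stopifnot(max_failures >= 1000)
  diag_len <- sqrt(length^2 + width^2)
  # the overlap test uses the minimum image, valid only when no second
  # periodic image can reach: require a box of at least two diagonals
  if (2 * diag_len > box_side)
    abort("rectangle does not fit in the periodic box")
  l2 <- length / 2; w2 <- width / 2
  L <- box_side
  # grid for neighbour lookup; cells at least one diagonal wide
  ncell <- max(1L, floor(L / diag_len))
  cw <- L / ncell
  grid <- vector("list", ncell * ncell)
  cell_of <- function(x, y)
    (as.integer(x / cw) %% ncell) * ncell + (as.integer(y / cw) %% ncell) + 1L

  xs <- ys <- as_ <- numeric(0)
  with_seed(seed, {
    fails <- 0L
    while (fails < max_failures) {
      x <- runif(1, 0, L); y <- runif(1, 0, L)
      ang <- if (oriented) 0 else runif(1, 0, pi)
      cx <- as.integer(x / cw); cy <- as.integer(y / cw)
      nb <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        cc <- ((cx + dx) %% ncell) * ncell + ((cy + dy) %% ncell) + 1L
        nb <- c(nb, grid[[cc]])
      }
      ok <- TRUE
      for (j in unique(nb)) {
        ddx <- x - xs[j]; ddx <- ddx - L * round(ddx / L)
        ddy <- y - ys[j]; ddy <- ddy - L * round(ddy / L)
        if (rects_overlap(ddx, ddy, ang, as_[j], l2, w2)) { ok <- FALSE; break }
      }
      if (ok) {
        xs <- c(xs, x); ys <- c(ys, y); as_ <- c(as_, ang)
        k <- length(xs)
        cc <- cell_of(x, y)
        grid[[cc]] <- c(grid[[cc]], k)
        fails <- 0L
      } else fails <- fails + 1L
    }
  })
  n <- length(xs)
  list(coverage = n * length * width / L^2,
       n_placed = n,
       placements = tibble(x = xs, y = ys, angle = as_))
}

# separating-axis test for two l x w rectangles with centre offset
# (dx, dy) and angles a1, a2 (half-lengths l2, w2)
rects_overlap <- function(dx, dy, a1, a2, l2, w2) {
  axes <- rbind(c(cos(a1), sin(a1)), c(-sin(a1), cos(a1)),
                c(cos(a2), sin(a2)), c(-sin(a2), cos(a2)))
  u1 <- c(cos(a1), sin(a1)); v1 <- c(-sin(a1), cos(a1))
  u2 <- c(cos(a2), sin(a2)); v2 <- c(-sin(a2), cos(a2))
  d <- c(dx, dy)
  for (k in 1:4) {
    ax <- axes[k, ]
    r1 <- l2 * abs(sum(u1 * ax)) + w2 * abs(sum(v1 * ax))
    r2 <- l2 * abs(sum(u2 * ax)) + w2 * abs(sum(v2 * ax))
    if (abs(sum(d * ax)) > r1 + r2) return(FALSE)
  }
  TRUE
}
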