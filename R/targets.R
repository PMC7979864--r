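# Rendering of point annotations into segmentation training targets.
#
# Conventions used throughout the package:
#   * images are matrices indexed [row, col]; a pixel at row r, column c has
#     0-based image coordinates x = c - 1 (column), y = r - 1 (row), with the
#     origin at the top-left corner;
#   * body orientation alpha is in degrees, measured clockwise from the
#     vertical pointing upwards, in [0, 360); cell-bees carry alpha = 0;
#   * class labels: 0 background, 1 full-bee (fully visible), 2 cell-bee
#     (abdomen inside a comb cell).

#' Bee geometry parameters
#'
#' Physical extent of a bee in pixels together with the fraction of the body
#' used for the rendered target blob and the radius of a capped brood cell.
#' The defaults describe a bee whose longest dimension is 80 px (half of it,
#' 40 px, is the `a` constant of the matching procedure) and a target blob
#' covering a third of the body dimensions, small enough that blobs of
#' neighbouring bees do not merge.
#'
#' @param body_length Bee body length in px.
#' @param body_width Bee body width in px.
#' @param region_fraction Fraction of the body dimensions covered by the
#'   rendered target region, in (0, 1).
#' @param brood_radius Radius in px of the disk marking a capped brood cell.
#' @return An object of class `bee_geometry`.
#' @export
bee_geometry <- function(body_length = 80, body_width = 30,
                         region_fraction = 1 / 3, brood_radius = 10) {
  stopifnot(body_length > 0, body_width > 0, brood_radius > 0,
            region_fraction > 0, region_fraction < 1)
  structure(list(body_length = body_length, body_width = body_width,
                 region_fraction = region_fraction,
                 brood_radius = brood_radius),
            class = "bee_geometry")
}

#' Construct and validate a bee annotation table
#'
#' @param x,y 0-based pixel coordinates of body centres (x = column,
#'   y = row).
#' @param b Class label, 1 = full-bee, 2 = cell-bee.
#' @param alpha Body orientation in degrees, clockwise from vertical-up,
#'   in [0, 360); must be 0 for cell-bees.
#' @return A `data.frame` with columns `x`, `y`, `b`, `alpha`.
#' @export
bee_annotations <- function(x, y, b, alpha = NULL) {
  n <- length(x)
  if (is.null(alpha)) alpha <- rep(0, n)
  stopifnot(length(y) == n, length(b) == n, length(alpha) == n)
  if (n && !all(b %in% c(1, 2)))
    stop("class label b must be 1 (full-bee) or 2 (cell-bee)")
  if (n && any(alpha < 0 | alpha >= 360))
    stop("alpha must lie in [0, 360)")
  if (any(b == 2 & alpha != 0))
    stop("cell-bee annotations must have alpha = 0")
  data.frame(x = as.numeric(x), y = as.numeric(y),
             b = as.integer(b), alpha = as.numeric(alpha))
}

check_in_bounds <- function(x, y, shape, what = "annotation") {
  bad <- which(x < 0 | x > shape[2] - 1 | y < 0 | y > shape[1] - 1)
  if (length(bad))
    stop(sprintf("%s %d at (%.1f, %.1f) lies outside the %dx%d image",
                 what, bad[1], x[bad[1]], y[bad[1]], shape[1], shape[2]))
  invisible(TRUE)
}

# Unit axis vectors of a body at orientation alpha (degrees, clockwise from
# vertical-up) in (x, y) image coordinates with y increasing downwards.
body_axes <- function(alpha) {
  a <- alpha * pi / 180
  list(major = c(sin(a), -cos(a)), minor = c(cos(a), sin(a)))
}

# Linear indices (into an [H, W] matrix) of pixel centres inside the ellipse
# with semi-axes (sa along orientation alpha, sb across), centred at (x, y).
# Membership is inclusive, so a radius-10 disk contains the 317 integer
# lattice points at distance <= 10.
ellipse_indices <- function(x, y, alpha, sa, sb, shape) {
  r <- max(sa, sb)
  c0 <- max(1L, floor(x - r) + 1L); c1 <- min(shape[2], ceiling(x + r) + 1L)
  r0 <- max(1L, floor(y - r) + 1L); r1 <- min(shape[1], ceiling(y + r) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  cols <- c0:c1; rows <- r0:r1
  dx <- outer(rep(1, length(rows)), cols - 1 - x)
  dy <- outer(rows - 1 - y, rep(1, length(cols)))
  ax <- body_axes(alpha)
  along <- dx * ax$major[1] + dy * ax$major[2]
  perp <- dx * ax$minor[1] + dy * ax$minor[2]
  inside <- (along / sa)^2 + (perp / sb)^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2]] - 1L) * shape[1] + rows[ij[, 1]]
}

# Oriented unit-peak 2-D Gaussian values on the pixel grid, truncated at
# `trunc` standard deviations. Returns linear indices and values.
gaussian_patch <- function(x, y, alpha, sx, sy, shape, trunc = 5) {
  r <- trunc * max(sx, sy)
  c0 <- max(1L, floor(x - r) + 1L); c1 <- min(shape[2], ceiling(x + r) + 1L)
  r0 <- max(1L, floor(y - r) + 1L); r1 <- min(shape[1], ceiling(y + r) + 1L)
  if (c0 > c1 || r0 > r1) return(list(idx = integer(0), val = numeric(0)))
  cols <- c0:c1; rows <- r0:r1
  dx <- outer(rep(1, length(rows)), cols - 1 - x)
  dy <- outer(rows - 1 - y, rep(1, length(cols)))
  ax <- body_axes(alpha)
  along <- dx * ax$major[1] + dy * ax$major[2]
  perp <- dx * ax$minor[1] + dy * ax$minor[2]
  g <- exp(-(along^2 / (2 * sx^2) + perp^2 / (2 * sy^2)))
  keep <- which(g > 1e-8)
  ij <- arrayInd(keep, dim(g))
  list(idx = (cols[ij[, 2]] - 1L) * shape[1] + rows[ij[, 1]], val = g[keep])
}

target_semi_axes <- function(geom) {
  c(major = geom$region_fraction * geom$body_length / 2,
    minor = geom$region_fraction * geom$body_width / 2)
}

#' Render class and angle segmentation maps from bee annotations
#'
#' Each full-bee annotation produces an ellipse-shaped foreground region
#' (semi-axes `region_fraction` times half the body dimensions, major axis
#' along the body orientation) filled with class 1; each cell-bee produces a
#' disk of the same diameter as the ellipse major axis filled with class 2.
#' The angle map carries the annotated orientation over the same foreground
#' support and -1 on background. When regions overlap, later annotations
#' overwrite earlier ones pixel by pixel.
#'
#' @param annotations A `data.frame` as returned by [bee_annotations()].
#' @param shape Image shape `c(rows, cols)`.
#' @param geom A [bee_geometry()] object.
#' @return A list of class `segmentation_target` with `class_map` (integer
#'   matrix, 0/1/2) and `angle_map` (numeric matrix, degrees on foreground,
#'   -1 on background).
#' @export
render_bee_targets <- function(annotations, shape, geom = bee_geometry()) {
  shape <- as.integer(shape)
  class_map <- matrix(0L, shape[1], shape[2])
  angle_map <- matrix(-1, shape[1], shape[2])
  if (nrow(annotations)) {
    check_in_bounds(annotations$x, annotations$y, shape)
    ax <- target_semi_axes(geom)
    for (i in seq_len(nrow(annotations))) {
      an <- annotations[i, ]
      idx <- if (an$b == 1L) {
        ellipse_indices(an$x, an$y, an$alpha, ax["major"], ax["minor"], shape)
      } else {
        ellipse_indices(an$x, an$y, 0, ax["major"], ax["major"], shape)
      }
      class_map[idx] <- an$b
      angle_map[idx] <- an$alpha
    }
  }
  structure(list(class_map = class_map, angle_map = angle_map),
            class = "segmentation_target")
}

#' Render the pixel-weight map balancing foreground against background
#'
#' The weight map is `1 + sum over bees of bg_fg_ratio * G`, where `G` is a
#' unit-peak 2-D Gaussian centred on the bee whose standard deviations equal
#' the semi-axes of the rendered target region and whose axes follow the
#' body orientation. `bg_fg_ratio` is the ratio of background to foreground
#' pixel counts, computed once over a training set (see
#' [background_foreground_ratio()]). The additive baseline of 1 keeps the
#' map strictly positive everywhere.
#'
#' @inheritParams render_bee_targets
#' @param bg_fg_ratio Positive scalar, background-to-foreground pixel ratio.
#' @return A strictly positive numeric matrix.
#' @export
render_weight_map <- function(annotations, shape, geom = bee_geometry(),
                              bg_fg_ratio) {
  if (!is.numeric(bg_fg_ratio) || bg_fg_ratio <= 0)
    stop("bg_fg_ratio must be a positive number")
  shape <- as.integer(shape)
  w <- matrix(1, shape[1], shape[2])
  if (nrow(annotations)) {
    check_in_bounds(annotations$x, annotations$y, shape)
    ax <- target_semi_axes(geom)
    for (i in seq_len(nrow(annotations))) {
      an <- annotations[i, ]
      sx <- ax["major"]
      sy <- if (an$b == 1L) ax["minor"] else ax["major"]
      g <- gaussian_patch(an$x, an$y, an$alpha, sx, sy, shape)
      w[g$idx] <- w[g$idx] + bg_fg_ratio * g$val
    }
  }
  w
}

#' Background-to-foreground pixel ratio of a set of class maps
#'
#' @param class_maps A list of class maps (or a single matrix).
#' @return `N_background / N_foreground` over all maps.
#' @export
background_foreground_ratio <- function(class_maps) {
  if (is.matrix(class_maps)) class_maps <- list(class_maps)
  fg <- sum(vapply(class_maps, function(m) sum(m != 0), numeric(1)))
  bg <- sum(vapply(class_maps, function(m) sum(m == 0), numeric(1)))
  if (fg == 0) stop("class maps contain no foreground pixels")
  bg / fg
}

#' Render brood-cell segmentation targets
#'
#' Capped brood cells are marked by disks of radius `geom$brood_radius`
#' around each annotated cell centre; the weight map adds a 2-D Gaussian
#' scaled by 10 over each cell (sigma equal to the disk radius) to an
#' all-ones baseline.
#'
#' @param annotations `data.frame` with columns `x`, `y` (0-based pixel
#'   coordinates of cell centres).
#' @inheritParams render_bee_targets
#' @return A list with `mask` (logical matrix) and `weight_map`.
#' @export
render_brood_targets <- function(annotations, shape, geom = bee_geometry()) {
  shape <- as.integer(shape)
  mask <- matrix(FALSE, shape[1], shape[2])
  w <- matrix(1, shape[1], shape[2])
  if (nrow(annotations)) {
    check_in_bounds(annotations$x, annotations$y, shape, "brood annotation")
    r <- geom$brood_radius
    for (i in seq_len(nrow(annotations))) {
      an <- annotations[i, ]
      mask[ellipse_indices(an$x, an$y, 0, r, r, shape)] <- TRUE
      g <- gaussian_patch(an$x, an$y, 0, r, r, shape)
      w[g$idx] <- w[g$idx] + 10 * g$val
    }
  }
  list(mask = mask, weight_map = w)
}
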