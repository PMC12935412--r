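#' Arena configuration
#'
#' Geometry of the circular task arena: radius, centre, the inner-circle
#' threshold used by the radial partition, the intra-arena landmark
#' (obelisk), the encoded object locations, and the start position. All
#' coordinates are in virtual meters (vm) with the origin at the arena
#' centre; y increases toward the arena's arbitrary north, so the landmark
#' at (-10.5, 10.5) sits in the upper-left quadrant.
#'
#' Defaults reproduce the standard task layout: a 50 vm diameter arena, an
#' inner circle of radius 12.5 vm (25\% of the arena area), the obelisk at
#' (-10.5, 10.5), and four objects -- cat (-5, -14), chair (-4, 20),
#' bike (18, 10), carrot (5, 17).
#'
#' @param radius Arena radius in vm.
#' @param center Numeric length-2, arena centre.
#' @param inner_radius Radius of the inner circle of the radial partition;
#'   must be strictly between 0 and `radius`.
#' @param landmark Numeric length-2, intra-arena landmark coordinates.
#' @param objects Named list of numeric length-2 object coordinates; names
#'   are the object ids and must be unique.
#' @param start Numeric length-2, encoding start position.
#' @return An object of class `arena_config`.
#' @examples
#' arena <- arena_config()
#' arena$objects$cat
#' @export
arena_config <- function(radius = 25,
                         center = c(0, 0),
                         inner_radius = 12.5,
                         landmark = c(-10.5, 10.5),
                         objects = list(cat    = c(-5, -14),
                                        chair  = c(-4, 20),
                                        bike   = c(18, 10),
                                        carrot = c(5, 17)),
                         start = c(0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(inner_radius), length(inner_radius) == 1L)
  if (!(radius > inner_radius && inner_radius > 0))
    stop("need radius > inner_radius > 0", call. = FALSE)
  check_point(center, "center")
  check_point(landmark, "landmark")
  check_point(start, "start")
  if (is.null(names(objects)) || anyDuplicated(names(objects)) ||
      any(!nzchar(names(objects))))
    stop("objects must be a named list with unique non-empty ids",
         call. = FALSE)
  for (id in names(objects)) check_point(objects[[id]], id)
  x <- structure(list(radius = radius, center = as.numeric(center),
                      inner_radius = inner_radius,
                      landmark = as.numeric(landmark),
                      objects = lapply(objects, as.numeric),
                      start = as.numeric(start)),
                 class = "arena_config")
  if (point_distance(landmark, center) >= radius)
    stop("landmark must lie strictly inside the arena", call. = FALSE)
  for (id in names(objects))
    if (point_distance(x$objects[[id]], center) >= radius)
      stop("object '", id, "' must lie strictly inside the arena",
           call. = FALSE)
  x
}

#' @export
print.arena_config <- function(x, ...) {
  cat("Circular arena: radius", x$radius, "vm, inner circle", x$inner_radius,
      "vm (", format(100 * (x$inner_radius / x$radius)^2), "% of area )\n")
  cat("Landmark at (", x$landmark[1], ",", x$landmark[2], ")\n")
  cat("Objects:\n")
  for (id in names(x$objects))
    cat("  ", id, ": (", x$objects[[id]][1], ",", x$objects[[id]][2], ")\n")
  invisible(x)
}

check_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)))
    stop("'", what, "' must be two finite coordinates", call. = FALSE)
  invisible(p)
}

#' Euclidean distance between points
#'
#' @param p,q Numeric length-2 points, or two-column matrices of points
#'   (recycled row-wise against each other).
#' @return Distance(s) in vm.
#' @examples
#' point_distance(c(0, 0), c(3, 4))  # 5
#' @export
point_distance <- function(p, q) {
  if (is.matrix(p) || is.matrix(q)) {
    p <- as_point_matrix(p)
    q <- as_point_matrix(q)
    if (any(!is.finite(p)) || any(!is.finite(q)))
      stop("non-finite coordinates", call. = FALSE)
    return(sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2))
  }
  check_point(p); check_point(q)
  sqrt(sum((p - q)^2))
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    p
  } else {
    matrix(as.numeric(p), ncol = 2L, byrow = TRUE)
  }
}

#' Radial region of a point
#'
#' Classifies points into the inner circle (`dist <= inner_radius`,
#' boundary included), the outer annulus (`inner_radius < dist <= radius`),
#' or `outside` the arena (malformed input; never dropped silently).
#'
#' @param p A point or two-column matrix of points.
#' @param arena An [arena_config()].
#' @return Character vector in `c("inner", "outer", "outside")`.
#' @export
radial_region <- function(p, arena = arena_config()) {
  p <- as_point_matrix(p)
  d <- point_distance(p, matrix(arena$center, nrow(p), 2, byrow = TRUE))
  # 1e-9 slack so boundary-clipped points never round to "outside"
  ifelse(d <= arena$inner_radius, "inner",
         ifelse(d <= arena$radius + 1e-9, "outer", "outside"))
}

#' Quadrant region of a point
#'
#' Labels the upper-left quadrant (x < 0, y > 0; contains the landmark at
#' the default layout), the diametrically opposite lower-right quadrant
#' (x > 0, y < 0), or `other`. Points exactly on an axis are `other` and
#' excluded from quadrant-pair counts (a probability-zero set; avoids
#' double counting).
#'
#' @inheritParams radial_region
#' @return Character vector in `c("upper_left", "lower_right", "other")`.
#' @export
quadrant_region <- function(p, arena = arena_config()) {
  p <- as_point_matrix(p)
  x <- p[, 1] - arena$center[1]
  y <- p[, 2] - arena$center[2]
  ifelse(x < 0 & y > 0, "upper_left",
         ifelse(x > 0 & y < 0, "lower_right", "other"))
}

#' Area of an arena region
#'
#' @param label One of `"inner"`, `"outer"` (the annulus), `"arena"`,
#'   `"quadrant"` (any one quadrant), `"upper_left"`, `"lower_right"`.
#' @param arena An [arena_config()].
#' @return Area in square vm.
#' @export
region_area <- function(label, arena = arena_config()) {
  r <- arena$radius; ri <- arena$inner_radius
  switch(label,
         inner = pi * ri^2,
         outer = pi * (r^2 - ri^2),
         arena = pi * r^2,
         quadrant = ,
         upper_left = ,
         lower_right = pi * r^2 / 4,
         stop("unknown region label '", label, "'", call. = FALSE))
}

#' Clip a point to the arena boundary
#'
#' Models the invisible wall: points inside the arena are returned
#' unchanged; points outside are projected radially onto the boundary
#' circle.
#'
#' @inheritParams radial_region
#' @return Point(s) with the same shape as the input.
#' @export
clip_to_arena <- function(p, arena = arena_config()) {
  was_vec <- !is.matrix(p)
  m <- as_point_matrix(p)
  cx <- m[, 1] - arena$center[1]
  cy <- m[, 2] - arena$center[2]
  d <- sqrt(cx^2 + cy^2)
  f <- ifelse(d > arena$radius, arena$radius / d, 1)
  out <- cbind(arena$center[1] + cx * f, arena$center[2] + cy * f)
  if (was_vec) as.numeric(out[1, ]) else out
}
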