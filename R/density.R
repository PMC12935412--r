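#' Exact two-sided binomial test p value
#'
#' Two-sided exact p by the minimum-likelihood method: the sum of the
#' probabilities of all outcomes no more likely than the observed count
#' under Binomial(n, p0). This is the convention used by
#' [stats::binom.test()] and mainstream statistics packages.
#'
#' @param k Observed count, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null proportion, strictly between 0 and 1.
#' @return p value in \[0, 1\].
#' @examples
#' binomial_exact_test(5, 10, 0.5)   # modal outcome -> 1
#' binomial_exact_test(57, 320, 0.25)
#' @export
binomial_exact_test <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n))
    stop("need integer counts with 0 <= k <= n", call. = FALSE)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be strictly between 0 and 1", call. = FALSE)
  stats::binom.test(k, n, p0)$p.value
}

new_density_report <- function(scheme, labels, counts, areas, p0,
                               n_excluded) {
  counts <- as.numeric(counts)
  n_used <- sum(counts)
  dens <- counts / areas
  structure(list(
    scheme = scheme,
    table = data.frame(label = labels, count = counts, area = areas,
                       density = dens,
                       proportion = if (n_used > 0) counts / n_used else
                         rep(NA_real_, length(counts))),
    density_ratio = dens[1] / dens[2],
    n_used = n_used, n_excluded = n_excluded,
    p0 = p0,
    binomial_p = if (n_used > 0) binomial_exact_test(counts[1], n_used, p0)
                 else NA_real_
  ), class = "density_report")
}

#' Radial (inner/outer) density report
#'
#' Partitions in-arena points into the inner circle and the outer
#' annulus, computes area-normalised densities, the inner-to-outer
#' density ratio, and an exact binomial test of the inner count against
#' the expected area fraction (25\% at the default geometry).
#' Out-of-arena points are excluded and counted in `n_excluded`.
#'
#' @param points Two-column matrix or data frame of point coordinates.
#' @param arena An [arena_config()].
#' @return An object of class `density_report`.
#' @examples
#' radial_density_from_counts(57, 263)$density_ratio  # ~0.65
#' @export
radial_density_report <- function(points, arena = arena_config()) {
  m <- as_point_matrix(point_coords(points))
  if (nrow(m) < 1L) stop("no points supplied", call. = FALSE)
  lab <- radial_region(m, arena)
  n_out <- sum(lab == "outside")
  if (n_out > 0)
    warning(n_out, " point(s) outside the arena excluded", call. = FALSE)
  if (all(lab == "outside")) stop("no in-arena points", call. = FALSE)
  radial_density_from_counts(sum(lab == "inner"), sum(lab == "outer"),
                             arena, n_excluded = n_out)
}

#' @rdname radial_density_report
#' @param inner,outer Region counts, for building a report directly from
#'   published or tabulated counts.
#' @param n_excluded Number of excluded points to record.
#' @export
radial_density_from_counts <- function(inner, outer,
                                       arena = arena_config(),
                                       n_excluded = 0L) {
  p0 <- (arena$inner_radius / arena$radius)^2
  new_density_report("radial", c("inner", "outer"), c(inner, outer),
                     c(region_area("inner", arena),
                       region_area("outer", arena)),
                     p0, n_excluded)
}

#' Quadrant-pair density report
#'
#' Compares the landmark-containing upper-left quadrant with the
#' diametrically opposite lower-right quadrant: counts restricted to the
#' two quadrants, densities over the (equal) quadrant areas, the
#' upper-left-to-lower-right density ratio, and an exact binomial test of
#' the upper-left count against the null proportion 0.5. Points outside
#' both quadrants (including axis points) are excluded and counted in
#' `n_excluded`.
#'
#' @inheritParams radial_density_report
#' @return An object of class `density_report`.
#' @examples
#' quadrant_density_from_counts(103, 55)$density_ratio  # ~1.87
#' @export
quadrant_density_report <- function(points, arena = arena_config()) {
  m <- as_point_matrix(point_coords(points))
  if (nrow(m) < 1L) stop("no points supplied", call. = FALSE)
  lab <- quadrant_region(m, arena)
  inside <- radial_region(m, arena) != "outside"
  ul <- sum(lab == "upper_left" & inside)
  lr <- sum(lab == "lower_right" & inside)
  if (ul + lr == 0L)
    stop("no points in the compared quadrants", call. = FALSE)
  quadrant_density_from_counts(ul, lr, arena,
                               n_excluded = nrow(m) - ul - lr)
}

#' @rdname quadrant_density_report
#' @param upper_left,lower_right Quadrant counts for building a report
#'   directly from published or tabulated counts.
#' @param n_excluded Number of excluded points to record.
#' @export
quadrant_density_from_counts <- function(upper_left, lower_right,
                                         arena = arena_config(),
                                         n_excluded = 0L) {
  qa <- region_area("quadrant", arena)
  new_density_report("quadrant_pair", c("upper_left", "lower_right"),
                     c(upper_left, lower_right), c(qa, qa), 0.5,
                     n_excluded)
}

#' Compare two groups' density reports
#'
#' @param report_a,report_b `density_report`s with the same partition
#'   scheme (e.g. one per group).
#' @return List of class `density_comparison` with `ratio_a`, `ratio_b`,
#'   `difference` (a - b) and `ratio_of_ratios` (a / b).
#' @examples
#' compare_group_densities(radial_density_from_counts(57, 263),
#'                         radial_density_from_counts(76, 244))$difference
#' @export
compare_group_densities <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "density_report"),
            inherits(report_b, "density_report"))
  if (!identical(report_a$scheme, report_b$scheme))
    stop("partition scheme mismatch: ", report_a$scheme, " vs ",
         report_b$scheme, call. = FALSE)
  structure(list(scheme = report_a$scheme,
                 ratio_a = report_a$density_ratio,
                 ratio_b = report_b$density_ratio,
                 difference = report_a$density_ratio - report_b$density_ratio,
                 ratio_of_ratios =
                   report_a$density_ratio / report_b$density_ratio),
            class = "density_comparison")
}

point_coords <- function(points) {
  if (is.data.frame(points)) {
    xy <- intersect(c("x_vm", "y_vm"), names(points))
    if (length(xy) == 2L) return(cbind(points$x_vm, points$y_vm))
    xy <- intersect(c("response_x_vm", "response_y_vm"), names(points))
    if (length(xy) == 2L)
      return(cbind(points$response_x_vm, points$response_y_vm))
    if (ncol(points) == 2L) return(as.matrix(points))
    stop("cannot find coordinate columns in points data frame",
         call. = FALSE)
  }
  points
}

#' @export
print.density_report <- function(x, digits = 3, ...) {
  cat("Density report (", x$scheme, " partition), n = ", x$n_used,
      if (x$n_excluded > 0) paste0(" (+", x$n_excluded, " excluded)"),
      "\n", sep = "")
  print(cbind(x$table[1:2],
              round(x$table[c("area", "density", "proportion")], digits)),
        row.names = FALSE)
  cat("Density ratio (", x$table$label[1], "/", x$table$label[2], "): ",
      round(x$density_ratio, digits), "\n", sep = "")
  cat("Exact binomial p (p0 = ", x$p0, "): ",
      format.pval(x$binomial_p, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
print.density_comparison <- function(x, digits = 3, ...) {
  cat("Density-ratio comparison (", x$scheme, "):\n", sep = "")
  cat("  group A ratio:", round(x$ratio_a, digits),
      " group B ratio:", round(x$ratio_b, digits), "\n")
  cat("  difference (A - B):", round(x$difference, digits),
      " ratio of ratios (A / B):", round(x$ratio_of_ratios, digits), "\n")
  invisible(x)
}
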