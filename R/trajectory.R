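#' Step distances along a path
#'
#' Euclidean distances between consecutive position samples.
#'
#' @param path An `encoding_path`, a data frame with columns `x_vm` and
#'   `y_vm`, or a two-column matrix of positions in sample order.
#' @return Numeric vector of length `n_samples - 1`.
#' @export
step_distances <- function(path) {
  m <- path_matrix(path)
  if (nrow(m) < 2L)
    stop("insufficient data: need at least 2 samples, got ", nrow(m),
         call. = FALSE)
  sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
}

path_matrix <- function(path) {
  if (inherits(path, "encoding_path")) path <- path$samples
  if (is.data.frame(path)) {
    if (!all(c("x_vm", "y_vm") %in% names(path)))
      stop("path data frame needs columns x_vm and y_vm", call. = FALSE)
    if ("t_s" %in% names(path)) {
      dt <- diff(path$t_s)
      if (length(dt) && (any(dt <= 0) ||
                         any(abs(dt - dt[1]) > 1e-9)))
        warning("irregular or non-increasing timestamps; metrics are ",
                "defined per sample", call. = FALSE)
    }
    path <- cbind(path$x_vm, path$y_vm)
  }
  m <- as_point_matrix(path)
  if (any(!is.finite(m))) stop("non-finite path coordinates", call. = FALSE)
  m
}

#' Summarise a path
#'
#' Per-path movement metrics: mean step distance (average distance
#' traveled per 1 Hz time step), total distance (sum of all stepwise
#' distances), and the mean Euclidean distances of all samples (including
#' the first) from the landmark and from the arena centre.
#'
#' @inheritParams step_distances
#' @param arena An [arena_config()].
#' @param id,phase Optional identifiers carried into the output row.
#' @return One-row data frame with columns `participant_id`, `phase`,
#'   `n_samples`, `mean_step`, `total_distance`, `mean_dist_landmark`,
#'   `mean_dist_center`.
#' @export
path_summary <- function(path, arena = arena_config(),
                         id = NA_character_, phase = "encoding") {
  m <- path_matrix(path)
  if (nrow(m) < 2L)
    stop("insufficient data: need at least 2 samples, got ", nrow(m),
         call. = FALSE)
  steps <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
  dl <- point_distance(m, matrix(arena$landmark, nrow(m), 2, byrow = TRUE))
  dc <- point_distance(m, matrix(arena$center, nrow(m), 2, byrow = TRUE))
  data.frame(participant_id = id, phase = phase, n_samples = nrow(m),
             mean_step = sum(steps) / (nrow(m) - 1L),
             total_distance = sum(steps),
             mean_dist_landmark = mean(dl),
             mean_dist_center = mean(dc))
}

#' Path summaries for a whole cohort
#'
#' Sessions without a stored path (e.g. unsaved files) are skipped; the
#' number skipped is attached as attribute `n_missing` and reported.
#'
#' @param cohort An `ol_cohort` (see [simulate_cohort()], [read_sessions()]).
#' @param arena An [arena_config()]; defaults to the cohort's own.
#' @return Data frame with one row per session with a path, plus columns
#'   `group` and `subtype`.
#' @export
cohort_path_summaries <- function(cohort, arena = NULL) {
  if (is.null(arena)) arena <- attr(cohort, "arena")
  if (is.null(arena)) arena <- arena_config()
  rows <- list(); missing <- 0L
  for (s in cohort) {
    if (is.null(s$path)) { missing <- missing + 1L; next }
    r <- path_summary(s$path, arena, id = s$id, phase = "encoding")
    r$group <- s$group; r$subtype <- s$subtype
    rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows))
    stop("no sessions with stored paths", call. = FALSE)
  out <- do.call(rbind, rows)
  if (missing > 0L)
    message(missing, " session(s) without stored paths skipped; n used = ",
            nrow(out))
  attr(out, "n_missing") <- missing
  out
}

#' Welch two-sample t test
#'
#' Independent-samples t test with the Welch correction for unequal
#' variances (Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2 with
#'   nonzero variance.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::var(values_a) <= 0 && stats::var(values_b) <= 0)
    stop("degenerate samples: both variances are zero", call. = FALSE)
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}
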