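SCHEMA_VERSION <- 1L

#' Write a cohort to the session file format
#'
#' Writes three files into `dir`: `paths.csv` (long 1 Hz samples:
#' `participant_id`, `phase`, `t_s`, `x_vm`, `y_vm`), `trials.csv`
#' (`participant_id`, `trial_index`, `cue`, `object_id`,
#' `response_x_vm`, `response_y_vm`, `response_time_s`), and a YAML
#' `manifest.yaml` carrying the schema version, the arena configuration
#' and the per-participant roster (id, group, subtype, seed).
#'
#' @param cohort An `ol_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arena <- attr(cohort, "arena")
  if (is.null(arena)) arena <- arena_config()
  paths <- list(); trials <- list()
  roster <- list()
  for (s in cohort) {
    if (!is.null(s$path)) {
      p <- s$path$samples
      p <- data.frame(participant_id = s$id, phase = "encoding", p)
      paths[[length(paths) + 1L]] <- p
    }
    trials[[length(trials) + 1L]] <-
      data.frame(participant_id = s$id, s$trials)
    roster[[length(roster) + 1L]] <-
      list(id = s$id, group = s$group,
           subtype = if (is.na(s$subtype)) NULL else s$subtype,
           seed = s$seed, has_path = !is.null(s$path))
  }
  utils::write.csv(if (length(paths)) do.call(rbind, paths) else
    data.frame(participant_id = character(0), phase = character(0),
               t_s = numeric(0), x_vm = numeric(0), y_vm = numeric(0)),
    file.path(dir, "paths.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, trials), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  manifest <- list(schema_version = SCHEMA_VERSION,
                   seed = attr(cohort, "seed"),
                   arena = list(radius = arena$radius,
                                inner_radius = arena$inner_radius,
                                center = as.list(arena$center),
                                landmark = as.list(arena$landmark),
                                start = as.list(arena$start),
                                objects = lapply(arena$objects, as.list)),
                   participants = roster)
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}

arena_from_manifest <- function(m) {
  a <- m$arena
  arena_config(radius = a$radius, inner_radius = a$inner_radius,
               center = unlist(a$center), landmark = unlist(a$landmark),
               start = unlist(a$start),
               objects = lapply(a$objects, unlist))
}

#' Read sessions from the session file format
#'
#' Loads and validates a cohort written by [write_cohort()] (or any
#' files conforming to the same schema). Structural violations --
#' wrong trial counts, unknown cue or object tokens, duplicate trial
#' indices, out-of-arena responses, non-increasing path times -- are
#' collected into a validation report attached as attribute
#' `"validation"`. In lenient mode (default) violations are reported as
#' warnings; `strict = TRUE` aborts on any violation.
#'
#' @param paths_file,trials_file,manifest File paths; `paths_file` may
#'   be `NULL` when only recall trials were recorded.
#' @param strict Abort on any validation issue?
#' @return An `ol_cohort`.
#' @export
read_sessions <- function(paths_file, trials_file, manifest,
                          strict = FALSE) {
  m <- yaml::read_yaml(manifest)
  if (is.null(m$schema_version) || m$schema_version != SCHEMA_VERSION)
    stop("unknown schema version: ", m$schema_version %||% "<missing>",
         call. = FALSE)
  arena <- arena_from_manifest(m)
  trials <- utils::read.csv(trials_file, stringsAsFactors = FALSE)
  need_t <- c("participant_id", "trial_index", "cue", "object_id",
              "response_x_vm", "response_y_vm", "response_time_s")
  if (!all(need_t %in% names(trials)))
    stop("malformed trials file: need columns ",
         paste(need_t, collapse = ", "), call. = FALSE)
  paths <- NULL
  if (!is.null(paths_file) && file.exists(paths_file)) {
    paths <- utils::read.csv(paths_file, stringsAsFactors = FALSE)
    need_p <- c("participant_id", "phase", "t_s", "x_vm", "y_vm")
    if (!all(need_p %in% names(paths)))
      stop("malformed paths file: need columns ",
           paste(need_p, collapse = ", "), call. = FALSE)
  }
  issues <- character(0)
  note <- function(...) issues <<- c(issues, paste0(...))
  bad_cue <- setdiff(unique(trials$cue), c("ego", "allo"))
  if (length(bad_cue))
    stop("unknown cue token(s): ", paste(bad_cue, collapse = ", "),
         call. = FALSE)
  bad_obj <- setdiff(unique(trials$object_id), names(arena$objects))
  if (length(bad_obj))
    stop("unknown object id(s): ", paste(bad_obj, collapse = ", "),
         call. = FALSE)

  n_expected <- 4L * length(arena$objects)
  sessions <- list()
  for (p in m$participants) {
    tr <- trials[trials$participant_id == p$id, ]
    if (anyDuplicated(tr$trial_index))
      stop("duplicate trial indices for ", p$id, call. = FALSE)
    if (nrow(tr) != n_expected)
      note(p$id, ": ", nrow(tr), " trials (expected ", n_expected, ")")
    per <- table(tr$cue, tr$object_id)
    if (nrow(tr) == n_expected && any(per != 2L))
      note(p$id, ": objects not tested twice per cue")
    ooa <- point_distance(cbind(tr$response_x_vm, tr$response_y_vm),
                          matrix(arena$center, nrow(tr), 2,
                                 byrow = TRUE)) > arena$radius + 1e-9
    if (any(ooa))
      note(p$id, ": ", sum(ooa), " out-of-arena response(s)")
    path <- NULL
    if (!is.null(paths) && isTRUE(p$has_path)) {
      ps <- paths[paths$participant_id == p$id &
                    paths$phase == "encoding", ]
      if (nrow(ps)) {
        if (any(diff(ps$t_s) <= 0))
          note(p$id, ": non-increasing path timestamps")
        d <- point_distance(cbind(ps$x_vm, ps$y_vm),
                            matrix(arena$center, nrow(ps), 2,
                                   byrow = TRUE))
        if (any(d > arena$radius + 1e-9))
          note(p$id, ": ", sum(d > arena$radius + 1e-9),
               " out-of-arena path point(s)")
        path <- structure(list(samples = ps[c("t_s", "x_vm", "y_vm")],
                               events = NULL,
                               encoding_time = nrow(ps) / 60),
                          class = "encoding_path")
      }
    }
    sessions[[length(sessions) + 1L]] <- structure(
      list(id = p$id, group = p$group,
           subtype = p$subtype %||% NA_character_,
           seed = p$seed %||% NA_integer_, path = path,
           trials = tr[order(tr$trial_index),
                       setdiff(names(tr), "participant_id")],
           encoding_time = if (is.null(path)) NA_real_ else
             path$encoding_time),
      class = "ol_session")
  }
  if (length(issues)) {
    if (strict)
      stop("validation failed:\n  ", paste(issues, collapse = "\n  "),
           call. = FALSE)
    warning("validation issues:\n  ", paste(issues, collapse = "\n  "),
            call. = FALSE)
  }
  structure(sessions, class = "ol_cohort", arena = arena,
            seed = m$seed, validation = issues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
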