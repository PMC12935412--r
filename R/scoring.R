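#' Recall error for a single response
#'
#' Euclidean distance between the recalled position and the object's
#' encoded location, in vm.
#'
#' @param response Numeric length-2 response coordinates.
#' @param object_id Id of the cued object (must exist in
#'   `arena$objects`).
#' @param arena An [arena_config()].
#' @return Error in vm.
#' @export
recall_error <- function(response, object_id, arena = arena_config()) {
  point_distance(response, object_target(object_id, arena))
}

object_target <- function(object_id, arena) {
  tgt <- arena$objects[[object_id]]
  if (is.null(tgt))
    stop("unknown object id '", object_id, "'", call. = FALSE)
  tgt
}

#' Landmark attractor index
#'
#' Normalised shift of a response toward the intra-arena landmark:
#' `(d_target - d_responseLM) / d_target`, where `d_target` is the
#' distance from the object's encoded location to the landmark and
#' `d_responseLM` the distance from the response to the landmark.
#' Positive values indicate a bias toward the landmark; 1 means the
#' response sits on the landmark; 0 means it is as far from the landmark
#' as the target is.
#'
#' @inheritParams recall_error
#' @return Dimensionless index, at most 1.
#' @export
landmark_attractor_index <- function(response, object_id,
                                     arena = arena_config()) {
  attractor_index(response, object_target(object_id, arena),
                  arena$landmark, "landmark")
}

#' Centre attractor index
#'
#' Centre analogue of [landmark_attractor_index()]:
#' `(d_target - d_responseC) / d_target` with distances taken to the
#' arena centre. By this formula, positive values indicate responses
#' nearer the centre than the target is (centre-ward bias).
#'
#' @inheritParams recall_error
#' @return Dimensionless index, at most 1.
#' @export
center_attractor_index <- function(response, object_id,
                                   arena = arena_config()) {
  attractor_index(response, object_target(object_id, arena),
                  arena$center, "center")
}

attractor_index <- function(response, target, reference, what) {
  d_target <- point_distance(target, reference)
  if (d_target <= 0)
    stop("undefined index: target coincides with the ", what,
         call. = FALSE)
  (d_target - point_distance(response, reference)) / d_target
}

#' Nearest encoded object to a response
#'
#' @inheritParams recall_error
#' @return List with `object_id` (nearest encoded location, strict
#'   minimum), `distance`, and `ambiguous` (`TRUE` when two or more
#'   encoded locations are exactly equidistant).
#' @export
nearest_object <- function(response, arena = arena_config()) {
  d <- vapply(arena$objects, function(t) point_distance(response, t), 0)
  i <- which.min(d)
  list(object_id = names(d)[i], distance = unname(d[i]),
       ambiguous = sum(d == d[i]) > 1L)
}

#' Reference-frame switch labels
#'
#' Labels each trial of an ordered sequence by the transition from the
#' previous trial's cue: `first_trial` (excluded from switching models),
#' `no_switch`, `ego_to_allo`, or `allo_to_ego`.
#'
#' @param cues Character vector of cue conditions in presentation order;
#'   values must be `"ego"` or `"allo"`.
#' @return Character vector of labels, same length as `cues`.
#' @examples
#' switch_labels(c("ego", "ego", "allo"))
#' @export
switch_labels <- function(cues) {
  if (!length(cues)) return(character(0))
  if (!all(cues %in% c("ego", "allo")))
    stop("cues must be 'ego' or 'allo'", call. = FALSE)
  prev <- c(NA, cues[-length(cues)])
  ifelse(is.na(prev), "first_trial",
         ifelse(prev == cues, "no_switch",
                ifelse(prev == "ego", "ego_to_allo", "allo_to_ego")))
}

#' Score one session's recall trials
#'
#' Computes per-trial recall measures: Euclidean error, landmark and
#' centre attractor indices, nearest encoded object with the
#' object-location binding flag (response nearest to a non-cued object's
#' encoded location), and the reference-frame switch label. Trials must
#' carry presentation order in `trial_index`; responses outside the arena
#' are flagged via the `out_of_arena` column, never dropped.
#'
#' @param session An `ol_session`, or a trials data frame with columns
#'   `trial_index`, `cue`, `object_id`, `response_x_vm`, `response_y_vm`
#'   (and optionally `response_time_s`).
#' @param arena An [arena_config()].
#' @return Data frame with one row per trial.
#' @export
score_session <- function(session, arena = arena_config()) {
  if (inherits(session, "ol_session")) {
    trials <- session$trials
    id <- session$id; group <- session$group; subtype <- session$subtype
  } else {
    trials <- session
    id <- if (!is.null(trials$participant_id)) trials$participant_id[1]
          else NA_character_
    group <- if (!is.null(trials$group)) trials$group[1] else NA_character_
    subtype <- NA_character_
  }
  need <- c("trial_index", "cue", "object_id", "response_x_vm",
            "response_y_vm")
  if (!all(need %in% names(trials)))
    stop("trials need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(trials$trial_index))
    stop("duplicate trial indices", call. = FALSE)
  trials <- trials[order(trials$trial_index), ]
  n <- nrow(trials)
  err <- li <- ci <- nd <- numeric(n)
  nobj <- character(n); bind <- amb <- ooa <- logical(n)
  for (i in seq_len(n)) {
    resp <- c(trials$response_x_vm[i], trials$response_y_vm[i])
    oid <- trials$object_id[i]
    err[i] <- recall_error(resp, oid, arena)
    li[i] <- landmark_attractor_index(resp, oid, arena)
    ci[i] <- center_attractor_index(resp, oid, arena)
    nn <- nearest_object(resp, arena)
    nobj[i] <- nn$object_id; nd[i] <- nn$distance
    amb[i] <- nn$ambiguous
    bind[i] <- nn$object_id != oid || nn$ambiguous
    ooa[i] <- point_distance(resp, arena$center) > arena$radius + 1e-9
  }
  data.frame(participant_id = id, group = group, subtype = subtype,
             trial_index = trials$trial_index, cue = trials$cue,
             object_id = trials$object_id,
             response_x_vm = trials$response_x_vm,
             response_y_vm = trials$response_y_vm,
             response_time_s = if ("response_time_s" %in% names(trials))
               trials$response_time_s else NA_real_,
             error = err, landmark_index = li, center_index = ci,
             nearest_object = nobj, nearest_distance = nd,
             binding_flag = bind, binding_ambiguous = amb,
             switch_label = switch_labels(trials$cue),
             out_of_arena = ooa)
}

#' Score a whole cohort
#'
#' @param cohort An `ol_cohort`.
#' @param arena An [arena_config()]; defaults to the cohort's own.
#' @return Long data frame of per-trial scores (see [score_session()]),
#'   one row per trial per participant.
#' @export
score_cohort <- function(cohort, arena = NULL) {
  if (is.null(arena)) arena <- attr(cohort, "arena")
  if (is.null(arena)) arena <- arena_config()
  do.call(rbind, lapply(cohort, score_session, arena = arena))
}

#' Object-location binding error counts
#'
#' Counts binding errors (responses nearest to a non-cued object's
#' encoded location) per participant and cue condition, the unit of the
#' Poisson binding model.
#'
#' @param scores Per-trial score table from [score_cohort()] /
#'   [score_session()].
#' @return Data frame with columns `participant_id`, `group`, `cue`,
#'   `n_trials`, `binding_count`.
#' @export
binding_errors <- function(scores) {
  agg <- stats::aggregate(cbind(binding_count = scores$binding_flag,
                                n_trials = rep(1L, nrow(scores))),
                          by = list(participant_id = scores$participant_id,
                                    group = scores$group,
                                    cue = scores$cue),
                          FUN = sum)
  agg[order(agg$participant_id, agg$cue),
      c("participant_id", "group", "cue", "n_trials", "binding_count")]
}

#' Per-participant cue means
#'
#' Means of a per-trial measure within participant and cue, reshaped
#' wide; the per-participant predictors of the logistic diagnosis model.
#'
#' @param scores Per-trial score table.
#' @param measure Score column to average (default `"error"`).
#' @param by Grouping column (`"cue"` or `"switch_label"`); for
#'   `switch_label`, first trials are excluded.
#' @return Wide data frame: `participant_id`, `group`, one column per
#'   level of `by` named `<measure>_<level>`.
#' @export
participant_cue_means <- function(scores, measure = "error", by = "cue") {
  stopifnot(measure %in% names(scores), by %in% names(scores))
  if (by == "switch_label")
    scores <- scores[scores$switch_label != "first_trial", ]
  agg <- stats::aggregate(scores[[measure]],
                          by = list(participant_id = scores$participant_id,
                                    group = scores$group,
                                    level = scores[[by]]),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = c("participant_id", "group"),
                         timevar = "level", direction = "wide")
  names(wide) <- sub("^x\\.", paste0(measure, "_"), names(wide))
  rownames(wide) <- NULL
  wide
}
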