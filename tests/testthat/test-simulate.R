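arena <- arena_config()

test_that("noiseless unbiased walk goes straight between targets", {
  prof <- noiseless_profile()
  ids <- names(arena$objects)
  sched <- rep(ids, each = 4)
  path <- simulate_encoding_path(prof, arena, sched, seed = 1)
  # leg distances: start -> first target, then stop-point to next target;
  # each leg's walked distance can differ from the straight distance by
  # at most capture_radius + one step, and legs do not accumulate error
  stops <- c(list(arena$start), arena$objects[sched])
  legs <- sum(vapply(seq_along(sched), function(i)
    point_distance(stops[[i]], stops[[i + 1]]), 0))
  total <- sum(step_distances(path))
  expect_lt(abs(total - legs),
            length(sched) * (prof$capture_radius + prof$step_speed))
  # first leg is collinear: consecutive headings identical
  m <- as.matrix(path$samples[1:5, c("x_vm", "y_vm")])
  dirs <- atan2(diff(m[, 2]), diff(m[, 1]))
  expect_equal(max(dirs) - min(dirs), 0, tolerance = 1e-9)
})

test_that("encoding paths are reproducible and validate their schedule", {
  prof <- behavior_profile(heading_noise_sd = 0.3)
  p1 <- simulate_encoding_path(prof, arena, seed = 99)
  p2 <- simulate_encoding_path(prof, arena, seed = 99)
  expect_identical(p1, p2)
  expect_error(simulate_encoding_path(prof, arena,
                                      rep("cat", 16), seed = 1),
               "exactly 4 times")
  expect_error(simulate_encoding_path(prof, arena,
                                      names(arena$objects), seed = 1),
               "exactly 4 times")
})

test_that("encoding paths satisfy structural invariants", {
  prof <- behavior_profile(heading_noise_sd = 0.4,
                           thigmotaxis_weight = 0.5)
  path <- simulate_encoding_path(prof, arena, seed = 5)
  s <- path$samples
  expect_true(all(diff(s$t_s) == 1))  # 1 Hz, strictly increasing
  d <- sqrt(s$x_vm^2 + s$y_vm^2)
  expect_true(all(d <= arena$radius + 1e-9))
  expect_equal(nrow(path$events), 16L)
  expect_equal(as.integer(table(path$events$object_id)), rep(4L, 4))
  expect_equal(path$encoding_time, (nrow(s) - 1) / 60)
})

test_that("step cap aborts with diagnostics", {
  # heading noise so large the walk cannot reach its target in 50 steps
  prof <- behavior_profile(heading_noise_sd = 50)
  expect_error(simulate_encoding_path(prof, arena, seed = 3,
                                      max_steps = 50L),
               "step cap")
})

test_that("noiseless recall responses land exactly on their targets", {
  trials <- simulate_recall_trials(noiseless_profile(), arena, seed = 2)
  err <- mapply(function(x, y, o) recall_error(c(x, y), o, arena),
                trials$response_x_vm, trials$response_y_vm,
                trials$object_id)
  expect_equal(unname(err), rep(0, 16), tolerance = 1e-12)
})

test_that("full centre attraction collapses allocentric responses", {
  prof <- noiseless_profile(center_attraction = 1)
  trials <- simulate_recall_trials(prof, arena, seed = 4)
  allo <- trials[trials$cue == "allo", ]
  expect_equal(allo$response_x_vm, rep(0, 8), tolerance = 1e-12)
  expect_equal(allo$response_y_vm, rep(0, 8), tolerance = 1e-12)
  ego <- trials[trials$cue == "ego", ]  # unaffected by the centre dial
  err <- mapply(function(x, y, o) recall_error(c(x, y), o, arena),
                ego$response_x_vm, ego$response_y_vm, ego$object_id)
  expect_equal(unname(err), rep(0, 8), tolerance = 1e-12)
})

test_that("half landmark attraction puts responses at the midpoint", {
  prof <- noiseless_profile(landmark_attraction = 0.5)
  trials <- simulate_recall_trials(prof, arena, seed = 4)
  cat_ego <- trials[trials$cue == "ego" & trials$object_id == "cat", ][1, ]
  mid <- (arena$objects$cat + arena$landmark) / 2
  resp <- c(cat_ego$response_x_vm, cat_ego$response_y_vm)
  expect_equal(resp, mid, tolerance = 1e-12)
  # the midpoint halves the distance to the landmark, so the index is 1/2
  expect_equal(landmark_attractor_index(resp, "cat", arena), 0.5,
               tolerance = 1e-12)
})

test_that("recall trial structure invariants hold", {
  prof <- behavior_profile(recall_noise_sd = 20)
  trials <- simulate_recall_trials(prof, arena, seed = 10)
  expect_equal(nrow(trials), 16L)
  expect_equal(as.integer(table(trials$cue)), c(8L, 8L))
  per <- table(trials$cue, trials$object_id)
  expect_true(all(per == 2L))
  d <- sqrt(trials$response_x_vm^2 + trials$response_y_vm^2)
  expect_true(all(d <= arena$radius + 1e-9))
  expect_true(all(trials$response_time_s > 0))
})

test_that("thigmotaxis drives paths outward (Monte Carlo)", {
  mean_dc <- function(w) {
    prof <- behavior_profile(heading_noise_sd = 0.4,
                             thigmotaxis_weight = w)
    mean(vapply(1:100, function(s) {
      p <- simulate_encoding_path(prof, arena, seed = s)
      mean(sqrt(p$samples$x_vm^2 + p$samples$y_vm^2))
    }, 0))
  }
  expect_gt(mean_dc(1), mean_dc(0))
})

test_that("landmark approach weight draws paths toward the landmark", {
  mean_dl <- function(w) {
    prof <- behavior_profile(heading_noise_sd = 0.4,
                             landmark_approach_weight = w)
    mean(vapply(1:100, function(s) {
      p <- simulate_encoding_path(prof, arena, seed = s)
      mean(point_distance(as.matrix(p$samples[c("x_vm", "y_vm")]),
                          matrix(arena$landmark, nrow(p$samples), 2,
                                 byrow = TRUE)))
    }, 0))
  }
  d <- vapply(c(-0.3, 0, 0.3), mean_dl, 0)
  expect_true(all(diff(d) < 0))  # decreasing in the weight
})

test_that("centre attraction raises the centre attractor index", {
  mean_ci <- function(a) {
    prof <- behavior_profile(recall_noise_sd = 8, center_attraction = a)
    idx <- unlist(lapply(1:100, function(s) {
      tr <- simulate_recall_trials(prof, arena, seed = s)
      tr <- tr[tr$cue == "allo", ]
      mapply(function(x, y, o)
        center_attractor_index(c(x, y), o, arena),
        tr$response_x_vm, tr$response_y_vm, tr$object_id)
    }))
    mean(idx)
  }
  v <- vapply(c(0, 0.3, 0.7), mean_ci, 0)
  expect_true(all(diff(v) > 0))  # increasing in the dial
})

test_that("cohorts are deterministic and schema-valid at n = 1", {
  spec <- cohort_spec(n_per_group = 1, seed = 77)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  expect_length(c1, 2L)
  expect_setequal(vapply(c1, `[[`, "", "group"), c("HC", "aMCI"))
  for (s in c1) {
    expect_equal(nrow(s$trials), 16L)
    expect_true(all(table(s$trials$cue, s$trials$object_id) == 2L))
    expect_false(is.null(s$path))
    expect_true(is.finite(s$seed))
  }
})

test_that("all generated coordinates satisfy the arena constraint", {
  coh <- simulate_cohort(cohort_spec(n_per_group = 3, seed = 9))
  for (s in coh) {
    d_path <- sqrt(s$path$samples$x_vm^2 + s$path$samples$y_vm^2)
    expect_true(all(d_path <= arena$radius + 1e-9))
    d_resp <- sqrt(s$trials$response_x_vm^2 + s$trials$response_y_vm^2)
    expect_true(all(d_resp <= arena$radius + 1e-9))
  }
})
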