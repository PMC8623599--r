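test_that("iou matches direct arithmetic", {
  a <- c(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(iou(a, c(1, 1, 3, 3)), 1 / 7)
})

test_that("kp_distance contracts: identical pose 0, disjoint validity 1, half-diagonal 0.5", {
  pose <- tiny_pose(100, 100)
  box <- bbox_from_pose(pose, margin = 0.1)
  tr <- ambustride:::new_track(1L, box, pose, 0L)
  expect_equal(kp_distance(tr, pose), 0)

  other <- pose
  other[, 3] <- 0
  expect_equal(kp_distance(tr, other), 1)

  diag_len <- sqrt(sum((box[c(3, 4)] - box[c(1, 2)])^2))
  shift <- pose
  shift[, 1] <- pose[, 1] + diag_len / 2
  expect_equal(kp_distance(tr, shift), 0.5, tolerance = 1e-10)
})

test_that("association gates on IoU and matches the obvious pair", {
  pose <- tiny_pose(100, 100)
  box <- bbox_from_pose(pose, margin = 0.1)
  tr <- ambustride:::new_track(1L, box, pose, 0L)
  tr$pred_box <- box
  res <- associate(list(tr), list(pose))
  expect_equal(nrow(res$matches), 1)

  far <- tiny_pose(400, 400)
  res2 <- associate(list(tr), list(far))
  expect_equal(nrow(res2$matches), 0)
  expect_equal(res2$unmatched_tracks, 1L)
  expect_equal(res2$unmatched_detections, 1L)

  expect_equal(nrow(associate(list(), list(pose))$matches), 0)
})

test_that("branch-and-bound assignment is optimal against brute force", {
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  assign_min_cost <- get("assign_min_cost", envir = asNamespace("ambustride"))
  brute <- function(cost) {
    nr <- nrow(cost); nc <- ncol(cost)
    best <- NULL; best_key <- c(-1, Inf)
    cols <- c(seq_len(nc), rep(0L, nr))
    perms <- function(v, chosen = integer(0)) {
      if (length(chosen) == nr) {
        fin <- chosen != 0 & is.finite(cost[cbind(seq_len(nr), pmax(chosen, 1))])
        key <- c(sum(fin), sum(cost[cbind(which(fin), chosen[fin])]))
        if (key[1] > best_key[1] || (key[1] == best_key[1] && key[2] < best_key[2])) {
          best <<- ifelse(fin, chosen, 0L); best_key <<- key
        }
        return(invisible())
      }
      for (j in unique(v)) perms(v[-match(j, v)], c(chosen, j))
    }
    perms(cols)
    list(match = best, key = best_key)
  }
  for (s in 1:20) {
    cost <- with_seed(s, {
      m <- matrix(runif(12), 3, 4)
      m[m > 0.7] <- Inf
      m
    })
    got <- assign_min_cost(cost)
    want <- brute(cost)
    fin <- got != 0
    expect_equal(sum(fin), want$key[1], info = paste("seed", s))
    expect_equal(sum(cost[cbind(which(fin), got[fin])]), want$key[2],
                 tolerance = 1e-12, info = paste("seed", s))
  }
})

test_that("a single walker yields one track covering all frames", {
  sim <- simulate_walker(gait_params(duration = 3, noise_sd = 1, seed = 8))
  tracks <- track_sequence(sim$seq)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frames, 0:(n_frames(sim$seq) - 1))
  ## boxes always valid after Kalman updates
  expect_true(all(tracks[[1]]$boxes[, 3] > tracks[[1]]$boxes[, 1]))
  expect_true(all(tracks[[1]]$boxes[, 4] > tracks[[1]]$boxes[, 2]))
})

test_that("two non-crossing walkers keep constant ids with zero switches", {
  w1 <- gait_params(duration = 4, start_position = c(100, 120),
                    body_scale = 100, step_length = 55, seed = 11)
  w2 <- gait_params(duration = 4, start_position = c(300, 400),
                    body_scale = 100, step_length = 55, seed = 22,
                    stride_period = 1.1, swing_time_left = 0.45,
                    swing_time_right = 0.45)
  sc <- simulate_scene(list(w1, w2))
  tracks <- track_sequence(sc$seq)
  expect_length(tracks, 2)
  expect_equal(count_id_switches(tracks, sc$seq, sc$truth), 0)
})

test_that("keypoint-adapted association does not exceed pure-IoU switches on a crossing", {
  w1 <- gait_params(duration = 6, start_position = c(100, 250), seed = 11,
                    noise_sd = 1)
  w2 <- gait_params(duration = 6, start_position = c(100, 250), seed = 22,
                    noise_sd = 1, body_scale = 120, stride_period = 1.2)
  scx <- simulate_scene(list(w1, w2), crossing = TRUE)
  ## occlude the smaller walker while the boxes overlap (hard case)
  ioux <- vapply(seq_len(n_frames(scx$seq)), function(i) {
    ps <- scx$seq$frames[[i]]$poses
    iou(bbox_from_pose(ps[[1]]), bbox_from_pose(ps[[2]]))
  }, 1.0)
  win <- which(ioux > 0.2)
  occ <- seq(min(win) + 2, length.out = 12)
  seq2 <- scx$seq
  truth2 <- scx$truth
  for (i in occ) {
    keep <- scx$truth$frame_ids[[i]] != 2L
    seq2$frames[[i]]$poses <- seq2$frames[[i]]$poses[keep]
    truth2$frame_ids[[i]] <- truth2$frame_ids[[i]][keep]
  }
  sw_kp <- count_id_switches(track_sequence(seq2, tracker_config(kp_weight = 0.5)),
                             seq2, truth2)
  sw_iou <- count_id_switches(track_sequence(seq2, tracker_config(kp_weight = 0)),
                              seq2, truth2)
  expect_equal(sw_kp, 0)
  expect_lte(sw_kp, sw_iou)
})

test_that("a track resumes its id after an occlusion shorter than max_age", {
  sim <- simulate_walker(gait_params(duration = 4, seed = 5))
  seq2 <- sim$seq
  for (i in 45:64) seq2$frames[[i]]$poses <- list()   # 20-frame dropout
  tracks <- track_sequence(seq2, tracker_config(max_age = 30))
  expect_length(tracks, 1)
  expect_true(all(c(43L, 64L) %in% tracks[[1]]$frames))
})

test_that("pure-IoU tracking agrees with a greedy IoU matcher on an easy scene", {
  w1 <- gait_params(duration = 3, start_position = c(100, 120),
                    body_scale = 100, step_length = 55, seed = 1)
  w2 <- gait_params(duration = 3, start_position = c(300, 400),
                    body_scale = 100, step_length = 55, seed = 2)
  sc <- simulate_scene(list(w1, w2))
  tracks <- track_sequence(sc$seq, tracker_config(kp_weight = 0))
  ## oracle: frame-by-frame greedy IoU chaining of detections
  prev <- NULL; oracle_ids <- NULL
  for (f in sc$seq$frames) {
    boxes <- lapply(f$poses, bbox_from_pose)
    if (is.null(prev)) {
      ids <- seq_along(boxes)
    } else {
      ids <- vapply(boxes, function(b)
        prev$ids[which.max(vapply(prev$boxes, iou, 1.0, b = b))], 1L)
    }
    oracle_ids <- rbind(oracle_ids, vapply(seq_along(ids), function(j)
      sc$truth$frame_ids[[f$frame_index + 1]][j], 1L)[order(ids)])
    prev <- list(boxes = boxes, ids = ids)
  }
  ## both keep identities constant: every oracle column is constant and the
  ## tracker reports zero switches
  expect_true(all(apply(oracle_ids, 2, function(v) length(unique(v)) == 1)))
  expect_equal(count_id_switches(tracks, sc$seq, sc$truth), 0)
})
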