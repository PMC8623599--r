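#' Tracker configuration
#'
#' SORT-style tracking-by-detection over keypoint-derived boxes: a
#' constant-velocity Kalman filter on box center/scale/aspect, IoU-gated
#' one-to-one association, and a keypoint-adapted object model — the
#' association cost blends box overlap with the distance between the track's
#' keypoint template and the candidate pose, which reduces identity switches
#' when boxes of different persons overlap.
#'
#' @param iou_threshold Minimum IoU for an admissible match (gate).
#' @param max_age Frames a track survives without a match (1 s at 30 fps).
#' @param min_hits Matches needed before a track is reported.
#' @param kp_weight Blend weight lambda in `[0, 1]`: association cost is
#'   `(1 - lambda) * (1 - IoU) + lambda * kp_distance`. `0` is plain SORT.
#' @param kp_decay Exponential decay of the keypoint template update.
#' @param margin Box margin passed to [bbox_from_pose()].
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(iou_threshold = 0.3, max_age = 30, min_hits = 3,
                           kp_weight = 0.5, kp_decay = 0.8, margin = 0.10) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1, max_age >= 1,
            kp_weight >= 0, kp_weight <= 1)
  structure(list(iou_threshold = iou_threshold, max_age = max_age,
                 min_hits = min_hits, kp_weight = kp_weight,
                 kp_decay = kp_decay, margin = margin),
            class = "tracker_config")
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as `c(x_min, y_min, x_max, y_max)`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  if (inter <= 0) return(0)
  area <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  unname(inter / area)
}

## ---- Kalman filter (constant-velocity SORT model) -------------------------
## State [cx, cy, s, r, vcx, vcy, vs]: box center, scale (area), aspect ratio
## (constant), and velocities. Noise matrices follow the reference SORT
## implementation.

bbox_to_z <- function(box) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  c(box[1] + w / 2, box[2] + h / 2, w * h, w / h)
}

z_to_bbox <- function(z) {
  s <- max(z[3], 1)            # scale floor keeps the box valid
  r <- max(z[4], 1e-3)
  w <- sqrt(s * r); h <- s / w
  c(z[1] - w / 2, z[2] - h / 2, z[1] + w / 2, z[2] + h / 2)
}

kf_new <- function(box) {
  F_ <- diag(7); F_[1, 5] <- F_[2, 6] <- F_[3, 7] <- 1
  H_ <- cbind(diag(4), matrix(0, 4, 3))
  R_ <- diag(c(1, 1, 10, 10))
  P_ <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
  Q_ <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))
  x <- c(bbox_to_z(box), 0, 0, 0)
  list(x = x, P = P_, F_ = F_, H = H_, R = R_, Q = Q_)
}

kf_predict <- function(kf) {
  if (kf$x[3] + kf$x[7] <= 0) kf$x[7] <- 0
  kf$x <- as.numeric(kf$F_ %*% kf$x)
  kf$P <- kf$F_ %*% kf$P %*% t(kf$F_) + kf$Q
  kf
}

kf_update <- function(kf, box) {
  z <- bbox_to_z(box)
  y <- z - as.numeric(kf$H %*% kf$x)
  S <- kf$H %*% kf$P %*% t(kf$H) + kf$R
  K <- kf$P %*% t(kf$H) %*% solve(S)
  kf$x <- kf$x + as.numeric(K %*% y)
  kf$P <- (diag(7) - K %*% kf$H) %*% kf$P
  kf
}

## ---- keypoint-adapted object model ---------------------------------------

## New track state (mutable environment while tracking).
new_track <- function(id, box, pose, frame) {
  tr <- new.env(parent = emptyenv())
  tr$id <- id
  tr$kf <- kf_new(box)
  tr$hits <- 1L
  tr$age <- 0L                 # frames since last match
  tr$frames <- frame
  tr$boxes <- matrix(box, 1, 4)
  tr$poses <- list(pose)
  ctr <- bbox_to_z(box)[1:2]
  tr$tmpl <- sweep(pose[, 1:2, drop = FALSE], 2, ctr)  # offsets from center
  tr$tmpl_valid <- pose[, 3] > 0
  tr$pred_box <- box
  tr
}

#' Keypoint distance between a track and a candidate pose
#'
#' Mean Euclidean distance between the track's predicted keypoint locations
#' (its exponentially updated template placed at the Kalman-predicted box
#' center) and the candidate's keypoints, over keypoints valid in both,
#' normalized by the predicted box diagonal and clipped to `[0, 1]`. With no
#' commonly valid keypoints the distance is 1 (maximally dissimilar).
#'
#' @param track A track (as produced inside [track_sequence()]).
#' @param pose Candidate 25x3 keypoint matrix.
#' @return Distance in `[0, 1]`.
#' @export
kp_distance <- function(track, pose) {
  box <- track$pred_box
  ctr <- bbox_to_z(box)[1:2]
  diag_len <- sqrt((box[3] - box[1])^2 + (box[4] - box[2])^2)
  common <- track$tmpl_valid & pose[, 3] > 0
  if (!any(common) || diag_len <= 0) return(1)
  pred <- sweep(track$tmpl[common, , drop = FALSE], 2, ctr, "+")
  d <- sqrt(rowSums((pred - pose[common, 1:2, drop = FALSE])^2))
  min(mean(d) / diag_len, 1)
}

## Exact minimum-cost one-to-one assignment (maximal matching first, then
## cost) by branch-and-bound enumeration; rows = tracks, cols = detections,
## Inf = forbidden pair. Suitable for the small person counts of this domain.
assign_min_cost <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(integer(0))
  if (max(nr, nc) > 8) return(assign_greedy(cost))
  best <- list(val = Inf, nmatch = -1L, match = rep(0L, nr))
  match <- rep(0L, nr)
  used <- rep(FALSE, nc)
  recurse <- function(i, val, nmatch) {
    if (i > nr) {
      if (nmatch > best$nmatch ||
          (nmatch == best$nmatch && val < best$val)) {
        best <<- list(val = val, nmatch = nmatch, match = match)
      }
      return(invisible())
    }
    remaining <- nr - i + 1L
    if (nmatch + remaining < best$nmatch) return(invisible())
    for (j in seq_len(nc)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <<- TRUE; match[i] <<- j
        recurse(i + 1L, val + cost[i, j], nmatch + 1L)
        used[j] <<- FALSE; match[i] <<- 0L
      }
    }
    recurse(i + 1L, val, nmatch)
  }
  recurse(1L, 0, 0L)
  best$match
}

assign_greedy <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  match <- rep(0L, nr)
  repeat {
    if (!any(is.finite(cost))) break
    k <- which.min(cost)
    i <- (k - 1L) %% nr + 1L; j <- (k - 1L) %/% nr + 1L
    match[i] <- j
    cost[i, ] <- Inf; cost[, j] <- Inf
  }
  match
}

#' Associate live tracks with detections
#'
#' Optimal one-to-one assignment minimizing
#' `(1 - lambda) * (1 - IoU) + lambda * kp_distance`, with pairs whose IoU is
#' below `cfg$iou_threshold` forbidden regardless of cost.
#'
#' @param tracks List of track objects with predicted boxes.
#' @param detections List of 25x3 candidate pose matrices.
#' @param cfg A [tracker_config()].
#' @param image_size Optional clamp for detection boxes.
#' @return List with `matches` (2-column matrix of track/detection indices),
#'   `unmatched_tracks`, `unmatched_detections`.
#' @export
associate <- function(tracks, detections, cfg = tracker_config(),
                      image_size = NULL) {
  nt <- length(tracks); nd <- length(detections)
  empty <- list(matches = matrix(0L, 0, 2),
                unmatched_tracks = seq_len(nt),
                unmatched_detections = seq_len(nd))
  if (nt == 0 || nd == 0) return(empty)
  det_boxes <- lapply(detections, bbox_from_pose,
                      margin = cfg$margin, image_size = image_size)
  cost <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) {
    for (j in seq_len(nd)) {
      ov <- iou(tracks[[i]]$pred_box, det_boxes[[j]])
      if (ov < cfg$iou_threshold) next
      cost[i, j] <- (1 - cfg$kp_weight) * (1 - ov) +
        cfg$kp_weight * kp_distance(tracks[[i]], detections[[j]])
    }
  }
  match <- assign_min_cost(cost)
  mt <- which(match > 0L)
  list(matches = cbind(track = mt, detection = match[mt]),
       unmatched_tracks = which(match == 0L),
       unmatched_detections = setdiff(seq_len(nd), match[mt]))
}

#' Track all persons through a keypoint sequence
#'
#' Per frame: Kalman predict for every live track, IoU-gated association with
#' the keypoint-blended cost, Kalman update and exponential keypoint-template
#' update for matches, new tracks for unmatched detections, and removal of
#' tracks unmatched for more than `max_age` frames. Tracks are reported once
#' they have at least `min_hits` matches; their pre-confirmation frames are
#' kept so no leading video is lost.
#'
#' @param seq A [kp_sequence()].
#' @param cfg A [tracker_config()].
#' @return List of `amb_track` objects: `id`, `frames` (0-based), `boxes`
#'   (n x 4), `poses` (list of 25x3), `hits`.
#' @export
track_sequence <- function(seq, cfg = tracker_config()) {
  stopifnot(inherits(seq, "kp_sequence"))
  live <- list()
  done <- list()
  next_id <- 1L
  for (f in seq$frames) {
    dets <- Filter(function(p) sum(p[, 3] > 0) >= 2, f$poses)
    for (tr in live) {
      tr$kf <- kf_predict(tr$kf)
      tr$pred_box <- z_to_bbox(tr$kf$x[1:4])
    }
    res <- associate(live, dets, cfg, image_size = seq$image_size)
    if (nrow(res$matches) > 0) {
      for (k in seq_len(nrow(res$matches))) {
        tr <- live[[res$matches[k, 1]]]
        pose <- dets[[res$matches[k, 2]]]
        box <- bbox_from_pose(pose, margin = cfg$margin,
                              image_size = seq$image_size)
        tr$kf <- kf_update(tr$kf, box)
        post_box <- z_to_bbox(tr$kf$x[1:4])
        tr$hits <- tr$hits + 1L
        tr$age <- 0L
        tr$frames <- c(tr$frames, f$frame_index)
        tr$boxes <- rbind(tr$boxes, post_box)
        tr$poses <- c(tr$poses, list(pose))
        ctr <- bbox_to_z(post_box)[1:2]
        off <- sweep(pose[, 1:2, drop = FALSE], 2, ctr)
        valid <- pose[, 3] > 0
        both <- valid & tr$tmpl_valid
        tr$tmpl[both, ] <- cfg$kp_decay * tr$tmpl[both, , drop = FALSE] +
          (1 - cfg$kp_decay) * off[both, , drop = FALSE]
        fresh <- valid & !tr$tmpl_valid
        tr$tmpl[fresh, ] <- off[fresh, , drop = FALSE]
        tr$tmpl_valid <- tr$tmpl_valid | valid
      }
    }
    for (i in res$unmatched_tracks) live[[i]]$age <- live[[i]]$age + 1L
    keep <- vapply(live, function(tr) tr$age <= cfg$max_age, TRUE)
    done <- c(done, live[!keep])
    live <- live[keep]
    for (j in res$unmatched_detections) {
      pose <- dets[[j]]
      box <- bbox_from_pose(pose, margin = cfg$margin,
                            image_size = seq$image_size)
      live[[length(live) + 1]] <- new_track(next_id, box, pose, f$frame_index)
      next_id <- next_id + 1L
    }
  }
  all_tracks <- c(done, live)
  confirmed <- Filter(function(tr) tr$hits >= cfg$min_hits, all_tracks)
  confirmed <- confirmed[order(vapply(confirmed, function(tr) tr$id, 1L))]
  lapply(confirmed, function(tr) {
    structure(list(id = tr$id, frames = as.integer(tr$frames),
                   boxes = tr$boxes, poses = tr$poses, hits = tr$hits),
              class = "amb_track")
  })
}

#' @export
print.amb_track <- function(x, ...) {
  cat(sprintf("<amb_track> id %d: frames %d-%d (%d observed)\n",
              x$id, min(x$frames), max(x$frames), length(x$frames)))
  invisible(x)
}

#' Count identity switches against simulator ground truth
#'
#' Every observed track/frame pose is matched back to the true walker whose
#' simulated pose it is (nearest pose in that frame); for each true walker the
#' number of changes in the covering track id is counted — the standard
#' identity-switch metric.
#'
#' @param tracks Output of [track_sequence()].
#' @param seq The tracked [kp_sequence()].
#' @param truth The `scene_truth` from [simulate_scene()].
#' @return Integer number of identity switches summed over walkers.
#' @export
count_id_switches <- function(tracks, seq, truth) {
  ## walker id -> (frame, covering track id) pairs
  cover <- lapply(truth$walkers, function(w) NULL)
  names(cover) <- vapply(truth$walkers, function(w) as.character(w$id), "")
  for (tr in tracks) {
    for (k in seq_along(tr$frames)) {
      fi <- tr$frames[k] + 1L
      frame_poses <- seq$frames[[fi]]$poses
      d <- vapply(frame_poses, function(p)
        mean(abs(p[, 1:2] - tr$poses[[k]][, 1:2])), 1.0)
      wid <- as.character(truth$frame_ids[[fi]][which.min(d)])
      cover[[wid]] <- rbind(cover[[wid]], c(tr$frames[k], tr$id))
    }
  }
  sum(vapply(cover, function(m) {
    if (is.null(m) || nrow(m) < 2) return(0L)
    ids <- m[order(m[, 1]), 2]
    sum(diff(ids) != 0L)
  }, 1L))
}
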