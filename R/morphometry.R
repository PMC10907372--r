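#' Detect and measure droplets in a simulated concentration field
#'
#' Thresholds the active-monomer field at the dense/dilute midpoint (by
#' default the midpoint of the one-species binodal at the run's `chi`),
#' labels connected components with 8-connectivity, discards components
#' smaller than `min_size` cells, and measures each droplet. On periodic
#' grids, components touching opposite edges are merged and centroids/second
#' moments are computed with circular unwrapping, so a droplet crossing the
#' boundary is counted once.
#'
#' @param field 2-D numeric matrix (a 3-D array is labeled slice by slice and
#'   records carry a `slice` column; "area" is then per-slice area).
#' @param threshold Dense-phase threshold; defaults to
#'   `droplet_threshold(params)`.
#' @param min_size Minimum component size in cells (default 4).
#' @param params Optional [model_params()] used for the default threshold.
#' @param periodic Treat the domain as periodic (default `TRUE`).
#' @param frame_time Time stamp copied into each record.
#' @return A data frame of droplet records with columns `frame_time`, `id`,
#'   `area` (cells), `equivalent_diameter`, `eccentricity`, `cx`, `cy`.
#' @export
label_droplets <- function(field, threshold = NULL, min_size = 4,
                           params = NULL, periodic = TRUE, frame_time = NA) {
  if (!all(is.finite(field)))
    stop("label_droplets: field contains non-finite values", call. = FALSE)
  if (is.null(threshold)) {
    if (is.null(params))
      stop("label_droplets: supply either threshold or params", call. = FALSE)
    threshold <- droplet_threshold(params)
  }
  if (length(dim(field)) == 3) {
    out <- do.call(rbind, lapply(seq_len(dim(field)[3]), function(z) {
      df <- label_droplets(field[, , z], threshold, min_size,
                           periodic = periodic, frame_time = frame_time)
      if (nrow(df)) df$slice <- z
      df
    }))
    return(out)
  }
  mask <- field > threshold
  lab <- label_mask(mask, periodic = periodic)
  measure_label_matrix(lab, min_size = min_size, periodic = periodic,
                       frame_time = frame_time)
}

# 8-connected labeling built on EBImage's 4-connected bwlabel plus a
# union-find merge over diagonal (and optionally periodic-wrap) adjacencies.
label_mask <- function(mask, periodic = FALSE) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  if (periodic) {
    pairs <- rbind(pairs,
      cbind(lab[nr, ], lab[1, ]),                        # row wrap
      cbind(lab[nr, -nc], lab[1, -1]),
      cbind(lab[nr, -1], lab[1, -nc]),
      cbind(lab[, nc], lab[, 1]),                        # column wrap
      cbind(lab[-nr, nc], lab[-1, 1]),
      cbind(lab[-1, nc], lab[-nr, 1]))
  }
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  n_lab <- max(lab)
  parent <- seq_len(n_lab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

# Per-label area, equivalent diameter, eccentricity and centroid, with
# circular coordinate unwrapping on periodic grids.
measure_label_matrix <- function(lab, min_size = 4, periodic = FALSE,
                                 frame_time = NA) {
  empty <- data.frame(frame_time = numeric(), id = integer(),
                      area = numeric(), equivalent_diameter = numeric(),
                      eccentricity = numeric(), cx = numeric(),
                      cy = numeric())
  if (max(lab) == 0) return(empty)
  idx <- which(lab > 0)
  ids <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  recs <- lapply(sort(unique(ids)), function(id) {
    sel <- ids == id
    if (sum(sel) < min_size) return(NULL)
    x <- rc[sel, 1]; y <- rc[sel, 2]
    if (periodic) {
      x <- unwrap_circular(x, nrow(lab))
      y <- unwrap_circular(y, ncol(lab))
    }
    area <- length(x)
    mu20 <- mean((x - mean(x))^2)
    mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + disc) / 2
    l2 <- (mu20 + mu02 - disc) / 2
    ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
    # map unwrapped centroids back into the principal window (0, N]
    wrap <- function(m, N) if (periodic) ((m - 1) %% N) + 1 else m
    data.frame(frame_time = frame_time, id = id, area = area,
               equivalent_diameter = 2 * sqrt(area / pi),
               eccentricity = ecc, cx = wrap(mean(x), nrow(lab)),
               cy = wrap(mean(y), ncol(lab)))
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) return(empty)
  recs$id <- seq_len(nrow(recs))
  recs
}

# Shift periodic coordinates into a window centred on their circular mean.
unwrap_circular <- function(x, N) {
  theta <- 2 * pi * (x - 1) / N
  mu <- atan2(mean(sin(theta)), mean(cos(theta)))
  cx <- mu * N / (2 * pi) + 1
  d <- (x - cx + N / 2) %% N - N / 2
  cx + d
}

#' Per-frame droplet metrics along a trajectory
#'
#' Runs [label_droplets()] on every snapshot and assembles count, total area
#' and mean area in time order. Jumps in the mean-area trajectory occur
#' whenever the discrete droplet count changes.
#'
#' @param traj A `ch_trajectory` from [run_scenario()].
#' @param threshold Dense-phase threshold; defaults to the trajectory's
#'   parameter-derived threshold.
#' @param min_size Minimum droplet size in cells.
#' @return A data frame with columns `frame_time`, `count`, `total_area`,
#'   `mean_area` (`NA` when no droplets are present).
#' @export
trajectory_metrics <- function(traj, threshold = NULL, min_size = 4) {
  stopifnot(inherits(traj, "ch_trajectory"))
  if (is.null(threshold)) threshold <- droplet_threshold(traj$params)
  rows <- lapply(seq_along(traj$snapshots), function(k) {
    recs <- tryCatch(
      label_droplets(traj$snapshots[[k]]$n, threshold, min_size,
                     frame_time = traj$times[k]),
      error = function(e) stop(sprintf("trajectory_metrics: frame %d: %s",
                                       k, conditionMessage(e)), call. = FALSE))
    data.frame(frame_time = traj$times[k], count = nrow(recs),
               total_area = sum(recs$area),
               mean_area = if (nrow(recs)) mean(recs$area) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Track droplets across frames by maximum pixel overlap
#'
#' Assigns each droplet in frame `k+1` to the frame-`k` track whose labeled
#' pixels it overlaps the most (ties broken by larger overlap area, then by
#' lower label id); unmatched droplets open new tracks. Returns per-track
#' area time series used for dissolution half-times.
#'
#' @param traj A `ch_trajectory`.
#' @param threshold,min_size As in [label_droplets()].
#' @return A data frame with columns `track`, `frame_time`, `area` (one row
#'   per track per frame in which it is present).
#' @export
track_droplets <- function(traj, threshold = NULL, min_size = 4) {
  stopifnot(inherits(traj, "ch_trajectory"))
  if (is.null(threshold)) threshold <- droplet_threshold(traj$params)
  labs <- lapply(traj$snapshots, function(s) {
    lab <- label_mask(s$n > threshold, periodic = TRUE)
    # drop under-sized components
    tab <- tabulate(lab[lab > 0])
    small <- which(tab > 0 & tab < min_size)
    if (length(small)) lab[lab %in% small] <- 0L
    lab
  })
  out <- list()
  n_tracks <- 0L
  prev_track <- integer()  # label id -> track id in previous frame
  for (k in seq_along(labs)) {
    lab <- labs[[k]]
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    track_of <- setNames(integer(length(ids)), ids)
    if (k > 1L && length(ids)) {
      both <- labs[[k - 1]] > 0 & lab > 0
      if (any(both)) {
        ov <- table(prev = labs[[k - 1]][both], cur = lab[both])
        # each current label inherits the track of its max-overlap predecessor
        claims <- list()
        for (cur in colnames(ov)) {
          col <- ov[, cur]
          if (sum(col) == 0) next
          best_prev <- rownames(ov)[which(col == max(col))]
          best_prev <- min(as.integer(best_prev))  # tie -> lower label id
          claims[[cur]] <- c(prev = best_prev,
                             overlap = max(col), cur = as.integer(cur))
        }
        if (length(claims)) {
          cl <- do.call(rbind, claims)
          # one continuation per track: largest overlap, then lower cur id
          ord <- order(cl[, "prev"], -cl[, "overlap"], cl[, "cur"])
          cl <- cl[ord, , drop = FALSE]
          keep <- !duplicated(cl[, "prev"])
          for (i in which(keep)) {
            tr <- prev_track[[as.character(cl[i, "prev"])]]
            track_of[[as.character(cl[i, "cur"])]] <- tr
          }
        }
      }
    }
    for (id in names(track_of)) {
      if (track_of[[id]] == 0L) {
        n_tracks <- n_tracks + 1L
        track_of[[id]] <- n_tracks
      }
    }
    areas <- tabulate(lab[lab > 0])
    for (id in ids)
      out[[length(out) + 1L]] <- data.frame(
        track = track_of[[as.character(id)]], frame_time = traj$times[k],
        area = areas[id])
    prev_track <- track_of
  }
  if (!length(out))
    return(data.frame(track = integer(), frame_time = numeric(),
                      area = numeric()))
  res <- do.call(rbind, out)
  res[order(res$track, res$frame_time), ]
}

#' Dissolution half-time of a tracked droplet
#'
#' First time at which the droplet's area falls below half its initial value,
#' linearly interpolated between frames. A droplet that vanishes between
#' frames is treated as reaching zero area at the next frame time.
#'
#' @param times Frame times (increasing).
#' @param areas Droplet areas at those times; the series must start positive.
#'   `NA` after the last positive value marks droplet disappearance.
#' @return The half-time, or `NA` with attribute `status = "undissolved"` if
#'   the area never falls below half its initial value.
#' @export
dissolution_halftime <- function(times, areas) {
  if (!length(areas) || is.na(areas[1]) || areas[1] <= 0)
    stop("dissolution_halftime: series must start at a positive area",
         call. = FALSE)
  areas[is.na(areas)] <- 0
  half <- areas[1] / 2
  below <- which(areas < half)
  below <- below[below > 1]
  if (!length(below)) return(structure(NA_real_, status = "undissolved"))
  k <- below[1]
  # linear interpolation across the crossing frame pair
  t0 <- times[k - 1]; t1 <- times[k]
  a0 <- areas[k - 1]; a1 <- areas[k]
  t0 + (a0 - half) / (a0 - a1) * (t1 - t0)
}

#' Power-law exponent by least squares in log-log space
#'
#' Fits `log(y) ~ log(x)` and returns the slope (the scaling exponent) with
#' fit diagnostics. Used for droplet half-time vs initial radius and for
#' classifying dense-area-vs-time dissolution regimes (surface- vs
#' volume-driven), whose exponent ranges are configuration, not claims.
#'
#' @param x,y Positive numeric vectors of equal length >= 3.
#' @return A list with `exponent`, `prefactor`, `r_squared`, `stderr`.
#' @export
scaling_exponent <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("scaling_exponent: need at least 3 pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("scaling_exponent: values must be positive", call. = FALSE)
  fit <- lm(log(y) ~ log(x))
  sm <- summary(fit)
  list(exponent = unname(coef(fit)[2]),
       prefactor = exp(unname(coef(fit)[1])),
       r_squared = sm$r.squared,
       stderr = sm$coefficients[2, 2])
}

#' Interface sharpness of a droplet field
#'
#' Mean gradient magnitude (periodic central differences) over interface
#' cells, i.e. cells whose 4-neighborhood crosses the dense/dilute threshold.
#' Surface-driven dissolution (slow inhibitor diffusion) retains sharp
#' interfaces; volume-driven dissolution (fast diffusion) blurs droplets and
#' lowers this statistic.
#'
#' @param field 2-D numeric matrix.
#' @param threshold Dense/dilute threshold.
#' @return Scalar mean interface gradient magnitude (0 if no interface).
#' @export
interface_sharpness <- function(field, threshold) {
  sh <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[(seq_len(nr) - 1 + dr) %% nr + 1, (seq_len(nc) - 1 + dc) %% nc + 1]
  }
  gx <- (sh(field, 1, 0) - sh(field, -1, 0)) / 2
  gy <- (sh(field, 0, 1) - sh(field, 0, -1)) / 2
  gmag <- sqrt(gx^2 + gy^2)
  mask <- field > threshold
  boundary <- mask != sh(mask, 1, 0) | mask != sh(mask, -1, 0) |
    mask != sh(mask, 0, 1) | mask != sh(mask, 0, -1)
  if (!any(boundary)) return(0)
  mean(gmag[boundary])
}

#' Export per-droplet records along a trajectory to CSV
#'
#' @param traj A `ch_trajectory`.
#' @param path Output CSV path (columns
#'   `frame_time,id,area,equivalent_diameter,eccentricity,cx,cy`).
#' @param threshold,min_size As in [label_droplets()].
#' @return The combined data frame, invisibly if `path` is given.
#' @export
measure_fields_csv <- function(traj, path = NULL, threshold = NULL,
                               min_size = 4) {
  if (is.null(threshold)) threshold <- droplet_threshold(traj$params)
  recs <- do.call(rbind, lapply(seq_along(traj$snapshots), function(k)
    label_droplets(traj$snapshots[[k]]$n, threshold, min_size,
                   frame_time = traj$times[k])))
  if (!is.null(path)) {
    write.csv(recs, path, row.names = FALSE)
    return(invisible(recs))
  }
  recs
}
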