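#' Configuration of the micrograph quantification pipeline
#'
#' @param pixel_size Pixel size in micrometers per pixel (required for any
#'   micrometer-denominated output; no instrument default is assumed).
#' @param gaussian_sigma Gaussian pre-smoothing sigma in pixels (default 2).
#' @param dilation_radius Radius in pixels of the final disk dilation
#'   (default 5); compensates the systematic underestimation of the
#'   edge-threshold mask at the price of overestimating small objects.
#' @param opening_radius Radius of the binary opening that removes unenclosed
#'   lines and speckles (default 1).
#' @param edge_floor Robustness floor on the edge threshold, as a multiple of
#'   the median Sobel magnitude (default 3): the binarization threshold is
#'   `max(otsu, edge_floor * median)`, which suppresses the spurious
#'   detections Otsu would produce on frames containing only noise.
#' @param images_per_condition Number of images pooled per time point and
#'   condition (default 8).
#' @param zero_filter List with `min_count` (default 16), `diameter_cutoff`
#'   in micrometers (default 1.5) and `total_area_cutoff` in square
#'   micrometers (default 28.32, kept verbatim as the conventional value even
#'   though 16 disks of 1.5 micrometer diameter sum to 28.27).
#' @param border_policy Keep or remove objects touching the image border.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(pixel_size, gaussian_sigma = 2, dilation_radius = 5,
                         opening_radius = 1, edge_floor = 3,
                         images_per_condition = 8,
                         zero_filter = list(min_count = 16,
                                            diameter_cutoff = 1.5,
                                            total_area_cutoff = 28.32),
                         border_policy = c("keep", "remove")) {
  if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0)
    stop("quant_config: 'pixel_size' must be a positive number (um/px)",
         call. = FALSE)
  if (gaussian_sigma < 0 || dilation_radius < 0 || opening_radius < 0)
    stop("quant_config: radii and sigma must be >= 0", call. = FALSE)
  zf <- modifyList(list(min_count = 16, diameter_cutoff = 1.5,
                        total_area_cutoff = 28.32), zero_filter)
  if (zf$min_count < 1)
    stop("quant_config: zero_filter$min_count must be >= 1", call. = FALSE)
  if (edge_floor < 0)
    stop("quant_config: 'edge_floor' must be >= 0", call. = FALSE)
  structure(list(pixel_size = pixel_size, gaussian_sigma = gaussian_sigma,
                 dilation_radius = dilation_radius,
                 opening_radius = opening_radius, edge_floor = edge_floor,
                 images_per_condition = as.integer(images_per_condition),
                 zero_filter = zf,
                 border_policy = match.arg(border_policy)),
            class = "quant_config")
}

# Zero-padded shift used by the Sobel and thinning operators.
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(img, kx))
  gy <- EBImage::imageData(EBImage::filter2(img, t(kx)))
  sqrt(gx^2 + gy^2)
}

# Zhang-Suen morphological thinning to 1-px-thick strokes.
thin_mask <- function(mask) {
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P2 <- shift_pad(m, -1, 0); P3 <- shift_pad(m, -1, 1)
      P4 <- shift_pad(m, 0, 1);  P5 <- shift_pad(m, 1, 1)
      P6 <- shift_pad(m, 1, 0);  P7 <- shift_pad(m, 1, -1)
      P8 <- shift_pad(m, 0, -1); P9 <- shift_pad(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (pass == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

disc_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, "disc")

#' Segment condensates in a fluorescence micrograph by edge detection
#'
#' Pipeline, in order: Gaussian smoothing, Sobel edge magnitude, Otsu
#' threshold on the edge magnitude (with a noise floor, see
#' [quant_config()]), binary cleanup (removal of tiny specks), thinning to
#' 1-px edges, filling of enclosed
#' regions, binary opening (removes unenclosed lines and speckles), disk
#' dilation, connected-component labeling (8-connectivity). Because only
#' in-focus objects have sharp edges, the edge-based threshold selects
#' objects in the focal plane.
#'
#' @param image 2-D numeric matrix of grayscale intensities (any scale;
#'   the pipeline is invariant to intensity rescaling up to Otsu binning).
#'   Color or non-2-D input is an error; a constant image yields an empty
#'   labeling.
#' @param config A [quant_config()].
#' @return A list with `labels` (integer label matrix), and diagnostic
#'   intermediates `edge_magnitude`, `edge_mask`, `filled` and `overlay`
#'   (image with labeled object boundaries set to the maximum intensity).
#' @export
segment_condensates <- function(image, config) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("segment_condensates: image must be a 2-D numeric grayscale matrix",
         call. = FALSE)
  stopifnot(inherits(config, "quant_config"))
  empty <- function(mag) list(labels = matrix(0L, nrow(image), ncol(image)),
                              edge_magnitude = mag,
                              edge_mask = matrix(FALSE, nrow(image),
                                                 ncol(image)),
                              filled = matrix(FALSE, nrow(image),
                                              ncol(image)),
                              overlay = image)
  rng <- range(image)
  if (diff(rng) == 0) return(empty(matrix(0, nrow(image), ncol(image))))
  img <- (image - rng[1]) / diff(rng)
  if (config$gaussian_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(img, config$gaussian_sigma))
  mag <- sobel_magnitude(img)
  mag <- mag / max(mag)
  thr <- EBImage::otsu(EBImage::Image(mag), range = c(0, 1))
  # Otsu always splits a unimodal histogram, so on frames without real edges
  # it would binarize pure noise; the floor (a multiple of the median edge
  # magnitude, i.e. of the noise-gradient level) keeps blank frames blank
  # while never engaging on frames with genuine condensate edges.
  thr <- max(thr, config$edge_floor * median(mag))
  edges <- mag > thr
  # cleanup: drop isolated specks (< 5 px) before thinning
  lab0 <- label_mask(edges, periodic = FALSE)
  sizes <- tabulate(lab0[lab0 > 0])
  edges[lab0 %in% which(sizes < 5)] <- FALSE
  thin <- thin_mask(edges)
  filled <- EBImage::imageData(EBImage::fillHull(thin * 1)) > 0
  opened <- if (config$opening_radius > 0) {
    EBImage::imageData(EBImage::opening(filled * 1,
                                        disc_brush(config$opening_radius))) > 0
  } else filled
  dilated <- if (config$dilation_radius > 0) {
    EBImage::imageData(EBImage::dilate(opened * 1,
                                       disc_brush(config$dilation_radius))) > 0
  } else opened
  labels <- label_mask(dilated, periodic = FALSE)
  if (config$border_policy == "remove" && max(labels) > 0) {
    border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)]))
    labels[labels %in% border_ids[border_ids > 0]] <- 0L
  }
  overlay <- image
  if (max(labels) > 0) {
    interior <- EBImage::imageData(
      EBImage::erode((labels > 0) * 1, EBImage::makeBrush(3, "box"))) > 0
    overlay[labels > 0 & !interior] <- rng[2]
  }
  list(labels = labels, edge_magnitude = mag, edge_mask = edges,
       filled = filled, overlay = overlay)
}

#' Measure labeled condensates in micrometer units
#'
#' Per-label area (square micrometers), equivalent diameter (the diameter of
#' the circle with the same area), eccentricity and centroid (pixels).
#'
#' @param labels Integer label matrix from [segment_condensates()].
#' @param pixel_size Micrometers per pixel.
#' @return A data frame with columns `id`, `area_um2`, `equiv_diameter_um`,
#'   `eccentricity`, `cx`, `cy` (one row per label; empty for an empty mask).
#' @export
measure_condensates <- function(labels, pixel_size) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  recs <- measure_label_matrix(labels, min_size = 1, periodic = FALSE)
  data.frame(id = recs$id,
             area_um2 = recs$area * pixel_size^2,
             equiv_diameter_um = recs$equivalent_diameter * pixel_size,
             eccentricity = recs$eccentricity,
             cx = recs$cx, cy = recs$cy)
}

#' Zero-condensate filter for a pooled condition
#'
#' A condition (all images of one time point) is reported as containing zero
#' condensate when fewer than `min_count` condensates were detected AND they
#' are small in either sense: mean equivalent diameter at most
#' `diameter_cutoff` or total area below `total_area_cutoff`. This reading
#' (conjunction of the count clause with the size disjunction) guarantees
#' that a few large droplets are never zeroed out. The filter is idempotent.
#'
#' @param records Data frame of condensate records pooled over the
#'   condition's images (needs columns `area_um2`, `equiv_diameter_um`).
#' @param config A [quant_config()] supplying the three cutoffs.
#' @return The records unchanged, or an empty record set with attribute
#'   `zero_condition = TRUE`.
#' @export
apply_zero_filter <- function(records, config) {
  stopifnot(inherits(config, "quant_config"))
  zf <- config$zero_filter
  count <- nrow(records)
  zero <- if (count == 0) TRUE else {
    count < zf$min_count &&
      (mean(records$equiv_diameter_um) <= zf$diameter_cutoff ||
         sum(records$area_um2) < zf$total_area_cutoff)
  }
  if (zero) {
    out <- records[0, , drop = FALSE]
    attr(out, "zero_condition") <- TRUE
    out
  } else {
    attr(records, "zero_condition") <- FALSE
    records
  }
}

#' Normalize droplet metrics against a reference time point
#'
#' Divides each droplet area by the reference mean area, the total area by
#' the reference total, and the count by the reference count; the reference
#' is the same sample prior to adding invader (inhibitor) or anti-invader.
#'
#' @param records Condensate records of one time point (possibly an empty,
#'   zero-condition set).
#' @param reference Non-empty condensate records of the reference time point.
#' @return A list with `normalized_areas`, `normalized_mean_area`,
#'   `normalized_total_area`, `normalized_count`.
#' @export
normalize_metrics <- function(records, reference) {
  area_col <- function(df) {
    if ("area_um2" %in% names(df)) df$area_um2 else df$area
  }
  ref <- area_col(reference)
  if (is.null(ref) || length(ref) == 0)
    stop("normalize_metrics: reference record set is empty", call. = FALSE)
  a <- area_col(records)
  if (is.null(a)) a <- numeric()
  list(normalized_areas = a / mean(ref),
       normalized_mean_area = if (length(a)) mean(a) / mean(ref) else 0,
       normalized_total_area = sum(a) / sum(ref),
       normalized_count = length(a) / length(ref))
}

#' Box-plot summary statistics
#'
#' Median, 25th/75th percentiles (linear-interpolation quantile convention),
#' whiskers at the most extreme data points within 1.5 IQR of the box, and
#' the points beyond the whiskers flagged as outliers.
#'
#' @param values Non-empty numeric vector.
#' @return An object of class `box_summary`: list with `median`, `q25`,
#'   `q75`, `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
box_summary <- function(values) {
  if (!length(values)) stop("box_summary: empty input", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_low = min(values[in_fence]),
                 whisker_high = max(values[in_fence]),
                 outliers = sort(values[!in_fence]), n = length(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> n=%d median=%.4g box=[%.4g, %.4g] whiskers=[%.4g, %.4g] outliers=%d\n",
    x$n, x$median, x$q25, x$q75, x$whisker_low, x$whisker_high,
    length(x$outliers)))
  invisible(x)
}

#' Half-sample bootstrap of a droplet statistic
#'
#' Draws three sub-samples of half the observations (without replacement,
#' seeded), computes the mean of each sub-sample, and returns the mean and
#' standard error of the mean over the three sub-sample values.
#'
#' @param values Numeric vector of (typically normalized) observations,
#'   length >= 2.
#' @param seed Integer seed; results are reproducible per seed.
#' @return An object of class `bootstrap_result`: list with
#'   `subsample_means` (length 3), `mean`, `sem`, `seed`.
#' @export
bootstrap_sem <- function(values, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("bootstrap_sem: need at least 2 observations",
                  call. = FALSE)
  m <- floor(n / 2)
  means <- with_seed(seed, vapply(1:3, function(k)
    mean(values[sample.int(n, m, replace = FALSE)]), numeric(1)))
  structure(list(subsample_means = means, mean = mean(means),
                 sem = sd(means) / sqrt(3), seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> mean=%.4g sem=%.4g (seed %d)\n",
              x$mean, x$sem, x$seed))
  invisible(x)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' @param path Image file (8- or 16-bit grayscale TIFF/PNG).
#' @return Numeric intensity matrix.
#' @export
read_micrograph <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else stop("read_micrograph: color images are not supported; ",
              "supply a single-channel grayscale image", call. = FALSE)
  }
  img
}
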