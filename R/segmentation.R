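#' Segmentation configuration
#'
#' Parameters of the image-analysis front end.  Geometry bounds are given
#' in micrometres and converted to pixels via \code{pixel_size}; defaults
#' correspond to E. coli rod dimensions (width 0.5-1.5 um, length 1-6 um).
#'
#' @param pixel_size um per pixel.
#' @param dark_cells \code{TRUE} when cells appear dark on a bright
#'   background (brightfield); set \code{FALSE} for inverted contrast.
#' @param local_window side of the local-adaptive-threshold window (px,
#'   odd).
#' @param local_offset offset above the local mean (normalised units) for a
#'   pixel to vote cell.
#' @param surface_sigma Gaussian sigma (px) of the background-surface
#'   estimate used by the adaptive-masking vote.
#' @param surface_offset offset above the background surface.
#' @param min_discriminability Otsu between-class variance fraction below
#'   which a frame is treated as foreground-free (degenerate-frame guard).
#' @param min_width,max_width,min_length,max_length single-cell geometry
#'   bounds (um) used for marker splitting.
#' @param min_area,max_area region area bounds (um^2) for size filtering.
#' @param split_depth maximum recursion depth when splitting oversized
#'   markers.
#' @param split_tolerance watershed tolerance (elevation units) used when
#'   splitting oversized components; smaller values split more eagerly.
#' @return list of class \code{seg_config}.
#' @export
seg_config <- function(pixel_size = 0.1, dark_cells = TRUE,
                       local_window = 51, local_offset = 0.04,
                       surface_sigma = 25, surface_offset = 0.04,
                       min_discriminability = 0.75,
                       min_width = 0.5, max_width = 1.5,
                       min_length = 1, max_length = 6,
                       min_area = 0.8, max_area = 20,
                       split_depth = 4, split_tolerance = 0.15) {
  stopifnot(pixel_size > 0, local_window %% 2 == 1, min_area > 0,
            max_area > min_area)
  structure(list(pixel_size = pixel_size, dark_cells = dark_cells,
                 local_window = local_window, local_offset = local_offset,
                 surface_sigma = surface_sigma,
                 surface_offset = surface_offset,
                 min_discriminability = min_discriminability,
                 min_width = min_width, max_width = max_width,
                 min_length = min_length, max_length = max_length,
                 min_area = min_area, max_area = max_area,
                 split_depth = split_depth,
                 split_tolerance = split_tolerance),
            class = "seg_config")
}

#' Preprocess a microscopy frame
#'
#' Contrast stretch to [0, 1], median-filter denoising and unsharp-mask
#' edge sharpening.  A constant frame is returned unchanged with a warning.
#'
#' @param frame numeric intensity matrix.
#' @param denoise "gaussian" (small Gaussian kernel; linear, so contrast
#'   inversion commutes with preprocessing), "median" (edge-preserving,
#'   slower) or "none".
#' @param denoise_par Gaussian sigma or median radius (px).
#' @param sharpen unsharp-mask amount (0 disables).
#' @param sharpen_sigma blur sigma of the unsharp mask.
#' @return matrix in [0, 1].
#' @export
preprocess_frame <- function(frame, denoise = c("gaussian", "median", "none"),
                             denoise_par = 1, sharpen = 0.4,
                             sharpen_sigma = 2) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  denoise <- match.arg(denoise)
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("constant frame: returned unchanged")
    return(frame)
  }
  x <- (frame - rng[1]) / diff(rng)
  if (denoise == "gaussian") {
    x <- gauss_blur(x, denoise_par)
  } else if (denoise == "median") {
    x <- ebi_mat(EBImage::medianFilter(EBImage::Image(x), denoise_par))
  }
  if (sharpen > 0) {
    x <- x + sharpen * (x - gauss_blur(x, sharpen_sigma))
    x[x < 0] <- 0; x[x > 1] <- 1
  }
  rng <- range(x)               # final stretch to the full output range
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  x
}

ebi_mat <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}

#' Hybrid cell/background classification
#'
#' Votes each pixel cell or background by three methods: a global Otsu
#' threshold, a local adaptive threshold over a sliding window, and an
#' adaptive masking method based on a smooth background-surface estimate.
#' A pixel is cell if at least two of the three methods vote cell.  A
#' degenerate-frame guard returns all-background when the foreground and
#' background intensity classes are not separated beyond the frame's noise.
#'
#' @param frame preprocessed frame ([preprocess_frame()]), values in [0,1].
#' @param config a [seg_config()].
#' @return logical matrix, \code{TRUE} = cell.
#' @export
classify_background <- function(frame, config = seg_config()) {
  stopifnot(is.matrix(frame))
  y <- if (config$dark_cells) 1 - frame else frame   # cells bright in y

  th <- EBImage::otsu(EBImage::Image(y), range = c(0, 1))
  hi <- y > th
  if (sum(hi) == 0 || sum(!hi) == 0) return(matrix(FALSE, nrow(y), ncol(y)))
  # degenerate-frame guard: Otsu discriminability (between-class variance
  # fraction).  A unimodal noise-only frame peaks near 0.64; frames with a
  # genuine foreground class score well above it.
  p1 <- mean(hi)
  eta <- p1 * (1 - p1) * (mean(y[hi]) - mean(y[!hi]))^2 /
    max(stats::var(as.vector(y)), 1e-12)
  if (eta < config$min_discriminability)
    return(matrix(FALSE, nrow(y), ncol(y)))

  v_global <- hi
  local_mean <- box_mean(y, config$local_window)
  v_local <- y > local_mean + config$local_offset
  surface <- background_surface(y, config$surface_sigma,
                                config$surface_offset)
  v_surface <- y > surface + config$surface_offset
  votes <- v_global + v_local + v_surface
  votes >= 2
}

# Iterative adaptive-masking background surface: the surface is
# re-estimated from background-classified pixels only (normalised Gaussian
# convolution), so that it interpolates under dense colonies instead of
# following them.
background_surface <- function(y, sigma, offset, iters = 2) {
  surf <- gauss_blur(y, sigma)
  for (i in seq_len(iters)) {
    bg <- (y <= surf + offset) * 1
    num <- gauss_blur(y * bg, sigma)
    den <- gauss_blur(bg, sigma)
    surf <- num / pmax(den, 1e-6)
  }
  surf
}

box_mean <- function(m, w) {
  k <- matrix(1 / (w * w), w, w)
  ebi_mat(EBImage::filter2(EBImage::Image(m), k, boundary = "replicate"))
}

#' Create cell markers from a binary mask
#'
#' Connected components of the mask become candidate markers; components
#' whose estimated rod dimensions exceed the configured single-cell bounds
#' are split recursively using the watershed transform of their distance
#' map (intensity valleys between touching rods coincide with distance-map
#' necks), until dimensions are in bounds or the split-depth limit is hit.
#' Components smaller than the minimum cell area are dropped.
#'
#' @param mask logical matrix from [classify_background()].
#' @param frame preprocessed intensity frame (reserved for edge cues).
#' @param config a [seg_config()].
#' @return integer marker label matrix (0 = background).
#' @export
create_markers <- function(mask, frame = NULL, config = seg_config()) {
  stopifnot(is.matrix(mask))
  cellness <- if (is.null(frame)) NULL else
    if (config$dark_cells) 1 - frame else frame
  px <- config$pixel_size
  min_area_px <- config$min_area / px^2
  max_len_px <- config$max_length / px
  max_wid_px <- config$max_width / px
  lab <- ebi_mat(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  out <- matrix(0L, nrow(mask), ncol(mask))
  next_lab <- 1L
  comps <- split(which(lab > 0), lab[lab > 0])
  queue <- lapply(comps, function(idx) list(idx = idx, depth = 0L))
  while (length(queue) > 0) {
    item <- queue[[1]]; queue <- queue[-1]
    idx <- item$idx
    if (length(idx) < min_area_px) next
    dims <- component_dims(idx, nrow(mask))
    if ((dims$length <= max_len_px && dims$width <= max_wid_px) ||
        item$depth >= config$split_depth) {
      out[idx] <- next_lab; next_lab <- next_lab + 1L
      next
    }
    subs <- split_component(idx, nrow(mask), ncol(mask), cellness,
                            config$split_tolerance)
    if (length(subs) <= 1) {          # unsplittable: accept as is
      out[idx] <- next_lab; next_lab <- next_lab + 1L
    } else {
      queue <- c(queue, lapply(subs, function(s)
        list(idx = s, depth = item$depth + 1L)))
    }
  }
  out
}

# principal-axis extent estimates (px) of a pixel component
component_dims <- function(idx, nrow_m) {
  r <- (idx - 1L) %% nrow_m + 1L
  c <- (idx - 1L) %/% nrow_m + 1L
  if (length(idx) == 1) return(list(length = 1, width = 1))
  cv <- stats::cov(cbind(r, c))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  # uniform rod of length L has axial variance L^2/12
  list(length = sqrt(12 * ev[1]), width = sqrt(16 * ev[2]))
}

# watershed split of an oversized component: elevation combines the
# distance map (geometry: necks between touching rods) with the intensity
# valleys of the preprocessed frame (edge information between cells)
split_component <- function(idx, H, W, cellness = NULL, tolerance = 0.15) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
  sub <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
  sub[cbind(r - r0 + 1, c - c0 + 1)] <- 1
  dm <- ebi_mat(EBImage::distmap(EBImage::Image(sub)))
  elev <- 0.3 * dm / max(dm, 1)
  if (!is.null(cellness)) {
    ysub <- cellness[r0:r1, c0:c1, drop = FALSE]
    elev <- elev + ysub * sub
  }
  ws <- ebi_mat(EBImage::watershed(EBImage::Image(elev * sub),
                                   tolerance = tolerance, ext = 1))
  labs <- sort(unique(ws[ws > 0]))
  if (length(labs) <= 1) return(list(idx))
  lapply(labs, function(l) {
    w <- which(ws == l & sub > 0)
    rr <- (w - 1L) %% nrow(sub) + r0
    cc <- (w - 1L) %/% nrow(sub) + c0
    (cc - 1L) * H + rr
  })
}

#' Watershed refinement of markers into cell regions
#'
#' Seeded watershed (EBImage::propagate) on the preprocessed intensity,
#' constrained to the cell mask: every marker grows into exactly one
#' region, with boundaries between competing markers placed along
#' intensity ridges (the bright gaps between dark touching cells).
#'
#' @param markers integer marker matrix from [create_markers()].
#' @param frame preprocessed intensity frame.
#' @param mask logical cell mask.
#' @param config a [seg_config()].
#' @return integer label matrix (class \code{LabelMask} semantics:
#'   0 = background).
#' @export
watershed_refine <- function(markers, frame, mask, config = seg_config()) {
  stopifnot(is.matrix(markers), is.matrix(frame), is.matrix(mask))
  if (max(markers) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  markers[!mask] <- 0L                 # enforce markers within mask
  y <- if (config$dark_cells) 1 - frame else frame
  lab <- EBImage::propagate(EBImage::Image(y),
                            seeds = EBImage::Image(markers),
                            mask = EBImage::Image(mask * 1) > 0.5)
  m <- ebi_mat(lab)
  storage.mode(m) <- "integer"
  m
}

#' Per-region measurements
#'
#' Region features on a label mask, measured on a fluorescence frame:
#' area A (px), total fluorescence F, mean F/A, background-corrected
#' fluorescence (F minus area times the mean background level), centroid,
#' and geometry features (major/minor axis, eccentricity, solidity,
#' perimeter, intensity CV).
#'
#' @param labels integer label matrix (0 = background).
#' @param fluor fluorescence intensity matrix of the same shape.
#' @return data.frame with one row per label present in the mask, plus the
#'   frame background level as attribute \code{background}.
#' @export
measure_regions <- function(labels, fluor) {
  stopifnot(is.matrix(labels), all(dim(labels) == dim(fluor)))
  H <- nrow(labels)
  idx <- which(labels > 0)
  bg <- if (length(idx) < length(labels))
    mean(fluor[labels == 0]) else 0
  if (length(idx) == 0) {
    out <- data.frame(label = integer(0), area = numeric(0), F = numeric(0),
                      mean_F = numeric(0), F_corr = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      major_px = numeric(0), minor_px = numeric(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      perimeter = numeric(0), int_cv = numeric(0))
    attr(out, "background") <- bg
    return(out)
  }
  lab <- labels[idx]
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  ff <- fluor[idx]
  # boundary pixels: any 4-neighbour with a different label
  per_px <- perimeter_pixels(labels)
  pp <- per_px[idx]
  groups <- split(seq_along(idx), lab)
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    n <- length(sel)
    r <- rr[sel]; c <- cc[sel]; f <- ff[sel]
    if (n > 2) {
      cv <- stats::cov(cbind(r, c))
      e <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      e <- pmax(e, 1e-12)
      maj <- 4 * sqrt(e[1]); min_ <- 4 * sqrt(e[2])
      ecc <- sqrt(1 - e[2] / e[1])
      sol <- n / max(chull_area(r, c), n)
    } else {
      maj <- n; min_ <- 1; ecc <- 0; sol <- 1
    }
    data.frame(label = as.integer(g), area = n, F = sum(f),
               mean_F = mean(f), F_corr = sum(f) - n * bg,
               centroid_r = mean(r), centroid_c = mean(c),
               major_px = maj, minor_px = min_, eccentricity = ecc,
               solidity = sol, perimeter = sum(pp[sel]),
               int_cv = if (mean(f) > 0) stats::sd(f) / mean(f) else 0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  attr(out, "background") <- bg
  out
}

perimeter_pixels <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(-1L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- labels
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  diffn <- (pad[1:H, 2:(W + 1)] != ctr) |
           (pad[3:(H + 2), 2:(W + 1)] != ctr) |
           (pad[2:(H + 1), 1:W] != ctr) |
           (pad[2:(H + 1), 3:(W + 2)] != ctr)
  diffn & ctr > 0
}

chull_area <- function(r, c) {
  pts <- unique(cbind(r, c))
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2 + nrow(pts) * 0.5
}

#' Train the mis-segmentation classifier
#'
#' Fits a support vector machine (radial kernel) distinguishing true cells
#' from segmentation artifacts on the geometry + intensity feature vector
#' of [measure_regions()] rows.  This programmatic training API replaces
#' interactive labelling.
#'
#' @param regions data.frame of region features ([measure_regions()] rows).
#' @param is_cell logical vector: \code{TRUE} for true cells.
#' @return object of class \code{region_classifier}.
#' @export
train_region_classifier <- function(regions, is_cell) {
  stopifnot(nrow(regions) == length(is_cell))
  X <- classifier_features(regions)
  y <- factor(ifelse(is_cell, "cell", "artifact"),
              levels = c("artifact", "cell"))
  if (length(unique(y)) < 2) stop("need both classes in the training set")
  model <- e1071::svm(X, y, kernel = "radial", scale = TRUE)
  structure(list(model = model), class = "region_classifier")
}

classifier_features <- function(regions) {
  as.matrix(regions[, c("area", "perimeter", "eccentricity", "solidity",
                        "mean_F", "int_cv")])
}

#' Filter segmented regions by size and classifier score
#'
#' Removes regions outside the configured area bounds and, when a trained
#' classifier is supplied, regions the classifier scores as artifacts.
#'
#' @param labels integer label matrix.
#' @param regions matching [measure_regions()] table (recomputed when
#'   \code{NULL}).
#' @param fluor fluorescence frame (needed when \code{regions} is NULL or a
#'   classifier is used).
#' @param config a [seg_config()].
#' @param classifier optional [train_region_classifier()] model; pass
#'   \code{"none"} (default NULL) for size-only filtering.
#' @return list with \code{labels} (filtered matrix) and \code{regions}
#'   (surviving rows).
#' @export
filter_regions <- function(labels, regions = NULL, fluor = NULL,
                           config = seg_config(), classifier = NULL) {
  if (is.null(regions)) {
    if (is.null(fluor)) stop("need fluor to compute region features")
    regions <- measure_regions(labels, fluor)
  }
  if (nrow(regions) == 0) return(list(labels = labels, regions = regions))
  px2 <- config$pixel_size^2
  keep <- regions$area * px2 >= config$min_area &
          regions$area * px2 <= config$max_area
  if (!is.null(classifier)) {
    if (!inherits(classifier, "region_classifier"))
      stop("classifier must be a trained region_classifier")
    pred <- stats::predict(classifier$model, classifier_features(regions))
    keep <- keep & pred == "cell"
  }
  drop <- regions$label[!keep]
  if (length(drop) > 0) labels[labels %in% drop] <- 0L
  list(labels = labels, regions = regions[keep, , drop = FALSE])
}

#' Segment one frame end to end
#'
#' Preprocess, hybrid background classification, marker creation,
#' watershed refinement, size/classifier filtering and measurement.
#'
#' @param bf brightfield-like frame (matrix).
#' @param fluor fluorescence frame (matrix), used for measurements; when
#'   \code{NULL} the brightfield frame is measured.
#' @param config a [seg_config()].
#' @param classifier optional region classifier.
#' @return list with \code{labels}, \code{regions}, \code{mask}.
#' @export
segment_frame <- function(bf, fluor = NULL, config = seg_config(),
                          classifier = NULL) {
  if (is.null(fluor)) fluor <- bf
  pre <- preprocess_frame(bf)
  mask <- classify_background(pre, config)
  markers <- create_markers(mask, pre, config)
  labels <- watershed_refine(markers, pre, mask, config)
  flt <- filter_regions(labels, fluor = fluor, config = config,
                        classifier = classifier)
  list(labels = flt$labels, regions = flt$regions, mask = mask)
}

#' Segment a rendered or loaded image stack
#'
#' Applies [segment_frame()] to every frame of a stack.
#'
#' @param bf list of brightfield matrices (or a [render_frames()] result,
#'   in which case both channels are taken from it).
#' @param fluor list of fluorescence matrices.
#' @param config a [seg_config()].
#' @param classifier optional region classifier.
#' @return list of class \code{segmentation}: \code{labels} (list),
#'   \code{regions} (list of data.frames), \code{t}.
#' @export
segment_stack <- function(bf, fluor = NULL, config = seg_config(),
                          classifier = NULL) {
  t <- NULL
  if (inherits(bf, "rendered_stack")) {
    t <- bf$t; fluor <- bf$fluor; bf <- bf$bf
  }
  stopifnot(is.list(bf))
  if (is.null(fluor)) fluor <- bf
  res <- lapply(seq_along(bf), function(k)
    segment_frame(bf[[k]], fluor[[k]], config, classifier))
  structure(list(labels = lapply(res, `[[`, "labels"),
                 regions = lapply(res, `[[`, "regions"),
                 t = if (is.null(t)) seq_along(bf) else t),
            class = "segmentation")
}
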