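#' Render a simulated colony into synthetic microscopy stacks
#'
#' Rasterises each frame of a colony simulation into a fluorescence image
#' (per-pixel sum of cell reporter density p over the cell footprint,
#' Gaussian PSF blur, constant background, Poisson shot noise), a
#' brightfield-like image (bright background with dark rod profiles) and a
#' ground-truth label mask.  Images are 16-bit; masks use 0 for background
#' and the simulator cell_id as the label.  Pixel convention: matrices are
#' indexed [row, col] with the origin at the top-left; a pixel centre at
#' (row, col) maps to ((col - 0.5), (row - 0.5)) * pixel_size in um.
#'
#' @param sim a [simulate_colony()] result.
#' @param config a [sim_config()] (default: the one stored in \code{sim}).
#' @param blur apply the Gaussian PSF (default TRUE).
#' @param noise apply Poisson shot noise / brightfield read noise.
#' @param seed RNG seed for the rendering noise.
#' @return list of class \code{rendered_stack}: \code{fluor}, \code{bf},
#'   \code{masks} (lists of integer matrices), \code{t}, \code{pixel_size}.
#' @export
render_frames <- function(sim, config = sim$config, blur = TRUE,
                          noise = TRUE, seed = NULL) {
  stopifnot(inherits(sim, "colony_sim"), inherits(config, "sim_config"))
  if (config$pixel_size <= 0) stop("pixel_size must be positive")
  if (!is.null(seed)) set.seed(seed)
  px <- config$pixel_size
  W <- max(1L, round(config$trap_size[1] / px))
  H <- max(1L, round(config$trap_size[2] / px))
  nfr <- length(sim$frames)
  fluor <- vector("list", nfr); bf <- vector("list", nfr)
  masks <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    r <- rasterize_colony(sim$frames[[k]], W, H, px)
    fl <- r$fluor
    if (blur && config$psf_sigma_px > 0)
      fl <- gauss_blur(fl, config$psf_sigma_px)
    lambda <- config$fluor_bg + config$fluor_gain * fl
    img <- if (noise) {
      matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
    } else lambda
    fluor[[k]] <- clamp16(img)

    dark <- gauss_blur(r$dark, 1)
    bfi <- config$bf_bg - config$bf_depth * dark
    if (noise) bfi <- bfi + stats::rnorm(length(bfi), 0, config$bf_noise)
    bf[[k]] <- clamp16(matrix(bfi, nrow(bfi)))
    masks[[k]] <- r$mask
  }
  structure(list(fluor = fluor, bf = bf, masks = masks, t = sim$t,
                 pixel_size = px),
            class = "rendered_stack")
}

clamp16 <- function(m) {
  m[m < 0] <- 0; m[m > 65535] <- 65535
  storage.mode(m) <- "integer"
  m
}

# Rasterise one colony frame: returns fluorescence density (p summed over
# overlapping footprints), a darkness profile for the brightfield channel,
# and the ground-truth label mask (nearest-axis cell wins overlaps).  The
# first- and second-nearest axis distances are tracked per pixel so the
# brightfield channel shows the thin bright cell-wall boundary between
# adjacent cells along their equidistant line.
rasterize_colony <- function(colony, W, H, px) {
  fl <- matrix(0, H, W)
  mask <- matrix(0L, H, W)
  dbuf <- matrix(Inf, H, W)
  d2buf <- matrix(Inf, H, W)
  if (nrow(colony) == 0)
    return(list(fluor = fl, dark = matrix(0, H, W), mask = mask))
  w <- colony$width[1]
  for (i in seq_len(nrow(colony))) {
    L <- colony$length[i]
    cx <- colony$x[i]; cy <- colony$y[i]
    ux <- cos(colony$theta[i]); uy <- sin(colony$theta[i])
    half <- max(L - w, 0) / 2
    ext <- L / 2 + w
    c0 <- max(1L, floor((cx - ext) / px) + 1L)
    c1 <- min(W, ceiling((cx + ext) / px))
    r0 <- max(1L, floor((cy - ext) / px) + 1L)
    r1 <- min(H, ceiling((cy + ext) / px))
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1 - 0.5) * px - cx
    ys <- (r0:r1 - 0.5) * px - cy
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    gy <- matrix(ys, length(ys), length(xs))
    proj <- gx * ux + gy * uy
    proj <- pmin(pmax(proj, -half), half)
    d <- sqrt((gx - proj * ux)^2 + (gy - proj * uy)^2)
    inside <- d <= w / 2
    rows <- r0:r1; cols <- c0:c1
    if (any(inside)) {
      sub_fl <- fl[rows, cols, drop = FALSE]
      sub_fl[inside] <- sub_fl[inside] + colony$p[i]
      fl[rows, cols] <- sub_fl
    }
    sub_db <- dbuf[rows, cols, drop = FALSE]
    sub_d2 <- d2buf[rows, cols, drop = FALSE]
    sub_mk <- mask[rows, cols, drop = FALSE]
    near <- d <= w                      # track second distances up to w
    closer <- near & d < sub_db
    second <- near & !closer & d < sub_d2
    sub_d2[second] <- d[second]
    sub_d2[closer] <- sub_db[closer]
    sub_db[closer] <- d[closer]
    sub_mk[closer & inside] <- colony$cell_id[i]
    dbuf[rows, cols] <- sub_db
    d2buf[rows, cols] <- sub_d2
    mask[rows, cols] <- sub_mk
  }
  # near-top-hat darkness with a soft rim, multiplied by a boundary dip
  # where a second cell axis runs nearby (equidistant cell-wall line)
  r <- w / 2
  dark <- matrix(0, H, W)
  inside <- dbuf <= r
  dark[inside] <- pmin(1.8 * (1 - (dbuf[inside] / r)^2), 1)
  dip <- matrix(1, H, W)
  both <- is.finite(d2buf)
  gap <- (d2buf[both] - dbuf[both]) / (0.35 * w)
  dip[both] <- 0.4 + 0.6 * pmin(pmax(gap, 0), 1)
  dark <- dark * dip
  list(fluor = fl, dark = dark, mask = mask)
}

# Sum-preserving Gaussian blur (EBImage); kernel capped to the frame size
gauss_blur <- function(m, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(m)) - 1
  if (rmax %% 2 == 0) rmax <- rmax - 1
  r <- min(r, rmax)
  out <- EBImage::gblur(EBImage::Image(m), sigma = sigma, radius = r,
                        boundary = "replicate")
  mm <- EBImage::imageData(out)
  dim(mm) <- dim(m)
  mm
}
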