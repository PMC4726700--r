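# shared fixtures built in code; kept deliberately small so the default
# test run stays fast

tiny_chemostat_config <- function(...) {
  chemostat_sim_config(duration = 150, ...)     # 51 frames, <= ~20 cells
}

# simulate + render a small colony once per test session
rendered_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_chemostat_config()
      sim <- simulate_colony(cfg, ahl = 12, seed = 42)
      stack <- render_frames(sim, seed = 420)
      cache <<- list(cfg = cfg, sim = sim, stack = stack,
                     seg = seg_config(pixel_size = cfg$pixel_size,
                                      max_length = 1.1 * cfg$division_length,
                                      max_width = 1.6 * cfg$cell_width))
    }
    cache
  }
})

# object-level matching (IoU >= 0.5) between predicted and truth masks
match_objects <- function(pred, gt, iou_min = 0.5) {
  gl <- setdiff(unique(gt[gt > 0]), 0)
  pl <- setdiff(unique(pred[pred > 0]), 0)
  matched <- 0L; used <- integer(0)
  for (g in gl) {
    gm <- gt == g
    cand <- table(pred[gm & pred > 0])
    best <- NA_integer_; best_iou <- 0
    for (p in names(cand)) {
      pm <- pred == as.integer(p)
      iou <- sum(gm & pm) / sum(gm | pm)
      if (iou > best_iou) { best_iou <- iou; best <- as.integer(p) }
    }
    if (!is.na(best) && best_iou >= iou_min && !(best %in% used)) {
      matched <- matched + 1L
      used <- c(used, best)
    }
  }
  list(recall = matched / max(length(gl), 1),
       precision = length(used) / max(length(pl), 1),
       n_gt = length(gl), n_pred = length(pl))
}

# distance (in pixels, chessboard-ish via repeated dilation) from any
# labelled pixel; used to find deep-background regions
gauss_dist0 <- function(mask) {
  as.matrix(EBImage::distmap(EBImage::Image((mask == 0) * 1)))
}

# draw a rod footprint into a matrix (hand-built masks for tracking tests)
draw_rod <- function(m, r0, c0, r1, c1, half_width, value) {
  H <- nrow(m); W <- ncol(m)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  vx <- c1 - c0; vy <- r1 - r0
  len2 <- max(vx^2 + vy^2, 1e-9)
  tt <- pmin(pmax(((cc - c0) * vx + (rr - r0) * vy) / len2, 0), 1)
  d <- sqrt((cc - (c0 + tt * vx))^2 + (rr - (r0 + tt * vy))^2)
  m[d <= half_width] <- value
  m
}
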