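#' Maximum-overlap frame-to-frame assignment
#'
#' For each labelled cell in the later frame, the cell with maximal pixel
#' overlap in the earlier frame is assigned as its parent.  Ties are broken
#' by the larger overlap fraction of the child, then by the smaller
#' centroid distance.  Labels with no overlap map to NA (new cell); a
#' parent shared by two later labels marks a division event.
#'
#' @param mask_t earlier label mask (integer matrix, 0 = background).
#' @param mask_t1 later label mask, same shape.
#' @return data.frame with one row per later-frame label: \code{child},
#'   \code{parent} (NA if new), \code{overlap}, \code{parent2},
#'   \code{overlap2} (second-best), and \code{division} flag (parent shared
#'   with another child).
#' @export
max_overlap_assign <- function(mask_t, mask_t1) {
  stopifnot(all(dim(mask_t) == dim(mask_t1)))
  kids <- sort(unique(mask_t1[mask_t1 > 0]))
  if (length(kids) == 0)
    return(data.frame(child = integer(0), parent = integer(0),
                      overlap = integer(0), parent2 = integer(0),
                      overlap2 = integer(0), division = logical(0)))
  sel <- which(mask_t1 > 0)
  a <- mask_t[sel]; b <- mask_t1[sel]
  has <- a > 0
  ov <- if (any(has)) {
    tab <- table(parent = a[has], child = b[has])
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else data.frame(parent = character(0), child = character(0),
                    Freq = integer(0))
  cent_t <- label_centroids(mask_t)
  cent_t1 <- label_centroids(mask_t1)
  rows <- lapply(kids, function(k) {
    o <- ov[ov$child == as.character(k) & ov$Freq > 0, ]
    if (nrow(o) == 0)
      return(data.frame(child = k, parent = NA_integer_, overlap = 0L,
                        parent2 = NA_integer_, overlap2 = 0L))
    o$parent <- as.integer(o$parent)
    best <- o[o$Freq == max(o$Freq), ]
    if (nrow(best) > 1) {      # tie: smaller centroid distance wins
      ck <- cent_t1[cent_t1$label == k, c("r", "c")]
      d <- sqrt((cent_t$r[match(best$parent, cent_t$label)] - ck$r)^2 +
                (cent_t$c[match(best$parent, cent_t$label)] - ck$c)^2)
      best <- best[order(d, best$parent), ][1, , drop = FALSE]
    }
    rest <- o[o$parent != best$parent[1], ]
    p2 <- if (nrow(rest) > 0) rest$parent[which.max(rest$Freq)] else
      NA_integer_
    o2 <- if (nrow(rest) > 0) max(rest$Freq) else 0L
    data.frame(child = k, parent = best$parent[1],
               overlap = as.integer(best$Freq[1]),
               parent2 = p2, overlap2 = as.integer(o2))
  })
  out <- do.call(rbind, rows)
  out$division <- !is.na(out$parent) &
    out$parent %in% out$parent[duplicated(out$parent[!is.na(out$parent)])]
  shared <- table(out$parent[!is.na(out$parent)])
  out$division <- !is.na(out$parent) &
    out$parent %in% as.integer(names(shared)[shared >= 2])
  out
}

label_centroids <- function(mask) {
  idx <- which(mask > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), r = numeric(0), c = numeric(0)))
  H <- nrow(mask)
  lab <- mask[idx]
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  data.frame(label = as.integer(names(tapply(r, lab, mean))),
             r = as.numeric(tapply(r, lab, mean)),
             c = as.numeric(tapply(c, lab, mean)))
}

#' Build a lineage tree from a label-mask sequence
#'
#' Chains maximum-overlap assignments into trajectories: a later label
#' continuing a single earlier label extends its trajectory; two later
#' labels sharing a parent close the parent's trajectory and open two
#' daughter trajectories; labels with no parent open new root trajectories;
#' labels with no successor close their trajectory (cell left the trap or
#' was lost).
#'
#' @param masks list of label masks (equal shapes).
#' @param regions optional list of [measure_regions()] tables (one per
#'   frame) supplying per-label area and fluorescence; areas are taken from
#'   the masks when absent.
#' @param t frame times in minutes (default 0, 1, 2, ... frame index).
#' @return object of class \code{lineage_tree}: \code{trajectories} (long
#'   data.frame cell_id, frame, t_min, label, area, F, parent_id),
#'   \code{tracks} (cell_id, parent_id, start_frame, end_frame),
#'   \code{assignments} (per-transition tables from
#'   [max_overlap_assign()]).
#' @export
build_lineage <- function(masks, regions = NULL, t = NULL) {
  nfr <- length(masks)
  if (nfr < 2) stop("need at least 2 frames")
  shp <- dim(masks[[1]])
  for (m in masks) if (!all(dim(m) == shp)) stop("frame shape mismatch")
  if (is.null(t)) t <- seq_len(nfr) - 1

  get_AF <- function(k, label) {
    if (!is.null(regions)) {
      reg <- regions[[k]]
      i <- match(label, reg$label)
      if (!is.na(i)) return(c(A = reg$area[i],
                              F = if ("F_corr" %in% names(reg))
                                reg$F_corr[i] else reg$F[i]))
    }
    c(A = sum(masks[[k]] == label), F = NA_real_)
  }

  next_cell <- 1L
  # active map: frame label -> cell_id
  labs1 <- sort(unique(masks[[1]][masks[[1]] > 0]))
  active <- stats::setNames(seq_along(labs1), labs1)
  next_cell <- length(labs1) + 1L
  parent_of <- stats::setNames(rep(NA_integer_, length(labs1)),
                               seq_along(labs1))
  rows <- list()
  add_row <- function(cell, k, label) {
    af <- get_AF(k, label)
    rows[[length(rows) + 1]] <<- data.frame(
      cell_id = cell, frame = k, t_min = t[k], label = label,
      area = unname(af["A"]), F = unname(af["F"]))
  }
  for (l in labs1) add_row(active[[as.character(l)]], 1L, l)

  assignments <- vector("list", nfr - 1)
  for (k in seq_len(nfr - 1)) {
    asg <- max_overlap_assign(masks[[k]], masks[[k + 1]])
    assignments[[k]] <- asg
    new_active <- integer(0)
    if (nrow(asg) > 0) for (i in seq_len(nrow(asg))) {
      child <- asg$child[i]
      if (is.na(asg$parent[i])) {            # new cell entering
        cell <- next_cell; next_cell <- next_cell + 1L
        parent_of[as.character(cell)] <- NA_integer_
      } else if (asg$division[i]) {          # division: new daughter track
        pcell <- active[[as.character(asg$parent[i])]]
        cell <- next_cell; next_cell <- next_cell + 1L
        parent_of[as.character(cell)] <- pcell
      } else {                               # continuation
        cell <- active[[as.character(asg$parent[i])]]
      }
      new_active[as.character(child)] <- cell
      add_row(cell, k + 1L, child)
    }
    active <- new_active
  }
  traj <- do.call(rbind, rows)
  traj$parent_id <- unname(parent_of[as.character(traj$cell_id)])
  agg <- split(traj$frame, traj$cell_id)
  tracks <- data.frame(
    cell_id = as.integer(names(agg)),
    parent_id = unname(parent_of[names(agg)]),
    start_frame = vapply(agg, min, numeric(1)),
    end_frame = vapply(agg, max, numeric(1)))
  rownames(tracks) <- NULL
  structure(list(trajectories = traj, tracks = tracks,
                 assignments = assignments, t = t),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  nd <- sum(!is.na(x$tracks$parent_id))
  cat(sprintf("Lineage tree: %d trajectories (%d daughters), %d frames\n",
              nrow(x$tracks), nd, length(x$t)))
  invisible(x)
}

#' Correct tracking links by fluorescence-jump detection
#'
#' Flags potential mother-daughter mismatches as frame-to-frame
#' fluorescence changes more than \code{threshold} times the trajectory's
#' local noise (robust SD = 1.4826 x MAD of dF over a sliding window).
#' Each flagged link is re-resolved either by reassignment to the
#' second-best-overlap parent (when that parent's trajectory ended at the
#' flagged frame) or by splitting the trajectory into a division at the
#' flagged link, whichever leaves the smaller residual jump.
#'
#' @param tree a [build_lineage()] result with fluorescence values.
#' @param window sliding window length (frames, odd; default 11).
#' @param threshold flag threshold in units of the robust noise (default 2).
#' @return the corrected \code{lineage_tree} with a \code{corrections}
#'   data.frame attached (cell_id, frame, action, dF).
#' @export
correct_lineage <- function(tree, window = 11, threshold = 2) {
  stopifnot(inherits(tree, "lineage_tree"))
  traj <- tree$trajectories
  if (all(is.na(traj$F))) stop("trajectories carry no fluorescence values")
  corrections <- data.frame(cell_id = integer(0), frame = integer(0),
                            action = character(0), dF = numeric(0))
  next_cell <- max(traj$cell_id) + 1L
  for (cell in unique(traj$cell_id)) {
    seg <- traj[traj$cell_id == cell, ]
    seg <- seg[order(seg$frame), ]
    n <- nrow(seg)
    if (n < window + 1) next
    dF <- diff(seg$F)
    flags <- flag_jumps(dF, window, threshold)
    if (!any(flags)) next
    i <- which(flags)[1]                 # handle the first jump per pass
    frame_i <- seg$frame[i + 1]
    # option A: split into a division at the jump (daughter keeps the tail)
    resid_split <- abs(seg$F[i + 1] - seg$F[i] / 2)
    # option B: reassign tail to the second-best overlap parent, if its
    # trajectory ended exactly at the previous frame
    resid_re <- Inf
    asg <- tree$assignments[[frame_i - 1]]
    alt <- asg$parent2[match(seg$label[i + 1], asg$child)]
    alt_cell <- NA_integer_
    if (length(alt) == 1 && !is.na(alt)) {
      prev <- traj[traj$frame == frame_i - 1 & traj$label == alt, ]
      if (nrow(prev) == 1) {
        ends <- max(traj$frame[traj$cell_id == prev$cell_id])
        if (ends == frame_i - 1) {
          resid_re <- abs(seg$F[i + 1] - prev$F)
          alt_cell <- prev$cell_id
        }
      }
    }
    tail_sel <- traj$cell_id == cell & traj$frame >= frame_i
    if (resid_re < resid_split && !is.na(alt_cell)) {
      traj$cell_id[tail_sel] <- alt_cell
      traj$parent_id[tail_sel] <- tree$tracks$parent_id[
        match(alt_cell, tree$tracks$cell_id)]
      act <- "relabel"
    } else {
      traj$cell_id[tail_sel] <- next_cell
      traj$parent_id[tail_sel] <- cell
      next_cell <- next_cell + 1L
      act <- "split"
    }
    corrections <- rbind(corrections,
                         data.frame(cell_id = cell, frame = frame_i,
                                    action = act, dF = dF[i]))
  }
  agg <- split(traj$frame, traj$cell_id)
  par_lookup <- traj$parent_id[match(as.integer(names(agg)), traj$cell_id)]
  tree$trajectories <- traj
  tree$tracks <- data.frame(cell_id = as.integer(names(agg)),
                            parent_id = par_lookup,
                            start_frame = vapply(agg, min, numeric(1)),
                            end_frame = vapply(agg, max, numeric(1)))
  rownames(tree$tracks) <- NULL
  tree$corrections <- corrections
  tree
}

# robust jump detection on a dF series: deviation from the sliding-window
# median exceeding threshold x (1.4826 MAD), with a positive noise floor
flag_jumps <- function(dF, window, threshold) {
  n <- length(dF)
  if (n < window) return(rep(FALSE, n))
  h <- (window - 1) %/% 2
  flags <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    w <- dF[lo:hi]
    med <- stats::median(w)
    noise <- 1.4826 * stats::median(abs(w - med))
    noise <- max(noise, 1e-12, 0.08 * abs(med))
    flags[i] <- abs(dF[i] - med) > threshold * noise
  }
  flags
}

#' Count flagged links on a lineage (diagnostic)
#'
#' Returns the fraction of frame-to-frame links flagged by the
#' fluorescence-jump heuristic without applying corrections; useful as a
#' false-positive diagnostic on clean data.
#'
#' @inheritParams correct_lineage
#' @return list with \code{flagged}, \code{links}, \code{rate}.
#' @export
flag_rate <- function(tree, window = 11, threshold = 2) {
  traj <- tree$trajectories
  tot <- 0L; fl <- 0L
  for (cell in unique(traj$cell_id)) {
    seg <- traj[traj$cell_id == cell, ]
    n <- nrow(seg)
    if (n < window + 1) next
    seg <- seg[order(seg$frame), ]
    dF <- diff(seg$F)
    tot <- tot + length(dF)
    fl <- fl + sum(flag_jumps(dF, window, threshold))
  }
  list(flagged = fl, links = tot, rate = if (tot > 0) fl / tot else 0)
}
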