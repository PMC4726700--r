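test_that("identical masks map to themselves with no divisions", {
  m <- matrix(0L, 30, 30)
  m <- draw_rod(m, 10, 5, 10, 15, 2, 1L)
  m <- draw_rod(m, 22, 10, 22, 22, 2, 2L)
  asg <- max_overlap_assign(m, m)
  expect_equal(asg$parent, asg$child)
  expect_false(any(asg$division))
})

test_that("a label split into two halves flags a division", {
  m0 <- matrix(0L, 30, 40)
  m0 <- draw_rod(m0, 15, 5, 15, 30, 2, 7L)
  m1 <- matrix(0L, 30, 40)
  m1 <- draw_rod(m1, 15, 5, 15, 16, 2, 1L)
  m1 <- draw_rod(m1, 15, 20, 15, 30, 2, 2L)
  asg <- max_overlap_assign(m0, m1)
  expect_equal(asg$parent, c(7L, 7L))
  expect_true(all(asg$division))
})

test_that("assignment equals brute-force argmax on toy masks", {
  set.seed(20)
  for (rep in 1:5) {
    m0 <- matrix(sample(0:3, 400, replace = TRUE, prob = c(0.5, rep(0.17, 3))),
                 20, 20)
    m1 <- matrix(sample(0:3, 400, replace = TRUE, prob = c(0.5, rep(0.17, 3))),
                 20, 20)
    asg <- max_overlap_assign(m0, m1)
    for (i in seq_len(nrow(asg))) {
      ov <- vapply(1:3, function(p) sum(m0 == p & m1 == asg$child[i]),
                   numeric(1))
      if (all(ov == 0)) {
        expect_true(is.na(asg$parent[i]))
      } else {
        expect_equal(ov[asg$parent[i]], max(ov))
        expect_equal(asg$overlap[i], max(ov))
      }
    }
  }
})

test_that("lineage from ground-truth masks matches the simulated lineage", {
  fix <- rendered_fixture()
  masks <- fix$stack$masks
  tree <- build_lineage(masks, t = fix$stack$t)
  traj <- tree$trajectories
  gt <- fix$sim$trajectories

  # every frame-to-frame link must agree with the generative lineage:
  # a tracked label continues the same ground-truth cell or, at a division,
  # the tracked parent's label is the ground-truth parent cell
  n_links <- 0; n_good <- 0
  for (k in seq_len(length(masks) - 1)) {
    asg <- tree$assignments[[k]]
    for (i in seq_len(nrow(asg))) {
      if (is.na(asg$parent[i])) next
      n_links <- n_links + 1
      gt_parent <- gt$parent_id[gt$cell_id == asg$child[i]][1]
      ok <- asg$parent[i] == asg$child[i] ||
        (!is.na(gt_parent) && asg$parent[i] == gt_parent)
      n_good <- n_good + ok
    }
  }
  expect_equal(n_good / n_links, 1)

  # tree structure: same number of division events as the ground truth
  gt_divs <- length(unique(stats::na.omit(gt$parent_id)))
  tracked_divs <- length(unique(stats::na.omit(tree$tracks$parent_id)))
  expect_equal(tracked_divs, gt_divs)
})

test_that("tree invariants hold: acyclic, single parent, two children max", {
  fix <- rendered_fixture()
  tree <- build_lineage(fix$stack$masks, t = fix$stack$t)
  tracks <- tree$tracks
  expect_equal(anyDuplicated(tracks$cell_id), 0)
  kids <- table(stats::na.omit(tracks$parent_id))
  expect_true(all(kids <= 2))
  # children start strictly after their parent starts (no cycles)
  for (i in which(!is.na(tracks$parent_id))) {
    p <- tracks[tracks$cell_id == tracks$parent_id[i], ]
    expect_lt(p$start_frame, tracks$start_frame[i])
  }
})

test_that("area bookkeeping at divisions is consistent", {
  fix <- rendered_fixture()
  tree <- build_lineage(fix$stack$masks, t = fix$stack$t)
  tracks <- tree$tracks
  traj <- tree$trajectories
  kids <- split(tracks$cell_id, tracks$parent_id)
  checked <- 0
  for (p in names(kids)) {
    if (length(kids[[p]]) != 2) next
    f <- tracks$start_frame[tracks$cell_id == kids[[p]][1]]
    a_kids <- sum(traj$area[traj$cell_id %in% kids[[p]] & traj$frame == f])
    a_mom <- traj$area[traj$cell_id == as.numeric(p) & traj$frame == f - 1]
    if (length(a_mom) == 1 && a_mom > 0) {
      expect_lt(abs(a_kids / a_mom - 1), 0.3)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})

test_that("single non-dividing cell yields one closed trajectory", {
  m <- matrix(0L, 25, 25)
  m <- draw_rod(m, 12, 5, 12, 18, 2, 1L)
  masks <- list(m, m, m, m)
  tree <- build_lineage(masks)
  expect_equal(nrow(tree$tracks), 1)
  expect_true(is.na(tree$tracks$parent_id))
  expect_equal(tree$tracks$end_frame, 4)
  # cell leaving the trap: trajectory terminates at last frame seen
  masks2 <- list(m, m, matrix(0L, 25, 25), matrix(0L, 25, 25))
  tree2 <- build_lineage(masks2)
  expect_equal(tree2$tracks$end_frame, 2)
})

test_that("smooth trajectories raise no correction flags", {
  m <- matrix(0L, 25, 25)
  m <- draw_rod(m, 12, 5, 12, 18, 2, 1L)
  masks <- replicate(30, m, simplify = FALSE)
  regions <- lapply(1:30, function(k)
    data.frame(label = 1L, area = 60, F = 100 * exp(0.05 * k),
               F_corr = 100 * exp(0.05 * k)))
  tree <- build_lineage(masks, regions)
  expect_equal(flag_rate(tree)$flagged, 0)
  corr <- correct_lineage(tree)
  expect_equal(nrow(corr$corrections), 0)
})

test_that("an injected fluorescence halving is flagged and split", {
  m <- matrix(0L, 25, 25)
  m <- draw_rod(m, 12, 5, 12, 18, 2, 1L)
  masks <- replicate(40, m, simplify = FALSE)
  F <- 100 * exp(0.04 * (1:40))
  F[21:40] <- F[21:40] / 2                     # missed division
  regions <- lapply(1:40, function(k)
    data.frame(label = 1L, area = 60, F = F[k], F_corr = F[k]))
  tree <- build_lineage(masks, regions)
  expect_gt(flag_rate(tree)$flagged, 0)
  corr <- correct_lineage(tree)
  expect_equal(corr$corrections$action, "split")
  expect_equal(corr$corrections$frame, 21)
  # tree invariants survive the correction
  kids <- table(stats::na.omit(corr$tracks$parent_id))
  expect_true(all(kids <= 2))
})

test_that("false-positive flag rate on clean simulated data is low", {
  fix <- rendered_fixture()
  tree <- build_lineage(fix$stack$masks, t = fix$stack$t)
  # attach ground-truth fluorescence to the trajectories
  gt <- fix$sim$trajectories
  key_tr <- paste(tree$trajectories$label, tree$trajectories$frame)
  key_gt <- paste(gt$cell_id, gt$frame)
  tree$trajectories$F <- gt$F[match(key_tr, key_gt)]
  fr <- flag_rate(tree)
  expect_gt(fr$links, 100)
  expect_lte(fr$rate, 0.02)
})
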