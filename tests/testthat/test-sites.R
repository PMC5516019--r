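test_that("centroids are per-axis means", {
  expect_equal(pose_centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(pose_centroid(matrix(c(4, -1, 2), 1)), c(4, -1, 2),
               ignore_attr = TRUE)
  set.seed(7)
  atoms <- matrix(rnorm(21), ncol = 3) # 7-atom synthetic ligand
  manual <- c(sum(atoms[, 1]), sum(atoms[, 2]), sum(atoms[, 3])) / 7
  expect_equal(pose_centroid(atoms), manual, ignore_attr = TRUE)
  expect_error(pose_centroid(matrix(numeric(0), ncol = 3)), "zero atoms")
})

test_that("well-separated pose clouds are recovered as distinct sites", {
  ctx <- thermo_context()
  # two tight blobs 30 A apart
  a <- generate_pose_cloud(c(0, 0, 0), k = 0.5, m = 40, ctx = ctx, seed = 11)
  b <- generate_pose_cloud(c(30, 0, 0), k = 0.5, m = 40, ctx = ctx, seed = 12)
  poses <- pose_table(sprintf("p%02d", 1:80),
                      c(a[, 1], b[, 1]), c(a[, 2], b[, 2]), c(a[, 3], b[, 3]))
  sites <- suppressWarnings(cluster_poses(poses, cutoff = 6))
  expect_identical(nrow(sites), 2L)
  assign <- attr(sites, "assignments")
  truth <- rep(c("A", "B"), each = 40)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(assign, truth), 1)
})

test_that("the 12-site synthetic layout is recovered with non-overlapping spheres", {
  ps <- generate_pose_set(poses_per_site = 30, seed = 5)
  sites <- cluster_poses(ps$poses, cutoff = 6)
  expect_identical(nrow(sites), 12L)
  centers <- as.matrix(sites[, c("cx", "cy", "cz")])
  dc <- as.matrix(dist(centers))
  expect_gte(min(dc[upper.tri(dc)]), 15)
  # recovered centers lie close to the planted ones
  truth <- ps$layout
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((sites$cx - truth$cx[i])^2 + (sites$cy - truth$cy[i])^2 +
                (sites$cz - truth$cz[i])^2)
    expect_lt(min(d), 2.5)
  }
  skip_if_not_installed("mclust")
  assign <- attr(sites, "assignments")
  r1 <- ps$poses[ps$poses$round == 1L, ]
  expect_equal(mclust::adjustedRandIndex(assign[r1$pose_id], ps$labels), 1)
})

test_that("clustering is invariant under pose input order", {
  ps <- generate_pose_set(poses_per_site = 20, seed = 9)
  poses <- ps$poses[ps$poses$round == 1L, ]
  sites1 <- cluster_poses(poses)
  set.seed(1)
  shuffled <- poses[sample(nrow(poses)), ]
  sites2 <- cluster_poses(shuffled)
  expect_equal(sites1$cx, sites2$cx, tolerance = 1e-12)
  expect_equal(sites1$radius, sites2$radius, tolerance = 1e-12)
  a1 <- attr(sites1, "assignments")
  a2 <- attr(sites2, "assignments")
  expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])
  # every pose belongs to exactly one site
  expect_identical(sort(names(a1)), sort(poses$pose_id))
  expect_identical(sum(sites1$n_poses), nrow(poses))
})

test_that("degenerate pose sets collapse to a single floored site", {
  poses <- pose_table(c("a", "b", "c"), 0, 0, 0)
  sites <- cluster_poses(poses)
  expect_identical(nrow(sites), 1L)
  expect_equal(sites$radius, 4) # floor
  expect_warning(cluster_poses(pose_table(c("a", "b"), c(0, 5), 0, 0),
                               cutoff = 2), "apart")
})

test_that("double-occupancy poses flag exactly their partner sites", {
  ps <- generate_pose_set(poses_per_site = 30,
                          doubles_for = c("linker", "interface"),
                          doubles_per_site = 8, seed = 3)
  sites <- cluster_poses(ps$poses, cutoff = 6)
  # map recovered site ids to planted ids via nearest centers
  truth <- ps$layout
  near <- vapply(seq_len(nrow(sites)), function(i) {
    d <- sqrt((truth$cx - sites$cx[i])^2 + (truth$cy - sites$cy[i])^2 +
                (truth$cz - sites$cz[i])^2)
    truth$site_id[which.min(d)]
  }, character(1))
  # rewrite partner ids into recovered ids
  p2 <- ps$poses[ps$poses$round == 2L, ]
  p2$partner_site <- sites$site_id[match(p2$partner_site, near)]
  upd <- assign_double_occupancy(sites, p2)
  expected <- near %in% truth$site_id[truth$class_id %in% c("linker", "interface")]
  expect_identical(upd$supports_double, expected)
  expect_identical(sum(upd$supports_double), 8L)
  # a few poses may scatter beyond the spherical site volume; they must be
  # reported, not silently swallowed
  n_assigned <- sum(upd$n_poses_double)
  expect_identical(n_assigned + length(attr(upd, "unassigned")), nrow(p2))
  expect_lt(length(attr(upd, "unassigned")) / nrow(p2), 0.1)
  # a pose far outside every sphere is reported unassigned
  stray <- pose_table("stray", 500, 500, 500, round = 2L)
  upd2 <- assign_double_occupancy(sites, stray)
  expect_identical(attr(upd2, "unassigned"), "stray")
  expect_false(any(upd2$supports_double))
})

test_that("pose centroids can be read from a multi-copy PDB", {
  skip_if_not_installed("bio3d")
  path <- tempfile(fileext = ".pdb")
  fmt <- "HETATM%5d  C%d  LIG %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C"
  lines <- c(
    sprintf(fmt, 1, 1, "A", 1, 0, 0, 0),
    sprintf(fmt, 2, 2, "A", 1, 2, 0, 0),
    sprintf(fmt, 3, 1, "A", 2, 10, 10, 10),
    sprintf(fmt, 4, 2, "A", 2, 12, 10, 10),
    "END"
  )
  writeLines(lines, path)
  poses <- read_poses_pdb(path, "LIG")
  expect_identical(nrow(poses), 2L)
  expect_equal(sort(poses$x), c(1, 11))
  expect_error(read_poses_pdb(path, "XYZ"), "no atoms")
})
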