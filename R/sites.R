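# Resolution of binding-site volumes from docking-pose centroids. Sites are
# resolved by deterministic single-linkage agglomeration of round-1 pose
# centroids at a distance cutoff; each cluster becomes a spherical site
# volume (center = mean member centroid, radius = maximal member distance,
# floored). Round-2 poses (re-docking with one ligand pre-bound) are then
# tested for containment to flag sites that accommodate two ligands at once.
# Inputs are assumed expressed in a receptor-fixed frame with z along the
# membrane normal; no structural fitting is performed here.

#' Centroid of a set of atom coordinates
#'
#' Arithmetic mean per Cartesian axis, `R = (1/N_atom) * sum (x,y,z)`.
#'
#' @param coords Numeric matrix (or data frame) with columns x, y, z and one
#'   row per atom; must be non-empty with finite entries.
#' @return Numeric length-3 vector `(x, y, z)` in A.
#' @examples
#' pose_centroid(rbind(c(0, 0, 0), c(2, 0, 0))) # (1, 0, 0)
#' @export
pose_centroid <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L)
    stop("cannot take the centroid of zero atoms", call. = FALSE)
  if (ncol(coords) != 3L || any(!is.finite(coords)))
    stop("`coords` must be a finite n x 3 matrix", call. = FALSE)
  colMeans(coords)
}

#' Docking-pose table
#'
#' @param pose_id Identifiers, one per pose.
#' @param x,y,z Centroid coordinates in the receptor-fixed frame (A).
#' @param round 1 for first-round docking poses, 2 for re-docking poses
#'   generated with one ligand pre-bound.
#' @param partner_site For round-2 poses, the site id of the pre-bound
#'   ligand (NA if unknown).
#' @return Data frame of class `pose_table`.
#' @export
pose_table <- function(pose_id, x, y, z, round = 1L, partner_site = NA) {
  df <- data.frame(
    pose_id = as.character(pose_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    round = as.integer(rep_len(round, length(pose_id))),
    partner_site = as.character(rep_len(partner_site, length(pose_id))),
    stringsAsFactors = FALSE
  )
  .validate_pose_table(df)
}

.validate_pose_table <- function(df) {
  need <- c("pose_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pose table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("pose table is empty", call. = FALSE)
  if (!"round" %in% names(df)) df$round <- 1L
  if (!"partner_site" %in% names(df)) df$partner_site <- NA_character_
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("pose coordinates must be finite", call. = FALSE)
  if (!all(df$round %in% c(1L, 2L)))
    stop("`round` must be 1 or 2", call. = FALSE)
  if (anyDuplicated(df$pose_id))
    stop("duplicate pose ids", call. = FALSE)
  class(df) <- unique(c("pose_table", class(df)))
  df
}

#' Cluster docking poses into binding sites
#'
#' Deterministic single-linkage agglomerative clustering of round-1 pose
#' centroids at a distance cutoff. Each resulting cluster defines a
#' spherical site volume: center at the mean member centroid, radius the
#' maximal member distance to the center (with a floor). Sites are labelled
#' in order of ascending center z (then x, y), so the labelling is
#' independent of pose input order.
#'
#' @param poses A [pose_table()]; only `round == 1` rows are clustered.
#' @param cutoff Single-linkage merge distance in A (default 6).
#' @param radius_floor Minimum site radius in A (default 4).
#' @param min_separation Emit a warning if any two site centers are closer
#'   than this (default 15 A, the expected non-overlap scale).
#' @return Data frame of class `binding_sites` with columns `site_id`, `cx`,
#'   `cy`, `cz`, `radius`, `n_poses`, `n_poses_double`, `supports_double`;
#'   the per-pose site assignment is attached as attribute `assignments`
#'   (named by pose id).
#' @export
cluster_poses <- function(poses, cutoff = 6, radius_floor = 4,
                          min_separation = 15) {
  poses <- .validate_pose_table(poses)
  p1 <- poses[poses$round == 1L, , drop = FALSE]
  if (nrow(p1) == 0L) stop("no round-1 poses to cluster", call. = FALSE)
  xyz <- as.matrix(p1[, c("x", "y", "z")])
  labels <- if (nrow(p1) == 1L) {
    1L
  } else {
    hc <- stats::hclust(stats::dist(xyz), method = "single")
    stats::cutree(hc, h = cutoff)
  }
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    colMeans(xyz[labels == l, , drop = FALSE])
  }))
  ord <- order(round(centers[, 3], 6), round(centers[, 1], 6),
               round(centers[, 2], 6))
  relabel <- match(labels, sort(unique(labels))[ord])
  centers <- centers[ord, , drop = FALSE]
  nsite <- nrow(centers)
  site_id <- sprintf("S%02d", seq_len(nsite))
  radius <- vapply(seq_len(nsite), function(i) {
    d <- sqrt(rowSums(sweep(xyz[relabel == i, , drop = FALSE], 2,
                            centers[i, ])^2))
    max(max(d), radius_floor)
  }, numeric(1))
  if (nsite > 1L) {
    dc <- as.matrix(stats::dist(centers))
    mind <- min(dc[upper.tri(dc)])
    if (mind < min_separation)
      warning(sprintf("two site centers are only %.1f A apart (< %.1f A separation check)",
                      mind, min_separation), call. = FALSE)
  }
  out <- data.frame(
    site_id = site_id,
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    radius = radius,
    n_poses = as.integer(tabulate(relabel, nsite)),
    n_poses_double = 0L,
    supports_double = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  assignments <- site_id[relabel]
  names(assignments) <- p1$pose_id
  attr(out, "assignments") <- assignments
  class(out) <- unique(c("binding_sites", class(out)))
  out
}

#' Assign re-docking poses to resolved sites (double occupancy)
#'
#' A round-2 pose is assigned to site `j` when its centroid lies within the
#' site sphere and (if recorded) its partner site is `j`; sites receiving at
#' least one such pose are flagged as supporting double occupancy. Poses
#' falling outside every site sphere (or inside a sphere that contradicts
#' their recorded partner) are reported as unassigned.
#'
#' @param sites A `binding_sites` table from [cluster_poses()].
#' @param poses A [pose_table()]; only `round == 2` rows are considered.
#' @return The updated `binding_sites` table, with attribute `unassigned`
#'   (pose ids) and attribute `assignments2` (site per assigned round-2
#'   pose).
#' @export
assign_double_occupancy <- function(sites, poses) {
  if (!inherits(sites, "binding_sites"))
    stop("`sites` must come from cluster_poses()", call. = FALSE)
  poses <- .validate_pose_table(poses)
  p2 <- poses[poses$round == 2L, , drop = FALSE]
  centers <- as.matrix(sites[, c("cx", "cy", "cz")])
  assigned <- character(0)
  unassigned <- character(0)
  counts <- stats::setNames(rep(0L, nrow(sites)), sites$site_id)
  for (i in seq_len(nrow(p2))) {
    d <- sqrt(colSums((t(centers) - c(p2$x[i], p2$y[i], p2$z[i]))^2))
    inside <- which(d <= sites$radius)
    partner <- p2$partner_site[i]
    j <- if (!is.na(partner) && nzchar(partner)) match(partner, sites$site_id)
         else NA_integer_
    hit <- if (!is.na(j)) {
      # recorded partner must contain the pose
      if (j %in% inside) j else NA_integer_
    } else if (length(inside) >= 1L) {
      # unknown or foreign partner label: containment decides
      inside[which.min(d[inside])]
    } else {
      NA_integer_
    }
    if (is.na(hit)) {
      unassigned <- c(unassigned, p2$pose_id[i])
    } else {
      counts[hit] <- counts[hit] + 1L
      assigned[p2$pose_id[i]] <- sites$site_id[hit]
    }
  }
  sites$n_poses_double <- as.integer(counts)
  sites$supports_double <- counts > 0L
  attr(sites, "unassigned") <- unassigned
  attr(sites, "assignments2") <- assigned
  sites
}

#' Read pose centroids from a PDB file
#'
#' Computes one centroid per ligand copy (HETATM records of the given residue
#' name, grouped by chain and residue number) in a PDB file. Requires the
#' bio3d package.
#'
#' @param path Path to a PDB file.
#' @param resname Ligand residue name (e.g. "LIG").
#' @param round Docking round to record for all poses (1 or 2).
#' @return A [pose_table()] with one row per ligand copy.
#' @export
read_poses_pdb <- function(path, resname, round = 1L) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_poses_pdb() requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom$resid == resname
  if (!any(sel))
    stop("no atoms with residue name '", resname, "' in ", path, call. = FALSE)
  atoms <- pdb$atom[sel, , drop = FALSE]
  grp <- paste(atoms$chain, atoms$resno)
  ids <- unique(grp)
  cent <- t(vapply(ids, function(g) {
    pose_centroid(atoms[grp == g, c("x", "y", "z")])
  }, numeric(3)))
  pose_table(pose_id = gsub(" ", "_", ids),
             x = cent[, 1], y = cent[, 2], z = cent[, 3], round = round)
}
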