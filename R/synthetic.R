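# Seeded synthetic-data generators. These emulate the study conditions of a
# tetrameric membrane receptor: three symmetry classes of sites replicated
# over a 4-fold axis (12 sites), with double occupancy supported at the two
# high-affinity classes. Pose clouds are drawn from the Boltzmann
# distribution of the harmonic restraint (per-axis variance 1/(beta*k)), and
# a Metropolis sampler over occupancy vectors provides an independent
# stochastic oracle for the analytic state probabilities. All generators are
# seeded and bit-reproducible, and always return the ground truth beside the
# data.

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Synthetic multi-site system specification
#'
#' Describes an f-fold symmetric receptor with several symmetry classes of
#' binding sites. The defaults mirror a tetrameric channel with three
#' classes (12 sites): a high-affinity "linker" class and an intermediate
#' "interface" class, both saturable at two ligands, and a weak "face" class
#' holding at most one. Class-level restraint constants (kcal/mol/A^2) and
#' cumulative work values (kcal/mol) are the class means; per-site values
#' are drawn around them with log-normal (k) and normal (work) spreads.
#' Sites are laid out on f-fold rings (one ring per class at distinct z), so
#' that inter-site separations exceed the 15 A non-overlap scale.
#'
#' @param fold Oligomeric symmetry order (default 4).
#' @param classes Data frame with one row per class: `class_id`, `n_max`
#'   (1 or 2), `k1`, `w1`, and for `n_max = 2` also `k2`, `w21` (the
#'   second-ligand conditional work).
#' @param k_spread Log-sd of the per-site force-constant scatter.
#' @param work_sd Sd (kcal/mol) of the per-site work scatter.
#' @param ring_radius Ring radius in A.
#' @param ring_z z positions of the class rings (A, one per class).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fold = 4,
                           classes = data.frame(
                             class_id = c("linker", "interface", "face"),
                             n_max = c(2L, 2L, 1L),
                             k1 = c(0.07, 0.10, 0.40),
                             w1 = c(-6.5, -4.5, -1.0),
                             k2 = c(0.004, 0.15, NA),
                             w21 = c(-5.5, -3.8, NA),
                             stringsAsFactors = FALSE
                           ),
                           k_spread = 0.3, work_sd = 0.5,
                           ring_radius = 25, ring_z = NULL) {
  stopifnot(fold >= 1, nrow(classes) >= 1)
  if (is.null(ring_z))
    ring_z <- seq(-17, 17, length.out = max(nrow(classes), 2L))[seq_len(nrow(classes))]
  structure(list(fold = as.integer(fold), classes = classes,
                 k_spread = k_spread, work_sd = work_sd,
                 ring_radius = ring_radius, ring_z = ring_z),
            class = "synthetic_spec")
}

# Site layout implied by a spec: fold sites per class on a ring.
.synthetic_layout <- function(spec) {
  rows <- list()
  for (i in seq_len(nrow(spec$classes))) {
    cl <- spec$classes$class_id[i]
    ang <- 2 * pi * (seq_len(spec$fold) - 1L) / spec$fold
    for (f in seq_len(spec$fold)) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("%s%d", cl, f), class_id = cl,
        n_max = spec$classes$n_max[i],
        cx = spec$ring_radius * cos(ang[f]),
        cy = spec$ring_radius * sin(ang[f]),
        cz = spec$ring_z[i], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic affinity table with known ground truth
#'
#' Samples per-site restraint constants and work values around the class
#' means of a [synthetic_spec()] and returns both the affinity table and the
#' ground truth used to produce it (sampled inputs plus the implied binding
#' constants), for recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param reservoir A [ligand_reservoir()] used for the ground-truth
#'   constants.
#' @param ctx A [thermo_context()].
#' @param seed Integer RNG seed; identical seeds give identical tables.
#' @return List with `affinities` (an [affinity_table()]), `classes` (a
#'   [symmetry_classes()]) and `truth` (a `site_constants` table).
#' @export
generate_affinity_table <- function(spec = synthetic_spec(),
                                    reservoir = ligand_reservoir(-0.1),
                                    ctx = thermo_context(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- .synthetic_layout(spec)
  rows <- .with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(layout))) {
      cl <- spec$classes[spec$classes$class_id == layout$class_id[i], ]
      k1 <- cl$k1 * exp(stats::rnorm(1, 0, spec$k_spread))
      w1 <- cl$w1 + stats::rnorm(1, 0, spec$work_sd)
      out[[length(out) + 1L]] <- data.frame(
        site_id = layout$site_id[i], region = layout$class_id[i],
        level = 1L, k = I(list(k1)), work = w1, work_error = 0.2,
        stringsAsFactors = FALSE
      )
      if (cl$n_max >= 2L) {
        k2 <- cl$k2 * exp(stats::rnorm(1, 0, spec$k_spread))
        w21 <- cl$w21 + stats::rnorm(1, 0, spec$work_sd)
        w2 <- compose_two_step_work(w1, w21, 0.2, 0.2)
        out[[length(out) + 1L]] <- data.frame(
          site_id = layout$site_id[i], region = layout$class_id[i],
          level = 2L, k = I(list(k2)), work = w2$work, work_error = w2$error,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
  aff <- .validate_affinity_table(rows)
  list(
    affinities = aff,
    classes = symmetry_classes(layout$class_id, layout$site_id),
    layout = layout,
    truth = binding_constants(aff, reservoir, ctx)
  )
}

#' Sample a harmonic-restraint pose cloud
#'
#' Draws `m` ligand centroids from the Boltzmann distribution of an
#' isotropic harmonic restraint of force constant `k` about `center`:
#' independent Gaussians with per-axis variance `1/(beta*k)`.
#'
#' @param center Length-3 site center (A).
#' @param k Restraint force constant (kcal/mol/A^2, > 0).
#' @param m Number of poses (>= 1).
#' @param ctx A [thermo_context()].
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @return An `m` x 3 matrix of centroids.
#' @export
generate_pose_cloud <- function(center, k, m, ctx = thermo_context(),
                                seed = NULL) {
  stopifnot(length(center) == 3L, k > 0, m >= 1)
  ctx <- .as_context(ctx)
  sd <- sqrt(1 / (ctx$beta * k))
  .with_seed(seed, {
    matrix(stats::rnorm(3 * m, mean = rep(center, each = m), sd = sd),
           ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
  })
}

#' Generate a full synthetic pose set with planted site labels
#'
#' One harmonic pose cloud per site of the spec layout (round 1), plus
#' optional round-2 clouds with the partner site recorded, for clustering
#' and double-occupancy recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param poses_per_site Round-1 poses per site.
#' @param doubles_for Character vector of site ids (or class ids) that
#'   receive round-2 poses; default: all sites whose class has `n_max >= 2`.
#' @param doubles_per_site Round-2 poses per such site.
#' @param pose_k Effective force constant governing the pose scatter within
#'   a site (kcal/mol/A^2). The default 0.3 corresponds to the ~1.4 A
#'   positional scatter typical of docking solutions within one pocket,
#'   which is what site resolution operates on; it is narrower than the
#'   loosest FEP restraints, which describe the thermal ligand motion
#'   rather than pose reproducibility.
#' @param ctx A [thermo_context()].
#' @param seed Integer RNG seed.
#' @return List with `poses` (a [pose_table()]), `labels` (true site id per
#'   round-1 pose) and `layout`.
#' @export
generate_pose_set <- function(spec = synthetic_spec(), poses_per_site = 50,
                              doubles_for = NULL, doubles_per_site = 10,
                              pose_k = 0.3, ctx = thermo_context(),
                              seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- .synthetic_layout(spec)
  if (is.null(doubles_for))
    doubles_for <- layout$site_id[layout$n_max >= 2L]
  doubles_for <- union(doubles_for,
                       layout$site_id[layout$class_id %in% doubles_for])
  doubles_for <- intersect(doubles_for, layout$site_id)
  .with_seed(seed, {
    tabs <- list()
    labels <- character(0)
    for (i in seq_len(nrow(layout))) {
      ctr <- c(layout$cx[i], layout$cy[i], layout$cz[i])
      xyz <- generate_pose_cloud(ctr, pose_k, poses_per_site, ctx)
      tabs[[length(tabs) + 1L]] <- pose_table(
        sprintf("%s_r1_%03d", layout$site_id[i], seq_len(poses_per_site)),
        xyz[, 1], xyz[, 2], xyz[, 3], round = 1L
      )
      labels <- c(labels, rep(layout$site_id[i], poses_per_site))
      if (layout$site_id[i] %in% doubles_for) {
        xyz2 <- generate_pose_cloud(ctr, pose_k, doubles_per_site, ctx)
        tabs[[length(tabs) + 1L]] <- pose_table(
          sprintf("%s_r2_%03d", layout$site_id[i], seq_len(doubles_per_site)),
          xyz2[, 1], xyz2[, 2], xyz2[, 3], round = 2L,
          partner_site = layout$site_id[i]
        )
      }
    }
    poses <- do.call(rbind, tabs)
    class(poses) <- unique(c("pose_table", class(poses)))
    list(poses = poses, labels = labels, layout = layout)
  })
}

#' Metropolis sampler over occupancy states
#'
#' Independent stochastic oracle for the analytic occupancy distribution: a
#' Metropolis chain over occupancy vectors with stationary weight
#' `c^n * K(state)`. At each step one site is picked uniformly and a uniform
#' level 0..n_max proposed for it; marginals are time-averaged over the
#' post-burn-in chain and standard errors estimated by batch means over
#' thinned snapshots.
#'
#' @param constants A `site_constants` table.
#' @param concentration Reservoir concentration in mM.
#' @param steps Total Metropolis steps (default 1e5).
#' @param burnin Steps discarded before averaging (default `steps/10`).
#' @param seed Integer RNG seed.
#' @return List with `marginals` (named list of per-site level-frequency
#'   vectors), `se` (matching standard errors), `acceptance` rate and
#'   `steps`.
#' @export
mc_occupancy_sampler <- function(constants, concentration, steps = 1e5,
                                 burnin = floor(steps / 10), seed = 1L) {
  constants <- .validate_site_constants(constants)
  stopifnot(steps >= 1)
  lw <- .level_log_weights(constants, concentration)
  nmax <- max_occupancy(constants)
  s <- length(nmax)
  .with_seed(seed, {
    js <- sample.int(s, steps, replace = TRUE)
    props <- floor(stats::runif(steps) * (nmax[js] + 1L))
    lu <- log(stats::runif(steps))
    occ <- rep(0L, s)
    counts <- matrix(0, nrow = max(nmax) + 1L, ncol = s)
    t_last <- rep(as.numeric(burnin), s)
    n_acc <- 0L
    thin <- max(1L, floor((steps - burnin) / 4000))
    snaps <- matrix(0L, nrow = floor((steps - burnin) / thin), ncol = s)
    isnap <- 0L
    for (t in seq_len(steps)) {
      j <- js[t]
      prop <- props[t]
      if (prop != occ[j]) {
        dl <- lw[[j]][prop + 1L] - lw[[j]][occ[j] + 1L]
        if (dl >= 0 || lu[t] < dl) {
          if (t > burnin) {
            counts[occ[j] + 1L, j] <- counts[occ[j] + 1L, j] +
              (t - max(t_last[j], burnin))
            t_last[j] <- t
          }
          occ[j] <- prop
          n_acc <- n_acc + 1L
        }
      }
      if (t > burnin && (t - burnin) %% thin == 0L && isnap < nrow(snaps)) {
        isnap <- isnap + 1L
        snaps[isnap, ] <- occ
      }
    }
    for (j in seq_len(s)) {
      counts[occ[j] + 1L, j] <- counts[occ[j] + 1L, j] +
        (steps - max(t_last[j], burnin))
    }
    denom <- steps - burnin
    marginals <- lapply(seq_len(s), function(j) {
      p <- counts[seq_len(nmax[j] + 1L), j] / denom
      names(p) <- 0:nmax[j]
      p
    })
    nb <- 20L
    bsize <- max(1L, floor(isnap / nb))
    se <- lapply(seq_len(s), function(j) {
      vapply(0:nmax[j], function(n) {
        if (isnap < nb) return(NA_real_)
        bm <- vapply(seq_len(nb), function(b) {
          idx <- ((b - 1L) * bsize + 1L):min(b * bsize, isnap)
          mean(snaps[idx, j] == n)
        }, numeric(1))
        stats::sd(bm) / sqrt(nb)
      }, numeric(1))
    })
    names(marginals) <- names(nmax)
    names(se) <- names(nmax)
    list(marginals = marginals, se = se,
         acceptance = n_acc / steps, steps = steps)
  })
}
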