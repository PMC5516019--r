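# Symmetry-class averaging for f-fold symmetric oligomers. Sites related by
# the oligomer symmetry are physically indistinguishable; their per-site
# constants differ only through finite sampling of the receptor conformation.
# Class averages are taken on the linear K scale (arithmetic mean) with the
# population standard deviation (divisor f) as the associated statistical
# error, and class free energies are recomputed from the mean constants.

#' Symmetry class definitions
#'
#' @param class_id Character vector of class labels, one per site.
#' @param site_id Character vector of site identifiers; each site belongs to
#'   exactly one class (the classes partition the site set).
#' @return A data frame of class `symmetry_classes`.
#' @examples
#' symmetry_classes(rep(c("A", "B"), each = 2), c("s1", "s2", "s3", "s4"))
#' @export
symmetry_classes <- function(class_id, site_id) {
  df <- data.frame(class_id = as.character(class_id),
                   site_id = as.character(site_id),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no class assignments given", call. = FALSE)
  if (anyDuplicated(df$site_id))
    stop("each site must belong to exactly one class; duplicated: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "),
         call. = FALSE)
  class(df) <- unique(c("symmetry_classes", class(df)))
  df
}

.check_class_cover <- function(classes, site_ids) {
  if (!inherits(classes, "symmetry_classes"))
    stop("`classes` must be a symmetry_classes object", call. = FALSE)
  uncovered <- setdiff(site_ids, classes$site_id)
  if (length(uncovered))
    stop("site(s) not covered by any symmetry class: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  invisible(classes)
}

#' Class average and spread of per-site estimates
#'
#' Arithmetic mean over the `f` member sites of a class, with the population
#' standard deviation (divisor `f`, not `f - 1`) as the statistical error:
#' the members are the complete set of symmetry-related copies, not a sample
#' from a larger population.
#'
#' @param values Numeric vector of per-site values for one class (length
#'   `f >= 1`).
#' @return List with elements `mean` and `sd`.
#' @examples
#' class_average(c(11.8, 25.1, 41.9, 3.30)) # mean 20.5, sd 14.6
#' @export
class_average <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values))
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  m <- mean(values)
  list(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Symmetry-class binding constants
#'
#' Class-averaged constants per occupancy level, with population spreads and
#' the standard free energy recomputed from the mean constant.
#'
#' @param constants A `site_constants` table (see [binding_constants()]).
#' @param classes A [symmetry_classes()] definition covering every site.
#' @return Data frame of class `class_constants`: `class_id`, `level`,
#'   `fold`, `K_mean`, `K_sd`, `dG0` (kcal/mol).
#' @examples
#' cst <- binding_constants(kv12_affinity_table(), ligand_reservoir(-0.1))
#' class_constants(cst, kv12_symmetry_classes())
#' @export
class_constants <- function(constants, classes) {
  constants <- .validate_site_constants(constants)
  .check_class_cover(classes, unique(constants$site_id))
  ctx <- attr(constants, "ctx")
  if (is.null(ctx)) ctx <- thermo_context()
  rows <- list()
  for (cl in unique(classes$class_id)) {
    members <- classes$site_id[classes$class_id == cl]
    members <- intersect(members, constants$site_id)
    if (length(members) == 0L) next
    nmax <- unique(max_occupancy(constants)[members])
    if (length(nmax) != 1L)
      stop("class ", cl, ": member sites have differing maximum occupancy",
           call. = FALSE)
    for (n in seq_len(nmax)) {
      Ks <- constants$K[constants$site_id %in% members & constants$level == n]
      ca <- class_average(Ks)
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = cl, level = n, fold = length(members),
        K_mean = ca$mean, K_sd = ca$sd,
        dG0 = standard_binding_free_energy(ca$mean, n, ctx),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ctx") <- ctx
  class(out) <- unique(c("class_constants", class(out)))
  out
}

#' Substitute class-mean affinities into a per-site constants table
#'
#' Every member site of a class receives the class-mean `K_n` for each level
#' (and the free energy recomputed from it), producing the symmetrized
#' per-site table used for symmetric state reconstruction. Averaging is done
#' on the K scale; by linearity, the dilute-limit titration slope
#' `sum_j K_1j` is preserved exactly.
#'
#' @inheritParams class_constants
#' @return A `site_constants` table with class-mean constants, plus columns
#'   `class_id` and `K_sd`.
#' @export
symmetrize_affinities <- function(constants, classes) {
  constants <- .validate_site_constants(constants)
  .check_class_cover(classes, unique(constants$site_id))
  ctx <- attr(constants, "ctx")
  cls <- class_constants(constants, classes)
  out <- constants
  out$class_id <- classes$class_id[match(out$site_id, classes$site_id)]
  key <- paste(out$class_id, out$level)
  ckey <- paste(cls$class_id, cls$level)
  idx <- match(key, ckey)
  out$K <- cls$K_mean[idx]
  out$logK <- log(out$K)
  out$dG0 <- cls$dG0[idx]
  out$K_sd <- cls$K_sd[idx]
  out$K_lo <- NA_real_
  out$K_hi <- NA_real_
  attr(out, "symmetrized") <- TRUE
  out
}

#' Reconstruct a state constant from class-level affinities
#'
#' For an occupancy state of the full (distinguishable-site) receptor, the
#' state constant is the product over symmetry classes of the class constant
#' for each member site's occupancy: `K(state) = prod_k prod_{j in class k}
#' Kbar_{n_j}`. The exponent of each class-level constant is the number of
#' member sites carrying that occupancy in the state (the multiset reading of
#' the symmetry numbers, which sum to `s` over every state). Equivalent to
#' [state_constant()] applied to [symmetrize_affinities()] output.
#'
#' @param cls A `class_constants` table.
#' @param state Named integer occupancy vector (names are site ids).
#' @param classes A [symmetry_classes()] covering the state's sites.
#' @param log If `TRUE`, return the log constant.
#' @return The reconstructed state constant in mM^-n.
#' @export
symmetric_state_constant <- function(cls, state, classes, log = FALSE) {
  if (!inherits(cls, "class_constants"))
    stop("`cls` must be a class_constants object", call. = FALSE)
  if (is.null(names(state)))
    stop("`state` must be named by site id", call. = FALSE)
  .check_class_cover(classes, names(state))
  lK <- 0
  for (j in seq_along(state)) {
    n <- as.integer(state[[j]])
    if (n == 0L) next
    cl <- classes$class_id[classes$site_id == names(state)[j]]
    row <- cls[cls$class_id == cl & cls$level == n, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("class ", cl, " has no level-", n, " constant", call. = FALSE)
    lK <- lK + log(row$K_mean)
  }
  if (log) lK else exp(lK)
}
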