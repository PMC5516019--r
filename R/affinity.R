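# Per-site, per-occupancy-level equilibrium constants from restrained-FEP
# inputs. A site occupied by n ligands restrained with harmonic constants
# k_1..k_n has
#
#   K_n = (1/n!) * prod_i (2*pi/(beta*k_i))^(3/2) * exp(-beta*(W*_n - n*mu))
#
# with W*_n the cumulative reversible work of coupling n ligands from gas
# phase into the site and mu the reservoir excess chemical potential. K_n is
# computed in log space (A^(3n) internally) and only exponentiated/converted
# to mM^-n at the end, so large |W*| cannot overflow.

#' Per-site restrained-FEP affinity table
#'
#' Constructs the validated table of per-site, per-occupancy-level inputs:
#' harmonic restraint constants, cumulative reversible work values and their
#' statistical errors. Levels for a site must form a contiguous range
#' `1..n_max`.
#'
#' @param site_id Character or factor site identifiers (one per row).
#' @param region Free-text region label per row (e.g. "S4S5-linker").
#' @param level Integer occupancy level `n >= 1` per row.
#' @param k Harmonic force constants in kcal/mol/A^2: a numeric vector (one
#'   constant per row) or a list of numeric vectors (one constant per ligand
#'   in that level's restrained setup).
#' @param work Cumulative reversible work `W*_n` in kcal/mol (gas phase to
#'   `n` bound).
#' @param work_error Statistical error on `work` (kcal/mol, >= 0).
#' @return A data frame of class `affinity_table` with list-column `k`.
#' @seealso [read_affinity_table()], [binding_constants()]
#' @examples
#' aff <- affinity_table(site_id = "S1", region = "pocket", level = 1,
#'                       k = 0.127, work = -7.5, work_error = 0.1)
#' @export
affinity_table <- function(site_id, region, level, k, work, work_error = 0) {
  if (!is.list(k)) k <- as.list(k)
  df <- data.frame(
    site_id = as.character(site_id),
    region = as.character(region),
    level = as.integer(level),
    work = as.numeric(work),
    work_error = as.numeric(rep_len(work_error, length(site_id))),
    stringsAsFactors = FALSE
  )
  df$k <- lapply(k, as.numeric)
  .validate_affinity_table(df)
}

.validate_affinity_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("site_id", "region", "level", "k", "work", "work_error")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("affinity table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("affinity table is empty", call. = FALSE)
  if (anyNA(df$work) || anyNA(df$level))
    stop("affinity table contains non-numeric work or level entries",
         call. = FALSE)
  if (any(df$level < 1L))
    stop("occupancy levels must be >= 1", call. = FALSE)
  bad_k <- vapply(df$k, function(ki) {
    length(ki) == 0L || anyNA(ki) || any(!is.finite(ki)) || any(ki <= 0)
  }, logical(1))
  if (any(bad_k))
    stop("all force constants must be positive and finite (rows ",
         paste(which(bad_k), collapse = ", "), ")", call. = FALSE)
  if (anyNA(df$work_error) || any(df$work_error < 0))
    stop("work errors must be >= 0", call. = FALSE)
  key <- paste(df$site_id, df$level)
  if (anyDuplicated(key))
    stop("duplicate (site_id, level) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  for (s in unique(df$site_id)) {
    lv <- sort(df$level[df$site_id == s])
    if (!identical(lv, seq_len(max(lv))))
      stop("site ", s, ": occupancy levels must be contiguous 1..n_max, got ",
           paste(lv, collapse = ","), call. = FALSE)
  }
  class(df) <- unique(c("affinity_table", class(df)))
  df
}

#' Maximum occupancy per site
#'
#' @param x An `affinity_table` or `site_constants` object.
#' @return Named integer vector of `n_max` per site, in first-appearance order.
#' @export
max_occupancy <- function(x) {
  stopifnot(is.data.frame(x), all(c("site_id", "level") %in% names(x)))
  ids <- unique(x$site_id)
  out <- vapply(ids, function(s) max(x$level[x$site_id == s]), integer(1))
  names(out) <- ids
  out
}

#' Effective volume of a harmonically restrained ligand
#'
#' The configurational volume `(2*pi/(beta*k))^(3/2)` sampled by a ligand
#' centroid under an isotropic harmonic restraint of force constant `k`.
#'
#' @param k Force constant(s) in kcal/mol/A^2, positive.
#' @param ctx A [thermo_context()].
#' @return Effective volume(s) in A^3; strictly decreasing in `k`.
#' @examples
#' effective_volume(0.127, thermo_context()) # ~158.7 A^3
#' @export
effective_volume <- function(k, ctx = thermo_context()) {
  ctx <- .as_context(ctx)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0))
    stop("`k` must be positive and finite (kcal/mol/A^2)", call. = FALSE)
  (2 * pi / (ctx$beta * k))^1.5
}

#' Compose a two-step double-occupancy work value
#'
#' The cumulative reversible work for two bound ligands is obtained as a
#' two-step process: coupling to the vacant site (`w1`) followed by coupling
#' of a second ligand to the pre-occupied site (`w2_given_1`). By default the
#' per-step statistical errors are added linearly, matching how composed
#' errors are quoted in the reference table; quadrature is available for
#' independent per-step estimates.
#'
#' @param w1 Reversible work of the first ligand (kcal/mol).
#' @param w2_given_1 Reversible work of the second ligand given the first
#'   (kcal/mol).
#' @param error1,error2 Statistical errors of the two steps (kcal/mol).
#' @param error_rule Either `"linear"` (default) or `"quadrature"`.
#' @return List with elements `work` (= `w1 + w2_given_1`) and `error`.
#' @examples
#' compose_two_step_work(-4.5, -3.6, 0.2, 0.2) # work -8.1, error 0.4
#' @export
compose_two_step_work <- function(w1, w2_given_1, error1 = 0, error2 = 0,
                                  error_rule = c("linear", "quadrature")) {
  error_rule <- match.arg(error_rule)
  err <- switch(error_rule,
                linear = abs(error1) + abs(error2),
                quadrature = sqrt(error1^2 + error2^2))
  list(work = w1 + w2_given_1, error = err)
}

# Force constants entering the effective-volume product for (site, level).
# Levels listing one constant per ligand are used as-is. Levels listing a
# single constant are expanded according to `k_convention`:
#   mixed     - ligand m takes the constant reported at level m (the restraint
#               actually applied when that ligand was coupled); this is the
#               convention that reproduces the reference table's double-
#               occupancy free energies.
#   per_level - all n ligands take the level-n constant.
.level_k_vector <- function(tbl, site_id, level,
                            k_convention = c("mixed", "per_level")) {
  k_convention <- match.arg(k_convention)
  rows <- tbl[tbl$site_id == site_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown site: ", site_id, call. = FALSE)
  if (!level %in% rows$level)
    stop("site ", site_id, " has no occupancy level ", level, call. = FALSE)
  k_here <- rows$k[[match(level, rows$level)]]
  if (length(k_here) == level) return(k_here)
  if (length(k_here) != 1L)
    stop("site ", site_id, " level ", level, ": expected 1 or ", level,
         " force constants, got ", length(k_here), call. = FALSE)
  if (level == 1L) return(k_here)
  if (k_convention == "per_level") return(rep(k_here, level))
  vapply(seq_len(level), function(m) rows$k[[match(m, rows$level)]][1L],
         numeric(1))
}

# log K in A^(3n) units
.log_state_constant_A <- function(kvec, work, n, mu, ctx) {
  -lfactorial(n) + sum(1.5 * log(2 * pi / (ctx$beta * kvec))) -
    ctx$beta * (work - n * mu)
}

#' Per-site binding constant for a given occupancy level
#'
#' Computes the equilibrium constant for binding `n` ligands to one site,
#' `K_n = (1/n!) prod_i(2 pi/(beta k_i))^(3/2) exp(-beta (W*_n - n mu))`,
#' converted from A^(3n) to mM^-n.
#'
#' @param tbl An [affinity_table()].
#' @param site_id Site identifier.
#' @param level Occupancy level `n` (1..n_max for that site).
#' @param reservoir A [ligand_reservoir()] supplying the excess chemical
#'   potential.
#' @param ctx A [thermo_context()].
#' @param k_convention How single-constant levels map onto per-ligand
#'   restraint constants; see [binding_constants()].
#' @param log If `TRUE`, return `log(K_n)` instead of `K_n`.
#' @return The binding constant in mM^-n (or its log).
#' @export
site_binding_constant <- function(tbl, site_id, level, reservoir,
                                  ctx = thermo_context(),
                                  k_convention = c("mixed", "per_level"),
                                  log = FALSE) {
  tbl <- .validate_affinity_table(tbl)
  ctx <- .as_context(ctx)
  reservoir <- .as_reservoir(reservoir)
  k_convention <- match.arg(k_convention)
  n <- as.integer(level)
  kvec <- .level_k_vector(tbl, site_id, n, k_convention)
  row <- tbl[tbl$site_id == site_id & tbl$level == n, , drop = FALSE]
  lK <- .log_state_constant_A(kvec, row$work, n, reservoir$excess_mu, ctx) +
    n * log(.density_per_mM)
  if (log) lK else exp(lK)
}

#' Standard binding free energy from a binding constant
#'
#' `dG0 = -beta^-1 * log(K_n * (C0)^n)` with `C0 = 1 M = 1000 mM`.
#'
#' @param K Binding constant(s) in mM^-n, positive.
#' @param n Number of bound ligands (integer >= 1), recycled against `K`.
#' @param ctx A [thermo_context()].
#' @return Standard binding free energy in kcal/mol.
#' @examples
#' standard_binding_free_energy(25.1, 1) # ~ -6.0 kcal/mol
#' @export
standard_binding_free_energy <- function(K, n, ctx = thermo_context()) {
  ctx <- .as_context(ctx)
  if (!is.numeric(K) || any(!is.finite(K)) || any(K <= 0))
    stop("`K` must be positive and finite", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  -(log(K) + n * log(1000)) / ctx$beta
}

#' Per-site binding constants and standard free energies
#'
#' Applies [site_binding_constant()] to every (site, level) row of an
#' affinity table and attaches standard free energies and the asymmetric
#' bounds implied by the work errors (`K * exp(+/- beta * error)`).
#'
#' The `"mixed"` force-constant convention assigns to ligand `m` of an
#' `n`-occupied site the restraint constant reported at level `m`; it
#' reflects the sequential restrained coupling actually performed and is the
#' default. `"per_level"` uses the level-`n` constant for all `n` ligands.
#'
#' @inheritParams site_binding_constant
#' @return A data frame of class `site_constants` with columns `site_id`,
#'   `region`, `level`, `logK` (log mM^-n), `K` (mM^-n), `dG0` (kcal/mol),
#'   `K_lo`, `K_hi`. The reservoir and context are attached as attributes.
#' @examples
#' tbl <- kv12_affinity_table()
#' res <- ligand_reservoir(excess_mu = -0.1)
#' head(binding_constants(tbl, res))
#' @export
binding_constants <- function(tbl, reservoir, ctx = thermo_context(),
                              k_convention = c("mixed", "per_level")) {
  tbl <- .validate_affinity_table(tbl)
  ctx <- .as_context(ctx)
  reservoir <- .as_reservoir(reservoir)
  k_convention <- match.arg(k_convention)
  logK <- mapply(function(s, n) {
    site_binding_constant(tbl, s, n, reservoir, ctx, k_convention, log = TRUE)
  }, tbl$site_id, tbl$level)
  out <- data.frame(
    site_id = tbl$site_id,
    region = tbl$region,
    level = tbl$level,
    logK = as.numeric(logK),
    K = exp(as.numeric(logK)),
    stringsAsFactors = FALSE
  )
  out$dG0 <- standard_binding_free_energy(out$K, out$level, ctx)
  out$K_lo <- exp(out$logK - ctx$beta * tbl$work_error)
  out$K_hi <- exp(out$logK + ctx$beta * tbl$work_error)
  attr(out, "reservoir") <- reservoir
  attr(out, "ctx") <- ctx
  attr(out, "k_convention") <- k_convention
  class(out) <- unique(c("site_constants", class(out)))
  out
}

.validate_site_constants <- function(x) {
  if (!inherits(x, "site_constants"))
    stop("expected a site_constants object (see binding_constants())",
         call. = FALSE)
  x
}

#' Decompose a standard binding free energy into its three contributions
#'
#' Splits `dG0(n)` for one site into (i) the restrained coupling work minus
#' the reservoir excess potential, `W*_n - n*mu`; (ii) the expansion term
#' `-beta^-1 log prod_i (C0 * (2 pi/(beta k_i))^(3/2))`, the free-energy
#' change of releasing the restrained ligands into the standard volume; and
#' (iii) the indistinguishability correction `-beta^-1 log(1/n!)`. The three
#' terms sum exactly to [standard_binding_free_energy()] of the corresponding
#' constant.
#'
#' @inheritParams site_binding_constant
#' @return Named numeric vector with elements `work`, `expansion`,
#'   `indistinguishability` and attribute `total`.
#' @export
free_energy_decomposition <- function(tbl, site_id, level, reservoir,
                                      ctx = thermo_context(),
                                      k_convention = c("mixed", "per_level")) {
  tbl <- .validate_affinity_table(tbl)
  ctx <- .as_context(ctx)
  reservoir <- .as_reservoir(reservoir)
  k_convention <- match.arg(k_convention)
  n <- as.integer(level)
  kvec <- .level_k_vector(tbl, site_id, n, k_convention)
  row <- tbl[tbl$site_id == site_id & tbl$level == n, , drop = FALSE]
  terms <- c(
    work = row$work - n * reservoir$excess_mu,
    expansion = -sum(log(ctx$standard_density *
                           (2 * pi / (ctx$beta * kvec))^1.5)) / ctx$beta,
    indistinguishability = lfactorial(n) / ctx$beta
  )
  attr(terms, "total") <- sum(terms)
  terms
}
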