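# Occupancy-state enumeration and probabilities. Under the independent-site
# factorization the weight of a state (n_1,...,n_s) at reservoir
# concentration c is
#
#   w(state) = c^n * K(n_1,...,n_s) = prod_j c^{n_j} K_{n_j}
#
# and probabilities follow by normalization. All weights are handled in log
# space and normalized with log-sum-exp so that strongly bound sites (large
# beta*|W*|) cannot overflow.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Named list, per site, of log-level-weights: lw[[j]][n+1] = n*log(c) + logK_n
.level_log_weights <- function(constants, concentration) {
  constants <- .validate_site_constants(constants)
  nmax <- max_occupancy(constants)
  lc <- if (concentration > 0) log(concentration) else -Inf
  out <- lapply(names(nmax), function(s) {
    rows <- constants[constants$site_id == s, , drop = FALSE]
    lw <- c(0, rows$logK[order(rows$level)] + rows$level[order(rows$level)] * lc)
    if (concentration == 0) lw[-1] <- -Inf
    names(lw) <- 0:nmax[[s]]
    lw
  })
  names(out) <- names(nmax)
  out
}

#' Number of enumerable occupancy states
#'
#' `prod_j (n_j_max + 1)` over all sites; the empty site set gives 1.
#'
#' @param x An `affinity_table` or `site_constants` object, or an integer
#'   vector of per-site maximum occupancies.
#' @return The total number of occupancy states (double, to allow > 2^31).
#' @examples
#' count_states(rep(2L, 12)) # 531441
#' @export
count_states <- function(x) {
  nmax <- if (is.numeric(x)) as.integer(x) else max_occupancy(x)
  if (length(nmax) == 0L) return(1)
  prod(nmax + 1)
}

#' Binding constant of a full occupancy state
#'
#' Under independent sites, `K(n_1,...,n_s)` factorizes as the product of the
#' per-site constants `K_{n_j}` (Eq. of the independent-site model); the
#' empty state has constant 1.
#'
#' @param constants A `site_constants` table from [binding_constants()].
#' @param state Integer vector of per-site occupancies, named by site id or
#'   in the site order of `constants`.
#' @param log If `TRUE`, return the log constant.
#' @return The state constant in mM^-n with `n = sum(state)`.
#' @export
state_constant <- function(constants, state, log = FALSE) {
  constants <- .validate_site_constants(constants)
  nmax <- max_occupancy(constants)
  state <- .normalize_state(state, nmax)
  lK <- 0
  for (j in seq_along(state)) {
    n <- state[[j]]
    if (n > 0L) {
      s <- names(state)[j]
      lK <- lK + constants$logK[constants$site_id == s & constants$level == n]
    }
  }
  if (log) lK else exp(lK)
}

.normalize_state <- function(state, nmax) {
  state <- stats::setNames(as.integer(round(state)), names(state))
  if (is.null(names(state))) {
    if (length(state) != length(nmax))
      stop("state length (", length(state), ") does not match number of sites (",
           length(nmax), ")", call. = FALSE)
    names(state) <- names(nmax)
  }
  unknown <- setdiff(names(state), names(nmax))
  if (length(unknown))
    stop("unknown site(s) in state: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  state <- state[names(nmax)]
  state[is.na(state)] <- 0L
  names(state) <- names(nmax)
  if (any(state < 0L) || any(state > nmax))
    stop("state occupancies must lie in 0..n_max per site", call. = FALSE)
  state
}

#' Occupancy-state probability distribution
#'
#' `state_probabilities()` enumerates every occupancy state and returns the
#' normalized distribution `rho(n_1,...,n_s) \\propto c^n K(n_1,...,n_s)` at
#' the given reservoir concentration. Systems above `enumeration_cap` states
#' must use [factorized_distribution()] (identical marginals and averages
#' under the independent-site model, without enumeration).
#'
#' @param constants A `site_constants` table.
#' @param concentration Reservoir concentration in mM (>= 0). Values >= 1 M
#'   are accepted with a warning: the dilute-reservoir theory is stretched
#'   there.
#' @param enumeration_cap Maximum number of states to enumerate (default
#'   1e6).
#' @return An object of class `state_distribution` with `mode =
#'   "enumerated"`: site ids, the integer state matrix, per-state log weights
#'   and probabilities.
#' @examples
#' tbl <- kv12_affinity_table()
#' cst <- binding_constants(tbl, ligand_reservoir(-0.1))
#' dist <- state_probabilities(cst, concentration = 1)
#' sum(dist$prob) # 1
#' @export
state_probabilities <- function(constants, concentration,
                                enumeration_cap = 1e6) {
  constants <- .validate_site_constants(constants)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop("`concentration` must be a single number >= 0 (mM)", call. = FALSE)
  .check_concentration(concentration)
  nmax <- max_occupancy(constants)
  n_states <- count_states(nmax)
  if (n_states > enumeration_cap)
    stop("state space has ", format(n_states, big.mark = ","),
         " states (> cap ", format(enumeration_cap, big.mark = ","),
         "); use factorized_distribution()", call. = FALSE)
  lw <- .level_log_weights(constants, concentration)
  states <- as.matrix(expand.grid(lapply(nmax, function(m) 0:m),
                                  KEEP.OUT.ATTRS = FALSE))
  storage.mode(states) <- "integer"
  colnames(states) <- names(nmax)
  logw <- rep(0, nrow(states))
  for (j in seq_along(nmax)) logw <- logw + unname(lw[[j]][states[, j] + 1L])
  logZ <- .logsumexp(logw)
  structure(
    list(mode = "enumerated", concentration = concentration,
         site_ids = names(nmax), max_occupancy = nmax,
         states = states, log_weight = logw, prob = exp(logw - logZ)),
    class = "state_distribution"
  )
}

#' @describeIn state_probabilities Factorized (per-site marginal) form of the
#'   same distribution, usable at any system size.
#' @export
factorized_distribution <- function(constants, concentration) {
  constants <- .validate_site_constants(constants)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop("`concentration` must be a single number >= 0 (mM)", call. = FALSE)
  .check_concentration(concentration)
  nmax <- max_occupancy(constants)
  lw <- .level_log_weights(constants, concentration)
  marginals <- lapply(lw, function(v) {
    p <- exp(v - .logsumexp(v))
    p / sum(p)
  })
  structure(
    list(mode = "factorized", concentration = concentration,
         site_ids = names(nmax), max_occupancy = nmax,
         marginals = marginals),
    class = "state_distribution"
  )
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf("<state_distribution> %s, %d sites, c = %.4g mM\n",
              x$mode, length(x$site_ids), x$concentration))
  invisible(x)
}

#' Marginal occupancy probabilities per site
#'
#' `rho(n_j)`: the probability that site `j` holds exactly `n_j` ligands,
#' regardless of the other sites. For an enumerated distribution this
#' coarse-grains the state probabilities; for a factorized distribution (or
#' a `site_constants` table plus concentration) it is the closed form
#' `rho(n_j) = c^{n_j} K_{n_j} / sum_m c^m K_m`.
#'
#' @param x A `state_distribution` or a `site_constants` table.
#' @param concentration Required when `x` is a `site_constants` table.
#' @param sites Optional character vector restricting the output.
#' @return Named list (per site) of probability vectors over levels
#'   `0..n_max`, each summing to 1.
#' @export
marginal_occupancy <- function(x, concentration = NULL, sites = NULL) {
  if (inherits(x, "site_constants")) {
    if (is.null(concentration))
      stop("`concentration` is required with a site_constants input",
           call. = FALSE)
    x <- factorized_distribution(x, concentration)
  }
  if (!inherits(x, "state_distribution"))
    stop("`x` must be a state_distribution or site_constants object",
         call. = FALSE)
  out <- if (x$mode == "factorized") {
    x$marginals
  } else {
    lapply(seq_along(x$site_ids), function(j) {
      p <- vapply(0:x$max_occupancy[[j]], function(n) {
        sum(x$prob[x$states[, j] == n])
      }, numeric(1))
      names(p) <- 0:x$max_occupancy[[j]]
      p
    })
  }
  names(out) <- x$site_ids
  if (!is.null(sites)) {
    unknown <- setdiff(sites, x$site_ids)
    if (length(unknown))
      stop("unknown site(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    out <- out[sites]
  }
  out
}

#' Macrostate probabilities over the total number of bound ligands
#'
#' `rho(n) = sum over states with total occupancy n of rho(n_1,...,n_s)`.
#' For factorized input this is computed exactly by polynomial convolution of
#' the per-site level weights, with no enumeration.
#'
#' @inheritParams marginal_occupancy
#' @return Named numeric vector `rho(0..N)` summing to 1, `N = sum(n_max)`.
#' @export
macrostate_probabilities <- function(x, concentration = NULL) {
  if (inherits(x, "site_constants")) {
    if (is.null(concentration))
      stop("`concentration` is required with a site_constants input",
           call. = FALSE)
    x <- factorized_distribution(x, concentration)
  }
  if (!inherits(x, "state_distribution"))
    stop("`x` must be a state_distribution or site_constants object",
         call. = FALSE)
  if (x$mode == "enumerated") {
    tot <- rowSums(x$states)
    N <- sum(x$max_occupancy)
    p <- vapply(0:N, function(n) sum(x$prob[tot == n]), numeric(1))
  } else {
    p <- 1
    for (m in x$marginals) {
      np <- numeric(length(p) + length(m) - 1L)
      for (i in seq_along(m)) {
        idx <- i:(i + length(p) - 1L)
        np[idx] <- np[idx] + m[i] * p
      }
      p <- np
    }
  }
  p <- p / sum(p)
  names(p) <- seq_along(p) - 1L
  p
}

#' Ensemble average of a state-dependent property
#'
#' `<A> = sum_states A(state) * rho(state)` over an enumerated distribution.
#'
#' @param dist An enumerated `state_distribution`.
#' @param property Either a function taking an integer occupancy vector and
#'   returning a scalar, or a numeric vector of per-state values aligned with
#'   `dist$states`.
#' @return The probability-weighted mean.
#' @export
ensemble_average <- function(dist, property) {
  if (!inherits(dist, "state_distribution") || dist$mode != "enumerated")
    stop("`dist` must be an enumerated state_distribution", call. = FALSE)
  vals <- if (is.function(property)) {
    apply(dist$states, 1L, property)
  } else {
    as.numeric(property)
  }
  if (length(vals) != length(dist$prob) || anyNA(vals))
    stop("`property` must yield one finite value per state", call. = FALSE)
  sum(vals * dist$prob)
}

#' Mean number of bound ligands
#'
#' `<n> = sum_j sum_m m * rho(m at site j)`, computed from marginals (exact
#' for both enumerated and factorized distributions since occupancy is
#' additive over sites).
#'
#' @inheritParams marginal_occupancy
#' @param per_site If `TRUE`, return the named per-site averages `<n_j>`.
#' @return Scalar `<n>` or named per-site vector.
#' @export
mean_occupancy <- function(x, concentration = NULL, per_site = FALSE) {
  marg <- marginal_occupancy(x, concentration)
  per <- vapply(marg, function(p) sum(p * (seq_along(p) - 1L)), numeric(1))
  if (per_site) per else sum(per)
}

#' Titration curve
#'
#' Average occupancy (total and per site) as a function of reservoir
#' concentration. In the dilute limit the slope `d<n>/dc` equals the sum of
#' single-occupancy constants, `sum_j K_1j` (see [dilute_limit_slope()]);
#' with saturable sites `<n>` approaches `sum_j n_j_max` at high
#' concentration.
#'
#' @param constants A `site_constants` table.
#' @param concentrations Numeric vector of concentrations in mM (>= 0).
#' @return A data frame of class `titration_curve` with columns
#'   `concentration`, `n_mean`, and one `n_<site>` column per site.
#' @export
titration_curve <- function(constants, concentrations) {
  constants <- .validate_site_constants(constants)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  rows <- lapply(concentrations, function(cc) {
    per <- suppressWarnings(mean_occupancy(constants, cc, per_site = TRUE))
    c(concentration = cc, n_mean = sum(per), per)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("concentration", "n_mean",
                  paste0("n_", names(rows[[1]])[-(1:2)]))
  .check_concentration(concentrations)
  class(out) <- unique(c("titration_curve", class(out)))
  out
}

#' @export
plot.titration_curve <- function(x, ...) {
  graphics::plot(x$concentration, x$n_mean, type = "b", log = "x",
                 xlab = "reservoir concentration (mM)",
                 ylab = "mean bound ligands <n>", ...)
  invisible(x)
}

#' Dilute-limit titration slope
#'
#' As `c -> 0`, `d<n>/dc -> sum_j K_1j` (mM^-1): only singly-occupied states
#' contribute at first order in concentration.
#'
#' @param constants A `site_constants` table.
#' @return The limiting slope in mM^-1.
#' @export
dilute_limit_slope <- function(constants) {
  constants <- .validate_site_constants(constants)
  sum(constants$K[constants$level == 1L])
}

#' Rank occupancy states by probability
#'
#' @param dist An enumerated `state_distribution`.
#' @param top Number of states to keep (default all).
#' @return Data frame with `state` (digit string "n1n2..."), `total` and
#'   `prob`, sorted by descending probability; ties broken by lexicographic
#'   occupancy string.
#' @export
sorted_states <- function(dist, top = NULL) {
  if (!inherits(dist, "state_distribution") || dist$mode != "enumerated")
    stop("`dist` must be an enumerated state_distribution", call. = FALSE)
  str <- apply(dist$states, 1L, paste, collapse = "")
  ord <- order(-dist$prob, str)
  if (!is.null(top)) ord <- utils::head(ord, top)
  data.frame(state = str[ord], total = rowSums(dist$states)[ord],
             prob = dist$prob[ord], stringsAsFactors = FALSE)
}
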