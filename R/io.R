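# Tabular I/O. The universal dialect is tab-separated text with
# '#'-prefixed header/comment lines; K-like columns are written in
# scientific notation with 3 significant digits. Every output file carries
# the tool version, a config hash and input checksums in its header so runs
# are attributable; with a fixed seed, outputs are byte-identical.

.pkg_version <- function() {
  as.character(utils::packageVersion("multibind"))
}

.fmt_sci <- function(x) formatC(x, format = "E", digits = 2)

# Header lines for an output table.
.output_header <- function(config = NULL, inputs = character(0)) {
  h <- sprintf("# multibind %s", .pkg_version())
  if (!is.null(config)) h <- c(h, sprintf("# config_hash: %s", config_hash(config)))
  for (p in inputs) {
    if (file.exists(p))
      h <- c(h, sprintf("# input %s md5: %s", basename(p),
                        unname(tools::md5sum(p))))
  }
  h
}

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  df
}

#' Read a per-site affinity table (TSV)
#'
#' Expected columns: `site_id`, `region`, `level`, `k_list` (semicolon-
#' separated force constants, kcal/mol/A^2), `work_kcal_mol`,
#' `error_kcal_mol`. Lines starting with `#` are comments. Duplicate
#' (site, level) rows, non-numeric fields and non-contiguous levels are
#' rejected with the offending row reported.
#'
#' @param path Path to the TSV file.
#' @return An [affinity_table()].
#' @export
read_affinity_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("site_id", "region", "level", "k_list", "work_kcal_mol",
            "error_kcal_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  k <- lapply(strsplit(as.character(df$k_list), ";", fixed = TRUE),
              function(v) suppressWarnings(as.numeric(v)))
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  work <- num("work_kcal_mol")
  err <- num("error_kcal_mol")
  level <- suppressWarnings(as.integer(df$level))
  bad <- which(is.na(work) | is.na(err) | is.na(level) |
                 vapply(k, anyNA, logical(1)))
  if (length(bad))
    stop(path, ": non-numeric field(s) in data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  affinity_table(df$site_id, df$region, level, k, work, err)
}

#' Write a per-site affinity table (TSV)
#'
#' @param tbl An [affinity_table()].
#' @param path Output path.
#' @param config Optional [run_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(tbl, path, config = NULL) {
  tbl <- .validate_affinity_table(tbl)
  out <- data.frame(
    site_id = tbl$site_id, region = tbl$region, level = tbl$level,
    k_list = vapply(tbl$k, function(v) paste(format(v, trim = TRUE),
                                             collapse = ";"), character(1)),
    work_kcal_mol = tbl$work, error_kcal_mol = tbl$work_error,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path, .output_header(config))
}

#' Read symmetry class definitions (TSV: class_id, site_id)
#'
#' @param path Path to the TSV file.
#' @return A [symmetry_classes()] object.
#' @export
read_symmetry_classes <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(c("class_id", "site_id"), names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  symmetry_classes(df$class_id, df$site_id)
}

#' Write a per-site constants table (TSV)
#'
#' Columns: site_id, region, level, K (mM^-n, 3 significant digits), dG0
#' (kcal/mol), K_lo, K_hi.
#'
#' @param constants A `site_constants` table.
#' @param path Output path.
#' @param config Optional [run_config()] recorded in the header.
#' @param inputs Paths of input files to checksum into the header.
#' @return `path`, invisibly.
#' @export
write_constants_table <- function(constants, path, config = NULL,
                                  inputs = character(0)) {
  constants <- .validate_site_constants(constants)
  out <- data.frame(
    site_id = constants$site_id, region = constants$region,
    level = constants$level,
    K = .fmt_sci(constants$K), dG0 = sprintf("%.2f", constants$dG0),
    K_lo = .fmt_sci(constants$K_lo), K_hi = .fmt_sci(constants$K_hi),
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path, .output_header(config, inputs))
}

#' Write a Table-2-style class constants table (TSV)
#'
#' @param cls A `class_constants` table.
#' @inheritParams write_constants_table
#' @export
write_class_table <- function(cls, path, config = NULL,
                              inputs = character(0)) {
  stopifnot(inherits(cls, "class_constants"))
  out <- data.frame(
    class_id = cls$class_id, level = cls$level, fold = cls$fold,
    K_mean = .fmt_sci(cls$K_mean), K_sd = .fmt_sci(cls$K_sd),
    dG0 = sprintf("%.2f", cls$dG0), stringsAsFactors = FALSE
  )
  .write_tsv(out, path, .output_header(config, inputs))
}

#' Write a ranked occupancy-state table (TSV)
#'
#' @param dist An enumerated `state_distribution`.
#' @param path Output path.
#' @param top Number of top-probability states to keep (default 100).
#' @param config Optional [run_config()].
#' @export
write_state_table <- function(dist, path, top = 100, config = NULL) {
  tab <- sorted_states(dist, top)
  tab$prob <- .fmt_sci(tab$prob)
  .write_tsv(tab, path, c(.output_header(config),
                          sprintf("# concentration_mM: %g", dist$concentration),
                          sprintf("# sites: %s",
                                  paste(dist$site_ids, collapse = ","))))
}

#' Write a titration table (TSV)
#'
#' @param curve A `titration_curve` data frame.
#' @param path Output path.
#' @param config Optional [run_config()].
#' @export
write_titration_table <- function(curve, path, config = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  .write_tsv(curve, path, .output_header(config))
}

#' Write a binding-sites table (TSV)
#'
#' @param sites A `binding_sites` table.
#' @param path Output path.
#' @param config Optional [run_config()].
#' @export
write_sites_table <- function(sites, path, config = NULL) {
  stopifnot(inherits(sites, "binding_sites"))
  .write_tsv(as.data.frame(sites), path, .output_header(config))
}

#' Run configuration
#'
#' Validated key-value bundle of the tunable parameters shared across the
#' pipeline; round-trippable through YAML.
#'
#' @param temperature_K Temperature (K, > 0).
#' @param excess_mu_kcal_mol Reservoir excess chemical potential (kcal/mol).
#' @param concentrations_mM Concentrations to evaluate (mM, >= 0).
#' @param enumeration_cap Maximum enumerable state count.
#' @param cluster_cutoff_A Single-linkage cutoff for pose clustering (A).
#' @param grid_spacing_A Density grid spacing (A).
#' @param kernel_bandwidth_A Kernel sigma for conditional densities (A), or
#'   `NA` for the automatic rule.
#' @param seed Integer RNG seed.
#' @param output_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(temperature_K = 298.15, excess_mu_kcal_mol = -0.1,
                       concentrations_mM = c(1, 10, 100, 1000),
                       enumeration_cap = 1e6, cluster_cutoff_A = 6,
                       grid_spacing_A = 0.5, kernel_bandwidth_A = NA,
                       seed = 1L, output_dir = ".") {
  if (temperature_K <= 0) stop("temperature_K must be > 0", call. = FALSE)
  if (any(concentrations_mM < 0))
    stop("concentrations_mM must be >= 0", call. = FALSE)
  if (cluster_cutoff_A <= 0 || grid_spacing_A <= 0)
    stop("cutoffs and spacings must be > 0", call. = FALSE)
  structure(list(
    temperature_K = temperature_K,
    excess_mu_kcal_mol = excess_mu_kcal_mol,
    concentrations_mM = concentrations_mM,
    enumeration_cap = enumeration_cap,
    cluster_cutoff_A = cluster_cutoff_A,
    grid_spacing_A = grid_spacing_A,
    kernel_bandwidth_A = kernel_bandwidth_A,
    seed = as.integer(seed),
    output_dir = output_dir
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

#' @rdname run_config
#' @param config A `run_config` to serialize.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialization, recorded in output headers so a
#' result file can be tied to the exact parameter set that produced it.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
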