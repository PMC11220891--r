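#' Read / write reflection lists as plain text
#'
#' One record per line, whitespace-delimited `h k l intensity`; comment
#' lines start with `#`. Reading requires a [unit_cell()] to reconstruct the
#' Cartesian q vectors.
#'
#' @param peaks A [bragg_peaks()] list.
#' @param path File path.
#' @param cell A [unit_cell()] (reading only).
#' @param q_max Optional cutoff attribute for the reconstructed list.
#' @return `write_reflections` returns `path` invisibly; `read_reflections`
#'   returns a [bragg_peaks()] list.
#' @export
write_reflections <- function(peaks, path) {
  stopifnot(inherits(peaks, "bragg_peaks"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# h k l intensity", con)
  writeLines(sprintf("%d %d %d %.17g",
                     peaks$h, peaks$k, peaks$l, peaks$intensity), con)
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path, cell, q_max = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("h", "k", "l", "intensity"))
  rb <- reciprocal_basis(cell)
  qv <- as.matrix(tab[, c("h", "k", "l")]) %*% rb
  bragg_peaks(tab$h, tab$k, tab$l, qv, tab$intensity, q_max = q_max)
}

#' Read unit-cell parameters from core CIF cell tags
#'
#' Minimal reader for the six `_cell_length_*` / `_cell_angle_*` tags of a
#' crystallographic information file; parenthesised standard uncertainties
#' are stripped.
#'
#' @param path CIF file path.
#' @return A [unit_cell()].
#' @export
read_cell_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    hit <- grep(paste0("^[[:space:]]*", tag, "[[:space:]]"), lines,
                value = TRUE)
    if (!length(hit)) stop(sprintf("CIF tag %s not found", tag), call. = FALSE)
    val <- sub(paste0(".*", tag, "[[:space:]]+"), "", hit[1])
    as.numeric(sub("\\(.*\\)", "", val))
  }
  unit_cell(grab("_cell_length_a"), grab("_cell_length_b"),
            grab("_cell_length_c"), grab("_cell_angle_alpha"),
            grab("_cell_angle_beta"), grab("_cell_angle_gamma"))
}

#' Binary array container with a JSON sidecar header
#'
#' Arrays (correlation volumes, intensity volumes, harmonic order matrices,
#' masks) are persisted as little-endian doubles in `<path>` with a plain-text
#' JSON header `<path>.json` holding the dimensions and metadata.
#'
#' @param x Numeric (or logical) array.
#' @param path Output file path.
#' @param meta Named list of additional metadata to store in the header.
#' @return `write_array_bin` returns `path` invisibly; `read_array_bin`
#'   returns the array with the metadata in attribute `meta`.
#' @export
write_array_bin <- function(x, path, meta = list()) {
  hdr <- c(list(dim = dim(x), storage = "double", endian = "little"), meta)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.numeric(x)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_array_bin
#' @export
read_array_bin <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  x <- array(x, dim = hdr$dim)
  attr(x, "meta") <- hdr[setdiff(names(hdr), c("dim", "storage", "endian"))]
  x
}

#' Save / load a correlation volume via the binary container
#' @param cv A [correlation_volume()].
#' @param path Output path (a `.json` sidecar header is written next to it).
#' @return `write_volume` returns `path`; `read_volume` the restored object.
#' @export
write_volume <- function(cv, path) {
  stopifnot(inherits(cv, "correlation_volume"))
  write_array_bin(cv$values, path,
                  meta = list(kind = "correlation_volume", q_max = cv$q_max,
                              angular = cv$angular))
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  x <- read_array_bin(path)
  meta <- attr(x, "meta")
  attr(x, "meta") <- NULL
  correlation_volume(x, q_max = meta$q_max, angular = meta$angular)
}

# defaults mirror the production-scale run configuration
run_config_defaults <- function() {
  list(n_q = 300L, n_eta = 5760L, n_theta = 500L, n_phi = 1000L,
       l_cut = 45L, support_width = 5L, beta = 0.9,
       recipe = "120HIO", seed = 1L, q_max = NA_real_)
}

#' Load and validate a run configuration
#'
#' A single human-readable YAML key-value file; unknown keys are errors
#' (fail closed). Missing keys take the defaults (production-scale sampling:
#' `n_q 300, n_eta 5760, n_theta 500, n_phi 1000, l_cut 45, support width 5,
#' beta 0.9, recipe "120HIO"`).
#'
#' @param path YAML config path (`load_config`), or a named list
#'   (`validate_config`).
#' @return The validated config list, or an error listing every violated
#'   invariant by name.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, cfg)
  bad <- character(0)
  if (out$n_phi != 2 * out$n_theta)
    bad <- c(bad, "grid convention: n_phi must equal 2 * n_theta")
  if (out$l_cut > out$n_theta / 2)
    bad <- c(bad, "band limit: l_cut must be <= n_theta / 2")
  if (out$support_width %% 2 != 1 || out$support_width < 1)
    bad <- c(bad, "support width must be odd and positive")
  if (out$beta <= 0 || out$beta >= 2)
    bad <- c(bad, "beta must lie in (0, 2)")
  if (any(c(out$n_q, out$n_eta) < 2))
    bad <- c(bad, "n_q and n_eta must be >= 2")
  if (length(bad))
    stop("invalid config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  out
}

#' Save a run configuration
#' @param cfg Config list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a reproducibility manifest for a CLI run
#'
#' JSON with the package version, a hash of the effective config, the seed
#' and a timestamp: enough to rerun the deterministic stages bit-for-bit.
#'
#' @param cfg Validated config list.
#' @param path Output path.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  blob <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                           digits = NA)
  man <- c(list(package = "braggfxs",
                version = as.character(utils::packageVersion("braggfxs")),
                config = cfg,
                config_hash = sprintf("%08x", sum(utf8ToInt(blob) *
                                                    seq_along(utf8ToInt(blob)) %% 2^16)),
                seed = cfg$seed,
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Append a JSON-lines telemetry record
#'
#' @param record Named list (one iteration's telemetry).
#' @param path JSON-lines file path (appended).
#' @return `path`, invisibly.
#' @export
log_telemetry <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
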