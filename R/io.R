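# Format adapters: life-table CSV, dense matrix CSV and MatrixMarket
# interchange, analysis reports (JSON), and run configuration (YAML).

#' Write / read a life table as CSV
#'
#' One row per individual per day; columns `individual_id`,
#' `maternal_age`, `day`, `alive` (0/1), `censored` (0/1), `offspring`
#' (integer); header required; UTF-8. Writing is deterministic
#' (byte-identical for identical input).
#'
#' @param data a life-table data.frame.
#' @param path CSV file path.
#' @export
write_life_table <- function(data, path) {
  cols <- c("individual_id", "maternal_age", "day", "alive", "censored",
            "offspring")
  stopifnot(all(cols %in% names(data)))
  utils::write.csv(data[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @return `read_life_table()` returns a validated `life_table`
#'   data.frame.
#' @export
read_life_table <- function(path) {
  cols <- c("individual_id", "maternal_age", "day", "alive", "censored",
            "offspring")
  header <- names(utils::read.csv(path, nrows = 0))
  if (!all(cols %in% header))
    stop("malformed life-table CSV: need columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(individual_id = "character"))
  if (any(d$day < 1) || any(!d$alive %in% 0:1) || any(!d$censored %in% 0:1)
      || any(d$offspring < 0))
    stop("malformed life-table CSV: out-of-range values", call. = FALSE)
  bad <- vapply(split(d$day, d$individual_id),
                function(dd) !all(sort(dd) == seq_along(dd)), logical(1))
  if (any(bad))
    stop("malformed life-table CSV: non-consecutive days for ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  structure(d[, cols], class = c("life_table", "data.frame"))
}

#' Write a block matrix to disk
#'
#' CSV format: a comment header line records `s`, `omega`, the matrix kind
#' (`U`, `F` or `A`) and the state ordering convention, followed by the
#' dense matrix. MatrixMarket format (`.mtx`): sparse coordinate file via
#' the Matrix package, with the same metadata in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param m a dense square matrix.
#' @param path output path; a `.mtx` extension selects MatrixMarket.
#' @param s,omega class counts recorded in the metadata.
#' @param kind one of `"U"`, `"F"`, `"A"`.
#' @export
write_block_matrix <- function(m, path, s, omega, kind = "A") {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m), "CsparseMatrix"),
                                "generalMatrix"), path)
    jsonlite::write_json(list(s = s, omega = omega, kind = kind,
                              ordering = "maternal-age-within-age"),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  } else {
    header <- sprintf(
      "# block matrix: s=%d omega=%d kind=%s ordering=maternal-age-within-age flat_index=(age-1)*s+maternal_age",
      s, omega, kind)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(format(m, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read one block matrix file (CSV with metadata header, or MatrixMarket)
#'
#' @param path matrix file written by [write_block_matrix()].
#' @return a dense matrix with attributes `s`, `omega`, `kind`.
#' @export
read_block_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    meta_path <- paste0(path, ".meta.json")
    if (!file.exists(meta_path))
      stop("metadata header missing: expected ", meta_path, call. = FALSE)
    meta <- jsonlite::read_json(meta_path)
  } else {
    first <- readLines(path, n = 1)
    if (!grepl("^# block matrix:", first))
      stop("metadata header missing in ", path, call. = FALSE)
    get_num <- function(key) as.integer(sub(paste0(".*", key, "=(\\d+).*"),
                                            "\\1", first))
    meta <- list(s = get_num("s"), omega = get_num("omega"),
                 kind = sub(".*kind=(\\w+).*", "\\1", first))
    m <- as.matrix(utils::read.csv(path, header = FALSE, skip = 1))
    dimnames(m) <- NULL
  }
  attr(m, "s") <- meta$s; attr(m, "omega") <- meta$omega
  attr(m, "kind") <- meta$kind
  m
}

#' Read a block model from matrix files
#'
#' Whole-matrix mode: `u_path` and `f_path` each hold one `s*omega` square
#' matrix. Per-age-block mode: `block_dir` holds files `U_1..U_{omega-1}`
#' and `F_1..F_omega` (any of `.csv`/`.mtx`), each an `s x s` age block --
#' `U_j` carries the survival probabilities of age class `j` on its
#' diagonal and `F_j` the fertilities of age class `j` in its row `j`.
#' Both modes validate the block structure and reject files with nonzeros
#' in forbidden positions.
#'
#' @param u_path,f_path whole-matrix files.
#' @param block_dir directory of per-age-block files.
#' @return a `block_model`.
#' @export
read_block_model <- function(u_path = NULL, f_path = NULL,
                             block_dir = NULL) {
  if (!is.null(block_dir)) {
    files <- list.files(block_dir, pattern = "^[UF]_\\d+\\.(csv|mtx)$")
    if (length(files) == 0)
      stop("no U_j / F_j block files found in ", block_dir, call. = FALSE)
    f_files <- sort(files[startsWith(files, "F_")])
    u_files <- sort(files[startsWith(files, "U_")])
    omega <- length(f_files)
    first <- read_block_matrix(file.path(block_dir, f_files[1]))
    s <- nrow(first)
    n <- s * omega
    Um <- matrix(0, n, n); Fm <- matrix(0, n, n)
    for (f in files) {
      j <- as.integer(sub("^[UF]_(\\d+)\\..*$", "\\1", f))
      blk <- read_block_matrix(file.path(block_dir, f))
      if (!all(dim(blk) == s))
        stop("block ", f, " is not ", s, "x", s, call. = FALSE)
      cols <- block_index(seq_len(s), j, s)
      if (startsWith(f, "U_")) {
        Um[block_index(seq_len(s), j + 1L, s), cols] <- blk
      } else {
        Fm[seq_len(s), cols] <- blk
      }
    }
  } else {
    if (is.null(u_path) || is.null(f_path))
      stop("supply u_path and f_path, or block_dir", call. = FALSE)
    Um <- read_block_matrix(u_path)
    Fm <- read_block_matrix(f_path)
    s <- attr(Um, "s"); omega <- attr(Um, "omega")
    if (!identical(dim(Um), dim(Fm)))
      stop("U and F dimensions differ", call. = FALSE)
  }
  block_model_from_matrices(Um, Fm, s, omega)
}

#' Write both matrices of a block model
#'
#' @param model a `block_model`.
#' @param dir output directory.
#' @param format `"csv"` or `"mtx"`.
#' @return the two file paths, invisibly.
#' @export
write_block_model <- function(model, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  up <- file.path(dir, paste0("U.", format))
  fp <- file.path(dir, paste0("F.", format))
  write_block_matrix(model$U, up, model$s, model$omega, "U")
  write_block_matrix(model$F, fp, model$s, model$omega, "F")
  invisible(c(U = up, F = fp))
}

#' Machine-readable analysis report
#'
#' Collects the eigen-analysis of a model (growth rate, log growth rate,
#' R0, stable structure, reproductive values) plus named young-corner
#' structure summaries into a list, and optionally writes it as JSON at
#' full precision.
#'
#' @param model a `block_model`.
#' @param path optional JSON output path.
#' @param summaries named list of `c(max_age, max_maternal_age)` bounds for
#'   [structure_summary()].
#' @return the report list, invisibly when `path` is given.
#' @export
analysis_report <- function(model, path = NULL,
                            summaries = list(
                              young_corner = c(3, 5))) {
  e <- eigen_analysis(model)
  rep <- list(lam = e$lam, log_lam = e$log_lam,
              R0 = net_reproductive_rate(model),
              s = model$s, omega = model$omega,
              w = as.numeric(e$w), v = as.numeric(e$v),
              structure_summaries = lapply(summaries, function(b)
                structure_summary(e, b[1], b[2])))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

#' Run configuration round-trip
#'
#' A flat run configuration (paths, dimensions, scenario and fitting
#' options, simulation design, seed) serialised losslessly to YAML.
#' `config_hash()` gives an md5 fingerprint for provenance logging.
#'
#' @param ... configuration fields overriding the defaults.
#' @return `run_config()` returns a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(s = 16L, omega = 16L,
              reference_maternal_age = 3L, target_lambda = 1,
              fit_starts = 5L, fit_reltol = 1e-10,
              maternal_ages = c(3L, 5L, 7L, 9L), n_per_cohort = 72L,
              max_day = 16L, censor_prob = 0.01, seed = 1L,
              out_dir = "results", verbosity = 1L)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' @rdname run_config
#' @export
config_hash <- function(path) unname(tools::md5sum(path))

#' Append a provenance line to a run log
#'
#' Records the config hash, seed, and the artifact just written, so every
#' output file can be traced to the configuration that produced it.
#'
#' @param log_path log file (created if absent).
#' @param config_path the config file governing the run.
#' @param artifact path of the artifact written.
#' @param note free-text note.
#' @export
log_provenance <- function(log_path, config_path, artifact, note = "") {
  line <- sprintf("%s config=%s md5=%s artifact=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  config_path, config_hash(config_path), artifact, note)
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}
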