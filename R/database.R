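DB_SCHEMA_VERSION <- 1L

#' Build the simulated-anthesis database
#'
#' Simulates every parameter set in every site-year and stores the anthesis
#' dates (days after sowing) in a dense integer matrix: the lookup structure
#' for per-line inversion. Failure to flower within the horizon is stored as
#' the sentinel `-1`.
#'
#' @param sets Parameter sets from [generate_sobol_sets()] (any tibble with
#'   `p1`, `p2`, `p2o`, `phint` columns works; generation order is the row
#'   order and is preserved).
#' @param siteyears Site-year tibble (rows from [site_year()] or
#'   [make_siteyears()]).
#' @param control A [phenology_control()].
#' @return A `sim_database` object: list with `sets` (tibble), `siteyears`
#'   (metadata tibble without weather), `anthesis` (`n_sets x n_siteyears`
#'   integer matrix, columns named by `site_id`), and `meta` (box, skip,
#'   control, schema version).
#' @export
build_database <- function(sets, siteyears, control = phenology_control()) {
  stopifnot(nrow(sets) >= 1, nrow(siteyears) >= 1)
  anthesis <- matrix(NA_integer_, nrow = nrow(sets), ncol = nrow(siteyears),
                     dimnames = list(NULL, siteyears$site_id))
  for (j in seq_len(nrow(siteyears))) {
    anthesis[, j] <- simulate_anthesis_batch(siteyears[j, ], sets, control)
  }
  box <- attr(sets, "box")
  meta <- list(schema_version = DB_SCHEMA_VERSION,
               n_sets = nrow(sets), site_ids = siteyears$site_id,
               box = if (!is.null(box)) as.data.frame(box) else NULL,
               skip = attr(sets, "skip") %||% NA_integer_,
               control = control)
  structure(list(sets = tibble::as_tibble(sets),
                 siteyears = dplyr::select(siteyears, -"weather"),
                 anthesis = anthesis, meta = meta),
            class = "sim_database")
}

#' @export
print.sim_database <- function(x, ...) {
  cat(sprintf("<sim_database> %d parameter sets x %d site-years (%s)\n",
              nrow(x$anthesis), ncol(x$anthesis),
              paste(colnames(x$anthesis), collapse = ", ")))
  nf <- sum(x$anthesis < 0)
  cat(sprintf("  %d entries, %d did-not-flower (%.2f%%)\n",
              length(x$anthesis), nf, 100 * nf / length(x$anthesis)))
  invisible(x)
}

#' Tidy a simulation database into a long tibble
#'
#' @param x A `sim_database`.
#' @param ... Unused.
#' @return A tibble with `set` (row index), `site_year`, `anthesis_dap`
#'   (`NA` where the simulation did not flower).
#' @export
tidy.sim_database <- function(x, ...) {
  tibble::tibble(
    set = rep(seq_len(nrow(x$anthesis)), times = ncol(x$anthesis)),
    site_year = rep(colnames(x$anthesis), each = nrow(x$anthesis)),
    anthesis_dap = ifelse(c(x$anthesis) < 0, NA_integer_, c(x$anthesis)))
}

# Canonical md5 of database content (sets + anthesis files).
database_hash <- function(dir) {
  files <- file.path(dir, c("sets.csv", "anthesis.csv"))
  unname(tools::md5sum(files))
}

#' Persist a simulation database to a directory
#'
#' Columnar plain-text layout: `sets.csv` (parameter sets in generation
#' order), `anthesis.csv` (one integer column per site-year, sentinel -1),
#' `siteyears.csv`, and `meta.json` carrying the schema version, phenology
#' configuration, box and the md5 content hashes. Writing is deterministic,
#' so save-load-save reproduces files byte-identically.
#'
#' @param db A `sim_database`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "sim_database"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(db$sets, file.path(dir, "sets.csv"))
  readr::write_csv(tibble::as_tibble(db$anthesis), file.path(dir, "anthesis.csv"))
  readr::write_csv(db$siteyears, file.path(dir, "siteyears.csv"))
  meta <- db$meta
  meta$control <- unclass(meta$control)
  meta$hash <- as.list(rlang::set_names(database_hash(dir),
                                        c("sets.csv", "anthesis.csv")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Load a simulation database from a directory
#'
#' Verifies the schema version and the recorded content hashes; a truncated
#' or altered file raises an integrity error rather than being silently
#' reinterpreted.
#'
#' @param dir Directory written by [write_database()].
#' @return A `sim_database`.
#' @export
read_database <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(paste("no database at", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), DB_SCHEMA_VERSION)) {
    abort(sprintf("database schema version %s not supported (expected %d)",
                  meta$schema_version, DB_SCHEMA_VERSION))
  }
  hashes <- database_hash(dir)
  stored <- unlist(meta$hash)[c("sets.csv", "anthesis.csv")]
  if (!identical(unname(stored), hashes)) {
    abort("database integrity check failed: content hash mismatch (truncated or edited file?)")
  }
  sets <- readr::read_csv(file.path(dir, "sets.csv"),
                          col_types = readr::cols(.default = readr::col_double()))
  anth <- readr::read_csv(file.path(dir, "anthesis.csv"),
                          col_types = readr::cols(.default = readr::col_integer()))
  siteyears <- readr::read_csv(file.path(dir, "siteyears.csv"),
                               show_col_types = FALSE)
  if (nrow(sets) != meta$n_sets || nrow(anth) != meta$n_sets) {
    abort("database integrity check failed: row count mismatch")
  }
  anthesis <- as.matrix(anth)
  storage.mode(anthesis) <- "integer"
  meta$hash <- NULL
  control <- meta$control
  meta$control <- do.call(phenology_control, control)
  structure(list(sets = sets, siteyears = siteyears, anthesis = anthesis,
                 meta = meta),
            class = "sim_database")
}
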