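#' Achievable anthesis-date tuples over a site-year subset
#'
#' The set of distinct simulated anthesis-date tuples the model produces
#' anywhere in the scanned parameter box — the achievable region of
#' phenotype space. Each tuple keeps one witness: the first database row (in
#' generation order) that produces it. Rows failing to flower on any subset
#' member are excluded.
#'
#' @param db A `sim_database`.
#' @param subset Character vector of site-year ids (length >= 1); default
#'   all site-years in the database.
#' @return An `achievable_set`: list with `tuples` (integer matrix, one row
#'   per distinct tuple, columns named by site-year), `witness` (database
#'   row index per tuple), `subset`, `n_rows` (eligible rows scanned).
#' @export
achievable_tuples <- function(db, subset = NULL) {
  stopifnot(inherits(db, "sim_database"))
  subset <- subset %||% colnames(db$anthesis)
  if (length(subset) == 0) abort("subset must contain at least one site-year")
  bad <- setdiff(subset, colnames(db$anthesis))
  if (length(bad) > 0) {
    abort(paste("subset site-years not in database:", paste(bad, collapse = ", ")))
  }
  sub <- db$anthesis[, subset, drop = FALSE]
  elig <- which(rowSums(sub < 0) == 0)
  sub <- sub[elig, , drop = FALSE]
  if (nrow(sub) == 0) abort("no database row flowered on every subset site-year")
  key <- do.call(paste, c(asplit(sub, 2), sep = ","))
  first <- !duplicated(key)
  structure(list(tuples = sub[first, , drop = FALSE],
                 witness = elig[first],
                 subset = subset, n_rows = length(elig)),
            class = "achievable_set")
}

#' @export
print.achievable_set <- function(x, ...) {
  cat(sprintf("<achievable_set> %d distinct tuples over {%s} (%d eligible rows)\n",
              nrow(x$tuples), paste(x$subset, collapse = ", "), x$n_rows))
  invisible(x)
}

#' Classify observed tuples against the achievable set
#'
#' A line's observation tuple is expressible when it matches an achievable
#' tuple exactly; otherwise it is assigned the nearest achievable tuple
#' under the RMSE metric (equivalently Euclidean distance for a fixed
#' subset), with ties broken by first-witness order. The returned parameters
#' are those of the chosen tuple's witness row, mirroring what the database
#' scan reports for such lines.
#'
#' @param ach An [achievable_tuples()] result.
#' @param observations Long observations tibble; only lines observed on the
#'   whole subset are classified.
#' @param db The `sim_database` the achievable set came from (for witness
#'   parameters); optional, parameters omitted when absent.
#' @return A tibble, one row per line: `line_id`, observed tuple columns
#'   (`obs_<site>`), `expressible`, nearest tuple columns (`nearest_<site>`),
#'   `distance_days` (RMSE to nearest tuple; 0 iff expressible),
#'   `witness_row`, and witness parameters if `db` given.
#' @export
classify_lines <- function(ach, observations, db = NULL) {
  stopifnot(inherits(ach, "achievable_set"))
  subset <- ach$subset
  observations <- observations[observations$site_year %in% subset, ]
  if (nrow(observations) == 0) abort("no observations on the subset site-years")
  om <- obs_matrix(observations, subset)
  complete <- rowSums(is.na(om)) == 0
  om <- om[complete, , drop = FALSE]
  if (nrow(om) == 0) abort("no line is observed on the full subset")
  tup <- ach$tuples
  k <- length(subset)
  # squared distances lines x tuples via the expansion |a-b|^2 = |a|^2 - 2ab + |b|^2
  cross <- om %*% t(tup)
  d2 <- outer(rowSums(om^2), rowSums(tup^2), "+") - 2 * cross
  d2 <- pmax(d2, 0)
  nearest <- apply(d2, 1, which.min) # ties -> lowest tuple index = first witness
  dist <- sqrt(d2[cbind(seq_len(nrow(om)), nearest)] / k)
  res <- tibble::tibble(line_id = rownames(om))
  for (j in seq_len(k)) res[[paste0("obs_", subset[j])]] <- om[, j]
  res$expressible <- dist == 0
  for (j in seq_len(k)) res[[paste0("nearest_", subset[j])]] <- tup[nearest, j]
  res$distance_days <- dist
  res$witness_row <- ach$witness[nearest]
  if (!is.null(db)) {
    res <- dplyr::bind_cols(res, db$sets[res$witness_row, ])
  }
  res
}

#' Summarise expressivity over a panel of lines
#'
#' Counts expressible and inexpressible lines and, for two-site-year
#' subsets, lays phenotype space out as a numeric tableau: for each
#' achievable date pair the witness P1, and for each observed-but-
#' inexpressible date pair the number of lines stranded there.
#'
#' @param reports A [classify_lines()] result.
#' @param ach The [achievable_tuples()] set used (required for the tableau).
#' @param db Optional `sim_database` for witness P1 values in the tableau.
#' @return A list of class `expressivity_summary`: `n_lines`,
#'   `n_expressible`, `n_inexpressible`, `mean_distance_days` (over
#'   inexpressible lines), and for 2-D subsets `tableau` (long tibble with
#'   `date_1`, `date_2`, `achievable`, `witness_p1`, `n_inexpressible`).
#' @export
expressivity_summary <- function(reports, ach = NULL, db = NULL) {
  stopifnot(nrow(reports) >= 1)
  inx <- !reports$expressible
  out <- list(n_lines = nrow(reports),
              n_expressible = sum(!inx),
              n_inexpressible = sum(inx),
              mean_distance_days = if (any(inx)) mean(reports$distance_days[inx]) else 0)
  if (!is.null(ach) && length(ach$subset) == 2) {
    achv <- tibble::tibble(date_1 = ach$tuples[, 1], date_2 = ach$tuples[, 2],
                           achievable = TRUE,
                           witness_p1 = if (!is.null(db)) db$sets$p1[ach$witness] else NA_real_)
    oc <- reports[!reports$expressible, ]
    if (nrow(oc) > 0) {
      obs_cols <- paste0("obs_", ach$subset)
      counts <- dplyr::count(oc, .data[[obs_cols[1]]], .data[[obs_cols[2]]],
                             name = "n_inexpressible")
      names(counts)[1:2] <- c("date_1", "date_2")
      counts$achievable <- FALSE
      counts$witness_p1 <- NA_real_
      out$tableau <- dplyr::bind_rows(achv, counts)
    } else {
      achv$n_inexpressible <- NA_integer_
      out$tableau <- achv
    }
  }
  structure(out, class = "expressivity_summary")
}

#' @export
print.expressivity_summary <- function(x, ...) {
  cat(sprintf("<expressivity_summary> %d lines: %d expressible, %d inexpressible",
              x$n_lines, x$n_expressible, x$n_inexpressible))
  if (x$n_inexpressible > 0) {
    cat(sprintf(" (mean distance %.2f days)", x$mean_distance_days))
  }
  cat("\n")
  invisible(x)
}

#' Frontier cells of a two-dimensional achievable set
#'
#' Boundary of the achievable region on the integer date lattice: achievable
#' date pairs with at least one 4-neighbour outside the set.
#'
#' @param ach A 2-D [achievable_tuples()] result.
#' @return A tibble `date_1`, `date_2` of frontier cells.
#' @export
frontier_cells <- function(ach) {
  stopifnot(inherits(ach, "achievable_set"))
  if (length(ach$subset) != 2) {
    abort("the frontier is defined for two-site-year subsets only")
  }
  tup <- ach$tuples
  key <- paste(tup[, 1], tup[, 2])
  on_frontier <- vapply(seq_len(nrow(tup)), function(i) {
    nb <- paste(tup[i, 1] + c(1, -1, 0, 0), tup[i, 2] + c(0, 0, 1, -1))
    !all(nb %in% key)
  }, logical(1))
  tibble::tibble(date_1 = tup[on_frontier, 1], date_2 = tup[on_frontier, 2])
}
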