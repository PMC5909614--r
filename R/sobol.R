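# Direction-number seeds (primitive polynomial degree s, coefficient code a,
# initial values m) for Sobol dimensions 2..6; dimension 1 is the base-2
# van der Corput sequence. Joe-Kuo "new" table, 30-bit precision.
sobol_seeds <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3))
)

sobol_bits <- 30L

# 30-bit direction numbers for one dimension.
sobol_directions <- function(dim) {
  B <- sobol_bits
  if (dim == 1) return(bitwShiftL(1L, B - seq_len(B)))
  sd <- sobol_seeds[[dim - 1]]
  s <- sd$s
  m <- integer(B)
  m[seq_len(s)] <- as.integer(sd$m)
  a_bits <- as.integer(intToBits(sd$a))[seq_len(max(s - 1, 1))]
  for (i in (s + 1):B) {
    val <- bitwXor(m[i - s], bitwShiftL(m[i - s], s))
    if (s > 1) {
      for (k in seq_len(s - 1)) {
        if (a_bits[s - k] == 1L) val <- bitwXor(val, bitwShiftL(m[i - k], k))
      }
    }
    m[i] <- val
  }
  bitwShiftL(m, B - seq_len(B))
}

#' Sobol low-discrepancy sequence
#'
#' Unscrambled Sobol points in the unit hypercube, generated in Gray-code
#' order with Joe-Kuo direction numbers at 30-bit precision (dimension up to
#' 6). The generation order is deterministic and is what defines the
#' "first-best-found" convention of the database scan downstream. The first
#' point is the origin.
#'
#' @param n Number of points (>= 1).
#' @param d Dimension (1-6).
#' @param skip Number of initial points to discard (burn-in), default 0.
#' @return An `n x d` numeric matrix with entries in `[0, 1)`.
#' @examples
#' sobol_sequence(8, 2)
#' @export
sobol_sequence <- function(n, d, skip = 0) {
  stopifnot(n >= 1, d >= 1, d <= 6, skip >= 0)
  v <- vapply(seq_len(d), sobol_directions, integer(sobol_bits))
  total <- n + skip
  state <- integer(d)
  out <- matrix(0, nrow = n, ncol = d)
  scale <- 2^sobol_bits
  if (skip == 0) out[1, ] <- 0
  for (i in seq_len(total - 1)) {
    c <- 1L
    ii <- i
    while (bitwAnd(ii, 1L) == 0L) {
      ii <- bitwShiftR(ii, 1L)
      c <- c + 1L
    }
    state <- bitwXor(state, v[c, ])
    if (i >= skip) out[i - skip + 1, ] <- state / scale
  }
  out
}

#' Define a parameter box for the quasi-random scan
#'
#' Each axis has a range and a rounding resolution; generated points are
#' snapped to the resolution grid anchored at the axis minimum, which caps
#' the number of distinct values per axis at `(max - min) / resolution + 1`.
#'
#' @param ... Named axes, each a numeric vector `c(min, max, resolution)`.
#'   Axis order is the generation order of the Sobol dimensions.
#' @return A tibble of class `parameter_box` with columns `name`, `min`,
#'   `max`, `resolution`.
#' @examples
#' parameter_box(p1 = c(150, 450, 0.01), phint = c(25, 70, 0.001))
#' @export
parameter_box <- function(...) {
  axes <- list(...)
  stopifnot(length(axes) >= 1, !is.null(names(axes)), all(names(axes) != ""))
  box <- purrr::imap_dfr(axes, function(ax, nm) {
    stopifnot(length(ax) == 3, ax[1] < ax[2], ax[3] > 0)
    tibble::tibble(name = nm, min = ax[1], max = ax[2], resolution = ax[3])
  })
  class(box) <- c("parameter_box", class(box))
  box
}

#' Coerce a data frame of axes to a parameter box
#'
#' Useful for reconstructing the box recorded in database metadata.
#'
#' @param df Data frame with columns `name`, `min`, `max`, `resolution`.
#' @return A [parameter_box()].
#' @export
as_parameter_box <- function(df) {
  args <- purrr::pmap(df[c("name", "min", "max", "resolution")],
                      function(name, min, max, resolution) c(min, max, resolution))
  do.call(parameter_box, rlang::set_names(args, df$name))
}

#' Standard four-parameter box
#'
#' Ranges and rounding resolutions for the four anthesis genotype-specific
#' parameters: P1 in 150-450 GDD at 0.01, P2O in 10-14 h at 0.01, P2 in 0-2
#' d/h at 0.0001, PHINT in 25-70 GDD at 0.001 (up to 30001, 401, 20001 and
#' 45001 distinct values per axis respectively).
#'
#' @return A [parameter_box()].
#' @export
default_parameter_box <- function() {
  parameter_box(p1 = c(150, 450, 0.01), p2o = c(10, 14, 0.01),
                p2 = c(0, 2, 1e-4), phint = c(25, 70, 0.001))
}

#' Extended box for the continuous (differential evolution) search
#'
#' Ranges deliberately wider than biological expectation: P1 75-600 GDD,
#' P2O 6-21 h, P2 0-6 d/h, PHINT 20-100 GDD. Resolutions are kept from the
#' standard box (the continuous search itself does not round).
#'
#' @return A [parameter_box()].
#' @export
extended_parameter_box <- function() {
  parameter_box(p1 = c(75, 600, 0.01), p2o = c(6, 21, 0.01),
                p2 = c(0, 6, 1e-4), phint = c(20, 100, 0.001))
}

#' Six-parameter box including cardinal temperatures
#'
#' Adds base and optimum temperature axes to a four-parameter box so the
#' scan explores the thermal-time response as well.
#'
#' @param box A four-parameter box to extend.
#' @param tbase Range/resolution for the base temperature, degrees C.
#' @param topt Range/resolution for the optimum temperature, degrees C.
#' @return A [parameter_box()] with six axes.
#' @export
six_parameter_box <- function(box = default_parameter_box(),
                              tbase = c(6, 10, 0.01), topt = c(30, 38, 0.01)) {
  stopifnot(nrow(box) == 4)
  args <- c(purrr::pmap(box, function(name, min, max, resolution) {
    c(min, max, resolution)
  }) |> rlang::set_names(box$name),
  list(tbase = tbase, topt = topt))
  do.call(parameter_box, args)
}

#' Generate quasi-random parameter sets inside a box
#'
#' Scales a Sobol sequence into the box and snaps each axis to its rounding
#' resolution. Row order is generation order; it is recorded implicitly by
#' the row index and defines the first-best-found convention of the
#' database scan.
#'
#' @param box A [parameter_box()].
#' @param n Number of parameter sets.
#' @param skip Sobol burn-in, default 0.
#' @param max_entries Refuse to generate more than this many values
#'   (`n * dimension`) in one call; shard the scan instead. Default `2^26`.
#' @return A tibble with one column per axis, `n` rows, class
#'   `sobol_sets`; attributes record the box, `n` and `skip`.
#' @export
generate_sobol_sets <- function(box, n, skip = 0, max_entries = 2^26) {
  stopifnot(inherits(box, "parameter_box"), n >= 1)
  d <- nrow(box)
  if (n * d > max_entries) {
    abort(sprintf(paste(
      "n = %d sets x %d axes exceeds the memory budget (%d values);",
      "generate the scan in shards (see `skip`)."), n, d, max_entries))
  }
  u <- sobol_sequence(n, d, skip = skip)
  cols <- purrr::map(seq_len(d), function(j) {
    x <- box$min[j] + u[, j] * (box$max[j] - box$min[j])
    snapped <- box$min[j] +
      round((x - box$min[j]) / box$resolution[j]) * box$resolution[j]
    # re-round to the decimal scale of the resolution so values are exactly
    # representable in text and survive CSV round trips bit-identically
    round(snapped, ceiling(-log10(box$resolution[j])) + 1)
  })
  sets <- tibble::as_tibble(rlang::set_names(cols, box$name))
  structure(sets, box = box, skip = skip,
            class = c("sobol_sets", class(sets)))
}
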