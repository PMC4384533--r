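#' Atmospheric fraction-modern calibration curve
#'
#' Tabulated atmospheric F14C against decimal calendar year with one-sigma
#' uncertainties. This is the calibration reference against which tissue
#' measurements are inverted: the bomb pulse (above-ground weapons testing,
#' 1955–1963) nearly doubled atmospheric 14CO2, which has since declined
#' exponentially through ocean/biosphere exchange, giving a dated tracer.
#' Rows are sorted by year; duplicate years are rejected.
#'
#' @param year decimal calendar years (strictly increasing after sorting).
#' @param f14c atmospheric fraction modern, all `> 0`.
#' @param sigma one-sigma uncertainty of `f14c`, all `>= 0`.
#' @param label free-text provenance (e.g. hemisphere zone).
#' @return A `data.frame` of class `atm_curve` with attribute `label`.
#' @seealso [read_curve()], [splice_curves()], [curve_at()],
#'   [synthetic_bomb_curve()]
#' @export
atm_curve <- function(year, f14c, sigma, label = "") {
  if (length(year) != length(f14c) || length(year) != length(sigma))
    stop("year, f14c and sigma must have equal length")
  if (length(year) < 2)
    stop("an atmospheric curve needs at least 2 rows")
  if (any(!is.finite(year)) || any(!is.finite(f14c)) || any(!is.finite(sigma)))
    stop("non-finite value in curve")
  o <- order(year)
  year <- year[o]; f14c <- f14c[o]; sigma <- sigma[o]
  dup <- duplicated(year)
  if (any(dup))
    stop(sprintf("duplicate year(s) in curve: %s",
                 paste(unique(year[dup]), collapse = ", ")))
  if (any(f14c <= 0)) stop("all f14c values must be > 0")
  if (any(sigma < 0)) stop("all sigma values must be >= 0")
  structure(data.frame(year = year, f14c = f14c, sigma = sigma),
            class = c("atm_curve", "data.frame"), label = label)
}

#' Read an atmospheric curve from a delimited text file
#'
#' Expects a UTF-8 table with header `year,f14c,sigma`, comma- or
#' tab-delimited (auto-detected from the header line); lines starting with
#' `#` are ignored. A Hua-style hemispheric compilation exported in this
#' format can be supplied directly.
#'
#' @param path file path.
#' @param label provenance label attached to the curve (defaults to the
#'   file name).
#' @return An [atm_curve()].
#' @export
read_curve <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 3)
    stop(sprintf("parse error in '%s': need a header plus >= 2 data rows", path))
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- read.table(text = lines, header = TRUE, sep = sep,
                   strip.white = TRUE, colClasses = "character")
  need <- c("year", "f14c", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("parse error in '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  num <- lapply(need, function(col) suppressWarnings(as.numeric(df[[col]])))
  names(num) <- need
  for (col in need) {
    bad <- which(is.na(num[[col]]))
    if (length(bad))
      stop(sprintf("parse error in '%s': non-numeric '%s' in data row %d (%s)",
                   path, col, bad[1], df[[col]][bad[1]]))
  }
  atm_curve(num$year, num$f14c, num$sigma, label = label)
}

#' Splice a pre-bomb curve onto a bomb-pulse curve
#'
#' Combines a tree-ring (pre-bomb) record with a bomb-pulse compilation at a
#' boundary year: points of `prebomb` strictly before `boundary_year` are
#' kept, points of `bomb` at or after it. Overlapping rows on the wrong side
#' of the boundary are dropped.
#'
#' @param prebomb an [atm_curve()] covering years below the boundary, or
#'   `NULL` for none.
#' @param bomb an [atm_curve()] covering years at/above the boundary.
#' @param boundary_year decimal year at which to switch records.
#' @return An [atm_curve()] spanning both records.
#' @export
splice_curves <- function(prebomb, bomb, boundary_year) {
  stopifnot(inherits(bomb, "atm_curve"))
  post <- bomb[bomb$year >= boundary_year, , drop = FALSE]
  if (is.null(prebomb)) {
    pre <- NULL
  } else {
    stopifnot(inherits(prebomb, "atm_curve"))
    pre <- prebomb[prebomb$year < boundary_year, , drop = FALSE]
  }
  year <- c(pre$year, post$year)
  if (length(year) < 2) stop("splice error: fewer than 2 rows remain")
  if (any(diff(year) <= 0))
    stop("splice error: combined year sequence not strictly increasing")
  lab <- paste(c(attr(prebomb, "label"), attr(bomb, "label")), collapse = " + ")
  atm_curve(year, c(pre$f14c, post$f14c), c(pre$sigma, post$sigma),
            label = sub("^ \\+ ", "", lab))
}

#' Evaluate a curve at arbitrary dates by linear interpolation
#'
#' Both the value and its sigma are interpolated linearly between bracketing
#' knots; evaluation is exact at knots. No extrapolation: dates outside the
#' tabulated domain are an error.
#'
#' @param curve an [atm_curve()].
#' @param t decimal year(s) within the curve domain.
#' @return An [f14c_value()] of the same length as `t`.
#' @export
curve_at <- function(curve, t) {
  stopifnot(inherits(curve, "atm_curve"))
  rng <- range(curve$year)
  if (any(!is.finite(t)) || any(t < rng[1]) || any(t > rng[2]))
    stop(sprintf("domain error: date outside curve domain [%g, %g]",
                 rng[1], rng[2]))
  f <- approx(curve$year, curve$f14c, xout = t, rule = 1)$y
  s <- approx(curve$year, curve$sigma, xout = t, rule = 1)$y
  f14c_value(f, s)
}

# Piecewise fixture emulating the southern-hemisphere bomb-pulse shape:
# a slight Suess-effect decline to 1955, a steep linear rise to the 1965
# peak of 1.600, then an exponential decline with a 16-yr e-folding time.
bomb_fixture_f <- function(t) {
  ifelse(t < 1955, 0.980 - 0.0002 * (t - 1900),
  ifelse(t < 1965, 0.969 + 0.0631 * (t - 1955),
                   1.0 + 0.600 * exp(-(t - 1965) / 16)))
}

#' Synthetic bomb-pulse calibration curve (test fixture)
#'
#' Tabulates a southern-hemisphere-shaped fixture on \[1900, 2000\]:
#' `F(t) = 0.980 − 0.0002 (t−1900)` before 1955 (Suess decline),
#' `0.969 + 0.0631 (t−1955)` on the rising limb 1955–1965, and
#' `1 + 0.600 exp(−(t−1965)/16)` on the falling limb 1965–2000, with a
#' constant one-sigma of 0.005 by default. The shape mimics the published
#' southern-hemisphere pulse but is a synthetic fixture, not measured data.
#'
#' @param grid_step tabulation step in years, `0 < grid_step <= 1`.
#' @param sigma constant one-sigma attached to every knot.
#' @return An [atm_curve()].
#' @examples
#' crv <- synthetic_bomb_curve(0.25)
#' curve_at(crv, 1950)  # 0.970
#' @export
synthetic_bomb_curve <- function(grid_step = 0.25, sigma = 0.005) {
  if (!is.numeric(grid_step) || length(grid_step) != 1 ||
      !is.finite(grid_step) || grid_step <= 0 || grid_step > 1)
    stop("parameter error: grid_step must be in (0, 1]")
  year <- seq(1900, 2000, by = grid_step)
  if (year[length(year)] < 2000) year <- c(year, 2000)
  atm_curve(year, bomb_fixture_f(year), rep(sigma, length(year)),
            label = "synthetic SH bomb-pulse fixture")
}

#' @export
print.atm_curve <- function(x, ...) {
  cat(sprintf("Atmospheric F14C curve '%s': %d knots, %.2f-%.2f\n",
              attr(x, "label") %||% "", nrow(x),
              min(x$year), max(x$year)))
  cat(sprintf("  F14C range %.4f-%.4f, median sigma %.4f\n",
              min(x$f14c), max(x$f14c), stats::median(x$sigma)))
  invisible(x)
}

#' @export
plot.atm_curve <- function(x, ...,
                           xlab = "calendar year", ylab = "atmospheric F14C") {
  plot(x$year, x$f14c, type = "l", xlab = xlab, ylab = ylab, ...)
  lines(x$year, x$f14c + x$sigma, lty = 3)
  lines(x$year, x$f14c - x$sigma, lty = 3)
  invisible(x)
}
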