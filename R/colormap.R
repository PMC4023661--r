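# Value -> color mapping. Diverging schemes are defined by ordered RGB stops
# at fractions of the display range; interpolation is piecewise-linear per
# sRGB channel with round-half-up, so identical inputs give identical hex
# colors on every platform.

hex_to_rgb <- function(hex) {
  hex <- sub("^#", "", tolower(hex))
  as.integer(strtoi(c(substr(hex, 1, 2), substr(hex, 3, 4),
                      substr(hex, 5, 6)), 16L))
}

rgb_to_hex <- function(rgb) {
  sprintf("#%02x%02x%02x", rgb[1], rgb[2], rgb[3])
}

#' Construct a color scheme
#'
#' @param name scheme name.
#' @param stops data frame with columns `frac` (strictly increasing fractions
#'   of the display range, first 0, last 1) and `color` (`#rrggbb`).
#' @param special named colors for flagged cells: `WILDTYPE` and `MISSING`.
#' @return A `color_scheme` object.
#' @export
color_scheme <- function(name, stops,
                         special = c(WILDTYPE = "#000000",
                                     MISSING = "#cccccc")) {
  stops <- as.data.frame(stops)
  if (stops$frac[1L] != 0 || stops$frac[nrow(stops)] != 1 ||
      any(diff(stops$frac) <= 0))
    hm_abort("RANGE_ERROR",
             "scheme stops must run from fraction 0 to 1, strictly increasing")
  stops$color <- tolower(stops$color)
  structure(list(name = name, stops = stops,
                 special = vapply(special, tolower, character(1))),
            class = "color_scheme")
}

builtin_schemes <- function() {
  list(
    # low expression green, high expression red, black midpoint
    "green-black-red" = color_scheme(
      "green-black-red",
      data.frame(frac = c(0, 0.5, 1),
                 color = c("#00ff00", "#000000", "#ff0000"))),
    # little/no predicted effect dark blue, unpredictable white, strong
    # effect dark red; wildtype cells black
    "blue-white-red" = color_scheme(
      "blue-white-red",
      data.frame(frac = c(0, 0.5, 1),
                 color = c("#00008b", "#ffffff", "#8b0000")))
  )
}

#' Look up a built-in color scheme by name
#'
#' Two diverging schemes are built in: `"green-black-red"` (expression heat
#' maps: low in green, high in red) and `"blue-white-red"` (effect scores:
#' little effect dark blue, unreliable white, strong effect dark red). Both
#' carry the special colors wildtype = black, missing = light grey.
#'
#' @param name scheme name.
#' @return A [color_scheme()].
#' @export
get_scheme <- function(name) {
  schemes <- builtin_schemes()
  if (!name %in% names(schemes))
    hm_abort("UNKNOWN_SCHEME",
             sprintf("unknown scheme '%s'; available: %s", name,
                     paste(names(schemes), collapse = ", ")))
  schemes[[name]]
}

# round-half-up, deterministic across platforms (round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

interp_stops <- function(f, stops) {
  # f in [0,1]; piecewise-linear per channel between bracketing stops
  k <- findInterval(f, stops$frac, rightmost.closed = TRUE)
  k <- max(1L, min(k, nrow(stops) - 1L))
  f0 <- stops$frac[k]; f1 <- stops$frac[k + 1L]
  t <- if (f1 > f0) (f - f0) / (f1 - f0) else 0
  c0 <- hex_to_rgb(stops$color[k]); c1 <- hex_to_rgb(stops$color[k + 1L])
  rgb_to_hex(round_half_up(c0 + t * (c1 - c0)))
}

#' Map a value (and its flag) to a color
#'
#' Flagged cells short-circuit to the scheme's special colors (wildtype black,
#' missing grey). Otherwise `v` is clamped into `[range_min, range_max]` and
#' mapped to a fraction that is 0 at `range_min`, 0.5 at `range_mid` and 1 at
#' `range_max`, piecewise-linearly on each half, then interpolated between the
#' scheme's stops per sRGB channel with round-half-up to integer channels.
#'
#' @param v value (ignored for flagged cells).
#' @param flag `"NONE"`, `"WILDTYPE"` or `"MISSING"`.
#' @param scheme a [color_scheme()].
#' @param range_min,range_mid,range_max display range,
#'   `range_min <= range_mid <= range_max`, `range_min < range_max`.
#' @return A `#rrggbb` hex color string.
#' @examples
#' s <- get_scheme("blue-white-red")
#' value_to_color(-1, "NONE", s, -2, 0, 2) # halfway dark blue -> white
#' @export
value_to_color <- function(v, flag, scheme, range_min, range_mid, range_max) {
  if (range_min >= range_max ||
      range_mid < range_min || range_mid > range_max)
    hm_abort("BAD_RANGE",
             sprintf("need range_min <= range_mid <= range_max with min < max (got %g, %g, %g)",
                     range_min, range_mid, range_max))
  if (flag == "WILDTYPE") return(scheme$special[["WILDTYPE"]])
  if (flag == "MISSING") return(scheme$special[["MISSING"]])
  v <- min(max(v, range_min), range_max)
  f <- if (v <= range_mid) {
    if (range_mid > range_min) 0.5 * (v - range_min) / (range_mid - range_min)
    else 0.5
  } else {
    0.5 + 0.5 * (v - range_mid) / (range_max - range_mid)
  }
  interp_stops(f, scheme$stops)
}

#' Build a scale-bar specification
#'
#' Partitions `[range_min, range_max]` into `n_segments` equal-width value
#' intervals, each colored by [value_to_color()] at its midpoint, with tick
#' values at the range minimum, midpoint and maximum. Rendered below the heat
#' map so readers can map colors back to values.
#'
#' @inheritParams value_to_color
#' @param n_segments number of color swatches, at least 2.
#' @return A `scale_bar` object: `segments` data frame (`lo`, `hi`, `color`),
#'   `tick_values`, and `orientation = "horizontal"`.
#' @export
build_scale_bar <- function(scheme, range_min, range_mid, range_max,
                            n_segments = 64L) {
  if (n_segments < 2L)
    hm_abort("BAD_RANGE", "n_segments must be at least 2")
  if (range_min >= range_max ||
      range_mid < range_min || range_mid > range_max)
    hm_abort("BAD_RANGE", "need range_min <= range_mid <= range_max, min < max")
  edges <- range_min + (range_max - range_min) * (0:n_segments) / n_segments
  lo <- edges[-(n_segments + 1L)]
  hi <- edges[-1L]
  mids <- (lo + hi) / 2
  cols <- vapply(mids, value_to_color, character(1), flag = "NONE",
                 scheme = scheme, range_min = range_min,
                 range_mid = range_mid, range_max = range_max)
  structure(
    list(segments = data.frame(lo = lo, hi = hi, color = cols),
         tick_values = unique(c(range_min, range_mid, range_max)),
         orientation = "horizontal"),
    class = "scale_bar"
  )
}

# Resolve AUTO range fields against the data: (min, max) over unflagged
# cells, symmetrized about 0 when the data spans 0 so the diverging midpoint
# stays meaningful; AUTO midpoint is 0 for a sign-spanning range, else the
# arithmetic midpoint.
resolve_range <- function(m, cfg) {
  rmin <- cfg$range_min; rmax <- cfg$range_max; rmid <- cfg$range_mid
  if (is_auto(rmin) || is_auto(rmax)) {
    vals <- m$values[m$flags == "NONE"]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) vals <- c(0, 1)
    dmin <- min(vals); dmax <- max(vals)
    if (dmin < 0 && dmax > 0) {
      ext <- max(abs(dmin), abs(dmax))
      dmin <- -ext; dmax <- ext
    }
    if (dmin == dmax) { dmin <- dmin - 0.5; dmax <- dmax + 0.5 }
    if (is_auto(rmin)) rmin <- dmin
    if (is_auto(rmax)) rmax <- dmax
  }
  if (is_auto(rmid))
    rmid <- if (rmin < 0 && rmax > 0) 0 else (rmin + rmax) / 2
  list(min = rmin, mid = rmid, max = rmax)
}
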