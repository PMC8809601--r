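#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random number
#' generator state afterwards, so seeded helpers never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Construct an axis-aligned rectangle in projected metres
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds in metres.
#' @return Named numeric vector of class `"rect"`.
#' @examples
#' rect_m(0, 0, 10000, 10000)  # a 100 km^2 block
#' @export
rect_m <- function(xmin, ymin, xmax, ymax) {
  r <- c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  if (any(!is.finite(r))) stop("rectangle bounds must be finite")
  if (xmax <= xmin || ymax <= ymin) stop("rectangle has non-positive extent")
  class(r) <- "rect"
  r
}

#' Area of a rectangle in square metres
#' @param r A rectangle from [rect_m()].
#' @return Area in m^2.
#' @export
rect_area <- function(r) {
  unname((r[["xmax"]] - r[["xmin"]]) * (r[["ymax"]] - r[["ymin"]]))
}

as_rect <- function(r) {
  if (inherits(r, "rect")) return(r)
  if (is.numeric(r) && length(r) == 4) return(rect_m(r[[1]], r[[2]], r[[3]], r[[4]]))
  stop("not a rectangle: expected c(xmin, ymin, xmax, ymax)")
}

# Local metre-true <-> geographic conversion, equirectangular about an anchor.
# Adequate at landscape (tens of km) scale near the equator; the anchor is the
# geographic position of the projected origin (0, 0).
M_PER_DEG_LAT <- 110574

xy_to_lonlat <- function(x, y, origin_lonlat = c(34.25, 0.07)) {
  lat0 <- origin_lonlat[[2]]
  m_per_deg_lon <- M_PER_DEG_LAT * cos(lat0 * pi / 180)
  cbind(lon = origin_lonlat[[1]] + x / m_per_deg_lon,
        lat = lat0 + y / M_PER_DEG_LAT)
}

lonlat_to_xy <- function(lon, lat, origin_lonlat = c(34.25, 0.07)) {
  lat0 <- origin_lonlat[[2]]
  m_per_deg_lon <- M_PER_DEG_LAT * cos(lat0 * pi / 180)
  cbind(x = (lon - origin_lonlat[[1]]) * m_per_deg_lon,
        y = (lat - lat0) * M_PER_DEG_LAT)
}

stop_value <- function(...) stop(..., call. = FALSE)
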