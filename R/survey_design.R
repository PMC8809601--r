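#' Partition a square block into tiles and sub-tiles
#'
#' Builds the hierarchical LDSF sampling frame: a square block divided into a
#' regular grid of `n_tiles` tiles, each tile further divided into
#' `n_subtiles_per_tile` sub-tiles on a regular grid. With the defaults a
#' 100 km^2 block yields 16 tiles of 6.25 km^2.
#'
#' @param extent Square block rectangle from [rect_m()], projected metres.
#' @param n_tiles Number of tiles; must be a perfect square.
#' @param n_subtiles_per_tile Sub-tiles per tile, laid on the most nearly
#'   square `r x c` grid with `r * c = n_subtiles_per_tile`.
#' @return A `sampling_frame`: list with `block`, `tiles` and `subtiles`
#'   data frames (ids plus bounds), empty selections, and the partition
#'   parameters.
#' @examples
#' frame <- partition_block(rect_m(0, 0, 10000, 10000))
#' nrow(frame$tiles)  # 16
#' @export
partition_block <- function(extent, n_tiles = 16, n_subtiles_per_tile = 10) {
  extent <- as_rect(extent)
  w <- extent[["xmax"]] - extent[["xmin"]]
  h <- extent[["ymax"]] - extent[["ymin"]]
  if (rect_area(extent) <= 0) stop_value("block extent has zero area")
  if (abs(w - h) > 1e-6 * max(w, h)) stop_value("block extent must be square")
  k <- sqrt(n_tiles)
  if (n_tiles < 1 || abs(k - round(k)) > 1e-9)
    stop_value("n_tiles must be a perfect square (regular grid)")
  k <- as.integer(round(k))
  if (n_subtiles_per_tile < 1) stop_value("n_subtiles_per_tile must be >= 1")

  tile_w <- w / k
  ij <- expand.grid(col = seq_len(k), row = seq_len(k))
  tiles <- data.frame(
    tile_id = sprintf("T%02d", seq_len(n_tiles)),
    xmin = extent[["xmin"]] + (ij$col - 1) * tile_w,
    ymin = extent[["ymin"]] + (ij$row - 1) * tile_w,
    stringsAsFactors = FALSE
  )
  tiles$xmax <- tiles$xmin + tile_w
  tiles$ymax <- tiles$ymin + tile_w

  # most nearly square factorisation r * c = n, r <= c
  n <- as.integer(n_subtiles_per_tile)
  divs <- seq_len(n)[n %% seq_len(n) == 0]
  r <- max(divs[divs <= sqrt(n)])
  cc <- n %/% r
  sub_w <- tile_w / cc
  sub_h <- tile_w / r
  sub_ij <- expand.grid(col = seq_len(cc), row = seq_len(r))
  subtiles <- do.call(rbind, lapply(seq_len(n_tiles), function(t) {
    data.frame(
      tile_id = tiles$tile_id[t],
      subtile_id = sprintf("%s-S%02d", tiles$tile_id[t], seq_len(n)),
      xmin = tiles$xmin[t] + (sub_ij$col - 1) * sub_w,
      ymin = tiles$ymin[t] + (sub_ij$row - 1) * sub_h,
      stringsAsFactors = FALSE
    )
  }))
  subtiles$xmax <- subtiles$xmin + sub_w
  subtiles$ymax <- subtiles$ymin + sub_h
  rownames(subtiles) <- NULL

  structure(
    list(block = extent, tiles = tiles, subtiles = subtiles,
         selected_tile_ids = character(), selected_subtile_ids = character(),
         n_tiles = n_tiles, n_subtiles_per_tile = n, seed = NA_integer_),
    class = "sampling_frame")
}

#' @export
print.sampling_frame <- function(x, ...) {
  cat(sprintf(
    "LDSF sampling frame: %.2f km^2 block, %d tiles, %d sub-tiles (%d/tile)\n",
    rect_area(x$block) / 1e6, nrow(x$tiles), nrow(x$subtiles),
    x$n_subtiles_per_tile))
  if (length(x$selected_tile_ids))
    cat(sprintf("selected: %d tiles, %d sub-tiles (seed %d)\n",
                length(x$selected_tile_ids), length(x$selected_subtile_ids),
                x$seed))
  invisible(x)
}

#' Randomly select tiles and sub-tiles from a sampling frame
#'
#' Draws `n_tiles_sel` tiles, then `n_subtiles_sel` sub-tiles from within the
#' selected tiles only, balanced across them (any remainder after integer
#' division is spread over randomly chosen selected tiles). The selection is
#' a deterministic function of the frame and the seed.
#'
#' @param frame A `sampling_frame` from [partition_block()].
#' @param n_tiles_sel Number of tiles to select.
#' @param n_subtiles_sel Total number of sub-tiles to select.
#' @param seed Integer seed controlling the draw.
#' @return The frame with `selected_tile_ids` and `selected_subtile_ids` set.
#' @export
select_units <- function(frame, n_tiles_sel = 8, n_subtiles_sel = 32,
                         seed = 1) {
  stopifnot(inherits(frame, "sampling_frame"))
  if (n_tiles_sel > nrow(frame$tiles))
    stop_value("requested more tiles than the frame contains")
  per_tile_avail <- frame$n_subtiles_per_tile
  if (n_subtiles_sel > n_tiles_sel * per_tile_avail)
    stop_value("requested more sub-tiles than available in the selected tiles")

  with_seed(seed, {
    tile_ids <- sort(sample(frame$tiles$tile_id, n_tiles_sel))
    quota <- rep(n_subtiles_sel %/% n_tiles_sel, n_tiles_sel)
    extra <- n_subtiles_sel %% n_tiles_sel
    if (extra > 0) {
      bump <- sample(seq_len(n_tiles_sel), extra)
      quota[bump] <- quota[bump] + 1
    }
    sub_ids <- unlist(lapply(seq_along(tile_ids), function(i) {
      pool <- frame$subtiles$subtile_id[frame$subtiles$tile_id == tile_ids[i]]
      sort(sample(pool, quota[i]))
    }), use.names = FALSE)
    frame$selected_tile_ids <- tile_ids
    frame$selected_subtile_ids <- sub_ids
    frame$seed <- as.integer(seed)
    frame
  })
}

#' Draw candidate field coordinates inside a sub-tile
#'
#' Draws `n_pairs` uniform random points in the sub-tile. Following the field
#' protocol, the first two points are the primary sampling coordinates and any
#' further points are fallbacks, used only when a primary field fails the
#' selection criteria.
#'
#' @param subtile Rectangle of the sub-tile (projected metres).
#' @param n_pairs Number of coordinate pairs to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `y`, `status` (`"primary"` or
#'   `"fallback"`).
#' @export
draw_field_coordinates <- function(subtile, n_pairs = 3, seed = 1) {
  subtile <- as_rect(subtile)
  if (n_pairs < 0) stop_value("n_pairs must be >= 0")
  if (n_pairs == 0)
    return(data.frame(x = numeric(), y = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    data.frame(
      x = runif(n_pairs, subtile[["xmin"]], subtile[["xmax"]]),
      y = runif(n_pairs, subtile[["ymin"]], subtile[["ymax"]]),
      status = ifelse(seq_len(n_pairs) <= 2, "primary", "fallback"),
      stringsAsFactors = FALSE)
  })
}

#' Lay out the Y-frame plot geometry for one field
#'
#' The central plot is placed `offset_m` from the field anchor along
#' `boundary_bearing` (degrees clockwise from north), and three satellite
#' plots are placed `radius_m` from the central plot at bearings
#' `boundary_bearing + 0, 120, 240` degrees, i.e. distributed uniformly at
#' 360 degrees.
#'
#' @param field_anchor Numeric `c(x, y)` of the field boundary anchor (m).
#' @param boundary_bearing Bearing in degrees clockwise from north.
#' @param radius_m Central-to-satellite distance, default 12.2 m.
#' @param offset_m Boundary-to-central-plot distance, default 20 m.
#' @param plot_area_m2 Nominal plot area, default 2.5 m^2.
#' @return A `y_frame`: list with `central` (x, y), `satellites` (3 x 2
#'   matrix), the geometry parameters and the plot labels A (central) and
#'   B-D (satellites, clockwise).
#' @export
layout_y_frame <- function(field_anchor, boundary_bearing = 0,
                           radius_m = 12.2, offset_m = 20,
                           plot_area_m2 = 2.5) {
  if (radius_m < 0) stop_value("radius_m must be >= 0")
  b <- boundary_bearing * pi / 180
  central <- c(x = field_anchor[[1]] + offset_m * sin(b),
               y = field_anchor[[2]] + offset_m * cos(b))
  bearings <- b + c(0, 2, 4) * pi / 3
  satellites <- cbind(x = central[["x"]] + radius_m * sin(bearings),
                      y = central[["y"]] + radius_m * cos(bearings))
  rownames(satellites) <- c("B", "C", "D")
  structure(list(central = central, satellites = satellites,
                 radius_m = radius_m, boundary_offset_m = offset_m,
                 plot_area_m2 = plot_area_m2,
                 boundary_bearing = boundary_bearing),
            class = "y_frame")
}

#' Generate the full plot table for a selected sampling frame
#'
#' For every selected sub-tile, draws candidate field coordinates, keeps the
#' first `fields_per_subtile` primary fields, assigns each a random boundary
#' bearing, and lays a Y-frame of one central plot (A) and three satellites
#' (B-D). The defaults (32 selected sub-tiles, 2 fields each) give 64 fields
#' and 256 plots.
#'
#' @param frame A selected `sampling_frame` (see [select_units()]).
#' @param fields_per_subtile Fields sampled per sub-tile, default 2.
#' @param seed Integer seed for coordinates and bearings.
#' @param radius_m,offset_m Y-frame geometry, see [layout_y_frame()].
#' @param origin_lonlat Geographic anchor `c(lon, lat)` of the projected
#'   origin, used to report lon/lat alongside projected coordinates.
#' @return Data frame with one row per plot: `block_id`, `tile_id`,
#'   `subtile_id`, `field_id`, `plot_id`, `plot_label`, `role`
#'   (`"central"`/`"satellite"`), `x`, `y`, `lon`, `lat`.
#' @export
survey_plots <- function(frame, fields_per_subtile = 2, seed = 1,
                         radius_m = 12.2, offset_m = 20,
                         origin_lonlat = c(34.25, 0.07)) {
  stopifnot(inherits(frame, "sampling_frame"))
  if (!length(frame$selected_subtile_ids))
    stop_value("frame has no selected sub-tiles; call select_units() first")
  subs <- frame$subtiles[match(frame$selected_subtile_ids,
                               frame$subtiles$subtile_id), ]
  rows <- with_seed(seed, {
    out <- vector("list", nrow(subs))
    for (i in seq_len(nrow(subs))) {
      st <- subs[i, ]
      pts <- data.frame(
        x = runif(fields_per_subtile, st$xmin, st$xmax),
        y = runif(fields_per_subtile, st$ymin, st$ymax))
      bearing <- runif(fields_per_subtile, 0, 360)
      fld <- vector("list", fields_per_subtile)
      for (f in seq_len(fields_per_subtile)) {
        yf <- layout_y_frame(c(pts$x[f], pts$y[f]), bearing[f],
                             radius_m = radius_m, offset_m = offset_m)
        field_id <- sprintf("%s-F%d", st$subtile_id, f)
        fld[[f]] <- data.frame(
          block_id = "B1", tile_id = st$tile_id, subtile_id = st$subtile_id,
          field_id = field_id,
          plot_label = c("A", rownames(yf$satellites)),
          role = c("central", rep("satellite", 3)),
          x = c(yf$central[["x"]], yf$satellites[, "x"]),
          y = c(yf$central[["y"]], yf$satellites[, "y"]),
          stringsAsFactors = FALSE)
      }
      out[[i]] <- do.call(rbind, fld)
    }
    do.call(rbind, out)
  })
  rows$plot_id <- paste0(rows$field_id, "-", rows$plot_label)
  ll <- xy_to_lonlat(rows$x, rows$y, origin_lonlat)
  rows$lon <- ll[, "lon"]
  rows$lat <- ll[, "lat"]
  rownames(rows) <- NULL
  attr(rows, "origin_lonlat") <- origin_lonlat
  attr(rows, "radius_m") <- radius_m
  rows[, c("block_id", "tile_id", "subtile_id", "field_id", "plot_id",
           "plot_label", "role", "x", "y", "lon", "lat")]
}

#' Write a plot table as CSV
#' @param plots Plot table from [survey_plots()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plots_csv <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

rect_polygon_lonlat <- function(r, origin_lonlat) {
  corners <- rbind(c(r[["xmin"]], r[["ymin"]]), c(r[["xmax"]], r[["ymin"]]),
                   c(r[["xmax"]], r[["ymax"]]), c(r[["xmin"]], r[["ymax"]]),
                   c(r[["xmin"]], r[["ymin"]]))
  ll <- xy_to_lonlat(corners[, 1], corners[, 2], origin_lonlat)
  lapply(seq_len(nrow(ll)), function(i) c(ll[i, "lon"], ll[i, "lat"]))
}

#' Write a sampling frame as GeoJSON
#'
#' Emits a FeatureCollection of the block, tile and sub-tile polygons in
#' WGS84 longitude/latitude, with ids and selection flags as properties.
#'
#' @param frame A `sampling_frame`.
#' @param path Output file path.
#' @param origin_lonlat Geographic anchor of the projected origin.
#' @return `path`, invisibly.
#' @export
write_frame_geojson <- function(frame, path, origin_lonlat = c(34.25, 0.07)) {
  stopifnot(inherits(frame, "sampling_frame"))
  feat <- function(rect, props) {
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(rect_polygon_lonlat(rect, origin_lonlat))))
  }
  features <- list(feat(frame$block, list(level = "block", id = "B1")))
  for (i in seq_len(nrow(frame$tiles))) {
    t <- frame$tiles[i, ]
    features[[length(features) + 1]] <- feat(
      rect_m(t$xmin, t$ymin, t$xmax, t$ymax),
      list(level = "tile", id = t$tile_id,
           selected = t$tile_id %in% frame$selected_tile_ids))
  }
  for (i in seq_len(nrow(frame$subtiles))) {
    s <- frame$subtiles[i, ]
    features[[length(features) + 1]] <- feat(
      rect_m(s$xmin, s$ymin, s$xmax, s$ymax),
      list(level = "subtile", id = s$subtile_id,
           selected = s$subtile_id %in% frame$selected_subtile_ids))
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write survey plots as a GeoJSON point layer
#'
#' @param plots Plot table from [survey_plots()] (or any data frame with
#'   `lon`/`lat` columns); remaining columns become feature properties.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plots_geojson <- function(plots, path) {
  stopifnot(all(c("lon", "lat") %in% names(plots)))
  keep <- setdiff(names(plots), c("lon", "lat"))
  features <- lapply(seq_len(nrow(plots)), function(i) {
    list(type = "Feature",
         properties = as.list(plots[i, keep, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(plots$lon[i], plots$lat[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
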