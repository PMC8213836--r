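#' Tessellate a square sensor surface into hexagons
#'
#' Divides a square surface of the given side length into equally sized
#' flat-topped hexagons with in-radius `in_radius_nm` and returns their
#' centers. The centers form a triangular lattice with nearest-neighbour
#' spacing `2 * in_radius_nm`, so levers placed on distinct centers can
#' never be closer than that spacing. At the default in-radius of 2.5 nm
#' the minimum possible lever distance is 5 nm, an approximate physical
#' packing limit set by DNA radius and electrostatic repulsion.
#'
#' The lattice is oriented with a row of centers along x, the first center
#' at `(in_radius_nm, in_radius_nm)`; centers strictly inside the square
#' are kept, partial boundary hexagons are dropped. Results are
#' orientation-invariant in distribution for the downstream simulation.
#'
#' @param side_length_nm Side of the square surface in nm. Must be at
#'   least `4 * in_radius_nm`.
#' @param in_radius_nm Hexagon in-radius in nm (default 2.5).
#' @return An object of class `hex_grid`: a list with `side_length_nm`,
#'   `in_radius_nm` and `centers` (a two-column matrix of x/y in nm).
#' @examples
#' g <- build_hex_grid(100)
#' nrow(g$centers)
#' @export
build_hex_grid <- function(side_length_nm, in_radius_nm = 2.5) {
  if (!is.finite(side_length_nm) || side_length_nm <= 0 ||
      !is.finite(in_radius_nm) || in_radius_nm <= 0) {
    stop_invalid("side_length_nm and in_radius_nm must be positive")
  }
  if (side_length_nm < 4 * in_radius_nm) {
    stop_invalid("side_length_nm (%g) must be at least 4 * in_radius_nm (%g)",
                 side_length_nm, 4 * in_radius_nm)
  }
  s <- 2 * in_radius_nm          # center-to-center spacing
  row_h <- in_radius_nm * sqrt(3) # vertical distance between lattice rows
  n_rows <- floor((side_length_nm - in_radius_nm) / row_h) + 1
  rows <- lapply(seq_len(n_rows) - 1L, function(j) {
    y <- in_radius_nm + j * row_h
    x0 <- in_radius_nm + (j %% 2) * in_radius_nm # odd rows shifted half a step
    x <- seq(x0, side_length_nm, by = s)
    x <- x[x < side_length_nm]
    cbind(x = x, y = rep(y, length(x)))
  })
  centers <- do.call(rbind, rows)
  structure(
    list(side_length_nm = side_length_nm,
         in_radius_nm = in_radius_nm,
         centers = centers),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %g nm square, in-radius %g nm, %d hexagon centers\n",
              x$side_length_nm, x$in_radius_nm, nrow(x$centers)))
  invisible(x)
}

#' Per-hexagon occupancy probability for a target mean lever distance
#'
#' A hexagon holds a lever with probability equal to the ratio of its area
#' to the area of a hexagon with in-radius `mean_distance_nm / 2`. The
#' hexagon area constant cancels, leaving the squared ratio of in-radii,
#' so on average one lever falls per hexagon of in-radius `d / 2` and the
#' target mean inter-lever distance `d` is realized.
#'
#' @param mean_distance_nm Target mean inter-lever distance d in nm.
#' @param in_radius_nm Tessellation in-radius in nm (default 2.5).
#' @return Probability in `[0, 1]`, clamped at 1 when `d <= 2 * in_radius`.
#' @examples
#' occupancy_probability(50)  # 0.01
#' occupancy_probability(200) # 0.000625
#' @export
occupancy_probability <- function(mean_distance_nm, in_radius_nm = 2.5) {
  if (!is.finite(mean_distance_nm) || mean_distance_nm <= 0) {
    stop_invalid("mean_distance_nm must be positive")
  }
  if (!is.finite(in_radius_nm) || in_radius_nm <= 0) {
    stop_invalid("in_radius_nm must be positive")
  }
  min(1, (in_radius_nm / (mean_distance_nm / 2))^2)
}

#' Stochastically place DNA nanolevers on a hexagonal grid
#'
#' Draws an independent Bernoulli variable per hexagon center with the
#' occupancy probability from [occupancy_probability()], so the levers are
#' stochastically distributed but maintain the given average distance.
#' Placement is fully reproducible for a fixed seed.
#'
#' @param grid A `hex_grid` from [build_hex_grid()].
#' @param mean_distance_nm Target mean inter-lever distance in nm; must be
#'   at least `2 * grid$in_radius_nm` (a denser field cannot be realized).
#' @param seed Integer seed for the placement draw.
#' @return An object of class `lever_field`: a list with `anchors`
#'   (two-column matrix of x/y in nm), `mean_distance_nm`, `occupancy_p`,
#'   `seed`, `in_radius_nm` and `side_length_nm`.
#' @examples
#' g <- build_hex_grid(500)
#' f <- place_levers(g, mean_distance_nm = 50, seed = 1)
#' nrow(f$anchors)
#' @export
place_levers <- function(grid, mean_distance_nm, seed) {
  if (!inherits(grid, "hex_grid")) stop_invalid("grid must be a hex_grid")
  if (!is.finite(mean_distance_nm) ||
      mean_distance_nm < 2 * grid$in_radius_nm) {
    stop_invalid(
      "mean_distance_nm (%g) must be at least 2 * in_radius_nm (%g)",
      mean_distance_nm, 2 * grid$in_radius_nm)
  }
  p <- occupancy_probability(mean_distance_nm, grid$in_radius_nm)
  occupied <- with_seed(seed, runif(nrow(grid$centers)) < p)
  anchors <- grid$centers[occupied, , drop = FALSE]
  structure(
    list(anchors = anchors,
         mean_distance_nm = mean_distance_nm,
         occupancy_p = p,
         seed = as.integer(seed),
         in_radius_nm = grid$in_radius_nm,
         side_length_nm = grid$side_length_nm),
    class = "lever_field"
  )
}

#' @export
print.lever_field <- function(x, ...) {
  cat(sprintf(
    "<lever_field> %d levers on %g nm square (mean distance %g nm, p = %g, seed %d)\n",
    nrow(x$anchors), x$side_length_nm, x$mean_distance_nm, x$occupancy_p,
    x$seed))
  invisible(x)
}

#' Write / read a lever field as CSV plus JSON sidecar
#'
#' The CSV carries `lever_id,x_nm,y_nm`; the sidecar (`<path>.json`)
#' carries the generating parameters `side_length_nm`, `in_radius_nm`,
#' `mean_distance_nm` and `seed`, so a written field round-trips exactly.
#'
#' @param field A `lever_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lever_field <- function(field, path) {
  stopifnot(inherits(field, "lever_field"))
  df <- data.frame(lever_id = seq_len(nrow(field$anchors)),
                   x_nm = field$anchors[, 1],
                   y_nm = field$anchors[, 2])
  write.csv(df, path, row.names = FALSE)
  meta <- list(side_length_nm = field$side_length_nm,
               in_radius_nm = field$in_radius_nm,
               mean_distance_nm = field$mean_distance_nm,
               seed = field$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lever_field
#' @export
read_lever_field <- function(path) {
  df <- read.csv(path)
  if (!all(c("lever_id", "x_nm", "y_nm") %in% names(df))) {
    stop_invalid("lever field CSV must have columns lever_id,x_nm,y_nm")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(side_length_nm = NA_real_, in_radius_nm = 2.5,
         mean_distance_nm = NA_real_, seed = NA_integer_)
  }
  structure(
    list(anchors = cbind(x = df$x_nm, y = df$y_nm),
         mean_distance_nm = meta$mean_distance_nm,
         occupancy_p = if (is.na(meta$mean_distance_nm)) NA_real_ else
           occupancy_probability(meta$mean_distance_nm, meta$in_radius_nm),
         seed = as.integer(meta$seed),
         in_radius_nm = meta$in_radius_nm,
         side_length_nm = meta$side_length_nm),
    class = "lever_field"
  )
}
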