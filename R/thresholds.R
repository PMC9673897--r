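#' Hexagonal-packing spacing model
#'
#' The population-density score rests on an idealised model of perfectly
#' spaced people on a hexagonal tessellation: each person occupies one
#' hexagon, standing at its centroid, and the apothem `d` (centre to side
#' midpoint) is half the centre-to-centre spacing. A 2 m distancing
#' requirement with freedom to move corresponds to an apothem of 3 m. The
#' apothem is swept from `d_min` to `d_max` in steps of `d_step` to produce
#' the score thresholds.
#'
#' @param d_min,d_max,d_step apothem range and increment in metres
#'   (defaults 3, 11, 1).
#' @return an object of class `spacing_model`.
#' @seealso [build_threshold_table()], [hexagon_area()], [max_density()]
#' @export
spacing_model <- function(d_min = 3, d_max = 11, d_step = 1) {
  if (d_min < 1) stop("d_min must be >= 1 m")
  if (d_max <= d_min) stop("d_max must exceed d_min")
  if (d_step <= 0) stop("d_step must be positive")
  k <- (d_max - d_min) / d_step
  if (abs(k - round(k)) > 1e-9)
    stop("(d_max - d_min) must be divisible by d_step")
  structure(list(d_min = d_min, d_max = d_max, d_step = d_step),
            class = "spacing_model")
}

#' Area of a regular hexagon from its apothem
#'
#' A regular hexagon with apothem `d` has area `2 * sqrt(3) * d^2`. An
#' apothem of 3 m gives 31.18 m^2 (2 dp), the space one person needs to keep
#' 2 m from everyone while remaining free to move.
#'
#' @param apothem apothem in metres (> 0); vectorised.
#' @return area in m^2 (unrounded).
#' @export
hexagon_area <- function(apothem) {
  if (any(!is.finite(apothem)) || any(apothem <= 0))
    stop("apothem must be positive")
  2 * sqrt(3) * apothem^2
}

#' Maximum population density for a given spacing apothem
#'
#' One person per hexagon of apothem `d` corresponds to a density of
#' `1e6 / hexagon_area(d)` persons per km^2 (31.18 m^2 per person is
#' 32,075 per km^2; 419.16 m^2 is 2,386 per km^2). The unrounded area is
#' used; printed values are nearest-integer renderings.
#'
#' @inheritParams hexagon_area
#' @return density in persons per km^2 (unrounded).
#' @export
max_density <- function(apothem) {
  1e6 / hexagon_area(apothem)
}

#' Build the population-score threshold table
#'
#' One row per apothem in `seq(d_min, d_max, d_step)`, with the hexagon area,
#' the maximum sustainable density `T(d)` and the population score assigned
#' to densities in `[T(d), T(d - d_step))`. With the default model the scores
#' run 10 (3 m) down to 2 (11 m); densities at or above `T(d_min)` score 10
#' and non-zero densities below `T(d_max)` score 1.
#'
#' @param model a [spacing_model()].
#' @param scores integer scores for the rows, decreasing; by default
#'   `10, 9, ..., 2`, which requires exactly 9 rows.
#' @return data.frame of class `spacing_thresholds` with columns `apothem_m`,
#'   `hex_area_m2`, `max_density_km2`, `pop_score`.
#' @export
build_threshold_table <- function(model = spacing_model(), scores = NULL) {
  stopifnot(inherits(model, "spacing_model"))
  d <- seq(model$d_min, model$d_max, by = model$d_step)
  if (is.null(scores)) {
    if (length(d) != 9L)
      stop("model has ", length(d), " steps; the default score range 10..2 ",
           "needs exactly 9 - supply `scores` explicitly")
    scores <- 10:2
  }
  scores <- as.integer(scores)
  if (length(scores) != length(d))
    stop("need one score per apothem step")
  if (length(scores) > 1L && any(diff(scores) >= 0))
    stop("scores must be strictly decreasing")
  tab <- data.frame(apothem_m = d,
                    hex_area_m2 = hexagon_area(d),
                    max_density_km2 = max_density(d),
                    pop_score = scores)
  class(tab) <- c("spacing_thresholds", "data.frame")
  tab
}

#' @export
print.spacing_thresholds <- function(x, ...) {
  cat("Population-density score thresholds (hexagonal spacing model)\n")
  shown <- data.frame(apothem_m = x$apothem_m,
                      hex_area_m2 = round(x$hex_area_m2, 2),
                      max_density_km2 = round(x$max_density_km2),
                      pop_score = x$pop_score)
  print.data.frame(shown, row.names = FALSE, ...)
  invisible(x)
}

#' Export the threshold table as delimited text
#'
#' @param table a `spacing_thresholds` table.
#' @param path output path; tab-separated with a header.
#' @return `path`, invisibly.
#' @export
write_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "spacing_thresholds"))
  out <- data.frame(apothem = table$apothem_m,
                    area_m2 = table$hex_area_m2,
                    max_density_per_km2 = table$max_density_km2,
                    pop_score = table$pop_score)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
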