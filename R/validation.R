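# Technical-validation comparisons: settlement-type classification of units
# and score-distribution summaries.

#' Classify units as informal settlements by area overlap
#'
#' A unit is `Informal` when at least `threshold` (default 50%) of its area
#' lies within the informal-settlement polygons; otherwise `Other`. Used when
#' the informal-settlement reference is an extent-polygon map.
#'
#' @param records a `score_records` object.
#' @param informal_polygons list of informal-settlement regions (unit CRS).
#' @param threshold minimum overlap fraction (inclusive).
#' @return data.frame of class `settlement_classmap`: `unit_ID`, `class`,
#'   `overlap` plus the rule used.
#' @export
assign_by_area_overlap <- function(records, informal_polygons, threshold = 0.5) {
  stopifnot(inherits(records, "score_records"))
  inf_union <- rc_union(lapply(informal_polygons, as_region))
  frac <- vapply(seq_along(records$geometry), function(i) {
    g <- as_region(records$geometry[[i]])
    a <- region_area(g)
    if (a <= 0) return(0)
    ov <- rc_intersect(g, inf_union)
    if (length(ov) == 0L) 0 else region_area(ov) / a
  }, numeric(1))
  out <- data.frame(unit_ID = records$unit_ID,
                    class = ifelse(frac >= threshold, "Informal", "Other"),
                    overlap = frac, stringsAsFactors = FALSE)
  attr(out, "rule_used") <- "area_overlap"
  class(out) <- c("settlement_classmap", "data.frame")
  out
}

#' Classify units by the majority settlement type of their buildings
#'
#' Each unit takes the modal type label of the buildings intersecting it
#' (building-level settlement maps). Ties and units without buildings
#' default to `Other`; ties are reported in a message.
#'
#' @param records a `score_records` object.
#' @param buildings `list(regions = <list of regions>, type = <character>)`
#'   with labels `"Informal"` / `"Other"` (any non-Informal label counts as
#'   Other).
#' @return a `settlement_classmap` data.frame.
#' @export
assign_by_majority_type <- function(records, buildings) {
  stopifnot(inherits(records, "score_records"),
            length(buildings$regions) == length(buildings$type))
  labs <- ifelse(buildings$type == "Informal", "Informal", "Other")
  bboxes <- lapply(buildings$regions, function(r) region_bbox(as_region(r)))
  n_ties <- 0L
  cls <- vapply(seq_along(records$geometry), function(i) {
    g <- as_region(records$geometry[[i]])
    bb <- region_bbox(g)
    touching <- vapply(seq_along(buildings$regions), function(k) {
      fb <- bboxes[[k]]
      if (fb["xmin"] > bb["xmax"] || bb["xmin"] > fb["xmax"] ||
          fb["ymin"] > bb["ymax"] || bb["ymin"] > fb["ymax"]) return(FALSE)
      regions_overlap(g, buildings$regions[[k]])
    }, logical(1))
    if (!any(touching)) return("Other")
    tab <- table(labs[touching])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) { n_ties <<- n_ties + 1L; return("Other") }
    top
  }, character(1))
  if (n_ties > 0L)
    message(n_ties, " unit(s) with tied majority type assigned to 'Other'")
  out <- data.frame(unit_ID = records$unit_ID, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "rule_used") <- "majority_building_type"
  class(out) <- c("settlement_classmap", "data.frame")
  out
}

#' Joint distribution of population and built scores by settlement class
#'
#' For each settlement class, the proportion of (scored) units with each
#' observed combination of population-density and built scores. Units with
#' nodata scores are excluded; within-class proportions sum to 1.
#'
#' @param records a `score_records` object.
#' @param classmap a `settlement_classmap`.
#' @return data.frame with `POPscore`, `BUILTscore`, `class`, `n`,
#'   `proportion`.
#' @export
joint_score_distribution <- function(records, classmap) {
  d <- records$data
  cls <- classmap$class[match(records$unit_ID, classmap$unit_ID)]
  keep <- d$POPscore != -99 & d$BUILTscore != -99
  d <- d[keep, , drop = FALSE]; cls <- cls[keep]
  out <- list()
  for (cl in sort(unique(classmap$class))) {
    sub <- d[cls == cl, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no scored units in class '", cl, "'")
      next
    }
    tab <- as.data.frame(table(POPscore = sub$POPscore,
                               BUILTscore = sub$BUILTscore),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      POPscore = as.integer(tab$POPscore),
      BUILTscore = as.integer(tab$BUILTscore),
      class = cl, n = tab$Freq,
      proportion = tab$Freq / nrow(sub),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-class proportion of units at or above a score threshold
#'
#' @param records a `score_records` object.
#' @param classmap a `settlement_classmap`.
#' @param field `"POPscore"`, `"BUILTscore"` or `"INDEXvalue"`.
#' @param threshold exceedance threshold (proportion of units with
#'   `field >= threshold` is reported, nodata units excluded).
#' @return named numeric vector of per-class proportions.
#' @export
score_exceedance <- function(records, classmap,
                             field = c("POPscore", "BUILTscore", "INDEXvalue"),
                             threshold) {
  field <- match.arg(field)
  d <- records$data
  cls <- classmap$class[match(records$unit_ID, classmap$unit_ID)]
  keep <- d$POPscore != -99
  vals <- d[[field]][keep]; cls <- cls[keep]
  vapply(split(vals, cls), function(v) mean(v >= threshold), numeric(1))
}

#' Export a validation table as delimited text
#'
#' @param x a data.frame (e.g. from [joint_score_distribution()]).
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_validation_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
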