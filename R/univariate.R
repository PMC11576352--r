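# Per-variable box statistics (min / Q1 / median / Q3 / max) by class or
# whole cohort, and placement of one sample within its group's distribution.

#' Box statistics per variable and group
#'
#' Computes the five-number summary (min, first quartile, median, third
#' quartile, max) of every chemical-shift variable, either per annotated
#' class or over the whole cohort. Quartiles use linear interpolation of
#' order statistics (the type-7 convention); a group of one sample reports
#' all five numbers equal to its single value.
#'
#' @param m A [spectra_matrix].
#' @param annotations Annotation data frame (`sample_id`, `class`); required
#'   for `grouping = "by_class"`, where every sample must be annotated.
#' @param grouping `"by_class"` or `"whole"`.
#' @return Data frame of class `box_stats` with columns `ppm`, `group`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max` (one row per variable x group).
#' @export
box_stats <- function(m, annotations = NULL,
                      grouping = c("by_class", "whole")) {
  grouping <- match.arg(grouping)
  ids <- sample_ids(m)
  if (grouping == "by_class") {
    if (is.null(annotations)) stop("by_class grouping requires annotations")
    cls <- annotations$class[match(ids, annotations$sample_id)]
    if (anyNA(cls))
      stop("unannotated sample(s): ", paste(ids[is.na(cls)], collapse = ", "))
    groups <- split(seq_along(ids), cls)
  } else {
    groups <- list(all = seq_along(ids))
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    Xg <- m$X[groups[[g]], , drop = FALSE]
    qs <- apply(Xg, 2, stats::quantile, probs = c(0, .25, .5, .75, 1),
                type = 7, names = FALSE)
    data.frame(ppm = m$ppm, group = g, n = nrow(Xg),
               min = qs[1, ], q1 = qs[2, ], median = qs[3, ],
               q3 = qs[4, ], max = qs[5, ], row.names = NULL)
  }))
  class(out) <- c("box_stats", "data.frame")
  out
}

#' Place a sample within its group's distribution at one variable
#'
#' Reports where one sample sits relative to its class at a chosen chemical
#' shift: its value, the group, its percentile (midrank of the value among
#' the group values, divided by the group size, so a unique maximum scores
#' exactly 1), and whether the value lies inside the interquartile range.
#'
#' @param m A [spectra_matrix].
#' @param annotations Annotation data frame (`sample_id`, `class`).
#' @param sample_id Sample to place.
#' @param ppm Chemical shift, snapped to the nearest grid point.
#' @param grouping `"by_class"` (place within the sample's class) or
#'   `"whole"` (within the full cohort).
#' @return List with `sample_id`, `ppm` (snapped), `value`, `group`, `n`,
#'   `percentile`, `inside_iqr`, `q1`, `q3`.
#' @export
locate_sample <- function(m, annotations, sample_id, ppm,
                          grouping = c("by_class", "whole")) {
  grouping <- match.arg(grouping)
  ids <- sample_ids(m)
  if (!sample_id %in% ids) stop("unknown sample id: ", sample_id)
  d <- snap_ppm(m$ppm, ppm)
  if (grouping == "by_class") {
    g <- annotations$class[match(sample_id, annotations$sample_id)]
    if (is.na(g)) stop("sample not annotated: ", sample_id)
    members <- ids[ids %in% annotations$sample_id[annotations$class == g]]
  } else {
    g <- "all"
    members <- ids
  }
  vals <- m$X[members, d]
  v <- m$X[sample_id, d]
  n <- length(vals)
  percentile <- (sum(vals < v) + (sum(vals == v) + 1) / 2) / n
  qs <- stats::quantile(vals, probs = c(.25, .75), type = 7, names = FALSE)
  list(sample_id = sample_id, ppm = m$ppm[d], value = v, group = g, n = n,
       percentile = percentile,
       inside_iqr = v >= qs[1] && v <= qs[2], q1 = qs[1], q3 = qs[2])
}
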