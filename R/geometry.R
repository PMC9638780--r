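#' Electrode array: a 32-channel planar skull-surface grid
#'
#' Validates and stores the channel table of a 32-electrode surface grid:
#' integer channel ids, anatomical labels, planar anterior-posterior (AP) and
#' medial-lateral (ML) coordinates in mm relative to bregma, hemisphere, and a
#' rostral/middle/caudal region class. Pairwise distances are plain Euclidean
#' distances on the (AP, ML) plane.
#'
#' @param table a data.frame with columns `id`, `label`, `ap_mm`, `ml_mm`,
#'   `hemisphere` (left/right/midline), `region_class` (rostral/middle/caudal)
#' @return an object of class `electrode_array` (a validated data.frame)
#' @export
electrode_array <- function(table) {
  req <- c("id", "label", "ap_mm", "ml_mm", "hemisphere", "region_class")
  if (!all(req %in% names(table)))
    stop("missing columns: ", paste(setdiff(req, names(table)), collapse = ", "))
  if (nrow(table) != 32L)
    stop("wrong row count: expected 32 channels, got ", nrow(table))
  if (anyDuplicated(table$id))
    stop("duplicate channel ids")
  if (any(!is.finite(table$ap_mm)) || any(!is.finite(table$ml_mm)))
    stop("missing coordinates")
  if (anyDuplicated(table[, c("ap_mm", "ml_mm")]))
    stop("duplicate coordinate pairs")
  if (!all(table$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left/right/midline")
  if (!all(table$region_class %in% c("rostral", "middle", "caudal")))
    stop("region_class must be rostral/middle/caudal")
  tab <- table[order(table$id), req]
  rownames(tab) <- NULL
  class(tab) <- c("electrode_array", "data.frame")
  tab
}

#' Load an electrode layout table from CSV
#'
#' @param path CSV file with header `id,label,ap_mm,ml_mm,hemisphere,region_class`
#' @return an `electrode_array`
#' @export
load_electrode_array <- function(path) {
  electrode_array(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The packaged default 32-channel grid layout
#'
#' A synthetic planar layout emulating a commercial 32-channel rodent
#' skull-surface grid: 4 columns by 8 rows, shortest inter-electrode distance
#' 1.3 mm and longest 13.9 mm.
#'
#' @return an `electrode_array`
#' @export
default_electrode_array <- function() {
  load_electrode_array(system.file("extdata", "layout32_synthetic.csv",
                                   package = "sleepcoh", mustWork = TRUE))
}

#' Pairwise Euclidean distances between electrodes
#'
#' @param array an `electrode_array`
#' @return symmetric 32 x 32 matrix of distances in mm, dimnames = channel ids
#' @export
pairwise_distances <- function(array) {
  stopifnot(inherits(array, "electrode_array"))
  d <- as.matrix(stats::dist(array[, c("ap_mm", "ml_mm")]))
  dimnames(d) <- list(array$id, array$id)
  d
}

#' Partition electrode pairs by a distance threshold
#'
#' All 496 unordered channel pairs are split into a short set (distance <=
#' threshold) and a long set (distance > threshold); pairs at exactly the
#' threshold distance are assigned to the short set.
#'
#' @param array an `electrode_array`
#' @param threshold_mm distance threshold in mm, within \[1, 14\]
#' @param side `"short"` or `"long"`
#' @return a `pair_set`: list with `threshold_mm`, `side`, and `pairs`, a
#'   data.frame of columns `chan_a`, `chan_b` (ids, `chan_a < chan_b`), `dist_mm`
#' @export
pairs_by_threshold <- function(array, threshold_mm, side = c("short", "long")) {
  side <- match.arg(side)
  if (!is.finite(threshold_mm) || threshold_mm < 1 || threshold_mm > 14)
    stop("threshold outside physical range [1, 14] mm")
  d <- pairwise_distances(array)
  ids <- array$id
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(chan_a = ids[idx[, 1]], chan_b = ids[idx[, 2]],
                      dist_mm = d[idx])
  keep <- if (side == "short") pairs$dist_mm <= threshold_mm
          else pairs$dist_mm > threshold_mm
  out <- list(threshold_mm = threshold_mm, side = side,
              pairs = pairs[keep, , drop = FALSE])
  rownames(out$pairs) <- NULL
  class(out) <- "pair_set"
  out
}

## hemisphere x region_class group label for each channel
region_group <- function(array) paste(array$hemisphere, array$region_class)

#' All unordered pairs of regional channel groups
#'
#' Regions are the 6 hemisphere-by-class groups (left/right x
#' rostral/middle/caudal); used for region-averaged dynamic connectivity.
#'
#' @param array an `electrode_array`
#' @return data.frame with 15 rows, columns `region_a`, `region_b`
#' @export
region_pairs <- function(array) {
  stopifnot(inherits(array, "electrode_array"))
  grp <- region_group(array)
  want <- as.vector(outer(c("left", "right"), c("rostral", "middle", "caudal"),
                          paste))
  n <- table(factor(grp, levels = want))
  if (any(n == 0))
    stop("empty region group: ", paste(names(n)[n == 0], collapse = ", "))
  cmb <- utils::combn(sort(want), 2)
  data.frame(region_a = cmb[1, ], region_b = cmb[2, ])
}

#' Channel ids belonging to one regional group
#'
#' @param array an `electrode_array`
#' @param region group label, e.g. `"right middle"`
#' @return integer vector of channel ids
#' @export
region_channels <- function(array, region) {
  ids <- array$id[region_group(array) == region]
  if (length(ids) == 0) stop("empty region group: ", region)
  ids
}

#' @export
print.electrode_array <- function(x, ...) {
  cat("<electrode_array> 32 channels\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  cat("...\n")
  invisible(x)
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> side=%s threshold=%g mm: %d pairs\n",
              x$side, x$threshold_mm, nrow(x$pairs)))
  invisible(x)
}
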