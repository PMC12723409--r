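#' Ellipse parameters from second-order image moments
#'
#' Fits an ellipse to a pixel blob via the eigendecomposition of the
#' normalized second central moments (regionprops convention): axis lengths
#' are \eqn{4\sqrt{\lambda}} and eccentricity is
#' \eqn{\sqrt{1 - \lambda_{min}/\lambda_{max}}}.
#'
#' @param coords Two-column matrix of pixel coordinates (row, col).
#' @return List with `major_px`, `minor_px`, `eccentricity`.
#' @export
moments_ellipse <- function(coords) {
  n <- nrow(coords)
  if (n < 1) stop("empty blob")
  if (n == 1) return(list(major_px = 1, minor_px = 1, eccentricity = 0))
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  S <- crossprod(cc) / n
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0] <- 0
  list(major_px = 4 * sqrt(ev[2]), minor_px = 4 * sqrt(ev[1]),
       eccentricity = if (ev[2] > 0) sqrt(max(0, 1 - ev[1] / ev[2])) else 0)
}

#' Isolate myelinated-axon candidates from a label mask
#'
#' Blob analysis on the axon class: 8-connected axon components are labeled,
#' holes inside each axon blob are filled, and every myelin pixel is assigned
#' to its geodesically nearest axon component, which separates the shared
#' myelin of adjacent fibers. Myelin regions with no reachable axon are
#' counted as orphans.
#'
#' @param mask A `label_mask`.
#' @return A list of class `axon_candidates`: `candidates` (each with
#'   `axon_idx` and `myelin_idx` coordinate matrices), `n_orphan_myelin`
#'   (myelin components not assignable to any axon), `dims`, `pixel_size`,
#'   `preparation`.
#' @export
extract_axon_instances <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  cls <- mask$classes
  ax <- cls == 1L
  my <- cls == 2L
  dims <- dim(cls)
  if (!any(ax)) {
    orphans <- if (any(my)) max(EBImage::bwlabel(my * 1)) else 0L
    return(structure(list(candidates = list(), n_orphan_myelin = orphans,
                          dims = dims, pixel_size = mask$pixel_size,
                          preparation = mask$preparation),
                     class = "axon_candidates"))
  }
  lab <- EBImage::fillHull(EBImage::bwlabel(ax * 1))
  lab <- matrix(as.integer(lab), dims[1], dims[2])
  ax_filled <- lab > 0L
  my <- my & !ax_filled # hole filling takes precedence over stray myelin
  assigned <- EBImage::propagate(matrix(0, dims[1], dims[2]), seeds = lab,
                                 mask = (ax_filled | my) * 1)
  assigned <- matrix(as.integer(assigned), dims[1], dims[2])
  n_lab <- max(lab)
  empty <- matrix(0L, 0, 2, dimnames = list(NULL, c("row", "col")))
  pos_ax <- which(lab > 0L)
  ax_by_label <- split(pos_ax, lab[pos_ax])
  pos_my <- which(my & assigned > 0L)
  my_by_label <- split(pos_my, assigned[pos_my])
  cands <- lapply(seq_len(n_lab), function(i) {
    key <- as.character(i)
    ai <- ax_by_label[[key]]
    mi <- my_by_label[[key]]
    list(id = i,
         axon_idx = if (is.null(ai)) empty else arrayInd(ai, dims),
         myelin_idx = if (is.null(mi)) empty else arrayInd(mi, dims))
  })
  orphan_px <- my & assigned == 0L
  orphans <- if (any(orphan_px)) max(EBImage::bwlabel(orphan_px * 1)) else 0L
  structure(list(candidates = cands, n_orphan_myelin = as.integer(orphans),
                 dims = dims, pixel_size = mask$pixel_size,
                 preparation = mask$preparation),
            class = "axon_candidates")
}

## fraction of axon boundary pixels with >= 1 myelin pixel among their
## 8-neighbours; boundary = axon pixels with a non-axon 8-neighbour
.myelin_coverage <- function(axon_idx, myelin_idx, dims) {
  if (!nrow(myelin_idx)) return(0)
  ## work in the blob's bounding box (1-px margin) for speed
  r_off <- max(1L, min(axon_idx[, 1]) - 1L)
  c_off <- max(1L, min(axon_idx[, 2]) - 1L)
  nr <- min(dims[1], max(axon_idx[, 1]) + 1L) - r_off + 1L
  nc <- min(dims[2], max(axon_idx[, 2]) + 1L) - c_off + 1L
  ar <- axon_idx[, 1] - r_off + 1L; ac <- axon_idx[, 2] - c_off + 1L
  in_ax <- matrix(FALSE, nr, nc); in_ax[cbind(ar, ac)] <- TRUE
  in_my <- matrix(FALSE, nr, nc)
  keep <- myelin_idx[, 1] >= r_off & myelin_idx[, 1] < r_off + nr &
    myelin_idx[, 2] >= c_off & myelin_idx[, 2] < c_off + nc
  in_my[cbind(myelin_idx[keep, 1] - r_off + 1L,
              myelin_idx[keep, 2] - c_off + 1L)] <- TRUE
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  ## off-image pixels count as outside the blob, but the mask-boundary
  ## clamp above means axon pixels on the image edge see the margin row
  boundary <- rep(FALSE, nrow(axon_idx))
  touched <- rep(FALSE, nrow(axon_idx))
  at_edge <- axon_idx[, 1] == 1L | axon_idx[, 1] == dims[1] |
    axon_idx[, 2] == 1L | axon_idx[, 2] == dims[2]
  boundary <- boundary | at_edge
  for (k in seq_len(nrow(off))) {
    r <- ar + off$dr[k]; c <- ac + off$dc[k]
    inside <- r >= 1 & r <= nr & c >= 1 & c <= nc
    lin <- pmax(r, 1L) + nr * (pmax(c, 1L) - 1L)
    boundary <- boundary | !(inside & in_ax[lin])
    touched <- touched | (inside & in_my[lin])
  }
  if (!any(boundary)) return(1)
  mean(touched[boundary])
}

#' Measure a single axon candidate
#'
#' Inner and outer ellipses are fitted to the axon pixels and to the
#' axon-plus-myelin pixels by second-order image moments; the inner diameter
#' is the inner minor axis scaled by the pixel size (the minor axis, rather
#' than an equivalent-area diameter, so obliquely sectioned axons are not
#' overestimated), the outer diameter likewise, and g-ratio and myelin
#' thickness follow.
#'
#' @param candidate One element of `extract_axon_instances()$candidates`.
#' @param pixel_size Pixel edge length, \eqn{\mu m}.
#' @param dims Mask dimensions (rows, cols).
#' @param border_px Border margin for the truncation flag (default 4).
#' @return A one-row data.frame (`axon_record`): `id`, `inner_diameter`,
#'   `outer_diameter`, `myelin_thickness`, `g`, `eccentricity`,
#'   `myelin_coverage`, `touches_border`, `area_px`.
#' @export
measure_axon <- function(candidate, pixel_size, dims, border_px = 4L) {
  ai <- candidate$axon_idx
  mi <- candidate$myelin_idx
  inner <- moments_ellipse(ai)
  allpx <- rbind(ai, mi)
  outer <- moments_ellipse(allpx)
  inner_d <- inner$minor_px * pixel_size
  outer_d <- outer$minor_px * pixel_size
  border <- any(allpx[, 1] <= border_px | allpx[, 2] <= border_px |
                allpx[, 1] > dims[1] - border_px |
                allpx[, 2] > dims[2] - border_px)
  data.frame(
    id = candidate$id,
    cx = mean(ai[, 2]), cy = mean(ai[, 1]),
    inner_diameter = inner_d,
    outer_diameter = outer_d,
    myelin_thickness = (outer_d - inner_d) / 2,
    g = if (outer_d > 0) inner_d / outer_d else NA_real_,
    eccentricity = inner$eccentricity,
    myelin_coverage = .myelin_coverage(ai, mi, dims),
    touches_border = border,
    area_px = nrow(ai))
}

#' Filter axon candidates by the preparation-specific rejection rules
#'
#' Applies, in order: unmyelinated (no assigned myelin), minimum blob area,
#' border overlap (any blob pixel within the 4-pixel image margin),
#' insufficient myelin perimeter coverage, and excessive eccentricity.
#' Thresholds depend on the preparation: conventional dehydrated material
#' (`epon`) uses coverage >= 0.95 and eccentricity <= 0.92; cryo-fixed
#' material (`cryo`) uses 0.85 and 0.975. Every exclusion is tallied by its
#' (first triggered) reason, so accepted + exclusions = candidates.
#'
#' @param extraction An `axon_candidates` object.
#' @param preparation `"epon"` or `"cryo"`; defaults to the mask's.
#' @param coverage_min,eccentricity_max Optional threshold overrides.
#' @param border_px Border margin, px (default 4).
#' @param min_area_px Minimum axon blob area for a meaningful moment ellipse
#'   (default 10 px).
#' @return A `morphometry_result`: `records` (accepted `axon_record` rows),
#'   `counts` (named: accepted and each exclusion reason, plus
#'   `myelin_without_axon` orphans), `n_candidates`.
#' @export
filter_axon_instances <- function(extraction, preparation = NULL,
                                  coverage_min = NULL, eccentricity_max = NULL,
                                  border_px = 4L, min_area_px = 10L) {
  stopifnot(inherits(extraction, "axon_candidates"))
  preparation <- preparation %||% extraction$preparation
  if (!preparation %in% c("epon", "cryo"))
    stop("config error: unknown preparation '", preparation, "'")
  defaults <- default_config()$morpho[[preparation]]
  coverage_min <- coverage_min %||% defaults$coverage_min
  eccentricity_max <- eccentricity_max %||% defaults$eccentricity_max
  reasons <- c("no_myelin", "min_area", "border", "low_coverage",
               "high_eccentricity")
  counts <- setNames(integer(length(reasons)), reasons)
  recs <- list()
  for (cand in extraction$candidates) {
    rec <- measure_axon(cand, extraction$pixel_size, extraction$dims,
                        border_px = border_px)
    reason <- if (nrow(cand$myelin_idx) == 0) "no_myelin"
      else if (rec$area_px < min_area_px) "min_area"
      else if (rec$touches_border) "border"
      else if (rec$myelin_coverage < coverage_min) "low_coverage"
      else if (rec$eccentricity > eccentricity_max) "high_eccentricity"
      else NA_character_
    if (is.na(reason)) recs[[length(recs) + 1L]] <- rec
    else counts[[reason]] <- counts[[reason]] + 1L
  }
  records <- if (length(recs)) do.call(rbind, recs)
    else data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                    inner_diameter = numeric(0), outer_diameter = numeric(0),
                    myelin_thickness = numeric(0), g = numeric(0),
                    eccentricity = numeric(0), myelin_coverage = numeric(0),
                    touches_border = logical(0), area_px = integer(0))
  structure(list(
    records = records,
    counts = c(accepted = nrow(records), counts,
               myelin_without_axon = extraction$n_orphan_myelin),
    n_candidates = length(extraction$candidates)),
    class = "morphometry_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("morphometry: %d candidates, %d accepted\n",
              x$n_candidates, x$counts[["accepted"]]))
  print(x$counts)
  invisible(x)
}

#' Full morphometry of a label mask
#'
#' Convenience wrapper: [extract_axon_instances()] then
#' [filter_axon_instances()], with [distribution_stats()] of the accepted
#' inner diameters.
#'
#' @param mask A `label_mask`.
#' @param ... Passed to [filter_axon_instances()].
#' @return A `morphometry_result` with an added `stats` element (NULL when
#'   nothing was accepted).
#' @export
analyze_mask <- function(mask, ...) {
  res <- filter_axon_instances(extract_axon_instances(mask), ...)
  res$stats <- if (nrow(res$records))
    distribution_stats(res$records$inner_diameter, weighted = TRUE) else NULL
  res
}
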