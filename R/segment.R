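#' Segment circular bead regions in a dual-channel field
#'
#' Detects beads from the union of above-threshold signal in both channels
#' with a disc matched filter: the union mask is convolved with a disc of
#' roughly half the expected bead radius, giving a coverage score that peaks
#' at bead centres regardless of how lumpy the spheroid content inside a
#' bead is. Local maxima of the score (with greedy non-maximum suppression
#' at just under one bead diameter) become bead centres; above-threshold
#' pixels are then assigned to the nearest centre, each pixel to at most
#' one bead, and the centre and radius are refined as the minimal
#' enclosing circle of the assigned pixels (the bead circumscribes its
#' spheroids). Touching beads keep separate score peaks, so they are
#' returned as separate regions. Centre accuracy is limited by how far the
#' spheroids reach toward the bead boundary: small beads holding only a
#' couple of spheroids carry genuinely less positional information.
#'
#' @param field A [bead_field()].
#' @param config [calibration_config()] supplying the low thresholds.
#' @param bead_diameter_um Expected bead diameter (prior knowledge of the
#'   encapsulation process; 525 um for the validated beads). Sets the
#'   matched-filter scale, not a hard size constraint.
#' @param min_coverage Minimum disc-coverage score for a peak to count as a
#'   bead (fraction of the matched disc holding above-threshold pixels).
#' @param suppress_factor Non-maximum-suppression distance between bead
#'   centres, in units of the expected radius.
#' @param assign_factor Pixel-assignment cutoff distance from a bead
#'   centre, in units of the expected radius.
#' @return Object of class `bead_segmentation`: list with `labels` (integer
#'   matrix, 0 = background) and `beads` (data frame: `bead`, `x_px`,
#'   `y_px`, `radius_px`, `area_px`). An empty field yields a zero-row
#'   table with a warning.
#' @export
segment_beads <- function(field, config = default_calibration(),
                          bead_diameter_um = 525,
                          min_coverage = 0.2,
                          suppress_factor = 1.4,
                          assign_factor = 1.6) {
  if (!inherits(field, "bead_field")) stop_param("field must be a bead_field")
  psz <- field$fda$pixel_size_um
  r_exp <- bead_diameter_um / 2 / psz

  mask <- field$fda$pixels >= config$low_fda | field$pi$pixels >= config$low_pi
  empty_out <- function() {
    warning("no beads found in field", call. = FALSE)
    structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                   beads = data.frame(bead = integer(), x_px = numeric(),
                                      y_px = numeric(), radius_px = numeric(),
                                      area_px = integer())),
              class = "bead_segmentation")
  }
  if (!any(mask)) return(empty_out())
  # drop isolated speckle (noise pixels crossing the threshold) so neither
  # the matched filter nor the enclosing-circle fit sees them
  mask <- EBImage::opening(mask + 0, EBImage::makeBrush(3L, "disc")) > 0
  if (!any(mask)) return(empty_out())

  # coverage score: mean mask occupancy of a disc of half the bead radius
  disc_r <- max(3L, as.integer(round(r_exp / 2)))
  k <- EBImage::makeBrush(2L * disc_r + 1L, "disc")
  score <- EBImage::filter2(mask + 0, k / sum(k), boundary = 0)

  # local maxima via a grey-scale max filter at just under the bead radius
  win <- EBImage::makeBrush(2L * as.integer(round(0.8 * r_exp)) + 1L, "disc")
  mx <- EBImage::dilate(score, win)
  peak <- score >= mx - 1e-12 & score >= min_coverage
  if (!any(peak)) return(empty_out())

  # plateau peaks collapse to their centroid, then greedy suppression keeps
  # the strongest of any pair of centres closer than suppress_factor radii
  plab <- EBImage::imageData(EBImage::bwlabel(peak))
  ids <- setdiff(unique(as.integer(plab)), 0L)
  cand <- do.call(rbind, lapply(ids, function(id) {
    idx <- which(plab == id, arr.ind = TRUE)
    data.frame(x = mean(idx[, 2]), y = mean(idx[, 1]),
               s = max(score[plab == id]))
  }))
  cand <- cand[order(-cand$s), ]
  centers <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (!nrow(centers) ||
        all((centers$x - cand$x[i])^2 + (centers$y - cand$y[i])^2 >
            (suppress_factor * r_exp)^2))
      centers <- rbind(centers, cand[i, ])
  }

  # assign mask pixels to the nearest centre within assign_factor radii and
  # refine each centre as the minimal enclosing circle of its pixels;
  # pixels nearly equidistant to two centres are left out of the circle fit
  # (they belong to whichever centre estimate is currently better, so they
  # would drag the fit), and the assign/fit loop runs twice so the second
  # pass assigns against refined centres
  midx <- which(mask, arr.ind = TRUE)
  margin <- 0.1 * r_exp
  for (pass in 1:3) {
    d2 <- vapply(seq_len(nrow(centers)), function(j)
      (midx[, 2] - centers$x[j])^2 + (midx[, 1] - centers$y[j])^2,
      numeric(nrow(midx)))
    d2 <- matrix(d2, nrow = nrow(midx))
    nearest <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(nrow(midx)), nearest)]
    d2[cbind(seq_len(nrow(midx)), nearest)] <- Inf
    dsecond <- dmin
    if (ncol(d2) > 1)
      dsecond <- d2[cbind(seq_len(nrow(midx)), max.col(-d2, ties.method = "first"))]
    ok <- dmin <= (assign_factor * r_exp)^2
    uncontested <- ok & (ncol(d2) == 1 | sqrt(dsecond) - sqrt(dmin) > margin)
    for (j in seq_len(nrow(centers))) {
      sel <- uncontested & nearest == j
      if (!any(sel)) next
      mec <- enclosing_circle(midx[sel, 2], midx[sel, 1])
      centers$x[j] <- mec$x; centers$y[j] <- mec$y; centers$r[j] <- mec$r
    }
  }

  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[cbind(midx[ok, 1], midx[ok, 2])] <- nearest[ok]

  rows <- lapply(seq_len(nrow(centers)), function(j) {
    sel <- ok & nearest == j
    if (!any(sel)) return(NULL)
    data.frame(bead = j,
               x_px = centers$x[j], y_px = centers$y[j],
               radius_px = centers$r[j],
               area_px = sum(sel))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_out())
  beads <- do.call(rbind, rows)
  # renumber consecutively and rewrite labels accordingly
  remap <- integer(nrow(centers))
  remap[beads$bead] <- seq_len(nrow(beads))
  labels[labels > 0] <- remap[labels[labels > 0]]
  beads$bead <- seq_len(nrow(beads))
  structure(list(labels = labels, beads = beads),
            class = "bead_segmentation")
}

# Approximate minimal enclosing circle (Badoiu-Clarkson iteration): the bead
# circle circumscribes its cell content, so the MEC centre of a bead's
# above-threshold pixels estimates the bead centre far better than their
# centroid when the spheroids sit asymmetrically inside the bead.
enclosing_circle <- function(xs, ys, iters = 200L) {
  cx <- mean(xs); cy <- mean(ys)
  for (k in seq_len(iters)) {
    d2 <- (xs - cx)^2 + (ys - cy)^2
    i <- which.max(d2)
    step <- 1 / (k + 1)
    cx <- cx + (xs[i] - cx) * step
    cy <- cy + (ys[i] - cy) * step
  }
  list(x = cx, y = cy, r = sqrt(max((xs - cx)^2 + (ys - cy)^2)))
}

#' @export
print.bead_segmentation <- function(x, ...) {
  cat(sprintf("<bead_segmentation> %d bead region(s)\n", nrow(x$beads)))
  if (nrow(x$beads)) print(utils::head(x$beads, 10))
  invisible(x)
}
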