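#' Iba-1 area fraction (Iba1-RA)
#'
#' Fraction of the field occupied by Iba-1+ signal, used in the nerve
#' fibre / ganglion cell layer where densely overlapping cells cannot be
#' counted individually. The mask is produced by the same
#' normalise-then-threshold rule as cell counting (default 0.2 of the
#' per-image maximum); `method = "otsu"` instead picks the threshold by
#' Otsu's criterion on the normalised image.
#'
#' @param img A calibrated [field_image()].
#' @param params A [detection_params()]; only `threshold` is used.
#' @param method `"fraction_of_max"` (default) or `"otsu"`.
#' @return Scalar fraction in `[0, 1]`, with attributes `area_um2`
#'   (labelled area in um^2) and `method`. An empty field gives 0.
#' @export
area_fraction <- function(img, params = detection_params(),
                          method = c("fraction_of_max", "otsu")) {
  method <- match.arg(method)
  norm <- normalize_field(img)
  if (isTRUE(attr(norm, "empty_field"))) {
    return(structure(0, area_um2 = 0, method = method))
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(norm$pixels), range = c(0, 1))
  } else {
    params$threshold
  }
  mask <- norm$pixels >= thr
  frac <- sum(mask) / length(mask)
  structure(frac, area_um2 = sum(mask) * img$pixel_size_um^2,
            method = method)
}

#' Polygon area by the shoelace formula
#'
#' Exact signed-area computation for a simple closed polygon given as an
#' ordered vertex list; the absolute value is returned. Used for soma
#' contours traced by an analyst (the manual pathway) and internally for
#' convex-hull arbor areas.
#'
#' @param poly Two-column matrix or data frame of vertices `(y, x)` in um,
#'   in order; the polygon is closed implicitly.
#' @return Area in um^2.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  y <- poly[, 1]; x <- poly[, 2]
  yn <- c(y[-1], y[1]); xn <- c(x[-1], x[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Soma (cell body) area
#'
#' Two pathways, mirroring how cell-body areas are obtained in practice:
#'
#' * a traced contour (ordered polygon vertices in um) — area by the
#'   shoelace formula, the automated stand-in for interactive contour
#'   tracing; self-intersecting contours are rejected;
#' * a logical soma mask with its pixel size — pixel count times pixel
#'   area.
#'
#' @param x Either a two-column matrix/data frame of polygon vertices
#'   `(y, x)` in um, or a logical matrix mask.
#' @param pixel_size_um Required when `x` is a mask.
#' @return Area in um^2.
#' @export
soma_area <- function(x, pixel_size_um = NULL) {
  if (is.matrix(x) && is.logical(x)) {
    if (is.null(pixel_size_um)) {
      abort("pixel_size_um is required for a mask input")
    }
    if (!any(x)) abort("empty soma mask")
    return(sum(x) * pixel_size_um^2)
  }
  poly <- as.matrix(x)
  if (is_self_intersecting(poly)) abort("self-intersecting soma contour")
  polygon_area(poly)
}

# Segment-pair crossing test over non-adjacent polygon edges.
is_self_intersecting <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- setdiff(seq(i + 2, jmax), i)
    for (j in js) {
      if (intersects(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Arbor area from process-tip points
#'
#' Area of the convex hull of the most distal process tips of one cell —
#' the deterministic counterpart of hand-drawing a polygon through the
#' distal tips. Fewer than three tips, or collinear tips, give area 0 with
#' attribute `degenerate = TRUE`. Note the hull necessarily contains the
#' soma and can overestimate strongly concave arbors.
#'
#' @param tips Two-column matrix or data frame of tip coordinates `(y, x)`
#'   in um.
#' @return Area in um^2; attribute `degenerate` flags undefined hulls.
#' @export
arbor_area <- function(tips) {
  tips <- as.matrix(tips)
  if (nrow(tips) < 3) return(structure(0, degenerate = TRUE))
  h <- chull(tips[, 2], tips[, 1])
  if (length(h) < 3) return(structure(0, degenerate = TRUE))
  a <- polygon_area(tips[h, , drop = FALSE])
  if (a == 0) return(structure(0, degenerate = TRUE))
  structure(a, degenerate = FALSE)
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iterative thinning of a binary mask to a 1-px-wide 8-connected
#' skeleton. Implemented here because no installed image package exposes
#' 2-D skeletonization.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  img <- matrix(FALSE, nr + 2, nc + 2)
  img[2:(nr + 1), 2:(nc + 1)] <- mask
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- (1 + max(0, dr)):(nrow(m) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(m) + min(0, dc))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift(img, 1, 0);  p3 <- shift(img, 1, -1)
      p4 <- shift(img, 0, -1); p5 <- shift(img, -1, -1)
      p6 <- shift(img, -1, 0); p7 <- shift(img, -1, 1)
      p8 <- shift(img, 0, 1);  p9 <- shift(img, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- img & b >= 2 & b <= 6 & a == 1
      if (pass == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nr + 1), 2:(nc + 1)]
}

skeleton_neighbour_count <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sk
  nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  nb
}

#' Extract distal process tips from a single-cell mask
#'
#' Skeletonizes the cell's binary mask and reports skeleton endpoints
#' (skeleton pixels with exactly one skeleton neighbour) as tip
#' coordinates in um. Optionally, endpoint branches shorter than
#' `min_branch_um` are discarded as spurs by tracing each endpoint to the
#' nearest skeleton junction; the default is no pruning, since thinning
#' of disc-plus-stroke cells yields clean endpoints and staircase
#' junction artefacts can make length tracing cut real branches short.
#'
#' @param mask Logical matrix covering one cell.
#' @param pixel_size_um Pixel size in um.
#' @param min_branch_um Minimum traced branch length for a tip to count;
#'   0 (default) disables pruning.
#' @return Tibble `y_um`, `x_um` of tip positions (zero-based
#'   pixel-centre convention).
#' @export
extract_tips <- function(mask, pixel_size_um = 1, min_branch_um = 0) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) abort("empty cell mask")
  sk <- skeletonize(mask)
  nb <- skeleton_neighbour_count(sk)
  ends <- which(sk & nb == 1, arr.ind = TRUE)
  if (nrow(ends) == 0) {
    return(tibble(y_um = double(), x_um = double()))
  }
  if (min_branch_um > 0) {
    min_branch_px <- min_branch_um / pixel_size_um
    keep <- vapply(seq_len(nrow(ends)), function(i) {
      branch_length(sk, nb, ends[i, ]) >= min_branch_px
    }, logical(1))
    ends <- ends[keep, , drop = FALSE]
  }
  tibble(y_um = (ends[, 1] - 1) * pixel_size_um,
         x_um = (ends[, 2] - 1) * pixel_size_um)
}

# Walk from an endpoint along the skeleton until a junction (>= 3
# neighbours) or another endpoint; returns path length in px.
branch_length <- function(sk, nb, start) {
  cur <- start
  prev <- c(NA_integer_, NA_integer_)
  len <- 0
  repeat {
    nbrs <- expand.grid(dr = -1:1, dc = -1:1)
    nbrs <- nbrs[!(nbrs$dr == 0 & nbrs$dc == 0), ]
    cand <- cbind(cur[1] + nbrs$dr, cur[2] + nbrs$dc)
    ok <- cand[, 1] >= 1 & cand[, 1] <= nrow(sk) &
      cand[, 2] >= 1 & cand[, 2] <= ncol(sk)
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[sk[cand], , drop = FALSE]
    if (!is.na(prev[1])) {
      cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0) return(len)          # isolated or dead end
    if (nb[cur[1], cur[2]] >= 3 && len > 0) return(len)  # reached junction
    nxt <- cand[1, ]
    if (nb[nxt[1], nxt[2]] >= 3) return(len + 1)
    prev <- cur
    cur <- nxt
    len <- len + sqrt(sum((cur - prev)^2))
    if (len > max(dim(sk))) return(len)       # safety on loops
  }
}

#' Count vertical processes in the OPL-OS interface plane
#'
#' Microglial processes that cross between the outer plexiform layer and
#' the photoreceptor outer segments appear as bright puncta in the plane
#' between the two layers. They are counted with the standard detection
#' chain tuned to punctum scale: a small minimum segment size and a tight
#' merge radius.
#'
#' @param plane A [field_image()] of the interface plane.
#' @param params A [detection_params()]; the default uses
#'   `min_distance_um = 8` and `min_segment_px = 2`.
#' @return Integer punctum count, with the underlying `cell_set` as
#'   attribute `spots`.
#' @export
count_vertical_processes <- function(plane,
                                     params = detection_params(
                                       min_distance_um = 8,
                                       min_segment_px = 2)) {
  cs <- count_cells(plane, params)
  structure(n_cells(cs), spots = cs)
}

#' Automated soma areas for a whole field
#'
#' Recovers individual cell-body areas from a field by keeping only the
#' high-intensity core of the labelled signal: somata are substantially
#' brighter than processes, so thresholding the normalised image at
#' `core_frac` of the maximum isolates one compact blob per soma even
#' where arbors of neighbouring cells touch. Blobs below `min_area_um2`
#' are discarded as fragments.
#'
#' @param img A calibrated [field_image()] of the Iba-1 channel.
#' @param core_frac Fraction of the per-image maximum that defines the
#'   soma core (default 0.55; processes are rendered/imaged well below
#'   this, somata above).
#' @param min_area_um2 Minimum blob area to count as a soma.
#' @return Numeric vector of soma areas in um^2 (possibly empty).
#' @export
soma_areas_field <- function(img, core_frac = 0.55, min_area_um2 = 10) {
  norm <- normalize_field(img)
  if (isTRUE(attr(norm, "empty_field"))) return(numeric(0))
  lab <- label_components(norm$pixels >= core_frac)
  if (max(lab) == 0L) return(numeric(0))
  areas <- tabulate(lab[lab > 0L]) * img$pixel_size_um^2
  areas[areas >= min_area_um2]
}

#' Automated arbor areas for a whole field
#'
#' For each deduplicated cell whose thresholded component is isolated
#' (contains exactly one cell), extracts skeleton tips and reports the
#' convex-hull arbor area. Cells whose components merged with a neighbour
#' are skipped, as are degenerate hulls.
#'
#' @param img A calibrated [field_image()].
#' @param params A [detection_params()].
#' @param max_cells Measure at most this many cells (sampled in raster
#'   order), mirroring per-retina subsampling of measured cells.
#' @param min_branch_um Spur-suppression length for [extract_tips()].
#' @return Numeric vector of arbor areas in um^2.
#' @export
arbor_areas_field <- function(img, params = detection_params(),
                              max_cells = 10, min_branch_um = 5) {
  norm <- normalize_field(img)
  if (isTRUE(attr(norm, "empty_field"))) return(numeric(0))
  mask <- apply_threshold(norm, params)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(numeric(0))
  cents <- segment_centroids(mask, params, pixel_size_um = img$pixel_size_um)
  if (nrow(cents) == 0) return(numeric(0))
  # component label of each centroid, via the nearest labelled pixel of
  # its component (the centre of mass can fall off the mask)
  s <- img$pixel_size_um
  complab <- vapply(seq_len(nrow(cents)), function(i) {
    r <- pmin(pmax(round(cents$y_um[i] / s) + 1, 1), nrow(mask))
    c <- pmin(pmax(round(cents$x_um[i] / s) + 1, 1), ncol(mask))
    if (lab[r, c] > 0L) return(lab[r, c])
    idx <- which(lab > 0L, arr.ind = TRUE)
    d2 <- (idx[, 1] - r)^2 + (idx[, 2] - c)^2
    lab[idx[which.min(d2), , drop = FALSE]]
  }, integer(1))
  # a cell is isolated when its centroid forms a singleton cluster under
  # the dedup rule, i.e. its component holds exactly one cell
  cl <- single_linkage_clusters(cbind(cents$y_um, cents$x_um),
                                params$min_distance_um)
  singleton <- as.integer(names(table(cl))[table(cl) == 1])
  isolated <- unique(complab[cl %in% singleton])
  out <- numeric(0)
  for (lb in head(isolated, max_cells)) {
    idx <- which(lab == lb, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(nrow(mask), max(idx[, 1]) + 2)
    c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(ncol(mask), max(idx[, 2]) + 2)
    sub <- lab[r0:r1, c0:c1] == lb
    tips <- extract_tips(sub, pixel_size_um = img$pixel_size_um,
                         min_branch_um = min_branch_um)
    if (nrow(tips) >= 3) {
      a <- arbor_area(cbind(tips$y_um, tips$x_um))
      if (!isTRUE(attr(a, "degenerate"))) out <- c(out, as.numeric(a))
    }
  }
  out
}
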