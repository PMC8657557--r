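#' Generate an elliptical cell outline
#'
#' Samples an ellipse with semi-axes \code{semiMajor >= semiMinor} as an
#' ordered, closed, non-self-intersecting polygon. The analytic roundness
#' of such an outline is the axis ratio b/a: area is pi*a*b while the
#' maximum Feret diameter is 2a, giving pi*a*b / (pi*a^2).
#'
#' @param semiMajor,semiMinor ellipse semi-axes in pixels.
#' @param nVertices number of boundary vertices (>= 16).
#' @param rotation rotation angle in radians.
#' @param center numeric length-2 centre (x, y).
#' @return matrix with columns \code{x}, \code{y} (vertices in order; the
#'   polygon is implicitly closed).
#' @examples
#' roundnessScore(ellipseOutline(2, 1, 360))   # ~0.5
#' @export
ellipseOutline <- function(semiMajor, semiMinor, nVertices = 360,
                           rotation = 0, center = c(0, 0)) {
  if (!is.finite(semiMajor) || !is.finite(semiMinor) ||
      semiMinor <= 0 || semiMajor < semiMinor)
    stop("require semiMajor >= semiMinor > 0", call. = FALSE)
  if (nVertices < 16) stop("nVertices must be >= 16", call. = FALSE)
  t <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  x0 <- semiMajor * cos(t); y0 <- semiMinor * sin(t)
  x <- center[1] + x0 * cos(rotation) - y0 * sin(rotation)
  y <- center[2] + x0 * sin(rotation) + y0 * cos(rotation)
  cbind(x = x, y = y)
}

#' Simulate a cell population with known morphology classes
#'
#' Draws \code{nCells} elliptical outlines whose axis ratios (roundness)
#' come from per-class truncated-normal distributions, returning both the
#' outlines and the generating class labels for recovery tests. Default
#' class distributions are well separated from the default control-derived
#' cutoffs: epithelial N(0.93, 0.02), mixed N(0.50, 0.05), mesenchymal
#' N(0.10, 0.02), truncated to (0.02, 1].
#'
#' @param nCells number of cells.
#' @param classMix numeric length-3 proportions (epithelial, mixed,
#'   mesenchymal); must sum to 1.
#' @param axisRatioParams named list with entries \code{epithelial},
#'   \code{mixed}, \code{mesenchymal}, each \code{c(mean, sd)} of the
#'   axis-ratio distribution.
#' @param semiMajor semi-major axis in pixels for every cell.
#' @param nVertices vertices per outline.
#' @param seed integer RNG seed.
#' @return list with \code{outlines} (list of vertex matrices),
#'   \code{labels} (character vector), \code{ratios} (numeric).
#' @examples
#' pop <- simulateCellPopulation(50, c(1, 0, 0), seed = 1)
#' table(pop$labels)
#' @export
simulateCellPopulation <- function(nCells, classMix = c(1, 1, 1) / 3,
                                   axisRatioParams = list(
                                     epithelial = c(0.93, 0.02),
                                     mixed = c(0.50, 0.05),
                                     mesenchymal = c(0.10, 0.02)),
                                   semiMajor = 20, nVertices = 360, seed = 1) {
  if (length(classMix) != 3 || any(classMix < 0) ||
      abs(sum(classMix) - 1) > 1e-8)
    stop("classMix must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  classes <- c("epithelial", "mixed", "mesenchymal")
  with_seed(seed, {
    labels <- sample(classes, nCells, replace = TRUE, prob = classMix)
    ratios <- vapply(labels, function(cl) {
      p <- axisRatioParams[[cl]]
      r <- rnorm(1, p[1], p[2])
      while (r <= 0.02 || r > 1) r <- rnorm(1, p[1], p[2])
      r
    }, numeric(1), USE.NAMES = FALSE)
    rot <- runif(nCells, 0, pi)
    outlines <- lapply(seq_len(nCells), function(i)
      ellipseOutline(semiMajor, semiMajor * ratios[i], nVertices, rot[i]))
    names(outlines) <- sprintf("cell_%04d", seq_len(nCells))
    list(outlines = outlines, labels = labels, ratios = ratios)
  })
}

#' Simulate binary assay masks with known ground truth
#'
#' Builds time-indexed 0/1 occupancy grids for three assay geometries,
#' together with the true quantity a correct quantifier must recover
#' (integer pixel arithmetic, so recovery is exact):
#' \itemize{
#'   \item \code{wound}: a confluent field (1) with a vertical cell-free
#'     strip; \code{params$widths} gives the strip width at each timepoint.
#'     Truth: percent closure at each later timepoint relative to t0.
#'   \item \code{spheroid}: a filled disc whose radius grows;
#'     \code{params$radii} per timepoint. Truth: invasion area
#'     (occupied-pixel gain times pixel area).
#'   \item \code{brdu}: \code{params$nTotal} non-touching 3x3 nuclei of
#'     which \code{params$nPositive} are BrdU-positive. Truth: percent
#'     positive. Masks: \code{dapi} (all nuclei) and \code{brdu}.
#' }
#'
#' @param kind one of \code{"wound"}, \code{"spheroid"}, \code{"brdu"}.
#' @param params named list of geometry parameters; see Details above.
#'   Common: \code{dims} (rows, cols; default c(60, 100) for wound,
#'   c(120, 120) otherwise), \code{pixelSize} (micrometres per pixel,
#'   default 1).
#' @param seed integer RNG seed (used by \code{brdu} placement only).
#' @return list with \code{masks} (named list of 0/1 integer matrices) and
#'   \code{truth} (named list of true quantities).
#' @examples
#' w <- simulateAssayMasks("wound", list(widths = c(20, 5)))
#' w$truth$closure_pct
#' @export
simulateAssayMasks <- function(kind = c("wound", "spheroid", "brdu"),
                               params = list(), seed = 1) {
  kind <- match.arg(kind)
  px <- params$pixelSize %||% 1
  if (kind == "wound") {
    dims <- params$dims %||% c(60L, 100L)
    widths <- params$widths %||% c(20L, 5L)
    if (any(widths < 0) || any(widths > dims[2]))
      stop("wound widths must lie in [0, ncol]", call. = FALSE)
    if (any(diff(widths) > 0))
      stop("wound widths must be non-increasing over time", call. = FALSE)
    mid <- dims[2] / 2
    masks <- lapply(widths, function(w) {
      m <- matrix(1L, dims[1], dims[2])
      if (w > 0) {
        cols <- seq(floor(mid - w / 2) + 1L, length.out = w)
        m[, cols] <- 0L
      }
      m
    })
    names(masks) <- paste0("t", seq_along(widths) - 1L)
    a <- widths * dims[1]
    truth <- list(wound_area_px = a,
                  closure_pct = 100 * (a[1] - a[-1]) / a[1])
    list(masks = masks, truth = truth)
  } else if (kind == "spheroid") {
    dims <- params$dims %||% c(120L, 120L)
    radii <- params$radii %||% c(20, 32)
    if (any(diff(radii) < 0))
      stop("spheroid radii must be non-decreasing", call. = FALSE)
    ctr <- (dims + 1) / 2
    rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
    cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
    masks <- lapply(radii, function(r) matrix(as.integer(d2 <= r^2), dims[1], dims[2]))
    names(masks) <- paste0("t", seq_along(radii) - 1L)
    a <- vapply(masks, sum, numeric(1))
    truth <- list(occupied_px = a,
                  invasion_area = (a[-1] - a[1]) * px^2)
    list(masks = masks, truth = truth)
  } else {
    dims <- params$dims %||% c(120L, 120L)
    nTotal <- params$nTotal %||% 120L
    nPositive <- params$nPositive %||% 30L
    if (nPositive > nTotal) stop("nPositive must not exceed nTotal", call. = FALSE)
    ## nuclei are 3x3 blocks on a disjoint 5x5 lattice so components never touch
    gr <- floor(dims[1] / 5); gc <- floor(dims[2] / 5)
    if (gr * gc < nTotal) stop("grid too small for nTotal nuclei", call. = FALSE)
    with_seed(seed, {
      cells <- sample.int(gr * gc, nTotal)
      pos <- sample(cells, nPositive)
      put <- function(idx) {
        m <- matrix(0L, dims[1], dims[2])
        r0 <- ((idx - 1) %% gr) * 5 + 2
        c0 <- ((idx - 1) %/% gr) * 5 + 2
        for (i in seq_along(idx))
          m[r0[i] + 0:2, c0[i] + 0:2] <- 1L
        m
      }
      masks <- list(dapi = put(cells), brdu = put(pos))
      truth <- list(n_total = nTotal, n_positive = nPositive,
                    positive_pct = 100 * nPositive / nTotal)
      list(masks = masks, truth = truth)
    })
  }
}
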