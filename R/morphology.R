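#' Roundness score of a cell outline
#'
#' The actual area (AA) of the closed outline polygon (shoelace formula)
#' divided by the expected area (EA) of the circle whose diameter is the
#' cell's longest axis (the maximum Feret diameter, i.e. the largest
#' pairwise vertex distance): \eqn{score = AA / (\pi (d/2)^2)}, clipped
#' to (0, 1]. A score of 1 indicates a round (epithelial-like) cell; a
#' score approaching 0 a spindle-shaped (mesenchymal-like) cell. The
#' score is invariant to translation, rotation and uniform scaling.
#'
#' @param outline matrix or data.frame of ordered vertices with columns
#'   x, y (closed polygon; at least 3 vertices).
#' @return numeric score in (0, 1].
#' @examples
#' roundnessScore(ellipseOutline(1, 1, 360))  # ~1 (circle)
#' roundnessScore(ellipseOutline(2, 1, 360))  # ~0.5
#' @export
roundnessScore <- function(outline) {
  v <- as.matrix(outline)[, 1:2, drop = FALSE]
  if (nrow(v) < 3) stop("outline needs at least 3 vertices", call. = FALSE)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  if (area <= 0) stop("outline has zero area", call. = FALSE)
  ## Feret diameter: the farthest pair lies on the convex hull
  h <- grDevices::chull(v)
  d <- max(stats::dist(v[h, , drop = FALSE]))
  clip01(area / (pi * (d / 2)^2), 1e-12, 1)
}

#' @rdname roundnessScore
#' @param outlines list of outlines (e.g. from
#'   \code{\link{simulateCellPopulation}}).
#' @return \code{roundnessScores}: named numeric vector of scores.
#' @export
roundnessScores <- function(outlines) {
  vapply(outlines, roundnessScore, numeric(1))
}

#' Derive morphology cutoffs from control populations
#'
#' Computes classification thresholds from roundness scores of epithelial
#' and mesenchymal control cells: the epithelial cutoff is the epithelial
#' control mean minus one sample SD, the mesenchymal cutoff the
#' mesenchymal control mean plus one sample SD. Overlapping cutoffs
#' (mesenchymal at or above epithelial) indicate inadequate controls and
#' raise an error.
#'
#' @param epithelialScores,mesenchymalScores numeric vectors of control
#'   roundness scores (at least 2 each).
#' @return a \linkS4class{MorphologyCutoffs}.
#' @examples
#' deriveCutoffs(c(0.7, 0.8, 0.9), c(0.15, 0.2, 0.25))
#' @export
deriveCutoffs <- function(epithelialScores, mesenchymalScores) {
  if (length(epithelialScores) < 2 || length(mesenchymalScores) < 2)
    stop("need at least 2 scores per control population", call. = FALSE)
  epi <- mean(epithelialScores) - sd(epithelialScores)
  mes <- mean(mesenchymalScores) + sd(mesenchymalScores)
  if (mes >= epi)
    stop(sprintf(paste("control populations overlap (mesenchymal cutoff %.3f >=",
                       "epithelial cutoff %.3f); better separated controls required"),
                 mes, epi), call. = FALSE)
  obj <- new("MorphologyCutoffs", epithelialCut = epi, mesenchymalCut = mes)
  validObject(obj)
  obj
}

#' Classify cells by roundness score
#'
#' Scores at or above the epithelial cutoff are epithelial, at or below
#' the mesenchymal cutoff mesenchymal, and strictly between the cutoffs
#' "mixed" (neither epithelial nor mesenchymal). Population percentages
#' are reported over all cells.
#'
#' @param scores named or unnamed numeric vector of roundness scores.
#' @param cutoffs a \linkS4class{MorphologyCutoffs}.
#' @return a \linkS4class{MorphologyReport}.
#' @examples
#' cut <- deriveCutoffs(c(0.7, 0.8, 0.9), c(0.15, 0.2, 0.25))
#' classifyCells(c(0.9, 0.5, 0.1), cut)
#' @export
classifyCells <- function(scores, cutoffs) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  validObject(cutoffs)
  cls <- ifelse(scores >= cutoffs@epithelialCut, "epithelial",
         ifelse(scores <= cutoffs@mesenchymalCut, "mesenchymal", "mixed"))
  ids <- names(scores) %||% sprintf("cell_%04d", seq_along(scores))
  cells <- data.frame(cell_id = ids, score = as.numeric(scores), class = cls,
                      row.names = NULL, stringsAsFactors = FALSE)
  pct <- 100 * vapply(c("epithelial", "mixed", "mesenchymal"),
                      function(k) mean(cls == k), numeric(1))
  new("MorphologyReport", cells = cells, percentages = pct, cutoffs = cutoffs)
}
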