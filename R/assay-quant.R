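## Mask-based quantifiers for the functional assays: scratch-wound
## closure, spheroid invasion, transwell per-FOV summaries and BrdU
## proliferation. Masks are binary occupancy grids (1 = cells present).

.check_mask <- function(m, name) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1)))
    stop(name, " must be a binary 0/1 mask", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Percent wound closure between two timepoints
#'
#' The wound at t0 is the largest cell-free connected component of the
#' initial mask; its bounding box defines the analysis window, which is
#' then tracked at the later timepoint. Closure is
#' \eqn{100 (A_0 - A_t) / A_0} where \eqn{A} is the cell-free area inside
#' the window. Values outside [0, 100] (cells retracting beyond the
#' window) are clipped, with the unclipped value kept in the
#' \code{"raw"} attribute and flagged via \code{"flagged"}.
#'
#' @param mask0,maskT binary masks (1 = cells) at t0 and t, identical
#'   dimensions.
#' @return numeric percent closure with attributes \code{raw} and
#'   \code{flagged}.
#' @examples
#' w <- simulateAssayMasks("wound", list(widths = c(20, 5)))
#' woundClosure(w$masks$t0, w$masks$t1)
#' @export
woundClosure <- function(mask0, maskT) {
  m0 <- .check_mask(mask0, "mask0"); mt <- .check_mask(maskT, "maskT")
  if (!all(dim(m0) == dim(mt)))
    stop("masks must share dimensions", call. = FALSE)
  lab <- EBImage::bwlabel(1L - m0)
  if (max(lab) == 0) stop("zero initial wound area", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  wound <- lab == which.max(sizes)
  idx <- which(wound, arr.ind = TRUE)
  win_r <- range(idx[, 1]); win_c <- range(idx[, 2])
  w0 <- m0[win_r[1]:win_r[2], win_c[1]:win_c[2], drop = FALSE]
  wt <- mt[win_r[1]:win_r[2], win_c[1]:win_c[2], drop = FALSE]
  a0 <- sum(w0 == 0L)
  at <- sum(wt == 0L)
  raw <- 100 * (a0 - at) / a0
  out <- clip01(raw, 0, 100)
  attr(out, "raw") <- raw
  attr(out, "flagged") <- raw < 0 || raw > 100
  out
}

#' Spheroid invasion area between two timepoints
#'
#' The gain in occupied area from t0 to t, in physical units:
#' \eqn{(A_t - A_0) \cdot pixelSize^2}. Negative growth is floored at 0
#' with the raw value kept in the \code{"raw"} attribute and flagged.
#'
#' @param mask0,maskT binary masks (1 = spheroid/halo), identical
#'   dimensions; \code{mask0} must be non-empty.
#' @param pixelSize micrometres per pixel (default 1).
#' @return invasion area in square micrometres, attributes \code{raw},
#'   \code{flagged}.
#' @export
spheroidInvasion <- function(mask0, maskT, pixelSize = 1) {
  m0 <- .check_mask(mask0, "mask0"); mt <- .check_mask(maskT, "maskT")
  if (!all(dim(m0) == dim(mt)))
    stop("masks must share dimensions", call. = FALSE)
  if (sum(m0) == 0) stop("empty t0 spheroid mask", call. = FALSE)
  raw <- (sum(mt) - sum(m0)) * pixelSize^2
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  attr(out, "flagged") <- raw < 0
  out
}

#' Count nuclei in a binary mask
#'
#' Connected-component count (8-connectivity) of a nuclei mask.
#'
#' @param mask binary mask with non-touching nuclei.
#' @return integer count.
#' @export
countNuclei <- function(mask) {
  m <- .check_mask(mask, "mask")
  max(EBImage::bwlabel(m))
}

#' Percent BrdU-positive cells
#'
#' @param brduPositive count of BrdU-positive nuclei.
#' @param totalNuclei total (DAPI-positive) nuclei count; must be
#'   positive and at least \code{brduPositive}.
#' @return percent positive in [0, 100].
#' @examples
#' brduFraction(30, 120)  # 25
#' @export
brduFraction <- function(brduPositive, totalNuclei) {
  if (totalNuclei <= 0) stop("totalNuclei must be positive", call. = FALSE)
  if (brduPositive < 0 || brduPositive > totalNuclei)
    stop("brduPositive must lie in [0, totalNuclei]", call. = FALSE)
  100 * brduPositive / totalNuclei
}

#' Mean and SEM over high-power fields of view
#'
#' Transwell-style readouts are summarized as the arithmetic mean over
#' HP-FOVs with the standard error of the mean (sample SD over
#' \eqn{\sqrt n}). A single field gives SEM 0 with a flag.
#'
#' @param counts numeric per-FOV counts (typically 5 fields per well).
#' @return list with \code{mean}, \code{sem}, \code{n}, \code{flagged}
#'   (TRUE when n = 1 and the SEM is undefined).
#' @examples
#' fovSummary(c(10, 12, 14, 16, 18))
#' @export
fovSummary <- function(counts) {
  if (length(counts) == 0) stop("empty FOV counts", call. = FALSE)
  n <- length(counts)
  list(mean = mean(counts),
       sem = if (n > 1) sd(counts) / sqrt(n) else 0,
       n = n, flagged = n == 1)
}
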