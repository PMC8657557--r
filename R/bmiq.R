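## Beta-mixture quantile (BMIQ) normalization.
##
## Type II Infinium probes read compressed toward 0.5 relative to type I
## probes. BMIQ fits a three-state Beta mixture (unmethylated U,
## hemimethylated H, methylated M) to each design type within a sample,
## then maps type II betas onto the type I distribution: U and M states by
## Beta quantile mapping onto the corresponding type I components, and the
## H state by a conformal shift-and-dilation onto the gap between the
## transformed U maximum and M minimum, preserving the empirical gaps
## between states. Type I betas are untouched.

## Weighted maximum-likelihood estimate of Beta(a, b) shape parameters.
## Depends on the data only through the weighted means of log(x) and
## log(1-x); solved by Newton iteration in (log a, log b) starting from
## the supplied values (typically the previous EM iterate).
.beta_wmle <- function(T1, T2, a0 = 1, b0 = 1) {
  la <- log(a0); lb <- log(b0)
  for (it in 1:60) {
    a <- exp(la); b <- exp(lb)
    g1 <- digamma(a) - digamma(a + b) - T1
    g2 <- digamma(b) - digamma(a + b) - T2
    if (max(abs(g1), abs(g2)) < 1e-10) break
    t_ab <- trigamma(a + b)
    ## Jacobian wrt (la, lb), chain rule d/dla = a * d/da
    J11 <- a * (trigamma(a) - t_ab); J12 <- -b * t_ab
    J21 <- -a * t_ab;                J22 <- b * (trigamma(b) - t_ab)
    det <- J11 * J22 - J12 * J21
    if (!is.finite(det) || abs(det) < 1e-12) break
    dla <- (g1 * J22 - g2 * J12) / det
    dlb <- (g2 * J11 - g1 * J21) / det
    ## damp large steps to stay in a stable region
    sc <- max(1, abs(dla) / 2, abs(dlb) / 2)
    la <- la - dla / sc; lb <- lb - dlb / sc
    ## bound shapes away from degenerate point-mass components
    la <- min(max(la, -6), log(50)); lb <- min(max(lb, -6), log(50))
  }
  c(exp(la), exp(lb))
}

## method-of-moments Beta shapes from (possibly weighted) mean/variance
.beta_mom <- function(mu, v) {
  v <- max(v, 1e-6)
  mu <- min(max(mu, 1e-3), 1 - 1e-3)
  k <- mu * (1 - mu) / v - 1
  if (k <= 0) k <- 0.1
  pmax(c(mu * k, (1 - mu) * k), 1e-3)
}

#' Fit a three-state Beta mixture by EM
#'
#' Fits a mixture of \code{nStates} Beta densities to a vector of beta
#' values. Initialisation is deterministic: values are assigned to states
#' by thresholds (< 0.25 unmethylated, 0.25-0.75 hemimethylated, > 0.75
#' methylated) and per-state method-of-moments shapes seed the EM. The
#' M-step solves the weighted Beta maximum-likelihood equations exactly,
#' so the log-likelihood trace is non-decreasing. States are relabelled
#' so component means increase (U < H < M); per-value assignments are by
#' maximum posterior with ties broken toward H.
#'
#' @param betas numeric vector of beta values; clipped to
#'   [1e-6, 1 - 1e-6] before likelihood evaluation. At least 100 values
#'   required.
#' @param nStates number of mixture components (default 3).
#' @param tol EM convergence tolerance on the log-likelihood
#'   (default 1e-4).
#' @param maxIter maximum EM iterations (default 100); reaching it raises
#'   a warning.
#' @return a \linkS4class{BetaMixtureFit}.
#' @examples
#' fit <- fitBetaMixture(rbeta(2000, 2, 10))
#' fit
#' @export
fitBetaMixture <- function(betas, nStates = 3, tol = 1e-4, maxIter = 100) {
  x <- clip01(betas, 1e-6, 1 - 1e-6)
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("need at least 100 beta values", call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("degenerate input: all values identical", call. = FALSE)
  K <- nStates
  ## threshold initialisation
  cuts <- if (K == 3) c(0.25, 0.75) else stats::quantile(x, seq_len(K - 1) / K)
  grp <- findInterval(x, cuts) + 1L
  shapes <- matrix(NA_real_, K, 2)
  w <- numeric(K)
  for (k in seq_len(K)) {
    xk <- x[grp == k]
    if (length(xk) < 2) xk <- stats::quantile(x, probs = c(k - 0.75, k - 0.25) / K)
    shapes[k, ] <- .beta_mom(mean(xk), stats::var(xk))
    w[k] <- max(length(x[grp == k]), 1) / length(x)
  }
  w <- w / sum(w)

  lx <- log(x); l1x <- log1p(-x)
  ll_trace <- numeric(0)
  converged <- FALSE
  dens <- matrix(0, length(x), K)
  for (iter in seq_len(maxIter)) {
    for (k in seq_len(K))
      dens[, k] <- w[k] * dbeta(x, shapes[k, 1], shapes[k, 2])
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < tol) { converged <- TRUE; break }
    r <- dens / rs
    cw <- colSums(r)
    w <- cw / sum(cw)
    for (k in seq_len(K)) {
      if (cw[k] < 1e-8) next  # empty component: keep parameters
      T1 <- sum(r[, k] * lx) / cw[k]
      T2 <- sum(r[, k] * l1x) / cw[k]
      shapes[k, ] <- .beta_wmle(T1, T2, shapes[k, 1], shapes[k, 2])
    }
  }
  if (!converged)
    warning("EM reached maxIter without meeting tolerance", call. = FALSE)

  means <- shapes[, 1] / rowSums(shapes)
  o <- order(means)
  shapes <- shapes[o, , drop = FALSE]
  w <- w[o]
  state_names <- if (K == 3) c("U", "H", "M") else paste0("S", seq_len(K))
  names(w) <- state_names
  rownames(shapes) <- state_names
  colnames(shapes) <- c("a", "b")

  for (k in seq_len(K))
    dens[, k] <- w[k] * dbeta(x, shapes[k, 1], shapes[k, 2])
  post <- dens / pmax(rowSums(dens), 1e-300)
  assign <- max.col(post, ties.method = "first")
  if (K == 3) {
    ## break exact posterior ties toward the hemimethylated state
    tie <- abs(post[, 1] - post[, 2]) < 1e-12 | abs(post[, 3] - post[, 2]) < 1e-12
    assign[tie & (assign == 1 | assign == 3)] <- 2L
  }
  new("BetaMixtureFit", weights = w, shapes = shapes,
      states = factor(state_names[assign], levels = state_names),
      logLik = ll_trace, converged = converged)
}

## Map one sample's type II betas onto its type I mixture fit.
.bmiq_sample <- function(b2, fit1, fit2) {
  st <- as.character(fit2@states)
  out <- clip01(b2, 1e-6, 1 - 1e-6)
  U2 <- st == "U"; H2 <- st == "H"; M2 <- st == "M"
  a1 <- fit1@shapes; a2 <- fit2@shapes
  if (any(U2)) {
    p <- pbeta(out[U2], a2["U", 1], a2["U", 2])
    out[U2] <- qbeta(p, a1["U", 1], a1["U", 2])
  }
  if (any(M2)) {
    p <- pbeta(out[M2], a2["M", 1], a2["M", 2], lower.tail = FALSE)
    out[M2] <- qbeta(p, a1["M", 1], a1["M", 2], lower.tail = FALSE)
  }
  if (any(H2)) {
    rawU_max <- if (any(U2)) max(b2[U2]) else 0
    rawM_min <- if (any(M2)) min(b2[M2]) else 1
    nU_max <- if (any(U2)) max(out[U2]) else 0
    nM_min <- if (any(M2)) min(out[M2]) else 1
    minH <- min(b2[H2]); maxH <- max(b2[H2])
    ## shift H so its gap to the U state is preserved, then dilate so its
    ## gap to the M state is preserved too
    nminH <- nU_max + (minH - rawU_max)
    nmaxH <- nM_min - (rawM_min - maxH)
    if (maxH > minH && nmaxH > nminH) {
      hf <- (nmaxH - nminH) / (maxH - minH)
      out[H2] <- nminH + hf * (b2[H2] - minH)
    } else {
      ## degenerate H span: place proportionally in the transformed gap
      out[H2] <- nU_max + (b2[H2] - rawU_max) / max(rawM_min - rawU_max, 1e-12) *
        max(nM_min - nU_max, 0)
    }
  }
  clip01(out)
}

#' BMIQ normalization of type II probes
#'
#' Normalizes each sample independently: fits three-state Beta mixtures
#' to the sample's type I and type II betas, then transforms the type II
#' betas onto the type I distribution (quantile mapping for the U and M
#' states, shift-and-dilation for the H state). Type I betas are returned
#' bit-identical; the transform is monotone within each state and outputs
#' stay in [0,1].
#'
#' @param x a \linkS4class{MethylationExperiment} whose manifest gives a
#'   design type for every probe.
#' @param tol,maxIter EM settings passed to \code{\link{fitBetaMixture}}.
#' @return a \linkS4class{MethylationExperiment} with normalized betas.
#' @examples
#' cfg <- simulationConfig(nProbes = 3000, seed = 4)
#' sim <- simulateMethylation(simulateManifest(cfg), cfg)
#' norm <- bmiqNormalize(sim$experiment)
#' @export
bmiqNormalize <- function(x, tol = 1e-4, maxIter = 100) {
  man <- probeManifest(x)
  if (any(!man$design_type %in% c("I", "II")))
    stop("design_type must be 'I' or 'II' for every probe", call. = FALSE)
  type2 <- man$design_type == "II"
  if (!any(type2)) return(x)
  if (!any(!type2))
    stop("no type I probes to serve as the reference distribution", call. = FALSE)
  beta <- betaValues(x)
  out <- beta
  for (s in seq_len(ncol(beta))) {
    fit1 <- tryCatch(
      suppressWarnings(fitBetaMixture(beta[!type2, s], tol = tol, maxIter = maxIter)),
      error = function(e) stop("type I mixture fit failed for sample '",
                               colnames(beta)[s], "': ", conditionMessage(e),
                               call. = FALSE))
    fit2 <- tryCatch(
      suppressWarnings(fitBetaMixture(beta[type2, s], tol = tol, maxIter = maxIter)),
      error = function(e) stop("type II mixture fit failed for sample '",
                               colnames(beta)[s], "': ", conditionMessage(e),
                               call. = FALSE))
    out[type2, s] <- .bmiq_sample(beta[type2, s], fit1, fit2)
  }
  se <- x
  SummarizedExperiment::assay(se, "beta") <- out
  se
}

#' Kolmogorov-Smirnov distance between type I and type II betas
#'
#' Convenience diagnostic: the two-sample KS statistic between the type I
#' and type II beta distributions of one sample, used to measure how much
#' normalization reduced the design-type bias.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param sample column index or name.
#' @return the KS statistic (numeric).
#' @export
designTypeKS <- function(x, sample = 1) {
  man <- probeManifest(x)
  b <- betaValues(x)[, sample]
  t2 <- man$design_type == "II"
  as.numeric(suppressWarnings(
    stats::ks.test(b[!t2], b[t2]))$statistic)
}
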