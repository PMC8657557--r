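#' Per-probe two-tailed pooled-variance t-tests
#'
#' For every probe, an unpaired equal-variance t-test between the samples
#' of \code{groupA} and \code{groupB}. The statistic is
#' \eqn{t = (\bar x_A - \bar x_B) / (s_p \sqrt{1/n_A + 1/n_B})} with the
#' pooled variance on \eqn{n_A + n_B - 2} degrees of freedom, and the
#' two-tailed p-value from the t distribution. The reported effect size
#' \code{delta_beta} is \code{mean_B - mean_A}. Benjamini-Hochberg
#' q-values are computed across all tested probes.
#'
#' Degenerate probes with zero pooled variance are handled by convention:
#' equal means give t = 0, p = 1; unequal means give p = 0 and are
#' flagged in the \code{degenerate} column.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param groupA,groupB group labels present in the sample sheet.
#' @param useMValues logical; test on M-values
#'   \eqn{\log_2(\beta/(1-\beta))} (betas clipped to [0.001, 0.999])
#'   instead of betas. Default \code{FALSE}: betas are tested directly.
#' @return data.frame with one row per probe: \code{probe_id},
#'   \code{mean_A}, \code{mean_B}, \code{delta_beta}, \code{t_statistic},
#'   \code{df}, \code{p_value}, \code{q_value}, \code{degenerate}.
#' @examples
#' cfg <- simulationConfig(nProbes = 500, seed = 5)
#' sim <- simulateMethylation(simulateManifest(cfg), cfg)
#' head(ttestProbes(sim$experiment, "C0", "Z0"))
#' @export
ttestProbes <- function(x, groupA, groupB, useMValues = FALSE) {
  grp <- sampleGroups(x)
  if (!groupA %in% grp || !groupB %in% grp)
    stop("groups not found in sample sheet: ",
         paste(setdiff(c(groupA, groupB), grp), collapse = ", "), call. = FALSE)
  b <- betaValues(x)
  A <- b[, grp == groupA, drop = FALSE]
  B <- b[, grp == groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2 || nB < 2)
    stop("need at least 2 replicates per group", call. = FALSE)
  mA_beta <- rowMeans(A); mB_beta <- rowMeans(B)
  if (useMValues) {
    A <- log2(clip01(A, 1e-3, 1 - 1e-3) / (1 - clip01(A, 1e-3, 1 - 1e-3)))
    B <- log2(clip01(B, 1e-3, 1 - 1e-3) / (1 - clip01(B, 1e-3, 1 - 1e-3)))
  }
  mA <- rowMeans(A); mB <- rowMeans(B)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * row_var(A) + (nB - 1) * row_var(B)) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  p <- 2 * pt(-abs(t), df)
  degenerate <- se == 0
  zero_equal <- degenerate & (mA == mB)
  t[zero_equal] <- 0; p[zero_equal] <- 1
  p[degenerate & !zero_equal] <- 0
  t[degenerate & !zero_equal] <- sign(mA - mB)[degenerate & !zero_equal] * Inf
  data.frame(probe_id = rownames(b), mean_A = mA_beta, mean_B = mB_beta,
             delta_beta = mB_beta - mA_beta, t_statistic = t, df = df,
             p_value = p, q_value = bhFDR(p), degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Computes \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1,
#' preserving the p-value ordering.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return numeric vector of q-values in the input order.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Identify rescue sites from two differential contrasts
#'
#' A rescue site is a probe significantly hypermethylated in the
#' knockdown (Z0 vs C0: \code{delta_beta > 0}, q at or below \code{fdr})
#' whose methylation is significantly reduced again under the
#' demethylating drug (Z5 vs Z0: \code{delta_beta < 0}, q at or below
#' \code{fdr}). In \code{"sign"} mode direction alone is required; in
#' \code{"strict"} mode the drug-induced loss must additionally cancel
#' the knockdown-induced gain to within a relative tolerance:
#' \eqn{|\Delta_{Z0Z5} + \Delta_{C0Z0}| \le strictTol \cdot \Delta_{C0Z0}}.
#'
#' @param diffC0Z0 result of \code{ttestProbes(x, "C0", "Z0")} (or any
#'   contrast whose positive deltas mark the gain of interest).
#' @param diffZ0Z5 result of \code{ttestProbes(x, "Z0", "Z5")}.
#' @param fdr q-value cutoff applied to both contrasts (default 0.05).
#' @param mode \code{"sign"} (default) or \code{"strict"}.
#' @param strictTol relative tolerance for strict mode (default 0.5).
#' @param manifest optional probe manifest used to attach gene symbols.
#' @return data.frame with columns \code{probe_id}, \code{delta_C0Z0},
#'   \code{delta_Z0Z5}, \code{q_C0Z0}, \code{q_Z0Z5}, \code{mode},
#'   \code{gene} (empty when no manifest given).
#' @export
identifyRescueSites <- function(diffC0Z0, diffZ0Z5, fdr = 0.05,
                                mode = c("sign", "strict"), strictTol = 0.5,
                                manifest = NULL) {
  mode <- match.arg(mode)
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0,1)", call. = FALSE)
  if (!identical(diffC0Z0$probe_id, diffZ0Z5$probe_id))
    stop("contrasts cover different probe sets", call. = FALSE)
  sel <- diffC0Z0$q_value <= fdr & diffZ0Z5$q_value <= fdr &
    diffC0Z0$delta_beta > 0 & diffZ0Z5$delta_beta < 0
  if (mode == "strict")
    sel <- sel & abs(diffZ0Z5$delta_beta + diffC0Z0$delta_beta) <=
      strictTol * abs(diffC0Z0$delta_beta)
  sel[is.na(sel)] <- FALSE
  out <- data.frame(probe_id = diffC0Z0$probe_id[sel],
                    delta_C0Z0 = diffC0Z0$delta_beta[sel],
                    delta_Z0Z5 = diffZ0Z5$delta_beta[sel],
                    q_C0Z0 = diffC0Z0$q_value[sel],
                    q_Z0Z5 = diffZ0Z5$q_value[sel],
                    mode = rep_len(mode, sum(sel)), stringsAsFactors = FALSE)
  out$gene <- if (!is.null(manifest))
    manifest$gene[match(out$probe_id, manifest$probe_id)]
  else rep_len("", nrow(out))
  out$gene[is.na(out$gene)] <- ""
  out
}

#' Collapse rescue sites to a gene-level table
#'
#' Maps each rescue site to its manifest gene symbol (kept with an empty
#' symbol when unannotated; no silent drops) and counts sites per gene.
#'
#' @param sites rescue-site table from \code{\link{identifyRescueSites}}.
#' @param manifest probe manifest with a populated \code{gene} column.
#' @return data.frame with columns \code{gene}, \code{n_sites},
#'   \code{probe_ids} (comma-separated), ordered by decreasing site count.
#' @export
annotateGenes <- function(sites, manifest) {
  gene <- manifest$gene[match(sites$probe_id, manifest$probe_id)]
  gene[is.na(gene)] <- ""
  sp <- split(sites$probe_id, gene)
  out <- data.frame(gene = names(sp),
                    n_sites = vapply(sp, length, integer(1)),
                    probe_ids = vapply(sp, paste, character(1), collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_sites, out$gene), , drop = FALSE]
}
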