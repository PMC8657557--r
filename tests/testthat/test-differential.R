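test_that("pooled t-test reproduces the textbook worked example", {
  beta <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  x <- make_mexp(beta, rep(c("A", "B"), each = 3))
  res <- ttestProbes(x, "A", "B")
  expect_equal(res$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(res$delta_beta, 0.3)
  ## identical groups: t = 0, p = 1
  x2 <- make_mexp(rbind(rep(c(0.2, 0.3, 0.4), 2)), rep(c("A", "B"), each = 3))
  res2 <- ttestProbes(x2, "A", "B")
  expect_equal(res2$t_statistic, 0)
  expect_equal(res2$p_value, 1)
})

test_that("t, p and q match the stats-package oracle to 1e-10", {
  set.seed(201)
  n <- 1000
  beta <- matrix(runif(n * 8, 0.05, 0.95), n, 8)
  x <- make_mexp(beta, rep(c("A", "B"), each = 4))
  res <- ttestProbes(x, "A", "B")
  oracle_t <- oracle_p <- numeric(n)
  for (i in seq_len(n)) {
    tt <- t.test(beta[i, 1:4], beta[i, 5:8], var.equal = TRUE)
    oracle_t[i] <- unname(tt$statistic)
    oracle_p[i] <- tt$p.value
  }
  expect_equal(res$t_statistic, oracle_t, tolerance = 1e-10)
  expect_equal(res$p_value, oracle_p, tolerance = 1e-10)
  expect_equal(res$q_value, p.adjust(oracle_p, "BH"), tolerance = 1e-10)
})

test_that("degenerate zero-variance probes follow the stated conventions", {
  beta <- rbind(c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),   # equal, zero var
                c(0.2, 0.2, 0.2, 0.5, 0.5, 0.5))   # unequal, zero var
  x <- make_mexp(beta, rep(c("A", "B"), each = 3))
  res <- ttestProbes(x, "A", "B")
  expect_equal(res$p_value, c(1, 0))
  expect_equal(res$t_statistic[1], 0)
  expect_true(all(res$degenerate))
})

test_that("type-I error of the probe t-test is calibrated under the null", {
  set.seed(202)
  n <- 10000
  beta <- pmin(pmax(matrix(rnorm(n * 8, 0.5, 0.05), n, 8), 0), 1)
  x <- make_mexp(beta, rep(c("A", "B"), each = 4))
  res <- ttestProbes(x, "A", "B")
  rate <- mean(res$p_value <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("BH step-up q-values follow the formula and preserve order", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.037), 0.037)
  expect_error(bhFDR(numeric(0)), "empty")
  set.seed(203)
  for (k in 1:5) {
    p <- runif(200)^2
    q <- bhFDR(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    ## order preserved
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("statistics are invariant to permuting samples within groups", {
  sim <- sim_fixture(nProbes = 300, seed = 53)
  x <- sim$experiment
  grp <- sampleGroups(x)
  perm <- unlist(lapply(unique(grp), function(g) sample(which(grp == g))))
  res1 <- ttestProbes(x, "C0", "Z0")
  res2 <- ttestProbes(x[, perm], "C0", "Z0")
  expect_equal(res1$t_statistic, res2$t_statistic)
  expect_equal(res1$q_value, res2$q_value)
})

test_that("rescue calls follow the sign and strict rules", {
  mk <- function(d1, d2, q1 = 0.01, q2 = 0.01) {
    list(data.frame(probe_id = "cg1", mean_A = 0.3, mean_B = 0.3 + d1,
                    delta_beta = d1, t_statistic = 1, df = 6, p_value = q1,
                    q_value = q1, degenerate = FALSE),
         data.frame(probe_id = "cg1", mean_A = 0.3 + d1, mean_B = 0.3 + d1 + d2,
                    delta_beta = d2, t_statistic = 1, df = 6, p_value = q2,
                    q_value = q2, degenerate = FALSE))
  }
  ## exact reversion: rescue under both modes
  r <- mk(0.3, -0.3)
  expect_equal(nrow(identifyRescueSites(r[[1]], r[[2]], mode = "sign")), 1)
  expect_equal(nrow(identifyRescueSites(r[[1]], r[[2]], mode = "strict")), 1)
  ## same direction: never a rescue
  r2 <- mk(0.3, 0.2)
  expect_equal(nrow(identifyRescueSites(r2[[1]], r2[[2]], mode = "sign")), 0)
  ## partial reversion: sign yes, strict (tol 0.5) no
  r3 <- mk(0.3, -0.1)
  expect_equal(nrow(identifyRescueSites(r3[[1]], r3[[2]], mode = "sign")), 1)
  expect_equal(nrow(identifyRescueSites(r3[[1]], r3[[2]], mode = "strict")), 0)
  ## non-significant contrast blocks the call
  r4 <- mk(0.3, -0.3, q2 = 0.2)
  expect_equal(nrow(identifyRescueSites(r4[[1]], r4[[2]])), 0)
  ## mismatched probe sets rejected
  r5 <- mk(0.3, -0.3)
  r5[[2]]$probe_id <- "cgX"
  expect_error(identifyRescueSites(r5[[1]], r5[[2]]), "different probe sets")
})

test_that("strict-mode rescue set is nested in the sign-mode set", {
  sim <- sim_fixture(nProbes = 3000, seed = 59, nDifferential = 100,
                     nRescue = 50)
  qc <- runQC(sim$experiment, "partial")
  d1 <- ttestProbes(qc$experiment, "C0", "Z0")
  d2 <- ttestProbes(qc$experiment, "Z0", "Z5")
  sgn <- identifyRescueSites(d1, d2, mode = "sign")
  strict <- identifyRescueSites(d1, d2, mode = "strict")
  expect_true(all(strict$probe_id %in% sgn$probe_id))
  ## rescue set is inside both significant sets
  sig1 <- d1$probe_id[d1$q_value <= 0.05]
  sig2 <- d2$probe_id[d2$q_value <= 0.05]
  expect_true(all(sgn$probe_id %in% intersect(sig1, sig2)))
})

test_that("gene annotation equals a brute-force join and drops nothing", {
  man <- make_manifest(20)
  man$gene <- c(rep("GENEA", 3), rep("GENEB", 2), rep("", 2),
                sprintf("G%02d", 8:20))
  sites <- data.frame(probe_id = man$probe_id[c(1, 2, 4, 6)],
                      delta_C0Z0 = 0.3, delta_Z0Z5 = -0.3,
                      q_C0Z0 = 0.01, q_Z0Z5 = 0.01, mode = "sign",
                      stringsAsFactors = FALSE)
  tab <- annotateGenes(sites, man)
  expect_equal(sum(tab$n_sites), 4)          # no silent drops
  expect_equal(tab$n_sites[tab$gene == "GENEA"], 2)
  expect_equal(tab$n_sites[tab$gene == ""], 1)
  ## brute-force oracle join
  oracle <- table(man$gene[match(sites$probe_id, man$probe_id)])
  for (k in seq_along(oracle))
    expect_equal(tab$n_sites[tab$gene == names(oracle)[k]],
                 as.integer(oracle[k]), ignore_attr = TRUE)
})
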