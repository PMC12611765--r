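makeTable <- function(mat, groups) {
  rownames(mat) <- if (is.null(rownames(mat)))
    sprintf("TG %d:1", seq(40, by = 2, length.out = nrow(mat)))
  else rownames(mat)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  lipidomeTable(mat, groups)
}

test_that("log10 transform handles values and zeros per the substitution rule", {
  m <- rbind(c(100, 1000, 100, 1000), c(1, 10, 100, 1000),
             c(0, 10, 20, 40))
  tb <- log10Transform(makeTable(m, c("a", "a", "b", "b")))
  expect_equal(processingState(tb), "log10")
  lg <- assayMatrix(tb, "log10")
  expect_equal(lg[1, ], log10(c(100, 1000, 100, 1000)), ignore_attr = TRUE)
  expect_equal(lg[2, 1], 0)
  # zero replaced by one fifth of the feature's minimum positive value
  expect_equal(lg[3, 1], log10(10 / 5))
  expect_equal(nrow(metadata(tb)$zeroReplaced), 1L)
  expect_error(log10Transform(tb), "state 'raw'")
})

test_that("autoscaling yields mean zero, unit sd, and is idempotent", {
  set.seed(31)
  m <- matrix(10^runif(80, 3, 7), 20, 4)
  m <- rbind(m, rep(1000, 4))  # constant feature
  tb <- autoscale(log10Transform(makeTable(m, c("a", "a", "b", "b"))))
  sc <- assayMatrix(tb, "autoscaled")
  expect_true(all(abs(rowMeans(sc)) < 1e-12))
  expect_true(all(abs(apply(sc[1:20, ], 1, sd) - 1) < 1e-12))
  # constant features become zero vectors and are flagged
  expect_equal(unname(sc[21, ]), rep(0, 4))
  expect_length(metadata(tb)$constantFeatures, 1L)
  # two-sample feature standardizes to +/- 1/sqrt(2) with the n-1 sd
  m2 <- matrix(c(10, 1000), 1, 2, dimnames = list("TG 40:1", NULL))
  sc2 <- assayMatrix(autoscale(log10Transform(makeTable(m2, c("a", "b")))))
  expect_equal(unname(sc2[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # idempotence
  tb2 <- autoscale(tb)
  expect_equal(assayMatrix(tb2, "autoscaled"), sc, tolerance = 1e-12)
})

test_that("differential test matches t.test per feature and handles identical groups", {
  set.seed(32)
  m <- matrix(10^rnorm(200, 5, 0.3), 25, 8)
  g <- rep(c("WT", "KO"), each = 4)
  tb <- autoscale(log10Transform(makeTable(m, g)))
  res <- differentialTest(tb, "KO", "WT")
  # cross-check a few features against stats::t.test on the same values
  sc <- assayMatrix(tb, "autoscaled")
  for (i in c(1, 7, 25)) {
    tt <- t.test(sc[i, g == "KO"], sc[i, g == "WT"])
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # fold change computed on raw means
  raw <- assayMatrix(tb, "raw")
  expect_equal(res$fc, rowMeans(raw[, g == "KO"]) /
                 rowMeans(raw[, g == "WT"]), ignore_attr = TRUE)
  # identical groups: fold change 1, p = 1
  mid <- cbind(m[, 1:4], m[, 1:4])
  tbid <- autoscale(log10Transform(makeTable(mid, g)))
  rid <- differentialTest(tbid, "KO", "WT")
  expect_equal(rid$fc, rep(1, nrow(mid)))
  expect_true(all(rid$p == 1))
})

test_that("BH q-values are monotone in p-rank and bounded below by p", {
  set.seed(33)
  m <- matrix(10^rnorm(400, 5, 0.2), 50, 8)
  tb <- autoscale(log10Transform(makeTable(m, rep(c("a", "b"), each = 4))))
  res <- differentialTest(tb, "a", "b")
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("volcano classification applies strict dual thresholds", {
  res <- data.frame(fc = c(2, 4, 4, 0.4, 1), q = c(0.01, 0.01, 0.2, 0.01, 0.5))
  out <- volcanoClassify(res)
  expect_equal(out$label, c("ns", "up", "ns", "down", "ns"))
  expect_equal(attr(out, "counts"), c(up = 1L, down = 1L, ns = 3L))
})

test_that("hierarchical clustering recovers planted blocks deterministically", {
  set.seed(34)
  g <- rep(c("a", "b"), each = 4)
  block1 <- matrix(10^(5 + rnorm(40, 0, 0.05)), 10, 8)
  block2 <- matrix(10^(5 + rnorm(40, 0, 0.05)), 10, 8)
  block1[, 5:8] <- block1[, 5:8] * 16
  block2[, 1:4] <- block2[, 1:4] * 16
  m <- rbind(block1, block2)
  rownames(m) <- sprintf("TG %d:1", seq(40, by = 2, length.out = 20))
  tb <- autoscale(log10Transform(makeTable(m, g)))
  cl <- hierarchicalCluster(tb, k = 2)
  expect_length(unique(cl$clusters[1:10]), 1L)
  expect_length(unique(cl$clusters[11:20]), 1L)
  expect_false(cl$clusters[1] == cl$clusters[11])
  # permuting input order leaves memberships unchanged
  perm <- sample(20)
  tbp <- autoscale(log10Transform(makeTable(m[perm, ], g)))
  clp <- hierarchicalCluster(tbp, k = 2)
  same <- outer(cl$clusters, cl$clusters, "==")
  samep <- outer(clp$clusters[rownames(m)], clp$clusters[rownames(m)], "==")
  expect_equal(same, samep, ignore_attr = TRUE)
  # duplicate rows merge at height zero
  dup <- rbind(m, m[1, , drop = FALSE])
  rownames(dup)[21] <- "TG 80:1"
  tbd <- autoscale(log10Transform(makeTable(dup, g)))
  expect_equal(min(hierarchicalCluster(tbd)$hclust$height), 0)
})

test_that("essentiality correlation reports r, q, and flags degenerate input", {
  set.seed(36)
  ess <- rnorm(200)
  mets <- rbind(identical = ess,
                noise1 = rnorm(200), noise2 = rnorm(200),
                constant = rep(1, 200))
  out <- essentialityCorrelation(mets, ess)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_lt(out$q[1], 1e-10)
  expect_true(all(abs(out$r[2:3]) < 0.2))
  expect_true(all(out$q[2:3] > 0.2))
  expect_true(is.na(out$r[4]) && out$flag[4] == "undefined")
  # missing values handled pairwise complete
  mets2 <- mets
  mets2[1, 1:10] <- NA
  out2 <- essentialityCorrelation(mets2, ess)
  expect_equal(out2$n[1], 190L)
  expect_equal(out2$r[1], 1, tolerance = 1e-12)
})
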