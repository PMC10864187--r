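test_that("maximum projection equals the per-pixel maximum", {
  set.seed(1)
  stack <- array(rnorm(6 * 7 * 5), dim = c(6, 7, 5))
  expect_equal(maxZProjection(stack), naiveMaxProjection(stack))
  single <- array(stack[, , 1], dim = c(6, 7, 1))
  expect_equal(maxZProjection(single), stack[, , 1])
  expect_identical(maxZProjection(stack[, , 1]), stack[, , 1])
  expect_error(maxZProjection(array(1, dim = c(2, 2, 2, 2))), "2-D|3-D")
})

test_that("blank images yield no puncta", {
  img <- matrix(5, 64, 64)
  expect_equal(nrow(detectPuncta(img, threshold = 10)), 0L)
})

test_that("planted spots are recovered with sub-pixel centroid accuracy", {
  sim <- simulateSpotImages(shape = c(256, 256), nSpots = 50,
                            amplitude = 100, background = 100,
                            minSeparationPx = 10, seed = 4)
  puncta <- detectPuncta(sim$images[[1]])
  expect_equal(nrow(puncta), 50L)
  truth <- sim$truth
  d <- sqrt(outer(puncta$row, truth$row, "-")^2 +
              outer(puncta$col, truth$col, "-")^2)
  nearest <- apply(d, 1, min)
  expect_true(all(nearest < 1))
})

test_that("punctum intensity is the maximum pixel it covers", {
  img <- matrix(0, 32, 32)
  img[10:12, 10:12] <- 50
  img[11, 11] <- 80
  p <- detectPuncta(img, threshold = 20, minAreaPx = 2)
  expect_equal(nrow(p), 1L)
  expect_equal(p$intensity, 80)
  expect_equal(p$area, 9L)
  expect_equal(p$row, 10)   # 0-based centroid of rows 10:12 (1-based)
  expect_equal(p$col, 10)
})

test_that("detection respects 8-connectivity and the area filter", {
  img <- matrix(0, 16, 16)
  img[3, 3] <- 10; img[4, 4] <- 10              # diagonal pair: one punctum
  img[10, 10] <- 10                             # isolated single pixel
  p <- detectPuncta(img, threshold = 5, minAreaPx = 2)
  expect_equal(nrow(p), 1L)
  expect_equal(p$area, 2L)
  p1 <- detectPuncta(img, threshold = 5, minAreaPx = 1)
  expect_equal(nrow(p1), 2L)
})

test_that("identical and disjoint puncta sets colocalize as expected", {
  a <- data.frame(row = c(5, 20, 40), col = c(5, 22, 41))
  res <- colocalize(a, a, radiusPx = 2)
  expect_equal(res$pctBothA, 100)
  expect_equal(res$pctBothB, 100)
  expect_equal(res$pctOnlyA, 0)
  b <- data.frame(row = a$row + 50, col = a$col + 50)
  res2 <- colocalize(a, b, radiusPx = 2)
  expect_equal(res2$nBoth, 0L)
  expect_equal(res2$pctOnlyA, 100)
  empty <- data.frame(row = numeric(), col = numeric())
  res3 <- colocalize(a, empty, radiusPx = 2)
  expect_true(is.na(res3$pctBothB))
  expect_equal(res3$pctOnlyA, 100)
})

test_that("matching is one-to-one and fractions are conserved", {
  set.seed(7)
  a <- data.frame(row = runif(30, 0, 100), col = runif(30, 0, 100))
  b <- data.frame(row = runif(25, 0, 100), col = runif(25, 0, 100))
  res <- colocalize(a, b, radiusPx = 10)
  expect_equal(anyDuplicated(res$matches$i), 0L)
  expect_equal(anyDuplicated(res$matches$j), 0L)
  expect_equal(res$pctBothA + res$pctOnlyA, 100)
  expect_equal(res$pctBothB + res$pctOnlyB, 100)
  expect_true(all(res$matches$dist <= 10))
})

test_that("a planted colocalization fraction is recovered", {
  sim <- simulateSpotImages(shape = c(512, 512), nSpots = 200, nChannels = 2,
                            colocFraction = 0.8, minSeparationPx = 8,
                            seed = 21)
  pa <- detectPuncta(sim$images[[1]])
  pb <- detectPuncta(sim$images[[2]])
  res <- colocalize(pa, pb, radiusPx = 2)
  # 95% binomial interval around 80% at n = 200
  ci <- 100 * (0.8 + c(-1, 1) * 1.96 * sqrt(0.8 * 0.2 / 200))
  expect_gte(res$pctBothB, ci[1])
  expect_lte(res$pctBothB, ci[2])
})

test_that("per-cell counts assign centroids to mask labels exactly", {
  mask <- matrix(1L, 20, 20)
  p <- data.frame(row = runif(12, 1, 18), col = runif(12, 1, 18))
  counts <- perCellCounts(list(gene = p), mask)
  expect_equal(unname(counts["cell_1", "gene"]), 12L)

  mask2 <- matrix(0L, 20, 20)
  mask2[1:10, 1:10] <- 1L
  mask2[11:20, 11:20] <- 2L
  puncta <- list(g1 = data.frame(row = c(2, 3, 15), col = c(2, 3, 15)),
                 g2 = data.frame(row = c(5, 15, 2), col = c(15, 2, 5)))
  counts2 <- perCellCounts(puncta, mask2)
  expect_equal(unname(counts2[, "g1"]), c(2L, 1L))
  expect_equal(unname(counts2[, "g2"]), c(1L, 0L))
  expect_equal(unname(attr(counts2, "background")),
               c(0L, 2L))
  # conservation: cells + background = total
  expect_equal(sum(counts2) + sum(attr(counts2, "background")),
               sum(vapply(puncta, nrow, integer(1))))
})

test_that("planted per-cell counts are recovered exactly", {
  set.seed(31)
  mask <- matrix(0L, 60, 60)
  mask[5:25, 5:25] <- 1L
  mask[35:55, 30:55] <- 2L
  planted <- list(c(7L, 3L), c(2L, 9L))  # per cell, per target
  puncta <- lapply(1:2, function(t) {
    ps <- lapply(1:2, function(cell) {
      n <- planted[[cell]][t]
      idx <- which(mask == cell, arr.ind = TRUE)
      pick <- idx[sample(nrow(idx), n), , drop = FALSE]
      data.frame(row = pick[, 1] - 1, col = pick[, 2] - 1)
    })
    do.call(rbind, ps)
  })
  names(puncta) <- c("t1", "t2")
  counts <- perCellCounts(puncta, mask)
  expect_equal(unname(counts[, "t1"]), c(7L, 2L))
  expect_equal(unname(counts[, "t2"]), c(3L, 9L))
})

test_that("expression filters drop cells per the high/low rules", {
  counts <- matrix(c(4, 5, 12, 0,
                     2, 1, 3, 0), ncol = 2,
                   dimnames = list(paste0("cell_", 1:4), c("hi", "lo")))
  cls <- c(hi = "high", lo = "low")
  f <- filterCells(counts, cls)
  expect_true(is.na(f["cell_1", "hi"]))      # 4 < 5 excluded
  expect_equal(f["cell_2", "hi"], 5)          # 5 retained
  expect_true(is.na(f["cell_2", "lo"]))      # 1 < 2 excluded
  expect_equal(f["cell_1", "lo"], 2)          # 2 is not fewer than 2
  expect_false("cell_4" %in% rownames(f))     # excluded everywhere
  zeros <- matrix(0, 3, 2, dimnames = list(NULL, c("hi", "lo")))
  expect_equal(nrow(filterCells(zeros, cls)), 0L)
  expect_error(filterCells(counts, c(hi = "high", lo = "mid")), "unknown")
  expect_error(filterCells(counts, c(hi = "high")), "class")
})

test_that("overlay reconstruction conserves puncta across channels", {
  set.seed(8)
  puncta <- lapply(1:15, function(k)
    data.frame(row = runif(k), col = runif(k), intensity = runif(k)))
  names(puncta) <- paste0("gene", 1:15)
  tab <- overlayReconstruction(puncta, round = rep(1:5, each = 3),
                               fluor = rep(c("488", "565", "647"), 5))
  expect_equal(nrow(tab), sum(1:15))
  expect_equal(as.integer(table(tab$target)["gene7"]), 7L)
  single <- lapply(1:15, function(k) data.frame(row = 0, col = 0,
                                                intensity = 1))
  names(single) <- paste0("g", 1:15)
  expect_equal(nrow(overlayReconstruction(single)), 15L)
  expect_equal(nrow(overlayReconstruction(list())), 0L)
})
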