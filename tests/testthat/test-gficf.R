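test_that("gene_frequency normalizes each cell to sum one and keeps zeros", {
  m <- rc(matrix(c(2, 1, 1, 0), ncol = 1))
  expect_equal(as.numeric(gene_frequency(m)), c(0.5, 0.25, 0.25, 0))
  m2 <- rc(matrix(c(7, 0, 0), ncol = 1))
  expect_equal(as.numeric(gene_frequency(m2)), c(1, 0, 0))

  set.seed(3)
  m3 <- rc(matrix(rpois(200, 2) + rep(c(1, 0), 100), 20))
  gf <- gene_frequency(m3)
  expect_true(all(abs(Matrix::colSums(gf) - 1) < 1e-12))
  # sparsity pattern unchanged
  expect_identical(as.matrix(gf) == 0, as.matrix(m3$counts) == 0)

  m4 <- rc(matrix(c(1, 0, 0, 0), 2), cells = c("ok", "empty"))
  expect_error(gene_frequency(m4), "empty")
})

test_that("inverse_cell_frequency evaluates log(N/(n_i + 1))", {
  # N = 100 cells: gene A unexpressed, gene B in 99 cells, gene C in all 100
  counts <- rbind(A = rep(0, 100),
                  B = c(0, rep(1, 99)),
                  C = rep(2, 100))
  m <- rc(counts, genes = rownames(counts))
  icf <- inverse_cell_frequency(m)
  expect_equal(icf$n_cells_expressing, c(0L, 99L, 100L))
  expect_equal(icf$icf[1], log(100))
  expect_equal(icf$icf[2], 0)
  expect_equal(icf$icf[3], log(100 / 101))   # negative under the formula
  # monotone non-increasing in n_i, invariant under cell permutation
  expect_true(all(diff(icf$icf[order(icf$n_cells_expressing)]) <= 0))
  perm <- sample(100)
  m_perm <- rc(counts[, perm], genes = rownames(counts),
               cells = m$cell_ids[perm])
  expect_equal(inverse_cell_frequency(m_perm)$icf, icf$icf)
})

test_that("gficf_transform matches a dense triple-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    counts <- matrix(rpois(15 * 8, 1.5), 15)
    counts[1, colSums(counts) == 0] <- 1
    m <- rc(counts)
    g <- gficf_transform(m)
    expect_lt(max(abs(as.matrix(g$weights) - gficf_oracle(counts))), 1e-12)
    expect_true(all(abs(sqrt(Matrix::colSums(g$weights^2)) - 1) < 1e-9))
  }
})

test_that("gficf columns are invariant to per-cell depth scaling", {
  set.seed(9)
  counts <- matrix(rpois(30 * 6, 2), 30)
  counts[1, colSums(counts) == 0] <- 1
  g1 <- gficf_transform(rc(counts))
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7L    # multiply one cell's counts
  scaled[, 5] <- scaled[, 5] * 3L
  g2 <- gficf_transform(rc(scaled))
  expect_lt(max(abs(as.matrix(g1$weights) - as.matrix(g2$weights))), 1e-12)
})

test_that("degenerate all-zero weighted cells raise an error", {
  # genes 1-2 expressed in 2/3 cells each -> ICF = log(3/3) = 0; gene 3 never
  counts <- cbind(C1 = c(4, 0, 0), C2 = c(0, 4, 0), C3 = c(2, 2, 0))
  m <- rc(counts, cells = colnames(counts))
  expect_equal(inverse_cell_frequency(m)$icf, c(0, 0, log(3)))
  expect_error(gficf_transform(m), "degenerate")
})

test_that("negative-ICF policy: clamp by default, literal formula on request", {
  # n = (1, 3) over N = 3 cells: ICF = (log(1.5), log(0.75))
  counts <- cbind(C1 = c(3, 1), C2 = c(0, 2), C3 = c(0, 5))
  m <- rc(counts, cells = colnames(counts))
  g_neg <- gficf_transform(m, allow_negative_icf = TRUE)
  expect_equal(g_neg$icf$icf, c(log(1.5), log(0.75)))
  # C2, C3 weight vectors are proportional to (0, log 0.75) -> L2 (0, -1)
  expect_equal(as.numeric(g_neg$weights[, "C2"]), c(0, -1))
  expect_equal(as.numeric(g_neg$weights[, "C3"]), c(0, -1))
  # default policy clamps gene 2 to 0, leaving C2/C3 all-zero -> error
  expect_error(gficf_transform(m), "degenerate")
  # clamping is flagged where it does not degenerate: with N = 3 and add-one
  # smoothing only n_i = 1 genes keep a positive ICF, so every cell gets a
  # private gene next to the ubiquitous (clamped) one
  counts2 <- rbind(g1 = c(2, 0, 0), g2 = c(1, 3, 5),
                   g3 = c(0, 4, 0), g4 = c(0, 0, 6))
  g_cl <- gficf_transform(rc(counts2, genes = rownames(counts2)))
  expect_identical(g_cl$icf$clamped, c(FALSE, TRUE, FALSE, FALSE))
  # the recorded ICF keeps the formula value; the weights use the clamp
  expect_equal(g_cl$icf$icf,
               c(log(3 / 2), log(3 / 4), log(3 / 2), log(3 / 2)))
  expect_equal(as.numeric(g_cl$weights["g2", ]), c(0, 0, 0))
})

test_that("add_one_outside smoothing variant computes log(N/n_i + 1)", {
  counts <- cbind(c(1, 2, 0), c(0, 3, 0), c(2, 1, 0))
  m <- rc(counts)
  icf <- inverse_cell_frequency(m, smoothing = "add_one_outside")
  expect_equal(icf$icf[1:2], c(log(3 / 2 + 1), log(2)))
  expect_identical(icf$icf[3], Inf)   # unexpressed gene, limit value
  g <- gficf_transform(m, smoothing = "add_one_outside")
  expect_true(all(is.finite(g$weights@x)))
  expect_true(all(abs(sqrt(Matrix::colSums(g$weights^2)) - 1) < 1e-9))
})

test_that("log base cancels under L2 when ICF is applied uniformly", {
  set.seed(5)
  counts <- matrix(rpois(40 * 8, 2), 40)
  counts[1, colSums(counts) == 0] <- 1
  m <- rc(counts)
  g_nat <- gficf_transform(m, allow_negative_icf = TRUE)
  g_2 <- gficf_transform(m, log_base = 2, allow_negative_icf = TRUE)
  expect_lt(max(abs(as.matrix(g_nat$weights) - as.matrix(g_2$weights))),
            1e-12)
})
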