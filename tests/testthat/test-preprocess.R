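test_that("low-expression filtering drops the lowest-mean genes", {
  Y <- tiny_expression(matrix(c(1, 10, 100, 1000, 1, 10, 100, 1000), 4, 2),
                       genes = c("lo1", "lo2", "hi1", "hi2"))
  expect_identical(filter_low_expression(Y, 0), Y)
  out <- filter_low_expression(Y, 0.5)
  expect_equal(rownames(out), c("hi1", "hi2"))

  # exact count: floor(drop_fraction * m)
  set.seed(5)
  big <- tiny_expression(matrix(runif(2000), 1000, 2))
  expect_equal(nrow(filter_low_expression(big, 0.5)), 500L)
  expect_error(filter_low_expression(Y, 1), "drop_fraction")

  # idempotence: filtering half then nothing equals filtering half once
  once <- filter_low_expression(big, 0.5)
  expect_identical(filter_low_expression(once, 0), once)
})

test_that("CV filtering keeps the most variable genes in order", {
  Y <- tiny_expression(matrix(c(1, 1, 1, 2, 1, 3), 2, 3, byrow = TRUE),
                       genes = c("flat", "ramp"), samples = c("a", "b", "c"))
  # CV of (1,2,3) = 1/2; CV of (1,1,1) = 0
  expect_identical(filter_top_cv(Y, 1), Y)
  expect_equal(rownames(filter_top_cv(Y, 0.5)), "ramp")

  set.seed(6)
  big <- tiny_expression(matrix(runif(1500), 500, 3))
  expect_equal(nrow(filter_top_cv(big, 0.5)), 250L)
  expect_error(filter_top_cv(tiny_expression(matrix(1:2, 2, 1)), 0.5),
               "at least 2 samples")
  # survivors keep their original relative order
  kept <- filter_top_cv(big, 0.3)
  expect_true(!is.unsorted(match(rownames(kept), rownames(big))))
})

test_that("zero-mean genes get CV 0 and are dropped first", {
  Y <- tiny_expression(rbind(c(0, 0, 0), c(5, 6, 7)),
                       genes = c("zero", "live"), samples = c("a", "b", "c"))
  expect_equal(rownames(filter_top_cv(Y, 0.5)), "live")
})

test_that("marker selection from pure profiles applies all three thresholds", {
  # 2 cell types x 3 replicates; log2 values chosen by hand
  # gene  A-mean  B-mean  selected-for
  # mk_a   10       2     A (log2FC 8, second max 4+eps < 128)
  # flat    5       5     none (log2FC 0)
  # weak    6       5.2   none (log2FC 0.8 < 1.5)
  # high    12      9     none (second-highest linear max 2^9 = 512 > 128)
  vals <- rbind(
    mk_a = 2^c(10, 10, 10, 2, 2, 2),
    flat = 2^c(5, 5, 5, 5, 5, 5),
    weak = 2^c(6.0, 6.1, 5.9, 5.2, 5.3, 5.1),
    high = 2^c(12, 12.1, 11.9, 9, 9.1, 8.9))
  pure <- tiny_expression(vals, genes = rownames(vals),
                          samples = paste0("s", 1:6))
  labels <- rep(c("A", "B"), each = 3)
  mk <- suppressWarnings(select_markers_from_pure(pure, labels))
  expect_equal(names(mk), "A")
  expect_equal(mk$A, "mk_a")

  st <- attr(mk, "stats")
  # zero within-group variance with different means => p = 0 (limit)
  expect_equal(st$p_value[st$gene_id == "mk_a"], 0)
  expect_equal(st$p_value[st$gene_id == "flat"], 1)
  # the p-value limit agrees with a jittered standard t-test
  set.seed(9)
  x <- c(10, 10, 10) + rnorm(3, sd = 1e-6)
  y <- c(2, 2, 2) + rnorm(3, sd = 1e-6)
  expect_lt(t.test(x, y, var.equal = TRUE)$p.value, 1e-10)
})

test_that("marker lists are disjoint, thresholded, and capped at top_n", {
  set.seed(11)
  K <- 3; reps <- 3; m <- 300
  base <- 2^runif(m, 4, 6)          # low baseline so the cap is satisfied
  X <- matrix(rep(base, K), m, K)
  marker_idx <- split(1:60, rep(1:K, each = 20))
  for (k in 1:K) X[marker_idx[[k]], k] <- X[marker_idx[[k]], k] * 50
  pure <- X[, rep(1:K, each = reps)] * matrix(2^rnorm(m * K * reps, sd = 0.1),
                                              m, K * reps)
  pure <- tiny_expression(pure, genes = sprintf("g%03d", 1:m),
                          samples = paste0("s", 1:(K * reps)))
  labels <- rep(paste0("ct", 1:K), each = reps)
  params <- marker_selection_params(top_n = 10)
  mk <- suppressWarnings(select_markers_from_pure(pure, labels, params))

  expect_true(all(lengths(mk) <= 10))
  expect_equal(anyDuplicated(unlist(mk)), 0L)

  # re-check every selected gene against the thresholds independently
  st <- attr(mk, "stats")
  lg <- log2(pure)
  for (ct in names(mk)) {
    for (g in mk[[ct]]) {
      row <- st[st$gene_id == g, ]
      expect_equal(row$cell_type, ct)
      expect_lt(row$p_value, params$p_threshold)
      expect_gt(row$log2_fold_change, params$log2fc_threshold)
      expect_lt(row$second_highest_max, params$second_highest_cap)
      # fold change re-derived from the raw data
      gm <- tapply(lg[g, ], labels, mean)
      expect_equal(row$log2_fold_change,
                   unname(sort(gm, decreasing = TRUE)[1] -
                          sort(gm, decreasing = TRUE)[2]))
    }
  }

  fdr <- marker_fdr_report(mk)
  expect_equal(fdr$cell_type, names(mk))
  expect_true(all(fdr$max_fdr >= 0 & fdr$max_fdr <= 1))
})

test_that("marker selection rejects degenerate designs", {
  pure <- tiny_expression(matrix(2^runif(20, 4, 8), 5, 4),
                          samples = paste0("s", 1:4))
  expect_error(select_markers_from_pure(pure, c("A", "A", "A", "B")),
               "fewer than 2 replicates")
  expect_error(select_markers_from_pure(pure, rep("A", 4)),
               "at least 2 cell types")
})
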