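test_that("row normalization projects genes onto the simplex", {
  Y <- tiny_expression(rbind(c(2, 2), c(1, 3)))
  N <- normalize_rows(Y)
  expect_equal(N["g1", ], c(s1 = 0.5, s2 = 0.5))
  expect_equal(N["g2", ], c(s1 = 0.25, s2 = 0.75))

  set.seed(3)
  R <- tiny_expression(matrix(runif(60) + 0.01, 20, 3))
  expect_equal(unname(rowSums(normalize_rows(R))), rep(1, 20),
               tolerance = 1e-12)

  Z <- tiny_expression(rbind(c(0, 0), c(1, 1)), genes = c("dead", "live"))
  expect_error(normalize_rows(Z), "dead")
})

test_that("initial centers anchor marker means and sample the rest", {
  set.seed(2)
  Y <- tiny_expression(matrix(runif(40), 10, 4))
  # single-marker anchor equals the gene row
  mk1 <- marker_catalog(list(A = "g3"))
  ic <- init_centers(Y, mk1, C = 3, seed = 1)
  expect_equal(ic$centers[1, ], Y["g3", ])
  # two-marker anchor equals the hand average
  Y2 <- tiny_expression(rbind(c(0, 2), c(2, 0), c(5, 5), c(7, 1)))
  ic2 <- init_centers(Y2, marker_catalog(list(A = c("g1", "g2"))), C = 2,
                      seed = 1)
  expect_equal(unname(ic2$centers[1, ]), c(1, 1))
  # random centers are distinct non-marker gene rows
  ic3 <- init_centers(Y, mk1, C = 8, seed = 7)
  expect_length(ic3$random_gene_ids, 7L)
  expect_false("g3" %in% ic3$random_gene_ids)
  expect_equal(anyDuplicated(ic3$random_gene_ids), 0L)
  expect_error(init_centers(Y, mk1, C = 11, seed = 1), "non-marker")
})

test_that("anchored clustering co-clusters markers and recovers structure", {
  # 30 genes around 3 well-separated centroids; oracle = nearest centroid
  set.seed(21)
  centroids <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  truth <- rep(1:3, each = 10)
  pts <- centroids[truth, ] + matrix(rnorm(90, sd = 0.3), 30, 3)
  pts <- abs(pts)
  Y <- tiny_expression(pts, genes = sprintf("g%02d", 1:30),
                       samples = c("a", "b", "c"))
  mk <- marker_catalog(list(T1 = c("g01", "g02"), T2 = c("g11", "g12")))
  model <- cluster_anchored(Y, mk, C = 3, seed = 1, restarts = 5)

  expect_s3_class(model, "cluster_model")
  expect_equal(model$C, 3L)
  expect_true(all(model$sizes > 0))
  # markers of each type share one cluster, anchored clusters come first
  expect_length(unique(model$assignments[mk$T1]), 1L)
  expect_length(unique(model$assignments[mk$T2]), 1L)
  expect_equal(unname(model$assignments["g01"]), 1L)
  expect_equal(unname(model$assignments["g11"]), 2L)
  # recovered partition equals the generating partition (oracle:
  # nearest-centroid assignment on the true centroids)
  d2 <- as.matrix(dist(rbind(centroids, pts)))[4:33, 1:3]
  oracle <- apply(d2, 1L, which.min)
  expect_equal(length(unique(paste(model$assignments, oracle))), 3L)

  # agreement with stats::kmeans on the same marker-averaged input
  Yw <- semicam:::collapse_marker_rows(Y, mk)
  ref <- kmeans(Yw, centers = 3, nstart = 10)
  expect_equal(length(unique(paste(model$assignments, ref$cluster))), 3L)
})

test_that("cluster centers are means of their (marker-averaged) members", {
  set.seed(22)
  Y <- tiny_expression(matrix(runif(50) * 10, 10, 5))
  mk <- marker_catalog(list(A = c("g1", "g2", "g3")))
  model <- cluster_anchored(Y, mk, C = 4, seed = 2, restarts = 3)
  Yw <- semicam:::collapse_marker_rows(Y, mk)
  for (cl in seq_len(model$C)) {
    members <- names(model$assignments)[model$assignments == cl]
    expect_equal(unname(model$centers[cl, ]),
                 unname(colMeans(Yw[members, , drop = FALSE])))
  }
})

test_that("margin-of-error matches hand-derived and grid values", {
  # point equal to a vertex
  V <- rbind(c(1, 0), c(0, 1))
  r1 <- margin_of_error(c(1, 0), V)
  expect_equal(r1$delta, 0, tolerance = 1e-9)
  expect_equal(r1$weights, c(1, 0), tolerance = 1e-8)
  # interior point (mean of vertices)
  expect_equal(margin_of_error(c(0.5, 0.5), V)$delta, 0, tolerance = 1e-9)
  # outside point: delta = sqrt(2)/2 at the midpoint
  r3 <- margin_of_error(c(1, 1), V)
  expect_equal(r3$delta, sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(r3$weights, c(0.5, 0.5), tolerance = 1e-8)
  expect_error(margin_of_error(c(1, 1, 1), V), "dimension")

  # vertex-order invariance with permuted weights
  set.seed(31)
  V3 <- matrix(runif(9), 3, 3)
  g <- runif(3)
  a <- margin_of_error(g, V3)
  b <- margin_of_error(g, V3[c(3, 1, 2), ])
  expect_equal(a$delta, b$delta, tolerance = 1e-9)
  expect_equal(a$weights, b$weights[c(2, 3, 1)], tolerance = 1e-7)
})

test_that("margin-of-error agrees with the dense-grid oracle", {
  set.seed(32)
  for (i in 1:40) {
    K <- sample(2:3, 1)
    n <- sample(2:4, 1)
    V <- matrix(runif(K * n), K, n)
    g <- if (i %% 3 == 0) {
      w <- runif(K); as.numeric(t(V) %*% (w / sum(w)))  # in-hull point
    } else runif(n)
    delta <- margin_of_error(g, V)$delta
    expect_equal(delta, grid_margin_oracle(g, V), tolerance = 1e-3)
    if (i %% 3 == 0) expect_lt(delta, 1e-7)
  }
})

test_that("vertex search enumerates subsets and finds the tightest simplex", {
  # hand-checkable 2D geometry: interior centers have delta 0 only under
  # the {(1,0), (0,1)} hull
  centers <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.7, 0.3))
  model <- structure(list(assignments = setNames(rep(1:4, each = 1),
                                                 paste0("g", 1:4)),
                          centers = centers, anchored = integer(0),
                          C = 4L, L = 0L, anchored_types = character(0),
                          sizes = rep(1L, 4), tot_withinss = 0,
                          normalized = TRUE),
                     class = "cluster_model")
  sel <- find_vertices(model, K = 2, L = 0)
  expect_equal(sort(sel$vertex_cluster_indices), c(1L, 2L))
  expect_equal(sel$n_candidates_evaluated, choose(4, 2))
  expect_equal(sel$total_margin, 0, tolerance = 1e-9)

  # candidate counting: C=10, K=4, L=2 => choose(8,2) = 28
  set.seed(33)
  C10 <- matrix(runif(40), 10, 4)
  m10 <- structure(list(assignments = setNames(sample(1:10, 60, TRUE),
                                               paste0("g", 1:60)),
                        centers = C10, anchored = 1:2, C = 10L, L = 2L,
                        anchored_types = c("A", "B"),
                        sizes = rep(6L, 10), tot_withinss = 1,
                        normalized = TRUE),
                   class = "cluster_model")
  sel10 <- find_vertices(m10, K = 4, L = 2)
  expect_equal(sel10$n_candidates_evaluated, 28L)
  expect_true(all(1:2 %in% sel10$vertex_cluster_indices))

  # C = K: single forced candidate with empty margin sum
  selCK <- find_vertices(m10, K = 10, L = 2)
  expect_equal(selCK$n_candidates_evaluated, 1L)
  expect_equal(selCK$total_margin, 0)

  expect_error(find_vertices(m10, K = 4, L = 2, candidate_budget = 10),
               "budget")
})

test_that("vertex search equals exhaustive enumeration with the grid oracle", {
  set.seed(34)
  for (trial in 1:5) {
    C <- sample(6:8, 1); K <- 3; L <- sample(0:2, 1); n <- 3
    centers <- matrix(runif(C * n), C, n)
    model <- structure(list(assignments = setNames(sample(seq_len(C), 40,
                                                          TRUE),
                                                   paste0("g", 1:40)),
                            centers = centers, anchored = seq_len(L),
                            C = C, L = L,
                            anchored_types = head(c("A", "B"), L),
                            sizes = rep(1L, C), tot_withinss = 1,
                            normalized = TRUE),
                       class = "cluster_model")
    sel <- find_vertices(model, K, L)
    # oracle: enumerate subsets, score each by grid-oracle margins
    subs <- combn(setdiff(seq_len(C), seq_len(L)), K - L)
    totals <- apply(subs, 2L, function(s) {
      vidx <- c(seq_len(L), s)
      sum(vapply(setdiff(seq_len(C), vidx), function(cc)
        grid_margin_oracle(centers[cc, ], centers[vidx, , drop = FALSE]),
        numeric(1)))
    })
    best <- c(seq_len(L), subs[, which.min(totals)])
    expect_equal(sel$vertex_cluster_indices, best)
    expect_equal(sel$total_margin, min(totals), tolerance = 1e-3)
  }
})

test_that("novel-marker extraction returns the vertex clusters' genes", {
  set.seed(35)
  d <- exclusive_marker_dataset(m = 40, K = 3, markers_per_type = 4,
                                n = 6, seed = 4)
  Yn <- normalize_rows(d$Y[rowSums(d$Y) > 0, ])
  known <- marker_catalog(d$markers[1:2])
  model <- cluster_anchored(Yn, known, C = 5, seed = 1, restarts = 5)
  sel <- find_vertices(model, K = 3, L = 2)
  out <- extract_novel_markers(model, sel, known)

  expect_equal(n_marker_types(out), 3L)
  expect_equal(names(out)[1:2], c("celltype_1", "celltype_2"))
  expect_match(names(out)[3], "^celltype_3")
  # known markers stay in their clusters' lists
  expect_true(all(known$celltype_1 %in% out[[1]]))
  expect_true(all(known$celltype_2 %in% out[[2]]))
  # the output partitions exactly the genes of the selected clusters
  sel_genes <- names(model$assignments)[model$assignments %in%
                                          sel$vertex_cluster_indices]
  expect_setequal(unlist(out), sel_genes)
  expect_equal(anyDuplicated(unlist(out)), 0L)
})
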