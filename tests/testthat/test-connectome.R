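test_that("symmetric_density averages directed counts", {
  m <- matrix(c(0, 4, 1, 2, 0, 3, 1, 5, 0), 3, 3, byrow = TRUE)
  out <- symmetric_density(m)
  expect_equal(out[1, 2], 3)   # (4 + 2) / 2
  expect_equal(out[2, 1], 3)
  expect_identical(out, t(out))
  expect_true(all(diag(out) == 0))

  sym <- matrix(c(5, 2, 2, 5), 2, 2)
  out2 <- symmetric_density(sym)
  expect_equal(out2, matrix(c(0, 2, 2, 0), 2, 2))

  set.seed(1)
  r <- matrix(runif(64, 0, 10), 8, 8)
  expected <- (r + t(r)) / 2
  diag(expected) <- 0
  expect_equal(symmetric_density(r), expected)

  expect_error(symmetric_density(matrix(0, 2, 3)), "square")
})

test_that("build_weighted_network thresholds and weights edges", {
  parc <- generate_parcellation(1, "Brain-stem")   # 3 regions
  counts <- matrix(0, 3, 3)
  counts[1, 2] <- counts[2, 1] <- 5
  counts[2, 3] <- counts[3, 2] <- 3
  counts[1, 3] <- counts[3, 1] <- 1
  fa <- matrix(0, 3, 3)
  fa[1, 2] <- fa[2, 1] <- 0.4
  fa[2, 3] <- fa[3, 2] <- 0.3
  fa[1, 3] <- fa[3, 1] <- 0.2
  net <- build_weighted_network(counts, fa, parc, threshold = 2)
  expect_equal(unname(net$weights[1, 2]), 0.4)
  expect_equal(unname(net$weights[2, 3]), 0.3)
  expect_equal(unname(net$weights[1, 3]), 0)

  empty <- build_weighted_network(matrix(0, 3, 3), fa, parc, threshold = 0)
  expect_true(all(empty$weights == 0))
})

test_that("all four weight modes match an element-wise oracle", {
  parc <- generate_parcellation(4, c("Brain-stem", "Left-Caudate",
                                     "Right-Caudate", "Left-Putamen"))
  n <- nrow(parc)
  set.seed(7)
  counts <- symmetric_density(matrix(rpois(n^2, 6), n, n))
  fa <- symmetric_density(matrix(runif(n^2, 0, 1), n, n))
  fa <- pmin(fa, 1)
  sizes <- runif(n, 50, 200)
  lengths <- symmetric_density(matrix(runif(n^2, 10, 80), n, n))
  tau <- 4
  mask <- counts > tau
  diag(mask) <- FALSE

  for (mode in c("fa", "count", "count_roi_norm", "count_length_norm")) {
    net <- build_weighted_network(counts, fa, parc, threshold = tau,
                                  weight_mode = mode, roi_sizes = sizes,
                                  lengths = lengths)
    expected <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && mask[i, j]) {
        expected[i, j] <- switch(mode,
          fa = fa[i, j],
          count = counts[i, j],
          count_roi_norm = counts[i, j] / ((sizes[i] + sizes[j]) / 2),
          count_length_norm = counts[i, j] / lengths[i, j])
      }
    }
    expect_equal(unname(net$weights), expected, tolerance = 1e-12,
                 label = mode)
  }
})

test_that("missing auxiliary inputs and bad FA are rejected", {
  parc <- generate_parcellation(1, "Brain-stem")
  counts <- symmetric_density(matrix(3, 3, 3))
  expect_error(build_weighted_network(counts, NULL, parc,
                                      weight_mode = "fa"), "fa matrix")
  expect_error(build_weighted_network(counts, parcellation = parc,
                                      weight_mode = "count_roi_norm"),
               "roi_sizes")
  expect_error(build_weighted_network(counts, parcellation = parc,
                                      weight_mode = "count_length_norm"),
               "lengths")
  bad_fa <- matrix(2, 3, 3); diag(bad_fa) <- 0
  expect_error(build_weighted_network(counts, bad_fa, parc), "\\[0, 1\\]")
})

test_that("consensus mask is the intersection of supports", {
  parc <- small_parcellation()
  n <- nrow(parc)
  set.seed(3)
  nets <- lapply(1:14, function(i) {
    weighted_network(rand_graph(n, 0.5), parc, "fa")
  })
  mask <- consensus_mask(nets)
  # loop oracle: AND-chain over supports
  expected <- matrix(TRUE, n, n)
  for (net in nets) expected <- expected & (net$weights > 0)
  diag(expected) <- FALSE
  expect_equal(unname(mask), unname(expected + 0))
  # mask support is a subset of every input support
  for (net in nets) {
    expect_true(all(net$weights[mask == 1] > 0))
  }
  # fixed point: masking then recomputing consensus changes nothing
  masked <- lapply(nets, apply_mask, mask = mask)
  expect_equal(consensus_mask(masked), mask)

  one <- consensus_mask(nets[1])
  expect_equal(unname(one), unname((nets[[1]]$weights > 0) + 0))

  a <- matrix(0, n, n); a[1, 2] <- a[2, 1] <- 0.5
  b <- matrix(0, n, n); b[2, 3] <- b[3, 2] <- 0.5
  disjoint <- list(weighted_network(a, parc, "fa"),
                   weighted_network(b, parc, "fa"))
  expect_true(all(consensus_mask(disjoint) == 0))
})

test_that("apply_mask multiplies element-wise and preserves mode", {
  parc <- small_parcellation()
  n <- nrow(parc)
  set.seed(4)
  net <- weighted_network(rand_graph(n, 0.6), parc, "fa")
  ones <- matrix(1, n, n); diag(ones) <- 0
  expect_equal(apply_mask(net, ones)$weights, net$weights)
  expect_true(all(apply_mask(net, matrix(0, n, n))$weights == 0))
  mask <- (rand_graph(n, 0.5) > 0) + 0
  out <- apply_mask(net, mask)
  expect_equal(unname(out$weights), unname(net$weights * mask))
  expect_equal(out$weight_mode, net$weight_mode)
  bad <- mask; bad[1, 2] <- 1 - bad[1, 2]
  expect_error(apply_mask(net, bad), "symmetric")
})

test_that("edge classes follow the anatomical rule and partition all pairs", {
  parc <- generate_parcellation()
  lbl <- function(x) which(parc$label == x)
  expect_equal(edge_class_of(parc, lbl("lh-precentral"),
                             lbl("lh-parsopercularis")), "left")
  expect_equal(edge_class_of(parc, lbl("rh-precentral"),
                             lbl("rh-insula")), "right")
  expect_equal(edge_class_of(parc, lbl("lh-precentral"),
                             lbl("rh-precentral")), "interhemispheric")
  expect_equal(edge_class_of(parc, lbl("Left-Caudate"),
                             lbl("rh-insula")), "subcortical")
  expect_equal(edge_class_of(parc, lbl("Left-Caudate"),
                             lbl("Right-Caudate")), "subcortical")
  expect_error(edge_class_of(parc, 3, 3), "differ")

  cls <- edge_class_matrix(parc)
  ut <- cls[upper.tri(cls)]
  n <- nrow(parc)
  expect_equal(length(ut), n * (n - 1) / 2)
  expect_equal(sum(table(ut)), n * (n - 1) / 2)
  # spot-check consistency with the scalar rule
  set.seed(5)
  for (rep in 1:50) {
    ij <- sample.int(n, 2)
    expect_equal(cls[ij[1], ij[2]], edge_class_of(parc, ij[1], ij[2]))
  }
})

test_that("edge-class means average over all pairs with zeros included", {
  parc <- small_parcellation()
  n <- nrow(parc)
  w <- matrix(0.4, n, n); diag(w) <- 0
  net <- weighted_network(w, parc, "fa")
  m <- edge_class_mean_weights(net)
  expect_true(all(abs(m - 0.4) < 1e-12))

  # only left-left edges present
  left <- which(parc$hemisphere == "left" & parc$tissue == "cortical")
  w2 <- matrix(0, n, n)
  w2[left, left] <- 0.5; diag(w2) <- 0
  m2 <- edge_class_mean_weights(weighted_network(w2, parc, "fa"))
  expect_gt(m2["left"], 0)
  expect_equal(unname(m2["right"]), 0)
  expect_equal(unname(m2["interhemispheric"]), 0)
  expect_equal(unname(m2["subcortical"]), 0)

  # random network against a loop-and-average oracle
  set.seed(6)
  w3 <- rand_graph(n, 0.5)
  m3 <- edge_class_mean_weights(weighted_network(w3, parc, "fa"))
  cls <- edge_class_matrix(parc)
  for (cl in names(m3)) {
    tot <- 0; cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (cls[i, j] == cl) { tot <- tot + w3[i, j]; cnt <- cnt + 1 }
    }
    expect_equal(unname(m3[cl]), tot / cnt, tolerance = 1e-12)
  }
})

test_that("raising the threshold never adds edges", {
  parc <- small_parcellation()
  n <- nrow(parc)
  set.seed(8)
  for (rep in 1:10) {
    counts <- symmetric_density(matrix(rpois(n^2, 8), n, n))
    fa <- pmin(symmetric_density(matrix(runif(n^2), n, n)), 1)
    taus <- sort(sample(0:15, 4))
    supports <- lapply(taus, function(tau) {
      build_weighted_network(counts, fa, parc, threshold = tau)$weights > 0
    })
    for (k in 2:length(supports)) {
      expect_true(all(supports[[k]] <= supports[[k - 1]]))
    }
  }
})
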