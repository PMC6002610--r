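test_that("pairwise correlations match a brute-force two-pass oracle", {
  set.seed(111)
  m <- expression_matrix(
    matrix(rexp(60, 1 / 50), 10,
           dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6))),
    "TPM")
  g <- correlation_graph(m, "samples", threshold = -1 + 1e-9,
                         log2_transform = FALSE)
  # oracle: explicit covariance / sigma computation per pair
  vals <- unclass(m)
  for (k in seq_len(nrow(g$edges))) {
    a <- vals[, g$edges$from[k]]
    b <- vals[, g$edges$to[k]]
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(g$edges$weight[k], num / den, tolerance = 1e-12)
  }
  expect_equal(nrow(g$edges), choose(6, 2))
})

test_that("thresholding is signed and identical samples correlate at 1", {
  base <- c(1, 5, 2, 9, 4)
  m <- expression_matrix(
    cbind(s1 = base, s2 = base, s3 = 10 - base),
    "TPM", gene_ids = sprintf("g%d", 1:5))
  g <- correlation_graph(m, "samples", threshold = 0.9, log2_transform = FALSE)
  expect_equal(nrow(g$edges), 1L)     # only the identical pair; r = -1 excluded
  expect_setequal(c(g$edges$from, g$edges$to), c("s1", "s2"))
  expect_equal(g$edges$weight, 1, tolerance = 1e-12)
})

test_that("constant profiles are kept edgeless with a warning", {
  m <- expression_matrix(
    cbind(s1 = c(1, 2, 3), s2 = c(1.1, 2.2, 2.9), s3 = c(5, 5, 5)),
    "TPM", gene_ids = c("g1", "g2", "g3"))
  expect_warning(g <- correlation_graph(m, "samples", 0.5,
                                        log2_transform = FALSE),
                 "constant")
  expect_true("s3" %in% g$nodes)
  expect_false("s3" %in% c(g$edges$from, g$edges$to))
  expect_error(correlation_graph(m[1:2, ], "samples", 0.5), "3 observations")
})

test_that("MCL keeps two disconnected cliques as two clusters", {
  blocks <- rbind(matrix(1, 5, 5), matrix(0, 5, 5))
  profiles <- cbind(blocks, 1 - blocks)  # 10 features x 10 nodes
  set.seed(121)
  profiles <- profiles * 10 + matrix(rnorm(100, sd = 0.01), 10)
  colnames(profiles) <- sprintf("n%02d", 1:10)
  rownames(profiles) <- sprintf("f%02d", 1:10)
  g <- correlation_graph(expression_matrix(profiles, "log2"),
                         "samples", 0.9, log2_transform = FALSE)
  cl <- mcl_cluster(g, inflation = 2.2)
  expect_length(cl$sizes, 2L)
  expect_equal(unname(cl$sizes), c(5L, 5L))
  # the two cliques are separated exactly
  expect_equal(length(unique(cl$membership[sprintf("n%02d", 1:5)])), 1L)
  expect_equal(length(unique(cl$membership[sprintf("n%02d", 6:10)])), 1L)
})

test_that("an edgeless node set yields singletons flagged below min_size", {
  set.seed(131)
  m <- expression_matrix(
    matrix(rnorm(50), 10, dimnames = list(sprintf("g%02d", 1:10),
                                          sprintf("s%d", 1:5))),
    "log2")
  g <- correlation_graph(m, "samples", 0.9999, log2_transform = FALSE)
  expect_equal(nrow(g$edges), 0L)
  cl <- mcl_cluster(g, min_size = 3)
  expect_length(cl$sizes, 5L)
  expect_true(all(cl$sizes == 1L))
  expect_true(all(cl$small))
})

test_that("planted three-block structure is recovered exactly", {
  for (seed in 1:3) {            # the 10-seed sweep runs in acceptance
    set.seed(200 + seed)
    n_per <- 8; n_feat <- 150
    truth <- rep(1:3, each = n_per)
    centers <- matrix(rnorm(n_feat * 3), n_feat)
    prof <- centers[, truth] + matrix(rnorm(n_feat * 3 * n_per, sd = 0.3),
                                      n_feat)
    dimnames(prof) <- list(sprintf("f%03d", 1:n_feat),
                           sprintf("n%02d", 1:(3 * n_per)))
    g <- correlation_graph(expression_matrix(prof, "log2"), "samples", 0.5,
                           log2_transform = FALSE)
    cl <- mcl_cluster(g)
    expect_equal(ari(cl$membership, truth), 1.0)
  }
})

test_that("clusters never span components and ignore node input order", {
  set.seed(141)
  n_feat <- 60
  prof <- matrix(rnorm(n_feat * 15), n_feat,
                 dimnames = list(sprintf("f%02d", 1:n_feat),
                                 sprintf("n%02d", 1:15)))
  prof[, 6:10] <- prof[, 6] + matrix(rnorm(n_feat * 5, sd = 0.4), n_feat)
  prof[, 11:15] <- prof[, 11] + matrix(rnorm(n_feat * 5, sd = 0.4), n_feat)
  em <- expression_matrix(prof, "log2")
  g <- correlation_graph(em, "samples", 0.4, log2_transform = FALSE)
  cl <- mcl_cluster(g)
  comp <- graph_components(g)
  for (k in unique(cl$membership)) {     # each cluster within one component
    members <- names(cl$membership)[cl$membership == k]
    expect_length(unique(comp[members]), 1L)
  }

  perm <- sample(ncol(prof))
  g2 <- correlation_graph(em[, perm], "samples", 0.4, log2_transform = FALSE)
  cl2 <- mcl_cluster(g2)
  expect_identical(cl2$membership[names(cl$membership)], cl$membership)
})

test_that("GraphML export round-trips through a reference parser", {
  set.seed(151)
  prof <- matrix(rnorm(300), 15,
                 dimnames = list(sprintf("f%02d", 1:15), sprintf("n%02d", 1:20)))
  prof[, 11:20] <- prof[, 11:20] + 3 * prof[, 11]
  g <- correlation_graph(expression_matrix(prof, "log2"), "samples", 0.3,
                         log2_transform = FALSE)
  cl <- mcl_cluster(g)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, path, clustering = cl,
                 node_data = data.frame(node = g$nodes,
                                        batch = rep(c("x", "y"), 10)))
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), length(g$nodes))
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_setequal(igraph::V(back)$name, g$nodes)
  ord <- match(g$nodes, igraph::V(back)$name)
  expect_equal(igraph::V(back)$cluster[ord],
               unname(cl$membership[g$nodes]))
  ends <- igraph::as_edgelist(back)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got_w <- setNames(igraph::E(back)$weight, key(ends[, 1], ends[, 2]))
  expect_equal(unname(got_w[key(g$edges$from, g$edges$to)]),
               g$edges$weight, tolerance = 1e-6)

  # empty graph still yields a valid, parseable document
  empty <- structure(list(nodes = character(0),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = numeric(0)),
                          threshold = 0.9, axis = "samples"),
                     class = "correlation_graph")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, p2)
  expect_equal(igraph::vcount(igraph::read_graph(p2, format = "graphml")), 0)
})
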