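# independent brute-force recomputation of the core map operations on small
# fixtures: correlation maps, the group t statistic, and cluster labeling
# (the latter cross-checked against igraph components)

test_that("correlation maps match voxel-by-voxel brute force to 1e-10", {
  g <- volume_grid(c(8, 8, 8))
  nt <- 40
  set.seed(21)
  run <- run_from_fun(g, nt, fun = function(v) rnorm(nt))
  mask <- array(runif(prod(g$dims)) < 0.5, g$dims)
  seed_series <- rnorm(nt)
  cm <- correlation_map(seed_series, run, mask)
  for (f in sample(which(mask), 50)) {
    idx <- arrayInd(f, g$dims)
    manual <- cor(seed_series, run$data[idx[1], idx[2], idx[3], ])
    expect_equal(cm$values[f], manual, tolerance = 1e-10)
  }
  expect_true(all(is.na(cm$values[!mask])))
})

test_that("the group statistic matches per-voxel t.test to 1e-10", {
  dims <- c(5, 5, 5)
  nA <- 6; nB <- 5
  set.seed(22)
  mk <- function(group) {
    structure(list(values = array(rnorm(prod(dims), mean = 0.2), dims),
                   type = "z", seed = "s", subject_id = "x", group = group),
              class = "conn_map")
  }
  a <- lapply(seq_len(nA), function(i) mk("A"))
  b <- lapply(seq_len(nB), function(i) mk("B"))
  st <- voxelwise_group_test(a, b)
  A <- sapply(a, function(m) as.numeric(m$values))
  B <- sapply(b, function(m) as.numeric(m$values))
  for (v in sample(prod(dims), 40)) {
    tt <- t.test(A[v, ], B[v, ], var.equal = TRUE)
    zref <- sign(tt$statistic) *
      qnorm(pt(abs(tt$statistic), tt$parameter, lower.tail = FALSE),
            lower.tail = FALSE)
    expect_equal(st$values[v], unname(zref), tolerance = 1e-10)
  }
  # Welch variant agrees with t.test(var.equal = FALSE) on the t scale
  stw <- voxelwise_group_test(a, b, var_equal = FALSE)
  v <- 17
  ttw <- t.test(A[v, ], B[v, ], var.equal = FALSE)
  zrefw <- sign(ttw$statistic) *
    qnorm(pt(abs(ttw$statistic), ttw$parameter, lower.tail = FALSE),
          lower.tail = FALSE)
  expect_equal(stw$values[v], unname(zrefw), tolerance = 1e-10)
})

test_that("component labeling agrees with igraph under both connectivities", {
  skip_if_not_installed("igraph")
  set.seed(23)
  dims <- c(10, 10, 10)
  mask <- array(runif(prod(dims)) < 0.35, dims)
  for (conn in c(6L, 26L)) {
    lab <- lffconn:::label_components_cpp(mask, dims, conn)
    vox <- which(mask)
    coords <- arrayInd(vox, dims)
    # adjacency by pairwise offset check
    edges <- c()
    for (i in seq_along(vox)) {
      d <- abs(sweep(coords, 2, coords[i, ], "-"))
      cheb <- apply(d, 1, max)
      manh <- rowSums(d)
      adj <- if (conn == 6L) which(manh == 1) else which(cheb == 1)
      adj <- adj[adj > i]
      if (length(adj)) edges <- c(edges, rbind(i, adj))
    }
    gr <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
    comp <- igraph::components(gr)$membership
    ours <- lab[vox]
    # same partition: label vectors equal up to relabeling
    expect_equal(length(unique(ours)), max(comp))
    expect_true(all(tapply(comp, ours, function(x) length(unique(x))) == 1))
    expect_true(all(tapply(ours, comp, function(x) length(unique(x))) == 1))
  }
})
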