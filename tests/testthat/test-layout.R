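# Ordering and display geometry: Ward clustering, polar coordinates,
# similarity networks, heatmap ordering.

test_that("ward_cluster matches the Lance-Williams oracle", {
  # hand-set 4-point distances with an unambiguous merge sequence
  d4 <- matrix(c(0, 0.1, 0.8, 0.9,
                 0.1, 0, 0.7, 0.85,
                 0.8, 0.7, 0, 0.2,
                 0.9, 0.85, 0.2, 0), 4, 4)
  sim4 <- 1 - d4
  dimnames(sim4) <- list(letters[1:4], letters[1:4])
  wc <- ward_cluster(sim4)
  or <- ward_oracle(stats::as.dist(d4))
  expect_equal(wc$linkage$height, or$height, tolerance = 1e-12)
  expect_equal(t(apply(cbind(wc$linkage$left, wc$linkage$right), 1, sort)),
               or$merge, ignore_attr = TRUE)

  # random instances
  for (seed in 1:3) {
    set.seed(seed)
    n <- 8
    x <- matrix(rnorm(n * 2), n)
    d <- as.matrix(dist(x))
    d <- d / max(d)
    sim <- 1 - d
    wc <- ward_cluster(sim)
    or <- ward_oracle(stats::as.dist(d))
    expect_equal(wc$linkage$height, or$height, tolerance = 1e-10)
    expect_equal(t(apply(cbind(wc$linkage$left, wc$linkage$right), 1, sort)),
                 or$merge, ignore_attr = TRUE)
    # heights monotone non-decreasing; leaf order a bijection
    expect_false(is.unsorted(wc$linkage$height))
    expect_setequal(wc$leaf_order, seq_len(n))
  }
})

test_that("ward_cluster handles degenerate sizes", {
  one <- ward_cluster(matrix(1, 1, 1, dimnames = list("a", "a")))
  expect_equal(one$leaf_order, 1L)
  expect_equal(nrow(one$linkage), 0L)

  twin <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  wc <- ward_cluster(twin)
  expect_equal(wc$linkage$height, 0)
  expect_error(ward_cluster(matrix(numeric(0), 0, 0)), "empty")
})

test_that("polar_layout places compounds on category rings in leaf order", {
  sim <- diag(4); dimnames(sim) <- list(paste0("c", 1:4), paste0("c", 1:4))
  sim[sim == 0] <- 0.2
  wc <- ward_cluster(sim)
  lay <- polar_layout(wc, categories = c("A", "E", "A", "B"), jitter = FALSE)
  # without jitter the angles are the exact grid in leaf order
  got <- sort(lay$angle)
  expect_equal(got, c(0, pi / 2, pi, 3 * pi / 2))
  rank_of <- match(seq_len(4), wc$leaf_order)
  expect_equal(lay$angle, (rank_of - 1) * pi / 2)
  # ring bands: all A compounds share a radius distinct from E
  expect_equal(lay$radius[lay$category == "A"], c(1, 1))
  expect_equal(lay$radius[lay$category == "E"], 5)

  # determinism under a fixed seed, bitwise
  l1 <- polar_layout(wc, categories = c("A", "E", "A", "B"), jitter_seed = 99L)
  l2 <- polar_layout(wc, categories = c("A", "E", "A", "B"), jitter_seed = 99L)
  expect_identical(l1, l2)
  # jitter preserves the angular order of leaves
  ord <- order(l1$angle[wc$leaf_order])
  expect_equal(ord, seq_len(4))

  expect_error(polar_layout(wc, categories = c("A", "Z", "A", "B")),
               "unknown categor")
})

test_that("polar layout jitter keeps angular order on larger instances", {
  set.seed(5)
  n <- 40
  sim <- matrix(runif(n * n, 0, 0.5), n, n)
  sim <- (sim + t(sim)) / 2; diag(sim) <- 1
  dimnames(sim) <- list(paste0("c", 1:n), paste0("c", 1:n))
  wc <- ward_cluster(sim)
  lay <- polar_layout(wc, categories = rep(LETTERS[1:5], 8), jitter_seed = 3L)
  expect_false(is.unsorted(lay$angle[wc$leaf_order]))
  expect_true(all(lay$angle >= 0 & lay$angle < 2 * pi))
})

test_that("network edges require similarity strictly above the threshold", {
  sim <- matrix(c(1, 0.5, 0.6,
                  0.5, 1, 0.5 + 1e-9,
                  0.6, 0.5 + 1e-9, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_network(sim, threshold = 0.5)
  el <- igraph::as_edgelist(net$graph)
  pairs <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(pairs, c("a-c", "b-c"))  # a-b sits exactly at 0.5: no edge
  # edge weights carry the similarity
  expect_equal(sort(igraph::E(net$graph)$weight), sort(c(0.6, 0.5 + 1e-9)))

  single <- build_network(matrix(1, 1, 1, dimnames = list("x", "x")))
  expect_equal(igraph::vcount(single$graph), 1)
  expect_equal(igraph::ecount(single$graph), 0)
})

test_that("network edge set equals brute-force thresholding (n = 100)", {
  set.seed(11)
  n <- 100
  sim <- matrix(runif(n * n), n, n)
  sim <- (sim + t(sim)) / 2; diag(sim) <- 1
  ids <- sprintf("c%03d", 1:n)
  dimnames(sim) <- list(ids, ids)
  net <- build_network(sim, threshold = 0.5)
  el <- igraph::as_edgelist(net$graph)
  got <- sort(apply(el, 1, function(r) paste(sort(r), collapse = "|")))
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sim[i, j] > 0.5) want <- c(want, paste(ids[i], ids[j], sep = "|"))
  }
  expect_equal(got, sort(want))
})

test_that("extract_clusters returns large components sorted by size", {
  # path of 6, triangle of 3, 4 isolated nodes
  n <- 13
  sim <- diag(n)
  link <- function(i, j) sim[i, j] <<- sim[j, i] <<- 0.9
  for (i in 1:5) link(i, i + 1)
  link(7, 8); link(8, 9); link(7, 9)
  ids <- sprintf("n%02d", 1:n)
  dimnames(sim) <- list(ids, ids)
  net <- build_network(sim, 0.5)
  cl5 <- extract_clusters(net, min_size = 5)
  expect_length(cl5, 1)
  expect_setequal(cl5[[1]], ids[1:6])
  cl3 <- extract_clusters(net, min_size = 3)
  expect_length(cl3, 2)
  expect_equal(lengths(cl3), c(6L, 3L))
  expect_length(extract_clusters(net, min_size = 20), 0)
})

test_that("heatmap ordering sorts by counter-screen average, strongest first", {
  rec <- data.frame(compound_id = c("b", "a", "c"),
                    mbp_average = c(8.5, 4.0, 9.0))
  expect_equal(order_heatmap(rec)$compound_id, c("c", "b", "a"))
  ties <- data.frame(compound_id = c("z", "m", "a"),
                     mbp_average = c(5, 5, 5))
  expect_equal(order_heatmap(ties)$compound_id, c("a", "m", "z"))
  nas <- data.frame(compound_id = c("a", "b"), mbp_average = c(NA, 3))
  out <- order_heatmap(nas)
  expect_equal(out$compound_id, c("b", "a"))
  expect_equal(out$mbp_missing, c(FALSE, TRUE))
  # published hit table: colforsin (9.00) ranks above IBMX (8.50)
  t1 <- screen_table1()
  t1$compound_id <- t1$name
  t1$mbp_average <- t1$mbp_score
  ordered <- order_heatmap(t1)
  expect_lt(which(ordered$name == "COLFORSIN"),
            which(grepl("IBMX", ordered$name)))
  expect_equal(ordered$name[1], "COLFORSIN")
})
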