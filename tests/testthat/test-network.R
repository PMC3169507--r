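test_that("the three-complex toy reproduces its hand enumeration", {
  ds <- figure1_toy()
  g <- build_bipartite(ds)
  expect_equal(degree_summary(g, "protein")$degrees[["b"]], 3)
  expect_equal(degree_summary(g, "complex")$degrees[["A"]], 3)

  pr <- project(g, "protein")
  expect_equal(projection_weight(pr, "b", "e"), 2L)
  expect_equal(node_strength(pr, "b"), 5)

  pc <- project(g, "complex")
  expect_equal(projection_weight(pc, "B", "C"), 2L)
  expect_length(pc$nodes, 3)
  expect_equal(nrow(pc$edges), 3)
  comp <- connected_components(pc)
  expect_length(comp, 1)
  expect_equal(comp[[1]], c("A", "B", "C"))
})

test_that("role filters select membership subsets and drop isolated nodes", {
  ds <- complexome_dataset(data.frame(
    complex = c("A", "A", "B"), protein = c("a", "b", "b"),
    role = c("core", "attachment", "core")))
  core <- suppressMessages(build_bipartite(ds, "core"))
  expect_equal(nrow(core$edges), 2)
  expect_false("A" %in% core$edges$complex[core$edges$protein == "b"])

  one <- complexome_dataset(data.frame(complex = "A", protein = "a",
                                       role = "core"))
  att <- suppressMessages(build_bipartite(one, "attachment"))
  expect_equal(nrow(att$edges), 0)

  # filter monotonicity on a generated complexome
  sim <- generate_complexome(M = 30, N = 90, mean_complex_size = 4,
                             mean_membership = 2, n_functions = 10,
                             seed = 3)
  all_e <- build_bipartite(sim$dataset, "all")$edges
  for (r in c("core", "attachment")) {
    sub <- suppressMessages(build_bipartite(sim$dataset, r))$edges
    expect_true(all(paste(sub$complex, sub$protein) %in%
                      paste(all_e$complex, all_e$protein)))
  }
})

test_that("projected weights equal brute-force shared-partner counts", {
  for (seed in 1:20) {
    set.seed(seed)
    M <- sample(2:12, 1); N <- sample(3:20, 1)
    memb <- matrix(rbinom(N * M, 1, 0.35), N, M)
    keep_c <- colSums(memb) > 0; keep_p <- rowSums(memb) > 0
    memb <- memb[keep_p, keep_c, drop = FALSE]
    if (nrow(memb) < 2 || ncol(memb) < 1) next
    cx <- sprintf("c%02d", seq_len(ncol(memb)))
    pr_ids <- sprintf("p%02d", seq_len(nrow(memb)))
    idx <- which(memb > 0, arr.ind = TRUE)
    ds <- complexome_dataset(data.frame(complex = cx[idx[, 2]],
                                        protein = pr_ids[idx[, 1]],
                                        role = "core"))
    proj <- project(build_bipartite(ds), "protein")
    for (i in seq_len(nrow(memb) - 1)) for (j in (i + 1):nrow(memb)) {
      expected <- sum(memb[i, ] & memb[j, ])
      expect_equal(projection_weight(proj, pr_ids[i], pr_ids[j]),
                   as.integer(expected))
    }
    # strength sum rule: total strength is twice the total edge weight
    expect_equal(sum(node_strength(proj)), 2 * sum(proj$edges$weight))
  }
})

test_that("strength sums complex sizes when no pair shares two complexes", {
  # disjoint complexes: every protein pair shares at most one complex
  ds <- complexome_dataset(data.frame(
    complex = rep(c("A", "B"), c(3, 4)),
    protein = c("a1", "a2", "a3", "b1", "b2", "b3", "b4"), role = "core"))
  proj <- project(build_bipartite(ds), "protein")
  sizes <- c(3, 4)
  expect_equal(sum(node_strength(proj)), sum(sizes * (sizes - 1)))
})

test_that("degree summaries report mean, sd, max and cumulative P", {
  ds <- complexome_dataset(data.frame(
    complex = rep(c("A", "B", "C"), c(2, 2, 5)),
    protein = sprintf("p%d", c(1:2, 3:4, 5:9)), role = "core"))
  s <- degree_summary(build_bipartite(ds), "complex")
  expect_equal(s$mean, 3)
  expect_equal(s$max, 5)
  expect_equal(s$cumulative$P[s$cumulative$k == min(s$cumulative$k)], 1)
  expect_true(all(diff(s$cumulative$P) <= 0))
  empty <- structure(list(complexes = character(), proteins = character(),
                          edges = data.frame(complex = character(),
                                             protein = character()),
                          roles = "all"), class = "bipartite_graph")
  expect_error(degree_summary(empty, "complex"), "empty")
})

test_that("rankings break ties lexicographically and cap n", {
  v <- c(a = 3, b = 1, c = 3)
  expect_equal(top_nodes(v, 2)$node, c("a", "c"))
  expect_equal(nrow(top_nodes(v, 10)), 3)
})

test_that("components of an edgeless projection are singletons", {
  ds <- complexome_dataset(data.frame(
    complex = c("A", "B", "C", "D"),
    protein = c("w", "x", "y", "z"), role = "core"))
  proj <- project(build_bipartite(ds), "protein")
  comp <- connected_components(proj)
  expect_length(comp, 4)
  expect_true(all(lengths(comp) == 1))
  expect_equal(node_strength(proj, "w"), 0)
  expect_error(node_strength(proj, "nope"), "unknown node")
})

test_that("graphs export to GraphML and weighted edge lists", {
  g <- build_bipartite(figure1_toy())
  proj <- project(g, "protein")
  gml <- tempfile(fileext = ".graphml")
  write_graphml(proj, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(back), nrow(proj$edges))
  el <- tempfile(fileext = ".tsv")
  write_edgelist(proj, el)
  lines <- read.delim(el, header = FALSE)
  expect_equal(nrow(lines), nrow(proj$edges))
  expect_equal(lines[[3]], proj$edges$weight)
})
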