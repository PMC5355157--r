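test_that("Spearman matrix: symmetry, monotone pairs, constant exclusion", {
  set.seed(71)
  v <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  v[2, ] <- exp(v[1, ])          # perfectly monotone in g1
  v[5, ] <- 4                    # constant
  m <- expr_matrix(v)
  expect_warning(sp <- spearman_matrix(m), "constant")
  expect_equal(sp$rho["g1", "g2"], 1)
  expect_equal(sp$rho, t(sp$rho))
  expect_equal(unname(diag(sp$rho)[1:4]), rep(1, 4))
  expect_true(all(is.na(sp$rho["g5", ])))
  expect_equal(sp$constant, "g5")
  expect_error(spearman_matrix(expr_matrix(v[, 1:5])), "10 samples")
})

test_that("sample Spearman rho concentrates on the bivariate-normal value", {
  # population Spearman of bivariate normal r = 0.6: (6/pi) asin(0.3)
  target <- (6 / pi) * asin(0.3)
  set.seed(72)
  rbar <- mean(replicate(300, {
    z <- rnorm(30); x <- z; y <- 0.6 * z + sqrt(1 - 0.36) * rnorm(30)
    cor(x, y, method = "spearman")
  }))
  expect_lt(abs(rbar - target), 0.03)
})

test_that("edge thresholding: planted blocks edge within, background stays out", {
  blk <- simulate_correlated_blocks(c(20, 15, 12), 60, 0.8, 500, seed = 73)
  sp <- spearman_matrix(blk$matrix)
  g <- build_graph(sp, rho_cut = 0.6)
  memb <- blk$truth$block_assignments
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- key(g$edges$from, g$edges$to)
  within <- unlist(lapply(1:3, function(b) {
    gs <- names(memb)[memb == b]
    pr <- t(combn(gs, 2)); key(pr[, 1], pr[, 2])
  }))
  bg <- names(memb)[memb == 0]
  prb <- t(combn(bg, 2))
  expect_gte(mean(within %in% edges), 0.95)
  expect_lte(mean(key(prb[, 1], prb[, 2]) %in% edges), 0.01)
  expect_true(all(abs(g$edges$rho) >= 0.6))
  expect_true(all(g$edges$p_adj <= 0.05))

  # impossible threshold empties the graph
  expect_equal(nrow(build_graph(sp, rho_cut = 1.01)$edges), 0)
  expect_error(build_graph(sp, alpha_edge = 0), "alpha_edge")
})

test_that("graph construction is invariant to sample permutation", {
  blk <- simulate_correlated_blocks(c(10), 20, 0.7, 100, seed = 74)
  g1 <- build_graph(spearman_matrix(blk$matrix), rho_cut = 0.6)
  set.seed(99)
  o <- sample(ncol(blk$matrix$values))
  perm <- expr_matrix(blk$matrix$values[, o], blk$matrix$sample_class[o])
  g2 <- build_graph(spearman_matrix(perm), rho_cut = 0.6)
  expect_equal(g1$edges, g2$edges)
})

test_that("communities are the positive components of planted blocks", {
  blk <- simulate_correlated_blocks(c(20, 12), 40, 0.8, 400, seed = 75)
  g <- build_graph(spearman_matrix(blk$matrix), rho_cut = 0.6)
  comm <- find_communities(g, min_size = 5)
  expect_equal(comm$n_communities, 2)
  expect_equal(unname(comm$sizes), c(20L, 12L))
  memb <- blk$truth$block_assignments
  for (b in 1:2) {
    ids <- names(memb)[memb == b]
    expect_length(unique(comm$membership[ids]), 1)
  }
  # empty graph: zero communities
  g0 <- build_graph(spearman_matrix(blk$matrix), rho_cut = 1.01)
  expect_equal(find_communities(g0)$n_communities, 0)
})

test_that("negative bridges are found, ranked, and monotone in bridge_min", {
  hub <- simulate_correlated_blocks(c(25), 40, 0.8, 400,
                                    n_negative_hubs = 4, hub_rho = -0.7,
                                    seed = 76)
  g <- build_graph(spearman_matrix(hub$matrix), rho_cut = 0.6)
  comm <- find_communities(g)
  main <- names(comm$membership)[comm$membership ==
                                   comm$membership[["b1_g001"]]]
  br3 <- negative_bridges(g, main, bridge_min = 3)
  br1 <- negative_bridges(g, main, bridge_min = 1)
  expect_setequal(br3$gene, hub$truth$negative_hubs)
  expect_true(all(br3$gene %in% br1$gene))
  expect_true(all(diff(br3$n_negative) <= 0))

  # a graph with no negative edges yields an empty list
  pos <- simulate_correlated_blocks(c(10), 10, 0.8, 300, seed = 77)
  gp <- build_graph(spearman_matrix(pos$matrix), rho_cut = 0.6)
  expect_equal(nrow(negative_bridges(gp, names(
    which(pos$truth$block_assignments == 1)))), 0)
  expect_error(negative_bridges(g, 99, communities = comm), "unknown")
})

test_that("graph exports round-trip through the package reader", {
  blk <- simulate_correlated_blocks(c(8), 10, 0.8, 200,
                                    n_negative_hubs = 2, hub_rho = -0.7,
                                    seed = 78)
  g <- build_graph(spearman_matrix(blk$matrix), rho_cut = 0.6)
  comm <- find_communities(g)
  f <- tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml", communities = comm)
  back <- read_coex_graph(f, "graphml")
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(back$edges), key(g$edges))
  o1 <- order(key(g$edges)); o2 <- order(key(back$edges))
  expect_equal(back$edges$rho[o2], g$edges$rho[o1], tolerance = 1e-12)
  expect_equal(back$edges$sign[o2], g$edges$sign[o1])

  fe <- tempfile(fileext = ".tsv")
  export_graph(g, fe, "edges")
  ed <- read_coex_graph(fe, "edges")
  expect_equal(nrow(ed), nrow(g$edges))
  expect_equal(sort(ed$rho), sort(g$edges$rho), tolerance = 1e-12)

  # an empty graph still writes valid files
  g0 <- build_graph(spearman_matrix(blk$matrix), rho_cut = 1.01)
  export_graph(g0, f, "graphml")
  expect_equal(nrow(read_coex_graph(f, "graphml")$edges), 0)
})
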