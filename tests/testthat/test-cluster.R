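# Point-wise t-maps, cluster formation and the permutation null.

null_group <- function(n, nr = 20, nc = 50) {
  lapply(seq_len(n), function(i) matrix(rnorm(nr * nc), nr, nc))
}

test_that("identical constant groups give t = 0 and no clusters", {
  g <- lapply(1:4, function(i) matrix(5, 6, 8))
  pm <- pointwise_tmap(g, g)
  expect_true(all(pm$t_map == 0))
  res <- permutation_test(g, g, cluster_config(n_permutations = 50))
  expect_length(res$clusters, 0)
})

test_that("swapping group labels negates the t-map", {
  set.seed(1)
  a <- null_group(5, 6, 8)
  b <- null_group(6, 6, 8)
  expect_equal(pointwise_tmap(a, b)$t_map, -pointwise_tmap(b, a)$t_map)
  expect_equal(pointwise_tmap(a, b)$p_map, pointwise_tmap(b, a)$p_map)
})

test_that("t-map matches t.test point by point", {
  set.seed(2)
  a <- null_group(5, 3, 4)
  b <- null_group(7, 3, 4)
  pm <- pointwise_tmap(a, b)
  for (pt in c(1, 7, 12)) {
    x <- sapply(a, function(m) m[pt])
    y <- sapply(b, function(m) m[pt])
    tt <- t.test(x, y)
    expect_equal(pm$t_map[pt], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pm$p_map[pt], tt$p.value, tolerance = 1e-10)
  }
  expect_error(pointwise_tmap(a, null_group(5, 4, 4)), "mismatch")
  expect_error(pointwise_tmap(a[1], b), "two animals")
})

test_that("point-wise null rate sits at the 0.025 cluster-forming threshold", {
  set.seed(3)
  rate <- mean(replicate(60, {
    pm <- pointwise_tmap(null_group(10), null_group(10))
    mean(pm$p_map < 0.025)
  }))
  se <- sqrt(0.025 * 0.975 / (60 * 1000))
  expect_lt(abs(rate - 0.025), 5 * se + 0.003)
})

test_that("cluster formation respects the mask geometry and connectivity", {
  tm <- matrix(0, 20, 30)
  pm <- matrix(1, 20, 30)
  tm[6:10, 11:20] <- 5
  pm[6:10, 11:20] <- 0.001
  cl <- find_clusters(pm, tm, cluster_config())
  expect_length(cl, 1)
  expect_equal(cl[[1]]$area, 50)
  expect_equal(cl[[1]]$sign, 1)

  # diagonal-touching blocks: two clusters under 4-connectivity, one under 8
  tm2 <- matrix(0, 6, 6)
  pm2 <- matrix(1, 6, 6)
  tm2[1:2, 1:2] <- 3; pm2[1:2, 1:2] <- 0.01
  tm2[3:4, 3:4] <- 3; pm2[3:4, 3:4] <- 0.01
  expect_length(find_clusters(pm2, tm2, cluster_config()), 2)
  expect_length(find_clusters(pm2, tm2,
                              cluster_config(connectivity = "8-neighbour")), 1)

  # opposite signs never merge
  tm3 <- matrix(c(3, -3), 1, 2)
  pm3 <- matrix(0.01, 1, 2)
  expect_length(find_clusters(pm3, tm3, cluster_config()), 2)
  expect_length(find_clusters(matrix(1, 4, 4), matrix(0, 4, 4),
                              cluster_config()), 0)
})

test_that("small-group permutation null equals exhaustive enumeration", {
  skip_if_not_installed("igraph")
  set.seed(4)
  a <- null_group(3, 4, 4)
  b <- lapply(null_group(3, 4, 4), function(m) m + 1.5)
  cfg <- cluster_config(n_permutations = 2000, max_exhaustive = 100)
  res <- permutation_test(a, b, cfg)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, choose(6, 3))

  # independent oracle: loop over all 20 relabelings with t.test + igraph
  pool <- c(a, b)
  combs <- combn(6, 3)
  oracle_max <- sapply(seq_len(ncol(combs)), function(j) {
    ga <- pool[combs[, j]]
    gb <- pool[setdiff(1:6, combs[, j])]
    tmat <- matrix(0, 4, 4)
    pmat <- matrix(1, 4, 4)
    for (pt in 1:16) {
      x <- sapply(ga, function(m) m[pt]); y <- sapply(gb, function(m) m[pt])
      ht <- t.test(x, y)
      tmat[pt] <- ht$statistic; pmat[pt] <- ht$p.value
    }
    areas <- c(0)
    for (sgn in c(1, -1)) {
      sel <- which(pmat < 0.025 & sign(tmat) == sgn)
      if (length(sel)) {
        rc <- cbind((sel - 1) %% 4 + 1, (sel - 1) %/% 4 + 1)
        adj <- outer(seq_along(sel), seq_along(sel), Vectorize(function(i, j) {
          sum(abs(rc[i, ] - rc[j, ])) == 1
        }))
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        areas <- c(areas, igraph::components(g)$csize)
      }
    }
    max(areas)
  })
  expect_equal(sort(res$null_areas), sort(oracle_max))
})

test_that("results are seed-deterministic and invariant to within-group order", {
  set.seed(5)
  a <- null_group(8, 10, 12)
  b <- null_group(8, 10, 12)
  cfg <- cluster_config(n_permutations = 200, rng_seed = 42)
  r1 <- permutation_test(a, b, cfg)
  r2 <- permutation_test(a, b, cfg)
  expect_identical(r1$null_areas, r2$null_areas)
  expect_identical(cluster_table(r1), cluster_table(r2))
  r3 <- permutation_test(a[sample(8)], b, cfg)
  expect_equal(r3$t_map, r1$t_map)
})

test_that("family-wise error stays controlled and planted effects are found", {
  set.seed(6)
  cfg <- cluster_config(n_permutations = 300, rng_seed = 7)
  n_sims <- 60
  fwer <- mean(replicate(n_sims, {
    res <- permutation_test(null_group(10, 15, 20), null_group(10, 15, 20), cfg)
    any(vapply(res$clusters, function(cl) cl$significant, logical(1)))
  }))
  se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lte(fwer, 0.05 + 3 * se)

  hits <- mean(replicate(20, {
    a <- lapply(1:10, function(i) {
      m <- matrix(rnorm(15 * 20), 15, 20)
      m[5:10, ] <- m[5:10, ] + 3 # planted band, 3 between-subject SDs
      m
    })
    res <- permutation_test(a, null_group(10, 15, 20), cfg)
    nr <- 15
    any(vapply(res$clusters, function(cl) {
      cl$significant && any(((cl$members - 1) %% nr + 1) %in% 5:10)
    }, logical(1)))
  }))
  expect_gte(hits, 0.95)
})
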