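# Cluster-based permutation test for group differences between
# time-frequency maps.
#
# A Welch two-sample t-test is run at every time-frequency point; points with
# two-sided p below the cluster-forming threshold (0.025) are grouped into
# connected clusters (separately for positive and negative t), each cluster's
# area (grid-point count) is measured, and observed areas are compared with
# the distribution of the maximum surrogate cluster area obtained by
# re-running the whole procedure under random relabelings of the animals.
# The max-statistic null controls family-wise error; a pooled null (all
# surrogate cluster areas) is available behind a flag.

#' Cluster-test configuration
#'
#' @param point_alpha two-sided point-wise cluster-forming threshold
#' @param n_permutations number of random relabelings
#' @param cluster_percentile percentile of the surrogate-area null an observed
#'   cluster must exceed to be significant
#' @param connectivity `"4-neighbour"` (edge-sharing, default) or
#'   `"8-neighbour"` (also diagonal) grid adjacency
#' @param rng_seed integer seed for the relabelings
#' @param null_type `"max"` (per-permutation maximum area; FWER-controlling,
#'   default) or `"pooled"` (all surrogate areas)
#' @param max_exhaustive when the number of distinct relabelings is at most
#'   this, enumerate all of them instead of sampling
#' @return a list of class `cluster_config`
#' @export
cluster_config <- function(point_alpha = 0.025, n_permutations = 2000,
                           cluster_percentile = 95,
                           connectivity = c("4-neighbour", "8-neighbour"),
                           rng_seed = 1, null_type = c("max", "pooled"),
                           max_exhaustive = 100) {
  stopifnot(point_alpha > 0, point_alpha < 1, n_permutations >= 1)
  structure(list(point_alpha = point_alpha, n_permutations = n_permutations,
                 cluster_percentile = cluster_percentile,
                 connectivity = match.arg(connectivity),
                 rng_seed = rng_seed, null_type = match.arg(null_type),
                 max_exhaustive = max_exhaustive),
            class = "cluster_config")
}

# Coerce a group (list of stp_map / matrices, or subjects x f x t array) to a
# subjects x points matrix plus the grid dimensions.
group_matrix <- function(g) {
  if (is.array(g) && length(dim(g)) == 3) {
    dims <- dim(g)[2:3]
    m <- matrix(g, nrow = dim(g)[1])
    return(list(m = m, dims = dims))
  }
  if (!is.list(g)) stop("group must be a list of maps or a 3-d array", call. = FALSE)
  mats <- lapply(g, function(x) if (inherits(x, "stp_map")) x$power else x)
  dims <- dim(mats[[1]])
  if (any(!vapply(mats, function(x) identical(dim(x), dims), logical(1)))) {
    stop("map grid mismatch within a group", call. = FALSE)
  }
  list(m = do.call(rbind, lapply(mats, as.vector)), dims = dims)
}

# Vectorized Welch t for many label permutations at once.
# x: pooled subjects x points matrix; amat: B x N 0/1 matrix selecting group A.
# Returns list(t, df): B x points matrices.
welch_t_perms <- function(x, amat, n_a, n_b) {
  sa <- amat %*% x
  sa2 <- amat %*% (x^2)
  tot <- matrix(colSums(x), nrow(amat), ncol(x), byrow = TRUE)
  tot2 <- matrix(colSums(x^2), nrow(amat), ncol(x), byrow = TRUE)
  ma <- sa / n_a
  mb <- (tot - sa) / n_b
  va <- (sa2 - n_a * ma^2) / (n_a - 1)
  vb <- (tot2 - sa2 - n_b * mb^2) / (n_b - 1)
  va[va < 0] <- 0
  vb[vb < 0] <- 0
  se2 <- va / n_a + vb / n_b
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
  tt[!is.finite(tt)] <- 0
  df[!is.finite(df)] <- n_a + n_b - 2
  list(t = tt, df = df)
}

#' Point-wise Welch t-map between two groups of maps
#'
#' @param group_a,group_b per-animal time-frequency maps: lists of `stp_map`
#'   objects or matrices (all on one grid), or `subjects x freq x time` arrays
#' @return list with matrices `t_map` and `p_map` (two-sided)
#' @export
pointwise_tmap <- function(group_a, group_b) {
  ga <- group_matrix(group_a)
  gb <- group_matrix(group_b)
  if (!identical(ga$dims, gb$dims)) stop("map grid mismatch between groups", call. = FALSE)
  n_a <- nrow(ga$m)
  n_b <- nrow(gb$m)
  if (n_a < 2 || n_b < 2) stop("need at least two animals per group", call. = FALSE)
  x <- rbind(ga$m, gb$m)
  amat <- matrix(0, 1, n_a + n_b)
  amat[1, seq_len(n_a)] <- 1
  w <- welch_t_perms(x, amat, n_a, n_b)
  p <- 2 * stats::pt(abs(w$t), w$df, lower.tail = FALSE)
  list(t_map = matrix(w$t, ga$dims[1], ga$dims[2]),
       p_map = matrix(p, ga$dims[1], ga$dims[2]))
}

# Label connected components of a logical matrix. Returns an integer matrix
# (0 = background). Iterative flood fill; `conn` is 4 or 8.
label_components <- function(mask, conn = 4) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  if (conn == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          q <- r2 + (c2 - 1L) * nr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

#' Find supra-threshold clusters in a t/p map pair
#'
#' Connected components of `{p < point_alpha}`, formed separately for
#' positive and negative t.
#'
#' @param p_map,t_map aligned matrices
#' @param cfg a [cluster_config()]
#' @return list of clusters, each `list(members, area, sign)`; `members` are
#'   linear indices into the map
#' @export
find_clusters <- function(p_map, t_map, cfg = cluster_config()) {
  stopifnot(identical(dim(p_map), dim(t_map)))
  conn <- if (cfg$connectivity == "4-neighbour") 4 else 8
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- p_map < cfg$point_alpha & sign(t_map) == sgn
    lab <- label_components(mask, conn)
    if (max(lab) > 0) {
      for (k in seq_len(max(lab))) {
        mem <- which(lab == k)
        out[[length(out) + 1]] <- list(members = mem, area = length(mem),
                                       sign = sgn)
      }
    }
  }
  out
}

# areas of all clusters in one permutation's t/p map (vectors)
perm_cluster_areas <- function(tt, df, dims, cfg, conn) {
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  areas <- integer(0)
  for (sgn in c(1, -1)) {
    mask <- matrix(p < cfg$point_alpha & sign(tt) == sgn, dims[1], dims[2])
    lab <- label_components(mask, conn)
    if (max(lab) > 0) areas <- c(areas, tabulate(lab[lab > 0L]))
  }
  areas
}

#' Cluster-based permutation test between two groups of maps
#'
#' Recomputes the point-wise Welch t/p maps and cluster areas under random
#' relabelings of the pooled animals (preserving group sizes) and marks an
#' observed cluster significant when its area exceeds the
#' `cluster_percentile` of the surrogate null (per-permutation maximum area by
#' default). When the number of distinct relabelings is small
#' (`<= max_exhaustive`) all of them are enumerated, making the null exact.
#' Deterministic for a fixed `rng_seed`.
#'
#' @inheritParams pointwise_tmap
#' @param cfg a [cluster_config()]
#' @return a `cluster_result`: `t_map`, `p_map`, `clusters` (each with
#'   `members`, `area`, `sign`, `null_percentile`, `p_cluster`,
#'   `significant`), `null_areas`, `area_threshold`, `n_permutations`,
#'   `exhaustive`
#' @export
permutation_test <- function(group_a, group_b, cfg = cluster_config()) {
  ga <- group_matrix(group_a)
  gb <- group_matrix(group_b)
  if (!identical(ga$dims, gb$dims)) stop("map grid mismatch between groups", call. = FALSE)
  n_a <- nrow(ga$m)
  n_b <- nrow(gb$m)
  if (n_a < 2 || n_b < 2) stop("need at least two animals per group", call. = FALSE)
  if (n_a + n_b < 6) {
    warning("very small groups: the permutation null is coarse")
  }
  x <- rbind(ga$m, gb$m)
  dims <- ga$dims
  conn <- if (cfg$connectivity == "4-neighbour") 4 else 8

  obs <- pointwise_tmap(group_a, group_b)
  clusters <- find_clusters(obs$p_map, obs$t_map, cfg)

  n_tot <- n_a + n_b
  n_comb <- choose(n_tot, n_a)
  exhaustive <- n_comb <= cfg$max_exhaustive
  if (exhaustive) {
    combs <- utils::combn(n_tot, n_a)
    amat <- matrix(0, ncol(combs), n_tot)
    amat[cbind(rep(seq_len(ncol(combs)), each = n_a), as.vector(combs))] <- 1
  } else {
    set.seed(cfg$rng_seed)
    amat <- t(vapply(seq_len(cfg$n_permutations), function(i) {
      a <- numeric(n_tot)
      a[sample.int(n_tot, n_a)] <- 1
      a
    }, numeric(n_tot)))
  }

  null_areas <- numeric(0)
  chunk <- 200L
  starts <- seq(1, nrow(amat), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1, nrow(amat))
    w <- welch_t_perms(x, amat[rows, , drop = FALSE], n_a, n_b)
    for (i in seq_along(rows)) {
      areas <- perm_cluster_areas(w$t[i, ], w$df[i, ], dims, cfg, conn)
      if (cfg$null_type == "max") {
        null_areas <- c(null_areas, if (length(areas)) max(areas) else 0)
      } else {
        null_areas <- c(null_areas, if (length(areas)) areas else 0)
      }
    }
  }

  thr <- stats::quantile(null_areas, cfg$cluster_percentile / 100, type = 1,
                         names = FALSE)
  clusters <- lapply(clusters, function(cl) {
    cl$null_percentile <- 100 * mean(null_areas < cl$area)
    cl$p_cluster <- mean(null_areas >= cl$area)
    cl$significant <- cl$area > thr
    cl
  })
  structure(list(t_map = obs$t_map, p_map = obs$p_map, clusters = clusters,
                 null_areas = null_areas, area_threshold = thr,
                 n_permutations = nrow(amat), exhaustive = exhaustive,
                 config = cfg),
            class = "cluster_result")
}

#' Tabulate a cluster result
#'
#' @param res a `cluster_result`
#' @param freqs_hz,t optional grid axes used to report cluster extents
#' @return data frame with one row per cluster
#' @export
cluster_table <- function(res, freqs_hz = NULL, t = NULL) {
  if (length(res$clusters) == 0) {
    return(data.frame(cluster = integer(0), sign = integer(0),
                      area = integer(0), null_percentile = numeric(0),
                      p_cluster = numeric(0), significant = logical(0)))
  }
  nr <- nrow(res$t_map)
  rows <- lapply(seq_along(res$clusters), function(k) {
    cl <- res$clusters[[k]]
    ri <- ((cl$members - 1) %% nr) + 1
    ci <- ((cl$members - 1) %/% nr) + 1
    out <- data.frame(cluster = k, sign = cl$sign, area = cl$area,
                      null_percentile = cl$null_percentile,
                      p_cluster = cl$p_cluster, significant = cl$significant)
    if (!is.null(freqs_hz)) {
      out$f_min_hz <- freqs_hz[min(ri)]
      out$f_max_hz <- freqs_hz[max(ri)]
    }
    if (!is.null(t)) {
      out$t_min_s <- t[min(ci)]
      out$t_max_s <- t[max(ci)]
    }
    out
  })
  do.call(rbind, rows)
}
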