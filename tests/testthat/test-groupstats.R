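# Mann-Whitney, Holm-Sidak / Sidak adjustments, repeated-measures ANOVA.

test_that("Mann-Whitney exact p matches enumeration of rank assignments", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_true(mw$exact)

  # oracle: enumerate all C(6,3) = 20 assignments of the pooled ranks
  pool <- 1:6
  combs <- combn(6, 3)
  u_null <- apply(combs, 2, function(ix) {
    sum(rank(pool)[ix]) - 3 * 4 / 2
  })
  p_exact <- mean(u_null <= 0) * 2
  expect_equal(mw$p, p_exact)
  expect_equal(mw$p, 0.1)
})

test_that("Mann-Whitney symmetry, identical samples, and tie fallback", {
  a <- c(1.2, 3.4, 2.2, 5.5)
  b <- c(0.3, 4.1, 2.9)
  m1 <- mann_whitney(a, b)
  m2 <- mann_whitney(b, a)
  expect_equal(m2$U, length(a) * length(b) - m1$U)
  expect_equal(m1$p, m2$p)

  same <- mann_whitney(c(1, 2, 3), c(1.5, 2.5, 0.5))
  expect_gt(same$p, 0.5)
  x <- c(1, 1, 2, 3)
  expect_false(mann_whitney(x, x + 0.5)$exact) # ties -> approximation
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Holm-Sidak step-down matches the hand-computed closed form", {
  expect_equal(holm_sidak_adjust(0.2), 0.2)
  p <- c(0.01, 0.04, 0.03)
  # sorted: .01 -> 1-.99^3, .03 -> 1-.97^2, .04 -> 1-.96; then cummax
  exp_sorted <- cummax(c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.96))
  expect_equal(holm_sidak_adjust(p), exp_sorted[c(1, 3, 2)])
  expect_equal(holm_sidak_adjust(c(0, 0, 0)), c(0, 0, 0))
  expect_true(all(holm_sidak_adjust(runif(10)) <= 1))
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Sidak single-step adjustment and monotonicity", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.05, 2), 1 - 0.95^2)
  p <- runif(6)
  expect_true(all(sidak_adjust(p) >= p))
})

# direct sums-of-squares oracle for a balanced two-between x one-within design
ss_oracle <- function(d) {
  n <- length(unique(d$animal_id))
  k <- length(unique(d$w))
  grand <- mean(d$value)
  subj_means <- tapply(d$value, d$animal_id, mean)
  cell_of <- sapply(split(d, d$animal_id), function(s) paste(s$g[1], s$tr[1]))
  ss_subj_tot <- k * sum((subj_means - grand)^2)
  bcell <- tapply(d$value, list(d$g, d$tr), mean)
  ng <- table(d$g, d$tr)[1] / k # animals per cell
  ss_g <- k * ng * 2 * sum((tapply(d$value, d$g, mean) - grand)^2)
  ss_tr <- k * ng * 2 * sum((tapply(d$value, d$tr, mean) - grand)^2)
  ss_cells <- k * ng * sum((bcell - grand)^2)
  ss_gt <- ss_cells - ss_g - ss_tr
  ss_err_b <- ss_subj_tot - ss_cells
  ss_w <- n * sum((tapply(d$value, d$w, mean) - grand)^2)
  wg <- tapply(d$value, list(d$w, d$g), mean)
  wtr <- tapply(d$value, list(d$w, d$tr), mean)
  wgt <- tapply(d$value, list(d$w, d$g, d$tr), mean)
  ss_wg <- ng * 2 * sum((wg - grand)^2) - ss_w - ss_g
  ss_wtr <- ng * 2 * sum((wtr - grand)^2) - ss_w - ss_tr
  ss_wcells <- ng * sum((wgt - grand)^2)
  ss_wgt <- ss_wcells - ss_w - ss_g - ss_tr - ss_gt - ss_wg - ss_wtr
  ss_tot <- sum((d$value - grand)^2)
  ss_err_w <- ss_tot - ss_wcells - ss_err_b
  list(g = ss_g, tr = ss_tr, gt = ss_gt, err_b = ss_err_b,
       w = ss_w, wg = ss_wg, wtr = ss_wtr, wgt = ss_wgt, err_w = ss_err_w,
       df = c(g = 1, tr = 1, gt = 1, err_b = n - 4,
              w = k - 1, wg = k - 1, wtr = k - 1, wgt = k - 1,
              err_w = (n - 4) * (k - 1)))
}

test_that("rm_anova reproduces the direct sums-of-squares partition to 1e-10", {
  set.seed(9)
  d <- expand.grid(animal_id = 1:8, w = c(3, 6, 9))
  d$g <- rep(rep(c("WT", "KO"), each = 4), 3)
  d$tr <- rep(rep(c("sal", "nlx"), each = 2, times = 2), 3)
  d$value <- rnorm(nrow(d)) + d$w / 10 + (d$g == "KO") * 0.8 +
    (d$tr == "nlx") * (d$w / 20)
  a <- rm_anova(d, between = c("g", "tr"), within = "w")
  o <- ss_oracle(d)
  f_oracle <- c(
    g = (o$g / o$df[["g"]]) / (o$err_b / o$df[["err_b"]]),
    tr = (o$tr / o$df[["tr"]]) / (o$err_b / o$df[["err_b"]]),
    gt = (o$gt / o$df[["gt"]]) / (o$err_b / o$df[["err_b"]]),
    w = (o$w / o$df[["w"]]) / (o$err_w / o$df[["err_w"]]),
    wg = (o$wg / o$df[["wg"]]) / (o$err_w / o$df[["err_w"]]),
    wtr = (o$wtr / o$df[["wtr"]]) / (o$err_w / o$df[["err_w"]]),
    wgt = (o$wgt / o$df[["wgt"]]) / (o$err_w / o$df[["err_w"]]))
  got <- c(g = a$F[a$effect == "g"], tr = a$F[a$effect == "tr"],
           gt = a$F[a$effect == "g x tr"], w = a$F[a$effect == "w"],
           wg = a$F[a$effect == "g x w"], wtr = a$F[a$effect == "tr x w"],
           wgt = a$F[a$effect == "g x tr x w"])
  expect_equal(got, f_oracle, tolerance = 1e-10)
  expect_equal(a$df_err[a$effect == "g"], o$df[["err_b"]])
  expect_equal(a$df_err[a$effect == "w"], o$df[["err_w"]])
})

test_that("Greenhouse-Geisser epsilon is exactly 1 for two within levels", {
  set.seed(10)
  d <- expand.grid(animal_id = 1:8, w = c(3, 6))
  d$g <- rep(rep(c("WT", "KO"), each = 4), 2)
  d$tr <- rep(rep(c("sal", "nlx"), each = 2, times = 2), 2)
  d$value <- rnorm(nrow(d))
  a <- rm_anova(d, between = c("g", "tr"), within = "w")
  expect_equal(attr(a, "gg_epsilon"), 1)
  # with k levels epsilon is bounded below by 1/(k-1) and above by 1
  d3 <- expand.grid(animal_id = 1:8, w = c(3, 6, 9))
  d3$g <- rep(rep(c("WT", "KO"), each = 4), 3)
  d3$tr <- rep(rep(c("sal", "nlx"), each = 2, times = 2), 3)
  d3$value <- rnorm(nrow(d3)) + (d3$w == 9) * rnorm(nrow(d3), 0, 3)
  a3 <- rm_anova(d3, between = c("g", "tr"), within = "w")
  eps <- attr(a3, "gg_epsilon")
  expect_gte(eps, 0.5)
  expect_lte(eps, 1)
  gw <- a3[a3$effect == "w", ]
  expect_equal(gw$gg_p,
               pf(gw$F, eps * gw$df, eps * gw$df_err, lower.tail = FALSE))
})

test_that("constant data gives F = 0 and incomplete animals are excluded", {
  d <- expand.grid(animal_id = 1:8, w = c(3, 6, 9))
  d$g <- rep(rep(c("WT", "KO"), each = 4), 3)
  d$tr <- rep(rep(c("sal", "nlx"), each = 2, times = 2), 3)
  d$value <- 5
  a <- rm_anova(d, between = c("g", "tr"), within = "w")
  expect_true(all(a$F == 0))
  expect_true(all(a$p_use == 1))

  d2 <- d
  d2$value <- rnorm(nrow(d2))
  d2 <- d2[-1, ] # animal 1 loses one width
  expect_message(a2 <- rm_anova(d2, between = c("g", "tr"), within = "w"),
                 "excluded 1")
})

test_that("Sidak post hoc contrasts adjust across the family", {
  set.seed(11)
  d <- expand.grid(animal_id = 1:16, w = c(3, 6, 9))
  d$g <- rep(rep(c("WT", "KO"), each = 8), 3)
  d$tr <- rep(rep(c("sal", "nlx"), each = 4, times = 2), 3)
  d$value <- rnorm(nrow(d)) + (d$tr == "nlx") * 1.5
  ph <- sidak_posthoc(d, factor = "tr", by = "g")
  expect_equal(nrow(ph), 2)
  expect_equal(ph$p_sidak, sidak_adjust(ph$p_raw, m = 2))
  expect_true(all(ph$p_sidak >= ph$p_raw))
  expect_error(sidak_posthoc(d[d$tr == "sal", ], factor = "tr", by = "g"),
               "fewer than two")
})
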