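# Group-level statistics on per-animal measures: Mann-Whitney tests with
# Holm-Sidak adjustment for ERP peaks, and mixed repeated-measures ANOVA with
# Greenhouse-Geisser correction and Sidak post hoc contrasts for the
# gap-ASSR ITPC. Cortical regions and ages are analyzed separately, never as
# factors.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration p-value when the combined sample size is at most 12 and
#' there are no ties; normal approximation with tie correction otherwise.
#'
#' @param u,v numeric samples
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return list with the U statistic (for the first sample) and `p`
#' @export
mann_whitney <- function(u, v, alternative = "two.sided") {
  if (length(u) == 0 || length(v) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(u, v)) > 0
  exact <- (length(u) + length(v) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(u, v, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m p-values ascending, sets `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`,
#' enforces monotone non-decrease, caps at 1, and returns the adjusted values
#' in the input order.
#'
#' @param pvals p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
holm_sidak_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- 1 - (1 - pvals[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Sidak single-step adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of m comparisons.
#'
#' @param pvals raw p-values
#' @param m family size (default `length(pvals)`)
#' @return adjusted p-values
#' @export
sidak_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1 - (1 - pvals)^m, 1)
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate mixed-design sums-of-squares partition for between-subject
#' factors crossed with one within-subject factor: between effects are tested
#' against the between-subject error, within and interaction effects against
#' the subject-by-within error. Animals with incomplete within-subject data
#' are excluded with a message. The Greenhouse-Geisser epsilon is estimated
#' from the pooled within-cell covariance of the within-factor responses and
#' applied to the within-factor degrees of freedom; by convention the
#' corrected p-value is reported for use when `epsilon < gg_threshold`.
#'
#' @param table data frame of per-animal measures
#' @param between character vector of between-subject factor columns (e.g.
#'   `c("genotype", "treatment")`)
#' @param within within-subject factor column (e.g. `"gap_width_ms"`)
#' @param subject subject identifier column
#' @param dv response column
#' @param gg_threshold epsilon below which the corrected p is the one to read
#' @return data frame of class `rm_anova`: `effect`, `df`, `df_err`, `F`,
#'   `p`, `gg_epsilon`, `gg_p`, `p_use`; attribute `gg_epsilon`
#' @export
rm_anova <- function(table, between, within, subject = "animal_id",
                     dv = "value", gg_threshold = 0.75) {
  stopifnot(all(c(between, within, subject, dv) %in% names(table)))
  df <- table[, c(subject, between, within, dv)]
  names(df) <- c(".subj", paste0(".b", seq_along(between)), ".w", ".y")
  df$.subj <- factor(df$.subj)
  for (b in grep("^\\.b", names(df), value = TRUE)) df[[b]] <- factor(df[[b]])
  df$.w <- factor(df$.w)
  k <- nlevels(df$.w)
  if (k < 2) stop("within-subject factor needs at least two levels", call. = FALSE)

  counts <- table(df$.subj)
  complete <- names(counts)[counts == k]
  if (length(complete) < nlevels(df$.subj)) {
    message(sprintf("rm_anova: excluded %d animal(s) with incomplete within-subject data",
                    nlevels(df$.subj) - length(complete)))
    df <- df[df$.subj %in% complete, , drop = FALSE]
    df$.subj <- droplevels(df$.subj)
  }
  bnames <- grep("^\\.b", names(df), value = TRUE)
  cells <- interaction(df[bnames], drop = TRUE)
  if (any(tapply(df$.y, list(cells, df$.w), length) < 1, na.rm = FALSE) ||
      anyNA(tapply(df$.y, list(cells, df$.w), length))) {
    stop("design error: empty between-cell", call. = FALSE)
  }

  bterm <- paste(bnames, collapse = " * ")
  fml <- stats::as.formula(paste0(".y ~ (", bterm, ") * .w + Error(.subj/.w)"))
  fit <- stats::aov(fml, data = df)
  sm <- summary(fit)

  grab <- function(stratum) {
    tab <- sm[[stratum]][[1]]
    eff <- trimws(rownames(tab))
    data.frame(effect = eff, df = tab$Df, SS = tab$`Sum Sq`,
               F = if ("F value" %in% names(tab)) tab$`F value` else NA,
               p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA,
               stringsAsFactors = FALSE)
  }
  btab <- grab("Error: .subj")
  wtab <- grab("Error: .subj:.w")
  ss_total <- sum((df$.y - mean(df$.y))^2)
  df_err_b <- btab$df[btab$effect == "Residuals"]
  df_err_w <- wtab$df[wtab$effect == "Residuals"]

  # Greenhouse-Geisser epsilon from the pooled within-cell covariance
  wide <- tapply(df$.y, list(df$.subj, df$.w), mean)
  cell_of <- tapply(as.character(cells), df$.subj, function(x) x[1])
  cell_of <- cell_of[rownames(wide)]
  centered <- wide
  for (cl in unique(cell_of)) {
    rows <- which(cell_of == cl)
    centered[rows, ] <- sweep(wide[rows, , drop = FALSE], 2,
                              colMeans(wide[rows, , drop = FALSE]))
  }
  n_subj <- nrow(wide)
  g <- length(unique(cell_of))
  S <- crossprod(centered) / (n_subj - g)
  C <- qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
  if (!is.finite(eps)) eps <- 1 # degenerate (e.g. constant) data
  eps <- min(max(eps, 1 / (k - 1)), 1)

  assemble <- function(tab, df_err, within_stratum) {
    tab <- tab[tab$effect != "Residuals", , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    # guard against 0/0 ratios computed from numerical-noise sums of squares
    negligible <- tab$SS < 1e-10 * max(ss_total, .Machine$double.eps)
    tab$F[negligible] <- 0
    tab$p[negligible] <- 1
    out <- data.frame(effect = tab$effect, F = tab$F, df = tab$df,
                      df_err = df_err, p = tab$p,
                      gg_epsilon = NA_real_, gg_p = NA_real_)
    if (within_stratum) {
      out$gg_epsilon <- eps
      out$gg_p <- stats::pf(out$F, eps * out$df, eps * df_err,
                            lower.tail = FALSE)
    }
    out
  }
  res <- rbind(assemble(btab, df_err_b, FALSE), assemble(wtab, df_err_w, TRUE))
  res$F[!is.finite(res$F)] <- 0
  res$p[!is.finite(res$p) & res$F == 0] <- 1
  res$gg_p[res$F == 0 & !is.na(res$gg_epsilon)] <- 1
  res$p_use <- ifelse(!is.na(res$gg_p) & eps < gg_threshold, res$gg_p, res$p)
  pretty <- function(x) {
    x <- gsub("\\.w", within, x)
    for (i in seq_along(between)) {
      x <- gsub(paste0("\\.b", i), between[i], x)
    }
    gsub(":", " x ", x)
  }
  res$effect <- pretty(res$effect)
  rownames(res) <- NULL
  structure(res, gg_epsilon = eps, gg_threshold = gg_threshold,
            class = c("rm_anova", "data.frame"))
}

#' Sidak-corrected post hoc pairwise contrasts
#'
#' Pairwise Welch t contrasts between the levels of one between-subject
#' factor, within every combination of the remaining between-subject factors,
#' computed on per-animal means over the within-subject levels. P-values are
#' Sidak-adjusted for the number of contrasts in the family.
#'
#' @inheritParams rm_anova
#' @param factor the between-subject factor whose levels are contrasted
#' @param by character vector of stratifying between-subject factors (may be
#'   empty)
#' @return data frame with one row per contrast: stratum, levels compared,
#'   group means, t, df, raw and Sidak-adjusted p
#' @export
sidak_posthoc <- function(table, factor, by = character(), subject = "animal_id",
                          dv = "value") {
  stopifnot(all(c(factor, by, subject, dv) %in% names(table)))
  agg <- stats::aggregate(table[[dv]],
                          by = c(list(subject = table[[subject]]),
                                 lapply(c(factor, by), function(f) table[[f]])),
                          FUN = mean)
  names(agg) <- c("subject", factor, by, "y")
  strata <- if (length(by) == 0) {
    data.frame(.dummy = 1)
  } else {
    unique(agg[, by, drop = FALSE])
  }
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- agg
    label <- ""
    if (length(by) > 0) {
      for (b in by) sub <- sub[sub[[b]] == strata[s, b], , drop = FALSE]
      label <- paste(vapply(by, function(b) paste0(b, "=", strata[s, b]),
                            character(1)), collapse = ", ")
    }
    levs <- unique(sub[[factor]])
    if (length(levs) < 2) next
    prs <- utils::combn(as.character(levs), 2)
    for (j in seq_len(ncol(prs))) {
      a <- sub$y[sub[[factor]] == prs[1, j]]
      b <- sub$y[sub[[factor]] == prs[2, j]]
      tt <- stats::t.test(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = label, level_1 = prs[1, j], level_2 = prs[2, j],
        mean_1 = mean(a), mean_2 = mean(b),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value)
    }
  }
  if (length(rows) == 0) stop("unknown contrast: factor has fewer than two levels",
                              call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_sidak <- sidak_adjust(out$p_raw, m = nrow(out))
  out
}
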