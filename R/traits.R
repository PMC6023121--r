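#' Log-transform the trait columns of a leaf-trait table
#'
#' Applies the natural logarithm to every numeric trait column, leaving the
#' species id and PFT label untouched. Trait values must be strictly
#' positive; offending species/trait combinations are named in the error.
#'
#' @param traits Data frame with columns `species`, `pft` and one numeric
#'   column per trait.
#' @return The table with trait columns log-transformed.
#' @export
log_transform_traits <- function(traits) {
  trait_cols <- setdiff(names(traits), c("species", "pft"))
  for (tc in trait_cols) {
    v <- traits[[tc]]
    if (!is.numeric(v)) stop("trait column '", tc, "' is not numeric")
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      stop("non-positive trait value(s): ",
           paste(sprintf("%s/%s", traits$species[bad], tc), collapse = ", "))
    }
    traits[[tc]] <- log(v)
  }
  traits
}

#' One-way ANOVA for a grouped trait
#'
#' Classical between/within sum-of-squares decomposition with the F test.
#' Requires at least two groups with at least two observations each. The
#' fully degenerate case (every observation identical) is reported as
#' `F = 0`, `p = 1`.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (or coercible).
#' @return Data frame with `F`, `df_between`, `df_within`, `p`,
#'   `ss_between`, `ss_within`.
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4, 10, 11, 12), rep(c("A", "B", "C"), each = 3))
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("values and groups differ in length")
  if (anyNA(values) || anyNA(groups)) stop("missing values are not supported")
  tab <- table(groups)
  if (length(tab) < 2) stop("at least two groups are required")
  if (any(tab < 2))
    stop("each group needs >= 2 observations; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  k <- length(tab)
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(tab * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- k - 1L
  dfw <- n - k
  if (ssb == 0 && ssw == 0) {
    Fstat <- 0; p <- 1
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  data.frame(F = Fstat, df_between = dfb, df_within = dfw, p = p,
             ss_between = ssb, ss_within = ssw)
}

#' Tukey-Kramer HSD pairwise comparisons
#'
#' All pairwise group comparisons after a one-way ANOVA, using the
#' Tukey-Kramer statistic for unequal sample sizes:
#' `q = |m_i - m_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))`, with p-values from the
#' studentized-range distribution (`stats::ptukey`). Groups are additionally
#' summarised by a compact letter display: groups sharing a letter do not
#' differ at level `alpha`.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `"tukey_hsd"` with `pairs` (data frame: `group1`,
#'   `group2`, `diff`, `se`, `q`, `p_adj`, `significant`) and `letters`
#'   (named character vector).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  aov1 <- anova_oneway(values, groups)  # validates input
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  mns <- tapply(values, groups, mean)
  msw <- aov1$ss_within / aov1$df_within
  df <- aov1$df_within

  cmb <- utils::combn(levels(groups), 2)
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ])
  pairs$diff <- as.numeric(mns[pairs$group2] - mns[pairs$group1])
  pairs$se <- as.numeric(sqrt(msw / 2 *
                                (1 / n[pairs$group1] + 1 / n[pairs$group2])))
  pairs$q <- abs(pairs$diff) / pairs$se
  pairs$p_adj <- stats::ptukey(pairs$q, nmeans = k, df = df, lower.tail = FALSE)
  pairs$significant <- pairs$p_adj < alpha
  rownames(pairs) <- NULL

  structure(list(pairs = pairs,
                 letters = cld_letters(pairs, levels(groups), mns),
                 alpha = alpha, df = df, msw = msw),
            class = "tukey_hsd")
}

# Compact letter display by the interval method: groups are ordered by mean
# and every maximal run of mutually non-significant groups receives one
# letter. Exact when the non-significance pattern is contiguous in the mean
# order (the usual case for location-shift alternatives).
cld_letters <- function(pairs, group_names, means) {
  ord <- names(sort(means))
  k <- length(ord)
  sig <- matrix(FALSE, k, k, dimnames = list(ord, ord))
  for (r in seq_len(nrow(pairs))) {
    g1 <- pairs$group1[r]; g2 <- pairs$group2[r]
    sig[g1, g2] <- sig[g2, g1] <- pairs$significant[r]
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  # drop runs contained in another run
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      a != b && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  letters_out <- stats::setNames(rep("", k), ord)
  for (ri in seq_along(runs)) {
    lab <- letters[(ri - 1) %% 26 + 1]
    for (g in ord[runs[[ri]]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out[group_names]
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat("Tukey-Kramer HSD (alpha =", x$alpha, ")\n")
  print(x$pairs, digits = 4)
  cat("Letters:", paste(names(x$letters), x$letters, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' ANOVA and Tukey-Kramer tests for every leaf trait
#'
#' Log-transforms the trait table, then runs [anova_oneway()] and
#' [tukey_hsd()] per trait with the PFT label as the grouping factor.
#'
#' @param traits Leaf-trait table (`species`, `pft`, trait columns), raw
#'   (positive) scale.
#' @param alpha Significance level for post hoc letters.
#' @return List with `anova` (one row per trait), `tukey` (named list of
#'   `"tukey_hsd"` objects) and `log_traits`.
#' @export
trait_group_tests <- function(traits, alpha = 0.05) {
  lt <- log_transform_traits(traits)
  trait_cols <- setdiff(names(lt), c("species", "pft"))
  an <- do.call(rbind, lapply(trait_cols, function(tc) {
    cbind(trait = tc, anova_oneway(lt[[tc]], lt$pft))
  }))
  rownames(an) <- NULL
  tk <- stats::setNames(
    lapply(trait_cols, function(tc) tukey_hsd(lt[[tc]], lt$pft, alpha = alpha)),
    trait_cols)
  list(anova = an, tukey = tk, log_traits = lt)
}

#' K-means clustering with elbow selection of K
#'
#' Standardizes the (log-scale) species-by-trait matrix to zero mean/unit
#' variance, runs best-of-restarts K-means for every K in `k_range`, and
#' selects K* at the elbow, operationalised as the maximum second difference
#' of the within-cluster sum of squares over the interior of `k_range`.
#' Reports the intra/inter-group variance split (WSS and BSS as percent of
#' total SS) and, when labels are supplied, the cross-tabulation against the
#' a-priori grouping.
#'
#' @param x Numeric matrix/data frame, species in rows (log scale
#'   recommended).
#' @param k_range Candidate cluster counts (default `2:5`).
#' @param restarts Random restarts per K (default 50).
#' @param seed Seed for the restarts.
#' @param labels Optional a-priori group labels (length `nrow(x)`).
#' @return List of class `"kmeans_elbow"`: `per_k` (data frame with K, WSS,
#'   BSS, intra_pct, inter_pct), `k_star`, `assignments` (for K*),
#'   `agreement` (contingency table, if labels given), `degenerate` flag.
#' @export
kmeans_elbow <- function(x, k_range = 2:5, restarts = 50L, seed = 1L,
                         labels = NULL) {
  x <- as.matrix(x)
  if (max(k_range) >= nrow(x))
    stop("max(k_range) must be smaller than the number of species")
  sds <- apply(x, 2, stats::sd)
  xs <- if (any(sds == 0)) sweep(x, 2, colMeans(x), "-") else scale(x)
  tss <- sum(xs^2)
  degenerate <- tss < 1e-12

  if (degenerate) {
    # all points coincide: WSS is zero at every K and no elbow exists
    per_k <- data.frame(K = k_range, wss = 0, bss = 0,
                        intra_pct = NA_real_, inter_pct = NA_real_)
    fits <- NULL
  } else {
    set.seed(seed)
    fits <- lapply(k_range, function(k)
      stats::kmeans(xs, centers = k, nstart = restarts, iter.max = 100L))
    per_k <- data.frame(
      K = k_range,
      wss = vapply(fits, function(f) f$tot.withinss, numeric(1)),
      bss = vapply(fits, function(f) f$betweenss, numeric(1))
    )
    per_k$intra_pct <- per_k$wss / tss * 100
    per_k$inter_pct <- per_k$bss / tss * 100
  }

  if (degenerate || length(k_range) < 3) {
    k_star <- NA_integer_
  } else {
    d2 <- diff(per_k$wss, differences = 2)  # indexed by interior K
    k_star <- k_range[which.max(d2) + 1L]
  }

  out <- list(per_k = per_k, k_star = k_star, degenerate = degenerate,
              fits = if (is.null(fits)) NULL else
                stats::setNames(fits, paste0("K", k_range)))
  if (!is.na(k_star)) {
    out$assignments <- fits[[match(k_star, k_range)]]$cluster
    if (!is.null(labels)) out$agreement <- table(cluster = out$assignments,
                                                 label = labels)
  }
  class(out) <- "kmeans_elbow"
  out
}

#' @export
print.kmeans_elbow <- function(x, ...) {
  cat("K-means elbow scan\n")
  print(x$per_k, digits = 4)
  cat("Selected K* =", x$k_star, if (x$degenerate) "(degenerate input)" else "", "\n")
  invisible(x)
}

#' Agreement between a clustering and reference groups
#'
#' Fraction of points whose cluster's majority reference group matches their
#' own (best-mapping agreement).
#'
#' @param cluster Integer/character cluster assignments.
#' @param reference Reference group labels.
#' @return Agreement fraction in `[0, 1]`.
#' @export
cluster_agreement <- function(cluster, reference) {
  tab <- table(cluster, reference)
  sum(apply(tab, 1, max)) / sum(tab)
}
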