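#' Prune correlated predictors and cap block width
#'
#' Reproduces the two-step predictor reduction of the gradient protocol.
#' Within each block, while any predictor pair has `|Pearson r|` above
#' `r_threshold`, the pair with the largest `|r|` is examined and its member
#' with the lower preliminary VIP is dropped; the preliminary VIP comes from
#' a one-component PLS of all (pooled) predictors on the full multivariate
#' response set. Afterwards, any block still wider than `target_width` loses
#' its lowest-VIP variables until the width is met. Every removal is logged
#' with its reason.
#'
#' @param env Environment table (see [as_environment_table()]).
#' @param responses Numeric site-by-response matrix/data frame used for the
#'   preliminary VIP (covers should already be arcsine-sqrt transformed).
#' @param r_threshold Correlation threshold (default 0.85).
#' @param target_width Maximum variables per block (default 8).
#' @return List with `env` (pruned table, block tags preserved), `removed`
#'   (data frame `variable`, `block`, `reason`, `detail`) and `vip`
#'   (preliminary VIP vector).
#' @export
prune_correlated <- function(env, responses, r_threshold = 0.85,
                             target_width = 8L) {
  if (target_width < 1) stop("target_width must be >= 1")
  blocks <- env_blocks(env)
  pred <- names(blocks)
  if (min(table(blocks)) < 2) stop("each block needs >= 2 variables")
  X <- as.matrix(env[pred])
  Y <- as.matrix(responses)
  vip0 <- pls_vip(pls_fit(X, Y, ncomp = 1))

  removed <- data.frame(variable = character(0), block = character(0),
                        reason = character(0), detail = character(0))
  keep <- pred
  for (b in unique(blocks)) {
    vars <- keep[blocks[keep] == b]
    repeat {
      if (length(vars) < 2) break
      cm <- abs(stats::cor(X[, vars, drop = FALSE]))
      diag(cm) <- 0
      if (max(cm) <= r_threshold) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- vars[ij]
      drop_var <- pair[which.min(vip0[pair])]
      partner <- setdiff(pair, drop_var)
      removed <- rbind(removed, data.frame(
        variable = drop_var, block = b, reason = "correlated",
        detail = sprintf("|r| = %.3f with %s (VIP %.3f < %.3f)",
                         max(cm), partner, vip0[drop_var], vip0[partner])))
      vars <- setdiff(vars, drop_var)
    }
    while (length(vars) > target_width) {
      drop_var <- vars[which.min(vip0[vars])]
      removed <- rbind(removed, data.frame(
        variable = drop_var, block = b, reason = "width",
        detail = sprintf("lowest VIP in block (%.3f)", vip0[drop_var])))
      vars <- setdiff(vars, drop_var)
    }
    keep <- setdiff(keep, setdiff(pred[blocks == b], vars))
  }
  keep <- pred[pred %in% keep]
  env2 <- as_environment_table(env[c("site", keep)], blocks[keep])
  rownames(removed) <- NULL
  list(env = env2, removed = removed, vip = vip0)
}

#' VIP prescreening of predictors for a single response
#'
#' One-component preliminary PLS1 of the pooled predictor table on the
#' response; predictors with VIP above `vip_cut` are kept, truncated to the
#' `max_vars` highest when more exceed the cut.
#'
#' @param X Site-by-predictor matrix/data frame.
#' @param y Single response vector (analysis scale).
#' @param vip_cut VIP cut-off (default 0.9).
#' @param max_vars Cap on retained predictors (default 15).
#' @return Character vector of retained predictor names (VIP-descending).
#' @export
prescreen_vip <- function(X, y, vip_cut = 0.9, max_vars = 15L) {
  X <- as.matrix(X)
  vip <- pls_vip(pls_fit(X, y, ncomp = 1))
  sel <- sort(vip[vip > vip_cut], decreasing = TRUE)
  names(utils::head(sel, max_vars))
}

#' Partition sites into near-equal random groups
#'
#' @param n Number of sites.
#' @param n_groups Number of groups (default 5, each ~20% of sites).
#' @param seed Seed for the random assignment.
#' @return Integer vector of group ids in `1..n_groups`; sizes differ by at
#'   most one.
#' @export
lno_partition <- function(n, n_groups = 5L, seed = 1L) {
  if (n_groups > n) stop("n_groups exceeds the number of sites")
  set.seed(seed)
  sample(rep(seq_len(n_groups), length.out = n))
}

#' Leave-N-out cross-validation of a PLS model
#'
#' Sites are randomly split into `n_groups` near-equal groups. For every
#' group, a model is refit on the remaining sites (scaling refit; predictor
#' selection frozen by the caller) and its component count chosen by the
#' maximum-Q2 rule; reported `Q2` is, by default, the internal leave-one-out
#' Q2 of each training subsample (`lno_eval = "holdout"` evaluates each
#' fold's omitted group instead). The full-data model is fitted and reported
#' alongside, and fold-wise N, Q2, R2, VIP and standardized coefficients are
#' summarised as mode/range and mean/SD.
#'
#' Non-significant fits (no component with Q2 above the threshold) are
#' reported with one component and flagged, matching how single-component
#' models with negative Q2 are conventionally tabulated.
#'
#' @param X Site-by-predictor matrix (already reduced/selected).
#' @param Y Response vector or matrix (analysis scale).
#' @param n_groups Number of LNO groups (default 5).
#' @param seed Seed for the partition.
#' @param threshold Q2 entry threshold (default 0.097).
#' @param ncomp_max Maximum components examined.
#' @param lno_eval `"internal"` (default) or `"holdout"`.
#' @return List of class `"lno_cv"` with `full` (N, Q2, R2, significant,
#'   vip, coef), `folds` (data frame), `vip` and `coef` fold summaries
#'   (mean/SD), `partition`, and `summary` (mode/range of N, mean/SD of Q2
#'   and R2).
#' @export
lno_crossvalidate <- function(X, Y, n_groups = 5L, seed = 1L,
                              threshold = 0.097, ncomp_max = 10L,
                              lno_eval = c("internal", "holdout")) {
  lno_eval <- match.arg(lno_eval)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  part <- lno_partition(n, n_groups = n_groups, seed = seed)

  fit_one <- function(Xt, Yt, Xv = NULL, Yv = NULL) {
    amax <- min(ncomp_max, nrow(Xt) - 2, ncol(Xt))
    sel <- pls_select_ncomp(Xt, Yt, threshold = threshold, ncomp_max = amax)
    a_rep <- max(sel$ncomp, 1L)
    fit <- pls_fit(Xt, Yt, ncomp = a_rep)
    q2 <- if (lno_eval == "holdout" && !is.null(Xv)) {
      press <- sum((Yv - predict(fit, Xv, ncomp = a_rep))^2)
      1 - press / sum(sweep(Yv, 2, colMeans(Yt), "-")^2)
    } else {
      sel$q2_cum[a_rep]
    }
    list(N = a_rep, significant = sel$significant, q2 = q2,
         r2 = fit$r2y_cum[a_rep],
         vip = pls_vip(fit), coef = coef.pls_model(fit))
  }

  full <- fit_one(X, Y)
  folds <- lapply(seq_len(n_groups), function(k) {
    idx <- part == k
    fit_one(X[!idx, , drop = FALSE], Y[!idx, , drop = FALSE],
            X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
  })

  Nk <- vapply(folds, `[[`, integer(1), "N")
  q2k <- vapply(folds, `[[`, numeric(1), "q2")
  r2k <- vapply(folds, `[[`, numeric(1), "r2")
  vip_mat <- do.call(rbind, lapply(folds, `[[`, "vip"))
  coef_mat <- do.call(rbind, lapply(folds, function(f) drop(f$coef)))
  if (is.null(dim(coef_mat))) coef_mat <- matrix(coef_mat, ncol = 1)

  mode_N <- as.integer(names(sort(table(Nk), decreasing = TRUE))[1])
  summary <- list(
    N_mode = mode_N, N_range = range(Nk),
    q2_mean = mean(q2k), q2_sd = stats::sd(q2k),
    r2_mean = mean(r2k), r2_sd = stats::sd(r2k)
  )
  structure(list(
    full = full,
    folds = data.frame(fold = seq_len(n_groups), N = Nk, Q2 = q2k, R2 = r2k),
    vip = list(mean = colMeans(vip_mat), sd = apply(vip_mat, 2, stats::sd)),
    coef = list(mean = colMeans(coef_mat), sd = apply(coef_mat, 2, stats::sd)),
    partition = part, summary = summary, threshold = threshold,
    lno_eval = lno_eval
  ), class = "lno_cv")
}

#' @export
print.lno_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Full model: N = %d, Q2 = %.3f, R2 = %.3f%s\n",
              x$full$N, x$full$q2, x$full$r2,
              if (x$full$significant) "" else " (not significant)"))
  cat(sprintf("LNO: N mode %d (range %d-%d), Q2 %.3f +/- %.3f, R2 %.3f +/- %.3f\n",
              s$N_mode, s$N_range[1], s$N_range[2],
              s$q2_mean, s$q2_sd, s$r2_mean, s$r2_sd))
  invisible(x)
}

block_combos <- function() c("C", "S", "P", "C+S", "C+P", "S+P", "C+S+P")

combo_columns <- function(env, combo) {
  blocks <- env_blocks(env)
  code <- c(C = "climate", S = "soil", P = "physical")
  parts <- strsplit(combo, "+", fixed = TRUE)[[1]]
  if (length(parts) == 0 || !all(parts %in% names(code)))
    stop("invalid block combination: ", combo)
  names(blocks)[blocks %in% code[parts]]
}

#' Multivariate PLS models for block combinations
#'
#' Fits one multivariate-response PLS model per predictor-block combination
#' (climate, soil, physical, and their pairwise/triple unions), each with
#' component selection and leave-N-out summary, yielding the comparison-table
#' structure of the protocol (7 rows per response set).
#'
#' @param env Pruned environment table.
#' @param responses Multivariate response matrix (analysis scale).
#' @param combos Character vector of combinations among
#'   `"C" "S" "P" "C+S" "C+P" "S+P" "C+S+P"`.
#' @inheritParams lno_crossvalidate
#' @return Data frame, one row per combination: full-model `N`, `Q2`, `R2`,
#'   `significant`, and LNO summaries (`N_mode`, `N_min`, `N_max`,
#'   `Q2_lno_mean`, `Q2_lno_sd`, `R2_lno_mean`, `R2_lno_sd`); the per-combo
#'   `lno_cv` objects are attached as attribute `fits`.
#' @export
combination_models <- function(env, responses, combos = block_combos(),
                               n_groups = 5L, seed = 1L, threshold = 0.097,
                               ncomp_max = 10L,
                               lno_eval = c("internal", "holdout")) {
  lno_eval <- match.arg(lno_eval)
  Y <- as.matrix(responses)
  fits <- lapply(combos, function(cb) {
    X <- as.matrix(env[combo_columns(env, cb)])
    lno_crossvalidate(X, Y, n_groups = n_groups, seed = seed,
                      threshold = threshold, ncomp_max = ncomp_max,
                      lno_eval = lno_eval)
  })
  names(fits) <- combos
  out <- do.call(rbind, lapply(combos, function(cb) {
    f <- fits[[cb]]
    s <- f$summary
    data.frame(combo = cb, N = f$full$N, Q2 = f$full$q2, R2 = f$full$r2,
               significant = f$full$significant && f$full$q2 > threshold,
               N_mode = s$N_mode, N_min = s$N_range[1], N_max = s$N_range[2],
               Q2_lno_mean = s$q2_mean, Q2_lno_sd = s$q2_sd,
               R2_lno_mean = s$r2_mean, R2_lno_sd = s$r2_sd)
  }))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Univariate PLS models per PFT response
#'
#' For each response (percent cover and Simpson diversity of the five PFTs,
#' plus total canopy cover and total diversity): covers are arcsine-sqrt
#' transformed, predictors are VIP-prescreened on the pooled (pruned)
#' predictor table, and the model is assessed by [lno_crossvalidate()]. The
#' summary table mirrors the univariate-model report, and the VIP report
#' lists only predictors whose across-fold mean VIP exceeds 1, VIP-descending.
#'
#' @param env Pruned environment table.
#' @param responses Response table with `site`, `cover_*` and `div_*` columns
#'   (raw percent / 1-D scale).
#' @param vip_cut,max_vars Prescreening parameters (defaults 0.9 and 15).
#' @inheritParams lno_crossvalidate
#' @return List with `summary` (one row per response), `vip_report` (rows
#'   with fold-mean VIP > 1) and `fits` (named `lno_cv` list).
#' @export
univariate_models <- function(env, responses, vip_cut = 0.9, max_vars = 15L,
                              n_groups = 5L, seed = 1L, threshold = 0.097,
                              ncomp_max = 10L,
                              lno_eval = c("internal", "holdout")) {
  lno_eval <- match.arg(lno_eval)
  resp_names <- c(paste0("cover_", c("GG", "ES", "ET", "DS", "DT")),
                  "cover_total_canopy",
                  paste0("div_", c("GG", "ES", "ET", "DS", "DT")), "div_total")
  missing_resp <- setdiff(resp_names, names(responses))
  if (length(missing_resp))
    stop("missing response column(s): ", paste(missing_resp, collapse = ", "))
  pred <- setdiff(names(env), "site")
  X_all <- as.matrix(env[pred])

  fits <- list(); rows <- list(); vip_rows <- list()
  for (r in resp_names) {
    y <- responses[[r]]
    if (startsWith(r, "cover")) y <- arcsine_sqrt(y / 100)
    sel_vars <- prescreen_vip(X_all, y, vip_cut = vip_cut, max_vars = max_vars)
    if (length(sel_vars) < 2) sel_vars <- pred  # degenerate prescreen
    f <- lno_crossvalidate(X_all[, sel_vars, drop = FALSE], y,
                           n_groups = n_groups, seed = seed,
                           threshold = threshold, ncomp_max = ncomp_max,
                           lno_eval = lno_eval)
    fits[[r]] <- f
    s <- f$summary
    rows[[r]] <- data.frame(
      response = r, N = f$full$N, Q2 = f$full$q2, R2 = f$full$r2,
      significant = f$full$significant && f$full$q2 > threshold,
      n_predictors = length(sel_vars),
      N_mode = s$N_mode, N_min = s$N_range[1], N_max = s$N_range[2],
      Q2_lno_mean = s$q2_mean, Q2_lno_sd = s$q2_sd,
      R2_lno_mean = s$r2_mean, R2_lno_sd = s$r2_sd)
    vm <- f$vip$mean
    keep <- names(sort(vm[vm > 1], decreasing = TRUE))
    if (length(keep)) {
      vip_rows[[r]] <- data.frame(
        response = r, predictor = keep,
        vip_mean = f$vip$mean[keep], vip_sd = f$vip$sd[keep],
        coef_mean = f$coef$mean[keep], coef_sd = f$coef$sd[keep])
    }
  }
  summary <- do.call(rbind, rows); rownames(summary) <- NULL
  vip_report <- if (length(vip_rows)) do.call(rbind, vip_rows) else
    data.frame(response = character(0), predictor = character(0),
               vip_mean = numeric(0), vip_sd = numeric(0),
               coef_mean = numeric(0), coef_sd = numeric(0))
  rownames(vip_report) <- NULL
  list(summary = summary, vip_report = vip_report, fits = fits)
}

#' Configuration for the full analysis pipeline
#'
#' @param r_threshold Correlation-pruning threshold (default 0.85).
#' @param target_width Post-pruning block width (default 8).
#' @param vip_cut,max_vars Univariate prescreening parameters (0.9, 15).
#' @param q2_threshold Component-entry Q2 threshold (default 0.097).
#' @param n_groups Leave-N-out groups (default 5).
#' @param ncomp_max Maximum PLS components examined (default 10).
#' @param seed Seed controlling all pipeline randomness (LNO partitions and
#'   K-means restarts).
#' @param combos Block combinations for the multivariate stage.
#' @param alpha Significance level of the trait stage (default 0.05).
#' @param k_range,restarts K-means elbow scan parameters (2:5, 50).
#' @param lno_eval Fold Q2 convention, see [lno_crossvalidate()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(r_threshold = 0.85, target_width = 8L,
                            vip_cut = 0.9, max_vars = 15L,
                            q2_threshold = 0.097, n_groups = 5L,
                            ncomp_max = 10L, seed = 1L,
                            combos = block_combos(), alpha = 0.05,
                            k_range = 2:5, restarts = 50L,
                            lno_eval = "internal") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full gradient-analysis pipeline
#'
#' Executes, on a dataset with environment, response and leaf-trait tables:
#' (1) schema validation; (2) the trait stage (log-transform, per-trait
#' one-way ANOVA with Tukey-Kramer letters, K-means elbow against the
#' a-priori PFT grouping); (3) correlation pruning of the predictor blocks;
#' (4) multivariate block-combination models for the cover and diversity
#' response sets; (5) univariate per-response models with VIP prescreening
#' and leave-N-out summaries. All randomness flows from `config$seed`, so a
#' run is exactly replayable.
#'
#' @param dataset A `"synthetic_dataset"` or a list with elements
#'   `environment`, `responses`, `traits` of the same shapes.
#' @param config A [pipeline_config()].
#' @return List of class `"pls_report"` with elements `traits`
#'   (anova/tukey/kmeans), `pruning`, `combination` (cover and diversity
#'   tables), `univariate` (summary and VIP report), `config` and `seed`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  validate_dataset(dataset)
  env <- dataset$environment
  resp <- dataset$responses

  tg <- trait_group_tests(dataset$traits, alpha = config$alpha)
  km <- kmeans_elbow(tg$log_traits[setdiff(names(tg$log_traits),
                                           c("species", "pft"))],
                     k_range = config$k_range, restarts = config$restarts,
                     seed = config$seed, labels = dataset$traits$pft)

  cover_cols <- paste0("cover_", c("GG", "ES", "ET", "DS", "DT"))
  div_cols <- paste0("div_", c("GG", "ES", "ET", "DS", "DT"))
  Y_cover <- arcsine_sqrt(as.matrix(resp[cover_cols]) / 100)
  Y_div <- as.matrix(resp[div_cols])

  pr <- prune_correlated(env, cbind(Y_cover, Y_div),
                         r_threshold = config$r_threshold,
                         target_width = config$target_width)

  comb_cover <- combination_models(pr$env, Y_cover, combos = config$combos,
                                   n_groups = config$n_groups,
                                   seed = config$seed,
                                   threshold = config$q2_threshold,
                                   ncomp_max = config$ncomp_max,
                                   lno_eval = config$lno_eval)
  comb_div <- combination_models(pr$env, Y_div, combos = config$combos,
                                 n_groups = config$n_groups,
                                 seed = config$seed,
                                 threshold = config$q2_threshold,
                                 ncomp_max = config$ncomp_max,
                                 lno_eval = config$lno_eval)

  uni <- univariate_models(pr$env, resp, vip_cut = config$vip_cut,
                           max_vars = config$max_vars,
                           n_groups = config$n_groups, seed = config$seed,
                           threshold = config$q2_threshold,
                           ncomp_max = config$ncomp_max,
                           lno_eval = config$lno_eval)

  structure(list(
    traits = list(anova = tg$anova, tukey = tg$tukey, kmeans = km),
    pruning = pr,
    combination = list(cover = comb_cover, diversity = comb_div),
    univariate = uni,
    partition = attr(comb_cover, "fits")[[1]]$partition,
    config = config, seed = config$seed
  ), class = "pls_report")
}

#' @export
print.pls_report <- function(x, ...) {
  cat("Gradient-analysis report\n")
  cat("  Trait ANOVAs:", nrow(x$traits$anova), "traits; K* =",
      x$traits$kmeans$k_star, "\n")
  cat("  Pruning removed:", paste(x$pruning$removed$variable, collapse = ", "), "\n")
  cat("  Combination models (cover):\n")
  print(x$combination$cover[c("combo", "N", "Q2", "R2", "significant")],
        digits = 3)
  cat("  Univariate models:\n")
  print(x$univariate$summary[c("response", "N", "Q2", "R2", "significant")],
        digits = 3)
  invisible(x)
}

validate_dataset <- function(dataset) {
  problems <- character(0)
  for (el in c("environment", "responses", "traits")) {
    if (is.null(dataset[[el]])) problems <- c(problems, paste("missing element:", el))
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))
  env <- dataset$environment; resp <- dataset$responses
  if (is.null(attr(env, "blocks")))
    problems <- c(problems, "environment table lacks block tags")
  if (!"site" %in% names(env)) problems <- c(problems, "environment lacks 'site'")
  if (!"site" %in% names(resp)) problems <- c(problems, "responses lack 'site'")
  if (!length(problems) && !identical(as.character(env$site),
                                      as.character(resp$site)))
    problems <- c(problems, "environment and responses site ids differ")
  resp_needed <- c(paste0("cover_", c("GG", "ES", "ET", "DS", "DT")),
                   "cover_total_canopy",
                   paste0("div_", c("GG", "ES", "ET", "DS", "DT")), "div_total")
  miss <- setdiff(resp_needed, names(resp))
  if (length(miss))
    problems <- c(problems, paste("missing response column(s):",
                                  paste(miss, collapse = ", ")))
  tr <- dataset$traits
  if (!all(c("species", "pft") %in% names(tr)))
    problems <- c(problems, "traits table needs 'species' and 'pft' columns")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  invisible(TRUE)
}
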