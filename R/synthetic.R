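#' Target marginals for the synthetic environment table
#'
#' One row per sampled environmental variable: block membership, target
#' mean/SD and observed range for 34 Mediterranean headwater streams, the
#' marginal family used by the generator, and the loading of the variable on
#' the latent aridity axis (positive = increases with aridity). Near-
#' symmetric variables use a range-truncated normal whose underlying
#' parameters are calibrated so the truncated moments hit the targets;
#' skewed or over-dispersed bounded variables (where no truncated normal can
#' reach the target SD inside the observed range) use a range-scaled beta
#' with exactly moment-matched shape parameters. Derived columns (PP/PET, de
#' Martonne, Emberger Q2, C:N) are computed, not sampled, and do not appear
#' here.
#'
#' @return Data frame with columns `variable`, `block`, `mean`, `sd`, `min`,
#'   `max`, `family`, `loading`.
#' @export
env_marginal_targets <- function() {
  df <- utils::read.csv(text = "
variable,block,mean,sd,min,max,family,loading
PP,climate,833,325,297,1414,norm,-0.85
PET,climate,741,65,633,920,norm,0.80
DaysPP,climate,58,17,28,89,norm,-0.75
Tmean,climate,13.8,2.0,10.3,18.3,norm,0.85
Tmin_jan,climate,2.6,2.7,-1.3,8.2,norm,0.55
Tmax_jul,climate,29.5,2.3,22.9,33.0,norm,0.70
Trange,climate,26.9,3.8,14.9,31.5,norm,0.45
EC,soil,1020,717,301,3290,beta,0.60
pH_w,soil,7.37,0.96,5.25,8.81,norm,0.55
CaCO3,soil,18.97,27.38,0.01,85.86,beta,0.30
OC,soil,2.64,1.79,0.10,5.41,beta,-0.55
N,soil,0.122,0.089,0.017,0.358,beta,-0.50
P,soil,329,164,92,783,beta,0
CEC,soil,14.89,9.69,2.68,47.80,beta,0.20
AW,soil,4.79,2.26,1.26,11.07,beta,0
BS,soil,88.88,15.77,45.69,100,beta,0.50
ESP,soil,2.65,5.71,0.13,32.39,beta,0.55
altitude,physical,763,391,47,1465,norm,-0.70
slope,physical,20,5,9,31,norm,0
basin_area,physical,559,346,12,1480,beta,0
southern_orientation,physical,67,65,1,180,beta,0.20
bankfull_width,physical,9,5,3,19,beta,0
active_width,physical,2.2,1,0.75,5,beta,-0.30
hard_substrate,physical,34,23,5,80,beta,-0.20
discharge,physical,98,147,3,597,beta,-0.40
", stringsAsFactors = FALSE)
  df
}

#' Default signed effect matrix from predictors to PFT responses
#'
#' Encodes, as standardized effects on the analysis scale (arcsine-sqrt for
#' covers, evenness scale for diversities), the qualitative sign structure of
#' the gradient study: aridity (acting through the UNEP PP/PET index, mean
#' temperature and the aridity-coupled soil variables) favours giant
#' graminoids and disfavours deciduous trees; precipitation and mild winters
#' favour evergreens; altitude favours deciduous trees. Effects are planted
#' on the UNEP index where the field system reports it among the top
#' predictors, which is also what makes the redundant aridity indices (de
#' Martonne) and PET prunable by the preliminary-VIP rule. Magnitudes are
#' free generator parameters (no effect sizes are reported for the field
#' system); defaults give the downstream models realistic, recoverable
#' signal.
#'
#' @return Numeric matrix, predictors in rows, responses in columns.
#' @export
default_effect_matrix <- function() {
  responses <- c("cover_GG", "cover_ES", "cover_ET", "cover_DS", "cover_DT",
                 "div_GG", "div_ES", "div_ET", "div_DS", "div_DT", "div_total")
  predictors <- c("PP", "PP_PET", "Q2", "DaysPP", "Tmean", "Tmin_jan",
                  "Tmax_jul", "Trange", "EC", "pH_w", "OC", "CN", "CaCO3",
                  "P", "ESP", "BS", "altitude", "hard_substrate",
                  "southern_orientation")
  B <- matrix(0, length(predictors), length(responses),
              dimnames = list(predictors, responses))
  set_eff <- function(resp, ...) {
    e <- c(...)
    B[names(e), resp] <<- e
  }
  set_eff("cover_GG", PP_PET = -0.40, Tmean = 0.15, EC = 0.35, pH_w = 0.25,
          ESP = 0.25)
  set_eff("cover_ES", PP = 0.20, Q2 = 0.45, Tmin_jan = 0.30,
          altitude = -0.25)
  set_eff("cover_ET", DaysPP = 0.30, Q2 = 0.45, Tmin_jan = 0.20)
  set_eff("cover_DS", DaysPP = 0.10)
  set_eff("cover_DT", Tmean = -0.15, EC = -0.35, ESP = -0.30, altitude = 0.35,
          hard_substrate = -0.20)
  set_eff("div_GG", pH_w = 0.45, Tmean = 0.15, OC = -0.25, PP_PET = -0.30,
          BS = 0.20)
  set_eff("div_ES", hard_substrate = 0.35, Tmin_jan = 0.30, PP = 0.20,
          Q2 = 0.40, altitude = -0.20)
  set_eff("div_ET", Trange = -0.40, Tmin_jan = 0.30, Q2 = 0.40)
  set_eff("div_DS", DaysPP = 0.35, CN = 0.30, Trange = 0.30, Tmax_jul = 0.25,
          CaCO3 = 0.20)
  set_eff("div_DT", altitude = 0.35, OC = 0.30, Tmean = -0.15, P = 0.25,
          ESP = -0.20, CaCO3 = 0.20)
  set_eff("div_total", Tmean = 0.05)
  B
}

#' Configuration for the synthetic stream-site generator
#'
#' @param n_sites Number of stream sites (>= 10; default 34, the study size).
#' @param seed Integer seed; identical configurations produce bit-identical
#'   datasets. `NULL` leaves the RNG state untouched.
#' @param block_targets Per-variable marginal targets, see [env_marginal_targets()].
#' @param climate_soil_coupling Named loadings of the soil variables coupled
#'   to the aridity axis (`EC`, `pH_w`, `ESP`, `BS` positive, `OC` negative);
#'   overrides the corresponding `block_targets$loading` entries. Set to zero
#'   to decouple soils from climate.
#' @param effect_matrix Signed predictor-to-response effects, see
#'   [default_effect_matrix()].
#' @param noise_sd Residual SD of the response linear predictors (> 0,
#'   default 0.3, arcsine scale for covers).
#' @param cover_simplex If `TRUE` (default), site rows whose summed PFT cover
#'   exceeds a plausible canopy-plus-understorey total (160%) are rescaled
#'   down to it.
#' @param species_counts Named species counts per PFT for the leaf-trait
#'   table (default `c(GG=3, ES=6, ET=5, DS=3, DT=15)`).
#' @param trait_separation Multiplier in `[0, 1]` on the between-PFT
#'   log-median trait differences (1 = full separation, 0 = identical
#'   groups, for type-I-error checks).
#' @param trait_sdlog Within-PFT log-scale trait SD (default 0.18).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_sites = 34L,
                       seed = 1L,
                       block_targets = env_marginal_targets(),
                       climate_soil_coupling = c(EC = 0.60, pH_w = 0.55,
                                                 ESP = 0.55, BS = 0.50,
                                                 OC = -0.55),
                       effect_matrix = default_effect_matrix(),
                       noise_sd = 0.3,
                       cover_simplex = TRUE,
                       species_counts = c(GG = 3L, ES = 6L, ET = 5L,
                                          DS = 3L, DT = 15L),
                       trait_separation = 1,
                       trait_sdlog = 0.18) {
  if (n_sites < 10) stop("n_sites must be >= 10")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (any(!is.finite(effect_matrix))) stop("effect sizes must be finite")
  if (any(block_targets$min > block_targets$max))
    stop("infeasible bounds (min > max) for: ",
         paste(block_targets$variable[block_targets$min > block_targets$max],
               collapse = ", "))
  if (any(species_counts < 1)) stop("species counts must be >= 1")
  keep <- intersect(names(climate_soil_coupling), block_targets$variable)
  block_targets$loading[match(keep, block_targets$variable)] <-
    climate_soil_coupling[keep]
  structure(list(
    n_sites = as.integer(n_sites), seed = seed,
    block_targets = block_targets,
    climate_soil_coupling = climate_soil_coupling,
    effect_matrix = effect_matrix,
    noise_sd = noise_sd, cover_simplex = cover_simplex,
    species_counts = species_counts,
    trait_separation = trait_separation, trait_sdlog = trait_sdlog
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic stream-site configuration:", x$n_sites, "sites, seed",
      if (is.null(x$seed)) "NULL" else x$seed, "\n")
  cat("  ", nrow(x$block_targets), "sampled variables,",
      sum(x$effect_matrix != 0), "non-zero planted effects, noise_sd =",
      x$noise_sd, "\n")
  invisible(x)
}

# ---- calibrated-marginal machinery -----------------------------------------

# closed-form mean/sd of a normal truncated to [lo, hi]
trunc_norm_moments <- function(par1, par2, lo, hi) {
  a <- (lo - par1) / par2; b <- (hi - par1) / par2
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z < 1e-12) return(c(NA, NA))
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- par1 + par2 * (da - db) / Z
  v <- par2^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

# solve for the (mu, sigma) whose [lo,hi]-truncated normal matches the
# target mean/sd (deterministic Nelder-Mead from the untruncated start), or
# moment-match a [lo,hi]-scaled beta in closed form
calibrate_marginal <- function(family, mean, sd, lo, hi) {
  if (family == "norm") {
    obj <- function(par) {
      ms <- trunc_norm_moments(par[1], exp(par[2]), lo, hi)
      if (anyNA(ms)) return(1e6)
      ((ms[1] - mean) / mean)^2 + ((ms[2] - sd) / sd)^2
    }
    opt <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    list(family = "norm", par1 = opt$par[1], par2 = exp(opt$par[2]),
         lo = lo, hi = hi)
  } else if (family == "beta") {
    m <- (mean - lo) / (hi - lo)
    v <- (sd / (hi - lo))^2
    nu <- m * (1 - m) / v - 1
    if (!is.finite(nu) || nu <= 0)
      stop("target SD infeasible inside [min, max] for a beta marginal")
    list(family = "beta", par1 = m * nu, par2 = (1 - m) * nu, lo = lo, hi = hi)
  } else stop("unknown marginal family: ", family)
}

# map a standard-normal score to the calibrated marginal (comonotone
# inverse-CDF transform, preserving the latent rank structure)
trunc_quantile <- function(cal, s) {
  u <- stats::pnorm(s)
  if (cal$family == "norm") {
    pa <- stats::pnorm(cal$lo, cal$par1, cal$par2)
    pb <- stats::pnorm(cal$hi, cal$par1, cal$par2)
    stats::qnorm(pa + u * (pb - pa), cal$par1, cal$par2)
  } else {
    cal$lo + (cal$hi - cal$lo) * stats::qbeta(u, cal$par1, cal$par2)
  }
}

# ---- environment ------------------------------------------------------------

#' Generate a synthetic stream-site environment table
#'
#' Draws one latent aridity axis per landscape plus a shared soil
#' organic-matter factor; every variable is a loading on the aridity axis
#' plus independent Gaussian residual, pushed through a marginal calibrated
#' so that the truncated distribution matches its configured mean/SD and
#' stays inside the configured range. Potential evapotranspiration runs
#' against precipitation (r ~ -0.88), which makes PET strongly redundant
#' with the UNEP PP/PET ratio and reproduces the collinearity that motivates
#' correlation pruning downstream. The aridity indices (PP/PET, de Martonne,
#' Emberger Q2) and C:N are computed from the sampled columns, not sampled.
#'
#' @param config A [sim_config()].
#' @return Data frame (`site` + 29 numeric columns) with attribute `blocks`
#'   (named block membership) and attribute `aridity` (the latent axis).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tg <- config$block_targets
  n <- config$n_sites

  z <- stats::rnorm(n)          # aridity axis (hot/dry high)
  f_org <- stats::rnorm(n)      # shared organic-matter factor (OC, N)
  eps <- matrix(stats::rnorm(n * nrow(tg)), n, nrow(tg))

  scores <- matrix(NA_real_, n, nrow(tg), dimnames = list(NULL, tg$variable))
  for (j in seq_len(nrow(tg))) {
    v <- tg$variable[j]; lam <- tg$loading[j]
    if (v == "PET") next  # filled from Tmean below
    if (v %in% c("OC", "N")) {
      gam <- if (v == "OC") 0.70 else 0.72
      del <- sqrt(max(1 - lam^2 - gam^2, 0))
      scores[, j] <- lam * z + gam * f_org + del * eps[, j]
    } else {
      scores[, j] <- lam * z + sqrt(1 - lam^2) * eps[, j]
    }
  }
  # PET runs against PP (hot, clear-sky sites are the driest); the strong
  # anti-correlation makes PET redundant with the UNEP ratio PP/PET, which
  # is what lets the correlation-pruning stage discard it downstream
  j_pet <- match("PET", tg$variable)
  rho_pet <- -0.93
  scores[, j_pet] <- rho_pet * scores[, "PP"] +
    sqrt(1 - rho_pet^2) * eps[, j_pet]

  vals <- matrix(NA_real_, n, nrow(tg), dimnames = list(NULL, tg$variable))
  for (j in seq_len(nrow(tg))) {
    cal <- calibrate_marginal(tg$family[j], tg$mean[j], tg$sd[j],
                              tg$min[j], tg$max[j])
    vals[, j] <- trunc_quantile(cal, scores[, j])
  }

  env <- as.data.frame(vals)
  env$active_width <- pmin(env$active_width, env$bankfull_width)
  env$PP_PET <- unep_aridity(env$PP, env$PET)
  env$IDM <- de_martonne(env$PP, env$Tmean)
  env$Q2 <- emberger_q2(env$PP, env$Tmax_jul, env$Tmin_jan)
  env$CN <- env$OC / env$N

  blocks <- stats::setNames(tg$block, tg$variable)
  blocks <- c(blocks, PP_PET = "climate", IDM = "climate", Q2 = "climate",
              CN = "soil")
  env <- cbind(site = sprintf("site_%03d", seq_len(n)), env)
  env <- as_environment_table(env, blocks)
  attr(env, "aridity") <- z
  env
}

#' Tag a site-by-predictor data frame with block membership
#'
#' @param df Data frame with a `site` column and numeric predictor columns.
#' @param blocks Named character vector mapping every predictor column to
#'   `"climate"`, `"soil"` or `"physical"`.
#' @return The data frame with attribute `blocks`.
#' @export
as_environment_table <- function(df, blocks) {
  pred <- setdiff(names(df), "site")
  missing_tag <- setdiff(pred, names(blocks))
  if (length(missing_tag))
    stop("columns without block tag: ", paste(missing_tag, collapse = ", "))
  bad <- !blocks[pred] %in% c("climate", "soil", "physical")
  if (any(bad))
    stop("invalid block tag for: ", paste(pred[bad], collapse = ", "))
  attr(df, "blocks") <- blocks[pred]
  df
}

#' @rdname as_environment_table
#' @param env An environment table.
#' @export
env_blocks <- function(env) {
  b <- attr(env, "blocks")
  if (is.null(b)) stop("environment table carries no block tags")
  b
}

# ---- responses --------------------------------------------------------------

#' Generate PFT cover and diversity responses from an environment table
#'
#' Covers are built on the arcsine-square-root scale, where the planted
#' effects are linear: `theta = theta0 + X_std %*% beta + noise`, clipped to
#' `[0, pi/2]` and back-transformed to percent. Per-PFT Simpson diversity
#' comes from a symmetric Dirichlet species-abundance draw whose
#' concentration (hence evenness) increases with the same linear predictor.
#' Total canopy cover is a monotone (complement-product) function of the
#' three woody-canopy covers, and total diversity is Simpson 1-D over the
#' pooled, cover-weighted species abundances of all PFTs.
#'
#' @param env Environment table from [simulate_environment()].
#' @param config A [sim_config()]; all predictors named in
#'   `config$effect_matrix` must be columns of `env`.
#' @return Data frame with `site`, five `cover_*` columns, `cover_total_canopy`,
#'   five `div_*` columns and `div_total`.
#' @export
simulate_pft_responses <- function(env, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(env) == 0) stop("env is empty")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  B <- config$effect_matrix
  unknown <- setdiff(rownames(B), names(env))
  if (length(unknown))
    stop("effect_matrix names unknown predictor(s): ",
         paste(unknown, collapse = ", "))
  X <- as.matrix(env[rownames(B)])
  Xs <- scale(X)
  eta <- Xs %*% B
  n <- nrow(env)
  pfts <- c("GG", "ES", "ET", "DS", "DT")

  theta0 <- c(GG = arcsine_sqrt(0.15), ES = arcsine_sqrt(0.12),
              ET = arcsine_sqrt(0.15), DS = arcsine_sqrt(0.08),
              DT = arcsine_sqrt(0.35))
  covers <- sapply(pfts, function(g) {
    th <- theta0[g] + eta[, paste0("cover_", g)] +
      stats::rnorm(n, 0, config$noise_sd)
    100 * inv_arcsine_sqrt(pmin(pmax(th, 0), pi / 2))
  })
  colnames(covers) <- paste0("cover_", pfts)

  if (isTRUE(config$cover_simplex)) {
    tot <- rowSums(covers)
    over <- tot > 160
    covers[over, ] <- covers[over, , drop = FALSE] * 160 / tot[over]
  }

  canopy <- 100 * (1 - (1 - covers[, "cover_ES"] / 100) *
                       (1 - covers[, "cover_ET"] / 100) *
                       (1 - covers[, "cover_DT"] / 100))

  sp_counts <- config$species_counts[pfts]
  divs <- matrix(0, n, length(pfts), dimnames = list(NULL, paste0("div_", pfts)))
  pooled <- vector("list", n)
  for (i in seq_len(n)) pooled[[i]] <- numeric(0)
  for (g in pfts) {
    S <- sp_counts[[g]]
    conc <- exp(0.8 + eta[, paste0("div_", g)] +
                  stats::rnorm(n, 0, config$noise_sd))
    for (i in seq_len(n)) {
      ab <- stats::rgamma(S, shape = conc[i])
      if (sum(ab) <= 0) ab <- rep(1, S)
      p <- ab / sum(ab)
      divs[i, paste0("div_", g)] <- if (S == 1) 0 else simpson_diversity(p)
      pooled[[i]] <- c(pooled[[i]], p * covers[i, paste0("cover_", g)])
    }
  }
  div_total <- vapply(seq_len(n), function(i) {
    ab <- pooled[[i]]
    if (sum(ab) <= 0) 0 else simpson_diversity(ab)
  }, numeric(1))

  data.frame(site = env$site, covers, cover_total_canopy = canopy,
             divs, div_total = div_total, check.names = FALSE)
}

# ---- leaf traits ------------------------------------------------------------

# log-scale trait medians per PFT; units as measured in the field protocol
# (SLA area per dry mass, toughness penetrometer grams, N/lignin % dry mass,
# C:N dimensionless, Si % dry mass)
trait_log_medians <- function() {
  m <- rbind(
    GG = c(SLA = 10, toughness = 550, N_mass = 1.5, CN = 32, lignin = 4.0, Si = 2.50),
    ES = c(SLA = 8,  toughness = 450, N_mass = 1.1, CN = 42, lignin = 16,  Si = 0.25),
    ET = c(SLA = 7,  toughness = 400, N_mass = 1.2, CN = 40, lignin = 15,  Si = 0.20),
    DS = c(SLA = 16, toughness = 180, N_mass = 2.2, CN = 21, lignin = 12,  Si = 0.30),
    DT = c(SLA = 18, toughness = 150, N_mass = 2.4, CN = 19, lignin = 12,  Si = 0.15)
  )
  log(m)
}

#' Generate a synthetic species-by-leaf-trait table
#'
#' Species-level lognormal trait draws around per-PFT medians whose ordering
#' reproduces the trait syndromes of the field system: deciduous groups have
#' higher SLA and leaf N but lower toughness and C:N than evergreens; giant
#' graminoids are silicon-rich and lignin-poor. `trait_separation = 0`
#' collapses all groups onto the common median (null configuration).
#'
#' @param config A [sim_config()].
#' @return Data frame: `species`, `pft`, and six trait columns (`SLA`,
#'   `toughness`, `N_mass`, `CN`, `lignin`, `Si`), raw positive scale.
#' @export
simulate_leaf_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  counts <- config$species_counts
  M <- trait_log_medians()[names(counts), , drop = FALSE]
  overall <- colMeans(M)
  Meff <- sweep(sweep(M, 2, overall, "-") * config$trait_separation,
                2, overall, "+")
  rows <- lapply(names(counts), function(g) {
    S <- counts[[g]]
    vals <- exp(matrix(rep(Meff[g, ], each = S), S, ncol(M)) +
                  matrix(stats::rnorm(S * ncol(M), 0, config$trait_sdlog),
                         S, ncol(M)))
    colnames(vals) <- colnames(M)
    data.frame(species = sprintf("%s_sp%02d", g, seq_len(S)), pft = g, vals)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic gradient dataset
#'
#' Runs [simulate_environment()], [simulate_pft_responses()] and
#' [simulate_leaf_traits()] under one configuration and retains the planted
#' effect matrix for parameter-recovery scoring.
#'
#' @param config A [sim_config()].
#' @return Object of class `"synthetic_dataset"`: list with `environment`,
#'   `responses`, `traits`, `truth` (the effect matrix used) and `config`.
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 1))
#' head(ds$responses)
#' @export
simulate_dataset <- function(config = sim_config()) {
  env <- simulate_environment(config)
  resp <- simulate_pft_responses(env, config)
  traits <- simulate_leaf_traits(config)
  structure(list(environment = env, responses = resp, traits = traits,
                 truth = config$effect_matrix, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic gradient dataset:", nrow(x$environment), "sites,",
      ncol(x$environment) - 1, "environmental variables,",
      nrow(x$traits), "species\n")
  invisible(x)
}
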