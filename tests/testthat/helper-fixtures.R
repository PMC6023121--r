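# Shared fixtures, built in code.

random_xy <- function(n, p, m = 1, beta = NULL, noise = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- matrix(rnorm(p * m), p, m)
  Y <- X %*% beta + matrix(rnorm(n * m, sd = noise), n, m)
  colnames(Y) <- paste0("y", seq_len(m))
  list(X = X, Y = Y, beta = beta)
}

# multivariate response matrix on the analysis scale for a dataset
analysis_responses <- function(ds) {
  pfts <- c("GG", "ES", "ET", "DS", "DT")
  cbind(arcsine_sqrt(as.matrix(ds$responses[paste0("cover_", pfts)]) / 100),
        as.matrix(ds$responses[paste0("div_", pfts)]))
}

merged_pft <- function(pft) c(GG = "GG", ES = "EV", ET = "EV",
                              DS = "DE", DT = "DE")[pft]
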