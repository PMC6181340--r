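# Small seeded estimation problems used across test files.

# A tiny random instance with arbitrary covariates: J units, up to
# max_pix pixels each, K categories, M design columns (intercept +
# M-1 covariates).  Returns the pieces both as tidy tables and as the
# matrices an independent oracle works with.
tiny_instance <- function(J = 5, max_pix = 4, K = 3, M = 3, seed = 1) {
  withr::with_seed(seed, {
    npix <- sample.int(max_pix, J, replace = TRUE)
    n <- sum(npix)
    units <- sprintf("u%02d", rep(seq_len(J), npix))
    covs <- matrix(rnorm(n * (M - 1)), n)
    colnames(covs) <- paste0("x", seq_len(M - 1))
    px <- tibble::tibble(
      pixel_id = sprintf("p%03d", seq_len(n)),
      unit_l1 = units,
      area_km2 = runif(n, 50, 100)
    )
    px <- dplyr::bind_cols(px, tibble::as_tibble(covs))
    spec <- design_spec(lapply(colnames(covs), term_linear))
    beta <- matrix(rnorm(M * (K - 1), sd = 0.5), M)
    crops <- c("other", paste0("crop", seq_len(K - 1)))
    # observed shares: Dirichlet noise around the model aggregate
    W <- build_design(px, spec)
    G <- cropdown::pixel_shares(W, beta, crops)
    H <- rowsum(G * px$area_km2, units) / as.vector(rowsum(px$area_km2, units))
    gm <- matrix(rgamma(length(H), shape = 50 * H), nrow(H))
    y <- gm / rowSums(gm)
    rownames(y) <- rownames(H)
    shares <- tibble::tibble(
      unit_l1 = rep(rownames(H), K),
      crop = rep(crops, each = J),
      share = as.vector(y)
    )
    list(pixels = px, shares = shares, spec = spec, beta = beta,
         crops = crops, W = W, y = y, units = units)
  })
}

# Default noiseless recovery setup shared by several tests: K = 2,
# M = 4 (intercept + temperature + precipitation + soil carbon).
noiseless_setup <- function(J = 200, seed = 42) {
  cfg <- synthetic_config(J = J, seed = seed, noise = "none",
                          exclusion_rate = 0)
  land <- simulate_landscape(cfg)
  y <- simulate_shares(land, cfg)
  list(cfg = cfg, land = land, y = y)
}
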