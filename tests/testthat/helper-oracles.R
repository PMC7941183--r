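# Independent oracles and shared fixtures for the test suite. These
# deliberately re-derive quantities by brute force (pair enumeration, dense
# grid + bisection) so they share no code path with the package internals
# they check.

# Brute-force Fowlkes-Mallows index by enumerating all item pairs.
fm_oracle <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- unname(a); b <- unname(b)
  n <- length(a)
  shared <- 0; pairs_a <- 0; pairs_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      pairs_a <- pairs_a + sa
      pairs_b <- pairs_b + sb
      shared <- shared + (sa && sb)
    }
  }
  if (shared == 0) return(0)
  shared / sqrt(pairs_a * pairs_b)
}

# Random partition of n items into at most k groups, guaranteed >= 1
# non-singleton group so the FM index is defined.
random_partition <- function(n, k) {
  repeat {
    p <- sample(seq_len(k), n, replace = TRUE)
    if (any(table(p) >= 2)) return(p)
  }
}

# Brute-force POD: dense log-grid scan for the first benchmark crossing of a
# Hill curve, refined by plain interval bisection (no uniroot).
pod_bisection_oracle <- function(bottom, top, ec50, hill, vehicle_sd,
                                 lo = 1e-3, hi = 100, n_grid = 2000) {
  f <- function(c) abs(bottom + (top - bottom) / (1 + (ec50 / c)^hill) - 100) -
    vehicle_sd
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  v <- f(grid)
  if (v[1] >= 0) return(lo)
  idx <- which(v[-1] >= 0 & v[-n_grid] < 0)
  if (length(idx) == 0) return(Inf)
  a <- grid[idx[1]]; b <- grid[idx[1] + 1]
  for (i in 1:80) {
    m <- sqrt(a * b)
    if (f(m) < 0) a <- m else b <- m
  }
  sqrt(a * b)
}

# A hill_fit object built directly from known parameters (no fitting), for
# exercising derive_pod against closed-form oracles.
make_hill_fit <- function(bottom, top, ec50, hill) {
  structure(
    list(
      bottom = bottom, top = top, ec50 = ec50, hill = hill,
      direction = if (top > bottom) "increasing" else "decreasing",
      rss = 0, rss_flat = 1, f_pvalue = 0, converged = TRUE, n = 15,
      data = tibble::tibble(conc_uM = c(100, 10, 1, 0.1, 0.01),
                            response_pct = hill_response(
                              c(100, 10, 1, 0.1, 0.01), bottom, top, ec50, hill
                            ))
    ),
    class = "hill_fit"
  )
}

# Reduced screen (10 chemicals, 2 cell types) reused across module tests;
# built once per test run.
.screen_cache <- new.env(parent = emptyenv())

small_design <- function() {
  chems <- atsdr_chemicals() %>%
    dplyr::group_by(class) %>%
    dplyr::slice_head(n = 2) %>%
    dplyr::ungroup()
  phen <- toxscreen:::default_phenotypes()
  phen <- phen[phen$cell_type %in% c("hepatocyte", "cardiomyocyte"), ]
  screen_design(chemicals = chems, phenotypes = phen)
}

small_screen <- function(seed = 101, noise_sd = 10) {
  key <- paste0("scr_", seed, "_", noise_sd)
  if (is.null(.screen_cache[[key]])) {
    .screen_cache[[key]] <- simulate_screen(
      profiles = class_potency_profiles(c("hepatocyte", "cardiomyocyte")),
      design = small_design(), noise_sd = noise_sd, seed = seed
    )
  }
  .screen_cache[[key]]
}

small_pods <- function(seed = 101, noise_sd = 10) {
  key <- paste0("pods_", seed, "_", noise_sd)
  if (is.null(.screen_cache[[key]])) {
    scr <- small_screen(seed, noise_sd)
    .screen_cache[[key]] <- fit_pod_table(normalize_to_vehicle(scr$measurements))
  }
  .screen_cache[[key]]
}
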