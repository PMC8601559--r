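# Shared fixtures and independent oracles, built in code at test time.

# categorical test raster with a deterministic code pattern
pattern_raster <- function(nr = 6, nc = 5, codes = c(21L, 41L, 82L),
                           cell = 30, origin = c(1000, 5000)) {
  m <- matrix(codes[(seq_len(nr * nc) %% length(codes)) + 1L], nr, nc)
  land_raster(m, origin = origin, cell_size = cell)
}

# independent direct O(n k^2) convolution oracle for Gaussian smoothing;
# deliberately loop-based and unrelated to the package's separable pass
direct_smooth <- function(m, kern_mat, edge = "renormalize") {
  h <- (nrow(kern_mat) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && is.finite(m[ii, jj])) {
        w <- kern_mat[di + h + 1L, dj + h + 1L]
        num <- num + w * m[ii, jj]
        den <- den + w
      }
    }
    out[i, j] <- if (edge == "renormalize") {
      if (den > 0) num / den else NA_real_
    } else num
  }
  out[!is.finite(m)] <- NA_real_
  out
}

# wrap bare matrices as a smoothed_stack (for PCA-level tests)
fake_stack <- function(layers, codes = seq_along(layers), cell = 30) {
  names(layers) <- as.character(codes)
  structure(list(codes = as.integer(codes), layers = layers,
                 origin = c(0, 0), cell_size = cell, crs = "",
                 sigma = NA_real_, edge_policy = "renormalize"),
            class = "smoothed_stack")
}

# brute-force occupancy likelihood by enumeration over the latent state
enum_nll <- function(beta, des) {
  kp <- ncol(des$X_psi)
  psi <- plogis(drop(des$X_psi %*% beta[seq_len(kp)]))
  p <- plogis(drop(des$X_p %*% beta[kp + seq_len(ncol(des$X_p))]))
  ll <- 0
  for (i in seq_len(nrow(des$X_psi))) {
    rows <- which(des$site_index == i)
    yi <- des$y[rows]; pi <- p[rows]
    # z = 1 term and z = 0 term, enumerated explicitly
    lik_occ <- psi[i] * prod(pi^yi * (1 - pi)^(1 - yi))
    lik_unocc <- (1 - psi[i]) * as.numeric(all(yi == 0))
    ll <- ll + log(lik_occ + lik_unocc)
  }
  as.numeric(-ll)
}

# small ragged occupancy dataset with covariates, deterministic given seed
toy_occu_data <- function(n_sites = 12, seed = 42, n_cities = 2) {
  set.seed(seed)
  sites <- data.frame(
    site_id = sprintf("s%03d", seq_len(n_sites)),
    city = rep(sprintf("c%d", seq_len(n_cities)), length.out = n_sites),
    x = runif(n_sites), y = runif(n_sites),
    HS = rnorm(n_sites), BG = rnorm(n_sites))
  J <- sample(1:4, n_sites, replace = TRUE)
  visits <- data.frame(
    site_id = rep(sites$site_id, J),
    date_s = round(runif(sum(J), 0, 18), 2),
    y = rbinom(sum(J), 1, 0.4))
  # guarantee at least one detection overall so fits are not degenerate
  visits$y[1] <- 1L
  occu_data(sites, visits)
}

# checklist fixture: 10 rows, 3 violating the stationary/complete/season
# filters, spread over 3 sites in 2 cities
toy_checklists <- function() {
  data.frame(
    checklist_id = sprintf("C%02d", 1:10),
    site_id = c("A", "A", "B", "B", "B", "C", "C", "A", "B", "C"),
    city = c(rep("east", 5), rep("west", 5)),
    x = c(rep(105, 5), rep(405, 5)),
    y = c(rep(195, 5), rep(495, 5)),
    date = c("2018-04-01", "2018-04-11", "2018-05-02", "2018-06-30",
             "2018-09-30", "2018-07-15", "2018-08-01",
             "2018-03-20",      # out of season
             "2018-05-10",      # traveling, below
             "2018-06-01"),     # incomplete, below
    protocol = c(rep("stationary", 8), "traveling", "stationary"),
    complete = c(rep(1L, 9), 0L),
    detected = c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 1L))
}
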