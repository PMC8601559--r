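## chi-square statistic on detection-history frequencies for one parameter
## vector, given the fit's design.  Sites are grouped into cohorts by their
## number of visits J (histories are ragged); within a cohort the observed
## count of each binary history is compared with its expected count under
## the model, E_h = sum_i Pr(history = h | x_i).  For small J all 2^J
## histories are enumerated; for large J the observed distinct histories
## plus a pooled remainder cell are used.  Cells with expected count below
## `pool_min` are merged into one pooled cell per cohort.
occu_gof_chisq <- function(beta, des, y, pool_min = 2, enum_max = 10L) {
  b <- split_beta(beta, des)
  psi <- stats::plogis(drop(des$X_psi %*% b$psi))
  p <- stats::plogis(drop(des$X_p %*% b$p))
  n <- nrow(des$X_psi)
  J <- tabulate(des$site_index, n)
  chisq <- 0
  for (j in sort(unique(J))) {
    sites_j <- which(J == j)
    rows <- which(des$site_index %in% sites_j)
    ord <- rows[order(des$site_index[rows])]
    pm <- matrix(p[ord], nrow = length(sites_j), ncol = j, byrow = TRUE)
    ym <- matrix(y[ord], nrow = length(sites_j), ncol = j, byrow = TRUE)
    psi_j <- psi[sites_j]
    obs_keys <- apply(ym, 1L, paste, collapse = "")
    hist_mat <- if (j <= enum_max) {
      m <- as.matrix(expand.grid(rep(list(0:1), j)))[, j:1, drop = FALSE]
      m
    } else {
      uk <- unique(obs_keys)
      do.call(rbind, lapply(strsplit(uk, ""), as.integer))
    }
    keys <- apply(hist_mat, 1L, paste, collapse = "")
    E <- vapply(seq_len(nrow(hist_mat)), function(i) {
      h <- hist_mat[i, ]
      cond <- exp(colSums(log(t(pm)) * h + log(1 - t(pm)) * (1 - h)))
      sum(psi_j * cond + (1 - psi_j) * (sum(h) == 0))
    }, numeric(1))
    O <- as.numeric(table(factor(obs_keys, levels = keys)))
    if (j > enum_max) {  # pooled remainder of unobserved histories
      E <- c(E, max(length(sites_j) - sum(E), 0))
      O <- c(O, 0)
    }
    pool <- E < pool_min
    if (sum(!pool)) {
      chisq <- chisq + sum((O[!pool] - E[!pool])^2 / E[!pool])
    }
    if (sum(pool) && sum(E[pool]) > 0)
      chisq <- chisq + (sum(O[pool]) - sum(E[pool]))^2 / sum(E[pool])
  }
  chisq
}

#' Parametric-bootstrap goodness of fit
#'
#' A detection-history frequency chi-square test in the style of the
#' MacKenzie-Bailey occupancy goodness-of-fit test, generalised to ragged
#' visit counts by forming one cohort per distinct number of visits.  The
#' observed statistic compares observed and expected history counts under
#' the fitted model; its null distribution is obtained by simulating
#' `n_boot` data sets from the fitted model, refitting the same structure to
#' each (started at the fitted coefficients), and recomputing the statistic.
#' The p-value is the share of bootstrap statistics at or above the observed
#' one, and the overdispersion factor is
#' `c_hat = chisq_obs / mean(chisq_boot)`.
#'
#' @param fit a converged [occu_fit()].
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer seed; the bootstrap sample is deterministic given it.
#' @param pool_min cells with expected count below this are pooled within
#'   their cohort.
#' @return object of class `occu_gof`: list with `chisq_obs`, `chisq_boot`,
#'   `p_value`, `c_hat`, `n_boot`, `seed`.
#' @export
mb_gof <- function(fit, n_boot = 100L, seed = 1L, pool_min = 2) {
  stopifnot(inherits(fit, "occu_fit"))
  if (n_boot < 1L) stop("n_boot must be >= 1")
  des <- fit$design
  obs <- occu_gof_chisq(fit$coefficients, des, des$y, pool_min)
  b <- split_beta(fit$coefficients, des)
  psi <- stats::plogis(drop(des$X_psi %*% b$psi))
  p <- stats::plogis(drop(des$X_p %*% b$p))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      z <- stats::rbinom(length(psi), 1L, psi)
      y_star <- as.integer(z[des$site_index] *
                             stats::rbinom(length(p), 1L, p))
      des_b <- des
      des_b$y <- y_star
      opt <- tryCatch(
        stats::optim(fit$coefficients, occu_nll, occu_nll_grad, des = des_b,
                     method = "BFGS", control = list(maxit = 300)),
        error = function(e) NULL)
      par <- if (is.null(opt)) fit$coefficients else opt$par
      occu_gof_chisq(par, des_b, y_star, pool_min)
    }, numeric(1))
  })
  structure(list(chisq_obs = obs, chisq_boot = boot,
                 p_value = mean(boot >= obs - 1e-12),
                 c_hat = obs / mean(boot), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "occu_gof")
}

#' @export
print.occu_gof <- function(x, ...) {
  cat("Parametric-bootstrap goodness of fit (detection-history chi-square)\n")
  cat(sprintf("  observed chi-square: %.3f\n", x$chisq_obs))
  cat(sprintf("  bootstrap mean:      %.3f  (n_boot = %d)\n",
              mean(x$chisq_boot), x$n_boot))
  cat(sprintf("  p-value: %.3f   c-hat: %.3f\n", x$p_value, x$c_hat))
  invisible(x)
}
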