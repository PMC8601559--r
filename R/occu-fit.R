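## ---- model structures and design matrices ---------------------------------

#' Parse a model-structure label into a formula
#'
#' Structures are written in compact selection-table notation, e.g. `"1"`,
#' `"HS+BG"`, `"city*HS+BG"`, `"city*(HS*BG)"`, `"city*date+date2+HS+BG"`.
#' `a*b` expands to main effects plus interaction; `date2` is the squared
#' scaled date, materialised at design-build time.
#'
#' @param x a structure label, or an existing one-sided formula (returned
#'   unchanged).
#' @return a one-sided formula.
#' @export
parse_structure <- function(x) {
  if (inherits(x, "formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  stats::as.formula(paste("~", x), env = baseenv())
}

structure_label <- function(f) {
  if (is.character(f)) return(f)
  gsub(" ", "", paste(deparse(f[[length(f)]]), collapse = ""))
}

## visit-level design data: visit rows joined with their site covariates,
## plus the date / date2 detection covariates
visit_frame <- function(data) {
  idx <- match(data$visits$site_id, data$sites$site_id)
  site_cov <- data$sites[idx, setdiff(names(data$sites), c("site_id", "x", "y")),
                         drop = FALSE]
  vf <- cbind(data$visits[c("site_id", "y")], site_cov,
              date = data$visits$date_s,
              date2 = data$visits$date_s^2)
  rownames(vf) <- NULL
  vf
}

check_vars <- function(formula, df, what) {
  miss <- setdiff(all.vars(formula), names(df))
  if (length(miss))
    stop("missing ", what, " covariate(s): ", paste(miss, collapse = ", "))
}

#' Build occupancy and detection design matrices
#'
#' Occupancy covariates are site-level (one design row per site); detection
#' covariates are visit-level (one row per checklist, site covariates
#' replicated, plus scaled `date` and `date2`).  Coding is R's treatment
#' contrast with the alphabetically first factor level as reference and a
#' single intercept per submodel; interaction columns are products of coded
#' columns.
#'
#' @param psi,p one-sided formulas or structure labels.
#' @param data an [occu_data].
#' @return list with `X_psi`, `X_p`, response `y`, `site_index` (site of
#'   each visit row), `K`, per-submodel `terms` and `xlevels`.
#' @export
build_occu_design <- function(psi, p, data) {
  stopifnot(inherits(data, "occu_data"))
  psi <- parse_structure(psi); p <- parse_structure(p)
  vf <- visit_frame(data)
  check_vars(psi, data$sites, "occupancy")
  check_vars(p, vf, "detection")
  mf_psi <- stats::model.frame(psi, data$sites)
  mf_p <- stats::model.frame(p, vf)
  t_psi <- stats::terms(mf_psi); t_p <- stats::terms(mf_p)
  X_psi <- stats::model.matrix(t_psi, mf_psi)
  X_p <- stats::model.matrix(t_p, mf_p)
  list(X_psi = X_psi, X_p = X_p, y = data$visits$y,
       site_index = match(data$visits$site_id, data$sites$site_id),
       K = ncol(X_psi) + ncol(X_p),
       terms = list(psi = t_psi, p = t_p),
       xlevels = list(psi = stats::.getXlevels(t_psi, mf_psi),
                      p = stats::.getXlevels(t_p, mf_p)))
}

## ---- likelihood ------------------------------------------------------------

split_beta <- function(beta, des)
  list(psi = beta[seq_len(ncol(des$X_psi))],
       p = beta[ncol(des$X_psi) + seq_len(ncol(des$X_p))])

## per-site pieces shared by value and gradient
occu_lik_parts <- function(beta, des) {
  b <- split_beta(beta, des)
  psi <- stats::plogis(drop(des$X_psi %*% b$psi))
  eta_p <- drop(des$X_p %*% b$p)
  pv <- stats::plogis(eta_p)
  y <- des$y
  n <- nrow(des$X_psi)
  g <- factor(des$site_index, levels = seq_len(n))
  # log conditional detection-history probability given occupied
  logc <- as.vector(rowsum(y * stats::plogis(eta_p, log.p = TRUE) +
                           (1 - y) * stats::plogis(-eta_p, log.p = TRUE), g))
  nodet <- as.vector(rowsum(y, g)) == 0
  cond <- exp(logc)
  lik <- psi * cond + (1 - psi) * nodet
  list(psi = psi, p = pv, cond = cond, nodet = nodet, lik = lik, g = g)
}

#' Negative log-likelihood of the single-season occupancy model
#'
#' The zero-inflated Bernoulli likelihood with imperfect detection: for site
#' `i` with history `y_i`,
#' `L_i = psi_i * prod_j p_ij^y_ij (1-p_ij)^(1-y_ij) + (1-psi_i) * 1[sum_j y_ij = 0]`,
#' with logit links on both submodels.  Ragged visit counts are supported.
#'
#' @param beta coefficient vector (occupancy block then detection block).
#' @param des a [build_occu_design()] result.
#' @return the exact negative log of the product of site likelihoods.
#' @export
occu_nll <- function(beta, des) {
  parts <- occu_lik_parts(beta, des)
  -sum(log(pmax(parts$lik, .Machine$double.xmin)))
}

#' @rdname occu_nll
#' @return `occu_nll_grad()` returns the analytic gradient.
#' @export
occu_nll_grad <- function(beta, des) {
  parts <- occu_lik_parts(beta, des)
  L <- pmax(parts$lik, .Machine$double.xmin)
  # d L_i / d eta_psi = (cond - nodet) * psi (1 - psi)
  w_psi <- (parts$cond - parts$nodet) * parts$psi * (1 - parts$psi) / L
  # d L_i / d eta_p over visit j: psi * cond * (y - p)
  w_site <- parts$psi * parts$cond / L
  w_p <- w_site[des$site_index] * (des$y - parts$p)
  -c(drop(crossprod(des$X_psi, w_psi)), drop(crossprod(des$X_p, w_p)))
}

## ---- AICc ------------------------------------------------------------------

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, with `n` the number of
#' sites (the sampling unit of the occupancy likelihood).  Undefined
#' (`NA`) when `n <= K + 1`.
#'
#' @param loglik maximised log-likelihood.
#' @param K number of estimated parameters.
#' @param n number of sites.
#' @return the AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) return(NA_real_)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

## ---- fitting ---------------------------------------------------------------

#' Fit a single-season occupancy model
#'
#' Maximum-likelihood fit of logit-linear occupancy (`psi`) and detection
#' (`p`) submodels by quasi-Newton (BFGS with the analytic gradient),
#' started from zeros with up to `restarts` jittered restarts (seeded).  A
#' fit is declared converged when the optimiser reports success, the
#' gradient max-norm is below `grad_tol` and the numerical Hessian is
#' positive definite; non-convergence is recorded in the result, never
#' raised, because realistic candidate sets routinely contain structures the
#' data cannot support.  Standard errors come from the inverse Hessian and
#' are only available for converged fits.
#'
#' @param psi,p one-sided formulas or structure labels (see
#'   [parse_structure()]); occupancy covariates are site columns of `data`,
#'   detection covariates additionally include `date` and `date2`.
#' @param data an [occu_data].
#' @param start optional start vector (default zeros).
#' @param restarts maximum jittered restarts after a failed attempt.
#' @param seed seed for restart jitter.
#' @param grad_tol gradient max-norm convergence tolerance.
#' @param hessian compute the numerical Hessian (needed for SEs and the
#'   positive-definiteness check; disable only for throwaway refits).
#' @param control passed to [stats::optim()].
#' @return object of class `occu_fit`.
#' @examples
#' set.seed(1)
#' sites <- data.frame(site_id = sprintf("s%03d", 1:150),
#'                     city = "a", x = 0, y = 0, HS = rnorm(150))
#' visits <- data.frame(site_id = rep(sites$site_id, each = 3),
#'                      date_s = rep(0:2, 150), y = 0L)
#' d <- simulate_occu(~HS, ~1, beta_psi = c(0.4, 1), beta_p = 0.2,
#'                    sites = sites, visits = visits, seed = 2)
#' fit <- occu_fit(~HS, ~1, d)
#' summary(fit)
#' @export
occu_fit <- function(psi = ~1, p = ~1, data, start = NULL, restarts = 3L,
                     seed = 1L, grad_tol = 1e-4, hessian = TRUE,
                     control = list(maxit = 500, reltol = 1e-12)) {
  stopifnot(inherits(data, "occu_data"))
  des <- build_occu_design(psi, p, data)
  K <- des$K
  n <- nrow(des$X_psi)
  if (is.null(start)) start <- numeric(K)
  if (length(start) != K) stop("start vector has wrong length")

  attempt <- function(par0) {
    opt <- tryCatch(
      stats::optim(par0, occu_nll, occu_nll_grad, des = des, method = "BFGS",
                   control = control, hessian = hessian),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    gn <- max(abs(occu_nll_grad(opt$par, des)))
    pd <- FALSE
    V <- NULL
    if (hessian) {
      ch <- tryCatch(chol(opt$hessian), error = function(e) NULL)
      if (!is.null(ch)) {
        pd <- TRUE
        V <- chol2inv(ch)
        # Newton polish: quasi-Newton often stops with a small but
        # above-tolerance gradient; a few damped Newton steps finish the job
        for (i in 1:10) {
          if (gn < grad_tol / 10) break
          g <- occu_nll_grad(opt$par, des)
          step <- drop(V %*% g)
          f0 <- opt$value
          lam <- 1
          repeat {
            cand <- opt$par - lam * step
            f1 <- occu_nll(cand, des)
            if (is.finite(f1) && f1 <= f0 + 1e-12) break
            lam <- lam / 2
            if (lam < 1e-4) { cand <- opt$par; f1 <- f0; break }
          }
          if (identical(cand, opt$par)) break
          opt$par <- cand; opt$value <- f1
          gn <- max(abs(occu_nll_grad(opt$par, des)))
        }
        H <- tryCatch(stats::optimHess(opt$par, occu_nll, occu_nll_grad,
                                       des = des),
                      error = function(e) opt$hessian)
        ch2 <- tryCatch(chol(H), error = function(e) NULL)
        if (!is.null(ch2)) {
          opt$hessian <- H
          V <- chol2inv(ch2)
        } else pd <- FALSE
      }
    }
    list(opt = opt, grad_norm = gn,
         converged = opt$convergence == 0 && gn < grad_tol && (!hessian || pd),
         vcov = V)
  }

  best <- attempt(start)
  tries <- 0L
  while ((is.null(best) || !best$converged) && tries < restarts) {
    tries <- tries + 1L
    jitter <- with_seed(seed + tries, stats::rnorm(K, 0, 0.5))
    cand <- attempt(start + jitter)
    if (!is.null(cand) &&
        (is.null(best) || (cand$converged && !best$converged) ||
         (cand$converged == best$converged && cand$opt$value < best$opt$value)))
      best <- cand
  }
  if (is.null(best)) stop("optimisation failed at every start")

  coefs <- best$opt$par
  names(coefs) <- c(paste0("psi.", colnames(des$X_psi)),
                    paste0("p.", colnames(des$X_p)))
  ll <- -best$opt$value
  aic_c <- aicc(ll, K, n)
  converged <- best$converged && !is.na(aic_c)
  V <- best$vcov
  if (!is.null(V)) dimnames(V) <- list(names(coefs), names(coefs))
  structure(list(coefficients = coefs, vcov = V, logLik = ll,
                 K = K, n_sites = n, AICc = aic_c,
                 converged = converged, grad_norm = best$grad_norm,
                 psi_formula = parse_structure(psi), p_formula = parse_structure(p),
                 design = des, data = data,
                 call = match.call()),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("Occupancy model  psi %s,  p %s\n",
              structure_label(x$psi_formula), structure_label(x$p_formula)))
  cat(sprintf("  sites: %d   K: %d   -logLik: %.2f   AICc: %s   converged: %s\n",
              x$n_sites, x$K, -x$logLik,
              if (is.na(x$AICc)) "NA" else sprintf("%.2f", x$AICc),
              x$converged))
  invisible(x)
}

#' @export
summary.occu_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, object$K)
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.occu_fit"
  out
}

#' @export
print.summary.occu_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (logit scale):\n")
  stats::printCoefmat(x$coefficients, digits = 4, na.print = "NA")
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) object$coefficients

#' @export
vcov.occu_fit <- function(object, ...) object$vcov

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, nobs = object$n_sites,
            class = "logLik")
}

#' @export
AIC.occu_fit <- function(object, ..., k = 2) -2 * object$logLik + k * object$K

#' Visit-level residuals
#'
#' Response residuals are `y_ij - psi_i * p_ij` (the unconditional expected
#' detection); Pearson residuals divide by the binomial standard deviation.
#'
#' @param object an [occu_fit()].
#' @param type `"pearson"` or `"response"`.
#' @param ... unused.
#' @return numeric vector, one element per visit row.
#' @export
residuals.occu_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  b <- split_beta(object$coefficients, object$design)
  psi <- stats::plogis(drop(object$design$X_psi %*% b$psi))
  p <- stats::plogis(drop(object$design$X_p %*% b$p))
  mu <- psi[object$design$site_index] * p
  r <- object$design$y - mu
  if (type == "pearson") r <- r / sqrt(pmax(mu * (1 - mu), .Machine$double.eps))
  r
}

#' Predict occupancy or detection probabilities
#'
#' Computes the logit-scale linear predictor for new covariate rows, its
#' delta-method standard error from the coefficient covariance, and a 95%
#' Wald interval, all back-transformed to the probability scale (so the
#' interval stays inside (0, 1)).  Factor levels must match those seen in
#' fitting.  For `quantity = "p"`, `date2` is filled in from `date` when
#' absent.
#'
#' @param object an [occu_fit()].
#' @param newdata data frame of covariates.
#' @param quantity `"psi"` (occupancy) or `"p"` (detection).
#' @param level confidence level.
#' @param ... unused.
#' @return data frame with `estimate`, `se`, `lower`, `upper`.
#' @export
predict.occu_fit <- function(object, newdata, quantity = c("psi", "p"),
                             level = 0.95, ...) {
  quantity <- match.arg(quantity)
  des <- object$design
  tt <- stats::delete.response(des$terms[[quantity]])
  if (quantity == "p" && !("date2" %in% names(newdata)) &&
      "date" %in% names(newdata))
    newdata$date2 <- newdata$date^2
  mf <- stats::model.frame(tt, newdata, xlev = des$xlevels[[quantity]])
  X <- stats::model.matrix(tt, mf)
  b <- split_beta(object$coefficients, des)[[quantity]]
  off <- if (quantity == "psi") 0L else ncol(des$X_psi)
  eta <- drop(X %*% b)
  se <- rep(NA_real_, length(eta))
  if (!is.null(object$vcov)) {
    V <- object$vcov[off + seq_len(ncol(X)), off + seq_len(ncol(X)), drop = FALSE]
    se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- stats::plogis(eta)
  data.frame(estimate = est,
             se = se * est * (1 - est),  # delta method on probability scale
             lower = stats::plogis(eta - zq * se),
             upper = stats::plogis(eta + zq * se))
}

#' Simulate detection histories from a model
#'
#' Draws latent occupancy `z_i ~ Bernoulli(psi_i)` and detections
#' `y_ij ~ z_i * Bernoulli(p_ij)` under given coefficients and covariate
#' frames.  The workhorse behind parametric bootstrapping, calibration
#' experiments and the package's synthetic study data.
#'
#' @param psi,p one-sided formulas or structure labels.
#' @param beta_psi,beta_p coefficient vectors matching the design columns.
#' @param sites site covariate frame (`site_id`, `city`, `x`, `y`, ...).
#' @param visits visit plan (`site_id`, `date_s`); a date column is optional.
#' @param seed integer seed (deterministic output).
#' @return an [occu_data] with simulated `y`.
#' @export
simulate_occu <- function(psi, p, beta_psi, beta_p, sites, visits, seed = 1L) {
  if (!("y" %in% names(visits))) visits$y <- 0L
  visits$y <- as.integer(visits$y)
  skel <- occu_data(sites, visits)
  des <- build_occu_design(psi, p, skel)
  if (length(beta_psi) != ncol(des$X_psi) || length(beta_p) != ncol(des$X_p))
    stop("coefficient vectors do not match design dimensions (",
         ncol(des$X_psi), " + ", ncol(des$X_p), " columns)")
  psi_prob <- stats::plogis(drop(des$X_psi %*% beta_psi))
  p_prob <- stats::plogis(drop(des$X_p %*% beta_p))
  y <- with_seed(seed, {
    z <- stats::rbinom(length(psi_prob), 1L, psi_prob)
    as.integer(z[des$site_index] * stats::rbinom(length(p_prob), 1L, p_prob))
  })
  skel$visits$y <- y
  skel
}

#' @export
simulate.occu_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  b <- split_beta(object$coefficients, object$design)
  lapply(seq_len(nsim), function(i)
    simulate_occu(object$psi_formula, object$p_formula, b$psi, b$p,
                  object$data$sites, object$data$visits,
                  seed = seed + i - 1L))
}
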