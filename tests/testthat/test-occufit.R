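test_that("design matrices follow treatment coding with a single intercept", {
  d <- toy_occu_data(n_sites = 20, n_cities = 10)
  des <- build_occu_design(~1, ~1, d)
  expect_equal(ncol(des$X_psi), 1L)
  expect_true(all(des$X_psi == 1))
  des2 <- build_occu_design(~city, ~1, d)
  expect_equal(ncol(des2$X_psi), 10L)  # intercept + 9 city contrasts
  des3 <- build_occu_design(~1, ~city * date + date2 + HS + BG, d)
  expect_equal(ncol(des3$X_p), 23L)    # 1 + 9 + 1 + 9 + 1 + 1 + 1
  expect_error(build_occu_design(~elev, ~1, d), "missing occupancy covariate")
})

test_that("parameter counts reproduce the published selection-table K values", {
  p_best <- "city*date+date2+HS+BG"
  expect_equal(count_params("city*HS+BG", p_best, 10), 44L)
  expect_equal(count_params("city*(HS*BG)", p_best, 10), 63L)
  expect_equal(count_params("1", p_best, 10), 24L)
  expect_equal(count_params("city*(HS+BG)", p_best, 10), 53L)
  # detection-stage rows fitted against the global occupancy structure
  expect_equal(count_params("city*(HS*BG)", "city*date+HS+BG", 10), 62L)
  expect_equal(count_params("city*(HS*BG)", "city*HS", 10), 60L)
  expect_equal(count_params("city*(HS*BG)", "date", 10), 42L)
  expect_equal(count_params("city*(HS*BG)", "1", 10), 41L)
  # occupancy-block structure widths
  expect_equal(count_params("city*(HS+BG)", "1", 10) - 1L, 30L)
})

test_that("candidate sets have the published sizes and members", {
  det <- candidate_detection_models()
  occ <- candidate_occupancy_models()
  expect_length(det, 26L)
  expect_length(occ, 16L)
  expect_true(all(c("city*HS", "1", "city*date+date2+HS+BG",
                    "city*date+HS+BG", "city", "date", "HS", "BG")
                  %in% names(det)))
  expect_true(all(c("1", "HS", "BG", "HS+BG", "HS*BG", "city", "city+HS",
                    "city+BG", "city+HS+BG", "city+HS*BG", "city*HS",
                    "city*BG", "city*HS+BG", "city*BG+HS", "city*(HS+BG)",
                    "city*(HS*BG)") %in% names(occ)))
  # the full additive detection model is deliberately absent
  expect_false("city+date+date2+HS+BG" %in% names(det))
  # user-supplied configs pass through validated
  expect_length(candidate_detection_models(c("1", "date", "HS+BG")), 3L)
  expect_error(candidate_detection_models(character(0)), "empty")
  expect_error(candidate_occupancy_models(c("1", "1")), "duplicate")
})

test_that("the likelihood matches hand arithmetic on one-site cases", {
  sites <- data.frame(site_id = "s1", city = "c", x = 0, y = 0)
  v1 <- data.frame(site_id = "s1", date_s = 0, y = 1L)
  des1 <- build_occu_design(~1, ~1, occu_data(sites, v1))
  # psi = p = 0.5 at beta = 0: -log(0.5 * 0.5)
  expect_equal(occu_nll(c(0, 0), des1), -log(0.25), tolerance = 1e-12)
  v2 <- data.frame(site_id = c("s1", "s1"), date_s = 0:1, y = c(0L, 0L))
  des2 <- build_occu_design(~1, ~1, occu_data(sites, v2))
  # -log(0.5 * 0.25 + 0.5)
  expect_equal(occu_nll(c(0, 0), des2), -log(0.625), tolerance = 1e-12)
  expect_equal(round(occu_nll(c(0, 0), des2), 4), 0.47)
})

test_that("the likelihood equals the latent-state enumeration oracle", {
  for (seed in 1:5) {
    d <- toy_occu_data(n_sites = sample(5:20, 1), seed = seed)
    des <- build_occu_design(~city + HS, ~date + BG, d)
    set.seed(seed * 100)
    beta <- rnorm(ncol(des$X_psi) + ncol(des$X_p), 0, 0.5)
    expect_equal(occu_nll(beta, des), enum_nll(beta, des), tolerance = 1e-10)
  }
})

test_that("the analytic gradient matches finite differences", {
  d <- toy_occu_data(n_sites = 15, seed = 2)
  des <- build_occu_design(~HS, ~date, d)
  set.seed(3)
  beta <- rnorm(4, 0, 0.5)
  g <- occu_nll_grad(beta, des)
  h <- 1e-6
  g_num <- vapply(seq_along(beta), function(i) {
    e <- replace(numeric(4), i, h)
    (occu_nll(beta + e, des) - occu_nll(beta - e, des)) / (2 * h)
  }, numeric(1))
  expect_equal(g, g_num, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("AICc follows the small-sample correction formula", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7, tolerance = 1e-12)
  expect_true(is.na(aicc(-5, 9, 10)))          # n <= K + 1
  # AICc approaches AIC as n grows
  expect_equal(aicc(-100, 5, 1e7), 210, tolerance = 1e-4)
})

test_that("simulation honours the generating probabilities", {
  n <- 10000
  sites <- data.frame(site_id = sprintf("s%05d", 1:n), city = "c", x = 0, y = 0)
  visits <- data.frame(site_id = rep(sites$site_id, each = 4),
                       date_s = rep(0:3, n), y = 0L)
  d <- simulate_occu(~1, ~1, qlogis(0.6), qlogis(0.4), sites, visits, seed = 31)
  # closed form: psi * (1 - (1-p)^J) = 0.6 * (1 - 0.6^4) = 0.52224
  expect_equal(naive_occupancy(d), 0.6 * (1 - 0.6^4), tolerance = 0.02)
  d0 <- simulate_occu(~1, ~1, qlogis(0.6), -50, sites, visits, seed = 31)
  expect_true(all(d0$visits$y == 0))
  d1 <- simulate_occu(~1, ~1, 50, 50, sites[1:50, ],
                      visits[visits$site_id %in% sites$site_id[1:50], ],
                      seed = 1)
  expect_true(all(tapply(d1$visits$y, d1$visits$site_id, max) == 1))
  expect_identical(simulate_occu(~1, ~1, 0, 0, sites[1:10, ],
                                 visits[1:40, ], seed = 7)$visits$y,
                   simulate_occu(~1, ~1, 0, 0, sites[1:10, ],
                                 visits[1:40, ], seed = 7)$visits$y)
  expect_error(simulate_occu(~1, ~1, c(0, 1), 0, sites[1:10, ], visits[1:40, ]),
               "dimension")
})

test_that("the MLE recovers generating parameters on simulated data", {
  n <- 600
  set.seed(5)
  sites <- data.frame(site_id = sprintf("s%04d", 1:n), city = "c",
                      x = 0, y = 0, HS = rnorm(n))
  visits <- data.frame(site_id = rep(sites$site_id, each = 4),
                       date_s = rep(0:3, n), y = 0L)
  truth_psi <- c(qlogis(0.6), 0.8)
  truth_p <- qlogis(0.4)
  d <- simulate_occu(~HS, ~1, truth_psi, truth_p, sites, visits, seed = 11)
  fit <- occu_fit(~HS, ~1, d)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(coef(fit) - c(truth_psi, truth_p)) < 3 * se))
  expect_equal(fit$K, 3L)
  expect_equal(fit$AICc, aicc(fit$logLik, 3, n), tolerance = 1e-12)
  # summary and logLik plumbing
  expect_s3_class(summary(fit), "summary.occu_fit")
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_equal(attr(logLik(fit), "df"), 3L)
})

test_that("boundary data (every visit a detection) is flagged, not raised", {
  n <- 40
  sites <- data.frame(site_id = sprintf("s%02d", 1:n), city = "c", x = 0, y = 0)
  visits <- data.frame(site_id = rep(sites$site_id, each = 3),
                       date_s = rep(0:2, n), y = 1L)
  d <- occu_data(sites, visits)
  fit <- occu_fit(~1, ~1, d, restarts = 1)
  expect_false(fit$converged)
  expect_gt(plogis(coef(fit)[1]), 0.95)
})

test_that("models wider than the data are flagged with undefined AICc", {
  d <- toy_occu_data(n_sites = 8, n_cities = 4, seed = 3)
  fit <- occu_fit(~city + HS + BG, ~city + date + date2, d, restarts = 0)
  expect_true(is.na(fit$AICc))
  expect_false(fit$converged)
})

test_that("prediction back-transforms the linear predictor with delta-method CIs", {
  n <- 200
  sites <- data.frame(site_id = sprintf("s%03d", 1:n), city = "c1", x = 0, y = 0)
  visits <- data.frame(site_id = rep(sites$site_id, each = 4),
                       date_s = rep(0:3, n), y = 0L)
  d <- simulate_occu(~1, ~1, qlogis(0.6), qlogis(0.4), sites, visits, seed = 8)
  fit <- occu_fit(~1, ~1, d)
  pr <- predict(fit, data.frame(city = "c1"), "psi")
  expect_equal(pr$estimate, plogis(coef(fit)[1]), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(pr$lower > 0 && pr$upper < 1 && pr$lower < pr$upper)
  # beta = 0 gives probability one half
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(predict(fit0, data.frame(city = "c1"), "psi")$estimate, 0.5)
  # date2 is derived from date automatically for detection predictions
  fit_d <- occu_fit(~1, ~date + date2, d)
  pr_d <- predict(fit_d, data.frame(date = c(0, 9, 18)), "p")
  expect_equal(nrow(pr_d), 3L)
  expect_true(all(pr_d$estimate > 0 & pr_d$estimate < 1))
})

test_that("fitted monotone effects give monotone prediction surfaces", {
  n <- 500
  set.seed(21)
  sites <- data.frame(site_id = sprintf("s%04d", 1:n), city = "c", x = 0, y = 0,
                      HS = rnorm(n), BG = rnorm(n))
  visits <- data.frame(site_id = rep(sites$site_id, each = 3),
                       date_s = rep(0:2, n), y = 0L)
  d <- simulate_occu(~HS + BG, ~1, c(0.2, 1, -0.8), qlogis(0.5),
                     sites, visits, seed = 9)
  fit <- occu_fit(~HS + BG, ~1, d)
  grid <- expand.grid(HS = seq(-2, 2, length.out = 5),
                      BG = seq(-2, 2, length.out = 5))
  pr <- predict(fit, grid, "psi")$estimate
  m <- matrix(pr, 5, 5)
  expect_true(all(diff(m[, 3]) > 0))   # increasing in HS (positive effect)
  expect_true(all(diff(m[3, ]) < 0))   # decreasing in BG (negative effect)
  expect_error(predict(fit, data.frame(HS = 0), "psi"), "BG")
})

test_that("simulate method resimulates from the fitted model deterministically", {
  d <- toy_occu_data(n_sites = 30, seed = 12)
  fit <- occu_fit(~1, ~1, d)
  s1 <- simulate(fit, nsim = 2, seed = 4)
  s2 <- simulate(fit, nsim = 2, seed = 4)
  expect_identical(s1[[1]]$visits$y, s2[[1]]$visits$y)
  expect_false(identical(s1[[1]]$visits$y, s1[[2]]$visits$y))
  expect_length(residuals(fit), nrow(d$visits))
})
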