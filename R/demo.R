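#' Validate and complete a pipeline run configuration
#'
#' The configuration mirrors the analysis decision ledger of a landscape
#' gradient study: which classes, what smoothing scale, what window, which
#' PCA conventions, which occupancy candidate sets, and explicit seeds for
#' every stochastic stage (landscape generation, checklist simulation,
#' thinning, optimiser restarts, bootstrap).  Unknown keys are rejected to
#' guard against typos; omitted keys take the defaults below.  The preset
#' `"scale1500"` switches the smoothing kernel to the 1500-m sensitivity
#' scale.
#'
#' @param config a named list, a path to a JSON file, or `NULL` for all
#'   defaults.
#' @param preset optional preset name (`"scale1500"`).
#' @return a completed configuration list of class `run_config`.
#' @export
validate_run_config <- function(config = NULL, preset = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- list(
    n_cities = 3L,
    n_rows = 200L, n_cols = 200L, cell_size = 100,
    proportions = NULL,            # NULL = default 15-class city recipe
    sigma = 500, edge_policy = "renormalize",
    retention_rule = "cumulative", surface_mode = "weighted_average",
    n_sites_per_city = 300L, visits_mean = 3,
    max_sites_per_city = 250L,
    season_start = "2018-04-01", season_end = "2018-09-30",
    beta_psi = NULL,                    # default built below for psi_true
    beta_p = c(-0.3, 0.25, -0.02, 0.3), # ~ date + date2 + BG
    psi_true = "city+HS+BG", p_true = "date+date2+BG",
    det_models = NULL, occ_models = NULL, global_psi = "city*(HS*BG)",
    n_boot = 50L,
    seeds = list(landscape = 101L, checklists = 202L, thinning = 303L,
                 fit = 404L, gof = 505L))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(preset)) {
    if (preset == "scale1500") cfg$sigma <- 1500
    else stop("unknown preset: ", preset)
  }
  if (cfg$sigma <= 0) stop("sigma must be positive")
  if (!cfg$edge_policy %in% c("renormalize", "zero_pad"))
    stop("edge_policy must be 'renormalize' or 'zero_pad'")
  if (cfg$n_cities < 1L) stop("need at least one city")
  if (cfg$max_sites_per_city < 1L) stop("max_sites_per_city must be >= 1")
  if (cfg$n_boot < 1L) stop("n_boot must be >= 1")
  needed <- c("landscape", "checklists", "thinning", "fit", "gof")
  if (!all(needed %in% names(cfg$seeds))) stop("seeds must name all stages: ",
                                               paste(needed, collapse = ", "))
  if (is.null(cfg$beta_psi)) {
    if (cfg$psi_true != "city+HS+BG")
      stop("beta_psi must be supplied when psi_true is overridden")
    # intercept, city contrasts (alternating mild effects), HS, BG
    cfg$beta_psi <- c(0.3, rep(c(0.2, -0.1), length.out = cfg$n_cities - 1),
                      0.4, 0.9)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a checklist survey table over gradient surfaces
#'
#' Draws survey sites uniformly over each city window, extracts their
#' hard-to-soft and brown-to-green values, simulates detection histories
#' from logit-linear occupancy and detection models, and re-expresses the
#' result as a raw checklist table -- including a sprinkling of
#' traveling-protocol and incomplete checklists (with detections blanked)
#' so that downstream filtering has something to do.
#'
#' @param surfaces per-city named list: each element a list with `HS` and
#'   `BG` continuous [land_raster]s.
#' @param cfg a [validate_run_config()] configuration.
#' @return checklist data frame (see [read_checklists()] for the schema).
#' @export
simulate_checklists <- function(surfaces, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  season_start <- as.Date(cfg$season_start)
  season_days <- as.integer(as.Date(cfg$season_end) - season_start)
  cities <- names(surfaces)
  sites_all <- do.call(rbind, lapply(seq_along(cities), function(k) {
    hs <- surfaces[[k]]$HS
    ext <- raster_extent(hs)
    n <- cfg$n_sites_per_city
    with_seed(cfg$seeds$checklists + k, {
      data.frame(site_id = sprintf("%s_L%04d", cities[k], seq_len(n)),
                 city = cities[k],
                 x = stats::runif(n, ext[1] + hs$cell_size, ext[2] - hs$cell_size),
                 y = stats::runif(n, ext[3] + hs$cell_size, ext[4] - hs$cell_size))
    })
  }))
  for (nm in c("HS", "BG")) {
    vals <- unlist(lapply(seq_along(cities), function(k) {
      rows <- sites_all$city == cities[k]
      extract_at_points(surfaces[[k]][[nm]],
                        data.frame(id = sites_all$site_id[rows],
                                   x = sites_all$x[rows],
                                   y = sites_all$y[rows]))$value
    }))
    sites_all[[nm]] <- vals
  }
  # centre gradients over all sites so intercepts are interpretable
  sites_all$HS <- sites_all$HS - mean(sites_all$HS)
  sites_all$BG <- sites_all$BG - mean(sites_all$BG)

  visits <- with_seed(cfg$seeds$checklists, {
    J <- pmax(1L, stats::rpois(nrow(sites_all), cfg$visits_mean))
    data.frame(site_id = rep(sites_all$site_id, J),
               date = season_start + sample.int(season_days + 1L,
                                                sum(J), replace = TRUE) - 1L)
  })
  visits$date_s <- scale_date(visits$date, season_start)
  visits$y <- 0L
  sim <- simulate_occu(cfg$psi_true, cfg$p_true, cfg$beta_psi, cfg$beta_p,
                       sites_all, visits, seed = cfg$seeds$checklists + 9L)
  v <- sim$visits
  s <- sim$sites
  idx <- match(v$site_id, s$site_id)
  tbl <- data.frame(checklist_id = sprintf("C%06d", seq_len(nrow(v))),
                    site_id = v$site_id, city = as.character(s$city[idx]),
                    x = s$x[idx], y = s$y[idx],
                    date = as.character(v$date),
                    protocol = "stationary", complete = 1L,
                    detected = v$y)
  # decoy rows exercised by the protocol/completeness filters
  decoys <- with_seed(cfg$seeds$checklists + 17L, {
    n_dec <- max(4L, nrow(tbl) %/% 20L)
    pick <- sample.int(nrow(tbl), n_dec, replace = TRUE)
    d <- tbl[pick, ]
    d$checklist_id <- sprintf("CX%05d", seq_len(n_dec))
    half <- seq_len(n_dec) <= n_dec / 2
    d$protocol[half] <- "traveling"
    d$complete[!half] <- 0L
    d$detected <- 0L
    d
  })
  rbind(tbl, decoys)
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates two or more synthetic city landscapes, smooths every class,
#' fits the pooled correlation PCA, orients and retains axes by the broken
#' stick rule, writes the hard-to-soft and brown-to-green gradient surfaces,
#' simulates a checklist survey over them, prepares detection histories
#' (filter, thin, attach covariates), runs two-stage AICc selection and a
#' bootstrap goodness-of-fit test, and writes a machine-readable run report
#' recording every seed and decision.  Rerunning with the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param config a [validate_run_config()] result (or list/path accepted by
#'   it).
#' @param out_dir artifact directory (created).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the fitted `gradient_model`, the
#'   `occu_selection`, the `occu_gof`, the prepared data and the report.
#' @export
run_demo <- function(config = NULL, out_dir = tempfile("gradocc_demo_"),
                     quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cities <- sprintf("city%02d", seq_len(cfg$n_cities))
  span <- cfg$n_cols * cfg$cell_size

  say("landscape", "generating ", cfg$n_cities, " synthetic city landscape(s)")
  landscapes <- stage("landscape", lapply(seq_len(cfg$n_cities), function(k) {
    rec <- if (is.null(cfg$proportions))
      default_city_recipe(seed = cfg$seeds$landscape + k)
    else landscape_recipe(cfg$proportions, seed = cfg$seeds$landscape + k)
    generate_landscape(rec, cfg$n_rows, cfg$n_cols, cfg$cell_size,
                       origin = c((k - 1) * 2 * span, 0))
  }))
  names(landscapes) <- cities

  say("smooth", "Gaussian smoothing at sigma = ", cfg$sigma, " m")
  stacks <- stage("smooth", lapply(landscapes, smooth_stack, sigma = cfg$sigma,
                                   edge_policy = cfg$edge_policy))

  say("pca", "pooled correlation PCA with broken-stick retention")
  model <- stage("pca", {
    m <- gradient_pca(stacks, rule = cfg$retention_rule)
    orient_axes(m)
  })
  write_gradient_model(model, file.path(out_dir, "gradient_model.json"))

  say("surface", "writing gradient surfaces (", model$m, " retained axis/axes)")
  surfaces <- stage("surface", lapply(seq_along(stacks), function(k) {
    hs <- gradient_surface(stacks[[k]], model, 1L, cfg$surface_mode)
    bg <- if (model$m >= 2L)
      gradient_surface(stacks[[k]], model, 2L, cfg$surface_mode)
    else gradient_surface(stacks[[k]], model, 2L, cfg$surface_mode,
                          allow_unretained = TRUE)
    write_land_raster(hs, file.path(out_dir, paste0(cities[k], "_HS.asc")))
    write_land_raster(bg, file.path(out_dir, paste0(cities[k], "_BG.asc")))
    list(HS = hs, BG = bg)
  }))
  names(surfaces) <- cities

  say("checklists", "simulating and preparing checklist data")
  data <- stage("checklists", {
    tbl <- simulate_checklists(surfaces, cfg)
    utils::write.csv(tbl, file.path(out_dir, "checklists.csv"), row.names = FALSE)
    tbl <- filter_checklists(tbl, cfg$season_start, cfg$season_end)
    d <- build_histories(tbl, cfg$season_start)
    d <- thin_sites(d, cfg$max_sites_per_city, seed = cfg$seeds$thinning)
    d <- attach_covariates(d, list(
      HS = mosaic_rasters(lapply(surfaces, `[[`, "HS")),
      BG = mosaic_rasters(lapply(surfaces, `[[`, "BG"))))
    # recentre as in simulation
    d$sites$HS <- d$sites$HS - mean(d$sites$HS)
    d$sites$BG <- d$sites$BG - mean(d$sites$BG)
    write_occu_data(d, file.path(out_dir, "occu_data"))
    d
  })

  say("select", "two-stage AICc model selection")
  sel <- stage("select", occu_select(
    data,
    det_models = if (is.null(cfg$det_models)) candidate_detection_models()
                 else candidate_detection_models(cfg$det_models),
    occ_models = if (is.null(cfg$occ_models)) candidate_occupancy_models()
                 else candidate_occupancy_models(cfg$occ_models),
    global_psi = cfg$global_psi, seed = cfg$seeds$fit))
  write_selection(sel, out_dir)

  say("gof", "bootstrap goodness of fit (n_boot = ", cfg$n_boot, ")")
  gof <- stage("gof", mb_gof(sel$best_fit, n_boot = cfg$n_boot,
                             seed = cfg$seeds$gof))

  report <- list(
    config = unclass(cfg),
    composition = lapply(landscapes, composition),
    gradient_model = list(sdev = model$sdev, var_pct = model$var_pct,
                          broken_stick_first = model$broken_stick[1],
                          retained = model$m),
    naive_occupancy = naive_occupancy(data),
    n_sites = nrow(data$sites), n_visits = nrow(data$visits),
    best_detection = sel$best_p, best_occupancy = sel$best_psi,
    best_AICc = sel$best_fit$AICc,
    gof = list(chisq_obs = gof$chisq_obs, p_value = gof$p_value,
               c_hat = gof$c_hat))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    "# Synthetic pipeline run report", "",
    sprintf("- cities: %d; grid %d x %d at %g m; sigma %g m (%s edges)",
            cfg$n_cities, cfg$n_rows, cfg$n_cols, cfg$cell_size, cfg$sigma,
            cfg$edge_policy),
    sprintf("- retained axes: %d (broken-stick first proportion %.3f)",
            model$m, model$broken_stick[1]),
    sprintf("- sites: %d, visits: %d, naive occupancy: %.3f",
            nrow(data$sites), nrow(data$visits), naive_occupancy(data)),
    sprintf("- best detection structure: %s", sel$best_p),
    sprintf("- best occupancy structure: %s (AICc %.2f)", sel$best_psi,
            sel$best_fit$AICc),
    sprintf("- goodness of fit: chi-square %.2f, p = %.3f, c-hat = %.2f",
            gof$chisq_obs, gof$p_value, gof$c_hat),
    sprintf("- seeds: %s", paste(names(cfg$seeds), unlist(cfg$seeds),
                                 sep = "=", collapse = ", "))),
    file.path(out_dir, "report.md"))

  invisible(list(config = cfg, landscapes = landscapes, stacks = stacks,
                 model = model, surfaces = surfaces, data = data,
                 selection = sel, gof = gof, report = report,
                 out_dir = out_dir))
}

#' Mosaic non-overlapping rasters sharing a grid
#'
#' Combines rasters laid out on one common grid (same cell size, aligned
#' origins) into a single raster covering their joint bounding box, nodata
#' where none covers.  Used to stitch per-city surfaces so site covariates
#' can be extracted with one call.
#'
#' @param rasters list of continuous [land_raster]s.
#' @return a continuous [land_raster].
#' @export
mosaic_rasters <- function(rasters) {
  stopifnot(length(rasters) >= 1L)
  if (length(rasters) == 1L) return(rasters[[1]])
  cs <- rasters[[1]]$cell_size
  for (r in rasters)
    if (abs(r$cell_size - cs) > 1e-9) stop("cell sizes differ")
  exts <- vapply(rasters, raster_extent, numeric(4))
  xmin <- min(exts[1, ]); xmax <- max(exts[2, ])
  ymin <- min(exts[3, ]); ymax <- max(exts[4, ])
  nc <- as.integer(round((xmax - xmin) / cs))
  nr <- as.integer(round((ymax - ymin) / cs))
  out <- matrix(NA_real_, nr, nc)
  for (r in rasters) {
    c0 <- as.integer(round((r$origin[1] - xmin) / cs))
    r0 <- as.integer(round((ymax - r$origin[2]) / cs))
    out[r0 + seq_len(nrow(r$values)), c0 + seq_len(ncol(r$values))] <- r$values
  }
  land_raster(out, origin = c(xmin, ymax), cell_size = cs, type = "continuous",
              crs = rasters[[1]]$crs)
}
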