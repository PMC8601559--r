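#' Default detection candidate set (26 structures)
#'
#' All additive combinations of the detection covariate pool -- `city`
#' (factor), `date`, `date + date2`, `HS`, `BG` -- under marginality
#' (`date2` never without `date`), *excluding* the full additive model,
#' plus three single-interaction structures: `city*date+date2+HS+BG`,
#' `city*date+HS+BG` and `city*HS`.  That yields 26 candidates.  The set is
#' an editable configuration artifact: pass your own labels to replace it.
#'
#' @param config optional character vector of structure labels overriding
#'   the default set.
#' @return named list of one-sided formulas.
#' @export
candidate_detection_models <- function(config = NULL) {
  if (is.null(config)) {
    combos <- expand.grid(city = c("", "city"),
                          date = c("", "date", "date+date2"),
                          HS = c("", "HS"), BG = c("", "BG"),
                          stringsAsFactors = FALSE)
    labels <- apply(combos, 1L, function(row) {
      terms <- row[nzchar(row)]
      if (!length(terms)) "1" else paste(terms, collapse = "+")
    })
    labels <- setdiff(labels, "city+date+date2+HS+BG")
    config <- c(labels, "city*date+date2+HS+BG", "city*date+HS+BG", "city*HS")
  }
  if (!length(config)) stop("empty candidate configuration")
  if (anyDuplicated(config)) stop("duplicate candidate structures")
  out <- lapply(config, parse_structure)
  names(out) <- vapply(config, structure_label, character(1))
  out
}

#' Default occupancy candidate set (16 structures)
#'
#' The occupancy covariate pool is `city`, `HS`, `BG`; the default set is
#' every combination of gradient main effects, the `HS*BG` interaction, and
#' city-by-gradient interactions:
#' `1, HS, BG, HS+BG, HS*BG, city, city+HS, city+BG, city+HS+BG, city+HS*BG,
#' city*HS, city*BG, city*HS+BG, city*BG+HS, city*(HS+BG), city*(HS*BG)`.
#'
#' @inheritParams candidate_detection_models
#' @return named list of one-sided formulas.
#' @export
candidate_occupancy_models <- function(config = NULL) {
  if (is.null(config))
    config <- c("1", "HS", "BG", "HS+BG", "HS*BG",
                "city", "city+HS", "city+BG", "city+HS+BG", "city+HS*BG",
                "city*HS", "city*BG", "city*HS+BG", "city*BG+HS",
                "city*(HS+BG)", "city*(HS*BG)")
  if (!length(config)) stop("empty candidate configuration")
  if (anyDuplicated(config)) stop("duplicate candidate structures")
  out <- lapply(config, parse_structure)
  names(out) <- vapply(config, structure_label, character(1))
  out
}

#' Count parameters of an occupancy/detection structure pair
#'
#' Total design-matrix width (the selection-table `K`) under treatment
#' coding for a study with `n_cities` cities.  Continuous covariates named
#' in either structure contribute one column each (plus interactions).
#'
#' @param psi,p structures (labels or formulas).
#' @param n_cities number of cities in the `city` factor.
#' @return integer K.
#' @examples
#' count_params("city*HS+BG", "city*date+date2+HS+BG", n_cities = 10)  # 44
#' @export
count_params <- function(psi, p, n_cities) {
  psi <- parse_structure(psi); p <- parse_structure(p)
  vars <- union(all.vars(psi), all.vars(p))
  template <- data.frame(city = factor(sprintf("city%02d", seq_len(n_cities))))
  for (v in setdiff(vars, "city")) template[[v]] <- 0
  ncol(stats::model.matrix(psi, template)) +
    ncol(stats::model.matrix(p, template))
}

## assemble a ranked selection table from fits
selection_table <- function(fits, labels) {
  K <- vapply(fits, function(f) f$K, numeric(1))
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  aic <- vapply(fits, function(f) f$AICc, numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tab <- data.frame(model = labels, K = K, AICc = aic, dAICc = NA_real_,
                    weight = NA_real_, negLogLik = -ll, converged = conv,
                    stringsAsFactors = FALSE)
  ok <- conv & is.finite(aic)
  if (any(ok)) {
    best <- min(aic[ok])
    tab$dAICc[ok] <- aic[ok] - best
    w <- exp(-0.5 * tab$dAICc[ok])
    tab$weight[ok] <- w / sum(w)
  }
  ord <- order(!ok, aic)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$AICc <- round(y$AICc, digits); y$dAICc <- round(y$dAICc, digits)
  y$weight <- round(y$weight, 3); y$negLogLik <- round(y$negLogLik, digits)
  print.data.frame(y, ...)
  invisible(x)
}

#' Two-stage AICc model selection
#'
#' Stage one fits every detection structure with the occupancy component
#' held at the global (most complex) structure and ranks them by AICc;
#' non-converged fits are listed but excluded from ranking.  The detection
#' structure of the top-ranked converged model is then fixed, and stage two
#' ranks every occupancy structure under it.  Weights within each stage are
#' Akaike weights over the converged models.
#'
#' @param data an [occu_data].
#' @param det_models,occ_models named lists of structures (defaults:
#'   [candidate_detection_models()], [candidate_occupancy_models()]).
#' @param global_psi the global occupancy structure used throughout stage
#'   one; must be one of `occ_models`.
#' @param ... passed to [occu_fit()] (e.g. `restarts`, `seed`).
#' @return object of class `occu_selection`: list with `detection` and
#'   `occupancy` [selection tables][print.selection_table], `best_p`,
#'   `best_psi` labels and the `best_fit` ([occu_fit()]) of the stage-two
#'   winner.
#' @export
occu_select <- function(data, det_models = candidate_detection_models(),
                        occ_models = candidate_occupancy_models(),
                        global_psi = "city*(HS*BG)", ...) {
  stopifnot(inherits(data, "occu_data"))
  if (is.character(det_models)) det_models <- candidate_detection_models(det_models)
  if (is.character(occ_models)) occ_models <- candidate_occupancy_models(occ_models)
  g_label <- structure_label(global_psi)
  if (!(g_label %in% names(occ_models)))
    stop("global_psi (", g_label, ") must be one of the occupancy candidates")

  fits1 <- lapply(det_models, function(p) occu_fit(occ_models[[g_label]], p, data, ...))
  stage1 <- selection_table(fits1, names(det_models))
  if (!any(stage1$converged)) stop("no detection model converged in stage one")
  best_p <- stage1$model[which(stage1$converged)[1]]

  fits2 <- lapply(occ_models, function(psi)
    occu_fit(psi, det_models[[best_p]], data, ...))
  stage2 <- selection_table(fits2, names(occ_models))
  if (!any(stage2$converged)) stop("no occupancy model converged in stage two")
  best_i <- which(stage2$converged)[1]

  structure(list(detection = stage1, occupancy = stage2,
                 global_psi = g_label, best_p = best_p,
                 best_psi = stage2$model[best_i],
                 best_fit = attr(stage2, "fits")[[best_i]]),
            class = "occu_selection")
}

#' @export
print.occu_selection <- function(x, ...) {
  cat("Two-stage occupancy model selection\n")
  cat(sprintf("\nStage 1: detection (psi fixed at global %s)\n", x$global_psi))
  print(x$detection)
  cat(sprintf("\nStage 2: occupancy (p fixed at %s)\n", x$best_p))
  print(x$occupancy)
  cat(sprintf("\nSelected model: psi ~ %s,  p ~ %s\n", x$best_psi, x$best_p))
  invisible(x)
}

#' Write selection tables as CSV
#'
#' @param sel an [occu_select()] result.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_selection <- function(sel, dir) {
  stopifnot(inherits(sel, "occu_selection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "selection_detection.csv")
  p2 <- file.path(dir, "selection_occupancy.csv")
  utils::write.csv(as.data.frame(sel$detection), p1, row.names = FALSE)
  utils::write.csv(as.data.frame(sel$occupancy), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
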