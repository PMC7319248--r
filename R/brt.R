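#' Boosted regression tree configuration
#'
#' Defaults follow standard practice for presence/absence cetacean BRTs:
#' tree complexity (interaction depth) 3, bag fraction 0.6, and a learning
#' rate tuned downward until the cross-validation-optimal model contains at
#' least 1,000 trees.
#'
#' @param tree_complexity Maximum tree interaction depth (>= 1).
#' @param bag_fraction Stochastic subsample fraction per tree (0, 1\].
#' @param min_trees Minimum cross-validated optimal tree count.
#' @param learn_rate_init Starting learning rate ("shrinkage").
#' @param learn_rate_shrink Multiplicative factor applied when the optimal
#'   tree count falls short.
#' @param variant Variable combination: `"dyn_bathy"` (dynamic +
#'   bathymetric), `"dyn_bathy_lat"`, `"dyn_bathy_lon"`, or `"all"`.
#' @param n_iterations Number of stochastic model iterations for
#'   [select_best_brt()].
#' @param cv_folds Cross-validation folds for the optimal tree count.
#' @param offer_year Offer year as a candidate predictor.
#' @param seed RNG seed (bagging + folds + random screen variable).
#' @return Object of class `brt_config`.
#' @export
brt_config <- function(tree_complexity = 3, bag_fraction = 0.6,
                       min_trees = 1000, learn_rate_init = 0.05,
                       learn_rate_shrink = 0.5,
                       variant = c("all", "dyn_bathy", "dyn_bathy_lat",
                                   "dyn_bathy_lon"),
                       n_iterations = 10, cv_folds = 10,
                       offer_year = FALSE, seed = 1) {
  variant <- match.arg(variant)
  if (tree_complexity < 1) stop("tree_complexity must be >= 1")
  if (bag_fraction <= 0 || bag_fraction > 1) stop("bag_fraction must be in (0, 1]")
  if (min_trees < 1) stop("min_trees must be >= 1")
  structure(list(tree_complexity = tree_complexity,
                 bag_fraction = bag_fraction, min_trees = min_trees,
                 learn_rate_init = learn_rate_init,
                 learn_rate_shrink = learn_rate_shrink, variant = variant,
                 n_iterations = n_iterations, cv_folds = cv_folds,
                 offer_year = offer_year, seed = seed),
            class = "brt_config")
}

brt_variant_vars <- function(variant, offer_year = FALSE) {
  dyn <- c("sst", "sst_sd", "ssh", "ssh_sd", "mld")
  v <- switch(variant,
    dyn_bathy = c(dyn, "depth"),
    dyn_bathy_lat = c(dyn, "depth", "lat"),
    dyn_bathy_lon = c(dyn, "depth", "lon"),
    all = c(dyn, "depth", "lat", "lon"))
  if (offer_year) v <- c(v, "year")
  v
}

#' Fit a presence/absence boosted regression tree
#'
#' Gradient-boosted trees with binomial deviance loss, interaction depth
#' equal to the configured tree complexity and per-tree subsampling equal
#' to the bag fraction. A uniform-random screening variable is appended to
#' the candidate covariates; [screen_predictors()] later retains only
#' variables with more influence than that screen. The learning rate is
#' multiplied by the shrink factor until the cross-validation-optimal tree
#' count reaches `min_trees`; it is an error for the learning rate to
#' underflow below 1e-5 first. Deterministic for a fixed config seed.
#'
#' @param segments Segment table (response is occupancy, `n_sight > 0`).
#' @param config A [brt_config()].
#' @param features Optional explicit feature set (defaults to the
#'   config variant's variables plus the random screen).
#' @param add_screen Append the random screening variable (default TRUE).
#' @return Object of class `brt_fit` with the fitted booster, per-variable
#'   relative influence (%), CV-optimal tree count and CV deviance.
#' @export
fit_brt <- function(segments, config = brt_config(), features = NULL,
                    add_screen = TRUE) {
  y <- as.integer(segments$n_sight > 0)
  if (length(unique(y)) < 2) stop("single-class response")
  if (is.null(features))
    features <- brt_variant_vars(config$variant, config$offer_year)
  miss <- setdiff(features, names(segments))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(segments[, features, drop = FALSE])
  set.seed(config$seed)
  if (add_screen) {
    X <- cbind(X, random_screen = stats::runif(nrow(X)))
    features <- c(features, "random_screen")
  }

  lr <- config$learn_rate_init
  repeat {
    if (lr < 1e-5)
      stop("learning rate underflowed below 1e-5 before reaching ",
           config$min_trees, " trees")
    res <- brt_cv_best(X, y, config, lr)
    if (res$best_trees >= config$min_trees) break
    lr <- lr * config$learn_rate_shrink
  }

  params <- brt_params(config, lr)
  set.seed(config$seed)
  booster <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(X, label = y),
                                nrounds = res$best_trees, verbose = 0)
  infl <- stats::setNames(rep(0, length(features)), features)
  if (length(features) == 1L) {
    infl[features] <- 100
  } else {
    imp <- xgboost::xgb.importance(model = booster)
    infl[imp$Feature] <- imp$Gain * 100
  }

  structure(list(model = booster, influence = infl,
                 best_trees = res$best_trees,
                 cv_deviance = 2 * res$best_logloss,
                 learn_rate = lr, features = features,
                 config = config, data = segments,
                 has_screen = add_screen),
            class = "brt_fit")
}

brt_params <- function(config, lr) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       eta = lr, max_depth = config$tree_complexity,
       subsample = config$bag_fraction, nthread = 1,
       seed = config$seed)
}

# k-fold CV curve; returns the iteration minimizing mean held-out logloss
brt_cv_best <- function(X, y, config, lr) {
  max_rounds <- max(ceiling(config$min_trees * 1.5), 50)
  set.seed(config$seed)
  cv <- xgboost::xgb.cv(params = brt_params(config, lr),
                        data = xgboost::xgb.DMatrix(X, label = y),
                        nrounds = max_rounds, nfold = config$cv_folds,
                        early_stopping_rounds = 25, verbose = 0)
  curve <- cv$evaluation_log$test_logloss_mean
  best <- which.min(curve)
  list(best_trees = best, best_logloss = curve[best])
}

#' @export
print.brt_fit <- function(x, ...) {
  cat("BRT fit:", x$best_trees, "trees, learning rate", x$learn_rate, "\n")
  cat("  CV deviance (per obs):", signif(x$cv_deviance, 4), "\n")
  print(round(sort(x$influence, decreasing = TRUE), 2))
  invisible(x)
}

#' Screen BRT predictors against the random variable
#'
#' Retains the variables whose relative influence strictly exceeds the
#' random screening variable's, then refits the BRT on the retained set
#' only (the screen itself is never retained).
#'
#' @param fit A `brt_fit` containing the random screen variable.
#' @return A `brt_fit` refit on the retained variables, with a `retained`
#'   element.
#' @export
screen_predictors <- function(fit) {
  if (!isTRUE(fit$has_screen)) stop("fit does not contain the random screen variable")
  retained <- screen_rule(fit$influence)
  if (length(retained) == 0)
    stop("no informative predictors: the random screen variable beats every covariate")
  refit <- fit_brt(fit$data, fit$config, features = retained,
                   add_screen = FALSE)
  refit$retained <- retained
  refit
}

#' Predictor-screening retention rule
#'
#' Given a named relative-influence vector containing `random_screen`,
#' returns the variables whose influence strictly exceeds the screen's.
#'
#' @param influence Named numeric vector of relative influences (%).
#' @return Character vector of retained variable names (may be empty).
#' @export
screen_rule <- function(influence) {
  if (!"random_screen" %in% names(influence))
    stop("influence vector lacks the random screen variable")
  screen <- influence[["random_screen"]]
  setdiff(names(influence)[influence > screen], "random_screen")
}

#' Predict presence probability from a BRT
#'
#' @param object A `brt_fit`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Probabilities in \[0, 1\].
#' @export
predict.brt_fit <- function(object, newdata, ...) {
  feats <- object$features
  miss <- setdiff(setdiff(feats, "random_screen"), names(newdata))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  X <- matrix(0, nrow(newdata), length(feats),
              dimnames = list(NULL, feats))
  for (f in setdiff(feats, "random_screen")) X[, f] <- newdata[[f]]
  if ("random_screen" %in% feats) X[, "random_screen"] <- 0.5
  as.numeric(stats::predict(object$model, xgboost::xgb.DMatrix(X)))
}

#' Fit and select the best BRT over variants and iterations
#'
#' Fits every variable-combination variant for `n_iterations` stochastic
#' iterations each (varying the bagging/fold seed), screens predictors
#' against the random variable, and ranks the candidates by
#' cross-validated deviance with training AUC and TSS as tie-breakers
#' (exact ties go to the lowest seed index). Candidates that fail (e.g. no
#' informative predictors) are recorded and skipped.
#'
#' @param segments Segment table.
#' @param config Base [brt_config()]; its `variant` is ignored.
#' @param variants Variants to try.
#' @return The winning screened `brt_fit` with a `leaderboard` data.frame
#'   attached.
#' @export
select_best_brt <- function(segments, config = brt_config(),
                            variants = c("dyn_bathy", "dyn_bathy_lat",
                                         "dyn_bathy_lon", "all")) {
  y <- as.integer(segments$n_sight > 0)
  rows <- list(); fits <- list()
  for (v in variants) for (it in seq_len(config$n_iterations)) {
    cfg <- config
    cfg$variant <- v
    cfg$seed <- config$seed + it - 1L
    cand <- tryCatch({
      f0 <- fit_brt(segments, cfg)
      screen_predictors(f0)
    }, error = function(e) e)
    i <- length(rows) + 1L
    if (inherits(cand, "error")) {
      rows[[i]] <- data.frame(variant = v, iteration = it, seed = cfg$seed,
                              converged = FALSE, cv_deviance = NA,
                              auc = NA, tss = NA, n_trees = NA)
    } else {
      p <- predict(cand, segments)
      a <- auc(y, p)
      th <- max_sss_threshold(y, p)
      rows[[i]] <- data.frame(variant = v, iteration = it, seed = cfg$seed,
                              converged = TRUE,
                              cv_deviance = cand$cv_deviance,
                              auc = a, tss = tss(y, p, th),
                              n_trees = cand$best_trees)
      fits[[i]] <- cand
    }
  }
  lb <- do.call(rbind, rows)
  ok <- which(lb$converged)
  if (length(ok) == 0) stop("all BRT candidates failed")
  ord <- ok[order(lb$cv_deviance[ok], -lb$auc[ok], -lb$tss[ok], lb$seed[ok])]
  best <- fits[[ord[1]]]
  best$leaderboard <- lb
  best
}

#' Serialize a fitted BRT as JSON
#'
#' Writes the boosted ensemble (tree dump in the engine's JSON format)
#' together with the configuration, retained variables, influence vector
#' and CV summary.
#'
#' @param fit A `brt_fit`.
#' @param path Output path.
#' @export
write_brt_json <- function(fit, path) {
  trees <- xgboost::xgb.dump(fit$model, dump_format = "json")
  obj <- list(
    features = fit$features,
    retained = fit$retained,
    influence_pct = as.list(fit$influence),
    n_trees = fit$best_trees,
    learn_rate = fit$learn_rate,
    cv_deviance = fit$cv_deviance,
    config = fit$config[c("tree_complexity", "bag_fraction", "min_trees",
                          "variant", "cv_folds", "seed")],
    trees = jsonlite::parse_json(paste(trees, collapse = "")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a BRT influence table / leaderboard as CSV
#'
#' @param fit A `brt_fit`.
#' @param path Output path.
#' @export
write_brt_influence_csv <- function(fit, path) {
  utils::write.csv(data.frame(variable = names(fit$influence),
                              influence_pct = as.numeric(fit$influence)),
                   path, row.names = FALSE)
  invisible(path)
}
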