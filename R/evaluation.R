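#' Mean absolute error
#'
#' @param estimates,truths Equal-length nonempty numeric vectors, ug/m3.
#' @return Mean of `|estimates - truths|`.
#' @export
mae <- function(estimates, truths) {
  check_error_pair(estimates, truths)
  mean(abs(estimates - truths))
}

#' Root mean square error
#'
#' Always at least as large as [mae()] on the same vectors (power-mean
#' inequality); more sensitive to occasional large deviations.
#'
#' @inheritParams mae
#' @return Square root of the mean squared difference.
#' @export
rmse <- function(estimates, truths) {
  check_error_pair(estimates, truths)
  sqrt(mean((estimates - truths)^2))
}

check_error_pair <- function(estimates, truths) {
  if (length(estimates) == 0L || length(estimates) != length(truths)) {
    stop("estimates and truths must be nonempty vectors of equal length",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Composition of absolute errors by magnitude
#'
#' Bins `|estimates - truths|` into the intervals
#' `[0, e1), [e1, e2), ..., [e_last, Inf)` (lower-inclusive, upper-exclusive)
#' and returns the proportion of errors in each bin. The default edges
#' `c(5, 10, 15, 20)` ug/m3 partition errors into the magnitude classes
#' used when comparing interpolators on pollutant fields.
#'
#' @inheritParams mae
#' @param edges Strictly increasing bin edges, ug/m3.
#' @return Numeric vector of `length(edges) + 1` proportions summing to 1.
#' @examples
#' bin_absolute_errors(c(1, 6, 11, 16, 21), rep(0, 5)) # 0.2 each
#' @export
bin_absolute_errors <- function(estimates, truths, edges = c(5, 10, 15, 20)) {
  check_error_pair(estimates, truths)
  if (length(edges) < 1L || any(diff(edges) <= 0) || any(edges <= 0)) {
    stop("edges must be positive and strictly increasing", call. = FALSE)
  }
  err <- abs(estimates - truths)
  counts <- tabulate(findInterval(err, edges) + 1L,
                     nbins = length(edges) + 1L)
  counts / length(err)
}

#' Error summary for one estimate/truth pair
#'
#' @inheritParams bin_absolute_errors
#' @return An object of class `error_summary` with fields `mae`, `rmse`,
#'   `n`, `bin_edges` and `bin_proportions`.
#' @export
error_summary <- function(estimates, truths, edges = c(5, 10, 15, 20)) {
  structure(
    list(mae = mae(estimates, truths),
         rmse = rmse(estimates, truths),
         n = length(estimates),
         bin_edges = edges,
         bin_proportions = bin_absolute_errors(estimates, truths, edges)),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d, MAE = %.4f, RMSE = %.4f ug/m3\n",
              x$n, x$mae, x$rmse))
  lab <- c(sprintf("<%g", x$bin_edges),
           sprintf(">=%g", x$bin_edges[length(x$bin_edges)]))
  cat("  error bins: ",
      paste(sprintf("%s: %.1f%%", lab, 100 * x$bin_proportions),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Spatially stratified hold-out cross-validation plan
#'
#' Builds `n_folds` folds; each fold holds out a validation set ("set A")
#' of `holdout_size` stations that is well distributed over the study zone,
#' with the remaining stations forming the training set ("set B"). Spatial
#' balance is enforced by partitioning the stations into `holdout_size`
#' spatial clusters (seeded k-means on lon/lat) and drawing exactly one
#' station per cluster into each fold. When every cluster has at least
#' `n_folds` members, draws are made without replacement across folds, so
#' the validation sets are pairwise disjoint; smaller clusters fall back to
#' independent draws per fold (noted in a message).
#'
#' @param stations A [station_set()] with more than `holdout_size` stations.
#' @param n_folds Number of folds (default 8).
#' @param holdout_size Validation stations per fold (default 15).
#' @param seed Integer seed; plans are a deterministic function of it.
#' @return An object of class `cv_plan`: `folds` is a list whose elements
#'   have integer index vectors `validation` and `training`; `clusters`
#'   holds the k-means cluster label of every station.
#' @examples
#' st <- sample_stations(ie1_preset(), n = 225, seed = 7, noise_sd = 5)
#' plan <- make_cv_folds(st, seed = 7)
#' lengths(lapply(plan$folds, `[[`, "validation"))
#' @export
make_cv_folds <- function(stations, n_folds = 8, holdout_size = 15, seed) {
  stopifnot(inherits(stations, "station_set"))
  stopifnot_scalar_number(n_folds, "n_folds")
  stopifnot_scalar_number(holdout_size, "holdout_size")
  n_folds <- as.integer(n_folds)
  holdout_size <- as.integer(holdout_size)
  if (n_folds < 1L) stop("n_folds must be >= 1", call. = FALSE)
  if (stations$n <= holdout_size) {
    stop("need more stations than holdout_size", call. = FALSE)
  }
  with_seed(seed, {
    km <- stats::kmeans(cbind(stations$lons, stations$lats),
                        centers = holdout_size, nstart = 5, iter.max = 100)
    clusters <- km$cluster
    sizes <- tabulate(clusters, nbins = holdout_size)
    disjoint <- all(sizes >= n_folds)
    if (!disjoint) {
      message("some spatial clusters have fewer members than folds; ",
              "validation sets may overlap across folds")
    }
    # picks[[cl]]: the station drawn from cluster cl for each fold
    picks <- lapply(seq_len(holdout_size), function(cl) {
      members <- which(clusters == cl)
      if (disjoint) {
        sample(members, n_folds)
      } else if (length(members) == 1L) {
        rep(members, n_folds)
      } else {
        sample(members, n_folds, replace = TRUE)
      }
    })
    folds <- lapply(seq_len(n_folds), function(f) {
      val <- sort(vapply(picks, `[[`, integer(1), f))
      list(validation = val, training = setdiff(seq_len(stations$n), val))
    })
    structure(list(n_folds = n_folds, holdout_size = holdout_size,
                   seed = seed, folds = folds, clusters = clusters,
                   disjoint = disjoint),
              class = "cv_plan")
  })
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds, holdout %d, seed %s, %s validation sets\n",
              x$n_folds, x$holdout_size, format(x$seed),
              if (x$disjoint) "disjoint" else "possibly overlapping"))
  invisible(x)
}

#' Interpolation method specifications
#'
#' Lightweight descriptors consumed by [run_cross_validation()] and the
#' `compare` pipeline: each names a method and carries its parameters.
#'
#' @param s,k Polynomial orders for the surface fit.
#' @param model A [variogram_model()] for kriging.
#' @param params A [cressman_params()] for Cressman analysis.
#' @param domain Optional fixed [domain_box()] for the surface fit; the
#'   default (`NULL`) uses each training set's own bounding box.
#' @return An object of class `interp_method`.
#' @export
opf_method <- function(s, k, domain = NULL) {
  structure(list(name = "opf", s = check_order(s, "s"),
                 k = check_order(k, "k"), domain = domain),
            class = "interp_method")
}

#' @rdname opf_method
#' @export
kriging_method <- function(model = variogram_model()) {
  stopifnot(inherits(model, "variogram_model"))
  structure(list(name = "kriging", model = model), class = "interp_method")
}

#' @rdname opf_method
#' @export
cressman_method <- function(params = cressman_params()) {
  stopifnot(inherits(params, "cressman_params"))
  structure(list(name = "cressman", params = params), class = "interp_method")
}

# Fit on a training station set and predict at query coordinates.
predict_method <- function(method, train, lons, lats) {
  switch(method$name,
    opf = {
      dom <- method$domain
      if (is.null(dom)) dom <- station_bbox(train)
      surf <- fit_surface(train, method$s, method$k, domain = dom,
                          max_order = max(10L, method$s, method$k))
      evaluate_surface(surf, lons, lats)
    },
    kriging = ordinary_kriging(train, lons, lats, model = method$model)$values,
    cressman = cressman_interpolate(train, lons, lats,
                                    params = method$params)$values,
    stop("unknown method: ", method$name, call. = FALSE)
  )
}

#' Run hold-out cross-validation for one interpolation method
#'
#' For each fold of the plan, the method is fit using only the training
#' stations (set B) and evaluated at the held-out validation stations
#' (set A) against their observed values. Per-fold error summaries are
#' returned together with the across-fold averages (the arithmetic mean of
#' the fold MAEs and RMSEs).
#'
#' @param stations A [station_set()].
#' @param method An [opf_method()], [kriging_method()] or
#'   [cressman_method()].
#' @param plan A [make_cv_folds()] plan for the same stations.
#' @return An object of class `cv_result`: `fold_table` (data frame with
#'   columns `fold`, `mae`, `rmse`, `n`), `summaries` (per-fold
#'   [error_summary()] objects), `mean_mae`, `mean_rmse`.
#' @examples
#' st <- sample_stations(ie1_preset(), n = 225, seed = 7, noise_sd = 5)
#' plan <- make_cv_folds(st, seed = 7)
#' run_cross_validation(st, opf_method(5, 5), plan)
#' @export
run_cross_validation <- function(stations, method, plan) {
  stopifnot(inherits(stations, "station_set"),
            inherits(method, "interp_method"),
            inherits(plan, "cv_plan"))
  summaries <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    fold <- plan$folds[[f]]
    train <- subset_stations(stations, fold$training)
    est <- tryCatch(
      predict_method(method, train,
                     stations$lons[fold$validation],
                     stations$lats[fold$validation]),
      error = function(e) {
        stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE)
      })
    summaries[[f]] <- error_summary(est, stations$values[fold$validation])
  }
  fold_table <- data.frame(
    fold = seq_len(plan$n_folds),
    mae = vapply(summaries, `[[`, numeric(1), "mae"),
    rmse = vapply(summaries, `[[`, numeric(1), "rmse"),
    n = vapply(summaries, `[[`, integer(1), "n")
  )
  structure(list(method = method$name, fold_table = fold_table,
                 summaries = summaries,
                 mean_mae = mean(fold_table$mae),
                 mean_rmse = mean(fold_table$rmse)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> method %s: mean MAE %.4f, mean RMSE %.4f over %d folds\n",
              x$method, x$mean_mae, x$mean_rmse, nrow(x$fold_table)))
  print(x$fold_table, row.names = FALSE)
  invisible(x)
}

#' Cross-validated search over polynomial orders
#'
#' Runs [run_cross_validation()] with the surface fit at every order pair
#' `(s, k)` in `1..max_order` squared and records the across-fold mean MAE.
#' Order pairs whose coefficient count exceeds the training-set size on any
#' fold cannot be fit and are flagged invalid (`NA` in the matrix) rather
#' than silently skipped. The selected orders minimize the mean MAE over
#' valid cells; ties prefer the smaller `s + k`, then the smaller `s`
#' (parsimony).
#'
#' @param stations A [station_set()].
#' @param plan A [make_cv_folds()] plan.
#' @param max_order Largest order searched per axis (default 10).
#' @return An object of class `order_search_result`: `mae_matrix`
#'   (`max_order` rows for `s`, columns for `k`, `NA` = infeasible),
#'   `best_s`, `best_k`, `best_mae`.
#' @export
order_search <- function(stations, plan, max_order = 10) {
  stopifnot(inherits(stations, "station_set"), inherits(plan, "cv_plan"))
  stopifnot_scalar_number(max_order, "max_order")
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("max_order must be >= 1", call. = FALSE)
  min_train <- min(vapply(plan$folds, function(f) length(f$training),
                          integer(1)))
  M <- matrix(NA_real_, max_order, max_order,
              dimnames = list(s = seq_len(max_order), k = seq_len(max_order)))
  for (s in seq_len(max_order)) {
    for (k in seq_len(max_order)) {
      if ((s + 1L) * (k + 1L) > min_train) next # infeasible on some fold
      cv <- run_cross_validation(stations,
                                 opf_method(s, k),
                                 plan)
      M[s, k] <- cv$mean_mae
    }
  }
  if (!any(is.finite(M))) {
    stop("no feasible order pair: every (s, k) cell is invalid", call. = FALSE)
  }
  cand <- which(M == min(M, na.rm = TRUE), arr.ind = TRUE)
  ord <- order(cand[, 1] + cand[, 2], cand[, 1])
  best <- cand[ord[1L], ]
  structure(list(mae_matrix = M,
                 best_s = unname(best[1L]), best_k = unname(best[2L]),
                 best_mae = M[best[1L], best[2L]]),
            class = "order_search_result")
}

#' @export
print.order_search_result <- function(x, ...) {
  cat(sprintf("<order_search_result> best orders (s=%d, k=%d), mean CV MAE %.4f\n",
              x$best_s, x$best_k, x$best_mae))
  invisible(x)
}
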