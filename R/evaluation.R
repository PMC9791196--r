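#' Average root-mean-square error of parameter recovery
#'
#' For a parameter class with one true value per item and one estimate per
#' item and replication, the item-level RMSE across the G replications is
#' averaged over items:
#' \deqn{ARMSE = \frac{1}{M}\sum_j \sqrt{\frac{1}{G}\sum_g
#'   (\hat\delta_{jg} - \delta_j)^2}.}
#' When the true parameters are themselves redrawn each replication,
#' \code{truth} may be a G x M matrix and each replication's estimate is
#' compared with its own truth.
#'
#' @param estimates G x M matrix (replications in rows, parameters in
#'   columns).
#' @param truth length-M vector, or G x M matrix for redrawn truths.
#' @return scalar ARMSE (>= 0).
#' @examples
#' armse(matrix(c(1.3, 2.4), 1), c(1, 2))  # (0.3 + 0.4) / 2 = 0.35
#' @export
armse <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (is.matrix(truth)) {
    if (!all(dim(truth) == dim(estimates)))
      stop("truth matrix must match the dimensions of estimates")
    err <- estimates - truth
  } else {
    if (length(truth) != ncol(estimates))
      stop("length of truth must equal the number of estimate columns")
    err <- sweep(estimates, 2, truth)
  }
  mean(sqrt(colMeans(err^2)))
}

#' Average truth-estimate correlation of parameter recovery
#'
#' The Pearson correlation between the estimates of replication g and the
#' true values, averaged over the G replications:
#' \deqn{ACor = \frac{1}{G}\sum_g r(\hat\delta_{\cdot g}, \delta).}
#'
#' @inheritParams armse
#' @return scalar in [-1, 1].
#' @export
acor <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  M <- ncol(estimates)
  if (M < 3) stop("need at least 3 parameters to correlate")
  truth_mat <- if (is.matrix(truth)) {
    if (!all(dim(truth) == dim(estimates)))
      stop("truth matrix must match the dimensions of estimates")
    truth
  } else {
    if (length(truth) != M)
      stop("length of truth must equal the number of estimate columns")
    matrix(truth, nrow(estimates), M, byrow = TRUE)
  }
  rs <- vapply(seq_len(nrow(estimates)), function(g) {
    if (sd(truth_mat[g, ]) == 0)
      stop("true parameters are constant; correlation undefined")
    if (sd(estimates[g, ]) == 0)
      stop("estimates of replication ", g,
           " have zero variance; correlation undefined")
    cor(estimates[g, ], truth_mat[g, ])
  }, numeric(1))
  mean(rs)
}

#' Correlations among person-level score vectors
#'
#' Pearson correlations over persons for every pair of named score vectors
#' (e.g. the bifactor general-factor EAP vs. the UIRT EAP, or the six
#' bifactor factors among themselves). Vectors are aligned by person id
#' (names); at least 3 common persons are required.
#'
#' @param score_sets named list of numeric vectors; names of each vector are
#'   person ids (unnamed vectors must all have equal length and are aligned
#'   by position).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
score_correlations <- function(score_sets) {
  stopifnot(is.list(score_sets), length(score_sets) >= 2,
            !is.null(names(score_sets)))
  named <- !vapply(score_sets, function(v) is.null(names(v)), logical(1))
  if (all(named)) {
    ids <- Reduce(intersect, lapply(score_sets, names))
    if (length(ids) < 3) stop("fewer than 3 common persons across scores")
    mat <- vapply(score_sets, function(v) v[ids],
                  numeric(length(ids)))
  } else {
    len <- unique(vapply(score_sets, length, integer(1)))
    if (length(len) != 1) stop("unnamed score vectors differ in length")
    if (len < 3) stop("fewer than 3 common persons across scores")
    mat <- vapply(score_sets, identity, numeric(len))
  }
  stats::cor(mat)
}

#' Monte Carlo replication study: model selection and parameter recovery
#'
#' Repeats the full simulate-and-fit pipeline of one generating condition:
#' each replication draws true item parameters (afresh by default),
#' abilities and masked responses, fits the requested models, and records
#' the four model-selection indices. Recovery (ARMSE and ACor per parameter
#' class) is computed for the correctly specified fit, comparing each
#' replication's estimates with that replication's generating values.
#'
#' Parameter classes: the general slope \code{a0} (FIBF, UIRT), the specific
#' slopes \code{a1..aD} by dimension (FIBF, MIRT), and the pooled intercepts
#' \code{b}.
#'
#' @param model generating model ("FIBF", "MIRT" or "UIRT").
#' @param G number of replications.
#' @param design a \code{\link{build_design}} object.
#' @param fit_models which models to fit to every replication (default: all
#'   three competitors).
#' @param seed master seed; per-replication sub-seeds are derived from it.
#' @param tol,max_iter,quad_nodes passed to \code{\link{irt_fit}};
#'   \code{quad_nodes} may be a named vector with per-model entries.
#' @param redraw_params redraw the generating item parameters each
#'   replication (default) or keep one fixed draw.
#' @param keep_fits retain the fitted model objects of the final
#'   replication (for inspection).
#' @return object of class \code{replication_study}: \code{indices}
#'   (replication x model table of AIC/SABIC/HQ/BIC with convergence flags),
#'   \code{best_by_index} (G x 4 matrix of winning model tags),
#'   \code{recovery} (\code{recovery_report}: ARMSE/ACor per class),
#'   \code{seeds}, and the configuration.
#' @export
run_replication_study <- function(model = c("FIBF", "MIRT", "UIRT"),
                                  G = 20L, design = build_design(),
                                  fit_models = c("FIBF", "MIRT", "UIRT"),
                                  seed = 1L, tol = 1e-3, max_iter = 300L,
                                  quad_nodes = NULL,
                                  redraw_params = TRUE, keep_fits = FALSE) {
  model <- match.arg(model)
  fit_models <- match.arg(fit_models, MODELS, several.ok = TRUE)
  stopifnot(G >= 1)
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 2, G + 1L)
  fixed_items <- NULL
  if (!redraw_params) {
    set.seed(seeds[G + 1L])
    fixed_items <- sim_item_params(model, design)
  }
  qn_for <- function(fm) {
    if (is.null(quad_nodes)) return(NULL)
    if (!is.null(names(quad_nodes)) && fm %in% names(quad_nodes))
      return(quad_nodes[[fm]])
    if (is.null(names(quad_nodes))) return(quad_nodes[1])
    NULL
  }

  idx_rows <- list()
  est <- NULL   # per-class lists of G x n matrices
  tru <- NULL
  best <- matrix(NA_character_, G, 4,
                 dimnames = list(NULL, c("AIC", "SABIC", "HQ", "BIC")))
  for (g in seq_len(G)) {
    set.seed(seeds[g])
    sub <- sample.int(2^31 - 1, 3)
    if (redraw_params) {
      set.seed(sub[1])
      items_true <- sim_item_params(model, design)
    } else items_true <- fixed_items
    set.seed(sub[2])
    ab <- sim_abilities(model, design$N, design$n_domains)
    set.seed(sub[3])
    X <- sim_responses(items_true, ab$theta, design, model)

    fits <- list()
    for (fm in fit_models) {
      fits[[fm]] <- suppressWarnings(
        irt_fit(X, fm, domains = design$items$domain, K = design$items$K,
                quad_nodes = qn_for(fm), tol = tol, max_iter = max_iter,
                n_domains = design$n_domains))
      idx <- fit_indices(fits[[fm]])
      idx_rows[[length(idx_rows) + 1L]] <- data.frame(
        replication = g, model = fm, t(idx),
        converged = fits[[fm]]$converged, stringsAsFactors = FALSE)
    }
    if (length(fit_models) > 1L) {
      cmp <- compare_fits(fits)
      best[g, ] <- cmp$best_by_index
    }
    if (keep_fits && g == G) last_fits <- fits
    if (model %in% fit_models) {
      pr <- recovery_classes(fits[[model]]$items, items_true, model,
                             design$n_domains)
      if (is.null(est)) {
        est <- lapply(pr, function(cl) matrix(NA_real_, G,
                                              length(cl$estimate)))
        tru <- lapply(pr, function(cl) matrix(NA_real_, G,
                                              length(cl$truth)))
        names(est) <- names(tru) <- names(pr)
      }
      for (cl in names(pr)) {
        est[[cl]][g, ] <- pr[[cl]]$estimate
        tru[[cl]][g, ] <- pr[[cl]]$truth
      }
    }
  }
  recovery <- NULL
  if (!is.null(est)) {
    tab <- data.frame(
      class = names(est),
      ARMSE = vapply(names(est), function(cl) armse(est[[cl]], tru[[cl]]),
                     numeric(1)),
      ACor = vapply(names(est), function(cl) acor(est[[cl]], tru[[cl]]),
                    numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    recovery <- structure(list(table = tab, G = G, estimates = est,
                               truth = tru, model = model),
                          class = "recovery_report")
  }
  structure(list(model = model, G = G, N = design$N, M = design$M,
                 fit_models = fit_models,
                 indices = do.call(rbind, idx_rows), best_by_index = best,
                 recovery = recovery, seeds = seeds[seq_len(G)],
                 seed = seed, tol = tol, max_iter = max_iter,
                 redraw_params = redraw_params,
                 fits = if (keep_fits) last_fits else NULL),
            class = "replication_study")
}

# align the correctly specified fit with the generating values, by
# parameter class
recovery_classes <- function(items_hat, items_true, model, n_domains) {
  stopifnot(identical(items_hat$item_id, items_true$item_id))
  out <- list()
  if (model != "MIRT")
    out$a0 <- list(estimate = items_hat$a0, truth = items_true$a0)
  if (model != "UIRT") {
    for (v in seq_len(n_domains)) {
      idx <- which(items_true$domain == v)
      out[[paste0("a", v)]] <- list(estimate = items_hat$av[idx],
                                    truth = items_true$av[idx])
    }
  }
  bh <- intercept_matrix(items_hat)
  bt <- intercept_matrix(items_true)
  keep <- !is.na(as.vector(bt))
  out$b <- list(estimate = as.vector(bh)[keep],
                truth = as.vector(bt)[keep])
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery for the correctly specified", x$model,
      "fit over", x$G, "replications:\n")
  tab <- x$table
  tab$ARMSE <- round(tab$ARMSE, 3)
  tab$ACor <- round(tab$ACor, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.replication_study <- function(x, ...) {
  cat("Replication study | generating model:", x$model, "| G =", x$G,
      "| N =", x$N, "| M =", x$M, "\n")
  if (length(x$fit_models) > 1L) {
    cat("selection frequencies (rows = index):\n")
    for (ix in colnames(x$best_by_index)) {
      tb <- table(factor(x$best_by_index[, ix], levels = x$fit_models))
      cat(sprintf("  %-6s %s\n", ix,
                  paste(names(tb), tb, sep = ":", collapse = "  ")))
    }
  }
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
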