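#' Fit an item response model by marginal maximum likelihood
#'
#' Calibrates a full-information bifactor (FIBF), unidimensional (UIRT), or
#' between-item multidimensional (MIRT) model to a persons-by-items matrix of
#' integer category codes with NA for missing-by-design cells, using an EM
#' algorithm with fixed Gauss-Hermite quadrature.
#'
#' For the bifactor model the marginal likelihood is evaluated with the
#' dimension-reduction identity: conditional on the general factor the
#' specific factors are independent across item groups, so the
#' (1 + D)-dimensional integral factors into a 1-D outer integral times D 1-D
#' inner integrals. UIRT uses a single 1-D grid. MIRT uses a D-dimensional
#' tensor grid whose nodes are transformed by the symmetric square root of
#' the current latent correlation matrix (so every dimension mixes all base
#' coordinates); the matrix is updated each cycle from the posterior second
#' moments and rescaled to unit diagonal (slopes absorb the scale).
#'
#' The M-step maximises each item's expected complete-data log-likelihood by
#' Fisher scoring with step-halving (parameters box-constrained to
#' [-10, 10]). Every third cycle the parameter update (items, and for MIRT
#' the latent correlations) is extrapolated along the EM step direction
#' (Ramsay-type acceleration); an extrapolation or correlation update that
#' lowers the marginal log-likelihood is discarded in favour of the plain
#' item-only EM update, so the recorded log-likelihood trace is
#' non-decreasing.
#'
#' Identification: the latent scale is fixed by standard-normal priors
#' (unit-diagonal correlation matrix for MIRT); after convergence any factor
#' whose slopes sum to a negative value is reflected.
#'
#' @param responses integer matrix (persons x items), category codes 0..K-1,
#'   NA = not administered. Each item needs at least one observed response.
#' @param model "FIBF", "UIRT" or "MIRT".
#' @param domains integer vector (length M) giving each item's specific
#'   factor / dimension; required for FIBF and MIRT.
#' @param K optional integer vector of per-item category counts; inferred
#'   from the data when omitted.
#' @param quad_nodes 1-D quadrature nodes: default 21 (FIBF outer and inner
#'   grids, UIRT) or 5 per dimension (MIRT).
#' @param tol EM stopping rule: |change in marginal log-likelihood| < tol.
#' @param max_iter maximum EM cycles.
#' @param init optional item parameter table (as returned by \code{coef}) to
#'   start from.
#' @param Sigma optional starting latent correlation matrix (MIRT).
#' @param n_domains number of specific factors (default: max of
#'   \code{domains}).
#' @param accelerate logical; use the every-third-cycle extrapolation.
#' @param verbose print the log-likelihood each cycle.
#' @return an object of class \code{irt_fit} with components \code{items}
#'   (estimated parameter table), \code{loglik}, \code{n_params}, \code{N},
#'   \code{converged}, \code{n_iter}, \code{trace} (accepted log-likelihoods),
#'   \code{Sigma} (MIRT), and the data/design information needed by the
#'   methods (\code{predict}, \code{simulate}, \code{residuals}, ...).
#' @examples
#' sim <- sim_study("UIRT", build_design(n_persons = 400), seed = 7)
#' fit <- irt_fit(sim$responses, "UIRT", tol = 1e-3)
#' fit
#' @export
irt_fit <- function(responses, model = c("FIBF", "UIRT", "MIRT"),
                    domains = NULL, K = NULL, quad_nodes = NULL,
                    tol = 1e-4, max_iter = 500L, init = NULL, Sigma = NULL,
                    n_domains = NULL, accelerate = TRUE, verbose = FALSE) {
  model <- match.arg(model)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  N <- nrow(responses); M <- ncol(responses)
  item_ids <- colnames(responses)
  if (is.null(item_ids)) item_ids <- sprintf("i%03d", seq_len(M))

  n_obs_item <- colSums(!is.na(responses))
  if (any(n_obs_item == 0))
    stop("item(s) without any observed response: ",
         paste(item_ids[n_obs_item == 0], collapse = ", "))
  if (is.null(K)) {
    K <- pmax(2L, apply(responses, 2, max, na.rm = TRUE) + 1L)
  } else K <- as.integer(rep_len(K, M))
  bad <- which(apply(responses, 2, max, na.rm = TRUE) >= K)
  if (length(bad))
    stop("responses exceed K - 1 for item(s): ",
         paste(item_ids[bad], collapse = ", "))
  item_type <- ifelse(K == 2L, "dichotomous", "graded")

  if (model != "UIRT") {
    if (is.null(domains))
      stop(model, " requires a 'domains' vector assigning each item to a ",
           "specific factor")
    domains <- as.integer(rep_len(domains, M))
    if (is.null(n_domains)) n_domains <- max(domains)
  } else {
    if (is.null(n_domains)) n_domains <- if (is.null(domains)) 1L
                                         else max(domains)
    if (is.null(domains)) domains <- rep(1L, M)
  }
  D <- as.integer(n_domains)

  if (is.null(quad_nodes)) quad_nodes <- if (model == "MIRT") 5L else 21L
  quad_nodes <- as.integer(quad_nodes)

  # ---- starting values -----------------------------------------------------
  Kmax <- max(K)
  if (!is.null(init)) {
    pin <- init[match(item_ids, init$item_id), ]
    a0 <- pin$a0; av <- pin$av
    b <- intercept_matrix(pin)
    if (ncol(b) < Kmax - 1L)
      b <- cbind(b, matrix(NA_real_, M, Kmax - 1L - ncol(b)))
  } else {
    a0 <- if (model == "MIRT") rep(0, M) else rep(1, M)
    av <- if (model == "UIRT") rep(0, M) else rep(1, M)
    b <- matrix(NA_real_, M, Kmax - 1L)
    for (j in seq_len(M)) {
      x <- responses[, j]; x <- x[!is.na(x)]
      ck <- vapply(seq_len(K[j] - 1L), function(k) mean(x >= k), numeric(1))
      bk <- pmin(pmax(qlogis(pmin(pmax(ck, 1e-3), 1 - 1e-3)), -3), 3)
      bk <- bk - (seq_len(K[j] - 1L) - 1L) * 1e-3  # break ties, keep order
      b[j, seq_len(K[j] - 1L)] <- bk
    }
  }
  if (model == "MIRT") {
    SigmaC <- if (is.null(Sigma)) diag(D) else check_latent_cov(Sigma, D)
  } else SigmaC <- NULL

  # ---- quadrature ----------------------------------------------------------
  gq <- gh_quadrature(quad_nodes)
  if (model == "FIBF") {
    Q0 <- Qs <- quad_nodes
    g0 <- rep(gq$nodes, each = Qs)      # grid index g = q0*Qs + qs
    gs <- rep(gq$nodes, times = Q0)
    Zgrid <- cbind(g0, gs, deparse.level = 0)
  } else if (model == "UIRT") {
    Zgrid <- matrix(gq$nodes, ncol = 1)
  } else {
    base <- gh_grid(quad_nodes, D)
  }

  par_vec <- function(a0, av, b) c(a0, av, ifelse(is.na(b), 0, b))
  grp0 <- domains - 1L

  build_probs <- function(a0, av, b, Theta = NULL) {
    lapply(seq_len(M), function(j) {
      bj <- b[j, seq_len(K[j] - 1L)]
      if (model == "FIBF")
        glogit_probs(c(a0[j], av[j], bj), Zgrid, K[j])
      else if (model == "UIRT")
        glogit_probs(c(a0[j], bj), Zgrid, K[j])
      else
        glogit_probs(c(av[j], bj), Theta[, domains[j], drop = FALSE], K[j])
    })
  }
  run_estep <- function(a0, av, b, SigmaC, counts) {
    if (model == "MIRT") {
      Theta <- base$nodes %*% sigma_sqrt(SigmaC)
      probs <- build_probs(a0, av, b, Theta)
      es <- joint_estep(responses, probs, base$weights, Theta,
                        counts, FALSE, counts)
      es$Theta <- Theta
      es
    } else if (model == "UIRT") {
      probs <- build_probs(a0, av, b)
      joint_estep(responses, probs, gq$weights, Zgrid, counts, FALSE, FALSE)
    } else {
      probs <- build_probs(a0, av, b)
      bifactor_estep(responses, probs, grp0, D, gq$weights, gq$weights,
                     gq$nodes, gq$nodes, counts, FALSE)
    }
  }

  ordering_ok <- function(b) {
    all(vapply(seq_len(M), function(j) {
      if (K[j] <= 2L) TRUE else all(diff(b[j, seq_len(K[j] - 1L)]) < 0)
    }, logical(1)))
  }

  # ---- EM cycles -----------------------------------------------------------
  # With the latent grid fixed, the item-only EM update increases the
  # (discretised) marginal log-likelihood by construction. Two kinds of
  # update are not guaranteed ascent steps and are therefore treated as
  # proposals, confirmed by the next E-step and rolled back to the plain
  # item-only update when they lower the log-likelihood:
  #   * the Ramsay-type extrapolation, and
  #   * the MIRT latent-correlation update, which moves the Cholesky-
  #     transformed grid itself (the ascent property holds for the exact
  #     integral, not its tensor-quadrature approximation). After two
  #     rejected proposals the correlation matrix is frozen.
  trace <- numeric(0)
  ll_prev <- -Inf
  cur <- list(a0 = a0, av = av, b = b, Sigma = SigmaC)
  em_backup <- NULL      # guaranteed-ascent state behind a risky proposal
  step_prev <- NULL
  risky <- FALSE
  prop_had_accel <- FALSE
  sigma_active <- model == "MIRT"
  sigma_rejections <- 0L
  converged <- FALSE
  bounded_items <- character(0)
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    es <- run_estep(cur$a0, cur$av, cur$b, cur$Sigma, counts = TRUE)
    ll <- es$loglik
    if (risky && ll < ll_prev - 1e-8) {
      # proposal lowered the log-likelihood: fall back
      if (!prop_had_accel && !identical(cur$Sigma, em_backup$Sigma)) {
        sigma_rejections <- sigma_rejections + 1L
        if (sigma_rejections >= 2L) sigma_active <- FALSE
      }
      cur <- em_backup
      step_prev <- NULL
      es <- run_estep(cur$a0, cur$av, cur$b, cur$Sigma, counts = TRUE)
      ll <- es$loglik
    }
    risky <- FALSE
    prop_had_accel <- FALSE
    trace <- c(trace, ll)
    if (verbose) cat(sprintf("EM cycle %3d  loglik %.4f\n", iter, ll))
    if (iter > 1L && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll

    # M-step (item parameters; latent covariance for MIRT)
    new <- cur
    for (j in seq_len(M)) {
      rj <- es$r[[j]]
      if (model == "FIBF") {
        Zj <- Zgrid
        pj <- c(cur$a0[j], cur$av[j], cur$b[j, seq_len(K[j] - 1L)])
      } else if (model == "UIRT") {
        Zj <- Zgrid
        pj <- c(cur$a0[j], cur$b[j, seq_len(K[j] - 1L)])
      } else {
        zv <- es$Theta[, domains[j]]
        grp <- match(zv, unique(zv))     # collapse duplicated grid values
        rj <- rowsum(rj, grp, reorder = FALSE)
        Zj <- matrix(unique(zv), ncol = 1)
        pj <- c(cur$av[j], cur$b[j, seq_len(K[j] - 1L)])
      }
      ms <- fit_item_glogit(rj, Zj, pj, K[j])
      if (ms$bounded) bounded_items <- union(bounded_items, item_ids[j])
      if (model == "FIBF") {
        new$a0[j] <- ms$par[1]; new$av[j] <- ms$par[2]
        new$b[j, seq_len(K[j] - 1L)] <- ms$par[-(1:2)]
      } else if (model == "UIRT") {
        new$a0[j] <- ms$par[1]
        new$b[j, seq_len(K[j] - 1L)] <- ms$par[-1]
      } else {
        new$av[j] <- ms$par[1]
        new$b[j, seq_len(K[j] - 1L)] <- ms$par[-1]
      }
    }
    plain <- new                          # item-only update, ascent-safe
    if (sigma_active) {
      Snew <- (es$S + t(es$S)) / (2 * N)
      dsc <- sqrt(pmax(diag(Snew), 1e-6))
      Sprop <- Snew / tcrossprod(dsc)
      diag(Sprop) <- 1
      if (max(abs(Sprop - cur$Sigma)) > 1e-5) {
        new$Sigma <- Sprop
        new$av <- new$av * dsc[domains]   # absorb latent rescaling
        risky <- TRUE
      } else sigma_active <- FALSE        # correlations have settled
    }

    # Ramsay-type extrapolation along the EM direction every third cycle
    step_cur <- par_vec(new$a0, new$av, new$b) -
      par_vec(cur$a0, cur$av, cur$b)
    if (accelerate && iter >= 6L && iter %% 3L == 0L &&
        !is.null(step_prev) && sum(step_prev^2) > 0) {
      ratio <- min(sqrt(sum(step_cur^2) / sum(step_prev^2)), 0.95)
      lambda <- min(1 / (1 - ratio), 10)
      if (lambda > 1) {
        acc <- new
        v <- par_vec(cur$a0, cur$av, cur$b) + lambda * step_cur
        acc$a0 <- pmin(pmax(v[seq_len(M)], -10), 10)
        acc$av <- pmin(pmax(v[M + seq_len(M)], -10), 10)
        bacc <- matrix(v[2L * M + seq_len(M * (Kmax - 1L))], M, Kmax - 1L)
        bacc[is.na(cur$b)] <- NA
        acc$b <- bacc
        if (model == "MIRT" && !is.null(new$Sigma)) {
          # extrapolate the latent correlations along the same direction,
          # keeping the proposal positive definite
          Sacc <- cur$Sigma + lambda * (new$Sigma - cur$Sigma)
          Sacc <- pmin(pmax(Sacc, -0.99), 0.99)
          diag(Sacc) <- 1
          if (min(eigen(Sacc, symmetric = TRUE,
                        only.values = TRUE)$values) > 1e-6)
            acc$Sigma <- Sacc
        }
        if (ordering_ok(acc$b)) {
          new <- acc
          risky <- TRUE
          prop_had_accel <- TRUE
        }
      }
    }
    if (risky) em_backup <- plain
    step_prev <- step_cur
    cur <- new
  }

  if (!converged) {
    es <- run_estep(cur$a0, cur$av, cur$b, cur$Sigma, counts = FALSE)
    ll <- es$loglik
    trace <- c(trace, ll)
  }

  # ---- sign convention: reflect factors with negative total slope ----------
  if (model != "MIRT" && sum(cur$a0) < 0) cur$a0 <- -cur$a0
  if (model != "UIRT") {
    for (v in seq_len(D)) {
      idx <- which(domains == v)
      if (length(idx) && sum(cur$av[idx]) < 0) {
        cur$av[idx] <- -cur$av[idx]
        if (model == "MIRT" && !is.null(cur$Sigma)) {
          cur$Sigma[v, ] <- -cur$Sigma[v, ]
          cur$Sigma[, v] <- -cur$Sigma[, v]
        }
      }
    }
  }

  n_params <- switch(model,
    FIBF = sum(2L + (K - 1L)),
    UIRT = sum(1L + (K - 1L)),
    MIRT = sum(1L + (K - 1L)) + D * (D - 1L) %/% 2L)

  bmat <- cur$b
  colnames(bmat) <- paste0("b", seq_len(Kmax - 1L))
  items <- cbind(
    data.frame(item_id = item_ids, item_type = item_type, K = K,
               domain = domains, a0 = cur$a0, av = cur$av,
               stringsAsFactors = FALSE),
    as.data.frame(bmat))
  attr(items, "model") <- model

  warnings <- character(0)
  if (length(bounded_items))
    warnings <- c(warnings, paste("parameter hit the [-10, 10] bound for:",
                                  paste(bounded_items, collapse = ", ")))
  if (!converged)
    warnings <- c(warnings,
                  sprintf("EM did not reach |dloglik| < %g in %d cycles",
                          tol, max_iter))
  for (wmsg in warnings) warning(wmsg, call. = FALSE)

  structure(list(model = model, items = items, Sigma = cur$Sigma,
                 loglik = ll, n_params = n_params, N = N, M = M,
                 n_obs = sum(n_obs_item), converged = converged,
                 n_iter = iter, trace = trace, quad_nodes = quad_nodes,
                 domains = domains, n_domains = D, K = K,
                 responses = responses, warnings = warnings,
                 call = match.call()),
            class = "irt_fit")
}

#' Marginal log-likelihood of an item parameter table
#'
#' Evaluates the quadrature-approximated marginal log-likelihood of a
#' response matrix under fixed item parameters, using the same latent grids
#' as \code{\link{irt_fit}} (dimension-reduced for FIBF). A matrix with no
#' observed cells has log-likelihood 0.
#'
#' @inheritParams irt_fit
#' @param items item parameter table (see \code{\link{validate_item_params}}).
#' @param Sigma latent correlation matrix (MIRT; must be positive definite).
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(responses, items, model = c("FIBF", "UIRT",
                                                        "MIRT"),
                            quad_nodes = NULL, Sigma = NULL,
                            n_domains = NULL) {
  model <- match.arg(model)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(n_domains))
    n_domains <- if (model == "UIRT") 1L else max(items$domain)
  validate_item_params(items, model, n_domains)
  mx <- apply(responses, 2, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  mx[!is.finite(mx)] <- 0
  if (any(mx >= items$K))
    stop("responses exceed K - 1 for item(s): ",
         paste(items$item_id[mx >= items$K], collapse = ", "))
  if (all(is.na(responses))) return(0)
  if (is.null(quad_nodes)) quad_nodes <- if (model == "MIRT") 5L else 21L
  M <- nrow(items); K <- items$K; b <- intercept_matrix(items)
  gq <- gh_quadrature(quad_nodes)
  if (model == "MIRT") {
    if (is.null(Sigma)) stop("MIRT requires a latent correlation matrix")
    check_latent_cov(Sigma, n_domains)
    base <- gh_grid(quad_nodes, n_domains)
    Theta <- base$nodes %*% sigma_sqrt(Sigma)
    probs <- lapply(seq_len(M), function(j)
      glogit_probs(c(items$av[j], b[j, seq_len(K[j] - 1L)]),
                   Theta[, items$domain[j], drop = FALSE], K[j]))
    es <- joint_estep(responses, probs, base$weights, Theta,
                      FALSE, FALSE, FALSE)
  } else if (model == "UIRT") {
    Z <- matrix(gq$nodes, ncol = 1)
    probs <- lapply(seq_len(M), function(j)
      glogit_probs(c(items$a0[j], b[j, seq_len(K[j] - 1L)]), Z, K[j]))
    es <- joint_estep(responses, probs, gq$weights, Z, FALSE, FALSE, FALSE)
  } else {
    Qs <- quad_nodes
    Zg <- cbind(rep(gq$nodes, each = Qs), rep(gq$nodes, times = quad_nodes))
    probs <- lapply(seq_len(M), function(j)
      glogit_probs(c(items$a0[j], items$av[j], b[j, seq_len(K[j] - 1L)]),
                   Zg, K[j]))
    es <- bifactor_estep(responses, probs, items$domain - 1L,
                         as.integer(n_domains), gq$weights, gq$weights,
                         gq$nodes, gq$nodes, FALSE, FALSE)
  }
  es$loglik
}

#' Expected a posteriori (EAP) ability scores
#'
#' Posterior means and standard deviations of each latent factor given a
#' person's observed responses, under fixed (calibrated) item parameters.
#' For the bifactor model the general-factor posterior uses the
#' dimension-reduced outer integral and each specific factor the nested
#' inner integral. Persons with no observed responses receive the prior
#' (mean 0, SD 1).
#'
#' @param fit an \code{\link{irt_fit}} object.
#' @param responses optional response matrix to score (default: the
#'   calibration data).
#' @return data frame in long format: \code{person_id}, \code{factor}
#'   ("general" or "specific1".."specificD"), \code{eap}, \code{psd}.
#' @export
eap_scores <- function(fit, responses = NULL) {
  sc <- eap_matrix(fit, responses)
  long <- data.frame(
    person_id = rep(rownames(sc$eap), ncol(sc$eap)),
    factor = rep(colnames(sc$eap), each = nrow(sc$eap)),
    eap = as.vector(sc$eap),
    psd = as.vector(sc$psd),
    stringsAsFactors = FALSE)
  long[order(long$person_id), ]
}

# wide EAP/PSD matrices (persons x factors)
eap_matrix <- function(fit, responses = NULL) {
  if (is.null(responses)) responses <- fit$responses
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  items <- fit$items
  K <- items$K
  b <- intercept_matrix(items)
  M <- nrow(items)
  gq <- gh_quadrature(fit$quad_nodes)
  model <- fit$model
  if (model == "FIBF") {
    Qs <- fit$quad_nodes
    Zg <- cbind(rep(gq$nodes, each = Qs), rep(gq$nodes, times = Qs))
    probs <- lapply(seq_len(M), function(j)
      glogit_probs(c(items$a0[j], items$av[j], b[j, seq_len(K[j] - 1L)]),
                   Zg, K[j]))
    es <- bifactor_estep(responses, probs, fit$domains - 1L, fit$n_domains,
                         gq$weights, gq$weights, gq$nodes, gq$nodes,
                         FALSE, TRUE)
    fac <- c("general", paste0("specific", seq_len(fit$n_domains)))
  } else if (model == "UIRT") {
    Z <- matrix(gq$nodes, ncol = 1)
    probs <- lapply(seq_len(M), function(j)
      glogit_probs(c(items$a0[j], b[j, seq_len(K[j] - 1L)]), Z, K[j]))
    es <- joint_estep(responses, probs, gq$weights, Z, FALSE, TRUE, FALSE)
    fac <- "general"
  } else {
    base <- gh_grid(fit$quad_nodes, fit$n_domains)
    Theta <- base$nodes %*% sigma_sqrt(fit$Sigma)
    probs <- lapply(seq_len(M), function(j)
      glogit_probs(c(items$av[j], b[j, seq_len(K[j] - 1L)]),
                   Theta[, items$domain[j], drop = FALSE], K[j]))
    es <- joint_estep(responses, probs, base$weights, Theta,
                      FALSE, TRUE, FALSE)
    fac <- paste0("specific", seq_len(fit$n_domains))
  }
  pid <- rownames(responses)
  if (is.null(pid)) pid <- sprintf("p%04d", seq_len(nrow(responses)))
  eap <- es$eap; psd <- es$psd
  dimnames(eap) <- dimnames(psd) <- list(pid, fac)
  list(eap = eap, psd = psd)
}

# symmetric square root of a latent correlation matrix; used to transform
# the standard-normal tensor grid so that every dimension mixes all base
# coordinates (a triangular factor would leave dimension 1 supported on
# just the 1-D node values)
sigma_sqrt <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
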