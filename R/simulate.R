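#' Draw generating item parameters for a simulation condition
#'
#' Samples "true" item parameters for one of the three generating models.
#' Slopes: under FIBF the general slope is U(0.5, 2.5) and the specific slope
#' U(0, 1.5); under between-item MIRT the general slope is fixed at 0 and the
#' specific slope is U(0.5, 2.5); under UIRT the specific slope is fixed at 0
#' and the general slope is U(0.5, 2.5). Intercepts: dichotomous items draw
#' b ~ N(0, 1); three-category items draw a pair (u1 ~ U(-2, 0),
#' u2 | u1 ~ U(u1, u1 + 2)) which is stored in the canonical decreasing order
#' b1 = max(u1, u2), b2 = min(u1, u2) required for valid graded-response
#' category probabilities (the marginal distributions of the pair are
#' preserved, only the labelling changes).
#'
#' @param model generating model tag.
#' @param design a \code{\link{build_design}} object.
#' @return item parameter data frame (see \code{\link{validate_item_params}}).
#' @export
sim_item_params <- function(model = c("FIBF", "MIRT", "UIRT"), design) {
  model <- match.arg(model)
  it <- design$items
  M <- nrow(it)
  a0 <- switch(model,
    FIBF = runif(M, 0.5, 2.5),
    UIRT = runif(M, 0.5, 2.5),
    MIRT = rep(0, M))
  av <- switch(model,
    FIBF = runif(M, 0, 1.5),
    MIRT = runif(M, 0.5, 2.5),
    UIRT = rep(0, M))
  Kmax <- max(it$K)
  b <- matrix(NA_real_, M, Kmax - 1L)
  dich <- it$item_type == "dichotomous"
  b[dich, 1] <- rnorm(sum(dich))
  for (j in which(!dich)) {
    u1 <- runif(1, -2, 0)
    u2 <- runif(1, u1, u1 + 2)
    draws <- sort(c(u1, u2), decreasing = TRUE)
    if (it$K[j] > 3) {  # wider scales: extend by extra ordered uniform draws
      extra <- sort(runif(it$K[j] - 3L, u1 - 2, u1), decreasing = TRUE)
      draws <- c(draws, extra)
    }
    b[j, seq_len(it$K[j] - 1L)] <- draws
  }
  colnames(b) <- paste0("b", seq_len(Kmax - 1L))
  out <- cbind(it[c("item_id", "item_type", "K", "domain")],
               data.frame(a0 = a0, av = av), as.data.frame(b))
  attr(out, "model") <- model
  validate_item_params(out, model, design$n_domains)
  out
}

#' Draw generating abilities
#'
#' FIBF: orthogonal standard-normal general + specific factors,
#' \eqn{\theta ~ MVN(0, I)}. UIRT: a single N(0, 1) ability. MIRT:
#' \eqn{\theta ~ MVN(0, \Sigma_\theta)} with unit-diagonal \eqn{\Sigma_\theta};
#' if not supplied, its off-diagonals are drawn i.i.d. U(0.4, 0.8) and the
#' whole matrix is redrawn until positive definite.
#'
#' @param model generating model tag.
#' @param n number of persons.
#' @param n_domains number of specific factors.
#' @param Sigma optional latent covariance for MIRT (unit diagonal, PD).
#' @return list with \code{theta} (n x d matrix; d = 1 + n_domains for FIBF,
#'   1 for UIRT, n_domains for MIRT) and \code{Sigma} (MIRT only, else NULL).
#' @export
sim_abilities <- function(model = c("FIBF", "MIRT", "UIRT"), n,
                          n_domains = 5L, Sigma = NULL) {
  model <- match.arg(model)
  if (model == "FIBF") {
    d <- 1L + n_domains
    theta <- matrix(rnorm(n * d), n, d)
    return(list(theta = theta, Sigma = NULL))
  }
  if (model == "UIRT")
    return(list(theta = matrix(rnorm(n), n, 1L), Sigma = NULL))
  if (is.null(Sigma)) Sigma <- sim_latent_cov(n_domains)
  check_latent_cov(Sigma, n_domains)
  Z <- matrix(rnorm(n * n_domains), n, n_domains)
  list(theta = Z %*% chol(Sigma), Sigma = Sigma)
}

# unit-diagonal covariance with U(0.4, 0.8) off-diagonals, redrawn until PD
sim_latent_cov <- function(d, max_tries = 1000L) {
  for (t in seq_len(max_tries)) {
    S <- matrix(0, d, d)
    S[upper.tri(S)] <- runif(d * (d - 1) / 2, 0.4, 0.8)
    S <- S + t(S)
    diag(S) <- 1
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) return(S)
  }
  stop("failed to draw a positive definite latent covariance in ",
       max_tries, " attempts")
}

check_latent_cov <- function(Sigma, d) {
  if (!is.matrix(Sigma) || any(dim(Sigma) != d) ||
      max(abs(Sigma - t(Sigma))) > 1e-10 || any(abs(diag(Sigma) - 1) > 1e-10))
    stop("Sigma must be a symmetric ", d, "x", d, " matrix with unit diagonal")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma is not positive definite")
  invisible(Sigma)
}

#' Simulate masked item responses
#'
#' Draws each observed cell from the item's category distribution at the
#' person's true ability; cells outside the person's booklet are NA
#' (missing by design).
#'
#' @param items generating item parameters.
#' @param theta n x d ability matrix (layout per \code{model}).
#' @param design a \code{\link{build_design}} object.
#' @param model generating model tag.
#' @return integer N x M matrix of category codes (0-based) with NA for
#'   unadministered cells; persons in rows, items in columns.
#' @export
sim_responses <- function(items, theta, design,
                          model = c("FIBF", "MIRT", "UIRT")) {
  model <- match.arg(model)
  N <- nrow(theta)
  M <- nrow(items)
  stopifnot(M == design$M, N == length(design$person_booklet))
  X <- matrix(NA_integer_, N, M,
              dimnames = list(sprintf("p%04d", seq_len(N)), items$item_id))
  in_booklet <- lapply(seq_len(design$n_booklets),
                       function(b) which(design$person_booklet == b))
  item_booklets <- lapply(seq_len(M), function(j)
    which(vapply(design$booklet_items, function(bk) j %in% bk, logical(1))))
  for (j in seq_len(M)) {
    obs <- sort(unlist(in_booklet[item_booklets[[j]]]))
    if (!length(obs)) next
    it <- items[j, ]
    eta <- switch(model,
      FIBF = it$a0 * theta[obs, 1] + it$av * theta[obs, 1 + it$domain],
      UIRT = it$a0 * theta[obs, 1],
      MIRT = it$av * theta[obs, it$domain])
    u <- runif(length(obs))
    x <- integer(length(obs))
    for (k in seq_len(it$K - 1L)) {
      ck <- plogis(eta + it[[paste0("b", k)]])  # P(X >= k), decreasing in k
      x <- x + (u < ck)
    }
    X[obs, j] <- x
  }
  X
}

#' Simulate a complete study data set
#'
#' One call bundling the generating draws of a simulation condition: item
#' parameters, abilities (and latent covariance for MIRT), and the
#' missing-by-design response matrix, reproducible from a single seed.
#' Independent sub-seeds for the parameter, ability, and response draws are
#' derived from \code{seed} so components can be regenerated stably.
#'
#' @param model generating model tag.
#' @param design a \code{\link{build_design}} object.
#' @param seed integer seed.
#' @param Sigma optional latent covariance (MIRT).
#' @return object of class \code{irt_sim}: \code{model}, \code{design},
#'   \code{items} (true parameters), \code{theta} (true abilities),
#'   \code{Sigma}, \code{responses}, \code{seed}.
#' @examples
#' sim <- sim_study("FIBF", build_design(n_persons = 300), seed = 1)
#' dim(sim$responses)
#' @export
sim_study <- function(model = c("FIBF", "MIRT", "UIRT"),
                      design = build_design(), seed = 1L, Sigma = NULL) {
  model <- match.arg(model)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sub <- sample.int(2^31 - 1, 3)  # params / abilities / responses substreams
  set.seed(sub[1])
  items <- sim_item_params(model, design)
  set.seed(sub[2])
  ab <- sim_abilities(model, design$N, design$n_domains, Sigma)
  set.seed(sub[3])
  X <- sim_responses(items, ab$theta, design, model)
  structure(list(model = model, design = design, items = items,
                 theta = ab$theta, Sigma = ab$Sigma, responses = X,
                 seed = as.integer(seed)),
            class = "irt_sim")
}

#' @export
print.irt_sim <- function(x, ...) {
  cat("Simulated", x$model, "study data: N =", nrow(x$responses),
      "persons, M =", ncol(x$responses), "items (seed", paste0(x$seed, ")\n"))
  cat("  observed cells:", sum(!is.na(x$responses)), "of",
      length(x$responses), "\n")
  invisible(x)
}
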