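#' @useDynLib bifactorirt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis qlogis rnorm runif cor coef logLik sd var predict
#'   residuals simulate
#' @importFrom utils read.csv write.csv
NULL

MODELS <- c("FIBF", "UIRT", "MIRT")

#' Item parameter tables
#'
#' Items are stored as a data frame with one row per item and columns
#' \code{item_id}, \code{item_type} ("dichotomous" or "graded"),
#' \code{K} (number of response categories), \code{domain} (which of the
#' specific factors / MIRT dimensions the item loads on), \code{a0}
#' (general-factor slope), \code{av} (specific-factor slope) and intercepts
#' \code{b1}, \code{b2}, ... (\code{K - 1} of them, strictly decreasing for
#' graded items so that the cumulative probabilities P(X >= k) are
#' non-increasing in k; unused cells are NA).
#'
#' Under the UIRT constraint all \code{av} are 0; under the between-item MIRT
#' constraint all \code{a0} are 0.
#'
#' @param items item data frame as above.
#' @param model one of "FIBF", "UIRT", "MIRT".
#' @param n_domains number of specific factors.
#' @return the validated data frame, invisibly.
#' @export
validate_item_params <- function(items, model = c("FIBF", "UIRT", "MIRT"),
                                 n_domains = 5L) {
  model <- match.arg(model)
  need <- c("item_id", "item_type", "K", "domain", "a0", "av", "b1")
  miss <- setdiff(need, names(items))
  if (length(miss))
    stop("item table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(items$item_type %in% c("dichotomous", "graded")))
    stop("item_type must be 'dichotomous' or 'graded'")
  if (any(items$K < 2)) stop("K must be >= 2 for every item")
  if (any((items$K == 2) != (items$item_type == "dichotomous")))
    stop("K = 2 must coincide with item_type 'dichotomous'")
  if (model != "UIRT" &&
      (any(is.na(items$domain)) || any(!items$domain %in% seq_len(n_domains))))
    stop("domain must be an integer in 1..", n_domains)
  bmat <- intercept_matrix(items)
  for (j in seq_len(nrow(items))) {
    b <- bmat[j, seq_len(items$K[j] - 1)]
    if (any(!is.finite(b)))
      stop("item ", items$item_id[j], ": non-finite or missing intercepts")
    if (items$K[j] > 2 && any(diff(b) >= 0))
      stop("item ", items$item_id[j],
           ": graded intercepts must be strictly decreasing ",
           "(otherwise some category probabilities are negative)")
  }
  if (any(!is.finite(items$a0)) || any(!is.finite(items$av)))
    stop("non-finite slope parameters")
  if (model == "UIRT" && any(items$av != 0))
    stop("UIRT items must have av = 0")
  if (model == "MIRT" && any(items$a0 != 0))
    stop("MIRT items must have a0 = 0")
  invisible(items)
}

# K-1 intercepts of item row j as a matrix N_items x (Kmax-1)
intercept_matrix <- function(items) {
  bcols <- grep("^b[0-9]+$", names(items), value = TRUE)
  bcols <- bcols[order(as.integer(sub("b", "", bcols)))]
  as.matrix(items[, bcols, drop = FALSE])
}

# linear predictor a0*theta0 + av*theta_v for one item; theta layout depends
# on the model: FIBF c(theta0, theta1..thetaD), UIRT theta0, MIRT theta1..D.
item_predictor <- function(theta, item, model) {
  switch(model,
    FIBF = item$a0 * theta[1] + item$av * theta[1 + item$domain],
    UIRT = item$a0 * theta[1],
    MIRT = item$av * theta[item$domain]
  )
}

#' Response probability of a dichotomous (2PL) item
#'
#' Probability of a correct response under the bifactor two-parameter logistic
#' model: \eqn{P(X = 1 | \theta_0, \theta_v) = logit^{-1}(a_0\theta_0 +
#' a_v\theta_v + b)}. Under the UIRT constraint the specific term is absent;
#' under between-item MIRT the general term is absent.
#'
#' @param theta ability vector: \code{c(theta0, theta1..thetaD)} for FIBF,
#'   \code{theta0} for UIRT, \code{c(theta1..thetaD)} for MIRT.
#' @param item one-row item data frame or list with fields \code{item_type},
#'   \code{domain}, \code{a0}, \code{av}, \code{b1}.
#' @param model measurement model the ability vector refers to.
#' @return scalar probability in (0, 1).
#' @examples
#' it <- data.frame(item_id = "i1", item_type = "dichotomous", K = 2,
#'                  domain = 1, a0 = 1.2, av = 0.8, b1 = 0)
#' prob_dichotomous(c(0, 0, 0, 0, 0, 0), it)  # 0.5
#' @export
prob_dichotomous <- function(theta, item, model = c("FIBF", "UIRT", "MIRT")) {
  model <- match.arg(model)
  if (item$item_type != "dichotomous")
    stop("prob_dichotomous() called on a graded item; use prob_graded()")
  if (any(!is.finite(theta)) || !is.finite(item$a0) || !is.finite(item$av) ||
      !is.finite(item$b1))
    stop("non-finite ability or item parameters")
  plogis(item_predictor(theta, item, model) + item$b1)
}

#' Category probabilities of a graded item
#'
#' Category probabilities of the bifactor graded response model, obtained from
#' the cumulative logistic curves \eqn{P(X \ge k) = logit^{-1}(a_0\theta_0 +
#' a_v\theta_v + b_k)}, k = 1..K-1, with \eqn{P(X \ge 0) = 1} and
#' \eqn{P(X \ge K) = 0}; the category probability is the difference of
#' adjacent cumulative probabilities. Intercepts must be strictly decreasing
#' in k, which makes the cumulative curves nested and every category
#' probability nonnegative.
#'
#' @inheritParams prob_dichotomous
#' @return numeric vector of length K: \code{(P(X=0), ..., P(X=K-1))},
#'   summing to 1.
#' @examples
#' it <- data.frame(item_id = "g1", item_type = "graded", K = 3, domain = 1,
#'                  a0 = 0, av = 0, b1 = 1, b2 = -1)
#' prob_graded(rep(0, 6), it)  # (0.2689, 0.4621, 0.2689)
#' @export
prob_graded <- function(theta, item, model = c("FIBF", "UIRT", "MIRT")) {
  model <- match.arg(model)
  if (item$item_type != "graded")
    stop("prob_graded() called on a dichotomous item; use prob_dichotomous()")
  K <- item$K
  b <- as.numeric(item[paste0("b", seq_len(K - 1))])
  if (any(!is.finite(theta)) || any(!is.finite(b)))
    stop("non-finite ability or item parameters")
  if (K > 2 && any(diff(b) >= 0))
    stop("item ", item$item_id, ": graded intercepts must be strictly ",
         "decreasing")
  eta <- item_predictor(theta, item, model)
  cum <- c(1, plogis(eta + b), 0)
  -diff(cum)
}

#' Conditional log-likelihood of one person's responses
#'
#' Sum of log category probabilities over the observed items only, at a fixed
#' ability vector (local independence). Missing responses (NA) contribute
#' nothing.
#'
#' @param responses integer vector of category codes (0-based), NA = missing,
#'   aligned with the rows of \code{items}.
#' @param items item parameter table (see \code{\link{validate_item_params}}).
#' @param theta ability vector (layout per \code{model}).
#' @param model measurement model.
#' @return scalar log-likelihood; 0 when all responses are missing.
#' @export
loglik_person <- function(responses, items, theta,
                          model = c("FIBF", "UIRT", "MIRT")) {
  model <- match.arg(model)
  if (length(responses) != nrow(items))
    stop("responses must align with the item table")
  ll <- 0
  for (j in seq_along(responses)) {
    x <- responses[j]
    if (is.na(x)) next
    it <- items[j, ]
    if (x < 0 || x >= it$K)
      stop("item ", it$item_id, ": response code ", x,
           " outside 0..", it$K - 1)
    p <- if (it$item_type == "dichotomous") {
      pr <- prob_dichotomous(theta, it, model)
      if (x == 1) pr else 1 - pr
    } else {
      prob_graded(theta, it, model)[x + 1]
    }
    ll <- ll + log(p)
  }
  ll
}
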