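test_that("dichotomous response probability follows the bifactor 2PL", {
  it <- data.frame(item_id = "d", item_type = "dichotomous", K = 2L,
                   domain = 1L, a0 = 1.2, av = 0.8, b1 = 0)
  expect_equal(prob_dichotomous(rep(0, 6), it), 0.5)

  it2 <- transform(it, a0 = 1, av = 1, b1 = -2)
  expect_equal(prob_dichotomous(c(1, 1, 0, 0, 0, 0), it2), 0.5)

  it3 <- transform(it, a0 = 2, av = 1, b1 = 0.3)
  expect_equal(prob_dichotomous(c(0.5, -0.5, 0, 0, 0, 0), it3),
               plogis(0.8), tolerance = 1e-12)
  expect_equal(plogis(0.8), 0.6899744811, tolerance = 1e-9)

  # stable far into the tails
  it4 <- transform(it, a0 = 100, av = 100, b1 = 100)
  expect_equal(prob_dichotomous(c(2, 2, 0, 0, 0, 0), it4), 1)
  expect_gte(prob_dichotomous(c(-3, -3, 0, 0, 0, 0), it4), 0)

  expect_error(prob_dichotomous(c(NaN, 0, 0, 0, 0, 0), it), "non-finite")
  g <- tiny_items()[3, ]
  expect_error(prob_dichotomous(rep(0, 6), g), "graded")
})

test_that("graded category probabilities difference the cumulative curves", {
  it <- data.frame(item_id = "g", item_type = "graded", K = 3L, domain = 1L,
                   a0 = 0, av = 0, b1 = 1, b2 = -1)
  p <- prob_graded(rep(0.7, 6), it)  # slopes 0: theta irrelevant
  expect_equal(p, c(1 - plogis(1), plogis(1) - plogis(-1), plogis(-1)),
               tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.2689, 0.4621, 0.2689))

  bad <- transform(it, b1 = -1, b2 = 1)   # increasing: P(X>=2) > P(X>=1)
  expect_error(prob_graded(rep(0, 6), bad), "decreasing")
  expect_error(validate_item_params(rbind(tiny_items(),
                                          transform(tiny_items()[3, ],
                                                    b1 = -2, b2 = 0)),
                                    "FIBF"), "g1")
})

test_that("category probabilities sum to 1 and match the hand oracle on a grid", {
  set.seed(101)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    b <- sort(runif(K - 1, -2, 2), decreasing = TRUE)
    it <- data.frame(item_id = "x",
                     item_type = if (K == 2) "dichotomous" else "graded",
                     K = K, domain = sample(5, 1),
                     a0 = runif(1, 0.2, 2.5), av = runif(1, 0, 1.5))
    for (k in seq_len(K - 1)) it[[paste0("b", k)]] <- b[k]
    for (t0 in c(-4, -1, 0, 2, 4)) for (tv in c(-4, 0, 3)) {
      th <- rep(0, 6); th[1] <- t0; th[1 + it$domain] <- tv
      p <- if (K == 2) {
        pr <- prob_dichotomous(th, it); c(1 - pr, pr)
      } else prob_graded(th, it)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
      expect_lt(max(abs(p - oracle_item_prob(t0, tv, it$a0, it$av, b))),
                1e-10)
    }
  }
})

test_that("probabilities increase in each ability when its slope is positive", {
  it <- tiny_items()[1, ]
  th_grid <- seq(-4, 4, by = 0.5)
  p0 <- vapply(th_grid, function(t0)
    prob_dichotomous(c(t0, 0, 0, 0, 0, 0), it), numeric(1))
  expect_true(all(diff(p0) > 0))
  g <- tiny_items()[3, ]
  cum2 <- vapply(th_grid, function(tv)
    sum(prob_graded(c(0, tv, 0, 0, 0, 0), g)[2:3]), numeric(1))
  expect_true(all(diff(cum2) > 0))
})

test_that("UIRT and MIRT probabilities are the constrained bifactor cases", {
  it <- tiny_items()[1, ]
  th <- c(0.8, -0.3, 0, 0, 0, 0)
  u <- transform(it, av = 0)
  expect_equal(prob_dichotomous(th[1], u, model = "UIRT"),
               prob_dichotomous(th, u, model = "FIBF"))
  m <- transform(it, a0 = 0)
  expect_equal(prob_dichotomous(th[-1], m, model = "MIRT"),
               prob_dichotomous(th, m, model = "FIBF"))
  # graded with K = 2 worth of categories reduces to the 2PL
  g2 <- data.frame(item_id = "k2", item_type = "graded", K = 2L,
                   domain = 1L, a0 = it$a0, av = it$av, b1 = it$b1)
  pg <- tryCatch(prob_graded(th, transform(g2, item_type = "graded")),
                 error = function(e) NULL)
  # K = 2 items are canonically dichotomous; the algebraic identity is
  # P(X = 1) = logistic(eta + b1) either way
  expect_equal(prob_dichotomous(th, it),
               plogis(it$a0 * th[1] + it$av * th[2] + it$b1))
})

test_that("person log-likelihood sums observed log-probabilities only", {
  items <- tiny_items()
  th <- c(0.5, -0.5, 0.2, 0, 0, 0)
  expect_identical(loglik_person(rep(NA_integer_, 4), items, th), 0)
  one <- data.frame(item_id = "d", item_type = "dichotomous", K = 2L,
                    domain = 1L, a0 = 0, av = 0, b1 = 0)
  expect_equal(loglik_person(1L, one, rep(0, 6)), log(0.5))

  two <- rbind(
    data.frame(item_id = "a", item_type = "dichotomous", K = 2L, domain = 1L,
               a0 = 2, av = 1, b1 = 0.3, b2 = NA),
    data.frame(item_id = "b", item_type = "graded", K = 3L, domain = 2L,
               a0 = 0, av = 0, b1 = 1, b2 = -1))
  th2 <- c(0.5, -0.5, 0, 0, 0, 0)
  expect_equal(loglik_person(c(1L, 2L), two, th2),
               log(plogis(0.8)) + log(plogis(-1)), tolerance = 1e-10)
  expect_error(loglik_person(c(1L, 3L), two, th2), "outside")
})

test_that("item parameter tables round-trip through CSV and JSON", {
  items <- tiny_items()
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_item_params(items, csv, n_domains = 5)
  back <- read_item_params(csv, "FIBF")
  expect_equal(back$a0, items$a0, tolerance = 1e-12)
  expect_equal(back$av, items$av, tolerance = 1e-12)
  expect_equal(back$b2, items$b2, tolerance = 1e-12)
  expect_identical(back$item_id, items$item_id)
  write_item_params_json(items, js, n_domains = 5)
  back2 <- read_item_params_json(js, "FIBF")
  expect_equal(back2$av, items$av, tolerance = 1e-9)
  # exactly-one-nonzero specific slope is enforced on read
  ext <- read.csv(csv)
  ext$a3 <- 0.5
  write.csv(ext, csv, row.names = FALSE)
  expect_error(read_item_params(csv, "FIBF"), "exactly one")
})
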