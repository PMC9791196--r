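test_that("generating parameter draws follow the condition distributions", {
  d <- build_design(n_persons = 10)
  set.seed(2024)
  draws <- do.call(rbind, lapply(1:200, function(i) {
    p <- sim_item_params("FIBF", d)
    data.frame(a0 = p$a0, av = p$av)
  }))
  expect_true(all(draws$a0 >= 0.5 & draws$a0 <= 2.5))
  expect_true(all(draws$av >= 0 & draws$av <= 1.5))
  expect_equal(mean(draws$a0), 1.5, tolerance = 0.01)
  expect_equal(mean(draws$av), 0.75, tolerance = 0.01)

  # graded pairs, canonically reordered: b1 > b2 and b1 - b2 in (0, 2]
  set.seed(11)
  for (i in 1:50) {
    p <- sim_item_params("FIBF", d)
    g <- p[p$item_type == "graded", ]
    expect_true(all(g$b1 > g$b2))
    expect_true(all(g$b1 - g$b2 <= 2))
    expect_true(all(g$b1 <= 0 + 2))  # b1 = max(u1, u2) <= u1 + 2 <= 2
  }

  u <- sim_item_params("UIRT", d)
  expect_true(all(u$av == 0))
  m <- sim_item_params("MIRT", d)
  expect_true(all(m$a0 == 0))
  expect_true(all(m$av >= 0.5 & m$av <= 2.5))
})

test_that("ability draws have the specified latent covariance structure", {
  set.seed(5)
  ab <- sim_abilities("FIBF", 60000, 5)
  cc <- cor(ab$theta)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.02))
  expect_equal(unname(apply(ab$theta, 2, sd)), rep(1, 6), tolerance = 0.02)

  mm <- sim_abilities("MIRT", 60000, 5)
  off <- mm$Sigma[upper.tri(mm$Sigma)]
  expect_true(all(off >= 0.4 & off <= 0.8))
  expect_true(min(eigen(mm$Sigma, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)
  expect_equal(cor(mm$theta)[upper.tri(mm$Sigma)], off, tolerance = 0.03)

  one <- sim_abilities("UIRT", 1)
  expect_true(is.finite(one$theta[1, 1]))

  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(sim_abilities("MIRT", 10, 5, Sigma = bad),
               "positive definite")
})

test_that("simulated responses respect the design mask and the model", {
  d <- build_design(n_persons = 120)
  sim <- sim_study("FIBF", d, seed = 4)
  inc <- bifactorirt:::design_incidence(d)
  expect_identical(unname(!is.na(sim$responses)), inc)
  for (j in seq_len(d$M))
    expect_true(all(sim$responses[, j] < d$items$K[j], na.rm = TRUE))

  # deterministic item: predictor forced far positive gives all 1s
  items <- sim$items
  items$a0 <- 0; items$av <- 0; items$b1[1] <- 30
  th <- sim_abilities("FIBF", 120, 5)$theta
  X <- sim_responses(items, th, d, "FIBF")
  expect_true(all(X[!is.na(X[, 1]), 1] == 1L))
})

test_that("marginal response frequencies match the quadrature integral", {
  # one dichotomous bifactor item answered by everyone
  n <- 50000
  it <- data.frame(item_id = "i", item_type = "dichotomous", K = 2L,
                   domain = 1L, a0 = 1, av = 0.5, b1 = 0)
  d <- list(n_booklets = 1L, M = 1L, N = n, n_domains = 5L,
            items = it, booklet_items = list(1L),
            person_booklet = rep(1L, n))
  class(d) <- "test_design"
  set.seed(77)
  th <- sim_abilities("FIBF", n, 5)$theta
  X <- sim_responses(it, th, d, "FIBF")
  q <- gh_quadrature(41)
  pint <- sum(outer(q$weights, q$weights) *
                plogis(outer(q$nodes * 1, q$nodes * 0.5, "+")))
  expect_equal(mean(X[, 1]), pint, tolerance = 0.005)
})

test_that("identical seeds give bit-identical simulated studies", {
  d <- build_design(n_persons = 90)
  s1 <- sim_study("MIRT", d, seed = 123)
  s2 <- sim_study("MIRT", d, seed = 123)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$items, s2$items)
  expect_identical(s1$Sigma, s2$Sigma)
  s3 <- sim_study("MIRT", d, seed = 124)
  expect_false(identical(s1$responses, s3$responses))
})
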