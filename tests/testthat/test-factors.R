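random_corr <- function(p, k, seed) {
  set.seed(seed)
  L <- matrix(runif(p * k, -0.6, 0.6), p, k)
  L <- L / pmax(1, sqrt(rowSums(L^2)) / 0.9)   # communalities below 1
  R <- tcrossprod(L) + diag(1 - rowSums(L^2))
  list(R = R, L = L)
}

test_that("an exact factor structure is recovered to machine precision", {
  g <- random_corr(10, 1, 1)
  sol <- fit_minres(g$R, 1)
  expect_lt(sol$objective, 1e-12)
  expect_lt(max(abs(abs(sol$loadings) - abs(g$L))), 1e-6)
  expect_equal(unname(sol$uniquenesses),
               unname(1 - rowSums(g$L^2)), tolerance = 1e-5)
})

test_that("an identity correlation matrix yields null loadings", {
  sol <- fit_minres(diag(8), 1)
  expect_lt(max(abs(sol$loadings)), 1e-4)
})

test_that("minres matches an independent general-purpose minimizer", {
  # oracle: nlminb with numerical derivatives over the same objective,
  # restarted from several random points
  for (seed in 1:3) {
    g <- random_corr(6, 2, seed + 40)
    # perturb so the minimum is not exactly zero
    set.seed(seed)
    E <- matrix(rnorm(36, 0, 0.03), 6); E <- (E + t(E)) / 2; diag(E) <- 0
    R <- g$R + E
    sol <- fit_minres(R, 2)
    obj <- function(l) {
      La <- matrix(l, 6, 2); D <- R - tcrossprod(La); diag(D) <- 0; sum(D^2)
    }
    set.seed(seed + 100)
    oracle <- min(vapply(1:5, function(i)
      nlminb(runif(12, -0.7, 0.7), obj,
             control = list(iter.max = 2000, rel.tol = 1e-15))$objective,
      numeric(1)))
    expect_lt(abs(sol$objective - oracle), 1e-8)
  }
})

test_that("invalid correlation inputs are refused", {
  R <- diag(5); R[1, 2] <- 0.5                 # asymmetric
  expect_error(fit_minres(R, 1), "symmetric")
  expect_error(fit_minres(diag(5) * 2, 1), "unit diagonal")
  expect_error(fit_minres(diag(5), 5), "k must satisfy")
  expect_error(fit_minres(diag(5), 0), "k must satisfy")
})

test_that("varimax is a sign change for one factor and fixes simple structure", {
  L <- matrix(-seq(0.1, 0.9, length.out = 6), 6, 1)
  out <- varimax_rotate(L)
  expect_equal(abs(out), abs(L), ignore_attr = TRUE)
  expect_gt(out[which.max(abs(out)), 1], 0)
  # perfect simple structure: one nonzero per row, already optimal
  S <- rbind(c(0.8, 0), c(0.7, 0), c(0, 0.6), c(0, 0.5))
  out2 <- varimax_rotate(S)
  expect_equal(abs(out2), abs(S), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("varimax preserves the common factor space and communalities", {
  set.seed(5)
  for (i in 1:5) {
    L <- matrix(rnorm(30, 0, 0.4), 10, 3)
    out <- varimax_rotate(L)
    expect_lt(max(abs(tcrossprod(out) - tcrossprod(L))), 1e-10)
    # the (Kaiser-normalized) varimax criterion does not decrease
    crit <- function(M) {
      M <- M / sqrt(rowSums(M^2))
      sum(apply(M^2, 2, var))
    }
    expect_gte(crit(out) + 1e-12, crit(L))
  }
})

test_that("the scree elbow heuristic behaves on canonical profiles", {
  r <- retain_k(c(10, rep(1, 8)))
  expect_equal(r$suggested_k, 1L)
  expect_true(r$clear_elbow)
  expect_equal(nrow(r$scree), 9)
  # monotone geometric decay: heuristic picks k = 1, flagged unclear
  gdec <- 2 * 0.8^(0:9)
  r2 <- retain_k(gdec)
  expect_equal(r2$suggested_k, 1L)
  expect_false(r2$clear_elbow)
  # replication override wins regardless of the heuristic
  r3 <- retain_k(gdec, k_override = 5)
  expect_equal(r3$k, 5L)
  expect_error(retain_k(c(1, 2, 3)), "decreasing")
})

test_that("adherence scores standardize at baseline and carry scaling forward", {
  L <- reference_loadings()
  X <- generate_foodgroups(200, L, mode = "positive", seed = 4)
  base <- as.data.frame(X)
  ad <- adherence_scores(L, base)
  sc <- as.matrix(ad$scores)
  expect_equal(unname(colMeans(sc)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # zero intake: raw score 0, standardized = -mean/sd
  zero <- as.data.frame(matrix(0, 1, 28,
                               dimnames = list(NULL, colnames(X))))
  z <- adherence_scores(L, zero, scaling = ad$scaling)$scores
  expect_equal(unname(as.numeric(z)),
               unname(-ad$scaling$mean / ad$scaling$sd))
  # follow-up standardized with baseline parameters on a 3-row fixture
  fu <- as.data.frame(X[1:3, ] * 1.3)
  got <- as.matrix(adherence_scores(L, fu, scaling = ad$scaling)$scores)
  hand <- sweep(sweep(as.matrix(fu) %*% L, 2, ad$scaling$mean),
                2, ad$scaling$sd, `/`)
  colnames(hand) <- colnames(got)
  expect_equal(got, hand, ignore_attr = TRUE)
  expect_gt(max(abs(colMeans(got))), 1e-3)   # generally not mean zero
})

test_that("adherence scoring names offending food groups", {
  L <- reference_loadings()
  tbl <- as.data.frame(generate_foodgroups(5, L, seed = 1))
  tbl$fg_fruit <- NULL
  expect_error(adherence_scores(L, tbl), "fruit")
})

test_that("scaling parameters survive a JSON round trip", {
  L <- reference_loadings()
  X <- as.data.frame(generate_foodgroups(50, L, mode = "positive", seed = 2))
  ad <- adherence_scores(L, X)
  p <- withr::local_tempfile(fileext = ".json")
  write_scaling(ad$scaling, p)
  back <- read_scaling(p)
  expect_equal(back$mean, ad$scaling$mean, tolerance = 1e-12)
  expect_equal(back$sd, ad$scaling$sd, tolerance = 1e-12)
  s1 <- adherence_scores(L, X[1:4, ], scaling = back)$scores
  s2 <- adherence_scores(L, X[1:4, ], scaling = ad$scaling)$scores
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("factor matching finds the permutation and signs", {
  L <- reference_loadings()
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- L[, perm] %*% diag(c(1, -1, 1, -1, 1))
  m <- match_factors(shuffled, L)
  expect_equal(unname(m$congruence), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(m$matched), unname(L), tolerance = 1e-12)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(tucker_congruence(c(1, 2), c(2, 4)), 1)
})
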