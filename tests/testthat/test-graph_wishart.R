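test_that("prior log density: constraint set and unconstrained mode", {
  d <- tiny_data(p = 3, n = 4)
  g_null <- feature_graph(NULL, d)
  eta <- 2; eps <- 0.5
  # non-zero entry where the graph has no edge
  Om <- diag(3); Om[1, 2] <- Om[2, 1] <- 0.3
  expect_identical(log_prior_omega(Om, g_null, eta, eps), -Inf)
  # not positive definite
  g_full <- feature_graph(cbind(c(1, 1, 2), c(2, 3, 3)), d)
  bad <- matrix(0.9, 3, 3); diag(bad) <- c(1, 1, 0.1)
  expect_identical(log_prior_omega(bad, g_full, eta, eps), -Inf)
  # unconstrained mode: Omega* = ((11^T + eps I)/(1+eps))^-1, so the
  # off-diagonals of Omega*^-1 sit at 1/(1+eps)
  E <- matrix(1, 3, 3) + 0.1 * diag(3)
  mode_om <- solve(E / 1.1)
  expect_equal(solve(mode_om)[1, 2], 1 / 1.1, tolerance = 1e-10)
  lp0 <- log_prior_omega(mode_om, g_full, eta, 0.1)
  set.seed(1)
  for (k in 1:20) {
    pert <- matrix(rnorm(9, 0, 0.05), 3, 3)
    pert <- (pert + t(pert)) / 2
    expect_lt(log_prior_omega(mode_om + pert, g_full, eta, 0.1), lp0)
  }
})

test_that("isolated-node diagonal draw is Gamma with the stated moments", {
  # eta = 2, eps = 0.5, L = 2, a_jj = 4: shape 3.5, rate 2, mean 1.75
  d <- tiny_data(p = 1, n = 4)
  g <- feature_graph(NULL, d)
  hp <- bgb_hyperparameters(nu1 = 0, nu2 = 1, eta = 2, epsilon = 0.5)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, epsilon = 0.5)
  # a_jj = eta(1+eps) + (1/nu2) sum_l alpha~^2 = 3 + 1 = 4
  st$alpha <- matrix(c(1, 0), 1, 2)
  set.seed(2)
  draws <- replicate(4e3, sample_omega(st, g, hp)$Omega[1, 1])
  expect_equal(mean(draws), 3.5 / 2, tolerance = 0.04)
  expect_gt(stats::ks.test(draws, stats::pgamma, shape = 3.5,
                           rate = 2)$p.value, 0.01)
})

test_that("two-node chain matches the grid-normalized target density", {
  d <- tiny_data(p = 2, n = 4)
  g <- feature_graph(cbind(1, 2), d)
  hp <- bgb_hyperparameters(nu1 = 0, nu2 = 0.5, eta = 3, epsilon = 0.4)
  wl <- build_working_likelihood(d)
  L <- 2
  st <- tiny_state(wl, L = L, graph = g)
  st$alpha <- matrix(c(0.4, -0.3, 0.1, 0.5), 2, L)
  # fixed alpha -> fixed A; the Omega chain should reach the density
  # |Omega|^((Delta+L)/2) exp(-tr(A Omega)/2) on the PD cone
  At <- st$alpha - hp$nu1
  A <- hp$eta * (matrix(1, 2, 2) + hp$epsilon * diag(2)) +
    (At %*% t(At)) / hp$nu2
  Delta <- hp$eta * (1 + hp$epsilon)
  ex <- (Delta + L) / 2
  # 3-d grid oracle over (o11, o22, o12)
  o11 <- seq(0.02, 12, length.out = 70)
  o22 <- seq(0.02, 12, length.out = 70)
  o12 <- seq(-6, 6, length.out = 71)
  gr <- expand.grid(o11 = o11, o22 = o22, o12 = o12)
  det_g <- gr$o11 * gr$o22 - gr$o12^2
  lw <- rep(-Inf, nrow(gr))
  pos <- det_g > 0
  lw[pos] <- ex * log(det_g[pos]) -
    0.5 * (A[1, 1] * gr$o11[pos] + A[2, 2] * gr$o22[pos] +
             2 * A[1, 2] * gr$o12[pos])
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  om11 <- sum(w * gr$o11); om12 <- sum(w * gr$o12)
  sd11 <- sqrt(sum(w * gr$o11^2) - om11^2)
  sd12 <- sqrt(sum(w * gr$o12^2) - om12^2)
  set.seed(3)
  s <- st
  keep11 <- keep12 <- numeric(2000)
  for (it in 1:200) s <- sample_omega(s, g, hp) # burn-in
  for (it in 1:2000) {
    s <- sample_omega(s, g, hp)
    keep11[it] <- s$Omega[1, 1]
    keep12[it] <- s$Omega[1, 2]
  }
  expect_lt(abs(mean(keep11) - om11), 5 * sd11 / sqrt(300))
  expect_lt(abs(mean(keep12) - om12), 5 * sd12 / sqrt(300))
  expect_lt(abs(sd(keep11) - sd11), 0.15 * sd11)
  expect_lt(abs(sd(keep12) - sd12), 0.15 * sd12)
})

test_that("Sigma cache stays an exact inverse under rank-one updates", {
  set.seed(4)
  d <- tiny_data(p = 3, n = 5)
  g <- feature_graph(cbind(c(1, 2), c(2, 3)), d)
  hp <- bgb_hyperparameters(eta = 4, epsilon = 0.3)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, graph = g)
  st <- sample_omega(st, g, hp)
  expect_lt(max(abs(st$Sigma %*% st$Omega - diag(3))), 1e-8)
  expect_equal(st$Sigma, solve(st$Omega), tolerance = 1e-8)
  # diagonal Omega on the null graph: Sigma is the elementwise reciprocal
  gn <- feature_graph(NULL, d)
  stn <- tiny_state(wl, L = 2)
  stn <- sample_omega(stn, gn, hp)
  expect_equal(stn$Sigma, diag(1 / diag(stn$Omega)), tolerance = 1e-12)
})

test_that("cache error does not accumulate over a thousand sweeps", {
  set.seed(5)
  p <- 20
  d <- tiny_data(p = p, n = 4)
  em <- t(utils::combn(p, 2))
  em <- em[sample(nrow(em), 40), ]
  g <- feature_graph(em, d)
  hp <- bgb_hyperparameters(eta = 5, epsilon = 0.2)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, graph = g)
  gi <- bgb:::graph_info(g)
  for (it in 1:1000)
    st[c("Omega", "Sigma")] <- cpp_step_omega(
      st, gi, bgb:::hyper_for_cpp(hp), FALSE)[c("Omega", "Sigma")]
  expect_lt(max(abs(st$Sigma - solve(st$Omega))), 1e-6)
  # positive definiteness and the zero pattern are conserved exactly
  expect_true(all(eigen(st$Omega, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  adj <- as.matrix(g$adjacency) != 0
  off <- !diag(p)
  expect_true(all(st$Omega[off & !adj] == 0))
})

test_that("components are independent blocks: zeros conserved, no leakage", {
  set.seed(6)
  d <- tiny_data(p = 6, n = 4)
  # two components: {1,2,3} and {4,5}
  g <- feature_graph(cbind(c(1, 2, 4), c(2, 3, 5)), d)
  hp <- bgb_hyperparameters(eta = 3, epsilon = 0.2)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, graph = g)
  gi <- bgb:::graph_info(g)
  out <- withr::with_seed(9, cpp_step_omega(st, gi,
                                            bgb:::hyper_for_cpp(hp), FALSE))
  # cross-component entries exactly zero in Omega and Sigma
  expect_true(all(out$Omega[1:3, 4:6] == 0))
  expect_true(all(out$Sigma[1:3, 4:6] == 0))
  # perturbing the second block's alpha leaves the first block's draw
  # untouched (components are sampled in order from the same RNG stream)
  st2 <- st
  st2$alpha[4:5, ] <- st2$alpha[4:5, ] + 1
  out2 <- withr::with_seed(9, cpp_step_omega(st2, gi,
                                             bgb:::hyper_for_cpp(hp), FALSE))
  expect_identical(out$Omega[1:3, 1:3], out2$Omega[1:3, 1:3])
  expect_false(identical(out$Omega[4:6, 4:6], out2$Omega[4:6, 4:6]))
})

test_that("null-graph stationary diagonals match independent Gamma draws", {
  d <- tiny_data(p = 4, n = 4)
  g <- feature_graph(NULL, d)
  hp <- bgb_hyperparameters(nu1 = 0, nu2 = 0.5, eta = 2, epsilon = 0.5)
  wl <- build_working_likelihood(d)
  L <- 2
  st <- tiny_state(wl, L = L)
  set.seed(7)
  draws <- replicate(2000, sample_omega(st, g, hp)$Omega[2, 2])
  At <- st$alpha - hp$nu1
  ajj <- hp$eta * (1 + hp$epsilon) + sum(At[2, ]^2) / hp$nu2
  shape <- (hp$eta * (1 + hp$epsilon) + L) / 2 + 1
  ref <- rgamma(2000, shape, rate = ajj / 2)
  expect_gt(stats::ks.test(draws, ref)$p.value, 0.01)
})
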