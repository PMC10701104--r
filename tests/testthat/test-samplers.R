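test_that("W-row conditional: flat-prior limit and prior recovery", {
  d <- tiny_data(p = 1, n = 1)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 1)
  st$rho <- matrix(1, 1, 1)
  st$Z <- matrix(1, 1, 1)
  st$tau_w_sq <- matrix(1e12, 1, 1)
  mo <- w_row_moments(1, st, wl)
  expect_equal(mo$mean, wl$psi[1, 1] - st$m[1] + wl$kappa[1, 1],
               tolerance = 1e-6)
  # all-zero Z: the conditional reverts to the prior N(0, D_tau)
  d2 <- tiny_data(p = 2, n = 6)
  wl2 <- build_working_likelihood(d2)
  st2 <- tiny_state(wl2, L = 2)
  st2$Z <- matrix(0, 2, 6)
  mo2 <- w_row_moments(1, st2, wl2)
  expect_equal(mo2$mean, c(0, 0))
  expect_equal(mo2$cov, diag(st2$tau_w_sq[1, ]), tolerance = 1e-10)
})

test_that("W-row moments and draws match the dense-formula oracle", {
  d <- tiny_data(p = 4, n = 3, seed = 9)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, seed = 10)
  for (j in 1:4) {
    orc <- oracle_w_row_moments(j, st, wl)
    mo <- w_row_moments(j, st, wl)
    expect_equal(mo$mean, orc$mean, tolerance = 1e-10)
    expect_equal(mo$cov, orc$cov, tolerance = 1e-10)
  }
  set.seed(11)
  draws <- t(replicate(2e4, cpp_step_w(st, wl)$W[2, ]))
  orc <- oracle_w_row_moments(2, st, wl)
  expect_lt(max(abs(colMeans(draws) - orc$mean)), 0.02)
  expect_lt(max(abs(cov(draws) - orc$cov)), 0.02)
})

test_that("tau_w: inverse-Gaussian mean, prior fallback, shrinkage", {
  d <- tiny_data(p = 1, n = 2)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 1)
  st$alpha <- matrix(log(2), 1, 1) # lambda = 2
  st$W <- matrix(1, 1, 1)
  set.seed(12)
  inv_draws <- replicate(2e4, 1 / cpp_step_tau_w(st)$tau_w_sq[1, 1])
  expect_equal(mean(inv_draws), 2, tolerance = 0.03) # IG mean = |lambda/w|
  # w = 0 falls back to the prior Exp(lambda^2/2), mean 2/lambda^2
  st0 <- st; st0$W <- matrix(0, 1, 1)
  tz <- replicate(2e4, cpp_step_tau_w(st0)$tau_w_sq[1, 1])
  expect_equal(mean(tz), 2 / 4, tolerance = 0.02)
  # larger lambda shrinks tau stochastically
  med <- vapply(c(1, 10, 100), function(lam) {
    s <- st; s$alpha <- matrix(log(lam), 1, 1)
    median(replicate(2e3, cpp_step_tau_w(s)$tau_w_sq[1, 1]))
  }, 0)
  expect_true(all(diff(med) < 0))
})

test_that("scale-mixture identity: mixing tau^2 out recovers the Laplace", {
  set.seed(13)
  lam <- 1.7
  tau2 <- r_tau_w_prior(rep(lam, 1e5))
  w <- rnorm(1e5, 0, sqrt(tau2))
  plap <- function(q) ifelse(q < 0, 0.5 * exp(lam * q),
                             1 - 0.5 * exp(-lam * q))
  expect_gt(stats::ks.test(w, plap)$p.value, 0.01)
})

test_that("alpha MH: unit acceptance in the small-step limit and
           stationarity against a grid oracle", {
  d <- tiny_data(p = 1, n = 2)
  g <- feature_graph(NULL, d)
  hp <- bgb_hyperparameters(nu1 = 0.3, nu2 = 0.8)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 1)
  st$tau_w_sq <- matrix(0.6, 1, 1)
  omega <- 1.4
  st$Omega <- matrix(omega, 1, 1); st$Sigma <- matrix(1 / omega, 1, 1)
  set.seed(14)
  acc <- sum(replicate(200, mh_update_alpha(st, g, hp, q = 1e-12)$naccept))
  expect_equal(acc, 200)
  # stationary distribution vs numerically normalized 1-d target
  agrid <- seq(-6, 4, length.out = 4001)
  lt <- 2 * agrid - exp(2 * agrid) * st$tau_w_sq[1, 1] / 2 -
    (agrid - hp$nu1)^2 * omega / (2 * hp$nu2)
  wgt <- exp(lt - max(lt)); wgt <- wgt / sum(wgt)
  target_cdf <- cumsum(wgt)
  set.seed(15)
  s <- st
  for (it in 1:200) s$alpha <- mh_update_alpha(s, g, hp, q = 1)$alpha
  keep <- numeric(3000)
  for (it in 1:3000) {
    for (k in 1:12) s$alpha <- mh_update_alpha(s, g, hp, q = 1)$alpha
    keep[it] <- s$alpha[1, 1]
  }
  emp_cdf <- stats::ecdf(keep)
  expect_lt(max(abs(emp_cdf(agrid) - target_cdf)), 0.03)
  gm <- sum(wgt * agrid)
  gs <- sqrt(sum(wgt * agrid^2) - gm^2)
  expect_lt(abs(mean(keep) - gm), 5 * gs / sqrt(500))
})

test_that("alpha MH on a connected pair shows the graph-implied coupling", {
  d <- tiny_data(p = 2, n = 2)
  g <- feature_graph(cbind(1, 2), d)
  hp <- bgb_hyperparameters(nu1 = 0, nu2 = 0.5)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 1)
  st$tau_w_sq <- matrix(0.5, 2, 1)
  st$Omega <- matrix(c(2, 1.4, 1.4, 2), 2, 2)
  st$Sigma <- solve(st$Omega)
  # 2-d grid oracle for the joint of (alpha_1, alpha_2)
  agrid <- seq(-5, 3, length.out = 201)
  gr <- expand.grid(a1 = agrid, a2 = agrid)
  lt <- with(gr,
    2 * a1 - exp(2 * a1) * 0.5 / 2 + 2 * a2 - exp(2 * a2) * 0.5 / 2 -
      (2 * a1^2 + 2 * a2^2 + 2 * 1.4 * a1 * a2) / (2 * hp$nu2))
  wgt <- exp(lt - max(lt)); wgt <- wgt / sum(wgt)
  m1 <- sum(wgt * gr$a1); m2 <- sum(wgt * gr$a2)
  cc <- (sum(wgt * gr$a1 * gr$a2) - m1 * m2) /
    sqrt((sum(wgt * gr$a1^2) - m1^2) * (sum(wgt * gr$a2^2) - m2^2))
  set.seed(16)
  s <- st
  for (it in 1:300) s$alpha <- mh_update_alpha(s, g, hp, q = 0.8)$alpha
  keep <- matrix(0, 4000, 2)
  for (it in 1:4000) {
    for (k in 1:5) s$alpha <- mh_update_alpha(s, g, hp, q = 0.8)$alpha
    keep[it, ] <- s$alpha[, 1]
  }
  sc <- cor(keep[, 1], keep[, 2])
  # positive precision coupling induces negative correlation
  expect_lt(cc, 0)
  expect_lt(sc, 0)
  expect_lt(abs(sc - cc), 0.1)
  expect_lt(abs(mean(keep[, 1]) - m1), 0.1)
})

test_that("Z-column conditional: prior recovery, oracle moments, symmetry", {
  d <- tiny_data(p = 3, n = 4, seed = 17)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, seed = 18)
  # all-zero W reverts to the prior N(0, tau^2/delta)
  st0 <- st; st0$W <- matrix(0, 3, 2)
  mo0 <- z_col_moments(2, st0, wl)
  expect_equal(mo0$mean, c(0, 0))
  expect_equal(mo0$cov, diag(st0$tau_z_sq[, 2] / st0$delta[, 2]),
               tolerance = 1e-10)
  for (i in 1:4) {
    orc <- oracle_z_col_moments(i, st, wl)
    mo <- z_col_moments(i, st, wl)
    expect_equal(mo$mean, orc$mean, tolerance = 1e-10)
    expect_equal(mo$cov, orc$cov, tolerance = 1e-10)
  }
  set.seed(19)
  draws <- t(replicate(2e4, cpp_step_z(st, wl)$Z[, 3]))
  orc <- oracle_z_col_moments(3, st, wl)
  expect_lt(max(abs(colMeans(draws) - orc$mean)), 0.02)
  expect_lt(max(abs(cov(draws) - orc$cov)), 0.02)
  # linearity: negating W alone (precision unchanged) negates the mean,
  # and so does negating the pseudo-data (psi, kappa, m) alone
  stn <- st
  stn$W <- -st$W
  mon <- z_col_moments(3, stn, wl)
  expect_equal(mon$mean, -orc$mean, tolerance = 1e-10)
  expect_equal(mon$cov, orc$cov, tolerance = 1e-10)
  wln <- wl
  wln$psi <- -wl$psi
  wln$kappa <- -wl$kappa
  std <- st
  std$m <- -st$m
  mod <- z_col_moments(3, std, wln)
  expect_equal(mod$mean, -orc$mean, tolerance = 1e-10)
})

test_that("factor scale/rate pair targets its exact stationary law", {
  # single-site chain on (tau^2, delta) with z fixed: stationary mean of
  # delta is checked against a 2-d quadrature oracle
  d <- tiny_data(p = 1, n = 1)
  wl <- build_working_likelihood(d)
  hp <- bgb_hyperparameters(nu3 = 1, nu4 = 1)
  st <- tiny_state(wl, L = 1)
  st$Z <- matrix(1, 1, 1)
  # oracle: pi(tau2, delta | z) ~ Gamma(nu4,nu3) x Exp(delta/2) x
  # N(z; 0, tau2/delta)
  t2 <- seq(0.001, 60, length.out = 1200)
  de <- seq(0.001, 25, length.out = 1200)
  gr <- expand.grid(t2 = t2, de = de)
  lw <- with(gr, (hp$nu4 - 1) * log(de) - hp$nu3 * de + log(de / 2) -
               de * t2 / 2 + 0.5 * (log(de) - log(t2)) - de / (2 * t2))
  wgt <- exp(lw - max(lw)); wgt <- wgt / sum(wgt)
  target_mean_delta <- sum(wgt * gr$de)
  set.seed(20)
  s <- st
  keep <- numeric(4000)
  for (it in 1:500) {
    upd <- sample_tau_z_and_delta(s, hp)
    s$tau_z_sq <- upd$tau_z_sq; s$delta <- upd$delta
  }
  for (it in 1:4000) {
    upd <- sample_tau_z_and_delta(s, hp)
    s$tau_z_sq <- upd$tau_z_sq; s$delta <- upd$delta
    keep[it] <- s$delta[1, 1]
  }
  expect_lt(abs(mean(keep) - target_mean_delta),
            0.05 * target_mean_delta)
  # arithmetic sanity of the Gamma conditional rate at nu4=1, nu3=1,
  # tau2=1, z=1: mean (nu4+1.5)/(nu3 + 1/2 + 1/2) = 1.25
  expect_equal((1 + 1.5) / (1 + 0.5 + 0.5), 1.25)
})

test_that("larger nu4 yields sparser factors", {
  set.seed(21)
  d <- tiny_data(p = 8, n = 6, seed = 22)
  wl <- build_working_likelihood(d)
  g <- feature_graph(NULL, d)
  med_abs_z <- vapply(c(1, 8, 32), function(nu4) {
    hp <- bgb_hyperparameters(nu3 = 1, nu4 = nu4)
    st <- tiny_state(wl, L = 2, seed = 23)
    zs <- numeric(300)
    for (it in 1:300) {
      st <- gibbs_sweep(st, wl, g, hp)
      zs[it] <- median(abs(st$Z))
    }
    median(zs[101:300])
  }, 0)
  expect_true(all(diff(med_abs_z) < 0))
})

test_that("location update: weighted-mean limit and prior domination", {
  d <- tiny_data(p = 3, n = 50, seed = 24)
  wl <- build_working_likelihood(d)
  st <- tiny_state(wl, L = 2, seed = 25)
  st$W <- matrix(0, 3, 2) # mu = m 1^T
  st$rho <- matrix(rep(runif(3, 0.5, 2), 50), 3, 50)
  hp_flat <- bgb_hyperparameters(sigma_m_sq = 1e10)
  set.seed(26)
  draws <- replicate(2e3, sample_m(st, wl, hp_flat))
  expect_lt(max(abs(rowMeans(draws) - rowMeans(wl$x))), 0.1)
  hp_tight <- bgb_hyperparameters(sigma_m_sq = 1e-10)
  draws0 <- replicate(100, sample_m(st, wl, hp_tight))
  expect_lt(max(abs(draws0)), 1e-3)
  # moments against the closed form for one feature
  j <- 2
  vm <- 1 / (1 / hp_flat$sigma_m_sq + sum(st$rho[j, ]))
  mean_j <- vm * sum(wl$kappa[j, ] - st$rho[j, ] * (0 - wl$psi[j, ]))
  expect_lt(abs(mean(draws[j, ]) - mean_j), 4 * sqrt(vm / 2e3))
})

test_that("full sweep passes a Geweke joint-distribution check", {
  # two connected gaussian features, two samples, one factor; Omega fixed.
  # Forward-prior simulation and successive-conditional simulation must
  # produce the same joint distribution of (data, parameters).
  p <- 2; n <- 2; L <- 1
  hp <- bgb_hyperparameters(nu1 = 0.2, nu2 = 0.7, nu3 = 1.2, nu4 = 2,
                            sigma_m_sq = 0.8, zeta = 3)
  Omega <- matrix(c(1.5, 0.6, 0.6, 1.5), 2, 2)
  Sigma <- solve(Omega)
  ids <- list(paste0("g", 1:p), paste0("s", 1:n))
  make_wl <- function(x) {
    dimnames(x) <- ids
    build_working_likelihood(bgb_multiview(bgb_view(x)), zeta = hp$zeta)
  }
  draw_forward <- function() {
    m <- rnorm(p, 0, sqrt(hp$sigma_m_sq))
    alpha <- matrix(hp$nu1 + t(chol(hp$nu2 * Sigma)) %*% rnorm(p), p, L)
    lam <- exp(alpha)
    tau_w_sq <- matrix(rexp(p * L, rate = as.vector(lam)^2 / 2), p, L)
    W <- matrix(rnorm(p * L, 0, sqrt(as.vector(tau_w_sq))), p, L)
    delta <- matrix(rgamma(L * n, hp$nu4, hp$nu3), L, n)
    tau_z_sq <- matrix(rexp(L * n, rate = as.vector(delta) / 2), L, n)
    Z <- matrix(rnorm(L * n, 0, sqrt(as.vector(tau_z_sq / delta))), L, n)
    rho_j <- rgamma(p, hp$zeta / 2, hp$zeta / 2)
    mu <- matrix(m, p, n) + W %*% Z
    x <- mu + matrix(rnorm(p * n, 0, 1), p, n) / sqrt(rho_j)
    list(m = m, W = W, Z = Z, alpha = alpha, tau_w_sq = tau_w_sq,
         tau_z_sq = tau_z_sq, delta = delta,
         rho = matrix(rho_j, p, n), Omega = Omega, Sigma = Sigma, x = x)
  }
  monitor <- function(s) c(
    m = mean(s$m), m2 = mean(s$m^2),
    w = mean(s$W), w2 = mean(s$W^2),
    z = mean(s$Z), z2 = mean(s$Z^2),
    a = mean(s$alpha), a2 = mean(s$alpha^2),
    d = mean(s$delta), x2 = mean(s$x^2))
  set.seed(27)
  NF <- 6000
  fwd <- t(vapply(seq_len(NF), function(k) monitor(draw_forward()),
                  numeric(10)))
  # successive-conditional: parameter sweep (Omega held fixed), then
  # re-draw the data given the parameters
  gi <- list(comps = list(0:1), nb = list(1L, 0L))
  hpc <- bgb:::hyper_for_cpp(hp)
  s <- draw_forward()
  wl <- make_wl(s$x)
  NS <- 12000; thin <- 4
  succ <- matrix(0, NS / thin, 10)
  for (it in seq_len(NS)) {
    st <- s[c("m", "W", "Z", "alpha", "tau_w_sq", "tau_z_sq", "delta",
              "rho", "Omega", "Sigma")]
    st$rho <- cpp_step_rho(st, wl)$rho
    st$m <- cpp_step_m(st, wl, hpc)$m
    st$W <- cpp_step_w(st, wl)$W
    st$tau_w_sq <- cpp_step_tau_w(st)$tau_w_sq
    st$alpha <- cpp_step_alpha(st, gi, hpc, 1.2)$alpha
    st$Z <- cpp_step_z(st, wl)$Z
    td <- cpp_step_tau_z_delta(st, hpc)
    st$tau_z_sq <- td$tau_z_sq; st$delta <- td$delta
    mu <- matrix(st$m, p, n) + st$W %*% st$Z
    x <- mu + matrix(rnorm(p * n), p, n) / sqrt(st$rho[, 1])
    s <- c(st, list(x = x))
    wl <- make_wl(x)
    if (it %% thin == 0) succ[it / thin, ] <- monitor(s)
  }
  # compare first/second moments, allowing for autocorrelation in the
  # successive chain via an effective sample size from the lag-k acf
  ess <- function(v) {
    ac <- stats::acf(v, lag.max = 50, plot = FALSE)$acf[-1]
    ac <- ac[seq_len(max(1, which(ac < 0.05)[1] - 1))]
    length(v) / (1 + 2 * sum(ac))
  }
  for (k in seq_len(10)) {
    se <- sqrt(var(fwd[, k]) / NF + var(succ[, k]) / ess(succ[, k]))
    expect_lt(abs(mean(fwd[, k]) - mean(succ[, k])), 5 * se)
  }
})
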