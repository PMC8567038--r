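stationary_epochs <- function(A, n_trials, n_samples, seed, fs = 25) {
  if (is.matrix(A)) A <- list(A)
  n <- nrow(A[[1]])
  win <- c(0, n_samples * 1000 / fs)
  sch <- coefficient_schedule(length(A), list(list(interval = win, A = A)), diag(n))
  simulate_tvmvar(sch, n_trials, n, fs = fs, window = win, seed = seed)
}

test_that("AIC order selection prefers the minimum order on white noise", {
  hits <- vapply(1:20, function(seed) {
    ep <- white_epochs(2, 3, 300, fs = 25, seed = seed)
    select_model_order(ep, 1:4)$p == 1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("AIC recovers the order of a strong VAR(3)", {
  A3 <- list(diag(0.4, 3), matrix(0, 3, 3),
             {m <- diag(0.35, 3); m[2, 1] <- 0.4; m})
  expect_lt(companion_spectral_radius(A3), 1)
  hits <- vapply(1:10, function(seed) {
    ep <- stationary_epochs(A3, 1, 2000, seed = seed)
    sel <- select_model_order(ep, 1:5)
    expect_true(all(is.finite(sel$aic)))
    sel$p %in% c(3, 4)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("order selection rejects trials shorter than the largest candidate", {
  ep <- white_epochs(1, 2, 10, fs = 25)
  expect_error(select_model_order(ep, 1:20), "too large")
})

test_that("Kalman filter keeps zero coefficients on all-zero input", {
  m <- fit_tvmvar_kalman(matrix(0, 2, 100), 1, 0.02, fs = 25)
  expect_true(all(m$coefficients == 0))
})

test_that("Kalman estimates approach the least-squares fit on stationary data", {
  A <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  ep <- stationary_epochs(A, 1, 2000, seed = 42, fs = 500)
  m <- fit_tvmvar_kalman(ep$data[1, , ], 1, 0.02, fs = 500)
  est <- apply(m$coefficients[, , 1, 1501:2000], c(1, 2), mean)
  oracle <- adtfnet:::mvar_ls(t(ep$data[1, , ]), 1)$A[[1]]
  expect_lt(max(abs(est - oracle)), 0.1)
  expect_error(fit_tvmvar_kalman(ep$data[1, , ], 1, 1.5), "update_constant")
})

test_that("a mid-trial coefficient step is tracked past its half-way point within 200 samples", {
  A1 <- diag(0.5, 2)
  A2 <- A1; A2[1, 2] <- 0.8
  sch <- coefficient_schedule(1, list(
    list(interval = c(0, 2000), A = list(A1)),
    list(interval = c(2000, 4000), A = list(A2))), diag(2))
  for (seed in c(7, 8, 9)) {
    ep <- simulate_tvmvar(sch, 1, 2, fs = 500, window = c(0, 4000), seed = seed)
    m <- fit_tvmvar_kalman(ep$data[1, , ], 1, 0.02, fs = 500)
    traj <- m$coefficients[1, 2, 1, ]
    sw <- 1001  # first sample generated under the stepped coefficients
    cross <- which(traj[sw:length(traj)] >= 0.4)[1]
    expect_lte(cross, 200)
  }
})

test_that("transfer function honours identity, decoupling and the univariate closed form", {
  m0 <- fit_tvmvar_kalman(matrix(0, 2, 50), 1, 0.02, fs = 25)
  tf0 <- transfer_function(m0, c(1, 5, 10))
  expect_true(all(abs(tf0$H - array(rep(c(1, 0, 0, 1), times = 3 * 49),
                                    dim = dim(tf0$H))) < 1e-12 |
                    Mod(tf0$H) %in% c(0, 1)))
  for (fi in 1:3) for (ti in c(1, 10))
    expect_equal(tf0$H[, , fi, ti], diag(2) + 0i)

  # diagonal coefficients give a diagonal H
  ep <- stationary_epochs(diag(0.5, 2), 1, 500, seed = 1)
  md <- fit_tvmvar_kalman(ep$data[1, , ], 1, 0.02, fs = 25)
  md$coefficients[1, 2, 1, ] <- 0; md$coefficients[2, 1, 1, ] <- 0
  tfd <- transfer_function(md, c(1, 5, 10))
  expect_lt(max(Mod(tfd$H[1, 2, , ])), 1e-12)
  expect_lt(max(Mod(tfd$H[2, 1, , ])), 1e-12)

  # univariate a = 0.5 at fs 25: |H(f)|^2 = 1 / |1 - 0.5 e^{-i 2 pi f / 25}|^2
  mu <- fit_tvmvar_kalman(matrix(rnorm(100), 1, 100), 1, 0.02, fs = 25)
  mu$coefficients[1, 1, 1, ] <- 0.5
  tfu <- transfer_function(mu, c(1, 5, 10))
  for (fi in seq_along(c(1, 5, 10))) {
    f <- c(1, 5, 10)[fi]
    expected <- 1 / Mod(1 - 0.5 * exp(-2i * pi * f / 25))^2
    expect_equal(Mod(tfu$H[1, 1, fi, 1])^2, expected, tolerance = 1e-10)
  }
  expect_error(transfer_function(mu, c(1, 13)), "fs/2")
})

test_that("ADTF normalisation is exact and matches elementwise brute force", {
  # H = I
  m0 <- fit_tvmvar_kalman(matrix(0, 3, 30), 1, 0.02, fs = 25)
  a0 <- adtf(transfer_function(m0, 1:3))
  for (fi in 1:3) {
    expect_equal(a0$gamma2[, , fi, 1], diag(3))
  }

  # synthetic random transfer tensor
  set.seed(99)
  tf <- structure(list(
    H = array(complex(real = rnorm(2 * 2 * 4 * 5), imaginary = rnorm(80)),
              dim = c(2, 2, 4, 5)),
    freqs = 1:4, time_points = 1:5, fs = 25, n_channels = 2),
    class = "transfer_tensor")
  a <- adtf(tf)
  expect_true(all(a$gamma2 >= 0 & a$gamma2 <= 1))
  sums <- apply(a$gamma2, c(1, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  for (i in 1:2) for (j in 1:2) for (fi in 1:4) for (ti in 1:5) {
    brute <- Mod(tf$H[i, j, fi, ti])^2 /
      (Mod(tf$H[i, 1, fi, ti])^2 + Mod(tf$H[i, 2, fi, ti])^2)
    expect_equal(a$gamma2[i, j, fi, ti], brute, tolerance = 1e-12)
  }

  # equal-magnitude row splits evenly
  tf$H[1, 1, 1, 1] <- 3 + 4i; tf$H[1, 2, 1, 1] <- 5 + 0i
  ae <- adtf(tf)
  expect_equal(ae$gamma2[1, 1, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(ae$gamma2[1, 2, 1, 1], 0.5, tolerance = 1e-12)
})

test_that("band integration averages grid frequencies and preserves normalisation", {
  set.seed(5)
  g <- array(runif(3 * 3 * 10 * 6), dim = c(3, 3, 10, 6))
  for (ti in 1:6) for (fi in 1:10) {
    slab <- g[, , fi, ti]; g[, , fi, ti] <- slab / rowSums(slab)
  }
  at <- structure(list(gamma2 = g, freqs = 1:10, time_points = 1:6, fs = 25,
                       degenerate_rows = 0L), class = "adtf_tensor")
  net <- integrate_adtf(at, c(1, 10))
  sums <- apply(net$theta2, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)

  # constant in f: integral equals the constant
  gc <- g; for (fi in 1:10) gc[, , fi, ] <- g[, , 1, ]
  atc <- at; atc$gamma2 <- gc
  expect_equal(integrate_adtf(atc, c(2, 7))$theta2[, , 1], g[, , 1, 1],
               tolerance = 1e-12)

  # linear in f: band mean equals midpoint value on a uniform grid
  gl <- array(0, dim = c(1, 1, 10, 1))
  gl[1, 1, , 1] <- 0.1 * (1:10)
  atl <- structure(list(gamma2 = gl, freqs = 1:10, time_points = 1, fs = 25,
                        degenerate_rows = 0L), class = "adtf_tensor")
  expect_equal(integrate_adtf(atl, c(3, 7))$theta2[1, 1, 1], 0.1 * 5,
               tolerance = 1e-12)

  expect_error(integrate_adtf(at, c(11, 12)), "no grid frequencies")
})

test_that("trial averaging is an elementwise mean with grid checks", {
  mk <- function(x) structure(list(theta2 = array(x, c(2, 2, 3)),
                                   band = c(1, 10), freqs_used = 1:10,
                                   time_points = 1:3, fs = 25),
                              class = "integrated_network")
  avg <- average_networks(list(mk(0.2), mk(0.4)))
  expect_true(all(abs(avg$theta2 - 0.3) < 1e-12))

  set.seed(3)
  nets <- lapply(1:50, function(i) mk(runif(12)))
  pooled <- average_networks(nets)
  oracle <- Reduce(`+`, lapply(nets, `[[`, "theta2")) / 50
  expect_equal(pooled$theta2, oracle, tolerance = 1e-12)

  by_cond <- average_networks(nets, by = rep(c("LAI", "HAI"), 25))
  expect_named(by_cond, c("LAI", "HAI"))

  bad <- mk(0.1); bad$time_points <- 1:4; bad$theta2 <- array(0.1, c(2, 2, 4))
  expect_error(average_networks(list(mk(0.2), bad)), "mismatched")
})

test_that("substage summaries rank outflow, flag ties and order edges", {
  n <- 3
  th <- array(1 / n, c(n, n, 10))  # uniform network
  net <- structure(list(theta2 = th, band = c(1, 10), freqs_used = 1:10,
                        time_points = 1:10, fs = 25),
                   class = "integrated_network")
  s <- summarize_substages(net, stages = list(all = c(0, 400)),
                           channel_labels = c("a", "b", "c"),
                           epoch_window = c(0, 400))
  expect_true(s$all$tie)
  expect_equal(unname(diff(range(s$all$outflow))), 0)

  set.seed(8)
  th2 <- array(runif(n * n * 10), c(n, n, 10))
  net2 <- net; net2$theta2 <- th2
  s2 <- summarize_substages(net2, stages = list(all = c(0, 400)),
                            channel_labels = c("a", "b", "c"),
                            epoch_window = c(0, 400), top_k = n * (n - 1))
  expect_equal(nrow(s2$all$edges), n * (n - 1))
  expect_true(all(diff(s2$all$edges$weight) <= 0))
  W <- apply(th2, c(1, 2), sum); diag(W) <- 0
  expect_equal(max(s2$all$edges$weight), max(W))

  expect_error(summarize_substages(net2, stages = list(empty = c(1000, 1100)),
                                   channel_labels = c("a", "b", "c"),
                                   epoch_window = c(0, 400)),
               "no time points")
})

test_that("zero cross-coupling keeps off-diagonal integrated flow small", {
  ep <- stationary_epochs(diag(0.6, 2), 2, 2000, seed = 10)
  tn <- trial_networks(ep, p = 1, update_constant = 1e-4)
  th <- tn$networks$theta2
  off <- c(th[1, 2, -(1:500)], th[2, 1, -(1:500)])
  expect_lt(max(off), 0.05)
})

test_that("channel relabelling permutes all network outputs consistently", {
  sch <- switching_source_schedule()
  ep <- simulate_tvmvar(sch, 1, 3, fs = 25, window = c(0, 4000), seed = 14)
  perm <- c(3, 1, 2)
  x <- ep$data[1, , ]
  m1 <- fit_tvmvar_kalman(x, 1, 0.02, fs = 25)
  m2 <- fit_tvmvar_kalman(x[perm, ], 1, 0.02, fs = 25)
  a1 <- integrate_adtf(adtf(transfer_function(m1, 1:10)), c(1, 10))
  a2 <- integrate_adtf(adtf(transfer_function(m2, 1:10)), c(1, 10))
  expect_equal(a2$theta2, a1$theta2[perm, perm, ], tolerance = 1e-9)
})

test_that("the switching-source fixture is recovered end to end", {
  sch <- switching_source_schedule()
  ep <- simulate_tvmvar(sch, 20, 3, fs = 25, window = c(0, 4000), seed = 123)
  tn <- trial_networks(ep, p = 1)
  s <- summarize_substages(tn$networks,
                           stages = list(A = c(1000, 2000), B = c(3000, 4000)),
                           channel_labels = ep$channel_labels,
                           epoch_window = ep$window)
  expect_equal(s$A$source, "ch1")
  expect_equal(s$B$source, "ch2")
})
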