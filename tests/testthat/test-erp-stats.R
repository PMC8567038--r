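test_that("grand averages equal the brute-force trial mean", {
  ep <- white_epochs(2, 2, 50, fs = 50, conditions = c("A", "A"))
  ep$data[1, , ] <- 1; ep$data[2, , ] <- 3
  ga <- grand_average(ep)
  expect_true(all(ga$A == 2))

  rnd <- white_epochs(7, 3, 40, fs = 40, seed = 5,
                      conditions = c("A", "B", "A", "B", "A", "B", "B"))
  ga <- grand_average(rnd)
  for (cond in c("A", "B")) {
    idx <- which(rnd$condition_labels == cond)
    oracle <- matrix(0, 3, 40)
    for (tr in idx) oracle <- oracle + rnd$data[tr, , ]
    oracle <- oracle / length(idx)
    expect_equal(unname(ga[[cond]]), unname(oracle), tolerance = 1e-12)
  }
})

test_that("grand averages weight participants equally before pooling", {
  ep <- white_epochs(3, 1, 10, fs = 10, conditions = rep("A", 3))
  ep$participant_ids <- c("p1", "p1", "p2")
  ep$data[1, 1, ] <- 0; ep$data[2, 1, ] <- 2; ep$data[3, 1, ] <- 10
  ga <- grand_average(ep)
  expect_true(all(ga$A == (1 + 10) / 2))  # p1 mean 1, p2 mean 10
})

test_that("mean amplitude matches a brute-force window mean and is linear", {
  ep <- white_epochs(2, 2, 500, conditions = c("LAI", "HAI"))
  ep$window <- c(-200, 800)
  ep$data[] <- 3
  cw <- component_window("P2", c(140, 200), c("ch1", "ch2"))
  tab <- mean_amplitude(ep, cw)
  expect_true(all(abs(tab$amplitude[!is.na(tab$amplitude)] - 3) < 1e-12))

  # triangular bump peaking 5 uV at 170 ms
  tri <- white_epochs(1, 1, 500, conditions = "LAI")
  tri$window <- c(-200, 800)
  t_ms <- epoch_times(tri)
  tri$data[1, 1, ] <- pmax(0, 5 * (1 - abs(t_ms - 170) / 30))
  cw1 <- component_window("P2", c(140, 200), "ch1")
  got <- mean_amplitude(tri, cw1)
  idx <- ms_to_samples(tri, c(140, 200))
  expect_length(idx, 30)
  expect_equal(got$amplitude[got$condition == "LAI"],
               mean(tri$data[1, 1, idx]), tolerance = 1e-12)

  expect_error(mean_amplitude(tri, component_window("P2", c(140, 200), "Oz")),
               "absent")

  # linearity: amp(a x + b y) = a amp(x) + b amp(y)
  x <- white_epochs(1, 1, 500, seed = 1, conditions = "LAI"); x$window <- c(-200, 800)
  y <- white_epochs(1, 1, 500, seed = 2, conditions = "LAI"); y$window <- c(-200, 800)
  z <- x; z$data <- 2 * x$data + 3 * y$data
  ax <- mean_amplitude(x, cw1)$amplitude[1]
  ay <- mean_amplitude(y, cw1)$amplitude[1]
  az <- mean_amplitude(z, cw1)$amplitude[1]
  expect_equal(az, 2 * ax + 3 * ay, tolerance = 1e-12)
})

test_that("peak latency finds bumps, boundaries and flags flat windows", {
  n <- 500
  wave <- matrix(0, 1, n, dimnames = list("Cz", NULL))
  t_ms <- -200 + (seq_len(n) - 1) * 2
  wave[1, ] <- exp(-0.5 * ((t_ms - 360) / 40)^2)
  attr(wave, "fs") <- 500; attr(wave, "window") <- c(-200, 800)
  pk <- peak_latency(wave, "Cz", c(300, 400))
  expect_lte(abs(pk$latency_ms - 360), 2)
  expect_false(pk$indeterminate)

  mono <- wave; mono[1, ] <- seq_len(n)
  pk2 <- peak_latency(mono, "Cz", c(300, 400))
  expect_equal(pk2$latency_ms, 398)  # last sample of the half-open window

  noisy <- wave
  set.seed(4); noisy[1, ] <- wave[1, ] + rnorm(n, sd = 0.1)
  idx <- ms_to_samples(list(fs = 500, window = c(-200, 800)), c(300, 400))
  oracle_t <- t_ms[idx[which.max(noisy[1, idx])]]
  expect_equal(peak_latency(noisy, "Cz", c(300, 400))$latency_ms, oracle_t)

  flat <- wave; flat[1, ] <- 1
  expect_true(peak_latency(flat, "Cz", c(300, 400))$indeterminate)
})

test_that("repeated-measures ANOVA matches definitional sums of squares and aov", {
  tab <- amplitude_fixture(n_sub = 4, n_elec = 3, effect = 0.8, seed = 2)
  res <- rm_anova_2xK(tab)

  # brute-force definitional decomposition
  subs <- unique(tab$participant); conds <- unique(tab$condition)
  elecs <- unique(tab$electrode)
  S <- length(subs); A <- length(conds); K <- length(elecs)
  y <- function(s, a, b) tab$amplitude[tab$participant == subs[s] &
                                         tab$condition == conds[a] &
                                         tab$electrode == elecs[b]]
  Y <- array(0, c(S, A, K))
  for (s in 1:S) for (a in 1:A) for (b in 1:K) Y[s, a, b] <- y(s, a, b)
  gm <- mean(Y)
  ss_a <- S * K * sum((apply(Y, 2, mean) - gm)^2)
  ss_as <- K * sum((apply(Y, c(1, 2), mean) -
                      outer(apply(Y, 1, mean), rep(1, A)) -
                      outer(rep(1, S), apply(Y, 2, mean)) + gm)^2)
  F_a <- (ss_a / (A - 1)) / (ss_as / ((A - 1) * (S - 1)))
  expect_equal(res$F[res$effect == "condition"], F_a, tolerance = 1e-10)
  expect_equal(res$pes[res$effect == "condition"], ss_a / (ss_a + ss_as),
               tolerance = 1e-10)

  # independent route: base-R aov error strata
  tf <- tab
  tf$participant <- factor(tf$participant)
  tf$condition <- factor(tf$condition)
  tf$electrode <- factor(tf$electrode)
  fit <- summary(aov(amplitude ~ condition * electrode +
                       Error(participant / (condition * electrode)), data = tf))
  f_aov <- c(fit[["Error: participant:condition"]][[1]]["condition", "F value"],
             fit[["Error: participant:electrode"]][[1]]["electrode", "F value"],
             fit[["Error: participant:condition:electrode"]][[1]][
               "condition:electrode", "F value"])
  expect_equal(res$F, unname(f_aov), tolerance = 1e-8)

  # total SS partitions exactly into subject + effect + error strata
  m_s <- apply(Y, 1, mean); m_b <- apply(Y, 3, mean); m_a <- apply(Y, 2, mean)
  ss_total <- sum((Y - gm)^2)
  ss_subj <- A * K * sum((m_s - gm)^2)
  ss_b <- S * A * sum((m_b - gm)^2)
  ss_ab <- S * sum((apply(Y, c(2, 3), mean) - outer(m_a, rep(1, K)) -
                      outer(rep(1, A), m_b) + gm)^2)
  ss_bs <- A * sum((apply(Y, c(1, 3), mean) - outer(m_s, rep(1, K)) -
                      outer(rep(1, S), m_b) + gm)^2)
  ss_abs <- ss_total - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs
  F_ab <- (ss_ab / ((A - 1) * (K - 1))) /
    (ss_abs / ((A - 1) * (K - 1) * (S - 1)))
  expect_equal(res$F[res$effect == "condition:electrode"], F_ab,
               tolerance = 1e-10)
  expect_gte(ss_abs, 0)
})

test_that("ANOVA degenerate and bound contracts hold", {
  # duplicated condition values: zero condition effect
  tab <- amplitude_fixture(n_sub = 5, n_elec = 4, effect = 0, noise = 1, seed = 3)
  wide <- tab[tab$condition == "LAI", ]
  dup <- rbind(wide, transform(wide, condition = "HAI"))
  res <- rm_anova_2xK(dup)
  expect_equal(res$F[res$effect == "condition"], 0, tolerance = 1e-20)

  # 2-level factor: epsilon 1, GG p equals raw p
  expect_equal(res$epsilon[res$effect == "condition"], 1)
  expect_equal(res$p[res$effect == "condition"],
               res$p_gg[res$effect == "condition"])

  # epsilon bounds over random fixtures
  for (seed in 1:5) {
    r <- rm_anova_2xK(amplitude_fixture(n_sub = 6, n_elec = 5, effect = 0.3,
                                        seed = seed))
    K <- 5
    expect_gte(r$epsilon[r$effect == "electrode"], 1 / (K - 1))
    expect_lte(r$epsilon[r$effect == "electrode"], 1)
    expect_true(all(r$pes >= 0 & r$pes <= 1))
    expect_true(all(r$F >= 0))
  }

  bad <- amplitude_fixture(n_sub = 4, n_elec = 3)[-1, ]
  expect_error(rm_anova_2xK(bad), "missing cells")
})

test_that("post-hoc contrasts flag exactly the electrodes carrying an effect", {
  # strong effect at 6 of 8 electrodes, many participants
  tab <- amplitude_fixture(n_sub = 40, n_elec = 8, effect = 2,
                           effect_electrodes = 1:6, noise = 0.5, seed = 6)
  ph <- posthoc_by_electrode(tab)
  expect_setequal(ph$electrode[ph$significant], paste0("e", 1:6))

  # identical conditions: nothing significant
  wide <- tab[tab$condition == "LAI", ]
  dup <- rbind(wide, transform(wide, condition = "HAI"))
  ph0 <- posthoc_by_electrode(dup)
  expect_false(any(ph0$significant))
  expect_true(all(ph0$p >= 0.999))

  # paired t on 3 pairs matches the closed form
  x <- c(1.0, 2.0, 4.0); y <- c(0.5, 1.0, 2.5)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  small <- data.frame(participant = rep(paste0("s", 1:3), 2),
                      condition = rep(c("LAI", "HAI"), each = 3),
                      electrode = "e1", amplitude = c(x, y))
  ph3 <- posthoc_by_electrode(small)
  expect_equal(ph3$t, t_hand, tolerance = 1e-12)
  expect_equal(ph3$df, 2)
})

test_that("signed-rank statistic, exact p and antisymmetry follow the definitions", {
  # maximal one-sided statistic at n = 20
  y <- rnorm(20); x <- y + 1
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$statistic, 20 * 21 / 2)
  mu <- 20 * 21 / 4; v <- 20 * 21 * 41 / 24
  expect_equal(w$Z, (210 - mu - 0.5) / sqrt(v), tolerance = 1e-12)

  # exact p matches enumeration of all 2^6 sign assignments
  x6 <- c(1.2, 3.1, 2.2, 5.5, 0.3, 4.4)
  y6 <- c(0.8, 2.0, 2.9, 1.1, 0.9, 2.2)
  w6 <- wilcoxon_signed_rank(x6, y6)
  expect_true(w6$exact)
  d <- x6 - y6; r <- rank(abs(d)); W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  W_all <- signs %*% r
  p_enum <- mean(abs(W_all - 6 * 7 / 4) >= abs(W_obs - 6 * 7 / 4))
  expect_equal(w6$p, p_enum, tolerance = 1e-12)

  # antisymmetry
  wf <- wilcoxon_signed_rank(y6, x6)
  expect_equal(wf$Z, -w6$Z, tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("behavioural stats pair trials and summarise responded RTs", {
  b <- simulate_behavior(300, seed = 12)
  st <- behavior_stats(b)
  expect_equal(st$summary$condition, c("HAI", "LAI"))
  expect_gt(st$summary$mean_rt[1], st$summary$mean_rt[2])  # HAI slower
  expect_lt(st$test$p, 0.001)
  expect_gt(st$test$Z, 0)  # HAI - LAI pairing, HAI larger
})
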