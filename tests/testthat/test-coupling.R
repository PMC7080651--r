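coupling_tab <- function(rt, alpha, condition = "congruent",
                         included = TRUE) {
  data.frame(subject = "t", group = "HC", trial_id = seq_along(rt),
             condition = condition, rt = rt, correct = TRUE,
             artifact = FALSE, valid = TRUE, outlier = FALSE,
             included = included, alpha_power = alpha,
             stringsAsFactors = FALSE)
}

test_that("median split halves the trials with ties going to slow", {
  tab <- median_split(coupling_tab(c(400, 450, 500, 550), 1:4))
  expect_equal(tab$speed_bin, c("fast", "fast", "slow", "slow"))
  # odd count: the median trial itself lands in slow
  tab2 <- median_split(coupling_tab(c(400, 450, 500, 410, 420), 1:5))
  expect_equal(tab2$speed_bin[tab2$rt == 420], "slow")
  expect_equal(sum(tab2$speed_bin == "fast"), 2)
  # every fast RT <= every slow RT
  set.seed(5)
  for (i in 1:20) {
    rt <- sample(300:700, 12, replace = TRUE)
    if (max(rt) == min(rt)) next
    tb <- median_split(coupling_tab(rt, seq_along(rt)))
    expect_lte(max(tb$rt[tb$speed_bin == "fast"]),
               min(tb$rt[tb$speed_bin == "slow"]))
    # bin imbalance bounded by the number of median-tied trials
    expect_lte(abs(sum(tb$speed_bin == "fast") -
                     sum(tb$speed_bin == "slow")),
               sum(tb$rt == median(tb$rt)) + 1)
  }
})

test_that("median split is computed per condition and only on included trials", {
  rt <- c(400, 450, 500, 550, 700, 750, 800, 850)
  cond <- rep(c("congruent", "incongruent"), each = 4)
  tab <- median_split(coupling_tab(rt, 1:8, condition = cond))
  expect_equal(tab$speed_bin,
               rep(c("fast", "fast", "slow", "slow"), 2))
  # pooled variant: one global median
  tabp <- median_split(coupling_tab(rt, 1:8, condition = cond),
                       pooled = TRUE)
  expect_equal(tabp$speed_bin, rep(c("fast", "slow"), each = 4))
  # excluded trials never receive a bin
  rt10 <- c(400, 450, 500, 550, 600, 700, 750, 800, 850, 900)
  cond10 <- rep(c("congruent", "incongruent"), each = 5)
  inc <- c(rep(TRUE, 5), FALSE, rep(TRUE, 4))
  tab2 <- median_split(coupling_tab(rt10, 1:10, condition = cond10,
                                    included = inc))
  expect_equal(tab2$speed_bin[6], "unassigned")
  expect_error(median_split(coupling_tab(rep(500, 8), 1:8)), "identical")
  expect_error(median_split(coupling_tab(c(1, 2, 3), 1:3)), "at least 4")
})

test_that("speed-bin power means and their difference are correct", {
  tab <- median_split(coupling_tab(c(400, 450, 500, 550),
                                   c(2, 4, 10, 20)))
  bp <- speed_bin_power(tab)
  expect_equal(bp$alpha_fast, 3)
  expect_equal(bp$alpha_slow, 15)
  expect_equal(bp$alpha_diff, 12)
  # constant alpha -> zero difference
  bp0 <- speed_bin_power(median_split(coupling_tab(c(400, 450, 500, 550),
                                                   rep(5, 4))))
  expect_equal(bp0$alpha_diff, 0)
  # perfect monotone coupling -> fast mean below slow mean
  bp1 <- speed_bin_power(median_split(coupling_tab(c(400, 450, 500, 550),
                                                   c(400, 450, 500, 550))))
  expect_lt(bp1$alpha_fast, bp1$alpha_slow)
})

test_that("spearman_rho equals the rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(10); y <- rnorm(10)
    if (i %% 3 == 0) x <- round(x, 0)      # induce ties
    expect_equal(spearman_rho(x, y),
                 unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
})

test_that("spearman_rho is invariant under strictly increasing transforms", {
  set.seed(2)
  x <- abs(rnorm(30)) + 0.1; y <- rnorm(30)
  r0 <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r0, tolerance = 1e-12)
  expect_equal(spearman_rho(x^2, y), r0, tolerance = 1e-12)
  expect_equal(spearman_rho(x, exp(y)), r0, tolerance = 1e-12)
})

test_that("fisher_z matches the closed form and its small-rho behavior", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  expect_equal(fisher_z(-0.5), -log(3) / 2)
  # strictly increasing, odd
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(fisher_z(r), -fisher_z(-r))
  # near-identity below |rho| = 0.1 (within 0.5% relative)
  sm <- c(-0.1, -0.05, 0.01, 0.05, 0.1)
  expect_lt(max(abs(fisher_z(sm) / sm - 1)), 0.005)
  expect_error(fisher_z(1), "clamp")
  expect_equal(fisher_z(1, clamp = TRUE), fisher_z(1 - 1e-7))
})

test_that("subject coupling summarises rho, z and bin means per condition", {
  rt <- c(400, 450, 500, 550, 600, 650, 700, 750)
  alpha <- c(1, 3, 2, 4, 8, 6, 7, 5)
  cond <- rep(c("congruent", "incongruent"), each = 4)
  tab <- median_split(coupling_tab(rt, alpha, condition = cond))
  sc <- subject_coupling(tab)
  expect_setequal(sc$condition, c("congruent", "incongruent"))
  cg <- sc[sc$condition == "congruent", ]
  expect_equal(cg$rho, spearman_rho(alpha[1:4], rt[1:4]))
  expect_equal(cg$z, fisher_z(cg$rho))
  expect_equal(cg$n_trials, 4)
  expect_equal(sign(sc$z), sign(sc$rho))
})

test_that("RT outlier exclusion attenuates the recovered coupling; exclusion-free recovery is unbiased", {
  # the +/-2 SD RT exclusion range-restricts RT and shrinks the measured
  # rank correlation; on untrimmed trials the copula target is recovered
  # without bias. This quantifies why downstream recovery sits slightly
  # below fisher_z(target) at strong coupling.
  set.seed(515)
  rho <- 0.4
  err <- function(trim) {
    mean(replicate(500, {
      tab <- simulate_coupling_table(n_trials = 60, rho = rho)
      s <- tab[tab$condition == "congruent", ]
      keep <- rep(TRUE, 60)
      if (trim) {
        m <- mean(s$rt); sd0 <- sd(s$rt)
        keep <- s$rt >= m - 2 * sd0 & s$rt <= m + 2 * sd0
      }
      fisher_z(spearman_rho(s$alpha_power[keep], s$rt[keep]))
    })) - fisher_z(rho)
  }
  e_trim <- err(TRUE); e_free <- err(FALSE)
  expect_lt(abs(e_free), 0.02)       # unbiased without exclusion
  expect_lt(e_trim, -0.02)           # systematic attenuation with it
})

test_that("simulated cohorts recover the coupling through the full pipeline", {
  # low-noise recovery at a strong positive target
  p <- sim_params(n_per_group = 2, coupling_rho = 0.3, noise_amp = 0.3,
                  seed = 88)
  zs <- sapply(1:6, function(i) {
    rec <- simulate_subject(p, "HC", subject_seed = 1000 + i)
    mean(process_subject(rec)$coupling$z)
  })
  # mean z near fisher_z(0.3) = 0.31, SE ~ 0.04 over 6 x 2 conditions
  expect_lt(abs(mean(zs) - fisher_z(0.3)), 0.1)
})
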