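# Brute-force oracles computed directly from the definitional formulas.

test_that("unpaired and Welch t tests match the definitional formulas", {
  set.seed(10)
  a <- rnorm(8, 1); b <- rnorm(11)
  na <- length(a); nb <- length(b)

  # pooled-variance t
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_pool <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df_pool <- na + nb - 2
  r <- compare_two_groups(a, b, "unpaired-t")
  expect_equal(r$statistic, t_pool, tolerance = 1e-8)
  expect_equal(r$df, df_pool)
  expect_equal(r$p, 2 * pt(-abs(t_pool), df_pool), tolerance = 1e-8)

  # Welch
  se2 <- var(a) / na + var(b) / nb
  t_w <- (mean(a) - mean(b)) / sqrt(se2)
  df_w <- se2^2 / ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
  rw <- compare_two_groups(a, b, "welch-t")
  expect_equal(rw$statistic, t_w, tolerance = 1e-8)
  expect_equal(rw$df, df_w, tolerance = 1e-8)
  expect_equal(rw$p, 2 * pt(-abs(t_w), df_w), tolerance = 1e-8)
})

test_that("paired t equals a one-sample t on the differences", {
  set.seed(11)
  a <- rnorm(9, 0.5); b <- rnorm(9)
  d <- a - b
  t_d <- mean(d) / (sd(d) / sqrt(length(d)))
  r <- compare_two_groups(a, b, "paired-t")
  expect_equal(r$statistic, t_d, tolerance = 1e-8)
  expect_equal(r$df, length(d) - 1)
  expect_equal(r$p, 2 * pt(-abs(t_d), length(d) - 1), tolerance = 1e-8)
  expect_error(compare_two_groups(a, b[-1], "paired-t"), "equal-length")
})

test_that("exact Mann-Whitney matches full enumeration of rank assignments", {
  # tiny tie-free example enumerable by hand: a = {1, 2}, b = {3, 4}
  r <- compare_two_groups(c(1, 2), c(3, 4), "mann-whitney")
  # U = 0; only 1 of choose(4,2) = 6 assignments is as extreme per tail
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)

  # larger tie-free sample: enumerate U over all group assignments
  set.seed(12)
  a <- c(0.3, 1.7, 2.2, 5.1, 0.9)
  b <- c(1.1, 3.4, 4.2, 2.8, 6.0, 3.9)
  pool <- c(a, b); na <- length(a)
  combs <- combn(length(pool), na)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  u_all <- apply(combs, 2, function(i) u_of(pool[i], pool[-i]))
  m <- na * length(b)
  p_exact <- mean(pmin(u_all, m - u_all) <= min(u_obs, m - u_obs))
  r2 <- compare_two_groups(a, b, "mann-whitney")
  expect_equal(r2$statistic, u_obs)
  expect_equal(r2$p, p_exact, tolerance = 1e-10)
})

test_that("exact Wilcoxon signed rank matches sign-flip enumeration", {
  set.seed(13)
  a <- c(2.3, 1.1, 4.0, 0.2, 3.3, 5.1, 2.8)
  b <- c(1.9, 1.6, 2.2, 0.95, 2.1, 4.4, 1.05)  # all |d| distinct, no zeros
  d <- a - b
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% rk
  tot <- sum(rk)
  p_exact <- mean(pmin(v_all, tot - v_all) <= min(v_obs, tot - v_obs))
  r <- compare_two_groups(a, b, "wilcoxon")
  expect_equal(r$statistic, v_obs)
  expect_equal(r$p, p_exact, tolerance = 1e-10)
})

test_that("RM one-way ANOVA matches brute-force sums of squares", {
  set.seed(14)
  n_s <- 6; n_c <- 4  # 24 cells
  m <- matrix(rnorm(n_s * n_c), n_s, n_c) + rnorm(n_s) +
    rep(c(0, 0.5, 1, 1.5), each = n_s) * 0  # null condition effect
  m <- m + matrix(rep(c(0, 1, 2, 0.5), each = n_s), n_s, n_c)
  gm <- mean(m)
  ss_cond <- n_s * sum((colMeans(m) - gm)^2)
  ss_subj <- n_c * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  f_oracle <- (ss_cond / (n_c - 1)) / (ss_res / ((n_s - 1) * (n_c - 1)))
  tab <- rm_one_way_anova(m)
  expect_equal(tab$SS, c(ss_cond, ss_subj, ss_res), tolerance = 1e-8)
  expect_equal(tab$df, c(n_c - 1, n_s - 1, (n_s - 1) * (n_c - 1)))
  expect_equal(tab$F[1], f_oracle, tolerance = 1e-8)
  expect_equal(tab$p[1],
               pf(f_oracle, n_c - 1, (n_s - 1) * (n_c - 1), lower.tail = FALSE),
               tolerance = 1e-8)
  expect_error(rm_one_way_anova(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("mixed-design ANOVA matches brute-force sums of squares", {
  set.seed(15)
  n_per <- 5; n_w <- 4  # 2 groups x 5 subjects x 4 levels = 40 cells
  d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n_per)),
                   within = paste0("w", 1:n_w))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n_per, "g1", "g2")
  d$y <- rnorm(nrow(d)) + ifelse(d$group == "g1", 0, 1) +
    as.integer(sub("w", "", d$within)) * 0.5

  gm <- mean(d$y)
  cell <- tapply(d$y, list(d$group, d$within), mean)
  gmean <- tapply(d$y, d$group, mean)
  wmean <- tapply(d$y, d$within, mean)
  smean <- tapply(d$y, d$subject, mean)
  ss_group <- n_per * n_w * sum((gmean - gm)^2)
  ss_subj_tot <- n_w * sum((smean - gm)^2)
  ss_subj_within_g <- ss_subj_tot - ss_group
  ss_within <- 2 * n_per * sum((wmean - gm)^2)
  ss_cells <- n_per * sum((cell - gm)^2)
  ss_inter <- ss_cells - ss_group - ss_within
  ss_tot <- sum((d$y - gm)^2)
  ss_werr <- ss_tot - ss_cells - ss_subj_within_g

  tab <- rm_two_way_anova(d)
  expect_equal(tab$SS,
               c(ss_group, ss_subj_within_g, ss_within, ss_inter, ss_werr),
               tolerance = 1e-8)
  expect_equal(tab$df, c(1, 2 * n_per - 2, n_w - 1, n_w - 1,
                         (2 * n_per - 2) * (n_w - 1)))
  f_g <- (ss_group / 1) / (ss_subj_within_g / (2 * n_per - 2))
  f_i <- (ss_inter / (n_w - 1)) /
    (ss_werr / ((2 * n_per - 2) * (n_w - 1)))
  expect_equal(tab$F[1], f_g, tolerance = 1e-8)
  expect_equal(tab$F[4], f_i, tolerance = 1e-8)
})

test_that("Greenhouse-Geisser epsilon matches the eigenvalue definition", {
  set.seed(21)
  n_per <- 8; n_w <- 5
  d <- expand.grid(subject = sprintf("s%02d", 1:(2 * n_per)),
                   within = paste0("w", 1:n_w))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n_per, "g1", "g2")
  # heteroscedastic, correlated levels -> epsilon well below 1
  lv <- as.integer(sub("w", "", d$within))
  subj_gain <- rnorm(2 * n_per)
  d$y <- subj_gain[as.integer(factor(d$subject))] * lv + rnorm(nrow(d), sd = lv)

  tab <- suppressWarnings(rm_two_way_anova(d))
  eps <- tab$eps_gg[tab$effect == "within"]

  # oracle: eigenvalues of the contrast-space pooled covariance
  wide <- stats::xtabs(y ~ subject + within, data = d)
  grp <- d$group[match(rownames(wide), d$subject)]
  S <- ((n_per - 1) * cov(wide[grp == "g1", ]) +
          (n_per - 1) * cov(wide[grp == "g2", ])) / (2 * n_per - 2)
  ctr <- qr.Q(qr(cbind(1, diag(n_w))))[, 2:n_w]  # orthonormal contrasts
  lam <- eigen(t(ctr) %*% S %*% ctr, symmetric = TRUE)$values
  eps_oracle <- sum(lam)^2 / ((n_w - 1) * sum(lam^2))
  expect_equal(eps, eps_oracle, tolerance = 1e-8)

  # corrected p uses the F with both df scaled by epsilon
  Fw <- tab$F[tab$effect == "within"]
  df1 <- tab$df[tab$effect == "within"]
  df2 <- tab$df[tab$effect == "within_error"]
  expect_equal(tab$p_gg[tab$effect == "within"],
               pf(Fw, eps * df1, eps * df2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(eps < 1)
  # sphericity is trivial for two levels: epsilon = 1
  d2 <- d[d$within %in% c("w1", "w2"), ]
  tab2 <- rm_two_way_anova(d2)
  expect_equal(tab2$eps_gg[tab2$effect == "within"], 1)
})

test_that("mixed-design ANOVA drops incomplete subjects with a warning", {
  d <- expand.grid(subject = sprintf("s%d", 1:8), within = c("w1", "w2"))
  d$group <- rep(rep(c("g1", "g2"), each = 4), 2)
  set.seed(16); d$y <- rnorm(nrow(d))
  d <- d[!(d$subject == "s1" & d$within == "w2"), ]  # s1 incomplete
  expect_warning(tab <- rm_two_way_anova(d), "dropped")
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_equal(tab$df[tab$effect == "subjects_within_group"], 5)  # 7 - 2
})

test_that("balanced two-way ANOVA matches brute-force sums of squares", {
  set.seed(17)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                   rep = 1:4)
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "a2", 0.8, 0)
  gm <- mean(d$y)
  n_rep <- 4; nb <- 3; na_lev <- 2
  am <- tapply(d$y, d$A, mean); bm <- tapply(d$y, d$B, mean)
  cm <- tapply(d$y, list(d$A, d$B), mean)
  ss_a <- nb * n_rep * sum((am - gm)^2)
  ss_b <- na_lev * n_rep * sum((bm - gm)^2)
  ss_cells <- n_rep * sum((cm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((d$y - gm)^2) - ss_cells
  tab <- two_way_anova(d)
  expect_equal(tab$SS, c(ss_a, ss_b, ss_ab, ss_res), tolerance = 1e-8)
  expect_equal(tab$df, c(1, 2, 2, 18))
  expect_error(two_way_anova(d[-1, ]), "unbalanced")
})

test_that("BH adjustment matches the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # m * p_(j) / j = 0.04, 0.04, 0.04, 0.04 -> all 0.04
  expect_equal(bh_adjust(p), rep(0.04, 4))
  set.seed(18)
  p2 <- runif(9)
  m <- length(p2)
  o <- order(p2)
  adj <- rev(cummin(rev(m * p2[o] / seq_len(m))))
  oracle <- numeric(m); oracle[o] <- pmin(1, adj)
  expect_equal(bh_adjust(p2), oracle, tolerance = 1e-12)
  # adjusted values are monotone in the raw p values
  expect_equal(order(bh_adjust(p2)[order(p2)]), seq_len(m))
  # families are adjusted independently
  fam <- c(1, 1, 1, 1, 2, 2, 2, 2, 2)
  by_fam <- c(bh_adjust(p2[1:4]), bh_adjust(p2[5:9]))
  expect_equal(bh_adjust(p2, fam), by_fam)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5), family = c(1, 2)), "length")
})

test_that("group comparison validates inputs", {
  expect_error(compare_two_groups(1, c(1, 2)), "n >= 2")
})
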