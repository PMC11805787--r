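# Multilevel model fitting, ICC, nested comparisons, Johnson-Neyman regions
# and simple slopes.

test_that("grand-mean centering zeroes the mean and keeps the spread", {
  expect_equal(grand_mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(grand_mean_center(rep(7, 5)), rep(0, 5))
  set.seed(1)
  x <- rnorm(100, 0.65, 0.18)
  expect_lt(abs(mean(grand_mean_center(x))), 1e-12)
  expect_equal(sd(grand_mean_center(x)), sd(x))
})

test_that("without random terms the fit reduces to ordinary least squares", {
  cfg <- gen_config(n_participants = 20, trials_range = c(15, 15), seed = 7)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  spec <- model_spec(random = NULL)
  f <- fit_lmm(tr, p, spec)
  # independent construction of the same design through base lm
  d <- merge(tr, p, by = "participant_id")
  d$hp <- d$hand * d$position
  d$thp <- d$task * d$hp
  for (v in c("boa", "exo", "endo", "viwm", "vsowm", "siwm", "ssowm"))
    d[[paste0(v, "_c")]] <- d[[v]] - mean(p[[v]])
  ref <- lm(rt_ms ~ hand + position + hp + task + thp + boa_c + exo_c +
              endo_c + viwm_c + vsowm_c + siwm_c + ssowm_c + handedness +
              altL + school + education_years + gender + hp:boa_c +
              hp:exo_c + hp:endo_c + hp:viwm_c + hp:vsowm_c + hp:siwm_c +
              hp:ssowm_c + hp:siwm_c:ssowm_c, data = d)
  expect_equal(unname(f$gamma$estimate[match("hp", f$gamma$term)]),
               unname(coef(ref)[["hp"]]), tolerance = 1e-6)
  expect_equal(sort(f$gamma$estimate), sort(unname(coef(ref))),
               tolerance = 1e-6)
})

test_that("fit recovers generating coefficients at moderate scale", {
  cfg <- gen_config(n_participants = 60, trials_range = c(30, 30), seed = 17)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  f <- fit_lmm(tr, p, model_spec(), ddf = "satterthwaite")
  g <- f$gamma
  hp <- g[g$term == "hp", ]
  expect_lt(abs(hp$estimate - (-23.27)), 4 * hp$se)
  expect_true(is.finite(hp$df) && hp$df > 10)
  expect_equal(hp$t, hp$estimate / hp$se, tolerance = 1e-8)
  # variance components in the right regime
  expect_gt(f$sigma2, 40000)
  expect_lt(f$sigma2, 120000)
  expect_equal(dim(f$tau), c(4, 4))
})

test_that("ICC is tau00 / (tau00 + sigma2) and is recovered when planted", {
  # planted ICC of 0.293 through an intercept-only generator
  sigma2 <- 76098.4
  tau00 <- sigma2 * 0.293 / (1 - 0.293)
  fx <- default_fixed_effects()
  fx[] <- 0
  fx["intercept"] <- 1000
  cfg <- gen_config(n_participants = 160, trials_range = c(40, 40),
                    fixed_effects = fx, sigma2 = sigma2,
                    tau = diag(c(tau00, 0, 0, 0)), seed = 23)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  nf <- fit_lmm(tr, p, null_model_spec(), ddf = "none")
  expect_lt(abs(icc(nf) - 0.293), 0.03)
  expect_error(icc(fit_lmm(tr, p, model_spec(random = NULL))),
               "intercept-only")
})

test_that("nested model comparison uses FIML deviances", {
  cfg <- gen_config(n_participants = 30, trials_range = c(25, 25), seed = 29)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  nf <- fit_lmm(tr, p, null_model_spec(), ddf = "none")
  l1 <- fit_lmm(tr, p, model_spec(l2_cognitive = FALSE, l2_controls = FALSE,
                                  cli = FALSE, random = "intercept",
                                  estimation = "FIML"), ddf = "none")
  same <- compare_models(nf, nf)
  expect_equal(same$chi2, 0, tolerance = 1e-8)
  expect_equal(same$df, 0)
  cmp <- compare_models(nf, l1)
  expect_equal(cmp$df, 5)
  # strong planted level-1 effects: decisive improvement
  expect_gt(cmp$chi2, qchisq(0.999, 5))
  expect_lt(cmp$p, 0.001)
  expect_error(compare_models(l1, nf), "not nested")
})

test_that("jn_region handles the no-moderation and always-significant cases", {
  # gamma_c = 0 with a clearly significant focal effect: significant
  # everywhere, no boundaries
  r <- jn_region(gamma_f = -23, gamma_c = 0, v_ff = 16, v_fc = 0, v_cc = 0,
                 crit = 1.96, range = c(-3, 3))
  expect_length(r$boundaries, 0)
  expect_equal(unname(r$significant[1, ]), c(-3, 3))
  # crit -> 0 (alpha -> 1): the whole range is significant
  r2 <- jn_region(-23.27, -19.37, 16, 0.5, 60, crit = 1e-6, range = c(-1, 1))
  expect_equal(unname(r2$significant[1, ]), c(-1, 1), tolerance = 1e-3)
})

test_that("jn_region boundaries match a dense grid search", {
  for (s in 1:10) {
    set.seed(s)
    gf <- rnorm(1, -20, 10)
    gc <- rnorm(1, 0, 15)
    L <- matrix(rnorm(4), 2, 2)
    V <- crossprod(L) + diag(2) * 0.1
    crit <- qt(0.975, sample(30:200, 1))
    sd_w <- runif(1, 0.5, 5)
    lo <- -4 * sd_w; hi <- 4 * sd_w
    r <- jn_region(gf, gc, V[1, 1], V[1, 2], V[2, 2], crit, range = c(lo, hi))
    want <- jn_grid_boundaries(gf, gc, V[1, 1], V[1, 2], V[2, 2], crit,
                               lo, hi, step = 1e-4 * sd_w)
    got <- r$boundaries[r$boundaries > lo & r$boundaries < hi]
    expect_equal(length(got), length(want), info = paste("seed", s))
    if (length(want))
      expect_lt(max(abs(sort(got) - sort(want))), 2e-4 * sd_w)
  }
})

test_that("johnson_neyman extracts the right terms from a fit", {
  cfg <- gen_config(n_participants = 50, trials_range = c(30, 30), seed = 31)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  f <- fit_lmm(tr, p, model_spec(), ddf = "satterthwaite")
  j <- johnson_neyman(f, "vsowm", range = range(p$vsowm))
  expect_s3_class(j, "spoarc_jn")
  # boundaries reported on the uncentered moderator scale
  i_f <- match("hp", f$gamma$term)
  i_c <- match("hp:vsowm_c", f$gamma$term)
  jc <- jn_region(f$gamma$estimate[i_f], f$gamma$estimate[i_c],
                  f$vcov_fixed[i_f, i_f], f$vcov_fixed[i_f, i_c],
                  f$vcov_fixed[i_c, i_c],
                  qt(0.975, f$gamma$df[i_c]))
  expect_equal(j$boundaries, jc$boundaries + mean(p$vsowm), tolerance = 1e-10)
  # alpha -> 1 limit: significant everywhere except a vanishing sliver
  # around the conditional effect's zero crossing
  j1 <- johnson_neyman(f, "vsowm", alpha = 0.9999, range = range(p$vsowm))
  covered <- sum(j1$significant[, "hi"] - j1$significant[, "lo"])
  expect_gt(covered, 0.999 * diff(range(p$vsowm)))
})

test_that("simple slopes respond to the CLI sign and default to mean +- SD", {
  cfg <- gen_config(n_participants = 60, trials_range = c(30, 30), seed = 37)
  p <- generate_participants(cfg)
  # force the printed moments so the default levels are reproduced exactly
  p$vsowm <- as.numeric(scale(p$vsowm)) * 0.17 + 0.65
  tr <- generate_probe_trials(p, cfg)
  f <- fit_lmm(tr, p, model_spec(), ddf = "none")
  ss <- simple_slopes(f, "vsowm")
  expect_equal(ss$level, c(0.48, 0.65, 0.82), tolerance = 1e-10)
  expect_equal(ss$diff, ss$slope_right - ss$slope_left, tolerance = 1e-10)
  # planted negative CLI: right-minus-left slope decreases in the moderator
  gc <- f$gamma$estimate[match("hp:vsowm_c", f$gamma$term)]
  if (gc < 0) expect_true(all(diff(ss$diff) < 0))
  else expect_true(all(diff(ss$diff) > 0))
  # zero CLI coefficient: identical differences at all levels
  f0 <- f
  f0$gamma$estimate[match("hp:vsowm_c", f0$gamma$term)] <- 0
  ss0 <- simple_slopes(f0, "vsowm")
  expect_lt(diff(range(ss0$diff)), 1e-10)
  expect_warning(simple_slopes(f, "vsowm", restrict = c(0.60, 1)), "dropped")
})
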