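test_that("noiseless generator is exactly linear with the stated rate", {
  p <- kinetic_sim_params(noise_sd = 0, inhibition_fraction = 0,
                          rate_uninhibited = 2, inhibitors = character(0))
  plate <- simulate_kinetics(p)
  expect_identical(sort(unique(plate$time_min)), seq(0, 180, by = 15))
  blank <- plate[plate$condition == "blank" & plate$replicate == 1,
                 c("time_min", "signal")]
  smp <- plate[plate$condition == "sample" & plate$replicate == 1,
               c("time_min", "signal")]
  bs <- blank_subtract(smp, blank)
  expect_equal(bs$signal, 2 * bs$time_min)
  # straight-line fit has zero residual
  fit <- activity_rate(bs)
  expect_equal(fit$rate, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
})

test_that("full inhibition gives an identically zero product curve", {
  p <- kinetic_sim_params(noise_sd = 0, inhibition_fraction = 1)
  res <- process_plate(simulate_kinetics(p))
  inhib <- res$curves[res$curves$inhibitor == "cocktail", ]
  expect_equal(inhib$product, rep(0, nrow(inhib)))
  # sensitive fraction then equals the full uninhibited curve
  un <- res$curves[res$curves$inhibitor == "none", ]
  sens <- res$sensitive
  expect_equal(sens$sensitive_product, un$product)
})

test_that("blank subtraction retains and flags negative values", {
  s <- data.frame(time_min = c(0, 15), signal = c(1, 1))
  b <- data.frame(time_min = c(0, 15), signal = c(2, 0))
  out <- blank_subtract(s, b)
  expect_equal(out$signal, c(-1, 1))
  expect_true(attr(out, "negative_flagged"))
  expect_error(blank_subtract(s, data.frame(time_min = c(0, 30),
                                            signal = c(0, 0))),
               "time grids")
})

test_that("replicate averaging: mean and SEM arithmetic", {
  r1 <- data.frame(time_min = c(0, 15), signal = c(0, 2))
  r2 <- data.frame(time_min = c(0, 15), signal = c(2, 0))
  avg <- average_replicates(list(r1, r2))
  expect_equal(avg$product, c(1, 1))
  expect_equal(avg$sem, c(1, 1))
  expect_identical(avg$n_replicates, c(2L, 2L))
  one <- average_replicates(list(r1))
  expect_equal(one$product, r1$signal)
  expect_equal(one$sem, c(0, 0))
})

test_that("sensitive fraction is the pointwise difference and is additive", {
  p <- kinetic_sim_params(noise_sd = 0, inhibition_fraction = 0.5,
                          rate_uninhibited = 2)
  res <- process_plate(simulate_kinetics(p))
  un <- res$curves[res$curves$inhibitor == "none", ]
  ih <- res$curves[res$curves$inhibitor == "cocktail", ]
  sens <- res$sensitive
  # worked value: at t = 60 min, sensitive product = 0.5 * 2 * 60 = 60
  expect_equal(sens$sensitive_product[sens$time_min == 60], 60)
  # additivity at machine precision at every timepoint
  expect_equal(ih$product + sens$sensitive_product, un$product,
               tolerance = 1e-12)
})

test_that("percent inhibition recovers the generative fraction exactly when noiseless", {
  p <- kinetic_sim_params(noise_sd = 0, inhibition_fraction = 0.5)
  res <- process_plate(simulate_kinetics(p))
  expect_equal(res$rates$percent_inhibition, 0.5, tolerance = 1e-12)
  # inactive inhibitor: zero percent inhibition, zero sensitive product
  p0 <- kinetic_sim_params(noise_sd = 0, inhibition_fraction = 0)
  res0 <- process_plate(simulate_kinetics(p0))
  expect_equal(res0$rates$percent_inhibition, 0, tolerance = 1e-12)
  expect_equal(res0$sensitive$sensitive_product,
               rep(0, nrow(res0$sensitive)))
})

test_that("flat uninhibited curves flag percent inhibition as undefined", {
  flat <- data.frame(time_min = seq(0, 60, 15), product = rep(5, 5))
  rising <- data.frame(time_min = seq(0, 60, 15),
                       product = seq(0, 60, 15) * 1.5)
  expect_equal(activity_rate(flat)$rate, 0, tolerance = 1e-12)
  out <- percent_inhibition(flat, rising)
  expect_true(is.na(out$percent_inhibition))
  expect_identical(out$flag, "nonpositive_uninhibited_rate")
})

test_that("blank-subtract and average commute when blanks are shared", {
  set.seed(42)
  t <- seq(0, 180, 15)
  blank <- data.frame(time_min = t, signal = 50 + rnorm(length(t)))
  reps <- lapply(1:3, function(i)
    data.frame(time_min = t, signal = 50 + 2 * t + rnorm(length(t))))
  # subtract then average
  a <- average_replicates(lapply(reps, blank_subtract, blank = blank))
  # average then subtract
  avg <- average_replicates(reps)
  b <- blank_subtract(data.frame(time_min = t, signal = avg$product), blank)
  expect_equal(a$product, b$signal, tolerance = 1e-12)
})

test_that("noisy recovery: estimate within 3 propagated SE of truth", {
  set.seed(7)
  hits <- 0
  n <- 50
  for (i in 1:n) {
    p <- kinetic_sim_params(noise_sd = 3, inhibition_fraction = 0.5,
                            seed = 1000 + i)
    res <- process_plate(simulate_kinetics(p))
    if (abs(res$rates$percent_inhibition - 0.5) <= 3 * res$rates$se)
      hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})
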