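test_that("Brownian motion generator matches its definition", {
  x <- simulate_brownian(1024, seed = 42)
  expect_length(x, 1024)
  expect_identical(x, simulate_brownian(1024, seed = 42)) # seed determinism
  inc <- diff(simulate_brownian(1e5, seed = 7))
  n <- length(inc)
  expect_lt(abs(mean(inc)), 3 / sqrt(n))             # mean 0 within 3 SE
  expect_lt(abs(var(inc) - 1), 3 * sqrt(2 / n))      # variance 1 within 3 SE
  expect_error(simulate_brownian(1), class = "pw_domain_error")
})

test_that("fGn increments have the closed-form lag-1 autocorrelation", {
  set.seed(42)
  for (H in c(0.5, 0.7)) {
    ac <- replicate(60, {
      g <- simulate_fgn(4096, H)
      cor(g[-1], g[-length(g)])
    })
    theo <- 2^(2 * H - 1) - 1
    expect_lt(abs(mean(ac) - theo), 3 * sd(ac) / sqrt(length(ac)) + 0.01)
  }
})

test_that("fBm variance grows as t^(2H)", {
  set.seed(42)
  H <- 0.8
  nrep <- 200
  X <- t(replicate(nrep, simulate_fbm(512, H)))
  t_idx <- c(8, 16, 32, 64, 128, 256, 512)
  v <- apply(X[, t_idx], 2, var)
  exponent <- coef(lm(log(v) ~ log(t_idx)))[2]
  expect_lt(abs(exponent - 2 * H), 0.1)
})

test_that("fBm covariance matches the analytic kernel at small n", {
  set.seed(42)
  n <- 32
  nrep <- 10000
  X <- matrix(0, nrep, n)
  for (r in seq_len(nrep)) X[r, ] <- simulate_fbm(n, 0.7)
  emp <- cov(X)
  s <- seq_len(n)
  theo <- outer(s, s, function(a, b) {
    0.5 * (a^1.4 + b^1.4 - abs(a - b)^1.4)
  })
  # elementwise within z * SE; SE of a covariance entry from the Gaussian
  # fourth-moment formula (sigma_ii sigma_jj + sigma_ij^2) / nrep
  se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / nrep)
  z <- abs(emp - theo) / se
  expect_lt(mean(z > 3), 0.01)  # ~0.3% expected beyond 3 SE by chance
  expect_lt(max(z), 5)
  expect_error(simulate_fbm(64, 1.2), class = "pw_domain_error")
  expect_error(simulate_fbm(64, 0), class = "pw_domain_error")
})

test_that("circulant and Cholesky fBm generators agree in law", {
  set.seed(42)
  h_circ <- replicate(40, estimate_hurst(simulate_fbm(1024, 0.6))$hurst)
  h_chol <- replicate(40, {
    estimate_hurst(simulate_fbm(1024, 0.6, method = "cholesky"))$hurst
  })
  expect_lt(abs(mean(h_circ) - mean(h_chol)),
            3 * sqrt(var(h_circ) / 40 + var(h_chol) / 40))
})

test_that("contamination perturbs exactly the selected coefficients", {
  x <- simulate_brownian(1024, seed = 42)
  d <- dwt_forward(x, "db6", 9)
  expect_identical(contaminate_decomposition(d, n_per_level = 0, seed = 1), d)
  expect_identical(contaminate_decomposition(d, 100, noise_sd = 0, seed = 1),
                   d)
  cont <- contaminate_decomposition(d, 100, seed = 42)
  expect_identical(cont$smooth, d$smooth)
  n_diff <- mapply(function(a, b) sum(a != b), cont$details, d$details)
  expect_equal(unname(n_diff),
               pmin(100, vapply(d$details, length, integer(1))),
               ignore_attr = TRUE)
  # untouched positions are bit-identical
  fine <- names(d$details)[9]
  same <- cont$details[[fine]] == d$details[[fine]]
  expect_identical(cont$details[[fine]][same], d$details[[fine]][same])
  # reproducible from seed
  expect_identical(cont, contaminate_decomposition(d, 100, seed = 42))
  expect_error(contaminate_decomposition(d, 100, noise_sd = -1),
               class = "pw_domain_error")
})

test_that("simulated cohorts have the specified structure", {
  spec <- cohort_spec(2, 2, sessions_per_subject = 8, session_length = 2048,
                      missing_fraction = 0.3, blink_burst_length = 64,
                      seed = 42)
  cohort <- simulate_cohort(spec)
  counts <- dplyr::count(cohort, participant_id, session)
  expect_equal(nrow(counts), 4 * 8)
  expect_true(all(counts$n == 2048))
  frac <- cohort |>
    dplyr::group_by(participant_id, session) |>
    dplyr::summarise(f = mean(missing), .groups = "drop")
  expect_true(all(frac$f >= 0.25 & frac$f <= 0.35))
  expect_identical(cohort, simulate_cohort(spec))
  expect_setequal(unique(cohort$group), c("case", "control"))
  expect_error(cohort_spec(2, 2, missing_fraction = 0.9),
               class = "pw_domain_error")
  expect_error(cohort_spec(2, 2, H_case = 1.1), class = "pw_domain_error")
})

test_that("estimated H separates groups in the simulated direction", {
  cohort <- small_cohort(n_per_group = 4, H_case = 0.7, H_control = 0.95,
                         session_length = 8192, sessions = 2, seed = 42)
  h <- cohort |>
    dplyr::filter(!missing) |>
    dplyr::group_by(participant_id, group, session) |>
    dplyr::summarise(h = estimate_hurst(value)$hurst, .groups = "drop") |>
    dplyr::group_by(group) |>
    dplyr::summarise(h = mean(h), .groups = "drop")
  expect_lt(h$h[h$group == "case"], h$h[h$group == "control"])
})
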