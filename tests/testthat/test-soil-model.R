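test_that("monthly aggregation enforces the 90% completeness boundary", {
  # 30-day month at 24 records/day: 720 expected
  full <- purrr::map_dfr(as.Date("2020-06-01") + 0:29, sinusoid_day,
                         mean_t = 4, amplitude = 2)
  agg <- aggregate_monthly(full, nominal_frequency = 24)
  expect_equal(agg$completeness, 1)
  expect_equal(agg$soilT, 4, tolerance = 1e-10)

  # 647 of 720 records (89.9%): dropped; 648 (90.0%): retained
  expect_equal(nrow(aggregate_monthly(full[1:647, ], 24)), 0)
  expect_equal(nrow(aggregate_monthly(full[1:648, ], 24)), 1)
  expect_error(aggregate_monthly(full), "nominal_frequency")
})

test_that("monthly extremes are type-7 5%/95% quantiles", {
  const <- purrr::map_dfr(as.Date("2020-06-01") + 0:4, sinusoid_day,
                          mean_t = 2.5, amplitude = 0)
  ex <- monthly_extremes(const)
  expect_equal(ex$t_min, 2.5)
  expect_equal(ex$t_max, 2.5)

  seq100 <- tibble::tibble(
    timestamp = as.POSIXct("2020-06-01", tz = "UTC") + 3600 * (1:100),
    temperature = 1:100
  )
  ex2 <- monthly_extremes(seq100)
  expect_equal(ex2$t_min, 5.95)
  expect_equal(ex2$t_max, 95.05)

  few <- seq100[1:19, ]
  expect_true(is.na(monthly_extremes(few)$t_min))
})

test_that("monthly means correlate strongly with monthly extremes", {
  w <- cached_world("extremes", world_config(
    n_glaciers = 2, stations_per_glacier = 2, n_months = 8,
    residual_sd = 0.5, seed = 23
  ))
  tr <- generate_logger_traces(w)
  agg <- aggregate_monthly(tr, 24)
  ex <- monthly_extremes(tr)
  j <- dplyr::inner_join(agg, ex, by = c("station_id", "year", "month")) |>
    # the diurnal amplitude is snow-dependent, so the mean-extreme link is
    # assessed over the snow-free season the model reconstructs
    dplyr::inner_join(
      dplyr::select(w$months, "station_id", "year", "month", "sfd"),
      by = c("station_id", "year", "month")
    ) |>
    dplyr::filter(sfd > 20)
  expect_gt(cor(j$soilT, j$t_min), 0.9)
  expect_gt(cor(j$soilT, j$t_max), 0.9)
})

test_that("the design standardizes after transforming and filters on sfd", {
  w <- small_world()
  d <- build_design(w$months)
  for (col in c("mT", "rad", "sfd", "dg", "d")) {
    expect_lt(abs(mean(d[[col]])), 1e-10)
    expect_equal(sd(d[[col]]), 1, tolerance = 1e-10)
  }
  std <- design_standardization(d)
  expect_setequal(std$term, c("mT", "rad", "sfd", "dg", "d"))

  # transform order: sqrt(dg) enters standardization
  row400 <- w$months[1, ]
  row400$dg <- 400
  xs <- forelandclim:::standardize_design(row400, std)
  sdg <- std[std$term == "dg", ]
  expect_equal(xs$dg, (20 - sdg$mean) / sdg$sd)

  # sfd boundary: 20.0 excluded, 20.1 included
  df <- w$months[1:2, ]
  df$sfd <- c(20.0, 20.1)
  d2 <- build_design(df, standardization = std)
  expect_equal(nrow(d2), 1)

  expect_error(build_design(dplyr::select(w$months, -"rad")), "rad")
})

test_that("worlds without glacier variance fit with matching R2m and R2c", {
  w <- cached_world("no_glacier_var", world_config(
    n_glaciers = 6, stations_per_glacier = 4, n_months = 12,
    glacier_intercept_sd = 0, residual_sd = 0.5, seed = 19
  ))
  d <- build_design(w$months)
  expect_error(fit_soil_lmm(d), "singular")
  f <- fit_soil_lmm(d, singular = "allow")
  expect_lt(f$r2c - f$r2m, 0.02)
  expect_lte(f$r2m, f$r2c)
  expect_lte(f$r2c, 1)
})

test_that("fit summary, tidy and glance expose the expected structure", {
  w <- small_world()
  f <- fit_soil_lmm(build_design(w$months))
  td <- tidy(f)
  expect_setequal(td$term, model_term_names())
  expect_true(all(td$conf.low < td$conf.high))
  gl <- glance(f)
  expect_equal(gl$n_glaciers, 8)
  expect_gt(gl$r2m, 0.5)
  expect_gte(gl$r2c, gl$r2m)
  expect_error(fit_soil_lmm(build_design(w$months[w$months$glacier_id == "g01", ])),
               "2 glaciers")
})

test_that("glacier intercept variance is recovered within 25%", {
  w <- cached_world("recover", world_config(seed = 77))
  f <- fit_soil_lmm(build_design(w$months))
  expect_lt(abs(f$sigma_glacier - 1.5) / 1.5, 0.25)
  expect_lt(abs(f$sigma_residual - 1.5) / 1.5, 0.25)
})

test_that("semi-partial R2 decomposes exactly for orthogonal designs", {
  # orthogonalized main-effect columns, zero interaction coefficients:
  # the variance of the linear predictor decomposes term by term
  set.seed(30)
  n <- 500
  raw <- matrix(rnorm(n * 5), n, 5)
  q <- qr.Q(qr(cbind(1, raw)))[, 2:6] * sqrt(n)
  design <- tibble::tibble(
    mT = q[, 1], rad = q[, 2], sfd = q[, 3], dg = q[, 4], d = q[, 5],
    tc = 0, pf = 0, gl = rep(c("a", "b", "c"), length.out = n)
  )
  beta <- c("(Intercept)" = 1, mT = 2, rad = -1, sfd = 0.5, dg = 0.25,
            tc = 0, pf = 0, d = -0.75, "mT:sfd" = 0, "rad:sfd" = 0,
            "sfd:dg" = 0, "sfd:d" = 0, "rad:tc" = 0)
  s2_e <- 1
  sp <- forelandclim:::semi_partial_once(beta, design, s2_g = 0, s2_e = s2_e)
  mm <- forelandclim:::model_matrix_fixed(design)
  lp <- as.vector(mm %*% beta[colnames(mm)])
  r2m <- var(lp) / (var(lp) + s2_e)
  expect_equal(sum(sp$semi_partial_r2), r2m, tolerance = 1e-10)
  # a term with coefficient exactly zero contributes exactly zero
  expect_equal(sp$semi_partial_r2[sp$term == "pf"], 0)
})

test_that("semi-partial R2 on a fitted world is positive for true drivers", {
  w <- small_world()
  f <- fit_soil_lmm(build_design(w$months))
  sp <- semi_partial_r2(f, n_bootstrap = 10, seed = 4)
  expect_gt(sp$semi_partial_r2[sp$term == "mT"], 0.05)
  expect_true(all(c("conf.low", "conf.high") %in% names(sp)))
  expect_true(all(sp$conf.low <= sp$conf.high))
})

test_that("permutation importance is zero for inert predictors and ranks drivers", {
  w <- small_world()
  f <- fit_soil_lmm(build_design(w$months))

  # force pf (no interactions) to zero: permuting it cannot move predictions
  f0 <- f
  f0$coefficients["pf"] <- 0
  imp0 <- permutation_importance(f0, n_perm = 5, seed = 9)
  expect_equal(imp0$importance[imp0$predictor == "pf"], 0, tolerance = 1e-12)

  imp <- permutation_importance(f, n_perm = 30, seed = 9)
  expect_equal(
    imp$predictor[which.max(imp$importance)], "mT"
  )
  expect_true(all(imp$importance >= 0 & imp$importance <= 2))
})

test_that("leave-one-glacier-out produces one fold per glacier and stable means", {
  w <- small_world()
  d <- build_design(w$months)
  loo <- loo_by_glacier(d)
  expect_equal(nrow(loo$coefficients), 8)
  expect_setequal(loo$coefficients$glacier_id, unique(d$gl))

  f <- fit_soil_lmm(d)
  rel <- abs(loo$mean_coefficients - f$coefficients[names(loo$mean_coefficients)]) /
    abs(f$coefficients[names(loo$mean_coefficients)])
  expect_lt(max(rel), 0.05)

  expect_error(loo_by_glacier(d[d$gl %in% unique(d$gl)[1:2], ]), "3 glaciers")
})

test_that("mean-coefficient predictions are standardization-invariant", {
  w <- small_world()
  d <- build_design(w$months)
  loo <- loo_by_glacier(d)

  # raw-unit route: reconstruct raw covariates for the retained rows
  raw <- w$months[w$months$sfd > 20, ]
  p_raw <- predict_mean_coefficients(loo, raw)
  p_std <- predict_mean_coefficients(loo, d)
  expect_equal(p_raw$.pred, p_std$.pred, tolerance = 1e-10)

  # a row at the training mean of every predictor predicts the mean intercept
  std <- loo$standardization
  at_mean <- tibble::tibble(
    mT = std$mean[std$term == "mT"], rad = std$mean[std$term == "rad"],
    sfd = std$mean[std$term == "sfd"], dg = std$mean[std$term == "dg"]^2,
    tc = 0, pf = 0, depth_cm = std$mean[std$term == "d"]
  )
  p0 <- predict_mean_coefficients(loo, at_mean)
  expect_equal(p0$.pred, unname(loo$mean_coefficients["(Intercept)"]),
               tolerance = 1e-10)
})

test_that("validation is exact for perfect predictions and near the noise floor otherwise", {
  w <- small_world()
  d <- build_design(w$months)
  perfect <- dplyr::mutate(d, .pred = .data$soilT,
                           sfd_raw = w$months$sfd[w$months$sfd > 20])
  v <- validate_predictions(dplyr::mutate(perfect, sfd = .data$sfd_raw))
  expect_equal(v$wr2, 1)
  expect_equal(v$wmae, 0)

  # held-out predictions on a world with 1.5 degC residual noise and modest
  # glacier effects: wRMSE sits near the generator noise floor
  wn <- cached_world("noisefloor", world_config(
    n_glaciers = 10, stations_per_glacier = 5, n_months = 12,
    residual_sd = 1.5, glacier_intercept_sd = 0.5, seed = 55
  ))
  dn <- build_design(wn$months)
  loo <- loo_by_glacier(dn)
  preds <- predict_mean_coefficients(loo, dn)
  preds$sfd <- wn$months$sfd[wn$months$sfd > 20]
  vn <- validate_predictions(preds)
  expect_gt(vn$wrmse, 1.2)
  expect_lt(vn$wrmse, 2.0)
})

test_that("stations cluster by single linkage at 1000 m", {
  pts <- tibble::tibble(
    station_id = paste0("s", 1:6),
    x = c(0, 500, 900, 5000, 5600, 9000),
    y = 0
  )
  cl <- cluster_stations(pts, cutoff = 1000)
  # chain 1-2-3 links (gaps 500, 400); 4-5 links (600); 6 alone
  expect_equal(length(unique(cl$cluster)), 3)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[2], cl$cluster[3])
  expect_equal(cl$cluster[4], cl$cluster[5])
  expect_false(cl$cluster[5] == cl$cluster[6])
})

test_that("snow decoupling distorts residuals below the 20% sfd cutoff", {
  w <- cached_world("decouple", world_config(
    n_glaciers = 8, stations_per_glacier = 5, n_months = 18, seed = 61
  ))
  diag <- suppressWarnings(
    sfd_cutoff_diagnostics(w$months, cutoffs = c(0, 10, 20), min_rows = 50)
  )
  expect_equal(diag$cutoff, c(0, 10, 20))
  expect_gt(diag$curvature[1], diag$curvature[3])

  # a cutoff that drops everything is skipped with a warning
  expect_warning(
    out <- sfd_cutoff_diagnostics(w$months, cutoffs = 100, min_rows = 100),
    "skipped"
  )
  expect_equal(nrow(out), 0)
})
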