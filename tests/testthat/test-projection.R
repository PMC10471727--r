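test_that("projection with the generating coefficients closes the loop", {
  w <- small_world()
  truth <- w$truth
  # per-row burial depths so the prediction matches the generating design
  proj2 <- project_soil_temperature(
    truth$coefficients, truth$standardization, w$months,
    depth_cm = w$months$depth_cm
  )
  kept <- w$months$sfd > 20
  expect_equal(proj2$.pred[kept], w$months$mu_fixed[kept], tolerance = 1e-8)
  # snow-decoupled cells are masked
  expect_true(all(is.na(proj2$.pred[!kept])))
})

test_that("projection masks low-sfd and image-poor cells", {
  w <- small_world()
  cov <- w$months[1:3, ]
  cov$sfd <- c(15, 50, 50)
  cov$n_images <- c(30, 10, 30)
  p <- project_soil_temperature(w$truth$coefficients, w$truth$standardization,
                                cov, depth_cm = 5)
  expect_true(is.na(p$.pred[1])) # sfd 15 <= 20
  expect_true(is.na(p$.pred[2])) # 10 images < 15
  expect_false(is.na(p$.pred[3]))
})

test_that("covariates at the training mean predict the intercept", {
  w <- small_world()
  std <- w$truth$standardization
  m <- function(tm) std$mean[std$term == tm]
  cov <- tibble::tibble(
    mT = m("mT"), rad = m("rad"), sfd = m("sfd"), dg = m("dg")^2, tc = 0, pf = 0
  )
  p <- project_soil_temperature(w$truth$coefficients, std, cov,
                                depth_cm = m("d"))
  expect_equal(p$.pred, unname(w$truth$coefficients["(Intercept)"]),
               tolerance = 1e-10)
})

test_that("stratified sampling honors classes, completeness and the seed", {
  set.seed(99)
  # two 50 km cells of candidates; cell B lacks the farthest class
  mk_cell <- function(x0, classes) {
    purrr::map_dfr(classes, function(i) {
      cl <- distance_classes()[i, ]
      tibble::tibble(
        x = runif(8, x0, x0 + 49000), y = runif(8, 0, 49000),
        distance = runif(8, cl$lower, cl$upper)
      )
    })
  }
  cand <- dplyr::bind_rows(mk_cell(0, 1:5), mk_cell(50000, 1:4))
  pts <- stratified_sample(cand, seed = 5)
  expect_equal(length(unique(pts$cell_id)), 1) # incomplete cell dropped
  expect_equal(nrow(pts), 10)
  expect_equal(as.integer(table(pts$distance_class)), rep(2L, 5))

  # sampled distances lie inside their class band
  cls <- distance_classes()
  for (i in seq_len(nrow(pts))) {
    band <- cls[cls$label == pts$distance_class[i], ]
    expect_gte(pts$distance[i], band$lower)
    expect_lte(pts$distance[i], band$upper)
  }

  # no duplicated candidate within a class (sampling without replacement)
  expect_false(any(duplicated(pts[, c("x", "y")])))

  expect_identical(stratified_sample(cand, seed = 5), pts)
  expect_error(stratified_sample(cand), "seed")
  expect_error(stratified_sample(cand[0, ], seed = 1), "no valid")
})

test_that("delta_t is exact, antisymmetric and pairwise-masked", {
  temps <- tidyr::expand_grid(point_id = c("p1", "p2"), month = 1:12) |>
    dplyr::mutate(
      early = 2 + 0.3 * month, late = .data$early + 0.75
    ) |>
    tidyr::pivot_longer(c("early", "late"), names_to = "period",
                        values_to = "temperature")
  dt <- delta_t(temps)
  expect_equal(dt$delta_t, rep(0.75, 2))

  same <- dplyr::mutate(temps, temperature = 1)
  expect_equal(delta_t(same)$delta_t, rep(0, 2))

  # antisymmetry under period swap
  swapped <- dplyr::mutate(temps, period = ifelse(period == "early", "late", "early"))
  expect_equal(delta_t(swapped)$delta_t, -dt$delta_t)

  # a month masked in one period is dropped from both means
  masked <- temps
  masked$temperature[masked$point_id == "p1" & masked$month == 7 &
                       masked$period == "late"] <- NA
  dtm <- delta_t(masked)
  expect_equal(dtm$n_months[dtm$point_id == "p1"], 11)
  expect_equal(dtm$delta_t[dtm$point_id == "p1"], 0.75, tolerance = 1e-12)

  # seasonal selection: DJF only uses months 12, 1, 2
  djf <- delta_t(temps, season = "DJF")
  expect_equal(djf$n_months, rep(3, 2))
  expect_error(delta_t(dplyr::filter(temps, period == "early")), "both periods")
})

test_that("the generator trend propagates through projection as arithmetic says", {
  w <- small_world()
  cfg <- w$config
  delta <- cfg$trend * 1.5 # 15-year gap, degC/decade
  early <- w$months
  late <- dplyr::mutate(early, mT = .data$mT + delta)
  pe <- project_soil_temperature(w$truth$coefficients, w$truth$standardization,
                                 early, depth_cm = early$depth_cm)
  pl <- project_soil_temperature(w$truth$coefficients, w$truth$standardization,
                                 late, depth_cm = late$depth_cm)
  kept <- !is.na(pe$.pred) & !is.na(pl$.pred)
  std <- w$truth$standardization
  sd_mT <- std$sd[std$term == "mT"]
  z_sfd <- (early$sfd - std$mean[std$term == "sfd"]) / std$sd[std$term == "sfd"]
  expected <- (w$truth$coefficients["mT"] +
                 w$truth$coefficients["mT:sfd"] * z_sfd) * delta / sd_mT
  expect_equal(pl$.pred[kept] - pe$.pred[kept], unname(expected[kept]),
               tolerance = 1e-8)
})

test_that("t_var matches the quantile oracle and respects the buffer", {
  pt <- tibble::tibble(point_id = "p", x = 0, y = 0)
  const <- tidyr::expand_grid(x = seq(-200, 200, 50), y = seq(-200, 200, 50)) |>
    dplyr::mutate(temperature = 3)
  expect_equal(t_var(pt, const)$t_var, 0)

  # 100 cells inside the buffer with values 1..100: q90 - q10 = 79.2
  ring <- tibble::tibble(
    x = rep(seq(-45, 45, 10), 10), y = rep(seq(-45, 45, 10), each = 10),
    temperature = 1:100
  )
  expect_equal(t_var(pt, ring, radius = 250)$t_var, 79.2)

  # radius below the cell spacing: only the host cell remains
  expect_true(is.na(t_var(pt, ring, radius = 4)$t_var))
  expect_equal(t_var(tibble::tibble(point_id = "p", x = -45, y = -45),
                     ring, radius = 4, min_cells = 1)$t_var, 0)
})

test_that("buffering potential keeps the sign of the change and classes correctly", {
  b <- t_bp(c(2, 2, 0.5, 25, 0.3), c(1, -1, 1, -2, 0))
  expect_equal(b$t_bp[1:4], c(2, -2, 0.5, -12.5))
  expect_equal(as.character(b$t_bp_class),
               c("(1,10]", "(-10,-1]", "(-1,1]", "<=-10", ">10"))
  expect_true(is.infinite(b$t_bp[5])) # near-zero change sentinel

  # sign(T_bp) follows sign(delta_t) whenever t_var > 0
  set.seed(41)
  tv <- runif(50, 0.01, 3); dt <- rnorm(50)
  bb <- t_bp(tv, dt)
  expect_true(all(sign(bb$t_bp) == sign(dt)))

  # classification is scale-invariant in (t_var, |delta_t|)
  b1 <- t_bp(tv, dt)$t_bp_class
  b2 <- t_bp(tv * 7, dt * 7)$t_bp_class
  expect_equal(b1, b2)
  expect_error(t_bp(-1, 1), ">= 0")
})

test_that("summaries group by band and class with percentages summing to 100", {
  set.seed(42)
  rec <- tibble::tibble(
    band = latitude_band(runif(300, -60, 70)),
    distance_class = forelandclim:::classify_distance(
      sample(c(50, 500, 1000, 2000, 3000), 300, replace = TRUE)
    ),
    delta_t = rnorm(300, 0.6, 0.4),
    season_change = rnorm(300, 10, 5),
    t_bp_class = t_bp(runif(300, 0, 3), rnorm(300, 0.6, 0.4))$t_bp_class
  )
  s <- summarize_buffering(rec)
  sums <- tapply(s$buffering$percent,
                 paste(s$buffering$band, s$buffering$distance_class), sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-10)
  expect_true(all(s$changes$n >= 1))

  single <- summarize_buffering(tibble::tibble(
    band = latitude_band(50), distance_class = factor("0-100"),
    delta_t = 0.4
  ))
  expect_equal(single$changes$mean_delta_t, 0.4)
  expect_true(is.na(single$changes$sd_delta_t))
  expect_error(summarize_buffering(rec[0, ]), "no records")
})

test_that("latitude bands split at the Tropics", {
  expect_equal(as.character(latitude_band(c(50, 23.44, -23.44, -50, 0))),
               c("Northern", "Inter-tropical", "Inter-tropical", "Southern",
                 "Inter-tropical"))
})

test_that("the extrapolation audit counts strict range exceedances", {
  tr <- tibble::tibble(term = c("mT", "rad"), min = c(-5, 0), max = c(10, 30))
  inside <- tibble::tibble(mT = seq(-5, 10, length.out = 50),
                           rad = seq(0, 30, length.out = 50))
  a <- extrapolation_audit(inside, tr)
  expect_equal(a$pct_outside, c(0, 0))

  out5 <- tibble::tibble(mT = c(rep(0, 95), rep(11, 5)), rad = 15)
  a2 <- extrapolation_audit(out5, tr)
  expect_equal(a2$pct_outside[a2$term == "mT"], 5)
  expect_equal(a2$pct_outside[a2$term == "rad"], 0)

  w <- small_world()
  rng <- training_ranges(w$months)
  expect_setequal(rng$term, c("mT", "rad", "sfd", "dg"))
  expect_equal(extrapolation_audit(w$months, rng)$pct_outside, rep(0, 4))
})
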