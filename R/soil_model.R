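#' Model terms of the soil temperature mixed model
#'
#' The fixed structure is
#' `soilT ~ mT + rad + sfd + dg + tc + pf + d + sfd:mT + sfd:rad + sfd:dg +
#' sfd:d + tc:rad` with a random intercept per glacier (`1 | gl`), where
#' `mT` is downscaled macroclimate (deg C), `rad` daily cumulative
#' shortwave (MJ m-2 d-1), `sfd` monthly snow-free-day frequency (%), `dg`
#' the square-root-transformed distance from the glacier forefront, `tc`
#' and `pf` tree-cover and permafrost occurrence (0/1), and `d` burial
#' depth (cm, treated as continuous by default).
#'
#' @return Character vector of fixed-term names in model-matrix order.
#' @export
model_term_names <- function() {
  colnames(model_matrix_fixed(tibble::tibble(
    mT = c(0, 1), rad = c(0, 1), sfd = c(0, 1), dg = c(0, 1),
    tc = c(0, 1), pf = c(0, 1), d = c(0, 1)
  )))
}

# fixed-effects formula (response excluded); kept in one place so the
# generator, the fit and the projection all share the same design
fixed_formula <- function() {
  ~ mT + rad + sfd + dg + tc + pf + d +
    sfd:mT + sfd:rad + sfd:dg + sfd:d + tc:rad
}

model_matrix_fixed <- function(df) {
  stats::model.matrix(fixed_formula(), data = df)
}

# continuous columns standardized in the design (dg already sqrt-transformed)
continuous_terms <- function(depth_continuous = TRUE) {
  if (depth_continuous) c("mT", "rad", "sfd", "dg", "d") else c("mT", "rad", "sfd", "dg")
}

compute_standardization <- function(df, depth_continuous = TRUE) {
  terms <- continuous_terms(depth_continuous)
  vals <- lapply(terms, function(v) {
    x <- if (v == "dg") sqrt(df$dg) else if (v == "d") df$depth_cm else df[[v]]
    c(mean = mean(x), sd = stats::sd(x))
  })
  out <- tibble::tibble(
    term = terms,
    mean = vapply(vals, `[[`, numeric(1), "mean"),
    sd = vapply(vals, `[[`, numeric(1), "sd")
  )
  if (any(!is.finite(out$sd) | out$sd <= 0)) {
    stop("standardization impossible: zero or undefined sd for ",
         paste(out$term[!is.finite(out$sd) | out$sd <= 0], collapse = ", "),
         call. = FALSE)
  }
  out
}

standardize_design <- function(df, standardization) {
  s <- function(term) {
    r <- standardization[standardization$term == term, ]
    if (nrow(r) != 1) stop("no standardization entry for ", term, call. = FALSE)
    r
  }
  out <- tibble::tibble(
    mT = (df$mT - s("mT")$mean) / s("mT")$sd,
    rad = (df$rad - s("rad")$mean) / s("rad")$sd,
    sfd = (df$sfd - s("sfd")$mean) / s("sfd")$sd,
    dg = (sqrt(df$dg) - s("dg")$mean) / s("dg")$sd,
    tc = as.numeric(df$tc),
    pf = as.numeric(df$pf)
  )
  if ("d" %in% standardization$term) {
    out$d <- (df$depth_cm - s("d")$mean) / s("d")$sd
  } else {
    out$d <- df$depth_cm
  }
  out
}

#' Aggregate a logger trace to monthly means with a completeness filter
#'
#' Completeness of a month is the share of records present out of
#' `nominal_frequency x days in month`; months below `min_completeness`
#' (default 0.9) are dropped and the mean is taken over all retained raw
#' records.
#'
#' @param trace Tibble with `timestamp`, `temperature`, optional
#'   `station_id` and metadata columns.
#' @param nominal_frequency Declared records per day (required).
#' @param min_completeness Completeness cutoff in `[0, 1]`, default 0.9.
#' @return Tibble with `station_id` (if present), `year`, `month`,
#'   `n_records`, `completeness`, `soilT`.
#' @export
aggregate_monthly <- function(trace, nominal_frequency, min_completeness = 0.9) {
  if (missing(nominal_frequency) || !is.numeric(nominal_frequency) ||
      nominal_frequency <= 0) {
    stop("nominal_frequency (records/day) must be declared and positive",
         call. = FALSE)
  }
  keys <- intersect("station_id", names(trace))
  trace |>
    dplyr::mutate(
      year = as.integer(format(.data$timestamp, "%Y", tz = "UTC")),
      month = as.integer(format(.data$timestamp, "%m", tz = "UTC"))
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year", "month")))) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      soilT = mean(.data$temperature),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      completeness = pmin(1, .data$n_records /
                            (nominal_frequency * days_in_month(.data$year, .data$month)))
    ) |>
    dplyr::filter(.data$completeness >= min_completeness) |>
    dplyr::relocate("completeness", .after = "n_records")
}

#' Monthly temperature extremes as 5% / 95% quantiles
#'
#' @param trace Tibble with `timestamp`, `temperature`, optional
#'   `station_id`.
#' @param min_records Minimum records in a month (default 20); months below
#'   it return `NA` extremes.
#' @return Tibble with `year`, `month`, `t_min`, `t_max` (type-7 quantiles).
#' @export
monthly_extremes <- function(trace, min_records = 20) {
  keys <- intersect("station_id", names(trace))
  trace |>
    dplyr::mutate(
      year = as.integer(format(.data$timestamp, "%Y", tz = "UTC")),
      month = as.integer(format(.data$timestamp, "%m", tz = "UTC"))
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year", "month")))) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      t_min = if (dplyr::n() >= min_records) {
        stats::quantile(.data$temperature, 0.05, type = 7, names = FALSE)
      } else NA_real_,
      t_max = if (dplyr::n() >= min_records) {
        stats::quantile(.data$temperature, 0.95, type = 7, names = FALSE)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Build the standardized design table
#'
#' Drops months with `sfd <= sfd_cutoff` (strictly greater retained),
#' square-root transforms the glacier distance, and standardizes the
#' continuous predictors to zero mean and unit variance. The
#' standardization is computed from this table unless one is supplied
#' (validation and projection reuse the training standardization
#' unchanged).
#'
#' @param df Tibble with `soilT` (optional for projection inputs), `mT`,
#'   `rad`, `sfd`, `dg`, `tc`, `pf`, `depth_cm`, `gl` and optional label
#'   columns.
#' @param sfd_cutoff Snow-decoupling cutoff, percent (default 20).
#' @param standardization Optional standardization tibble from a previous
#'   [build_design()] call.
#' @param depth_continuous Standardize depth as a continuous predictor
#'   (default) or leave it on its raw cm scale.
#' @return A tibble (class `fc_design`) with the standardized predictor
#'   columns plus carried-through labels; the standardization is attached
#'   as attribute `"standardization"` (see [design_standardization()]).
#' @export
build_design <- function(df, sfd_cutoff = 20, standardization = NULL,
                         depth_continuous = TRUE) {
  need <- c("mT", "rad", "sfd", "dg", "tc", "pf", "depth_cm", "gl")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("unresolvable covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !stats::complete.cases(df[, need])
  if (any(bad)) {
    stop("unresolvable covariates in rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (any(df$dg < 0)) stop("dg must be >= 0", call. = FALSE)
  kept <- df[df$sfd > sfd_cutoff, , drop = FALSE]
  if (is.null(standardization)) {
    standardization <- compute_standardization(kept, depth_continuous)
  }
  xs <- standardize_design(kept, standardization)
  carry <- setdiff(names(kept), c(names(xs), "depth_cm"))
  out <- dplyr::bind_cols(kept[, carry, drop = FALSE], xs)
  out <- tibble::as_tibble(out)
  attr(out, "standardization") <- standardization
  attr(out, "sfd_cutoff") <- sfd_cutoff
  class(out) <- c("fc_design", class(out))
  out
}

#' @rdname build_design
#' @param design An `fc_design`.
#' @export
design_standardization <- function(design) attr(design, "standardization")

#' Fit the soil temperature linear mixed model
#'
#' REML fit (via lme4) of the full fixed structure with a single random
#' intercept on glacier. Marginal and conditional R2 follow the
#' variance-partitioning form: with `s2_f` the variance of the fixed linear
#' predictor, `s2_g` the glacier-intercept variance and `s2_e` the residual
#' variance, `R2m = s2_f / (s2_f + s2_g + s2_e)` and
#' `R2c = (s2_f + s2_g) / (s2_f + s2_g + s2_e)`.
#'
#' @param design An `fc_design` from [build_design()] containing `soilT`
#'   and `gl`.
#' @param singular `"error"` (default) stops on a singular fit (glacier
#'   variance collapsed to zero) with advice; `"allow"` keeps the fit,
#'   which is the right choice for worlds generated without between-glacier
#'   variance.
#' @return An `fc_soil_fit`: lme4 model plus coefficients, variance
#'   components, R2m/R2c, the design and its standardization.
#' @export
fit_soil_lmm <- function(design, singular = c("error", "allow")) {
  singular <- match.arg(singular)
  if (!"soilT" %in% names(design)) stop("design lacks a soilT response", call. = FALSE)
  if (dplyr::n_distinct(design$gl) < 2) {
    stop("at least 2 glaciers are required to fit the random intercept",
         call. = FALSE)
  }
  f <- stats::update(fixed_formula(), soilT ~ . + (1 | gl))
  model <- suppressMessages(lme4::lmer(f, data = design, REML = TRUE))
  if (singular == "error" && lme4::isSingular(model, tol = 1e-5)) {
    stop(paste(
      "singular fit: the glacier-intercept variance collapsed to (near) zero;",
      "consider more glaciers or dropping the random intercept"
    ), call. = FALSE)
  }
  conv <- model@optinfo$conv$lme4
  msgs <- setdiff(conv$messages, grep("singular", conv$messages, value = TRUE))
  if (length(msgs) > 0) {
    stop("mixed-model fit did not converge cleanly: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  beta <- lme4::fixef(model)
  vc <- as.data.frame(lme4::VarCorr(model))
  s2_g <- vc$vcov[vc$grp == "gl"]
  s2_e <- stats::sigma(model)^2
  lp <- as.vector(model_matrix_fixed(design) %*% beta)
  s2_f <- stats::var(lp)
  tot <- s2_f + s2_g + s2_e
  structure(
    list(
      model = model,
      coefficients = beta,
      sigma_glacier = sqrt(s2_g),
      sigma_residual = sqrt(s2_e),
      r2m = s2_f / tot,
      r2c = (s2_f + s2_g) / tot,
      design = design,
      standardization = design_standardization(design)
    ),
    class = "fc_soil_fit"
  )
}

#' @export
print.fc_soil_fit <- function(x, ...) {
  cat(sprintf(
    "soil temperature LMM: %d rows, %d glaciers | R2m %.3f, R2c %.3f\n",
    nrow(x$design), dplyr::n_distinct(x$design$gl), x$r2m, x$r2c
  ))
  cat(sprintf("  sigma(glacier) %.3f, sigma(residual) %.3f degC\n",
              x$sigma_glacier, x$sigma_residual))
  invisible(x)
}

#' @export
tidy.fc_soil_fit <- function(x, ...) {
  se <- sqrt(diag(as.matrix(stats::vcov(x$model))))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    conf.low = unname(x$coefficients - stats::qnorm(0.975) * se),
    conf.high = unname(x$coefficients + stats::qnorm(0.975) * se)
  )
}

#' @export
glance.fc_soil_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$design),
    n_glaciers = dplyr::n_distinct(x$design$gl),
    r2m = x$r2m,
    r2c = x$r2c,
    sigma_glacier = x$sigma_glacier,
    sigma_residual = x$sigma_residual,
    reml_criterion = lme4::REMLcrit(x$model)
  )
}

#' Semi-partial R2 of each fixed term
#'
#' For each fixed term, its contribution is removed from the full fit's
#' linear predictor (coefficients are not re-estimated) and the drop in
#' explained variance relative to the full model's total variance
#' (`s2_f + s2_g + s2_e`) is the term's semi-partial R2. Confidence
#' intervals come from a glacier-block bootstrap: glaciers are resampled
#' with replacement, the model is refit, and the decomposition recomputed.
#'
#' @param fit An `fc_soil_fit`.
#' @param n_bootstrap Bootstrap replicates (default 1000); 0 skips the
#'   intervals.
#' @param seed Seed for the bootstrap resampling.
#' @return Tibble with `term`, `semi_partial_r2`, and bootstrap `conf.low`,
#'   `conf.high` (2.5/97.5 percentiles) when requested.
#' @export
semi_partial_r2 <- function(fit, n_bootstrap = 1000, seed = 1) {
  stopifnot(inherits(fit, "fc_soil_fit"))
  point <- semi_partial_once(fit$coefficients, fit$design,
                             fit$sigma_glacier^2, fit$sigma_residual^2)
  if (n_bootstrap > 0) {
    set.seed(seed)
    gl_ids <- unique(fit$design$gl)
    boots <- purrr::map(seq_len(n_bootstrap), function(b) {
      take <- sample(gl_ids, length(gl_ids), replace = TRUE)
      dfb <- purrr::map_dfr(seq_along(take), function(i) {
        rows <- fit$design[fit$design$gl == take[i], ]
        rows$gl <- paste0(take[i], "_", i) # resampled copies are distinct groups
        rows
      })
      fb <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(stats::update(fixed_formula(), soilT ~ . + (1 | gl)),
                     data = dfb, REML = TRUE)
        )),
        error = function(e) NULL
      )
      if (is.null(fb)) return(NULL)
      vc <- as.data.frame(lme4::VarCorr(fb))
      s2g <- vc$vcov[vc$grp == "gl"]
      if (length(s2g) != 1 || !is.finite(s2g)) s2g <- 0
      semi_partial_once(lme4::fixef(fb), dfb, s2g,
                        stats::sigma(fb)^2)$semi_partial_r2
    })
    boots <- do.call(rbind, boots[!vapply(boots, is.null, logical(1))])
    point$conf.low <- apply(boots, 2, stats::quantile, 0.025, type = 7, na.rm = TRUE)
    point$conf.high <- apply(boots, 2, stats::quantile, 0.975, type = 7, na.rm = TRUE)
  }
  point
}

semi_partial_once <- function(beta, design, s2_g, s2_e) {
  mm <- model_matrix_fixed(design)
  beta <- beta[colnames(mm)]
  lp_full <- as.vector(mm %*% beta)
  tot <- stats::var(lp_full) + s2_g + s2_e
  terms <- setdiff(colnames(mm), "(Intercept)")
  sp <- vapply(terms, function(tm) {
    lp_red <- lp_full - mm[, tm] * beta[tm]
    (stats::var(lp_full) - stats::var(lp_red)) / tot
  }, numeric(1))
  tibble::tibble(term = terms, semi_partial_r2 = unname(sp))
}

#' Permutation importance of each raw predictor
#'
#' Each raw predictor column is permuted `n_perm` times; the design matrix
#' is rebuilt from the permuted column so additive and interactive
#' contributions are broken jointly, fixed-effect predictions are
#' recomputed, and the Pearson correlation `r` between original and
#' permuted predictions is taken. Importance is the mean of `1 - r`.
#'
#' @param fit An `fc_soil_fit`.
#' @param n_perm Permutations per predictor (default 1000).
#' @param seed Seed for the permutation stream.
#' @return Tibble with `predictor` and `importance` (`NA` when predictions
#'   are constant and `r` is undefined).
#' @export
permutation_importance <- function(fit, n_perm = 1000, seed = 1) {
  stopifnot(inherits(fit, "fc_soil_fit"))
  set.seed(seed)
  design <- fit$design
  beta <- fit$coefficients
  pred0 <- as.vector(model_matrix_fixed(design) %*% beta[colnames(model_matrix_fixed(design))])
  preds <- c("mT", "rad", "sfd", "dg", "tc", "pf", "d")
  if (stats::sd(pred0) == 0) {
    return(tibble::tibble(predictor = preds, importance = NA_real_))
  }
  purrr::map_dfr(preds, function(p) {
    one_minus_r <- vapply(seq_len(n_perm), function(k) {
      dperm <- design
      dperm[[p]] <- sample(dperm[[p]])
      predp <- as.vector(model_matrix_fixed(dperm) %*% beta)
      r <- suppressWarnings(stats::cor(pred0, predp))
      1 - r
    }, numeric(1))
    tibble::tibble(predictor = p, importance = mean(one_minus_r))
  })
}

#' Leave-one-glacier-out transferability analysis
#'
#' Refits the full model once per held-out glacier; stores each fold's
#' fixed coefficients and their unweighted arithmetic mean (standardized
#' scale). Held-out predictions use the fold's own coefficients with the
#' random effect omitted; [predict_mean_coefficients()] applies the mean
#' vector to arbitrary new rows. Folds that fail to converge are dropped
#' from the mean with a warning.
#'
#' @param design An `fc_design` with `soilT` and `gl`.
#' @return An `fc_loo`: `coefficients` (fold x term tibble),
#'   `mean_coefficients`, `predictions` (held-out rows with `.pred`),
#'   `standardization`.
#' @export
loo_by_glacier <- function(design) {
  gl_ids <- unique(design$gl)
  if (length(gl_ids) < 3) stop("at least 3 glaciers are required", call. = FALSE)
  f <- stats::update(fixed_formula(), soilT ~ . + (1 | gl))
  folds <- purrr::map(gl_ids, function(g) {
    train <- design[design$gl != g, ]
    test <- design[design$gl == g, ]
    fitg <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(f, data = train, REML = TRUE))),
      error = function(e) NULL
    )
    if (is.null(fitg)) {
      warning("leave-one-out fold for glacier ", g, " failed to converge; skipped")
      return(NULL)
    }
    beta <- lme4::fixef(fitg)
    mm <- model_matrix_fixed(test)
    preds <- dplyr::mutate(test, .pred = as.vector(mm %*% beta[colnames(mm)]))
    list(glacier = g, beta = beta, preds = preds)
  })
  folds <- folds[!vapply(folds, is.null, logical(1))]
  coefs <- purrr::map_dfr(folds, function(fd) {
    tibble::as_tibble(as.list(fd$beta)) |>
      dplyr::mutate(glacier_id = fd$glacier, .before = 1)
  })
  mean_beta <- colMeans(as.matrix(coefs[, -1]))
  names(mean_beta) <- names(coefs)[-1]
  structure(
    list(
      coefficients = coefs,
      mean_coefficients = mean_beta,
      predictions = purrr::map_dfr(folds, "preds"),
      standardization = design_standardization(design)
    ),
    class = "fc_loo"
  )
}

#' @export
print.fc_loo <- function(x, ...) {
  cat(sprintf("leave-one-glacier-out: %d folds, %d held-out predictions\n",
              nrow(x$coefficients), nrow(x$predictions)))
  invisible(x)
}

#' Predict soil temperature from mean leave-one-out coefficients
#'
#' Applies a fixed-coefficient vector to new rows with the random effect
#' omitted. Raw-unit inputs (columns `mT`, `rad`, `sfd`, `dg` in m,
#' `depth_cm`) are standardized with the stored training standardization;
#' already-standardized designs (class `fc_design`) are used as is, so both
#' routes give identical predictions.
#'
#' @param object An `fc_loo` (or any list with `mean_coefficients` and
#'   `standardization`).
#' @param newdata Tibble of raw covariates, or an `fc_design`.
#' @return `newdata` with a `.pred` column appended.
#' @export
predict_mean_coefficients <- function(object, newdata) {
  beta <- object$mean_coefficients
  if (inherits(newdata, "fc_design")) {
    xs <- newdata
  } else {
    xs <- standardize_design(newdata, object$standardization)
  }
  mm <- model_matrix_fixed(xs)
  dplyr::mutate(tibble::as_tibble(newdata),
                .pred = as.vector(mm %*% beta[colnames(mm)]))
}

#' Weighted validation of predictions against observations
#'
#' Builds the hierarchical weights from the supplied labels and delegates
#' to [weighted_stats()]. For external-style data without a glacier level,
#' pass spatial cluster labels from [cluster_stations()] as the group.
#'
#' @param df Tibble with observed and predicted columns plus `region`,
#'   group and `sfd` columns.
#' @param observed,predicted Column names (strings).
#' @param group Column name of the grouping level (default `"glacier_id"`).
#' @return Tibble with `wr2`, `wmae`, `wrmse`.
#' @export
validate_predictions <- function(df, observed = "soilT", predicted = ".pred",
                                 group = "glacier_id") {
  w <- build_weights(df, region = "region", group = group)
  weighted_stats(df[[observed]], df[[predicted]], w$weight)
}

#' Single-linkage spatial clusters of stations
#'
#' Groups stations closer than `cutoff` meters (single linkage on pairwise
#' Euclidean distance of projected coordinates), the grouping used in place
#' of the glacier level for external validation data.
#'
#' @param df Tibble with `station_id`, `x`, `y` (meters).
#' @param cutoff Linkage distance in meters (default 1000).
#' @return `df` with a `cluster` label column appended.
#' @export
cluster_stations <- function(df, cutoff = 1000) {
  if (nrow(df) == 1) return(dplyr::mutate(df, cluster = "c1"))
  hc <- stats::hclust(stats::dist(df[, c("x", "y")]), method = "single")
  dplyr::mutate(df, cluster = paste0("c", stats::cutree(hc, h = cutoff)))
}

#' Residual diagnostics across snow-free-day cutoffs
#'
#' Refits the model retaining only rows above each sfd cutoff and
#' summarizes the residual-vs-fitted structure: the slope of a linear
#' residual trend, a binned curvature index (SD of decile-bin mean
#' residuals) that picks up the snow-decoupling distortion, and a
#' heteroscedasticity index (correlation of absolute residuals with fitted
#' values). Cutoffs leaving fewer than `min_rows` rows are skipped with a
#' warning.
#'
#' @param df Raw monthly table as for [build_design()].
#' @param cutoffs Candidate sfd cutoffs, percent (default 0--90 by 10).
#' @param min_rows Minimum retained rows per cutoff (default 100).
#' @return Tibble with `cutoff`, `n_rows`, `trend_slope`, `curvature`,
#'   `heteroscedasticity`.
#' @export
sfd_cutoff_diagnostics <- function(df, cutoffs = seq(0, 90, by = 10),
                                   min_rows = 100) {
  purrr::map_dfr(cutoffs, function(ct) {
    kept <- df[df$sfd > ct, , drop = FALSE]
    if (nrow(kept) < min_rows) {
      warning(sprintf("cutoff %g%% leaves %d rows (< %d); skipped",
                      ct, nrow(kept), min_rows))
      return(NULL)
    }
    design <- build_design(kept, sfd_cutoff = ct)
    fit <- tryCatch(fit_soil_lmm(design), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    res <- stats::residuals(fit$model)
    fitted <- stats::fitted(fit$model)
    bins <- cut(fitted, breaks = stats::quantile(fitted, seq(0, 1, 0.1), type = 7),
                include.lowest = TRUE)
    tibble::tibble(
      cutoff = ct,
      n_rows = nrow(kept),
      trend_slope = unname(stats::coef(stats::lm(res ~ fitted))[2]),
      curvature = stats::sd(tapply(res, bins, mean), na.rm = TRUE),
      heteroscedasticity = suppressWarnings(stats::cor(abs(res), fitted))
    )
  })
}
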