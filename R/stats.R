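# Population comparison of lambda_max / lambda_cut measurements:
# random-intercept linear mixed models fitted by REML, type-III F tests
# with Satterthwaite (or containment) denominator df, estimated marginal
# means, and intraclass correlation coefficients.
#
# The model is y = X beta + Z b + e with one random intercept per bird,
# b ~ N(0, sigma_b^2), e ~ N(0, sigma_e^2). With theta = sigma_b^2 /
# sigma_e^2 the covariance is sigma_e^2 (I + theta Z Z'), block diagonal by
# bird, so all GLS quantities reduce to per-bird crossproducts via the
# Woodbury identity: V_i^{-1} = I - theta/(1 + n_i theta) J. The REML
# criterion is profiled over theta and minimised by a bounded 1-D search,
# with the boundary theta = 0 evaluated explicitly.

#' Assemble a measurement set
#'
#' Validates the value/bird/population triples fed to the mixed-model
#' routines: every bird must belong to exactly one population and at least
#' two birds must be present.
#'
#' @param value Numeric measurements (nm).
#' @param bird_id Bird identifier per measurement.
#' @param population Population label per measurement.
#' @param type Optional pigment or droplet type label, carried as an
#'   attribute.
#' @return A data.frame of class `measurement_set`.
#' @export
measurement_set <- function(value, bird_id, population, type = NULL) {
  stopifnot(is.numeric(value), length(value) == length(bird_id),
            length(value) == length(population))
  if (any(!is.finite(value))) stop("non-finite values", call. = FALSE)
  bird_id <- as.character(bird_id)
  population <- as.character(population)
  pop_per_bird <- tapply(population, bird_id, function(p) length(unique(p)))
  if (any(pop_per_bird > 1L))
    stop("a bird maps to more than one population", call. = FALSE)
  if (length(unique(bird_id)) < 2L)
    stop("need at least two birds", call. = FALSE)
  out <- data.frame(value = value, bird_id = bird_id,
                    population = population, stringsAsFactors = FALSE)
  attr(out, "type") <- type
  class(out) <- c("measurement_set", "data.frame")
  out
}

# Per-bird sufficient statistics for the grouped GLS algebra.
.lmm_suff <- function(y, bird, X) {
  birds <- sort(unique(bird))
  lapply(birds, function(b) {
    i <- bird == b
    Xi <- X[i, , drop = FALSE]
    yi <- y[i]
    list(n = sum(i), XtX = crossprod(Xi), Xty = crossprod(Xi, yi),
         yty = sum(yi^2), Xs = colSums(Xi), ys = sum(yi))
  })
}

# GLS quantities at a given theta. Returns beta, XtVX (= X'V^-1 X), the
# GLS residual quadratic form and log|V| (with sigma_e^2 factored out).
.lmm_gls <- function(suff, theta) {
  p <- length(suff[[1]]$Xs)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yVy <- 0
  logdetV <- 0
  for (s in suff) {
    ci <- theta / (1 + s$n * theta)
    XtVX <- XtVX + s$XtX - ci * tcrossprod(s$Xs)
    XtVy <- XtVy + s$Xty - ci * s$Xs * s$ys
    yVy <- yVy + s$yty - ci * s$ys^2
    logdetV <- logdetV + log1p(s$n * theta)
  }
  beta <- solve(XtVX, XtVy)
  rss <- yVy - sum(beta * XtVy)
  list(beta = drop(beta), XtVX = XtVX, rss = max(rss, 0),
       logdetV = logdetV)
}

# Profiled -2 REML log-likelihood (up to an additive constant).
.reml_crit <- function(suff, theta, n, p) {
  g <- .lmm_gls(suff, theta)
  s2 <- max(g$rss / (n - p), 1e-300)   # perfect fits: keep the log finite
  g$logdetV + determinant(g$XtVX, logarithm = TRUE)$modulus[1] +
    (n - p) * log(s2)
}

# Full -2 REML log-likelihood at explicit variance components, used for the
# numerical information matrix behind the Satterthwaite approximation.
.reml_m2ll <- function(suff, vb, ve, n, p) {
  theta <- vb / ve
  g <- .lmm_gls(suff, theta)
  g$logdetV + (n - p) * log(ve) +
    determinant(g$XtVX / ve, logarithm = TRUE)$modulus[1] + g$rss / ve
}

# REML fit core shared by fit_lmm() and icc().
.reml_core <- function(y, bird, X) {
  n <- length(y)
  p <- ncol(X)
  suff <- .lmm_suff(y, bird, X)
  crit <- function(u) .reml_crit(suff, exp(u), n, p)
  opt <- stats::optimize(crit, interval = c(-16, 12), tol = 1e-8)
  c0 <- .reml_crit(suff, 0, n, p)
  if (c0 <= opt$objective || exp(opt$minimum) < 1e-10) {
    theta <- 0
    boundary <- TRUE
  } else {
    theta <- exp(opt$minimum)
    boundary <- FALSE
    # the profiled criterion is numerically flat near its minimum, so
    # polish with Newton steps on wide-step finite differences, where the
    # curvature signal still beats evaluation noise
    cr <- function(th) .reml_crit(suff, th, n, p)
    for (it in 1:3) {
      h <- 2e-3 * theta
      f1 <- cr(theta - h); f2 <- cr(theta); f3 <- cr(theta + h)
      c2 <- (f1 + f3 - 2 * f2) / h^2
      if (!is.finite(c2) || c2 <= 0) break
      step <- -(f3 - f1) / (2 * h) / c2
      if (!is.finite(step) || abs(step) > 10 * h) break
      theta <- max(theta + step, 1e-12)
      if (abs(step) < 1e-9 * theta) break
    }
  }
  g <- .lmm_gls(suff, theta)
  ve <- g$rss / (n - p)
  vb <- theta * ve
  covb <- ve * solve(g$XtVX)
  loglik <- -0.5 * (.reml_crit(suff, theta, n, p) +
                      (n - p) * (1 + log(2 * pi)))
  list(beta = g$beta, cov_beta = covb, var_bird = vb, var_resid = ve,
       theta = theta, boundary = boundary, n = n, p = p,
       n_birds = length(suff), suff = suff, reml_loglik = loglik)
}

# Satterthwaite denominator df for the scalar contrast L beta:
# nu = 2 g^2 / (grad' A grad), g = L cov(beta) L', A = 2 H^{-1} with H the
# numerical Hessian of the -2 REML log-likelihood in (var_bird, var_resid).
# At the theta = 0 boundary the model degenerates to OLS and the residual
# df n - p is used instead.
.satterthwaite_df <- function(fit, L) {
  if (fit$boundary) return(fit$n - fit$p)
  vb <- fit$var_bird; ve <- fit$var_resid
  gfun <- function(vbx, vex) {
    g <- .lmm_gls(fit$suff, vbx / vex)
    drop(t(L) %*% (vex * solve(g$XtVX)) %*% L)
  }
  hb <- max(1e-8, 1e-4 * vb)
  he <- max(1e-8, 1e-4 * ve)
  grad <- c((gfun(vb + hb, ve) - gfun(vb - hb, ve)) / (2 * hb),
            (gfun(vb, ve + he) - gfun(vb, ve - he)) / (2 * he))
  m2 <- function(v) .reml_m2ll(fit$suff, v[1], v[2], fit$n, fit$p)
  H <- matrix(0, 2, 2)
  x0 <- c(vb, ve)
  h <- c(hb, he)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (m2(x0 + ei + ej) - m2(x0 + ei - ej) -
                  m2(x0 - ei + ej) + m2(x0 - ei - ej)) / (4 * h[i] * h[j])
  }
  # H is the Hessian of -2 loglik, so the observed information of the
  # loglik is H/2 and Var(vc_hat) ~ (H/2)^{-1} = 2 H^{-1}
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(A)) return(fit$n_birds - fit$p)
  gval <- drop(t(L) %*% fit$cov_beta %*% L)
  denom <- drop(t(grad) %*% A %*% grad)
  if (!is.finite(denom) || denom <= 0) return(fit$n_birds - fit$p)
  nu <- 2 * gval^2 / denom
  max(1, min(nu, fit$n - fit$p))
}

#' Random-intercept mixed model for a population comparison
#'
#' Fits, by restricted maximum likelihood, a linear mixed model with a
#' fixed effect for population of origin and a random intercept for bird
#' identity (accounting for non-independence of cells measured within a
#' bird). Reports the population contrast, its type-III F test with the
#' chosen denominator-df approximation, estimated marginal means with
#' standard errors, and the REML variance components.
#'
#' The fit uses population-mean (cell-means) coding, so the estimated
#' marginal means are the fixed-effect coefficients themselves. A fit whose
#' between-bird variance is driven to zero is reported with
#' `boundary = TRUE` rather than an error; its denominator df falls back to
#' the residual df, where the F statistic coincides with the one-way ANOVA
#' F on cell values.
#'
#' @param data A [measurement_set()] (or data.frame with `value`,
#'   `bird_id`, `population`).
#' @param df_method `"satterthwaite"` (default) or `"containment"`
#'   (number of birds minus number of populations).
#' @return An object of class `lmm_result`: `fixed_effect_estimate`
#'   (second population minus first, in label sort order), `F`, `df_num`,
#'   `df_den`, `p`, `emm` (data.frame population/emm/se), `var_bird`,
#'   `var_resid`, `icc_implied`, `reml_loglik`, `boundary`, `df_method`,
#'   and `df_den_alternatives` (both rules, for reporting).
#' @export
fit_lmm <- function(data, df_method = c("satterthwaite", "containment")) {
  df_method <- match.arg(df_method)
  pops <- sort(unique(data$population))
  if (length(pops) < 2L)
    stop("need at least two populations to compare", call. = FALSE)
  X <- sapply(pops, function(p) as.numeric(data$population == p))
  fit <- .reml_core(data$value, data$bird_id, X)
  q <- length(pops) - 1L
  # all-pairwise-to-first contrasts span the population effect (type III)
  Cm <- cbind(-1, diag(q))
  Cb <- drop(Cm %*% fit$beta)
  CVC <- Cm %*% fit$cov_beta %*% t(Cm)
  # a zero-residual fit makes the contrast variance singular; an exact
  # group difference then has an unbounded F
  Fstat <- tryCatch(drop(t(Cb) %*% solve(CVC, Cb)) / q,
                    error = function(e) if (any(Cb != 0)) Inf else NA_real_)
  L <- c(-1, 1, rep(0, length(pops) - 2L))
  df_sat <- .satterthwaite_df(fit, L)
  df_cont <- max(1, fit$n_birds - length(pops))
  df_den <- if (df_method == "satterthwaite") df_sat else df_cont
  emm <- data.frame(population = pops, emm = fit$beta,
                    se = sqrt(diag(fit$cov_beta)), stringsAsFactors = FALSE)
  res <- list(fixed_effect_estimate = unname(fit$beta[2L] - fit$beta[1L]),
              F = Fstat, df_num = q, df_den = df_den,
              p = stats::pf(Fstat, q, df_den, lower.tail = FALSE),
              emm = emm,
              var_bird = fit$var_bird, var_resid = fit$var_resid,
              icc_implied = fit$var_bird / (fit$var_bird + fit$var_resid),
              reml_loglik = fit$reml_loglik, boundary = fit$boundary,
              n = fit$n, n_birds = fit$n_birds,
              df_method = df_method,
              df_den_alternatives = c(satterthwaite = df_sat,
                                      containment = df_cont))
  class(res) <- "lmm_result"
  res
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (REML): %d cells, %d birds\n",
              x$n, x$n_birds))
  print(x$emm, row.names = FALSE)
  cat(sprintf("contrast %.3f nm; F(%d, %.1f) = %.3f, p = %.4g [%s df]\n",
              x$fixed_effect_estimate, x$df_num, x$df_den, x$F, x$p,
              x$df_method))
  cat(sprintf("var components: bird %.4g, residual %.4g%s\n",
              x$var_bird, x$var_resid,
              if (x$boundary) " (boundary fit: var_bird = 0)" else ""))
  invisible(x)
}

#' Intraclass correlation coefficient from an intercepts-only mixed model
#'
#' Fits an intercepts-only model (no population effect) with a random
#' intercept per bird by REML and returns the ratio of between-bird
#' variance to total variance — the fraction of measurement variance
#' attributable to differences between individuals.
#'
#' When no bird contributes more than one measurement the between/within
#' decomposition is unidentifiable and the ICC is reported as undefined
#' (`NA` with a reason) rather than a number.
#'
#' @param data A [measurement_set()] or compatible data.frame.
#' @return An object of class `icc_result`: `icc`, `var_bird`,
#'   `var_resid`, `boundary`, `reason`.
#' @export
icc <- function(data) {
  sizes <- table(data$bird_id)
  if (length(sizes) < 2L || all(sizes < 2L)) {
    res <- list(icc = NA_real_, var_bird = NA_real_, var_resid = NA_real_,
                boundary = NA,
                reason = "too few repeated measurements across individuals")
    class(res) <- "icc_result"
    return(res)
  }
  X <- matrix(1, nrow = length(data$value), ncol = 1L)
  fit <- .reml_core(data$value, data$bird_id, X)
  res <- list(icc = fit$var_bird / (fit$var_bird + fit$var_resid),
              var_bird = fit$var_bird, var_resid = fit$var_resid,
              boundary = fit$boundary, reason = NULL)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC undefined:", x$reason, "\n")
  } else {
    cat(sprintf("ICC = %.3f (var_bird %.4g, var_resid %.4g)%s\n", x$icc,
                x$var_bird, x$var_resid,
                if (isTRUE(x$boundary)) " [boundary]" else ""))
  }
  invisible(x)
}

#' Population comparison report for pigments and droplets
#'
#' Builds the per-type comparison tables: one row per pigment class (and,
#' if droplet results are given, per droplet type) with cell counts per
#' population, estimated marginal means with standard errors, the type-III
#' F test of the population effect, and the ICC where repeated
#' measurements allow it. Only records passing quality control enter the
#' pigment table. Types absent from a population, or too sparse to model,
#' are reported with missing statistics.
#'
#' @param cell_results Per-cell results data.frame (from
#'   [process_records()]), with columns `bird_id`, `population`,
#'   `pigment_class`, `lambda_max_primary`, `qc_passed`.
#' @param droplet_results Optional [measure_droplets()] table.
#' @param df_method Denominator-df rule, see [fit_lmm()].
#' @param alpha Significance level for flags.
#' @return An object of class `comparison_report`: `pigments` data.frame,
#'   optional `droplets` data.frame, and `meta` (df rule used plus both
#'   df alternatives per type).
#' @export
comparison_report <- function(cell_results, droplet_results = NULL,
                              df_method = c("satterthwaite", "containment"),
                              alpha = 0.05) {
  df_method <- match.arg(df_method)
  keep <- cell_results[isTRUE_vec(cell_results$qc_passed) &
                         !is.na(cell_results$lambda_max_primary), ,
                       drop = FALSE]
  pops <- sort(unique(cell_results$population))
  classes <- intersect(c("UVS", "SWS", "MWS", "LWS", "rod"),
                       unique(keep$pigment_class))
  df_alt <- list()
  rows <- lapply(classes, function(cl) {
    d <- keep[keep$pigment_class == cl, , drop = FALSE]
    row <- data.frame(pigment = cl, stringsAsFactors = FALSE)
    for (p in pops) {
      vals <- d$lambda_max_primary[d$population == p]
      row[[paste0("n_", p)]] <- length(vals)
      row[[paste0("mean_", p)]] <- if (length(vals)) mean(vals) else NA_real_
      row[[paste0("se_", p)]] <-
        if (length(vals) >= 2L) stats::sd(vals) / sqrt(length(vals))
        else NA_real_
    }
    row$F <- NA_real_; row$df_num <- NA_real_; row$df_den <- NA_real_
    row$p <- NA_real_; row$significant <- NA
    row$icc <- NA_real_; row$var_bird <- NA_real_; row$var_resid <- NA_real_
    n_per_pop <- vapply(pops, function(p) sum(d$population == p), integer(1))
    if (all(n_per_pop >= 2L) && length(unique(d$bird_id)) >= 2L) {
      fit <- tryCatch(fit_lmm(measurement_set(d$lambda_max_primary,
                                              d$bird_id, d$population,
                                              type = cl),
                              df_method = df_method),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        for (p in pops) {
          row[[paste0("mean_", p)]] <- fit$emm$emm[fit$emm$population == p]
          row[[paste0("se_", p)]] <- fit$emm$se[fit$emm$population == p]
        }
        row$F <- fit$F; row$df_num <- fit$df_num; row$df_den <- fit$df_den
        row$p <- fit$p; row$significant <- fit$p < alpha
        df_alt[[cl]] <<- fit$df_den_alternatives
      }
    }
    ic <- tryCatch(icc(data.frame(value = d$lambda_max_primary,
                                  bird_id = d$bird_id,
                                  population = d$population)),
                   error = function(e) NULL)
    if (!is.null(ic) && !is.na(ic$icc)) {
      row$icc <- ic$icc; row$var_bird <- ic$var_bird
      row$var_resid <- ic$var_resid
    }
    row
  })
  pig <- if (length(rows)) do.call(rbind, rows) else NULL
  drp <- if (!is.null(droplet_results))
    summarize_droplets(droplet_results, df_method = df_method,
                       alpha = alpha)
  else NULL
  structure(list(pigments = pig, droplets = drp,
                 meta = list(df_method = df_method, alpha = alpha,
                             df_den_alternatives = df_alt,
                             populations = pops)),
            class = "comparison_report")
}

# TRUE for TRUE, FALSE for FALSE/NA, vectorised.
isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.comparison_report <- function(x, ...) {
  cat("Population comparison report\n")
  if (!is.null(x$pigments)) {
    cat("\nVisual pigments (lambda_max, nm):\n")
    print(x$pigments, row.names = FALSE, digits = 5)
  }
  if (!is.null(x$droplets)) {
    cat("\nOil droplets (lambda_cut, nm):\n")
    print(x$droplets, row.names = FALSE, digits = 5)
  }
  cat(sprintf("\ndenominator df rule: %s; alpha = %g\n", x$meta$df_method,
              x$meta$alpha))
  invisible(x)
}
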