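#' Fit the amplitude mixed-effects model
#'
#' Fits, by maximum likelihood, one of the two model variants for the ramp
#' amplitudes:
#'
#' * `base`:     `amplitude ~ 1 + Time + Group + (1 | Group)`
#' * `extended`: `amplitude ~ 1 + Age + Time + Group + Age:Group + (1 | Group)`
#'
#' `Time` is the preceding dark duration in milliseconds, `Group` a treatment
#' contrast with Control as the reference (a negative Group coefficient means
#' lower amplitudes in the AMD group), and `Age` is centered at the cohort
#' mean. Estimation is ML (not REML) so that AIC/BIC are comparable across
#' fixed-effect structures. Only ramp-phase rows enter the model; missing
#' rows are dropped with a message.
#'
#' The two-level `(1 | Group)` random intercept is retained as specified even
#' though it is confounded with the fixed Group effect; its variance is
#' typically estimated at the boundary (zero) and the fit is then flagged
#' `boundary = TRUE` while remaining converged. `random = "subject"`
#' refits with a per-subject random intercept as a sensitivity analysis.
#'
#' Coefficient p-values use the same residual degrees of freedom as the
#' marginal ANOVA: `df = n_obs - rank(X)`.
#'
#' @param table Amplitude table (needs `amplitude`, `dark_ms`, `group`,
#'   `age_years`, `phase`, `missing`, `subject_id`).
#' @param variant `"base"` or `"extended"`.
#' @param random `"group"` (as specified) or `"subject"` (sensitivity refit).
#' @param normalize If `TRUE`, divide each amplitude by the subject's
#'   baseline diameter (requires a `baseline_mm` column), putting amplitudes
#'   on a dimensionless relative scale.
#' @return A `plr_lmm_fit` list: `beta`, `se`, `t`, `p_value`, `df_resid`,
#'   `aic`, `bic`, `log_lik`, `sigma_resid`, `random_intercept_sd`,
#'   `boundary`, `converged`, `n_obs`, `n_dropped`, `variant`, `random`,
#'   and the underlying `lme4` fit in `model`.
#' @export
fit_lmm <- function(table, variant = c("base", "extended"),
                    random = c("group", "subject"), normalize = FALSE) {
  variant <- match.arg(variant)
  random <- match.arg(random)

  d <- table[table$phase == "ramp", ]
  n_all <- nrow(d)
  d <- d[!d$missing & !is.na(d$amplitude), ]
  n_dropped <- n_all - nrow(d)
  if (n_dropped > 0) {
    message(n_dropped, " missing ramp row(s) dropped before model fit")
  }
  if (nrow(d) == 0) stop("no non-missing ramp amplitudes to fit")
  groups <- unique(d$group)
  if (length(groups) < 2) {
    stop("design error: model with a Group term needs two groups, found ",
         paste(groups, collapse = ", "))
  }
  if (normalize) {
    if (!"baseline_mm" %in% names(d)) {
      stop("normalize = TRUE needs a 'baseline_mm' column")
    }
    d$amplitude <- d$amplitude / d$baseline_mm
  }

  d$Group <- factor(d$group, levels = c("Control", "AMD"))
  d$Time <- d$dark_ms
  age_center <- mean(unique(d[, c("subject_id", "age_years")])$age_years)
  d$Age <- d$age_years - age_center

  fixed <- if (variant == "base") "Time + Group" else
    "Age + Time + Group + Age:Group"
  ranef_term <- if (random == "group") "(1 | Group)" else "(1 | subject_id)"
  form <- stats::as.formula(paste("amplitude ~ 1 +", fixed, "+", ranef_term))

  # Time stays in ms by design; silence the scale advisory that triggers
  fit <- suppressMessages(lme4::lmer(
    form, data = d, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.scaleX = "ignore",
                                calc.derivs = FALSE)
  ))

  beta <- lme4::fixef(fit)
  dropped <- attr(stats::model.matrix(fit), "col.dropped")
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- stats::nobs(fit)
  df_resid <- n_obs - length(beta)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_resid)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- vc$sdcor[vc$grp != "Residual"][1]
  boundary <- lme4::isSingular(fit, tol = 1e-5)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) ||
    all(grepl("singular|boundary", conv_msgs, ignore.case = TRUE))

  structure(
    list(
      variant = variant, random = random, normalize = normalize,
      formula = form,
      beta = beta, se = se, t = tval, p_value = pval,
      df_resid = df_resid,
      aic = stats::AIC(fit), bic = stats::BIC(fit),
      log_lik = as.numeric(stats::logLik(fit)),
      sigma_resid = stats::sigma(fit),
      random_intercept_sd = re_sd,
      boundary = boundary, converged = converged,
      n_obs = n_obs, n_dropped = n_dropped,
      age_center = age_center,
      aliased = dropped,
      model = fit
    ),
    class = "plr_lmm_fit"
  )
}

#' @export
print.plr_lmm_fit <- function(x, ...) {
  cat("<plr_lmm_fit>", x$variant, "variant, ML,",
      deparse(x$formula), "\n")
  if (!x$converged) cat("  ** fit did not converge **\n")
  if (x$boundary) {
    cat("  note: random-intercept variance at the boundary (zero)\n")
  }
  coefs <- data.frame(
    estimate = signif(x$beta, 5), se = signif(x$se, 4),
    t = signif(x$t, 4), p = signif(x$p_value, 3)
  )
  print(coefs)
  cat(sprintf("  n = %d (%d dropped), AIC %.1f, BIC %.1f, sigma %.5f, RE sd %.5f\n",
              x$n_obs, x$n_dropped, x$aic, x$bic, x$sigma_resid,
              x$random_intercept_sd))
  invisible(x)
}

#' Marginal (Type-III) ANOVA of the fixed effects
#'
#' F-tests of each fixed-effect term adjusted for all other terms, with
#' residual degrees of freedom `n_obs - rank(X)`. Every term in the fitted
#' models is single-df (binary group, continuous covariates), so each
#' marginal F statistic equals the squared coefficient t-statistic.
#'
#' @param fit A converged [fit_lmm()] result.
#' @return Tibble with one row per fixed term (including the intercept):
#'   `term`, `f`, `df_num`, `df_den`, `p_value`.
#' @export
marginal_anova <- function(fit) {
  stopifnot(inherits(fit, "plr_lmm_fit"))
  if (!fit$converged) stop("cannot compute ANOVA from a non-converged fit")
  if (!is.null(fit$aliased) && length(fit$aliased)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(fit$aliased), collapse = ", "))
  }
  tibble(
    term = names(fit$beta),
    f = as.numeric(fit$t)^2,
    df_num = 1L,
    df_den = fit$df_resid,
    p_value = as.numeric(fit$p_value)
  )
}

#' Summarize a model fit as a report
#'
#' @param fit A [fit_lmm()] result.
#' @param anova Optional [marginal_anova()] table (computed if the fit
#'   converged and none is given).
#' @return A `plr_fit_report`: a plain list (JSON-ready) with coefficients,
#'   information criteria, variance components and ANOVA rows.
#' @export
summarize_fit <- function(fit, anova = NULL) {
  if (is.null(anova) && fit$converged) anova <- marginal_anova(fit)
  rep <- list(
    variant = fit$variant,
    formula = deparse(fit$formula),
    converged = fit$converged,
    boundary = fit$boundary,
    n_obs = fit$n_obs,
    n_dropped = fit$n_dropped,
    coefficients = lapply(seq_along(fit$beta), function(i) {
      list(term = names(fit$beta)[i],
           estimate = unname(fit$beta[i]), se = unname(fit$se[i]),
           t = unname(fit$t[i]), p_value = unname(fit$p_value[i]))
    }),
    aic = fit$aic, bic = fit$bic, log_lik = fit$log_lik,
    sigma_resid = fit$sigma_resid,
    random_intercept_sd = fit$random_intercept_sd,
    df_resid = fit$df_resid,
    anova = if (is.null(anova)) NULL else
      lapply(seq_len(nrow(anova)), function(i) as.list(anova[i, ]))
  )
  class(rep) <- c("plr_fit_report", "list")
  rep
}

#' Write / read a fit report as JSON
#'
#' @param report A [summarize_fit()] report.
#' @param path JSON path.
#' @return `path` invisibly / the report list.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  class(rep) <- c("plr_fit_report", "list")
  rep
}

#' @export
print.plr_fit_report <- function(x, ...) {
  cat("<plr_fit_report>", x$variant, "\n ", x$formula, "\n")
  if (!isTRUE(x$converged)) cat("  ** NON-CONVERGED FIT **\n")
  for (co in x$coefficients) {
    cat(sprintf("  %-14s %12.6g (se %.3g, p %.3g)\n",
                co$term, co$estimate, co$se, co$p_value))
  }
  cat(sprintf("  AIC %.1f  BIC %.1f  sigma %.5g  RE sd %.5g\n",
              x$aic, x$bic, x$sigma_resid, x$random_intercept_sd))
  invisible(x)
}
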