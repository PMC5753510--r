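# Random-effects meta-analysis of two-group expression summaries.
#
# Effect size: Hedges' g (standardized mean difference with the small-sample
# correction J = 1 - 3/(4*df - 1)), control minus case, so a gene
# downregulated in tumours yields a positive SMD. Pooling: DerSimonian-Laird
# method-of-moments tau^2 with normal-quantile confidence intervals, matching
# the defaults of the conventional meta-analysis tooling this mirrors.

KNOWN_STRATA <- c("tissue", "vascular_invasion", "cirrhosis", "metastasis")
Z975 <- stats::qnorm(0.975)

#' Two-group summary statistics
#'
#' Bundles the sample size, mean and standard deviation of one study arm.
#'
#' @param n Sample count (>= 2; the SD of a single observation is undefined).
#' @param mean Group mean expression (platform-arbitrary units).
#' @param sd Group standard deviation (same units, >= 0).
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(10, 1.2, 0.8)
#' @export
group_summary <- function(n, mean, sd) {
  if (!is_count(n) || n < 2) stopf("group size must be an integer >= 2, got %s", format(n))
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean)) stopf("mean must be a single number")
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) stopf("sd must be a single number >= 0")
  structure(list(n = as.integer(n), mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "group_summary")
}

#' Hedges' g standardized mean difference
#'
#' Computes the bias-corrected SMD between control and case summaries,
#' `g = J * (control - case) / s_pooled`, with
#' `J = 1 - 3/(4*(n1 + n2 - 2) - 1)`, sampling variance
#' `(n1 + n2)/(n1*n2) + g^2/(2*(n1 + n2))` and a 95% normal-quantile CI.
#' The control-minus-case direction means a transcript lower in cases
#' (e.g. a miRNA downregulated in tumours) gives a positive g.
#'
#' @param case,control `group_summary` objects (case = diseased arm).
#' @param study_id Optional label carried through to pooling.
#' @return One-row data frame with columns `study_id`, `g`, `variance`,
#'   `ci_low`, `ci_high`.
#' @examples
#' hedges_g(group_summary(10, 0, 1), group_summary(10, 1, 1))
#' @export
hedges_g <- function(case, control, study_id = NA_character_) {
  if (!inherits(case, "group_summary")) case <- do.call(group_summary, as.list(case)[c("n", "mean", "sd")])
  if (!inherits(control, "group_summary")) control <- do.call(group_summary, as.list(control)[c("n", "mean", "sd")])
  n1 <- control$n; n2 <- case$n
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * control$sd^2 + (n2 - 1) * case$sd^2) / df
  if (sp2 <= 0) {
    if (control$mean != case$mean)
      stopf("degenerate effect: pooled SD is zero but group means differ")
    d <- 0
  } else {
    d <- (control$mean - case$mean) / sqrt(sp2)
  }
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  data.frame(study_id = study_id, g = g, variance = v,
             ci_low = g - Z975 * sqrt(v), ci_high = g + Z975 * sqrt(v),
             stringsAsFactors = FALSE)
}

#' Per-study effect sizes for a study table
#'
#' Applies [hedges_g()] to every row of a wide study table (as produced by
#' [simulate_meta_studies()] or [read_studies_tsv()]).
#'
#' @param studies Data frame with columns `study_id`, `stratum`, `n_case`,
#'   `mean_case`, `sd_case`, `n_control`, `mean_control`, `sd_control`.
#' @return Data frame of effect estimates, one row per study, carrying
#'   `stratum` through.
#' @export
study_effects <- function(studies) {
  need <- c("study_id", "n_case", "mean_case", "sd_case",
            "n_control", "mean_control", "sd_control")
  miss <- setdiff(need, names(studies))
  if (length(miss)) stopf("study table is missing columns: %s", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    hedges_g(group_summary(s$n_case, s$mean_case, s$sd_case),
             group_summary(s$n_control, s$mean_control, s$sd_control),
             study_id = as.character(s$study_id))
  }))
  if ("stratum" %in% names(studies)) out$stratum <- as.character(studies$stratum)
  out
}

#' Pool effect sizes with a random-effects (DerSimonian-Laird) model
#'
#' Fixed-effect weights `w = 1/v` give Cochran's
#' `Q = sum(w * (g - g_FE)^2)`; the method-of-moments between-study variance
#' is `tau2 = max(0, (Q - df)/C)` with `C = sum(w) - sum(w^2)/sum(w)`.
#' Random-effects weights `1/(v + tau2)` produce the pooled SMD, its normal
#' 95% CI, z and two-sided p. Heterogeneity is summarised by
#' `I2 = max(0, (Q - df)/Q) * 100` and the chi-square upper-tail p of Q;
#' the heterogeneity flag fires when `p_het < 0.05` or `I2 > 50`.
#' Two significance summaries are reported side by side: the conventional
#' zero-crossing p, and the unit-interval rule (CI must not overlap +1 or
#' -1) used as the decision criterion in SMD screens of expression data.
#'
#' @param effects Data frame with columns `g` and `variance` (and optionally
#'   `study_id`), e.g. from [study_effects()].
#' @param model `"random"` (default) or `"fixed"`; the fixed model forces
#'   `tau2 = 0` in the pooling weights (heterogeneity statistics are
#'   reported either way).
#' @return An object of class `pooled_result`: a list with `smd`, `se`,
#'   `ci_low`, `ci_high`, `z`, `p`, `Q`, `df`, `p_het`, `i2`, `tau2`,
#'   `model`, `heterogeneity_flag`, `significance_flag`, `k`, and per-study
#'   `weights` (normalised percent).
#' @examples
#' eff <- data.frame(g = c(0.5, 0.5), variance = c(0.1, 0.2))
#' pool_random_effects(eff)
#' @export
pool_random_effects <- function(effects, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (is.null(effects) || nrow(effects) == 0L) stopf("at least one effect estimate is required")
  g <- effects$g; v <- effects$variance
  if (any(!is.finite(g)) || any(!is.finite(v)) || any(v <= 0))
    stopf("effect estimates require finite g and variance > 0")
  k <- length(g)
  df <- k - 1L

  w <- 1 / v
  g_fe <- sum(w * g) / sum(w)
  Q <- sum(w * (g - g_fe)^2)
  if (df > 0L) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (C > 0) max(0, (Q - df) / C) else 0
    p_het <- stats::pchisq(Q, df, lower.tail = FALSE)
    i2 <- if (Q > df) (Q - df) / Q * 100 else 0
  } else {
    tau2 <- 0; p_het <- 1; i2 <- 0
  }

  wstar <- if (model == "random") 1 / (v + tau2) else w
  smd <- sum(wstar * g) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  z <- smd / se
  res <- structure(list(
    smd = smd, se = se,
    ci_low = smd - Z975 * se, ci_high = smd + Z975 * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    Q = Q, df = df, p_het = p_het, i2 = i2, tau2 = tau2,
    model = model,
    heterogeneity_flag = (p_het < 0.05) || (i2 > 50),
    k = k,
    study_id = if ("study_id" %in% names(effects)) effects$study_id else rep(NA_character_, k),
    weights = 100 * wstar / sum(wstar)
  ), class = "pooled_result")
  res$significance_flag <- significance_rule(res)
  res
}

#' Unit-interval significance rule for a pooled SMD
#'
#' Declares a pooled standardized mean difference significant only when its
#' 95% CI overlaps neither +1 nor -1 (closed interval: touching a boundary
#' counts as overlap). This is stricter than the usual zero-crossing test
#' and flags effects of at least one pooled SD in either direction.
#'
#' @param result A `pooled_result`, or anything with `ci_low`/`ci_high`
#'   fields; alternatively pass `ci_low` and `ci_high` directly.
#' @param ci_low,ci_high Explicit CI bounds (used when `result` is missing).
#' @return Logical scalar.
#' @examples
#' significance_rule(ci_low = 0.38, ci_high = 0.88)   # TRUE
#' significance_rule(ci_low = -2.71, ci_high = -0.16) # FALSE: contains -1
#' @export
significance_rule <- function(result = NULL, ci_low = NULL, ci_high = NULL) {
  if (!is.null(result)) {
    ci_low <- result$ci_low; ci_high <- result$ci_high
  }
  if (is.null(ci_low) || is.null(ci_high) || ci_low > ci_high)
    stopf("a computed CI (ci_low <= ci_high) is required")
  inside <- function(x) ci_low <= x && x <= ci_high
  !(inside(1) || inside(-1))
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s-effects pooled SMD over %d studies\n", x$model, x$k))
  cat(sprintf("  SMD = %.3f, 95%% CI [%.3f, %.3f], z = %.3f, p = %.3g\n",
              x$smd, x$ci_low, x$ci_high, x$z, x$p))
  cat(sprintf("  Q = %.3f (df = %d, p_het = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
              x$Q, x$df, x$p_het, x$i2, x$tau2))
  cat(sprintf("  heterogeneity: %s; unit-interval rule: %s\n",
              if (x$heterogeneity_flag) "present" else "absent",
              if (x$significance_flag) "significant" else "not significant"))
  invisible(x)
}

#' @export
as.data.frame.pooled_result <- function(x, ...) {
  data.frame(smd = x$smd, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             z = x$z, p = x$p, Q = x$Q, df = x$df, p_het = x$p_het,
             i2 = x$i2, tau2 = x$tau2, model = x$model,
             heterogeneity_flag = x$heterogeneity_flag,
             significance_flag = x$significance_flag, k = x$k,
             stringsAsFactors = FALSE)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the effects with each study omitted in turn, to locate studies
#' driving heterogeneity or the pooled estimate.
#'
#' @param effects Effect data frame with >= 2 rows (see
#'   [pool_random_effects()]).
#' @inheritParams pool_random_effects
#' @return Named list of `pooled_result` objects, one per omitted study
#'   (names = omitted `study_id`).
#' @export
leave_one_out <- function(effects, model = "random") {
  if (is.null(effects) || nrow(effects) < 2L)
    stopf("leave-one-out requires at least two effect estimates")
  ids <- if ("study_id" %in% names(effects)) as.character(effects$study_id)
         else paste0("study_", seq_len(nrow(effects)))
  out <- lapply(seq_len(nrow(effects)), function(i)
    pool_random_effects(effects[-i, , drop = FALSE], model = model))
  names(out) <- ids
  out
}

#' Summarise a list of pooled results as one table
#'
#' @param results Named list of `pooled_result` objects (e.g. from
#'   [leave_one_out()]).
#' @return Data frame, one row per result, with an `omitted` column.
#' @export
pooled_table <- function(results) {
  out <- do.call(rbind, lapply(results, as.data.frame))
  out <- cbind(omitted = names(results), out)
  rownames(out) <- NULL
  out
}

#' Pool one clinicopathological stratum
#'
#' Restricts a study table to the requested stratum (tissue comparison,
#' vascular invasion, cirrhosis, or metastasis) and pools it.
#'
#' @param studies Wide study table (see [study_effects()]).
#' @param stratum One of `"tissue"`, `"vascular_invasion"`, `"cirrhosis"`,
#'   `"metastasis"`.
#' @inheritParams pool_random_effects
#' @return A `pooled_result` for the stratum.
#' @export
subgroup_compare <- function(studies, stratum, model = "random") {
  if (!stratum %in% KNOWN_STRATA)
    stopf("unknown stratum '%s' (expected one of: %s)", stratum,
          paste(KNOWN_STRATA, collapse = ", "))
  sel <- studies[studies$stratum == stratum, , drop = FALSE]
  if (nrow(sel) == 0L) stopf("no studies in stratum '%s'", stratum)
  pool_random_effects(study_effects(sel), model = model)
}

#' Forest-plot data table
#'
#' Per-study effect, CI and pooling weight in a plotting-ready table
#' (the numeric content of a forest plot, without rendering).
#'
#' @param effects Effect data frame (see [pool_random_effects()]).
#' @param pooled Optional `pooled_result` from the same effects; computed
#'   if missing.
#' @return Data frame with `study_id`, `g`, `ci_low`, `ci_high`,
#'   `weight_percent`, followed by one `POOLED` row.
#' @export
forest_table <- function(effects, pooled = NULL) {
  if (is.null(pooled)) pooled <- pool_random_effects(effects)
  ids <- if ("study_id" %in% names(effects)) as.character(effects$study_id)
         else paste0("study_", seq_len(nrow(effects)))
  rbind(
    data.frame(study_id = ids, g = effects$g, ci_low = effects$ci_low,
               ci_high = effects$ci_high, weight_percent = pooled$weights,
               stringsAsFactors = FALSE),
    data.frame(study_id = "POOLED", g = pooled$smd, ci_low = pooled$ci_low,
               ci_high = pooled$ci_high, weight_percent = 100,
               stringsAsFactors = FALSE)
  )
}
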