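#' Extract per-disc, per-region gag records from maps and ROIs
#'
#' For every disc ROI and region (NP, AF), averages the gag-score map over the
#' region's voxels and joins the subject's metadata, producing one record per
#' disc x region — the observation unit of the cohort mixed model. Regions
#' whose voxels are all missing in the map are flagged, logged and excluded.
#'
#' @param maps Named list of gag-score matrices, one per subject.
#' @param roisets Named list of `roi_set` objects, one per subject.
#' @param metadata Data frame with one row per subject (columns `subject`,
#'   `cohort`, `age`, `gender`, `stable_vertebra`).
#' @param truth Optional truth table (as in a `gag_cohort`) supplying
#'   Pfirrmann grades per disc.
#' @return Data frame of records: subject, cohort, age, gender, segment,
#'   region, pfirrmann, affection, gag (%).
#' @export
summarize_discs <- function(maps, roisets, metadata, truth = NULL) {
  recs <- list()
  dropped <- 0L
  for (id in names(roisets)) {
    md <- metadata[metadata$subject == id, , drop = FALSE]
    if (nrow(md) != 1) abort("metadata missing or duplicated for %s", id)
    map <- maps[[id]]
    for (d in roisets[[id]]$discs) {
      for (reg in c("NP", "AF")) {
        vox <- if (reg == "NP") d$np else d$af
        vals <- map[vox]
        vals <- vals[is.finite(vals)]
        if (length(vals) == 0) {
          dropped <- dropped + 1L
          log_msg("summarize_discs: %s %s %s has no valid voxels; excluded",
                  id, d$segment, reg)
          next
        }
        pf <- NA_integer_
        if (!is.null(truth)) {
          tr <- truth[truth$subject == id & truth$segment == d$segment &
                      truth$region == reg, ]
          if (nrow(tr) == 1) pf <- tr$pfirrmann
        }
        aff <- if (identical(md$cohort, "AIS") && !is.na(md$stable_vertebra))
          classify_affection(d$segment, md$stable_vertebra) else NA_character_
        recs[[length(recs) + 1L]] <- data.frame(
          subject = id, cohort = md$cohort, age = md$age, gender = md$gender,
          segment = d$segment, region = reg, pfirrmann = pf,
          affection = aff, gag = mean(vals), stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped > 0) log_msg("summarize_discs: %d empty record(s) excluded", dropped)
  do.call(rbind, recs)
}

# internal: drop fixed-effect terms whose factor has < 2 observed levels
prune_formula <- function(formula, data) {
  rhs_terms <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
  keep <- vapply(rhs_terms, function(tm) {
    vars <- all.vars(stats::as.formula(paste("~", tm)))
    all(vapply(vars, function(v) {
      x <- data[[v]]
      if (is.null(x)) return(FALSE)
      if (is.numeric(x)) length(unique(x)) > 1 else length(unique(x)) > 1
    }, logical(1)))
  }, logical(1))
  dropped <- rhs_terms[!keep]
  if (length(dropped))
    log_msg("fit_lmm: dropping constant term(s): %s",
            paste(dropped, collapse = ", "))
  bars <- lme4::findbars(formula)
  rhs <- paste(c(rhs_terms[keep],
                 vapply(bars, function(b) paste0("(", deparse(b), ")"), "")),
               collapse = " + ")
  stats::as.formula(paste(deparse(formula[[2]]), "~", rhs),
                    env = environment(formula))
}

#' Fit the cohort linear mixed model
#'
#' REML fit of a linear mixed model on disc x region gag records with a
#' subject-specific random intercept. The default fixed effects are cohort,
#' region, segment, age, gender, Pfirrmann grade, and the cohort x segment
#' and cohort x region interactions; any term whose variable is constant in
#' the data (e.g. a single observed Pfirrmann grade) is dropped with a
#' message rather than producing a rank-deficient fit. Degrees of freedom and
#' p-values downstream use the Satterthwaite approximation.
#'
#' @param records Data frame of disc records (see [summarize_discs()]).
#' @param formula Model formula in lme4 syntax; NULL for the default.
#' @param reml Fit by REML (default TRUE).
#' @return An object of class `gag_lmm`: the lmerTest fit, the formula used,
#'   variance components, and a convergence flag.
#' @export
fit_lmm <- function(records, formula = NULL, reml = TRUE) {
  if (length(unique(records$subject[records$cohort == "control"])) +
      length(unique(records$subject[records$cohort == "AIS"])) <
      length(unique(records$subject)))
    abort("records contain subjects outside the control/AIS cohorts")
  if (any(!is.finite(records$gag))) abort("records contain non-finite gag values")
  if (is.null(formula))
    formula <- gag ~ cohort + region + segment + age + gender + pfirrmann +
      cohort:segment + cohort:region + (1 | subject)
  df <- records
  for (v in c("cohort", "region", "segment", "gender", "affection"))
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  if ("pfirrmann" %in% names(df)) df$pfirrmann <- factor(df$pfirrmann)
  formula <- prune_formula(formula, df)

  fit <- lmerTest::lmer(formula, data = df, REML = reml)
  conv <- fit@optinfo$conv$lme4
  converged <- is.null(conv$messages) || length(conv$messages) == 0
  singular <- lme4::isSingular(fit)
  if (!converged)
    log_msg("fit_lmm: convergence warnings: %s",
            paste(conv$messages, collapse = "; "))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, formula = formula,
                 var_subject = vc$vcov[vc$grp == "subject"][1],
                 var_residual = vc$vcov[vc$grp == "Residual"][1],
                 converged = converged, singular = singular,
                 method = if (reml) "REML" else "ML",
                 df_method = "Satterthwaite"),
            class = "gag_lmm")
}

#' @exportS3Method base::print
print.gag_lmm <- function(x, ...) {
  cat("<gag_lmm> ", x$method, " fit, df: ", x$df_method, "\n", sep = "")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  var(subject) = %.4f, var(residual) = %.4f%s\n",
              x$var_subject, x$var_residual,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Age-corrected marginal means and contrasts
#'
#' Model-predicted (estimated marginal) means per group at a fixed age
#' (default 23.1 years), averaging over the observed distribution of the
#' remaining covariates (proportional weights), with Wald 95% confidence
#' intervals and pairwise contrast p-values (Satterthwaite degrees of
#' freedom).
#'
#' @param fit A `gag_lmm`.
#' @param specs Grouping specification for emmeans, e.g. `~ cohort` or
#'   `~ cohort + segment`.
#' @param age Age (years) at which covariates are corrected.
#' @return List with `means` (data frame: group columns, mean, lower, upper)
#'   and `contrasts` (data frame with estimates and p-values).
#' @export
corrected_means <- function(fit, specs = ~cohort, age = 23.1) {
  stopifnot(inherits(fit, "gag_lmm"))
  at <- list()
  if ("age" %in% all.vars(fit$formula)) at$age <- age
  em <- emmeans::emmeans(fit$fit, specs, at = at, weights = "proportional",
                         lmer.df = "satterthwaite")
  ms <- as.data.frame(summary(em, infer = c(TRUE, FALSE), level = 0.95))
  names(ms)[names(ms) == "emmean"] <- "mean"
  names(ms)[names(ms) == "lower.CL"] <- "lower"
  names(ms)[names(ms) == "upper.CL"] <- "upper"
  # exploratory analysis: unadjusted pairwise p-values (no multiplicity
  # correction)
  cs <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                adjust = "none"),
                              infer = c(TRUE, TRUE)))
  list(means = ms, contrasts = cs, age = age)
}

#' Cohort-by-segment corrected-means report
#'
#' Formats age-corrected means per cohort and segment plus an all-segments
#' column, mirroring the layout of a cohort comparison table: one row per
#' cohort, one column per segment, cells "mean [lower, upper]", with a row of
#' per-segment contrast p-values.
#'
#' @param fit A `gag_lmm` fitted on both cohorts.
#' @param age Correction age in years.
#' @return List with `table` (character data frame) and the underlying
#'   numeric `by_segment` and `overall` summaries.
#' @export
cohort_segment_report <- function(fit, age = 23.1) {
  by_seg <- corrected_means(fit, ~cohort + segment, age = age)
  overall <- corrected_means(fit, ~cohort, age = age)
  fmt <- function(m, l, u) sprintf("%.3f [%.3f, %.3f]", m, l, u)
  segs <- disc_segments()
  rows <- lapply(unique(by_seg$means$cohort), function(co) {
    cells <- vapply(segs, function(s) {
      r <- by_seg$means[by_seg$means$cohort == co & by_seg$means$segment == s, ]
      fmt(r$mean, r$lower, r$upper)
    }, "")
    ov <- overall$means[overall$means$cohort == co, ]
    c(cohort = as.character(co), cells, all = fmt(ov$mean, ov$lower, ov$upper))
  })
  by_seg_c <- corrected_means(fit, ~cohort | segment, age = age)
  seg_p <- vapply(segs, function(s) {
    p <- by_seg_c$contrasts$p.value[by_seg_c$contrasts$segment == s]
    sprintf("%.3f", p[1])
  }, "")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  tab <- rbind(tab, c("p-value", seg_p,
                      sprintf("%.3f", overall$contrasts$p.value[1])))
  list(table = tab, by_segment = by_seg, overall = overall)
}

#' Affection-by-segment corrected-means report for patients
#'
#' Fits the patient-only mixed model of NP gag scores on affection status and
#' segment (random subject intercept) and formats corrected means per
#' affection group and segment with the overall contrast p-value.
#'
#' @param records Disc records restricted (internally) to the AIS cohort and
#'   NP region.
#' @param age Correction age in years.
#' @return List with `table`, the `gag_lmm` fit and the emmeans summaries;
#'   segments without both affection groups show "n/a".
#' @export
affection_report <- function(records, age = 23.1) {
  ais <- records[records$cohort == "AIS" & records$region == "NP" &
                 !is.na(records$affection), ]
  if (nrow(ais) == 0) abort("no patient NP records with affection labels")
  fit <- fit_lmm(ais, formula = gag ~ affection + segment + age + gender +
                   pfirrmann + (1 | subject))
  by_seg <- corrected_means(fit, ~affection + segment, age = age)
  overall <- corrected_means(fit, ~affection, age = age)
  fmt <- function(m, l, u) sprintf("%.3f [%.3f, %.3f]", m, l, u)
  segs <- disc_segments()
  rows <- lapply(c("affected", "unaffected"), function(a) {
    cells <- vapply(segs, function(s) {
      present <- any(ais$affection == a & ais$segment == s)
      if (!present) return("n/a")
      r <- by_seg$means[by_seg$means$affection == a & by_seg$means$segment == s, ]
      fmt(r$mean, r$lower, r$upper)
    }, "")
    ov <- overall$means[overall$means$affection == a, ]
    c(affection = a, cells, all = fmt(ov$mean, ov$lower, ov$upper))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  list(table = tab, fit = fit, by_segment = by_seg, overall = overall,
       p_overall = overall$contrasts$p.value[1])
}
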