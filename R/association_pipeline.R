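# Orchestration of the full analysis: GRS and single-SNP mixed-model
# associations for baseline and treatment response, in the full sample and
# within triglyceride strata, with Bonferroni-corrected significance flags
# and paired change tests. Stratified and full-sample analyses share one
# code path; the stratum is only a sample filter.

#' Bonferroni-corrected significance threshold
#'
#' Returns `alpha / m` exactly. Significance decisions use this exact value;
#' only display should round (e.g. 0.05/14 = 0.003571..., shown as 0.004).
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return The corrected per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || m < 1) {
    stop("bonferroni_threshold domain error: m must be >= 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  alpha / m
}

#' Analysis plan
#'
#' @param phenotypes phenotype subset (default all 14).
#' @param stages `"baseline"` and/or `"response"`.
#' @param strata any of `"full"`, `"tg_low"` (TG < cutoff), `"tg_high"`
#'   (TG >= cutoff).
#' @param alpha family-wise significance level.
#' @param tg_cutoff triglyceride stratification threshold, mg/dL.
#' @param min_n smallest stratum size still fitted; below it the result row
#'   is emitted with `estimable = FALSE`.
#' @return A list of class `analysis_plan`.
#' @export
analysis_plan <- function(phenotypes = nmr_phenotypes(),
                          stages = c("baseline", "response"),
                          strata = c("full", "tg_low", "tg_high"),
                          alpha = 0.05, tg_cutoff = 150, min_n = 30L) {
  assert_phenotype(phenotypes)
  structure(list(phenotypes = phenotypes,
                 stages = match.arg(stages, several.ok = TRUE),
                 strata = match.arg(strata, several.ok = TRUE),
                 alpha = alpha, tg_cutoff = tg_cutoff,
                 min_n = as.integer(min_n)),
            class = "analysis_plan")
}

#' Family-block random-effect covariance
#'
#' Alternative to the pedigree relationship matrix: a block matrix with 1 for
#' every within-family pair, equivalent to a family-indicator random
#' intercept.
#'
#' @param ped pedigree_table.
#' @return n x n matrix with a `families` attribute.
#' @export
family_matrix <- function(ped) {
  ids <- ped$individual_id
  M <- outer(ped$family_id, ped$family_id, `==`) * 1
  dimnames(M) <- list(ids, ids)
  attr(M, "families") <- stats::setNames(ped$family_id, ids)
  M
}

# covariate design shared by all models: age, male indicator, BMI, smoker,
# center indicator(s); constant columns (e.g. one-center strata) are dropped
covariate_design <- function(samples) {
  X <- cbind(age = samples$age,
             sex_male = as.numeric(samples$sex == "male"),
             bmi = samples$bmi,
             smoker = as.numeric(samples$smoker > 0))
  centers <- sort(unique(samples$center))
  if (length(centers) > 1L) {
    for (ct in centers[-1L]) {
      X <- cbind(X, as.numeric(samples$center == ct))
      colnames(X)[ncol(X)] <- paste0("center_", ct)
    }
  }
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X[, keep, drop = FALSE]
}

# one mixed-model association; predictor is a numeric vector or a factor
# (categorical genotype). Returns the F/p/d for the predictor term.
fit_one_association <- function(y, predictor, samples, A, families, min_n,
                                df_convention = "n_minus_2") {
  ok <- !is.na(y) & (if (is.factor(predictor)) !is.na(predictor)
                     else !is.na(predictor))
  covars <- covariate_design(samples)
  ok <- ok & stats::complete.cases(covars)
  n <- sum(ok)
  if (n < min_n) {
    return(list(estimable = FALSE, n = n))
  }
  pred <- predictor[ok]
  if (is.factor(predictor)) {
    pred <- droplevels(pred)
    if (nlevels(pred) < 2L) return(list(estimable = FALSE, n = n))
    P <- stats::model.matrix(~pred)[, -1L, drop = FALSE]
    colnames(P) <- paste0("predictor", seq_len(ncol(P)))
  } else {
    if (stats::sd(pred) == 0) return(list(estimable = FALSE, n = n))
    P <- matrix(pred, ncol = 1L, dimnames = list(NULL, "predictor"))
  }
  X <- cbind(`(Intercept)` = 1, P, covars[ok, , drop = FALSE])
  idx <- which(ok)
  fit <- reml_fit(y[ok], X, A[idx, idx, drop = FALSE],
                  families = families[idx])
  w <- wald_f(fit, colnames(P))
  list(estimable = TRUE, n = n, f_value = w$f_value, p_value = w$p_value,
       cohens_d = cohens_d_from_f(w$f_value, n), h2 = fit$h2, fit = fit)
}

stratum_ids <- function(panel, plan) {
  tg <- tg_strata(panel, cutoff = plan$tg_cutoff)
  list(full = panel$samples$sample_id, tg_low = tg$low, tg_high = tg$high)
}

#' GRS-phenotype mixed-model associations
#'
#' For every requested (phenotype, stage, stratum) cell, fits the pedigree
#' linear mixed model of the transformed phenotype on the phenotype's GRS
#' plus age, sex, BMI, smoking and center, and records the Wald F, p value,
#' Cohen's d and the Bonferroni flag at `alpha / n_tests`, where `n_tests`
#' is the number of phenotypes with a nonempty GRS. Complete cases per
#' model; strata below `min_n` yield non-estimable rows.
#'
#' @param panel phenotype_panel.
#' @param grs grs_matrix from [build_grs()].
#' @param ped pedigree_table.
#' @param plan analysis_plan.
#' @param policy transform policy (default [default_transform_policy()]).
#' @param random_effect `"kinship"` (pedigree relationship matrix, default)
#'   or `"family"` (family-indicator random intercept).
#' @return A result data.frame; attributes `threshold` and `n_tests` record
#'   the exact corrected threshold.
#' @export
run_grs_associations <- function(panel, grs, ped, plan = analysis_plan(),
                                 policy = default_transform_policy(),
                                 random_effect = c("kinship", "family")) {
  random_effect <- match.arg(random_effect)
  A_full <- if (random_effect == "kinship") relationship_matrix(ped) else
    family_matrix(ped)
  sample_ids <- panel$samples$sample_id
  a_idx <- match(sample_ids, rownames(A_full))
  if (anyNA(a_idx)) stop("panel samples missing from pedigree", call. = FALSE)
  A <- A_full[a_idx, a_idx, drop = FALSE]
  families <- attr(A_full, "families")[a_idx]
  transformed <- apply_transforms(panel, policy)
  strata <- stratum_ids(panel, plan)

  grs_phenos <- colnames(grs$values)[grs$n_snps_used > 0L]
  phenos <- intersect(plan$phenotypes, grs_phenos)
  n_tests <- length(phenos)
  threshold <- bonferroni_threshold(plan$alpha, n_tests)
  g_idx <- match(sample_ids, rownames(grs$values))

  rows <- list()
  for (ph in phenos) {
    x <- grs$values[g_idx, ph]
    for (stage in plan$stages) {
      y_all <- transformed[[stage]][, ph]
      for (st in plan$strata) {
        in_st <- sample_ids %in% strata[[st]]
        y <- ifelse(in_st, y_all, NA_real_)
        res <- fit_one_association(y, ifelse(in_st, x, NA_real_),
                                   panel$samples, A, families, plan$min_n)
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = ph, stage = stage, stratum = st, predictor = "GRS",
          n = res$n,
          f_value = if (res$estimable) res$f_value else NA_real_,
          cohens_d = if (res$estimable) res$cohens_d else NA_real_,
          p_value = if (res$estimable) res$p_value else NA_real_,
          significant_bonferroni = if (res$estimable)
            res$p_value < threshold else NA,
          estimable = res$estimable,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "n_tests") <- n_tests
  out
}

#' Single-SNP mixed-model associations
#'
#' Fits the same mixed model per retained manifest entry with the SNP as the
#' predictor (minor allele coded). Typed SNPs enter additively by default or
#' as a three-class categorical (joint 2-df Wald F) with
#' `coding = "categorical"`; imputed SNPs always enter as dosages.
#'
#' @param panel phenotype_panel.
#' @param g genotype_matrix.
#' @param manifest snp_manifest (only `available & passed_qc` entries run).
#' @param ped pedigree_table.
#' @param plan analysis_plan.
#' @param policy transform policy.
#' @param coding `"additive"` (default) or `"categorical"` for typed SNPs.
#' @param random_effect as in [run_grs_associations()].
#' @return A result data.frame, one row per (entry, stage, stratum).
#' @export
run_single_snp_associations <- function(panel, g, manifest, ped,
                                        plan = analysis_plan(),
                                        policy = default_transform_policy(),
                                        coding = c("additive", "categorical"),
                                        random_effect = c("kinship", "family")) {
  coding <- match.arg(coding)
  random_effect <- match.arg(random_effect)
  A_full <- if (random_effect == "kinship") relationship_matrix(ped) else
    family_matrix(ped)
  sample_ids <- panel$samples$sample_id
  a_idx <- match(sample_ids, rownames(A_full))
  A <- A_full[a_idx, a_idx, drop = FALSE]
  families <- attr(A_full, "families")[a_idx]
  transformed <- apply_transforms(panel, policy)
  strata <- stratum_ids(panel, plan)
  retained <- manifest[manifest$available & manifest$passed_qc &
                         manifest$phenotype %in% plan$phenotypes, ,
                       drop = FALSE]
  v_idx <- match(sample_ids, rownames(g$values))

  rows <- list()
  for (r in seq_len(nrow(retained))) {
    snp <- retained$snp_id[r]
    ph <- retained$phenotype[r]
    j <- snp_index(g, snp)
    v <- g$values[v_idx, j]
    typed <- g$snp_meta$source[j] == "typed"
    pred_all <- if (typed && coding == "categorical")
      factor(v, levels = c(0, 1, 2)) else v
    for (stage in plan$stages) {
      y_all <- transformed[[stage]][, ph]
      for (st in plan$strata) {
        in_st <- sample_ids %in% strata[[st]]
        y <- ifelse(in_st, y_all, NA_real_)
        pred <- if (is.factor(pred_all)) {
          p2 <- pred_all
          p2[!in_st] <- NA
          p2
        } else ifelse(in_st, pred_all, NA_real_)
        res <- fit_one_association(y, pred, panel$samples, A, families,
                                   plan$min_n)
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = ph, stage = stage, stratum = st, predictor = snp,
          coding = if (typed) coding else "dosage",
          n = res$n,
          f_value = if (res$estimable) res$f_value else NA_real_,
          cohens_d = if (res$estimable) res$cohens_d else NA_real_,
          p_value = if (res$estimable) res$p_value else NA_real_,
          estimable = res$estimable,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Paired pre/post change report
#'
#' Paired t tests of post- versus pre-treatment values per phenotype, in the
#' full sample and within the triglyceride strata (raw values by default, as
#' change tables usually report raw means; set `transformed = TRUE` to test
#' on the analysis scale).
#'
#' @param panel phenotype_panel.
#' @param plan analysis_plan (supplies strata and the TG cutoff).
#' @param transformed test log-transformed values where the baseline policy
#'   says log (default FALSE).
#' @param policy transform policy used when `transformed = TRUE`.
#' @return data.frame with one row per (phenotype, stratum).
#' @export
change_report <- function(panel, plan = analysis_plan(), transformed = FALSE,
                          policy = default_transform_policy()) {
  strata <- stratum_ids(panel, plan)
  sample_ids <- panel$samples$sample_id
  rows <- list()
  for (ph in intersect(plan$phenotypes, colnames(panel$baseline))) {
    pre_all <- panel$baseline[, ph]
    post_all <- panel$post[, ph]
    if (transformed && policy_transform(policy, ph, "baseline") == "log") {
      pre_all <- log(pre_all)
      post_all <- log(post_all)
    }
    for (st in plan$strata) {
      in_st <- sample_ids %in% strata[[st]]
      pre <- pre_all[in_st]
      post <- post_all[in_st]
      n_ok <- sum(!is.na(pre) & !is.na(post))
      if (n_ok < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = ph, stratum = st, n_pairs = n_ok,
          mean_baseline = NA_real_, mean_post = NA_real_,
          t_statistic = NA_real_, p_value = NA_real_, estimable = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      ct <- paired_change_test(pre, post)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, stratum = st, n_pairs = ct$n_pairs,
        mean_baseline = ct$mean_pre, mean_post = ct$mean_post,
        t_statistic = ct$t_statistic, p_value = ct$p_value, estimable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Refresh manifest flags from data
#'
#' Sets `available` from SNP presence in the genotype data and `passed_qc`
#' from a QC report's exclusion flags, so the manifest accounting reflects
#' the dataset actually analysed.
#'
#' @param manifest snp_manifest.
#' @param g genotype_matrix (pre-QC).
#' @param qc_report per-SNP report from [apply_qc()] (optional).
#' @return The updated [snp_manifest].
#' @export
update_manifest_flags <- function(manifest, g, qc_report = NULL) {
  manifest$available <- manifest$snp_id %in% g$snp_meta$snp_id
  if (!is.null(qc_report)) {
    excluded <- qc_report$snp_id[qc_report$excluded]
    manifest$passed_qc <- !(manifest$snp_id %in% excluded)
  }
  snp_manifest(as.data.frame(manifest))
}
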