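# Analysis-phenotype construction: selective log transforms, the pre/post
# treatment-response ratio, paired change tests, and triglyceride
# stratification.

#' Default transform policy
#'
#' Skewed measures are natural-log transformed before analysis; the rest stay
#' on the original scale. At baseline the untransformed exceptions are small
#' LDL concentration, HDL total particles, large HDL concentration, small HDL
#' concentration, LDL diameter and HDL diameter. For the fenofibrate-response
#' ratio the untransformed exceptions are LDL total particles, LDL diameter
#' and HDL diameter. The log base does not affect test statistics or
#' association p values.
#'
#' @return data.frame with columns `phenotype`, `stage`
#'   (`"baseline"`/`"response"`), `transform` (`"log"`/`"identity"`).
#' @export
default_transform_policy <- function() {
  baseline_identity <- c("small_ldl", "hdl_total", "large_hdl", "small_hdl",
                         "ldl_diameter", "hdl_diameter")
  response_identity <- c("ldl_total", "ldl_diameter", "hdl_diameter")
  rbind(
    data.frame(phenotype = NMR_PHENOTYPES, stage = "baseline",
               transform = ifelse(NMR_PHENOTYPES %in% baseline_identity,
                                  "identity", "log")),
    data.frame(phenotype = NMR_PHENOTYPES, stage = "response",
               transform = ifelse(NMR_PHENOTYPES %in% response_identity,
                                  "identity", "log"))
  )
}

policy_transform <- function(policy, phenotype, stage) {
  hit <- policy$transform[policy$phenotype == phenotype & policy$stage == stage]
  if (length(hit) != 1L) {
    stop("transform policy must cover (", phenotype, ", ", stage,
         ") exactly once", call. = FALSE)
  }
  hit
}

#' Treatment-response ratio
#'
#' Response is defined as the ratio of pre-treatment to post-treatment value,
#' so a decrease on treatment yields a ratio above 1.
#'
#' @param pre,post strictly positive values (vectors recycled elementwise).
#' @return `pre / post`.
#' @export
#' @examples
#' response_ratio(40, 20) # 2
response_ratio <- function(pre, post) {
  if (any(pre <= 0, na.rm = TRUE) || any(post <= 0, na.rm = TRUE)) {
    stop("response_ratio domain error: values must be strictly positive",
         call. = FALSE)
  }
  pre / post
}

#' Build transformed analysis phenotypes
#'
#' Computes the per-sample response ratio from the panel's baseline and
#' post-treatment measures, then applies the transform policy: log-stage
#' phenotypes are replaced by their natural log, identity-stage phenotypes are
#' untouched. The applied policy is recorded in the output's `policy`
#' attribute.
#'
#' @param panel phenotype_panel.
#' @param policy data.frame as from [default_transform_policy()].
#' @return List with matrices `baseline` and `response` (samples x
#'   phenotypes) on the analysis scale.
#' @export
apply_transforms <- function(panel, policy = default_transform_policy()) {
  phenos <- colnames(panel$baseline)
  baseline <- panel$baseline
  response <- matrix(NA_real_, nrow = nrow(baseline), ncol = length(phenos),
                     dimnames = dimnames(baseline))
  ok <- !is.na(panel$baseline) & !is.na(panel$post)
  response[ok] <- response_ratio(panel$baseline[ok], panel$post[ok])
  out <- list(baseline = baseline, response = response)
  for (stage in names(out)) {
    for (ph in phenos) {
      if (policy_transform(policy, ph, stage) == "log") {
        v <- out[[stage]][, ph]
        if (any(v <= 0, na.rm = TRUE)) {
          bad <- rownames(out[[stage]])[which(v <= 0)[1L]]
          stop("cannot log-transform nonpositive value: sample ", bad,
               ", phenotype ", ph, ", stage ", stage, call. = FALSE)
        }
        out[[stage]][, ph] <- log(v)
      }
    }
  }
  attr(out, "policy") <- policy
  out
}

#' Paired change test
#'
#' Two-sided paired t test of post versus pre values (equivalently a
#' one-sample t test on the paired differences), on pairwise-complete pairs.
#'
#' @param pre,post equal-length paired vectors.
#' @return List with `n_pairs`, `mean_pre`, `mean_post`, `t_statistic`,
#'   `p_value`.
#' @export
paired_change_test <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]
  post <- post[ok]
  if (length(pre) < 2L) {
    stop("paired change test requires at least 2 complete pairs", call. = FALSE)
  }
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(n_pairs = length(d), mean_pre = mean(pre),
                  mean_post = mean(post), t_statistic = 0, p_value = 1))
    }
    stop("paired change test degenerate: differences have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(n_pairs = length(d), mean_pre = mean(pre), mean_post = mean(post),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Stratify samples by baseline fasting triglycerides
#'
#' Splits samples at the hypertriglyceridemia indication threshold; the
#' boundary value falls in the high stratum (TG >= cutoff). Samples with
#' missing TG belong to neither stratum and are reported via a message.
#'
#' @param panel phenotype_panel.
#' @param cutoff mg/dL (default 150).
#' @return List with character vectors `low` (TG < cutoff) and `high`
#'   (TG >= cutoff) of sample ids.
#' @export
tg_strata <- function(panel, cutoff = 150) {
  tg <- panel$samples$tg_baseline
  ids <- panel$samples$sample_id
  n_missing <- sum(is.na(tg))
  if (n_missing > 0L) {
    message(n_missing, " sample(s) with missing TG excluded from strata")
  }
  list(low = ids[!is.na(tg) & tg < cutoff],
       high = ids[!is.na(tg) & tg >= cutoff])
}
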