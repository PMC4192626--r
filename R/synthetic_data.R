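# Generator for family-study data with known genetic architecture:
# multigeneration pedigrees with sibships of at least two, gene-dropped
# genotypes with injected missingness/Mendelian-error/dosage-noise artifacts,
# a SNP-phenotype manifest with configurable availability/QC accounting, and
# baseline/post-treatment phenotype panels whose generative model mirrors the
# analysis model (additive GRS effect + pedigree polygenic effect + residual,
# treatment response on the log pre/post ratio with a null genetic effect by
# default).
#
# Every operation re-seeds deterministically from config$seed plus a fixed
# per-stage offset, so individual stages and the whole study are reproducible.

#' Simulation configuration
#'
#' Defaults describe the emulated study: ~91 three-generation families with
#' sibships of 2-4 (about 820 individuals), 60 SNPs at MAF U(0.05, 0.5) of
#' which 77% are imputed dosages, a 189-entry SNP-phenotype manifest with 26
#' entries flagged unavailable and 3 flagged QC-failing (160 retained),
#' polygenic heritability 0.4, a baseline GRS effect of 0.1 SD per allele and
#' a null GRS effect on treatment response, and a triglyceride distribution
#' with 31% of samples at or above 150 mg/dL.
#'
#' @param n_families number of independent families.
#' @param generations pedigree depth (>= 2).
#' @param sibship_range (min, max) sibship size, min >= 2.
#' @param n_snps number of simulated SNPs (in linkage equilibrium).
#' @param maf_range minor allele frequency range, within (0, 0.5].
#' @param fraction_imputed fraction of SNPs carried as imputed dosages.
#' @param missing_rate per-call missingness rate for typed SNPs.
#' @param mendelian_error_rate per-call corruption rate for typed SNPs.
#' @param dosage_noise_sd sd of imputation noise added to dosages (clipped to
#'   \[0, 2\]).
#' @param grs_beta_baseline per-allele baseline effect, phenotype-SD units.
#' @param grs_beta_response per-allele effect on log(pre/post) response.
#' @param heritability_polygenic proportion of baseline variance from the
#'   pedigree polygenic effect.
#' @param covariate_effects named list of covariate effect sizes (SD units).
#' @param manifest_n_entries,manifest_n_unavailable,manifest_n_qc_fail
#'   manifest accounting: total entries, entries flagged unavailable, entries
#'   flagged as failing QC (flagged entries are disjoint, grouped by SNP).
#' @param tg_fraction_high fraction of samples with TG >= 150 mg/dL.
#' @param tg_missing_rate fraction of samples with missing TG.
#' @param response_noise_sd residual sd of log response.
#' @param response_family_sd sd of the familial (pedigree-transmitted
#'   polygenic) log-response effect; keeps the generative response model
#'   within the covariance family the analysis model fits.
#' @param seed integer master seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 91L,
                              generations = 3L,
                              sibship_range = c(2L, 4L),
                              n_snps = 60L,
                              maf_range = c(0.05, 0.5),
                              fraction_imputed = 0.77,
                              missing_rate = 0.01,
                              mendelian_error_rate = 0.001,
                              dosage_noise_sd = 0.05,
                              grs_beta_baseline = 0.1,
                              grs_beta_response = 0,
                              heritability_polygenic = 0.4,
                              covariate_effects = list(age = 0.01,
                                                       sex_male = 0.2,
                                                       bmi = 0.02,
                                                       smoker = 0.15,
                                                       center = 0.1),
                              manifest_n_entries = 189L,
                              manifest_n_unavailable = 26L,
                              manifest_n_qc_fail = 3L,
                              tg_fraction_high = 0.31,
                              tg_missing_rate = 0.03,
                              response_noise_sd = 0.2,
                              response_family_sd = 0.1,
                              seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              generations = as.integer(generations),
              sibship_range = as.integer(sibship_range),
              n_snps = as.integer(n_snps),
              maf_range = maf_range,
              fraction_imputed = fraction_imputed,
              missing_rate = missing_rate,
              mendelian_error_rate = mendelian_error_rate,
              dosage_noise_sd = dosage_noise_sd,
              grs_beta_baseline = grs_beta_baseline,
              grs_beta_response = grs_beta_response,
              heritability_polygenic = heritability_polygenic,
              covariate_effects = covariate_effects,
              manifest_n_entries = as.integer(manifest_n_entries),
              manifest_n_unavailable = as.integer(manifest_n_unavailable),
              manifest_n_qc_fail = as.integer(manifest_n_qc_fail),
              tg_fraction_high = tg_fraction_high,
              tg_missing_rate = tg_missing_rate,
              response_noise_sd = response_noise_sd,
              response_family_sd = response_family_sd,
              seed = as.integer(seed))
  props <- c(cfg$fraction_imputed, cfg$missing_rate, cfg$mendelian_error_rate,
             cfg$tg_fraction_high, cfg$tg_missing_rate)
  if (any(props < 0 | props > 1)) {
    stop("config error: proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$generations < 2L) {
    stop("config error: generations must be >= 2", call. = FALSE)
  }
  if (cfg$sibship_range[1L] < 2L || cfg$sibship_range[2L] < cfg$sibship_range[1L]) {
    stop("config error: sibship min must be >= 2 and <= max", call. = FALSE)
  }
  if (cfg$maf_range[1L] <= 0 || cfg$maf_range[2L] > 0.5 ||
      cfg$maf_range[1L] > cfg$maf_range[2L]) {
    stop("config error: maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (cfg$heritability_polygenic < 0 || cfg$heritability_polygenic >= 1) {
    stop("config error: heritability must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$manifest_n_unavailable + cfg$manifest_n_qc_fail >=
      cfg$manifest_n_entries) {
    stop("config error: flagged manifest entries must leave some retained",
         call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# per-stage seed offsets (kept small; master seed stays within 32-bit range)
SIM_SEED_OFFSETS <- c(pedigree = 0L, genotypes = 1L, artifacts = 2L,
                      phenotypes = 3L, manifest = 4L)

sim_seed <- function(config, stage) {
  set.seed((config$seed + SIM_SEED_OFFSETS[[stage]]) %% .Machine$integer.max)
}

#' Simulate multigeneration family pedigrees
#'
#' Each family starts from a founder couple; every subsequent generation is a
#' full sibship (size drawn from `sibship_range`) of the previous couple, and
#' for pedigrees deeper than two generations the first sib pairs with a
#' married-in founder to produce the next sibship. All non-founders have both
#' parents in the table. A `generation` column (0 = top founders) is kept for
#' age assignment.
#'
#' @param config simulation_config.
#' @return A [pedigree_table].
#' @export
simulate_pedigrees <- function(config) {
  sim_seed(config, "pedigree")
  rows <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("fam%03d", f)
    counter <- 0L
    nid <- function() {
      counter <<- counter + 1L
      sprintf("%s_i%02d", fam, counter)
    }
    recs <- list()
    add <- function(id, father, mother, sex, gen) {
      recs[[length(recs) + 1L]] <<- data.frame(
        family_id = fam, individual_id = id,
        father_id = father, mother_id = mother, sex = sex, generation = gen,
        stringsAsFactors = FALSE)
    }
    father <- nid(); mother <- nid()
    add(father, NA_character_, NA_character_, "male", 0L)
    add(mother, NA_character_, NA_character_, "female", 0L)
    for (gen in seq_len(config$generations - 1L)) {
      rng <- config$sibship_range
      s <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
      sibs <- character(s)
      sexes <- sample(c("male", "female"), s, replace = TRUE)
      for (k in seq_len(s)) {
        sibs[k] <- nid()
        add(sibs[k], father, mother, sexes[k], gen)
      }
      if (gen < config$generations - 1L) {
        continuing <- sibs[1L]
        spouse <- nid()
        spouse_sex <- if (sexes[1L] == "male") "female" else "male"
        add(spouse, NA_character_, NA_character_, spouse_sex, gen)
        if (sexes[1L] == "male") {
          father <- continuing; mother <- spouse
        } else {
          father <- spouse; mother <- continuing
        }
      }
    }
    rows[[f]] <- do.call(rbind, recs)
  }
  pedigree_table(do.call(rbind, rows))
}

#' Gene-drop genotypes through a pedigree
#'
#' Per SNP (independently; linkage equilibrium), founder allele copies are
#' Bernoulli(MAF) draws and each child inherits one uniformly chosen allele
#' per parent, so the pre-corruption matrix contains no Mendelian
#' inconsistencies by construction. A configured fraction of SNPs is carried
#' as imputed dosages (equal to the true allele count until noise is
#' injected); the rest are typed hard calls.
#'
#' @param ped pedigree_table.
#' @param config simulation_config.
#' @return List with `genotypes` (a clean [genotype_matrix]) and `truth`
#'   (per-SNP MAF and provenance; extended by later stages).
#' @export
drop_genotypes <- function(ped, config) {
  sim_seed(config, "genotypes")
  n <- nrow(ped)
  m <- config$n_snps
  ids <- ped$individual_id
  snp_ids <- sprintf("snp%03d", seq_len(m))
  maf <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
  bases <- c("A", "C", "G", "T")
  minor <- sample(bases, m, replace = TRUE)
  major <- vapply(minor, function(b) sample(setdiff(bases, b), 1L), character(1))

  ord <- ped_topological_order(ped)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  for (i in ord) {
    if (is.na(fa[i])) {
      H1[i, ] <- stats::rbinom(m, 1L, maf)
    } else {
      pick <- stats::runif(m) < 0.5
      H1[i, ] <- ifelse(pick, H1[fa[i], ], H2[fa[i], ])
    }
    if (is.na(mo[i])) {
      H2[i, ] <- stats::rbinom(m, 1L, maf)
    } else {
      pick <- stats::runif(m) < 0.5
      H2[i, ] <- ifelse(pick, H1[mo[i], ], H2[mo[i], ])
    }
  }
  values <- H1 + H2
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, snp_ids)

  # freeze the coded-allele orientation on the realized sample: fold SNPs
  # whose drawn allele came out above 0.5 (ties break alphabetically), the
  # same rule the file readers apply, so emitted files round-trip exactly
  freq <- colMeans(values) / 2
  flip <- freq > 0.5 | (freq == 0.5 & minor > major)
  if (any(flip)) {
    values[, flip] <- 2 - values[, flip, drop = FALSE]
    tmp <- minor[flip]
    minor[flip] <- major[flip]
    major[flip] <- tmp
    maf[flip] <- 1 - maf[flip]
  }

  n_imputed <- round(config$fraction_imputed * m)
  imputed <- sample(seq_len(m), n_imputed)
  source <- rep("typed", m)
  source[imputed] <- "imputed"
  meta <- data.frame(snp_id = snp_ids, minor_allele = minor,
                     major_allele = major, source = source,
                     stringsAsFactors = FALSE)
  truth <- list(snp_ids = snp_ids, maf = stats::setNames(maf, snp_ids),
                source = stats::setNames(source, snp_ids))
  list(genotypes = genotype_matrix(values, meta), truth = truth)
}

#' Inject genotyping artifacts
#'
#' Typed hard calls are set missing at `missing_rate` and, among the
#' remaining calls, resampled uniformly from the two wrong genotypes at
#' `mendelian_error_rate`; imputed dosages receive Gaussian noise of sd
#' `dosage_noise_sd` truncated to \[0, 2\]. The corruption log (one row per
#' altered call) is attached as attribute `"corruption"`.
#'
#' @param g clean genotype_matrix.
#' @param ped pedigree_table (for family ids in the corruption log).
#' @param config simulation_config.
#' @return The corrupted [genotype_matrix] with a `"corruption"` attribute.
#' @export
inject_artifacts <- function(g, ped, config) {
  if (config$missing_rate < 0 || config$missing_rate > 1 ||
      config$mendelian_error_rate < 0 || config$mendelian_error_rate > 1) {
    stop("config error: rates must lie in [0, 1]", call. = FALSE)
  }
  sim_seed(config, "artifacts")
  values <- g$values
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)
  log_rows <- list()
  typed_cols <- which(g$snp_meta$source == "typed")
  for (j in typed_cols) {
    v <- values[, j]
    drop_mask <- stats::runif(length(v)) < config$missing_rate
    if (any(drop_mask)) {
      for (i in which(drop_mask)) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          snp_id = g$snp_meta$snp_id[j], sample_id = rownames(values)[i],
          family_id = unname(fam_of[rownames(values)[i]]),
          type = "missing", old = v[i], new = NA_real_)
      }
      v[drop_mask] <- NA_real_
    }
    err_mask <- !is.na(v) & stats::runif(length(v)) < config$mendelian_error_rate
    if (any(err_mask)) {
      for (i in which(err_mask)) {
        new_val <- sample(setdiff(c(0, 1, 2), v[i]), 1L)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          snp_id = g$snp_meta$snp_id[j], sample_id = rownames(values)[i],
          family_id = unname(fam_of[rownames(values)[i]]),
          type = "mendelian", old = v[i], new = new_val)
        v[i] <- new_val
      }
    }
    values[, j] <- v
  }
  imputed_cols <- which(g$snp_meta$source == "imputed")
  if (length(imputed_cols) > 0L && config$dosage_noise_sd > 0) {
    noise <- matrix(stats::rnorm(nrow(values) * length(imputed_cols),
                                 0, config$dosage_noise_sd),
                    nrow = nrow(values))
    values[, imputed_cols] <- pmin(2, pmax(0, values[, imputed_cols] + noise))
  }
  out <- genotype_matrix(values, g$snp_meta)
  corruption <- if (length(log_rows) > 0L) do.call(rbind, log_rows) else
    data.frame(snp_id = character(0), sample_id = character(0),
               family_id = character(0), type = character(0),
               old = numeric(0), new = numeric(0))
  attr(out, "corruption") <- corruption
  out
}

# Allocate manifest entries among the 14 phenotypes and draw each
# phenotype's SNP set and published-beta signs. Part of the truth record.
make_manifest_truth <- function(truth, config) {
  sim_seed(config, "manifest")
  n_entries <- config$manifest_n_entries
  n_ph <- length(NMR_PHENOTYPES)
  base <- n_entries %/% n_ph
  extra <- n_entries %% n_ph
  per_ph <- rep(base, n_ph) + c(rep(1L, extra), rep(0L, n_ph - extra))
  # a small SNP panel caps each phenotype's allocation at the panel size
  per_ph <- pmin(per_ph, length(truth$snp_ids))
  entries <- do.call(rbind, lapply(seq_len(n_ph), function(k) {
    data.frame(snp_id = sample(truth$snp_ids, per_ph[k]),
               phenotype = NMR_PHENOTYPES[k],
               beta_sign = sample(c(-1L, 1L), per_ph[k], replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  truth$entries <- entries
  truth
}

# subset-sum: pick SNP ids (from `pool`, with per-SNP entry counts `counts`)
# whose counts sum exactly to `target`; NULL when infeasible
pick_snps_with_total <- function(pool, counts, target) {
  if (target == 0L) return(character(0))
  reach <- vector("list", target + 1L)
  reach[[1L]] <- character(0)
  for (k in seq_along(pool)) {
    ck <- counts[k]
    if (ck > target) next
    for (s in rev(seq_len(target - ck + 1L))) {
      if (!is.null(reach[[s]]) && is.null(reach[[s + ck]])) {
        reach[[s + ck]] <- c(reach[[s]], pool[k])
      }
    }
  }
  reach[[target + 1L]]
}

#' Emit a SNP-phenotype manifest with availability/QC accounting
#'
#' Builds the manifest from the truth record's entry table and flags whole
#' SNPs (all their entries) as unavailable or QC-failing so that the flagged
#' entry counts hit the configured totals exactly, emulating the way a
#' published association list shrinks to the analysable set. Every phenotype
#' is guaranteed at least one retained entry.
#'
#' @param truth truth record containing `entries` (see [simulate_study()]).
#' @param config simulation_config.
#' @return A [snp_manifest] with `available`/`passed_qc` flags set.
#' @export
emit_manifest <- function(truth, config = simulation_config()) {
  entries <- truth$entries
  if (is.null(entries) || nrow(entries) == 0L) {
    return(snp_manifest(data.frame(snp_id = character(0),
                                   phenotype = character(0),
                                   beta_sign = integer(0),
                                   available = logical(0),
                                   passed_qc = logical(0))))
  }
  sim_seed(config, "manifest")
  n_unavail <- min(config$manifest_n_unavailable, nrow(entries))
  n_qcfail <- min(config$manifest_n_qc_fail,
                  nrow(entries) - n_unavail)
  # flags act on whole SNPs where the entry counts allow an exact hit;
  # reorder SNPs randomly before the subset-sum so placement varies with
  # the seed, and fall back to entry-level flags when no grouping works
  counts_tab <- table(entries$snp_id)
  for (attempt in seq_len(50L)) {
    pool <- sample(names(counts_tab))
    counts <- as.integer(counts_tab[pool])
    unavail_snps <- pick_snps_with_total(pool, counts, n_unavail)
    if (is.null(unavail_snps)) break
    rest <- setdiff(pool, unavail_snps)
    rest_counts <- as.integer(counts_tab[rest])
    qcfail_snps <- pick_snps_with_total(rest, rest_counts, n_qcfail)
    if (is.null(qcfail_snps)) next
    available <- !(entries$snp_id %in% unavail_snps)
    passed_qc <- !(entries$snp_id %in% qcfail_snps)
    retained <- entries$phenotype[available & passed_qc]
    if (all(unique(entries$phenotype) %in% retained)) {
      return(snp_manifest(data.frame(entries, available = available,
                                     passed_qc = passed_qc,
                                     stringsAsFactors = FALSE)))
    }
  }
  for (attempt in seq_len(50L)) {
    flagged <- sample(nrow(entries), n_unavail + n_qcfail)
    available <- !(seq_len(nrow(entries)) %in% flagged[seq_len(n_unavail)])
    passed_qc <- !(seq_len(nrow(entries)) %in%
                     setdiff(flagged, flagged[seq_len(n_unavail)]))
    retained <- entries$phenotype[available & passed_qc]
    if (all(unique(entries$phenotype) %in% retained)) {
      return(snp_manifest(data.frame(entries, available = available,
                                     passed_qc = passed_qc,
                                     stringsAsFactors = FALSE)))
    }
  }
  stop("could not place manifest flags without emptying a phenotype",
       call. = FALSE)
}

# additive polygenic values flowing down the pedigree: founders ~
# N(0, sigma2), child = parental mean + Mendelian-sampling N(0, sigma2/2);
# a missing parent contributes as an unrelated founder
draw_breeding_values <- function(ord, fa, mo, sigma2) {
  bv <- numeric(length(ord))
  if (sigma2 <= 0) return(bv)
  for (i in ord) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      bv[i] <- stats::rnorm(1, 0, sqrt(sigma2))
    } else {
      pm <- mean(c(if (!is.na(fa[i])) bv[fa[i]], if (!is.na(mo[i])) bv[mo[i]]))
      bv[i] <- pm + stats::rnorm(1, 0, sqrt(sigma2 / 2))
    }
  }
  bv
}

# effective generation depth used for age assignment: married-in founders
# take the depth of their co-parent
effective_depth <- function(ped) {
  ord <- ped_topological_order(ped)
  ids <- ped$individual_id
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  depth <- rep(0L, nrow(ped))
  for (i in ord) {
    parents <- c(fa[i], mo[i])
    parents <- parents[!is.na(parents)]
    if (length(parents) > 0L) depth[i] <- max(depth[parents]) + 1L
  }
  eff <- depth
  for (i in seq_len(nrow(ped))) {
    if (!is.na(fa[i]) && !is.na(mo[i])) {
      d <- depth[i] - 1L
      eff[fa[i]] <- max(eff[fa[i]], d)
      eff[mo[i]] <- max(eff[mo[i]], d)
    }
  }
  eff
}

#' Simulate baseline and post-treatment phenotypes
#'
#' The generative model mirrors the analysis model. On a latent SD-unit
#' scale, baseline = covariate effects + `grs_beta_baseline` x (centred true
#' GRS) + polygenic breeding value + residual, where breeding values flow
#' down the pedigree (child = parental mean + Mendelian-sampling noise of
#' variance sigma2_g/2). The observed measure is `exp(meanlog + sdlog * latent)`
#' for phenotypes the transform policy treats as log-normal, and
#' `mean + scale * latent` otherwise. Treatment response is generated on the
#' log pre/post scale: `log(ratio) = mu + grs_beta_response x GRS + family
#' effect + noise`, and the post value is derived as `pre / ratio`.
#' Triglycerides are log-normal with a configurable fraction at or above
#' 150 mg/dL.
#'
#' @param ped pedigree_table.
#' @param g genotype_matrix (use the clean, pre-corruption matrix).
#' @param manifest snp_manifest or truth entry table giving the causal
#'   SNP-phenotype map and true effect directions.
#' @param config simulation_config.
#' @return List with `panel` (a [phenotype_panel]) and `truth` additions
#'   (per-phenotype true GRS, breeding values, analysis-scale effect sizes).
#' @export
simulate_phenotypes <- function(ped, g, manifest, config) {
  sim_seed(config, "phenotypes")
  ids <- ped$individual_id
  n <- length(ids)
  missing_snps <- setdiff(unique(manifest$snp_id), g$snp_meta$snp_id)
  if (length(missing_snps) > 0L) {
    stop("manifest SNP(s) missing from genotypes: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  info <- nmr_phenotype_info()
  policy <- default_transform_policy()
  ce <- config$covariate_effects
  h2 <- config$heritability_polygenic

  depth <- effective_depth(ped)
  age <- pmax(18, 75 - 26 * depth + stats::runif(n, -5, 5))
  bmi <- pmin(55, pmax(16, stats::rnorm(n, 28.25, 5.62)))
  smoker <- stats::rbinom(n, 1L, 0.078)
  fam_levels <- unique(ped$family_id)
  center_of_family <- stats::setNames(
    sample(c("MN", "UT"), length(fam_levels), replace = TRUE), fam_levels)
  center <- unname(center_of_family[ped$family_id])
  covar_lin <- ce$age * (age - mean(age)) +
    ce$sex_male * (ped$sex == "male") +
    ce$bmi * (bmi - mean(bmi)) +
    ce$smoker * smoker +
    ce$center * (center == "UT")

  ord <- ped_topological_order(ped)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)

  phenos <- NMR_PHENOTYPES
  baseline <- matrix(NA_real_, n, length(phenos), dimnames = list(ids, phenos))
  post <- matrix(NA_real_, n, length(phenos), dimnames = list(ids, phenos))
  z_true <- matrix(NA_real_, n, length(phenos), dimnames = list(ids, phenos))
  bv_all <- matrix(NA_real_, n, length(phenos), dimnames = list(ids, phenos))
  beta_base_analysis <- stats::setNames(numeric(length(phenos)), phenos)
  beta_resp_analysis <- stats::setNames(numeric(length(phenos)), phenos)

  gvals <- g$values[match(ids, rownames(g$values)), , drop = FALSE]
  for (k in seq_along(phenos)) {
    ph <- phenos[k]
    entries <- manifest[manifest$phenotype == ph, , drop = FALSE]
    z <- if (nrow(entries) > 0L) {
      contrib <- gvals[, match(entries$snp_id, g$snp_meta$snp_id), drop = FALSE]
      rowSums(sweep_recode(contrib, entries$beta_sign))
    } else rep(0, n)
    zc <- z - mean(z)
    var_grs <- config$grs_beta_baseline^2 * stats::var(zc)
    resid_var <- 1 - h2 - var_grs
    if (resid_var <= 0.02) {
      stop("config error: heritability + GRS variance leave no residual",
           call. = FALSE)
    }
    bv <- draw_breeding_values(ord, fa, mo, h2)
    latent <- covar_lin + config$grs_beta_baseline * zc + bv +
      stats::rnorm(n, 0, sqrt(resid_var))

    row <- info[info$phenotype == ph, ]
    if (policy_transform(policy, ph, "baseline") == "log") {
      sdlog <- min(0.8, row$typical_sd / row$typical_mean)
      pre <- exp(log(row$typical_mean) + sdlog * latent)
      beta_base_analysis[ph] <- sdlog * config$grs_beta_baseline
    } else {
      scale_eff <- min(row$typical_sd, row$typical_mean / 4)
      pre <- pmax(row$typical_mean * 1e-3,
                  row$typical_mean + scale_eff * latent)
      beta_base_analysis[ph] <- scale_eff * config$grs_beta_baseline
    }
    bv_resp <- draw_breeding_values(ord, fa, mo, config$response_family_sd^2)
    log_ratio <- log(row$typical_response_ratio) +
      config$grs_beta_response * zc + bv_resp +
      stats::rnorm(n, 0, config$response_noise_sd)
    beta_resp_analysis[ph] <- config$grs_beta_response
    baseline[, k] <- pre
    post[, k] <- pre / exp(log_ratio)
    z_true[, k] <- z
    bv_all[, k] <- bv
  }

  sdlog_tg <- 0.5
  meanlog_tg <- log(150) - stats::qnorm(1 - config$tg_fraction_high) * sdlog_tg
  tg <- exp(stats::rnorm(n, meanlog_tg, sdlog_tg))
  tg[stats::runif(n) < config$tg_missing_rate] <- NA_real_

  samples <- data.frame(sample_id = ids, age = age, sex = ped$sex, bmi = bmi,
                        smoker = smoker, center = center, tg_baseline = tg,
                        stringsAsFactors = FALSE)
  panel <- phenotype_panel(samples, baseline, post)
  list(panel = panel,
       truth = list(z_true = z_true, breeding_values = bv_all,
                    beta_baseline_analysis = beta_base_analysis,
                    beta_response_analysis = beta_resp_analysis,
                    heritability = h2))
}

#' Simulate a complete family study
#'
#' Orchestrates the generator: pedigrees, manifest allocation, gene-dropped
#' genotypes, phenotypes generated from the clean genotypes, artifact
#' injection, and manifest flag placement. Deterministic given
#' `config$seed`.
#'
#' @param config simulation_config.
#' @return List with `ped`, `genotypes` (corrupted), `genotypes_clean`,
#'   `manifest`, `panel` and `truth` (ground-truth record for recovery
#'   tests).
#' @export
simulate_study <- function(config = simulation_config()) {
  ped <- simulate_pedigrees(config)
  dropped <- drop_genotypes(ped, config)
  truth <- make_manifest_truth(dropped$truth, config)
  manifest_true <- snp_manifest(data.frame(truth$entries, available = TRUE,
                                           passed_qc = TRUE,
                                           stringsAsFactors = FALSE))
  sim_ph <- simulate_phenotypes(ped, dropped$genotypes, manifest_true, config)
  truth <- c(truth, sim_ph$truth)
  genotypes <- inject_artifacts(dropped$genotypes, ped, config)
  manifest <- emit_manifest(truth, config)
  list(ped = ped, genotypes = genotypes,
       genotypes_clean = dropped$genotypes,
       manifest = manifest, panel = sim_ph$panel, truth = truth)
}
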