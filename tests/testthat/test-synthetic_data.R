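test_that("pedigree simulation honours structure and determinism", {
  cfg <- simulation_config(n_families = 1, generations = 2,
                           sibship_range = c(2, 2), seed = 401)
  ped <- simulate_pedigrees(cfg)
  expect_equal(nrow(ped), 4L)
  expect_equal(sum(is_founder(ped)), 2L)
  expect_equal(sum(!is_founder(ped)), 2L)

  cfg3 <- simulation_config(n_families = 100, generations = 3, seed = 402)
  ped3 <- simulate_pedigrees(cfg3)   # validation checks connectivity/acyclicity
  expect_s3_class(ped3, "pedigree_table")
  expect_equal(length(unique(ped3$family_id)), 100L)
  non_founders <- !is_founder(ped3)
  expect_true(all(!is.na(ped3$father_id[non_founders]) &
                    !is.na(ped3$mother_id[non_founders])))
  # fathers male, mothers female
  expect_true(all(ped3$sex[match(stats::na.omit(ped3$father_id),
                                 ped3$individual_id)] == "male"))
  expect_true(all(ped3$sex[match(stats::na.omit(ped3$mother_id),
                                 ped3$individual_id)] == "female"))

  expect_identical(simulate_pedigrees(cfg3), simulate_pedigrees(cfg3))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(sibship_range = c(1, 3)), "sibship")
  expect_error(simulation_config(generations = 1), "generations")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(missing_rate = 1.5), "proportions")
  expect_error(simulation_config(heritability_polygenic = 1), "heritability")
})

test_that("gene dropping matches founder allele-frequency expectations", {
  cfg <- simulation_config(n_families = 400, generations = 2,
                           sibship_range = c(2, 2), n_snps = 4,
                           maf_range = c(0.5, 0.5), seed = 403)
  dropped <- drop_genotypes(simulate_pedigrees(cfg), cfg)
  ped <- simulate_pedigrees(cfg)
  founders <- is_founder(ped)
  founder_mean <- colMeans(dropped$genotypes$values[founders, ])
  # 800 founders, MAF 0.5: mean dosage 1.0 within Monte-Carlo error
  mc_sd <- sqrt(2 * 0.5 * 0.5 / sum(founders))
  expect_true(all(abs(founder_mean - 1.0) < 4 * mc_sd))

  # founder frequencies converge on the configured MAF across a range
  cfg2 <- simulation_config(n_families = 400, generations = 2,
                            sibship_range = c(2, 2), n_snps = 30, seed = 404)
  ped2 <- simulate_pedigrees(cfg2)
  dropped2 <- drop_genotypes(ped2, cfg2)
  founder_freq <- colMeans(dropped2$genotypes$values[is_founder(ped2), ]) / 2
  expect_true(all(abs(founder_freq - dropped2$truth$maf) < 0.05))
})

test_that("a MAF range collapsed to near zero fixes all genotypes", {
  cfg <- simulation_config(n_families = 5, n_snps = 5,
                           maf_range = c(1e-12, 1e-12), seed = 405)
  dropped <- drop_genotypes(simulate_pedigrees(cfg), cfg)
  expect_true(all(dropped$genotypes$values == 0))
})

test_that("pre-corruption genotypes contain zero Mendelian errors", {
  cfg <- simulation_config(n_families = 30, n_snps = 25, fraction_imputed = 0.4,
                           seed = 406)
  ped <- simulate_pedigrees(cfg)
  dropped <- drop_genotypes(ped, cfg)
  typed <- dropped$genotypes$snp_meta$snp_id[
    dropped$genotypes$snp_meta$source == "typed"]
  errs <- vapply(typed, function(s)
    mendelian_error_families(dropped$genotypes, ped, s), integer(1))
  expect_true(all(errs == 0L))
})

test_that("artifact injection respects rates and logs corruptions", {
  cfg0 <- simulation_config(n_families = 10, missing_rate = 0,
                            mendelian_error_rate = 0, dosage_noise_sd = 0,
                            seed = 407)
  ped <- simulate_pedigrees(cfg0)
  clean <- drop_genotypes(ped, cfg0)$genotypes
  same <- inject_artifacts(clean, ped, cfg0)
  expect_equal(same$values, clean$values)

  cfg_sat <- simulation_config(n_families = 10, missing_rate = 1,
                               mendelian_error_rate = 0, seed = 407)
  sat <- inject_artifacts(clean, ped, cfg_sat)
  typed_cols <- sat$snp_meta$source == "typed"
  expect_true(all(is.na(sat$values[, typed_cols])))
  expect_true(!anyNA(sat$values[, !typed_cols]))

  # binomial expectation: one trio family, 1000 typed SNPs, 5% corruption
  cfg_err <- simulation_config(n_families = 1, generations = 2,
                               sibship_range = c(2, 2), n_snps = 1000,
                               fraction_imputed = 0, missing_rate = 0,
                               mendelian_error_rate = 0.05, seed = 408)
  ped1 <- simulate_pedigrees(cfg_err)
  clean1 <- drop_genotypes(ped1, cfg_err)$genotypes
  corrupted <- inject_artifacts(clean1, ped1, cfg_err)
  log <- attr(corrupted, "corruption")
  n_calls <- nrow(clean1$values) * 1000
  expect_true(abs(nrow(log) - 0.05 * n_calls) <
                4 * sqrt(n_calls * 0.05 * 0.95))
  # the log describes exactly the cells that changed
  changed <- which(is.na(corrupted$values) != is.na(clean1$values) |
                     (!is.na(corrupted$values) & !is.na(clean1$values) &
                        corrupted$values != clean1$values))
  expect_equal(length(changed), nrow(log))
  expect_true(all(log$new != log$old | is.na(log$new)))
})

test_that("dosage noise is clipped to the legal range", {
  cfg <- simulation_config(n_families = 20, fraction_imputed = 1,
                           dosage_noise_sd = 0.8, seed = 409)
  ped <- simulate_pedigrees(cfg)
  clean <- drop_genotypes(ped, cfg)$genotypes
  noisy <- inject_artifacts(clean, ped, cfg)
  expect_true(min(noisy$values) >= 0 && max(noisy$values) <= 2)
  expect_false(identical(noisy$values, clean$values))
})

test_that("sib-pair phenotype correlation approximates h2/2", {
  # 400 independent full-sib pairs, h2 = 0.5, no GRS or covariate effects
  cfg <- simulation_config(n_families = 400, generations = 2,
                           sibship_range = c(2, 2), n_snps = 20,
                           heritability_polygenic = 0.5,
                           grs_beta_baseline = 0,
                           covariate_effects = list(age = 0, sex_male = 0,
                                                    bmi = 0, smoker = 0,
                                                    center = 0),
                           seed = 410)
  st <- simulate_study(cfg)
  sibs <- st$ped[!is_founder(st$ped), ]
  y <- log(st$panel$baseline[, "medium_vldl"])
  first <- sibs$individual_id[!duplicated(sibs$family_id)]
  second <- sibs$individual_id[duplicated(sibs$family_id)]
  r <- stats::cor(y[first], y[second])
  # expected r = h2/2 = 0.25; sampling sd of r at n=400 is about 0.047
  expect_true(abs(r - 0.25) < 3 * 0.047)
})

test_that("null response effect leaves log-response unassociated with GRS", {
  cfg <- simulation_config(n_families = 80, grs_beta_response = 0, seed = 411)
  st <- simulate_study(cfg)
  z <- st$truth$z_true[, "small_vldl"]
  log_resp <- log(st$panel$baseline[, "small_vldl"] /
                    st$panel$post[, "small_vldl"])
  ols <- summary(stats::lm(log_resp ~ z))
  expect_gt(ols$coefficients["z", "Pr(>|t|)"], 0.001)
})

test_that("manifest emission reproduces the published-list accounting", {
  cfg <- simulation_config(seed = 412)
  ped <- simulate_pedigrees(cfg)
  truth <- fenogrs:::make_manifest_truth(drop_genotypes(ped, cfg)$truth, cfg)
  man <- emit_manifest(truth, cfg)
  expect_equal(nrow(man), 189L)
  expect_equal(sum(!man$available), 26L)
  expect_equal(sum(man$available & !man$passed_qc), 3L)
  retained <- man[man$available & man$passed_qc, ]
  expect_equal(nrow(retained), 160L)
  expect_equal(length(unique(retained$phenotype)), 14L)
  # flags are grouped by SNP, as availability and QC act on whole SNPs
  by_snp <- split(man$available, man$snp_id)
  expect_true(all(vapply(by_snp, function(x) all(x) || all(!x), logical(1))))

  all_true <- simulation_config(manifest_n_unavailable = 0,
                                manifest_n_qc_fail = 0, seed = 412)
  man2 <- emit_manifest(truth, all_true)
  expect_true(all(man2$available & man2$passed_qc))

  empty <- emit_manifest(list(entries = NULL), cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("whole-study simulation is reproducible and emits identical files", {
  cfg <- simulation_config(n_families = 5, seed = 413)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(a$panel, f1)
  write_phenotypes(b$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(as.data.frame(a$manifest), as.data.frame(b$manifest))
})
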