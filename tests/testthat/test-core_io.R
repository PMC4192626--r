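test_that("fam reader handles a trio and founder coding", {
  path <- withr::local_tempfile(fileext = ".fam")
  writeLines(c("f1 dad 0 0 1 -9",
               "f1 mom 0 0 2 -9",
               "f1 kid dad mom 1 -9"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree_table")
  expect_equal(nrow(ped), 3L)
  expect_equal(sum(is_founder(ped)), 2L)
  expect_true(is.na(ped$father_id[ped$individual_id == "dad"]))
  expect_equal(ped$sex, c("male", "female", "male"))
})

test_that("pedigree validation rejects malformed files", {
  self_parent <- withr::local_tempfile(fileext = ".fam")
  writeLines(c("f1 kid kid 0 1 -9"), self_parent)
  expect_error(read_pedigree(self_parent), "its own parent")

  dup <- withr::local_tempfile(fileext = ".fam")
  writeLines(c("f1 a 0 0 1 -9", "f1 a 0 0 2 -9"), dup)
  expect_error(read_pedigree(dup), "duplicate individual")

  cycle <- data.frame(family_id = "f1",
                      individual_id = c("a", "b"),
                      father_id = c("b", "a"),
                      mother_id = c(NA, NA),
                      sex = "male")
  expect_error(pedigree_table(cycle), "cyclic parentage")

  split_fam <- data.frame(family_id = "f1",
                          individual_id = c("a", "b"),
                          father_id = NA_character_,
                          mother_id = NA_character_,
                          sex = "male")
  expect_error(pedigree_table(split_fam), "connected")
})

test_that("pedigree round-trips through the fam dialect", {
  cfg <- simulation_config(n_families = 5, seed = 301)
  ped <- simulate_pedigrees(cfg)
  path <- withr::local_tempfile(fileext = ".fam")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_equal(as.data.frame(back),
               as.data.frame(ped)[names(as.data.frame(back))])
})

test_that("generated pedigree fixtures have family sizes >= 3 and line counts match", {
  cfg <- simulation_config(n_families = 40, seed = 302)
  ped <- simulate_pedigrees(cfg)
  path <- withr::local_tempfile(fileext = ".fam")
  write_pedigree(ped, path)
  expect_equal(length(readLines(path)), nrow(ped))
  expect_true(all(table(ped$family_id) >= 3))
})

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")

test_that("VCF reader: GT loads as typed, DS as imputed dosage", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t0/0\t0/0",
               "1\t200\trs2\tA\tG\t.\t.\t.\tGT:DS\t0/1:1.3\t0/0:0.2\t0/0:0.1"),
             path)
  g <- read_genotypes(path, dialect = "vcf")
  expect_equal(g$snp_meta$source, c("typed", "imputed"))
  expect_equal(unname(g$values["s1", ]), c(1, 1.3))
  expect_equal(unname(g$values["s2", "rs2"]), 0.2)
  expect_equal(g$snp_meta$minor_allele, c("G", "G"))
})

test_that("VCF reader orients to the minor allele and polices dosages", {
  flip <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t1/1\t1/1\t0/1"), flip)
  g <- read_genotypes(flip, dialect = "vcf")
  # ALT frequency 5/6 > 0.5: REF becomes the coded minor allele
  expect_equal(g$snp_meta$minor_allele, "A")
  expect_equal(unname(g$values[, "rs1"]), c(0, 0, 1))

  bad_ds <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               "1\t100\trs1\tA\tG\t.\t.\t.\tGT:DS\t0/1:2.5\t0/0:0.1\t0/0:0.1"),
             bad_ds)
  expect_error(read_genotypes(bad_ds, dialect = "vcf"), "DS outside")

  multi <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header,
               "1\t100\trs1\tA\tG,T\t.\t.\t.\tGT\t0/1\t0/0\t0/0",
               "1\t200\trs2\tA\tG\t.\t.\t.\tGT\t0/1\t./.\t0/0"), multi)
  expect_warning(g2 <- read_genotypes(multi, dialect = "vcf"),
                 "non-biallelic")
  expect_equal(g2$snp_meta$snp_id, "rs2")
  expect_true(is.na(g2$values["s2", "rs2"]))
})

test_that("ped/map and dosage TSV round-trip their matrices", {
  cfg <- simulation_config(n_families = 8, n_snps = 12, fraction_imputed = 0,
                           missing_rate = 0.05, seed = 303)
  st <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".ped")
  # complete hard calls round-trip bit-exactly
  write_genotypes(st$genotypes_clean, path, dialect = "ped_map", ped = st$ped)
  back <- read_genotypes(path, dialect = "ped_map")
  expect_equal(back$values, st$genotypes_clean$values)
  expect_equal(back$snp_meta$source, st$genotypes_clean$snp_meta$source)
  # with missingness the reader's orientation is frozen from observed calls;
  # a write-read cycle of the reader's own output is the identity
  path_m <- withr::local_tempfile(fileext = ".ped")
  write_genotypes(st$genotypes, path_m, dialect = "ped_map", ped = st$ped)
  once <- read_genotypes(path_m, dialect = "ped_map")
  path_m2 <- withr::local_tempfile(fileext = ".ped")
  write_genotypes(once, path_m2, dialect = "ped_map", ped = st$ped)
  twice <- read_genotypes(path_m2, dialect = "ped_map")
  expect_equal(twice$values, once$values)
  expect_equal(twice$snp_meta, once$snp_meta)

  cfg2 <- simulation_config(n_families = 8, n_snps = 12, fraction_imputed = 1,
                            seed = 304)
  st2 <- simulate_study(cfg2)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(st2$genotypes, path2, dialect = "dosage_tsv")
  back2 <- read_genotypes(path2, dialect = "dosage_tsv")
  expect_equal(back2$values, st2$genotypes$values, tolerance = 1e-8)
  expect_true(all(back2$snp_meta$source == "imputed"))
})

test_that("genotype matrix invariants are enforced", {
  vals <- matrix(c(0, 1, 2, 3), ncol = 1,
                 dimnames = list(paste0("s", 1:4), "snp1"))
  meta <- data.frame(snp_id = "snp1", minor_allele = "A", major_allele = "G",
                     source = "typed")
  expect_error(genotype_matrix(vals, meta), "0/1/2")
  vals[4] <- NA
  expect_silent(genotype_matrix(vals, meta))
  meta$source <- "imputed"
  expect_error(genotype_matrix(vals, meta), "imputed")
})

test_that("manifest reader validates vocabulary, signs and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tphenotype\tbeta_sign\tavailable\tpassed_qc",
               "rs1\tsmall_vldl\t+\tTRUE\tTRUE",
               "rs2\thdl_diameter\t-\tTRUE\tFALSE"), path)
  man <- read_manifest(path)
  expect_equal(man$beta_sign, c(1L, -1L))
  expect_equal(man$passed_qc, c(TRUE, FALSE))

  # phenotypes outside the 14-measure NMR vocabulary are rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tphenotype\tbeta_sign\tavailable\tpassed_qc",
               "rs1\tApoA1\t+\tTRUE\tTRUE"), bad)
  expect_error(read_manifest(bad), "unknown phenotype")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tphenotype\tbeta_sign\tavailable\tpassed_qc",
               "rs1\tsmall_vldl\t+\tTRUE\tTRUE",
               "rs1\tsmall_vldl\t-\tTRUE\tTRUE"), dup)
  expect_error(read_manifest(dup), "duplicate")

  badsign <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tphenotype\tbeta_sign\tavailable\tpassed_qc",
               "rs1\tsmall_vldl\t0\tTRUE\tTRUE"), badsign)
  expect_error(read_manifest(badsign), "beta_sign")
})

test_that("packaged 189-entry manifest fixture parses and round-trips", {
  fixture <- system.file("extdata", "manifest_synthetic_189.tsv",
                         package = "fenogrs")
  man <- read_manifest(fixture)
  expect_equal(nrow(man), 189L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, path)
  expect_equal(as.data.frame(read_manifest(path)), as.data.frame(man))
})

test_that("phenotype panel round-trips and enforces positivity", {
  cfg <- simulation_config(n_families = 6, seed = 305)
  st <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(st$panel, path)
  back <- read_phenotypes(path)
  expect_equal(back$baseline, st$panel$baseline, tolerance = 1e-6)
  expect_equal(back$post, st$panel$post, tolerance = 1e-6)
  expect_equal(back$samples$tg_baseline, st$panel$samples$tg_baseline,
               tolerance = 1e-6)

  bad <- st$panel$baseline
  bad[1, 1] <- -1
  expect_error(phenotype_panel(st$panel$samples, bad, st$panel$post),
               "strictly positive")
})
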