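# SNP-level quality control: monomorphic filter, call-rate filter, and
# MAF-stratified exclusion by the number of families harbouring Mendelian
# errors. Thresholds default to the rules used for family GWAS hard calls.

#' Default QC thresholds
#'
#' Call-rate exclusion is strict (`< min_call_rate` fails, exactly at the
#' boundary passes). The Mendelian rule is stratified by MAF with half-open
#' strata: MAF >= 0.20 tolerates errors in up to 3 families; 0.10 <= MAF <
#' 0.20 up to 2; 0.05 <= MAF < 0.10 up to 1; MAF < 0.05 tolerates none.
#'
#' @param min_call_rate minimum call rate retained (default 0.96).
#' @param maf_breaks lower bounds of the MAF strata, descending.
#' @param max_error_families maximum tolerated error-family count per stratum.
#' @param check_duos also check parent-child duos (default TRUE).
#' @param maf_founders_only compute stratification MAF on founders only
#'   (default FALSE: all non-missing samples).
#' @return A list of thresholds for [apply_qc()].
#' @export
qc_thresholds <- function(min_call_rate = 0.96,
                          maf_breaks = c(0.20, 0.10, 0.05, 0),
                          max_error_families = c(3L, 2L, 1L, 0L),
                          check_duos = TRUE,
                          maf_founders_only = FALSE) {
  stopifnot(length(maf_breaks) == length(max_error_families))
  list(min_call_rate = min_call_rate, maf_breaks = maf_breaks,
       max_error_families = as.integer(max_error_families),
       check_duos = check_duos, maf_founders_only = maf_founders_only)
}

#' Genotyping call rate of a SNP
#'
#' Fraction of non-missing calls over all samples. Imputed SNPs have call
#' rate 1 by construction.
#'
#' @param g genotype_matrix.
#' @param snp SNP id.
#' @return Proportion in \[0, 1\].
#' @export
call_rate <- function(g, snp) {
  j <- snp_index(g, snp)
  if (g$snp_meta$source[j] == "imputed") return(1)
  mean(!is.na(g$values[, j]))
}

#' Minor allele frequency of a SNP
#'
#' Allele frequency of the stored coded (minor) allele among non-missing
#' calls, folded into \[0, 0.5\]. Signals explicitly when every call is
#' missing.
#'
#' @param g genotype_matrix.
#' @param snp SNP id.
#' @param samples optional subset of sample ids.
#' @return Proportion in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(g, snp, samples = NULL) {
  j <- snp_index(g, snp)
  v <- g$values[, j]
  if (!is.null(samples)) v <- v[rownames(g$values) %in% samples]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("MAF undefined: all calls missing for SNP ", snp, call. = FALSE)
  }
  min(mean(v) / 2, 1 - mean(v) / 2)
}

# child count c compatible with one parent's count p?
# p = 0 transmits 0 -> child in {0,1}; p = 2 transmits 1 -> child in {1,2}
duo_compatible <- function(p, c) {
  !((p == 0 & c == 2) | (p == 2 & c == 0))
}

# trio compatibility: exists a_f in transmissible(f), a_m in transmissible(m)
# with a_f + a_m = c, where transmissible(0)={0}, (1)={0,1}, (2)={1}
trio_compatible <- function(f, m, c) {
  tr <- list(`0` = 0L, `1` = 0L:1L, `2` = 1L)
  fa <- tr[[as.character(f)]]
  mo <- tr[[as.character(m)]]
  c %in% outer(fa, mo, `+`)
}

#' Count families with Mendelian errors at a SNP
#'
#' A family is counted when it contains at least one parent-offspring
#' genotype configuration impossible under biallelic Mendelian inheritance.
#' Trios (both parents genotyped) are checked against transmissible-allele
#' logic; duos (one parent genotyped) are checked for the opposite-homozygote
#' configuration when `check_duos` is on. Missing genotypes never create
#' errors. Only defined for typed SNPs; dosages are not checked.
#'
#' @param g genotype_matrix.
#' @param ped pedigree_table.
#' @param snp SNP id.
#' @param check_duos also test single-genotyped-parent duos (default TRUE).
#' @return Integer count of distinct families with >= 1 error.
#' @export
mendelian_error_families <- function(g, ped, snp, check_duos = TRUE) {
  j <- snp_index(g, snp)
  if (g$snp_meta$source[j] == "imputed") {
    stop("Mendelian check not applicable: SNP ", snp, " is imputed",
         call. = FALSE)
  }
  v <- g$values[, j]
  geno <- v[match(ped$individual_id, rownames(g$values))]
  fa <- geno[match(ped$father_id, ped$individual_id)]
  mo <- geno[match(ped$mother_id, ped$individual_id)]
  err <- logical(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    c_i <- geno[i]
    if (is.na(c_i)) next
    f_i <- fa[i]
    m_i <- mo[i]
    if (!is.na(f_i) && !is.na(m_i)) {
      err[i] <- !trio_compatible(f_i, m_i, c_i)
    } else if (check_duos) {
      p <- if (!is.na(f_i)) f_i else m_i
      if (!is.na(p)) err[i] <- !duo_compatible(p, c_i)
    }
  }
  length(unique(ped$family_id[err]))
}

#' Apply SNP quality control
#'
#' Exclusions are applied in order: monomorphic (no variation among observed
#' calls), call rate (typed SNPs below the threshold), then the MAF-stratified
#' Mendelian family-error rule (typed SNPs only). The report lists every SNP
#' with its call rate, MAF, error-family count and exclusion reason.
#'
#' @param g genotype_matrix.
#' @param ped pedigree_table.
#' @param thresholds list from [qc_thresholds()].
#' @return List with elements `genotypes` (filtered [genotype_matrix]) and
#'   `report` (per-SNP data.frame).
#' @export
apply_qc <- function(g, ped, thresholds = qc_thresholds()) {
  snps <- g$snp_meta$snp_id
  typed <- g$snp_meta$source == "typed"
  n_fam <- length(unique(ped$family_id))
  maf_samples <- if (thresholds$maf_founders_only) {
    ped$individual_id[is_founder(ped)]
  } else NULL

  report <- data.frame(snp_id = snps, source = g$snp_meta$source,
                       call_rate = NA_real_, maf = NA_real_,
                       n_error_families = NA_integer_,
                       excluded = FALSE, reason = "none",
                       stringsAsFactors = FALSE)
  for (k in seq_along(snps)) {
    v <- g$values[, k]
    obs <- v[!is.na(v)]
    report$call_rate[k] <- if (typed[k]) mean(!is.na(v)) else 1
    if (length(obs) > 0L) {
      report$maf[k] <- min(mean(obs) / 2, 1 - mean(obs) / 2)
    }
    # monomorphic: no variation among post-missingness observed calls
    if (length(obs) == 0L || length(unique(obs)) == 1L) {
      report$excluded[k] <- TRUE
      report$reason[k] <- "monomorphic"
      next
    }
    if (typed[k] && report$call_rate[k] < thresholds$min_call_rate) {
      report$excluded[k] <- TRUE
      report$reason[k] <- "call_rate"
      next
    }
    if (typed[k]) {
      maf_strat <- if (is.null(maf_samples)) report$maf[k] else
        minor_allele_frequency(g, snps[k], samples = maf_samples)
      ne <- mendelian_error_families(g, ped, snps[k],
                                     check_duos = thresholds$check_duos)
      report$n_error_families[k] <- min(ne, n_fam)
      stratum <- findInterval(maf_strat, rev(thresholds$maf_breaks),
                              left.open = FALSE)
      # findInterval over ascending breaks; map back to descending order
      stratum <- length(thresholds$maf_breaks) - stratum + 1L
      if (ne > thresholds$max_error_families[stratum]) {
        report$excluded[k] <- TRUE
        report$reason[k] <- "mendelian"
      }
    }
  }
  keep <- !report$excluded
  filtered <- genotype_matrix(g$values[, keep, drop = FALSE],
                              g$snp_meta[keep, , drop = FALSE])
  list(genotypes = filtered, report = report)
}
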