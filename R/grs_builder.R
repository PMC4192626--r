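# Unweighted, direction-of-effect recoded genetic risk scores. Each of the
# 14 phenotypes gets its own score: the sum, over the manifest entries
# retained for that phenotype, of the recoded allele count or dosage. A SNP
# listed for several phenotypes contributes to each, possibly with different
# recoding.

#' Recode a dosage by the published direction of effect
#'
#' With a positive published beta the minor allele stays the coded allele and
#' the contribution is the dosage itself; with a negative beta the major
#' allele becomes the coded allele, i.e. the contribution is `2 - dosage`.
#'
#' @param dosage value(s) in \[0, 2\] (hard call or dosage).
#' @param beta_sign +1 or -1 (scalar or vector recycled against `dosage`).
#' @return Recoded contribution(s) in \[0, 2\].
#' @export
#' @examples
#' recode_contribution(2, -1)   # 0
#' recode_contribution(0.4, -1) # 1.6
recode_contribution <- function(dosage, beta_sign) {
  if (!all(beta_sign %in% c(-1, 1))) {
    stop("beta_sign must be +1 or -1", call. = FALSE)
  }
  ifelse(beta_sign > 0, dosage, 2 - dosage)
}

#' Filter a manifest to retained associations
#'
#' Keeps entries that are both available in the genotype data and passed QC,
#' mirroring the accounting that reduces a published association list to the
#' analysable set. Removal counts are attached as attributes and messaged.
#'
#' @param manifest snp_manifest.
#' @return The retained [snp_manifest]; attributes `n_unavailable`,
#'   `n_failed_qc`, `n_input` record the accounting.
#' @export
filter_manifest <- function(manifest) {
  unavailable <- !manifest$available
  failed_qc <- manifest$available & !manifest$passed_qc
  keep <- manifest$available & manifest$passed_qc
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(manifest)
  attr(out, "n_input") <- nrow(manifest)
  attr(out, "n_unavailable") <- sum(unavailable)
  attr(out, "n_failed_qc") <- sum(failed_qc)
  message("manifest filter: ", nrow(manifest), " entries, ",
          sum(unavailable), " unavailable, ", sum(failed_qc),
          " failed QC, ", nrow(out), " retained")
  if (nrow(out) == 0L) warning("no manifest entries retained", call. = FALSE)
  out
}

#' Build per-phenotype unweighted genetic risk scores
#'
#' For each phenotype with at least one retained manifest entry, the score of
#' a sample is the unweighted sum of [recode_contribution()] over that
#' phenotype's SNPs. The default missing-data policy is complete-case: a
#' sample missing any contributing hard call gets `NA` for that phenotype's
#' score. `"mean_impute"` substitutes the SNP's mean recoded contribution.
#'
#' @param g genotype_matrix.
#' @param manifest snp_manifest; only entries with `available & passed_qc`
#'   are used (apply [filter_manifest()] first for the accounting message).
#' @param missing_policy `"complete_case"` (default) or `"mean_impute"`.
#' @return An object of class `grs_matrix`: list with `values` (samples x
#'   phenotypes), `n_snps_used` (per phenotype) and `summary` (per-phenotype
#'   min/max/mean/sd).
#' @export
build_grs <- function(g, manifest,
                      missing_policy = c("complete_case", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  retained <- manifest[manifest$available & manifest$passed_qc, , drop = FALSE]
  absent <- setdiff(unique(retained$snp_id), g$snp_meta$snp_id)
  if (length(absent) > 0L) {
    stop("retained manifest SNP(s) absent from genotypes: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  phenos <- intersect(NMR_PHENOTYPES, unique(retained$phenotype))
  n <- nrow(g$values)
  values <- matrix(NA_real_, nrow = n, ncol = length(phenos),
                   dimnames = list(rownames(g$values), phenos))
  n_used <- setNames(integer(length(phenos)), phenos)
  for (ph in phenos) {
    entries <- retained[retained$phenotype == ph, , drop = FALSE]
    cols <- match(entries$snp_id, g$snp_meta$snp_id)
    contrib <- g$values[, cols, drop = FALSE]
    contrib <- sweep_recode(contrib, entries$beta_sign)
    if (missing_policy == "mean_impute" && anyNA(contrib)) {
      mu <- colMeans(contrib, na.rm = TRUE)
      for (j in seq_len(ncol(contrib))) {
        contrib[is.na(contrib[, j]), j] <- mu[j]
      }
    }
    values[, ph] <- rowSums(contrib)   # NA propagates under complete_case
    n_used[ph] <- nrow(entries)
  }
  summary <- data.frame(
    phenotype = phenos,
    n_snps = as.integer(n_used),
    min = apply(values, 2, min, na.rm = TRUE),
    max = apply(values, 2, max, na.rm = TRUE),
    mean = colMeans(values, na.rm = TRUE),
    sd = apply(values, 2, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  structure(list(values = values, n_snps_used = n_used, summary = summary),
            class = "grs_matrix")
}

sweep_recode <- function(mat, signs) {
  neg <- signs < 0
  if (any(neg)) mat[, neg] <- 2 - mat[, neg, drop = FALSE]
  mat
}

#' @export
print.grs_matrix <- function(x, ...) {
  cat("grs_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "phenotype scores\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a GRS matrix and its summary as TSV
#'
#' @param grs grs_matrix.
#' @param path samples-by-phenotypes score table output path.
#' @param summary_path optional path for the per-phenotype
#'   min/max/mean/sd summary.
#' @return `path`, invisibly.
#' @export
write_grs <- function(grs, path, summary_path = NULL) {
  out <- data.frame(sample_id = rownames(grs$values), grs$values,
                    check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.table(grs$summary, summary_path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(path)
}
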