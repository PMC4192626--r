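# Domain types and readers/writers for pedigree, genotype/dosage, manifest,
# phenotype and result files. Readers validate on load and raise typed errors;
# there is no silent coercion.

## ---- pedigree ----

#' Construct and validate a pedigree table
#'
#' A pedigree table holds one row per individual with `family_id`,
#' `individual_id`, `father_id`, `mother_id` (`NA` for founders) and `sex`
#' (`"male"`, `"female"` or `"unknown"`). Validation enforces unique
#' individual ids, that every non-missing parent id is present in the table,
#' that parentage is acyclic, and that each family's members form a single
#' connected component.
#'
#' @param df data.frame with the columns above (extra columns are kept).
#' @return The validated data.frame with class `pedigree_table`.
#' @export
pedigree_table <- function(df) {
  required <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("pedigree format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$individual_id <- as.character(df$individual_id)
  df$family_id <- as.character(df$family_id)
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup) > 0L) {
    stop("pedigree format error: duplicate individual id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female", "unknown"))) {
    stop("pedigree format error: sex must be male/female/unknown", call. = FALSE)
  }
  for (col in c("father_id", "mother_id")) {
    known <- is.na(df[[col]]) | df[[col]] %in% df$individual_id
    if (!all(known)) {
      stop("pedigree validation error: ", col, " not in table for individual(s): ",
           paste(df$individual_id[!known], collapse = ", "), call. = FALSE)
    }
  }
  # acyclicity (also yields a topological order, recomputed on demand later)
  ped_topological_order(df)
  # per-family connectivity through parent-child edges
  for (fam in unique(df$family_id)) {
    sub <- df[df$family_id == fam, , drop = FALSE]
    if (nrow(sub) > 1L && !ped_is_connected(sub)) {
      stop("pedigree validation error: family ", fam,
           " is not a connected component", call. = FALSE)
    }
  }
  class(df) <- c("pedigree_table", "data.frame")
  df
}

# Kahn topological sort: parents before children; error names an individual
# on a parentage cycle.
ped_topological_order <- function(df) {
  ids <- df$individual_id
  idx <- seq_along(ids)
  names(idx) <- ids
  fa <- ifelse(is.na(df$father_id), NA_integer_, idx[df$father_id])
  mo <- ifelse(is.na(df$mother_id), NA_integer_, idx[df$mother_id])
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", length(ids))
  for (i in idx) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) {
        if (p == i) {
          stop("pedigree validation error: individual ", ids[i],
               " is its own parent", call. = FALSE)
        }
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- idx[indeg == 0L]
  while (length(queue) > 0L) {
    i <- queue[1L]
    queue <- queue[-1L]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < length(ids)) {
    bad <- ids[setdiff(idx, order_out)][1L]
    stop("pedigree validation error: cyclic parentage involving individual ",
         bad, call. = FALSE)
  }
  order_out
}

ped_is_connected <- function(sub) {
  ids <- sub$individual_id
  adj <- lapply(seq_along(ids), function(i) integer(0))
  idx <- seq_along(ids)
  names(idx) <- ids
  for (i in idx) {
    for (p in c(sub$father_id[i], sub$mother_id[i])) {
      if (!is.na(p) && p %in% ids) {
        j <- idx[[p]]
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  seen <- logical(length(ids))
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  all(seen)
}

#' Identify founders
#'
#' @param ped pedigree_table.
#' @return Logical vector, `TRUE` for individuals with neither parent recorded.
#' @export
is_founder <- function(ped) {
  is.na(ped$father_id) & is.na(ped$mother_id)
}

#' Read a pedigree file
#'
#' Reads the whitespace-delimited six-column PLINK `.fam` dialect
#' (family, individual, father, mother, sex, phenotype). Founder parents coded
#' `"0"` become missing; sex codes 1/2/other map to male/female/unknown.
#'
#' @param path file path.
#' @param dialect only `"fam"` is supported.
#' @return A validated [pedigree_table].
#' @export
read_pedigree <- function(path, dialect = "fam") {
  dialect <- match.arg(dialect, "fam")
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype_code"))
  raw$father_id[raw$father_id == "0"] <- NA_character_
  raw$mother_id[raw$mother_id == "0"] <- NA_character_
  raw$sex <- c("1" = "male", "2" = "female")[raw$sex]
  raw$sex[is.na(raw$sex)] <- "unknown"
  raw$phenotype_code <- NULL
  pedigree_table(raw)
}

#' Write a pedigree table as a PLINK .fam file
#'
#' @param ped pedigree_table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(ped$family_id, ped$individual_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sex_code, "-9")
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- genotypes ----

#' Construct and validate a genotype matrix
#'
#' Values are minor-allele counts: typed SNPs take values in \{0, 1, 2\} or
#' `NA` (missing); imputed SNPs carry dosages anywhere in \[0, 2\] and are
#' never missing. Allele orientation (which allele is minor) is decided when
#' the file is loaded and then frozen in `snp_meta`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids).
#' @param snp_meta data.frame with columns `snp_id`, `minor_allele`,
#'   `major_allele`, `source` (`"typed"` or `"imputed"`), one row per column
#'   of `values`, in order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_meta) {
  if (is.null(rownames(values)) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("genotype format error: values must have sample and SNP dimnames",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values)) || anyDuplicated(rownames(values))) {
    stop("genotype format error: duplicate SNP or sample ids", call. = FALSE)
  }
  if (!identical(as.character(snp_meta$snp_id),
                 as.character(colnames(values)))) {
    stop("genotype format error: snp_meta rows must match value columns",
         call. = FALSE)
  }
  if (!all(snp_meta$source %in% c("typed", "imputed"))) {
    stop("genotype format error: source must be typed or imputed", call. = FALSE)
  }
  typed <- snp_meta$source == "typed"
  tv <- values[, typed, drop = FALSE]
  if (!all(is.na(tv) | tv %in% c(0, 1, 2))) {
    stop("genotype validation error: typed SNP values must be 0/1/2 or missing",
         call. = FALSE)
  }
  iv <- values[, !typed, drop = FALSE]
  if (anyNA(iv)) {
    stop("genotype validation error: imputed SNPs may not be missing",
         call. = FALSE)
  }
  if (length(iv) > 0L && (min(iv) < 0 || max(iv) > 2)) {
    stop("genotype validation error: dosages must lie in [0, 2]", call. = FALSE)
  }
  structure(list(values = values, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "samples x", ncol(x$values), "SNPs (",
      sum(x$snp_meta$source == "typed"), "typed,",
      sum(x$snp_meta$source == "imputed"), "imputed )\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

snp_index <- function(g, snp) {
  j <- match(snp, g$snp_meta$snp_id)
  if (is.na(j)) stop("unknown SNP id: ", snp, call. = FALSE)
  j
}

# orient a matrix of ALT-allele counts/dosages to minor-allele counts using
# observed frequencies; ties keep the ALT allele as minor
orient_to_minor <- function(vals, ref, alt) {
  freq <- mean(vals, na.rm = TRUE) / 2
  if (!is.na(freq) && freq > 0.5) {
    list(values = 2 - vals, minor = ref, major = alt)
  } else {
    list(values = vals, minor = alt, major = ref)
  }
}

count_gt_alt <- function(gt) {
  # "0/1", "1|1", ".", "./." -> ALT allele count or NA
  out <- rep(NA_real_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gsub("\\|", "/", gt[ok]), "/", fixed = TRUE)
  out[ok] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
  out
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  samples <- colnames(vcf@gt)[-1L]
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(!biallelic)) {
    warning("skipping ", sum(!biallelic), " non-biallelic VCF record(s): ",
            paste(fix[!biallelic, "ID"], collapse = ", "), call. = FALSE)
  }
  keep <- which(biallelic)
  n <- length(samples)
  snp_ids <- unname(fix[keep, "ID"])
  values <- matrix(NA_real_, nrow = n, ncol = length(keep),
                   dimnames = list(samples, snp_ids))
  meta <- data.frame(snp_id = snp_ids,
                     minor_allele = NA_character_, major_allele = NA_character_,
                     source = NA_character_, stringsAsFactors = FALSE)
  fmt <- vcf@gt[, "FORMAT"]
  gt_rows <- vcf@gt[, -1L, drop = FALSE]
  for (k in seq_along(keep)) {
    i <- keep[k]
    fields <- strsplit(fmt[i], ":", fixed = TRUE)[[1L]]
    cells <- strsplit(gt_rows[i, ], ":", fixed = TRUE)
    if ("DS" %in% fields) {
      pos <- match("DS", fields)
      ds <- suppressWarnings(as.numeric(vapply(cells, `[`, character(1), pos)))
      if (anyNA(ds)) {
        stop("genotype validation error: missing DS value at ", meta$snp_id[k],
             call. = FALSE)
      }
      if (min(ds) < 0 || max(ds) > 2) {
        stop("genotype validation error: DS outside [0, 2] at ", meta$snp_id[k],
             call. = FALSE)
      }
      vals <- ds
      src <- "imputed"
    } else {
      pos <- match("GT", fields)
      if (is.na(pos)) {
        stop("genotype format error: record ", meta$snp_id[k],
             " has neither GT nor DS", call. = FALSE)
      }
      vals <- count_gt_alt(vapply(cells, `[`, character(1), pos))
      src <- "typed"
    }
    o <- orient_to_minor(vals, fix[i, "REF"], fix[i, "ALT"])
    values[, k] <- o$values
    meta$minor_allele[k] <- o$minor
    meta$major_allele[k] <- o$major
    meta$source[k] <- src
  }
  genotype_matrix(values, meta)
}

read_genotypes_ped_map <- function(path, map_path) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) {
    stop("genotype format error: .ped has ", ncol(ped),
         " columns but .map implies ", 6L + 2L * m, call. = FALSE)
  }
  samples <- ped[[2L]]
  values <- matrix(NA_real_, nrow = nrow(ped), ncol = m,
                   dimnames = list(samples, map$snp_id))
  meta <- data.frame(snp_id = map$snp_id,
                     minor_allele = NA_character_, major_allele = NA_character_,
                     source = "typed", stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop("genotype format error: SNP ", map$snp_id[j],
           " has more than two alleles", call. = FALSE)
    }
    if (length(alleles) == 0L) alleles <- c("0", "0")
    counts <- table(factor(obs, levels = alleles))
    # minor = less frequent allele; tie broken alphabetically
    minor <- if (length(alleles) == 1L) alleles else
      alleles[order(as.numeric(counts), alleles)][1L]
    major <- if (length(alleles) == 1L) alleles else setdiff(alleles, minor)
    values[, j] <- ifelse(miss, NA_real_, (a1 == minor) + (a2 == minor))
    meta$minor_allele[j] <- minor
    meta$major_allele[j] <- major
  }
  genotype_matrix(values, meta)
}

read_genotypes_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "sample_id") {
    stop("genotype format error: first dosage column must be sample_id",
         call. = FALSE)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$sample_id
  if (anyNA(values)) {
    stop("genotype validation error: dosages may not be missing", call. = FALSE)
  }
  if (min(values) < 0 || max(values) > 2) {
    stop("genotype validation error: DS outside [0, 2]", call. = FALSE)
  }
  meta <- data.frame(snp_id = colnames(values),
                     minor_allele = NA_character_, major_allele = NA_character_,
                     source = "imputed", stringsAsFactors = FALSE)
  genotype_matrix(values, meta)
}

#' Read genotypes or dosages
#'
#' Supported dialects: `"vcf"` (GT records load as typed hard calls, DS records
#' as imputed dosages), `"ped_map"` (PLINK text pedigree/map pair, typed), and
#' `"dosage_tsv"` (samples x SNPs dosage table, imputed). Values are oriented
#' as minor-allele counts using the file's alleles plus observed frequencies at
#' load time; the orientation is then frozen in `snp_meta`.
#'
#' @param path genotype file (`.vcf`, `.ped` or `.tsv`).
#' @param dialect one of `"vcf"`, `"ped_map"`, `"dosage_tsv"`.
#' @param map_path for `ped_map`, the `.map` file (defaults to `path` with the
#'   extension swapped).
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, dialect = c("vcf", "ped_map", "dosage_tsv"),
                           map_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  switch(dialect,
         vcf = read_genotypes_vcf(path),
         ped_map = read_genotypes_ped_map(path, map_path),
         dosage_tsv = read_genotypes_dosage_tsv(path))
}

#' Write genotypes
#'
#' `ped_map` writes a PLINK text `.ped`/`.map` pair and requires every SNP to
#' be typed with known alleles; `dosage_tsv` writes the numeric matrix as TSV.
#'
#' @param g genotype_matrix.
#' @param path output path (`.ped` or `.tsv`); for `ped_map` the `.map` file is
#'   written alongside.
#' @param dialect `"ped_map"` or `"dosage_tsv"`.
#' @param ped optional pedigree_table supplying family/parent/sex columns for
#'   the `.ped` file; defaults to singleton records.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("ped_map", "dosage_tsv"),
                            ped = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "dosage_tsv") {
    out <- data.frame(sample_id = rownames(g$values), g$values,
                      check.names = FALSE)
    utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
    return(invisible(path))
  }
  if (any(g$snp_meta$source != "typed")) {
    stop("ped_map output requires typed SNPs only", call. = FALSE)
  }
  if (anyNA(g$snp_meta$minor_allele)) {
    stop("ped_map output requires known alleles", call. = FALSE)
  }
  samples <- rownames(g$values)
  if (is.null(ped)) {
    fam6 <- data.frame(fid = samples, iid = samples, fa = "0", mo = "0",
                       sex = "0", phe = "-9")
  } else {
    i <- match(samples, ped$individual_id)
    fam6 <- data.frame(fid = ped$family_id[i], iid = samples,
                       fa = ifelse(is.na(ped$father_id[i]), "0", ped$father_id[i]),
                       mo = ifelse(is.na(ped$mother_id[i]), "0", ped$mother_id[i]),
                       sex = c(male = "1", female = "2", unknown = "0")[ped$sex[i]],
                       phe = "-9")
  }
  allele_cols <- vector("list", ncol(g$values))
  for (j in seq_len(ncol(g$values))) {
    v <- g$values[, j]
    minor <- g$snp_meta$minor_allele[j]
    major <- g$snp_meta$major_allele[j]
    a1 <- ifelse(is.na(v), "0", ifelse(v >= 1, minor, major))
    a2 <- ifelse(is.na(v), "0", ifelse(v == 2, minor, major))
    allele_cols[[j]] <- data.frame(a1, a2)
  }
  out <- do.call(cbind, c(list(fam6), allele_cols))
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chrom = "0", snp_id = g$snp_meta$snp_id, cm = "0",
                    pos = seq_len(ncol(g$values)))
  utils::write.table(map, sub("\\.ped$", ".map", path), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- manifest ----

#' Construct and validate a SNP-phenotype association manifest
#'
#' The manifest drives GRS membership and allele recoding: one row per
#' (SNP, phenotype) association with the sign of the previously published
#' effect (`beta_sign`, +1 or -1, minor allele coded), an `available` flag
#' (SNP present in the genotype data) and a `passed_qc` flag.
#'
#' @param df data.frame with columns `snp_id`, `phenotype`, `beta_sign`,
#'   `available`, `passed_qc`.
#' @return The validated data.frame with class `snp_manifest`.
#' @export
snp_manifest <- function(df) {
  required <- c("snp_id", "phenotype", "beta_sign", "available", "passed_qc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("manifest format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  assert_phenotype(df$phenotype)
  if (!all(df$beta_sign %in% c(-1, 1))) {
    stop("manifest format error: beta_sign must be +1 or -1", call. = FALSE)
  }
  key <- paste(df$snp_id, df$phenotype)
  if (anyDuplicated(key)) {
    stop("manifest format error: duplicate (snp_id, phenotype) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  df$beta_sign <- as.integer(df$beta_sign)
  df$available <- as.logical(df$available)
  df$passed_qc <- as.logical(df$passed_qc)
  class(df) <- c("snp_manifest", "data.frame")
  df
}

#' Read a SNP-phenotype manifest
#'
#' TSV with header `snp_id`, `phenotype`, `beta_sign`, `available`,
#' `passed_qc`. `beta_sign` accepts `+`, `-`, `+1`, `1`, `-1`. Phenotype names
#' outside the 14-measure vocabulary are rejected.
#'
#' @param path file path.
#' @return A validated [snp_manifest].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  sign_map <- c("+" = 1L, "+1" = 1L, "1" = 1L, "-" = -1L, "-1" = -1L,
                "−" = -1L, "−1" = -1L)
  sign <- sign_map[tab$beta_sign]
  if (anyNA(sign)) {
    stop("manifest format error: beta_sign must be one of +, -, +1, -1 (got ",
         paste(unique(tab$beta_sign[is.na(sign)]), collapse = ", "), ")",
         call. = FALSE)
  }
  tab$beta_sign <- as.integer(sign)
  tab$available <- tolower(tab$available) %in% c("true", "t", "1", "yes")
  tab$passed_qc <- tolower(tab$passed_qc) %in% c("true", "t", "1", "yes")
  snp_manifest(tab)
}

#' Write a SNP-phenotype manifest as TSV
#'
#' @param manifest snp_manifest.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- as.data.frame(manifest)
  out$beta_sign <- ifelse(out$beta_sign > 0, "+1", "-1")
  out$available <- ifelse(out$available, "TRUE", "FALSE")
  out$passed_qc <- ifelse(out$passed_qc, "TRUE", "FALSE")
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

## ---- phenotype panel ----

#' Construct and validate a phenotype panel
#'
#' Holds per-sample covariates plus the 14 NMR measures at baseline and
#' post-treatment. Concentrations and diameters must be strictly positive
#' where non-missing.
#'
#' @param samples data.frame with columns `sample_id`, `age`, `sex`, `bmi`,
#'   `smoker`, `center`, `tg_baseline` (mg/dL; may be `NA`).
#' @param baseline,post numeric matrices (samples x phenotypes) with rownames
#'   equal to `samples$sample_id` and colnames drawn from [nmr_phenotypes()].
#' @return An object of class `phenotype_panel`.
#' @export
phenotype_panel <- function(samples, baseline, post) {
  required <- c("sample_id", "age", "sex", "bmi", "smoker", "center",
                "tg_baseline")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("phenotype format error: missing covariate column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("phenotype format error: duplicate sample ids", call. = FALSE)
  }
  for (m in list(baseline = baseline, post = post)) {
    if (!identical(rownames(m), samples$sample_id)) {
      stop("phenotype format error: measure rownames must match sample_id",
           call. = FALSE)
    }
  }
  assert_phenotype(colnames(baseline))
  assert_phenotype(colnames(post))
  if (any(baseline <= 0, na.rm = TRUE) || any(post <= 0, na.rm = TRUE)) {
    stop("phenotype validation error: measures must be strictly positive",
         call. = FALSE)
  }
  if (any(samples$tg_baseline <= 0, na.rm = TRUE)) {
    stop("phenotype validation error: TG must be strictly positive",
         call. = FALSE)
  }
  structure(list(samples = samples, baseline = baseline, post = post),
            class = "phenotype_panel")
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat("phenotype_panel:", nrow(x$samples), "samples,",
      ncol(x$baseline), "measures (baseline + post)\n")
  invisible(x)
}

#' Read a phenotype/covariate table
#'
#' Wide TSV: `sample_id`, `age`, `sex`, `bmi`, `smoker`, `center`,
#' `tg_baseline`, then `<phenotype>_baseline` and `<phenotype>_post` columns
#' for each measured phenotype.
#'
#' @param path file path.
#' @return A [phenotype_panel].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  base_cols <- grep("_baseline$", names(tab), value = TRUE)
  base_cols <- setdiff(base_cols, "tg_baseline")
  phenos <- sub("_baseline$", "", base_cols)
  assert_phenotype(phenos)
  baseline <- as.matrix(tab[paste0(phenos, "_baseline")])
  post <- as.matrix(tab[paste0(phenos, "_post")])
  colnames(baseline) <- colnames(post) <- phenos
  rownames(baseline) <- rownames(post) <- as.character(tab$sample_id)
  samples <- tab[c("sample_id", "age", "sex", "bmi", "smoker", "center",
                   "tg_baseline")]
  phenotype_panel(samples, baseline, post)
}

#' Write a phenotype panel as TSV
#'
#' @param panel phenotype_panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(panel, path) {
  base <- panel$baseline
  post <- panel$post
  colnames(base) <- paste0(colnames(base), "_baseline")
  colnames(post) <- paste0(colnames(post), "_post")
  out <- cbind(panel$samples, as.data.frame(base), as.data.frame(post))
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write an association result table as TSV
#'
#' Columns mirror the reporting layout: phenotype, stage, stratum, predictor,
#' n, F value, Cohen's d, p value and the Bonferroni significance flag.
#'
#' @param results data.frame as returned by [run_grs_associations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
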