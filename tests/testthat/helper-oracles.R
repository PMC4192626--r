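# Independent oracles and small fixture builders shared across tests.

# Brute-force Mendelian trio check by explicit allele-pair enumeration:
# a parent with genotype g carries allele pair (1,...,1,0,...,0) with g ones;
# the trio is possible iff some father allele + some mother allele = child.
oracle_trio_possible <- function(f, m, c) {
  alleles <- function(g) c(rep(1L, g), rep(0L, 2L - g))
  any(outer(alleles(f), alleles(m), `+`) == c)
}

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founder allele copies get unique labels; labels drop through the pedigree;
# A(i,j) is estimated as 2 * mean kinship, kinship = P(random allele of i
# IBD random allele of j). Returns the estimate and its Monte-Carlo sd.
oracle_mc_relationship <- function(ped, reps = 1e5, seed = 1) {
  set.seed(seed)
  ids <- ped$individual_id
  n <- length(ids)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  ord <- order(ped_depth(ped))
  P <- matrix(0L, reps, n)
  M <- matrix(0L, reps, n)
  for (i in ord) {
    if (is.na(fa[i])) {
      P[, i] <- 2L * i - 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      P[, i] <- ifelse(pick, P[, fa[i]], M[, fa[i]])
    }
    if (is.na(mo[i])) {
      M[, i] <- 2L * i
    } else {
      pick <- stats::runif(reps) < 0.5
      M[, i] <- ifelse(pick, P[, mo[i]], M[, mo[i]])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ids, ids))
  mc_sd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- ((P[, i] == P[, j]) + (P[, i] == M[, j]) +
              (M[, i] == P[, j]) + (M[, i] == M[, j])) / 4
      est[i, j] <- est[j, i] <- 2 * mean(s)
      mc_sd[i, j] <- mc_sd[j, i] <- 2 * stats::sd(s) / sqrt(reps)
    }
  }
  list(est = est, mc_sd = mc_sd)
}

ped_depth <- function(ped) {
  ids <- ped$individual_id
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  depth <- rep(NA_integer_, length(ids))
  while (anyNA(depth)) {
    for (i in which(is.na(depth))) {
      ps <- c(fa[i], mo[i])
      ps <- ps[!is.na(ps)]
      if (length(ps) == 0L) {
        depth[i] <- 0L
      } else if (!anyNA(depth[ps])) {
        depth[i] <- max(depth[ps]) + 1L
      }
    }
  }
  depth
}

# Direct matrix-formula REML log-likelihood (no eigendecomposition shortcut);
# used as the grid-search oracle for reml_fit.
oracle_reml_loglik <- function(lambda, yv, Xd, Am) {
  n <- length(yv)
  p <- ncol(Xd)
  V <- lambda * Am + diag(n)
  Vi <- solve(V)
  XtViX <- t(Xd) %*% Vi %*% Xd
  B <- solve(XtViX, t(Xd) %*% Vi %*% yv)
  r <- yv - Xd %*% B
  s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus))
}

# pedigree of n_fam independent father/mother/child trios
make_trio_pedigree <- function(n_fam) {
  rows <- lapply(seq_len(n_fam), function(f) {
    fam <- sprintf("f%02d", f)
    data.frame(
      family_id = fam,
      individual_id = paste0(fam, c("_fa", "_mo", "_ch")),
      father_id = c(NA, NA, paste0(fam, "_fa")),
      mother_id = c(NA, NA, paste0(fam, "_mo")),
      sex = c("male", "female", "unknown"),
      stringsAsFactors = FALSE)
  })
  pedigree_table(do.call(rbind, rows))
}

# one-SNP typed genotype matrix over a pedigree, values in pedigree row order
make_one_snp_matrix <- function(ped, values, snp_id = "snpX",
                                source = "typed") {
  v <- matrix(as.numeric(values), ncol = 1,
              dimnames = list(ped$individual_id, snp_id))
  genotype_matrix(v, data.frame(snp_id = snp_id, minor_allele = "A",
                                major_allele = "G", source = source,
                                stringsAsFactors = FALSE))
}

# trio-family genotype data with a controlled number of error families;
# non-error trios use the supplied Mendelian-consistent configuration
qc_fixture <- function(n_fam, n_err, ok_config, err_config = c(0, 0, 1)) {
  ped <- make_trio_pedigree(n_fam)
  vals <- rep(ok_config, n_fam)
  if (n_err > 0) {
    for (f in seq_len(n_err)) vals[(3 * (f - 1) + 1):(3 * f)] <- err_config
  }
  list(ped = ped, g = make_one_snp_matrix(ped, vals))
}

# phenotype-SD-scale simulated y over a pedigree with heritability h2 and a
# fixed-effect design, drawn directly from y ~ N(X beta, h2*A + (1-h2)*I)
# (independent of the package's phenotype generator)
draw_polygenic_y <- function(eigA, Xd, beta, h2) {
  n <- nrow(Xd)
  g <- drop(eigA$vectors %*% (sqrt(pmax(eigA$values, 0)) * stats::rnorm(n)))
  drop(Xd %*% beta) + sqrt(h2) * g + stats::rnorm(n, 0, sqrt(1 - h2))
}
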