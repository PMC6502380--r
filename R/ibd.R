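#' Posterior transmission probabilities at one marker
#'
#' For every offspring and each of its parents, the posterior probability
#' that the parent transmitted its first vs second stored allele, obtained
#' by enumerating the four equally likely transmissions and keeping those
#' consistent with the trio's genotypes; missing genotypes act as
#' wildcards, so an ungenotyped parent's meiosis stays at the uniform
#' prior. Inconsistent trios raise a Mendelian-error report naming the
#' trio and marker.
#'
#' @param genotypes a [genotype_matrix]
#' @param pedigree validated pedigree
#' @param marker marker id
#' @param ids offspring ids (default: all non-founders with genotypes)
#' @return list with `ids`, `sire`, `dam` and n x 2 matrices `p_sire`,
#'   `p_dam` of transmission posteriors
#' @export
transmission_posteriors <- function(genotypes, pedigree, marker, ids = NULL) {
  jm <- match(marker, colnames(genotypes$a1))
  if (is.na(jm)) stop_ctx("marker '%s' not in genotype panel", marker)
  ped <- as.data.frame(pedigree)
  if (is.null(ids))
    ids <- intersect(ped$individual_id[!is.na(ped$sire_id)],
                     rownames(genotypes$a1))
  row <- match(ids, ped$individual_id)
  if (anyNA(row)) stop_ctx("offspring id missing from pedigree")
  sire <- ped$sire_id[row]
  dam <- ped$dam_id[row]
  gt <- function(id_vec, k) {
    a <- matrix(NA_character_, length(id_vec), 1)
    ok <- id_vec %in% rownames(genotypes$a1)
    src <- if (k == 1L) genotypes$a1 else genotypes$a2
    a[ok] <- src[id_vec[ok], jm]
    a[, 1]
  }
  s1 <- gt(sire, 1L); s2 <- gt(sire, 2L)
  d1 <- gt(dam, 1L); d2 <- gt(dam, 2L)
  o1 <- gt(ids, 1L); o2 <- gt(ids, 2L)
  m <- function(p, o) is.na(p) | is.na(o) | p == o
  cons <- function(si, dj)
    (m(si, o1) & m(dj, o2)) | (m(si, o2) & m(dj, o1))
  w11 <- cons(s1, d1); w12 <- cons(s1, d2)
  w21 <- cons(s2, d1); w22 <- cons(s2, d2)
  tot <- w11 + w12 + w21 + w22
  if (any(tot == 0)) {
    b <- which(tot == 0)[1]
    stop_ctx("Mendelian error at marker %s: offspring %s (%s/%s) incompatible with %s (%s/%s) x %s (%s/%s)",
             marker, ids[b], o1[b], o2[b], sire[b], s1[b], s2[b],
             dam[b], d1[b], d2[b])
  }
  list(ids = ids, sire = sire, dam = dam,
       p_sire = cbind(p1 = (w11 + w12) / tot, p2 = (w21 + w22) / tot),
       p_dam = cbind(p1 = (w11 + w21) / tot, p2 = (w12 + w22) / tot))
}

#' Expected identity-by-descent matrix at one marker
#'
#' Single-marker expected IBD fraction among offspring, from genotype and
#' pedigree information: for each pair, the probability of having received
#' the same parental allele, averaged over the shared parents' meioses.
#' Fully informative full-sib pairs reach 0 or 1; uninformative meioses
#' contribute the prior 1/2; pairs sharing no parent get 0; the diagonal
#' is 1. (Single-marker expectation; no multipoint smoothing across
#' flanking markers.)
#'
#' @inheritParams transmission_posteriors
#' @return symmetric matrix with dimnames `ids`
#' @export
locus_ibd <- function(genotypes, pedigree, marker, ids = NULL) {
  tp <- transmission_posteriors(genotypes, pedigree, marker, ids)
  n <- length(tp$ids)
  Z <- matrix(0, n, n, dimnames = list(tp$ids, tp$ids))
  add_groups <- function(parent_ids, P) {
    for (g in unique(parent_ids)) {
      idx <- which(parent_ids == g)
      if (length(idx) < 2L) next
      Z[idx, idx] <<- Z[idx, idx] + tcrossprod(P[idx, , drop = FALSE]) / 2
    }
  }
  add_groups(tp$sire, tp$p_sire)
  add_groups(tp$dam, tp$p_dam)
  diag(Z) <- 1
  Z
}

#' Phenotype contrast between the two haplotypes of one parent
#'
#' Partitions a heterozygous parent's offspring by the inferred transmitted
#' haplotype (only offspring whose transmission is unambiguous are used)
#' and compares the phenotype between the two groups with a pooled-variance
#' two-sample t-test.
#'
#' @param y named phenotype vector (names = offspring ids)
#' @param genotypes a [genotype_matrix]
#' @param pedigree validated pedigree
#' @param parent_id the parent whose meioses are contrasted
#' @param marker marker id
#' @return list with per-haplotype `n`, `mean`, `sd`, plus `t`, `df`,
#'   `p_value`
#' @export
haplotype_contrast <- function(y, genotypes, pedigree, parent_id, marker) {
  jm <- match(marker, colnames(genotypes$a1))
  if (is.na(jm)) stop_ctx("marker '%s' not in genotype panel", marker)
  pg <- c(genotypes$a1[parent_id, jm], genotypes$a2[parent_id, jm])
  if (anyNA(pg) || pg[1] == pg[2])
    stop_ctx("parent '%s' is uninformative (homozygous or untyped) at %s",
             parent_id, marker)
  ped <- as.data.frame(pedigree)
  kids <- ped$individual_id[!is.na(ped$sire_id) &
                              (ped$sire_id == parent_id |
                                 ped$dam_id == parent_id)]
  kids <- intersect(kids, names(y)[!is.na(y)])
  if (length(kids) < 3L)
    stop_ctx("parent '%s': fewer than 3 phenotyped offspring", parent_id)
  tp <- transmission_posteriors(genotypes, pedigree, marker, ids = kids)
  P <- ifelse(tp$sire == parent_id, 1, 0) * tp$p_sire +
    ifelse(tp$dam == parent_id, 1, 0) * tp$p_dam
  hap <- ifelse(P[, 1] > 0.999, 1L, ifelse(P[, 2] > 0.999, 2L, NA_integer_))
  keep <- !is.na(hap)
  if (length(unique(hap[keep])) < 2L)
    stop_ctx("parent '%s': transmissions not informative enough at %s",
             parent_id, marker)
  g1 <- y[kids[keep][hap[keep] == 1L]]
  g2 <- y[kids[keep][hap[keep] == 2L]]
  n1 <- length(g1); n2 <- length(g2)
  v1 <- if (n1 > 1) (n1 - 1) * var(g1) else 0
  v2 <- if (n2 > 1) (n2 - 1) * var(g2) else 0
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  delta <- mean(g1) - mean(g2)
  tval <- if (sp2 == 0 && delta == 0) 0 else
    delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(n = c(hap1 = n1, hap2 = n2),
       mean = c(hap1 = mean(g1), hap2 = mean(g2)),
       sd = c(hap1 = sd(g1), hap2 = sd(g2)),
       t = tval, df = n1 + n2 - 2,
       p_value = 2 * pt(-abs(tval), n1 + n2 - 2))
}
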