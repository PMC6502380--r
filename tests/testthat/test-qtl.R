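test_that("pedigree kinship reproduces textbook relationships", {
  ped <- toy_pedigree()
  A <- pedigree_kinship(ped)
  # unrelated founders
  expect_equal(A["A", "B"], 0)
  expect_equal(A["A", "A"], 1)
  # full sibs 0.5, parent-offspring 0.5, half sibs 0.25
  expect_equal(A["C", "D"], 0.5)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["E", "G"], 0.25)      # share sire C only
  # path-counting checks on the third generation:
  # grandparent A -> E: 0.25; avuncular D -> E: 0.25
  expect_equal(A["A", "E"], 0.25)
  expect_equal(A["D", "E"], 0.25)
  # I, J: offspring of half sibs E x G, inbred F = A_EG / 2 = 0.125
  expect_equal(A["I", "I"], 1.125)
  # full sibs with related parents: 0.5 + (A_EG + F-terms)/... tabular value
  # checked against the direct identity A_IJ = (A_EE + 2 A_EG + A_GG) / 4
  expect_equal(A["I", "J"], (A["E", "E"] + 2 * A["E", "G"] + A["G", "G"]) / 4)
  expect_true(isSymmetric(A))
  sub <- pedigree_kinship(ped, ids = c("I", "J"))
  expect_equal(sub, A[c("I", "J"), c("I", "J")])
  expect_error(pedigree_kinship(ped, ids = "nobody"), "nobody")
})

test_that("locus IBD matches exhaustive transmission enumeration", {
  # uninformative AA x AA parents: prior 1/2 everywhere off-diagonal
  g <- trio_panel(c("A", "A"), c("A", "A"),
                  list(o1 = c("A", "A"), o2 = c("A", "A")))
  Z <- locus_ibd(g, trio_ped(c("o1", "o2")), "m1")
  expect_equal(Z["o1", "o2"], 0.5)
  expect_equal(diag(Z), c(o1 = 1, o2 = 1))

  # fully informative AB x CD
  g2 <- trio_panel(c("A", "B"), c("C", "D"),
                   list(o1 = c("A", "C"), o2 = c("A", "C"),
                        o3 = c("B", "D"), o4 = c("A", "D")))
  Z2 <- locus_ibd(g2, trio_ped(c("o1", "o2", "o3", "o4")), "m1")
  expect_equal(Z2["o1", "o2"], 1)
  expect_equal(Z2["o1", "o3"], 0)
  expect_equal(Z2["o1", "o4"], 0.5)    # same sire allele, other dam allele

  # one meiosis informative, the other at the prior: AB sire, AA dam
  g3 <- trio_panel(c("A", "B"), c("A", "A"),
                   list(o1 = c("A", "A"), o2 = c("A", "A"),
                        o3 = c("B", "A")))
  Z3 <- locus_ibd(g3, trio_ped(c("o1", "o2", "o3")), "m1")
  expect_equal(Z3["o1", "o2"], 0.75)   # sire meiosis shared + dam prior
  expect_equal(Z3["o1", "o3"], 0.25)   # sire differs + dam prior

  # ungenotyped dam contributes the prior for her meiosis
  g4 <- trio_panel(c("A", "B"), c(NA, NA),
                   list(o1 = c("A", "A"), o2 = c("B", "B")))
  Z4 <- locus_ibd(g4, trio_ped(c("o1", "o2")), "m1")
  expect_equal(Z4["o1", "o2"], 0.25)

  # unrelated pairs across families get zero
  ped2 <- validate_pedigree(data.frame(
    individual_id = c("s", "d", "s2", "d2", "o1", "p1"),
    sire_id = c(NA, NA, NA, NA, "s", "s2"),
    dam_id = c(NA, NA, NA, NA, "d", "d2"),
    strain = "Arna", family_id = c(NA, NA, NA, NA, "f1", "f2"),
    stringsAsFactors = FALSE))
  a1 <- matrix("A", 6, 1, dimnames = list(ped2$individual_id, "m1"))
  g5 <- genotype_matrix(a1, a1, data.frame(marker_id = "m1",
                                           linkage_group = 1,
                                           position_cM = 0))
  Z5 <- locus_ibd(g5, ped2, "m1")
  expect_equal(Z5["o1", "p1"], 0)

  # Mendelian inconsistency is reported with the trio and marker
  g6 <- trio_panel(c("A", "A"), c("A", "A"), list(o1 = c("B", "B")))
  expect_error(locus_ibd(g6, trio_ped("o1"), "m1"), "Mendelian error.*m1")
})

test_that("average locus IBD over unlinked markers approaches the kinship", {
  cfg <- sim_config(seed = 13, design = small_design(12, 2))
  cc <- simulate_cohort(cfg)
  ids <- cc$records$fish_id
  mean_ibd <- matrix(0, length(ids), length(ids))
  for (mk in cc$genotypes$map$marker_id[seq(1, 109, by = 4)])
    mean_ibd <- mean_ibd + locus_ibd(cc$genotypes, cc$pedigree, mk, ids = ids)
  mean_ibd <- mean_ibd / length(seq(1, 109, by = 4))
  A <- pedigree_kinship(cc$pedigree, ids)
  sib <- which(A == 0.5 & upper.tri(A), arr.ind = TRUE)
  # full sibs: expected IBD fraction 0.5 <-> additive relationship 0.5
  expect_equal(mean(mean_ibd[sib]), 0.5, tolerance = 0.02)
  unrel <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  expect_equal(max(abs(mean_ibd[unrel])), 0)
})

sim_vc_data <- function(n_fam, fam_size, s2a, s2q, s2e, seed,
                        p_covariates = 2) {
  set.seed(seed)
  n <- n_fam * fam_size
  fam <- rep(seq_len(n_fam), each = fam_size)
  G <- matrix(0, n, n)
  Zl <- matrix(0, n, n)
  for (f in seq_len(n_fam)) {
    idx <- which(fam == f)
    G[idx, idx] <- 0.5
    # a realized IBD pattern from actual transmissions (PSD by
    # construction): pi_ij = (1{same sire hap} + 1{same dam hap}) / 2
    sh <- sample(1:2, fam_size, TRUE)
    dh <- sample(1:2, fam_size, TRUE)
    pi_f <- (outer(sh, sh, "==") + outer(dh, dh, "==")) / 2
    Zl[idx, idx] <- pi_f
  }
  diag(G) <- 1
  X <- cbind(1, matrix(rnorm(n * (p_covariates - 1)), n))
  reff <- function(S, s2) {
    if (s2 == 0) return(rep(0, n))
    L <- chol(S + diag(1e-8, n))
    sqrt(s2) * as.numeric(crossprod(L, rnorm(n)))
  }
  y <- X %*% c(1, rep(0.5, p_covariates - 1)) + reff(G, s2a) +
    reff(Zl, s2q) + rnorm(n, 0, sqrt(s2e))
  list(y = as.numeric(y), X = X, G = G, Z = Zl)
}

test_that("QTL model fitting matches a grid-search oracle and is invariant", {
  d <- sim_vc_data(2, 12, s2a = 0.5, s2q = 0.8, s2e = 1, seed = 5)
  fits <- fit_qtl_models(d$y, d$X, d$G, d$Z)
  blocks <- matrix_blocks(d$G, d$Z)
  cb <- kypemorph:::build_vc_blocks(d$y, d$X, d$G, d$Z, blocks)
  grid <- expand.grid(ga = seq(-6, 3, by = 0.05), gq = seq(-6, 3, by = 0.05))
  nll <- mapply(function(a, q)
    as.numeric(kypemorph:::.vc_reml_eval(c(a, q), cb, TRUE)$nll),
    grid$ga, grid$gq)
  expect_lt(min(nll) - (-fits$fit1$loglik), 1e-4)

  # location-scale invariance of the LRT
  fits2 <- fit_qtl_models(3.7 * d$y + 11, d$X, d$G, d$Z)
  expect_equal(fits2$lrt, fits$lrt, tolerance = 1e-3)

  # Z = G: the QTL effect is confounded with the polygenic term, LRT ~ 0
  fits3 <- fit_qtl_models(d$y, d$X, d$G, d$G)
  expect_lt(fits3$lrt, 1e-3)

  expect_error(fit_vc_model(d$y, d$X[, c(1, 1)], d$G), "rank deficient")
  bad <- d$G; bad[1, 2] <- bad[2, 1] <- 5
  expect_error(fit_vc_model(d$y, d$X, bad), "positive semidefinite")
})

test_that("QTL variance proportion is the component share", {
  f <- structure(list(s2a = 1, s2q = 1, s2e = 2), class = "vc_fit")
  expect_equal(qtl_variance_proportion(f), 0.25)
  f0 <- structure(list(s2a = 1.3, s2q = 0, s2e = 2), class = "vc_fit")
  expect_equal(qtl_variance_proportion(f0), 0)
})

test_that("scan results are ordered and independent of marker order", {
  cfg <- sim_config(seed = 21, design = small_design(15, 2),
                    qtl = list(marker = "M2_1", q2 = 0.3))
  cc <- simulate_cohort(cfg)
  mk <- cc$genotypes$map$marker_id[c(1:8, 80:83)]
  s1 <- lrt_scan(cc$records, cc$genotypes, cc$pedigree, phenotype = "AKL",
                 markers = mk)
  s2 <- lrt_scan(cc$records, cc$genotypes, cc$pedigree, phenotype = "AKL",
                 markers = rev(mk))
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-6)
  expect_true(!is.unsorted(s1$linkage_group))
  expect_true(all(s1$lrt >= 0))
  expect_true(all(s1$p_value >= 0 & s1$p_value <= 1))
  expect_error(lrt_scan(cc$records, cc$genotypes, cc$pedigree,
                        phenotype = "XX"), "arg")

  # permuting phenotypes destroys the planted signal
  peak <- s1$lrt[s1$marker == "M2_1"]
  expect_gt(peak, 4)
  drops <- replicate(3, {
    prm <- cc$records
    prm$kype_length <- sample(prm$kype_length)
    sp <- lrt_scan(prm, cc$genotypes, cc$pedigree, phenotype = "AKL",
                   markers = "M2_1")
    sp$lrt
  })
  expect_lt(median(drops), peak / 2)
})

test_that("haplotype contrasts recover planted parental-allele effects", {
  # textbook pooled-t on a 6-offspring toy
  g <- trio_panel(c("A", "B"), c("C", "C"),
                  list(o1 = c("A", "C"), o2 = c("A", "C"), o3 = c("A", "C"),
                       o4 = c("B", "C"), o5 = c("B", "C"), o6 = c("B", "C")))
  ped <- trio_ped(paste0("o", 1:6))
  y <- c(o1 = 1.2, o2 = 0.8, o3 = 1.1, o4 = 2.3, o5 = 2.8, o6 = 2.1)
  hc <- haplotype_contrast(y, g, ped, "s", "m1")
  g1 <- y[1:3]; g2 <- y[4:6]
  sp <- sqrt((2 * var(g1) + 2 * var(g2)) / 4)
  t_ref <- (mean(g1) - mean(g2)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(hc$t, t_ref, tolerance = 1e-12)
  expect_equal(hc$df, 4)
  expect_equal(unname(hc$mean), c(mean(g1), mean(g2)))

  yc <- setNames(rep(1, 6), names(y))
  expect_equal(haplotype_contrast(yc, g, ped, "s", "m1")$t, 0)

  hom <- trio_panel(c("A", "A"), c("C", "C"), list(o1 = c("A", "C")))
  expect_error(haplotype_contrast(y, hom, trio_ped("o1"), "s", "m1"),
               "uninformative")

  # planted allelic effect shows in the inferred direction
  cfg <- sim_config(seed = 33, design = small_design(30, 1),
                    qtl = list(marker = "M5_2", q2 = 0.4))
  cc <- simulate_cohort(cfg)
  adj <- adjusted_traits(cc$records)
  akl <- setNames(adj$table$AKL, adj$table$fish_id)
  sires <- unique(cc$records$sire_id)
  found <- 0
  for (s in sires) {
    hc <- tryCatch(haplotype_contrast(akl, cc$genotypes, cc$pedigree, s,
                                      "M5_2"), error = function(e) NULL)
    if (!is.null(hc) && hc$p_value < 0.05) found <- found + 1
  }
  expect_gt(found, 0)
})
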