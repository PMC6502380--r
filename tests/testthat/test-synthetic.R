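test_that("simulated pedigree reproduces the cohort design", {
  cfg <- sim_config(seed = 2)
  ped <- simulate_pedigree(cfg)
  off <- ped[!is.na(ped$sire_id), ]
  # 37 families carrying kype-length-measured 1SW males, 528 males total
  expect_equal(length(unique(off$family_id[off$sea_winters == 1])), 37)
  expect_equal(nrow(off), 528)
  expect_equal(sum(off$kh_measured), 480)
  for (sw in 1:3)
    expect_equal(sum(off$sea_winters == sw), c(397, 81, 50)[sw])
  # hybrid families are crosses between the domesticated and wild founders
  fm <- off[off$strain == "HybridFM", ][1, ]
  expect_equal(ped$strain[ped$individual_id == fm$sire_id], "Mowi")
  expect_equal(ped$strain[ped$individual_id == fm$dam_id], "Figgjo")

  tiny <- sim_config(seed = 2, design = data.frame(
    strain = "Arna", sea_winters = 1L, families = 1L, n_individuals = 2L,
    n_kype_height = 2L))
  p2 <- simulate_pedigree(tiny)
  expect_equal(sum(is.na(p2$sire_id)), 2)
  expect_equal(sum(!is.na(p2$sire_id)), 2)

  empty <- tiny
  empty$design$n_individuals <- 0L
  empty$design$families <- 0L
  expect_error(simulate_pedigree(empty), "no families")
})

test_that("gene drop is Mendelian and deterministic in the seed", {
  cfg <- sim_config(seed = 9, design = small_design(10, 2))
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  off <- which(!is.na(ped$sire_id))
  # exhaustive Mendelian consistency: transmitted alleles exist in parents
  for (i in off) {
    sid <- ped$sire_id[i]; did <- ped$dam_id[i]
    expect_true(all(geno$a1[i, ] == geno$a1[sid, ] |
                      geno$a1[i, ] == geno$a2[sid, ]))
    expect_true(all(geno$a2[i, ] == geno$a1[did, ] |
                      geno$a2[i, ] == geno$a2[did, ]))
  }
  geno2 <- simulate_genotypes(ped, cfg)
  expect_identical(geno$a1, geno2$a1)
  cfg3 <- cfg; cfg3$seed <- 10L
  geno3 <- simulate_genotypes(ped, cfg3)
  expect_false(identical(geno$a1, geno3$a1))

  bad <- cfg
  bad$map$position_cM[2] <- -5
  expect_error(simulate_genotypes(ped, bad), "spacing|non-decreasing|negative")
})

test_that("Haldane map function matches its closed form and the gene drop", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(1e9), 0.5, tolerance = 1e-12)
  expect_equal(haldane(10), (1 - exp(-0.2)) / 2)

  # markers 0 cM apart co-segregate; empirical r at 10 cM matches Haldane
  des <- data.frame(strain = "Arna", sea_winters = 1L, families = 500L,
                    n_individuals = 10000L, n_kype_height = 0L)
  map <- data.frame(marker_id = c("a", "b", "c"), linkage_group = 1L,
                    position_cM = c(0, 0, 10))
  cfg <- sim_config(seed = 31, design = des, map = map)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  off <- which(!is.na(ped$sire_id))
  sire_row <- match(ped$sire_id[off], ped$individual_id)
  # phase is stored: offspring a1 is the sire-transmitted haplotype; use
  # meioses where the sire is heterozygous at both markers compared
  origin <- function(m) {
    het <- geno$a1[cbind(sire_row, m)] != geno$a2[cbind(sire_row, m)]
    ori <- ifelse(geno$a1[cbind(off, m)] == geno$a1[cbind(sire_row, m)],
                  1L, 2L)
    list(het = het, ori = ori)
  }
  o_a <- origin(1); o_b <- origin(2); o_c <- origin(3)
  both_ab <- o_a$het & o_b$het
  expect_gt(sum(both_ab), 2000)
  expect_equal(mean(o_a$ori[both_ab] != o_b$ori[both_ab]), 0)  # r = 0
  both_ac <- o_a$het & o_c$het
  r_hat <- mean(o_a$ori[both_ac] != o_c$ori[both_ac])
  r_true <- haldane(10)
  se <- sqrt(r_true * (1 - r_true) / sum(both_ac))
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("phenotypes follow the generating model in the noise-free limit", {
  cfg <- sim_config(seed = 4, design = small_design(5, 1),
                    traits = list(
                      kype_length = list(sigma2_a = 0, sigma2_e = 0),
                      kype_height = list(sigma2_a = 0, sigma2_e = 0)))
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, NULL, cfg)
  r <- sim$records
  tr <- cfg$traits$kype_length
  expected <- tr$a + tr$b * log10(r$fork_length) +
    unname(tr$strain_effects[r$strain]) + tr$sw_effects[r$sea_winters]
  expect_equal(log10(r$kype_length), expected, tolerance = 1e-12)
  expect_error(
    simulate_phenotypes(ped, NULL,
                        sim_config(seed = 4, design = small_design(5, 1),
                                   qtl = list(marker = "M1_1", q2 = 1))),
    "q2")
})

test_that("full-sib phenotypic covariance matches sigma2_a / 2", {
  des <- data.frame(strain = "Arna", sea_winters = 1L, families = 5000L,
                    n_individuals = 10000L, n_kype_height = 0L)
  cfg <- sim_config(seed = 8, design = des,
                    traits = list(kype_length = list(
                      b = 0, sigma2_a = 0.4, sigma2_e = 0.1)))
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, NULL, cfg)
  r <- sim$records
  y <- log10(r$kype_length)
  fam <- r$family_id
  first <- y[match(unique(fam), fam)]
  second <- y[nrow(r) + 1 - match(unique(fam), rev(fam))]
  cv <- cov(first, second)
  se <- sqrt((0.5^2 + 0.2^2) / 5000)   # var of a sample covariance, approx
  expect_lt(abs(cv - 0.2), 4 * se)
  # variance decomposition of the stored truth at large n
  expect_equal(var(sim$truth$per_individual$bv_kype_length), 0.4,
               tolerance = 0.05)
  expect_equal(var(sim$truth$per_individual$resid_kype_length), 0.1,
               tolerance = 0.02)
})

test_that("allometric slope is recovered with nominal CI coverage", {
  des <- data.frame(strain = "Arna", sea_winters = 1L, families = 30L,
                    n_individuals = 300L, n_kype_height = 300L)
  hits <- 0L
  for (s in seq_len(100)) {
    cfg <- sim_config(seed = 1000 + s, design = des,
                      traits = list(kype_length = list(
                        strain_effects = c(Mowi = 0, HybridFM = 0,
                                           HybridMF = 0, Arna = 0,
                                           Figgjo = 0, Vosso = 0),
                        sw_effects = c(0, 0, 0), sigma2_a = 0,
                        sigma2_e = 1e-3)))
    ped <- simulate_pedigree(cfg)
    sim <- simulate_phenotypes(ped, NULL, cfg)
    f <- loglog_fit(sim$records$fork_length, sim$records$kype_length)
    ci <- f$slope + c(-1, 1) * qt(0.975, f$df[2]) * f$slope_se
    if (cfg$traits$kype_length$b >= ci[1] && cfg$traits$kype_length$b <= ci[2])
      hits <- hits + 1L
  }
  expect_gte(hits, 93)
})

test_that("QTL effect contributes the configured variance fraction", {
  des <- data.frame(strain = "Arna", sea_winters = 1L, families = 100L,
                    n_individuals = 2000L, n_kype_height = 0L)
  map <- make_marker_map(4, 2, 50)
  cfg <- sim_config(seed = 12, design = des, map = map,
                    qtl = list(marker = "M1_1", q2 = 0.2))
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, geno, cfg)
  tt <- sim$truth$per_individual
  tr <- sim$truth$params$kype_length
  tot <- var(tt$bv_kype_length) + var(tt$qtl_kype_length) +
    var(tt$resid_kype_length)
  expect_equal(var(tt$qtl_kype_length) / tot, 0.2, tolerance = 0.035)
  expect_equal(tr$sigma2_q / (tr$sigma2_a + tr$sigma2_q + tr$sigma2_e), 0.2,
               tolerance = 1e-12)
})

test_that("cohorts are reproducible from the seed", {
  cfg <- sim_config(seed = 77, design = small_design(8, 2))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$genotypes$a1, c2$genotypes$a1)
  expect_identical(lapply(c1$landmarks, `[[`, "landmarks"),
                   lapply(c2$landmarks, `[[`, "landmarks"))
  cfg2 <- cfg; cfg2$seed <- 78L
  c3 <- simulate_cohort(cfg2)
  expect_false(identical(c1$records$fork_length, c3$records$fork_length))
})

test_that("landmark generator plants the intended shape structure", {
  # zero noise, zero displacement: configurations identical up to similarity
  des <- data.frame(strain = "Arna", sea_winters = 1:3,
                    families = 2L, n_individuals = 10L, n_kype_height = 10L)
  cfg <- sim_config(seed = 5, design = des, landmark_noise_sd = 0,
                    sw_displacement = lapply(1:3, function(i) matrix(0, 6, 2)))
  cc <- simulate_cohort(cfg)
  fit <- gpa(cc$landmarks)
  expect_lt(tail(fit$objective, 1), 1e-12)

  # planted SW displacement separates SW groups along PC1
  cfg2 <- sim_config(seed = 6, design = des, landmark_noise_sd = 0.004,
                     sw_displacement = default_sw_displacement(0.08))
  cc2 <- simulate_cohort(cfg2)
  fit2 <- gpa(cc2$landmarks)
  pca <- shape_pca(fit2)
  sw <- cc2$records$sea_winters[match(pca$specimen_ids,
                                      cc2$records$fish_id)]
  sep <- function(scores) {
    m <- tapply(scores, sw, mean)
    s <- tapply(scores, sw, sd)
    (max(m) - min(m)) / mean(s)
  }
  seps <- apply(pca$scores, 2, sep)
  expect_equal(which.max(seps), 1L, ignore_attr = TRUE)
  expect_gt(sep(pca$scores[, 1]), 3)

  # measured kype traits equal the phenotype/latent values
  m <- t(vapply(cc2$landmarks, measure_kype, numeric(2)))
  expect_equal(unname(m[, 1]), cc2$records$kype_length, tolerance = 1e-9)
  lat <- cc2$truth$per_individual$latent_kype_height
  expect_equal(unname(m[, 2]), lat, tolerance = 1e-9)
})
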