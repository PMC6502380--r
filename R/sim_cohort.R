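#' Simulate the pedigree of a common-garden cohort
#'
#' Creates unrelated founder pairs per family and full-sib offspring whose
#' per-cell counts follow `config$design`. Hybrid families are reciprocal
#' F1 crosses between the domesticated and one wild founder population
#' (HybridFM = Figgjo dam x Mowi sire, HybridMF = Mowi dam x Figgjo sire).
#' Offspring rows carry `sea_winters` and a `kh_measured` flag implementing
#' the kype-height photo-filtering pattern of the design.
#'
#' @param config a [sim_config]
#' @return `pedigree` data.frame with extra columns `role`, `sea_winters`,
#'   `kh_measured`
#' @export
simulate_pedigree <- function(config) {
  design <- config$design
  fam_per_strain <- tapply(design$families, design$strain, max)
  if (sum(design$n_individuals) == 0L || all(fam_per_strain == 0L))
    stop_ctx("simulate_pedigree: design has no families")
  founder_pop <- list(Mowi = c("Mowi", "Mowi"),
                      HybridFM = c("Mowi", "Figgjo"),   # sire pop, dam pop
                      HybridMF = c("Figgjo", "Mowi"),
                      Arna = c("Arna", "Arna"),
                      Figgjo = c("Figgjo", "Figgjo"),
                      Vosso = c("Vosso", "Vosso"))
  founders <- list()
  offspring <- list()
  for (s in unique(design$strain)) {
    k <- fam_per_strain[[s]]
    if (k == 0L) next
    pops <- founder_pop[[s]] %||% c(s, s)
    for (f in seq_len(k)) {
      fam <- sprintf("%s_f%d", s, f)
      founders[[fam]] <- data.frame(
        individual_id = c(sprintf("%s_sire", fam), sprintf("%s_dam", fam)),
        sire_id = NA_character_, dam_id = NA_character_,
        strain = pops, family_id = NA_character_, role = "founder",
        sea_winters = NA_integer_, kh_measured = NA,
        stringsAsFactors = FALSE)
    }
    cells <- design[design$strain == s, , drop = FALSE]
    cnt <- setNames(rep(0L, k), seq_len(k))
    for (i in seq_len(nrow(cells))) {
      n <- cells$n_individuals[i]
      if (n == 0L) next
      nf <- max(1L, min(cells$families[i], k))
      fam_idx <- rep_len(seq_len(nf), n)       # round-robin within the cell
      kh <- c(rep(TRUE, cells$n_kype_height[i]),
              rep(FALSE, n - cells$n_kype_height[i]))
      for (j in seq_len(n)) {
        f <- fam_idx[j]
        cnt[f] <- cnt[f] + 1L
        fam <- sprintf("%s_f%d", s, f)
        offspring[[length(offspring) + 1L]] <- data.frame(
          individual_id = sprintf("%s_o%d", fam, cnt[f]),
          sire_id = sprintf("%s_sire", fam), dam_id = sprintf("%s_dam", fam),
          strain = s, family_id = fam, role = "offspring",
          sea_winters = cells$sea_winters[i], kh_measured = kh[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  ped <- rbind(do.call(rbind, founders), do.call(rbind, offspring))
  rownames(ped) <- NULL
  validate_pedigree(ped)
}

#' Gene-drop genotypes along the linkage map
#'
#' Founder genotypes are drawn at Hardy-Weinberg proportions from the
#' configured allele frequencies and treated as phased. Each offspring
#' inherits, per parent and linkage group, a recombinant haplotype: the
#' transmitted founder haplotype switches between adjacent markers with the
#' Haldane recombination fraction r = (1 - exp(-2 d / 100)) / 2 for map
#' distance d cM; linkage groups segregate independently.
#'
#' @param pedigree output of [simulate_pedigree] (or any validated pedigree)
#' @param config a [sim_config]
#' @return a [genotype_matrix] covering all pedigree members
#' @export
simulate_genotypes <- function(pedigree, config) {
  map <- config$map
  d <- ave(map$position_cM, map$linkage_group,
           FUN = function(p) c(NA, diff(p)))
  if (any(stats::na.omit(d) < 0))
    stop_ctx("simulate_genotypes: negative marker spacing")
  with_seed(substream_seed(config$seed, "genotype"), {
    n <- nrow(pedigree)
    m <- nrow(map)
    ids <- pedigree$individual_id
    a1 <- matrix(NA_character_, n, m, dimnames = list(ids, map$marker_id))
    a2 <- a1
    rmat <- haldane(d)                      # NA at group starts
    is_founder <- is.na(pedigree$sire_id)
    draw <- function(p) ifelse(runif(m) < p, "B", "A")
    for (i in which(is_founder)) {
      a1[i, ] <- draw(config$maf)
      a2[i, ] <- draw(config$maf)
    }
    transmit <- function(parent_row) {
      # a fresh uniform haplotype at each group start is equivalent to a
      # switch with probability 1/2, so the whole meiosis vectorizes
      u <- runif(m)
      z <- ifelse(is.na(rmat), u < 0.5, u < rmat)
      hap <- 1L + cumsum(z) %% 2L
      ifelse(hap == 1L, a1[parent_row, ], a2[parent_row, ])
    }
    idx <- setNames(seq_len(n), ids)
    for (i in which(!is_founder)) {
      a1[i, ] <- transmit(idx[[pedigree$sire_id[i]]])
      a2[i, ] <- transmit(idx[[pedigree$dam_id[i]]])
    }
    genotype_matrix(a1, a2, map)
  })
}

#' Haldane map function
#' @param d map distance in centimorgans (vectorized)
#' @return recombination fraction in \[0, 0.5)
#' @export
haldane <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Simulate phenotypes under the allometric + genetic generating model
#'
#' For each trait, log10(trait) = a + b log10(fork length) + strain effect
#' + sea-winter effect + polygenic value + QTL effect + residual. Polygenic
#' values follow the pedigree (founders N(0, sigma2_a); offspring = mid-
#' parent + Mendelian-sampling N(0, sigma2_a / 2)). The QTL is biallelic and
#' additive at the configured panel marker, scaled so it explains the
#' fraction `q2` of the non-allometric variance sigma2_a + sigma2_q +
#' sigma2_e. Fork length is drawn per sea-winter class; wet and milt weight
#' follow lognormal links so gonadosomatic residuals are defined.
#'
#' @param pedigree output of [simulate_pedigree]
#' @param genotypes output of [simulate_genotypes]
#' @param config a [sim_config]
#' @return list with `records` (phenotype data.frame for offspring) and
#'   `truth` (per-individual breeding values, QTL effects, latent values and
#'   realized parameters)
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  if (config$qtl$q2 >= 1) stop_ctx("simulate_phenotypes: q2 must be < 1")
  with_seed(substream_seed(config$seed, "phenotype"), {
    ped <- pedigree
    n <- nrow(ped)
    off <- which(!is.na(ped$sire_id))
    idx <- setNames(seq_len(n), ped$individual_id)
    sw <- ped$sea_winters[off]
    n_off <- length(off)

    log_fl <- rnorm(n_off, config$log10_fl_mean[sw], config$log10_fl_sd)
    fl <- 10^log_fl
    wl <- config$weight_link
    log_wet <- wl[["a"]] + wl[["b"]] * log_fl + rnorm(n_off, 0, wl[["sd"]])
    ml <- config$milt_link
    log_milt <- ml[["a"]] + ml[["b"]] * log_wet + rnorm(n_off, 0, ml[["sd"]])

    # QTL allele count at the configured marker (0/1/2 copies of allele B)
    q2 <- config$qtl$q2
    qcount <- rep(0, n)
    p_b <- 0.5
    if (q2 > 0) {
      jm <- match(config$qtl$marker, config$map$marker_id)
      qcount <- (genotypes$a1[, jm] == "B") + (genotypes$a2[, jm] == "B")
      qcount <- as.numeric(qcount[ped$individual_id])
      p_b <- config$maf[jm]
    }

    truth <- data.frame(individual_id = ped$individual_id[off],
                        stringsAsFactors = FALSE)
    records <- data.frame(
      fish_id = ped$individual_id[off], sex = "male",
      strain = ped$strain[off], family_id = ped$family_id[off],
      sire_id = ped$sire_id[off], dam_id = ped$dam_id[off],
      sea_winters = sw,
      tank = sprintf("tank%d", sample.int(config$n_tanks, n_off,
                                          replace = TRUE)),
      fork_length = fl, kype_length = NA_real_, kype_height = NA_real_,
      milt_weight = 10^log_milt, wet_weight = 10^log_wet,
      genetic_sex = "male", stringsAsFactors = FALSE)

    params <- list(seed = config$seed, q2 = q2, qtl_marker = config$qtl$marker)
    for (trait in names(config$traits)) {
      tr <- config$traits[[trait]]
      bv <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (is.na(ped$sire_id[i])) bv[i] <- rnorm(1, 0, sqrt(tr$sigma2_a))
        else bv[i] <- (bv[idx[[ped$sire_id[i]]]] +
                         bv[idx[[ped$dam_id[i]]]]) / 2 +
            rnorm(1, 0, sqrt(tr$sigma2_a / 2))
      }
      sigma2_q <- if (q2 > 0)
        q2 / (1 - q2) * (tr$sigma2_a + tr$sigma2_e) else 0
      alpha <- if (sigma2_q > 0)
        sqrt(sigma2_q / (2 * p_b * (1 - p_b))) else 0
      qeff <- alpha * (qcount[off] - 2 * p_b)
      e <- rnorm(n_off, 0, sqrt(tr$sigma2_e))
      log_trait <- tr$a + tr$b * log_fl +
        unname(tr$strain_effects[ped$strain[off]]) +
        tr$sw_effects[sw] + bv[off] + qeff + e
      truth[[paste0("bv_", trait)]] <- bv[off]
      truth[[paste0("qtl_", trait)]] <- qeff
      truth[[paste0("resid_", trait)]] <- e
      truth[[paste0("latent_", trait)]] <- 10^log_trait
      records[[trait]] <- 10^log_trait
      params[[trait]] <- list(a = tr$a, b = tr$b, sigma2_a = tr$sigma2_a,
                              sigma2_q = sigma2_q, sigma2_e = tr$sigma2_e)
    }
    # photo-filtering pattern: kype height missing where the mouth was closed
    records$kype_height[!ped$kh_measured[off]] <- NA
    records <- validate_phenotypes(records)
    list(records = records,
         truth = list(per_individual = truth, params = params))
  })
}

#' Simulate landmark configurations for a cohort
#'
#' Each head is the mean shape plus its sea-winter displacement field (for
#' males; females get the female shift) plus isotropic Gaussian landmark
#' noise, scaled to a head size proportional to fork length, then randomly
#' rotated and translated; a digitizer pixel scale is attached. Kype
#' measurement points are placed so that [measure_kype] returns the fish's
#' kype length/height (the latent value where the phenotype record masks it,
#' since the mask models photo filtering, not the fish).
#'
#' @param records phenotype data.frame
#' @param config a [sim_config]
#' @param latent_kh optional vector of latent kype heights for masked fish
#' @return list of [landmark_config]
#' @export
simulate_landmarks <- function(records, config, latent_kh = NULL) {
  with_seed(substream_seed(config$seed, "landmarks"), {
    out <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      sw <- records$sea_winters[i]
      female <- records$sex[i] == "female"
      shape <- config$mean_shape +
        (if (female) config$female_shape_shift else
          config$sw_displacement[[sw]]) +
        matrix(rnorm(12, 0, config$landmark_noise_sd), 6, 2)
      size <- config$head_size_frac * records$fork_length[i]
      pts <- shape * size
      kl <- records$kype_length[i]
      kh <- records$kype_height[i]
      if (is.na(kh) && !is.null(latent_kh)) kh <- latent_kh[i]
      kp <- NULL
      if (!is.na(kl)) {
        if (is.na(kh)) kh <- 10^(config$allometry$kype_height[["a"]] +
                                   config$allometry$kype_height[["b"]] *
                                   log10(records$fork_length[i]))
        kp <- rbind(c(-size * 0.6, -size * 0.05),     # anterior lower jaw
                    c(-size * 0.6 + kl, -size * 0.05),# bottom of gill plate
                    c(-size * 0.6 + 0.3 * kl, -size * 0.05 + kh), # hook peak
                    c(-size * 0.6 + 0.3 * kl, -size * 0.05))      # curvature
      }
      theta <- runif(1, -pi / 8, pi / 8)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      shift <- runif(2, -5, 5)
      tf <- function(p) sweep(p %*% t(R), 2, shift, "+")
      scale_px <- 0.05                      # cm per pixel
      out[[i]] <- landmark_config(
        specimen_id = records$fish_id[i],
        landmarks = tf(pts), kype_points = if (is.null(kp)) NULL else tf(kp),
        scale = scale_px, sex = records$sex[i], sea_winters = sw)
    }
    out
  })
}

#' Simulate a full cohort (pedigree, genotypes, phenotypes, landmarks)
#' @param config a [sim_config]
#' @return list with `pedigree`, `genotypes`, `records`, `truth`, `landmarks`
#' @export
simulate_cohort <- function(config) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(ped, geno, config)
  lm <- simulate_landmarks(ph$records, config,
                           latent_kh = ph$truth$per_individual$latent_kype_height)
  list(pedigree = ped, genotypes = geno, records = ph$records,
       truth = ph$truth, landmarks = lm, config = config)
}
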