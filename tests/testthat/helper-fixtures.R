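# Shared fixtures, built in code.

# a small multi-strain design: 6 strains x 1SW, `fam` families each
small_design <- function(n_per_strain = 20, fam = 2) {
  data.frame(strain = c("Vosso", "Arna", "Figgjo", "Mowi", "HybridFM",
                        "HybridMF"),
             sea_winters = 1L, families = fam,
             n_individuals = n_per_strain, n_kype_height = n_per_strain,
             stringsAsFactors = FALSE)
}

# the 30-family / ~500-offspring design used for QTL power studies
power_design <- function() {
  data.frame(strain = c("Vosso", "Arna", "Figgjo", "Mowi", "HybridFM",
                        "HybridMF"),
             sea_winters = 1L, families = 5L,
             n_individuals = c(84, 84, 83, 83, 83, 83),
             n_kype_height = c(84, 84, 83, 83, 83, 83),
             stringsAsFactors = FALSE)
}

# random landmark configuration (optionally with kype points)
random_config <- function(id = "s1", kype = FALSE, scale = NULL) {
  landmark_config(id, matrix(rnorm(12, sd = 2), 6, 2),
                  kype_points = if (kype) matrix(rnorm(8, sd = 2), 4, 2),
                  scale = scale)
}

# apply a similarity transform (rotation theta, scale s, translation t)
similarity <- function(coords, theta, s, t) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(s * coords %*% t(R), 2, t, "+")
}

# hand-built 3-generation pedigree with textbook relationships
toy_pedigree <- function() {
  validate_pedigree(data.frame(
    individual_id = c("A", "B", "C", "D", "F", "H", "E", "G", "I", "J"),
    sire_id = c(NA, NA, "A", "A", NA, NA, "C", "C", "E", "E"),
    dam_id = c(NA, NA, "B", "B", NA, NA, "F", "H", "G", "G"),
    strain = "Vosso",
    family_id = c(NA, NA, "f1", "f1", NA, NA, "f2", "f3", "f4", "f4"),
    stringsAsFactors = FALSE))
}

# one-family trio genotypes at a single marker, from per-individual alleles
trio_panel <- function(sire, dam, kids) {
  ids <- c("s", "d", names(kids))
  a1 <- matrix(NA_character_, length(ids), 1, dimnames = list(ids, "m1"))
  a2 <- a1
  gt <- c(list(s = sire, d = dam), kids)
  for (id in ids) {
    a1[id, 1] <- gt[[id]][1]
    a2[id, 1] <- gt[[id]][2]
  }
  map <- data.frame(marker_id = "m1", linkage_group = 1, position_cM = 0)
  genotype_matrix(a1, a2, map)
}

trio_ped <- function(kids) {
  validate_pedigree(data.frame(
    individual_id = c("s", "d", kids),
    sire_id = c(NA, NA, rep("s", length(kids))),
    dam_id = c(NA, NA, rep("d", length(kids))),
    strain = "Arna",
    family_id = c(NA, NA, rep("f1", length(kids))),
    stringsAsFactors = FALSE))
}

# hand-built genotype matrix over a trio-friendly 2-marker map
toy_genotypes <- function(a1, a2, markers = c("m1", "m2"),
                          ids = rownames(a1)) {
  map <- data.frame(marker_id = markers,
                    linkage_group = seq_along(markers),
                    position_cM = 0)
  genotype_matrix(a1, a2, map)
}

# balanced one-way random-effects data: k groups, n per group
one_way_data <- function(k, n, mu = 0, sigma_b, sigma_e, seed) {
  set.seed(seed)
  b <- rnorm(k, 0, sigma_b)
  data.frame(g = factor(rep(seq_len(k), each = n)),
             y = mu + rep(b, each = n) + rnorm(k * n, 0, sigma_e))
}
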