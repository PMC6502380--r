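#' Marker map with evenly spaced markers
#'
#' Distributes `n_markers` as evenly as possible over `n_groups` linkage
#' groups (the salmon panel default: 109 SNPs over 29 groups, i.e. four
#' markers on the first 22 groups and three on the remaining 7), evenly
#' spaced along each group.
#'
#' @param n_markers total marker count
#' @param n_groups number of linkage groups
#' @param group_length group length in centimorgans
#' @return marker map data.frame (marker_id, linkage_group, position_cM)
#' @export
make_marker_map <- function(n_markers = 109L, n_groups = 29L,
                            group_length = 100) {
  base <- n_markers %/% n_groups
  extra <- n_markers %% n_groups
  per_group <- rep(base, n_groups) + rep(c(1L, 0L), c(extra, n_groups - extra))
  rows <- lapply(seq_len(n_groups), function(g) {
    k <- per_group[g]
    pos <- if (k == 1L) group_length / 2 else
      seq(0, group_length, length.out = k)
    data.frame(marker_id = sprintf("M%d_%d", g, seq_len(k)),
               linkage_group = g, position_cM = pos,
               stringsAsFactors = FALSE)
  })
  validate_marker_map(do.call(rbind, rows))
}

default_mean_shape <- function() {
  m <- rbind(c(-0.55, 0.00),   # upper-jaw apex
             c(0.35, 0.28),    # dorsal gill plate
             c(0.25, -0.30),   # ventral gill plate
             c(0.45, 0.02),    # posterior gill plate
             c(-0.25, -0.10),  # maxillary bone
             c(-0.30, 0.15))   # eye
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# dorsal shift of eye, posterior gill plate and maxilla, growing with SW age
default_sw_displacement <- function(step = 0.03) {
  lapply(1:3, function(sw) {
    d <- matrix(0, 6, 2)
    d[c(4, 5, 6), 2] <- (sw - 1) * step
    d[4, 1] <- (sw - 1) * step / 2
    d
  })
}

#' Simulation configuration for a synthetic cohort
#'
#' Bundles every parameter of the generating model. The defaults emulate
#' the study design: six strains (one domesticated, two reciprocal F1
#' hybrids, three wild) with the design's per-cell family and individual
#' counts; sea-winter-graded fork lengths; log10-log10 allometry of kype
#' length and height on fork length; additive strain and age effects on the
#' log10 traits; a pedigree-structured polygenic term; an optional biallelic
#' additive QTL placed on a panel marker; and lognormal body/milt weight
#' links so gonadosomatic residuals are well-defined.
#'
#' @param seed master integer seed (mandatory; all stages draw named
#'   sub-streams from it)
#' @param design data.frame (strain, sea_winters, families, n_individuals,
#'   n_kype_height); defaults to the male cells of [cohort_design_counts]
#' @param traits per-trait generating parameters; see defaults
#' @param qtl list(marker, q2) — QTL marker id and the fraction of
#'   non-allometric trait variance it explains (same QTL for both traits);
#'   `q2 = 0` disables it
#' @param map marker map (default [make_marker_map])
#' @param maf founder minor-allele frequency, recycled over markers
#' @param log10_fl_mean mean log10 fork length (cm) per sea-winter class
#' @param log10_fl_sd within-class SD of log10 fork length
#' @param weight_link,milt_link named vectors c(a, b, sd): log10 wet weight
#'   on log10 fork length, and log10 milt weight on log10 wet weight
#' @param n_tanks rearing tanks, assigned at random
#' @param mean_shape 6 x 2 mean head shape at unit centroid size
#' @param sw_displacement list of three 6 x 2 per-SW displacement fields
#' @param female_shape_shift 6 x 2 displacement of the female mean shape
#' @param landmark_noise_sd isotropic landmark noise SD (shape units)
#' @param head_size_frac head centroid size as a fraction of fork length
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       design = NULL,
                       traits = NULL,
                       qtl = list(marker = "M23_2", q2 = 0),
                       map = make_marker_map(),
                       maf = 0.5,
                       log10_fl_mean = c(1.778, 1.903, 1.991),
                       log10_fl_sd = 0.035,
                       weight_link = c(a = -2, b = 3, sd = 0.05),
                       milt_link = c(a = -1.3, b = 1, sd = 0.15),
                       n_tanks = 3L,
                       mean_shape = default_mean_shape(),
                       sw_displacement = default_sw_displacement(),
                       female_shape_shift = NULL,
                       landmark_noise_sd = 0.01,
                       head_size_frac = 0.25) {
  if (missing(seed)) stop_ctx("sim_config: a seed is mandatory")
  if (is.null(design)) {
    t1 <- cohort_design_counts()
    design <- t1[t1$sex == "male",
                 c("strain", "sea_winters", "families", "n_individuals",
                   "n_kype_height")]
    rownames(design) <- NULL
  }
  default_traits <- list(
    kype_length = list(
      a = -1.2, b = 1.3,
      strain_effects = c(Mowi = 0.012, HybridFM = 0, HybridMF = 0.0057,
                         Arna = -0.022, Figgjo = 0, Vosso = 0),
      sw_effects = c(0.002, 0.018, -0.032),
      sigma2_a = 6e-4, sigma2_e = 1e-3),
    kype_height = list(
      a = -3.3, b = 2.0,
      strain_effects = c(Mowi = -0.001, HybridFM = 0.040, HybridMF = 0.040,
                         Arna = 0.100, Figgjo = 0.115, Vosso = 0.070),
      sw_effects = c(-0.036, 0.179, 0.051),
      sigma2_a = 4e-3, sigma2_e = 6e-3))
  if (!is.null(traits))
    default_traits <- utils::modifyList(default_traits, traits)
  traits <- default_traits
  for (tr in traits) {
    if (tr$sigma2_a < 0 || tr$sigma2_e < 0)
      stop_ctx("sim_config: variances must be non-negative")
  }
  if (qtl$q2 < 0 || qtl$q2 >= 1)
    stop_ctx("sim_config: q2 must lie in [0, 1)")
  if (qtl$q2 > 0 && !qtl$marker %in% map$marker_id)
    stop_ctx("sim_config: QTL marker '%s' not in map", qtl$marker)
  if (is.null(female_shape_shift)) {
    female_shape_shift <- matrix(0, 6, 2)
    female_shape_shift[1, ] <- c(0.08, 0.02)   # blunter upper jaw
    female_shape_shift[6, 2] <- 0.04
  }
  maf <- rep_len(maf, nrow(map))
  if (any(maf <= 0 | maf >= 1))
    stop_ctx("sim_config: founder allele frequencies must be in (0, 1)")
  # convenience fields used by the design-counts fixture expansion
  allometry <- list(
    kype_length = c(a = traits$kype_length$a, b = traits$kype_length$b),
    kype_height = c(a = traits$kype_height$a, b = traits$kype_height$b))
  structure(list(seed = as.integer(seed), design = design, traits = traits,
                 qtl = qtl, map = map, maf = maf,
                 log10_fl_mean = log10_fl_mean, log10_fl_sd = log10_fl_sd,
                 weight_link = weight_link, milt_link = milt_link,
                 n_tanks = as.integer(n_tanks), mean_shape = mean_shape,
                 sw_displacement = sw_displacement,
                 female_shape_shift = female_shape_shift,
                 landmark_noise_sd = landmark_noise_sd,
                 head_size_frac = head_size_frac, allometry = allometry),
            class = "sim_config")
}

#' Serialize / restore a simulation configuration as JSON
#' @param config `sim_config` object
#' @param path output path
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors must become JSON objects, not bare arrays
  x$weight_link <- as.list(x$weight_link)
  x$milt_link <- as.list(x$milt_link)
  x$traits <- lapply(x$traits, function(tr) {
    tr$strain_effects <- as.list(tr$strain_effects)
    tr
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$design <- as.data.frame(x$design, stringsAsFactors = FALSE)
  x$map <- validate_marker_map(as.data.frame(x$map, stringsAsFactors = FALSE))
  as_mat <- function(m) do.call(rbind, lapply(m, unlist))   # rowmajor JSON
  x$sw_displacement <- lapply(raw$sw_displacement, as_mat)
  for (f in c("mean_shape", "female_shape_shift"))
    x[[f]] <- as_mat(raw[[f]])
  for (f in c("weight_link", "milt_link", "log10_fl_mean", "maf"))
    x[[f]] <- unlist(x[[f]])
  x$traits <- lapply(x$traits, function(tr) {
    tr$strain_effects <- unlist(tr$strain_effects)
    tr$sw_effects <- unlist(tr$sw_effects)
    tr
  })
  do.call(sim_config, x[setdiff(names(x), "allometry")])
}
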