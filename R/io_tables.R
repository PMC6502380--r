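PHENO_COLS <- c("fish_id", "sex", "strain", "family_id", "sire_id", "dam_id",
                "sea_winters", "tank", "fork_length", "kype_length",
                "kype_height", "milt_weight", "wet_weight", "genetic_sex")
PHENO_NUMERIC <- c("fork_length", "kype_length", "kype_height", "milt_weight",
                   "wet_weight")

#' Validate a phenotype table
#'
#' Checks the per-fish table against the pipeline's contract: one row per
#' fish with design factors (strain, family, sire, dam, sea-winter age,
#' tank) and linear measurements in cm/g. Missing kype measurements (mouth
#' obscured on the photograph) are `NA`, never zero.
#'
#' @param records data.frame with the columns of [read_phenotypes]
#' @return the validated data.frame (types coerced), invisibly usable
#' @export
validate_phenotypes <- function(records) {
  miss <- setdiff(PHENO_COLS, names(records))
  if (length(miss))
    stop_ctx("phenotype table: missing column(s) %s",
             paste(miss, collapse = ", "))
  for (cl in PHENO_NUMERIC) {
    v <- records[[cl]]
    if (is.character(v)) {
      v[!nzchar(trimws(v))] <- NA
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop_ctx("phenotype table: non-numeric %s in row %d", cl, bad[1])
      records[[cl]] <- num
    }
  }
  records$sea_winters <- as.integer(records$sea_winters)
  if (!all(records$sea_winters %in% 1:3))
    stop_ctx("phenotype table: sea_winters outside 1..3 in row %d",
             which(!records$sea_winters %in% 1:3)[1])
  bad <- which(!(records$fork_length > 0))
  if (length(bad))
    stop_ctx("phenotype table: non-positive fork_length in row %d", bad[1])
  for (cl in c("kype_length", "kype_height", "milt_weight")) {
    bad <- which(!is.na(records[[cl]]) & records[[cl]] <= 0)
    if (length(bad))
      stop_ctx("phenotype table: non-positive %s in row %d", cl, bad[1])
  }
  males <- records$sex == "male"
  bad <- which(males & !records$strain %in% STRAINS)
  if (length(bad))
    stop_ctx("phenotype table: unknown male strain '%s' in row %d",
             records$strain[bad[1]], bad[1])
  records
}

#' Read a per-fish phenotype table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) with one row per fish. Blank measurement cells become `NA`.
#'
#' @param path file path
#' @return validated data.frame, one row per fish
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_ctx("phenotype file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  validate_phenotypes(df)
}

#' Write a phenotype table as CSV
#' @param records phenotype data.frame
#' @param path output path
#' @export
write_phenotypes <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize the cohort the way the study tabulates it
#'
#' Cross-tabulates, per strain and sea-winter class, the number of males
#' usable for kype-length analysis (non-missing kype length) and for
#' kype-height analysis (non-missing kype height), plus per-SW totals, grand
#' totals and the female supplement. The three milt-producing but
#' genetically female fish are counted with the males by default, as in the
#' study dataset.
#'
#' @param records phenotype data.frame
#' @param include_genetic_females count genetically female milt producers
#'   with the males (default TRUE)
#' @return list with elements `cells` (strain x SW data.frame with
#'   `n_kype_length`, `n_kype_height`), `sw_totals`, `total_kype_length`,
#'   `total_kype_height`, `n_females`
#' @export
summarize_cohort <- function(records, include_genetic_females = TRUE) {
  if (nrow(records) == 0L) {
    cells <- data.frame(strain = character(), sea_winters = integer(),
                        n_kype_length = integer(), n_kype_height = integer())
    return(list(cells = cells,
                sw_totals = data.frame(sea_winters = integer(),
                                       n_kype_length = integer(),
                                       n_kype_height = integer()),
                total_kype_length = 0L, total_kype_height = 0L,
                n_females = 0L))
  }
  records <- validate_phenotypes(records)
  m <- records[records$sex == "male", , drop = FALSE]
  if (!include_genetic_females)
    m <- m[m$genetic_sex == "male", , drop = FALSE]
  grid <- expand.grid(strain = sort(unique(m$strain)), sea_winters = 1:3,
                      stringsAsFactors = FALSE)
  cnt <- function(keep) {
    vapply(seq_len(nrow(grid)), function(i) {
      sum(m$strain == grid$strain[i] & m$sea_winters == grid$sea_winters[i] &
            keep)
    }, integer(1))
  }
  grid$n_kype_length <- cnt(!is.na(m$kype_length))
  grid$n_kype_height <- cnt(!is.na(m$kype_height))
  sw <- data.frame(sea_winters = 1:3)
  sw$n_kype_length <- vapply(1:3, function(s)
    sum(grid$n_kype_length[grid$sea_winters == s]), integer(1))
  sw$n_kype_height <- vapply(1:3, function(s)
    sum(grid$n_kype_height[grid$sea_winters == s]), integer(1))
  list(cells = grid, sw_totals = sw,
       total_kype_length = sum(grid$n_kype_length),
       total_kype_height = sum(grid$n_kype_height),
       n_females = sum(records$sex == "female"))
}

#' Read a pedigree table
#'
#' Expects columns `individual_id`, `sire_id`, `dam_id`, `strain`,
#' `family_id`; founders have blank/NA parents. Validates that every named
#' parent is present, that the pedigree is acyclic, and that full-sib family
#' members share both parents.
#'
#' @param path file path (CSV or TSV)
#' @return data.frame of class `pedigree`
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop_ctx("pedigree file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  validate_pedigree(df)
}

#' Validate a pedigree data.frame
#' @param ped data.frame with individual_id, sire_id, dam_id, strain, family_id
#' @return the pedigree with class `pedigree`, topologically ordered
#' @export
validate_pedigree <- function(ped) {
  need <- c("individual_id", "sire_id", "dam_id", "strain", "family_id")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stop_ctx("pedigree: missing column(s) %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ped$individual_id))
    stop_ctx("pedigree: duplicated individual '%s'",
             ped$individual_id[duplicated(ped$individual_id)][1])
  for (p in c("sire_id", "dam_id")) {
    unknown <- setdiff(stats::na.omit(ped[[p]]), ped$individual_id)
    if (length(unknown))
      stop_ctx("pedigree: %s '%s' not present as an individual", p, unknown[1])
  }
  ord <- pedigree_order(ped)        # errors on cycles
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  # full sibs share both parents
  off <- ped[!is.na(ped$sire_id) & !is.na(ped$family_id), , drop = FALSE]
  if (nrow(off)) {
    key <- tapply(paste(off$sire_id, off$dam_id), off$family_id,
                  function(k) length(unique(k)))
    if (any(key > 1L))
      stop_ctx("pedigree: family '%s' has members with differing parents",
               names(key)[key > 1L][1])
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Topological order (parents before offspring); errors on cycles.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$individual_id)
  sire <- idx[ped$sire_id]
  dam <- idx[ped$dam_id]
  depth <- rep(NA_integer_, n)
  compute <- function(i, stack) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% stack)
      stop_ctx("pedigree: cycle involving individual '%s'",
               ped$individual_id[i])
    s <- sire[i]; d <- dam[i]
    ds <- if (is.na(s)) 0L else compute(s, c(stack, i))
    dd <- if (is.na(d)) 0L else compute(d, c(stack, i))
    depth[i] <<- max(ds, dd) + 1L
    depth[i]
  }
  for (i in seq_len(n)) compute(i, integer())
  order(depth, seq_len(n))
}

#' Write a pedigree as CSV
#' @param ped pedigree data.frame
#' @param path output path
#' @export
write_pedigree <- function(ped, path) {
  write.csv(as.data.frame(ped), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a marker map
#'
#' Columns `marker_id`, `linkage_group` (1..29 by default) and
#' `position_cM`; positions must be non-negative and non-decreasing within a
#' linkage group.
#'
#' @param path file path
#' @return data.frame sorted by linkage group and position
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop_ctx("map file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  map <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_marker_map(map)
}

validate_marker_map <- function(map) {
  need <- c("marker_id", "linkage_group", "position_cM")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop_ctx("marker map: missing column(s) %s", paste(miss, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop_ctx("marker map: duplicated marker id")
  if (any(map$position_cM < 0))
    stop_ctx("marker map: negative position")
  map <- map[order(map$linkage_group, map$position_cM), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Read a genotype table with its marker map
#'
#' The genotype file is an individual x marker table: first column
#' `individual_id`, remaining columns one per marker with diploid calls in
#' `"A/B"` form (`"./."` for missing). Every marker column must be present
#' in the map.
#'
#' @param path genotype file path
#' @param map_path marker map path (see [read_marker_map])
#' @return object of class `genotype_matrix`: list with character matrices
#'   `a1`, `a2` (individual x marker, NA = missing) and the `map`
#' @export
read_genotypes <- function(path, map_path) {
  if (!file.exists(path)) stop_ctx("genotype file not found: %s", path)
  map <- read_marker_map(map_path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (names(df)[1] != "individual_id")
    stop_ctx("genotype file: first column must be individual_id")
  markers <- names(df)[-1]
  unknown <- setdiff(markers, map$marker_id)
  if (length(unknown))
    stop_ctx("genotype file: marker '%s' absent from map", unknown[1])
  calls <- as.matrix(df[, -1, drop = FALSE])
  split_allele <- function(k) {
    a <- sub("/.*$", "", calls)
    if (k == 2L) a <- sub("^.*/", "", calls)
    a[a == "." | a == ""] <- NA
    matrix(a, nrow(calls), ncol(calls),
           dimnames = list(df$individual_id, markers))
  }
  g <- genotype_matrix(a1 = split_allele(1L), a2 = split_allele(2L),
                       map = map[map$marker_id %in% markers, , drop = FALSE])
  g
}

#' Construct a genotype_matrix object
#' @param a1,a2 character matrices (individual x marker) of allele calls
#' @param map marker map data.frame
#' @return validated `genotype_matrix`
#' @export
genotype_matrix <- function(a1, a2, map) {
  stopifnot(identical(dim(a1), dim(a2)))
  map <- validate_marker_map(map)
  if (!setequal(colnames(a1), map$marker_id))
    stop_ctx("genotype_matrix: marker columns and map disagree")
  ord <- match(map$marker_id, colnames(a1))
  structure(list(a1 = a1[, ord, drop = FALSE], a2 = a2[, ord, drop = FALSE],
                 map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers on %d linkage groups\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$map$linkage_group))))
  invisible(x)
}

#' Write genotypes (and map) to delimited text
#' @param geno `genotype_matrix`
#' @param path genotype table output path
#' @param map_path optional map output path
#' @export
write_genotypes <- function(geno, path, map_path = NULL) {
  calls <- matrix(paste(geno$a1, geno$a2, sep = "/"), nrow(geno$a1),
                  ncol(geno$a1))
  calls[is.na(geno$a1) | is.na(geno$a2)] <- "./."
  df <- data.frame(individual_id = rownames(geno$a1), calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("individual_id", colnames(geno$a1))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(map_path)) write.csv(geno$map, map_path, row.names = FALSE)
  invisible(path)
}

#' The study cohort design as per-cell counts
#'
#' Per-cell counts (sex x strain x sea-winter class) of families and
#' individuals in the kype-length and kype-height analysis subsets, as
#' tabulated for the study cohort: 397/81/50 males (1/2/3 SW) in the
#' kype-length subset, 378/58/44 in the kype-height subset, and 77 mature
#' 2SW females.
#'
#' @return data.frame with columns sex, strain, sea_winters, families,
#'   n_individuals, n_kype_height
#' @export
cohort_design_counts <- function() {
  path <- system.file("extdata", "cohort_design_counts.csv", package = "kypemorph")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Expand a counts table into a per-fish phenotype fixture
#'
#' Builds a synthetic phenotype table whose bookkeeping (cell counts, family
#' counts, missingness pattern of kype height) exactly matches a counts
#' table such as [cohort_design_counts]; measurements are drawn from the package's
#' allometric generating model so downstream regressions are well-defined.
#' Three milt-producing males (one domesticated, one hybrid, one wild) are
#' flagged genetically female, mirroring the study cohort.
#'
#' @param counts counts data.frame as returned by [cohort_design_counts]
#' @param seed integer seed for the simulated measurements
#' @return phenotype data.frame
#' @export
cohort_from_counts <- function(counts = cohort_design_counts(), seed = 1L) {
  cfg <- sim_config(seed = seed)
  with_seed(substream_seed(seed, "design-fixture"), {
    rows <- list()
    fam_counter <- 0L
    for (i in seq_len(nrow(counts))) {
      n <- counts$n_individuals[i]
      if (is.na(n) || n == 0L) next
      sexi <- counts$sex[i]
      strain <- counts$strain[i]
      sw <- counts$sea_winters[i]
      nf <- counts$families[i]
      if (is.na(nf) || nf == 0L) nf <- 1L
      fam <- sprintf("%s_f%d", strain, ((seq_len(n) - 1L) %% nf) + 1L)
      fl <- 10^(rnorm(n, cfg$log10_fl_mean[sw], cfg$log10_fl_sd))
      kl <- 10^(cfg$allometry$kype_length["a"] +
                  cfg$allometry$kype_length["b"] * log10(fl) +
                  rnorm(n, 0, 0.04))
      kh <- 10^(cfg$allometry$kype_height["a"] +
                  cfg$allometry$kype_height["b"] * log10(fl) +
                  rnorm(n, 0, 0.1))
      wet <- 10^(cfg$weight_link["a"] + cfg$weight_link["b"] * log10(fl) +
                   rnorm(n, 0, 0.05))
      milt <- 10^(cfg$milt_link["a"] + cfg$milt_link["b"] * log10(wet) +
                    rnorm(n, 0, 0.15))
      nh <- counts$n_kype_height[i]
      if (sexi == "female") {
        kl[] <- NA; kh[] <- NA; milt[] <- NA
      } else if (!is.na(nh) && nh < n) {
        kh[(nh + 1L):n] <- NA
      }
      fam_counter <- fam_counter + 1L
      rows[[i]] <- data.frame(
        fish_id = sprintf("%s_%s_sw%d_%03d", substr(sexi, 1, 1), strain, sw,
                          seq_len(n)),
        sex = sexi, strain = strain, family_id = fam,
        sire_id = paste0(fam, "_s"), dam_id = paste0(fam, "_d"),
        sea_winters = sw, tank = sprintf("tank%d", ((seq_len(n)) %% 3) + 1L),
        fork_length = fl, kype_length = kl, kype_height = kh,
        milt_weight = milt, wet_weight = wet,
        genetic_sex = ifelse(sexi == "female", "female", "male"),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    # three genetically female milt producers, one per genetic background
    for (s in c("Mowi", "HybridFM", "Arna")) {
      j <- which(out$sex == "male" & out$strain == s)[1]
      out$genetic_sex[j] <- "female"
      out$milt_weight[j] <- runif(1, 50.9, 232.4)
    }
    rownames(out) <- NULL
    validate_phenotypes(out)
  })
}
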