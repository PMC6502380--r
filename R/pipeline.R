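#' Run configuration for the full analysis
#'
#' Either `input` (paths to phenotype/TPS/pedigree/genotype/map files) or
#' `sim` (a [sim_config] to generate the cohort) must be supplied.
#'
#' @param out_dir output directory (created if needed)
#' @param input named list of paths: `phenotypes`, `tps`, `pedigree`,
#'   `genotypes`, `map` (any subset; stages needing missing inputs are
#'   skipped)
#' @param sim a [sim_config]
#' @param seed master seed (mandatory when simulating)
#' @param scan_phenotypes traits to scan for QTL
#' @param alpha_random,alpha_fixed backward-elimination thresholds
#' @return list of class `run_config`
#' @export
run_config <- function(out_dir, input = NULL, sim = NULL, seed = NULL,
                       scan_phenotypes = c("AKL", "KH"),
                       alpha_random = 0.1, alpha_fixed = 0.05) {
  if (is.null(input) && is.null(sim))
    stop_ctx("run_config: either input paths or a simulation config required")
  if (!is.null(sim) && is.null(seed %||% sim$seed))
    stop_ctx("run_config: seed mandatory when simulating")
  structure(list(out_dir = out_dir, input = input, sim = sim,
                 seed = seed %||% (if (!is.null(sim)) sim$seed else NULL),
                 scan_phenotypes = scan_phenotypes,
                 alpha_random = alpha_random, alpha_fixed = alpha_fixed),
            class = "run_config")
}

stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  message(line)
}

run_stage <- function(log_path, stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop_ctx("stage '%s' failed: %s", stage, conditionMessage(e)))
  stage_log(log_path, stage,
            sprintf("done in %.2fs", as.numeric(Sys.time() - t0, "secs")))
  out
}

#' Execute the full analysis pipeline
#'
#' Stages: load or simulate the cohort; re-measure kype traits from the
#' landmark points; tabulate the cohort; Procrustes alignment and shape PCA
#' with per-group confidence ellipses; allometric adjustment (AKL, AKH,
#' GSR); mixed-model selection, type-III ANOVA and Tukey EMMs for AKL and
#' AKH; variance-component QTL scans. Every stage writes plain CSV under
#' `out_dir`, plus `report.json` (machine-readable summary with provenance)
#' and `log.txt`. Outputs are a deterministic function of the seed and
#' configuration.
#'
#' @param config a [run_config]
#' @return the report list, invisibly; all artifacts under `config$out_dir`
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  cat("", file = log_path)
  report <- list(stages = list())

  cohort <- run_stage(log_path, "load", {
    if (!is.null(config$sim)) {
      cc <- simulate_cohort(config$sim)
      write_phenotypes(cc$records, file.path(out, "phenotypes.csv"))
      write_pedigree(cc$pedigree, file.path(out, "pedigree.csv"))
      write_genotypes(cc$genotypes, file.path(out, "genotypes.csv"),
                      file.path(out, "marker_map.csv"))
      write_tps(cc$landmarks, file.path(out, "landmarks.tps"))
      write_sim_config(config$sim, file.path(out, "sim_config.json"))
      cc
    } else {
      inp <- config$input
      if (is.null(inp$phenotypes))
        stop_ctx("input lacks a phenotype table")
      cc <- list(records = read_phenotypes(inp$phenotypes))
      if (!is.null(inp$tps)) cc$landmarks <- read_tps(inp$tps)
      if (!is.null(inp$pedigree)) cc$pedigree <- read_pedigree(inp$pedigree)
      if (!is.null(inp$genotypes))
        cc$genotypes <- read_genotypes(inp$genotypes, inp$map)
      cc
    }
  })
  report$stages$load <- list(n_records = nrow(cohort$records),
                             n_landmarks = length(cohort$landmarks))

  if (!is.null(cohort$landmarks)) {
    meas <- run_stage(log_path, "measure", {
      m <- t(vapply(cohort$landmarks, measure_kype, numeric(2)))
      df <- data.frame(
        specimen_id = vapply(cohort$landmarks, `[[`, "", "specimen_id"),
        kype_length = m[, 1], kype_height = m[, 2],
        stringsAsFactors = FALSE)
      write.csv(df, file.path(out, "measurements.csv"), row.names = FALSE)
      df
    })
    report$stages$measure <- list(n_measured = sum(!is.na(meas$kype_length)))
  }

  summ <- run_stage(log_path, "summarize", {
    s <- summarize_cohort(cohort$records)
    write.csv(s$cells, file.path(out, "cohort_cells.csv"), row.names = FALSE)
    write.csv(s$sw_totals, file.path(out, "cohort_sw_totals.csv"),
              row.names = FALSE)
    s
  })
  report$stages$cohort <- list(
    total_kype_length = summ$total_kype_length,
    total_kype_height = summ$total_kype_height,
    n_females = summ$n_females,
    sw_totals = summ$sw_totals)

  if (!is.null(cohort$landmarks) && length(cohort$landmarks) >= 3) {
    shp <- run_stage(log_path, "gpa", {
      fit <- gpa(cohort$landmarks)
      pca <- shape_pca(fit)
      sc <- data.frame(specimen_id = fit$specimen_ids,
                       centroid_size = unname(fit$centroid_sizes),
                       pca$scores[, 1:min(4, ncol(pca$scores))],
                       stringsAsFactors = FALSE)
      write.csv(sc, file.path(out, "pca_scores.csv"), row.names = FALSE)
      groups <- vapply(cohort$landmarks, function(cf) {
        r <- match(cf$specimen_id, cohort$records$fish_id)
        if (is.na(r)) "other" else if (cohort$records$sex[r] == "female")
          "female" else sprintf("%dSW", cohort$records$sea_winters[r])
      }, character(1))
      ell <- do.call(rbind, lapply(unique(groups), function(g) {
        idx <- which(groups == g)
        if (length(idx) < 3) return(NULL)
        e <- confidence_ellipse(pca$scores[idx, 1:2, drop = FALSE])
        data.frame(group = g, center_x = e$center[1], center_y = e$center[2],
                   axis1 = e$axes[1], axis2 = e$axes[2], angle = e$angle,
                   stringsAsFactors = FALSE)
      }))
      write.csv(ell, file.path(out, "pca_ellipses.csv"), row.names = FALSE)
      list(gpa = fit, pca = pca, groups = groups)
    })
    report$stages$morphometrics <- list(
      gpa_iterations = shp$gpa$iterations,
      pc_variance = round(shp$pca$var_prop[1:4], 4))
  }

  allo <- run_stage(log_path, "allometry", {
    a <- adjusted_traits(cohort$records[cohort$records$sex == "male", ,
                                        drop = FALSE])
    write.csv(a$table, file.path(out, "adjusted_traits.csv"),
              row.names = FALSE)
    fitrow <- function(f, nm) data.frame(
      trait = nm, slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared, f_statistic = f$f_statistic,
      df1 = f$df[1], df2 = f$df[2], n = f$n, stringsAsFactors = FALSE)
    tab <- rbind(fitrow(a$fits$AKL, "kype_length"),
                 fitrow(a$fits$AKH, "kype_height"),
                 fitrow(a$fits$GSR, "milt_weight"))
    write.csv(tab, file.path(out, "allometry_fits.csv"), row.names = FALSE)
    a
  })
  report$stages$allometry <- list(
    kl = c(slope = allo$fits$AKL$slope, r2 = allo$fits$AKL$r_squared,
           df2 = allo$fits$AKL$df[2]),
    kh = c(slope = allo$fits$AKH$slope, r2 = allo$fits$AKH$r_squared,
           df2 = allo$fits$AKH$df[2]))

  lmmres <- run_stage(log_path, "lmm", {
    d <- lmm_data(cohort$records, adj = allo)
    terms_ok <- usable_model_terms(d)
    res <- list()
    for (resp in c("AKL", "AKH")) {
      full <- build_formula(resp, terms_ok$fixed, terms_ok$random)
      sel <- backward_eliminate(full, d, config$alpha_random,
                                config$alpha_fixed)
      an <- type3_anova(sel$fit)
      write.csv(an, file.path(out, sprintf("anova_%s.csv", resp)),
                row.names = FALSE)
      write.csv(sel$trace, file.path(out, sprintf("elimination_%s.csv",
                                                  resp)), row.names = FALSE)
      emms <- list()
      for (fac in intersect(c("strain", "SW"), fixed_terms(sel$formula))) {
        em <- emmeans_tukey(sel$fit, fac)
        write.csv(em$emmeans,
                  file.path(out, sprintf("emm_%s_%s.csv", resp, fac)),
                  row.names = FALSE)
        write.csv(em$pairs,
                  file.path(out, sprintf("emm_pairs_%s_%s.csv", resp, fac)),
                  row.names = FALSE)
        emms[[fac]] <- em
      }
      res[[resp]] <- list(selected = sel, anova = an, emms = emms)
    }
    res
  })
  report$stages$lmm <- lapply(lmmres, function(r) list(
    formula = paste(deparse(r$selected$formula), collapse = " "),
    anova_terms = r$selected$fit$n))

  if (!is.null(cohort$genotypes) && !is.null(cohort$pedigree)) {
    scans <- run_stage(log_path, "qtlscan", {
      ss <- list()
      for (ph in config$scan_phenotypes) {
        sc <- lrt_scan(cohort$records, cohort$genotypes, cohort$pedigree,
                       phenotype = ph, adj = allo)
        write.csv(as.data.frame(sc),
                  file.path(out, sprintf("qtl_scan_%s.csv", ph)),
                  row.names = FALSE)
        ss[[ph]] <- sc
      }
      ss
    })
    report$stages$qtl <- lapply(scans, function(sc) {
      top <- sc[which.max(sc$lrt), ]
      list(top_marker = top$marker, linkage_group = top$linkage_group,
           lrt = top$lrt, p_value = top$p_value,
           qtl_proportion = top$qtl_proportion)
    })
  }

  report$provenance <- list(
    package = "kypemorph",
    version = as.character(utils::packageVersion("kypemorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(
      if (!is.null(config$sim)) file.path(out, "sim_config.json")
      else file.path(out, "phenotypes.csv"))))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  stage_log(log_path, "report", "written")
  invisible(report)
}

#' Simulation-recovery study
#'
#' Repeatedly simulates a cohort, runs the estimation stages and compares
#' them with the generating truth: allometric slope CI coverage, sign
#' recovery of the domesticated-vs-wild strain contrast on AKH, QTL
#' localization to the planted linkage group, bias/MAE of the estimated
#' QTL variance proportion, and (when no QTL is planted) the null
#' rejection rate of the locus test.
#'
#' @param base_config a [sim_config]; per-replicate seeds are derived from
#'   its seed
#' @param n_replicates number of replicates (>= 1)
#' @param scan_markers optional marker subset to scan (default: full panel)
#' @return list with `per_replicate` data.frame and `summary` (one row)
#' @export
run_recovery_study <- function(base_config, n_replicates,
                               scan_markers = NULL) {
  stopifnot(n_replicates >= 1)
  q2 <- base_config$qtl$q2
  true_lg <- if (q2 > 0)
    base_config$map$linkage_group[match(base_config$qtl$marker,
                                        base_config$map$marker_id)]
  else NA_integer_
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- base_config
    cfg$seed <- substream_seed(base_config$seed, sprintf("replicate%d", r))
    cc <- simulate_cohort(cfg)
    fitkl <- loglog_fit(cc$records$fork_length, cc$records$kype_length)
    b <- cfg$traits$kype_length$b
    ci <- fitkl$slope + c(-1, 1) * 1.96 * fitkl$slope_se
    adj <- adjusted_traits(cc$records)
    d <- lmm_data(cc$records, adj = adj)
    tk <- usable_model_terms(d, mains = c("SW", "strain"))
    mfit <- reml_fit(build_formula("AKH", tk$fixed[tk$fixed %in%
                                                     c("SW", "strain")],
                                   "1 | family"), d)
    em <- emmeans_tukey(mfit, "strain")
    mowi <- em$emmeans$emmean[em$emmeans$level == "Mowi"]
    wild <- mean(em$emmeans$emmean[em$emmeans$level %in%
                                     c("Arna", "Figgjo")])
    sc <- lrt_scan(cc$records, cc$genotypes, cc$pedigree, phenotype = "AKL",
                   markers = scan_markers, adj = adj)
    top <- sc[which.max(sc$lrt), ]
    at_true <- if (q2 > 0) sc[sc$marker == cfg$qtl$marker, ] else top
    data.frame(replicate = r, seed = cfg$seed,
               slope_hat = fitkl$slope, slope_in_ci = b >= ci[1] & b <= ci[2],
               strain_sign_ok = mowi < wild,
               top_marker = top$marker, top_lg = top$linkage_group,
               localized = if (q2 > 0) top$linkage_group == true_lg else NA,
               q2_hat = at_true$qtl_proportion,
               q2_err = if (q2 > 0) abs(at_true$qtl_proportion - q2)
               else NA_real_,
               null_reject = if (q2 == 0) any(top$p_value < 0.05) else NA,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  summary <- data.frame(
    n_replicates = n_replicates, q2_true = q2,
    slope_coverage = mean(per$slope_in_ci),
    strain_sign_rate = mean(per$strain_sign_ok),
    localization_rate = mean(per$localized),
    q2_mae = mean(per$q2_err),
    q2_bias = mean(per$q2_hat) - q2,
    null_rejection = mean(per$null_reject))
  list(per_replicate = per, summary = summary)
}
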