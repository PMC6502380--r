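#' Assemble the modelling data frame for the adjusted-trait mixed models
#'
#' Joins the adjusted traits (AKL, AKH, GSR) onto the phenotype table and
#' converts the design variables to factors: `SW` (sea-winter class),
#' `strain`, `family` (nested within strain by construction of the ids),
#' `sire`, `dam`, `tank`.
#'
#' @param records phenotype data.frame
#' @param adj result of [adjusted_traits] (computed if omitted)
#' @return data.frame ready for [reml_fit]
#' @export
lmm_data <- function(records, adj = NULL) {
  males <- records[records$sex == "male", , drop = FALSE]
  if (is.null(adj)) adj <- adjusted_traits(males)
  d <- merge(males, adj$table, by = "fish_id", sort = FALSE)
  d$SW <- factor(d$sea_winters, levels = 1:3, labels = c("1SW", "2SW", "3SW"))
  d$strain <- factor(d$strain, levels = intersect(STRAINS, unique(d$strain)))
  d$family <- factor(d$family_id)
  d$sire <- factor(d$sire_id)
  d$dam <- factor(d$dam_id)
  d$tank <- factor(d$tank)
  d
}

#' Random-intercept terms of a mixed-model formula
#' @param formula model formula
#' @return character vector like `"1 | family"`
#' @export
random_terms <- function(formula) {
  vapply(lme4::findbars(formula), function(b) deparse(b), character(1))
}

#' Fixed terms of a mixed-model formula
#' @param formula model formula
#' @return character vector of term labels
#' @export
fixed_terms <- function(formula) {
  attr(terms(lme4::nobars(formula)), "term.labels")
}

#' Assemble a mixed-model formula from term lists
#' @param response response column name
#' @param fixed character vector of fixed terms (may be empty)
#' @param random character vector of random terms like `"1 | family"`
#' @return a formula
#' @export
build_formula <- function(response, fixed, random) {
  rhs <- c(if (length(fixed)) fixed else "1",
           if (length(random)) sprintf("(%s)", random))
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")),
             env = globalenv())
}

# Satterthwaite needs the REML Hessian, which is legitimately indefinite
# when a variance component sits at its zero boundary (e.g. the fully
# confounded family/sire/dam intercepts of a strict full-sib design); those
# advisory warnings are muffled, everything else propagates.
quiet_boundary <- function(expr) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("negative eigenvalue|boundary|singular", conditionMessage(w)))
        invokeRestart("muffleWarning")
    },
    message = function(m) {
      # empty design cells (e.g. no 3SW Figgjo males) make interaction
      # columns collinear; lme4 correctly drops them, no need to narrate
      if (grepl("rank deficient", conditionMessage(m)))
        invokeRestart("muffleMessage")
    })
}

#' Model terms supported by a data set
#'
#' Keeps the fixed main effects whose factors have at least two observed
#' levels (numeric covariates need nonzero variance), their pairwise
#' interactions, and the random intercept terms whose grouping factors
#' have at least two levels — so the full study model degrades gracefully
#' on designs with, e.g., a single sea-winter class.
#'
#' @param d data.frame from [lmm_data]
#' @param mains candidate fixed main effects
#' @param random candidate random-intercept grouping columns
#' @return list with `fixed` and `random` character vectors
#' @export
usable_model_terms <- function(d, mains = c("SW", "strain", "GSR"),
                               random = c("family", "sire", "dam")) {
  ok <- vapply(mains, function(v) {
    x <- d[[v]]
    if (is.null(x)) return(FALSE)
    if (is.factor(x) || is.character(x))
      nlevels(droplevels(factor(x))) > 1L
    else isTRUE(var(x, na.rm = TRUE) > 0)
  }, logical(1))
  mains <- mains[ok]
  inter <- if (length(mains) >= 2)
    apply(utils::combn(mains, 2), 2, paste, collapse = ":") else character(0)
  rnd <- random[vapply(random, function(v) {
    x <- d[[v]]
    !is.null(x) && nlevels(droplevels(factor(x))) > 1L
  }, logical(1))]
  list(fixed = c(mains, inter), random = sprintf("1 | %s", rnd))
}

#' Fit a linear mixed model by REML
#'
#' Fits the model with lmerTest/lme4 when random intercept terms are
#' present (REML, variance components bounded at zero) or ordinary least
#' squares when none are; both return the same fit container so the
#' type-III ANOVA, elimination and EMM machinery can treat them uniformly.
#'
#' @param formula model formula, e.g.
#'   `AKL ~ SW*strain + SW*GSR + strain*GSR + (1|family) + (1|sire) + (1|dam)`
#' @param data data.frame from [lmm_data]
#' @return object of class `lmm_fit` with elements `model`, `formula`,
#'   `fixed` (estimates), `vcov_fixed`, `varcomp` (named variance
#'   components incl. `Residual`), `logLik` (REML when mixed), `is_mixed`,
#'   `n`
#' @export
reml_fit <- function(formula, data) {
  vars <- setdiff(all.vars(formula)[-1], c(".")) # response excluded
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop_ctx("reml_fit: data lacks column(s) %s", paste(miss, collapse = ", "))
  resp <- all.vars(formula)[1]
  data <- data[stats::complete.cases(data[, c(resp, vars), drop = FALSE]), ,
               drop = FALSE]
  data <- droplevels(data)
  rts <- random_terms(formula)
  for (rt in rts) {
    g <- trimws(sub("^.*\\|", "", rt))
    gl <- interaction(data[, all.vars(as.formula(paste("~", g))),
                           drop = FALSE], drop = TRUE)
    if (nlevels(gl) < 2L)
      stop_ctx("reml_fit: random term (%s) has a single level", rt)
  }
  if (length(rts)) {
    model <- tryCatch(
      quiet_boundary(
        lmerTest::lmer(formula, data = data, REML = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         calc.derivs = FALSE))),
      error = function(e) stop_ctx("reml_fit: %s", conditionMessage(e)))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "Residual",
                                        vc$grp))
    ll <- as.numeric(logLik(model, REML = TRUE))
  } else {
    model <- lm(formula, data = data)
    varcomp <- c(Residual = sum(resid(model)^2) / model$df.residual)
    ll <- as.numeric(logLik(model))
  }
  structure(list(model = model, formula = formula, data = data,
                 fixed = if (length(rts)) lme4::fixef(model) else coef(model),
                 vcov_fixed = as.matrix(vcov(model)),
                 varcomp = varcomp, logLik = ll,
                 is_mixed = length(rts) > 0, n = nrow(data)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s | n = %d, REML logLik = %.2f\n",
              paste(deparse(x$formula), collapse = " "), x$n, x$logLik))
  cat("variance components:\n")
  print(round(x$varcomp, 6))
  invisible(x)
}

# type III F for an OLS fit: marginal SS with sum-to-zero contrasts
type3_lm <- function(model) {
  mf <- model.frame(model)
  fac <- names(Filter(is.factor, mf[-1]))
  contr <- setNames(rep(list("contr.sum"), length(fac)), fac)
  X <- model.matrix(terms(model), mf,
                    contrasts.arg = if (length(fac)) contr else NULL)
  y <- stats::model.response(mf)
  asg <- attr(X, "assign")
  full <- lm.fit(X, y)
  rss <- sum(full$residuals^2)
  dfe <- length(y) - full$rank
  labs <- attr(terms(model), "term.labels")
  rows <- lapply(seq_along(labs), function(j) {
    keep <- asg != j
    red <- lm.fit(X[, keep, drop = FALSE], y)
    q <- full$rank - red$rank
    fval <- ((sum(red$residuals^2) - rss) / q) / (rss / dfe)
    data.frame(term = labs[j], sum_sq = sum(red$residuals^2) - rss,
               num_df = q, den_df = dfe, f_value = fval,
               p_value = pf(fval, q, dfe, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Type-III ANOVA with Satterthwaite denominator degrees of freedom
#'
#' For mixed fits, per-term F statistics from type-III contrasts with
#' Satterthwaite's two-moment approximation for the denominator df; in the
#' fixed-effects-only limit this reduces to the classical type-III ANOVA
#' with denominator df `n - p`.
#'
#' @param fit an `lmm_fit`
#' @return data.frame (term, sum_sq, num_df, den_df, f_value, p_value)
#' @export
type3_anova <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$is_mixed) return(type3_lm(fit$model))
  a <- quiet_boundary(anova(fit$model, type = 3, ddf = "Satterthwaite"))
  data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]],
             num_df = a[["NumDF"]], den_df = a[["DenDF"]],
             f_value = a[["F value"]], p_value = a[["Pr(>F)"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

# fixed terms that no retained interaction is marginal to
droppable_fixed <- function(labs) {
  parts <- lapply(strsplit(labs, ":", fixed = TRUE), sort)
  ok <- vapply(seq_along(labs), function(i) {
    !any(vapply(seq_along(labs), function(j) {
      i != j && all(parts[[i]] %in% parts[[j]])
    }, logical(1)))
  }, logical(1))
  labs[ok]
}

#' Backward elimination of random and fixed terms
#'
#' Stage 1 drops, one at a time, the random intercept term with the largest
#' REML likelihood-ratio p-value above `alpha_random`; the LRT against the
#' reduced model uses the boundary-corrected 50:50 mixture of chi-square 0
#' and 1. Stage 2 then drops the fixed term with the largest type-III
#' Satterthwaite p-value above `alpha_fixed`, respecting marginality (a
#' main effect is never dropped while one of its interactions remains).
#'
#' @param formula full model formula
#' @param data data.frame from [lmm_data]
#' @param alpha_random retention threshold for random terms (default 0.1)
#' @param alpha_fixed retention threshold for fixed terms (default 0.05)
#' @return list with `formula` (selected model), `fit` (its `lmm_fit`),
#'   `trace` (elimination log), `dropped_random` (named LRT p-values of the
#'   removed random terms, so e.g. a sire term can be re-added for the
#'   ANOVA step)
#' @export
backward_eliminate <- function(formula, data, alpha_random = 0.1,
                               alpha_fixed = 0.05) {
  resp <- all.vars(formula)[1]
  fx <- fixed_terms(formula)
  rnd <- random_terms(formula)
  trace <- list()
  note <- function(phase, term, stat, p, action)
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, term = term, statistic = stat, p_value = p,
      action = action, stringsAsFactors = FALSE)
  dropped_random <- numeric(0)

  repeat {
    if (!length(rnd)) break
    full <- reml_fit(build_formula(resp, fx, rnd), data)
    ps <- vapply(rnd, function(rt) {
      red <- reml_fit(build_formula(resp, fx, setdiff(rnd, rt)), data)
      lrt <- max(0, 2 * (full$logLik - red$logLik))
      if (lrt <= 1e-10) 1 else 0.5 * pchisq(lrt, 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(ps)
    if (ps[worst] > alpha_random) {
      note("random", rnd[worst], NA_real_, ps[worst], "dropped")
      dropped_random[rnd[worst]] <- ps[worst]
      rnd <- rnd[-worst]
    } else {
      for (k in seq_along(ps))
        note("random", rnd[k], NA_real_, ps[k], "kept")
      break
    }
  }

  repeat {
    fit <- reml_fit(build_formula(resp, fx, rnd), data)
    if (!length(fx)) break
    tab <- type3_anova(fit)
    cand <- tab[tab$term %in% droppable_fixed(fx), , drop = FALSE]
    if (!nrow(cand)) break
    worst <- which.max(cand$p_value)
    if (cand$p_value[worst] > alpha_fixed) {
      note("fixed", cand$term[worst], cand$f_value[worst],
           cand$p_value[worst], "dropped")
      fx <- setdiff(fx, cand$term[worst])
    } else {
      for (k in seq_len(nrow(tab)))
        note("fixed", tab$term[k], tab$f_value[k], tab$p_value[k], "kept")
      break
    }
  }
  final <- build_formula(resp, fx, rnd)
  list(formula = final, fit = reml_fit(final, data),
       trace = do.call(rbind, trace), dropped_random = dropped_random)
}

#' Estimated marginal means with Tukey-adjusted pairwise contrasts
#'
#' Marginal means average over the other factors' levels with equal
#' weights; pairwise differences are tested against the studentized range
#' distribution, with per-comparison Satterthwaite degrees of freedom for
#' mixed fits.
#'
#' @param fit an `lmm_fit`
#' @param factor name of a factor in the fitted model
#' @return list with `emmeans` (level, emmean, se, df) and `pairs`
#'   (contrast, estimate, se, df, t_ratio, p_raw, p_tukey)
#' @export
emmeans_tukey <- function(fit, factor) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!factor %in% all.vars(lme4::nobars(fit$formula)))
    stop_ctx("emmeans_tukey: factor '%s' is not in the model", factor)
  emm <- quiet_boundary(emmeans::emmeans(fit$model, specs = factor,
                                         lmer.df = "satterthwaite"))
  es <- as.data.frame(summary(emm))
  adj <- as.data.frame(quiet_boundary(
    summary(emmeans::contrast(emm, "pairwise"), adjust = "tukey")))
  raw <- as.data.frame(quiet_boundary(
    summary(emmeans::contrast(emm, "pairwise"), adjust = "none")))
  list(emmeans = data.frame(level = es[[1]], emmean = es$emmean,
                            se = es$SE, df = es$df,
                            stringsAsFactors = FALSE),
       pairs = data.frame(contrast = adj$contrast, estimate = adj$estimate,
                          se = adj$SE, df = adj$df, t_ratio = adj$t.ratio,
                          p_raw = raw$p.value, p_tukey = adj$p.value,
                          stringsAsFactors = FALSE))
}
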