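#' Repeated-measures comparison of metabolic estimates across methods
#'
#' Fits a linear mixed model of a metabolic response on species and
#' respirometry method (fixed factors) with a random intercept per fish to
#' account for repeated measures on the same individuals; fish that did not
#' complete every method are retained. The species x method interaction is
#' tested first and removed when non-significant at `alpha` (model
#' simplification); omnibus F tests use Satterthwaite denominator degrees
#' of freedom, and all-pairs method contrasts carry a single-step
#' multiplicity adjustment (`"mvt"` by default, quasi-Monte-Carlo seeded
#' internally for reproducibility).
#'
#' @param data A metabolic-summary table (one row per fish x method) with
#'   columns `fish_id`, `species`, `method` and the response column.
#' @param response Response column name (e.g. `"mmr"`, `"smr"`).
#' @param transform `"identity"` (contrasts are differences) or `"log"`
#'   (the model is fitted to log(response); contrasts are log-ratios and
#'   predictions are back-transformed).
#' @param alpha Significance level for the interaction-removal rule.
#' @param adjust Multiplicity adjustment for the method contrasts
#'   (passed to emmeans; `"mvt"`, `"tukey"`, `"bonferroni"`, ...).
#' @param reml Fit by restricted maximum likelihood (default TRUE).
#' @return An object of class `comparison_result`: list with `model`,
#'   `fixed_effect_tests`, `interaction` (test and whether dropped),
#'   `contrasts` (estimate, df, t, adjusted p, CI), `predictions`
#'   (per method overall and per species, response scale),
#'   `percent_differences`, `response`, `transform`, `alpha`.
#' @export
fit_comparison <- function(data, response = "mmr",
                           transform = c("identity", "log"), alpha = 0.05,
                           adjust = "mvt", reml = TRUE) {
  transform <- match.arg(transform)
  df <- as.data.frame(data)
  stopifnot(all(c("fish_id", "species", "method", response) %in% names(df)))
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  if (length(unique(df$method)) < 2)
    stop("fit_comparison needs >= 2 methods")
  df$.y <- if (transform == "log") log(df[[response]]) else df[[response]]
  df$fish_id <- factor(df$fish_id)
  df$method <- factor(df$method)
  df$species <- factor(df$species)
  n_species <- nlevels(df$species)

  n_repeated <- sum(table(df$fish_id) >= 2)
  mixed <- n_repeated >= 2
  if (!mixed)
    warning("fewer than 2 fish with repeated measures: falling back to a fixed-effects linear model")

  fit_fun <- function(fml) {
    if (mixed) lmerTest::lmer(fml, data = df, REML = reml)
    else stats::lm(fml, data = df)
  }
  anova_tab <- function(mod) {
    a <- if (mixed) as.data.frame(stats::anova(mod, type = 3))
         else as.data.frame(stats::anova(mod))
    a$term <- rownames(a)
    names(a)[names(a) == "F value"] <- "F"
    names(a)[names(a) == "Pr(>F)"] <- "p"
    if (mixed) {
      names(a)[names(a) == "NumDF"] <- "df_num"
      names(a)[names(a) == "DenDF"] <- "df_den"
    } else {
      a$df_num <- a$Df
      a$df_den <- a["Residuals", "Df"]
      a <- a[rownames(a) != "Residuals", , drop = FALSE]
    }
    a[, c("term", "F", "df_num", "df_den", "p")]
  }

  interaction_test <- NULL; dropped <- FALSE
  if (n_species > 1) {
    rhs_full <- ".y ~ species * method"
    if (mixed) rhs_full <- paste(rhs_full, "+ (1 | fish_id)")
    full <- fit_fun(stats::as.formula(rhs_full))
    at <- anova_tab(full)
    interaction_test <- at[at$term == "species:method", , drop = FALSE]
    if (nrow(interaction_test) && interaction_test$p >= alpha) {
      dropped <- TRUE
      rhs <- ".y ~ species + method"
      if (mixed) rhs <- paste(rhs, "+ (1 | fish_id)")
      mod <- fit_fun(stats::as.formula(rhs))
    } else mod <- full
  } else {
    rhs <- ".y ~ method"
    if (mixed) rhs <- paste(rhs, "+ (1 | fish_id)")
    mod <- fit_fun(stats::as.formula(rhs))
  }

  emm <- emmeans::emmeans(mod, ~method, lmer.df = "satterthwaite")
  ctr <- withr::with_seed(1L, {
    as.data.frame(summary(emmeans::contrast(emm, "pairwise", adjust = adjust),
                          infer = c(TRUE, TRUE)))
  })
  names(ctr)[names(ctr) == "t.ratio"] <- "t"
  names(ctr)[names(ctr) == "p.value"] <- "p_adj"

  back <- function(x) if (transform == "log") exp(x) else x
  pred_overall <- as.data.frame(summary(emm))
  pred_overall <- data.frame(species = "overall",
                             method = as.character(pred_overall$method),
                             pred = back(pred_overall$emmean),
                             lower = back(pred_overall$lower.CL),
                             upper = back(pred_overall$upper.CL),
                             stringsAsFactors = FALSE)
  pred_sp <- NULL
  if (n_species > 1) {
    es <- as.data.frame(summary(emmeans::emmeans(mod, ~ method | species,
                                                 lmer.df = "satterthwaite")))
    pred_sp <- data.frame(species = as.character(es$species),
                          method = as.character(es$method),
                          pred = back(es$emmean), lower = back(es$lower.CL),
                          upper = back(es$upper.CL), stringsAsFactors = FALSE)
  }
  predictions <- rbind(pred_overall, pred_sp)

  methods <- levels(df$method)
  pd <- NULL
  for (a_m in methods) for (b_m in methods) {
    if (a_m == b_m) next
    pd <- rbind(pd, percent_difference_tbl(predictions, c(a_m, b_m)))
  }

  structure(list(model = mod, fixed_effect_tests = anova_tab(mod),
                 interaction = list(test = interaction_test,
                                    dropped = dropped),
                 contrasts = ctr, predictions = predictions,
                 percent_differences = pd, response = response,
                 transform = transform, alpha = alpha, mixed = mixed),
            class = "comparison_result")
}

percent_difference_tbl <- function(predictions, pair) {
  ov <- predictions[predictions$species == "overall", ]
  pa <- ov$pred[ov$method == pair[1]]
  pb <- ov$pred[ov$method == pair[2]]
  if (!length(pa) || !length(pb))
    stop("predictions missing for pair ", paste(pair, collapse = " vs "))
  if (pb <= 0) stop("reference prediction is non-positive")
  sp <- predictions[predictions$species != "overall", ]
  rng <- c(NA_real_, NA_real_)
  if (nrow(sp)) {
    per <- vapply(split(sp, sp$species), function(g) {
      100 * (g$pred[g$method == pair[1]] - g$pred[g$method == pair[2]]) /
        g$pred[g$method == pair[2]]
    }, numeric(1))
    rng <- range(per)
  }
  data.frame(method_a = pair[1], method_b = pair[2],
             percent = 100 * (pa - pb) / pb,
             species_min = rng[1], species_max = rng[2],
             stringsAsFactors = FALSE)
}

#' Model-predicted percent difference between two methods
#'
#' `100 * (pred_A - pred_B) / pred_B` from the population-level model
#' predictions, with the per-species range.
#'
#' @param result A [fit_comparison()] result (or its `predictions` frame).
#' @param pair Character `c(method_A, method_B)`.
#' @return One-row data frame: `method_a`, `method_b`, `percent`,
#'   `species_min`, `species_max`.
#' @export
percent_difference <- function(result, pair) {
  predictions <- if (inherits(result, "comparison_result"))
    result$predictions else result
  percent_difference_tbl(predictions, pair)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> response %s (%s scale), %s\n", x$response,
              x$transform,
              if (x$mixed) "LMM with fish random intercept" else "LM fallback"))
  cat(if (x$interaction$dropped)
    "interaction non-significant, removed\n" else "")
  print(x$fixed_effect_tests, row.names = FALSE)
  cat("\nMethod contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Assigns group letters so that two groups share a letter exactly when
#' their pairwise difference is non-significant: starting from one set
#' holding every group, each significant pair splits the sets containing
#' both members, subsets are absorbed, and letters are ordered by
#' decreasing group mean.
#'
#' @param means Named numeric vector of group means.
#' @param pmat Symmetric matrix of (adjusted) pairwise p-values with
#'   dimnames matching `names(means)`.
#' @param alpha Significance level.
#' @return Named character vector of letter strings.
#' @export
cld_letters <- function(means, pmat, alpha = 0.05) {
  g <- names(means)
  sets <- list(g)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (j <= i) next
    if (is.na(pmat[g[i], g[j]]) || pmat[g[i], g[j]] >= alpha) next
    new <- list()
    for (s in sets) {
      if (all(c(g[i], g[j]) %in% s))
        new <- c(new, list(setdiff(s, g[i])), list(setdiff(s, g[j])))
      else new <- c(new, list(s))
    }
    new <- new[lengths(new) > 0]
    keep <- rep(TRUE, length(new))
    for (a in seq_along(new)) for (b in seq_along(new)) {
      if (a != b && keep[a] && all(new[[a]] %in% new[[b]]) &&
            (length(new[[a]]) < length(new[[b]]) || a > b)) keep[a] <- FALSE
    }
    sets <- new[keep]
  }
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}

#' Linear model and Tukey-style comparison of Ucrit
#'
#' Fits a fixed-effects linear model of critical swimming speed on
#' swimming mode and species nested within mode (one Ucrit per fish),
#' reports the sequential F tests, all-pairs species contrasts with Tukey
#' adjustment and a compact letter display of species groups.
#'
#' @param data One row per fish with columns `fish_id`, `species`,
#'   `swim_mode` and the response column.
#' @param response `"ucrit_abs_cm_s"` or `"ucrit_rel_bl_s"`.
#' @param alpha Significance level for the letter display.
#' @return A list: `model`, `fixed_effect_tests`, `contrasts`,
#'   `species_means`, `letters`, `mode_means`.
#' @export
fit_ucrit_lm <- function(data, response = "ucrit_abs_cm_s", alpha = 0.05) {
  df <- as.data.frame(data)
  stopifnot(all(c("species", "swim_mode", response) %in% names(df)))
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  if (any(duplicated(df$fish_id)))
    stop("fit_ucrit_lm expects one Ucrit per fish")
  df$.y <- df[[response]]
  df$swim_mode <- factor(df$swim_mode)
  df$species <- factor(df$species)
  if (nlevels(df$species) < 2 && nlevels(df$swim_mode) < 2)
    stop("fit_ucrit_lm needs >= 2 groups")
  mod <- stats::lm(.y ~ swim_mode / species, data = df)
  a <- as.data.frame(stats::anova(mod))
  a$term <- rownames(a)
  names(a)[names(a) == "F value"] <- "F"
  names(a)[names(a) == "Pr(>F)"] <- "p"

  emm <- emmeans::emmeans(mod, ~species)
  ctr <- as.data.frame(summary(emmeans::contrast(emm, "pairwise",
                                                 adjust = "tukey")))
  sm <- as.data.frame(summary(emm))
  sm <- sm[!is.na(sm$emmean), , drop = FALSE]
  means <- stats::setNames(sm$emmean, as.character(sm$species))
  if (!length(means)) {
    ## one species per mode: species effects alias the mode effect and the
    ## nested emmeans are inestimable; fall back to observed species means
    means <- tapply(df$.y, df$species, mean)
    means <- means[!is.na(means)]
  }
  pmat <- matrix(NA_real_, length(means), length(means),
                 dimnames = list(names(means), names(means)))
  match_species <- function(lbl) {
    hits <- names(means)[startsWith(lbl, names(means))]
    if (!length(hits)) NA_character_ else hits[which.max(nchar(hits))]
  }
  for (i in seq_len(nrow(ctr))) {
    pr <- strsplit(ctr$contrast[i], " - ")[[1]]
    pr <- gsub("^\\(|\\)$", "", pr)
    ## nested labels carry the mode ("<species> <mode>"); match by prefix
    pr <- vapply(pr, match_species, character(1))
    if (!anyNA(pr) && all(pr %in% names(means))) {
      pmat[pr[1], pr[2]] <- ctr$p.value[i]
      pmat[pr[2], pr[1]] <- ctr$p.value[i]
    }
  }
  mode_means <- tapply(df$.y, df$swim_mode, mean)
  list(model = mod,
       fixed_effect_tests = a[a$term != "Residuals",
                              c("term", "F", "Df", "p")],
       contrasts = ctr, species_means = means,
       letters = cld_letters(means, pmat, alpha), mode_means = mode_means)
}
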