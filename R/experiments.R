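#' Run replicated scenarios
#'
#' Runs [run_scenario()] `n_reps` times with seeds derived from the master
#' seed.  Within a replicate all requested methods share the same genome,
#' traits, founders and historical phase (common random numbers), so
#' method contrasts are paired.
#'
#' @param config A [breeding_config()].
#' @param n_reps Number of replicates (>= 2 for any downstream ANOVA).
#' @param master_seed Master seed (default `config$seed`).
#' @param methods Character vector of method tags to run per replicate
#'   (default the configured method).
#' @return A `scenario_result` data frame: one row per (replicate, method,
#'   generation, sex, group) with the mean TBV of that group.
#' @export
run_replicates <- function(config, n_reps, master_seed = config$seed,
                           methods = config$method) {
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, "rep", r)
    base <- prepare_base(cfg)
    rows <- lapply(methods, function(m) run_scenario(cfg, base, method = m))
    rows <- do.call(rbind, rows)
    rows$replicate <- r
    out[[r]] <- rows
  }
  res <- do.call(rbind, out)
  res <- res[, c("replicate", setdiff(names(res), "replicate"))]
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' The feasibility experiment: KIS vs GBLUP, BayesB, TBV and the control
#'
#' Runs all four selection methods plus the 600-locus negative control on
#' common random numbers.
#'
#' @inheritParams run_replicates
#' @return A `scenario_result` covering the five method tags.
#' @export
feasibility_experiment <- function(config = breeding_config(), n_reps = 3,
                                   master_seed = config$seed) {
  run_replicates(config, n_reps, master_seed,
                 methods = c("KIS", "GBLUP", "BayesB", "TBV",
                             "negative_control"))
}

#' The robustness scenario families
#'
#' Builds and runs the six perturbation families around a base
#' configuration: nested false-negative locus deletion (equal and
#' effect-weighted ideals), pseudo-positive loci, QTL-count gradients,
#' foundation-population scale, selection proportion, and non-additive
#' (dominance/epistasis) architectures.
#'
#' @param base_config A [breeding_config()] (its `method` is used for
#'   every scenario; the study design uses KIS).
#' @param n_reps Replicates per scenario.
#' @param master_seed Master seed.
#' @param families Subset of
#'   `c("false_negative", "false_positive", "qtl_gradient",
#'   "foundation_scale", "selection_proportion", "nonadditive")`.
#' @param false_rates Rates for the false-negative / pseudo-positive
#'   families (default `c(0, 0.1, 0.2, 0.3)`).
#' @param qtl_gradients List of QTL-count pairs (default the base 100/500
#'   plus 100/350, 150/400, 200/500).
#' @param foundation_sizes Founder-pool gradient (default 100, 200, 500,
#'   1000, 2000).
#' @param selection_proportions List of `c(n_sires, n_dams)` pairs
#'   (default 3/10, 5/20, 10/30, 15/40, 20/50 out of 100 + 100).
#' @param nonadditive_proportions Default `c(0.1, 0.2, 0.3)`.
#' @param nonadditive_modes Default all of dominance, epistasis, both.
#' @return Named list of `scenario_result` tables, one per family.
#' @export
robustness_suite <- function(base_config = breeding_config(), n_reps = 3,
                             master_seed = base_config$seed,
                             families = c("false_negative", "false_positive",
                                          "qtl_gradient", "foundation_scale",
                                          "selection_proportion",
                                          "nonadditive"),
                             false_rates = c(0, 0.1, 0.2, 0.3),
                             qtl_gradients = list(c(100, 500), c(100, 350),
                                                  c(150, 400), c(200, 500)),
                             foundation_sizes = c(100, 200, 500, 1000, 2000),
                             selection_proportions = list(c(3, 10), c(5, 20),
                                                          c(10, 30),
                                                          c(15, 40),
                                                          c(20, 50)),
                             nonadditive_proportions = c(0.1, 0.2, 0.3),
                             nonadditive_modes = c("dominance", "epistasis",
                                                   "both")) {
  families <- match.arg(families, several.ok = TRUE)
  out <- list()

  # families whose perturbation acts from F1 onward share the base within
  # a replicate; families that change the genome/architecture/pool rebuild
  variant <- function(cfg, ...) {
    v <- modifyList(unclass(cfg), list(...))
    validate_config(v)
  }

  run_family_shared_base <- function(variants) {
    res <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      seed_r <- derive_seed(master_seed, "rep", r)
      cfg0 <- base_config; cfg0$seed <- seed_r
      base <- prepare_base(cfg0)
      rows <- lapply(variants, function(v) {
        v$seed <- seed_r
        run_scenario(v, base)
      })
      rows <- do.call(rbind, rows)
      rows$replicate <- r
      res[[r]] <- rows
    }
    res <- do.call(rbind, res)
    res <- res[, c("replicate", setdiff(names(res), "replicate"))]
    class(res) <- c("scenario_result", "data.frame")
    res
  }

  if ("false_negative" %in% families) {
    variants <- list()
    for (w in c("equal", "effect")) for (rt in false_rates)
      variants[[paste0("fn_", rt, "_", w)]] <-
        variant(base_config, false_negative_rate = rt, weighting = w,
                scenario_id = paste0("fn_", rt, "_", w))
    out$false_negative <- run_family_shared_base(variants)
  }
  if ("false_positive" %in% families) {
    variants <- lapply(false_rates, function(rt)
      variant(base_config, false_positive_rate = rt,
              scenario_id = paste0("fp_", rt)))
    out$false_positive <- run_family_shared_base(variants)
  }
  if ("qtl_gradient" %in% families) {
    res <- lapply(qtl_gradients, function(q) {
      cfg <- variant(base_config, qtl_counts = q,
                     scenario_id = paste0("qtl_", q[1], "_", q[2]))
      run_replicates(cfg, n_reps, master_seed)
    })
    out$qtl_gradient <- do.call(rbind, res)
  }
  if ("foundation_scale" %in% families) {
    res <- lapply(foundation_sizes, function(fn) {
      cfg <- variant(base_config, founder_n = fn,
                     offspring_per_generation = fn,
                     scenario_id = paste0("popsize_", fn))
      run_replicates(cfg, n_reps, master_seed)
    })
    out$foundation_scale <- do.call(rbind, res)
  }
  if ("selection_proportion" %in% families) {
    # proportions act from the cross onward; the historical phase keeps the
    # base design, so all levels share one base per replicate
    variants <- lapply(selection_proportions, function(sp)
      variant(base_config, n_sires = sp[1], n_dams = sp[2],
              scenario_id = paste0("SI_", sp[1], "_", sp[2])))
    out$selection_proportion <- run_family_shared_base(variants)
  }
  if ("nonadditive" %in% families) {
    res <- list()
    for (mode in nonadditive_modes) for (pr in nonadditive_proportions) {
      cfg <- variant(base_config, nonadditive_proportion = pr,
                     nonadditive_mode = mode,
                     scenario_id = paste0("na_", mode, "_", pr))
      res[[paste0(mode, pr)]] <- run_replicates(cfg, n_reps, master_seed)
    }
    out$nonadditive <- do.call(rbind, res)
  }
  out
}

# Compact letter display by insert-absorb: groups sharing a letter are not
# significantly different; significantly different groups never share one.
cld_insert_absorb <- function(sig, order_by) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!sig[i, j]) next
    newcols <- list()
    for (cl in cols) {
      if (cl[i] && cl[j]) {
        a <- cl; a[i] <- FALSE
        b <- cl; b[j] <- FALSE
        newcols <- c(newcols, list(a, b))
      } else newcols <- c(newcols, list(cl))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(newcols))
    for (u in seq_along(newcols)) for (v in seq_along(newcols)) {
      if (u != v && keep[u] && keep[v] &&
          all(newcols[[u]] <= newcols[[v]]) &&
          !identical(newcols[[u]], newcols[[v]]))
        keep[u] <- FALSE
    }
    cols <- unique(newcols[keep])
  }
  # order columns so the best-ranked member gets "A"
  first <- vapply(cols, function(cl) min(order_by[cl]), 0)
  cols <- cols[order(first)]
  vapply(seq_len(k), function(g)
    paste(LETTERS[which(vapply(cols, `[`, TRUE, g))], collapse = ""),
    "")
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' For every generation (and sex) in a replicated result table, fits a
#' one-way ANOVA of the replicate group means across the grouping levels,
#' runs Tukey HSD pairwise comparisons at `alpha`, and assigns compact
#' letters (groups sharing a letter are not significantly different).
#' With zero within-group variance the comparison falls back to exact
#' equality of means.
#'
#' @param result A `scenario_result` with a `replicate` column.
#' @param grouping Column defining the compared groups: `"method"` or
#'   `"scenario_id"`.
#' @param alpha Significance level (default 0.05).
#' @param group Which recorded group to analyse (default `"selected"`).
#' @param by_sex Analyse sexes separately (default) or pool them by
#'   averaging the per-sex means within a replicate.
#' @return A `significance_table` data frame: `generation_label`, `sex`,
#'   level, across-replicate `mean`, `letters`, and the ANOVA
#'   `f_value` / `p_value` of its generation.
#' @export
anova_letters <- function(result, grouping = c("method", "scenario_id"),
                          alpha = 0.05, group = "selected", by_sex = TRUE) {
  grouping <- match.arg(grouping)
  d <- result[result$group == group, ]
  if (!by_sex) {
    d2 <- data.frame(replicate = d$replicate,
                     generation_label = d$generation_label,
                     grp = d[[grouping]], mean_tbv = d$mean_tbv,
                     stringsAsFactors = FALSE)
    d <- aggregate(mean_tbv ~ replicate + generation_label + grp, d2, mean)
    d[[grouping]] <- d$grp
    d$sex <- "both"
  }
  gens <- unique(d$generation_label)
  sexes <- unique(d$sex)
  out <- list()
  for (gen in gens) for (sx in sexes) {
    dd <- d[d$generation_label == gen & d$sex == sx, ]
    agg <- aggregate(dd$mean_tbv,
                     list(replicate = dd$replicate, grp = dd[[grouping]]),
                     FUN = mean)
    lv <- sort(unique(as.character(agg$grp)))
    if (length(lv) < 2) stop_config("need >= 2 groups for ANOVA")
    if (min(table(agg$grp)) < 2)
      stop_config("need >= 2 replicates per group for ANOVA")
    agg$grp <- factor(agg$grp, levels = lv)
    fit <- aov(x ~ grp, data = agg)
    ms <- summary(fit)[[1]]
    resid_ms <- ms["Residuals", "Mean Sq"]
    means <- tapply(agg$x, agg$grp, mean)
    k <- length(lv)
    sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
    if (is.finite(resid_ms) && resid_ms > 1e-12 * max(1, mean(agg$x)^2)) {
      tk <- TukeyHSD(fit, conf.level = 1 - alpha)$grp
      for (r in rownames(tk)) {
        pair <- strsplit(r, "-", fixed = TRUE)[[1]]
        if (tk[r, "p adj"] < alpha)
          sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- TRUE
      }
    } else {
      # exact-comparison fallback: identical means share a letter
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
        sig[i, j] <- sig[j, i] <- means[i] != means[j]
    }
    rk <- rank(-means, ties.method = "first")
    letters <- cld_insert_absorb(sig, rk)
    out[[length(out) + 1]] <- data.frame(
      generation_label = gen, sex = sx, level = lv,
      mean = as.numeric(means), letters = letters,
      f_value = if (is.na(ms["grp", "F value"])) NA_real_
                else ms["grp", "F value"],
      p_value = if (is.na(ms["grp", "Pr(>F)"])) NA_real_
                else ms["grp", "Pr(>F)"],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "level"] <- grouping
  class(res) <- c("significance_table", "data.frame")
  res
}

#' Coefficient of variation across replicates
#'
#' `CV = sd / mean` of the recorded mean TBV across replicates, per
#' grouping cell (method x generation x sex by default).  Cells with zero
#' mean are flagged undefined (`NA` CV).
#'
#' @param result A `scenario_result`.
#' @param by Grouping columns.
#' @param group Which recorded group to use (default `"selected"`).
#' @return Data frame with `mean`, `sd`, `cv` and `undefined` per cell.
#' @export
coefficient_of_variation <- function(result,
                                     by = c("method", "generation_label",
                                            "sex"),
                                     group = "selected") {
  d <- result[result$group == group, ]
  if (length(unique(d$replicate)) < 2)
    stop_config("need >= 2 replicates for a CV")
  key <- lapply(by, function(cn) d[[cn]])
  names(key) <- by
  m <- aggregate(d$mean_tbv, key, FUN = mean)
  s <- aggregate(d$mean_tbv, key, FUN = sd)
  out <- m
  names(out)[ncol(out)] <- "mean"
  out$sd <- s$x
  out$undefined <- out$mean == 0
  out$cv <- ifelse(out$undefined, NA_real_, out$sd / out$mean)
  out
}
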