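#' Two-tailed paired t-test
#'
#' Thin, validating wrapper around the standard paired t statistic. A
#' zero-variance vector of differences (including identical inputs) is an
#' error, because the t statistic is undefined there.
#'
#' @param values_a,values_b equal-length paired numeric vectors, n >= 2
#' @return list with `t`, `df`, `p`
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (sd(d) == 0) {
    stop("zero variance of paired differences: t statistic undefined",
         call. = FALSE)
  }
  ht <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Validating wrapper around the standard step-down procedure (delegated
#' to [stats::p.adjust()]); input order is preserved in the output and
#' monotonicity is enforced by the procedure itself.
#'
#' @param pvalues numeric vector of raw p values in \[0, 1\]
#' @return adjusted p values, same order
#' @export
holm_bonferroni <- function(pvalues) {
  stop_if_not_prob(pvalues, "p values")
  p.adjust(pvalues, method = "holm")
}

# Significance annotation at the conventional 0.05 / 0.01 / 0.001 cutoffs.
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Per-group paired contrasts with interaction gating
#'
#' Reporting layer for the paired two-condition, two-group design: the
#' omnibus stage tests whether the condition effect differs between
#' groups (the group x condition interaction), and only if the overall
#' model and the interaction are significant are the per-group simple
#' contrasts evaluated (paired tests, Holm-Bonferroni adjusted across
#' groups), mirroring standard gated post-hoc logic. Two engines are
#' available: `"glmm"` fits a linear mixed model with a random subject
#' intercept (delegated to lmerTest; interaction p by Satterthwaite,
#' overall p by a likelihood-ratio test against the intercept-only
#' model), `"paired"` is a reduced mode that compares the per-subject
#' condition differences between groups with a Welch t-test.
#'
#' @param table data.frame with columns `subject`, `group`, `condition`,
#'   `value`; each subject must appear once per condition (unpaired
#'   subjects are dropped with a warning)
#' @param alpha gating significance level, default 0.05
#' @param engine `"glmm"` or `"paired"`
#' @return object of class `contrast_report`: list with `overall_p`,
#'   `interaction_p`, `gated` (logical), `contrasts` (data.frame per
#'   group with raw and adjusted p and star annotation, or `NULL` when
#'   gated out)
#' @export
contrast_report <- function(table, alpha = 0.05,
                            engine = c("glmm", "paired")) {
  engine <- match.arg(engine)
  stopifnot(all(c("subject", "group", "condition", "value") %in%
                  names(table)))
  conditions <- unique(table$condition)
  stopifnot(length(conditions) == 2)
  n_per <- table(table$subject)
  unpaired <- names(n_per)[n_per != 2L]
  if (length(unpaired)) {
    warning("dropping unpaired subject(s): ",
            paste(unpaired, collapse = ", "))
    table <- table[!table$subject %in% unpaired, , drop = FALSE]
  }
  wide <- merge(
    table[table$condition == conditions[1],
          c("subject", "group", "value")],
    table[table$condition == conditions[2], c("subject", "value")],
    by = "subject", suffixes = c("_a", "_b"))
  wide$diff <- wide$value_a - wide$value_b

  if (engine == "glmm") {
    fit <- lmerTest::lmer(value ~ group * condition + (1 | subject),
                          data = table, REML = FALSE)
    null <- lme4::lmer(value ~ 1 + (1 | subject), data = table,
                       REML = FALSE)
    overall_p <- anova(fit, null)$`Pr(>Chisq)`[2]
    an <- anova(fit)
    interaction_p <- an[grepl(":", rownames(an)), "Pr(>F)"]
  } else {
    groups <- split(wide$diff, wide$group)
    ht <- t.test(groups[[1]], groups[[2]])
    overall_p <- interaction_p <- ht$p.value
  }
  gated <- is.finite(overall_p) && overall_p < alpha &&
    is.finite(interaction_p) && interaction_p < alpha
  contrasts <- NULL
  if (gated) {
    by_group <- split(wide, wide$group)
    raw <- vapply(by_group, function(d) {
      paired_t(d$value_a, d$value_b)$p
    }, numeric(1))
    adj <- holm_bonferroni(raw)
    contrasts <- data.frame(group = names(by_group), p_raw = raw,
                            p_adjusted = adj,
                            stars = significance_stars(adj),
                            row.names = NULL)
  }
  structure(list(overall_p = overall_p, interaction_p = interaction_p,
                 gated = gated, contrasts = contrasts, engine = engine,
                 alpha = alpha),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("Contrast report (%s engine)\n", x$engine))
  cat(sprintf("  overall model p = %.3g, interaction p = %.3g\n",
              x$overall_p, x$interaction_p))
  if (!x$gated) {
    cat("  gate not passed: simple contrasts not evaluated\n")
  } else {
    cat("  simple contrasts (Holm-Bonferroni adjusted):\n")
    for (i in seq_len(nrow(x$contrasts))) {
      cat(sprintf("    %s: p_adj = %.3g %s\n", x$contrasts$group[i],
                  x$contrasts$p_adjusted[i], x$contrasts$stars[i]))
    }
  }
  invisible(x)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the configuration, the seed,
#' the package version and checksums of the listed output files, as JSON.
#'
#' @param path output JSON path
#' @param config a [synthetic_config()] or any serializable list
#' @param seed integer seed used
#' @param outputs character vector of output file paths
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(path, config, seed, outputs = character(0)) {
  manifest <- list(
    package = "neophys",
    version = as.character(utils::packageVersion("neophys")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = unclass(config),
    outputs = lapply(outputs, function(f) {
      list(file = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
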