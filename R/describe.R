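# Descriptive group comparisons: frequencies + chi-square for categorical
# variables, mean +/- SD + Mann-Whitney U for ordinal/continuous ones
# (reported as means for readability, tested on ranks).

.derived_variables <- c("onset_class", "same_town", "family_history_any",
                        "apoe_genotype", "apoe_e4")

.get_variable <- function(cohort, variable) {
  switch(variable,
    same_town = same_town_flag(cohort$father_birthplace,
                               cohort$mother_birthplace),
    family_history_any = {
      e <- dyad_eligible(cohort$paternal_history, cohort$maternal_history,
                         "any")
      ifelse(e == "excluded", NA_character_,
             ifelse(e == "exposed", "yes", "no"))
    },
    apoe_genotype = cohort$apoe,
    apoe_e4 = ifelse(is.na(cohort$apoe), NA_character_,
                     ifelse(grepl("e4", cohort$apoe), "yes", "no")),
    {
      if (!variable %in% names(cohort)) {
        stop("unknown variable: ", variable, call. = FALSE)
      }
      cohort[[variable]]
    })
}

.grouping_factor <- function(cohort, grouping) {
  switch(grouping,
    case_vs_control = factor(cohort$status, levels = c("control", "case")),
    eoad_vs_load = {
      g <- ifelse(cohort$status == "case", cohort$onset_class, NA_character_)
      factor(g, levels = c("EOAD", "LOAD"))
    },
    same_vs_different_town = {
      st <- same_town_flag(cohort$father_birthplace, cohort$mother_birthplace)
      factor(ifelse(st == "unknown", NA_character_, st),
             levels = c("same", "different"))
    },
    stop("unknown grouping: ", grouping, call. = FALSE))
}

#' Compare variables between subject groups
#'
#' Categorical variables are summarized as frequencies/percentages and tested
#' with a Pearson chi-square (df = (r-1)(c-1), no continuity correction);
#' numeric variables are summarized as mean +/- SD but tested with a
#' Mann-Whitney U (Wilcoxon rank-sum) test, since skewed clinical measures
#' are better compared on medians.
#'
#' @param cohort A `cohort` object.
#' @param grouping `"case_vs_control"`, `"eoad_vs_load"` (within cases) or
#'   `"same_vs_different_town"`.
#' @param variables Character vector: cohort columns or the derived variables
#'   `"same_town"`, `"family_history_any"`, `"apoe_genotype"`, `"apoe_e4"`,
#'   `"onset_class"`.
#' @return A list of `group_comparison` objects (one per variable), each with
#'   the per-group summary, the test used, its statistic and p-value.
#' @export
describe_groups <- function(cohort,
                            grouping = c("case_vs_control", "eoad_vs_load",
                                         "same_vs_different_town"),
                            variables = c("sex", "education",
                                          "family_history_any",
                                          "paternal_history",
                                          "maternal_history", "same_town",
                                          "apoe_genotype")) {
  stopifnot(inherits(cohort, "cohort"))
  grouping <- match.arg(grouping)
  g <- .grouping_factor(cohort, grouping)
  lapply(variables, function(v) {
    x <- .get_variable(cohort, v)
    .compare_one(v, x, g, grouping)
  })
}

.compare_one <- function(variable, x, g, grouping) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- droplevels(g[ok])
  if (is.character(x) || is.factor(x) || is.logical(x)) {
    tab <- table(x, g)
    test <- .safe_chisq(tab)
    pct <- prop.table(tab, margin = 2) * 100
    summary <- data.frame(level = rownames(tab))
    for (lev in colnames(tab)) {
      summary[[paste0(lev, "_n")]] <- as.integer(tab[, lev])
      summary[[paste0(lev, "_pct")]] <- round(pct[, lev], 1)
    }
    structure(list(variable = variable, grouping = grouping,
                   type = "categorical", summary = summary,
                   test = "chi_square", statistic = test$statistic,
                   df = test$df, p = test$p),
              class = "group_comparison")
  } else {
    means <- tapply(x, g, mean)
    sds <- tapply(x, g, stats::sd)
    meds <- tapply(x, g, stats::median)
    summary <- data.frame(group = levels(g), n = as.integer(table(g)),
                          mean = as.numeric(means), sd = as.numeric(sds),
                          median = as.numeric(meds))
    if (nlevels(g) == 2 && all(table(g) > 0)) {
      wt <- stats::wilcox.test(x ~ g, exact = FALSE, correct = FALSE)
      stat <- unname(wt$statistic)
      p <- wt$p.value
    } else {
      stat <- NA_real_
      p <- NA_real_
    }
    structure(list(variable = variable, grouping = grouping,
                   type = "numeric", summary = summary,
                   test = "mann_whitney", statistic = stat, df = NA_real_,
                   p = p),
              class = "group_comparison")
  }
}

.safe_chisq <- function(tab) {
  if (any(dim(tab) < 2)) {
    warning("chi-square skipped: fewer than two levels per margin")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    warning("chi-square skipped: zero expected cell count")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s (%s, %s): p = %s\n", x$variable,
              x$grouping, x$type, x$test,
              format.pval(x$p, digits = 3)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' APOE genotype frequencies by parental-birthplace concordance
#'
#' Cross-tabulates the six APOE genotypes against the same/different-town
#' flag (chi-square test) and reports the pooled homozygote (e2e2 + e4e4)
#' fraction per group — the expected footprint of remote consanguinity, which
#' inflates homozygosity at every locus.
#'
#' @param cohort A `cohort` object.
#' @return A `group_comparison` with an extra `homozygote_fraction` element
#'   (named numeric: same, different) and `homozygote_ratio` (same over
#'   different).
#' @export
apoe_by_birthplace <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  out <- .compare_one("apoe_genotype", .get_variable(cohort, "apoe_genotype"),
                      .grouping_factor(cohort, "same_vs_different_town"),
                      "same_vs_different_town")
  st <- same_town_flag(cohort$father_birthplace, cohort$mother_birthplace)
  ok <- !is.na(cohort$apoe) & st %in% c("same", "different")
  hz <- cohort$apoe[ok] %in% c("e2e2", "e4e4")
  frac <- tapply(hz, factor(st[ok], levels = c("same", "different")), mean)
  out$homozygote_fraction <- frac
  out$homozygote_ratio <- unname(frac["same"] / frac["different"])
  out
}
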