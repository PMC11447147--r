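# Dyad contingency tables, risk/odds ratios, the relative ratio Phi with its
# z test, the full pairwise comparison matrix, and descriptive group
# comparisons.

#' Define a parent-category by offspring-sex dyad
#'
#' @param parent `"father"`, `"mother"` or `"any"` (exactly one affected
#'   parent, both histories known).
#' @param offspring_sex `"male"`, `"female"` or `"any"`.
#' @return A `dyad_spec` object.
#' @export
dyad_spec <- function(parent = c("father", "mother", "any"),
                      offspring_sex = c("male", "female", "any")) {
  parent <- match.arg(parent)
  offspring_sex <- match.arg(offspring_sex)
  structure(list(parent = parent, offspring_sex = offspring_sex),
            class = "dyad_spec")
}

#' @export
format.dyad_spec <- function(x, ...) {
  child <- switch(x$offspring_sex, male = "son", female = "daughter",
                  any = "any child")
  parent <- switch(x$parent, any = "any parent", x$parent)
  paste0(parent, " -> ", child)
}

#' @export
print.dyad_spec <- function(x, ...) {
  cat("<dyad_spec>", format(x), "\n")
  invisible(x)
}

#' The seven standard dyads
#'
#' The cross product of parent category and offspring sex minus
#' (father, any child) and (mother, any child), in the conventional reporting
#' order: father->son, father->daughter, any->daughter, mother->daughter,
#' mother->son, any->son, any->any child.
#'
#' @return Named list of [dyad_spec()] objects.
#' @export
standard_dyad_specs <- function() {
  list(
    father_son      = dyad_spec("father", "male"),
    father_daughter = dyad_spec("father", "female"),
    any_daughter    = dyad_spec("any", "female"),
    mother_daughter = dyad_spec("mother", "female"),
    mother_son      = dyad_spec("mother", "male"),
    any_son         = dyad_spec("any", "male"),
    any_any         = dyad_spec("any", "any")
  )
}

#' Construct a dyad 2x2 exposure table from counts
#'
#' @param a Exposed cases.
#' @param n_case Total eligible cases (exposed + unexposed).
#' @param c Exposed controls.
#' @param n_ctrl Total eligible controls.
#' @param spec Optional [dyad_spec()].
#' @return A `dyad_table` with derived unexposed cells `b = n_case - a`,
#'   `d = n_ctrl - c` and exposure proportions `p = a/n_case`,
#'   `p_ctrl = c/n_ctrl`.
#' @export
dyad_table <- function(a, n_case, c, n_ctrl, spec = NULL) {
  stopifnot(a >= 0, c >= 0, a <= n_case, c <= n_ctrl)
  if (n_case == 0 || n_ctrl == 0) {
    stop("degenerate dyad table: zero eligible cases or controls",
         call. = FALSE)
  }
  structure(list(spec = spec, a = a, n_case = n_case, c = c, n_ctrl = n_ctrl,
                 b = n_case - a, d = n_ctrl - c,
                 p = a / n_case, p_ctrl = c / n_ctrl),
            class = "dyad_table")
}

#' @export
print.dyad_table <- function(x, ...) {
  lbl <- if (is.null(x$spec)) "" else paste0(" ", format(x$spec))
  cat(sprintf("<dyad_table>%s cases %d/%d (%.3f)  controls %d/%d (%.3f)\n",
              lbl, x$a, x$n_case, x$p, x$c, x$n_ctrl, x$p_ctrl))
  invisible(x)
}

#' Build a dyad table from a cohort
#'
#' Restricts to offspring of the dyad's sex, classifies exposure with
#' [dyad_eligible()] (excluded subjects are dropped from the denominators)
#' and cross-tabulates against case status.
#'
#' @param cohort A `cohort` object.
#' @param spec A [dyad_spec()].
#' @return A [dyad_table()].
#' @export
build_dyad_table <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "dyad_spec"))
  rows <- if (spec$offspring_sex == "any") rep(TRUE, nrow(cohort))
          else cohort$sex == spec$offspring_sex
  sub <- cohort[rows, , drop = FALSE]
  elig <- dyad_eligible(sub$paternal_history, sub$maternal_history,
                        spec$parent)
  keep <- elig != "excluded"
  case <- sub$status[keep] == "case"
  exposed <- elig[keep] == "exposed"
  dyad_table(a = sum(case & exposed), n_case = sum(case),
             c = sum(!case & exposed), n_ctrl = sum(!case), spec = spec)
}

#' Risk ratio (ratio of exposure prevalences) for a dyad table
#'
#' `value = (a/n_case) / (c/n_ctrl)`, the ratio of the exposure proportion in
#' cases to that in controls. The log standard error is
#' `sqrt((1-p)/a + (1-p')/c)` with a Wald 95% CI on the log scale.
#'
#' @param table A [dyad_table()].
#' @return An `effect_estimate`.
#' @export
risk_ratio <- function(table) {
  stopifnot(inherits(table, "dyad_table"))
  if (table$c == 0) {
    stop("infinite risk-ratio estimate (no exposed controls); ",
         "consider odds_ratio(correct = TRUE)", call. = FALSE)
  }
  value <- table$p / table$p_ctrl
  if (table$a == 0) {
    return(structure(list(measure = "risk_ratio", value = 0, log_se = NA_real_,
                          ci95 = c(0, NA_real_), one_sided = TRUE),
                     class = "effect_estimate"))
  }
  log_se <- sqrt((1 - table$p) / table$a + (1 - table$p_ctrl) / table$c)
  ci <- exp(log(value) + c(-1, 1) * stats::qnorm(0.975) * log_se)
  structure(list(measure = "risk_ratio", value = value, log_se = log_se,
                 ci95 = ci, one_sided = FALSE),
            class = "effect_estimate")
}

#' Odds ratio for a dyad table
#'
#' `value = (a*d)/(b*c)` with the Woolf log standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and a Wald 95% CI on the log scale.
#'
#' @param table A [dyad_table()].
#' @param correct Apply the Haldane–Anscombe +0.5 continuity correction to
#'   all four cells (required when any cell is zero; never applied silently).
#' @return An `effect_estimate`.
#' @export
odds_ratio <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "dyad_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0) && !correct) {
    stop("zero cell in dyad table; re-run with correct = TRUE for the ",
         "Haldane-Anscombe +0.5 continuity correction", call. = FALSE)
  }
  if (correct) cells <- cells + 0.5
  value <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  log_se <- sqrt(sum(1 / cells))
  ci <- exp(log(value) + c(-1, 1) * stats::qnorm(0.975) * log_se)
  structure(list(measure = "odds_ratio", value = value, log_se = log_se,
                 ci95 = ci, one_sided = FALSE),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<%s> %.3f (95%% CI %.3f-%.3f)\n", x$measure, x$value,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

# Per-dyad variance of the log effect under the chosen rule. The
# "paper_literal" rule is 1/(n p (1-p)) + 1/(n' p' (1-p')), which is
# algebraically the Woolf log-odds-ratio variance of that dyad
# (n p (1-p) = a b / n). Under "pooled_woolf" the variance follows the
# effect-measure scale actually compared (Woolf for OR, log-RR variance for
# RR).
.dyad_log_variance <- function(table, effect, variance_rule) {
  if (variance_rule == "paper_literal") {
    1 / (table$n_case * table$p * (1 - table$p)) +
      1 / (table$n_ctrl * table$p_ctrl * (1 - table$p_ctrl))
  } else {
    effect$log_se^2
  }
}

#' Compare two dyads: relative ratio Phi with a normal z test
#'
#' `phi = effect(t1)/effect(t2)` under the chosen measure;
#' `z = log(phi) / sqrt(v1 + v2)` where each dyad's log-scale variance `v_i`
#' follows `variance_rule`; two-sided p from the standard normal.
#'
#' Under `variance_rule = "paper_literal"` the per-dyad variance is
#' `1/(n p (1-p)) + 1/(n' p' (1-p'))` with `(n, p)` the eligible case total
#' and case exposure proportion and `(n', p')` their control counterparts —
#' exactly the Woolf variance of that dyad's log odds ratio. Under
#' `"pooled_woolf"` each dyad contributes the log-scale variance of the
#' effect measure actually compared.
#'
#' @param t1,t2 [dyad_table()] objects (numerator and denominator dyads).
#' @param mode `"risk_ratio"` (default; matches the published relative-risk
#'   scale of the Phi cells) or `"odds_ratio"`.
#' @param variance_rule `"paper_literal"` or `"pooled_woolf"`.
#' @return A `dyad_comparison` with `phi`, `z`, `p_two_sided`, the two
#'   effects, and the labels of both dyads.
#' @export
compare_dyads <- function(t1, t2, mode = c("risk_ratio", "odds_ratio"),
                          variance_rule = c("paper_literal", "pooled_woolf")) {
  mode <- match.arg(mode)
  variance_rule <- match.arg(variance_rule)
  eff <- switch(mode, risk_ratio = risk_ratio, odds_ratio = odds_ratio)
  e1 <- eff(t1)
  e2 <- eff(t2)
  phi <- e1$value / e2$value
  if (!is.finite(phi) || phi <= 0) {
    stop("degenerate estimate: phi is not a positive finite ratio",
         call. = FALSE)
  }
  v1 <- .dyad_log_variance(t1, e1, variance_rule)
  v2 <- .dyad_log_variance(t2, e2, variance_rule)
  if (!is.finite(v1) || !is.finite(v2)) {
    stop("degenerate estimate: non-finite dyad variance", call. = FALSE)
  }
  z <- log(phi) / sqrt(v1 + v2)
  structure(list(dyad_a = t1$spec, dyad_b = t2$spec, phi = phi, z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)), mode = mode,
                 variance_rule = variance_rule,
                 effect_a = e1, effect_b = e2),
            class = "dyad_comparison")
}

#' @export
print.dyad_comparison <- function(x, ...) {
  la <- if (is.null(x$dyad_a)) "A" else format(x$dyad_a)
  lb <- if (is.null(x$dyad_b)) "B" else format(x$dyad_b)
  cat(sprintf("<dyad_comparison> %s vs %s  Phi = %.3f, z = %.3f, p = %.3f (%s, %s)\n",
              la, lb, x$phi, x$z, x$p_two_sided, x$mode, x$variance_rule))
  invisible(x)
}

#' Full pairwise dyad-comparison matrix
#'
#' Builds (or accepts) a table per dyad and computes every lower-triangular
#' pairwise comparison in the given order, plus each dyad's own effect
#' estimate. A degenerate dyad flags its cells rather than failing the
#' matrix.
#'
#' @param x A `cohort` (tables built with [build_dyad_table()]) or a named
#'   list of [dyad_table()] objects.
#' @param specs Named list of [dyad_spec()]s (default
#'   [standard_dyad_specs()]); ignored when `x` is already a list of tables.
#' @param mode,variance_rule Passed to [compare_dyads()].
#' @return A `dyad_matrix`: list with `$tables`, `$effects` (data.frame) and
#'   `$comparisons` (long data.frame: row, col, phi, z, p, note).
#' @export
dyad_matrix <- function(x, specs = standard_dyad_specs(),
                        mode = c("risk_ratio", "odds_ratio"),
                        variance_rule = c("paper_literal", "pooled_woolf")) {
  mode <- match.arg(mode)
  variance_rule <- match.arg(variance_rule)
  if (inherits(x, "cohort")) {
    stopifnot(length(specs) >= 2)
    tables <- lapply(specs, function(s) build_dyad_table(x, s))
  } else {
    tables <- x
    stopifnot(is.list(tables), length(tables) >= 2,
              all(vapply(tables, inherits, TRUE, "dyad_table")))
    if (is.null(names(tables))) names(tables) <- paste0("dyad", seq_along(tables))
  }
  nm <- names(tables)
  eff_fun <- switch(mode, risk_ratio = risk_ratio, odds_ratio = odds_ratio)
  effects <- do.call(rbind, lapply(nm, function(k) {
    t <- tables[[k]]
    e <- tryCatch(eff_fun(t), error = function(err) NULL)
    data.frame(dyad = k,
               a = t$a, n_case = t$n_case, p_case = t$p,
               c = t$c, n_ctrl = t$n_ctrl, p_ctrl = t$p_ctrl,
               estimate = if (is.null(e)) NA_real_ else e$value,
               ci_lo = if (is.null(e)) NA_real_ else e$ci95[1],
               ci_hi = if (is.null(e)) NA_real_ else e$ci95[2],
               stringsAsFactors = FALSE)
  }))
  comps <- list()
  for (i in seq_along(nm)) {
    for (j in seq_len(i - 1L)) {
      cmp <- tryCatch(
        compare_dyads(tables[[nm[i]]], tables[[nm[j]]], mode, variance_rule),
        error = function(err) conditionMessage(err))
      comps[[length(comps) + 1L]] <- if (is.character(cmp)) {
        data.frame(row = nm[i], col = nm[j], phi = NA_real_, z = NA_real_,
                   p = NA_real_, note = cmp, stringsAsFactors = FALSE)
      } else {
        data.frame(row = nm[i], col = nm[j], phi = cmp$phi, z = cmp$z,
                   p = cmp$p_two_sided, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(tables = tables, effects = effects,
                 comparisons = do.call(rbind, comps),
                 mode = mode, variance_rule = variance_rule),
            class = "dyad_matrix")
}

#' @export
print.dyad_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<dyad_matrix> %d dyads, %d comparisons (%s, %s)\n",
              nrow(x$effects), nrow(x$comparisons), x$mode, x$variance_rule))
  eff <- x$effects
  eff$p_case <- round(eff$p_case, 3)
  eff$p_ctrl <- round(eff$p_ctrl, 3)
  eff$estimate <- round(eff$estimate, digits)
  print(eff[, c("dyad", "a", "n_case", "p_case", "c", "n_ctrl", "p_ctrl",
                "estimate")], row.names = FALSE)
  cmp <- x$comparisons
  cmp$phi <- round(cmp$phi, digits)
  cmp$z <- round(cmp$z, digits)
  cmp$p <- round(cmp$p, digits)
  print(cmp, row.names = FALSE)
  invisible(x)
}

#' Render a dyad matrix as a square TSV-ready data.frame
#'
#' Rows/columns follow the input dyad order; the `estimate` column carries
#' each dyad's own effect; off-diagonal cells are formatted
#' `"Phi=..., p=..."`, mirroring the conventional layout.
#'
#' @param m A `dyad_matrix`.
#' @param digits Rounding for the formatted cells.
#' @return A data.frame.
#' @export
format_dyad_matrix <- function(m, digits = 3) {
  nm <- names(m$tables)
  grid <- matrix("", length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(nrow(m$comparisons))) {
    r <- m$comparisons[k, ]
    grid[r$row, r$col] <- if (nzchar(r$note)) "degenerate" else
      sprintf("Phi=%s, p=%s", format(round(r$phi, digits)),
              format(round(r$p, digits)))
  }
  eff <- m$effects
  data.frame(
    dyad = nm,
    controls = sprintf("%d/%d (%s)", eff$c, eff$n_ctrl,
                       format(round(eff$p_ctrl, 3))),
    cases = sprintf("%d/%d (%s)", eff$a, eff$n_case,
                    format(round(eff$p_case, 3))),
    estimate = round(eff$estimate, digits),
    as.data.frame(grid, stringsAsFactors = FALSE),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published dyad exposure counts (worked example)
#'
#' Exposure counts for the seven standard dyads from a large Portuguese
#' case-control family-history study of Alzheimer's disease (907 cases, 2183
#' controls over 75 years of age): exposed/eligible cases and controls per
#' dyad. Shipped as a plain data.frame so the ratio pipeline can be exercised
#' and checked against the published relative risks without access to the
#' subject-level cohort.
#'
#' @return data.frame with columns `dyad`, `parent`, `offspring_sex`, `a`
#'   (exposed cases), `n_case`, `c` (exposed controls), `n_ctrl`.
#' @export
ad_dyad_counts <- function() {
  data.frame(
    dyad = c("father_son", "father_daughter", "any_daughter",
             "mother_daughter", "mother_son", "any_son", "any_any"),
    parent = c("father", "father", "any", "mother", "mother", "any", "any"),
    offspring_sex = c("male", "female", "female", "female", "male", "male",
                      "any"),
    a = c(52L, 64L, 184L, 140L, 92L, 128L, 312L),
    n_case = c(325L, 537L, 533L, 551L, 332L, 322L, 855L),
    c = c(36L, 64L, 189L, 134L, 59L, 90L, 279L),
    n_ctrl = c(761L, 1383L, 1382L, 1404L, 768L, 757L, 2139L),
    stringsAsFactors = FALSE)
}

#' Convert a counts data.frame into a named list of dyad tables
#'
#' @param counts A data.frame in the [ad_dyad_counts()] layout.
#' @return Named list of [dyad_table()] objects.
#' @export
as_dyad_tables <- function(counts) {
  out <- lapply(seq_len(nrow(counts)), function(i) {
    dyad_table(a = counts$a[i], n_case = counts$n_case[i],
               c = counts$c[i], n_ctrl = counts$n_ctrl[i],
               spec = dyad_spec(counts$parent[i], counts$offspring_sex[i]))
  })
  names(out) <- counts$dyad
  out
}
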