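test_that("build_dyad_table matches hand counts on a toy cohort", {
  # 2 exposed cases, 1 exposed control, 1 both-affected case (excluded),
  # sexes mixed
  co <- make_cohort(
    6,
    status = c("case", "case", "case", "control", "control", "control"),
    sex = c("male", "male", "female", "male", "male", "female"),
    age_of_onset = c(70, 70, 70, NA, NA, NA),
    paternal_history = c("yes", "yes", "yes", "yes", "no", "no"),
    maternal_history = c("no", "yes", "no", "no", "no", "no"))
  t_male <- build_dyad_table(co, dyad_spec("father", "male"))
  expect_equal(t_male$a, 1)        # one exposed male case (other is both-yes)
  expect_equal(t_male$n_case, 1)
  expect_equal(t_male$c, 1)
  expect_equal(t_male$n_ctrl, 2)
  t_any <- build_dyad_table(co, dyad_spec("father", "any"))
  expect_equal(t_any$a, 2)
  expect_equal(t_any$n_case, 2)
})

test_that("build_dyad_table equals a brute-force row scan on a synthetic cohort", {
  co <- generate_cohort(scenario_preset("paperlike", n_cases = 900,
                                        n_controls = 2100, seed = 3))
  for (parent in c("father", "mother", "any")) {
    for (osex in c("male", "female", "any")) {
      got <- build_dyad_table(co, dyad_spec(parent, osex))
      want <- brute_force_dyad(co, parent, osex)
      expect_equal(got$a, want$a, info = paste(parent, osex))
      expect_equal(got$n_case, want$n_case)
      expect_equal(got$c, want$c)
      expect_equal(got$n_ctrl, want$n_ctrl)
    }
  }
})

test_that("build_dyad_table reproduces the published father->son margins", {
  co <- father_son_margin_cohort()
  t <- build_dyad_table(co, dyad_spec("father", "male"))
  expect_equal(t$a, 52)
  expect_equal(t$n_case, 325)
  expect_equal(t$c, 36)
  expect_equal(t$n_ctrl, 761)
  expect_equal(round(risk_ratio(t)$value, 2), 3.38)
})

test_that("risk ratio equals the rational-arithmetic oracle on random tables", {
  set.seed(11)
  for (i in 1:50) {
    t <- random_dyad_table()
    expect_equal(risk_ratio(t)$value,
                 (t$a * t$n_ctrl) / (t$c * t$n_case))
  }
  # symmetry: equal proportions give exactly 1
  expect_equal(risk_ratio(dyad_table(5, 50, 10, 100))$value, 1)
})

test_that("odds ratio, Woolf SE, and the CI identity hold", {
  t <- dyad_table(52, 325, 36, 761)
  e <- odds_ratio(t)
  expect_equal(round(e$value, 3), 3.836)  # (52*725)/(273*36)
  expect_equal(e$value, (52 * 725) / (273 * 36))
  # a/b = c/d gives exactly 1
  expect_equal(odds_ratio(dyad_table(10, 30, 20, 60))$value, 1)
  # CI reconstructs from value and log_se
  expect_equal(e$ci95,
               exp(log(e$value) + c(-1, 1) * qnorm(0.975) * e$log_se))
  # zero-cell handling: error by default, continuity on request
  t0 <- dyad_table(0, 50, 5, 100)
  expect_error(odds_ratio(t0), "continuity")
  e0 <- odds_ratio(t0, correct = TRUE)
  expect_equal(e0$value, (0.5 * 95.5) / (50.5 * 5.5))
  expect_error(risk_ratio(dyad_table(5, 50, 0, 100)), "exposed controls")
})

test_that("Woolf identity: paper-literal variance equals reciprocal-cell sum", {
  set.seed(13)
  for (i in 1:200) {
    t <- random_dyad_table()
    lhs <- 1 / (t$n_case * t$p * (1 - t$p)) +
      1 / (t$n_ctrl * t$p_ctrl * (1 - t$p_ctrl))
    rhs <- 1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("compare_dyads: identity, reciprocity, antisymmetry", {
  t1 <- dyad_table(52, 325, 36, 761)
  t2 <- dyad_table(64, 537, 64, 1383)
  same <- compare_dyads(t1, t1)
  expect_equal(same$phi, 1)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)
  set.seed(17)
  for (mode in c("risk_ratio", "odds_ratio")) {
    for (vr in c("paper_literal", "pooled_woolf")) {
      for (i in 1:20) {
        a <- random_dyad_table()
        b <- random_dyad_table()
        ab <- compare_dyads(a, b, mode, vr)
        ba <- compare_dyads(b, a, mode, vr)
        expect_equal(ab$phi * ba$phi, 1, tolerance = 1e-12)
        expect_equal(ab$z, -ba$z, tolerance = 1e-12)
        expect_equal(ab$p_two_sided, ba$p_two_sided, tolerance = 1e-12)
      }
    }
  }
})

test_that("compare_dyads reproduces the published father->daughter vs father->son cell", {
  tabs <- as_dyad_tables(ad_dyad_counts())
  cmp <- compare_dyads(tabs$father_daughter, tabs$father_son)
  expect_equal(round(cmp$phi, 2), 0.76)
})

test_that("monotonicity: increasing exposed cases increases RR and OR", {
  t1 <- dyad_table(20, 100, 30, 200)
  t2 <- dyad_table(21, 100, 30, 200)
  expect_gt(risk_ratio(t2)$value, risk_ratio(t1)$value)
  expect_gt(odds_ratio(t2)$value, odds_ratio(t1)$value)
})

test_that("dyad_matrix entries equal pairwise compare_dyads calls", {
  tabs <- as_dyad_tables(ad_dyad_counts())
  m <- dyad_matrix(tabs)
  expect_equal(nrow(m$comparisons), choose(7, 2))
  for (k in sample(nrow(m$comparisons), 6)) {
    row <- m$comparisons[k, ]
    cmp <- compare_dyads(tabs[[row$row]], tabs[[row$col]])
    expect_equal(row$phi, cmp$phi)
    expect_equal(row$z, cmp$z)
  }
  # two identical specs give a single phi=1 cell
  m2 <- dyad_matrix(list(a = tabs[[1]], b = tabs[[1]]))
  expect_equal(nrow(m2$comparisons), 1)
  expect_equal(m2$comparisons$phi, 1)
})

test_that("degenerate dyads flag their matrix cells without failing", {
  tabs <- list(ok = dyad_table(10, 100, 10, 100),
               bad = dyad_table(0, 50, 0, 50))
  m <- dyad_matrix(tabs)
  expect_equal(nrow(m$comparisons), 1)
  expect_true(nzchar(m$comparisons$note[1]))
  expect_true(is.na(m$comparisons$phi[1]))
})

test_that("describe_groups: chi-square on published family-history margins", {
  co <- expand_history_cohort(data.frame(
    status = rep(c("control", "case"), each = 2),
    sex = "female",
    paternal = c("yes", "no", "yes", "no"),
    maternal = "no",
    n = c(414L, 1725L, 417L, 438L),
    stringsAsFactors = FALSE))
  d <- describe_groups(co, "case_vs_control", variables = "paternal_history")
  expect_equal(d[[1]]$test, "chi_square")
  expect_lt(d[[1]]$p, 0.001)
  # oracle: textbook chi-square from the 2x2 table
  tab <- matrix(c(1725, 414, 438, 417), 2)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(d[[1]]$statistic, sum((tab - exp_tab)^2 / exp_tab),
               tolerance = 1e-10)
  expect_equal(d[[1]]$df, 1)
})

test_that("identical groups give chi-square p = 1", {
  co <- expand_history_cohort(data.frame(
    status = rep(c("control", "case"), each = 2),
    sex = "male",
    paternal = c("yes", "no", "yes", "no"),
    maternal = "no",
    n = c(50L, 150L, 50L, 150L),
    stringsAsFactors = FALSE))
  d <- describe_groups(co, "case_vs_control", variables = "paternal_history")
  expect_equal(d[[1]]$p, 1)
})

test_that("numeric variables use Mann-Whitney and report mean +/- SD", {
  co <- make_cohort(40,
                    status = rep(c("case", "control"), each = 20),
                    age_of_onset = c(rep(70, 20), rep(NA, 20)),
                    education = c(rnorm(20, 8, 2), rnorm(20, 4, 2)))
  d <- describe_groups(co, "case_vs_control", variables = "education")
  expect_equal(d[[1]]$test, "mann_whitney")
  expect_named(d[[1]]$summary, c("group", "n", "mean", "sd", "median"))
  expect_lt(d[[1]]$p, 0.05)
})

test_that("Mann-Whitney p-values are uniform under the null", {
  set.seed(29)
  ps <- replicate(1000, {
    x <- rnorm(25)
    y <- rnorm(25)
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  })
  # occasional ties in approximate wilcox p-values trigger a ks.test warning
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("eoad_vs_load grouping splits cases by the onset-65 rule", {
  co <- make_cohort(30,
                    status = c(rep("case", 20), rep("control", 10)),
                    sex = "female",
                    age_of_onset = c(rep(60, 8), rep(70, 12), rep(NA, 10)),
                    education = rnorm(30, 5, 2))
  d <- describe_groups(co, "eoad_vs_load", variables = "education")
  expect_equal(sum(d[[1]]$summary$n), 20)  # controls excluded
})

test_that("apoe_by_birthplace reports genotype table and homozygote fractions", {
  # constructed: same-town group has double the homozygote fraction
  n1 <- 200; n2 <- 200
  co <- make_cohort(
    n1 + n2,
    status = "control", age_of_onset = NA_real_,
    father_birthplace = "x",
    mother_birthplace = c(rep("x", n1), rep("y", n2)),
    apoe = c(rep("e4e4", 40), rep("e3e3", 140), rep("e2e3", 20),
             rep("e4e4", 20), rep("e3e3", 160), rep("e2e3", 20)))
  r <- apoe_by_birthplace(co)
  expect_equal(unname(r$homozygote_fraction["same"]), 0.2)
  expect_equal(unname(r$homozygote_fraction["different"]), 0.1)
  expect_equal(r$homozygote_ratio, 2)
  expect_equal(r$test, "chi_square")
})

test_that("inbreeding inflates APOE homozygosity by F*2q(1-q) per allele", {
  cfg <- sim_config(n_cases = 500, n_controls = 2500,
                    loci = list(), pi_same_town = 0.5, kinship_phi = 0.25,
                    p_missing_birthplace = c(control = 0, case = 0),
                    seed = 19)
  co <- generate_cohort(cfg)
  r <- apoe_by_birthplace(co)
  q <- c(e2 = 0.065, e4 = 0.155)
  hwe <- sum(q^2)
  excess <- 0.25 * sum(q * (1 - q))
  expect_equal(unname(r$homozygote_fraction["different"]), hwe,
               tolerance = 0.35)  # relative; small expected fraction
  expect_equal(unname(r$homozygote_fraction["same"]), hwe + excess,
               tolerance = 0.25)
})
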