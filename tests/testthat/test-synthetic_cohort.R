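test_that("parental genotypes follow Hardy-Weinberg", {
  set.seed(21)
  loc <- locus("autosomal", q = 0.3)
  pg <- draw_parent_genotypes(loc, 1e5)
  # genotype frequencies q^2 / 2q(1-q) / (1-q)^2 within 4 MC standard errors
  for (gt in 0:2) {
    expected <- stats::dbinom(gt, 2, 0.3)
    se <- sqrt(expected * (1 - expected) / 1e5)
    expect_lt(abs(mean(pg$mother == gt) - expected), 4 * se)
  }
  locx <- locus("X", q = 0.2)
  px <- draw_parent_genotypes(locx, 1e5)
  expect_true(all(px$father %in% 0:1))
  expect_lt(abs(mean(px$father) - 0.2), 4 * sqrt(0.2 * 0.8 / 1e5))
  locy <- locus("Y", q = 0.2)
  py <- draw_parent_genotypes(locy, 10)
  expect_true(all(is.na(py$mother)))
})

test_that("q = 0 is rejected; all-non-risk limit via tiny q", {
  expect_error(locus("autosomal", q = 0))
  set.seed(22)
  loc <- locus("autosomal", q = 1e-9)
  pg <- draw_parent_genotypes(loc, 1e4)
  expect_true(all(pg$father == 0) && all(pg$mother == 0))
})

test_that("Mendelian transmission fractions are exact in forced cases", {
  locx <- locus("X", q = 0.2)
  n <- 1e5
  sons <- rep("male", n)
  # son of homozygous-risk mother is a risk hemizygote with probability 1
  expect_true(all(transmit(rep(0, 10), rep(2, 10), rep("male", 10),
                           locx) == 1))
  # son of heterozygous mother: risk fraction 1/2 within MC error
  g <- transmit(rep(0, n), rep(1, n), sons, locx)
  expect_lt(abs(mean(g) - 0.5), 4 * sqrt(0.25 / n))
  # daughters add the paternal X deterministically
  gd <- transmit(rep(1, 10), rep(0, 10), rep("female", 10), locx)
  expect_true(all(gd == 1))
  # Y: sons copy the father, daughters carry nothing ("absent")
  locy <- locus("Y", q = 0.2)
  expect_true(all(is.na(transmit(rep(1, 5), rep(NA, 5), rep("female", 5),
                                 locy))))
  expect_true(all(transmit(rep(1, 5), rep(NA, 5), rep("male", 5),
                           locy) == 1))
})

test_that("offspring homozygosity follows q^2 + F q (1-q)", {
  set.seed(23)
  n <- 1e5
  loc <- locus("autosomal", q = 0.1)
  pg <- draw_parent_genotypes(loc, n)
  # F = 0: HWE limit
  og0 <- offspring_genotype(pg$father, pg$mother, rep("female", n), loc,
                            same_town = TRUE, kinship_phi = 0)
  p0 <- mean(og0$g == 2)
  expect_lt(abs(p0 - 0.01), 4 * sqrt(0.01 * 0.99 / n))
  # F = 0.0625: 0.01 + 0.0625 * 0.09 = 0.015625
  og <- offspring_genotype(pg$father, pg$mother, rep("female", n), loc,
                           same_town = TRUE, kinship_phi = 0.0625)
  pF <- mean(og$g == 2)
  expect_lt(abs(pF - 0.015625), 4 * sqrt(0.015625 * (1 - 0.015625) / n))
})

test_that("liability follows the stated log-odds composition", {
  cfg <- sim_config(loci = list(locus("X", q = 0.2, gamma = 1.2,
                                      lambda_x = 0.4)),
                    beta0 = -2, beta_age = 0.1, beta_sex_female = 0.3)
  # all gamma = 0 reduces to covariates only
  cfg0 <- sim_config(loci = list(locus("X", q = 0.2, gamma = 0)),
                     beta0 = -2, beta_age = 0.1, beta_sex_female = 0.3)
  expect_equal(liability(list(2), "female", 80, cfg0),
               plogis(-2 + 0.5 + 0.3))
  # lambda_x = 0: heterozygous females at exactly baseline
  cfg_l0 <- sim_config(loci = list(locus("X", q = 0.2, gamma = 2,
                                         lambda_x = 0)),
                       beta0 = -2, beta_age = 0.1, beta_sex_female = 0.3)
  expect_equal(liability(list(1), "female", 75, cfg_l0),
               plogis(-2 + 0.3))
  # lambda_x = 1: female homozygote equals male hemizygote at equal covariates
  cfg_l1 <- sim_config(loci = list(locus("X", q = 0.2, gamma = 2,
                                         lambda_x = 1)),
                       beta0 = -2, beta_age = 0.1, beta_sex_female = 0)
  expect_equal(liability(list(2), "female", 80, cfg_l1),
               liability(list(1), "male", 80, cfg_l1))
  # heterozygous female: attenuated contribution
  expect_equal(liability(list(1), "female", 75, cfg),
               plogis(-2 + 0.3 + 0.4 * 1.2))
})

test_that("generate_cohort is deterministic and respects ascertainment", {
  cfg <- scenario_preset("null", n_cases = 150, n_controls = 350, seed = 24)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(co1), as.data.frame(co2))
  expect_equal(sum(co1$status == "case"), 150)
  expect_equal(sum(co1$status == "control"), 350)
  ctrl <- co1[co1$status == "control", ]
  expect_true(all(ctrl$age_at_assessment > 75))
  expect_true(all(is.na(ctrl$age_of_onset)))
  expect_true(all(!is.na(co1$age_of_onset[co1$status == "case"])))
  # different seeds differ
  co3 <- generate_cohort(scenario_preset("null", n_cases = 150,
                                         n_controls = 350, seed = 25))
  expect_false(identical(as.data.frame(co1), as.data.frame(co3)))
})

test_that("Mendelian conservation: offspring allele frequency matches q under F = 0", {
  set.seed(26)
  n <- 2e5
  loc <- locus("autosomal", q = 0.3)
  pg <- draw_parent_genotypes(loc, n)
  g <- transmit(pg$father, pg$mother, rep("female", n), loc)
  expect_lt(abs(mean(g) / 2 - 0.3), 4 * sqrt(0.3 * 0.7 / (2 * n)))
})

test_that("scenario presets are as documented", {
  expect_error(scenario_preset("bogus"), "null, x_linked")
  null_cfg <- scenario_preset("null")
  expect_true(all(vapply(null_cfg$loci, function(l) l$gamma == 0, TRUE)))
  expect_equal(scenario_preset("y_linked")$loci[[1]]$chromosome, "Y")
  pl <- scenario_preset("paperlike", n_cases = 10, n_controls = 20)
  expect_equal(pl$n_cases, 10)
  expect_equal(pl$n_controls, 20)
})

test_that("paperlike preset lands near the published exposure margins", {
  # pooled margins over three cohorts of n = 3090 each; +/- 3 percentage
  # points around the published control 4.7/8.9% and case 13.5/26.3%
  margins <- function(co, st, parent) {
    sub <- co[co$status == st, ]
    e <- dyad_eligible(sub$paternal_history, sub$maternal_history, parent)
    c(sum(e == "exposed"), sum(e != "excluded"))
  }
  tot <- matrix(0, 4, 2)
  for (s in 1:3) {
    co <- generate_cohort(scenario_preset("paperlike", seed = 100 + s))
    tot <- tot + rbind(margins(co, "control", "father"),
                       margins(co, "control", "mother"),
                       margins(co, "case", "father"),
                       margins(co, "case", "mother"))
  }
  rates <- 100 * tot[, 1] / tot[, 2]
  published <- c(4.7, 8.9, 13.5, 26.3)
  expect_true(all(abs(rates - published) <= 3),
              info = paste(round(rates, 1), collapse = " / "))
  # same-town fraction near 58-60%
  co <- generate_cohort(scenario_preset("paperlike", seed = 104))
  st <- same_town_flag(co$father_birthplace, co$mother_birthplace)
  expect_lt(abs(mean(st[st != "unknown"] == "same") - 0.59), 0.04)
})

test_that("power is non-decreasing in gamma on the x_linked grid", {
  gammas <- c(0, 2.75, 5.5)
  reps <- 200
  rates <- vapply(seq_along(gammas), function(gi) {
    rej <- vapply(1:reps, function(r) {
      cfg <- sim_config(
        loci = list(locus("X", q = 0.2, gamma = gammas[gi], lambda_x = 0)),
        beta0 = -5.2, beta_age = 0.07, beta_sex_female = 0.3,
        parent_death_age = list(father = c(71, 8), mother = c(80, 8)),
        n_cases = 300, n_controls = 700, seed = 40000 + gi * 1000 + r)
      co <- generate_cohort(cfg)
      cmp <- tryCatch(compare_dyads(
        build_dyad_table(co, dyad_spec("mother", "male")),
        build_dyad_table(co, dyad_spec("mother", "female")),
        variance_rule = "pooled_woolf"), error = function(e) NULL)
      !is.null(cmp) && cmp$p_two_sided < 0.05
    }, TRUE)
    mean(rej)
  }, 1)
  expect_true(all(diff(rates) >= 0),
              info = paste(round(rates, 3), collapse = " -> "))
})

test_that("unreachable targets produce an informative error", {
  cfg <- sim_config(n_cases = 5000, n_controls = 10, loci = list(),
                    beta0 = -12, seed = 27)
  expect_error(generate_cohort(cfg, max_batches = 2), "iteration cap")
})
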