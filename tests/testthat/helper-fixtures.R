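# Fixture builders. Everything is generated in code; no data files.

# Minimal valid subject rows; any column can be overridden.
make_cohort_df <- function(n = 4, ...) {
  df <- data.frame(
    subject_id = sprintf("id%03d", seq_len(n)),
    status = rep(c("case", "control"), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    age_at_assessment = rep(80, n),
    age_of_onset = ifelse(rep(c(TRUE, FALSE), length.out = n), 70, NA_real_),
    education = rep(4, n),
    year_of_birth = rep(1935L, n),
    paternal_history = rep("no", n),
    maternal_history = rep("no", n),
    father_birthplace = rep("town_a", n),
    mother_birthplace = rep("town_b", n),
    n_siblings = rep(2L, n),
    siblings_with_dementia = rep(0L, n),
    apoe = rep("e3e3", n),
    csf_abeta42 = rep(NA_real_, n),
    csf_ttau = rep(NA_real_, n),
    csf_ptau = rep(NA_real_, n),
    age_at_lp = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_cohort <- function(n = 4, ...) new_cohort(make_cohort_df(n, ...))

# Expand per-stratum counts of (paternal, maternal) history pairs into rows.
# counts: data.frame(status, sex, paternal, maternal, n) with "unknown" for NA.
expand_history_cohort <- function(counts) {
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$n == 0) return(NULL)
    make_cohort_df(
      r$n,
      status = r$status, sex = r$sex,
      age_of_onset = if (r$status == "case") 70 else NA_real_,
      paternal_history = if (r$paternal == "unknown") NA_character_
                         else r$paternal,
      maternal_history = if (r$maternal == "unknown") NA_character_
                         else r$maternal)
  }))
  rows$subject_id <- sprintf("h%05d", seq_len(nrow(rows)))
  new_cohort(rows)
}

# Male-control stratum whose father/mother/any-dyad denominators are
# 761/768/757 with exposures 36/59/90 (the published male-control margins):
# joint (paternal, maternal) cells yn=36, ny=54, uy=5, nn=667, nu=4, un=6,
# yy=2, uu=1 (total 775).
male_control_margin_counts <- function() {
  data.frame(
    status = "control", sex = "male",
    paternal = c("yes", "no", "unknown", "no", "no", "unknown", "yes",
                 "unknown"),
    maternal = c("no", "yes", "yes", "no", "unknown", "no", "yes",
                 "unknown"),
    n = c(36L, 54L, 5L, 667L, 4L, 6L, 2L, 1L),
    stringsAsFactors = FALSE)
}

# Cohort matching the published (father, male) dyad margins:
# cases 52/325 exposed, controls 36/761 exposed.
father_son_margin_cohort <- function() {
  ctrl <- male_control_margin_counts()
  cases <- data.frame(
    status = "case", sex = "male",
    paternal = c("yes", "no"), maternal = c("no", "no"),
    n = c(52L, 273L), stringsAsFactors = FALSE)
  # some female rows to prove the sex restriction matters
  females <- data.frame(
    status = c("case", "control"), sex = "female",
    paternal = "yes", maternal = "no", n = c(10L, 20L),
    stringsAsFactors = FALSE)
  expand_history_cohort(rbind(ctrl, cases, females))
}

# Naive O(rows) re-count of a dyad table, independent of build_dyad_table.
brute_force_dyad <- function(cohort, parent, offspring_sex) {
  a <- 0L; n_case <- 0L; cc <- 0L; n_ctrl <- 0L
  for (i in seq_len(nrow(cohort))) {
    if (offspring_sex != "any" && cohort$sex[i] != offspring_sex) next
    pat <- cohort$paternal_history[i]
    mat <- cohort$maternal_history[i]
    both_yes <- !is.na(pat) && !is.na(mat) && pat == "yes" && mat == "yes"
    st <- switch(parent,
      father = if (is.na(pat) || both_yes) NA else pat == "yes",
      mother = if (is.na(mat) || both_yes) NA else mat == "yes",
      any = if (is.na(pat) || is.na(mat) || both_yes) NA
            else (pat == "yes" || mat == "yes"))
    if (is.na(st)) next
    if (cohort$status[i] == "case") {
      n_case <- n_case + 1L
      if (st) a <- a + 1L
    } else {
      n_ctrl <- n_ctrl + 1L
      if (st) cc <- cc + 1L
    }
  }
  list(a = a, n_case = n_case, c = cc, n_ctrl = n_ctrl)
}

random_dyad_table <- function() {
  n_case <- sample(50:400, 1)
  n_ctrl <- sample(50:400, 1)
  dyad_table(a = sample(seq_len(n_case - 1), 1), n_case = n_case,
             c = sample(seq_len(n_ctrl - 1), 1), n_ctrl = n_ctrl)
}
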