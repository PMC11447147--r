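# Cohort schema, readers/writers, eligibility and exposure-classification
# rules. The cohort is an ordinary data.frame with class "cohort" plus a
# provenance attribute recording the source and every filter applied.

#' Cohort column schema
#'
#' Machine-readable description of the subject table: one row per column with
#' its type and whether it is mandatory. The same schema ships as
#' `inst/extdata/cohort_schema.json`.
#'
#' @return A data.frame with columns `column`, `type`
#'   (`character`/`numeric`/`integer`), and `required`.
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("subject_id", "status", "sex", "age_at_assessment",
               "age_of_onset", "education", "year_of_birth",
               "paternal_history", "maternal_history",
               "father_birthplace", "mother_birthplace",
               "n_siblings", "siblings_with_dementia", "apoe",
               "csf_abeta42", "csf_ttau", "csf_ptau", "age_at_lp"),
    type = c("character", "character", "character", "numeric",
             "numeric", "numeric", "integer",
             "character", "character",
             "character", "character",
             "integer", "integer", "character",
             "numeric", "numeric", "numeric", "numeric"),
    required = c(TRUE, TRUE, TRUE, rep(FALSE, 15)),
    stringsAsFactors = FALSE
  )
}

.yes_no_levels <- c("yes", "no")
.status_levels <- c("case", "control")
.sex_levels <- c("male", "female")

#' Construct and validate a cohort table
#'
#' Validates a data.frame against the cohort schema, derives the onset class
#' (early-onset if onset at 65 years or younger, late-onset if 66 or older)
#' and attaches provenance metadata. Unknown values must be encoded as `NA`
#' ("NA" in files), never as empty strings, so that a negative history is
#' always distinguishable from a missing one.
#'
#' @param df A data.frame with (at least) the required schema columns.
#' @param source Character scalar recorded in the provenance metadata.
#' @return A `cohort` object (data.frame subclass).
#' @export
new_cohort <- function(df, source = "in-memory") {
  stopifnot(is.data.frame(df))
  schema <- cohort_schema()
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(schema$column[schema$required], names(df))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # add optional columns absent from the input as all-NA
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(df)) {
      df[[col]] <- switch(schema$type[i],
                          character = NA_character_,
                          numeric = NA_real_,
                          integer = NA_integer_)
    }
  }
  df <- df[, schema$column, drop = FALSE]
  df <- .coerce_cohort_types(df, schema)
  .validate_cohort(df)
  df$onset_class <- ifelse(is.na(df$age_of_onset), NA_character_,
                           ifelse(df$age_of_onset <= 65, "EOAD", "LOAD"))
  structure(df,
            class = c("cohort", "data.frame"),
            provenance = list(
              source = source,
              filters = data.frame(filter = character(), removed = integer(),
                                   retained = integer(),
                                   stringsAsFactors = FALSE)))
}

.coerce_cohort_types <- function(df, schema) {
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    x <- df[[col]]
    if (is.character(x)) x[!is.na(x) & trimws(x) == ""] <- NA_character_
    df[[col]] <- switch(schema$type[i],
      character = as.character(x),
      numeric = .parse_num(x, col),
      integer = {
        v <- .parse_num(x, col)
        as.integer(round(v))
      })
  }
  for (col in c("status", "sex")) df[[col]] <- tolower(df[[col]])
  for (col in c("paternal_history", "maternal_history")) {
    v <- tolower(df[[col]])
    v[!is.na(v) & v %in% c("unknown", "na", "")] <- NA_character_
    bad <- !is.na(v) & !v %in% .yes_no_levels
    if (any(bad)) {
      stop("row-level error: invalid value in '", col, "' at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$apoe <- normalize_apoe(df$apoe)
  df
}

.parse_num <- function(x, col) {
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0) {
    stop("row-level error: unparseable value in '", col, "' at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  v
}

.validate_cohort <- function(df) {
  if (anyNA(df$subject_id) || any(trimws(df$subject_id) == "")) {
    stop("validation error: missing subject_id", call. = FALSE)
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stop("validation error: duplicate subject_id: ",
         paste(utils::head(unique(df$subject_id[dup]), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$status) || !all(df$status %in% .status_levels)) {
    stop("validation error: status must be 'case' or 'control', non-missing",
         call. = FALSE)
  }
  if (anyNA(df$sex) || !all(df$sex %in% .sex_levels)) {
    stop("validation error: sex must be 'male' or 'female', non-missing",
         call. = FALSE)
  }
  if (any(!is.na(df$age_of_onset) & df$status == "control")) {
    stop("validation error: age_of_onset present for control subject(s)",
         call. = FALSE)
  }
  sib_bad <- !is.na(df$n_siblings) & !is.na(df$siblings_with_dementia) &
    df$siblings_with_dementia > df$n_siblings
  if (any(sib_bad)) {
    stop("validation error: siblings_with_dementia > n_siblings at row(s) ",
         paste(utils::head(which(sib_bad), 5), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("csf_abeta42", "csf_ttau", "csf_ptau")) {
    if (any(!is.na(df[[col]]) & df[[col]] <= 0)) {
      stop("validation error: non-positive ", col, " value(s)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Normalize APOE genotype strings
#'
#' Accepts forms like `"e3/e4"`, `"E4E3"`, `"ε3ε4"` and returns the
#' sorted two-allele form `"e3e4"`; unknowns stay `NA`.
#'
#' @param x Character vector of genotype strings.
#' @return Character vector of normalized genotypes.
#' @export
normalize_apoe <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("ε", "e", x)
  x[!is.na(x) & x %in% c("", "na", "unknown")] <- NA_character_
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  alleles <- regmatches(x[ok], gregexpr("e[234]", x[ok]))
  good <- vapply(alleles, length, 1L) == 2L
  if (any(!good & nchar(x[ok]) > 0)) {
    stop("row-level error: unparseable APOE genotype: ",
         paste(utils::head(x[ok][!good], 5), collapse = ", "), call. = FALSE)
  }
  out[ok] <- vapply(alleles, function(a) paste(sort(a), collapse = ""), "")
  out
}

#' Read a cohort table from CSV/TSV
#'
#' Header matching is case-insensitive and order-free; missing values must be
#' the literal token `"NA"` (empty cells are also treated as missing). The
#' delimiter is inferred from the file extension unless given.
#'
#' @param path Path to the file.
#' @param dialect `"tab"`, `"comma"` or `NULL` (infer: `.csv` means comma).
#' @return A validated [new_cohort()] object with provenance `source = path`.
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "comma" else "tab"
  }
  sep <- switch(match.arg(dialect, c("tab", "comma")), tab = "\t", comma = ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = c("NA", ""),
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  new_cohort(df, source = path)
}

#' Write a cohort table to TSV
#'
#' Field values round-trip exactly through [read_cohort()]; unknowns are
#' written as the literal `NA` token.
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  df$onset_class <- NULL  # derived, not stored
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Provenance accessor: filters applied to a cohort
#'
#' @param cohort A `cohort` object.
#' @return A data.frame with columns `filter`, `removed`, `retained`.
#' @export
cohort_filters <- function(cohort) {
  attr(cohort, "provenance")$filters
}

.record_filter <- function(cohort, name, keep) {
  prov <- attr(cohort, "provenance")
  out <- cohort[keep, , drop = FALSE]
  prov$filters <- rbind(prov$filters, data.frame(
    filter = name, removed = sum(!keep), retained = sum(keep),
    stringsAsFactors = FALSE))
  attr(out, "provenance") <- prov
  class(out) <- class(cohort)
  out
}

#' Apply the control age-eligibility rule
#'
#' Controls are retained only if strictly older than 75 years at assessment
#' (a control aged exactly 75 is excluded); controls with missing age are
#' excluded and counted in the filter log. Cases are unaffected.
#'
#' @param cohort A `cohort` object.
#' @return The filtered cohort with the filter recorded in its provenance.
#' @export
apply_control_eligibility <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- cohort$status == "case" |
    (!is.na(cohort$age_at_assessment) & cohort$age_at_assessment > 75)
  .record_filter(cohort, "control_age_gt_75", keep)
}

#' Classify a subject's exposure for a parental dyad
#'
#' Implements the univariate eligibility rule: subjects with *both* parents
#' affected are excluded from every dyad, and a dyad requires the relevant
#' histories to be known. For `parent = "father"`: excluded if paternal
#' history is unknown or both histories are "yes"; otherwise exposed iff
#' paternal history is "yes" (symmetric for `"mother"`). For
#' `parent = "any"`: excluded if either history is unknown or both are "yes";
#' exposed iff exactly one parent is affected. Total and deterministic; the
#' three outcomes partition any input.
#'
#' @param paternal,maternal Character vectors with values `"yes"`, `"no"` or
#'   `NA` (unknown).
#' @param parent One of `"father"`, `"mother"`, `"any"`.
#' @return Character vector: `"exposed"`, `"unexposed"` or `"excluded"`.
#' @export
dyad_eligible <- function(paternal, maternal, parent = c("father", "mother", "any")) {
  parent <- match.arg(parent)
  both_yes <- !is.na(paternal) & !is.na(maternal) &
    paternal == "yes" & maternal == "yes"
  out <- rep("excluded", length(paternal))
  if (parent == "father") {
    known <- !is.na(paternal) & !both_yes
    out[known] <- ifelse(paternal[known] == "yes", "exposed", "unexposed")
  } else if (parent == "mother") {
    known <- !is.na(maternal) & !both_yes
    out[known] <- ifelse(maternal[known] == "yes", "exposed", "unexposed")
  } else {
    known <- !is.na(paternal) & !is.na(maternal) & !both_yes
    one_yes <- known & (paternal == "yes" | maternal == "yes")
    out[known] <- ifelse(one_yes[known], "exposed", "unexposed")
  }
  out
}

#' Normalize a birthplace string
#'
#' Trims and squeezes whitespace, strips common Latin diacritics and lowers
#' case, so that `"  Coimbra "` and `"coimbra"` compare equal. No gazetteer
#' or distance logic: distinct names — even of neighboring villages — stay
#' distinct.
#'
#' @param x Character vector of place names.
#' @return Normalized character vector (`NA` stays `NA`).
#' @export
normalize_place <- function(x) {
  x <- as.character(x)
  x <- gsub("\\s+", " ", trimws(x))
  from <- paste0("áàâãäçéèê",
                 "ëíìîïóòôõ",
                 "öúùûüýñ",
                 "ÁÀÂÃÄÇÉÈÊ",
                 "ËÍÌÎÏÓÒÔÕ",
                 "ÖÚÙÛÜÝÑ")
  to <- paste0("aaaaaceeeeiiiiooooouuuuyn", "AAAAACEEEEIIIIOOOOOUUUUYN")
  x <- chartr(from, to, x)
  tolower(x)
}

#' Same-birthplace (remote consanguinity) flag
#'
#' `"same"` iff both parental birthplaces are known and identical after
#' [normalize_place()]; `"unknown"` if either is missing; otherwise
#' `"different"`.
#'
#' @param father_birthplace,mother_birthplace Character vectors.
#' @return Character vector: `"same"`, `"different"` or `"unknown"`.
#' @export
same_town_flag <- function(father_birthplace, mother_birthplace) {
  f <- normalize_place(father_birthplace)
  m <- normalize_place(mother_birthplace)
  ifelse(is.na(f) | is.na(m), "unknown",
         ifelse(f == m, "same", "different"))
}

#' @export
print.cohort <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<cohort> %d subjects (%d cases, %d controls)  source: %s\n",
              nrow(x), sum(x$status == "case"), sum(x$status == "control"),
              prov$source))
  if (nrow(prov$filters) > 0) {
    cat("filters applied:\n")
    for (i in seq_len(nrow(prov$filters))) {
      cat(sprintf("  %s: removed %d, retained %d\n", prov$filters$filter[i],
                  prov$filters$removed[i], prov$filters$retained[i]))
    }
  }
  invisible(x)
}

#' Write a JSON filter log for a cohort
#'
#' @param cohort A `cohort` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(cohort, path) {
  log <- cohort_filters(cohort)
  jsonlite::write_json(
    lapply(seq_len(nrow(log)), function(i) list(
      filter_name = log$filter[i], removed = log$removed[i],
      retained = log$retained[i])),
    path, auto_unbox = TRUE)
  invisible(path)
}
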