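# Substance-use facet composites, impulsivity total and demographic encoding.

#' Load a facet composite specification
#'
#' Reads the YAML file mapping each facet (intent, access, fdhx) to its item
#' lists at baseline and year 2, the winsorization multiplier and the
#' impulsivity item list. The shipped spec uses the synthetic item names the
#' cohort generator emits; point `path` at an edited copy to use real item
#' names.
#'
#' @param path YAML file; default is the spec shipped with the package.
#' @return An object of class `composite_spec`.
#' @export
load_composite_spec <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "composite_spec.yaml", package = "neurocpm")
  spec <- yaml::read_yaml(path)
  for (facet in names(spec$facets)) {
    f <- spec$facets[[facet]]
    if (length(f$baseline_items) == 0L || length(f$year2_items) == 0L)
      stop("facet '", facet, "' has an empty item list")
    if (!all(f$year2_items %in% f$baseline_items))
      stop("facet '", facet, "': year2 items must be a subset of baseline items")
  }
  if (is.null(spec$winsor_z)) spec$winsor_z <- 3.5
  structure(spec, class = "composite_spec")
}

#' Items for a facet at a timepoint
#' @param spec a `composite_spec`.
#' @param facet facet name.
#' @param timepoint `"baseline"` or `"year2"`.
#' @return character vector of item names.
#' @export
facet_items <- function(spec, facet, timepoint = c("baseline", "year2")) {
  timepoint <- match.arg(timepoint)
  f <- spec$facets[[facet]]
  if (is.null(f)) stop("unknown facet: ", facet)
  if (timepoint == "baseline") f$baseline_items else f$year2_items
}

#' Facet composite score
#'
#' Per-subject mean over the facet's items at the given timepoint. Missing
#' responses are dropped from the mean by default (`na_rm = TRUE`); a subject
#' missing every item gets a missing score. Set `na_rm = FALSE` for
#' complete-case scoring.
#'
#' @param items data frame with a `subject` column and item columns.
#' @param spec a `composite_spec`.
#' @param facet facet name.
#' @param timepoint `"baseline"` or `"year2"`.
#' @param na_rm drop missing items from the mean (default) or require all.
#' @return An object of class `phenotype_vector` (fields `subject`, `score`,
#'   `facet`, `timepoint`, `winsorized`).
#' @export
compute_composite <- function(items, spec, facet,
                              timepoint = c("baseline", "year2"),
                              na_rm = TRUE) {
  timepoint <- match.arg(timepoint)
  cols <- facet_items(spec, facet, timepoint)
  missing_cols <- setdiff(cols, names(items))
  if (length(missing_cols) > 0L)
    stop("item table is missing: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(items[, cols, drop = FALSE])
  score <- rowMeans(m, na.rm = na_rm)
  score[is.nan(score)] <- NA_real_
  phenotype_vector(items$subject, score, facet, timepoint)
}

#' Phenotype vector container
#' @param subject subject ids.
#' @param score numeric scores (may contain NA).
#' @param facet facet name.
#' @param timepoint `"baseline"` or `"year2"`.
#' @param winsorized logical flag.
#' @return An object of class `phenotype_vector`.
#' @export
phenotype_vector <- function(subject, score, facet, timepoint,
                             winsorized = FALSE) {
  if (length(subject) != length(score)) stop("one score per subject")
  structure(list(subject = as.character(subject), score = as.numeric(score),
                 facet = facet, timepoint = timepoint,
                 winsorized = winsorized),
            class = "phenotype_vector")
}

#' Winsorize scores at mean +/- z standard deviations
#'
#' The mean and SD are computed once on the non-missing input scores; values
#' outside mean +/- z*SD are clamped to the bound (single pass, no
#' re-estimation). With fewer than 2 non-missing scores or zero SD the vector
#' passes through unchanged.
#'
#' @param scores a `phenotype_vector` (or numeric vector).
#' @param z SD multiplier (default 3.5).
#' @return the winsorized object (flag set for `phenotype_vector` input).
#' @export
winsorize <- function(scores, z = 3.5) {
  is_pv <- inherits(scores, "phenotype_vector")
  x <- if (is_pv) scores$score else as.numeric(scores)
  ok <- !is.na(x)
  if (sum(ok) >= 2L) {
    m <- mean(x[ok]); s <- sd(x[ok])
    if (s > 0) x <- pmin(pmax(x, m - z * s), m + z * s)
  }
  if (is_pv) {
    scores$score <- x
    scores$winsorized <- TRUE
    scores
  } else x
}

#' Impulsivity total score
#'
#' Sums the 20 impulsivity items (responses 1-4), giving a total in [20, 80];
#' higher scores mean more impulsivity.
#'
#' @param items data frame with a `subject` column and the 20 impulsivity item
#'   columns named in `spec`.
#' @param spec a `composite_spec` (supplies `upps_items`).
#' @param timepoint label attached to the result.
#' @return a `phenotype_vector`.
#' @export
upps_total <- function(items, spec = load_composite_spec(),
                       timepoint = c("baseline", "year2")) {
  timepoint <- match.arg(timepoint)
  cols <- spec$upps_items
  missing_cols <- setdiff(cols, names(items))
  if (length(missing_cols) > 0L)
    stop("item table is missing: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(items[, cols, drop = FALSE])
  bad <- m[!is.na(m)]
  if (any(bad < 1 | bad > 4 | bad != round(bad)))
    stop("impulsivity responses must be integers in 1..4")
  phenotype_vector(items$subject, rowSums(m), "upps", timepoint)
}

# the fixed race category set (one-hot encoded, in this order)
.race_categories <- c(
  "alaskan_native", "asian", "black", "chinese", "filipino", "guamanian",
  "hawaiian_native", "indian", "japanese", "korean", "native_american",
  "samoan", "vietnamese", "white", "other_asian", "other_pacific_islander",
  "other_race")

#' Demographic covariate column names
#' @return character vector: the deterministic covariate column set, in order.
#' @export
covariate_columns <- function() {
  c("sex_female", "ethnicity_hispanic", paste0("race_", .race_categories),
    "race_dont_know", "race_refused", "multiracial",
    "household_income", "parental_education")
}

#' Encode raw demographics as model covariates
#'
#' Deterministic encoding: sex and ethnicity binary coded; race as one-hot
#' indicators over the fixed category set plus don't-know / refused
#' indicators; a multiracial indicator set when more than one race category is
#' selected; household income and parental education carried through as
#' ordinal scores. The raw table's `race` field is a semicolon-separated list
#' of category codes, or `dont_know` / `refused`.
#'
#' @param demo data frame with columns `subject`, `sex` ("male"/"female"),
#'   `ethnicity` ("hispanic"/"not_hispanic"), `race`, `household_income`,
#'   `parental_education`.
#' @return An object of class `covariate_matrix`: fields `subject` and
#'   `values` (subjects x covariates numeric matrix with the columns of
#'   [covariate_columns()]).
#' @export
encode_demographics <- function(demo) {
  req <- c("subject", "sex", "ethnicity", "race", "household_income",
           "parental_education")
  missing_cols <- setdiff(req, names(demo))
  if (length(missing_cols) > 0L)
    stop("demographic table is missing: ", paste(missing_cols, collapse = ", "))
  n <- nrow(demo)
  bad_sex <- setdiff(unique(demo$sex), c("male", "female"))
  if (length(bad_sex) > 0L)
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_eth <- setdiff(unique(demo$ethnicity), c("hispanic", "not_hispanic"))
  if (length(bad_eth) > 0L)
    stop("unknown ethnicity value(s): ", paste(bad_eth, collapse = ", "))

  cols <- covariate_columns()
  m <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  m[, "sex_female"] <- as.numeric(demo$sex == "female")
  m[, "ethnicity_hispanic"] <- as.numeric(demo$ethnicity == "hispanic")
  race_sets <- strsplit(as.character(demo$race), ";", fixed = TRUE)
  for (i in seq_len(n)) {
    sel <- trimws(race_sets[[i]])
    if (identical(sel, "dont_know")) { m[i, "race_dont_know"] <- 1; next }
    if (identical(sel, "refused")) { m[i, "race_refused"] <- 1; next }
    unknown <- setdiff(sel, .race_categories)
    if (length(unknown) > 0L)
      stop("unknown race category value(s): ", paste(unknown, collapse = ", "))
    m[i, paste0("race_", sel)] <- 1
    if (length(sel) > 1L) m[i, "multiracial"] <- 1
  }
  m[, "household_income"] <- as.numeric(demo$household_income)
  m[, "parental_education"] <- as.numeric(demo$parental_education)
  if (!all(is.finite(m))) stop("covariates contain non-finite values")
  structure(list(subject = as.character(demo$subject), values = m),
            class = "covariate_matrix")
}

#' Write phenotype vectors as CSV
#' @param pvs list of `phenotype_vector` objects (or a single one).
#' @param path output CSV path.
#' @export
write_phenotypes <- function(pvs, path) {
  if (inherits(pvs, "phenotype_vector")) pvs <- list(pvs)
  rows <- do.call(rbind, lapply(pvs, function(p)
    data.frame(subject = p$subject, facet = p$facet, timepoint = p$timepoint,
               score = p$score, winsorized = p$winsorized)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
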