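#' Define a survey variable
#'
#' A variable specification records how one survey column is coded: its
#' role in the analysis (capital factor, violence outcome, or raw
#' questionnaire item), its measurement level, and — for ordered and
#' categorical variables — the ordered category labels. Likert items may be
#' flagged as reverse coded (egalitarian wording), in which case scale
#' scoring maps responses x to 6 - x.
#'
#' @param name Column identifier (unique within a codebook).
#' @param role One of `"factor"`, `"outcome"`, `"item"`.
#' @param level One of `"binary"`, `"ordinal"`, `"likert"`, `"categorical"`.
#' @param categories Ordered character vector of category labels. Binary
#'   variables must have exactly 2 (coded no/yes as 1/2); likert items have
#'   the five agreement levels and may omit this argument.
#' @param reverse_coded Logical; only meaningful for likert items.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, role, level, categories = NULL,
                          reverse_coded = FALSE) {
  role <- match.arg(role, c("factor", "outcome", "item"))
  level <- match.arg(level, c("binary", "ordinal", "likert", "categorical"))
  if (level == "likert" && is.null(categories)) {
    categories <- c("strongly disagree", "disagree", "indifferent",
                    "agree", "strongly agree")
  }
  if (level == "binary" && is.null(categories)) categories <- c("no", "yes")
  if (!is.character(categories) || length(categories) < 2)
    stop("'categories' must list at least 2 ordered labels", call. = FALSE)
  if (level == "binary" && length(categories) != 2L)
    stop("binary variable '", name, "' must have exactly 2 categories",
         call. = FALSE)
  if (level == "likert" && length(categories) != 5L)
    stop("likert item '", name, "' must have 5 ordered categories",
         call. = FALSE)
  if (reverse_coded && level != "likert")
    stop("'reverse_coded' applies to likert items only", call. = FALSE)
  structure(list(name = as.character(name), role = role, level = level,
                 categories = categories,
                 reverse_coded = isTRUE(reverse_coded)),
            class = "variable_spec")
}

#' Assemble a codebook
#'
#' @param ... `variable_spec` objects.
#' @return A named list of class `codebook`.
#' @export
codebook <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "variable_spec"))
    specs <- specs[[1]]
  ok <- vapply(specs, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all entries must be variable_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names in codebook: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(specs) <- nms
  structure(specs, class = "codebook")
}

new_survey_table <- function(values, specs) {
  stopifnot(is.matrix(values), inherits(specs, "codebook"))
  structure(list(values = values, specs = specs, n = nrow(values)),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat("Survey table:", x$n, "respondents x", ncol(x$values), "variables\n")
  roles <- vapply(x$specs, `[[`, character(1), "role")
  cat("  roles:", paste(sprintf("%s=%d", names(table(roles)), table(roles)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Read a coded survey table
#'
#' Loads a delimited file of integer category codes (1-based, one column per
#' codebook variable, header row) and validates every cell against the
#' codebook. Empty cells and `NA` are treated as missing.
#'
#' @param path CSV file path.
#' @param codebook A [codebook()] describing every analysis column.
#' @return A `survey_table`: integer matrix (`NA` = missing) plus the codebook.
#' @export
read_survey <- function(path, codebook) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(names(codebook), names(raw))
  if (length(missing_cols))
    stop("codebook column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  vals <- matrix(NA_integer_, nrow(raw), length(codebook),
                 dimnames = list(NULL, names(codebook)))
  for (nm in names(codebook)) {
    col <- raw[[nm]]
    suppressWarnings(codes <- as.integer(col))
    bad_parse <- which(!is.na(col) & col != "" & is.na(codes))
    if (length(bad_parse))
      stop(sprintf("unparseable cell in column '%s', row %d: '%s'",
                   nm, bad_parse[1], col[bad_parse[1]]), call. = FALSE)
    k <- length(codebook[[nm]]$categories)
    bad_range <- which(!is.na(codes) & (codes < 1L | codes > k))
    if (length(bad_range))
      stop(sprintf(
        "out-of-range code in column '%s', row %d: %d (valid 1..%d)",
        nm, bad_range[1], codes[bad_range[1]], k), call. = FALSE)
    vals[, nm] <- codes
  }
  new_survey_table(vals, codebook)
}

#' Write a survey table as CSV
#'
#' Inverse of [read_survey()]; integer codes, missing written as empty cells.
#'
#' @param table A `survey_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  utils::write.csv(as.data.frame(table$values), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Lifetime-indicator construction from yes/no items
#'
#' Aggregates a sphere's yes/no violence items into a single binary
#' indicator: a respondent scores 1 if she answered yes to any listed item.
#' Respondents with no yes and at least one missing item get `NA` (they are
#' removed by listwise deletion before estimation); all-no gives 0.
#'
#' @param table A `survey_table`.
#' @param item_names Character vector of binary item columns.
#' @return Integer vector of 0/1/`NA`, length `table$n`.
#' @export
derive_outcome <- function(table, item_names) {
  stopifnot(inherits(table, "survey_table"))
  if (length(item_names) == 0L)
    stop("'item_names' must list at least one item", call. = FALSE)
  missing <- setdiff(item_names, colnames(table$values))
  if (length(missing))
    stop("unknown item(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (nm in item_names)
    if (table$specs[[nm]]$level != "binary")
      stop("item '", nm, "' is not binary", call. = FALSE)
  # codes: 1 = no, 2 = yes
  yes <- table$values[, item_names, drop = FALSE] == 2L
  any_yes <- apply(yes, 1L, function(r) any(r, na.rm = TRUE))
  any_na <- apply(yes, 1L, anyNA)
  out <- ifelse(any_yes, 1L, ifelse(any_na, NA_integer_, 0L))
  as.integer(out)
}

#' Score a Likert attitude scale
#'
#' Per-respondent mean of 5-point items after reverse-coding (x -> 6 - x)
#' the items listed in `reverse_items` (egalitarian wording, so that higher
#' scores always mean stronger endorsement of traditional stereotypes).
#' Respondents with every item missing get `NA`; otherwise the mean of the
#' available items is used.
#'
#' @param table A `survey_table`.
#' @param item_names The scale's likert items (13 in the motivating study).
#' @param reverse_items Subset of `item_names` to reverse-code. Defaults to
#'   the items flagged `reverse_coded` in the codebook.
#' @return Numeric vector in \[1, 5\] (or `NA`), length `table$n`.
#' @export
score_stereotypes <- function(table, item_names, reverse_items = NULL) {
  stopifnot(inherits(table, "survey_table"))
  missing <- setdiff(item_names, colnames(table$values))
  if (length(missing))
    stop("unknown item(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (nm in item_names)
    if (table$specs[[nm]]$level != "likert")
      stop("item '", nm, "' is not a 5-point likert item", call. = FALSE)
  if (is.null(reverse_items))
    reverse_items <- item_names[vapply(table$specs[item_names], `[[`,
                                       logical(1), "reverse_coded")]
  if (length(setdiff(reverse_items, item_names)))
    stop("'reverse_items' must be a subset of 'item_names'", call. = FALSE)
  x <- table$values[, item_names, drop = FALSE] * 1.0
  x[, intersect(reverse_items, colnames(x))] <-
    6 - x[, intersect(reverse_items, colnames(x))]
  score <- rowMeans(x, na.rm = TRUE)
  score[!is.finite(score)] <- NA_real_
  score
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `k/(k-1) * (1 - sum(item variances) / var(row totals))`.
#'
#' @param items Numeric matrix, respondents x items (k >= 2 columns).
#' @return Scalar alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L) stop("need at least 2 items", call. = FALSE)
  if (nrow(items) < 3L) stop("need at least 3 respondents", call. = FALSE)
  if (anyNA(items)) items <- items[stats::complete.cases(items), , drop = FALSE]
  total_var <- stats::var(rowSums(items))
  if (total_var <= .Machine$double.eps)
    stop("total score is constant; alpha undefined", call. = FALSE)
  item_var <- sum(apply(items, 2L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

median_split <- function(x) {
  # above the sample median -> 1, ties -> 0; when the median is the top
  # category (heavily skewed ordinals) nothing lies above it, so ties join
  # the 1 side instead ("at least the median level") to keep both classes
  # nonempty
  med <- stats::median(x, na.rm = TRUE)
  if (med >= max(x, na.rm = TRUE)) as.integer(x >= med)
  else as.integer(x > med)
}

new_binary_dataset <- function(values, roles) {
  stopifnot(is.matrix(values), length(roles) == ncol(values))
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("binary dataset cells must be 0/1 with no missing", call. = FALSE)
  structure(list(values = values, roles = roles,
                 names = colnames(values)), class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat("Binary dataset:", nrow(x$values), "x", ncol(x$values),
      sprintf("(%d factors, %d outcomes)\n",
              sum(x$roles == "factor"), sum(x$roles == "outcome")))
  invisible(x)
}

#' Dichotomize analysis variables for Ising estimation
#'
#' Converts a survey table (plus optional derived numeric scores) into the
#' 0/1 matrix the Ising estimator needs. Binary variables map no/yes to
#' 0/1; ordered, likert and numeric score variables are split at their
#' sample median (strictly above the median -> 1, ties -> 0; when the
#' median coincides with the top observed level — heavily skewed
#' variables — ties join the 1 side instead, so both classes stay
#' nonempty). Respondents
#' with any missing analysis value are removed (listwise deletion) and the
#' deletion count is reported via a message.
#'
#' @param table A `survey_table`; only columns with role `factor` or
#'   `outcome` are used (items enter through derived columns).
#' @param derived Optional named list of numeric/integer vectors (length
#'   `table$n`) of derived analysis variables, e.g. sphere indicators from
#'   [derive_outcome()] or the stereotype score from [score_stereotypes()].
#' @param derived_roles Named character vector giving the role
#'   (`"factor"`/`"outcome"`) of each derived column; defaults to
#'   `"factor"` for numeric and `"outcome"` for integer 0/1 vectors.
#' @param quiet Suppress the deletion-count message.
#' @return A `binary_dataset` (all columns 0/1, no missing).
#' @export
binarize <- function(table, derived = NULL, derived_roles = NULL,
                     quiet = FALSE) {
  stopifnot(inherits(table, "survey_table"))
  keep <- names(table$specs)[vapply(table$specs, function(s)
    s$role %in% c("factor", "outcome"), logical(1))]
  cols <- list()
  roles <- character(0)
  for (nm in keep) {
    spec <- table$specs[[nm]]
    x <- table$values[, nm]
    cols[[nm]] <- if (spec$level == "binary") x - 1L else {
      b <- median_split(x)
      b[is.na(x)] <- NA_integer_
      b
    }
    roles[nm] <- spec$role
  }
  for (nm in names(derived)) {
    x <- derived[[nm]]
    if (length(x) != table$n)
      stop("derived column '", nm, "' has wrong length", call. = FALSE)
    already01 <- all(x %in% c(0L, 1L, NA))
    cols[[nm]] <- if (already01) as.integer(x) else {
      b <- median_split(x)
      b[is.na(x)] <- NA_integer_
      b
    }
    roles[nm] <- if (!is.null(derived_roles) && nm %in% names(derived_roles))
      derived_roles[[nm]] else if (already01) "outcome" else "factor"
  }
  m <- do.call(cbind, cols)
  complete <- stats::complete.cases(m)
  dropped <- sum(!complete)
  if (dropped && !quiet)
    message("binarize: dropped ", dropped,
            " respondent(s) with missing analysis values")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete respondents left", call. = FALSE)
  const <- colnames(m)[apply(m, 2L, function(c) length(unique(c)) < 2L)]
  if (length(const))
    stop("column(s) constant after binarization: ",
         paste(const, collapse = ", "), call. = FALSE)
  new_binary_dataset(m, roles)
}
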