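#' Extract a bone-age class from radiology report text
#'
#' Locates a bone-age statement via the keywords `"bone age"` or
#' `"skeletal"`, resolves ranges (`"13 to 14"`, `"13-14"`, en dashes) to
#' their arithmetic mean, and floors away sub-year precision. The mean is
#' computed in months before flooring, so `"13 to 14 years"` gives 13.
#' `"skeletally mature"` reports (and any parsed age above 18) map to 18.
#'
#' @param report_text character scalar with the report snippet.
#' @return integer bone-age class in 5..18.
#'
#' @section Errors:
#' * `baa_unparseable_report` when no keyword or no age statement is found,
#'   or the report carries multiple conflicting bone-age statements;
#' * `baa_out_of_cohort` when the parsed age is below 5 years (the 0-4 year
#'   bracket is excluded from the cohort).
#' @export
parse_bone_age <- function(report_text) {
  stopifnot(is.character(report_text), length(report_text) == 1L)
  txt <- tolower(report_text)
  if (!grepl("bone age|skeletal", txt))
    baa_stop("baa_unparseable_report",
             "no bone-age keyword ('bone age' or 'skeletal') found")
  if (grepl("skeletally\\s+mature", txt)) return(18L)

  num <- "([0-9]+(?:\\.[0-9]+)?)"
  # months-qualified forms first: "X years[,] [and] Y months"
  ym <- regmatches(txt, gregexpr(
    paste0(num, "\\s*years?[,]?(?:\\s*and)?\\s*", num, "\\s*months?"), txt,
    perl = TRUE))[[1]]
  rng <- regmatches(txt, gregexpr(
    paste0(num, "\\s*(?:to|-|–|—)\\s*", num, "\\s*years?"), txt,
    perl = TRUE))[[1]]
  single <- regmatches(txt, gregexpr(
    paste0(num, "\\s*years?"), txt, perl = TRUE))[[1]]
  grab <- function(s) as.numeric(regmatches(s, gregexpr(num, s, perl = TRUE))[[1]])

  months <- numeric(0)
  if (length(ym)) months <- c(months, vapply(ym, function(s) {
    v <- grab(s); v[1] * 12 + v[2]
  }, numeric(1)))
  if (length(rng)) months <- c(months, vapply(rng, function(s) {
    v <- grab(s); mean(v[1:2]) * 12
  }, numeric(1)))
  if (!length(months) && length(single)) {
    # plain "N years", but not ones already consumed by a range
    months <- vapply(single, function(s) grab(s)[1] * 12, numeric(1))
  }
  if (!length(months))
    baa_stop("baa_unparseable_report", "no bone-age value found in report")
  months <- unique(months)
  if (length(months) > 1L)
    baa_stop("baa_unparseable_report",
             "report contains conflicting bone-age statements")
  years <- floor(months / 12)
  if (years > 18) years <- 18
  if (years < 5)
    baa_stop("baa_out_of_cohort",
             sprintf("bone age %d is below the 5-18 year cohort", years))
  as.integer(years)
}

#' Split study ids into train/validation/test sets (70/15/15)
#'
#' A simple random split: 15% of ids (rounded) go to validation, 15% to
#' test, the remainder to training. The same seed always reproduces the
#' same split so repeated experiments compare like with like.
#'
#' @param ids character or integer vector of unique study ids.
#' @param seed integer seed driving the shuffle.
#' @param stratify_by optional factor of the same length as `ids`; when
#'   given, the 70/15/15 proportions are applied within each stratum
#'   (off by default, as the cohort split is simple random).
#' @return an object of class `dataset_split` with `train_ids`,
#'   `validation_ids`, `test_ids` and `seed`.
#' @export
split_dataset <- function(ids, seed, stratify_by = NULL) {
  ids <- unique(ids)
  n <- length(ids)
  if (n < 3L)
    baa_stop("baa_insufficient_data", "need at least 3 ids to split 70/15/15")
  if (is.null(stratify_by)) {
    sh <- with_seed(seed, sample(ids))
    n_val <- round(0.15 * n)
    n_test <- round(0.15 * n)
    out <- list(train_ids = sh[seq_len(n - n_val - n_test)],
                validation_ids = sh[n - n_val - n_test + seq_len(n_val)],
                test_ids = sh[n - n_test + seq_len(n_test)],
                seed = as.integer(seed))
  } else {
    stopifnot(length(stratify_by) == length(ids))
    parts <- split(ids, stratify_by)
    sub <- lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) < 3L) return(list(train_ids = p, validation_ids = character(0),
                                      test_ids = character(0)))
      split_dataset(p, seed + i)
    })
    out <- list(
      train_ids = unlist(lapply(sub, `[[`, "train_ids"), use.names = FALSE),
      validation_ids = unlist(lapply(sub, `[[`, "validation_ids"), use.names = FALSE),
      test_ids = unlist(lapply(sub, `[[`, "test_ids"), use.names = FALSE),
      seed = as.integer(seed))
  }
  structure(out, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d validation=%d test=%d (seed %d)\n",
              length(x$train_ids), length(x$validation_ids),
              length(x$test_ids), x$seed))
  invisible(x)
}

#' Write / read a dataset split as JSON
#' @param split a [split_dataset()] result.
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a `dataset_split` for the reader.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = x$train_ids, validation_ids = x$validation_ids,
                 test_ids = x$test_ids, seed = as.integer(x$seed)),
            class = "dataset_split")
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `id`, `path`, `sex`,
#' `chronological_age` and either `bone_age` or `report_text` (in which
#' case [parse_bone_age()] is applied; unparseable or out-of-cohort rows
#' are dropped with a warning).
#'
#' @param path CSV path.
#' @return data frame with an integer `bone_age` column.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "path", "sex")
  if (!all(req %in% names(m)))
    baa_stop("baa_format_error",
             sprintf("manifest must have columns %s", paste(req, collapse = ", ")))
  if (!"bone_age" %in% names(m)) {
    if (!"report_text" %in% names(m))
      baa_stop("baa_format_error", "manifest needs bone_age or report_text")
    age <- vapply(m$report_text, function(s) {
      tryCatch(parse_bone_age(s), baa_error = function(e) NA_integer_)
    }, integer(1), USE.NAMES = FALSE)
    if (anyNA(age))
      baa_warn("baa_dropped_rows",
               sprintf("dropping %d manifest rows with unusable reports",
                       sum(is.na(age))))
    m$bone_age <- age
    m <- m[!is.na(age), , drop = FALSE]
  }
  m
}
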