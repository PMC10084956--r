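#' Survey tables and codebooks
#'
#' A `survey_table` is the single data currency of the package: a data.frame
#' with one row per woman, factor columns for the categorical covariates, a
#' non-negative `weight` column, and (once assigned) `bmi`, `category` and
#' the binary `dbm` outcome. A codebook attribute records, per covariate,
#' the ordered level set and the reference level used for dummy coding.
#'
#' @param data data.frame with the covariate columns (coerced to factors with
#'   the codebook's level order), and optionally `weight`, `bmi`, `category`,
#'   `dbm`.
#' @param codebook named list, one entry per covariate:
#'   `list(levels = <character>, reference = <level>)`.
#' @return A `survey_table` (data.frame subclass) with the codebook attached.
#' @export
survey_table <- function(data, codebook) {
  stopifnot(is.data.frame(data), is.list(codebook), length(codebook) >= 1)
  if (is.null(names(codebook)) || any(names(codebook) == "")) {
    stop("codebook entries must be named by covariate", call. = FALSE)
  }
  for (v in names(codebook)) {
    cb <- codebook[[v]]
    if (!v %in% names(data)) stop(sprintf("covariate '%s' missing from data", v), call. = FALSE)
    if (length(cb$levels) < 2) stop(sprintf("covariate '%s' needs >= 2 levels", v), call. = FALSE)
    if (!cb$reference %in% cb$levels) {
      stop(sprintf("reference level '%s' not among levels of '%s'", cb$reference, v), call. = FALSE)
    }
    x <- as.character(data[[v]])
    bad <- !is.na(x) & !x %in% cb$levels
    if (any(bad)) {
      stop(sprintf("covariate '%s' has %d value(s) outside the codebook levels",
                   v, sum(bad)), call. = FALSE)
    }
    data[[v]] <- factor(x, levels = cb$levels)
  }
  if (is.null(data$weight)) data$weight <- rep(1, nrow(data))
  if (any(!is.finite(data$weight)) || any(data$weight < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  structure(data, codebook = codebook,
            class = c("survey_table", "data.frame"))
}

#' @export
print.survey_table <- function(x, ...) {
  cb <- attr(x, "codebook")
  cat(sprintf("<survey_table> %d rows, %d covariates (%s)\n",
              nrow(x), length(cb), paste(names(cb), collapse = ", ")))
  extra <- intersect(c("bmi", "category", "dbm"), names(x))
  if (length(extra)) cat("assigned columns:", paste(extra, collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

survey_codebook <- function(table) {
  cb <- attr(table, "codebook")
  if (is.null(cb)) stop("not a survey_table: codebook attribute missing", call. = FALSE)
  cb
}

#' Write a survey table as CSV with a sidecar YAML codebook
#'
#' @param table a `survey_table`.
#' @param path CSV path.
#' @param codebook_path YAML path (default: `path` with a `.codebook.yaml`
#'   suffix).
#' @return Invisibly, the two paths.
#' @export
write_survey_csv <- function(table, path,
                             codebook_path = paste0(sub("\\.csv$", "", path), ".codebook.yaml")) {
  cb <- survey_codebook(table)
  out <- as.data.frame(table)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(
    variables = lapply(cb, function(e) list(levels = as.list(e$levels),
                                            reference = e$reference,
                                            role = "covariate")),
    weight = "weight"
  )
  yaml::write_yaml(meta, codebook_path)
  invisible(c(path, codebook_path))
}

#' Read a survey table from CSV + YAML codebook
#'
#' Rows with a missing analysis variable or a level outside the codebook are
#' dropped (complete-case behaviour) and the dropped counts are reported via
#' `message()`. A missing weight column is replaced by unit weights with a
#' warning.
#'
#' @param path CSV path.
#' @param codebook_path YAML codebook path.
#' @return A validated `survey_table`.
#' @export
read_survey_csv <- function(path,
                            codebook_path = paste0(sub("\\.csv$", "", path), ".codebook.yaml")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!file.exists(codebook_path)) stop(sprintf("codebook not found: %s", codebook_path), call. = FALSE)
  meta <- yaml::read_yaml(codebook_path)
  if (is.null(meta$variables) || !length(meta$variables)) {
    stop(sprintf("malformed codebook '%s': no variables block", codebook_path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cb <- lapply(meta$variables, function(e) {
    if (is.null(e$levels) || is.null(e$reference)) {
      stop("malformed codebook: each variable needs levels and a reference", call. = FALSE)
    }
    list(levels = unlist(e$levels), reference = e$reference)
  })
  for (v in names(cb)) {
    if (!v %in% names(raw)) stop(sprintf("variable '%s' declared in codebook but absent from CSV", v), call. = FALSE)
  }
  wcol <- if (!is.null(meta$weight)) meta$weight else "weight"
  if (!wcol %in% names(raw)) {
    warning("weight column absent; using unit weights", call. = FALSE)
    raw$weight <- 1
  } else if (wcol != "weight") {
    raw$weight <- raw[[wcol]]
  }
  keep <- rep(TRUE, nrow(raw))
  n_missing <- 0L; n_unknown <- 0L
  for (v in names(cb)) {
    x <- as.character(raw[[v]])
    miss <- is.na(x) | x == ""
    unk <- !miss & !x %in% cb[[v]]$levels
    n_missing <- n_missing + sum(miss & keep)
    n_unknown <- n_unknown + sum(unk & keep)
    keep <- keep & !miss & !unk
  }
  if (n_missing + n_unknown > 0) {
    message(sprintf("dropped %d row(s): %d missing, %d outside codebook levels",
                    sum(!keep), n_missing, n_unknown))
  }
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out$category)) {
    out$category <- factor(out$category,
                           levels = c("underweight", "normal", "overweight", "obese"))
  }
  if (!is.null(out$dbm)) out$dbm <- as.integer(out$dbm)
  survey_table(out, cb)
}
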