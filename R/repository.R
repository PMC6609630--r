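## Repository of study-level DMET protein-abundance records: schema, readers,
## writers, the inclusion filter, and the study-set container consumed by
## dmet_meta().

#' Column dictionary of the abundance repository
#'
#' The flat-file schema used for literature abundance records. One row is one
#' observation of one protein in one tissue from one publication.
#'
#' @return Character vector of column names, in canonical order.
#' @export
repository_columns <- function() {
  c("protein_name", "gene_name", "uniprot_id", "tissue", "matrix",
    "stat_kind", "value", "value_sd", "range_min", "range_max",
    "value_cv_pct", "unit", "n_donors", "pooled", "method", "quant_mode",
    "age", "sex", "ethnicity", "genotype", "disease", "source", "year")
}

.tissue_levels <- c("liver", "intestine", "kidney", "brain", "lung", "other")
.matrix_levels <- c("microsomes", "homogenate", "S9", "membrane", "other")
.method_levels <- c("LC-MS/MS", "Western blot", "ELISA", "LC-MS global",
                    "mRNA", "activity", "other")
.numeric_cols  <- c("value", "value_sd", "range_min", "range_max",
                    "value_cv_pct", "n_donors", "year")

#' Canonical-unit scale factor
#'
#' The canonical abundance unit is pmol per mg of microsomal protein. Units
#' that differ from it by a power of ten (fmol/ug, pmol/ug, fmol/mg) are
#' accepted and rescaled; anything else is flagged non-canonical and returns
#' `NA`. The unit string on a record is always preserved verbatim; the flag is
#' derived, never written back.
#'
#' @param unit Character vector of unit strings.
#' @return Numeric vector: multiplier taking `value` to pmol/mg, or `NA` for
#'   non-canonical units.
#' @export
unit_scale_factor <- function(unit) {
  u <- tolower(trimws(as.character(unit)))
  u <- gsub("µ", "u", u)                      # micro sign -> u
  u <- gsub("\\s*(microsomal)?\\s*protein\\s*$", "", u)
  u <- gsub("\\s+", "", u)
  factors <- c("pmol/mg" = 1, "fmol/ug" = 1, "pmol/ug" = 1000,
               "fmol/mg" = 1e-3)
  out <- unname(factors[u])
  out
}

#' @rdname unit_scale_factor
#' @export
is_canonical_unit <- function(unit) !is.na(unit_scale_factor(unit))

.parse_numeric <- function(x, col, rows) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", "NaN")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("malformed numeric cell in column '%s' at data row(s) %s",
                 col, paste(rows[bad], collapse = ", ")), call. = FALSE)
  out
}

.parse_logical <- function(x, col, rows) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!(x %in% c("true", "t", "1", "yes", "false", "f", "0", "no",
                          "", "na")))
  if (length(bad))
    stop(sprintf("malformed logical cell in column '%s' at data row(s) %s",
                 col, paste(rows[bad], collapse = ", ")), call. = FALSE)
  out
}

.coerce_enum <- function(x, levels, col) {
  x <- trimws(as.character(x))
  unknown <- !is.na(x) & !(x %in% levels)
  if (any(unknown)) {
    warning(sprintf("column '%s': %d value(s) outside {%s} recoded to 'other'",
                    col, sum(unknown), paste(levels, collapse = ", ")),
            call. = FALSE)
    x[unknown] <- "other"
  }
  x
}

#' Read an abundance repository file
#'
#' Reads a CSV/TSV (or, with the readxl package, an xlsx) export of the
#' abundance repository. Missing cells become `NA`, never zero. Original data
#' row numbers (header excluded) are kept in the `.row` attribute for error
#' reporting. Unknown tissue/matrix/method values load as `"other"` with a
#' warning; malformed numeric cells are a row-level error.
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"tsv"`, `"xlsx"`; inferred from the file
#'   extension when `NULL`.
#' @return A `data.frame` with the columns of [repository_columns()].
#' @export
read_abundance_repository <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot infer format from extension '", ext, "'",
                          call. = FALSE))
  }
  format <- match.arg(format, c("csv", "tsv", "xlsx"))
  raw <- switch(format,
    csv  = utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, comment.char = "#"),
    tsv  = utils::read.delim(path, colClasses = "character",
                             check.names = FALSE, comment.char = "#"),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package", call. = FALSE)
      as.data.frame(readxl::read_excel(path, sheet = 1,
                                       col_types = "text"),
                    stringsAsFactors = FALSE)
    })
  missing_cols <- setdiff(repository_columns(), names(raw))
  if (length(missing_cols))
    stop("repository header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[repository_columns()]
  rows <- seq_len(nrow(raw))
  for (col in .numeric_cols) raw[[col]] <- .parse_numeric(raw[[col]], col, rows)
  raw$pooled <- .parse_logical(raw$pooled, "pooled", rows)
  raw$tissue <- .coerce_enum(raw$tissue, .tissue_levels, "tissue")
  raw$matrix <- .coerce_enum(raw$matrix, .matrix_levels, "matrix")
  raw$method <- .coerce_enum(raw$method, .method_levels, "method")
  for (col in setdiff(names(raw), c(.numeric_cols, "pooled")))
    raw[[col]][!is.na(raw[[col]]) & trimws(raw[[col]]) == ""] <- NA_character_
  attr(raw, ".row") <- rows
  validate_records(raw)
  raw
}

#' Write an abundance repository file
#'
#' Inverse of [read_abundance_repository()]; round-trips all non-missing
#' fields (text verbatim, numerics at full precision).
#'
#' @param records Repository `data.frame`.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_abundance_repository <- function(records, path) {
  stopifnot(is.data.frame(records))
  records <- records[repository_columns()]
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     na = "", qmethod = "double")
  invisible(path)
}

#' Validate repository records
#'
#' Checks record invariants: non-negative abundance, at least one donor, and
#' consistency between a reported %CV and 100*SD/mean (tolerance 0.5
#' percentage points, allowing for rounded literature values). Violations are
#' errors for the hard invariants and warnings for the consistency check.
#'
#' @param records Repository `data.frame`.
#' @return `records`, invisibly.
#' @export
validate_records <- function(records) {
  rows <- attr(records, ".row")
  if (is.null(rows)) rows <- seq_len(nrow(records))
  bad <- which(!is.na(records$value) & records$value < 0)
  if (length(bad))
    stop("negative abundance value at data row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  bad <- which(!is.na(records$n_donors) &
                 (records$n_donors < 1 | records$n_donors %% 1 != 0))
  if (length(bad))
    stop("n_donors must be a positive integer at data row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  have <- !is.na(records$value_cv_pct) & !is.na(records$value_sd) &
    !is.na(records$value) & records$value > 0
  dev <- abs(records$value_cv_pct[have] -
               100 * records$value_sd[have] / records$value[have])
  if (any(dev > 0.5))
    warning("reported %CV disagrees with 100*SD/mean by > 0.5 at data row(s) ",
            paste(rows[have][dev > 0.5], collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Construct a study set
#'
#' A study set holds the per-study summaries for one protein in one tissue
#' entering meta-analysis: study mean `x` (pmol/mg), standard deviation `sd`
#' (may be `NA`), donor count `n`, and coefficient of variation `cv` as a
#' fraction (derived as `sd/x` when not supplied). Reported `cv` must agree
#' with `sd/x` to 0.5% relative where both exist.
#'
#' @param protein Protein name.
#' @param tissue Tissue name.
#' @param label Character vector of study labels ("FirstAuthor, year" or a
#'   citation key).
#' @param x Study mean abundances (positive).
#' @param sd Study SDs; `NA` allowed.
#' @param n Donor counts (positive integers).
#' @param cv Study CVs as fractions; derived from `sd/x` when `NA`.
#' @param stat_kind `"mean"` or `"median"` per study (medians are pooled like
#'   means; the flag preserves provenance).
#' @return An object of class `study_set` with elements `protein`, `tissue`,
#'   `data` (one row per study), `k` and `N`.
#' @export
study_set <- function(protein, tissue = "liver", label, x, sd = NA_real_,
                      n, cv = NA_real_, stat_kind = "mean") {
  k <- length(x)
  if (k < 1) stop("a study set needs at least one study", call. = FALSE)
  data <- data.frame(label = as.character(label),
                     x = as.numeric(x),
                     sd = rep_len(as.numeric(sd), k),
                     n = as.integer(n),
                     cv = rep_len(as.numeric(cv), k),
                     stat_kind = rep_len(as.character(stat_kind), k),
                     stringsAsFactors = FALSE)
  if (any(!is.finite(data$x) | data$x <= 0))
    stop("study means must be positive", call. = FALSE)
  if (any(data$n < 1)) stop("donor counts must be >= 1", call. = FALSE)
  if (any(!is.na(data$sd) & data$sd < 0))
    stop("study SDs must be non-negative", call. = FALSE)
  derived <- is.na(data$cv) & !is.na(data$sd)
  data$cv[derived] <- data$sd[derived] / data$x[derived]
  both <- !is.na(data$cv) & !is.na(data$sd) & !derived & data$sd > 0
  rel <- abs(data$cv[both] - data$sd[both] / data$x[both]) /
    (data$sd[both] / data$x[both])
  if (any(rel > 0.005))
    warning(sprintf("study CV disagrees with SD/mean by > 0.5%% for: %s",
                    paste(data$label[both][rel > 0.005], collapse = ", ")),
            call. = FALSE)
  structure(list(protein = protein, tissue = tissue, data = data,
                 k = k, N = sum(data$n)),
            class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("Study set: %s (%s), k = %d studies, N = %d donors\n",
              x$protein, x$tissue, x$k, x$N))
  print(x$data, row.names = FALSE)
  invisible(x)
}

## Inclusion-criteria labels, in the order records are attributed to them.
.exclusion_reasons <- c("pooled_sample", "non_microsomal_matrix",
                        "ineligible_method", "relative_quantification",
                        "non_canonical_unit", "nonpositive_value",
                        "single_source")

#' Filter repository records for meta-analysis
#'
#' Applies the inclusion criteria: (i) individual (non-pooled) donor samples
#' only; (ii) absolute quantification by LC-MS/MS or Western blot; (iii)
#' canonical abundance units (pmol/mg microsomal protein, or power-of-ten
#' rescalable variants, which are rescaled) in liver-microsome-style
#' matrices; (iv) at least two independent sources (distinct citation keys)
#' per protein/tissue group. Each excluded record is attributed to exactly
#' one criterion, the first it fails, so that retained plus per-criterion
#' counts account for every input record.
#'
#' Records with missing SD pass the filter; downstream estimators that need
#' SD exclude them individually.
#'
#' @param records Repository `data.frame` from [read_abundance_repository()].
#' @return A list of [study_set()] objects (class `dmet_study_sets`) with
#'   attributes `exclusions` (named counts, including `retained`) and
#'   `excluded_rows` (data.frame of row index and reason).
#' @export
filter_for_meta <- function(records) {
  n <- nrow(records)
  rows <- attr(records, ".row")
  if (is.null(rows)) rows <- seq_len(n)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  if (n > 0) {
    flag(is.na(records$pooled) | records$pooled, "pooled_sample")
    flag(is.na(records$matrix) | records$matrix != "microsomes",
         "non_microsomal_matrix")
    flag(is.na(records$method) |
           !(records$method %in% c("LC-MS/MS", "Western blot")),
         "ineligible_method")
    flag(is.na(records$quant_mode) | records$quant_mode != "absolute",
         "relative_quantification")
    flag(!is_canonical_unit(records$unit), "non_canonical_unit")
    flag(is.na(records$value) | records$value <= 0, "nonpositive_value")
    ## criterion iv: >= 2 distinct sources per (protein, tissue) group
    elig <- is.na(reason)
    grp <- paste(records$protein_name, records$tissue, sep = "\r")
    nsrc <- tapply(records$source[elig], grp[elig],
                   function(s) length(unique(s)))
    single <- names(nsrc)[nsrc < 2]
    flag(grp %in% single, "single_source")
  }
  keep <- is.na(reason)
  counts <- c(retained = sum(keep),
              vapply(.exclusion_reasons,
                     function(r) sum(reason == r, na.rm = TRUE), integer(1)))
  sets <- list()
  if (any(keep)) {
    kept <- records[keep, , drop = FALSE]
    kept_rows <- rows[keep]
    scale <- unit_scale_factor(kept$unit)
    grp <- paste(kept$protein_name, kept$tissue, sep = "\r")
    for (g in unique(grp)) {
      i <- grp == g
      d <- kept[i, , drop = FALSE]
      s <- scale[i]
      lab <- ifelse(is.na(d$year), d$source,
                    paste0(d$source, ", ", d$year))
      ss <- study_set(protein = d$protein_name[1], tissue = d$tissue[1],
                      label = lab,
                      x = d$value * s,
                      sd = d$value_sd * s,
                      n = d$n_donors,
                      cv = d$value_cv_pct / 100,
                      stat_kind = d$stat_kind)
      attr(ss, "rows") <- kept_rows[i]
      sets[[paste(d$protein_name[1], d$tissue[1], sep = "/")]] <- ss
    }
  }
  structure(sets, class = "dmet_study_sets",
            exclusions = counts,
            excluded_rows = data.frame(
              row = rows[!keep],
              reason = reason[!keep],
              stringsAsFactors = FALSE))
}

#' Exclusion report of a filter run
#'
#' @param sets Result of [filter_for_meta()].
#' @return List with `counts` (retained + per-criterion exclusions), `total`,
#'   and `excluded_rows`.
#' @export
exclusion_report <- function(sets) {
  counts <- attr(sets, "exclusions")
  list(counts = as.list(counts),
       total = sum(counts),
       excluded_rows = attr(sets, "excluded_rows"))
}

#' @export
print.dmet_study_sets <- function(x, ...) {
  cat(sprintf("%d study set(s) after filtering:\n", length(x)))
  for (s in x)
    cat(sprintf("  %s (%s): k = %d, N = %d\n", s$protein, s$tissue, s$k, s$N))
  ex <- attr(x, "exclusions")
  cat("Exclusions:", paste(sprintf("%s=%d", names(ex), ex), collapse = ", "),
      "\n")
  invisible(x)
}
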