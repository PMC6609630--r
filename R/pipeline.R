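## File-in / file-out pipeline wrappers composing the modules end to end.
## These back the command-line front-end in inst/scripts/dmetpool.R.

.provenance_header <- function(inputs, extra = character()) {
  hashes <- vapply(inputs, function(p)
    paste0(basename(p), ":", substr(tools::md5sum(p)[[1]], 1, 8)),
    character(1))
  c(sprintf("# dmetpool %s",
            as.character(utils::packageVersion("dmetpool"))),
    paste0("# inputs: ", paste(hashes, collapse = "; ")),
    if (length(extra)) paste0("# ", extra))
}

.write_csv_prov <- function(df, path, inputs, extra = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(.provenance_header(inputs, extra), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  close(con)
  file.rename(tmp, path)                    # atomic-ish publish
  invisible(path)
}

#' Run the meta-analysis pipeline on a repository file
#'
#' Reads the repository, applies the inclusion filter, fits [dmet_meta()] to
#' every retained protein/tissue group, and writes: a heterogeneity table, a
#' pooling table, per-protein forest-row CSVs, a JSON exclusion report and a
#' JSON dump of every fit. Output CSVs carry provenance header comments.
#'
#' @param input Path to the repository CSV/TSV/xlsx.
#' @param out_dir Output directory (created if needed).
#' @param z Confidence quantile (default 1.96).
#' @param format Passed to [read_abundance_repository()].
#' @return Invisibly, the list of fits.
#' @export
run_meta_pipeline <- function(input, out_dir, z = 1.96, format = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_abundance_repository(input, format)
  sets <- filter_for_meta(records)
  fits <- lapply(sets, dmet_meta, z = z)
  if (length(fits)) {
    .write_csv_prov(heterogeneity_table(fits),
                    file.path(out_dir, "heterogeneity.csv"), input,
                    sprintf("z = %g", z))
    .write_csv_prov(pooling_table(fits),
                    file.path(out_dir, "pooling.csv"), input,
                    sprintf("z = %g", z))
    for (f in fits)
      .write_csv_prov(f$forest,
                      file.path(out_dir,
                                sprintf("forest_%s_%s.csv",
                                        gsub("[^A-Za-z0-9]", "_", f$protein),
                                        f$tissue)),
                      input)
    jsonlite::write_json(lapply(fits, meta_as_list),
                         file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    warning("no eligible study sets after filtering; empty outputs written",
            call. = FALSE)
    .write_csv_prov(data.frame(), file.path(out_dir, "heterogeneity.csv"),
                    input)
    .write_csv_prov(data.frame(), file.path(out_dir, "pooling.csv"), input)
  }
  rep <- exclusion_report(sets)
  jsonlite::write_json(list(counts = rep$counts, total = rep$total,
                            excluded_rows = rep$excluded_rows),
                       file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in fits) {
    message(sprintf("%s (%s): k = %d, k_used = %d", f$protein, f$tissue,
                    f$k, if (is.null(f$fe)) 0L else f$fe$k_used))
  }
  invisible(fits)
}

#' Run the IVIVE pipeline from parameter files
#'
#' @param drug Path to the drug YAML/JSON.
#' @param physiology Path to the physiology YAML/JSON.
#' @param enzymes Path to the enzyme kinetics CSV.
#' @param out_dir Output directory.
#' @return Invisibly, the [ivive_fit()] object; writes `ivive.csv` (the
#'   per-enzyme sheet) and `ivive.json` (scalar chain included).
#' @export
run_ivive_pipeline <- function(drug, physiology, enzymes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- ivive_fit(read_drug_params(drug), read_physiology(physiology),
                   read_enzyme_table(enzymes))
  inputs <- c(drug, physiology, enzymes)
  .write_csv_prov(fit$enzymes, file.path(out_dir, "ivive.csv"), inputs)
  jsonlite::write_json(list(CL_R = fit$CL_R, CL_H = fit$CL_H,
                            CLu_int_H = fit$CLu_int_H,
                            enzymes = fit$enzymes),
                       file.path(out_dir, "ivive.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Run the population-scaling pipeline
#'
#' For each population file, derives the per-isoform scale factors and the
#' scaled parameter sheet (adjusted Vmax at the mean and, where the spec
#' carries CI bounds, at the low/high abundance bounds; scaled intrinsic and
#' renal clearances) from the adult IVIVE fit.
#'
#' @param drug,physiology,enzymes Paths, as in [run_ivive_pipeline()].
#' @param adult Path to the adult population YAML.
#' @param populations Character vector of population YAML paths.
#' @param out_dir Output directory.
#' @return Invisibly, a list of per-population sheets; writes
#'   `population_parameters.csv`.
#' @export
run_scaling_pipeline <- function(drug, physiology, enzymes, adult,
                                 populations, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- ivive_fit(read_drug_params(drug), read_physiology(physiology),
                   read_enzyme_table(enzymes))
  adult_spec <- read_population(adult)
  sheets <- list()
  for (p in populations) {
    spec <- read_population(p)
    bounds <- "mean"
    if (any(vapply(spec$enzyme_abundance,
                   function(a) !is.null(a$low), logical(1))))
      bounds <- c("mean", "low", "high")
    sheet <- do.call(rbind, lapply(bounds, function(b)
      population_sheet(fit, spec, adult_spec, bound = b)))
    sheet$CL_R_pop_Lh <- attr(population_sheet(fit, spec, adult_spec),
                              "CL_R_pop")
    sheets[[spec$label]] <- sheet
  }
  all <- do.call(rbind, sheets)
  .write_csv_prov(all, file.path(out_dir, "population_parameters.csv"),
                  c(drug, physiology, enzymes, adult, populations))
  invisible(sheets)
}

#' Path to a packaged example asset
#'
#' Convenience accessor for the parameter files shipped under
#' `inst/extdata/` (e.g. `"lamotrigine.yaml"`, `"adult_physiology.yaml"`,
#' `"enzymes_lamotrigine.csv"`, `"populations/adult.yaml"`).
#'
#' @param file Relative file name; empty lists the directory.
#' @return Absolute path.
#' @export
dmetpool_example <- function(file = "") {
  if (file == "")
    return(system.file("extdata", package = "dmetpool"))
  path <- system.file("extdata", file, package = "dmetpool")
  if (path == "") stop("no packaged asset called '", file, "'",
                       call. = FALSE)
  path
}
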