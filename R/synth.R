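## Synthetic study-level abundance data with known ground truth: lognormal
## inter-individual variability within a study, multiplied by a lognormal
## per-laboratory bias between studies. Lognormality matches the geometric
## CI construction used in pooling.

#' Synthetic study-set configuration
#'
#' @param true_gm True geometric mean abundance (pmol/mg) shared by all
#'   laboratories.
#' @param gcv_within Within-study geometric CV (fraction) of individual
#'   donors; default 0.25, the biological inter-individual component with
#'   laboratory effects modelled separately by `bias_sd_log`.
#' @param bias_sd_log SD of the per-study multiplicative laboratory bias on
#'   the natural-log scale; 0 means all laboratories measure without bias.
#' @param k Number of studies.
#' @param n_range Integer pair: min/max donors per study (min at least 2, so
#'   a sample SD exists).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(true_gm = 40, gcv_within = 0.25, bias_sd_log = 0,
                         k = 10, n_range = c(20, 30), seed = 1) {
  stopifnot(true_gm > 0, gcv_within >= 0, bias_sd_log >= 0, k >= 1,
            length(n_range) == 2, n_range[1] >= 2, n_range[2] >= n_range[1])
  structure(list(true_gm = true_gm, gcv_within = gcv_within,
                 bias_sd_log = bias_sd_log, k = as.integer(k),
                 n_range = as.integer(n_range), seed = as.integer(seed)),
            class = "synth_config")
}

## Per-study substream: the j-th study always sees the same draws regardless
## of k, so enlarging a simulated corpus never rewrites its early studies.
.study_seed <- function(seed, j) (seed + 7919L * j) %% .Machine$integer.max

#' Generate a synthetic study set
#'
#' For study j: a laboratory bias \eqn{b_j \sim lognormal(0, bias\_sd\_log)},
#' a donor count \eqn{n_j} uniform on `n_range`, and \eqn{n_j} individual
#' abundances \eqn{\sim lognormal(\ln(gm \cdot b_j), \sigma_w)} with
#' \eqn{\sigma_w = \sqrt{\ln(gcv^2 + 1)}}; the study reports its sample mean,
#' sample SD, n and CV.
#'
#' @param cfg A [synth_config()].
#' @param protein,tissue Labels for the resulting [study_set()].
#' @return A [study_set()] with attribute `truth`: the config plus the
#'   implied population quantities (`sigma_within`, arithmetic mean
#'   `arith_mean = gm * exp((sigma_w^2 + bias_sd^2)/2)`, and total CV
#'   `total_cv = sqrt(exp(sigma_w^2 + bias_sd^2) - 1)`).
#' @export
generate_study_set <- function(cfg, protein = "SYNTH", tissue = "liver") {
  stopifnot(inherits(cfg, "synth_config"))
  sw <- sqrt(log(cfg$gcv_within^2 + 1))
  x <- sd <- numeric(cfg$k)
  n <- integer(cfg$k)
  for (j in seq_len(cfg$k)) {
    set.seed(.study_seed(cfg$seed, j))
    b <- stats::rnorm(1, 0, cfg$bias_sd_log)
    n[j] <- if (cfg$n_range[1] == cfg$n_range[2]) cfg$n_range[1] else
      sample(cfg$n_range[1]:cfg$n_range[2], 1)
    y <- stats::rlnorm(n[j], log(cfg$true_gm) + b, sw)
    x[j] <- mean(y)
    sd[j] <- stats::sd(y)
  }
  ss <- study_set(protein, tissue,
                  label = sprintf("lab%02d, %d", seq_len(cfg$k),
                                  2000L + seq_len(cfg$k)),
                  x = x, sd = sd, n = n)
  s2 <- sw^2 + cfg$bias_sd_log^2
  attr(ss, "truth") <- c(unclass(cfg),
                         list(sigma_within = sw,
                              arith_mean = cfg$true_gm * exp(s2 / 2),
                              total_cv = sqrt(exp(s2) - 1)))
  ss
}

#' Generate a synthetic abundance repository with known exclusions
#'
#' Builds a repository data.frame in the flat-file schema
#' ([repository_columns()]) whose pass/fail pattern under [filter_for_meta()]
#' is known by construction: eligible LC-MS/MS records from at least two
#' sources per protein, plus controlled contamination (pooled-donor rows,
#' relative-quantification rows, mRNA rows) and optionally one
#' single-source protein.
#'
#' @param n_proteins Number of eligible proteins.
#' @param k_per_protein Eligible studies per protein (each from a distinct
#'   source).
#' @param contamination Named fractions (of the eligible record count) of
#'   `pooled`, `relative` and `mrna` rows to inject; must sum to at most 1.
#' @param single_source_protein Add one protein represented by a single
#'   source (excluded entirely by criterion iv)?
#' @param cfg Base [synth_config()] controlling the abundance draws; its
#'   seed also drives row placement.
#' @return A repository `data.frame` with attribute `expected_exclusions`
#'   (named counts mirroring the filter's exclusion report).
#' @export
generate_repository_fixture <- function(n_proteins = 2, k_per_protein = 4,
                                        contamination = c(pooled = 0,
                                                          relative = 0,
                                                          mrna = 0),
                                        single_source_protein = FALSE,
                                        cfg = synth_config()) {
  stopifnot(sum(contamination) <= 1)
  rows <- list()
  blank <- function(protein, src, yr, x, sd, n) {
    data.frame(protein_name = protein, gene_name = protein,
               uniprot_id = NA_character_, tissue = "liver",
               matrix = "microsomes", stat_kind = "mean",
               value = x, value_sd = sd, range_min = NA_real_,
               range_max = NA_real_, value_cv_pct = round(100 * sd / x, 1),
               unit = "pmol/mg microsomal protein", n_donors = n,
               pooled = FALSE, method = "LC-MS/MS", quant_mode = "absolute",
               age = NA_character_, sex = NA_character_,
               ethnicity = NA_character_, genotype = NA_character_,
               disease = NA_character_, source = src, year = yr,
               stringsAsFactors = FALSE)
  }
  for (p in seq_len(n_proteins)) {
    cfg_p <- synth_config(true_gm = cfg$true_gm * p,
                          gcv_within = cfg$gcv_within,
                          bias_sd_log = cfg$bias_sd_log,
                          k = k_per_protein, n_range = cfg$n_range,
                          seed = cfg$seed + 1000L * p)
    ss <- generate_study_set(cfg_p, protein = sprintf("PROT%02d", p))
    d <- ss$data
    for (j in seq_len(nrow(d)))
      rows[[length(rows) + 1L]] <-
        blank(ss$protein, sprintf("Src%02d_%02d", p, j), 2000L + j,
              d$x[j], d$sd[j], d$n[j])
  }
  n_elig <- length(rows)
  n_contam <- round(contamination * n_elig)
  set.seed(cfg$seed)
  for (i in seq_len(sum(n_contam))) {
    kind <- rep(names(n_contam), n_contam)[i]
    r <- blank("PROT01", sprintf("Contam%02d", i), 2010L,
               stats::rlnorm(1, log(cfg$true_gm), 0.3), cfg$true_gm * 0.2,
               10L)
    if (kind == "pooled") r$pooled <- TRUE
    if (kind == "relative") { r$quant_mode <- "relative"; r$unit <- "ratio" }
    if (kind == "mrna") r$method <- "mRNA"
    rows[[length(rows) + 1L]] <- r
  }
  n_single <- 0L
  if (single_source_protein) {
    for (j in 1:2)   # two records, one source: still fails criterion iv
      rows[[length(rows) + 1L]] <-
        blank("PROT_SINGLE", "LoneSrc", 2005L,
              cfg$true_gm, cfg$true_gm * 0.2, 12L)
    n_single <- 2L
  }
  out <- do.call(rbind, rows)
  attr(out, "expected_exclusions") <-
    c(retained = n_elig,
      pooled_sample = unname(n_contam["pooled"]),
      ineligible_method = unname(n_contam["mrna"]),
      relative_quantification = unname(n_contam["relative"]),
      single_source = n_single)
  out
}

#' Write a simulated repository plus ground-truth sidecar
#'
#' @param records Result of [generate_repository_fixture()].
#' @param path CSV output path; a `<path>.truth.json` sidecar records the
#'   expected exclusion counts.
#' @return `path`, invisibly.
#' @export
write_simulated_repository <- function(records, path) {
  write_abundance_repository(records, path)
  jsonlite::write_json(
    list(expected_exclusions =
           as.list(attr(records, "expected_exclusions"))),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
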