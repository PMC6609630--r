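## Scale factors turning adult mean PBPK parameters into variability bounds
## (CI-based Vmax adjustment) and special-population parameters (paediatric /
## hepatic-impairment abundance and MPPGL scaling, renal clearance scaling),
## plus the wide acceptance range used for model evaluation.

#' Inter-laboratory variability scale factor from a CI bound
#'
#' Ratio of a weighted confidence bound of the adult abundance to the adult
#' weighted mean: the lower bound gives SF < 1, the upper SF > 1.
#'
#' @param ci_bound Weighted lower or higher CI abundance (pmol/mg).
#' @param WM Weighted mean abundance (pmol/mg).
#' @return Positive scalar scale factor.
#' @export
sf_ci <- function(ci_bound, WM) {
  if (any(!is.finite(ci_bound)) || any(ci_bound <= 0) || !is.finite(WM) ||
      WM <= 0)
    stop("sf_ci needs positive CI bound and weighted mean", call. = FALSE)
  ci_bound / WM
}

#' Population scale factors for enzyme abundance and MPPGL
#'
#' \eqn{SF_{DME_j}} is the ratio of the population's (mean or CI-bound)
#' isoform abundance to the healthy-adult mean; \eqn{SF_{MPPGL}} the ratio of
#' mean MPPGL values. Distinct disease aetiologies (e.g. alcoholic versus
#' HCV cirrhosis) carry separate population specs and hence separate factors;
#' the provenance string of the result keeps them apart.
#'
#' @param pop,adult `population_spec` objects ([read_population()]).
#' @param enzyme Isoform name present in both specs.
#' @param bound `"mean"`, `"low"` or `"high"` — which population abundance
#'   statistic enters the numerator.
#' @return List of class `scale_factor_set` with `SF_DME`, `SF_MPPGL` and
#'   `provenance`.
#' @export
sf_population <- function(pop, adult, enzyme, bound = c("mean", "low", "high")) {
  bound <- match.arg(bound)
  for (spec in list(pop, adult))
    if (is.null(spec$enzyme_abundance[[enzyme]]))
      stop("enzyme '", enzyme, "' absent from population spec '",
           spec$label, "'", call. = FALSE)
  num <- pop$enzyme_abundance[[enzyme]][[bound]]
  den <- adult$enzyme_abundance[[enzyme]][["mean"]]
  if (is.null(num) || is.null(den) || !is.finite(num) || !is.finite(den) ||
      den <= 0)
    stop("missing or non-positive abundance for enzyme '", enzyme, "'",
         call. = FALSE)
  structure(list(SF_DME = num / den,
                 SF_MPPGL = pop$MPPGL / adult$MPPGL,
                 provenance = sprintf("%s %s (%s bound)", enzyme, pop$label,
                                      bound)),
            class = "scale_factor_set")
}

#' Adjust Vmax by scale factors
#'
#' Mode `"ci"` multiplies by the inter-laboratory variability factor
#' `SF_CI` only; mode `"population"` multiplies by
#' `SF_DME * SF_MPPGL`. All factors act multiplicatively, so `SF = 1` is the
#' identity and applying a factor then its reciprocal restores the input.
#'
#' @param Vmax Vmax (pmol/min/pmol), non-negative.
#' @param mode `"ci"` or `"population"`.
#' @param SF_CI CI-based factor (mode `"ci"`).
#' @param SF_DME,SF_MPPGL Population factors (mode `"population"`); a
#'   `scale_factor_set` can be passed as `SF_DME`.
#' @return Adjusted Vmax.
#' @export
adjust_vmax <- function(Vmax, mode = c("ci", "population"), SF_CI = 1,
                        SF_DME = 1, SF_MPPGL = 1) {
  mode <- match.arg(mode)
  stopifnot(all(Vmax >= 0))
  if (inherits(SF_DME, "scale_factor_set")) {
    SF_MPPGL <- SF_DME$SF_MPPGL
    SF_DME <- SF_DME$SF_DME
  }
  switch(mode,
         ci = Vmax * SF_CI,
         population = Vmax * SF_DME * SF_MPPGL)
}

#' Scaled intrinsic clearance from an adjusted Vmax
#'
#' Forward IVIVE: converts an (adjusted) Vmax back to a whole-liver unbound
#' intrinsic clearance using the population's MPPGL and liver weight,
#' \deqn{CLu_{int} = \frac{V_{max} \cdot abundance \cdot ISEF}{K_m \cdot fu_{mic}}
#'   \cdot MPPGL \cdot LW \cdot 60 \cdot 10^{-6}.}
#' Exact inverse of the [ivive_fit()] chain when all scale factors are 1.
#'
#' @param adjusted_Vmax Vmax (pmol/min/pmol), non-negative.
#' @param Km_uM Michaelis constant (uM), positive.
#' @param abundance Enzyme abundance (pmol/mg).
#' @param ISEF Inter-system extrapolation factor.
#' @param fu_mic Unbound fraction in microsomes.
#' @param MPPGL Population mg microsomal protein per g liver.
#' @param liver_weight_g Population liver weight (g).
#' @return Scaled unbound intrinsic clearance (L/h).
#' @export
scaled_cluint <- function(adjusted_Vmax, Km_uM, abundance, ISEF = 1,
                          fu_mic = 1, MPPGL, liver_weight_g) {
  stopifnot(all(adjusted_Vmax >= 0), all(Km_uM > 0), all(abundance >= 0),
            MPPGL > 0, liver_weight_g > 0)
  adjusted_Vmax * abundance * ISEF / (Km_uM * fu_mic) *
    MPPGL * liver_weight_g * .lh_per_ulminmg
}

#' Scale renal clearance to a population
#'
#' \deqn{CL_{R,pop} = SF_{fu \times GFR} \cdot CL_R}, with
#' \deqn{SF_{fu \times GFR} = \frac{fu_{pop} \cdot GFR_{pop}}
#'   {fu_{adult} \cdot GFR_{adult}}.}
#' When `population_spec` objects are given, their GFR unit tags must match.
#'
#' @param CL_R_adult Adult renal plasma clearance (L/h).
#' @param pop,adult Either `population_spec` objects or lists with `fu_p`,
#'   `GFR` (and `GFR_unit`).
#' @return Scaled renal clearance, with attribute `SF_fu_GFR`.
#' @export
scale_clr <- function(CL_R_adult, pop, adult) {
  stopifnot(CL_R_adult >= 0)
  for (spec in list(pop, adult))
    if (is.null(spec$fu_p) || is.null(spec$GFR))
      stop("population spec '", spec$label %||% "?",
           "' lacks fu_p or GFR (no silent defaults)", call. = FALSE)
  u1 <- pop$GFR_unit %||% "mL/min"
  u2 <- adult$GFR_unit %||% "mL/min"
  if (!identical(u1, u2))
    stop("GFR unit mismatch: '", u1, "' vs '", u2, "'", call. = FALSE)
  den <- adult$fu_p * adult$GFR
  if (den <= 0) stop("adult fu_p * GFR must be positive", call. = FALSE)
  sf <- pop$fu_p * pop$GFR / den
  structure(sf * CL_R_adult, SF_fu_GFR = sf)
}

#' Model-evaluation acceptance range
#'
#' The wide (99.998%) geometric interval around an observed clinical mean,
#' i.e. [geometric_ci()] evaluated with `z = 4.26`: a predicted exposure
#' parameter falling inside it is considered acceptable. With a missing %CV
#' the range is undefined and both bounds are `NA`.
#'
#' @param observed_mean Observed clinical mean (e.g. Cmax or AUC), positive.
#' @param cv_pct Observed percent CV; `NA` allowed.
#' @param k Number of subjects in the clinical study.
#' @param z Standard-normal quantile; default 4.26.
#' @return Named vector `c(low, high)` (both `NA` when `cv_pct` is `NA`).
#' @export
acceptance_range <- function(observed_mean, cv_pct, k, z = 4.26) {
  geometric_ci(observed_mean, cv_pct, k, z)
}

#' Read a population specification (YAML/JSON)
#'
#' Fields: `label`, `age_years`, `weight_kg`, `liver_weight_g`, `MPPGL`,
#' `GFR` with `GFR_unit`, `fu_p`, and `enzyme_abundance` (per isoform:
#' `mean`, optional `low`/`high`), plus a free-form `provenance`. `fu_p` and
#' `GFR` have no defaults: population files must state them explicitly.
#'
#' @param path Path to the YAML/JSON file.
#' @return Object of class `population_spec`.
#' @export
read_population <- function(path) {
  p <- .read_structured(path)
  need <- c("label", "liver_weight_g", "MPPGL")
  miss <- need[!vapply(need, function(f) !is.null(p[[f]]), logical(1))]
  if (length(miss))
    stop("population spec missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(p$liver_weight_g > 0, p$MPPGL > 0)
  for (e in names(p$enzyme_abundance)) {
    a <- p$enzyme_abundance[[e]]
    if (is.null(a$mean))
      stop("enzyme_abundance entry '", e, "' lacks a mean", call. = FALSE)
    lo <- a$low %||% a$mean; hi <- a$high %||% a$mean
    if (!(lo <= a$mean && a$mean <= hi))
      stop("enzyme_abundance bounds out of order for '", e, "'",
           call. = FALSE)
  }
  class(p) <- "population_spec"
  p
}

#' Population parameter sheet
#'
#' Combines an adult IVIVE fit with a population spec: per-isoform adjusted
#' Vmax (`SF_DME * SF_MPPGL`), scaled intrinsic clearance using the
#' population liver weight and MPPGL, and the scaled renal clearance.
#'
#' @param fit A [ivive_fit()] result (adult parameters).
#' @param pop,adult `population_spec` objects.
#' @param bound Abundance statistic for `SF_DME` (`"mean"`, `"low"`,
#'   `"high"`).
#' @return A `data.frame`, one row per isoform, with attributes `CL_R_pop`
#'   and `SF_fu_GFR`.
#' @export
population_sheet <- function(fit, pop, adult, bound = "mean") {
  stopifnot(inherits(fit, "dmet_ivive"))
  enz <- fit$enzymes
  covered <- enz$enzyme %in% names(pop$enzyme_abundance)
  if (!any(covered))
    stop("population spec '", pop$label, "' covers none of the fitted ",
         "isoforms", call. = FALSE)
  enz <- enz[covered, , drop = FALSE]
  rows <- lapply(seq_len(nrow(enz)), function(i) {
    sf <- sf_population(pop, adult, enz$enzyme[i], bound)
    vmax_adj <- adjust_vmax(enz$Vmax_pmol_min_pmol[i], "population",
                            SF_DME = sf)
    clu <- scaled_cluint(vmax_adj, enz$Km_uM[i],
                         enz$abundance_pmol_per_mg[i], enz$ISEF[i],
                         fit$drug$fu_mic, pop$MPPGL, pop$liver_weight_g)
    data.frame(enzyme = enz$enzyme[i], population = pop$label,
               bound = bound, SF_DME = sf$SF_DME, SF_MPPGL = sf$SF_MPPGL,
               adjusted_Vmax_pmol_min_pmol = vmax_adj,
               scaled_CLu_int_Lh = clu,
               provenance = sf$provenance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  clr <- scale_clr(fit$CL_R, pop, adult)
  attr(out, "CL_R_pop") <- as.numeric(clr)
  attr(out, "SF_fu_GFR") <- attr(clr, "SF_fu_GFR")
  out
}
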