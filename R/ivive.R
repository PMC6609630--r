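## Well-stirred-liver IVIVE chain: back-calculation of unbound intrinsic
## hepatic clearance from systemic clearance, partition across enzyme
## isoforms, conversion to microsomal in vitro CLint, and Vmax derivation.

## L/h -> uL/min per mg microsomal protein conversion used exactly once in
## the CLint path (and its inverse in the scaled forward path).
.lh_per_ulminmg <- 60 * 1e-6

#' Back-calculate unbound intrinsic hepatic clearance (well-stirred model)
#'
#' \deqn{CLu_{int,H} = \frac{Q_{H,B} \cdot CL_H}{fu_p (Q_{H,B} - CL_H/B\!:\!P)}}
#' treating the liver as a single well-mixed compartment with hepatic blood
#' flow `Q_HB`, unbound plasma fraction `fu_p` and blood:plasma ratio `BP`.
#'
#' @param CL_H Hepatic plasma clearance (L/h).
#' @param Q_HB Hepatic blood flow (L/h).
#' @param fu_p Unbound fraction in plasma, in (0, 1].
#' @param BP Blood:plasma concentration ratio.
#' @return Unbound intrinsic hepatic clearance (L/h).
#' @export
back_calc_cluint_h <- function(CL_H, Q_HB, fu_p, BP = 1) {
  stopifnot(CL_H >= 0, Q_HB > 0, fu_p > 0, fu_p <= 1, BP > 0)
  if (Q_HB <= CL_H / BP)
    stop("hepatic clearance exceeds hepatic blood flow: well-stirred model ",
         "undefined (Q_HB <= CL_H/BP)", call. = FALSE)
  Q_HB * CL_H / (fu_p * (Q_HB - CL_H / BP))
}

#' Forward well-stirred hepatic clearance
#'
#' Algebraic inverse of [back_calc_cluint_h()]:
#' \deqn{CL_H = \frac{Q_{H,B}\, fu_p\, CLu_{int,H}}{Q_{H,B} + fu_p\, CLu_{int,H}/B\!:\!P}}
#' Always below the flow limit \eqn{Q_{H,B} \cdot B\!:\!P}.
#'
#' @param CLu_int_H Unbound intrinsic hepatic clearance (L/h).
#' @inheritParams back_calc_cluint_h
#' @return Hepatic plasma clearance (L/h).
#' @export
well_stirred_forward <- function(CLu_int_H, Q_HB, fu_p, BP = 1) {
  stopifnot(CLu_int_H >= 0, Q_HB > 0, fu_p > 0, BP > 0)
  Q_HB * fu_p * CLu_int_H / (Q_HB + fu_p * CLu_int_H / BP)
}

#' Partition hepatic intrinsic clearance across enzyme isoforms
#'
#' \deqn{CLu_{int,DME_j} = f_{m,DME_j} \cdot CLu_{int,H} / f_{CL,metabolism,H}}
#' with \eqn{f_{CL,metabolism,H} = 1 - f_{CL,renal}}.
#'
#' @param CLu_int_H Unbound intrinsic hepatic clearance (L/h).
#' @param f_m Named numeric vector of absolute metabolized fractions per
#'   isoform.
#' @param f_CL_renal Fraction of dose cleared renally, in [0, 1).
#' @return Named vector of per-isoform unbound intrinsic clearances (L/h).
#' @export
partition_cluint <- function(CLu_int_H, f_m, f_CL_renal) {
  stopifnot(CLu_int_H >= 0, all(f_m >= 0), f_CL_renal >= 0)
  if (f_CL_renal >= 1)
    stop("no hepatic pathway: f_CL_renal must be < 1", call. = FALSE)
  if (sum(f_m) + f_CL_renal > 1 + 1e-9)
    stop("metabolized fractions plus renal fraction exceed 1", call. = FALSE)
  f_m * CLu_int_H / (1 - f_CL_renal)
}

#' In vitro microsomal intrinsic clearance
#'
#' \deqn{CL_{int} = CLu_{int,DME_j} / (MPPGL \cdot LW \cdot 60 \cdot 10^{-6})}
#' converting a whole-liver L/h clearance to uL/min per mg microsomal protein
#' via the microsomal protein content per gram of liver (MPPGL) and the liver
#' weight LW (g).
#'
#' @param CLu_int_DME Per-isoform unbound intrinsic clearance (L/h).
#' @param MPPGL mg microsomal protein per g liver.
#' @param liver_weight_g Liver weight (g).
#' @return In vitro intrinsic clearance (uL/min/mg protein).
#' @export
invitro_clint <- function(CLu_int_DME, MPPGL, liver_weight_g) {
  stopifnot(all(CLu_int_DME >= 0), MPPGL > 0, liver_weight_g > 0)
  CLu_int_DME / (MPPGL * liver_weight_g * .lh_per_ulminmg)
}

#' Vmax from in vitro intrinsic clearance
#'
#' \deqn{V_{max,DME_j} = \frac{CL_{int,DME_j} \cdot K_{m,DME_j} \cdot fu_{mic}}
#'   {abundance_{DME_j} \cdot ISEF_{DME_j}}}
#' Units: (uL/min/mg) x (pmol/uL) / (pmol enzyme/mg) = pmol/min/pmol enzyme.
#'
#' @param clint In vitro intrinsic clearance (uL/min/mg protein).
#' @param Km_uM Michaelis constant (uM == pmol/uL).
#' @param abundance Enzyme abundance (pmol/mg microsomal protein), positive.
#' @param ISEF Inter-system extrapolation factor (default 1).
#' @param fu_mic Unbound fraction in the microsomal incubation (default 1).
#' @return Vmax (pmol/min/pmol enzyme).
#' @export
vmax_from_clint <- function(clint, Km_uM, abundance, ISEF = 1, fu_mic = 1) {
  stopifnot(all(clint >= 0), all(Km_uM >= 0))
  if (any(abundance <= 0)) stop("enzyme abundance must be positive",
                                call. = FALSE)
  if (any(ISEF <= 0)) stop("ISEF must be positive", call. = FALSE)
  clint * Km_uM * fu_mic / (abundance * ISEF)
}

#' Fit the full IVIVE chain
#'
#' Runs the whole extrapolation for one drug against one physiology:
#' derives `CL_R` and `CL_H` from the systemic clearance split,
#' back-calculates `CLu_int_H` with the well-stirred model, partitions it
#' over the isoforms in `enzymes`, and converts to microsomal CLint and Vmax
#' per isoform.
#'
#' @param drug A `drug_params` object ([read_drug_params()]) or equivalent
#'   list.
#' @param physiology A `physiology` object ([read_physiology()]) or list
#'   with `Q_HB`, `MPPGL`, `liver_weight_g`.
#' @param enzymes A data.frame with columns `enzyme`, `Km_uM`,
#'   `abundance_pmol_per_mg`, optional `f_m` (defaults to `drug$f_m`) and
#'   optional `ISEF` (default 1).
#' @return Object of class `dmet_ivive`: the per-enzyme parameter table plus
#'   the scalar chain (`CL_R`, `CL_H`, `CLu_int_H`).
#' @examples
#' drug <- list(CL_IV = 2, f_CL_renal = 0.10, fu_p = 0.45, BP = 1, fu_mic = 1,
#'              f_m = c(UGT1A3 = 0.086, UGT1A4 = 0.774, CYP = 0.04))
#' phys <- list(Q_HB = 81.8, MPPGL = 38, liver_weight_g = 1637.7)
#' enz <- data.frame(enzyme = c("UGT1A3", "UGT1A4"), Km_uM = c(70, 550),
#'                   abundance_pmol_per_mg = c(7.6, 7.9))
#' ivive_fit(drug, phys, enz)
#' @export
ivive_fit <- function(drug, physiology, enzymes) {
  drug <- .validate_drug(drug)
  physiology <- .validate_physiology(physiology)
  stopifnot(is.data.frame(enzymes),
            all(c("enzyme", "Km_uM", "abundance_pmol_per_mg") %in%
                  names(enzymes)))
  if (is.null(enzymes$ISEF)) enzymes$ISEF <- 1
  if (is.null(enzymes$f_m)) {
    miss <- setdiff(enzymes$enzyme, names(drug$f_m))
    if (length(miss))
      stop("no f_m for enzyme(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    enzymes$f_m <- unname(drug$f_m[enzymes$enzyme])
  }
  CLu_int_H <- back_calc_cluint_h(drug$CL_H, physiology$Q_HB, drug$fu_p,
                                  drug$BP)
  cluint_dme <- partition_cluint(CLu_int_H,
                                 stats::setNames(enzymes$f_m, enzymes$enzyme),
                                 drug$f_CL_renal)
  clint <- invitro_clint(cluint_dme, physiology$MPPGL,
                         physiology$liver_weight_g)
  vmax <- vmax_from_clint(clint, enzymes$Km_uM,
                          enzymes$abundance_pmol_per_mg, enzymes$ISEF,
                          drug$fu_mic)
  table <- data.frame(enzyme = enzymes$enzyme, f_m = enzymes$f_m,
                      Km_uM = enzymes$Km_uM,
                      abundance_pmol_per_mg = enzymes$abundance_pmol_per_mg,
                      ISEF = enzymes$ISEF,
                      CLu_int_DME_Lh = unname(cluint_dme),
                      invitro_CLint_uL_min_mg = unname(clint),
                      Vmax_pmol_min_pmol = unname(vmax),
                      stringsAsFactors = FALSE)
  structure(list(drug = drug, physiology = physiology, enzymes = table,
                 CL_R = drug$CL_R, CL_H = drug$CL_H, CLu_int_H = CLu_int_H),
            class = "dmet_ivive")
}

#' @export
print.dmet_ivive <- function(x, digits = 3, ...) {
  cat(sprintf("IVIVE chain (%s physiology)\n",
              x$physiology$label %||% "unnamed"))
  cat(sprintf("  CL_IV = %g L/h; CL_R = %g L/h; CL_H = %g L/h\n",
              x$drug$CL_IV, x$CL_R, x$CL_H))
  cat(sprintf("  CLu_int,H = %.*g L/h (well-stirred, Q_HB = %g L/h)\n",
              digits + 1, x$CLu_int_H, x$physiology$Q_HB))
  print(x$enzymes, row.names = FALSE, digits = digits)
  invisible(x)
}

.validate_drug <- function(drug) {
  need <- c("CL_IV", "f_CL_renal", "fu_p", "BP")
  miss <- need[!vapply(need, function(f) !is.null(drug[[f]]), logical(1))]
  if (length(miss))
    stop("drug parameters missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(drug$CL_IV > 0, drug$f_CL_renal >= 0, drug$f_CL_renal <= 1,
            drug$fu_p > 0, drug$fu_p <= 1, drug$BP > 0)
  if (is.null(drug$fu_mic)) drug$fu_mic <- 1
  stopifnot(drug$fu_mic > 0, drug$fu_mic <= 1)
  drug$f_m <- .normalize_fm(drug$f_m)
  if (!is.null(drug$f_m) &&
      sum(drug$f_m) + drug$f_CL_renal > 1 + 1e-9)
    stop("sum of f_m plus f_CL_renal exceeds 1", call. = FALSE)
  drug$CL_R <- drug$f_CL_renal * drug$CL_IV
  if (is.null(drug$CL_H)) drug$CL_H <- (1 - drug$f_CL_renal) * drug$CL_IV
  drug$f_CL_metabolism_H <- 1 - drug$f_CL_renal
  class(drug) <- "drug_params"
  drug
}

## f_m may be flat (enzyme -> fraction) or nested
## (family -> list(total=, split=)); nested entries expand to
## total * split / sum(split).
.normalize_fm <- function(f_m) {
  if (is.null(f_m)) return(NULL)
  out <- numeric(0)
  nm <- names(f_m)
  for (i in seq_along(f_m)) {
    el <- f_m[[i]]
    if (is.list(el)) {
      if (is.null(el$total) || is.null(el$split))
        stop("nested f_m entry '", nm[i], "' needs 'total' and 'split'",
             call. = FALSE)
      split <- unlist(el$split)
      out <- c(out, stats::setNames(el$total * split / sum(split),
                                    names(split)))
    } else {
      out <- c(out, stats::setNames(as.numeric(el), nm[i]))
    }
  }
  if (any(out < 0)) stop("f_m fractions must be non-negative", call. = FALSE)
  out
}

.validate_physiology <- function(p) {
  need <- c("Q_HB", "MPPGL", "liver_weight_g")
  miss <- need[!vapply(need, function(f) !is.null(p[[f]]), logical(1))]
  if (length(miss))
    stop("physiology missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(p$Q_HB > 0, p$MPPGL > 0, p$liver_weight_g > 0)
  class(p) <- "physiology"
  p
}

#' Read drug parameters from YAML/JSON
#'
#' @param path Path to a YAML or JSON file with fields `CL_IV`,
#'   `f_CL_renal`, `fu_p`, `BP`, optional `fu_mic`, `CL_H` and `f_m` (flat or
#'   nested family/total/split form, normalized to absolute fractions).
#' @return A validated `drug_params` object with derived `CL_R`, `CL_H` and
#'   `f_CL_metabolism_H`.
#' @export
read_drug_params <- function(path) {
  .validate_drug(.read_structured(path))
}

#' Read physiology from YAML/JSON
#'
#' @param path Path to a YAML or JSON file with `Q_HB` (L/h), `MPPGL`
#'   (mg/g), `liver_weight_g` and optional `label`.
#' @return A validated `physiology` object.
#' @export
read_physiology <- function(path) {
  .validate_physiology(.read_structured(path))
}

#' Read an enzyme kinetics table (CSV)
#'
#' @param path CSV with columns `enzyme`, `Km_uM`, `abundance_pmol_per_mg`,
#'   optional `f_m` and `ISEF`.
#' @return A `data.frame`.
#' @export
read_enzyme_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("enzyme", "Km_uM", "abundance_pmol_per_mg")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("enzyme table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

.read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
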