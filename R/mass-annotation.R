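# Negative-mode electrospray adduct arithmetic for metabolite
# annotation tables: theoretical m/z from the molecular formula and the
# adduct, and ppm error against the measured value.
#
# Ion m/z uses hydrogen-atom arithmetic by default: the electron mass
# is ignored, i.e. [M-H]- is treated as M minus one hydrogen atom.
# This is the convention the shipped annotation fixtures were printed
# under; `include_electron = TRUE` switches to proton-mass arithmetic
# (subtract a proton, add the charge electrons) for comparison.

.ADDUCTS <- list(
  "[M-H]-" = list(multiplier = 1L, delta = c(H = -1L), charge = -1L),
  "[M+Cl]-" = list(multiplier = 1L, delta = c(Cl = 1L), charge = -1L),
  "[M+HCOO]-" = list(multiplier = 1L, delta = c(C = 1L, H = 1L, O = 2L),
                     charge = -1L),
  "[2M+Na-2H]-" = list(multiplier = 2L, delta = c(Na = 1L, H = -2L),
                       charge = -1L)
)

# tolerate typographic variants: unicode minus, spaces, superscript
# charge markup
.normalize_adduct <- function(name) {
  x <- gsub("−", "-", name)
  x <- gsub("[[:space:]]", "", x)
  x <- gsub("\\^", "", x)
  x
}

#' Built-in negative-mode adducts
#'
#' @return Character vector of supported adduct names:
#'   `[M-H]-`, `[M+Cl]-`, `[M+HCOO]-`, `[2M+Na-2H]-`.
#' @export
adduct_names <- function() names(.ADDUCTS)

#' Theoretical adduct m/z
#'
#' `m/z = (multiplier × monoisotopic(M) + Σ signed monoisotopic masses
#' of the delta atoms) / |charge|`.
#'
#' @param formula Molecular formula (string, `chem_formula`, or named
#'   counts).
#' @param adduct Adduct name, one of [adduct_names()] (unicode minus
#'   and superscript markup are tolerated).
#' @param include_electron If `TRUE`, add the electron mass per
#'   negative charge (proton-mass arithmetic); default `FALSE`.
#' @return Theoretical m/z in Da.
#' @examples
#' adduct_mz("C7H6O5", "[M-H]-")   # 169.014 (gallic acid)
#' adduct_mz("C4H6O5", "[2M+Na-2H]-")
#' @export
adduct_mz <- function(formula, adduct, include_electron = FALSE) {
  f <- .validate_formula(.as_formula(formula))
  key <- .normalize_adduct(adduct)
  spec <- .ADDUCTS[[key]]
  if (is.null(spec)) {
    stop("unknown or unsupported adduct: ", sQuote(adduct),
         " (supported: ", paste(adduct_names(), collapse = ", "), ")",
         call. = FALSE)
  }
  # removing atoms must not exceed what the multiplied formula holds
  for (el in names(spec$delta)) {
    if (spec$delta[[el]] < 0) {
      have <- spec$multiplier * ifelse(el %in% names(f), f[[el]], 0L)
      if (have + spec$delta[[el]] < 0) {
        stop("adduct ", adduct, " would remove more ", el,
             " atoms than present", call. = FALSE)
      }
    }
  }
  mass <- spec$multiplier * monoisotopic_mass(f) +
    sum(spec$delta * .MONOISOTOPIC[names(spec$delta)])
  if (include_electron) {
    mass <- mass - spec$charge * .ELECTRON_MASS
  }
  mass / abs(spec$charge)
}

#' ppm mass error
#'
#' `(measured − theoretical) / theoretical × 1e6`.  Values are
#' conventionally displayed to two decimals, so deviations below
#' 0.005 ppm display as 0.00.
#'
#' @param measured,theoretical m/z values in Da; `theoretical` must be
#'   positive.
#' @return Signed ppm error (full precision; round for display).
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  (measured - theoretical) / theoretical * 1e6
}

#' Annotate a metabolite table
#'
#' Fills theoretical m/z and ppm error for every row of a metabolite
#' annotation table (columns `name`, `formula`, `adduct`,
#' `measured_mz`).  Input order is preserved; the returned table
#' carries a `n_within_5ppm` attribute counting rows with
#' |ppm| <= 5.
#'
#' @param rows data.frame with columns `name`, `formula`, `adduct`,
#'   `measured_mz`.
#' @param include_electron Passed to [adduct_mz()].
#' @return The input data.frame with `theoretical_mz` and `ppm_error`
#'   (rounded to two decimals) appended.
#' @export
annotate_table <- function(rows, include_electron = FALSE) {
  stopifnot(is.data.frame(rows))
  need <- c("name", "formula", "adduct", "measured_mz")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  theo <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    theo[i] <- tryCatch(
      adduct_mz(rows$formula[i], rows$adduct[i], include_electron),
      error = function(e) {
        stop("row ", i, " (", rows$name[i], "): ", conditionMessage(e),
             call. = FALSE)
      })
  }
  out <- rows
  out$theoretical_mz <- theo
  out$ppm_error <- round(ppm_error(rows$measured_mz, theo), 2)
  attr(out, "n_within_5ppm") <- sum(abs(out$ppm_error) <= 5)
  out
}

#' Read a metabolite annotation table
#'
#' Reads a CSV with columns `name`, `formula`, `adduct`, `measured_mz`
#' (additional columns pass through).  Lines starting with `#` are
#' comments.  Two transcriptions of published LC-QToF-HRMS annotation
#' tables for *Balanophora subcupularis* and *Balanophora tobiracola*
#' ethyl-acetate extracts ship with the package; see
#' `system.file("extdata", package = "xovscreen")`.
#'
#' @param path CSV path.
#' @return data.frame of annotation rows.
#' @export
read_annotation_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  check.names = FALSE)
}
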