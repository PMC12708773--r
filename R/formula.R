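#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula such as `"C7H6O5"` into a
#' named count vector.  An omitted count means one atom (`"CH4"` is
#' `c(C = 1, H = 4)`).  Only element symbols with embedded mass
#' constants (see [supported_elements()]) are accepted, so every parsed
#' formula has a defined monoisotopic mass and average molecular weight.
#'
#' @param text Formula string, e.g. `"C15H12O7"`.
#' @return An object of class `chem_formula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("C7H6O5")
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  # tokenize into (ElementSymbol, optional count) pairs; anything left
  # over means the grammar was violated
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    stop("malformed formula: ", sQuote(text), call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  unknown <- setdiff(sym, supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(cnt == 0L)) {
    stop("zero count for element(s): ",
         paste(sym[cnt == 0L], collapse = ", "), call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "chem_formula")
}

.as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    out <- as.integer(x)
    names(out) <- names(x)
    cls <- structure(out, class = "chem_formula")
    .validate_formula(cls)
    return(cls)
  }
  stop("cannot interpret input as a molecular formula", call. = FALSE)
}

.validate_formula <- function(f) {
  if (length(f) == 0L || sum(f) < 1L) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  unknown <- setdiff(names(f), supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(f < 0L)) stop("negative element count", call. = FALSE)
  invisible(f)
}

#' @export
format.chem_formula <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  nm <- names(x)
  ord <- order(match(nm, c("C", "H"), nomatch = 3L), nm)
  paste0(nm[ord], ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times the most-abundant-isotope mass over all elements,
#' using the embedded constants table.
#'
#' @param formula A `chem_formula`, a formula string, or a named count
#'   vector.
#' @return Mass in Da (u).
#' @examples
#' monoisotopic_mass("C7H6O5")  # gallic acid, 170.021523
#' @export
monoisotopic_mass <- function(formula) {
  f <- .validate_formula(.as_formula(formula))
  sum(as.numeric(f) * .MONOISOTOPIC[names(f)])
}

#' Average molecular weight of a formula
#'
#' Sum of count times standard atomic weight; this is the conventional
#' "molecular weight" used by the applicability-domain filter.
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da.
#' @examples
#' average_molecular_weight("C15H12O7")  # taxifolin, 304.25
#' @export
average_molecular_weight <- function(formula) {
  f <- .validate_formula(.as_formula(formula))
  sum(as.numeric(f) * .STANDARD_WEIGHT[names(f)])
}
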