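# A molecule library is a plain data.frame with one row per structure and
# columns:
#   id            record identifier (unique within a library)
#   name          optional human-readable compound name (NA if unknown)
#   smiles        the input SMILES as supplied
#   canonical_key canonical SMILES computed from the parsed graph; the
#                 deduplication key (stereo layers are retained, so two
#                 stereoisomers stay distinct)
#   formula       Hill-notation molecular formula derived from the graph
#   label         "active" / "inactive" / "unknown"
#   source        free-text provenance tag

.LABELS <- c("active", "inactive", "unknown")

.empty_library <- function() {
  data.frame(id = character(), name = character(), smiles = character(),
             canonical_key = character(), formula = character(),
             label = character(), source = character(),
             stringsAsFactors = FALSE)
}

.check_library <- function(mols, arg = "library") {
  need <- c("id", "smiles", "canonical_key", "formula", "label")
  miss <- setdiff(need, names(mols))
  if (length(miss)) {
    stop(arg, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(mols)
}

# run obabel quietly; input/output via temp files
.obabel <- function(input_lines, args) {
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  ferr <- tempfile(fileext = ".log")
  on.exit(unlink(c(fin, fout, ferr)), add = TRUE)
  writeLines(input_lines, fin)
  status <- suppressWarnings(
    system2("obabel", c(fin, args), stdout = fout, stderr = ferr)
  )
  if (!file.exists(fout)) return(character())
  readLines(fout, warn = FALSE)
}

# canonical SMILES for a single record, "" on parse failure; in-process
# via ChemmineOB (fast enough for per-record validation)
.canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  out <- strsplit(out, "[\t\n]")[[1]]
  if (length(out) == 0L || !nzchar(out[[1]])) "" else trimws(out[[1]])
}

# molecular formulas for a vector of known-valid canonical SMILES, one
# obabel invocation for the whole batch
.molecular_formulas <- function(can_smiles) {
  if (length(can_smiles) == 0L) return(character())
  lines <- paste(can_smiles, seq_along(can_smiles))
  out <- .obabel(lines, c("-osmi", "--append", "formula"))
  res <- rep(NA_character_, length(can_smiles))
  for (ln in out) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3L) next
    idx <- suppressWarnings(as.integer(parts[[2]]))
    if (!is.na(idx)) res[idx] <- parts[[length(parts)]]
  }
  res
}

#' Parse one chemical structure
#'
#' Parses a SMILES string into a one-row molecule library with a
#' canonical deduplication key and molecular formula.  Unparsable input
#' raises a condition of class `xov_parse_error` carrying the offending
#' text, so curation can count and log removals; a partially parsed
#' structure is never returned silently.
#'
#' @param smiles SMILES string.
#' @param id Record identifier (default `"mol1"`).
#' @param name Optional compound name.
#' @param label One of `"active"`, `"inactive"`, `"unknown"`.
#' @param source Free-text provenance tag.
#' @return A one-row molecule library `data.frame`.
#' @examples
#' parse_structure("c1ccccc1", id = "benzene")
#' @export
parse_structure <- function(smiles, id = "mol1", name = NA_character_,
                            label = "unknown", source = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  label <- match.arg(label, .LABELS)
  key <- .canonical_smiles(smiles)
  if (!nzchar(key)) {
    stop(structure(
      class = c("xov_parse_error", "error", "condition"),
      list(message = paste0("cannot parse structure: ", sQuote(smiles)),
           call = NULL, input = smiles, id = id)
    ))
  }
  formula <- .molecular_formulas(key)
  data.frame(id = id, name = name, smiles = smiles, canonical_key = key,
             formula = formula, label = label, source = source,
             stringsAsFactors = FALSE)
}

#' Parse a table of structures
#'
#' Vectorised companion to [parse_structure()]: takes a data.frame with
#' at least `id` and `smiles` columns (optionally `name`, `label`,
#' `source`) and returns the molecule library of the records that
#' parsed, together with the failures.
#'
#' @param records data.frame with columns `id`, `smiles` and optionally
#'   `name`, `label`, `source`.
#' @return A list with elements `library` (molecule library of parsed
#'   records, input order preserved) and `failures` (data.frame of
#'   `id`, `smiles` for records that could not be encoded).
#' @export
parse_structures <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (!all(c("id", "smiles") %in% names(records))) {
    stop("records must have 'id' and 'smiles' columns", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("record ids must be unique", call. = FALSE)
  }
  n <- nrow(records)
  name <- if ("name" %in% names(records)) as.character(records$name) else rep(NA_character_, n)
  label <- if ("label" %in% names(records)) as.character(records$label) else rep("unknown", n)
  source <- if ("source" %in% names(records)) as.character(records$source) else rep(NA_character_, n)
  bad_label <- !label %in% .LABELS
  if (any(bad_label)) {
    stop("invalid label(s): ", paste(unique(label[bad_label]), collapse = ", "),
         call. = FALSE)
  }
  keys <- vapply(as.character(records$smiles), .canonical_smiles, "",
                 USE.NAMES = FALSE)
  ok <- nzchar(keys)
  formula <- rep(NA_character_, n)
  formula[ok] <- .molecular_formulas(keys[ok])
  lib <- data.frame(id = as.character(records$id)[ok], name = name[ok],
                    smiles = as.character(records$smiles)[ok],
                    canonical_key = keys[ok], formula = formula[ok],
                    label = label[ok], source = source[ok],
                    stringsAsFactors = FALSE)
  failures <- data.frame(id = as.character(records$id)[!ok],
                         smiles = as.character(records$smiles)[!ok],
                         stringsAsFactors = FALSE)
  list(library = lib, failures = failures)
}

#' Read a labelled structure table from CSV
#'
#' Expects columns `id`, `smiles` and optionally `name`, `label`,
#' `source`.  No parsing is performed; feed the result to [curate()].
#'
#' @param path CSV file path.
#' @return data.frame of raw records.
#' @export
read_library_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a molecule library to CSV
#'
#' Writes the normalised library including the appended
#' `canonical_key` column.
#'
#' @param mols Molecule library.
#' @param path Output CSV path.
#' @export
write_library_csv <- function(mols, path) {
  .check_library(mols)
  utils::write.csv(mols, path, row.names = FALSE)
  invisible(path)
}
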