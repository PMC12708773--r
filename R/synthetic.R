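# Seeded synthetic molecular libraries with an implanted
# substructure-activity rule, so the whole pipeline (curation, split,
# training, screening) is testable without external data.
#
# Molecules are assembled from a fixed scaffold vocabulary (aromatic
# and heteroaromatic cores first, aliphatic rings last) with up to
# three substituents drawn from a fixed fragment vocabulary.  The first
# substituent, a galloyl-like ester, is the designated pharmacophore:
# a molecule is active iff it carries it (labels are then flipped with
# probability `label_noise`).  The chemistry loosely resembles a
# polyphenol library; it makes recovery testable, not medicinal sense.

# scaffold templates with three substitution slots; substituent
# fragments use ring-bond digit 9 so they can nest inside any template
.SCAFFOLDS <- c(
  "c1cc{A}cc{B}c1{C}",            # benzene
  "c1cc{A}c2cc{B}ccc2c1{C}",      # naphthalene
  "c1c{A}cc{B}c{C}n1",            # pyridine
  "c1cc{A}c2occ{B}c2c1{C}",       # benzofuran
  "c1c{A}c{B}c{C}s1",             # thiophene
  "c1c{A}c{B}c{C}[nH]1",          # pyrrole
  "c1cc{A}c2ncc{B}cc2c1{C}",      # quinoline
  "c1cc{A}c2cc{B}oc2c1{C}",       # benzofuran (2-isomer)
  "C1CC{A}CC{B}C1{C}",            # cyclohexane
  "C1CC{A}OC{B}C1{C}",            # oxane
  "C1CC{A}NC{B}C1{C}",            # piperidine
  "C1C{A}CC{B}C1{C}"              # cyclopentane
)

# first entry is the pharmacophore (galloyl-like ester)
.SUBSTITUENTS <- c(
  "OC(=O)c9cc(O)c(O)c(O)c9",      # galloyloxy  <- activity rule
  "O",                            # hydroxy
  "OC",                           # methoxy
  "C",                            # methyl
  "C(=O)O",                       # carboxyl
  "CC",                           # ethyl
  "CO",                           # hydroxymethyl
  "Cl",                           # chloro
  "N",                            # amino
  "OCC",                          # ethoxy
  "F",                            # fluoro
  "CC(C)C"                        # isopropyl
)

# deliberately out-of-domain screening structures: in the 200-700 Da
# window but far from the polyphenol-like vocabulary
.EXOTICS <- c(
  "CCCCCCCCCCCCCCCC",             # n-hexadecane
  "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",  # perfluorohexane
  "C1COCCOCCOCCOCCOCCO1",         # 18-crown-6
  "CCCCCCN(CCCCCC)CCCCCC",        # trihexylamine
  "CCCCCCCCCCCCCCCC(=O)OCC",      # ethyl palmitate
  "CCCCCCCCCCCCCCCCCCCC"          # n-icosane
)

.SMALL_OR_LARGE <- c(
  "CCO",                          # ethanol, far below 200 Da
  "CC(=O)O",                      # acetic acid
  "c1ccccc1O",                    # phenol
  "CCCCCC",                       # hexane
  paste0("CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC")  # C52, > 700 Da
)

#' Synthetic library configuration
#'
#' @param n_molecules Library size (at least 10; default 400).
#' @param active_fraction Target active fraction before label noise
#'   (default 0.45, a mildly imbalanced library).
#' @param label_noise Independent per-record label flip probability in
#'   `[0, 0.5]` (default 0).
#' @param scaffold_vocab_size Number of scaffold templates used, 2–12
#'   (default 8: the aromatic/heteroaromatic cores).
#' @param substituent_vocab_size Number of substituent fragments used,
#'   2–12 (default 8; the first is always the pharmacophore).
#' @param seed Integer seed; identical configurations generate
#'   identical libraries.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_molecules = 400L, active_fraction = 0.45,
                             label_noise = 0, scaffold_vocab_size = 8L,
                             substituent_vocab_size = 8L, seed = 7L) {
  stopifnot(n_molecules >= 10L,
            active_fraction >= 0, active_fraction <= 1,
            label_noise >= 0, label_noise <= 0.5,
            scaffold_vocab_size >= 2L,
            scaffold_vocab_size <= length(.SCAFFOLDS),
            substituent_vocab_size >= 2L,
            substituent_vocab_size <= length(.SUBSTITUENTS))
  structure(list(n_molecules = as.integer(n_molecules),
                 active_fraction = active_fraction,
                 label_noise = label_noise,
                 scaffold_vocab_size = as.integer(scaffold_vocab_size),
                 substituent_vocab_size = as.integer(substituent_vocab_size),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.fill_slot <- function(template, slot, fragment) {
  sub(paste0("\\{", slot, "\\}"),
      if (nzchar(fragment)) paste0("(", fragment, ")") else "",
      template)
}

.assemble <- function(scaffold, frags) {
  s <- .fill_slot(scaffold, "A", frags[1])
  s <- .fill_slot(s, "B", frags[2])
  .fill_slot(s, "C", frags[3])
}

#' Generate a labelled synthetic library
#'
#' Draws `n_molecules` scaffold/substituent combinations; a fixed count
#' `round(n * active_fraction)` of them carry the pharmacophore
#' fragment (and are labelled active), the rest never do.  Labels are
#' then flipped independently with probability `label_noise`.  All
#' generated structures parse and encode under all five fingerprint
#' schemes.
#'
#' @param config A [synthetic_config()].
#' @return Molecule library data.frame (ids `syn0001`..., source
#'   `"synthetic"`) with an extra logical column `has_pharmacophore`
#'   recording the ground-truth rule before noise.
#' @export
generate_library <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_molecules
  scaff <- .SCAFFOLDS[seq_len(config$scaffold_vocab_size)]
  subst <- .SUBSTITUENTS[seq_len(config$substituent_vocab_size)]
  inert <- subst[-1]
  n_active <- round(n * config$active_fraction)
  gen <- .with_seed(config$seed, {
    is_active <- sample(rep(c(TRUE, FALSE), c(n_active, n - n_active)))
    smiles <- character(n)
    for (i in seq_len(n)) {
      frags <- vapply(1:3, function(j) {
        if (stats::runif(1) < 0.35) "" else sample(inert, 1)
      }, "")
      if (is_active[i]) frags[sample(3L, 1L)] <- subst[1]
      smiles[i] <- .assemble(sample(scaff, 1), frags)
    }
    flip <- stats::runif(n) < config$label_noise
    list(smiles = smiles, is_active = is_active, flip = flip)
  })
  label <- ifelse(xor(gen$is_active, gen$flip), "active", "inactive")
  records <- data.frame(id = sprintf("syn%04d", seq_len(n)),
                        smiles = gen$smiles, label = label,
                        source = "synthetic", stringsAsFactors = FALSE)
  parsed <- parse_structures(records)
  if (nrow(parsed$failures) > 0L) {
    stop("internal error: generated structure(s) failed to parse: ",
         paste(parsed$failures$smiles, collapse = ", "), call. = FALSE)
  }
  lib <- parsed$library
  lib$has_pharmacophore <- gen$is_active
  lib
}

#' Generate a screening set with planted applicability-domain outcomes
#'
#' Emits three candidate strata with known expected filter outcomes:
#' `in_vocab` (copies of in-weight-window training molecules; expected
#' to pass), `mw_fail` (structures below 200 or above 700 Da; must fail
#' the weight criterion) and `exotic` (in-window structures far from
#' the training vocabulary; expected to fail the similarity criterion).
#'
#' @param config A [synthetic_config()] (its seed drives the draws).
#' @param train_mols Training library from [generate_library()].
#' @param n_per_stratum Candidates per stratum (default 8).
#' @return Unlabelled molecule library with a `stratum` column.
#' @export
generate_screening_set <- function(config, train_mols, n_per_stratum = 8L) {
  stopifnot(inherits(config, "synthetic_config"))
  .check_library(train_mols, "train_mols")
  mw <- .molecule_mw(train_mols, "average")
  in_window <- which(!is.na(mw) & mw >= 200 & mw <= 700)
  if (length(in_window) == 0L) {
    stop("no training molecule lies in the 200-700 Da window", call. = FALSE)
  }
  smiles <- .with_seed(config$seed + 1L, {
    iv <- train_mols$smiles[sample(in_window, n_per_stratum,
                                   replace = length(in_window) < n_per_stratum)]
    mwf <- sample(.SMALL_OR_LARGE, n_per_stratum, replace = TRUE)
    ex <- sample(.EXOTICS, n_per_stratum, replace = TRUE)
    c(iv, mwf, ex)
  })
  stratum <- rep(c("in_vocab", "mw_fail", "exotic"), each = n_per_stratum)
  records <- data.frame(id = sprintf("cand%03d", seq_along(smiles)),
                        smiles = smiles, label = "unknown",
                        source = "synthetic-screening",
                        stringsAsFactors = FALSE)
  parsed <- parse_structures(records)
  if (nrow(parsed$failures) > 0L) {
    stop("internal error: generated candidate(s) failed to parse",
         call. = FALSE)
  }
  out <- parsed$library
  out$stratum <- stratum[match(out$id, records$id)]
  out
}
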