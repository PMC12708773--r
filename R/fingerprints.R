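# Five fingerprint schemes are supported: MACCS-167 and the four
# extended-connectivity variants ECFP4/ECFP6 folded to 1024 or 2048 bits.
# Raw bits come from OpenBabel (MACCS key dictionary; ECFP circular
# hashing of radius 2 or 3 into 4096 bits) and the ECFP vectors are
# folded here by OR over the hashed index modulo n_bits.  Bits are
# binary presence indicators, not counts.

.SCHEME_TABLE <- data.frame(
  family = c("MACCS", "ECFP4", "ECFP4", "ECFP6", "ECFP6"),
  n_bits = c(167L, 1024L, 2048L, 1024L, 2048L),
  stringsAsFactors = FALSE
)

#' Construct a fingerprint scheme
#'
#' Exactly five scheme values are legal: MACCS only pairs with 167 bits,
#' ECFP4 and ECFP6 with 1024 or 2048.
#'
#' @param family One of `"MACCS"`, `"ECFP4"`, `"ECFP6"`.
#' @param n_bits Bit length: 167 for MACCS, 1024 or 2048 for ECFP.
#' @return An object of class `fp_scheme` with fields `family`,
#'   `n_bits` and an `id` string such as `"ECFP4-1024"`.
#' @examples
#' fp_scheme("ECFP4", 1024)
#' @export
fp_scheme <- function(family, n_bits) {
  family <- match.arg(family, c("MACCS", "ECFP4", "ECFP6"))
  n_bits <- as.integer(n_bits)
  ok <- any(.SCHEME_TABLE$family == family & .SCHEME_TABLE$n_bits == n_bits)
  if (!ok) {
    stop("illegal scheme: ", family, "-", n_bits,
         " (MACCS pairs with 167 bits; ECFP4/ECFP6 with 1024 or 2048)",
         call. = FALSE)
  }
  structure(list(family = family, n_bits = n_bits,
                 id = paste0(family, "-", n_bits)),
            class = "fp_scheme")
}

#' All five fingerprint schemes
#'
#' @return Named list of the five legal [fp_scheme()] values, in the
#'   conventional order MACCS-167, ECFP4-1024, ECFP4-2048, ECFP6-1024,
#'   ECFP6-2048.
#' @export
fp_schemes <- function() {
  out <- lapply(seq_len(nrow(.SCHEME_TABLE)), function(i) {
    fp_scheme(.SCHEME_TABLE$family[i], .SCHEME_TABLE$n_bits[i])
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' @export
print.fp_scheme <- function(x, ...) {
  cat("<fp_scheme>", x$id, "\n")
  invisible(x)
}

.as_scheme <- function(scheme) {
  if (inherits(scheme, "fp_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) {
    parts <- strsplit(scheme, "-", fixed = TRUE)[[1]]
    if (length(parts) == 2L) return(fp_scheme(parts[1], as.integer(parts[2])))
  }
  stop("not a fingerprint scheme: ", deparse(scheme), call. = FALSE)
}

# parse `obabel -ofpt -xh` output into an n x raw_bits 0/1 matrix; the
# hex words are printed from the highest 32-bit word down, least
# significant bit first within each word
.parse_fpt_hex <- function(lines, n_mol, raw_bits) {
  out <- matrix(0L, nrow = n_mol, ncol = raw_bits)
  n_words <- raw_bits %/% 32L
  cur <- NA_integer_
  words <- character()
  flush <- function(cur, words) {
    if (is.na(cur)) return()
    if (length(words) != n_words) {
      stop("unexpected fingerprint block length for record ", cur,
           call. = FALSE)
    }
    # decode each 32-bit word as two 16-bit halves (strtoi cannot
    # represent values >= 2^31 as integers)
    w <- vapply(words, function(x) {
      paste0(strrep("0", max(0L, 8L - nchar(x))), x)
    }, "", USE.NAMES = FALSE)
    lo <- strtoi(substr(w, 5L, 8L), base = 16L)
    hi <- strtoi(substr(w, 1L, 4L), base = 16L)
    pow <- bitwShiftL(1L, 0:15)
    for (p in seq_along(w)) {
      base <- (n_words - p) * 32L  # 0-based offset of this word's bit 0
      if (lo[p] != 0L) {
        out[cur, base + which(bitwAnd(lo[p], pow) != 0L)] <<- 1L
      }
      if (hi[p] != 0L) {
        out[cur, base + 16L + which(bitwAnd(hi[p], pow) != 0L)] <<- 1L
      }
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush(cur, words)
      title <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]]
      title <- title[nzchar(title)][1]
      cur <- suppressWarnings(as.integer(title))
      words <- character()
    } else if (!is.na(cur) && grepl("^[0-9a-fA-F ]+$", ln)) {
      # skip commentary lines such as "Possible superstructure of 1"
      tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
      words <- c(words, tok[nzchar(tok)])
    }
  }
  flush(cur, words)
  out
}

# fold a raw bit matrix to n_bits by OR over index modulo n_bits
# (raw width is always a multiple of the target here)
.fold_bits <- function(mat, n_bits) {
  k <- ncol(mat) %/% n_bits
  acc <- matrix(0L, nrow = nrow(mat), ncol = n_bits)
  for (j in seq_len(k)) {
    acc <- acc + mat[, ((j - 1L) * n_bits + 1L):(j * n_bits), drop = FALSE]
  }
  (acc > 0L) * 1L
}

#' Encode molecules as fingerprints
#'
#' Encodes every molecule of a library (or a character vector of SMILES)
#' under one scheme.  Encoding is deterministic: the same structure
#' always yields the same bits.
#'
#' @param mols Molecule library (uses the `canonical_key` column) or a
#'   character vector of SMILES.
#' @param scheme An [fp_scheme()] or its id string (e.g.
#'   `"ECFP4-1024"`).
#' @return Integer 0/1 matrix with one row per molecule (rownames are
#'   the library ids where available) and `n_bits` columns, with
#'   attribute `scheme` set to the scheme id.
#' @export
encode_fingerprints <- function(mols, scheme) {
  scheme <- .as_scheme(scheme)
  if (is.data.frame(mols)) {
    .check_library(mols)
    smiles <- mols$canonical_key
    ids <- mols$id
  } else {
    stopifnot(is.character(mols), length(mols) >= 1L)
    smiles <- vapply(mols, .canonical_smiles, "", USE.NAMES = FALSE)
    if (any(!nzchar(smiles))) {
      stop(structure(
        class = c("xov_parse_error", "error", "condition"),
        list(message = paste0("cannot encode structure(s): ",
                              paste(sQuote(mols[!nzchar(smiles)]), collapse = ", ")),
             call = NULL, input = mols[!nzchar(smiles)])
      ))
    }
    ids <- if (!is.null(names(mols))) names(mols) else as.character(seq_along(mols))
  }
  n <- length(smiles)
  input <- paste(smiles, seq_len(n))
  if (scheme$family == "MACCS") {
    lines <- .obabel(input, c("-ofpt", "-xf", "MACCS", "-xh"))
    raw <- .parse_fpt_hex(lines, n, 256L)
    bits <- raw[, seq_len(scheme$n_bits), drop = FALSE]
  } else {
    lines <- .obabel(input, c("-ofpt", "-xf", scheme$family, "-xN", "4096", "-xh"))
    raw <- .parse_fpt_hex(lines, n, 4096L)
    bits <- .fold_bits(raw, scheme$n_bits)
  }
  rownames(bits) <- ids
  attr(bits, "scheme") <- scheme$id
  bits
}

#' Tanimoto similarity of two fingerprints
#'
#' `Tc = |A intersect B| / |A union B|` over the set bits.  Two all-zero
#' vectors are defined as similarity 1 (identical absence of features)
#' with a warning.
#'
#' @param a,b 0/1 (or logical) bit vectors of equal length; if both
#'   carry a `scheme` attribute it must match.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("fingerprint scheme mismatch: ", sa, " vs ", sb, call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch", call. = FALSE)
  }
  uni <- sum(a | b)
  if (uni == 0L) {
    warning("both fingerprints are all-zero; Tanimoto defined as 1")
    return(1)
  }
  sum(a & b) / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computes all Tanimoto similarities between the rows of `a` and the
#' rows of `b` (defaults to `a` itself) using bit-count algebra:
#' `|A ∩ B|` by cross product, `|A ∪ B| = |A| + |B| − |A ∩ B|`.
#'
#' @param a,b Fingerprint matrices from [encode_fingerprints()] with the
#'   same scheme.
#' @return `nrow(a)` by `nrow(b)` similarity matrix.
#' @export
tanimoto_matrix <- function(a, b = NULL) {
  if (is.null(b)) b <- a
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("fingerprint scheme mismatch: ", sa, " vs ", sb, call. = FALSE)
  }
  if (ncol(a) != ncol(b)) stop("fingerprint length mismatch", call. = FALSE)
  inter <- a %*% t(b)
  uni <- outer(rowSums(a), rowSums(b), "+") - inter
  tc <- inter / uni
  zero <- uni == 0
  if (any(zero)) {
    warning("all-zero fingerprint pair(s); Tanimoto defined as 1")
    tc[zero] <- 1
  }
  dimnames(tc) <- list(rownames(a), rownames(b))
  tc
}

#' Pairwise-similarity diversity profile of a library
#'
#' Evaluates Tanimoto similarity over all unordered distinct pairs of a
#' library (self-pairs excluded) and summarises the distribution: share
#' of pairs below a threshold and a binned histogram over `[0, 1]`.
#' High `fraction_below` at threshold 0.4 indicates a structurally
#' diverse library.
#'
#' @param mols Molecule library (at least two molecules).
#' @param scheme Fingerprint scheme (default ECFP4-1024, the
#'   conventional diversity yardstick).
#' @param threshold Similarity threshold (default 0.4).
#' @param bin_width Histogram bin width over `[0, 1]` (default 0.05).
#' @return List with `n_pairs`, `fraction_below`, `histogram` (named
#'   counts per bin), `threshold` and `scheme`.
#' @export
diversity_profile <- function(mols, scheme = fp_scheme("ECFP4", 1024),
                              threshold = 0.4, bin_width = 0.05) {
  .check_library(mols)
  if (nrow(mols) < 2L) stop("need at least 2 molecules", call. = FALSE)
  scheme <- .as_scheme(scheme)
  fps <- encode_fingerprints(mols, scheme)
  tc <- tanimoto_matrix(fps)
  vals <- tc[upper.tri(tc)]
  n_pairs <- length(vals)
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, include.lowest = TRUE,
                      right = FALSE, plot = FALSE)
  # right = FALSE puts Tc == 1 in its own right-closed final bin
  counts <- h$counts
  names(counts) <- paste0("[", utils::head(breaks, -1), ",",
                          utils::tail(breaks, -1),
                          c(rep(")", length(counts) - 1L), "]"))
  list(n_pairs = n_pairs,
       fraction_below = mean(vals < threshold),
       histogram = counts,
       threshold = threshold,
       scheme = scheme$id)
}
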