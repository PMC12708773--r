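# Shared fixtures, all built in code.

# small polyphenol-flavoured SMILES set
tiny_smiles <- function() {
  c(benzene = "c1ccccc1",
    phenol = "c1ccccc1O",
    gallic_acid = "OC(=O)c1cc(O)c(O)c(O)c1",
    catechol = "Oc1ccccc1O",
    naringenin = "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12",
    taxifolin = "O=C1c2c(O)cc(O)cc2OC(C1O)c1ccc(O)c(O)c1",
    ethanol = "CCO",
    pyridine = "c1ccncc1")
}

# build a parsed library from named smiles + labels
make_library <- function(smiles, labels = NULL) {
  if (is.null(labels)) labels <- rep("unknown", length(smiles))
  parse_structures(data.frame(
    id = if (!is.null(names(smiles))) names(smiles) else paste0("m", seq_along(smiles)),
    smiles = unname(smiles), label = labels,
    stringsAsFactors = FALSE))$library
}

# a fake library (no chemistry) for split/stratification tests where only
# ids and labels matter
fake_library <- function(n, active_fraction = 0.45) {
  n_act <- round(n * active_fraction)
  data.frame(id = sprintf("f%04d", seq_len(n)),
             name = NA_character_,
             smiles = "C",
             canonical_key = sprintf("key%04d", seq_len(n)),
             formula = "CH4",
             label = rep(c("active", "inactive"), c(n_act, n - n_act)),
             source = "fake", stringsAsFactors = FALSE)
}

# random 0/1 fingerprint vectors of a given length
random_bits <- function(n_bits, density = 0.1) {
  as.integer(runif(n_bits) < density)
}

# brute-force Tanimoto on explicit bit-index sets
tanimoto_oracle <- function(a, b) {
  A <- which(a == 1L); B <- which(b == 1L)
  u <- length(union(A, B))
  if (u == 0) return(1)
  length(intersect(A, B)) / u
}

# brute-force AUC: concordant active/inactive pairs, ties half weight
auc_oracle <- function(truth, score) {
  pos <- score[truth]; neg <- score[!truth]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

extdata <- function(f) {
  path <- system.file("extdata", f, package = "xovscreen")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", f)
  path
}
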