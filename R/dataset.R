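#' Curate a labelled structure table
#'
#' Prepares a raw labelled table for modelling: records whose structure
#' cannot be parsed and encoded are removed and counted, and duplicate
#' structures are collapsed on the canonical key (first occurrence
#' wins).  Every removal is logged with its id and reason.  Output order
#' is the input order of the survivors.
#'
#' @param records data.frame with columns `id`, `smiles`, `label`
#'   (`"active"`/`"inactive"`) and optionally `name`, `source`.
#' @return List with `library` (curated molecule library) and `report`
#'   (a `curation_report`: counts `n_input`, `n_duplicates_removed`,
#'   `n_encoding_failures`, `n_retained` and a `removals` log).
#' @examples
#' \dontrun{
#' cur <- curate(read_library_csv("library.csv"))
#' cur$report
#' }
#' @export
curate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(c("id", "smiles", "label") %in% names(records))) {
    stop("records must have 'id', 'smiles' and 'label' columns",
         call. = FALSE)
  }
  if (any(records$label == "unknown")) {
    stop("training records must be labelled active/inactive, not unknown",
         call. = FALSE)
  }
  parsed <- parse_structures(records)
  lib <- parsed$library
  removals <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (nrow(parsed$failures)) {
    removals <- rbind(removals, data.frame(
      id = parsed$failures$id, reason = "encoding_failure",
      stringsAsFactors = FALSE))
  }
  dup <- duplicated(lib$canonical_key)
  if (any(dup)) {
    # duplicate structures must agree on their label before collapsing
    conflict <- vapply(unique(lib$canonical_key[dup]), function(k) {
      length(unique(lib$label[lib$canonical_key == k])) > 1L
    }, NA)
    if (any(conflict)) {
      keys <- unique(lib$canonical_key[dup])[conflict]
      ids <- lib$id[lib$canonical_key %in% keys]
      stop("conflicting labels on duplicate structures: ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    removals <- rbind(removals, data.frame(
      id = lib$id[dup], reason = "duplicate", stringsAsFactors = FALSE))
  }
  kept <- lib[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(
    n_input = nrow(records),
    n_duplicates_removed = sum(dup),
    n_encoding_failures = nrow(parsed$failures),
    n_retained = nrow(kept),
    removals = removals
  ), class = "curation_report")
  list(library = kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  cat("  input records:      ", x$n_input, "\n")
  cat("  duplicates removed: ", x$n_duplicates_removed, "\n")
  cat("  encoding failures:  ", x$n_encoding_failures, "\n")
  cat("  retained:           ", x$n_retained, "\n")
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Partitions a curated library into train, validation and test sets by
#' a two-stage stratified draw: first a test partition of
#' `ceiling(fractions[3] * n)` records is removed, then a validation
#' partition of `ceiling(fractions[2] * n)` records from the remainder;
#' what is left is the training set.  Both draws are stratified by label
#' with largest-remainder apportionment of the partition size across
#' classes, so per-class proportions in every partition track the
#' global proportions to within one compound.  Deterministic for a
#' fixed seed.
#'
#' @param mols Curated molecule library with at least two classes of at
#'   least three members each.
#' @param fractions Numeric length-3 vector `(train, validation, test)`
#'   summing to 1 (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed driving both draw stages.
#' @return A `split_assignment`: list with `train_ids`,
#'   `validation_ids`, `test_ids`, `seed`, `fractions`, `stratified`
#'   and a `class_counts` table per partition.
#' @examples
#' \dontrun{
#' split <- stratified_split(lib, seed = 42)
#' lengths(split[c("train_ids", "validation_ids", "test_ids")])
#' }
#' @export
stratified_split <- function(mols, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  .check_library(mols)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  }
  labels <- mols$label
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  if (any(table(labels) < 3L)) {
    stop("every class needs at least 3 members to stratify", call. = FALSE)
  }
  n <- nrow(mols)
  size_test <- as.integer(ceiling(fractions[3] * n))
  size_val <- as.integer(ceiling(fractions[2] * n))

  draw_stage <- function(pool_ids, pool_labels, size) {
    counts <- vapply(classes, function(cl) sum(pool_labels == cl), 0L)
    names(counts) <- classes
    take <- .apportion(counts, size)
    out <- character()
    for (i in seq_along(classes)) {
      ids_cl <- pool_ids[pool_labels == classes[i]]
      if (take[i] > 0L) out <- c(out, sample(ids_cl, take[i]))
    }
    out
  }

  res <- .with_seed(seed, {
    test_ids <- draw_stage(mols$id, labels, size_test)
    rem <- !(mols$id %in% test_ids)
    val_ids <- draw_stage(mols$id[rem], labels[rem], size_val)
    list(test = test_ids, val = val_ids)
  })
  train_ids <- setdiff(mols$id, c(res$test, res$val))
  part_of <- function(ids) table(factor(mols$label[mols$id %in% ids],
                                        levels = classes))
  structure(list(
    train_ids = train_ids,
    validation_ids = sort(res$val),
    test_ids = sort(res$test),
    seed = as.integer(seed),
    fractions = fractions,
    stratified = TRUE,
    class_counts = list(train = part_of(train_ids),
                        validation = part_of(res$val),
                        test = part_of(res$test))
  ), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment> seed", x$seed, "\n")
  cat("  train:", length(x$train_ids),
      " validation:", length(x$validation_ids),
      " test:", length(x$test_ids), "\n")
  invisible(x)
}

#' Write a split manifest
#'
#' Writes the partition assignment as CSV (`id`, `partition`) plus a
#' JSON sidecar recording seed, fractions and per-partition class
#' counts.
#'
#' @param split A `split_assignment`.
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  man <- rbind(
    data.frame(id = split$train_ids, partition = "train"),
    data.frame(id = split$validation_ids, partition = "validation"),
    data.frame(id = split$test_ids, partition = "test")
  )
  utils::write.csv(man, path, row.names = FALSE)
  side <- list(seed = split$seed, fractions = split$fractions,
               class_counts = lapply(split$class_counts, as.list))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
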