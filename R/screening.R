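# Applicability-domain filtering and five-model consensus screening.
# A candidate is in-domain when its average molecular weight lies in
# [200, 700] Da and the mean Tanimoto similarity to its five nearest
# training-set neighbours (reference scheme ECFP4-1024) is at least
# 0.4.  In-domain candidates are voted on by the five per-scheme
# classifiers at threshold 0.5; three or more active votes out of five
# make a consensus active.

#' Applicability-domain criteria
#'
#' @param mw_min,mw_max Molecular-weight window in Da (default
#'   200–700).
#' @param k_neighbors Number of nearest training neighbours (default
#'   5).
#' @param tc_threshold Minimum mean Tanimoto similarity to those
#'   neighbours (default 0.4).
#' @param reference_scheme Fingerprint scheme used for the similarity
#'   criterion (default ECFP4-1024).
#' @param mw_kind `"average"` (standard atomic weights, the
#'   conventional reading of molecular weight; default) or
#'   `"monoisotopic"` for sensitivity analysis.
#' @return An object of class `ad_criteria`.
#' @export
ad_criteria <- function(mw_min = 200, mw_max = 700, k_neighbors = 5L,
                        tc_threshold = 0.4,
                        reference_scheme = fp_scheme("ECFP4", 1024),
                        mw_kind = c("average", "monoisotopic")) {
  mw_kind <- match.arg(mw_kind)
  stopifnot(mw_min < mw_max, k_neighbors >= 1L,
            tc_threshold > 0, tc_threshold <= 1)
  structure(list(mw_min = mw_min, mw_max = mw_max,
                 k_neighbors = as.integer(k_neighbors),
                 tc_threshold = tc_threshold,
                 reference_scheme = .as_scheme(reference_scheme),
                 mw_kind = mw_kind),
            class = "ad_criteria")
}

.molecule_mw <- function(mols, kind) {
  vapply(mols$formula, function(f) {
    if (is.na(f)) return(NA_real_)
    tryCatch(
      if (kind == "average") average_molecular_weight(f)
      else monoisotopic_mass(f),
      error = function(e) NA_real_)
  }, 0, USE.NAMES = FALSE)
}

#' Applicability-domain filter
#'
#' For each candidate, computes the molecular weight and the mean
#' Tanimoto similarity to its `k_neighbors` most similar training
#' compounds under the reference scheme, and passes the candidate iff
#' both criteria hold.  Both failure reasons are reported when both
#' apply.  A candidate whose structure cannot be encoded is reported as
#' failing (reason `encoding_failure`) rather than dropped.
#'
#' @param candidates Molecule library of screening candidates.
#' @param train_mols Training molecule library.
#' @param criteria An [ad_criteria()] object.
#' @return data.frame with columns `candidate_id`, `name`, `mw`,
#'   `mean_top_k_tc`, `ad_pass`, `mw_out_of_range`,
#'   `low_neighbor_similarity`, `encoding_failure`.
#' @export
ad_filter <- function(candidates, train_mols, criteria = ad_criteria()) {
  .check_library(candidates, "candidates")
  .check_library(train_mols, "train_mols")
  stopifnot(inherits(criteria, "ad_criteria"), nrow(train_mols) >= 1L)
  k <- min(criteria$k_neighbors, nrow(train_mols))
  train_fps <- encode_fingerprints(train_mols, criteria$reference_scheme)
  enc_ok <- nzchar(candidates$canonical_key) & !is.na(candidates$canonical_key)
  mw <- .molecule_mw(candidates, criteria$mw_kind)
  mean_tc <- rep(NA_real_, nrow(candidates))
  if (any(enc_ok)) {
    cand_fps <- encode_fingerprints(candidates[enc_ok, , drop = FALSE],
                                    criteria$reference_scheme)
    tc <- tanimoto_matrix(cand_fps, train_fps)
    mean_tc[enc_ok] <- apply(tc, 1, function(row) {
      mean(sort(row, decreasing = TRUE)[seq_len(k)])
    })
  }
  mw_bad <- is.na(mw) | mw < criteria$mw_min | mw > criteria$mw_max
  tc_bad <- is.na(mean_tc) | mean_tc < criteria$tc_threshold
  data.frame(
    candidate_id = candidates$id,
    name = if ("name" %in% names(candidates)) candidates$name else NA_character_,
    mw = mw,
    mean_top_k_tc = mean_tc,
    ad_pass = enc_ok & !mw_bad & !tc_bad,
    mw_out_of_range = enc_ok & mw_bad,
    low_neighbor_similarity = enc_ok & tc_bad,
    encoding_failure = !enc_ok,
    stringsAsFactors = FALSE
  )
}

.check_model_set <- function(models) {
  if (!is.list(models) || length(models) != 5L ||
      !all(vapply(models, inherits, NA, "xo_classifier"))) {
    stop("models must be a list of five xo_classifier objects",
         call. = FALSE)
  }
  schemes <- vapply(models, `[[`, "", "scheme")
  if (anyDuplicated(schemes) || !setequal(schemes, names(fp_schemes()))) {
    stop("the five models must cover the five schemes exactly once; got: ",
         paste(schemes, collapse = ", "), call. = FALSE)
  }
  names(models) <- schemes
  models[names(fp_schemes())]
}

# majority rule over five voters: in-domain candidates are consensus
# active iff at least 3 of 5 votes are active
.vote_consensus <- function(n_active_votes, ad_pass) {
  ifelse(!ad_pass, "out_of_domain",
         ifelse(n_active_votes >= 3L, "active", "not_active"))
}

#' Five-model consensus screen
#'
#' Applies the applicability-domain filter, then votes every surviving
#' candidate with all five per-scheme classifiers at their decision
#' thresholds.  Three or more active votes out of five make the
#' consensus `active`; candidates failing the filter are
#' `out_of_domain` and receive no votes.  Verdicts are sorted by
#' descending vote count, then id.
#'
#' @param candidates Molecule library of screening candidates.
#' @param models List of five `xo_classifier` objects covering the five
#'   schemes exactly once.
#' @param train_mols Training molecule library (defines the
#'   applicability domain).
#' @param criteria An [ad_criteria()] object.
#' @return data.frame with per-candidate AD status, one vote column per
#'   scheme, `n_active_votes` and `consensus`
#'   (`active`/`not_active`/`out_of_domain`).
#' @export
consensus_screen <- function(candidates, models, train_mols,
                             criteria = ad_criteria()) {
  models <- .check_model_set(models)
  ad <- ad_filter(candidates, train_mols, criteria)
  in_dom <- ad$ad_pass
  votes <- matrix(NA_character_, nrow = nrow(ad), ncol = length(models),
                  dimnames = list(NULL, names(models)))
  if (any(in_dom)) {
    surv <- candidates[candidates$id %in% ad$candidate_id[in_dom], , drop = FALSE]
    for (sc in names(models)) {
      cls <- predict(models[[sc]], surv, type = "class")
      votes[match(surv$id, ad$candidate_id), sc] <- cls
    }
  }
  n_active <- rowSums(votes == "active", na.rm = TRUE)
  n_active[!in_dom] <- NA_integer_
  consensus <- .vote_consensus(n_active, in_dom)
  out <- cbind(ad, as.data.frame(votes, stringsAsFactors = FALSE),
               data.frame(n_active_votes = n_active, consensus = consensus,
                          stringsAsFactors = FALSE))
  ord <- order(-ifelse(is.na(out$n_active_votes), -1, out$n_active_votes),
               out$candidate_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decoy-spiked screening validation
#'
#' Draws `n_decoys` ground-truth-active training compounds that at
#' least one model already predicts active, mixes them into a screening
#' run, and counts per model how many it recovers (predicts active).  A
#' well-behaved model set recovers all of them.
#'
#' @param models List of five `xo_classifier` objects.
#' @param train_mols Labelled training molecule library.
#' @param n_decoys Number of decoys to draw (default 20).
#' @param seed Integer seed for the draw.
#' @param eligibility `"predicted"` (default: ground-truth active and
#'   predicted active by at least one model) or `"label_only"`.
#' @return List with `decoy_ids`, `per_model_recovered` (named counts),
#'   `n_decoys` and `all_recovered`.
#' @export
decoy_validation <- function(models, train_mols, n_decoys = 20L,
                             seed = 1L,
                             eligibility = c("predicted", "label_only")) {
  eligibility <- match.arg(eligibility)
  models <- .check_model_set(models)
  .check_library(train_mols, "train_mols")
  actives <- train_mols[train_mols$label == "active", , drop = FALSE]
  if (nrow(actives) == 0L) stop("no active training compounds", call. = FALSE)
  pred <- sapply(models, function(m) predict(m, actives, type = "class"))
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1,
                                         dimnames = list(NULL, names(models)))
  eligible <- if (eligibility == "predicted") {
    actives$id[rowSums(pred == "active") >= 1L]
  } else actives$id
  if (length(eligible) < n_decoys) {
    stop("eligible decoy pool has only ", length(eligible),
         " compounds, need ", n_decoys, call. = FALSE)
  }
  decoy_ids <- .with_seed(seed, sample(eligible, n_decoys))
  decoys <- actives[match(decoy_ids, actives$id), , drop = FALSE]
  rec <- vapply(models, function(m) {
    sum(predict(m, decoys, type = "class") == "active")
  }, 0)
  list(decoy_ids = decoy_ids,
       per_model_recovered = rec,
       n_decoys = as.integer(n_decoys),
       all_recovered = all(rec == n_decoys))
}
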