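# evaluate expr under a fixed, version-stable RNG state and restore the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  expr
}

# largest-remainder apportionment of `total` draws across classes with
# availability `counts`; deterministic (ties broken by class order)
.apportion <- function(counts, total) {
  stopifnot(total <= sum(counts))
  quota <- total * counts / sum(counts)
  alloc <- pmin(floor(quota), counts)
  short <- total - sum(alloc)
  if (short > 0) {
    frac <- quota - floor(quota)
    ord <- order(-frac, seq_along(counts))
    for (i in ord) {
      if (short == 0) break
      if (alloc[i] < counts[i]) {
        alloc[i] <- alloc[i] + 1
        short <- short - 1
      }
    }
  }
  as.integer(alloc)
}
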