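# Independent oracles for the placement model, implemented without reusing
# any package internals.

# All start sets of non-overlapping fold placements via combn() over every
# subset size the chain can host. Returns a character vector of canonical
# "s1,s2,..." keys.
brute_force_placements <- function(n_repeats, fold_repeats = 12,
                                   maximal_only = FALSE) {
  n <- floor(n_repeats)
  last <- n - fold_repeats + 1
  if (last < 1) return(character(0))
  starts <- seq_len(last)
  max_folds <- floor(n / fold_repeats)
  keys <- character(0)
  for (size in seq_len(max_folds)) {
    subs <- utils::combn(starts, size, simplify = FALSE)
    for (st in subs) {
      if (size > 1 && any(diff(st) < fold_repeats)) next
      if (maximal_only) {
        ends <- st + fold_repeats - 1
        gaps <- c(st[1] - 1, st[-1] - ends[-size] - 1, n - ends[size])
        if (any(gaps >= fold_repeats)) next
      }
      keys <- c(keys, paste(st, collapse = ","))
    }
  }
  sort(keys)
}

config_keys <- function(configs) {
  sort(vapply(configs, function(cf) paste(cf$starts, collapse = ","),
              character(1)))
}

# Exact distribution of the sequential (uniform-among-legal-starts)
# placement process by exhaustive recursion over placement orders.
# Returns a data.frame: key, prob, n_folds, has_adjacent.
sequential_placement_dist <- function(n_repeats, fold_repeats = 12) {
  n <- floor(n_repeats)
  legal <- function(placed) {
    last <- n - fold_repeats + 1
    if (last < 1) return(integer(0))
    cand <- seq_len(last)
    if (length(placed) == 0) return(cand)
    keep <- vapply(cand, function(s) {
      all(s + fold_repeats - 1 < placed | s > placed + fold_repeats - 1)
    }, logical(1))
    cand[keep]
  }
  acc <- new.env(parent = emptyenv())
  recurse <- function(placed, p) {
    lg <- legal(placed)
    if (length(lg) == 0) {
      key <- paste(sort(placed), collapse = ",")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
      return(invisible())
    }
    for (s in lg) recurse(c(placed, s), p / length(lg))
  }
  recurse(integer(0), 1)
  keys <- ls(acc)
  probs <- vapply(keys, function(k) acc[[k]], numeric(1))
  starts_list <- lapply(strsplit(keys, ","), as.integer)
  data.frame(
    key = keys,
    prob = probs,
    n_folds = vapply(starts_list, length, integer(1)),
    has_adjacent = vapply(starts_list, function(st) {
      length(st) > 1 && any(diff(sort(st)) == fold_repeats)
    }, logical(1)),
    stringsAsFactors = FALSE
  )
}
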