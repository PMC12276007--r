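#' @title Fold placement combinatorics on a pUG repeat chain
#' @description Constructors and enumeration of non-overlapping 12-repeat
#'   fold placements, classification of adjacent double folds, sequential
#'   (kinetic) placement simulation, and prediction of RNase T1-resistant
#'   fragments.
#' @name placement_model
NULL

#' Construct a fold configuration
#'
#' A fold configuration is a set of non-overlapping fold placements on a
#' repeat chain, expressed as repeat-level start indices. A configuration is
#' *maximal* when no further fold of `fold_repeats` repeats fits in any gap
#' or flank. Two placements are *adjacent* when zero repeats intervene —
#' such adjacent double folds resist RNase T1 digestion as a single block.
#'
#' @param n_repeats Chain length in repeats (integer part used for
#'   placement).
#' @param starts Sorted vector of 1-based repeat-level start indices.
#' @param fold_repeats Repeats per fold (default 12).
#' @return An object of class `fold_configuration` with elements
#'   `n_repeats`, `starts`, `fold_repeats`, `n_folds`, `is_maximal`,
#'   `n_adjacent_pairs`.
#' @export
fold_configuration <- function(n_repeats, starts, fold_repeats = 12) {
  starts <- sort(as.integer(starts))
  n_full <- floor(n_repeats)
  if (length(starts)) {
    stopifnot(all(starts >= 1), all(starts + fold_repeats - 1 <= n_full))
    if (length(starts) > 1 && any(diff(starts) < fold_repeats)) {
      stop("placements overlap", call. = FALSE)
    }
  }
  structure(
    list(
      n_repeats = n_repeats,
      starts = starts,
      fold_repeats = fold_repeats,
      n_folds = length(starts),
      is_maximal = is_maximal_configuration(n_full, starts, fold_repeats),
      n_adjacent_pairs = if (length(starts) > 1)
        sum(diff(starts) == fold_repeats) else 0L
    ),
    class = "fold_configuration"
  )
}

#' @export
print.fold_configuration <- function(x, ...) {
  cat(sprintf(
    "fold configuration on %g repeats: %d fold(s) at [%s]%s, %d adjacent pair(s)\n",
    x$n_repeats, x$n_folds, paste(x$starts, collapse = ", "),
    if (x$is_maximal) " (maximal)" else "", x$n_adjacent_pairs))
  invisible(x)
}

# TRUE when no further fold fits in any gap or flank.
is_maximal_configuration <- function(n_full, starts, fold_repeats) {
  gap_lengths <- gaps_of(n_full, starts, fold_repeats)
  all(gap_lengths < fold_repeats)
}

# Lengths of unoccupied intervals (5' flank, internal gaps, 3' flank).
gaps_of <- function(n_full, starts, fold_repeats) {
  if (length(starts) == 0) return(n_full)
  ends <- starts + fold_repeats - 1
  c(starts[1] - 1, starts[-1] - ends[-length(ends)] - 1, n_full - ends[length(ends)])
}

#' Enumerate fold configurations on a repeat chain
#'
#' Enumerates every non-empty set of non-overlapping `fold_repeats`-repeat
#' placements at repeat-level start positions on a chain of `n_repeats`
#' repeats, in deterministic (lexicographic) order. With
#' `maximal_only = TRUE`, only configurations to which no further fold can
#' be added are returned — the ensemble behind the stochastic-folding
#' prediction that 22% of configurations on a 29-repeat chain contain an
#' adjacent double fold.
#'
#' @param n_repeats Chain length in repeats (non-negative; the integer part
#'   hosts placements).
#' @param fold_repeats Repeats per fold (default 12).
#' @param maximal_only Keep only maximal configurations (default `FALSE`).
#' @return List of [fold_configuration()] objects (empty when no fold fits).
#' @examples
#' length(enumerate_configurations(29, maximal_only = TRUE))  # 27
#' @export
enumerate_configurations <- function(n_repeats, fold_repeats = 12,
                                     maximal_only = FALSE) {
  stopifnot(n_repeats >= 0, fold_repeats >= 1)
  n_full <- floor(n_repeats)
  last <- n_full - fold_repeats + 1
  if (last < 1) return(list())

  # depth-first extension: each configuration is a strictly increasing
  # start vector with consecutive starts >= fold_repeats apart
  acc <- list()
  recurse <- function(prefix, min_start) {
    for (s in seq(min_start, last)) {
      cfg <- c(prefix, s)
      acc[[length(acc) + 1L]] <<- cfg
      nxt <- s + fold_repeats
      if (nxt <= last) recurse(cfg, nxt)
    }
  }
  recurse(integer(0), 1L)

  configs <- lapply(acc, function(st)
    fold_configuration(n_repeats, st, fold_repeats))
  if (maximal_only) {
    configs <- Filter(function(cf) cf$is_maximal, configs)
  }
  configs
}

#' Placement statistics of a configuration ensemble
#'
#' Tallies an ensemble of configurations from one chain by fold count and
#' adjacency. `fraction_adjacent` is the fraction of configurations
#' containing at least one adjacent double fold (zero intervening repeats)
#' — over the maximal ensemble of a 29-repeat chain this is 6/27, the
#' predicted 22%.
#'
#' @param configs Non-empty list of [fold_configuration()] objects.
#' @return An object of class `placement_stats`: list with `n_configs`,
#'   `n_single`, `n_double`, `n_triple_plus`, `n_adjacent_double`,
#'   `fraction_adjacent`, and `mean_folds`.
#' @export
adjacency_stats <- function(configs) {
  if (!is.list(configs) || length(configs) == 0) {
    stop("configs must be a non-empty list of fold configurations",
         call. = FALSE)
  }
  n_folds <- vapply(configs, function(cf) cf$n_folds, integer(1))
  adj <- vapply(configs, function(cf) cf$n_adjacent_pairs > 0, logical(1))
  structure(
    list(
      n_configs = length(configs),
      n_single = sum(n_folds == 1L),
      n_double = sum(n_folds == 2L),
      n_triple_plus = sum(n_folds >= 3L),
      n_adjacent_double = sum(adj),
      fraction_adjacent = mean(adj),
      mean_folds = mean(n_folds)
    ),
    class = "placement_stats"
  )
}

#' @export
print.placement_stats <- function(x, ...) {
  cat(sprintf(
    paste0("placement ensemble: %d configurations ",
           "(%d single / %d double / %d triple+)\n",
           "  with adjacent double fold: %d (%.1f%%); mean folds %.3f\n"),
    x$n_configs, x$n_single, x$n_double, x$n_triple_plus,
    x$n_adjacent_double, 100 * x$fraction_adjacent, x$mean_folds))
  invisible(x)
}

#' Simulate sequential stochastic fold placement
#'
#' Kinetic placement model: per molecule, folds nucleate one at a time at a
#' start position drawn uniformly among the currently legal (non-overlapping)
#' starts, until no further fold fits. Every resulting configuration is
#' maximal, but the ensemble is weighted by the order of nucleation rather
#' than uniformly over maximal configurations, so its adjacency statistics
#' differ from [enumerate_configurations()] + [adjacency_stats()].
#'
#' @param n_repeats Chain length in repeats.
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed (required; the simulation is deterministic given
#'   the seed).
#' @param fold_repeats Repeats per fold (default 12).
#' @return List of [fold_configuration()] objects, one per molecule.
#' @export
simulate_sequential_folding <- function(n_repeats, n_molecules, seed,
                                        fold_repeats = 12) {
  stopifnot(n_molecules >= 1, is.numeric(seed))
  set.seed(as.integer(seed))
  n_full <- floor(n_repeats)
  last <- n_full - fold_repeats + 1

  replicate(n_molecules, {
    starts <- integer(0)
    repeat {
      legal <- legal_starts(n_full, starts, fold_repeats)
      if (length(legal) == 0) break
      pick <- legal[sample.int(length(legal), 1L)]
      starts <- sort(c(starts, pick))
    }
    fold_configuration(n_repeats, starts, fold_repeats)
  }, simplify = FALSE)
}

# Starts where a new fold fits without overlapping existing placements.
legal_starts <- function(n_full, starts, fold_repeats) {
  last <- n_full - fold_repeats + 1
  if (last < 1) return(integer(0))
  cand <- seq_len(last)
  if (length(starts) == 0) return(cand)
  occupied_from <- starts
  occupied_to <- starts + fold_repeats - 1
  ok <- vapply(cand, function(s) {
    all(s + fold_repeats - 1 < occupied_from | s > occupied_to)
  }, logical(1))
  cand[ok]
}

#' Predict RNase T1-resistant fragments of a fold configuration
#'
#' RNase T1 cleaves 3' of single-stranded guanosines, so folded repeats are
#' protected while unstructured repeats between and flanking folds are
#' digested away. Maximal blocks of adjacent placements survive as single
#' fragments (an adjacent double fold yields one 24-repeat fragment). The 5'
#' terminus of a fragment is the transcript chemistry (`"PPP"` triphosphate
#' or `"HO"` hydroxyl) when its block starts at repeat 1 and `"HO"`
#' otherwise (upstream cleavage leaves a 5' hydroxyl); the 3' terminus is
#' `"OH"` when the block reaches the chain 3' end and `"cyclicP"`
#' (2',3'-cyclic phosphate) otherwise.
#'
#' @param config A [fold_configuration()] with at least one placement.
#' @param five_prime_chemistry `"PPP"` or `"HO"`: the intact transcript's
#'   5' chemistry.
#' @return data.frame with columns `start_repeat`, `end_repeat`, `n_folds`,
#'   `five_prime`, `three_prime`, `length_nt`.
#' @export
predict_t1_fragments <- function(config, five_prime_chemistry = c("PPP", "HO")) {
  five_prime_chemistry <- match.arg(five_prime_chemistry)
  stopifnot(inherits(config, "fold_configuration"))
  if (config$n_folds == 0) {
    stop("configuration has no fold placements", call. = FALSE)
  }
  fr <- config$fold_repeats
  starts <- config$starts
  # merge adjacent placements into blocks
  block_id <- cumsum(c(1L, diff(starts) != fr))
  n_full <- floor(config$n_repeats)
  blocks <- lapply(split(starts, block_id), function(st) {
    s <- min(st); e <- max(st) + fr - 1
    data.frame(
      start_repeat = s,
      end_repeat = e,
      n_folds = length(st),
      five_prime = if (s == 1L) five_prime_chemistry else "HO",
      three_prime = if (e == n_full) "OH" else "cyclicP",
      length_nt = 2L * (e - s + 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
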