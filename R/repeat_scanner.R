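#' Parse an uninterrupted pUG repeat sequence
#'
#' Poly(UG) ("pUG") RNAs are dinucleotide repeats of alternating G and U that
#' can begin with either nucleotide. `parse_pug()` accepts a single
#' uninterrupted GU/UG run and returns its repeat-level description. Odd-length
#' runs are counted in half-repeat units (e.g. the 59-nt tract of NEAT1 is
#' 29.5 repeats).
#'
#' DNA-style input is tolerated: `T` is converted to `U` and lowercase is
#' uppercased. Sequences that are not a single alternating G/U run (e.g.
#' interrupted repeats) are rejected; use [find_pug_runs()] to scan those.
#'
#' @param sequence A single RNA string over `{A,C,G,U}` (or `T` for `U`).
#' @return An object of class `pug_sequence`: a list with elements
#'   `sequence` (normalised RNA string), `n_repeats` (repeat count, 0.5
#'   granularity), `phase` (`"G"` or `"U"`, the first nucleotide), and
#'   `n_nt` (nucleotide length).
#' @examples
#' parse_pug("GUGUGUGUGUGUGUGUGUGUGUGU")  # (GU)12: 12 repeats, G phase
#' parse_pug("ug")                        # 1 repeat, U phase
#' @export
parse_pug <- function(sequence) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% c("G", "U"))) {
    stop("not a pUG repeat: sequence contains nucleotides other than G/U; ",
         "use find_pug_runs() to scan interrupted sequences", call. = FALSE)
  }
  if (n > 1 && any(chars[-1] == chars[-n])) {
    stop("interrupted repeat: G/U do not alternate throughout; ",
         "use find_pug_runs() to locate individual runs", call. = FALSE)
  }
  structure(
    list(sequence = sequence, n_repeats = n / 2, phase = chars[1], n_nt = n),
    class = "pug_sequence"
  )
}

#' @export
print.pug_sequence <- function(x, ...) {
  cat(sprintf("pUG repeat chain: %g repeats (%d nt), %s-start phase\n",
              x$n_repeats, x$n_nt, x$phase))
  invisible(x)
}

# Uppercase, T->U, validate alphabet. Internal.
normalize_rna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) > 0) {
    stop("invalid nucleotide character(s) in sequence: '", bad, "'",
         call. = FALSE)
  }
  s
}

#' Locate maximal pUG repeat runs in an RNA sequence
#'
#' Scans an arbitrary RNA sequence for maximal runs of alternating G/U
#' (either phase) and reports those of at least `min_repeats` repeat units.
#' Runs are maximal (not extendable in either direction), non-overlapping,
#' and returned in 5'-to-3' order. Coordinates are 1-based inclusive at
#' nucleotide level; run lengths are reported in repeats (0.5 granularity).
#'
#' @param sequence RNA string (T accepted for U, case-insensitive).
#' @param min_repeats Minimum run length in repeat units (default 1, i.e.
#'   one full GU/UG dinucleotide).
#' @return A data.frame with one row per run and columns `start`, `end`
#'   (nucleotide coordinates), `n_repeats`, `n_g` (guanosine count in the
#'   run), and `phase`.
#' @examples
#' ho1 <- paste0(strrep("GU", 12), "A", "U", strrep("GU", 12))
#' find_pug_runs(ho1, min_repeats = 10)
#' @export
find_pug_runs <- function(sequence, min_repeats = 1) {
  stopifnot(is.numeric(min_repeats), length(min_repeats) == 1L,
            min_repeats >= 1)
  s <- normalize_rna(sequence)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c("G", "U")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c("G", "U") &&
             chars[j + 1L] != chars[j]) {
        j <- j + 1L
      }
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  len <- ends - starts + 1L
  n_repeats <- len / 2
  keep <- n_repeats >= min_repeats
  starts <- starts[keep]; ends <- ends[keep]; n_repeats <- n_repeats[keep]

  n_g <- vapply(seq_along(starts), function(k) {
    sum(chars[starts[k]:ends[k]] == "G")
  }, integer(1))
  phase <- if (length(starts)) chars[starts] else character(0)

  data.frame(start = starts, end = ends, n_repeats = n_repeats,
             n_g = n_g, phase = phase, stringsAsFactors = FALSE)
}

#' Legal start positions for a pUG fold on a repeat chain
#'
#' The pUG fold engages 12 consecutive repeats (12 guanosines). Given a
#' parsed repeat chain, returns every repeat-level start index `i` such that
#' repeats `i .. i + fold_repeats - 1` all exist as full repeats. Half
#' repeats at the chain end cannot host the final repeat of a fold.
#'
#' @param pug A `pug_sequence` from [parse_pug()], or a bare repeat count.
#' @param fold_repeats Repeats per fold (default 12).
#' @return Integer vector of 1-based repeat-level start indices (possibly
#'   empty).
#' @examples
#' valid_fold_starts(parse_pug(strrep("GU", 29)))  # 1..18
#' @export
valid_fold_starts <- function(pug, fold_repeats = 12) {
  n_repeats <- if (inherits(pug, "pug_sequence")) pug$n_repeats else pug
  stopifnot(is.numeric(n_repeats), n_repeats >= 0,
            is.numeric(fold_repeats), fold_repeats >= 1)
  n_full <- floor(n_repeats)
  last <- n_full - fold_repeats + 1
  if (last < 1) return(integer(0))
  seq_len(last)
}

#' Scan FASTA records for pUG repeat runs
#'
#' Reads a (multi-record) FASTA file and applies [find_pug_runs()] to each
#' record independently.
#'
#' @param path Path to a FASTA file.
#' @param min_repeats Passed to [find_pug_runs()].
#' @return A data.frame with columns `record_id`, `start`, `end`,
#'   `n_repeats`, `n_g`, `phase` (zero rows if no run qualifies).
#' @export
scan_fasta <- function(path, min_repeats = 1) {
  seqs <- read_fasta(path)
  out <- lapply(names(seqs), function(id) {
    runs <- find_pug_runs(seqs[[id]], min_repeats = min_repeats)
    if (nrow(runs) == 0) return(NULL)
    cbind(record_id = id, runs, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), n_repeats = numeric(0),
                      n_g = integer(0), phase = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
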