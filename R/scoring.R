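#' Structural score thresholds
#'
#' @param selfcomp_max Exclusive upper bound on the self-complementarity
#'   score; candidates are accepted when their score is strictly below this
#'   (default 10).
#' @param hairpin_dg_min Hairpin delta-G floor in kcal/mol; candidates with
#'   a more negative (more stable) hairpin are rejected (default -6.0).
#' @param dimer_flag_level Cross-dimer score at or above which a primer pair
#'   is flagged in reports (default 10).
#' @return A `score_thresholds` list.
#' @export
score_thresholds <- function(selfcomp_max = 10L, hairpin_dg_min = -6.0,
                             dimer_flag_level = 10L) {
  stopifnot(selfcomp_max > 0, hairpin_dg_min <= 0)
  structure(list(selfcomp_max = as.integer(selfcomp_max),
                 hairpin_dg_min = hairpin_dg_min,
                 dimer_flag_level = as.integer(dimer_flag_level)),
            class = "score_thresholds")
}

#' Self-complementarity score
#'
#' The largest number of Watson-Crick pairings formed when the primer
#' anneals antiparallel to a copy of itself, maximised over all relative
#' offsets. Scores below 10 are conventionally acceptable.
#'
#' @param seq Character vector of unambiguous sequences.
#' @return Integer scores in `[0, nchar(seq)]`.
#' @examples
#' self_complementarity("GAATTC") # 6: an EcoRI-site palindrome
#' @export
self_complementarity <- function(seq) {
  check_alphabet(seq, ambiguity_ok = FALSE)
  seq <- toupper(seq)
  rc <- reverse_complement(seq)
  vapply(seq_along(seq), function(i) pairing_max_cpp(seq[i], rc[i]),
         integer(1))
}

#' Cross-dimer score between two primers
#'
#' Shift-maximised Watson-Crick pairing count between `a` and the reverse
#' complement of `b`; symmetric in its arguments.
#'
#' @param a,b Unambiguous primer sequences (character scalars or equal-length
#'   vectors, scored elementwise).
#' @return Integer scores.
#' @export
cross_dimer_score <- function(a, b) {
  check_alphabet(a, ambiguity_ok = FALSE)
  check_alphabet(b, ambiguity_ok = FALSE)
  a <- toupper(a); b <- toupper(b)
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  rcb <- reverse_complement(b)
  vapply(seq_along(a), function(i) pairing_max_cpp(a[i], rcb[i]), integer(1))
}

#' Hairpin delta-G
#'
#' Minimum (most stable, most negative) free energy over all ungapped
#' stem-loop foldings with a stem of >= 3 contiguous Watson-Crick pairs and
#' a loop of 3-12 nt, under an additive model: loop penalty +3.5 kcal/mol,
#' A.T pair -1.0, G.C pair -1.5 kcal/mol. Returns 0 when no folding exists
#' or none is net-stabilising; values closer to zero are better.
#'
#' @param seq Character vector of unambiguous sequences.
#' @return Numeric delta-G values in kcal/mol, always <= 0.
#' @examples
#' hairpin_dg("GGGAAAACCC") # -1.0: 3-bp G.C stem over a 4-nt loop
#' @export
hairpin_dg <- function(seq) {
  check_alphabet(seq, ambiguity_ok = FALSE)
  vapply(toupper(seq), hairpin_dg_cpp, numeric(1), USE.NAMES = FALSE)
}

#' Repetitive-sequence filter
#'
#' Fails any sequence containing a mononucleotide run of 6 or more bases
#' (more than 5 repeats) or 5 or more tandem copies of a two-base motif
#' with distinct bases (more than 4 dinucleotide repeats).
#'
#' @param seq Character vector of unambiguous sequences.
#' @return Logical vector (`TRUE` = pass) with a `reason` attribute naming
#'   the offending run for each failure ("" for passes).
#' @export
repeat_filter <- function(seq) {
  check_alphabet(seq, ambiguity_ok = FALSE)
  seq <- toupper(seq)
  reason <- character(length(seq))
  pass <- rep(TRUE, length(seq))
  mono <- regmatches(seq, regexpr("(A{6,}|C{6,}|G{6,}|T{6,})", seq))
  hit_mono <- grepl("(A{6,}|C{6,}|G{6,}|T{6,})", seq)
  pass[hit_mono] <- FALSE
  reason[hit_mono] <- paste0("mononucleotide run ", mono)
  m <- regexpr("([ACGT][ACGT])\\1{4,}", seq, perl = TRUE)
  hit_di <- m > 0 & pass
  if (any(hit_di)) {
    runs <- substring(seq[hit_di], m[hit_di], m[hit_di] + 1L)
    # require the two bases of the motif to differ (AA runs are
    # mononucleotide territory)
    distinct <- substring(runs, 1L, 1L) != substring(runs, 2L, 2L)
    idx <- which(hit_di)[distinct]
    pass[idx] <- FALSE
    reason[idx] <- paste0("dinucleotide run ", runs[distinct], "x5+")
  }
  structure(pass, reason = reason)
}

#' 3'-terminal GC clamp
#'
#' @param seq Primer sequences in their own 5'->3' orientation (reverse
#'   primers are evaluated on the primer string, not the template strand).
#' @return Logical: `TRUE` when the 3'-terminal base is G or C.
#' @export
has_gc_clamp <- function(seq) {
  check_alphabet(seq, ambiguity_ok = FALSE)
  substring(toupper(seq), nchar(seq), nchar(seq)) %in% c("G", "C")
}
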