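#' Primer design parameters
#'
#' All user-tunable constraints for batch design. Defaults: primer length
#' 18-27 nt, Tm 52-62 C, GC 35-65%, 150-nt search windows at each end,
#' repetitive sequence excluded, no GC clamp requirement, specificity check
#' off.
#'
#' @param len_min,len_max Primer length bounds in nt.
#' @param tm_min,tm_max Melting-temperature bounds in degrees Celsius.
#' @param gc_min,gc_max GC-content bounds in percent.
#' @param window5 Forward-primer search span from the 5' end of each
#'   template, in nt.
#' @param window3 Reverse-primer search span from the 3' end, in nt.
#' @param require_gc_clamp Require a G or C at the 3' terminus (never
#'   enforced for allele-specific primers).
#' @param allow_repeats Keep candidates containing mononucleotide runs > 5
#'   or dinucleotide tandem repeats > 4 (excluded by default).
#' @param check_specificity Require each primer to occur exactly once
#'   across the whole input set (both strands, up to `max_mismatches`).
#' @param max_mismatches Mismatches tolerated by the specificity search.
#' @param thresholds A [score_thresholds()] object.
#' @param thermo A [thermo_conditions()] object.
#' @return A `design_params` list.
#' @export
design_params <- function(len_min = 18L, len_max = 27L,
                          tm_min = 52, tm_max = 62,
                          gc_min = 35, gc_max = 65,
                          window5 = 150L, window3 = 150L,
                          require_gc_clamp = FALSE,
                          allow_repeats = FALSE,
                          check_specificity = FALSE,
                          max_mismatches = 0L,
                          thresholds = score_thresholds(),
                          thermo = thermo_conditions()) {
  stopifnot(len_min >= 8, len_min <= len_max, tm_min <= tm_max,
            gc_min <= gc_max, window5 >= len_min, window3 >= len_min,
            max_mismatches >= 0)
  structure(list(len_min = as.integer(len_min), len_max = as.integer(len_max),
                 tm_min = tm_min, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 window5 = as.integer(window5), window3 = as.integer(window3),
                 require_gc_clamp = isTRUE(require_gc_clamp),
                 allow_repeats = isTRUE(allow_repeats),
                 check_specificity = isTRUE(check_specificity),
                 max_mismatches = as.integer(max_mismatches),
                 thresholds = thresholds, thermo = thermo),
            class = "design_params")
}

empty_candidates <- function() {
  data.frame(source_id = character(0), orientation = character(0),
             start = integer(0), length = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Enumerate raw primer candidates inside the search windows
#'
#' Forward candidates are every substring fully inside the first `window5`
#' bases; reverse candidates are reverse complements of every substring
#' fully inside the last `window3` bases. Windows larger than the sequence
#' are clipped. The `start` coordinate is always the 1-based plus-strand
#' position of the primer's 5' terminus (so a reverse candidate's start is
#' the right end of its template interval). No filters are applied.
#'
#' @param record A one-row data frame (or list) with `id` and `residues`.
#' @param params A [design_params()] object.
#' @return Data frame of candidates: `source_id`, `orientation`, `start`,
#'   `length`, `sequence`.
#' @export
enumerate_candidates <- function(record, params = design_params()) {
  residues <- record$residues[[1L]]
  id <- record$id[[1L]]
  L <- nchar(residues)
  if (L < params$len_min) {
    stop("record '", id, "' (", L, " nt) is shorter than len_min = ",
         params$len_min, call. = FALSE)
  }
  rows <- list(empty_candidates())
  w5 <- min(params$window5, L)
  w3 <- min(params$window3, L)
  left3 <- L - w3 + 1L
  for (len in seq.int(params$len_min, min(params$len_max, L))) {
    if (w5 >= len) {
      starts <- seq.int(1L, w5 - len + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = id, orientation = "forward", start = starts,
        length = len,
        sequence = substring(residues, starts, starts + len - 1L),
        stringsAsFactors = FALSE)
    }
    if (w3 >= len) {
      ends <- seq.int(left3 + len - 1L, L)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = id, orientation = "reverse", start = ends,
        length = len,
        sequence = reverse_complement(substring(residues, ends - len + 1L,
                                                ends)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

accepted_schema <- function() {
  data.frame(source_id = character(0), name = character(0),
             orientation = character(0), start = integer(0),
             length = integer(0), sequence = character(0),
             tm = numeric(0), gc_percent = numeric(0), selfcomp = integer(0),
             hairpin_dg = numeric(0), stringsAsFactors = FALSE)
}

#' Filter raw candidates down to accepted primers
#'
#' A candidate survives when its GC%, Tm, repeat content, GC clamp (if
#' required), self-complementarity (strictly below the threshold), hairpin
#' delta-G (at or above the floor) and, optionally, whole-input-set
#' specificity all pass. Survivors are deduplicated by (sequence,
#' orientation), keeping the smallest start, and sorted by start.
#' Filters are evaluated cheapest first; the order never changes the
#' accepted set.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param records The full input record set (used by the specificity check).
#' @param params A [design_params()] object.
#' @param enforce_clamp Override for the GC-clamp requirement
#'   (allele-specific primers are always exempt).
#' @return Accepted primers with metric columns `tm`, `gc_percent`,
#'   `selfcomp`, `hairpin_dg` and a `name` equal to the start coordinate.
#' @export
apply_filters <- function(candidates, records, params = design_params(),
                          enforce_clamp = params$require_gc_clamp) {
  if (nrow(candidates) == 0L) return(accepted_schema())
  keep <- !grepl("[RYMKWSBDHVN]", candidates$sequence)
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(accepted_schema())

  # dedup before scoring: every filter depends only on (sequence,
  # orientation), so keeping the smallest start first is equivalent
  ord <- order(cand$start, match(cand$orientation, c("forward", "reverse")))
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand[c("sequence", "orientation")]), , drop = FALSE]

  gc <- gc_percent(cand$sequence)
  keep <- gc >= params$gc_min & gc <= params$gc_max
  cand <- cand[keep, , drop = FALSE]; gc <- gc[keep]
  if (nrow(cand) == 0L) return(accepted_schema())

  if (!params$allow_repeats) {
    keep <- as.logical(repeat_filter(cand$sequence))
    cand <- cand[keep, , drop = FALSE]; gc <- gc[keep]
    if (nrow(cand) == 0L) return(accepted_schema())
  }
  if (enforce_clamp) {
    keep <- has_gc_clamp(cand$sequence)
    cand <- cand[keep, , drop = FALSE]; gc <- gc[keep]
    if (nrow(cand) == 0L) return(accepted_schema())
  }

  tm <- tm_calc(cand$sequence, params$thermo)
  keep <- tm >= params$tm_min & tm <= params$tm_max
  cand <- cand[keep, , drop = FALSE]; gc <- gc[keep]; tm <- tm[keep]
  if (nrow(cand) == 0L) return(accepted_schema())

  selfc <- self_complementarity(cand$sequence)
  hp <- hairpin_dg(cand$sequence)
  keep <- selfc < params$thresholds$selfcomp_max &
    hp >= params$thresholds$hairpin_dg_min
  cand <- cand[keep, , drop = FALSE]
  gc <- gc[keep]; tm <- tm[keep]; selfc <- selfc[keep]; hp <- hp[keep]
  if (nrow(cand) == 0L) return(accepted_schema())

  if (params$check_specificity) {
    counts <- vapply(cand$sequence, specificity_count, integer(1),
                     records = records,
                     max_mismatches = params$max_mismatches,
                     USE.NAMES = FALSE)
    keep <- counts == 1L
    cand <- cand[keep, , drop = FALSE]
    gc <- gc[keep]; tm <- tm[keep]; selfc <- selfc[keep]; hp <- hp[keep]
    if (nrow(cand) == 0L) return(accepted_schema())
  }

  out <- data.frame(source_id = cand$source_id,
                    name = as.character(cand$start),
                    orientation = cand$orientation,
                    start = cand$start, length = cand$length,
                    sequence = cand$sequence, tm = tm, gc_percent = gc,
                    selfcomp = selfc, hairpin_dg = hp,
                    stringsAsFactors = FALSE)
  ord <- order(out$start, match(out$orientation, c("forward", "reverse")),
               out$length)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count occurrences of a primer across an input set
#'
#' Number of ungapped alignment positions, on both strands of every record,
#' at which the primer matches with at most `max_mismatches` substitutions.
#' The primer's own origin site counts, so a count of 1 means "specific to
#' the whole input file".
#'
#' @param primer Unambiguous primer sequence.
#' @param records Data frame of records (`id`, `residues`).
#' @param max_mismatches Tolerated Hamming distance.
#' @return Integer occurrence count.
#' @export
specificity_count <- function(primer, records, max_mismatches = 0L) {
  check_alphabet(primer, ambiguity_ok = FALSE)
  primer <- toupper(primer)
  wide <- nchar(records$residues) >= nchar(primer)
  if (!any(wide)) return(0L)
  subjects <- Biostrings::DNAStringSet(records$residues[wide])
  fwd <- Biostrings::vcountPattern(primer, subjects,
                                   max.mismatch = max_mismatches,
                                   fixed = TRUE)
  rev <- Biostrings::vcountPattern(reverse_complement(primer), subjects,
                                   max.mismatch = max_mismatches,
                                   fixed = TRUE)
  as.integer(sum(fwd) + sum(rev))
}

#' Batch primer design over a record set
#'
#' Runs window enumeration and filtering per record (in input-file order)
#' and assembles the primer table plus positional records for mapping.
#' Per-record failures (for example a record shorter than `len_min`) are
#' collected, not fatal to the batch.
#'
#' @param records Data frame from [read_fasta()].
#' @param params A [design_params()] object.
#' @return List with `primers` (accepted primer table), `positions`
#'   (positional records, see [positional_records()]) and `errors`
#'   (named character vector of per-record failure messages).
#' @export
design_batch <- function(records, params = design_params()) {
  stopifnot(nrow(records) >= 1L)
  errors <- character(0)
  per_record <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    per_record[[i]] <- tryCatch({
      cand <- enumerate_candidates(records[i, , drop = FALSE], params)
      apply_filters(cand, records, params)
    }, error = function(e) {
      errors[[records$id[i]]] <<- conditionMessage(e)
      accepted_schema()
    })
  }
  primers <- do.call(rbind, per_record)
  rownames(primers) <- NULL
  list(primers = primers, positions = positional_records(primers),
       errors = errors)
}

#' Design primers flanking (bracketing) a SNP
#'
#' Forward candidates end strictly before the SNP; reverse candidates start
#' strictly after it (on the plus strand), each within the respective
#' search window, so any forward/reverse pair brackets the site and no
#' candidate overlaps the ambiguity code. Filtering as in
#' [apply_filters()].
#'
#' @param snp One row of a [read_rs_fasta()] data frame.
#' @param params A [design_params()] object.
#' @return Accepted primer table (same schema as [apply_filters()]).
#' @export
design_snp_flanking <- function(snp, params = design_params()) {
  residues <- snp$residues[[1L]]
  pos <- snp$snp_position[[1L]]
  L <- nchar(residues)
  if (pos - 1L < params$len_min) {
    stop("record '", snp$id[[1L]], "': SNP too close to 5' end for a ",
         params$len_min, "-nt primer", call. = FALSE)
  }
  if (L - pos < params$len_min) {
    stop("record '", snp$id[[1L]], "': SNP too close to 3' end for a ",
         params$len_min, "-nt primer", call. = FALSE)
  }
  id <- snp$id[[1L]]
  lo_f <- max(1L, pos - params$window5)
  hi_f <- pos - 1L
  lo_r <- pos + 1L
  hi_r <- min(L, pos + params$window3)
  rows <- list(empty_candidates())
  for (len in seq.int(params$len_min, params$len_max)) {
    if (hi_f - lo_f + 1L >= len) {
      starts <- seq.int(lo_f, hi_f - len + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = id, orientation = "forward", start = starts,
        length = len,
        sequence = substring(residues, starts, starts + len - 1L),
        stringsAsFactors = FALSE)
    }
    if (hi_r - lo_r + 1L >= len) {
      ends <- seq.int(lo_r + len - 1L, hi_r)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = id, orientation = "reverse", start = ends,
        length = len,
        sequence = reverse_complement(substring(residues, ends - len + 1L,
                                                ends)),
        stringsAsFactors = FALSE)
    }
  }
  apply_filters(do.call(rbind, rows), snp, params)
}

#' Design allele-specific genotyping primers at a SNP
#'
#' For each allele and orientation, the primer's 3' terminus is anchored
#' exactly at the SNP position with terminal base equal to the allele
#' (forward) or its complement (reverse); the remainder is copied from the
#' template. Among lengths `len_min..len_max` whose Tm lies in range, the
#' one closest to the midpoint `(tm_min + tm_max)/2` is kept (ties go to
#' the shorter primer). The GC-clamp requirement never applies here: the 3'
#' base is dictated by the allele. The alphabetically first allele is
#' labelled `wildtype`, the others `polymorphic` (a naming convention, not
#' an ancestry claim).
#'
#' @param snp One row of a [read_rs_fasta()] data frame.
#' @param params A [design_params()] object.
#' @return Data frame with columns `snp_id`, `allele`, `label`,
#'   `orientation`, `name`, `start`, `length`, `sequence`, `tm`,
#'   `gc_percent`, `selfcomp`, `hairpin_dg`, plus a `failures` attribute
#'   naming allele/orientation combinations with no admissible length.
#' @export
design_allele_specific <- function(snp, params = design_params()) {
  residues <- snp$residues[[1L]]
  pos <- snp$snp_position[[1L]]
  L <- nchar(residues)
  id <- snp$id[[1L]]
  alleles <- sort(snp$alleles[[1L]])
  tm_mid <- (params$tm_min + params$tm_max) / 2
  out <- list()
  failures <- character(0)
  for (allele in alleles) {
    label <- if (allele == alleles[1L]) "wildtype" else "polymorphic"
    for (orientation in c("forward", "reverse")) {
      best <- NULL
      for (len in seq.int(params$len_min, params$len_max)) {
        if (orientation == "forward") {
          s <- pos - len + 1L
          if (s < 1L) next
          seqc <- substring(residues, s, pos)
          substr(seqc, len, len) <- allele
          start <- s
        } else {
          e <- pos + len - 1L
          if (e > L) next
          plus <- substring(residues, pos, e)
          substr(plus, 1L, 1L) <- allele
          seqc <- reverse_complement(plus)
          start <- e
        }
        if (grepl("[RYMKWSBDHVN]", seqc)) next
        tm <- tm_calc(seqc, params$thermo)
        if (tm < params$tm_min || tm > params$tm_max) next
        dist <- abs(tm - tm_mid)
        if (is.null(best) || dist < best$dist) {
          best <- list(dist = dist, len = len, seq = seqc, tm = tm,
                       start = start)
        }
      }
      if (is.null(best)) {
        failures <- c(failures, sprintf("%s %s/%s: no length with Tm in [%g, %g]",
                                        id, allele, orientation,
                                        params$tm_min, params$tm_max))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        snp_id = id, allele = allele, label = label,
        orientation = orientation, name = as.character(best$start),
        start = best$start, length = best$len, sequence = best$seq,
        tm = best$tm, gc_percent = gc_percent(best$seq),
        selfcomp = self_complementarity(best$seq),
        hairpin_dg = hairpin_dg(best$seq), stringsAsFactors = FALSE)
    }
  }
  result <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(0), allele = character(0),
               label = character(0), orientation = character(0),
               name = character(0), start = integer(0), length = integer(0),
               sequence = character(0), tm = numeric(0),
               gc_percent = numeric(0), selfcomp = integer(0),
               hairpin_dg = numeric(0), stringsAsFactors = FALSE)
  rownames(result) <- NULL
  attr(result, "failures") <- failures
  result
}

#' All-pairs primer-dimer compatibility report
#'
#' Scores every unordered pair of primers (n choose 2) with the
#' cross-dimer score, for multiplex PCR pool vetting.
#'
#' @param primers Either a primer table with `name` and `sequence` columns
#'   (a `source_id` column, if present, qualifies duplicate names) or a
#'   named character vector of sequences.
#' @param thresholds A [score_thresholds()] object; pairs scoring at or
#'   above `dimer_flag_level` are flagged.
#' @return List with `n`, `k` (= 2) and `pairs`, a data frame of
#'   `name_a`, `name_b`, `score`, `flagged` with exactly n(n-1)/2 rows,
#'   ordered by the pair names.
#' @export
dimer_report <- function(primers, thresholds = score_thresholds()) {
  if (is.character(primers)) {
    seqs <- unname(primers)
    labels <- if (!is.null(names(primers))) names(primers) else
      as.character(seq_along(primers))
  } else {
    seqs <- primers$sequence
    labels <- primers$name
    if (anyDuplicated(labels) && "source_id" %in% names(primers)) {
      labels <- paste(primers$source_id, labels, sep = "_")
    }
    if (anyDuplicated(labels) && "length" %in% names(primers)) {
      labels <- paste0(labels, "L", primers$length)
    }
    if (anyDuplicated(labels) && "orientation" %in% names(primers)) {
      labels <- paste0(labels, substr(primers$orientation, 1L, 1L))
    }
  }
  n <- length(seqs)
  if (n < 2L) stop("dimer report needs at least 2 primers", call. = FALSE)
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }
  rc <- reverse_complement(seqs)
  idx <- utils::combn(n, 2L)
  score <- vapply(seq_len(ncol(idx)), function(j) {
    pairing_max_cpp(seqs[idx[1L, j]], rc[idx[2L, j]])
  }, integer(1))
  a <- labels[idx[1L, ]]
  b <- labels[idx[2L, ]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  pairs <- data.frame(name_a = a, name_b = b, score = score,
                      flagged = score >= thresholds$dimer_flag_level,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$name_a, pairs$name_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(n = n, k = 2L, pairs = pairs)
}
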