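# Independent brute-force oracles, deliberately coded apart from the
# package implementations (pure R, no shared helpers).

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# shift-maximised pairing count between a and reverse complement of b,
# as two explicit loops over shifts and positions
oracle_dimer_score <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  cv <- strsplit(oracle_revcomp(b), "")[[1L]]
  la <- length(av); lc <- length(cv)
  best <- 0L
  for (shift in seq.int(-(lc - 1L), la - 1L)) {
    i <- seq.int(max(1L, shift + 1L), min(la, lc + shift))
    best <- max(best, sum(av[i] == cv[i - shift]))
  }
  best
}

# exhaustive stem-loop enumeration with the additive energy model
oracle_hairpin <- function(s) {
  v <- strsplit(s, "")[[1L]]
  n <- length(v)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  best <- 0
  for (k in 3:max(3L, n)) {
    for (loop in 3:12) {
      span <- 2L * k + loop
      if (span > n) next
      for (i in seq_len(n - span + 1L)) {
        pairs_ok <- TRUE
        e <- 3.5
        for (j in seq_len(k)) {
          x <- v[i + j - 1L]; y <- v[i + span - j]
          if (comp[[x]] != y) { pairs_ok <- FALSE; break }
          e <- e + if (x %in% c("G", "C")) -1.5 else -1.0
        }
        if (pairs_ok && e < best) best <- e
      }
    }
  }
  best
}

# both-strand ungapped window scan counting matches with Hamming
# distance <= m; vectorised per window offset, not per window
oracle_specificity <- function(primer, records, m) {
  p <- strsplit(primer, "")[[1L]]
  k <- length(p)
  total <- 0L
  for (res in records$residues) {
    v <- strsplit(res, "")[[1L]]
    L <- length(v)
    if (L < k) next
    for (q in list(p, strsplit(oracle_revcomp(primer), "")[[1L]])) {
      mism <- integer(L - k + 1L)
      for (j in seq_len(k)) {
        mism <- mism + (v[seq.int(j, L - k + j)] != q[j])
      }
      total <- total + sum(mism <= m)
    }
  }
  total
}

# independent re-check of every enabled design constraint, including
# sequence/template consistency of the reported coordinates
verify_primers <- function(primers, records, params) {
  if (nrow(primers) == 0L) return(TRUE)
  for (i in seq_len(nrow(primers))) {
    p <- primers[i, ]
    template <- records$residues[records$id == p$source_id]
    tmpl_seq <- if (p$orientation == "forward") {
      substring(template, p$start, p$start + p$length - 1L)
    } else {
      oracle_revcomp(substring(template, p$start - p$length + 1L, p$start))
    }
    gc <- 100 * sum(strsplit(p$sequence, "")[[1L]] %in% c("G", "C")) /
      nchar(p$sequence)
    checks <- c(
      sequence_matches_template = identical(tmpl_seq, p$sequence),
      name_is_start = identical(p$name, as.character(p$start)),
      length_in_range = p$length >= params$len_min &&
        p$length <= params$len_max,
      gc_in_range = gc >= params$gc_min && gc <= params$gc_max,
      tm_in_range = p$tm >= params$tm_min && p$tm <= params$tm_max,
      tm_reproducible = abs(tm_calc(p$sequence, params$thermo) - p$tm) < 1e-9,
      repeats_ok = params$allow_repeats || oracle_repeat_pass(p$sequence),
      clamp_ok = !params$require_gc_clamp ||
        substring(p$sequence, nchar(p$sequence)) %in% c("G", "C"),
      selfcomp_ok = oracle_dimer_score(p$sequence, p$sequence) <
        params$thresholds$selfcomp_max,
      hairpin_ok = oracle_hairpin(p$sequence) >=
        params$thresholds$hairpin_dg_min,
      specificity_ok = !params$check_specificity ||
        oracle_specificity(p$sequence, records, params$max_mismatches) == 1L)
    if (!all(checks)) {
      return(structure(FALSE, failed = names(checks)[!checks],
                       primer = p$sequence))
    }
  }
  TRUE
}

# explicit run scan: no base repeated 6+ times in a row, no two-distinct-base
# motif tandemly repeated 5+ times
oracle_repeat_pass <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  runs <- rle(v)
  if (any(runs$lengths >= 6L)) return(FALSE)
  n <- length(v)
  for (i in seq_len(max(0L, n - 9L))) {
    motif <- v[c(i, i + 1L)]
    if (motif[1L] == motif[2L]) next
    reps <- 1L
    j <- i + 2L
    while (j + 1L <= n && v[j] == motif[1L] && v[j + 1L] == motif[2L]) {
      reps <- reps + 1L
      j <- j + 2L
    }
    if (reps >= 5L) return(FALSE)
  }
  TRUE
}

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
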