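# Nearest-neighbor thermodynamic parameter sets.
# Breslauer et al. 1986 (PNAS 83:3746) duplex stacks; SantaLucia 1998
# (PNAS 95:1460) unified set. delta_H kcal/mol, delta_S cal/(mol K).
# Each table carries all 16 dinucleotide steps (symmetric steps duplicated).
.nn_steps <- function(ten) {
  # expand the 10 unique duplex stacks to all 16 steps via the
  # reverse-complement identity XY == rc(XY)
  steps <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
             "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  rc2 <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]),
                                                  collapse = ""))
  out <- numeric(16)
  names(out) <- steps
  for (s in steps) out[s] <- if (s %in% names(ten)) ten[s] else ten[rc2(s)]
  out
}

NN_PARAMS <- list(
  breslauer = list(
    name = "breslauer",
    delta_H = .nn_steps(c(
      AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
      CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0)),
    delta_S = .nn_steps(c(
      AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
      CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6)),
    # classic helix-initiation entropy; no enthalpy of initiation
    init = function(seq) c(dH = 0, dS = -10.8)
  ),
  santalucia = list(
    name = "santalucia",
    delta_H = .nn_steps(c(
      AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
      CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)),
    delta_S = .nn_steps(c(
      AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
      CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)),
    # per-terminal initiation: G/C end (+0.1, -2.8), A/T end (+2.3, +4.1)
    init = function(seq) {
      ends <- c(substring(seq, 1L, 1L), substring(seq, nchar(seq), nchar(seq)))
      gc_ends <- sum(ends %in% c("G", "C"))
      at_ends <- 2L - gc_ends
      c(dH = 0.1 * gc_ends + 2.3 * at_ends,
        dS = -2.8 * gc_ends + 4.1 * at_ends)
    }
  )
)

GAS_CONSTANT <- 1.987 # cal/(mol K)

#' Thermodynamic reaction conditions
#'
#' @param monovalent_salt Monovalent cation concentration in mol/L
#'   (default 0.05 M). Must lie in (0, 1].
#' @param primer_concentration Total oligonucleotide concentration in mol/L
#'   (default 5e-8 M, i.e. 50 nM).
#' @param engine Tm engine: `"breslauer"` (nearest neighbor, Schildkraut salt
#'   correction; the default engine), `"santalucia"` (unified nearest
#'   neighbor, Owczarzy salt correction) or `"basic"` (length/GC rule).
#' @return A `thermo_conditions` list.
#' @export
thermo_conditions <- function(monovalent_salt = 0.05,
                              primer_concentration = 5e-8,
                              engine = c("breslauer", "santalucia", "basic")) {
  engine <- match.arg(engine)
  stopifnot(monovalent_salt > 0, monovalent_salt <= 1.0,
            primer_concentration > 0)
  structure(list(monovalent_salt = monovalent_salt,
                 primer_concentration = primer_concentration,
                 engine = engine),
            class = "thermo_conditions")
}

#' GC content of a sequence, in percent
#'
#' @param seq Character vector of unambiguous A/C/G/T strings.
#' @return Numeric vector, 100 * (G + C) / length.
#' @examples
#' gc_percent("GGCC") # 100
#' @export
gc_percent <- function(seq) {
  check_alphabet(seq, ambiguity_ok = FALSE)
  seq <- toupper(seq)
  100 * (nchar(gsub("[AT]", "", seq))) / nchar(seq)
}

#' Basic length/GC melting temperature
#'
#' The Wallace rule `2(A+T) + 4(G+C)` for primers shorter than 14 nt and the
#' GC-fraction formula `64.9 + 41 (G+C - 16.4) / length` otherwise.
#'
#' @param seq Character vector of unambiguous sequences, each >= 8 nt.
#' @param conditions Ignored by this engine; accepted for interface parity.
#' @return Tm in degrees Celsius.
#' @export
tm_basic <- function(seq, conditions = thermo_conditions()) {
  check_alphabet(seq, ambiguity_ok = FALSE)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (any(n < 8L)) stop("sequence shorter than 8 nt", call. = FALSE)
  gc <- nchar(gsub("[AT]", "", seq))
  at <- n - gc
  ifelse(n < 14L, 2 * at + 4 * gc, 64.9 + 41 * (gc - 16.4) / n)
}

.nn_sums <- function(seq, params) {
  chars <- strsplit(seq, "")[[1L]]
  steps <- paste0(chars[-length(chars)], chars[-1L])
  init <- params$init(seq)
  c(dH = sum(params$delta_H[steps]) + init[["dH"]],
    dS = sum(params$delta_S[steps]) + init[["dS"]])
}

# Schildkraut & Lifson: additive 16.6 log10([Na+]) relative to the 1 M
# reference at which the NN tables are defined.
salt_schildkraut <- function(tm_celsius, na_molar) {
  tm_celsius + 16.6 * log10(na_molar)
}

# Owczarzy et al. 2004 reciprocal-temperature correction with the
# GC-fraction term: 1/Tm([Na+]) = 1/Tm(1M)
#   + (4.29 fGC - 3.95) 1e-5 ln[Na+] + 9.40e-6 ln^2[Na+]
salt_owczarzy <- function(tm_celsius, na_molar, gc_fraction) {
  tm_k <- tm_celsius + 273.15
  inv <- 1 / tm_k + (4.29 * gc_fraction - 3.95) * 1e-5 * log(na_molar) +
    9.40e-6 * log(na_molar)^2
  1 / inv - 273.15
}

#' Nearest-neighbor melting temperature
#'
#' Sums published dinucleotide-stack enthalpies and entropies plus
#' initiation terms; Tm(K) = dH / (dS + R ln(C_T/4)), converted to Celsius
#' and salt-corrected (Schildkraut additive term for the Breslauer set,
#' Owczarzy GC-dependent reciprocal-temperature form for the SantaLucia
#' set).
#'
#' @param seq Character vector of unambiguous sequences, each >= 8 nt.
#' @param conditions A [thermo_conditions()] object supplying the monovalent
#'   salt and primer concentration.
#' @param parameter_set `"breslauer"` or `"santalucia"`.
#' @return Tm in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(seq, conditions = thermo_conditions(),
                                parameter_set = c("breslauer", "santalucia")) {
  parameter_set <- match.arg(parameter_set)
  check_alphabet(seq, ambiguity_ok = FALSE)
  seq <- toupper(seq)
  if (any(nchar(seq) < 8L)) stop("sequence shorter than 8 nt", call. = FALSE)
  params <- NN_PARAMS[[parameter_set]]
  ct_term <- GAS_CONSTANT * log(conditions$primer_concentration / 4)
  vapply(seq, function(s) {
    sums <- .nn_sums(s, params)
    tm_1m <- 1000 * sums[["dH"]] / (sums[["dS"]] + ct_term) - 273.15
    if (parameter_set == "breslauer") {
      salt_schildkraut(tm_1m, conditions$monovalent_salt)
    } else {
      salt_owczarzy(tm_1m, conditions$monovalent_salt,
                    (nchar(gsub("[AT]", "", s))) / nchar(s))
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Melting temperature under a conditions object's engine
#'
#' Dispatches to [tm_basic()] or [tm_nearest_neighbor()] according to
#' `conditions$engine`. The package default engine is the Breslauer
#' nearest-neighbor model with Schildkraut salt correction at 50 mM
#' monovalent salt and 50 nM primer.
#'
#' @inheritParams tm_nearest_neighbor
#' @return Tm in degrees Celsius.
#' @export
tm_calc <- function(seq, conditions = thermo_conditions()) {
  switch(conditions$engine,
         basic = tm_basic(seq, conditions),
         breslauer = tm_nearest_neighbor(seq, conditions, "breslauer"),
         santalucia = tm_nearest_neighbor(seq, conditions, "santalucia"))
}

#' Cross-engine Tm correlation
#'
#' Computes paired melting temperatures for a primer set under two engines
#' and returns their squared Pearson correlation, as used to benchmark one
#' Tm model against another.
#'
#' @param primers Character vector of >= 3 primer sequences.
#' @param engine_a,engine_b [thermo_conditions()] objects.
#' @return A list with `r_squared` and the paired values `tm_a`, `tm_b`.
#' @export
compare_tm_engines <- function(primers, engine_a, engine_b) {
  if (length(primers) < 3L) stop("need at least 3 primers", call. = FALSE)
  tm_a <- tm_calc(primers, engine_a)
  tm_b <- tm_calc(primers, engine_b)
  if (stats::sd(tm_a) == 0 || stats::sd(tm_b) == 0) {
    stop("degenerate Tm variance: all values equal under one engine",
         call. = FALSE)
  }
  list(r_squared = stats::cor(tm_a, tm_b)^2, tm_a = tm_a, tm_b = tm_b)
}

#' Seeded random primer generator
#'
#' Draws `n` primers with lengths uniform on `[length_min, length_max]`.
#' Each primer gets a target GC fraction uniform on `[gc_low, gc_high]`; the
#' rounded number of G/C positions is placed uniformly at random (so a
#' 20-mer at target 0.5 has exactly 10 G/C bases).
#'
#' @param n Number of primers.
#' @param length_min,length_max Length bounds in nt (min >= 8).
#' @param gc_low,gc_high GC-fraction bounds in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Character vector of `n` sequences.
#' @export
random_primers <- function(n, length_min = 18L, length_max = 30L,
                           gc_low = 0.2, gc_high = 0.8, seed = 1L) {
  stopifnot(n >= 1, length_min >= 8, length_min <= length_max,
            gc_low >= 0, gc_low <= gc_high, gc_high <= 1)
  set.seed(as.integer(seed))
  lens <- length_min +
    sample.int(length_max - length_min + 1L, n, replace = TRUE) - 1L
  gc_targets <- stats::runif(n, gc_low, gc_high)
  vapply(seq_len(n), function(i) {
    len <- lens[i]
    n_gc <- round(gc_targets[i] * len)
    bases <- character(len)
    gc_pos <- sample.int(len, n_gc)
    at_pos <- setdiff(seq_len(len), gc_pos)
    if (n_gc > 0L) bases[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    if (length(at_pos) > 0L)
      bases[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
    paste0(bases, collapse = "")
  }, character(1))
}
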