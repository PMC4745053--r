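#' Simulate random DNA records
#'
#' Each record draws a GC target uniform on `[0.35, 0.65]` and samples
#' bases i.i.d. at that composition, emulating typical genomic or
#' transcript templates. Fully reproducible from the seed.
#'
#' @param n_records Number of records (>= 1).
#' @param length Record length in nt (>= 50).
#' @param seed Integer seed.
#' @param gc_low,gc_high Per-record GC-target bounds.
#' @return Record data frame (`id`, `description`, `residues`).
#' @export
simulate_dna <- function(n_records, length = 1000L, seed = 1L,
                         gc_low = 0.35, gc_high = 0.65) {
  stopifnot(n_records >= 1, length >= 50)
  set.seed(as.integer(seed))
  gc <- stats::runif(n_records, gc_low, gc_high)
  residues <- vapply(seq_len(n_records), function(i) {
    paste0(sample(c("G", "C", "A", "T"), length, replace = TRUE,
                  prob = c(gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2,
                           (1 - gc[i]) / 2)), collapse = "")
  }, character(1))
  data.frame(id = sprintf("seq%03d", seq_len(n_records)),
             description = sprintf("simulated length=%d", length),
             residues = residues, stringsAsFactors = FALSE)
}

#' Simulate SNP flanking-sequence records (rs_fastA shape)
#'
#' Records of the canonical dbSNP flanking shape: odd length, a biallelic
#' IUPAC ambiguity code (drawn from R, Y, M, K, W, S) at the centre
#' position, and a header carrying `pos = <centre>|len<length>`.
#'
#' @param n_records Number of records (>= 1).
#' @param length Odd record length >= 101 (default 1001, giving
#'   `pos = 501|len1001`).
#' @param seed Integer seed.
#' @return Data frame in [read_rs_fasta()] layout.
#' @export
simulate_snp <- function(n_records, length = 1001L, seed = 1L) {
  stopifnot(n_records >= 1, length >= 101, length %% 2L == 1L)
  set.seed(as.integer(seed))
  centre <- (length + 1L) %/% 2L
  ids <- sprintf("rs%06d", sample.int(999999L, n_records))
  base <- simulate_dna(n_records, length, seed = sample.int(2^30, 1L))
  codes <- sample(c("R", "Y", "M", "K", "W", "S"), n_records, replace = TRUE)
  residues <- base$residues
  substr(residues, centre, centre) <- codes
  data.frame(id = ids,
             description = sprintf("pos = %d|len%d", centre, length),
             residues = residues, snp_position = centre,
             declared_length = length, iupac_code = codes,
             alleles = I(lapply(codes, expand_iupac)),
             stringsAsFactors = FALSE)
}

#' Write simulated fixtures to disk
#'
#' Generates a seeded FASTA (`kind = "dna"`) or rs_fastA (`kind = "snp"`)
#' file; identical arguments give byte-identical files.
#'
#' @param kind `"dna"` or `"snp"`.
#' @param n_records Number of records.
#' @param length Record length (odd and >= 101 for `"snp"`, >= 50 for
#'   `"dna"`).
#' @param seed Integer seed.
#' @param out Output file path.
#' @return Invisibly, `out`.
#' @export
simulate_fixtures <- function(kind = c("dna", "snp"), n_records, length,
                              seed = 1L, out) {
  kind <- match.arg(kind)
  records <- switch(kind,
                    dna = simulate_dna(n_records, length, seed),
                    snp = simulate_snp(n_records, length, seed))
  write_fasta(records, out)
  invisible(out)
}
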