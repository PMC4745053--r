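#' @useDynLib primerworks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Allowed residue alphabet: the four bases plus the 11 IUPAC ambiguity codes.
DNA_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIGUITY <- c("R", "Y", "M", "K", "W", "S", "B", "D", "H", "V", "N")
DNA_ALPHABET <- c(DNA_BASES, IUPAC_AMBIGUITY)

# R = A/G, Y = C/T, M = A/C, K = G/T, W = A/T, S = C/G,
# B = C/G/T, D = A/G/T, H = A/C/T, V = A/C/G, N = A/C/G/T
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC code to its base set
#'
#' @param code A single residue character (base or IUPAC ambiguity code).
#' @return Character vector of bases in alphabetical order; length 1 for the
#'   unambiguous bases A/C/G/T.
#' @examples
#' expand_iupac("R") # A G
#' expand_iupac("N") # A C G T
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("`code` must be a single character", call. = FALSE)
  }
  code <- toupper(code)
  out <- IUPAC_EXPANSION[[code]]
  if (is.null(out)) stop("unknown IUPAC code: '", code, "'", call. = FALSE)
  out
}

#' Reverse complement of a DNA string
#'
#' Antiparallel complement; IUPAC ambiguity codes map to their IUPAC
#' complements (R<->Y, M<->K, W<->W, S<->S, B<->V, D<->H, N<->N).
#'
#' @param seq Character vector of residue strings over the IUPAC alphabet.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("ATGC") # "GCAT"
#' @export
reverse_complement <- function(seq) {
  check_alphabet(seq)
  if (length(seq) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

check_alphabet <- function(seq, ambiguity_ok = TRUE) {
  if (!is.character(seq)) stop("sequence must be character", call. = FALSE)
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  pat <- if (ambiguity_ok) "^[ACGTRYMKWSBDHVNacgtrymkwsbdhvn]+$" else "^[ACGTacgt]+$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    chars <- gsub(if (ambiguity_ok) "[ACGTRYMKWSBDHVN]" else "[ACGT]", "",
                  toupper(seq[bad][1L]))
    stop("illegal residue character(s) '", substr(chars, 1L, 5L), "' in sequence",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a multi-record DNA FASTA file
#'
#' Residues are uppercased and internal whitespace removed; records are
#' returned in file order. The record id is the first whitespace-delimited
#' token of the header; the full remainder is kept as `description`.
#' Duplicate ids and characters outside the 15-letter IUPAC alphabet are
#' errors, reported with the record id and line number.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header_at <- grep("^>", lines)
  if (length(header_at) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  if (any(nzchar(trimws(lines[seq_len(header_at[1L] - 1L)])))) {
    stop("sequence data before first header in ", path, call. = FALSE)
  }
  ends <- c(header_at[-1L] - 1L, length(lines))
  ids <- character(length(header_at))
  descs <- character(length(header_at))
  seqs <- character(length(header_at))
  for (i in seq_along(header_at)) {
    header <- sub("^>", "", lines[header_at[i]])
    tokens <- strsplit(trimws(header), "\\s+")[[1L]]
    if (length(tokens) == 0L || !nzchar(tokens[1L])) {
      stop("empty record id at line ", header_at[i], call. = FALSE)
    }
    ids[i] <- tokens[1L]
    descs[i] <- trimws(sub("^\\S+", "", trimws(header)))
    body <- lines[seq(header_at[i] + 1L, ends[i])]
    body <- body[nzchar(trimws(body))]
    residues <- toupper(gsub("\\s+", "", paste0(body, collapse = "")))
    if (!nzchar(residues)) {
      stop("record '", ids[i], "' (line ", header_at[i], ") has no sequence",
           call. = FALSE)
    }
    if (!grepl("^[ACGTRYMKWSBDHVN]+$", residues)) {
      bad <- regmatches(residues, regexpr("[^ACGTRYMKWSBDHVN]", residues))
      stop("record '", ids[i], "' (line ", header_at[i],
           "): illegal residue character '", bad, "'", call. = FALSE)
    }
    seqs[i] <- residues
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  data.frame(id = ids, description = descs, residues = seqs,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' Sequence lines are wrapped at 70 columns.
#'
#' @param records Data frame with `id`, `residues` and optionally
#'   `description` columns, as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a dbSNP-style SNP flanking-sequence FASTA ("rs_fastA")
#'
#' Each header must carry the SNP coordinate and declared sequence length as
#' `pos = <int>|len<int>` (whitespace around `=` is tolerated), and the
#' residue at that 1-based position must be an IUPAC ambiguity code encoding
#' the allele set.
#'
#' @param path Path to an rs_fastA file.
#' @return A data frame with columns `id`, `description`, `residues`,
#'   `snp_position`, `declared_length`, `iupac_code`, and a list column
#'   `alleles` (alphabetical base sets).
#' @export
read_rs_fasta <- function(path) {
  records <- read_fasta(path)
  pat <- "pos\\s*=\\s*([0-9]+)\\|len([0-9]+)"
  header <- paste(records$id, records$description)
  m <- regexec(pat, header)
  hits <- regmatches(header, m)
  bad <- vapply(hits, length, 1L) == 0L
  if (any(bad)) {
    stop("record '", records$id[which(bad)[1L]],
         "': header lacks the 'pos = <int>|len<int>' pattern", call. = FALSE)
  }
  records$snp_position <- vapply(hits, function(h) as.integer(h[2L]), 1L)
  records$declared_length <- vapply(hits, function(h) as.integer(h[3L]), 1L)
  actual <- nchar(records$residues)
  off <- records$declared_length != actual
  if (any(off)) {
    i <- which(off)[1L]
    stop("record '", records$id[i], "': declared length ",
         records$declared_length[i], " != actual length ", actual[i],
         call. = FALSE)
  }
  records$iupac_code <- substring(records$residues, records$snp_position,
                                  records$snp_position)
  plain <- records$iupac_code %in% DNA_BASES
  if (any(plain)) {
    i <- which(plain)[1L]
    stop("record '", records$id[i], "': no ambiguity code at SNP site (position ",
         records$snp_position[i], " is '", records$iupac_code[i], "')",
         call. = FALSE)
  }
  records$alleles <- I(lapply(records$iupac_code, expand_iupac))
  records
}
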