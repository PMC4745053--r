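one_record <- function(id, residues) {
  data.frame(id = id, description = "", residues = residues,
             stringsAsFactors = FALSE)
}

test_that("candidate enumeration is window-constrained and coordinate-faithful", {
  set.seed(53)
  rec <- one_record("r1", random_dna(1, 60))
  params <- design_params(len_min = 18, len_max = 20, window5 = 30,
                          window3 = 30)
  cand <- enumerate_candidates(rec, params)
  fwd <- cand[cand$orientation == "forward", ]
  rev <- cand[cand$orientation == "reverse", ]
  expect_equal(nrow(fwd), 13L + 12L + 11L) # starts with s + len - 1 <= 30
  expect_true(all(fwd$start + fwd$length - 1L <= 30L))
  expect_true(all(rev$start - rev$length + 1L >= 31L)) # 60 - 30 + 1
  # coordinate contract: forward substring, reverse is its revcomp
  for (i in sample(nrow(cand), 20)) {
    p <- cand[i, ]
    tmpl <- if (p$orientation == "forward") {
      substring(rec$residues, p$start, p$start + p$length - 1L)
    } else {
      oracle_revcomp(substring(rec$residues, p$start - p$length + 1L,
                               p$start))
    }
    expect_identical(p$sequence, tmpl)
  }
  # a window equal to the sequence covers everything
  all_params <- design_params(len_min = 18, len_max = 18, window5 = 60,
                              window3 = 60)
  allc <- enumerate_candidates(rec, all_params)
  expect_equal(sum(allc$orientation == "forward"), 60L - 18L + 1L)
  expect_error(enumerate_candidates(one_record("tiny", "ACGTACGTAC"),
                                    design_params()),
               "shorter than len_min")
})

test_that("filtering rejects repeats, enforces every constraint and dedups", {
  rec <- one_record("allA", strrep("A", 200))
  res <- apply_filters(enumerate_candidates(rec, design_params()), rec,
                       design_params())
  expect_equal(nrow(res), 0L)

  recs <- simulate_dna(3, 600, seed = 59)
  params <- design_params(window5 = 100, window3 = 100)
  out <- design_batch(recs, params)
  expect_gt(nrow(out$primers), 0L)
  expect_true(isTRUE(verify_primers(out$primers, recs, params)))
  # dedup key and ordering
  key <- paste(out$primers$source_id, out$primers$sequence,
               out$primers$orientation)
  expect_false(any(duplicated(key)))
  for (id in unique(out$primers$source_id)) {
    expect_false(is.unsorted(out$primers$start[out$primers$source_id == id]))
  }
  # clamp-enabled run only emits clamped primers
  clamped <- design_batch(recs, design_params(window5 = 100, window3 = 100,
                                              require_gc_clamp = TRUE))
  expect_true(all(has_gc_clamp(clamped$primers$sequence)))
  expect_true(all(clamped$primers$sequence %in% out$primers$sequence))
})

test_that("specificity counts both strands with tolerated mismatches", {
  set.seed(61)
  bg <- strrep("A", 400) # primer cannot match an A-homopolymer background
  primer <- "CGTCGATTACGGCTAGGATC"
  mut <- primer
  substr(mut, 4, 4) <- "A" # one substitution
  recs <- data.frame(
    id = c("r1", "r2"),
    residues = c(paste0(bg, primer, bg),
                 paste0(bg, oracle_revcomp(primer), bg, mut, bg)),
    stringsAsFactors = FALSE)
  expect_equal(specificity_count(primer, recs[1, ], 0), 1L)
  expect_equal(specificity_count(primer, recs, 0), 2L) # once per strand
  expect_equal(specificity_count(primer, recs, 1), 3L) # + the mutant site
  # primer longer than every record
  expect_equal(specificity_count(strrep("ACGT", 6),
                                 one_record("short", "ACGTACGTAC"), 0), 0L)
  # brute-force equivalence on random inputs
  targets <- simulate_dna(4, 300, seed = 67)
  primers <- random_primers(8, 15, 22, 0.3, 0.7, seed = 67)
  for (m in 0:2) {
    expect_equal(
      vapply(primers, specificity_count, integer(1), records = targets,
             max_mismatches = m, USE.NAMES = FALSE),
      vapply(primers, oracle_specificity, integer(1), records = targets,
             m = m, USE.NAMES = FALSE),
      info = paste("mismatches =", m))
  }
})

test_that("batch design is deterministic, order-preserving and error-tolerant", {
  recs <- simulate_dna(2, 500, seed = 71)
  recs <- rbind(recs, one_record("runt", "ACGTACGT"))
  params <- design_params(window5 = 80, window3 = 80)
  out1 <- design_batch(recs, params)
  out2 <- design_batch(recs, params)
  expect_identical(out1$primers, out2$primers)
  expect_named(out1$errors, "runt")
  expect_match(out1$errors[["runt"]], "shorter than len_min")
  # record order in output equals input order
  expect_equal(unique(out1$primers$source_id),
               recs$id[recs$id %in% out1$primers$source_id])
  # positional rows conserve the accepted primer count
  expect_equal(nrow(out1$positions), nrow(out1$primers))
})

test_that("SNP-flanking primers strictly bracket the SNP", {
  snps <- simulate_snp(3, 1001, seed = 73)
  params <- design_params()
  for (i in seq_len(nrow(snps))) {
    fl <- design_snp_flanking(snps[i, , drop = FALSE], params)
    fwd <- fl[fl$orientation == "forward", ]
    rev <- fl[fl$orientation == "reverse", ]
    expect_gt(nrow(fwd), 0L)
    expect_gt(nrow(rev), 0L)
    expect_true(all(fwd$start + fwd$length - 1L <= 500L)) # 3' end before SNP
    expect_true(all(rev$start - rev$length + 1L >= 502L)) # starts after SNP
    expect_false(any(grepl("[RYMKWSBDHVN]", fl$sequence)))
  }
  edge <- snps[1, , drop = FALSE]
  edge$snp_position <- 5L
  edge$residues <- paste0("ACGT", edge$iupac_code,
                          substring(edge$residues, 6))
  expect_error(design_snp_flanking(edge, params), "too close to 5' end")
})

test_that("allele-specific primers anchor the allele at the 3' terminus", {
  snps <- simulate_snp(5, 1001, seed = 79)
  params <- design_params()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(snps))) {
    row <- snps[i, , drop = FALSE]
    asp <- design_allele_specific(row, params)
    expect_lte(nrow(asp), 2L * length(row$alleles[[1]]))
    for (j in seq_len(nrow(asp))) {
      p <- asp[j, ]
      terminal <- substring(p$sequence, p$length, p$length)
      if (p$orientation == "forward") {
        expect_equal(p$start + p$length - 1L, 501L)
        expect_equal(terminal, p$allele)
      } else {
        expect_equal(p$start - p$length + 1L, 501L)
        expect_equal(terminal, comp[[p$allele]])
      }
      expect_true(p$tm >= params$tm_min && p$tm <= params$tm_max)
    }
    # wildtype is the alphabetically first allele
    expect_equal(unique(asp$allele[asp$label == "wildtype"]),
                 sort(row$alleles[[1]])[1])
    # same-length allele mates differ at exactly the terminal position
    for (ori in unique(asp$orientation)) {
      sub <- asp[asp$orientation == ori, ]
      if (nrow(sub) == 2L && sub$length[1] == sub$length[2]) {
        diffs <- which(strsplit(sub$sequence[1], "")[[1]] !=
                         strsplit(sub$sequence[2], "")[[1]])
        expect_equal(diffs, nchar(sub$sequence[1]))
      }
    }
    # the GC-clamp requirement never applies to allele-specific primers
    clamped <- design_allele_specific(row, design_params(require_gc_clamp = TRUE))
    expect_identical(asp, clamped)
  }
})

test_that("allele-specific length selection picks the in-range Tm nearest midpoint", {
  snp <- simulate_snp(1, 1001, seed = 83)
  params <- design_params()
  asp <- design_allele_specific(snp, params)
  mid <- (params$tm_min + params$tm_max) / 2
  for (j in seq_len(nrow(asp))) {
    p <- asp[j, ]
    # rebuild every admissible length by hand and check none is closer
    for (len in params$len_min:params$len_max) {
      seqc <- if (p$orientation == "forward") {
        s <- 501L - len + 1L
        x <- substring(snp$residues, s, 501L)
        substr(x, len, len) <- p$allele
        x
      } else {
        x <- substring(snp$residues, 501L, 501L + len - 1L)
        substr(x, 1L, 1L) <- p$allele
        oracle_revcomp(x)
      }
      tm <- tm_calc(seqc, params$thermo)
      if (tm >= params$tm_min && tm <= params$tm_max) {
        better <- abs(tm - mid) < abs(p$tm - mid) - 1e-12
        expect_false(better, info = sprintf("%s/%s len %d beats chosen len %d",
                                            p$allele, p$orientation, len,
                                            p$length))
      }
    }
  }
})

test_that("dimer report enumerates every unordered pair exactly once", {
  set.seed(89)
  for (n in c(2L, 5L, 10L, 40L)) {
    seqs <- stats::setNames(random_dna(n, 20), paste0("p", seq_len(n)))
    rep <- dimer_report(seqs)
    expect_equal(nrow(rep$pairs), n * (n - 1L) / 2L)
    expect_equal(rep$k, 2L)
    key <- paste(pmin(rep$pairs$name_a, rep$pairs$name_b),
                 pmax(rep$pairs$name_a, rep$pairs$name_b))
    expect_false(any(duplicated(key)))
  }
  seqs <- stats::setNames(random_dna(6, 20), paste0("p", 1:6))
  rep <- dimer_report(seqs)
  # scores equal the symmetric cross-dimer score recomputed pairwise
  for (r in seq_len(nrow(rep$pairs))) {
    a <- seqs[[rep$pairs$name_a[r]]]
    b <- seqs[[rep$pairs$name_b[r]]]
    expect_equal(rep$pairs$score[r], cross_dimer_score(b, a))
  }
  expect_error(dimer_report(seqs[1]), "at least 2")
})
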