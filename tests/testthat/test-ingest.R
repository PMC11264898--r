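test_that("GenBank parsing extracts both strands, pseudogenes, and translates missing qualifiers", {
  g <- parse_genbank(write_gbk_minimal(), genome_id = "TST")
  expect_s3_class(g, "genome_record")
  expect_equal(length(g$contigs), 1L)
  expect_equal(g$contigs[[1]]$length, 80L)
  expect_equal(nrow(g$features), 3L)

  fwd <- g$features[g$features$locus_tag == "TST_0001", ]
  rev <- g$features[g$features$locus_tag == "TST_0002", ]
  pse <- g$features[g$features$locus_tag == "TST_0003", ]

  # 1-based inclusive -> 0-based half-open at the parsing boundary
  expect_equal(c(fwd$start, fwd$end), c(10L, 25L))
  expect_equal(fwd$strand, 1L)
  expect_equal(rev$strand, -1L)

  # no /translation qualifier: protein equals the independent codon-walk
  expect_equal(fwd$protein_seq, oracle_translate(fwd$nucleotide_seq))
  expect_equal(fwd$protein_seq, "MKLV")

  # minus strand: nucleotide span is the reverse complement of the contig slice
  contig <- g$contigs[[1]]$sequence
  expect_equal(rev$nucleotide_seq, oracle_revcomp(substr(contig, 46, 60)))
  expect_equal(rev$protein_seq, oracle_translate(rev$nucleotide_seq))
  expect_equal(rev$protein_seq, "MGPW")

  expect_equal(pse$kind, "pseudogene")
  expect_true(is.na(pse$protein_seq))
})

test_that("provided translation qualifiers are kept verbatim and round-trip through write_genbank", {
  fx <- fx_small()
  path <- tempfile(fileext = ".gbk")
  write_genbank(fx$genomes[[1]], path)
  g <- parse_genbank(path, genome_id = fx$genomes[[1]]$genome_id)
  orig <- fx$genomes[[1]]
  expect_equal(g$features$locus_tag, orig$features$locus_tag)
  expect_equal(g$features$start, orig$features$start)
  expect_equal(g$features$end, orig$features$end)
  expect_equal(g$features$strand, orig$features$strand)
  # translations in the file differ from a naive re-translation only if
  # mutated; verbatim retention means exact equality with the written ones
  expect_equal(g$features$protein_seq, orig$features$protein_seq)
  expect_equal(g$features$nucleotide_seq, orig$features$nucleotide_seq)
})

test_that("parse errors name the offending file and feature", {
  expect_error(parse_genbank(tempfile()), "not found")
  bad <- tempfile(fileext = ".gbk")
  writeLines("nothing here", bad)
  expect_error(parse_genbank(bad), "LOCUS")

  txt <- sub("11\\.\\.25", "11..999", gbk_text_minimal())
  bad2 <- tempfile(fileext = ".gbk")
  writeLines(txt, bad2)
  expect_error(parse_genbank(bad2), "TST_0001")
})

test_that("sanitize_identifiers renames collisions deterministically and is idempotent", {
  fx <- fx_small()
  a <- fx$genomes[[1]]
  b <- fx$genomes[[2]]
  # engineer collisions: genome b reuses a's first locus tag and contig name
  b$features$locus_tag[1] <- a$features$locus_tag[1]
  clash <- sanitize_identifiers(list(a, b))
  expect_equal(sum(clash$renames$kind == "locus_tag"), 1L)
  expect_equal(clash$renames$new[clash$renames$kind == "locus_tag"],
               paste0(a$features$locus_tag[1], "_dup1"))
  # idempotent
  again <- sanitize_identifiers(clash$genomes)
  expect_equal(nrow(again$renames), 0L)
  expect_identical(again$genomes, clash$genomes)

  # triple collision -> two distinct suffixes
  c3 <- a
  c3$features$locus_tag[2] <- a$features$locus_tag[1]
  c3$features$locus_tag[3] <- a$features$locus_tag[1]
  out <- sanitize_identifiers(list(c3))
  tags <- out$genomes[[1]]$features$locus_tag
  expect_equal(anyDuplicated(tags), 0L)
  expect_setequal(out$renames$new,
                  paste0(a$features$locus_tag[1], c("_dup1", "_dup2")))

  # unique input untouched
  clean <- sanitize_identifiers(fx$genomes)
  expect_equal(nrow(clean$renames), 0L)
})

test_that("sequence extraction respects alphabet and order, and round-trips FASTA", {
  g <- parse_genbank(write_gbk_minimal(), genome_id = "TST")
  prot <- extract_sequences(g, "protein")
  expect_equal(names(prot), c("TST_0001", "TST_0002"))  # pseudogene excluded
  nt <- extract_sequences(g, "nucleotide")
  expect_equal(names(nt), c("TST_0001", "TST_0002", "TST_0003"))

  fa <- tempfile(fileext = ".faa")
  Biostrings::writeXStringSet(prot, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(back), as.character(prot))

  noCDS <- g
  noCDS$features$kind <- "tRNA"
  noCDS$features$protein_seq <- NA_character_
  expect_warning(res <- extract_sequences(noCDS, "protein"), "no CDS")
  expect_equal(length(res), 0L)
})

test_that("genome summaries compute GC ignoring N and unionized coding density", {
  g <- structure(list(
    genome_id = "S", display_name = "S",
    contigs = list(c1 = list(accession = "c1", sequence = "ATGCNN", length = 6L)),
    features = empty_features_for_test()), class = "genome_record")
  s <- genome_summary(g)
  expect_equal(s$gc_percent, 50)
  expect_equal(s$total_length, 6L)

  # two disjoint CDS covering 300 bp of a 1000 bp contig
  seq1000 <- strrep("ACGT", 250)
  f <- data.frame(locus_tag = c("x1", "x2"), contig = "c1",
                  start = c(0L, 500L), end = c(100L, 700L),
                  strand = 1L, kind = "CDS", gene_name = NA, product = NA,
                  protein_seq = "M", nucleotide_seq = "ATG", compound = FALSE,
                  stringsAsFactors = FALSE)
  g2 <- structure(list(genome_id = "S2", display_name = "S2",
                       contigs = list(c1 = list(accession = "c1",
                                                sequence = seq1000,
                                                length = 1000L)),
                       features = f), class = "genome_record")
  expect_equal(genome_summary(g2)$coding_density, 0.3)

  # overlapping CDS count each bp once
  f$start <- c(0L, 50L); f$end <- c(100L, 150L)
  g2$features <- f
  expect_equal(genome_summary(g2)$coding_density, 0.15)

  # fixture bookkeeping: generator layout implies coding bp = sum of gene spans
  fx <- fx_small()
  for (g in fx$genomes[1:2]) {
    s <- genome_summary(g)
    expect_equal(s$n_cds, sum(g$features$kind == "CDS"))
    expected_density <- sum(g$features$end[g$features$kind == "CDS"] -
                              g$features$start[g$features$kind == "CDS"]) /
      g$contigs[[1]]$length
    expect_equal(s$coding_density, expected_density)
  }

  g$contigs[[1]]$sequence <- ""
  g$contigs[[1]]$length <- 0L
  expect_error(genome_summary(g), "zero length")
})
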