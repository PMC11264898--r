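test_that("region extraction windows are clipped and hold exactly the overlapping features", {
  fx <- fx_region_setup()$fx
  g <- fx$genomes[[1]]
  anchor <- g$features$locus_tag[2]
  af <- g$features[2, ]

  # huge window: whole contig
  big <- extract_region(g, anchor, window_bp = 10 * g$contigs[[1]]$length)
  expect_equal(big$window, c(0L, g$contigs[[1]]$length))
  expect_equal(nrow(big$features), nrow(g$features))

  # zero window: features overlapping the anchor's own span
  zero <- extract_region(g, anchor, window_bp = 0)
  expect_equal(zero$window, c(af$start, af$end))
  expect_true(anchor %in% zero$features$locus_tag)
  expect_true(all(zero$features$start < af$end & zero$features$end > af$start))

  # clipping at the contig start
  first <- g$features$locus_tag[1]
  clipped <- extract_region(g, first, window_bp = 10000)
  expect_equal(clipped$window[1], 0L)

  expect_error(extract_region(g, "NOPE_0001"), "unknown locus")
  expect_error(extract_region(g, anchor, window_bp = -1), "window_bp")
})

test_that("strand normalization flips tracks and flipping is an involution", {
  fx <- fx_region_setup()$fx
  g <- fx$genomes[[1]]
  anchor <- g$features$locus_tag[1]
  view <- extract_region(g, anchor, window_bp = 300)
  flipped <- pangrove:::flip_region(view)
  expect_true(flipped$flipped)
  # mirrored spans keep their width
  expect_setequal(flipped$features$disp_end - flipped$features$disp_start,
                  view$features$disp_end - view$features$disp_start)
  back <- pangrove:::flip_region(flipped)
  expect_false(back$flipped)
  ord <- order(back$features$locus_tag)
  orig <- view$features[order(view$features$locus_tag), ]
  expect_equal(back$features$disp_start[ord], orig$disp_start)
  expect_equal(back$features$disp_end[ord], orig$disp_end)
  expect_equal(back$features$disp_strand[ord], orig$disp_strand)
})

test_that("region comparisons link only orthologous genes and normalize anchor strand", {
  setup <- fx_region_setup()
  fx <- setup$fx; ogset <- setup$ogset
  # anchor: first gene of a family present in all genomes
  core_fam <- rownames(fx$truth$presence)[
    rowSums(fx$truth$presence >= 1) == length(fx$genomes)][1]
  anchor <- fx$truth$orthogroups$locus_tag[
    fx$truth$orthogroups$og_id == core_fam &
      fx$truth$orthogroups$genome_id == names(fx$genomes)[1]][1]

  rc <- compare_regions(fx$genomes, anchor, names(fx$genomes), ogset,
                        window_bp = 400)
  expect_equal(length(rc$tracks), length(fx$genomes))
  expect_equal(length(rc$notices), 0L)

  # every link joins two members of one orthogroup
  og_of <- pangrove:::og_index(ogset)
  for (i in seq_len(nrow(rc$links)))
    expect_identical(og_of[[rc$links$locus_a[i]]], og_of[[rc$links$locus_b[i]]])
  expect_true(all(rc$links$identity >= 0 & rc$links$identity <= 100))

  # each track displays its anchor ortholog on the reference anchor's strand
  ref_strand <- rc$tracks[[1]]$features$disp_strand[
    rc$tracks[[1]]$features$locus_tag == anchor]
  for (tr in rc$tracks[-1]) {
    astrand <- tr$features$disp_strand[tr$features$locus_tag == tr$anchor]
    expect_equal(astrand, ref_strand)
  }

  # genome lacking the family is skipped with a notice
  patchy <- rownames(fx$truth$presence)[
    apply(fx$truth$presence, 1, function(r) any(r == 0) && r[1] >= 1)][1]
  expect_false(is.na(patchy))  # guaranteed by the fixed fixture seed
  anchor2 <- fx$truth$orthogroups$locus_tag[
    fx$truth$orthogroups$og_id == patchy &
      fx$truth$orthogroups$genome_id == names(fx$genomes)[1]][1]
  rc2 <- compare_regions(fx$genomes, anchor2, names(fx$genomes), ogset,
                         window_bp = 200)
  absent <- names(fx$genomes)[fx$truth$presence[patchy, ] == 0]
  expect_equal(length(rc2$notices), length(absent))
  expect_false(any(vapply(rc2$tracks, `[[`, "", "genome_id") %in% absent))

  expect_error(compare_regions(fx$genomes, "GHOST_1", names(fx$genomes), ogset),
               "not assigned|not found")
})

test_that("duplicated genome comparison yields identical tracks fully linked at 100%", {
  setup <- fx_region_setup()
  fx <- setup$fx
  g <- fx$genomes[[1]]
  g2 <- g
  g2$genome_id <- "COPY"
  g2$features$locus_tag <- sub(g$genome_id, "COPY", g$features$locus_tag)
  acc2 <- paste0("COPY_contig1")
  names(g2$contigs) <- acc2
  g2$contigs[[1]]$accession <- acc2
  g2$features$contig <- acc2
  groups <- lapply(seq_len(nrow(g$features)), function(i)
    data.frame(genome_id = c(g$genome_id, "COPY"),
               locus_tag = c(g$features$locus_tag[i], g2$features$locus_tag[i]),
               stringsAsFactors = FALSE))
  names(groups) <- sprintf("OGD%03d", seq_along(groups))
  ogd <- pangrove:::new_orthogroup_set(groups)
  pair <- stats::setNames(list(g, g2), c(g$genome_id, "COPY"))
  rc <- compare_regions(pair, g$features$locus_tag[1], names(pair), ogd,
                        window_bp = 1e6)
  expect_equal(length(rc$tracks), 2L)
  expect_equal(nrow(rc$links), nrow(g$features))
  expect_true(all(rc$links$identity == 100))
})

test_that("circos rings index the reference CDS list and count homologs exactly", {
  setup <- fx_region_setup()
  fx <- setup$fx; ogset <- setup$ogset
  ref <- fx$genomes[[1]]
  comparison <- names(fx$genomes)[-1]
  ts <- circos_tracks(ref, fx$genomes, comparison, ogset)
  n_cds <- sum(ref$features$kind == "CDS")
  expect_equal(nrow(ts$orfs), n_cds)
  expect_equal(dim(ts$identity), c(n_cds, length(comparison)))
  expect_true(all(ts$orfs$homolog_count >= 0))

  # GC ring equals a direct base count
  i <- 1
  nt <- toupper(ts$orfs$locus_tag[i] |>
                  (\(lt) ref$features$nucleotide_seq[ref$features$locus_tag == lt])())
  bases <- strsplit(nt, "")[[1]]
  expect_equal(ts$orfs$gc_percent[i],
               100 * sum(bases %in% c("G", "C")) / length(bases))

  # homolog_count recount from the orthogroup table
  tru <- fx$truth$orthogroups
  for (i in seq_len(nrow(ts$orfs))) {
    og <- tru$og_id[tru$locus_tag == ts$orfs$locus_tag[i]]
    want <- sum(tru$og_id == og & tru$genome_id %in% comparison)
    expect_equal(ts$orfs$homolog_count[i], want)
  }

  # reference compared to itself: all present cells at 100%
  ts_self <- circos_tracks(ref, fx$genomes, ref$genome_id, ogset)
  expect_true(all(ts_self$identity[, 1] == 100, na.rm = TRUE))
  expect_true(all(!is.na(ts_self$identity[, 1])))

  js <- region_json(ts)
  expect_true(jsonlite::validate(js))
})
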