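test_that("the definition parser builds the expected trees", {
  a <- parse_module_definition("K00001")
  expect_equal(a$expression, list(type = "atom", id = "K00001"))

  d <- parse_module_definition("(K00001,K00002) K00003")
  expect_equal(d$expression$type, "steps")
  expect_equal(d$expression$children[[1]]$type, "alt")
  expect_equal(d$expression$children[[2]], list(type = "atom", id = "K00003"))

  cx <- parse_module_definition("K00001+K00002-K00003")
  expect_equal(cx$expression$type, "complex")
  expect_equal(length(cx$expression$children), 3L)
  expect_equal(cx$expression$children[[3]]$type, "optional")

  g <- parse_module_definition("K00001 -- K00002")
  expect_equal(g$expression$children[[2]]$type, "gap")
})

test_that("malformed definitions fail with a position", {
  expect_error(parse_module_definition("K00001+"), "position 7")
  expect_error(parse_module_definition("(K00001"), "position 1.*parenthesis")
  expect_error(parse_module_definition("K00001,"), "dangling ','")
  expect_error(parse_module_definition("K1"), "illegal token")
  expect_error(parse_module_definition(""), "empty")
})

test_that("serialization round-trips to an identical tree on a random corpus", {
  kos <- sprintf("K%05d", 1:9)
  set.seed(501)
  for (i in 1:120) {
    def <- random_module_definition(kos)
    parsed <- parse_module_definition(def)
    txt <- serialize_module_definition(parsed)
    expect_identical(parse_module_definition(txt)$expression, parsed$expression,
                     label = paste("round trip of", def))
  }
})

test_that("completeness follows the stated recursive semantics", {
  val <- function(def, kos)
    module_completeness(parse_module_definition(def), kos)$completeness
  expect_equal(val("K00001 K00002", "K00001"), 0.5)
  expect_equal(val("K00001+K00002", "K00001"), 0)
  expect_equal(val("K00001-K00002", "K00001"), 1)
  expect_equal(val("K00001,K00002", "K00002"), 1)
  expect_equal(val("K00001 -- K00002", "K00001"), 2 / 3)
  expect_equal(module_completeness(parse_module_definition("K00001 -- K00002"),
                                   "K00001", gap_value = 0)$completeness, 1 / 3)
  # nested module: satisfied only when fully complete
  defs <- list(M00002 = parse_module_definition("K00001 K00002", "M00002"))
  top <- parse_module_definition("M00002 K00003", "M00001")
  expect_equal(module_completeness(top, c("K00001", "K00002", "K00003"),
                                   definitions = defs)$completeness, 1)
  expect_equal(module_completeness(top, c("K00001", "K00003"),
                                   definitions = defs)$completeness, 0.5)
  expect_warning(module_completeness(top, "K00003"), "no supplied definition")
})

test_that("the evaluator agrees with exhaustive truth-table enumeration", {
  set.seed(502)
  for (i in 1:60) {
    kos <- sprintf("K%05d", sample(1:9, sample(3:6, 1)))
    def <- random_module_definition(kos)
    parsed <- parse_module_definition(def)
    atoms <- unique(regmatches(def, gregexpr("K[0-9]{5}", def))[[1]])
    n <- length(atoms)
    for (mask in 0:(2^n - 1)) {
      present <- atoms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      expect_equal(module_completeness(parsed, present)$completeness,
                   oracle_module_value(def, present),
                   label = sprintf("def '%s' with {%s}", def,
                                   paste(present, collapse = ",")))
    }
  }
})

test_that("adding a KO never decreases completeness", {
  set.seed(503)
  for (i in 1:25) {
    kos <- sprintf("K%05d", 1:8)
    def <- random_module_definition(kos)
    parsed <- parse_module_definition(def)
    present <- sample(kos, sample(0:6, 1))
    extra <- sample(setdiff(kos, present), 1)
    expect_gte(module_completeness(parsed, c(present, extra))$completeness,
               module_completeness(parsed, present)$completeness)
  }
})

test_that("annotation propagation adds exactly the orthogroup-shared KOs and is idempotent", {
  og <- pangrove:::new_orthogroup_set(list(
    OG1 = data.frame(genome_id = c("A", "B"), locus_tag = c("a1", "b1"),
                     stringsAsFactors = FALSE),
    OG2 = data.frame(genome_id = c("A", "B"), locus_tag = c("a2", "b2"),
                     stringsAsFactors = FALSE)))
  direct <- data.frame(genome_id = "A", locus_tag = "a1", ko = "K00001",
                       provenance = "direct", stringsAsFactors = FALSE)
  out <- propagate_annotations(direct, og)
  gained <- out[out$provenance == "propagated", ]
  expect_equal(nrow(gained), 1L)
  expect_equal(gained$locus_tag, "b1")
  expect_equal(gained$ko, "K00001")
  expect_equal(gained$source_og, "OG1")
  # direct rows untouched; idempotent
  expect_identical(out[out$provenance == "direct",
                       c("genome_id", "locus_tag", "ko")],
                   direct[, c("genome_id", "locus_tag", "ko")])
  expect_identical(propagate_annotations(out, og), out)

  # no shared orthogroup annotation -> no change
  lone <- data.frame(genome_id = "A", locus_tag = "a2", ko = "K00009",
                     provenance = "direct", stringsAsFactors = FALSE)
  og_single <- pangrove:::new_orthogroup_set(list(
    OGa = data.frame(genome_id = "A", locus_tag = "a2", stringsAsFactors = FALSE)))
  out2 <- propagate_annotations(lone, og_single)
  expect_equal(nrow(out2[out2$provenance == "propagated", ]), 0L)

  fx <- fx_small()
  expect_error(propagate_annotations(
    data.frame(genome_id = "A", locus_tag = "GHOST_1", ko = "K00001"),
    og, genomes = fx$genomes), "unknown gene")
})

test_that("fixture propagation cases flip exactly the predicted completeness cells", {
  fx <- fx_small()
  ogset <- pangrove:::new_orthogroup_set(
    lapply(split(fx$truth$orthogroups[, c("genome_id", "locus_tag")],
                 fx$truth$orthogroups$og_id),
           function(d) { rownames(d) <- NULL; d }))
  assignments <- propagate_annotations(fx$truth$ko, ogset)
  defs <- lapply(seq_len(nrow(fx$truth$modules)), function(i)
    parse_module_definition(fx$truth$modules$definition[i],
                            fx$truth$modules$module_id[i]))
  names(defs) <- fx$truth$modules$module_id
  gids <- names(fx$genomes)

  with_prop <- completeness_matrix(defs, assignments, gids,
                                   use_propagated = TRUE)
  without <- completeness_matrix(defs, assignments, gids,
                                 use_propagated = FALSE)
  # cell-wise monotonicity
  expect_true(all(with_prop$completeness >= without$completeness))
  # both levels match the generator's independent expectations
  mods <- rownames(fx$truth$completeness_direct)
  expect_equal(without$completeness[mods, gids],
               fx$truth$completeness_direct[, gids])
  expect_equal(with_prop$completeness[mods, gids],
               fx$truth$completeness_propagated[, gids])
  # cells differing between runs involve a propagated KO of that genome
  diff_cells <- which(with_prop$completeness != without$completeness,
                      arr.ind = TRUE)
  prop <- assignments[assignments$provenance == "propagated", ]
  for (r in seq_len(nrow(diff_cells))) {
    g <- gids[diff_cells[r, 2]]
    m <- rownames(with_prop$completeness)[diff_cells[r, 1]]
    atoms <- with_prop$results[[m]][[g]]$atoms
    expect_true(any(prop$genome_id == g & prop$ko %in% atoms))
  }
})

test_that("definition and assignment TSV readers parse the fixture outputs", {
  info <- fx_pipeline_dir()
  defs <- read_module_definitions(file.path(info$dir, "modules.tsv"))
  expect_equal(names(defs), info$fx$truth$modules$module_id)
  # serialization may drop redundant parentheses; the trees must match
  for (i in seq_along(defs))
    expect_identical(defs[[i]]$expression,
                     parse_module_definition(
                       info$fx$truth$modules$definition[i])$expression)
  ko <- read_ko_assignments(file.path(info$dir, "ko.tsv"))
  expect_equal(nrow(ko), nrow(info$fx$truth$ko))
  expect_true(all(ko$provenance == "direct"))
})
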