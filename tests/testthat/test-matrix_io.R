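# Character-matrix container, dialects and fixtures

test_that("packaged matrices have the published dimensions and symbol census", {
  m1 <- load_fixture("table1")
  expect_equal(dim(m1), c(26L, 33L))
  expect_match(m1$outgroup, "^Pseudopotamilla")
  # golden symbol census, frozen at first transcription
  expect_equal(sum(m1$cells == "?"), 26L)
  expect_equal(sum(m1$cells == "-"), 47L)
  expect_equal(sum(m1$cells == "V"), 1L)
  expect_equal(cell_state(m1, "Pseudobranchiomma paulista", 18)$kind,
               "variable")
  m5 <- load_fixture("table5")
  expect_equal(dim(m5), c(11L, 33L))
  expect_error(load_fixture("table9"), class = "unknown_fixture_error")
})

test_that("cell tokens decode into kinds and state sets", {
  m <- cm(c("0[12]?", "1-1", "2V0"))
  expect_equal(cell_state(m, 1, 1), list(kind = "determinate", states = 0L))
  expect_equal(cell_state(m, 1, 2),
               list(kind = "polymorphic", states = c(1L, 2L)))
  expect_equal(cell_state(m, 1, 3)$kind, "missing")
  expect_equal(cell_state(m, 2, 2)$kind, "inapplicable")
  expect_equal(cell_state(m, 3, 2)$kind, "variable")
})

test_that("every dialect round-trips cell-identically", {
  m <- cm(c("01[02]?-", "10V1?", "0011-", "11200"),
          taxa = c("Taxon one", "Taxon two", "Taxon three", "Taxon four"))
  for (d in c("csv", "nexus", "tnt")) {
    txt <- write_matrix(m, d)
    m2 <- read_matrix(txt, d)
    expect_identical(unname(m2$cells), unname(m$cells), label = d)
  }
  # fixture round-trip through its own dialect
  m1 <- load_fixture("table1")
  m1b <- read_matrix(write_matrix(m1, "csv"), "csv")
  expect_identical(m1b$cells, m1$cells)
  expect_identical(m1b$taxa, m1$taxa)
})

test_that("polymorphic cells render as sorted bracket runs in CSV/TNT", {
  m <- cm(c("[10]1", "01", "11", "00"))
  expect_match(write_matrix(m, "csv")[2L], "\\[01\\]")
  expect_match(write_matrix(m, "tnt")[4L], "\\[01\\]")
  expect_match(write_matrix(m, "nexus")[6L], "\\{01\\}")
})

test_that("malformed input raises classed errors", {
  expect_error(read_matrix("", "csv"), class = "matrix_shape_error")
  expect_error(read_matrix(c("taxon,1,2", "A,0,1", "B,0"), "csv"),
               class = "matrix_shape_error")
  expect_error(read_matrix(c("taxon,1", "A,0", "A,1"), "csv"),
               class = "duplicate_taxon_error")
  expect_error(read_matrix(c("taxon,1,2", "A,0,X", "B,0,1"), "csv"),
               class = "symbol_error")
  err <- tryCatch(read_matrix(c("taxon,1,2", "A,0,X", "B,1,1"), "csv"),
                  error = identity)
  expect_match(conditionMessage(err), "A")  # names the offending row
  expect_error(write_matrix(character_matrix(matrix("0", 0, 0),
                                             taxa = character(0)),
                            "csv"),
               class = "dialect_error")
})

test_that("en dash and hyphen both mean inapplicable; hyphen is emitted", {
  m <- read_matrix(c("taxon,1,2", "A,–,1", "B,0,1", "C,1,0", "D,0,0"),
                   "csv")
  expect_equal(cell_state(m, 1, 1)$kind, "inapplicable")
  expect_match(write_matrix(m, "csv")[2L], "A,-,1")
})

test_that("taxon names normalise to underscores for tree-facing output", {
  m <- cm(c("01", "10", "11", "00"),
          taxa = c("Genus species", "B", "C", "D"))
  nex <- write_matrix(m, "nexus")
  expect_true(any(grepl("Genus_species", nex)))
})

test_that("state masks give uncertainty cells the full observed set", {
  m <- cm(c("0?", "1-", "0V", "11", "10"), taxa = LETTERS[1:5])
  masks <- state_masks(m)
  expect_equal(masks[, 1L], c(1L, 2L, 1L, 2L, 2L))  # determinate bits
  expect_equal(masks[1L, 2L], 3L)                   # ? spans observed {0,1}
  expect_equal(masks[2L, 2L], 3L)                   # - likewise
  expect_equal(masks[3L, 2L], 3L)                   # V likewise
  expect_equal(masks[4L, 2L], 2L)
  # both documented V readings coincide for scoring
  expect_identical(state_masks(m, "missing"), state_masks(m, "polymorphic"))
})
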