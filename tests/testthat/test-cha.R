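test_that("frequency glyph encoding is total, exact and surjective", {
  expect_identical(freq_to_glyph(0.85), "8")
  expect_identical(freq_to_glyph(1.0), "!")
  expect_identical(freq_to_glyph(0.0), "0")
  expect_identical(freq_to_glyph(0.999), "9")
  # a 17-of-20 column is 85% and renders '8'
  expect_identical(freq_to_glyph(17 / 20), "8")
  expect_error(freq_to_glyph(-0.1), "\\[0, 1\\]")
  expect_error(freq_to_glyph(1.2), "\\[0, 1\\]")
  # surjective onto the 11 glyphs over a fine grid
  glyphs <- freq_to_glyph(seq(0, 1, by = 0.001))
  expect_setequal(unique(glyphs), c(as.character(0:9), "!"))
})

test_that("indel glyphs report weighted insert and gap fractions", {
  clean <- aln_from_strings(rep("ACDEF", 4))
  g <- indel_glyphs(clean)
  expect_true(all(g$insertion == "0"))
  expect_true(all(g$deletion == "0"))

  # 50% gapped column -> '5'
  half <- aln_from_strings(c("A-DEF", "A-DEF", "ACDEF", "ACDEF"))
  expect_identical(indel_glyphs(half, column = 2)$deletion, "5")

  # 17 of 20 rows carry an insert after column 3 -> '8'
  core <- do.call(rbind, rep(list(strsplit("ACDEF", "")[[1]]), 20))
  rownames(core) <- paste0("s", 1:20)
  ins <- c(rep(list(c("3" = "WW")), 17), rep(list(character(0)), 3))
  aln <- core_alignment(core, ins)
  expect_identical(indel_glyphs(aln, column = 3)$insertion, "8")
})

test_that("divergence bars are zero at equality, monotone, and rank planted columns", {
  expect_equal(bar_height(0.3, 0.3), 0)
  expect_equal(bar_height(0.1, 0.6), 0)   # background-enriched: no bar
  expect_gt(bar_height(0.9, 0.05), bar_height(0.6, 0.05))
  h <- bar_height(seq(0.1, 1, by = 0.1), 0.05)
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 0 & h <= 9))

  # planted columns outrank all others when contrasting a true group
  sf <- make_flat_superfamily(seqs_per_group = 40L, rng_seed = 11L)
  member <- sf$sequences$group == "G1"
  pat <- sf$truth$patterns[["G1"]]
  cols <- as.integer(names(pat))
  fg_freq <- vapply(seq_len(ncol(sf$alignment$core)), function(j) {
    target <- if (j %in% cols) pat[[as.character(j)]] else
      names(which.max(table(sf$alignment$core[member, j])))
    mean(sf$alignment$core[member, j] == target)
  }, numeric(1))
  bg_freq <- vapply(seq_len(ncol(sf$alignment$core)), function(j) {
    target <- if (j %in% cols) pat[[as.character(j)]] else
      names(which.max(table(sf$alignment$core[member, j])))
    mean(sf$alignment$core[!member, j] == target)
  }, numeric(1))
  heights <- bar_height(fg_freq, bg_freq)
  cat_cols <- c(5L, 25L, 40L, 41L, 42L)
  others <- setdiff(seq_along(heights), c(cols, cat_cols))
  expect_gt(min(heights[cols]), max(heights[others]))
})

test_that("column information content follows the Shannon formula", {
  expect_equal(column_information(c(A = 7)), log2(20), tolerance = 1e-12)
  unif <- setNames(rep(1, 20), AA_ALPHABET)
  expect_equal(column_information(unif), 0, tolerance = 1e-12)
  expect_equal(column_information(c(A = 3, C = 1)),
               log2(20) + 0.75 * log2(0.75) + 0.25 * log2(0.25),
               tolerance = 1e-12)
  expect_equal(column_information(c(A = 3, C = 1)), 3.5106, tolerance = 1e-4)
  # residue-vector form with weights, gaps ignored
  expect_equal(column_information(c("A", "A", "A", "C", "-")),
               column_information(c(A = 3, C = 1)))
})

test_that("rendered CHA matches the frozen golden fixture byte for byte", {
  fx <- make_cha_state()
  doc <- render_cha(fx$master, fx$state, "A", c("A1", "A2"))
  lines <- format_cha(doc)
  golden <- readLines(test_path("fixtures", "cha_golden.txt"))
  expect_identical(lines, golden)
})

test_that("CHA documents are internally consistent", {
  fx <- make_cha_state()
  doc <- render_cha(fx$master, fx$state, "A", c("A1", "A2"))
  lines <- format_cha(doc)
  expect_length(unique(nchar(lines)), 1L)   # fixed-width body
  # marker columns are exactly the node's pattern columns
  expect_identical(which(doc$markers), c(1L, 9L))
  # display absent from foreground is an error
  expect_error(render_cha(fx$master, fx$state, "A", "B1"), "foreground")

  # a one-sequence foreground shows '!' at every own residue
  one_master <- fx$master[c(1, 4)]
  spec1 <- hierarchy_spec(c("root", "A", "B"), c(NA, "root", "root"),
                          seeds = list(A = "A1", B = "B1"))
  st1 <- bpps_state(one_master, spec1, rng_seed = 1, temperature = 0)
  st1$patterns[[2]] <- list(cols = 1L, sets = list("D"))
  st1 <- corekin:::.rebuild_caches(st1)
  doc1 <- render_cha(one_master, st1, "A", "A1")
  expect_true(all(doc1$fg_glyphs == "!"))

  # HTML render encodes the same frequency lines as the text render
  html_path <- tempfile(fileext = ".html")
  write_cha_html(doc, html_path)
  html <- readLines(html_path)
  expect_true(any(grepl(paste0(doc$fg_glyphs, collapse = ""), html,
                        fixed = TRUE)))
  expect_true(any(grepl(paste0(doc$bg_glyphs, collapse = ""), html,
                        fixed = TRUE)))
})
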